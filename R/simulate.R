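# Synthetic-data generators. Every input class the pipeline consumes can be
# produced here with known ground truth: ultrametric species trees, binary
# ortholog presence/absence histories with planted ordered convergent losses,
# k-state repertoire histories, two-domain amino-acid alignments with gapped
# fragment clades and fast-evolving interface sites, and CA-only toy
# structures with declared inter-chain contacts. All generators are
# deterministic given `seed`.

#' Simulate an ultrametric species tree
#'
#' Pure-birth (Yule) topology rescaled to depth 1.0, with uniquely named tips
#' (`t1..tn`) and internal nodes (`nd<k>`).
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed; identical seeds give byte-identical trees.
#' @return a rooted, binary, ultrametric [ape::phylo] tree of depth 1.
#' @export
simulate_tree <- function(n_tips, seed = 1L) {
  if (!is.numeric(n_tips) || n_tips < 2) stop("n_tips must be >= 2")
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / max(node_depths(tr))
  tr$tip.label <- paste0("t", seq_len(n_tips))
  name_nodes(tr)
}

# newick fragment for a clade: rescale to `depth`, relabel tips/nodes and the
# clade root (node.label[1] is the root in ape ordering)
.clade_newick <- function(n_tips, depth, tip_prefix, node_prefix, root_label) {
  stopifnot(n_tips >= 2)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / max(node_depths(tr)) * depth
  tr$tip.label <- paste0(tip_prefix, seq_len(n_tips))
  tr$node.label <- paste0(node_prefix, seq_len(ape::Nnode(tr)))
  tr$node.label[1] <- root_label
  sub(";$", "", ape::write.tree(tr))
}

#' Simulate a species tree with two designated convergent clades
#'
#' Builds an ultrametric depth-1 tree whose root is the common ancestor
#' (`LCAfa`) of two focal clades. Each side of the root is a ladder ("path")
#' of equal-length branches, one side tip hanging off every intermediate node,
#' ending in the ancestor of a Yule clade (`LCAa` over tips `a1..`, `LCAf`
#' over tips `f1..`). This mirrors the two root-to-clade paths (A0..A5 /
#' F0..F7 style) along which convergent losses are planted.
#'
#' @param path_a_len,path_f_len number of branches from `LCAfa` to each
#'   focal ancestor.
#' @param clade_a_size,clade_f_size tip counts of the two focal clades.
#' @param depth_focal depth (time from root) of the focal ancestors, in (0,1).
#' @param outgroup_size tips of an outgroup clade attached above `LCAfa`
#'   (an outgroup retaining ancestral gene content is what makes presence at
#'   `LCAfa` reconstructible even for losses on the first path branches).
#' @param depth_lcafa depth of `LCAfa` below the root, in (0, `depth_focal`).
#' @param side_clade_size tips of the clade hanging off each intermediate
#'   path node (1 gives a single side tip); side clades provide the
#'   retaining witnesses that date each loss.
#' @param seed integer seed.
#' @return list with elements `tree` (named ultrametric [ape::phylo]),
#'   `focal` (named list `LCAfa`, `LCAa`, `LCAf`), `path_a`, `path_f`
#'   (node-name vectors, see [path_nodes()]), and `clade_a_tips`,
#'   `clade_f_tips`.
#' @export
simulate_convergent_tree <- function(path_a_len = 6, path_f_len = 8,
                                     clade_a_size = 8, clade_f_size = 8,
                                     depth_focal = 0.7, outgroup_size = 6,
                                     depth_lcafa = 0.15,
                                     side_clade_size = 3, seed = 1L) {
  stopifnot(path_a_len >= 1, path_f_len >= 1,
            depth_focal > 0, depth_focal < 1,
            depth_lcafa > 0, depth_lcafa < depth_focal)
  set.seed(seed)
  side <- function(len, clade_size, tag) {
    step <- (depth_focal - depth_lcafa) / len
    inner <- .clade_newick(clade_size, 1 - depth_focal, tag,
                           paste0("c", tag), paste0("LCA", tag))
    for (i in rev(seq_len(len - 1))) {
      avail <- 1 - depth_lcafa - i * step
      side_part <- if (side_clade_size >= 2) {
        sprintf("%s:%.10f",
                .clade_newick(side_clade_size, avail / 2,
                              sprintf("s%s%d_", tag, i),
                              sprintf("cs%s%d_", tag, i),
                              sprintf("S%s%d", toupper(tag), i)),
                avail / 2)
      } else sprintf("s%s%d:%.10f", tag, i, avail)
      inner <- sprintf("(%s:%.10f,%s)p%s%d", inner, step, side_part, tag, i)
    }
    sprintf("%s:%.10f", inner, step)
  }
  og <- .clade_newick(outgroup_size, 0.5, "o", "co", "OUT")
  nwk <- sprintf("((%s,%s)LCAfa:%.10f,%s:%.10f)root;",
                 side(path_a_len, clade_a_size, "a"),
                 side(path_f_len, clade_f_size, "f"),
                 depth_lcafa, og, 0.5)
  tree <- ape::read.tree(text = nwk)
  list(tree = tree,
       focal = list(LCAfa = "LCAfa", LCAa = "LCAa", LCAf = "LCAf"),
       path_a = path_nodes(tree, "LCAfa", "LCAa"),
       path_f = path_nodes(tree, "LCAfa", "LCAf"),
       clade_a_tips = clade_tips(tree, "LCAa"),
       clade_f_tips = clade_tips(tree, "LCAf"))
}

#' Simulate a gene tree with designated fragment clades
#'
#' Builds an ultrametric depth-1 gene tree as a root polytomy of Yule
#' clades, a designated subset of which carry single-domain fragment genes.
#' This emulates a gene family in which domain loss arose repeatedly in
#' several independent clades, the configuration under which
#' fragment-specific substitution enrichment is assessed.
#'
#' @param n_fragment_clades,n_background_clades clade counts (fragment tips
#'   are labelled `x<i>_<j>`, background tips `b<i>_<j>`).
#' @param clade_size tips per clade.
#' @param clade_depth depth of each clade, in (0, 1); stems make up the rest.
#' @param seed integer seed.
#' @return list with `tree`, `fragment_clades` (internal node names, usable
#'   as `fragment_clades` of [simulate_domain_msa()]) and `fragment_tips`.
#' @export
simulate_fragment_tree <- function(n_fragment_clades = 5,
                                   n_background_clades = 16,
                                   clade_size = 12, clade_depth = 0.6,
                                   seed = 1L) {
  stopifnot(clade_depth > 0, clade_depth < 1, clade_size >= 2)
  set.seed(seed)
  stem <- 1 - clade_depth
  part <- function(prefix, node_prefix, root_label, i)
    sprintf("%s:%.10f",
            .clade_newick(clade_size, clade_depth, paste0(prefix, i, "_"),
                          paste0(node_prefix, i, "_"), root_label),
            stem)
  frag <- vapply(seq_len(n_fragment_clades), function(i)
    part("x", "cx", paste0("FRAG", i), i), "")
  bg <- vapply(seq_len(n_background_clades), function(i)
    part("b", "cb", paste0("BG", i), i), "")
  tree <- ape::read.tree(text = sprintf("(%s)root;",
                                        paste(c(frag, bg), collapse = ",")))
  frag_nodes <- paste0("FRAG", seq_len(n_fragment_clades))
  list(tree = tree, fragment_clades = frag_nodes,
       fragment_tips = unlist(lapply(frag_nodes, clade_tips, tree = tree)))
}

#' Simulate independent binary gain/loss histories for many ortholog groups
#'
#' Forward simulation of the two-state Mk model (gain rate `q_gain` = rate
#' 0 to 1, loss rate `q_loss` = rate 1 to 0) down the tree, recording the
#' state of every node.
#'
#' @param tree a named [ape::phylo] tree.
#' @param q_gain,q_loss non-negative rates per unit branch length.
#' @param n_ogs number of ortholog groups (independent characters).
#' @param root_prob1 probability of presence at the root; default is the
#'   stationary frequency `q_gain / (q_gain + q_loss)` (0.5 if both rates 0).
#' @param seed integer seed.
#' @return an object of class `og_sim`: list with `tree`, `table` (tips x OG
#'   0/1 matrix), `history` (all nodes x OG 0/1 matrix), `truth` (planted
#'   loss-order data frame; empty until [plant_convergent_losses()]).
#' @export
simulate_binary_ogs <- function(tree, q_gain, q_loss, n_ogs,
                                root_prob1 = NULL, seed = 1L) {
  if (q_gain < 0 || q_loss < 0) stop("rates must be >= 0")
  if (is.null(root_prob1)) {
    s <- q_gain + q_loss
    root_prob1 <- if (s == 0) 0.5 else q_gain / s
  }
  if (root_prob1 < 0 || root_prob1 > 1) stop("root_prob1 must be in [0, 1]")
  set.seed(seed)
  nn <- ape::Ntip(tree) + ape::Nnode(tree)
  states <- matrix(NA_integer_, nn, n_ogs)
  states[root_id(tree), ] <- rbinom(n_ogs, 1, root_prob1)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; t <- tr$edge.length[e]
    P <- mk_transition(q_gain, q_loss, t)
    sp <- states[p, ]
    p1 <- ifelse(sp == 1L, P[2, 2], P[1, 2])
    states[ch, ] <- rbinom(n_ogs, 1, p1)
  }
  ogs <- sprintf("OG%04d", seq_len(n_ogs))
  dimnames(states) <- list(all_node_names(tree), ogs)
  structure(list(tree = tree,
                 table = states[tree$tip.label, , drop = FALSE],
                 history = states,
                 truth = data.frame(og = character(), branch_a = integer(),
                                    branch_f = integer())),
            class = "og_sim")
}

#' Plant ordered convergent losses along two root-to-clade paths
#'
#' Planted OGs are deterministic overwrites of a stochastic background: the
#' OG is present (1) at every node of the tree except the child of its
#' designated loss branch on each path and all of that child's descendants,
#' which are absent (0). Ground truth is therefore exactly recoverable.
#'
#' @param sim an `og_sim` from [simulate_binary_ogs()].
#' @param path_a,path_f node-name paths (see [path_nodes()]); branch `i` of a
#'   path joins its `i`-th and `(i+1)`-th names.
#' @param planted_orders data frame with columns `og`, `branch_a`, `branch_f`
#'   (1-based branch indices on each path). OG names already present in the
#'   background are overwritten; new names are appended.
#' @return the modified `og_sim`, with `truth` holding the planted orders.
#' @export
plant_convergent_losses <- function(sim, path_a, path_f, planted_orders) {
  stopifnot(inherits(sim, "og_sim"),
            all(c("og", "branch_a", "branch_f") %in% names(planted_orders)))
  tree <- sim$tree
  if (path_a[1] != path_f[1])
    stop("paths must start at a common ancestor")
  nb_a <- length(path_a) - 1L; nb_f <- length(path_f) - 1L
  if (any(planted_orders$branch_a < 1 | planted_orders$branch_a > nb_a) ||
      any(planted_orders$branch_f < 1 | planted_orders$branch_f > nb_f))
    stop("planted branch index not on the declared path")
  hist <- sim$history
  for (i in seq_len(nrow(planted_orders))) {
    og <- planted_orders$og[i]
    col <- rep(1L, nrow(hist))
    lost_a <- descendant_ids(tree, node_id(tree, path_a[planted_orders$branch_a[i] + 1L]))
    lost_f <- descendant_ids(tree, node_id(tree, path_f[planted_orders$branch_f[i] + 1L]))
    col[c(lost_a, lost_f)] <- 0L
    if (og %in% colnames(hist)) hist[, og] <- col
    else {
      hist <- cbind(hist, col)
      colnames(hist)[ncol(hist)] <- og
    }
  }
  sim$history <- hist
  sim$table <- hist[tree$tip.label, , drop = FALSE]
  sim$truth <- planted_orders
  sim
}

#' Sample planted loss orders for two paths
#'
#' Draws a loss branch on each path for `n` OGs, uniformly over branches,
#' avoiding the degenerate pair (first branch on both paths): a gene lost on
#' both first branches leaves no descendant evidence of presence at the
#' joint ancestor, so its two losses are indistinguishable from a single
#' loss on the ancestor's stem.
#'
#' @param n number of OGs.
#' @param n_branch_a,n_branch_f branch counts of the two paths.
#' @param seed integer seed.
#' @param prefix OG name prefix.
#' @return data frame (`og`, `branch_a`, `branch_f`) for
#'   [plant_convergent_losses()].
#' @export
sample_planted_orders <- function(n, n_branch_a, n_branch_f, seed = 1L,
                                  prefix = "LOSS") {
  set.seed(seed)
  ba <- sample.int(n_branch_a, n, replace = TRUE)
  bf <- sample.int(n_branch_f, n, replace = TRUE)
  while (any(bad <- ba == 1L & bf == 1L)) {
    bf[bad] <- sample.int(n_branch_f, sum(bad), replace = TRUE)
  }
  data.frame(og = sprintf("%s%03d", prefix, seq_len(n)),
             branch_a = ba, branch_f = bf)
}

#' Simulate a k-state repertoire history along a tree
#'
#' Continuous-time Markov simulation from a given root state under an
#' arbitrary rate matrix (off-diagonal >= 0, zero row sums), e.g. a 7-state
#' domain-repertoire model.
#'
#' @param tree a named [ape::phylo] tree.
#' @param rate_matrix k x k rate matrix; `rownames` are used as state labels
#'   (defaults to `1..k`).
#' @param root_state state label or index at the root.
#' @param seed integer seed.
#' @return named character vector: tip label -> state label. The full node
#'   history is attached as attribute `history`.
#' @export
simulate_repertoire_states <- function(tree, rate_matrix, root_state = 1L,
                                       seed = 1L) {
  Q <- as.matrix(rate_matrix)
  validate_rate_matrix(Q)
  k <- nrow(Q)
  labels <- rownames(Q)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  root <- if (is.character(root_state)) match(root_state, labels) else as.integer(root_state)
  if (is.na(root) || root < 1 || root > k) stop("invalid root_state")
  set.seed(seed)
  nn <- ape::Ntip(tree) + ape::Nnode(tree)
  states <- integer(nn)
  states[root_id(tree)] <- root
  tr <- ape::reorder.phylo(tree, "cladewise")
  Pcache <- list()
  for (e in seq_len(nrow(tr$edge))) {
    t <- tr$edge.length[e]
    key <- format(t, digits = 15)
    P <- Pcache[[key]]
    if (is.null(P)) {
      P <- ctmc_transition(Q, t)
      Pcache[[key]] <- P
    }
    p <- states[tr$edge[e, 1]]
    states[tr$edge[e, 2]] <- sample.int(k, 1L, prob = P[p, ])
  }
  names(states) <- all_node_names(tree)
  out <- labels[states[tree$tip.label]]
  names(out) <- tree$tip.label
  attr(out, "history") <- stats::setNames(labels[states], names(states))
  out
}

#' The 20-letter amino-acid alphabet used throughout the package
#' @return character vector of the 20 standard one-letter codes.
#' @export
aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# final state after n uniform jumps among the 19 other residues:
# P(same) = 1/20 + (19/20) * (-1/19)^n
.jump_states <- function(start, n_jumps) {
  out <- start
  idx <- which(n_jumps > 0)
  for (i in idx) {
    p_same <- 1 / 20 + (19 / 20) * (-1 / 19)^n_jumps[i]
    if (runif(1) < p_same) out[i] <- start[i]
    else out[i] <- sample(setdiff(1:20, start[i]), 1L)
  }
  out
}

#' Simulate a two-domain protein alignment with fragment clades
#'
#' Amino acids evolve under an equal-exchangeability (Poisson) jump process
#' with uniform frequencies. Tips inside `fragment_clades` have every
#' C-terminal-domain (ADH-region) column gapped, emulating single-domain
#' fragment genes; `interface_sites` (columns of the N-terminal ALDH region)
#' substitute at `rate_multiplier` times the base rate on branches inside the
#' fragment clades (stem branch included).
#'
#' @param tree a named [ape::phylo] gene tree.
#' @param len_aldh,len_adh column counts of the N- and C-terminal domains.
#' @param fragment_clades list of internal node names; each names a clade
#'   whose tips carry ALDH-only fragments. Clades must not overlap.
#' @param interface_sites integer sites in `1..len_aldh`.
#' @param rate_multiplier >= 1; fold-acceleration at interface sites on
#'   fragment-clade branches.
#' @param base_rate expected substitutions per site per unit branch length.
#' @param seed integer seed.
#' @return character matrix (tips x columns) of class `aa_msa`, with
#'   attributes `classes` (planted fragment class per tip), `interface_sites`
#'   and `fragment_tips`.
#' @export
simulate_domain_msa <- function(tree, len_aldh = 150, len_adh = 130,
                                fragment_clades, interface_sites = integer(),
                                rate_multiplier = 1, base_rate = 1,
                                seed = 1L) {
  if (rate_multiplier < 1) stop("rate_multiplier must be >= 1")
  if (length(interface_sites) &&
      (min(interface_sites) < 1 || max(interface_sites) > len_aldh))
    stop("interface_sites must lie in 1..len_aldh")
  frag_tips_by_clade <- lapply(fragment_clades, clade_tips, tree = tree)
  frag_tips <- unlist(frag_tips_by_clade)
  if (anyDuplicated(frag_tips)) stop("fragment clades overlap")
  set.seed(seed)
  L <- len_aldh + len_adh
  nn <- ape::Ntip(tree) + ape::Nnode(tree)
  # edges inside fragment clades, stem branch included
  frag_nodes <- unlist(lapply(fragment_clades,
                              function(nd) descendant_ids(tree, node_id(tree, nd))))
  tr <- ape::reorder.phylo(tree, "cladewise")
  frag_edge <- tr$edge[, 2] %in% frag_nodes
  states <- matrix(NA_integer_, nn, L)
  states[root_id(tree), ] <- sample.int(20, L, replace = TRUE)
  rates <- rep(base_rate, L)
  for (e in seq_len(nrow(tr$edge))) {
    t <- tr$edge.length[e]
    r <- rates
    if (frag_edge[e] && length(interface_sites))
      r[interface_sites] <- base_rate * rate_multiplier
    njump <- rpois(L, r * t)
    states[tr$edge[e, 2], ] <- .jump_states(states[tr$edge[e, 1], ], njump)
  }
  aa <- aa_alphabet()
  msa <- matrix(aa[states[seq_len(ape::Ntip(tree)), ]],
                ape::Ntip(tree), L,
                dimnames = list(tree$tip.label, NULL))
  msa[frag_tips, len_aldh + seq_len(len_adh)] <- "-"
  classes <- stats::setNames(rep("complete", ape::Ntip(tree)), tree$tip.label)
  classes[frag_tips] <- "ALDH_only"
  structure(msa, class = c("aa_msa", class(msa)),
            classes = classes,
            interface_sites = as.integer(interface_sites),
            fragment_tips = frag_tips)
}

#' Write a CA-only two-chain toy structure with declared contacts
#'
#' Chains B and C carry `n_residues_per_chain` alanine CA atoms each. Every
#' declared pair (B residue, C residue) is placed at exactly 4.0 A; all other
#' inter-chain residue pairs are farther than 6.0 A, so a 5 A contact rule
#' recovers the declared pairs exactly.
#'
#' @param n_residues_per_chain residues per chain.
#' @param contact_pairs data frame with columns `b`, `c` (residue indices);
#'   may have zero rows.
#' @param seed integer seed (sets only a sub-0.05 A coordinate jitter on
#'   non-contact residues).
#' @return single character scalar of PDB-format text.
#' @export
write_toy_structure <- function(n_residues_per_chain, contact_pairs = NULL,
                                seed = 1L) {
  n <- n_residues_per_chain
  if (is.null(contact_pairs))
    contact_pairs <- data.frame(b = integer(), c = integer())
  if (nrow(contact_pairs) &&
      (max(contact_pairs$b, contact_pairs$c) > n ||
       min(contact_pairs$b, contact_pairs$c) < 1))
    stop("contact pair indices must be in 1..n_residues_per_chain")
  if (anyDuplicated(contact_pairs$c))
    stop("geometric placement infeasible: a chain-C residue may join at most one contact pair")
  set.seed(seed)
  # chain B along the x axis, 20 A spacing; chain C parallel but 60 A away
  bx <- 20 * seq_len(n)
  cx <- 20 * seq_len(n); cy <- rep(60, n); cz <- rep(0, n)
  jitter <- function(m) matrix(runif(m * 3, -0.04, 0.04), m, 3)
  jB <- jitter(n); jC <- jitter(n)
  if (nrow(contact_pairs)) {
    jC[contact_pairs$c, ] <- 0
    jB[contact_pairs$b, ] <- 0
    # contacts: place each declared C residue 4.0 A from its B partner,
    # fanning multiple partners of one B residue around the y-z plane
    for (b in unique(contact_pairs$b)) {
      cs <- contact_pairs$c[contact_pairs$b == b]
      ang <- (seq_along(cs) - 1) * (pi / 3)
      cx[cs] <- 20 * b
      cy[cs] <- 4 * cos(ang)
      cz[cs] <- 4 * sin(ang)
    }
  }
  coords <- rbind(cbind(bx, 0, 0) + jB, cbind(cx, cy, cz) + jC)
  chain <- rep(c("B", "C"), each = n)
  resno <- rep(seq_len(n), 2)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(2 * n), chain, resno, coords[, 1], coords[, 2], coords[, 3])
  paste(c(lines, "END"), collapse = "\n")
}
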