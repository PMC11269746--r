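# Amino-acid ancestral sequence reconstruction on a fixed gene tree,
# per-branch substitution mapping, and fragment-specific site enrichment.

#' Amino-acid substitution model
#'
#' Equal-exchangeability model with arbitrary stationary frequencies (the
#' 20-state generalisation of F81, "Poisson" when frequencies are uniform);
#' an optional symmetric exchangeability matrix turns it into a GTR-type
#' model. Rates are scaled to one expected substitution per site per unit
#' branch length.
#'
#' @param freqs named length-20 frequency vector over [aa_alphabet()];
#'   default uniform.
#' @param exchangeability optional symmetric 20 x 20 matrix of relative
#'   exchangeabilities (diagonal ignored).
#' @return object of class `aa_model` with elements `freqs`, `Pfun(t)`.
#' @export
aa_model <- function(freqs = NULL, exchangeability = NULL) {
  aa <- aa_alphabet()
  if (is.null(freqs)) freqs <- stats::setNames(rep(1 / 20, 20), aa)
  if (length(freqs) != 20 || any(freqs < 0)) stop("freqs must be 20 non-negative values")
  if (!is.null(names(freqs))) freqs <- freqs[aa]
  freqs <- freqs / sum(freqs)
  names(freqs) <- aa
  if (is.null(exchangeability)) {
    beta <- 1 / (1 - sum(freqs^2))
    Pfun <- function(t) {
      e <- exp(-beta * t)
      P <- (1 - e) * matrix(freqs, 20, 20, byrow = TRUE)
      diag(P) <- diag(P) + e
      P
    }
  } else {
    S <- as.matrix(exchangeability)
    stopifnot(nrow(S) == 20, ncol(S) == 20)
    Q <- S * matrix(freqs, 20, 20, byrow = TRUE)
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    scale <- -sum(freqs * diag(Q))
    Q <- Q / scale
    dimnames(Q) <- list(aa, aa)
    Pfun <- .ctmc_Pfun(Q)
  }
  structure(list(freqs = freqs, Pfun = Pfun), class = "aa_model")
}

# map an MSA character matrix to 1..20 indices; gaps and ambiguity -> NA
.aa_indices <- function(msa) {
  aa <- aa_alphabet()
  idx <- match(toupper(msa), aa)
  matrix(idx, nrow(msa), ncol(msa), dimnames = dimnames(msa))
}

#' Empirical amino-acid frequencies of an alignment
#'
#' Counts over non-gap characters with one pseudocount per residue.
#'
#' @param msa character matrix.
#' @return named length-20 frequency vector.
#' @export
aa_frequencies <- function(msa) {
  idx <- .aa_indices(msa)
  n <- tabulate(idx[!is.na(idx)], 20) + 1
  stats::setNames(n / sum(n), aa_alphabet())
}

#' Marginal amino-acid ancestral sequence reconstruction
#'
#' Per-node, per-site posterior distributions over the 20 amino acids on a
#' fixed rooted gene tree, by up/down message passing. Gaps at tips are
#' missing data (uninformative partial vectors), not a 21st state. The root
#' prior is the model's stationary frequency vector.
#'
#' @param tree a named [ape::phylo] gene tree whose tips match `rownames(msa)`.
#' @param msa character matrix (tips x columns), gaps as `"-"`.
#' @param model an [aa_model()]; default equal exchangeability with the
#'   alignment's empirical frequencies.
#' @return object of class `aa_asr`: `posteriors` (array 20 x sites x
#'   nodes, node order as [all_node_names()]), `tree`, `model`, `msa`.
#' @export
marginal_asr_aa <- function(tree, msa, model = NULL) {
  if (!all(tree$tip.label %in% rownames(msa)))
    stop("MSA is missing tree tip(s): ",
         paste(setdiff(tree$tip.label, rownames(msa)), collapse = ", "))
  if (is.null(model)) model <- aa_model(freqs = aa_frequencies(msa))
  S <- .aa_indices(msa)[tree$tip.label, , drop = FALSE]
  post <- .ctmc_marginal(tree, S, 20L, model$Pfun, model$freqs)
  dimnames(post) <- list(aa_alphabet(), colnames(msa), all_node_names(tree))
  structure(list(posteriors = post, tree = tree, model = model, msa = msa),
            class = "aa_asr")
}

#' @export
print.aa_asr <- function(x, ...) {
  d <- dim(x$posteriors)
  cat(sprintf("Amino-acid ASR: %d sites x %d nodes\n", d[2], d[3]))
  invisible(x)
}

#' Call ancestral residues from posteriors
#'
#' A residue is called at a node/site iff its posterior is strictly greater
#' than `threshold` (default 0.5, so at most one residue can qualify);
#' otherwise the site is uncertain (`NA`).
#'
#' @param asr an `aa_asr` object (or a 20 x sites x nodes posterior array).
#' @param threshold posterior call threshold.
#' @return character matrix (nodes x sites) with `NA` for uncertain calls.
#' @export
call_states <- function(asr, threshold = 0.5) {
  post <- if (inherits(asr, "aa_asr")) asr$posteriors else asr
  aa <- dimnames(post)[[1]]
  n_site <- dim(post)[2]; n_node <- dim(post)[3]
  out <- matrix(NA_character_, n_node, n_site,
                dimnames = list(dimnames(post)[[3]], dimnames(post)[[2]]))
  for (v in seq_len(n_node)) {
    p <- post[, , v, drop = TRUE]
    p <- matrix(p, nrow = length(aa))
    top <- apply(p, 2, which.max)
    val <- p[cbind(top, seq_len(n_site))]
    called <- !is.na(val) & val > threshold
    out[v, called] <- aa[top[called]]
  }
  out
}

#' Map substitutions onto branches
#'
#' For every branch (parent, child) and site, emits a substitution event iff
#' both endpoint residues are known (tips use the observed alignment, gaps
#' are missing; internal nodes use the ancestral calls) and differ.
#' Branch/site combinations with an uncertain endpoint contribute no event
#' and are tallied in the `skipped` attribute.
#'
#' @param tree a named [ape::phylo] tree.
#' @param calls matrix from [call_states()].
#' @param msa tip alignment (character matrix).
#' @return data frame with columns `parent`, `child`, `site`, `from`, `to`;
#'   attribute `skipped` counts branch-site pairs skipped for uncertainty.
#' @export
map_substitutions <- function(tree, calls, msa) {
  nn <- all_node_names(tree)
  n_site <- ncol(calls)
  state_of <- function(name) {
    if (name %in% tree$tip.label) {
      s <- msa[name, ]
      s[!s %in% aa_alphabet()] <- NA_character_
      s
    } else calls[name, ]
  }
  ev <- list(); skipped <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    pn <- nn[tree$edge[e, 1]]; cn <- nn[tree$edge[e, 2]]
    ps <- state_of(pn); cs <- state_of(cn)
    known <- !is.na(ps) & !is.na(cs)
    skipped <- skipped + sum(!known)
    hit <- which(known & ps != cs)
    if (length(hit))
      ev[[length(ev) + 1]] <- data.frame(parent = pn, child = cn, site = hit,
                                         from = ps[hit], to = cs[hit])
  }
  out <- if (length(ev)) do.call(rbind, ev)
         else data.frame(parent = character(), child = character(),
                         site = integer(), from = character(), to = character())
  attr(out, "skipped") <- skipped
  rownames(out) <- NULL
  out
}

#' Branches belonging to fragment clades
#'
#' A branch is a fragment branch iff every tip descending from it carries a
#' fragment gene; this includes the stem branch of each maximal monophyletic
#' fragment clade. Branches are identified by their child node name.
#'
#' @param tree a named [ape::phylo] tree.
#' @param fragment_tips tip labels carrying fragment genes.
#' @return character vector of child-node names.
#' @export
fragment_branch_set <- function(tree, fragment_tips) {
  nn <- all_node_names(tree)
  keep <- character()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    tips <- if (ch <= ape::Ntip(tree)) nn[ch]
            else tree$tip.label[descendant_ids(tree, ch)[descendant_ids(tree, ch) <= ape::Ntip(tree)]]
    if (all(tips %in% fragment_tips)) keep <- c(keep, nn[ch])
  }
  keep
}

#' Per-site fragment-specific substitution enrichment
#'
#' For each alignment site, counts substitution events in total and on
#' fragment-clade branches; only sites substituted at least `min_events`
#' times are returned, with the fragment ratio.
#'
#' @param events data frame from [map_substitutions()].
#' @param fragment_branches child-node names of fragment branches, e.g. from
#'   [fragment_branch_set()].
#' @param min_events minimum total substitutions per site (default 5).
#' @return data frame with columns `site`, `total`, `fragment`, `ratio`.
#' @export
site_fragment_ratio <- function(events, fragment_branches, min_events = 5) {
  if (!nrow(events))
    return(data.frame(site = integer(), total = integer(),
                      fragment = integer(), ratio = numeric()))
  frag <- events$child %in% fragment_branches
  sites <- sort(unique(events$site))
  total <- vapply(sites, function(s) sum(events$site == s), 0L)
  nfrag <- vapply(sites, function(s) sum(events$site == s & frag), 0L)
  out <- data.frame(site = sites, total = total, fragment = nfrag,
                    ratio = nfrag / total)
  out[out$total >= min_events, , drop = FALSE]
}

#' Top fragment-enriched sites
#'
#' Orders sites by fragment ratio, breaking ties by higher fragment count
#' and then lower site index, and returns the first `k` (fewer if fewer
#' qualify).
#'
#' @param enrichments data frame from [site_fragment_ratio()].
#' @param k number of sites (default 15).
#' @return integer vector of site indices.
#' @export
top_sites <- function(enrichments, k = 15) {
  if (!nrow(enrichments)) stop("no sites to rank")
  o <- order(-enrichments$ratio, -enrichments$fragment, enrichments$site)
  utils::head(enrichments$site[o], k)
}

#' Compare fragment enrichment between structural site groups
#'
#' Pairwise Mann-Whitney tests ([mann_whitney()]) between site groups (e.g.
#' interface / ligand-binding / other) on (a) per-site fragment ratios and
#' (b) per-site fragment substitution counts. Groups with fewer than two
#' sites are skipped with a warning.
#'
#' @param enrichments data frame from [site_fragment_ratio()].
#' @param site_groups data frame (`site`, `group`) or named vector
#'   site -> group; sites absent from it are grouped as `"other"`.
#' @return data frame with `group1`, `group2`, `metric` (`"ratio"` or
#'   `"count"`), `U`, `p` (two-sided).
#' @export
group_enrichment <- function(enrichments, site_groups) {
  if (is.data.frame(site_groups))
    site_groups <- stats::setNames(as.character(site_groups$group),
                                   site_groups$site)
  grp <- site_groups[as.character(enrichments$site)]
  grp[is.na(grp)] <- "other"
  groups <- unique(grp)
  small <- vapply(groups, function(g) sum(grp == g) < 2, TRUE)
  if (any(small)) {
    warning("group(s) with < 2 sites skipped: ",
            paste(groups[small], collapse = ", "))
    groups <- groups[!small]
  }
  if (length(groups) < 2) stop("need at least two groups with >= 2 sites")
  combs <- utils::combn(groups, 2)
  rows <- list()
  for (j in seq_len(ncol(combs))) {
    g1 <- combs[1, j]; g2 <- combs[2, j]
    for (metric in c("ratio", "count")) {
      v <- if (metric == "ratio") enrichments$ratio else enrichments$fragment
      mw <- mann_whitney(v[grp == g1], v[grp == g2])
      rows[[length(rows) + 1]] <- data.frame(group1 = g1, group2 = g2,
                                             metric = metric,
                                             U = mw$U, p = mw$p)
    }
  }
  do.call(rbind, rows)
}
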