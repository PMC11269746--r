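# Convergence analysis over replicated ancestral reconstructions: per-OG
# presence/absence scenarios at three focal ancestors, loss-branch
# assignment along two root-to-clade paths, the loss-order similarity
# statistic S with its permutation null, branch-wise Jaccard overlap, and
# functional-category loss timing.

#' Replicated joint ancestral reconstructions for many ortholog groups
#'
#' For each OG (column of `pa_table`): fit binary Mk rates by ML, draw
#' `n_replicates` rate samples by MCMC ([mk_mcmc()]), and run a joint
#' reconstruction ([mk_joint()]) under every sampled rate pair. This mirrors
#' the replicate-over-posterior-rates design used for ancestral gene-content
#' reconstruction.
#'
#' @param tree a named [ape::phylo] tree.
#' @param pa_table tips x OGs 0/1 matrix (tip rownames).
#' @param n_replicates reconstructions per OG (the study-scale default is
#'   500; tests use fewer).
#' @param burn_in,thin MCMC settings, see [mk_mcmc()].
#' @param seed integer seed; OG `i` uses `seed + i - 1`.
#' @param root_prior see [mk_loglik()].
#' @return array of dimension (n_nodes, n_ogs, n_replicates) of 0/1 states,
#'   with node, OG and replicate dimnames.
#' @export
ancestral_replicates <- function(tree, pa_table, n_replicates = 500,
                                 burn_in = 500, thin = 10, seed = 1L,
                                 root_prior = "stationary") {
  ogs <- colnames(pa_table)
  if (is.null(ogs)) ogs <- sprintf("OG%04d", seq_len(ncol(pa_table)))
  nn <- ape::Ntip(tree) + ape::Nnode(tree)
  out <- array(NA_integer_, c(nn, ncol(pa_table), n_replicates),
               dimnames = list(all_node_names(tree), ogs,
                               paste0("rep", seq_len(n_replicates))))
  for (i in seq_len(ncol(pa_table))) {
    x <- stats::setNames(pa_table[, i], rownames(pa_table))
    chain <- mk_mcmc(tree, x, n_samples = n_replicates, burn_in = burn_in,
                     thin = thin, seed = seed + i - 1L,
                     root_prior = root_prior)
    for (r in seq_len(n_replicates)) {
      q <- chain$samples[r, ]
      out[, i, r] <- mk_joint(tree, x, q[1], q[2],
                              root_prior = root_prior)$states[, 1]
    }
  }
  out
}

.scenario_levels <- function() {
  g <- expand.grid(0:1, 0:1, 0:1)
  apply(g[, 3:1], 1, paste, collapse = "")
}

#' Classify per-OG presence/absence scenarios at three focal ancestors
#'
#' Each replicate's states at (`LCAfa`, `LCAa`, `LCAf`) form a triplet such
#' as "100" (present in the joint ancestor, absent in both focal ancestors).
#' Support fractions over the 8 triplets are computed per OG; the majority
#' scenario is the most supported one, ties broken toward the scenario with
#' more presences (conservative against inferring loss) and flagged.
#'
#' @param replicates array from [ancestral_replicates()] (nodes x OGs x
#'   replicates, node dimnames required).
#' @param focal_nodes named list/vector with entries `LCAfa`, `LCAa`, `LCAf`.
#' @return list with `fractions` (OGs x 8 matrix, rows summing to 1),
#'   `majority` (named character vector of triplets), `support` (majority
#'   fraction), `tie` (logical).
#' @export
classify_scenarios <- function(replicates, focal_nodes) {
  fn <- unlist(focal_nodes[c("LCAfa", "LCAa", "LCAf")])
  if (anyNA(fn)) stop("focal_nodes must name LCAfa, LCAa and LCAf")
  if (!all(fn %in% dimnames(replicates)[[1]]))
    stop("focal node missing from replicate states")
  sub <- replicates[fn, , , drop = FALSE]
  if (anyNA(sub)) stop("missing node state in a replicate")
  n_og <- dim(sub)[2]; n_rep <- dim(sub)[3]
  lv <- .scenario_levels()
  # per OG/replicate scenario code 1..8 from bits (LCAfa, LCAa, LCAf)
  code <- 4L * sub[1, , ] + 2L * sub[2, , ] + sub[3, , ] + 1L
  code <- matrix(code, n_og, n_rep)
  lv_by_code <- vapply(0:7, function(x) paste(as.integer(intToBits(x))[3:1], collapse = ""), "")
  frac <- t(apply(code, 1, function(z) tabulate(z, 8) / n_rep))
  colnames(frac) <- lv_by_code
  rownames(frac) <- dimnames(replicates)[[2]]
  n_ones <- vapply(strsplit(lv_by_code, ""), function(z) sum(z == "1"), 0L)
  pick <- function(fr) {
    top <- which(fr == max(fr))
    if (length(top) > 1) top <- top[order(-n_ones[top], top)][1]
    top
  }
  idx <- apply(frac, 1, pick)
  tie <- apply(frac, 1, function(fr) sum(fr == max(fr)) > 1)
  list(fractions = frac,
       majority = stats::setNames(lv_by_code[idx], rownames(frac)),
       support = stats::setNames(frac[cbind(seq_len(n_og), idx)], rownames(frac)),
       tie = stats::setNames(tie, rownames(frac)))
}

#' Select OGs commonly and independently lost in both focal lineages
#'
#' Returns OGs whose majority scenario is "100": present in the joint
#' ancestor, absent in both focal ancestors.
#'
#' @param scenarios result of [classify_scenarios()].
#' @param category_map optional data frame (`og`, `category`); when given,
#'   the result also carries a per-category split as attribute `by_category`.
#' @return character vector of OG names.
#' @export
select_commonly_lost <- function(scenarios, category_map = NULL) {
  ogs <- names(scenarios$majority)[scenarios$majority == "100"]
  if (!is.null(category_map)) {
    sp <- split(category_map$og, category_map$category)
    attr(ogs, "by_category") <- lapply(sp, intersect, x = ogs)
  }
  ogs
}

#' Assign the loss branch of one OG along a path
#'
#' Scans each replicate's node states along the path; replicates with exactly
#' one presence-to-absence transition and no regain vote for the branch where
#' the transition occurred ("loss occurred once" rule). The plurality branch
#' wins; ties are broken toward the earlier branch and flagged.
#'
#' @param replicates array from [ancestral_replicates()].
#' @param path node-name path (see [path_nodes()]); branch `i` joins names
#'   `i` and `i + 1`.
#' @param og OG name.
#' @return list with `branch` (1-based index), `support` (votes /
#'   qualifying replicates), `n_qualifying`, `tie`.
#' @export
assign_loss_branch <- function(replicates, path, og) {
  st <- replicates[path, og, , drop = TRUE]           # path-nodes x reps
  st <- matrix(st, length(path))
  d <- st[-nrow(st), , drop = FALSE] - st[-1, , drop = FALSE]
  losses <- colSums(d == 1)
  gains <- colSums(d == -1)
  ok <- losses == 1 & gains == 0
  if (!any(ok))
    stop("no-single-loss-scenario: OG '", og,
         "' has no qualifying replicate on this path")
  votes <- apply(d[, ok, drop = FALSE] == 1, 2, which.max)
  tab <- tabulate(votes, nrow(st) - 1L)
  best <- which(tab == max(tab))
  list(branch = best[1], support = max(tab) / sum(ok),
       n_qualifying = sum(ok), tie = length(best) > 1)
}

#' Assign loss branches for a set of OGs
#'
#' Vectorised wrapper around [assign_loss_branch()]; OGs with no qualifying
#' single-loss replicate are dropped with a warning.
#'
#' @inheritParams assign_loss_branch
#' @param ogs character vector of OG names.
#' @return data frame with columns `og`, `branch`, `support`, `n_qualifying`,
#'   `tie`.
#' @export
assign_loss_branches <- function(replicates, path, ogs) {
  rows <- lapply(ogs, function(og) {
    r <- tryCatch(assign_loss_branch(replicates, path, og),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(og = og, branch = r$branch, support = r$support,
               n_qualifying = r$n_qualifying, tie = r$tie)
  })
  dropped <- ogs[vapply(rows, is.null, TRUE)]
  if (length(dropped))
    warning("no single-loss scenario for: ", paste(dropped, collapse = ", "))
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

.rank_pair_signs <- function(r) sign(outer(r, r, "-"))

#' Loss-order similarity between two lineages
#'
#' Over all unordered pairs of OGs lost in both lineages, the fraction whose
#' relative loss order agrees: a pair is concordant iff the sign of the
#' branch-rank difference is the same in both lineages (sign 0 for a
#' same-branch tie, so pairs tied in both lineages count as concordant).
#' With `ties = "exclude"` pairs tied in either lineage are removed from the
#' denominator instead.
#'
#' @param rank_a,rank_f named numeric vectors (OG -> loss branch index) over
#'   the same OG set of size >= 2.
#' @param ties `"concordant"` (default) or `"exclude"`.
#' @return S in [0, 1].
#' @export
loss_order_similarity <- function(rank_a, rank_f, ties = "concordant") {
  ties <- match.arg(ties, c("concordant", "exclude"))
  common <- intersect(names(rank_a), names(rank_f))
  if (length(common) < 2) stop("need at least 2 OGs lost in both lineages")
  sa <- .rank_pair_signs(rank_a[common])
  sf <- .rank_pair_signs(rank_f[common])
  ut <- upper.tri(sa)
  if (ties == "exclude") {
    keep <- ut & sa != 0 & sf != 0
    if (!any(keep)) stop("no untied pairs to compare")
    return(mean(sa[keep] == sf[keep]))
  }
  mean(sa[ut] == sf[ut])
}

#' Permutation test of loss-order similarity
#'
#' The null shuffles the correspondence between OGs and loss branches within
#' each lineage independently, preserving each lineage's multiset of branch
#' labels (hence its tie structure). The p value is the plain ratio of
#' permutations with S' >= S_obs (it can be 0); an add-one-smoothed value is
#' also returned.
#'
#' @inheritParams loss_order_similarity
#' @param n_perm number of shuffles (default 10000).
#' @param seed integer seed.
#' @return list with `S_obs`, `p`, `p_smoothed`, `n_perm`, and the null
#'   scores `S_null`.
#' @export
permutation_pvalue <- function(rank_a, rank_f, n_perm = 10000, seed = 1L,
                               ties = "concordant") {
  if (n_perm < 1) stop("n_perm must be >= 1")
  ties <- match.arg(ties, c("concordant", "exclude"))
  common <- intersect(names(rank_a), names(rank_f))
  if (length(common) < 2) stop("need at least 2 OGs lost in both lineages")
  n <- length(common)
  sa <- .rank_pair_signs(rank_a[common])
  sf <- .rank_pair_signs(rank_f[common])
  ut <- upper.tri(sa)
  score <- function(A, F_) {
    if (ties == "exclude") {
      keep <- ut & A != 0 & F_ != 0
      if (!any(keep)) return(NA_real_)
      mean(A[keep] == F_[keep])
    } else mean(A[ut] == F_[ut])
  }
  S_obs <- score(sa, sf)
  set.seed(seed)
  S_null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    pa <- sample.int(n); pf <- sample.int(n)
    S_null[i] <- score(sa[pa, pa], sf[pf, pf])
  }
  p <- mean(S_null >= S_obs, na.rm = TRUE)
  list(S_obs = S_obs, p = p,
       p_smoothed = (sum(S_null >= S_obs, na.rm = TRUE) + 1) / (n_perm + 1),
       n_perm = n_perm, S_null = S_null)
}

#' Contingency table and chi-square test for loss overlap
#'
#' Cross-tabulates membership of `universe` OGs in the two lineages' lost
#' sets and tests independence with Pearson's chi-square ([chi_square()]).
#'
#' @param lost_a,lost_f character vectors, subsets of `universe`.
#' @param universe all OGs considered.
#' @return list with `table` (2 x 2: lost/retained in A x lost/retained in
#'   F), `statistic`, `p`.
#' @export
overlap_contingency <- function(lost_a, lost_f, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(lost_a %in% universe) || !all(lost_f %in% universe))
    stop("lost sets must be subsets of the universe")
  in_a <- universe %in% lost_a
  in_f <- universe %in% lost_f
  tab <- matrix(c(sum(in_a & in_f), sum(in_a & !in_f),
                  sum(!in_a & in_f), sum(!in_a & !in_f)),
                2, 2, byrow = FALSE,
                dimnames = list(A = c("lost", "retained"),
                                F = c("lost", "retained")))
  cs <- chi_square(tab)
  list(table = tab, statistic = cs$statistic, p = cs$p)
}

#' Branch-wise Jaccard overlap of lost OG sets
#'
#' Cell (i, j) is the Jaccard index of the OGs assigned to branch i of path A
#' and branch j of path F; cells with an empty union are reported as 0 and
#' flagged in attribute `empty_union`.
#'
#' @param assign_a,assign_f data frames from [assign_loss_branches()].
#' @param n_branch_a,n_branch_f branch counts of the two paths (default: max
#'   assigned index).
#' @return matrix (path-A branches x path-F branches).
#' @export
branch_jaccard <- function(assign_a, assign_f,
                           n_branch_a = max(assign_a$branch),
                           n_branch_f = max(assign_f$branch)) {
  sets_a <- split(assign_a$og, factor(assign_a$branch, levels = seq_len(n_branch_a)))
  sets_f <- split(assign_f$og, factor(assign_f$branch, levels = seq_len(n_branch_f)))
  out <- matrix(0, n_branch_a, n_branch_f,
                dimnames = list(paste0("A", seq_len(n_branch_a)),
                                paste0("F", seq_len(n_branch_f))))
  empty <- out == 0
  for (i in seq_len(n_branch_a)) for (j in seq_len(n_branch_f)) {
    u <- union(sets_a[[i]], sets_f[[j]])
    if (!length(u)) { empty[i, j] <- TRUE; next }
    out[i, j] <- length(intersect(sets_a[[i]], sets_f[[j]])) / length(u)
  }
  attr(out, "empty_union") <- empty
  out
}

#' Functional-category loss timing and rank concordance
#'
#' Loss timing of an OG is its 1-based branch index along the path; each
#' category's timing is the mean over member OGs, categories are ranked per
#' lineage (average ranks on ties) and per-category rank differences
#' reported.
#'
#' @param assign_a,assign_f data frames from [assign_loss_branches()].
#' @param category_map data frame (`og`, `category`); an OG may map to
#'   several categories.
#' @return data frame: `category`, `mean_a`, `mean_f`, `rank_a`, `rank_f`,
#'   `rank_diff` (absolute), `n_a`, `n_f`. Categories with no member OG in
#'   either assignment are excluded with a warning.
#' @export
category_loss_timing <- function(assign_a, assign_f, category_map) {
  ra <- stats::setNames(assign_a$branch, assign_a$og)
  rf <- stats::setNames(assign_f$branch, assign_f$og)
  cats <- unique(category_map$category)
  rows <- lapply(cats, function(cc) {
    ogs <- category_map$og[category_map$category == cc]
    ma <- ra[names(ra) %in% ogs]; mf <- rf[names(rf) %in% ogs]
    if (!length(ma) || !length(mf)) return(NULL)
    data.frame(category = cc, mean_a = mean(ma), mean_f = mean(mf),
               n_a = length(ma), n_f = length(mf))
  })
  dropped <- cats[vapply(rows, is.null, TRUE)]
  if (length(dropped))
    warning("empty category excluded: ", paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop("no category has members in both lineages")
  out$rank_a <- rank(out$mean_a)
  out$rank_f <- rank(out$mean_f)
  out$rank_diff <- abs(out$rank_a - out$rank_f)
  out[, c("category", "mean_a", "mean_f", "rank_a", "rank_f",
          "rank_diff", "n_a", "n_f")]
}
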