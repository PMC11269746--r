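# Statistical utilities: Pearson chi-square on contingency tables,
# Mann-Whitney U, Brownian-motion simulation on a tree, and phylogenetic
# ANOVA with a simulation null.

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction by default. All expected counts must be
#' positive (zero marginals are rejected).
#'
#' @param table_2x2 matrix of non-negative counts (any r x c, 2 x 2 in the
#'   typical use).
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with `statistic`, `p`, `df`, `expected`.
#' @export
chi_square <- function(table_2x2, correct = FALSE) {
  tab <- as.matrix(table_2x2)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal: expected counts must be positive")
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter), expected = res$expected)
}

#' Mann-Whitney U test
#'
#' Exact enumeration for small tie-free samples, otherwise the normal
#' approximation with tie correction (via [stats::wilcox.test()]).
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `U` (the statistic for `x`) and `p`.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) stop("samples must be non-empty")
  res <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative))
  list(U = unname(res$statistic), p = unname(res$p.value))
}

#' Simulate Brownian motion along a tree
#'
#' Root value 0; each branch adds an independent normal increment with
#' variance `sigma2` times the branch length.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param sigma2 BM rate (variance per unit branch length), > 0 (or 0 for a
#'   degenerate all-zero trait).
#' @param seed integer seed.
#' @param n_sim number of independent replicate traits.
#' @return tips x n_sim matrix of tip values (tip rownames); a named vector
#'   when `n_sim = 1`.
#' @export
brownian_simulate <- function(tree, sigma2, seed = 1L, n_sim = 1) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  set.seed(seed)
  nn <- ape::Ntip(tree) + ape::Nnode(tree)
  vals <- matrix(0, nn, n_sim)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    vals[ch, ] <- vals[p, ] + stats::rnorm(n_sim, 0, sqrt(sigma2 * tr$edge.length[e]))
  }
  out <- vals[seq_len(ape::Ntip(tree)), , drop = FALSE]
  rownames(out) <- tree$tip.label
  if (n_sim == 1) stats::setNames(out[, 1], tree$tip.label) else out
}

# one-way ANOVA F for every column of Y given fixed groups
.anova_F <- function(Y, g) {
  Y <- as.matrix(Y)
  n <- nrow(Y); k <- nlevels(g)
  counts <- as.vector(table(g))
  gs <- rowsum(Y, g)                 # k x m group sums
  gm <- gs / counts
  grand <- colSums(Y) / n
  ssb <- colSums(counts * (gm - rep(grand, each = k))^2)
  sst <- colSums((Y - rep(grand, each = n))^2)
  ssw <- sst - ssb
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Phylogenetic ANOVA with a Brownian-motion simulation null
#'
#' The observed one-way ANOVA F statistic is compared against F statistics
#' from traits simulated under Brownian motion on the tree (groups held
#' fixed), correcting the test for phylogenetic non-independence. The BM
#' rate is estimated from the data by the standard independent-contrasts
#' estimator (mean squared contrast).
#'
#' @param tree an [ape::phylo] tree (binary, with branch lengths).
#' @param groups named factor/character of group labels, one per tip (>= 2
#'   groups).
#' @param trait named numeric trait, one value per tip.
#' @param n_sim number of null simulations (default 1000).
#' @param seed integer seed.
#' @return object of class `phylo_anova`: `F_obs`, `p` (fraction of null F
#'   >= observed), `sigma2`, `n_sim`, `F_null`.
#' @export
phylogenetic_anova <- function(tree, groups, trait, n_sim = 1000, seed = 1L) {
  tips <- tree$tip.label
  if (!all(tips %in% names(groups)) || !all(tips %in% names(trait)))
    stop("groups and trait must cover every tip")
  g <- factor(groups[tips])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  y <- trait[tips]
  F_obs <- .anova_F(matrix(y, ncol = 1), g)
  pic <- ape::pic(y, ape::multi2di(tree))
  sigma2 <- mean(pic^2)
  sims <- brownian_simulate(tree, sigma2, seed = seed, n_sim = n_sim)
  F_null <- .anova_F(sims, g)
  structure(list(F_obs = F_obs, p = mean(F_null >= F_obs), sigma2 = sigma2,
                 n_sim = n_sim, F_null = F_null),
            class = "phylo_anova")
}

#' @export
print.phylo_anova <- function(x, ...) {
  cat(sprintf("Phylogenetic ANOVA: F = %.4f, p = %.4g (%d BM simulations, sigma2 = %.4g)\n",
              x$F_obs, x$p, x$n_sim, x$sigma2))
  invisible(x)
}
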