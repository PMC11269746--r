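# Scenario classification at focal ancestors, loss-branch assignment, the
# loss-order similarity statistic with its permutation null, overlap and
# Jaccard summaries, and category loss timing.

# build a replicate array (nodes x OGs x reps) from a list of per-OG
# node-state vectors repeated with given counts
rep_array <- function(node_names, og_states_list, n_rep) {
  ogs <- names(og_states_list)
  out <- array(NA_integer_, c(length(node_names), length(ogs), n_rep),
               dimnames = list(node_names, ogs, NULL))
  for (og in ogs) {
    st <- og_states_list[[og]]
    if (is.list(st)) {
      stopifnot(sum(vapply(st, `[[`, 0L, "n")) == n_rep)
      r <- 1L
      for (blk in st) for (k in seq_len(blk$n)) {
        out[names(blk$states), og, r] <- blk$states
        r <- r + 1L
      }
    } else {
      for (r in seq_len(n_rep)) out[names(st), og, r] <- st
    }
  }
  out
}

test_that("scenario triplets are counted, ties broken toward presence", {
  nodes <- c("LCAfa", "LCAa", "LCAf")
  reps <- rep_array(nodes, list(
    og1 = stats::setNames(c(1L, 0L, 1L), nodes),
    og2 = stats::setNames(c(1L, 0L, 0L), nodes),
    og3 = list(list(states = stats::setNames(c(1L, 0L, 0L), nodes), n = 300L),
               list(states = stats::setNames(c(1L, 1L, 0L), nodes), n = 200L)),
    og4 = list(list(states = stats::setNames(c(1L, 0L, 0L), nodes), n = 250L),
               list(states = stats::setNames(c(1L, 1L, 0L), nodes), n = 250L))
  ), 500L)
  sc <- classify_scenarios(reps, list(LCAfa = "LCAfa", LCAa = "LCAa",
                                      LCAf = "LCAf"))
  expect_equal(unname(sc$majority[c("og1", "og2", "og3")]),
               c("101", "100", "100"))
  expect_equal(unname(sc$support[c("og1", "og2", "og3")]), c(1, 1, 0.6))
  expect_equal(rowSums(sc$fractions), rep(1, 4), ignore_attr = TRUE)
  # tie: 250/250 broken toward more presences (110 over 100), flagged
  expect_equal(unname(sc$majority["og4"]), "110")
  expect_true(sc$tie[["og4"]])

  expect_equal(select_commonly_lost(sc), c("og2", "og3"))
  expect_error(classify_scenarios(reps[1:2, , , drop = FALSE],
                                  list(LCAfa = "LCAfa", LCAa = "LCAa",
                                       LCAf = "LCAf")), "missing")
})

test_that("loss branches are assigned by the single-loss plurality rule", {
  path <- c("P0", "P1", "P2", "P3", "P4", "P5")
  reps <- rep_array(path, list(
    clean = stats::setNames(c(1L, 1L, 1L, 0L, 0L, 0L), path),
    split = list(list(states = stats::setNames(c(1L, 1L, 0L, 0L, 0L, 0L), path), n = 6L),
                 list(states = stats::setNames(c(1L, 1L, 1L, 1L, 0L, 0L), path), n = 4L)),
    regain = list(list(states = stats::setNames(c(1L, 0L, 1L, 0L, 0L, 0L), path), n = 9L),
                  list(states = stats::setNames(c(1L, 0L, 0L, 0L, 0L, 0L), path), n = 1L)),
    never = stats::setNames(c(1L, 1L, 1L, 1L, 1L, 1L), path)
  ), 10L)
  a <- assign_loss_branch(reps, path, "clean")
  expect_equal(a$branch, 3L)
  expect_equal(a$support, 1.0)
  b <- assign_loss_branch(reps, path, "split")
  expect_equal(b$branch, 2L)
  expect_equal(b$support, 0.6)
  # replicates with a regain are excluded from voting
  c_ <- assign_loss_branch(reps, path, "regain")
  expect_equal(c_$n_qualifying, 1L)
  expect_equal(c_$branch, 1L)
  expect_error(assign_loss_branch(reps, path, "never"), "no-single-loss")
  expect_warning(assign_loss_branches(reps, path, c("clean", "split", "never")),
                 "never")
  df <- suppressWarnings(assign_loss_branches(reps, path,
                                              c("clean", "split", "never")))
  expect_equal(df$og, c("clean", "split"))
})

test_that("loss-order similarity follows the pairwise sign rule", {
  r5 <- stats::setNames(1:5, paste0("g", 1:5))
  expect_equal(loss_order_similarity(r5, r5), 1.0)
  rr <- stats::setNames(5:1, paste0("g", 1:5))
  expect_equal(loss_order_similarity(r5, rr), 0.0)
  # tie rule worked example: a = (1,1,2), f = (1,2,2) over (x,y,z)
  ra <- c(x = 1, y = 1, z = 2); rf <- c(x = 1, y = 2, z = 2)
  expect_equal(loss_order_similarity(ra, rf), 1 / 3)
  # symmetric in lineage order
  expect_equal(loss_order_similarity(rf, ra), 1 / 3)
  # exclude-ties variant drops pairs tied in either lineage
  expect_equal(loss_order_similarity(ra, rf, ties = "exclude"), 1.0)
  expect_error(loss_order_similarity(c(x = 1), c(x = 1)), "at least 2")
})

test_that("permutation test recovers planted order and is well defined at the floor", {
  set.seed(40)
  ra <- stats::setNames(sample(1:6, 20, replace = TRUE), paste0("g", 1:20))
  pv <- permutation_pvalue(ra, ra, n_perm = 2000, seed = 41)
  expect_equal(pv$S_obs, 1.0)
  expect_lt(pv$p, 0.01)
  pv2 <- permutation_pvalue(ra, ra, n_perm = 2000, seed = 41)
  expect_identical(pv$S_null, pv2$S_null)

  # fully reversed distinct orders: S = 0 is the achievable minimum, p = 1
  r <- stats::setNames(1:8, paste0("g", 1:8))
  rv <- stats::setNames(8:1, paste0("g", 1:8))
  pv3 <- permutation_pvalue(r, rv, n_perm = 500, seed = 42)
  expect_equal(pv3$S_obs, 0.0)
  expect_equal(pv3$p, 1.0)
  expect_error(permutation_pvalue(r, rv, n_perm = 0), "n_perm")
})

test_that("overlap contingency reproduces exact independence and planted overlap", {
  u <- paste0("u", 1:40)
  la <- u[1:20]; lf <- u[c(1:10, 21:30)]  # both = 10, a only = 10, f only = 10
  ov <- overlap_contingency(la, lf, u)
  expect_equal(as.vector(ov$table), c(10, 10, 10, 10))
  expect_equal(ov$statistic, 0)
  expect_equal(ov$p, 1)

  u2 <- paste0("x", 1:2000)
  both <- u2[1:30]
  la2 <- c(both, u2[31:50]); lf2 <- c(both, u2[51:70])
  ov2 <- overlap_contingency(la2, lf2, u2)
  expect_equal(ov2$table["lost", "lost"], 30)
  expect_lt(ov2$p, 1e-10)
  expect_error(overlap_contingency("a", "a", character()), "empty")
})

test_that("branch-wise Jaccard matches set arithmetic", {
  aa <- data.frame(og = c("a", "b", "c", "d"), branch = c(1, 1, 1, 2))
  ff <- data.frame(og = c("b", "c", "d", "e"), branch = c(1, 1, 1, 3))
  J <- branch_jaccard(aa, ff, n_branch_a = 2, n_branch_f = 3)
  expect_equal(J["A1", "F1"], 2 / 4)
  expect_equal(J["A2", "F3"], 0)          # {d} vs {e}: disjoint
  expect_equal(J["A2", "F1"], 1 / 3)      # {d} vs {b,c,d}
  expect_true(attr(J, "empty_union")["A1", "F2"])
  same <- data.frame(og = c("a", "b"), branch = c(1, 1))
  expect_equal(branch_jaccard(same, same)["A1", "F1"], 1.0)
})

test_that("category loss timing ranks categories per lineage", {
  cm <- data.frame(og = c("a", "b", "c", "d"),
                   category = c("K1", "K1", "K2", "K3"))
  aa <- data.frame(og = c("a", "b", "c", "d"), branch = c(1, 3, 3, 5))
  expect_equal(category_loss_timing(aa, aa, cm)$mean_a,
               c(2, 3, 5))
  out <- category_loss_timing(aa, aa, cm)
  expect_true(all(out$rank_diff == 0))

  # two categories swapped between lineages carry the maximal rank difference
  ff <- data.frame(og = c("a", "b", "c", "d"), branch = c(5, 7, 3, 1))
  out2 <- category_loss_timing(aa, ff, cm)
  swapped <- out2$category[out2$rank_diff == max(out2$rank_diff)]
  expect_setequal(swapped, c("K1", "K3"))
  cm2 <- rbind(cm, data.frame(og = "zzz", category = "K9"))
  expect_warning(category_loss_timing(aa, ff, cm2), "K9")
})
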