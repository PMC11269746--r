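# Synthetic-data generators: tree geometry, determinism, stationary
# behaviour of the binary and k-state simulators, planted ground truth, the
# two-domain alignment generator and the toy-structure writer.

test_that("simulated trees are ultrametric, depth 1, named and deterministic", {
  t2 <- simulate_tree(2, seed = 5)
  d <- ape::node.depth.edgelength(t2)[1:2]
  expect_equal(d, c(1, 1))
  expect_error(simulate_tree(1), "n_tips")

  n1 <- ape::write.tree(simulate_tree(64, seed = 1))
  n2 <- ape::write.tree(simulate_tree(64, seed = 1))
  expect_identical(n1, n2)

  tr <- simulate_tree(64, seed = 1)
  expect_true(is_ultrametric_tree(tr))
  depths <- ape::node.depth.edgelength(tr)[seq_len(64)]
  expect_equal(sum(depths), 64, tolerance = 1e-9)
  expect_false(anyDuplicated(all_node_names(tr)) > 0)
})

test_that("binary OG simulation matches trivial and stationary expectations", {
  tr <- simulate_tree(16, seed = 2)
  sim <- simulate_binary_ogs(tr, 0, 0, 25, root_prob1 = 1, seed = 3)
  expect_true(all(sim$table == 1L))
  expect_error(simulate_binary_ogs(tr, -0.1, 1, 5), ">= 0")

  # deep star-like tree: tips reach stationarity regardless of the root state
  deep <- tr
  deep$edge.length <- deep$edge.length * 10
  s1 <- simulate_binary_ogs(deep, 1, 1, 2000, root_prob1 = 0, seed = 4)
  expect_equal(mean(s1$table), 0.5, tolerance = 0.03)
  s2 <- simulate_binary_ogs(deep, 0.2, 2.0, 2000, root_prob1 = 1, seed = 5)
  expect_equal(mean(s2$table), 0.2 / 2.2, tolerance = 0.02)
})

test_that("planted convergent losses are exactly recoverable from the history", {
  ct <- simulate_convergent_tree(seed = 6)
  sim <- simulate_binary_ogs(ct$tree, 0.2, 0.5, 10, seed = 7)
  po <- data.frame(og = c("P1", "P2", "P3"),
                   branch_a = c(1L, 2L, 3L), branch_f = c(1L, 3L, 2L))
  sim <- plant_convergent_losses(sim, ct$path_a, ct$path_f, po)
  # states are 1 above the loss branch and 0 from its child downward
  for (i in 1:3) {
    h <- sim$history[, po$og[i]]
    expect_true(all(h[ct$path_a[seq_len(po$branch_a[i])]] == 1))
    expect_true(all(h[ct$path_a[-seq_len(po$branch_a[i])]] == 0))
    expect_true(all(h[ct$path_f[seq_len(po$branch_f[i])]] == 1))
    expect_true(all(h[ct$path_f[-seq_len(po$branch_f[i])]] == 0))
    expect_true(all(h[clade_tips(ct$tree, "OUT")] == 1))
  }
  # true rank pairs: (1,2,3) vs (1,3,2): pairs P1P2 +/+, P1P3 +/+, P2P3 +/-
  ra <- stats::setNames(po$branch_a, po$og)
  rf <- stats::setNames(po$branch_f, po$og)
  expect_equal(loss_order_similarity(ra, rf), 2 / 3)
  # planted branch off the path is rejected
  bad <- data.frame(og = "B", branch_a = 99L, branch_f = 1L)
  expect_error(plant_convergent_losses(sim, ct$path_a, ct$path_f, bad),
               "not on the declared path")
})

test_that("identical and reversed planted orders give S = 1 and S = 0", {
  ct <- simulate_convergent_tree(path_a_len = 6, path_f_len = 6, seed = 8)
  same <- data.frame(og = paste0("G", 1:6), branch_a = 1:6, branch_f = 1:6)
  ra <- stats::setNames(same$branch_a, same$og)
  expect_equal(loss_order_similarity(ra, ra), 1.0)
  rev_rf <- stats::setNames(6:1, same$og)
  expect_equal(loss_order_similarity(ra, rev_rf), 0.0)
})

test_that("planted order sampler avoids the unidentifiable double-first pair", {
  po <- sample_planted_orders(500, 6, 8, seed = 9)
  expect_false(any(po$branch_a == 1 & po$branch_f == 1))
  expect_true(all(po$branch_a %in% 1:6) && all(po$branch_f %in% 1:8))
})

test_that("k-state repertoire simulation is stationary and respects rate bias", {
  tr <- simulate_tree(24, seed = 10)
  Qz <- matrix(0, 3, 3)
  rs <- simulate_repertoire_states(tr, Qz, root_state = 2, seed = 11)
  expect_true(all(rs == "2"))
  expect_error(simulate_repertoire_states(tr, matrix(c(0, 1, 1, 0), 2, 2)),
               "sum to 0")

  # two-state symmetric chain on a deep star tree reaches frequency 1/2
  star <- ape::read.tree(text = paste0("(",
    paste(sprintf("s%d:8", 1:400), collapse = ","), ")r;"))
  Q2 <- matrix(c(-1, 1, 1, -1), 2, 2, byrow = TRUE)
  f <- simulate_repertoire_states(star, Q2, root_state = 1, seed = 12)
  expect_equal(mean(f == "1"), 0.5, tolerance = 0.03)

  # complete -> ALDH five-fold faster than complete -> ADH
  st <- c("complete", "ALDH", "ADH")
  Qb <- matrix(0, 3, 3, dimnames = list(st, st))
  Qb["complete", "ALDH"] <- 0.5
  Qb["complete", "ADH"] <- 0.1
  diag(Qb) <- -rowSums(Qb)
  wins <- 0
  big <- simulate_tree(300, seed = 13)
  for (s in 1:20) {
    tips <- simulate_repertoire_states(big, Qb, root_state = "complete",
                                       seed = 100 + s)
    wins <- wins + (sum(tips == "ALDH") > sum(tips == "ADH"))
  }
  expect_gte(wins / 20, 0.9)
})

test_that("domain MSA generator gaps fragment clades and is quiet under the null", {
  ft <- simulate_fragment_tree(seed = 14)
  msa <- simulate_domain_msa(ft$tree, 100, 80,
                             fragment_clades = as.list(ft$fragment_clades),
                             interface_sites = c(5, 25, 45, 65, 85),
                             rate_multiplier = 1, base_rate = 0.2, seed = 15)
  frag_rows <- msa[ft$fragment_tips, , drop = FALSE]
  expect_true(all(frag_rows[, 101:180] == "-"))
  expect_true(all(rowSums(frag_rows != "-") == 100))
  expect_true(all(msa[setdiff(rownames(msa), ft$fragment_tips), ] != "-"))

  # null configuration: interface sites statistically indistinguishable
  # (per-site count of tip residues differing from the column consensus)
  div <- apply(msa[, 1:100], 2, function(col) {
    col <- col[col != "-"]
    sum(col != names(which.max(table(col))))
  })
  p <- suppressWarnings(stats::wilcox.test(div[c(5, 25, 45, 65, 85)],
                                           div[-c(5, 25, 45, 65, 85)]))$p.value
  expect_gt(p, 0.01)

  expect_error(simulate_domain_msa(ft$tree, 100, 80,
                                   fragment_clades = list("FRAG1", "FRAG1")),
               "overlap")
  expect_error(simulate_domain_msa(ft$tree, 100, 80,
                                   fragment_clades = list("FRAG1"),
                                   interface_sites = 150), "1..len_aldh")
})

test_that("toy structures place declared contacts at 4 A and nothing else near", {
  pdb1 <- write_toy_structure(8, data.frame(b = 3L, c = 5L), seed = 16)
  at <- parse_structure(pdb1)
  hit <- chain_interface(at, "B", "C", 5.0)
  expect_equal(hit$resno, 3L)
  expect_equal(hit$min_distance, 4.0, tolerance = 1e-6)

  pdb0 <- write_toy_structure(8, NULL, seed = 17)
  expect_equal(nrow(chain_interface(parse_structure(pdb0), "B", "C", 5.0)), 0L)

  pairs10 <- data.frame(b = 1:10, c = 1:10)
  at10 <- parse_structure(write_toy_structure(10, pairs10, seed = 18))
  expect_equal(nrow(chain_interface(at10, "B", "C", 3.9)), 0L)
  expect_equal(nrow(chain_interface(at10, "B", "C", 6.1)), 10L)
  expect_equal(nrow(chain_interface(at10, "B", "C", 5.0)), 10L)

  expect_error(write_toy_structure(4, data.frame(b = 9L, c = 1L)), "1..n")
  expect_error(write_toy_structure(4, data.frame(b = c(1, 2), c = c(3, 3))),
               "infeasible")
})

test_that("generators are byte-identical under a fixed seed", {
  a <- simulate_binary_ogs(simulate_tree(12, 1), 0.3, 0.7, 20, seed = 2)
  b <- simulate_binary_ogs(simulate_tree(12, 1), 0.3, 0.7, 20, seed = 2)
  expect_identical(a$history, b$history)
  m1 <- simulate_domain_msa(simulate_fragment_tree(seed = 3)$tree, 40, 30,
                            fragment_clades = list("FRAG1"), seed = 4)
  m2 <- simulate_domain_msa(simulate_fragment_tree(seed = 3)$tree, 40, 30,
                            fragment_clades = list("FRAG1"), seed = 4)
  expect_identical(unclass(m1), unclass(m2))
  expect_identical(write_toy_structure(6, data.frame(b = 1L, c = 2L), seed = 5),
                   write_toy_structure(6, data.frame(b = 1L, c = 2L), seed = 5))
})
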