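# Mk machinery: transition matrices, pruning likelihood against analytic
# forms and brute-force enumeration, ML fitting, MCMC sampling, and
# joint/marginal ancestral reconstruction.

test_that("transition matrices are stochastic and reduce to identity at t = 0", {
  P <- mk_transition(0.3, 1.2, 0.7)
  expect_equal(rowSums(P), c("0" = 1, "1" = 1), tolerance = 1e-10)
  expect_equal(mk_transition(0.3, 1.2, 0), diag(2))
  Q <- matrix(c(-2, 1, 1, 2, -3, 1, 0.5, 0.5, -1), 3, 3, byrow = TRUE)
  expect_equal(rowSums(ctmc_transition(Q, 0.9)), rep(1, 3), tolerance = 1e-10)
  expect_equal(ctmc_transition(Q, 0), diag(3))
  expect_error(ctmc_transition(Q, -1), "negative")
  expect_error(mk_transition(-0.1, 1, 1), ">= 0")
})

test_that("two-tip likelihoods match analytic closed forms", {
  # both tips present, zero branch lengths, equal rates: only the root prior
  tr <- ape::read.tree(text = "(A:0,B:0)r;")
  expect_equal(mk_loglik(tr, c(A = 1, B = 1), 1, 1), log(0.5), tolerance = 1e-12)

  # equal branch lengths t: sum over root states of prior * P(root -> tip)^2
  t <- 0.37; q01 <- 0.8; q10 <- 0.3
  tr2 <- ape::read.tree(text = sprintf("(A:%f,B:%f)r;", t, t))
  s <- q01 + q10; pi1 <- q01 / s; pi0 <- q10 / s
  P11 <- pi1 + pi0 * exp(-s * t)
  P01 <- pi1 - pi1 * exp(-s * t)
  expect_equal(mk_loglik(tr2, c(A = 1, B = 1), q01, q10),
               log(pi0 * P01^2 + pi1 * P11^2), tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on small random instances", {
  for (i in 1:25) {
    n <- sample(4:6, 1)
    tr <- random_tree(n, seed = 300 + i)
    set.seed(400 + i)
    x <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    q01 <- runif(1, 0.1, 2); q10 <- runif(1, 0.1, 2)
    prior <- c(q10, q01) / (q01 + q10)
    oracle <- enum_ctmc(tr, x + 1L, 2, function(t) oracle_P2(q01, q10, t), prior)
    expect_equal(mk_loglik(tr, x, q01, q10), oracle$loglik, tolerance = 1e-8)
    j <- mk_joint(tr, x, q01, q10)
    expect_equal(j$log_prob, oracle$max_logprob, tolerance = 1e-9)
  }
})

test_that("the k-state engine at k = 2 agrees with the binary implementation", {
  tr <- random_tree(8, seed = 20)
  set.seed(21)
  x <- stats::setNames(sample(0:1, 8, replace = TRUE), tr$tip.label)
  Q <- matrix(c(-0.4, 0.4, 1.1, -1.1), 2, 2, byrow = TRUE)
  expect_equal(ctmc_loglik(tr, x + 1L, Q), mk_loglik(tr, x, 0.4, 1.1),
               tolerance = 1e-10)
})

test_that("likelihood is invariant to rerooting for the symmetric model", {
  tr <- random_tree(7, seed = 22)
  set.seed(23)
  x <- stats::setNames(sample(0:1, 7, replace = TRUE), tr$tip.label)
  l1 <- mk_loglik(tr, x, 0.7, 0.7)
  for (og in tr$tip.label[c(2, 5)]) {
    tr2 <- name_nodes(ape::root(ape::unroot(tr), outgroup = og,
                                resolve.root = TRUE))
    expect_equal(mk_loglik(tr2, x, 0.7, 0.7), l1, tolerance = 1e-9)
  }
})

test_that("missing tips and error contracts behave as documented", {
  tr <- random_tree(5, seed = 24)
  x <- stats::setNames(c(1, 0, NA, 1, 0), tr$tip.label)
  expect_true(is.finite(mk_loglik(tr, x, 0.5, 0.5)))
  # an NA tip equals summing the two resolved likelihoods
  x1 <- x; x1[3] <- 1; x0 <- x; x0[3] <- 0
  expect_equal(exp(mk_loglik(tr, x, 0.5, 0.5)),
               exp(mk_loglik(tr, x1, 0.5, 0.5)) + exp(mk_loglik(tr, x0, 0.5, 0.5)),
               tolerance = 1e-12)
  names(x)[1] <- "nosuchtip"
  expect_error(mk_loglik(tr, x, 1, 1), "tip")
  trneg <- tr; trneg$edge.length[2] <- -0.1
  expect_error(mk_loglik(trneg, stats::setNames(c(1, 0, 1, 1, 0), tr$tip.label),
                         1, 1), "negative")
})

test_that("ML fitting recovers rates and flags boundary data", {
  tr <- simulate_tree(64, seed = 25)
  expect_warning(f1 <- mk_fit(tr, stats::setNames(rep(1, 64), tr$tip.label)),
                 "boundary")
  expect_lte(coef(f1)["q10"], 1e-8)
  expect_true(f1$boundary)

  sim <- simulate_binary_ogs(tr, 0.3, 1.0, 400, seed = 26)
  f2 <- mk_fit(tr, sim$table)
  expect_equal(unname(coef(f2)), c(0.3, 1.0), tolerance = 0.3)
  expect_s3_class(f2, "mk_fit")
  expect_equal(unname(as.numeric(logLik(f2))), f2$logLik)

  # k = 3 toy: fitted likelihood dominates the generating parameters
  st <- c("a", "b", "c")
  Q3 <- matrix(0.4, 3, 3, dimnames = list(st, st)); diag(Q3) <- -0.8
  tips <- simulate_repertoire_states(simulate_tree(30, 27), Q3, seed = 28)
  tr30 <- simulate_tree(30, 27)
  f3 <- mk_fit(tr30, tips, k = 3, state_labels = st, n_starts = 2)
  ll_true <- sum(ctmc_loglik(tr30, tips, Q3))
  expect_gte(f3$logLik, ll_true - 1e-6)
})

test_that("MCMC sampling honours its contract and recovers rates", {
  tr <- simulate_tree(64, seed = 29)
  sim <- simulate_binary_ogs(tr, 0.2, 2.0, 40, seed = 30)
  ch <- mk_mcmc(tr, sim$table, n_samples = 60, burn_in = 100, thin = 5,
                seed = 31)
  expect_equal(nrow(ch$samples), 60)
  ch2 <- mk_mcmc(tr, sim$table, n_samples = 60, burn_in = 100, thin = 5,
                 seed = 31)
  expect_identical(ch$samples, ch2$samples)
  med <- apply(ch$samples, 2, stats::median)
  expect_true(all(med > c(0.1, 1.0)) && all(med < c(0.4, 4.0)))
  expect_s3_class(ch, "mk_mcmc")
  expect_equal(dim(as.matrix(ch)), c(60L, 2L))
})

test_that("autocorrelation behaves like white noise on iid draws", {
  set.seed(32)
  z <- rnorm(5000)
  a <- mk_acf(z, 10)
  expect_equal(a[1], 1.0)
  expect_true(all(abs(a[-1]) < 0.05))
  expect_equal(mk_acf(rep(c(1, -1), 50), 1)[2], -1, tolerance = 1e-10)
  expect_error(mk_acf(rep(2, 50), 5), "constant")
  expect_error(mk_acf(rnorm(5), 10), "max_lag")
})

test_that("joint reconstruction is consistent and flags symmetric ties", {
  tr <- simulate_tree(16, seed = 33)
  ones <- stats::setNames(rep(1, 16), tr$tip.label)
  j <- mk_joint(tr, ones, 0.01, 0.01)
  expect_true(all(j$states == 1))

  t2 <- ape::read.tree(text = "(A:0.4,B:0.4)r;")
  jt <- mk_joint(t2, c(A = 0, B = 1), 1, 1)
  expect_true(jt$tie)

  # joint probability never exceeds the total likelihood
  for (i in 1:10) {
    trr <- random_tree(6, seed = 500 + i)
    set.seed(600 + i)
    x <- stats::setNames(sample(0:1, 6, TRUE), trr$tip.label)
    expect_lte(mk_joint(trr, x, 0.6, 0.9)$log_prob,
               mk_loglik(trr, x, 0.6, 0.9) + 1e-12)
  }
})

test_that("marginal posteriors sum to one and match enumeration", {
  tr <- simulate_tree(12, seed = 34)
  ones <- stats::setNames(rep(1, 12), tr$tip.label)
  post1 <- mk_marginal(tr, ones, 0.01, 0.01)
  expect_true(all(post1 > 0.99))

  for (i in 1:10) {
    trr <- random_tree(4, seed = 700 + i)
    set.seed(800 + i)
    x <- stats::setNames(sample(0:1, 4, TRUE), trr$tip.label)
    q01 <- runif(1, 0.2, 1.5); q10 <- runif(1, 0.2, 1.5)
    prior <- c(q10, q01) / (q01 + q10)
    oracle <- enum_ctmc(trr, x + 1L, 2, function(t) oracle_P2(q01, q10, t), prior)
    post <- mk_marginal(trr, x, q01, q10)
    expect_equal(post[colnames(oracle$marginals), 1],
                 oracle$marginals[2, ], tolerance = 1e-8)
  }
})

test_that("flat and numeric root priors are honoured", {
  tr <- random_tree(5, seed = 35)
  set.seed(36)
  x <- stats::setNames(sample(0:1, 5, TRUE), tr$tip.label)
  lf <- mk_loglik(tr, x, 0.3, 0.9, root_prior = "flat")
  ln <- mk_loglik(tr, x, 0.3, 0.9, root_prior = c(0.5, 0.5))
  expect_equal(lf, ln, tolerance = 1e-12)
  expect_error(mk_loglik(tr, x, 0.3, 0.9, root_prior = c(1, 2, 3)), "length-k")
})
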