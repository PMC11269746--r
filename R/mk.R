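# Mk (continuous-time Markov) machinery for discrete characters on a fixed
# rooted tree: Felsenstein pruning likelihood, ML fitting, random-walk
# Metropolis sampling of binary gain/loss rates, and joint (Pupko-style
# dynamic programming) and marginal (up/down message passing) ancestral
# reconstruction. The binary case uses closed-form transition probabilities;
# the k-state case uses a spectral decomposition of Q with a Pade fallback.

#' Binary Mk transition probability matrix
#'
#' Closed form for the two-state chain with gain rate `q01` (0 to 1) and loss
#' rate `q10` (1 to 0): rows are the "from" state (0, 1), columns "to".
#'
#' @param q01,q10 non-negative rates.
#' @param t branch length (>= 0).
#' @return 2 x 2 stochastic matrix.
#' @export
mk_transition <- function(q01, q10, t) {
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0")
  if (t < 0) stop("negative branch length")
  s <- q01 + q10
  if (s == 0 || t == 0) {
    e <- exp(-s * t)  # == 1 when s == 0 or t == 0
    return(matrix(c(1, 0, 0, 1), 2, 2))
  }
  pi1 <- q01 / s; pi0 <- q10 / s
  e <- exp(-s * t)
  matrix(c(pi0 + pi1 * e, pi0 - pi0 * e,
           pi1 - pi1 * e, pi1 + pi0 * e),
         2, 2, byrow = FALSE,
         dimnames = list(c("0", "1"), c("0", "1")))
  # column-major fill: [0->0, 1->0, 0->1, 1->1]
}

# validate a k-state rate matrix: square, non-negative off-diagonal,
# zero row sums
validate_rate_matrix <- function(Q, tol = 1e-8) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("rate matrix must be square")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  if (any(abs(rowSums(Q)) > tol * (1 + max(abs(Q)))))
    stop("rate matrix rows must sum to 0")
  invisible(Q)
}

#' k-state transition probability matrix exp(Q t)
#'
#' Spectral decomposition when `Q` is diagonalisable with well-conditioned
#' eigenvectors, otherwise a Pade approximation. Rows are renormalised to sum
#' to one exactly; small negative entries from roundoff are clipped to zero.
#'
#' @param Q k x k rate matrix (off-diagonal >= 0, zero row sums).
#' @param t branch length (>= 0).
#' @return k x k stochastic matrix.
#' @export
ctmc_transition <- function(Q, t) {
  validate_rate_matrix(Q)
  if (t < 0) stop("negative branch length")
  k <- nrow(Q)
  if (t == 0 || all(Q == 0)) return(diag(k))
  P <- NULL
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi) && kappa(eg$vectors) < 1e10) {
      P <- Re(eg$vectors %*% (exp(eg$values * t) * Vi))
    }
  }
  if (is.null(P)) P <- pracma::expm(Q * t)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Factory: decompose Q once, return a fast t -> exp(Qt) closure.
.ctmc_Pfun <- function(Q) {
  k <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(eg) && kappa(eg$vectors) < 1e10) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      V <- eg$vectors; ev <- eg$values
      return(function(t) {
        if (t == 0) return(diag(k))
        P <- Re(V %*% (exp(ev * t) * Vi))
        P[P < 0] <- 0
        P / rowSums(P)
      })
    }
  }
  function(t) ctmc_transition(Q, t)
}

# ---- shared engine -------------------------------------------------------

# Resolve tip states into an integer matrix (tips x m, values 1..k or NA),
# rows ordered as tree$tip.label. `tip_states` may be a named vector or a
# matrix with tip rownames; values may be 0-based integers (binary), 1..k
# integers, or labels matched against `labels`.
.as_state_matrix <- function(tree, tip_states, k, labels = NULL) {
  if (is.null(dim(tip_states))) {
    tip_states <- matrix(tip_states, ncol = 1,
                         dimnames = list(names(tip_states), NULL))
  }
  if (is.null(rownames(tip_states))) stop("tip states must be named by tip")
  unknown <- setdiff(rownames(tip_states), tree$tip.label)
  if (length(unknown)) stop("tip not in tree: ", paste(unknown, collapse = ", "))
  missing <- setdiff(tree$tip.label, rownames(tip_states))
  if (length(missing)) stop("no state for tip: ", paste(missing, collapse = ", "))
  S <- tip_states[tree$tip.label, , drop = FALSE]
  if (is.character(S) || !is.null(labels)) {
    if (is.null(labels)) stop("state labels required for character input")
    idx <- match(S, labels)
    if (any(is.na(idx) & !is.na(S))) stop("tip state outside the model alphabet")
    S <- matrix(idx, nrow(S), ncol(S), dimnames = dimnames(S))
  } else {
    S <- matrix(as.integer(S), nrow(S), ncol(S), dimnames = dimnames(S))
    if (k == 2 && all(S %in% c(0L, 1L, NA))) S <- S + 1L
    if (any(S < 1 | S > k, na.rm = TRUE)) stop("tip state outside 1..k")
  }
  S
}

# Precompute traversal structures shared by all passes.
.tree_prep <- function(tree) {
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  nn <- ape::Ntip(tree) + ape::Nnode(tree)
  elen <- numeric(nn)               # branch length above each node
  elen[edge[, 2]] <- tr$edge.length
  parents <- unique(edge[, 1])      # postorder over internal nodes
  children <- split(edge[, 2], factor(edge[, 1], levels = parents))
  list(ntip = ape::Ntip(tree), nn = nn, elen = elen,
       parents = parents, children = children, root = root_id(tree))
}

.colmax <- function(M) {
  out <- M[1, ]
  for (i in seq_len(nrow(M))[-1]) out <- pmax(out, M[i, ])
  out
}

.resolve_prior <- function(root_prior, Q = NULL, q01 = NULL, q10 = NULL, k = 2) {
  if (is.numeric(root_prior)) {
    if (length(root_prior) != k || any(root_prior < 0))
      stop("numeric root prior must be a length-k non-negative vector")
    return(root_prior / sum(root_prior))
  }
  root_prior <- match.arg(root_prior, c("stationary", "flat"))
  if (root_prior == "flat") return(rep(1 / k, k))
  if (!is.null(q01)) {
    s <- q01 + q10
    if (s == 0) return(c(0.5, 0.5))
    return(c(q10, q01) / s)
  }
  # stationary distribution of Q: left null vector
  ns <- tryCatch({
    ev <- eigen(t(Q))
    v <- Re(ev$vectors[, which.min(abs(ev$values))])
    abs(v) / sum(abs(v))
  }, error = function(e) rep(1 / k, k))
  ns
}

# Up-pass (sum-product). Pfun(t) -> k x k transition matrix.
# Returns partials (list of k x m), per-edge messages M (list of k x m),
# and the accumulated per-column log scale at the root.
.ctmc_up <- function(prep, S, k, Pfun, keep_messages = FALSE) {
  m <- ncol(S)
  partial <- vector("list", prep$nn)
  for (i in seq_len(prep$ntip)) {
    Lt <- matrix(0, k, m)
    s <- S[i, ]
    na <- is.na(s)
    Lt[, na] <- 1
    if (any(!na)) Lt[cbind(s[!na], which(!na))] <- 1
    partial[[i]] <- Lt
  }
  msg <- if (keep_messages) vector("list", prep$nn) else NULL
  logscale <- numeric(m)
  for (j in seq_along(prep$parents)) {
    p <- prep$parents[j]
    Lp <- matrix(1, k, m)
    for (ch in prep$children[[j]]) {
      Mc <- Pfun(prep$elen[ch]) %*% partial[[ch]]
      if (keep_messages) msg[[ch]] <- Mc
      Lp <- Lp * Mc
    }
    scl <- .colmax(Lp)
    bad <- scl == 0
    if (any(bad)) scl[bad] <- 1  # impossible column; loglik -> -Inf later
    Lp <- Lp / rep(scl, each = k)
    logscale <- logscale + log(scl)
    partial[[p]] <- Lp
  }
  list(partial = partial, msg = msg, logscale = logscale)
}

# Fast scalar up-pass for a single binary character: avoids all matrix
# allocation inside MCMC loops. `s_tip` is an integer vector over tips with
# values 1 (state 0), 2 (state 1) or NA.
.mk_loglik_m1 <- function(prep, s_tip, q01, q10, prior) {
  s <- q01 + q10
  elen <- prep$elen
  if (s == 0) {
    e <- rep(1, prep$nn)
  } else {
    e <- exp(-s * elen)
  }
  pi1 <- if (s == 0) 0.5 else q01 / s
  pi0 <- 1 - pi1
  # per-node transition entries for the branch above each node
  P00 <- pi0 + pi1 * e; P01 <- pi1 - pi1 * e
  P10 <- pi0 - pi0 * e; P11 <- pi1 + pi0 * e
  L0 <- numeric(prep$nn); L1 <- numeric(prep$nn)
  tipna <- is.na(s_tip)
  L0[seq_len(prep$ntip)] <- ifelse(tipna, 1, s_tip == 1L)
  L1[seq_len(prep$ntip)] <- ifelse(tipna, 1, s_tip == 2L)
  logscale <- 0
  parents <- prep$parents
  children <- prep$children
  for (j in seq_along(parents)) {
    p <- parents[j]
    a <- 1; b <- 1
    for (ch in children[[j]]) {
      a <- a * (P00[ch] * L0[ch] + P01[ch] * L1[ch])
      b <- b * (P10[ch] * L0[ch] + P11[ch] * L1[ch])
    }
    m <- max(a, b)
    if (m > 0 && (m < 1e-200 || m > 1e200)) {
      a <- a / m; b <- b / m
      logscale <- logscale + log(m)
    }
    L0[p] <- a; L1[p] <- b
  }
  lik <- prior[1] * L0[prep$root] + prior[2] * L1[prep$root]
  log(lik) + logscale
}

# Pruning log-likelihood for arbitrary k; S is tips x m of 1..k / NA.
.ctmc_loglik <- function(tree, S, k, Pfun, prior) {
  prep <- .tree_prep(tree)
  up <- .ctmc_up(prep, S, k, Pfun)
  lik <- colSums(prior * up$partial[[prep$root]])
  log(lik) + up$logscale
}

# Marginal posteriors: returns array (k, m, nn).
.ctmc_marginal <- function(tree, S, k, Pfun, prior) {
  prep <- .tree_prep(tree)
  m <- ncol(S)
  up <- .ctmc_up(prep, S, k, Pfun, keep_messages = TRUE)
  outward <- vector("list", prep$nn)
  outward[[prep$root]] <- matrix(prior, k, m)
  # walk internal nodes root-ward first (reverse postorder = preorder)
  for (j in rev(seq_along(prep$parents))) {
    p <- prep$parents[j]
    Op <- outward[[p]]
    kids <- prep$children[[j]]
    for (ch in kids) {
      G <- Op
      for (sib in setdiff(kids, ch)) G <- G * up$msg[[sib]]
      Oc <- crossprod(Pfun(prep$elen[ch]), G)  # t(P) %*% G
      scl <- .colmax(Oc)
      scl[scl == 0] <- 1
      outward[[ch]] <- Oc / rep(scl, each = k)
    }
  }
  post <- array(NA_real_, c(k, m, prep$nn))
  for (v in seq_len(prep$nn)) {
    num <- outward[[v]] * up$partial[[v]]
    tot <- colSums(num)
    tot[tot == 0] <- NA_real_
    post[, , v] <- num / rep(tot, each = k)
  }
  post
}

# Joint (max-product) reconstruction with back-pointers; ties at any argmax
# are broken toward the lowest state index and flagged per column.
.ctmc_joint <- function(tree, S, k, Pfun, prior, tie_tol = 1e-12) {
  prep <- .tree_prep(tree)
  m <- ncol(S)
  logC <- vector("list", prep$nn)
  for (i in seq_len(prep$ntip)) {
    Lt <- matrix(-Inf, k, m)
    s <- S[i, ]
    na <- is.na(s)
    Lt[, na] <- 0
    if (any(!na)) Lt[cbind(s[!na], which(!na))] <- 0
    logC[[i]] <- Lt
  }
  backptr <- vector("list", prep$nn)  # per node: k x m best own-state given parent state
  tie <- rep(FALSE, m)
  for (j in seq_along(prep$parents)) {
    p <- prep$parents[j]
    acc <- matrix(0, k, m)
    for (ch in prep$children[[j]]) {
      lP <- log(Pfun(prep$elen[ch]))
      best <- matrix(-Inf, k, m)
      arg <- matrix(1L, k, m)
      for (s in seq_len(k)) {
        cand <- lP[s, ] + logC[[ch]]          # k x m
        bs <- cand[1, ]; ai <- rep(1L, m)
        for (x in seq_len(k)[-1]) {
          better <- cand[x, ] > bs + tie_tol
          tied <- abs(cand[x, ] - bs) <= tie_tol & is.finite(bs)
          tie <- tie | tied
          ai[better] <- x
          bs[better] <- cand[x, better]
        }
        best[s, ] <- bs
        arg[s, ] <- ai
      }
      backptr[[ch]] <- arg
      acc <- acc + best
    }
    logC[[p]] <- acc
  }
  rootscore <- log(prior) + logC[[prep$root]]
  states <- matrix(NA_integer_, prep$nn, m)
  bs <- rootscore[1, ]; ai <- rep(1L, m)
  for (x in seq_len(k)[-1]) {
    better <- rootscore[x, ] > bs + tie_tol
    tied <- abs(rootscore[x, ] - bs) <= tie_tol & is.finite(bs)
    tie <- tie | tied
    ai[better] <- x
    bs[better] <- rootscore[x, better]
  }
  states[prep$root, ] <- ai
  log_prob <- bs
  # pre-order back-tracking: parents before children
  for (j in rev(seq_along(prep$parents))) {
    p <- prep$parents[j]
    for (ch in prep$children[[j]]) {
      sp <- states[p, ]
      states[ch, ] <- backptr[[ch]][cbind(sp, seq_len(m))]
    }
  }
  list(states = states, log_prob = log_prob, tie = tie)
}

# ---- binary interface ----------------------------------------------------

#' Pruning log-likelihood of binary presence/absence data
#'
#' Felsenstein pruning under the two-state Mk model. `tip_states` may be a
#' named 0/1 vector (one character) or a tips x m matrix (m independent
#' characters, e.g. ortholog groups); `NA` means missing (all states
#' possible).
#'
#' @param tree a named [ape::phylo] tree.
#' @param tip_states named 0/1 vector or matrix with tip rownames.
#' @param q01,q10 gain and loss rates.
#' @param root_prior `"stationary"` (default), `"flat"`, or a numeric
#'   length-2 probability vector over states (0, 1).
#' @return numeric vector of per-character log-likelihoods (scalar for vector
#'   input).
#' @export
mk_loglik <- function(tree, tip_states, q01, q10, root_prior = "stationary") {
  if (q01 < 0 || q10 < 0) stop("rates must be >= 0")
  scalar <- is.null(dim(tip_states))
  S <- .as_state_matrix(tree, tip_states, 2L)
  prior <- .resolve_prior(root_prior, q01 = q01, q10 = q10, k = 2)
  ll <- .ctmc_loglik(tree, S, 2L, function(t) mk_transition(q01, q10, t), prior)
  if (scalar) ll[[1]] else ll
}

#' k-state pruning log-likelihood
#'
#' @param tree a named [ape::phylo] tree.
#' @param tip_states named vector/matrix of states; integers `1..k` or labels
#'   matching `rownames(Q)`; `NA` = missing.
#' @param Q k x k rate matrix.
#' @param root_prior `"stationary"`, `"flat"`, or numeric length-k vector.
#' @return per-character log-likelihood vector.
#' @export
ctmc_loglik <- function(tree, tip_states, Q, root_prior = "stationary") {
  validate_rate_matrix(Q)
  k <- nrow(Q)
  scalar <- is.null(dim(tip_states))
  S <- .as_state_matrix(tree, tip_states, k, labels = rownames(Q))
  prior <- .resolve_prior(root_prior, Q = Q, k = k)
  ll <- .ctmc_loglik(tree, S, k, .ctmc_Pfun(Q), prior)
  if (scalar) ll[[1]] else ll
}

#' Fit Mk model rates by maximum likelihood
#'
#' Binary (`k = 2`): gain/loss rates `q01`, `q10` maximising the pooled
#' pruning log-likelihood over all columns of `tip_states`. General `k`:
#' all `k(k-1)` off-diagonal rates, optimised from several starts (uniform
#' `1/(k(k-1))`, a transition-count heuristic, and random restarts) because
#' many-parameter Mk likelihoods are multimodal. Optimisation works on log
#' rates with the box constraint rate >= 1e-10.
#'
#' @param tree a named [ape::phylo] tree.
#' @param tip_states named vector or tips x m matrix of states.
#' @param k number of states (default 2).
#' @param root_prior see [mk_loglik()].
#' @param n_starts optimiser starts for `k > 2`.
#' @param state_labels optional state labels (required for character input
#'   when `k > 2`).
#' @return object of class `mk_fit` with components `rates` (named vector
#'   `q01`, `q10`) or `Q`, `logLik`, `boundary` (logical: data carried fewer
#'   than two observed states so the MLE sits on the rate floor), and
#'   `convergence`.
#' @export
mk_fit <- function(tree, tip_states, k = 2, root_prior = "stationary",
                   n_starts = 3, state_labels = NULL) {
  lower <- log(1e-10); upper <- log(1e4)
  if (k == 2) {
    S <- .as_state_matrix(tree, tip_states, 2L)
    boundary <- length(unique(stats::na.omit(as.vector(S)))) < 2
    if (boundary)
      warning("fewer than two observed tip states; boundary MLE returned")
    prep <- .tree_prep(tree)
    nll <- if (ncol(S) == 1) {
      s_tip <- S[, 1]
      function(lx) {
        q <- exp(lx)
        prior <- .resolve_prior(root_prior, q01 = q[1], q10 = q[2], k = 2)
        -.mk_loglik_m1(prep, s_tip, q[1], q[2], prior)
      }
    } else {
      function(lx) {
        q <- exp(lx)
        prior <- .resolve_prior(root_prior, q01 = q[1], q10 = q[2], k = 2)
        up <- .ctmc_up(prep, S, 2L, function(t) mk_transition(q[1], q[2], t))
        -sum(log(colSums(prior * up$partial[[prep$root]])) + up$logscale)
      }
    }
    starts <- list(log(c(0.5, 0.5)), log(c(0.1, 1)), log(c(1, 0.1)))
    best <- NULL
    for (st in starts[seq_len(max(1, n_starts))] ) {
      o <- tryCatch(stats::optim(st, nll, method = "L-BFGS-B",
                                 lower = lower, upper = upper),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("convergence-failure: binary Mk optimisation failed")
    # snap near-flat rates to the box floor (boundary MLEs such as "no loss
    # ever observed" leave the profile flat below some small rate)
    for (j in 1:2) {
      cand <- best$par
      cand[j] <- lower
      if (nll(cand) <= best$value + 1e-9) {
        best$par <- cand
        best$value <- min(best$value, nll(cand))
      }
    }
    rates <- stats::setNames(exp(best$par), c("q01", "q10"))
    out <- list(rates = rates, k = 2L, logLik = -best$value,
                boundary = boundary, convergence = best$convergence,
                n_char = ncol(S))
  } else {
    S <- .as_state_matrix(tree, tip_states, k, labels = state_labels)
    np <- k * (k - 1)
    off_idx <- which(row(diag(k)) != col(diag(k)))
    build_Q <- function(q) {
      Q <- matrix(0, k, k)
      Q[off_idx] <- q
      diag(Q) <- -rowSums(Q)
      Q
    }
    nll <- function(lx) {
      Q <- build_Q(exp(lx))
      prior <- .resolve_prior(root_prior, Q = Q, k = k)
      ll <- tryCatch(.ctmc_loglik(tree, S, k,
                                  .ctmc_Pfun(Q), prior),
                     error = function(e) -Inf)
      v <- -sum(ll)
      if (!is.finite(v)) 1e10 else v
    }
    # transition-count heuristic: observed tip-state frequencies
    freq <- tabulate(S[!is.na(S)], k) + 1
    heur <- rep(freq / sum(freq), times = k)[seq_len(np)]
    starts <- list(rep(log(1 / np), np), log(pmax(heur, 1e-6)))
    while (length(starts) < n_starts)
      starts[[length(starts) + 1]] <- log(1 / np) + stats::rnorm(np, 0, 1)
    best <- NULL
    for (st in starts) {
      o <- tryCatch(stats::optim(st, nll, method = "L-BFGS-B",
                                 lower = lower, upper = upper,
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("convergence-failure: k-state Mk optimisation failed")
    Q <- build_Q(exp(best$par))
    labs <- state_labels
    if (is.null(labs)) labs <- as.character(seq_len(k))
    dimnames(Q) <- list(labs, labs)
    out <- list(Q = Q, k = as.integer(k), logLik = -best$value,
                boundary = FALSE, convergence = best$convergence,
                n_char = ncol(S))
  }
  class(out) <- "mk_fit"
  out
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk model fit (k = %d, %d character%s)\n", x$k, x$n_char,
              if (x$n_char == 1) "" else "s"))
  if (x$k == 2) {
    cat(sprintf("  q01 (gain) = %.6g   q10 (loss) = %.6g\n",
                x$rates[1], x$rates[2]))
  } else {
    cat("  rate matrix Q:\n")
    print(signif(x$Q, 4))
  }
  cat(sprintf("  log-likelihood = %.4f\n", x$logLik))
  if (x$boundary) cat("  note: boundary MLE (uninformative data)\n")
  invisible(x)
}

#' @export
coef.mk_fit <- function(object, ...) {
  if (object$k == 2) object$rates else object$Q
}

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$logLik, df = if (object$k == 2) 2 else object$k * (object$k - 1),
            class = "logLik")
}

#' Sample binary Mk rates by random-walk Metropolis MCMC
#'
#' The chain starts at the maximum-likelihood estimate, proposes joint
#' Gaussian steps on log rates, and uses independent exponential priors with
#' mean twice the ML estimate for each rate. After `burn_in` iterations the
#' chain is thinned every `thin` iterations until `n_samples` samples are
#' collected.
#'
#' @param tree a named [ape::phylo] tree.
#' @param tip_states named 0/1 vector or tips x m matrix (columns pooled).
#' @param n_samples samples returned (default 500).
#' @param burn_in iterations discarded (default 500).
#' @param thin sampling interval (default 10).
#' @param seed integer seed; chains are deterministic given the seed.
#' @param proposal_sd standard deviation of the log-rate random walk.
#' @param prior_mean optional length-2 prior means (gain, loss); default
#'   `2 * pmax(MLE, 1e-8)`.
#' @param root_prior see [mk_loglik()].
#' @return object of class `mk_mcmc`: `samples` (n_samples x 2 matrix with
#'   columns `q01`, `q10`), `acceptance`, `mle`, and the settings.
#' @export
mk_mcmc <- function(tree, tip_states, n_samples = 500, burn_in = 500,
                    thin = 10, seed = 1L, proposal_sd = 0.5,
                    prior_mean = NULL, root_prior = "stationary") {
  S <- .as_state_matrix(tree, tip_states, 2L)
  fit <- suppressWarnings(mk_fit(tree, S, k = 2, root_prior = root_prior))
  mle <- pmax(fit$rates, 1e-10)
  if (is.null(prior_mean)) prior_mean <- 2 * pmax(mle, 1e-8)
  prep <- .tree_prep(tree)
  if (ncol(S) == 1) {
    s_tip <- S[, 1]
    ll <- function(q) {
      prior <- .resolve_prior(root_prior, q01 = q[1], q10 = q[2], k = 2)
      .mk_loglik_m1(prep, s_tip, q[1], q[2], prior)
    }
  } else {
    ll <- function(q) {
      prior <- .resolve_prior(root_prior, q01 = q[1], q10 = q[2], k = 2)
      up <- .ctmc_up(prep, S, 2L, function(t) mk_transition(q[1], q[2], t))
      sum(log(colSums(prior * up$partial[[prep$root]])) + up$logscale)
    }
  }
  lpost <- function(lx) {
    q <- exp(lx)
    ll(q) + sum(stats::dexp(q, rate = 1 / prior_mean, log = TRUE)) + sum(lx)
  }
  set.seed(seed)
  x <- log(mle)
  lp <- lpost(x)
  n_iter <- burn_in + n_samples * thin
  samples <- matrix(NA_real_, n_samples, 2,
                    dimnames = list(NULL, c("q01", "q10")))
  acc <- 0L; got <- 0L
  for (it in seq_len(n_iter)) {
    prop <- x + stats::rnorm(2, 0, proposal_sd)
    lp2 <- lpost(prop)
    if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
      x <- prop; lp <- lp2; acc <- acc + 1L
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      got <- got + 1L
      samples[got, ] <- exp(x)
    }
  }
  if (acc == 0L) stop("sampler-failure: zero acceptance over the full run")
  structure(list(samples = samples, acceptance = acc / n_iter, mle = mle,
                 burn_in = burn_in, thin = thin, seed = seed,
                 proposal_sd = proposal_sd, prior_mean = prior_mean),
            class = "mk_mcmc")
}

#' @export
print.mk_mcmc <- function(x, ...) {
  cat(sprintf("Mk MCMC: %d samples (burn-in %d, thin %d), acceptance %.2f\n",
              nrow(x$samples), x$burn_in, x$thin, x$acceptance))
  print(apply(x$samples, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  invisible(x)
}

#' @export
summary.mk_mcmc <- function(object, ...) {
  s <- object$samples
  data.frame(rate = colnames(s),
             mean = colMeans(s),
             median = apply(s, 2, stats::median),
             q2.5 = apply(s, 2, stats::quantile, 0.025),
             q97.5 = apply(s, 2, stats::quantile, 0.975),
             row.names = NULL)
}

#' @export
as.matrix.mk_mcmc <- function(x, ...) x$samples

#' Autocorrelation of an MCMC chain
#'
#' @param samples numeric vector, or an `mk_mcmc` object (uses `q01` unless
#'   `which` says otherwise).
#' @param max_lag maximum lag; needs at least `max_lag + 2` samples.
#' @param which column name for `mk_mcmc` input.
#' @return numeric vector of autocorrelations at lags `0..max_lag` (lag 0 is
#'   exactly 1).
#' @export
mk_acf <- function(samples, max_lag, which = "q01") {
  if (inherits(samples, "mk_mcmc")) samples <- samples$samples[, which]
  samples <- as.numeric(samples)
  if (length(samples) < max_lag + 2) stop("need at least max_lag + 2 samples")
  if (stats::var(samples) == 0) stop("undefined-variance: constant chain")
  n <- length(samples)
  vapply(0:max_lag, function(k) {
    if (k == 0) return(1)
    stats::cor(samples[seq_len(n - k)], samples[k + seq_len(n - k)])
  }, 0)
}

#' Joint (most-probable-path) ancestral reconstruction
#'
#' Pupko-style dynamic programming: an up-pass computes, for every node and
#' every possible parent state, the best state of the node; back-tracking
#' from the root returns the single assignment of states to all nodes with
#' maximal joint probability. Ties are broken toward the lowest state index
#' and flagged.
#'
#' @inheritParams mk_loglik
#' @return object of class `mk_joint`: `states` (all-nodes x m 0/1 matrix
#'   with node rownames), `log_prob` (per-character joint log-probability),
#'   `tie` (per-character logical).
#' @export
mk_joint <- function(tree, tip_states, q01, q10, root_prior = "stationary") {
  S <- .as_state_matrix(tree, tip_states, 2L)
  prior <- .resolve_prior(root_prior, q01 = q01, q10 = q10, k = 2)
  res <- .ctmc_joint(tree, S, 2L, function(t) mk_transition(q01, q10, t), prior)
  states <- res$states - 1L
  dimnames(states) <- list(all_node_names(tree), colnames(S))
  structure(list(states = states, log_prob = res$log_prob, tie = res$tie),
            class = "mk_joint")
}

#' @export
print.mk_joint <- function(x, ...) {
  cat(sprintf("Joint Mk reconstruction: %d node(s) x %d character(s)\n",
              nrow(x$states), ncol(x$states)))
  cat(sprintf("  joint log-probability: %s\n",
              paste(signif(utils::head(x$log_prob, 5), 6), collapse = ", ")))
  if (any(x$tie)) cat(sprintf("  %d character(s) had tied optima\n", sum(x$tie)))
  invisible(x)
}

#' k-state joint ancestral reconstruction
#'
#' @inheritParams ctmc_loglik
#' @return as [mk_joint()], with `states` holding 1..k indices (or labels if
#'   `Q` has rownames).
#' @export
ctmc_joint <- function(tree, tip_states, Q, root_prior = "stationary") {
  validate_rate_matrix(Q)
  k <- nrow(Q)
  S <- .as_state_matrix(tree, tip_states, k, labels = rownames(Q))
  prior <- .resolve_prior(root_prior, Q = Q, k = k)
  res <- .ctmc_joint(tree, S, k, .ctmc_Pfun(Q), prior)
  dimnames(res$states) <- list(all_node_names(tree), colnames(S))
  structure(list(states = res$states, log_prob = res$log_prob, tie = res$tie),
            class = "mk_joint")
}

#' Marginal ancestral state posteriors
#'
#' Up/down message passing: for every node the posterior probability of each
#' state given all tip data, integrating over all other nodes.
#'
#' @inheritParams mk_loglik
#' @return all-nodes x m matrix of posterior probabilities of state 1, with
#'   node rownames.
#' @export
mk_marginal <- function(tree, tip_states, q01, q10, root_prior = "stationary") {
  S <- .as_state_matrix(tree, tip_states, 2L)
  prior <- .resolve_prior(root_prior, q01 = q01, q10 = q10, k = 2)
  post <- .ctmc_marginal(tree, S, 2L, function(t) mk_transition(q01, q10, t), prior)
  out <- t(post[2, , , drop = TRUE])
  if (ncol(S) == 1) out <- matrix(post[2, 1, ], ncol = 1)
  dimnames(out) <- list(all_node_names(tree), colnames(S))
  out
}

#' k-state marginal ancestral posteriors
#'
#' @inheritParams ctmc_loglik
#' @return array of dimension (k, m, n_nodes): per-state posterior for every
#'   character (column) and node; node order is tips then internal nodes as
#'   in [all_node_names()].
#' @export
ctmc_marginal <- function(tree, tip_states, Q, root_prior = "stationary") {
  validate_rate_matrix(Q)
  k <- nrow(Q)
  S <- .as_state_matrix(tree, tip_states, k, labels = rownames(Q))
  prior <- .resolve_prior(root_prior, Q = Q, k = k)
  post <- .ctmc_marginal(tree, S, k, .ctmc_Pfun(Q), prior)
  dimnames(post) <- list(rownames(Q), colnames(S), all_node_names(tree))
  post
}
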