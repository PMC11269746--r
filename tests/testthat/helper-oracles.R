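# Independent brute-force oracles: enumerate every assignment of states to
# internal nodes and reduce by summation (likelihood / marginals) or
# maximisation (joint reconstruction). Transition matrices are built from
# closed forms derived independently of the package's implementations.

# 2-state transition matrix via spectral decomposition of the rate matrix:
# eigenvalues 0 and -(a+b) with stationary vector (b, a) / (a + b)
oracle_P2 <- function(q01, q10, t) {
  s <- q01 + q10
  if (s == 0) return(diag(2))
  U <- matrix(c(1, 1, q01, -q10), 2, 2)        # right eigenvectors
  D <- diag(c(1, exp(-s * t)))
  U %*% D %*% solve(U)
}

# 20-state equal-rates transition matrix via the jump-chain closed form:
# P(same) = 1/20 + (19/20) exp(-20 t / 19) at one expected jump per unit time
oracle_P20 <- function(t) {
  e <- exp(-20 * t / 19)
  P <- matrix((1 - e) / 20, 20, 20)
  diag(P) <- diag(P) + e
  P
}

# Enumerate all internal-node assignments for a k-state model.
# tip_states: named integer vector (1..k) over the tree's tips.
# Pfun(t): transition matrix. prior: length-k root prior.
# Returns loglik, the maximal joint log-probability, the argmax assignment
# (internal node states, named), and per-node marginal posteriors.
enum_ctmc <- function(tree, tip_states, k, Pfun, prior) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  labs <- c(tree$tip.label, tree$node.label)
  G <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  state_at <- function(id, asn) {
    if (id <= ntip) rep(tip_states[[labs[id]]], nrow(asn))
    else asn[, id - ntip]
  }
  prob <- prior[G[, 1]]                         # root is node ntip + 1
  for (e in seq_len(nrow(tree$edge))) {
    P <- Pfun(tree$edge.length[e])
    prob <- prob * P[cbind(state_at(tree$edge[e, 1], G),
                           state_at(tree$edge[e, 2], G))]
  }
  best <- which.max(prob)
  marg <- sapply(seq_len(nnode), function(j)
    tapply(prob, factor(G[, j], levels = seq_len(k)), sum))
  marg[is.na(marg)] <- 0
  marg <- sweep(marg, 2, colSums(marg), "/")
  colnames(marg) <- labs[ntip + seq_len(nnode)]
  list(loglik = log(sum(prob)),
       max_logprob = log(prob[best]),
       argmax = stats::setNames(G[best, ], labs[ntip + seq_len(nnode)]),
       marginals = marg)
}

# random named rooted tree with n tips and uniform branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1.5)
  name_nodes(tr)
}
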