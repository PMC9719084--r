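# Independent oracles: everything here re-derives means, covariances and
# densities by explicit path enumeration and solve()/det(), deliberately
# avoiding the package's chol/profile code paths.

# multivariate normal log-density via solve() and determinant()
naive_dmvnorm <- function(x, mean, V) {
  n <- length(x)
  r <- x - mean
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + as.numeric(t(r) %*% solve(V, r)))
}

# for each tip: the root-to-tip sequence of edge indices
naive_paths <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  edge_of <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  lapply(seq_len(ntip), function(i) {
    path <- integer(0); v <- i
    while (v != root) { path <- c(edge_of[v], path); v <- parent[v] }
    path
  })
}

# BM covariance by shared-edge enumeration
naive_bm_cov <- function(tree) {
  paths <- naive_paths(tree)
  n <- length(paths)
  M <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    M[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  }
  M
}

# per-regime shared-path covariance used by the two-rate BM model
naive_bmm_cov <- function(tree, edge_states, rates) {
  paths <- naive_paths(tree)
  n <- length(paths)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    M[i, j] <- sum(tree$edge.length[shared] * rates[edge_states[shared]])
  }
  M
}

# OU covariance from MRCA depths obtained by shared-path sums
naive_ou_cov <- function(tree, alpha, sigma2) {
  s <- naive_bm_cov(tree)
  depths <- diag(s)
  n <- nrow(s)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- depths[i] + depths[j] - 2 * s[i, j]
    V[i, j] <- sigma2 / (2 * alpha) * exp(-alpha * d) * (1 - exp(-2 * alpha * s[i, j]))
  }
  V
}

# Hansen-model tip means by explicit per-segment integration
naive_oum_mean <- function(tree, edge_states, root_state, alpha, theta) {
  paths <- naive_paths(tree)
  depths <- ape::node.depth.edgelength(tree)
  T <- max(depths[seq_len(ape::Ntip(tree))])
  vapply(paths, function(path) {
    m <- theta[[root_state]] * exp(-alpha * T)
    for (e in path) {
      tb <- depths[tree$edge[e, 1]]; te <- depths[tree$edge[e, 2]]
      w <- exp(-alpha * (T - te)) - exp(-alpha * (T - tb))
      m <- m + theta[[edge_states[e]]] * w
    }
    m
  }, numeric(1))
}

# shifted-OU tip means: base optimum plus per-shift offsets effective from
# the parent end of each shifted edge
naive_shift_mean <- function(tree, edges, alpha, theta0, delta) {
  paths <- naive_paths(tree)
  depths <- ape::node.depth.edgelength(tree)
  T <- max(depths[seq_len(ape::Ntip(tree))])
  vapply(paths, function(path) {
    m <- theta0
    for (j in seq_along(edges)) {
      if (edges[j] %in% path) {
        te <- depths[tree$edge[edges[j], 1]]
        m <- m + delta[j] * (1 - exp(-alpha * (T - te)))
      }
    }
    m
  }, numeric(1))
}

# exhaustive Fitch parsimony score: minimize state changes over all internal
# assignments (trees up to ~6 tips)
fitch_score_brute <- function(tree, tip_states) {
  ntip <- ape::Ntip(tree)
  states <- sort(unique(tip_states))
  nint <- tree$Nnode
  assign_ids <- rep(list(seq_along(states)), nint)
  grid <- do.call(expand.grid, assign_ids)
  best <- Inf
  tipv <- match(tip_states[tree$tip.label], states)
  for (r in seq_len(nrow(grid))) {
    nodev <- c(tipv, as.integer(grid[r, ]))
    ch <- sum(nodev[tree$edge[, 1]] != nodev[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# equal-branch-length star tree
star_tree <- function(n, len = 1) {
  ape::read.tree(text = paste0(
    "(", paste0("t", seq_len(n), ":", len, collapse = ","), ");"))
}

# small random ultrametric unit-depth tree (package generator; the oracle
# independence lives in the likelihood assembly, not the tree source)
small_tree <- function(n, seed) simulate_tree(n, seed = seed)
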