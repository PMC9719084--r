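# Blomberg's K and its permutation null.
#
# K compares the observed ratio MSE0/MSE (trait variance about the
# phylogenetically corrected mean over the phylogenetically corrected mean
# squared error) with its Brownian-motion expectation; K = 1 under BM, K -> 0
# when trait similarity is unrelated to the phylogeny.

# Shared plumbing: inverse-covariance solves reused by the permutation test.
.k_setup <- function(tree, trait) {
  validate_phylo(tree)
  n <- ape::Ntip(tree)
  if (n < 3L) stop("Blomberg's K needs at least 3 tips")
  if (is.null(names(trait))) stop("trait must be a named vector (names = tip labels)")
  extra <- setdiff(names(trait), tree$tip.label)
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(extra) || length(miss)) {
    stop("trait/tip label mismatch; missing from trait: {",
         paste(miss, collapse = ", "), "}, absent from tree: {",
         paste(extra, collapse = ", "), "}")
  }
  x <- as.numeric(trait[tree$tip.label])
  if (stats::var(x) == 0) stop("zero variance: trait is constant across tips")
  C <- phylo_vcv(tree)
  if (kappa(C, exact = FALSE) > 1e12) {
    stop("phylogenetic covariance matrix is numerically singular ",
         "(condition estimate > 1e12)")
  }
  R <- chol(C)
  Cinv <- chol2inv(R)
  s11 <- sum(Cinv)                       # 1' C^-1 1
  expected <- (sum(diag(C)) - n / s11) / (n - 1)
  list(x = x, n = n, Cinv = Cinv, s11 = s11, expected = expected,
       cinv_rowsum = rowSums(Cinv))
}

# vectorized K for columns of X (n x B), given the setup
.k_stat <- function(setup, X) {
  n <- setup$n
  a <- as.numeric(crossprod(setup$cinv_rowsum, X)) / setup$s11  # GLS mean per col
  centered <- sweep(X, 2L, a)
  mse0 <- colSums(centered^2) / (n - 1)
  # (x-a1)' Cinv (x-a1) = x'Cinv x - a^2 * s11
  mse <- (colSums(X * (setup$Cinv %*% X)) - a^2 * setup$s11) / (n - 1)
  (mse0 / mse) / setup$expected
}

#' Blomberg's K statistic for phylogenetic signal
#'
#' With `C = phylo_vcv(tree)` and phylogenetic (GLS) mean
#' `a = (1'C^-1 x) / (1'C^-1 1)`:
#' `MSE0 = (x - a)'(x - a)/(n-1)`, `MSE = (x - a)' C^-1 (x - a)/(n-1)`,
#' expected ratio `= (tr(C) - n/(1'C^-1 1))/(n-1)`, and
#' `K = (MSE0/MSE) / expected ratio`. K is invariant to affine transformations
#' of the trait, equals 1 exactly on an equal-branch-length star tree, and is 1
#' in expectation under Brownian motion.
#'
#' @param tree A `phylo` object (any tree with positive branch lengths).
#' @param trait Named numeric vector; names must exactly match the tip labels.
#' @return A list with `K`, `observed_ratio` (MSE0/MSE), `expected_ratio`,
#'   and `n`.
#' @export
blomberg_k <- function(tree, trait) {
  s <- .k_setup(tree, trait)
  K <- .k_stat(s, matrix(s$x, ncol = 1L))
  obs <- K * s$expected
  list(K = as.numeric(K), observed_ratio = as.numeric(obs),
       expected_ratio = s$expected, n = s$n)
}

#' Randomization test for Blomberg's K
#'
#' Permutes trait values across tips to emulate the null of no phylogenetic
#' signal (trait values randomly distributed over the tree) and reports the
#' add-one permutation p-value `p = (1 + #\{K_perm >= K_obs\}) / (n_perm + 1)`
#' (ties count as extreme, so p is never exactly zero and never below
#' `1/(n_perm + 1)`).
#'
#' @inheritParams blomberg_k
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed; permutations are deterministic given it.
#' @return An object of class `signal_result`: list with `K`, `p_value`,
#'   `n_perm`, `observed_ratio`, `expected_ratio`, `n`.
#' @export
k_permutation_test <- function(tree, trait, n_perm = 999L, seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  s <- .k_setup(tree, trait)
  k_obs <- as.numeric(.k_stat(s, matrix(s$x, ncol = 1L)))
  if (!is.null(seed)) set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) s$x[sample.int(s$n)], numeric(s$n))
  k_perm <- .k_stat(s, P)
  p <- (1 + sum(k_perm >= k_obs - 1e-12)) / (n_perm + 1)
  structure(
    list(K = k_obs, p_value = p, n_perm = as.integer(n_perm),
         observed_ratio = k_obs * s$expected, expected_ratio = s$expected,
         n = s$n),
    class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f  (n = %d)\n", x$K, x$n))
  cat(sprintf("  permutation p = %.4g  (%d permutations)\n", x$p_value, x$n_perm))
  invisible(x)
}
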