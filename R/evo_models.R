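# Maximum-likelihood fits of the five candidate trait-evolution models:
# BM (single rate), BMM (separate herbaceous/woody rates), Pagel's delta,
# OU1 (single optimum), OUM (regime-specific optima), compared by AICc.
#
# All models are Gaussian: x ~ MVN(mean, sigma2 * V(pars)) with the mean
# profiled by GLS and sigma2 profiled analytically, so only the shape
# parameter (rate ratio, delta, or alpha) is searched numerically.

# GLS with analytic sigma2 profile. V is the unit-scale covariance structure,
# X the mean design. Returns the profiled ML log-likelihood.
.gls_profile <- function(x, V, X) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) stop("covariance matrix is not positive definite")
  z <- backsolve(R, x, transpose = TRUE)
  Zx <- backsolve(R, X, transpose = TRUE)
  qrX <- qr(Zx)
  if (qrX$rank < ncol(X)) stop("rank-deficient design: unidentifiable configuration")
  beta <- qr.coef(qrX, z)
  resid <- z - Zx %*% beta
  Q <- sum(resid^2)
  n <- length(x)
  # floor for degenerate perfect fits (e.g. a trait regressed on itself)
  sigma2 <- max(Q / n, .Machine$double.eps^2)
  logdet <- 2 * sum(log(diag(R)))
  loglik <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(beta = as.numeric(beta), sigma2 = sigma2, loglik = loglik,
       logdet = logdet, R = R, qr = qrX)
}

.align_trait <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait must be a named vector")
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss)) stop("trait missing for tips: ", paste(miss, collapse = ", "))
  x <- as.numeric(trait[tree$tip.label])
  if (stats::var(x) == 0) stop("zero variance: trait is constant across tips")
  x
}

new_model_fit <- function(model, loglik, params, k, n,
                          convergence = TRUE, boundary = FALSE, extra = list()) {
  structure(
    c(list(model = model, loglik = loglik, params = params, k = k, n = n,
           aicc = if (n > k + 1) aicc(loglik, k, n) else NA_real_,
           convergence = convergence,
           boundary = boundary), extra),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit:  lnL = %.4f,  k = %d,  n = %d,  AICc = %.4f\n",
              x$model, x$loglik, x$k, x$n, x$aicc))
  p <- unlist(x$params)
  cat("  ", paste(sprintf("%s = %.6g", names(p), p), collapse = ",  "), "\n")
  if (x$boundary) cat("  (warning: estimate at parameter bound)\n")
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik Log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit single-rate Brownian motion by maximum likelihood
#'
#' The neutral drift model: `x ~ MVN(z0 * 1, sigma2 * C)` with
#' `C = phylo_vcv(tree)`. Both the root state `z0` (GLS mean) and the rate
#' `sigma2` have closed-form ML estimates; k = 2.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param trait Named numeric vector over the tips.
#' @return A `model_fit` object with parameters `sigma2` and `z0`.
#' @export
fit_bm <- function(tree, trait) {
  x <- .align_trait(tree, trait)
  C <- phylo_vcv(tree)
  g <- .gls_profile(x, C, matrix(1, length(x), 1L))
  new_model_fit("BM", g$loglik, list(sigma2 = g$sigma2, z0 = g$beta[1]),
                k = 2L, n = length(x))
}

#' Fit two-rate Brownian motion (BMM)
#'
#' Brownian motion with a separate rate on each of two branch regimes (e.g.
#' herbaceous vs woody): covariance `sigma2_1 * C_1 + sigma2_2 * C_2`, where
#' `C_r(i,j)` is the shared root-to-MRCA path length spent in regime r. The
#' rate ratio is found by bounded 1-D search with the overall scale and mean
#' profiled analytically; k = 3. The single-rate model is nested at ratio 1,
#' which is always evaluated, so `lnL(BMM) >= lnL(BM)` holds exactly.
#'
#' @inheritParams fit_bm
#' @param painting A two-regime [paint_regimes()] object on the same tree.
#' @return A `model_fit`; `params$sigma2` is a named vector with one rate per
#'   regime (sorted regime labels), plus `z0`.
#' @export
fit_bmm <- function(tree, trait, painting) {
  x <- .align_trait(tree, trait)
  if (length(painting$levels) == 1L) {
    stop("painting has a single regime; use fit_bm for a one-rate model")
  }
  if (length(painting$levels) != 2L) stop("fit_bmm requires exactly 2 regimes")
  Cr <- .regime_vcv(tree, painting)
  C1 <- Cr[[1]]; C2 <- Cr[[2]]
  tl1 <- sum(tree$edge.length[painting$edge_states == painting$levels[1]])
  tl2 <- sum(tree$edge.length[painting$edge_states == painting$levels[2]])
  if (tl1 <= 0 || tl2 <= 0) stop("each regime must occupy positive total branch length")
  X <- matrix(1, length(x), 1L)
  obj <- function(logr) .gls_profile(x, C1 + exp(logr) * C2, X)$loglik
  opt <- stats::optimize(obj, interval = c(-15, 15), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0)           # ratio 1 recovers single-rate BM exactly
  ll <- vapply(cand, obj, numeric(1))
  best <- which.max(ll)
  logr <- cand[best]
  g <- .gls_profile(x, C1 + exp(logr) * C2, X)
  rates <- stats::setNames(c(g$sigma2, g$sigma2 * exp(logr)), painting$levels)
  new_model_fit("BMM", g$loglik, list(sigma2 = rates, z0 = g$beta[1]),
                k = 3L, n = length(x),
                boundary = abs(logr) >= 15 - 1e-6,
                extra = list(regimes = painting$levels))
}

#' Pagel's delta transformation of a unit-depth covariance matrix
#'
#' On a unit-depth ultrametric tree, raising node depths to the power delta is
#' an elementwise power of the BM covariance matrix: `C'(i,j) = C(i,j)^delta`.
#' delta > 1 concentrates trait change toward the present (niche shifting);
#' delta < 1 is an early burst; delta = 1 leaves C unchanged.
#'
#' @param C Covariance matrix of a unit-depth ultrametric tree (unit diagonal).
#' @param delta Positive exponent.
#' @return The transformed matrix.
#' @export
delta_transform <- function(C, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("delta must be a single positive number")
  }
  if (max(abs(diag(C) - 1)) > 1e-6) {
    stop("delta_transform requires a unit-depth tree (unit diagonal)")
  }
  C^delta
}

#' Pagel's lambda transformation of a covariance matrix
#'
#' Multiplies off-diagonal entries by `lambda` in `[0, 1]`, leaving the
#' diagonal unchanged; lambda = 1 is the identity, lambda = 0 removes all
#' phylogenetic covariance.
#'
#' @param C Covariance matrix.
#' @param lambda Value in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
    stop("lambda must be a single number in [0, 1]")
  }
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Fit Pagel's delta model by maximum likelihood
#'
#' BM on a delta-power-transformed unit-depth tree. delta is found by bounded
#' 1-D search on the log scale with the mean and rate profiled; k = 3. A
#' likelihood-ratio test against the BM null (delta = 1, chi-squared on 1 df)
#' is reported in place of a regression-based test of delta = 1.
#'
#' @inheritParams fit_bm
#' @param delta_bounds Search bounds for delta (default `c(1e-3, 500)`; the
#'   upper bound is deliberately far above common library defaults because
#'   strongly tipward trait change yields very large delta).
#' @return A `model_fit` with parameters `delta`, `sigma2`, `z0`, and extras
#'   `lrt_stat`, `lrt_p` (test of delta = 1).
#' @export
fit_delta <- function(tree, trait, delta_bounds = c(1e-3, 500)) {
  .assert_ultrametric(tree, what = "fit_delta")
  if (abs(tree_depth(tree) - 1) > 1e-6) {
    stop("fit_delta requires a unit-depth tree; call rescale_depth() first")
  }
  x <- .align_trait(tree, trait)
  C <- phylo_vcv(tree)
  X <- matrix(1, length(x), 1L)
  obj <- function(logd) .gls_profile(x, delta_transform(C, exp(logd)), X)$loglik
  lb <- log(delta_bounds[1]); ub <- log(delta_bounds[2])
  # a few restarts guard against flat or multimodal profiles
  cuts <- seq(lb, ub, length.out = 4L)
  opts <- lapply(seq_len(3L), function(i) {
    stats::optimize(obj, interval = cuts[c(i, i + 1L)], maximum = TRUE, tol = 1e-8)
  })
  cand <- c(vapply(opts, `[[`, numeric(1), "maximum"), 0, lb, ub)
  ll <- vapply(cand, obj, numeric(1))
  logd <- cand[which.max(ll)]
  g <- .gls_profile(x, delta_transform(C, exp(logd)), X)
  ll1 <- obj(0)                        # delta = 1 (BM null)
  lrt <- max(0, 2 * (g$loglik - ll1))
  new_model_fit("DELTA", g$loglik,
                list(delta = exp(logd), sigma2 = g$sigma2, z0 = g$beta[1]),
                k = 3L, n = length(x),
                boundary = logd <= lb + 1e-8 || logd >= ub - 1e-8,
                extra = list(lrt_stat = lrt,
                             lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                             loglik_bm = ll1))
}

#' Ornstein-Uhlenbeck covariance matrix (root fixed at the optimum)
#'
#' For an ultrametric tree of depth T, with `s_ij` the depth of the MRCA of
#' tips i and j and `d_ij` their patristic distance:
#' `V(i,j) = sigma2/(2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha s_ij))`.
#' As alpha -> 0 this approaches the BM covariance `sigma2 * C` entrywise.
#'
#' @param tree An ultrametric `phylo` object.
#' @param alpha Positive pull strength toward the optimum.
#' @param sigma2 Positive diffusion rate (default 1, the unit-scale structure
#'   used internally by the profiled fits).
#' @return An n x n covariance matrix in tip-label order.
#' @export
ou_covariance <- function(tree, alpha, sigma2 = 1) {
  stopifnot(alpha > 0, sigma2 > 0)
  .assert_ultrametric(tree, what = "ou_covariance")
  s <- phylo_vcv(tree)
  .ou_cov_from_parts(s, alpha, sigma2)
}

# s = MRCA-depth matrix of an ultrametric tree (diag = tip depths)
.ou_cov_from_parts <- function(s, alpha, sigma2 = 1) {
  depths <- diag(s)
  d <- outer(depths, depths, `+`) - 2 * s   # patristic distances; 0 on the diagonal
  sigma2 / (2 * alpha) * exp(-alpha * d) * (1 - exp(-2 * alpha * s))
}

# Bounded 1-D alpha search shared by OU1/OUM: maximize f(log alpha) with
# log-spaced restarts, returning the best (log_alpha, value).
.alpha_search <- function(f, alpha_bounds, restarts = 3L, extra_candidates = NULL) {
  lb <- log(alpha_bounds[1]); ub <- log(alpha_bounds[2])
  cuts <- seq(lb, ub, length.out = restarts + 1L)
  cand <- vapply(seq_len(restarts), function(i) {
    stats::optimize(f, interval = cuts[c(i, i + 1L)], maximum = TRUE, tol = 1e-7)$maximum
  }, numeric(1))
  cand <- c(cand, lb, ub, extra_candidates)
  vals <- vapply(cand, f, numeric(1))
  best <- which.max(vals)
  list(log_alpha = cand[best], value = vals[best],
       boundary = cand[best] <= lb + 1e-7 || cand[best] >= ub - 1e-7)
}

#' Fit a single-optimum Ornstein-Uhlenbeck model (OU1)
#'
#' `x ~ MVN(theta * 1, V(alpha, sigma2))` with the OU covariance of
#' [ou_covariance()]; the root state is fixed at the optimum theta. alpha is
#' found by bounded search on the log scale with log-spaced restarts; theta
#' (GLS) and sigma2 are profiled analytically. k = 3.
#'
#' @inheritParams fit_bm
#' @param alpha_bounds Search bounds for alpha (default `c(1e-4, 1e3)`).
#' @param restarts Number of log-spaced optimizer restarts.
#' @return A `model_fit` with parameters `alpha`, `sigma2`, `theta`.
#' @export
fit_ou1 <- function(tree, trait, alpha_bounds = c(1e-4, 1e3), restarts = 3L) {
  .assert_ultrametric(tree, what = "fit_ou1")
  x <- .align_trait(tree, trait)
  s <- phylo_vcv(tree)
  X <- matrix(1, length(x), 1L)
  f <- function(la) .gls_profile(x, .ou_cov_from_parts(s, exp(la)), X)$loglik
  sr <- .alpha_search(f, alpha_bounds, restarts)
  alpha <- exp(sr$log_alpha)
  g <- .gls_profile(x, .ou_cov_from_parts(s, alpha), X)
  new_model_fit("OU1", g$loglik,
                list(alpha = alpha, sigma2 = g$sigma2, theta = g$beta[1]),
                k = 3L, n = length(x), boundary = sr$boundary)
}

#' Hansen-model design weights for regime-specific optima
#'
#' For tip i, a lineage segment lying in regime r between depths `(t_b, t_e]`
#' contributes `exp(-alpha (T - t_e)) - exp(-alpha (T - t_b))` to `W(i, r)`;
#' the residual root weight `exp(-alpha T)` goes to the root regime. Rows are
#' non-negative and sum to 1, so the single-optimum mean is nested in the
#' column space of W.
#'
#' @inheritParams ou_covariance
#' @param painting A [paint_regimes()] object on the same tree.
#' @return An n x R matrix (tips x regimes).
#' @export
oum_design_weights <- function(tree, painting, alpha) {
  stopifnot(alpha > 0)
  .assert_ultrametric(tree, what = "oum_design_weights")
  ntip <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  T <- max(depths[seq_len(ntip)])
  parent <- integer(ntip + tree$Nnode)
  edge_of <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  W <- matrix(0, ntip, length(painting$levels),
              dimnames = list(tree$tip.label, painting$levels))
  for (i in seq_len(ntip)) {
    v <- i
    while (v != root) {
      e <- edge_of[v]; p <- parent[v]
      r <- painting$edge_states[e]
      W[i, r] <- W[i, r] + exp(-alpha * (T - depths[v])) - exp(-alpha * (T - depths[p]))
      v <- p
    }
    W[i, painting$root_state] <- W[i, painting$root_state] + exp(-alpha * T)
  }
  W
}

#' Fit a multi-optimum Ornstein-Uhlenbeck model (OUM)
#'
#' OU with a regime-specific optimum (e.g. herbaceous vs woody): mean
#' `W(alpha) theta` from [oum_design_weights()], covariance as in OU1, root
#' fixed at the root-regime optimum. alpha is searched; theta and sigma2 are
#' profiled. k = 4 for two regimes. The OU1 alpha estimate is always included
#' as a candidate, and the OU1 mean lies in W's column space, so
#' `lnL(OUM) >= lnL(OU1)` holds exactly.
#'
#' @inheritParams fit_ou1
#' @param painting A two-regime [paint_regimes()] object.
#' @param ou1 Optionally, a previously computed [fit_ou1()] result to reuse.
#' @return A `model_fit` with `params$theta` a named vector of per-regime
#'   optima, plus `alpha` and `sigma2`.
#' @export
fit_oum <- function(tree, trait, painting, alpha_bounds = c(1e-4, 1e3),
                    restarts = 3L, ou1 = NULL) {
  .assert_ultrametric(tree, what = "fit_oum")
  if (length(painting$levels) < 2L) stop("fit_oum requires at least 2 regimes")
  x <- .align_trait(tree, trait)
  s <- phylo_vcv(tree)
  if (is.null(ou1)) ou1 <- fit_ou1(tree, trait, alpha_bounds, restarts)
  f <- function(la) {
    a <- exp(la)
    .gls_profile(x, .ou_cov_from_parts(s, a), oum_design_weights(tree, painting, a))$loglik
  }
  sr <- .alpha_search(f, alpha_bounds, restarts,
                      extra_candidates = log(ou1$params$alpha))
  alpha <- exp(sr$log_alpha)
  g <- .gls_profile(x, .ou_cov_from_parts(s, alpha),
                    oum_design_weights(tree, painting, alpha))
  theta <- stats::setNames(g$beta, painting$levels)
  new_model_fit("OUM", g$loglik,
                list(alpha = alpha, sigma2 = g$sigma2, theta = theta),
                k = 2L + length(painting$levels), n = length(x),
                boundary = sr$boundary,
                extra = list(regimes = painting$levels))
}

#' Compare model fits by AICc
#'
#' Orders fits by AICc, computes delta-AICc relative to the minimum, and flags
#' the equivalence set (all fits with delta-AICc < 2). The best model is the
#' lowest AICc; exact ties go to the model with fewer parameters, then to
#' declaration order.
#'
#' @param fits A list of `model_fit` objects on the same data.
#' @return An object of class `model_comparison` with a `table` data.frame
#'   (model, k, loglik, AICc, dAICc, equivalent), `best` (model name), and
#'   `equivalence_set`.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2L) stop("need at least 2 fits to compare")
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L) stop("fits have differing sample sizes n")
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    k = vapply(fits, function(f) as.integer(f$k), integer(1)),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    AICc = vapply(fits, `[[`, numeric(1), "aicc"),
    stringsAsFactors = FALSE)
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$equivalent <- tab$dAICc < 2
  ord <- order(tab$AICc, tab$k, seq_len(nrow(tab)))
  best <- tab$model[ord[1]]
  structure(
    list(table = tab, best = best,
         equivalence_set = tab$model[tab$equivalent],
         fits = stats::setNames(fits, tab$model)),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  tab <- x$table[order(x$table$AICc), ]
  print(tab, row.names = FALSE, digits = 6)
  cat("best model:", x$best, " | equivalence set (dAICc < 2):",
      paste(x$equivalence_set, collapse = ", "), "\n")
  invisible(x)
}
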