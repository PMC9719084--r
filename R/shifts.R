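# Detection of optimum shifts under a single-alpha, single-sigma2 OU model:
# greedy forward stepwise search over edges, scored by a penalized
# information criterion with a per-shift placement cost.

# Design matrix for an OU model with optimum shifts on `edges`: intercept
# (base optimum, root fixed there) plus one column per shifted edge with entry
# 1 - exp(-alpha (T - t_e)) for every tip descending through the edge, where
# t_e is the PARENT-end depth of the edge (the whole edge evolves toward the
# new optimum), 0 elsewhere.
.shift_design <- function(tree, edges, alpha, desc = NULL) {
  ntip <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  T <- max(depths[seq_len(ntip)])
  if (is.null(desc)) desc <- .edge_descendants(tree)
  X <- matrix(1, ntip, 1L + length(edges))
  if (length(edges)) {
    for (j in seq_along(edges)) {
      e <- edges[j]
      col <- numeric(ntip)
      t_e <- depths[tree$edge[e, 1]]
      col[desc[[e]]] <- 1 - exp(-alpha * (T - t_e))
      X[, j + 1L] <- col
    }
  }
  colnames(X) <- c("theta0", if (length(edges)) paste0("edge", edges))
  X
}

#' Log-likelihood of an OU model with optimum shifts on given edges
#'
#' Single alpha and sigma2; the root is fixed at the base optimum theta0, and
#' each shifted edge contributes an additional optimum effective from the
#' parent end of that edge. Optima are estimated by GLS under the OU
#' covariance; sigma2 is profiled.
#'
#' @param tree An ultrametric `phylo` object.
#' @param trait Named numeric vector over the tips.
#' @param edges Integer vector of edge indices (rows of `tree$edge`); may be
#'   empty, in which case the model is exactly OU1 at the given alpha.
#' @param alpha Positive pull strength.
#' @return A list with `loglik`, `theta0`, `delta` (per-shift optimum offsets),
#'   `theta` (shifted optimum values `theta0 + delta`), `sigma2`, `edges`,
#'   `alpha`.
#' @export
shift_loglik <- function(tree, trait, edges, alpha) {
  .assert_ultrametric(tree, what = "shift_loglik")
  edges <- as.integer(edges)
  if (length(edges) && (any(edges < 1L) || any(edges > nrow(tree$edge)))) {
    stop("edge indices out of range")
  }
  if (anyDuplicated(edges)) stop("shifted edges must be distinct")
  x <- .align_trait(tree, trait)
  V <- ou_covariance(tree, alpha)
  X <- .shift_design(tree, edges, alpha)
  g <- .gls_profile(x, V, X)           # errors if rank deficient
  delta <- if (length(edges)) g$beta[-1L] else numeric(0)
  list(loglik = g$loglik, theta0 = g$beta[1L], delta = delta,
       theta = g$beta[1L] + delta, sigma2 = g$sigma2,
       edges = edges, alpha = alpha)
}

#' Stepwise search for OU optimum shifts with a penalized criterion
#'
#' Greedy forward search: starting from the no-shift OU model, at each step
#' add the single edge that maximizes the log-likelihood (alpha re-optimized
#' each step), and accept the step only if the penalized criterion
#' `crit(m) = -2 lnL + (3 + m) ln(n) + m (2 ln(E) + per_shift_penalty)`
#' improves, where E is the number of candidate edges. The `2 ln E` term is a
#' placement-cost surrogate for the singular/partial BIC penalties used for
#' shift-model selection; `per_shift_penalty` is a knob on top of it
#' (`Inf` disables shifts entirely). The search is deterministic.
#'
#' @inheritParams shift_loglik
#' @param max_shifts Maximum number of shifts to consider (must be < E).
#' @param alpha_bounds Bounds for the alpha search.
#' @param per_shift_penalty Extra penalty per shift added to the default
#'   criterion (default 0).
#' @param restarts Optimizer restarts for alpha.
#' @return An object of class `shift_config`: list with `edges`, `m`,
#'   `theta0`, `theta`, `delta`, `alpha`, `sigma2`, `loglik`, `criterion`,
#'   `n_candidates`, `trace` (per-step criterion path), `tip_specific`
#'   (logical, per shift: pendant edge or not), `tree`.
#' @export
search_shifts <- function(tree, trait, max_shifts = 8L,
                          alpha_bounds = c(1e-4, 1e3),
                          per_shift_penalty = 0, restarts = 3L) {
  .assert_ultrametric(tree, what = "search_shifts")
  x <- .align_trait(tree, trait)
  n <- length(x)
  E <- nrow(tree$edge)
  if (max_shifts >= E) stop("max_shifts must be smaller than the number of edges")
  desc <- .edge_descendants(tree)
  s <- phylo_vcv(tree)

  profile_fit <- function(edges) {
    f <- function(la) {
      a <- exp(la)
      tryCatch(
        .gls_profile(x, .ou_cov_from_parts(s, a), .shift_design(tree, edges, a, desc))$loglik,
        error = function(e) -Inf)
    }
    sr <- .alpha_search(f, alpha_bounds, restarts)
    a <- exp(sr$log_alpha)
    g <- .gls_profile(x, .ou_cov_from_parts(s, a), .shift_design(tree, edges, a, desc))
    list(alpha = a, gls = g, loglik = g$loglik)
  }
  crit <- function(loglik, m) {
    -2 * loglik + (3 + m) * log(n) + m * (2 * log(E) + per_shift_penalty)
  }

  cur_edges <- integer(0)
  cur <- profile_fit(cur_edges)
  cur_crit <- crit(cur$loglik, 0L)
  trace <- data.frame(m = 0L, edge = NA_integer_, loglik = cur$loglik,
                      criterion = cur_crit, accepted = TRUE)

  while (length(cur_edges) < max_shifts) {
    # score candidates at the current alpha via the whitened regression
    a <- cur$alpha
    R <- chol(.ou_cov_from_parts(s, a))
    zw <- backsolve(R, x, transpose = TRUE)
    Xcur <- backsolve(R, .shift_design(tree, cur_edges, a, desc), transpose = TRUE)
    candidates <- setdiff(seq_len(E), cur_edges)
    best_edge <- NA_integer_; best_q <- Inf
    for (e in candidates) {
      Xe <- backsolve(R, .shift_design(tree, e, a, desc)[, 2L, drop = FALSE],
                      transpose = TRUE)
      Xfull <- cbind(Xcur, Xe)
      qrX <- qr(Xfull)
      if (qrX$rank < ncol(Xfull)) next   # unidentifiable placement
      q <- sum(qr.resid(qrX, zw)^2)
      if (q < best_q - 1e-12) { best_q <- q; best_edge <- e }
    }
    if (is.na(best_edge)) break
    prop_edges <- c(cur_edges, best_edge)
    prop <- profile_fit(prop_edges)
    prop_crit <- crit(prop$loglik, length(prop_edges))
    accepted <- is.finite(prop_crit) && prop_crit < cur_crit
    trace <- rbind(trace, data.frame(m = length(prop_edges), edge = best_edge,
                                     loglik = prop$loglik, criterion = prop_crit,
                                     accepted = accepted))
    if (!accepted) break
    cur_edges <- prop_edges
    cur <- prop
    cur_crit <- prop_crit
  }

  beta <- cur$gls$beta
  delta <- if (length(cur_edges)) beta[-1L] else numeric(0)
  ntip <- ape::Ntip(tree)
  structure(
    list(edges = cur_edges, m = length(cur_edges),
         theta0 = beta[1L], delta = delta, theta = beta[1L] + delta,
         alpha = cur$alpha, sigma2 = cur$gls$sigma2, loglik = cur$loglik,
         criterion = cur_crit, n_candidates = E, trace = trace,
         tip_specific = tree$edge[cur_edges, 2] <= ntip,
         tree = tree),
    class = "shift_config")
}

#' @export
print.shift_config <- function(x, ...) {
  cat(sprintf("OU shift configuration: m = %d shift(s), alpha = %.4g, lnL = %.4f\n",
              x$m, x$alpha, x$loglik))
  cat(sprintf("  base optimum theta0 = %.4g; criterion = %.4f (%d candidate edges)\n",
              x$theta0, x$criterion, x$n_candidates))
  if (x$m > 0) {
    for (j in seq_len(x$m)) {
      cat(sprintf("  shift %d: edge %d%s, optimum %.4g (offset %+.4g)\n",
                  j, x$edges[j],
                  if (x$tip_specific[j]) " [tip-specific]" else "",
                  x$theta[j], x$delta[j]))
    }
  }
  invisible(x)
}
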