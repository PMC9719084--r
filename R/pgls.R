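# Phylogenetic generalized least squares with simultaneous ML estimation of
# Pagel's lambda, and the pairwise element-interaction matrix built from it.

#' Phylogenetic generalized least squares with estimated Pagel's lambda
#'
#' Fits `y = X beta + eps`, `eps ~ MVN(0, sigma2 * C_lambda)` where `C_lambda`
#' is the [lambda_transform()]ed BM covariance. lambda is estimated by bounded
#' ML on `[0, 1]` (endpoints included; boundary estimates are reported, not
#' clamped away), beta by GLS, and coefficients are tested with t statistics
#' on `n - p` degrees of freedom. At lambda = 0 the fit coincides with
#' ordinary least squares; at lambda = 1 with BM-GLS.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param response Named numeric vector over the tips.
#' @param predictors Named numeric vector, or a data.frame/matrix with one
#'   column per predictor and rownames (or a `species` column) matching the
#'   tip labels.
#' @param lambda Optionally fix lambda instead of estimating it.
#' @return An object of class `pgls_fit`: list with `coefficients` (data.frame
#'   with estimate, se, t, p), `lambda`, `lambda_fixed`, `loglik`, `sigma2`
#'   (ML), `n`, `df_residual`.
#' @export
fit_pgls <- function(tree, response, predictors, lambda = NULL) {
  validate_phylo(tree)
  y <- .align_trait(tree, response)
  if (is.vector(predictors) && is.numeric(predictors)) {
    predictors <- data.frame(x = predictors, row.names = names(predictors))
  }
  predictors <- as.data.frame(predictors)
  if (!is.null(predictors$species)) {
    rownames(predictors) <- predictors$species
    predictors$species <- NULL
  }
  miss <- setdiff(tree$tip.label, rownames(predictors))
  if (length(miss)) stop("predictors missing for tips: ", paste(miss, collapse = ", "))
  Xp <- as.matrix(predictors[tree$tip.label, , drop = FALSE])
  storage.mode(Xp) <- "double"
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, Xp)
  p <- ncol(X)
  if (n <= p + 1) stop("too few species for the number of predictors")
  if (qr(X)$rank < p) stop("rank error: collinear predictors")
  C <- phylo_vcv(tree)

  obj <- function(l) .gls_profile(y, lambda_transform(C, l), X)$loglik
  if (is.null(lambda)) {
    opt <- stats::optimize(obj, interval = c(0, 1), maximum = TRUE, tol = 1e-7)
    cand <- c(opt$maximum, 0, 1)
    ll <- vapply(cand, obj, numeric(1))
    lam <- cand[which.max(ll)]
    fixed <- FALSE
  } else {
    stopifnot(lambda >= 0, lambda <= 1)
    lam <- lambda
    fixed <- TRUE
  }
  g <- .gls_profile(y, lambda_transform(C, lam), X)
  # unbiased residual variance for the coefficient tests
  Q <- g$sigma2 * n
  s2_u <- Q / (n - p)
  XtVinvX_inv <- chol2inv(qr.R(g$qr))
  se <- sqrt(diag(XtVinvX_inv) * s2_u)
  tval <- g$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  coefs <- data.frame(estimate = g$beta, se = se, t = tval, p = pval,
                      row.names = colnames(X))
  structure(
    list(coefficients = coefs, lambda = lam, lambda_fixed = fixed,
         loglik = g$loglik, sigma2 = g$sigma2, n = n, df_residual = n - p),
    class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (n = %d, lambda%s = %.4f, lnL = %.4f)\n",
              x$n, if (x$lambda_fixed) " [fixed]" else "", x$lambda, x$loglik))
  printCoefmat(as.matrix(x$coefficients), P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

.p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pairwise PGLS slopes between leaf elements
#'
#' One [fit_pgls()] per unordered element pair, with the *row* element
#' regressed on the *column* element (the lower-triangle layout of the
#' element-interaction table). Concentrations are log10-transformed before
#' fitting. By default no multiple-testing adjustment is applied, matching the
#' convention of reporting raw per-pair significance; `adjust = "holm"`
#' applies a Holm correction across the pairs.
#'
#' @param tree A `phylo` object.
#' @param traits A [trait_table()] (or data.frame with a `species` column and
#'   element columns).
#' @param elements Which element columns to use (default: all present among
#'   C, N, P, K, Ca, Mg).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return An object of class `pgls_matrix`: list of lower-triangular matrices
#'   `slope`, `p`, `lambda`, plus `stars` (character) and `elements`.
#' @export
pairwise_element_pgls <- function(tree, traits, elements = NULL,
                                  adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  traits <- as.data.frame(traits)
  if (is.null(elements)) {
    elements <- intersect(c("C", "N", "P", "K", "Ca", "Mg"), names(traits))
  }
  if (length(elements) < 2L) stop("need at least 2 element columns")
  sp <- if (!is.null(traits$species)) traits$species else rownames(traits)
  m <- length(elements)
  slope <- p <- lam <- matrix(NA_real_, m, m, dimnames = list(elements, elements))
  pairs <- list()
  for (i in seq_len(m)) for (j in seq_len(i - 1L)) {
    yi <- stats::setNames(log10(traits[[elements[i]]]), sp)
    xj <- stats::setNames(log10(traits[[elements[j]]]), sp)
    fit <- fit_pgls(tree, yi, xj)
    slope[i, j] <- fit$coefficients["x", "estimate"]
    p[i, j] <- fit$coefficients["x", "p"]
    lam[i, j] <- fit$lambda
    pairs[[paste(elements[i], "~", elements[j])]] <- fit
  }
  if (adjust == "holm") {
    idx <- lower.tri(p)
    p[idx] <- stats::p.adjust(p[idx], method = "holm")
  }
  stars <- matrix("", m, m, dimnames = dimnames(p))
  stars[lower.tri(stars)] <- .p_stars(p[lower.tri(p)])
  structure(
    list(slope = slope, p = p, lambda = lam, stars = stars,
         elements = elements, adjust = adjust, fits = pairs),
    class = "pgls_matrix")
}

#' @export
print.pgls_matrix <- function(x, digits = 2, ...) {
  m <- length(x$elements)
  out <- matrix("", m, m, dimnames = list(x$elements, x$elements))
  idx <- lower.tri(out)
  out[idx] <- paste0(formatC(x$slope[idx], digits = digits, format = "f"),
                     x$stars[idx])
  cat("Pairwise PGLS slopes (row ~ column, log10 scale",
      if (x$adjust != "none") paste0("; ", x$adjust, "-adjusted p"), "):\n", sep = "")
  print(out, quote = FALSE)
  invisible(x)
}
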