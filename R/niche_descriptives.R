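# Non-phylogenetic description of the biogeochemical niche: life-form group
# summaries with one-way ANOVA, PCA of elemental composition, and fold-range
# statistics. All inference is on log10 concentrations; summaries are
# reported on the raw mg/g scale.

.ELEMENTS <- c("C", "N", "P", "K", "Ca", "Mg")
.LIFE_FORMS <- c("fern", "herb", "evergreen", "deciduous")

#' Construct and validate a species trait table
#'
#' A species x elements table of leaf concentrations (mg per g dry mass, all
#' strictly positive) with a life-form label per species (`fern`, `herb`,
#' `evergreen`, `deciduous`). A derived coarse label (`herbaceous` = fern or
#' herb, `woody` = evergreen or deciduous) is added as column `group`.
#'
#' @param df A data.frame with columns `species`, `life_form`, and one or more
#'   of C, N, P, K, Ca, Mg.
#' @return The validated data.frame with class `trait_table` and an
#'   `elements` attribute.
#' @export
trait_table <- function(df) {
  df <- as.data.frame(df)
  if (is.null(df$species)) stop("trait table needs a 'species' column")
  if (anyDuplicated(df$species)) stop("duplicate species in trait table")
  if (is.null(df$life_form)) stop("trait table needs a 'life_form' column")
  lf <- as.character(df$life_form)
  bad <- setdiff(unique(lf), .LIFE_FORMS)
  if (length(bad)) {
    stop("unknown life forms: ", paste(bad, collapse = ", "),
         " (expected ", paste(.LIFE_FORMS, collapse = "/"), ")")
  }
  elements <- intersect(.ELEMENTS, names(df))
  if (!length(elements)) stop("no element columns (C, N, P, K, Ca, Mg) found")
  for (el in elements) {
    v <- df[[el]]
    if (!is.numeric(v) || anyNA(v) || any(v <= 0)) {
      stop("element '", el, "' must be strictly positive and complete")
    }
  }
  df$life_form <- lf
  df$group <- ifelse(lf %in% c("fern", "herb"), "herbaceous", "woody")
  structure(df, elements = elements, class = c("trait_table", "data.frame"))
}

.tt_elements <- function(table) {
  el <- attr(table, "elements")
  if (is.null(el)) el <- intersect(.ELEMENTS, names(table))
  el
}

#' Log10-transformed element matrix of a trait table
#' @param table A [trait_table()].
#' @return Numeric matrix (species x elements) of log10 concentrations, with
#'   species rownames.
#' @export
log10_traits <- function(table) {
  el <- .tt_elements(table)
  m <- log10(as.matrix(as.data.frame(table)[el]))
  rownames(m) <- table$species
  m
}

#' Group summaries and one-way ANOVA per element
#'
#' For a chosen life-form contrast, reports the per-group mean and standard
#' error on the raw concentration scale, and an F test per element computed on
#' log10 values (classic one-way fixed-effects ANOVA). Significance letters
#' are assigned at alpha = 0.05: with two groups, distinct letters iff the F
#' test is significant, ordered by group mean.
#'
#' @param table A [trait_table()].
#' @param grouping One of `"herbaceous_woody"` (all species),
#'   `"evergreen_deciduous"` (woody species only), or `"fern_herb"`
#'   (herbaceous species only).
#' @param extra Optional named list of additional per-species numeric columns
#'   (e.g. PC scores) to summarize alongside the elements; these are analyzed
#'   on their own scale.
#' @return An object of class `group_summary`: list with `summary` (long
#'   data.frame: variable, group, n, mean, se, letter) and `anova` (variable,
#'   F, df1, df2, p).
#' @export
summarize_groups <- function(table,
                             grouping = c("herbaceous_woody",
                                          "evergreen_deciduous", "fern_herb"),
                             extra = NULL) {
  grouping <- match.arg(grouping)
  df <- as.data.frame(table)
  g <- switch(grouping,
    herbaceous_woody = factor(df$group, levels = c("herbaceous", "woody")),
    evergreen_deciduous = {
      df <- df[df$group == "woody", , drop = FALSE]
      factor(df$life_form, levels = c("evergreen", "deciduous"))
    },
    fern_herb = {
      df <- df[df$group == "herbaceous", , drop = FALSE]
      factor(df$life_form, levels = c("fern", "herb"))
    })
  counts <- table(g)
  if (any(counts == 0)) stop("empty group in grouping '", grouping, "'")
  if (any(counts < 2)) stop("each group needs at least 2 species")

  el <- .tt_elements(table)
  vars <- c(stats::setNames(lapply(el, function(e) {
    list(raw = df[[e]], test = log10(df[[e]]))
  }), el), lapply(extra, function(v) {
    v <- v[match(df$species, names(v))]
    list(raw = v, test = v)
  }))

  sum_rows <- list(); an_rows <- list()
  for (nm in names(vars)) {
    raw <- vars[[nm]]$raw; tv <- vars[[nm]]$test
    means <- tapply(raw, g, mean)
    ses <- tapply(raw, g, function(v) stats::sd(v) / sqrt(length(v)))
    if (stats::var(tv) == 0) {
      Fv <- 0; pv <- 1; df1 <- nlevels(g) - 1L; df2 <- length(tv) - nlevels(g)
    } else {
      a <- stats::anova(stats::lm(tv ~ g))
      Fv <- a$`F value`[1]; pv <- a$`Pr(>F)`[1]
      df1 <- a$Df[1]; df2 <- a$Df[2]
    }
    letters_ <- if (pv < 0.05) {
      # two groups: distinct letters, A to the larger mean
      lv <- levels(g)[order(-means)]
      stats::setNames(c("A", "B"), lv)[levels(g)]
    } else stats::setNames(rep("A", nlevels(g)), levels(g))
    sum_rows[[nm]] <- data.frame(
      variable = nm, group = levels(g), n = as.integer(counts),
      mean = as.numeric(means), se = as.numeric(ses),
      letter = as.character(letters_), stringsAsFactors = FALSE)
    an_rows[[nm]] <- data.frame(variable = nm, F = Fv, df1 = df1, df2 = df2,
                                p = pv, stringsAsFactors = FALSE)
  }
  structure(
    list(summary = do.call(rbind, c(sum_rows, make.row.names = FALSE)),
         anova = do.call(rbind, c(an_rows, make.row.names = FALSE)),
         grouping = grouping),
    class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group summary (", x$grouping, "), mean ± SE with ANOVA letters:\n", sep = "")
  s <- x$summary
  s$value <- sprintf("%.3g ± %.2g %s", s$mean, s$se, s$letter)
  print(stats::reshape(s[c("variable", "group", "value")],
                       direction = "wide", idvar = "group",
                       timevar = "variable"), row.names = FALSE)
  cat("\nANOVA on log10 values:\n")
  print(x$anova, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Principal component analysis of elemental composition
#'
#' PCA of the species x element matrix. The default is correlation-matrix PCA
#' (unit-variance columns) of log10 concentrations; `scale. = FALSE` switches
#' to covariance PCA and `use_log10 = FALSE` to raw concentrations. A
#' deterministic sign convention is applied: in each loading column the
#' largest-magnitude entry is made positive.
#'
#' @param table A [trait_table()].
#' @param scale. Scale columns to unit variance (default TRUE).
#' @param use_log10 Analyze log10 concentrations (default TRUE).
#' @return An object of class `pca_result`: list with `loadings` (elements x
#'   PCs), `scores` (species x PCs), `var_prop` (proportion of variance per
#'   axis), and the `PC1`/`PC2` score vectors (named by species).
#' @export
pca_scores <- function(table, scale. = TRUE, use_log10 = TRUE) {
  el <- .tt_elements(table)
  if (nrow(table) < 3L) stop("PCA needs at least 3 species")
  M <- as.matrix(as.data.frame(table)[el])
  if (use_log10) M <- log10(M)
  rownames(M) <- table$species
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(el[sds == 0], collapse = ", "))
  }
  pr <- stats::prcomp(M, center = TRUE, scale. = scale.)
  rot <- pr$rotation; sc <- pr$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j] }
  }
  vp <- pr$sdev^2 / sum(pr$sdev^2)
  structure(
    list(loadings = rot, scores = sc, var_prop = vp,
         PC1 = stats::setNames(sc[, 1], rownames(M)),
         PC2 = stats::setNames(sc[, 2], rownames(M))),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% (cumulative %.1f%%) of total variation\n",
              100 * x$var_prop[1], 100 * x$var_prop[2],
              100 * sum(x$var_prop[1:2])))
  cat("Loadings:\n")
  print(round(x$loadings[, 1:min(3, ncol(x$loadings))], 3))
  invisible(x)
}

#' Fold range (max/min ratio) of each element across species
#'
#' @param table A [trait_table()].
#' @return Named numeric vector of max/min ratios (>= 1).
#' @export
fold_ranges <- function(table) {
  el <- .tt_elements(table)
  vapply(stats::setNames(el, el), function(e) {
    v <- as.data.frame(table)[[e]]
    max(v) / min(v)
  }, numeric(1))
}
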