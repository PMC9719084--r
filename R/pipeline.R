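# End-to-end orchestration: log10 transform -> descriptives -> signal ->
# five model fits + AICc comparison -> shift search -> pairwise PGLS, and the
# 100-tree grafting robustness replication.

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (comments with `#`). Values are parsed as
#' numeric where possible. Unknown keys are kept.
#'
#' @param file Path to the config file, or `NULL` for defaults.
#' @return A named list of settings merged over the defaults: `n_perm` (999),
#'   `seed` (1), `alpha_min` (1e-4), `alpha_max` (1e3), `delta_min` (1e-3),
#'   `delta_max` (500), `max_shifts` (8), `per_shift_penalty` (0),
#'   `pca_scale` (1 = correlation PCA), `pca_log10` (1), `do_shifts` (1).
#' @export
read_config <- function(file = NULL) {
  defaults <- list(n_perm = 999, seed = 1, alpha_min = 1e-4, alpha_max = 1e3,
                   delta_min = 1e-3, delta_max = 500, max_shifts = 8,
                   per_shift_penalty = 0, pca_scale = 1, pca_log10 = 1,
                   do_shifts = 1)
  if (is.null(file)) return(defaults)
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("bad config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    defaults[[key]] <- if (is.na(num)) val else num
  }
  defaults
}

#' Read a species trait CSV
#'
#' Expected columns: `species`, element concentrations among C, N, P, K, Ca,
#' Mg (mg/g), and `life_form`.
#'
#' @param file Path to the CSV.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(file) {
  trait_table(utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE))
}

#' Run the full biogeochemical-niche analysis
#'
#' Reproduces the whole workflow on a tree and trait table: log10 transform;
#' life-form descriptives with ANOVA and PCA; Blomberg's K with permutation
#' test per variable (six elements plus PC1/PC2 scores); ML fits of BM, BMM,
#' Pagel's delta, OU1 and OUM per variable with AICc comparison; OU optimum
#' shift search per variable; and the pairwise PGLS element-interaction
#' matrix. Regimes for BMM/OUM are the coarse herbaceous/woody life forms
#' painted by Fitch parsimony. Any stage failure is caught, recorded in the
#' report, and the run continues. Deterministic given the config seed.
#'
#' @param tree A `phylo` object or path to a Newick file. Tips not in the
#'   trait table are pruned with a warning; at least 3 species must overlap.
#' @param traits A [trait_table()], data.frame, or path to a trait CSV.
#' @param config A named list as from [read_config()] (partial lists are
#'   merged over the defaults).
#' @return An object of class `analysis_report`.
#' @export
run_full_analysis <- function(tree, traits, config = list()) {
  cfg <- utils::modifyList(read_config(NULL), as.list(config))
  if (is.character(tree)) tree <- read_newick(file = tree)
  if (is.character(traits)) traits <- read_trait_table(traits)
  if (!inherits(traits, "trait_table")) traits <- trait_table(traits)

  common <- intersect(tree$tip.label, traits$species)
  if (length(common) < 3L) stop("fewer than 3 species shared by tree and trait table")
  extra <- setdiff(tree$tip.label, traits$species)
  if (length(extra)) {
    warning("pruning ", length(extra), " tip(s) absent from the trait table")
    tree <- ape::drop.tip(tree, extra)
  }
  if (length(setdiff(traits$species, tree$tip.label))) {
    traits <- trait_table(as.data.frame(traits)[traits$species %in% tree$tip.label, ])
  }
  tree <- rescale_depth(tree, 1)
  elements <- .tt_elements(traits)

  section <- function(expr) {
    tryCatch(expr, error = function(e) structure(list(error = conditionMessage(e)),
                                                 class = "failed_section"))
  }
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S "), ...))

  note("descriptives")
  pca <- section(pca_scores(traits, scale. = cfg$pca_scale != 0,
                            use_log10 = cfg$pca_log10 != 0))
  pcs <- if (!inherits(pca, "failed_section")) {
    list(PC1 = pca$PC1, PC2 = pca$PC2)
  } else NULL
  descriptives <- list(
    herbaceous_woody = section(summarize_groups(traits, "herbaceous_woody", extra = pcs)),
    evergreen_deciduous = section(summarize_groups(traits, "evergreen_deciduous", extra = pcs)),
    fern_herb = section(summarize_groups(traits, "fern_herb", extra = pcs)),
    pca = pca,
    fold_ranges = section(fold_ranges(traits)))

  logm <- log10_traits(traits)
  variables <- stats::setNames(
    lapply(elements, function(e) stats::setNames(logm[, e], rownames(logm))),
    elements)
  if (!is.null(pcs)) variables <- c(variables, pcs)

  painting <- section(paint_regimes(
    tree, stats::setNames(traits$group, traits$species)[tree$tip.label]))
  two_regimes <- !inherits(painting, "failed_section") &&
    length(painting$levels) == 2L

  note("signal (", cfg$n_perm, " permutations)")
  signal <- lapply(variables, function(v) {
    section(k_permutation_test(tree, v, n_perm = cfg$n_perm, seed = cfg$seed))
  })

  note("model fits")
  ab <- c(cfg$alpha_min, cfg$alpha_max)
  models <- lapply(variables, function(v) section({
    fits <- list(fit_bm(tree, v))
    if (two_regimes) fits <- c(fits, list(fit_bmm(tree, v, painting)))
    fits <- c(fits, list(fit_delta(tree, v, c(cfg$delta_min, cfg$delta_max))))
    ou1 <- fit_ou1(tree, v, ab)
    fits <- c(fits, list(ou1))
    if (two_regimes) fits <- c(fits, list(fit_oum(tree, v, painting, ab, ou1 = ou1)))
    compare_models(fits)
  }))

  shifts <- NULL
  if (cfg$do_shifts != 0) {
    note("shift search")
    shifts <- lapply(variables, function(v) section(
      search_shifts(tree, v, max_shifts = cfg$max_shifts, alpha_bounds = ab,
                    per_shift_penalty = cfg$per_shift_penalty)))
  }

  note("pairwise PGLS")
  pgls <- if (length(elements) >= 2L) {
    section(pairwise_element_pgls(tree, traits, elements))
  } else structure(list(error = "fewer than 2 element columns"),
                   class = "failed_section")

  note("done")
  structure(
    list(descriptives = descriptives, signal = signal, models = models,
         shifts = shifts, pgls = pgls, painting = painting,
         variables = names(variables), elements = elements,
         tree = tree, traits = traits,
         meta = list(seed = cfg$seed, config = cfg,
                     n_species = ape::Ntip(tree),
                     package_version = as.character(utils::packageVersion("bgcniche")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time())),
         log = log),
    class = "analysis_report")
}

# Table-2-shaped wide data.frame from the per-variable comparisons; optima of
# element variables are also back-transformed to the concentration scale.
.model_table <- function(report) {
  rows <- lapply(report$variables, function(v) {
    cmp <- report$models[[v]]
    sig <- report$signal[[v]]
    row <- data.frame(variable = v, stringsAsFactors = FALSE)
    row$K <- if (!inherits(sig, "failed_section")) sig$K else NA
    row$K_p <- if (!inherits(sig, "failed_section")) sig$p_value else NA
    if (inherits(cmp, "failed_section")) return(row)
    back <- v %in% report$elements
    for (f in cmp$fits) {
      pre <- f$model
      row[[paste0(pre, "_AICc")]] <- f$aicc
      if (f$model == "BM") row$Sigma <- f$params$sigma2
      if (f$model == "BMM") {
        row$Sigma_H <- f$params$sigma2[["herbaceous"]]
        row$Sigma_W <- f$params$sigma2[["woody"]]
      }
      if (f$model == "OU1") {
        row$alpha <- f$params$alpha
        row$Opt <- if (back) 10^f$params$theta else f$params$theta
      }
      if (f$model == "OUM") {
        th <- f$params$theta
        row$Opt_H <- if (back) 10^th[["herbaceous"]] else th[["herbaceous"]]
        row$Opt_W <- if (back) 10^th[["woody"]] else th[["woody"]]
      }
      if (f$model == "DELTA") { row$delta <- f$params$delta; row$delta_p <- f$lrt_p }
    }
    row$best <- cmp$best
    row
  })
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] }))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Biogeochemical-niche analysis report\n")
  cat("  species:", x$meta$n_species, " variables:",
      paste(x$variables, collapse = ", "), "\n\n")
  tab <- .model_table(x)
  show <- intersect(c("variable", "K", "K_p", "best", "delta", "alpha",
                      "Opt_H", "Opt_W"), names(tab))
  print(tab[show], row.names = FALSE, digits = 3)
  if (!is.null(x$shifts)) {
    m <- vapply(x$shifts, function(s)
      if (inherits(s, "failed_section")) NA_integer_ else s$m, integer(1))
    cat("\noptimum shifts detected:",
        paste(sprintf("%s=%s", names(m), m), collapse = ", "), "\n")
  }
  if (!inherits(x$pgls, "failed_section")) { cat("\n"); print(x$pgls) }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits TSV tables shaped like the study's summary tables (group means,
#' per-variable signal + model comparison, pairwise PGLS slopes, shift
#' configurations), a machine-readable JSON report with all fits and seeds,
#' and a plain-text run log.
#'
#' @param report An [run_full_analysis()] result.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)

  sums <- lapply(names(report$descriptives), function(g) {
    d <- report$descriptives[[g]]
    if (inherits(d, "group_summary")) cbind(grouping = g, d$summary)
  })
  sums <- do.call(rbind, Filter(Negate(is.null), sums))
  if (!is.null(sums)) wr(sums, "table1_group_summaries.tsv")
  wr(.model_table(report), "table2_signal_and_models.tsv")
  if (!inherits(report$pgls, "failed_section")) {
    sl <- report$pgls$slope
    df <- data.frame(element = rownames(sl), round(sl, 4), check.names = FALSE)
    wr(df, "table3_pgls_slopes.tsv")
  }
  if (!is.null(report$shifts)) {
    rows <- lapply(names(report$shifts), function(v) {
      s <- report$shifts[[v]]
      if (inherits(s, "failed_section") || s$m == 0) return(NULL)
      data.frame(variable = v, edge = s$edges,
                 tip_specific = s$tip_specific,
                 optimum = s$theta, offset = s$delta,
                 alpha = s$alpha, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, Filter(Negate(is.null), rows))
    if (!is.null(rows)) wr(rows, "shifts.tsv")
  }
  keep <- report[c("variables", "elements", "meta", "log")]
  keep$signal <- lapply(report$signal, unclass)
  keep$model_table <- .model_table(report)
  keep$tree_newick <- write_newick(report$tree)
  jsonlite::write_json(keep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Phylogenetic-uncertainty replication of the signal tests
#'
#' Emulates the 100-random-trees robustness check: taxa missing from the
#' backbone are grafted with fresh random placements per replicate, the tree
#' is rescaled to unit depth, and the Blomberg's K permutation verdict
#' (significant at `alpha` or not) is recorded per variable. The output is the
#' fraction of replicate trees whose verdict matches the reference tree's
#' (the grafting drawn directly from `seed`).
#'
#' @param backbone A `phylo` object (or Newick path): the backbone tree.
#' @param placements Placement table as for [graft_missing_taxa()]; may be
#'   empty/`NULL`, in which case all replicates are identical.
#' @param traits A [trait_table()] (or data.frame/CSV path) covering all tips
#'   after grafting.
#' @param n_trees Number of replicate trees (default 100).
#' @param seed Integer seed.
#' @param n_perm Permutations per signal test (default 999).
#' @param alpha Significance level for the verdict (default 0.05).
#' @param include_pcs Also test PC1/PC2 score signal (default TRUE).
#' @return A data.frame with one row per variable: `variable`,
#'   `reference_K`, `reference_significant`, `agreement` (fraction in
#'   `[0, 1]`), `n_trees`.
#' @export
tree_uncertainty_replicates <- function(backbone, placements, traits,
                                        n_trees = 100L, seed = 1L,
                                        n_perm = 999L, alpha = 0.05,
                                        include_pcs = TRUE) {
  if (is.character(backbone)) backbone <- read_newick(file = backbone)
  if (is.character(traits)) traits <- read_trait_table(traits)
  if (!inherits(traits, "trait_table")) traits <- trait_table(traits)
  logm <- log10_traits(traits)
  vars <- stats::setNames(lapply(colnames(logm), function(e)
    stats::setNames(logm[, e], rownames(logm))), colnames(logm))
  if (include_pcs) {
    pca <- pca_scores(traits)
    vars <- c(vars, list(PC1 = pca$PC1, PC2 = pca$PC2))
  }
  # the permutation seed is held fixed across replicates so that the only
  # randomness under comparison is the grafting itself (zero placements
  # must give agreement exactly 1)
  verdicts <- function(tr) {
    tr <- rescale_depth(tr, 1)
    vapply(vars, function(v) {
      r <- k_permutation_test(tr, v[tr$tip.label], n_perm = n_perm, seed = seed)
      c(K = r$K, sig = as.numeric(r$p_value <= alpha))
    }, numeric(2))
  }
  ref_tree <- graft_missing_taxa(backbone, placements, seed = seed)
  ref <- verdicts(ref_tree)
  agree <- matrix(0, length(vars), n_trees)
  for (b in seq_len(n_trees)) {
    tr <- graft_missing_taxa(backbone, placements, seed = seed + b)
    vb <- verdicts(tr)
    agree[, b] <- as.numeric(vb["sig", ] == ref["sig", ])
  }
  data.frame(variable = names(vars),
             reference_K = as.numeric(ref["K", ]),
             reference_significant = ref["sig", ] == 1,
             agreement = rowMeans(agree),
             n_trees = n_trees,
             row.names = NULL)
}
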