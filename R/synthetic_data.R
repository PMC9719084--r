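# Generators for trees, regimes, and traits with known ground truth under
# every model the package fits, plus a study-mimicking 102-species fixture.
# Simulation draws are exact multivariate-normal samples from the mean and
# covariance each model definition implies, so simulator and fitter share the
# model definitions but not an approximation.

#' Simulate a pure-birth (Yule) tree rescaled to unit depth
#'
#' Classic crown-conditioned Yule process: starting from two lineages, each
#' waiting time to the next speciation is exponential with rate (number of
#' lineages) x `birth_rate`, and a uniformly chosen lineage splits; after the
#' n-th lineage appears the process runs for one further exponential waiting
#' time so all tips are contemporaneous. The tree is then rescaled to depth 1
#' (the pre-rescaling crown age is kept in attribute `raw_depth`).
#'
#' @param n Number of tips (>= 2).
#' @param seed Integer seed; the result is deterministic given it.
#' @param birth_rate Speciation rate of the Yule process (default 1).
#' @return An ultrametric `phylo` object of depth 1 with tips `t1 ... tn`.
#' @export
simulate_tree <- function(n, seed, birth_rate = 1) {
  if (n < 2L) stop("need at least 2 tips")
  set.seed(seed)
  # node records; ids 1, 2 are the root's children
  parent <- c(0L, 0L); start <- c(0, 0); end <- c(NA_real_, NA_real_)
  active <- c(1L, 2L); t <- 0
  while (length(active) < n) {
    k <- length(active)
    t <- t + stats::rexp(1, k * birth_rate)
    j <- active[sample.int(k, 1L)]
    end[j] <- t
    id1 <- length(parent) + 1L; id2 <- id1 + 1L
    parent <- c(parent, j, j); start <- c(start, t, t)
    end <- c(end, NA_real_, NA_real_)
    active <- c(setdiff(active, j), id1, id2)
  }
  t_end <- t + stats::rexp(1, n * birth_rate)
  end[active] <- t_end

  children <- split(seq_along(parent), parent)
  tip_counter <- 0L
  build <- function(id) {
    len <- end[id] - start[id]
    kids <- children[[as.character(id)]]
    if (is.null(kids)) {
      tip_counter <<- tip_counter + 1L
      sprintf("t%d:%.17g", tip_counter, len)
    } else {
      sprintf("(%s,%s):%.17g", build(kids[1]), build(kids[2]), len)
    }
  }
  nwk <- sprintf("(%s,%s);", build(1L), build(2L))
  tree <- ape::read.tree(text = nwk)
  raw_depth <- tree_depth(tree)
  tree <- rescale_depth(tree, 1)
  attr(tree, "raw_depth") <- raw_depth
  tree
}

#' Simulate tip regimes and their parsimony painting
#'
#' `method = "clade"` assigns the second state to one whole subtree (a clean
#' two-block structure, emulating phylogenetically clustered life forms);
#' `method = "mk"` evolves a symmetric 2-state Markov character along the
#' branches at rate `rate` per direction (the probability that child and
#' parent states differ across a branch of length t is `(1 - exp(-2 q t))/2`).
#'
#' @param tree A `phylo` object.
#' @param method `"clade"` or `"mk"`.
#' @param seed Integer seed.
#' @param states Two regime labels (default `c("A", "B")`).
#' @param clade_size For `"clade"`: target clade size; the internal node whose
#'   clade size is closest to it is used (ties to the smallest node id). If
#'   `NULL`, a node is drawn uniformly among those covering 20-50% of tips.
#' @param rate For `"mk"`: transition rate per direction.
#' @param root_state For `"mk"`: state at the root (default `states[1]`).
#' @return A list with `tip_states` (named character) and `painting`
#'   (a [paint_regimes()] object).
#' @export
simulate_regimes <- function(tree, method = c("clade", "mk"), seed = 1L,
                             states = c("A", "B"), clade_size = NULL,
                             rate = 0.5, root_state = states[1]) {
  method <- match.arg(method)
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  if (method == "clade") {
    desc <- .edge_descendants(tree)
    sizes <- lengths(desc)
    internal <- which(tree$edge[, 2] > ntip)
    if (is.null(clade_size)) {
      ok <- internal[sizes[internal] >= max(2, floor(0.2 * ntip)) &
                     sizes[internal] <= ceiling(0.5 * ntip)]
      if (!length(ok)) ok <- internal
      e <- ok[sample.int(length(ok), 1L)]
    } else {
      e <- internal[order(abs(sizes[internal] - clade_size),
                          tree$edge[internal, 2])][1L]
    }
    tip_states <- stats::setNames(rep(states[1], ntip), tree$tip.label)
    tip_states[desc[[e]]] <- states[2]
  } else {
    node_state <- integer(ntip + tree$Nnode)
    node_state[ntip + 1L] <- match(root_state, states)
    pre <- ape::reorder.phylo(tree, "cladewise")
    o <- match(paste(pre$edge[, 1], pre$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
    for (i in seq_len(nrow(pre$edge))) {
      p <- pre$edge[i, 1]; v <- pre$edge[i, 2]
      len <- tree$edge.length[o[i]]
      flip <- stats::runif(1) < 0.5 * (1 - exp(-2 * rate * len))
      node_state[v] <- if (flip) 3L - node_state[p] else node_state[p]
    }
    tip_states <- stats::setNames(states[node_state[seq_len(ntip)]], tree$tip.label)
  }
  list(tip_states = tip_states, painting = paint_regimes(tree, tip_states))
}

# mean vector and covariance implied by a model spec; shared by simulate_trait
.model_mean_cov <- function(tree, model, params, painting = NULL) {
  n <- ape::Ntip(tree)
  ones <- rep(1, n)
  switch(model,
    BM = {
      C <- phylo_vcv(tree)
      list(mean = (params$z0 %||% 0) * ones, cov = params$sigma2 * C)
    },
    BMM = {
      if (is.null(painting)) stop("BMM simulation needs a regime painting")
      Cr <- .regime_vcv(tree, painting)
      s <- params$sigma2   # named by regime
      if (is.null(names(s))) names(s) <- painting$levels
      V <- Reduce(`+`, lapply(painting$levels, function(r) s[[r]] * Cr[[r]]))
      list(mean = (params$z0 %||% 0) * ones, cov = V)
    },
    DELTA = {
      C <- phylo_vcv(tree)
      list(mean = (params$z0 %||% 0) * ones,
           cov = params$sigma2 * delta_transform(C, params$delta))
    },
    OU1 = {
      list(mean = params$theta * ones,
           cov = ou_covariance(tree, params$alpha, params$sigma2))
    },
    OUM = {
      if (is.null(painting)) stop("OUM simulation needs a regime painting")
      W <- oum_design_weights(tree, painting, params$alpha)
      th <- params$theta
      if (is.null(names(th))) names(th) <- painting$levels
      list(mean = as.numeric(W %*% th[colnames(W)]),
           cov = ou_covariance(tree, params$alpha, params$sigma2))
    },
    SHIFT = {
      X <- .shift_design(tree, params$edges, params$alpha)
      beta <- c(params$theta0, params$delta)
      list(mean = as.numeric(X %*% beta),
           cov = ou_covariance(tree, params$alpha, params$sigma2))
    },
    stop("unknown model '", model, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate trait values under a trait-evolution model
#'
#' Exact multivariate-normal draw from the mean and covariance the chosen
#' model implies on the tree. Supported models and their `params`:
#' * `"BM"`: `sigma2`, optional `z0` (root state, default 0).
#' * `"BMM"`: `sigma2` (named per-regime vector), `z0`; needs `painting`.
#' * `"DELTA"`: `sigma2`, `delta`, `z0` (unit-depth tree).
#' * `"OU1"`: `alpha`, `sigma2`, `theta`.
#' * `"OUM"`: `alpha`, `sigma2`, `theta` (named per-regime); needs `painting`.
#' * `"SHIFT"`: `alpha`, `sigma2`, `theta0`, `edges`, `delta` (per-edge
#'   optimum offsets).
#' * `"BM_PAIR"`: correlated pair; `sigma2_x`, `slope`, `intercept`
#'   (default 0), `sigma2_resid` — `x` is BM and
#'   `y = intercept + slope x + BM residual`.
#'
#' @param tree An ultrametric `phylo` object (unit depth for DELTA).
#' @param model Model name (see above).
#' @param params Named list of parameters.
#' @param seed Integer seed.
#' @param painting Regime painting for BMM/OUM.
#' @param n_rep Number of independent replicate draws (columns).
#' @return For most models a numeric matrix (tips x `n_rep`) with tip-label
#'   rownames (a named vector if `n_rep = 1`); for `"BM_PAIR"` a list with
#'   matrices `x` and `y`.
#' @export
simulate_trait <- function(tree, model, params, seed = 1L, painting = NULL,
                           n_rep = 1L) {
  set.seed(seed)
  n <- ape::Ntip(tree)
  if (model == "BM_PAIR") {
    C <- phylo_vcv(tree)
    Lx <- chol(params$sigma2_x * C)
    Le <- chol(params$sigma2_resid * C)
    X <- t(Lx) %*% matrix(stats::rnorm(n * n_rep), n)
    Y <- (params$intercept %||% 0) + params$slope * X +
      t(Le) %*% matrix(stats::rnorm(n * n_rep), n)
    rownames(X) <- rownames(Y) <- tree$tip.label
    return(list(x = if (n_rep == 1L) X[, 1] else X,
                y = if (n_rep == 1L) Y[, 1] else Y))
  }
  mc <- .model_mean_cov(tree, model, params, painting)
  L <- chol(mc$cov)
  Z <- matrix(stats::rnorm(n * n_rep), n)
  out <- mc$mean + t(L) %*% Z
  rownames(out) <- tree$tip.label
  if (n_rep == 1L) out[, 1] else out
}

# Table-mimicking fixture constants: life-form group means (mg/g) and
# log10-scale element dispersions/correlations for the synthetic community.
.FIXTURE_MEANS <- rbind(
  fern      = c(C = 396, N = 22.44, P = 1.69, K = 16.09, Ca = 6.58, Mg = 2.23),
  herb      = c(C = 390, N = 26.53, P = 1.94, K = 17.73, Ca = 7.08, Mg = 2.38),
  evergreen = c(C = 433, N = 19.16, P = 1.30, K = 9.08,  Ca = 8.49, Mg = 3.73),
  deciduous = c(C = 398, N = 24.59, P = 1.86, K = 13.94, Ca = 13.20, Mg = 4.81))
# within-life-form dispersions on the log10 scale, back-computed from the
# group-level standard errors (SE * sqrt(n) / (mean * ln 10), averaged over
# the four life forms)
.FIXTURE_SD_LOG10 <- c(C = 0.028, N = 0.079, P = 0.099, K = 0.115,
                       Ca = 0.252, Mg = 0.147)
.FIXTURE_COR <- local({
  el <- c("C", "N", "P", "K", "Ca", "Mg")
  R <- diag(6); dimnames(R) <- list(el, el)
  set_ <- function(a, b, v) { R[a, b] <<- v; R[b, a] <<- v }
  set_("N", "P", 0.60); set_("N", "K", 0.45); set_("P", "K", 0.55)
  set_("Ca", "Mg", 0.95)
  set_("C", "N", -0.45); set_("C", "P", -0.40); set_("C", "K", -0.35)
  # C vs Ca/Mg essentially uncorrelated: C varies little, so even a small
  # correlation would produce visibly non-zero slopes on the C column
  set_("C", "Ca", 0); set_("C", "Mg", 0)
  set_("N", "Ca", 0.05); set_("N", "Mg", 0.05)
  set_("P", "Ca", 0.10); set_("P", "Mg", 0.05)
  set_("K", "Ca", 0.10); set_("K", "Mg", 0.15)
  R
})

#' Generate a study-mimicking synthetic community fixture
#'
#' A synthetic stand-in for a 102-species subtropical forest community: a
#' 102-tip unit-depth Yule tree whose tips are assigned, in cladewise order,
#' to contiguous life-form blocks of 19 ferns, 16 herbs, 43 evergreen and 24
#' deciduous woody species (so life forms are phylogenetically clustered), and
#' six leaf element concentrations drawn on the log10 scale around the
#' life-form group means, with a strong positive N-P-K correlation block, a
#' Ca-Mg correlation of 0.95, negative C-nutrient correlations, and partially
#' phylogenetic residuals (a lambda-style mix of BM and independent noise,
#' weight `phylo_weight`, giving the weak-but-nonzero signal regime typical of
#' such data). All values are synthetic; nothing is measured data.
#'
#' @param seed Integer seed.
#' @param n_fern,n_herb,n_evergreen,n_deciduous Group sizes
#'   (defaults 19/16/43/24).
#' @param phylo_weight Weight of the BM component in the residual covariance
#'   across species (default 0.35).
#' @return A list with `tree` (102-tip unit-depth `phylo`), `traits`
#'   (a [trait_table()]), and `params` (the ground-truth generator settings:
#'   group means, log10 SDs, correlation matrix, weights, seed).
#' @export
make_study_fixture <- function(seed = 1L, n_fern = 19L, n_herb = 16L,
                               n_evergreen = 43L, n_deciduous = 24L,
                               phylo_weight = 0.35) {
  sizes <- c(fern = n_fern, herb = n_herb,
             evergreen = n_evergreen, deciduous = n_deciduous)
  n <- sum(sizes)
  tree <- simulate_tree(n, seed = seed)
  # tips in plotting (cladewise) order -> contiguous life-form blocks
  pre <- ape::reorder.phylo(tree, "cladewise")
  tip_order <- pre$edge[pre$edge[, 2] <= n, 2]
  life_form <- character(n)
  life_form[tip_order] <- rep(names(sizes), sizes)
  names(life_form) <- tree$tip.label

  el <- colnames(.FIXTURE_MEANS)
  mu <- log10(.FIXTURE_MEANS[life_form, el, drop = FALSE])
  Sigma_el <- diag(.FIXTURE_SD_LOG10[el]) %*% .FIXTURE_COR[el, el] %*%
    diag(.FIXTURE_SD_LOG10[el])
  C_sp <- phylo_weight * phylo_vcv(tree) + (1 - phylo_weight) * diag(n)
  set.seed(seed + 1L)
  Z <- matrix(stats::rnorm(n * length(el)), n)
  resid <- t(chol(C_sp)) %*% Z %*% chol(Sigma_el)
  vals <- 10^(mu + resid)
  df <- data.frame(species = tree$tip.label, vals, life_form = life_form,
                   row.names = NULL, check.names = FALSE)
  traits <- trait_table(df)
  list(tree = tree, traits = traits,
       params = list(seed = seed, sizes = sizes,
                     group_means = .FIXTURE_MEANS,
                     sd_log10 = .FIXTURE_SD_LOG10,
                     cor_log10 = .FIXTURE_COR,
                     phylo_weight = phylo_weight))
}
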