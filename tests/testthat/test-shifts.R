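test_that("shift_loglik with no shifts equals the OU1 likelihood", {
  tr <- small_tree(20, seed = 5)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 6)
  ou1 <- fit_ou1(tr, x)
  s <- shift_loglik(tr, x, integer(0), alpha = ou1$params$alpha)
  expect_equal(s$loglik, ou1$loglik, tolerance = 1e-9)
  expect_equal(s$theta0, ou1$params$theta, tolerance = 1e-8)
})

test_that("shifted-OU means match the closed-form oracle; alpha limits", {
  tr <- small_tree(12, seed = 8)
  desc <- bgcniche:::.edge_descendants(tr)
  internal <- which(tr$edge[, 2] > ape::Ntip(tr))
  e <- internal[which.max(lengths(desc)[internal] *
                          (lengths(desc)[internal] < 12))]
  alpha <- 4; theta0 <- 1; delta <- 2.5
  mu <- naive_shift_mean(tr, e, alpha, theta0, delta)
  X <- bgcniche:::.shift_design(tr, e, alpha)
  expect_equal(as.numeric(X %*% c(theta0, delta)), mu, tolerance = 1e-12)
  # pendant shift: that tip's mean moves by delta * (1 - exp(-alpha * len))
  pend <- which(tr$edge[, 2] == 1L)
  mu_p <- naive_shift_mean(tr, pend, alpha, theta0, delta)
  len <- tr$edge.length[pend]
  expect_equal(mu_p[1], theta0 + delta * (1 - exp(-alpha * len)), tolerance = 1e-12)
  expect_equal(mu_p[-1], rep(theta0, 11), ignore_attr = TRUE)
  # alpha -> infinity: design column approaches the descendant indicator
  Xb <- bgcniche:::.shift_design(tr, e, 1e4)
  ind <- numeric(12); ind[desc[[e]]] <- 1
  expect_equal(unname(Xb[, 2]), ind, tolerance = 1e-10)
})

test_that("shift likelihood matches brute-force MVN at fitted parameters", {
  for (seed in 1:4) {
    tr <- small_tree(7, seed = 600 + seed)
    x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 700 + seed)
    internal <- which(tr$edge[, 2] > 7)
    e <- internal[1 + (seed %% length(internal))]
    alpha <- c(0.5, 2, 8, 30)[seed]
    s <- shift_loglik(tr, x, e, alpha)
    mu <- naive_shift_mean(tr, s$edges, alpha, s$theta0, s$delta)
    expect_equal(s$loglik,
                 naive_dmvnorm(x[tr$tip.label], mu,
                               naive_ou_cov(tr, alpha, s$sigma2)),
                 tolerance = 1e-6)
  }
})

test_that("shift_loglik input validation", {
  tr <- small_tree(8, seed = 3)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 4)
  expect_error(shift_loglik(tr, x, c(1, 1), 2), "distinct")
  expect_error(shift_loglik(tr, x, 999, 2), "out of range")
})

test_that("greedy search: monotone lnL, infinite penalty guard, determinism", {
  tr <- small_tree(32, seed = 15)
  reg_edges <- which(tr$edge[, 2] > 32)
  e_true <- reg_edges[which.max(tr$edge.length[reg_edges])]
  x <- simulate_trait(tr, "SHIFT",
                      list(alpha = 8, sigma2 = 1, theta0 = 0,
                           edges = e_true, delta = 3),
                      seed = 16)
  s <- search_shifts(tr, x, max_shifts = 4)
  expect_true(all(diff(s$trace$loglik[s$trace$accepted]) > -1e-9))
  s_inf <- search_shifts(tr, x, max_shifts = 4, per_shift_penalty = Inf)
  expect_equal(s_inf$m, 0L)
  s2 <- search_shifts(tr, x, max_shifts = 4)
  expect_identical(s$edges, s2$edges)
  expect_error(search_shifts(tr, x, max_shifts = nrow(tr$edge)), "max_shifts")
})

test_that("a large shift is recovered on or adjacent to the true edge", {
  tr <- small_tree(64, seed = 25)
  desc <- bgcniche:::.edge_descendants(tr)
  sizes <- lengths(desc)
  # root-child edges excluded: a root-edge shift equals one on its sibling
  cand <- which(sizes >= 8 & sizes <= 32 & tr$edge[, 1] != 65L)
  e_true <- cand[which.max(tr$edge.length[cand])]
  alpha <- 8; sigma2 <- 1
  delta <- 4 * sqrt(sigma2 / (2 * alpha))
  x <- simulate_trait(tr, "SHIFT",
                      list(alpha = alpha, sigma2 = sigma2, theta0 = 0,
                           edges = e_true, delta = delta),
                      seed = 26)
  s <- search_shifts(tr, x)
  expect_gte(s$m, 1L)
  adjacent <- unique(c(e_true,
                       which(tr$edge[, 2] == tr$edge[e_true, 1]),  # parent
                       which(tr$edge[, 1] == tr$edge[e_true, 2]),  # children
                       which(tr$edge[, 1] == tr$edge[e_true, 1]))) # siblings
  expect_true(any(s$edges %in% adjacent))
})

test_that("shuffling the trait destroys detected shifts", {
  tr <- small_tree(48, seed = 35)
  desc <- bgcniche:::.edge_descendants(tr)
  sizes <- lengths(desc)
  cand <- which(sizes >= 6 & sizes <= 24)
  e_true <- cand[which.max(tr$edge.length[cand])]
  x <- simulate_trait(tr, "SHIFT",
                      list(alpha = 8, sigma2 = 1, theta0 = 0,
                           edges = e_true, delta = 3),
                      seed = 36)
  m_obs <- search_shifts(tr, x)$m
  set.seed(37)
  m_shuf <- vapply(1:10, function(i) {
    xs <- setNames(sample(as.numeric(x)), names(x))
    search_shifts(tr, xs)$m
  }, numeric(1))
  expect_lte(stats::median(m_shuf), m_obs)
})
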