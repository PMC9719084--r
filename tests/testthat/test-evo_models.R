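test_that("fit_bm reproduces the closed-form 2-tip hand computation", {
  tr <- read_newick("(A:1,B:1);")
  x <- setNames(c(0, 2), c("A", "B"))
  f <- fit_bm(tr, x)
  expect_equal(f$params$z0, 1)
  expect_equal(f$params$sigma2, 1)
  expect_equal(f$loglik, -(log(2 * pi) + 1), tolerance = 1e-12)
  expect_true(is.na(f$aicc))  # undefined at n = k + 1
})

test_that("aicc follows its closed form and errors when undefined", {
  expect_equal(aicc(0, 2, 102), 4 + 12 / 99)
  expect_equal(aicc(0, 2, 1e9), 4, tolerance = 1e-6)
  expect_equal(aicc(-50, 4, 102), 100 + 8 + 40 / 97)
  expect_error(aicc(0, 3, 4), "n must exceed")
})

test_that("delta and lambda transforms match their definitions", {
  tr <- small_tree(8, seed = 2)
  C <- phylo_vcv(tr)
  expect_equal(delta_transform(C, 1), C)
  expect_identical(max(abs(delta_transform(C, 1) - C)), 0)
  expect_equal(delta_transform(matrix(c(1, .5, .5, 1), 2), 2)[1, 2], 0.25)
  st_C <- phylo_vcv(star_tree(5))
  expect_equal(delta_transform(st_C, 7), st_C)   # 0^delta = 0
  expect_error(delta_transform(C, 0), "positive")
  expect_error(delta_transform(2 * C, 2), "unit-depth")

  expect_equal(lambda_transform(C, 1), C)
  expect_identical(max(abs(lambda_transform(C, 1) - C)), 0)
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  expect_equal(lambda_transform(matrix(c(1, .5, .5, 1), 2), 0.4)[1, 2], 0.2)
  expect_error(lambda_transform(C, 1.2), "\\[0, 1\\]")
})

test_that("OU covariance: disjoint paths, diagonal, BM limit", {
  tr <- read_newick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  V <- ou_covariance(tr, alpha = 2, sigma2 = 3)
  # A and C share no path: s = 0, so covariance is 0
  expect_equal(unname(V["A", "C"]), 0)
  # A and B: MRCA depth 0.5, patristic distance 1
  expect_equal(unname(V["A", "B"]),
               3 / 4 * exp(-2 * 1) * (1 - exp(-2 * 2 * 0.5)))
  expect_equal(unname(diag(V)), rep(3 / 4 * (1 - exp(-4)), 4))
  st <- star_tree(4)   # s_ij = 0 off-diagonal
  Vs <- ou_covariance(st, alpha = 1, sigma2 = 1)
  expect_equal(unname(Vs[1, 2]), 0)
  # alpha -> 0 limit reproduces the BM covariance
  expect_lt(max(abs(ou_covariance(tr, 1e-8, 2) - 2 * phylo_vcv(tr))), 1e-6)
  expect_error(ou_covariance(read_newick("((A:1,B:2):1,C:2);"), 1), "ultrametric")
})

test_that("OUM design weights: single regime, large-alpha limit, hand check", {
  tr <- read_newick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  one_reg <- paint_regimes(tr, setNames(rep("w", 4), tr$tip.label))
  W1 <- oum_design_weights(tr, one_reg, alpha = 3)
  expect_equal(unname(W1[, 1]), rep(1, 4))

  st <- setNames(c("H", "H", "W", "W"), c("A", "B", "C", "D"))
  p <- paint_regimes(tr, st)
  Wbig <- oum_design_weights(tr, p, alpha = 500)
  expect_equal(unname(Wbig[match("A", rownames(Wbig)), "H"]), 1, tolerance = 1e-12)
  expect_equal(unname(Wbig[match("C", rownames(Wbig)), "W"]), 1, tolerance = 1e-12)

  a <- 2
  W <- oum_design_weights(tr, p, alpha = a)
  expect_equal(unname(rowSums(W)), rep(1, 4), tolerance = 1e-12)
  # per-segment hand computation for tip A (root regime is H):
  # pendant (depth .5 -> 1, H) and stem (0 -> .5, H), root weight exp(-a)
  wA_H <- (exp(0) - exp(-a * 0.5)) + (exp(-a * 0.5) - exp(-a * 1)) + exp(-a)
  expect_equal(unname(W[match("A", rownames(W)), "H"]), wA_H, tolerance = 1e-12)
  # tip C: pendant+stem in W, residual root weight in H
  wC_W <- (exp(0) - exp(-a * 0.5)) + (exp(-a * 0.5) - exp(-a * 1))
  expect_equal(unname(W[match("C", rownames(W)), "W"]), wC_W, tolerance = 1e-12)
  expect_equal(unname(W[match("C", rownames(W)), "H"]), exp(-a), tolerance = 1e-12)
  # oracle agreement on the implied means
  theta <- c(H = 2, W = -1)
  expect_equal(as.numeric(W %*% theta),
               naive_oum_mean(tr, p$edge_states, p$root_state, a, theta),
               tolerance = 1e-12)
})

test_that("model nesting holds on every fit", {
  for (seed in 1:6) {
    tr <- small_tree(24, seed = 200 + seed)
    reg <- simulate_regimes(tr, "clade", seed = seed)
    x <- simulate_trait(tr, "BM", list(sigma2 = 0.7), seed = 300 + seed)
    bm <- fit_bm(tr, x)
    bmm <- fit_bmm(tr, x, reg$painting)
    dl <- fit_delta(tr, x)
    ou1 <- fit_ou1(tr, x)
    oum <- fit_oum(tr, x, reg$painting, ou1 = ou1)
    expect_gte(bmm$loglik, bm$loglik - 1e-9)
    expect_gte(dl$loglik, bm$loglik - 1e-9)
    expect_gte(oum$loglik, ou1$loglik - 1e-9)
  }
})

test_that("small-tree log-likelihoods match brute-force MVN evaluation", {
  # reduced-scale version of the oracle-equivalence acceptance criterion
  for (seed in 1:8) {
    n <- 4 + (seed %% 5)
    tr <- small_tree(n, seed = 400 + seed)
    reg <- simulate_regimes(tr, "clade", seed = seed, clade_size = max(2, n %/% 2))
    x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 500 + seed)

    bm <- fit_bm(tr, x)
    expect_equal(bm$loglik,
                 naive_dmvnorm(x[tr$tip.label], rep(bm$params$z0, n),
                               bm$params$sigma2 * naive_bm_cov(tr)),
                 tolerance = 1e-6)

    bmm <- fit_bmm(tr, x, reg$painting)
    Vb <- naive_bmm_cov(tr, reg$painting$edge_states, bmm$params$sigma2)
    expect_equal(bmm$loglik,
                 naive_dmvnorm(x[tr$tip.label], rep(bmm$params$z0, n), Vb),
                 tolerance = 1e-6)

    dl <- fit_delta(tr, x)
    Vd <- dl$params$sigma2 * naive_bm_cov(tr)^dl$params$delta
    expect_equal(dl$loglik,
                 naive_dmvnorm(x[tr$tip.label], rep(dl$params$z0, n), Vd),
                 tolerance = 1e-6)

    ou1 <- fit_ou1(tr, x)
    expect_equal(ou1$loglik,
                 naive_dmvnorm(x[tr$tip.label], rep(ou1$params$theta, n),
                               naive_ou_cov(tr, ou1$params$alpha, ou1$params$sigma2)),
                 tolerance = 1e-6)

    oum <- fit_oum(tr, x, reg$painting, ou1 = ou1)
    mu <- naive_oum_mean(tr, reg$painting$edge_states, reg$painting$root_state,
                         oum$params$alpha, oum$params$theta)
    expect_equal(oum$loglik,
                 naive_dmvnorm(x[tr$tip.label], mu,
                               naive_ou_cov(tr, oum$params$alpha, oum$params$sigma2)),
                 tolerance = 1e-6)
  }
})

test_that("BMM recovers contrasting rates and errors on one regime", {
  tr <- small_tree(60, seed = 77)
  reg <- simulate_regimes(tr, "clade", seed = 3, clade_size = 30)
  x <- simulate_trait(tr, "BMM",
                      list(sigma2 = c(A = 0.1, B = 1.0), z0 = 0),
                      seed = 9, painting = reg$painting)
  f <- fit_bmm(tr, x, reg$painting)
  expect_lt(f$params$sigma2[["A"]], f$params$sigma2[["B"]])
  one <- paint_regimes(tr, setNames(rep("A", 60), tr$tip.label))
  expect_error(fit_bmm(tr, x, one), "fit_bm")
})

test_that("delta fit: null calibration and power on single draws", {
  tr <- small_tree(100, seed = 55)
  xb <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 56)
  f0 <- fit_delta(tr, xb)
  expect_gte(f0$loglik, fit_bm(tr, xb)$loglik - 1e-9)
  xd <- simulate_trait(tr, "DELTA", list(sigma2 = 1, delta = 5), seed = 57)
  f5 <- fit_delta(tr, xd)
  expect_gt(f5$params$delta, 1)
  expect_lt(f5$lrt_p, 0.05)
})

test_that("OU1/OUM recover simulated optima on single draws", {
  tr <- small_tree(100, seed = 61)
  x <- simulate_trait(tr, "OU1", list(alpha = 20, sigma2 = 1, theta = 5), seed = 62)
  f <- fit_ou1(tr, x)
  expect_lt(abs(f$params$theta - 5), 0.3)

  reg <- simulate_regimes(tr, "clade", seed = 2, clade_size = 50)
  xm <- simulate_trait(tr, "OUM",
                       list(alpha = 15, sigma2 = 1, theta = c(A = 2, B = -2)),
                       seed = 63, painting = reg$painting)
  fm <- fit_oum(tr, xm, reg$painting)
  expect_lt(abs(fm$params$theta[["A"]] - 2), 0.3)
  expect_lt(abs(fm$params$theta[["B"]] + 2), 0.3)
})

test_that("compare_models applies the AICc rule, tie-breaks, and guards", {
  mk <- function(model, aicc_target, k, n = 102) {
    # choose loglik to land on the requested AICc
    ll <- -(aicc_target - 2 * k - 2 * k * (k + 1) / (n - k - 1)) / 2
    new_fit <- fit_bm(small_tree(4, 1),
                      setNames(c(1, 2, 3, 2.5), paste0("t", 1:4)))
    new_fit$model <- model; new_fit$loglik <- ll
    new_fit$k <- k; new_fit$n <- n; new_fit$aicc <- aicc(ll, k, n)
    new_fit
  }
  cmp <- compare_models(list(mk("m1", 10, 3), mk("m2", 11.5, 3), mk("m3", 20, 3)))
  expect_equal(cmp$best, "m1")
  expect_setequal(cmp$equivalence_set, c("m1", "m2"))
  expect_equal(min(cmp$table$dAICc), 0)

  tie <- compare_models(list(mk("big", 10, 3), mk("small", 10, 2)))
  expect_equal(tie$best, "small")

  f1 <- mk("a", 10, 2); f2 <- mk("b", 11, 2); f2$n <- 50
  expect_error(compare_models(list(f1, f2)), "differing")
})
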