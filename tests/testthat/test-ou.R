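test_that("mean-weight rows sum to one and obey the single-regime closed form", {
  tr <- fixture_tree4()
  map1 <- single_regime_map(tr)
  for (a in c(0.001, 0.05, 0.5)) {
    W <- ou_mean_weights(tr, map1, c(all = a))
    expect_equal(unname(rowSums(W)), rep(1, 4), tolerance = 1e-12)
    Ti <- node_depths(tr)[1:4]
    expect_equal(unname(W[, "all"]), 1 - exp(-a * Ti), tolerance = 1e-12)
  }
  # alpha -> 0: all weight returns to the root state
  W0 <- ou_mean_weights(tr, map1, c(all = 0))
  expect_equal(unname(W0[, "Z0"]), rep(1, 4))

  # two-era painting on a hand-built 2-tip tree: hand-evaluated exponentials
  t2 <- ape::read.tree(text = "(A:10,B:10);")
  t2$root.time <- 10
  m2 <- paint_eras(t2, 4, labels = c("old", "young")) # switch at depth 6
  a <- 0.1
  W2 <- ou_mean_weights(t2, m2, c(old = a, young = a))
  expect_equal(unname(W2["A", "Z0"]), exp(-a * 10), tolerance = 1e-12)
  expect_equal(unname(W2["A", "old"]), exp(-a * 4) - exp(-a * 10), tolerance = 1e-12)
  expect_equal(unname(W2["A", "young"]), 1 - exp(-a * 4), tolerance = 1e-12)
})

test_that("OU covariance obeys closed forms and the Brownian limit", {
  tr <- fixture_tree4()
  map <- single_regime_map(tr)
  a <- 0.04; b <- 0.002
  V <- ou_covariance(tr, map, c(all = a), c(all = b))
  Ti <- node_depths(tr)[1:4]
  expect_equal(unname(diag(V)), b / (2 * a) * (1 - exp(-2 * a * Ti)),
               tolerance = 1e-12)
  S <- shared_times(tr)
  off <- b / (2 * a) * (1 - exp(-2 * a * S["A", "B"])) *
    exp(-a * (Ti[1] + Ti[2] - 2 * S["A", "B"]))
  expect_equal(V["A", "B"], off, tolerance = 1e-12)

  # alpha -> 0 limit reduces to Brownian covariance within 1e-6 relative
  # (entries with zero shared time are exactly zero in both)
  Vbm <- ou_covariance(tr, map, c(all = 1e-10), c(all = b))
  pos <- S > 0
  expect_lt(max(abs(Vbm[pos] - b * S[pos]) / (b * S[pos])), 1e-6)
  expect_equal(unname(Vbm[!pos]), rep(0, sum(!pos)), tolerance = 1e-15)

  # positive-definite and symmetric across parameter draws
  set.seed(1)
  for (i in 1:5) {
    aa <- stats::runif(1, 1e-4, 0.2); bb <- stats::runif(1, 1e-4, 0.05)
    Vi <- ou_covariance(tr, map, c(all = aa), c(all = bb))
    expect_equal(Vi, t(Vi), tolerance = 1e-12)
    expect_true(all(eigen(Vi, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("measurement error enters only the covariance diagonal", {
  tr <- fixture_tree4()
  map <- single_regime_map(tr)
  se <- c(A = 0.1, B = 0, C = 0.2, D = 0.05)
  V0 <- ou_covariance(tr, map, c(all = 0.02), c(all = 0.001))
  V1 <- ou_covariance(tr, map, c(all = 0.02), c(all = 0.001), se = se)
  expect_equal(unname(diag(V1) - diag(V0)), unname(se[rownames(V0)]^2),
               tolerance = 1e-12)
  V0d <- V0; diag(V0d) <- 0; V1d <- V1; diag(V1d) <- 0
  expect_equal(V1d, V0d, tolerance = 1e-15)
})

test_that("analytic moments match Monte-Carlo moments for multi-regime paintings", {
  tr <- fixture_tree4()
  map <- paint_eras(tr, 50, labels = c("basal", "derived"))
  cases <- list(
    shared = list(a = c(basal = 0.03, derived = 0.03), b = c(basal = 2e-3, derived = 2e-3)),
    oumv = list(a = c(basal = 0.03, derived = 0.03), b = c(basal = 2e-3, derived = 8e-3)),
    oumva = list(a = c(basal = 0.03, derived = 0.01), b = c(basal = 2e-3, derived = 8e-3)))
  th <- c(basal = 0, derived = 1)
  n_rep <- 20000
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    V <- ou_covariance(tr, map, cs$a, cs$b)
    W <- ou_mean_weights(tr, map, cs$a)
    mu <- drop(W %*% c(0.3, th))
    X <- simulate_trait(tr, map = map, alpha = cs$a, beta = cs$b, theta = th,
                        Z0 = 0.3, se_scale = 0, n_rep = n_rep,
                        seed = derive_seed(1, nm))
    Vemp <- stats::cov(t(X))
    mu_emp <- rowMeans(X)
    se_mean <- sqrt(diag(V) / n_rep)
    expect_true(all(abs(mu - mu_emp) < 3.5 * se_mean))
    se_cov <- sqrt((outer(diag(V), diag(V)) + V^2) / n_rep)
    expect_true(all(abs(V - Vemp) < 3.5 * se_cov))
  }
})

test_that("BM log-likelihood matches closed forms and brute-force assembly", {
  # cherry with equal pendant branches: bivariate normal closed form
  tr <- ape::read.tree(text = "(A:7,B:7);")
  tr$root.time <- 7
  y <- c(A = 0.3, B = -0.1)
  b <- 0.004; z0 <- 0.05
  V <- matrix(b * c(7, 0, 0, 7), 2)
  lnL_closed <- -log(2 * pi) - 0.5 * determinant(V)$modulus[1] -
    0.5 * drop(t(y - z0) %*% solve(V) %*% (y - z0))
  expect_equal(bm_loglik(tr, y, b, z0), lnL_closed, tolerance = 1e-12)

  # scaling invariance: durations * c and beta / c leave lnL unchanged
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 13; tr2$root.time <- 7 * 13
  expect_equal(bm_loglik(tr2, y, b / 13, z0), bm_loglik(tr, y, b, z0),
               tolerance = 1e-10)

  # 5-tip tree against independent path-enumeration covariance assembly
  tr5 <- fixture_tree5()
  set.seed(8)
  y5 <- stats::setNames(stats::rnorm(5, 0, 0.3), tr5$tip.label)
  Vb <- brute_bm_cov(tr5, 0.002)
  lnL_brute <- mvtnorm_logdens(y5, rep(0.1, 5), Vb)
  expect_equal(bm_loglik(tr5, y5, 0.002, 0.1), lnL_brute, tolerance = 1e-10)
})

test_that("AICc and Akaike weights follow their closed forms", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7, tolerance = 1e-12)
  expect_error(aicc(0, 9, 10), "undefined")
  w <- akaike_weights(c(10, 10, 10))
  expect_equal(w, rep(1 / 3, 3), tolerance = 1e-12)
  w2 <- akaike_weights(c(10, 12))
  expect_equal(w2[1] / w2[2], exp(1), tolerance = 1e-12)
  expect_equal(sum(w2), 1, tolerance = 1e-12)
})

test_that("derived quantities recompute half-life, trend coefficient and metre optima", {
  f <- list(alpha = c(r1 = log(2)), theta = c(r1 = 0.5), se_theta = c(r1 = 0.1))
  d <- derived_quantities(f)
  expect_equal(d$half_life, 1)
  expect_equal(d$mu, log(2) * 0.5)
  expect_equal(d$mu_hi, log(2) * 0.7)
  expect_equal(d$theta_m, 10^0.5)
  f0 <- list(alpha = c(r1 = 0), theta = c(r1 = 0.5), se_theta = c(r1 = 0.1))
  expect_equal(derived_quantities(f0)$half_life, Inf)
})

test_that("model fitting recovers nesting, permutation invariance and convergence", {
  tr <- simulate_tree(50, 120, seed = 6)
  map <- single_regime_map(tr)
  tv <- simulate_trait(tr, map = map, alpha = c(all = 0), beta = c(all = 1e-3),
                       theta = c(all = 0), Z0 = 0.2, se_scale = 0, seed = 7)
  y <- stats::setNames(tv$value, tv$taxon)
  fbm <- fit_model(model_spec("BM1", mserr = FALSE), tr, y)
  fou <- fit_model(model_spec("OU1", mserr = FALSE), tr, y)
  expect_true(fbm$convergence && fou$convergence)
  # OU1 nests BM1: its optimised likelihood cannot be lower
  expect_gte(fou$lnL, fbm$lnL - 1e-6)
  # on BM data attraction is weak: no real likelihood gain over BM and a
  # fitted half-life not much shorter than the tree span
  expect_lt(fou$lnL - fbm$lnL, 3)
  expect_lt(fou$alpha[[1]], 0.05)
  expect_equal(fbm$k, 2L); expect_equal(fou$k, 3L)

  # permuting taxon order leaves the likelihood unchanged
  yp <- y[sample(names(y))]
  fbm2 <- fit_model(model_spec("BM1", mserr = FALSE), tr, yp)
  expect_equal(fbm2$lnL, fbm$lnL, tolerance = 1e-9)

  # parameter counts for the multi-regime families (2 regimes)
  m <- paint_eras(tr, 100, labels = c("e1", "e2"))
  expect_equal(model_k_for_test("OUM", m, tr, y), 4L)    # a, b, th1, th2
  expect_equal(model_k_for_test("OUMV", m, tr, y), 5L)
  expect_equal(model_k_for_test("OUMA", m, tr, y), 5L)
  expect_equal(model_k_for_test("OUMVA", m, tr, y), 6L)
})

test_that("a separate root state is estimated when requested", {
  tr <- simulate_tree(60, 140, seed = 12)
  map <- paint_eras(tr, 120, labels = c("basal", "derived"))
  tv <- simulate_trait(tr, map = map, alpha = c(basal = 0.05, derived = 0.05),
                       beta = c(basal = 1e-3, derived = 1e-3),
                       theta = c(basal = 0.1, derived = 0.7), Z0 = -0.4,
                       se_scale = 0, seed = 13)
  f <- fit_model(model_spec("OUM", regime_map = map, root_mode = "separate",
                            mserr = FALSE), tr, tv, seed = 1)
  expect_true(f$convergence)
  expect_equal(f$k, 5L) # a, b, th1, th2, Z0
  expect_true(is.finite(f$Z0) && is.finite(f$se_Z0))
  # the derived optimum is recovered above the basal one
  expect_gt(f$theta[["derived"]], f$theta[["basal"]])
})
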