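test_that("tree simulation is seeded, sized and non-ultrametric", {
  t1 <- simulate_tree(2, 100, seed = 4)
  expect_equal(ape::Ntip(t1), 2L)
  expect_lte(max(node_depths(t1)), 100 + 1e-9)

  expect_identical(ape::write.tree(simulate_tree(20, 120, seed = 9)),
                   ape::write.tree(simulate_tree(20, 120, seed = 9)))
  expect_error(simulate_tree(1, 100, seed = 1), "n_tips")

  big <- simulate_tree(100, 160, seed = 2)
  depths <- node_depths(big)[seq_len(100)]
  expect_gt(stats::var(depths), 0) # extinct lineages: heterogeneous tip depths
  expect_equal(max(depths), 160, tolerance = 1e-9)
})

test_that("exact OU transitions reproduce the BM and stationary limits", {
  tr <- ape::read.tree(text = "(A:5,B:5);")
  tr$root.time <- 5
  map <- single_regime_map(tr)
  # BM limit: variance ~ beta * t over replicates
  X <- simulate_trait(tr, map = map, alpha = c(all = 0), beta = c(all = 0.02),
                      theta = c(all = 0), Z0 = 1, se_scale = 0,
                      n_rep = 10000, seed = 1)
  expect_equal(stats::var(X["A", ]), 0.02 * 5, tolerance = 0.05)
  expect_equal(mean(X["A", ]), 1, tolerance = 0.02)

  # stationary limit: alpha * t >> 1 gives mean theta, variance beta/(2 alpha)
  trl <- ape::read.tree(text = "(A:400,B:400);")
  trl$root.time <- 400
  Xs <- simulate_trait(trl, map = single_regime_map(trl), alpha = c(all = 0.3),
                       beta = c(all = 0.02), theta = c(all = 2), Z0 = 0,
                       se_scale = 0, n_rep = 10000, seed = 2)
  expect_equal(mean(Xs["A", ]), 2, tolerance = 0.01)
  expect_equal(stats::var(Xs["A", ]), 0.02 / (2 * 0.3), tolerance = 0.06)
})

test_that("exact transitions agree with Euler-Maruyama on one branch", {
  tr <- ape::read.tree(text = "(A:5,B:5);")
  tr$root.time <- 5
  n_rep <- 10000
  X <- simulate_trait(tr, map = single_regime_map(tr), alpha = c(all = 0.3),
                      beta = c(all = 0.02), theta = c(all = 1), Z0 = 0,
                      se_scale = 0, n_rep = n_rep, seed = 3)["A", ]
  set.seed(4)
  em <- em_simulate(n_rep, 5, 0.3, 0.02, 1, 0)
  # means and variances within 3 Monte-Carlo standard errors of each other
  mc_se_mean <- sqrt(stats::var(X) / n_rep + stats::var(em) / n_rep)
  expect_lt(abs(mean(X) - mean(em)), 3 * mc_se_mean)
  mc_se_var <- sqrt(2 / (n_rep - 1)) * sqrt(stats::var(X) * stats::var(em))
  expect_lt(abs(stats::var(X) - stats::var(em)), 3 * mc_se_var)
})

test_that("observation noise adds se^2 to the tip variance", {
  tr <- ape::read.tree(text = "(A:5,B:5);")
  tr$root.time <- 5
  X0 <- simulate_trait(tr, map = single_regime_map(tr), alpha = c(all = 0),
                       beta = c(all = 0.001), theta = c(all = 0), Z0 = 0,
                       se_scale = 0.3, n_rep = 10000, seed = 5)
  expect_equal(stats::var(X0["A", ]), 0.001 * 5 + 0.09, tolerance = 0.05)
})

test_that("missingness deletion matches the requested fractions", {
  tab <- complete_measurements(sprintf("t%04d", 1:1000))
  same <- apply_missingness(tab, c(phIV4 = 0), seed = 1)
  expect_identical(same, tab)
  gone <- apply_missingness(tab, c(phIV4 = 1), seed = 1)
  expect_true(all(is.na(gone$phIV4)))
  part <- apply_missingness(tab, c(phIV4 = 0.3), seed = 2)
  n_del <- sum(is.na(part$phIV4))
  # binomial(1000, 0.3) central 99% interval
  expect_gte(n_del, stats::qbinom(0.005, 1000, 0.3))
  expect_lte(n_del, stats::qbinom(0.995, 1000, 0.3))
})

test_that("the synthetic deposit has the study's structure and exercises the parsers", {
  dir <- withr::local_tempdir()
  st <- simulate_study(sim_scenario(seed = 7), dir = dir)
  expect_equal(ape::Ntip(st$cladogram), 109L)
  expect_false(ape::is.binary.phylo(st$cladogram))
  expect_equal(nrow(st$measurements), 168L)
  # block-missingness leaves roughly a fifth of taxa with complete forelimbs
  n_direct <- count_direct_wingspans(st$measurements)
  expect_gte(n_direct, 20)
  expect_lte(n_direct, 55)

  clad <- read_newick(file.path(dir, "tree.nwk"))
  expect_equal(sort(clad$tip.label), sort(st$cladogram$tip.label))
  meas <- read_measurements(file.path(dir, "measurements.csv"))
  expect_equal(nrow(meas), 168L)
  ages <- read_ages(file.path(dir, "ages.csv"))
  expect_true(all(ages$age_max >= ages$age_min))
  # stratigraphic windows contain the true tip ages
  truth <- tip_ages(st$true_tree)
  expect_true(all(ages$age_max + 1e-9 >= truth[ages$taxon] &
                    ages$age_min - 1e-9 <= truth[ages$taxon]))
})

test_that("the two-era scenario produces a flat-then-increasing size trajectory", {
  sc <- sim_scenario(seed = 11)
  st <- simulate_study(sc)
  age <- tip_ages(st$true_tree)
  tv <- stats::setNames(st$true_traits$value, st$true_traits$taxon)
  df <- data.frame(taxon = names(age), value = tv[names(age)], age = unname(age))
  tf <- suppressMessages(trend_regressions(df, boundary_Ma = 145, seed = 1))
  old_ols <- tf[tf$label == "older" & tf$method == "ols", ]
  yng_ols <- tf[tf$label == "younger" & tf$method == "ols", ]
  # constrained early regime: slope indistinguishable from 0
  expect_gt(old_ols$p_value, 0.01)
  # trending late regime: significantly negative slope vs age
  expect_lt(yng_ols$slope, 0)
  expect_lt(yng_ols$p_value, 0.01)
})
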