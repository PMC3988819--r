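test_that("wingspan summation follows the configured element set and rescaling", {
  rec <- list(humerus = 100, ulna = 200, mcIV = 150, phIV1 = 250, phIV2 = 220,
              phIV3 = 180, phIV4 = 60, rescale_factor = 1)
  expect_equal(compute_wingspan(rec), log10(1.160), tolerance = 1e-12)
  rec$rescale_factor <- 2
  expect_equal(compute_wingspan(rec), log10(1.160) + log10(2), tolerance = 1e-12)
  rec$phIV4 <- NA
  expect_true(is.na(compute_wingspan(rec)))
})

test_that("adult filtering keeps only adults and errors when none remain", {
  tab <- complete_measurements()
  expect_equal(suppressMessages(filter_adults(tab)), tab)
  tab$status <- c("adult", "juvenile", "subadult", "adult", "adult", "juvenile")
  out <- suppressMessages(filter_adults(tab))
  expect_equal(nrow(out), 3L)
  expect_true(all(out$status == "adult"))
  tab$status <- "juvenile"
  expect_error(filter_adults(tab), "no adult")
})

test_that("phalanx IV-4 estimation fills only missing values and is idempotent", {
  sc <- sim_scenario(n_tips = 60, seed = 41, missingness = c(phIV4 = 0.4))
  tt <- simulate_tree(60, 160, seed = 42)
  tv <- simulate_trait(tt, sc, map = single_regime_map(tt, "basal"),
                       alpha = c(basal = 0.02), beta = c(basal = 8e-4),
                       theta = c(basal = 0), seed = 43)
  meas <- simulate_measurements(tt, stats::setNames(tv$value, tv$taxon), seed = 44)
  holy <- apply_missingness(meas, c(phIV4 = 0.4), seed = 45)
  observed <- !is.na(holy$phIV4)
  out <- suppressMessages(estimate_phalanx4(holy, tt))
  # observed values untouched, missing ones filled from phalanx IV-3
  expect_equal(out$phIV4[observed], holy$phIV4[observed])
  expect_true(all(!is.na(out$phIV4[!is.na(holy$phIV3)])))
  expect_true(all(out$phIV4_imputed[!observed & !is.na(holy$phIV3)]))
  expect_true(all(out$phIV4_se_log10[out$phIV4_imputed] > 0))
  # idempotent: a second pass changes nothing
  again <- suppressMessages(estimate_phalanx4(out, tt))
  expect_equal(again$phIV4, out$phIV4, tolerance = 1e-12)
  # imputations are nearly unbiased on the log scale
  err <- log10(out$phIV4[!observed]) - log10(meas$phIV4[!observed])
  expect_lt(abs(mean(err)), 3 * stats::sd(err) / sqrt(length(err)) + 0.02)
})

test_that("the wingspan cascade prefers direct sums and records provenance", {
  tt <- simulate_tree(80, 160, seed = 51)
  tv <- simulate_trait(tt, map = single_regime_map(tt, "b"),
                       alpha = c(b = 0.02), beta = c(b = 8e-4),
                       theta = c(b = 0.3), Z0 = 0.3, se_scale = 0, seed = 52)
  meas <- simulate_measurements(tt, stats::setNames(tv$value, tv$taxon), seed = 53)
  # engineer the tiers: 50 complete, 10 phIV2-only, 10 phIV1-only (no phIV2),
  # 5 humerus-only, 5 mandible-only
  wingcols <- c("humerus", "ulna", "mcIV", "phIV1", "phIV2", "phIV3", "phIV4")
  kill <- function(rows, keep) {
    for (cl in setdiff(wingcols, keep)) meas[rows, cl] <<- NA_real_
    if (!"mandible" %in% keep) meas[rows, "mandible"] <<- NA_real_
  }
  kill(51:60, c("phIV2", "mandible"))
  kill(61:70, "phIV1")
  kill(71:75, "humerus")
  kill(76:80, "mandible")
  out <- suppressMessages(estimate_wingspan_cascade(meas, tt))
  pv <- stats::setNames(out$provenance, out$taxon)
  expect_equal(sum(pv == "measured"), 50L)
  expect_equal(sum(pv == "estimated:phIV2"), 10L)
  expect_equal(sum(pv == "estimated:phIV1"), 10L)
  expect_equal(sum(pv == "estimated:humerus"), 5L)
  expect_equal(sum(pv == "estimated:mandible"), 5L)
  expect_true(all(out$se[out$provenance == "measured"] == 0))
  expect_true(all(out$se[out$provenance != "measured"] > 0))
  # estimates track the truth
  err <- out$value - stats::setNames(tv$value, tv$taxon)[out$taxon]
  expect_lt(mean(abs(err[pv != "measured"])), 0.25)
})

test_that("a taxon with no usable predictor is dropped with a message", {
  tt <- simulate_tree(40, 120, seed = 61)
  tv <- simulate_trait(tt, map = single_regime_map(tt, "b"), alpha = c(b = 0.02),
                       beta = c(b = 8e-4), theta = c(b = 0.3), Z0 = 0.3,
                       se_scale = 0, seed = 62)
  meas <- simulate_measurements(tt, stats::setNames(tv$value, tv$taxon), seed = 63)
  for (cl in c(element_columns <- c("skull","mandible","rostrum","humerus","ulna",
                                    "radius","mcIV","phIV1","phIV2","phIV3","phIV4")))
    meas[1, cl] <- NA_real_
  expect_message(out <- estimate_wingspan_cascade(meas, tt), "no usable predictor")
  expect_false(meas$taxon[1] %in% out$taxon)
  expect_equal(nrow(out), 39L)
})

test_that("direct wingspan counting ignores imputed phalanges", {
  tab <- complete_measurements()
  expect_equal(count_direct_wingspans(tab), 6L)
  tab$phIV4[1:2] <- NA
  expect_equal(count_direct_wingspans(tab), 4L)
  tab$phIV4[1] <- 55
  tab$phIV4_imputed <- c(TRUE, rep(FALSE, 5))
  expect_equal(count_direct_wingspans(tab), 4L)
})
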