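# Orchestration: replicate calibrated trees -> trait assembly -> model
# fitting -> AICc weights -> aggregation into comparison tables.

#' Build a pipeline configuration
#'
#' @param tree path to the cladogram Newick file (or a `phylo`).
#' @param measurements path to the measurement CSV (or a data.frame).
#' @param ages path to the stratigraphic age CSV (or a data.frame); when
#'   `NULL`, `age_max`/`age_min` columns of the measurement table are used.
#' @param n_replicate_trees replicate calibrations (default 25).
#' @param calibration `"mbl"` or `"equal"`.
#' @param min_bl minimum branch length (Ma) for `"mbl"`.
#' @param root_buffer root buffer (Ma) for `"equal"`.
#' @param clade_schemes named list of clade paintings, each a named list of
#'   tip vectors (passed to [paint_clades()]).
#' @param era_schemes named list of numeric boundary-age vectors (passed to
#'   [paint_eras()]).
#' @param families model families to fit across every regime scheme.
#' @param single_families single-regime reference models (always fitted).
#' @param root_modes root treatments fitted for each multi-regime model.
#' @param cascade_order wingspan predictor preference order.
#' @param exclude regression-outlier taxa.
#' @param trend_boundary_Ma era boundary for the trend regressions.
#' @param trend_age taxon age used in the trend regressions: stratigraphic
#'   `"midpoint"` (default) or the `"sampled"` tip ages of replicate 1.
#' @param mserr include per-tip error variances in model fitting.
#' @param seed master seed.
#' @param out_dir optional output directory for result files.
#' @return configuration list of class `pt_config`.
#' @export
pipeline_config <- function(tree, measurements, ages = NULL,
                            n_replicate_trees = 25,
                            calibration = c("mbl", "equal"), min_bl = 2,
                            root_buffer = 10,
                            clade_schemes = list(),
                            era_schemes = list(),
                            families = c("OUM", "OUMV", "OUMA"),
                            single_families = c("BM1", "OU1"),
                            root_modes = "theta",
                            cascade_order = c("phIV2", "phIV1", "humerus", "mandible"),
                            exclude = character(),
                            trend_boundary_Ma = 145,
                            trend_age = c("midpoint", "sampled"),
                            mserr = TRUE, seed = 1, out_dir = NULL) {
  trend_age <- match.arg(trend_age)
  calibration <- match.arg(calibration)
  if (n_replicate_trees < 1) stop_fmt("n_replicate_trees must be >= 1")
  if (!length(families) && !length(single_families))
    stop_fmt("configuration lists no model families")
  if (length(families) && !length(clade_schemes) && !length(era_schemes))
    stop_fmt("multi-regime families need at least one regime scheme")
  structure(as.list(environment()), class = "pt_config")
}

#' Run the full analysis pipeline
#'
#' For each replicate: resolve polytomies and sample tip ages (seeded),
#' time-calibrate, assemble the adult trait vector (phalanx IV-4 then
#' wingspan imputation, fitted on that replicate's tree), paint the
#' configured regime schemes, fit every model, and compute AICc weights
#' over the model set. Models that fail to converge are dropped for that
#' replicate (with the per-model success count reported). Era-split trend
#' regressions use stratigraphic midpoint ages. Taxa present in the tree
#' but absent from the measurements are pruned with a warning.
#'
#' @param config a `pt_config` from [pipeline_config()].
#' @return list of class `pt_result`: `fits` (long data.frame of per-tree
#'   per-model results), `weights` (per-tree AICc weights), `trend`,
#'   `traits` (replicate 1 trait vector), `n_success`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pt_config"))
  clad <- if (inherits(config$tree, "phylo")) config$tree else read_newick(config$tree)
  meas <- if (is.data.frame(config$measurements)) config$measurements
          else read_measurements(config$measurements)
  ages <- if (is.null(config$ages)) {
    if (!all(c("age_max", "age_min") %in% names(meas)))
      stop_fmt("no age table and no age columns in measurements")
    meas[c("taxon", "age_max", "age_min")]
  } else if (is.data.frame(config$ages)) config$ages else read_ages(config$ages)

  drop_tips <- setdiff(clad$tip.label, meas$taxon)
  if (length(drop_tips)) {
    warn_fmt("%d taxa in tree but not in measurements; pruned (%s%s)",
             length(drop_tips), paste(utils::head(drop_tips, 3), collapse = ", "),
             if (length(drop_tips) > 3) ", ..." else "")
    clad <- ape::drop.tip(clad, drop_tips)
  }
  drop_ages <- setdiff(clad$tip.label, ages$taxon)
  if (length(drop_ages)) {
    warn_fmt("%d taxa without stratigraphic ages; pruned", length(drop_ages))
    clad <- ape::drop.tip(clad, drop_ages)
  }
  if (ape::Ntip(clad) < 3) stop_fmt("fewer than 3 usable taxa; aborting")
  ages <- ages[ages$taxon %in% clad$tip.label, , drop = FALSE]

  fit_rows <- list(); weight_rows <- list(); traits1 <- NULL
  for (rep_i in seq_len(config$n_replicate_trees)) {
    phy <- resolve_polytomies(clad, derive_seed(config$seed, "resolve", rep_i))
    ta <- sample_tip_ages(ages, derive_seed(config$seed, "tip_ages", rep_i))
    tr <- if (config$calibration == "mbl")
      calibrate_mbl(phy, ta, min_bl = config$min_bl)
    else calibrate_equal(phy, ta, root_buffer = config$root_buffer)

    traits <- suppressMessages(
      assemble_traits(meas[meas$taxon %in% tr$tip.label, , drop = FALSE], tr,
                      order = config$cascade_order, exclude = config$exclude))
    tr_fit <- ape::keep.tip(tr, intersect(tr$tip.label, traits$taxon))
    if (rep_i == 1L) traits1 <- traits

    specs <- build_model_specs(tr_fit, config)
    fits <- lapply(seq_along(specs), function(j)
      tryCatch(fit_model(specs[[j]], tr_fit, traits,
                         seed = derive_seed(config$seed, paste0("fit_", names(specs)[j]), rep_i),
                         n_starts = 8),
               error = function(e) NULL))
    names(fits) <- names(specs)
    ok <- vapply(fits, function(f) !is.null(f) && isTRUE(f$convergence) &&
                   is.finite(f$aicc), TRUE)
    if (!any(ok)) next
    aiccs <- vapply(fits[ok], `[[`, 0, "aicc")
    w <- akaike_weights(aiccs)
    weight_rows[[rep_i]] <- data.frame(replicate = rep_i, model = names(w),
                                       aicc = unname(aiccs), weight = unname(w),
                                       all_converged = all(ok),
                                       stringsAsFactors = FALSE)
    fit_rows[[rep_i]] <- do.call(rbind, lapply(names(fits)[ok], function(nm) {
      f <- fits[[nm]]
      if (is.null(f$derived)) {
        data.frame(replicate = rep_i, model = nm, regime = "all",
                   alpha = 0, half_life = Inf,
                   beta = unname(unlist(f$beta)[1]),
                   theta = f$Z0, se_theta = f$se_Z0,
                   mu = 0, theta_m = 10^f$Z0,
                   Z0 = f$Z0, se_Z0 = f$se_Z0,
                   lnL = f$lnL, k = f$k, n = f$n, aicc = f$aicc,
                   stringsAsFactors = FALSE)
      } else {
        d <- f$derived
        data.frame(replicate = rep_i, model = nm, regime = d$regime,
                   alpha = d$alpha, half_life = d$half_life,
                   beta = unname(unlist(f$beta)[d$regime]),
                   theta = d$theta,
                   se_theta = unname(unlist(f$se_theta)[d$regime]),
                   mu = d$mu, theta_m = d$theta_m,
                   Z0 = f$Z0, se_Z0 = f$se_Z0,
                   lnL = f$lnL, k = f$k, n = f$n, aicc = f$aicc,
                   stringsAsFactors = FALSE)
      }
    }))
  }
  weights <- do.call(rbind, weight_rows)
  if (is.null(weights)) {
    warn_fmt("no replicate had any converged model")
    weights <- data.frame()
  }

  tage <- if (config$trend_age %||% "midpoint" == "sampled") {
    sample_tip_ages(ages, derive_seed(config$seed, "tip_ages", 1L))
  } else stats::setNames((ages$age_max + ages$age_min) / 2, ages$taxon)
  ttab <- traits1
  ttab$age <- tage[ttab$taxon]
  trend <- tryCatch(
    trend_regressions(ttab[!is.na(ttab$age), ], config$trend_boundary_Ma,
                      seed = derive_seed(config$seed, "trend")),
    error = function(e) { warn_fmt("trend regression failed: %s", conditionMessage(e)); NULL })

  res <- list(fits = do.call(rbind, fit_rows), weights = weights,
              trend = trend, traits = traits1,
              n_success = if (nrow(weights)) table(weights$model) else NULL,
              provenance = list(seed = config$seed,
                                n_replicate_trees = config$n_replicate_trees,
                                calibration = config$calibration,
                                config_hash = config_hash(config)))
  class(res) <- "pt_result"
  res
}

build_model_specs <- function(tree, config) {
  specs <- list()
  for (fam in config$single_families)
    specs[[fam]] <- model_spec(fam, root_mode = "theta", mserr = config$mserr)
  maps <- list()
  for (nm in names(config$clade_schemes))
    maps[[nm]] <- paint_clades(tree, config$clade_schemes[[nm]])
  for (nm in names(config$era_schemes))
    maps[[nm]] <- paint_eras(tree, config$era_schemes[[nm]])
  for (fam in config$families) for (nm in names(maps)) for (rm in config$root_modes) {
    label <- paste0(fam, "_", nm, if (rm == "separate") "+root" else "")
    specs[[label]] <- model_spec(fam, regime_map = maps[[nm]], root_mode = rm,
                                 mserr = config$mserr, name = label)
  }
  specs
}

config_hash <- function(config) {
  x <- config[setdiff(names(config), c("tree", "measurements", "ages", "out_dir"))]
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  sprintf("%08x", derive_seed(0, s))
}

#' Aggregate replicate results into comparison tables
#'
#' Per model: the median and absolute range of each parameter across
#' replicates, and the median and interquartile range of the AICc weight.
#' Models are filtered to those whose median weight is at least
#' `keep_frac` times the best median weight. Both the median of per-tree
#' derived quantities (e.g. half-lives) and the derived value of the median
#' parameter are reported, since the two aggregation orders differ.
#'
#' @param result a `pt_result` from [run_pipeline()].
#' @param keep_frac weight-filtering fraction (default 0.5).
#' @return list with `params` (per model x regime parameter summaries),
#'   `model_weights` (per-model weight summaries, filtered), and
#'   `weights_full` (unfiltered).
#' @export
aggregate_fits <- function(result, keep_frac = 0.5) {
  stopifnot(inherits(result, "pt_result"))
  w <- result$weights
  if (!nrow(w)) { warn_fmt("no successful replicates"); return(list(params = data.frame(), model_weights = data.frame(), weights_full = data.frame())) }
  agg_w <- do.call(rbind, lapply(split(w, w$model), function(d)
    data.frame(model = d$model[1], n_success = nrow(d),
               weight_median = stats::median(d$weight),
               weight_q1 = stats::quantile(d$weight, 0.25, names = FALSE),
               weight_q3 = stats::quantile(d$weight, 0.75, names = FALSE),
               stringsAsFactors = FALSE)))
  rownames(agg_w) <- NULL
  agg_w <- agg_w[order(-agg_w$weight_median), , drop = FALSE]
  keep <- agg_w$weight_median >= keep_frac * max(agg_w$weight_median)

  f <- result$fits
  key <- interaction(f$model, f$regime, drop = TRUE)
  params <- do.call(rbind, lapply(split(f, key), function(d) {
    med <- function(v) stats::median(v)
    rng <- function(v) range(v)
    data.frame(model = d$model[1], regime = d$regime[1],
               n_success = length(unique(d$replicate)),
               alpha_median = med(d$alpha), alpha_lo = rng(d$alpha)[1], alpha_hi = rng(d$alpha)[2],
               half_life_median = med(d$half_life),
               half_life_of_median_alpha = if (med(d$alpha) > 0) log(2) / med(d$alpha) else Inf,
               beta_median = med(d$beta), beta_lo = rng(d$beta)[1], beta_hi = rng(d$beta)[2],
               theta_median = med(d$theta), theta_lo = rng(d$theta)[1], theta_hi = rng(d$theta)[2],
               se_theta_median = med(d$se_theta),
               theta_m_median = med(d$theta_m),
               mu_median = med(d$mu),
               stringsAsFactors = FALSE)
  }))
  rownames(params) <- NULL
  list(params = params,
       model_weights = agg_w[keep, , drop = FALSE],
       weights_full = agg_w)
}

#' Write pipeline outputs to a directory
#'
#' Writes `table_params.tsv` (parameter summaries), `weights.tsv`
#' (per-model weight distributions), `trend_fits.tsv`, `traits.csv` and
#' `fits.json`.
#'
#' @param result a `pt_result`.
#' @param dir output directory.
#' @param keep_frac passed to [aggregate_fits()].
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, keep_frac = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  agg <- aggregate_fits(result, keep_frac)
  utils::write.table(agg$params, file.path(dir, "table_params.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(agg$weights_full, file.path(dir, "weights.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(result$trend))
    utils::write.table(result$trend, file.path(dir, "trend_fits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  write_traits(result$traits, file.path(dir, "traits.csv"))
  write_fits_json(list(weights = result$weights, fits = result$fits,
                       provenance = result$provenance),
                  file.path(dir, "fits.json"))
  invisible(dir)
}
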