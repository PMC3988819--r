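# Non-phylogenetic era-split regressions of log10 wingspan on geological
# age, capturing the long-term trajectory of the size distribution (the
# interplay of along-lineage evolution and species sorting).

#' Split a trait table at a time boundary
#'
#' Taxa are partitioned by their age relative to `boundary_Ma`; a taxon
#' whose age equals the boundary goes to the older subset (documented tie
#' rule).
#'
#' @param traits data.frame with columns `taxon`, `value` and `age` (Ma).
#' @param boundary_Ma split age (Ma before present).
#' @return list with `older` and `younger` data.frames; both must be
#'   non-empty.
#' @export
split_by_interval <- function(traits, boundary_Ma) {
  stopifnot(all(c("taxon", "value", "age") %in% names(traits)))
  older <- traits[traits$age >= boundary_Ma, , drop = FALSE]
  younger <- traits[traits$age < boundary_Ma, , drop = FALSE]
  if (!nrow(older)) stop_fmt("no taxa older than %g Ma", boundary_Ma)
  if (!nrow(younger)) stop_fmt("no taxa younger than %g Ma", boundary_Ma)
  message(sprintf("split_by_interval: %d older, %d younger than %g Ma",
                  nrow(older), nrow(younger), boundary_Ma))
  list(older = older, younger = younger)
}

#' Ordinary least squares trend fit
#'
#' Regresses log10 wingspan on age (Ma before present); the slope is in
#' log10(m)/Ma, negative when size increases towards the present. The 95%
#' confidence interval is t-based.
#'
#' @param age numeric ages (Ma).
#' @param log_size numeric log10 wingspans (m).
#' @param label interval label carried into the result.
#' @return data.frame of class row: `label`, `method`, `n`, `slope`,
#'   `slope_lo`, `slope_hi`, `p_value`, `intercept`, `intercept_m`.
#' @export
ols_fit <- function(age, log_size, label = "interval") {
  check_trend_input(age, log_size)
  fit <- stats::lm(log_size ~ age)
  sm <- summary(fit)
  ci <- stats::confint(fit, "age", level = 0.95)
  data.frame(label = label, method = "ols", n = length(age),
             slope = unname(stats::coef(fit)["age"]),
             slope_lo = ci[1], slope_hi = ci[2],
             p_value = sm$coefficients["age", "Pr(>|t|)"],
             intercept = unname(stats::coef(fit)["(Intercept)"]),
             intercept_m = 10^unname(stats::coef(fit)["(Intercept)"]),
             stringsAsFactors = FALSE)
}

#' Major axis trend fit
#'
#' The slope comes from the leading eigenvector of the 2x2 covariance
#' matrix of (age, log10 wingspan); the 95% confidence interval is a seeded
#' nonparametric bootstrap (percentile, `n_boot` resamples). The p-value is
#' that of the correlation test (slope = 0 iff correlation = 0).
#'
#' @inheritParams ols_fit
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return data.frame shaped as in [ols_fit()] with `method = "major_axis"`.
#' @export
major_axis_fit <- function(age, log_size, label = "interval",
                           n_boot = 2000, seed = 1) {
  check_trend_input(age, log_size)
  ma_slope <- function(x, y) {
    v <- stats::cov(cbind(x, y))
    # closed form for the first principal axis of a 2x2 covariance
    (v[2, 2] - v[1, 1] + sqrt((v[2, 2] - v[1, 1])^2 + 4 * v[1, 2]^2)) /
      (2 * v[1, 2])
  }
  b <- ma_slope(age, log_size)
  a <- mean(log_size) - b * mean(age)
  set.seed(seed)
  n <- length(age)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::var(age[idx]) == 0) return(NA_real_)
    ma_slope(age[idx], log_size[idx])
  }, 0)
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  p <- stats::cor.test(age, log_size)$p.value
  data.frame(label = label, method = "major_axis", n = n,
             slope = b, slope_lo = ci[1], slope_hi = ci[2],
             p_value = p, intercept = a, intercept_m = 10^a,
             stringsAsFactors = FALSE)
}

check_trend_input <- function(age, log_size) {
  if (length(age) != length(log_size)) stop_fmt("age/size length mismatch")
  if (length(age) < 3L) stop_fmt("need >= 3 points, got %d", length(age))
  if (stats::var(age) == 0) stop_fmt("zero age variance")
  invisible(TRUE)
}

#' Era-split trend regressions
#'
#' Splits the trait table at `boundary_Ma` and fits both OLS and major-axis
#' regressions in each interval.
#'
#' @inheritParams split_by_interval
#' @param seed seed for the major-axis bootstrap.
#' @return data.frame with one row per interval x method.
#' @export
trend_regressions <- function(traits, boundary_Ma = 145, seed = 1) {
  sp <- split_by_interval(traits, boundary_Ma)
  rbind(
    ols_fit(sp$older$age, sp$older$value, "older"),
    major_axis_fit(sp$older$age, sp$older$value, "older", seed = seed),
    ols_fit(sp$younger$age, sp$younger$value, "younger"),
    major_axis_fit(sp$younger$age, sp$younger$value, "younger", seed = seed))
}
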