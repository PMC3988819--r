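# Maximum-likelihood fitting of BM and single/multi-regime OU models.
#
# Families: BM1 (single-rate Brownian motion), OU1 (single-regime OU) and
# the multi-regime family OUM (regime-specific theta), OUMV (+ regime beta),
# OUMA (+ regime alpha), OUMVA (regime theta, beta and alpha). The root is
# non-stationary and fixed: either aliased to the basal regime's optimum
# (root_mode "theta") or a separately estimated Z0 (root_mode "separate",
# the "+ root" variants). Conditional on (alpha, beta) the optima enter the
# mean linearly through the OU weight matrix, so they are profiled out by
# GLS; alpha/beta are optimised on the log scale by multi-start L-BFGS-B.

#' Specify a macroevolutionary model
#'
#' @param family one of `"BM1"`, `"OU1"`, `"OUM"`, `"OUMV"`, `"OUMA"`,
#'   `"OUMVA"`.
#' @param regime_map regime map (required for OUM* families; ignored with a
#'   message by BM1/OU1).
#' @param root_mode `"theta"` (root state equals the basal regime's optimum)
#'   or `"separate"` (a distinct root parameter `Z0` is estimated).
#' @param mserr logical: add per-tip measurement error variance (`se^2`) to
#'   the covariance diagonal.
#' @param name optional label used in comparison tables.
#' @return an object of class `pt_model_spec`.
#' @export
model_spec <- function(family = c("BM1", "OU1", "OUM", "OUMV", "OUMA", "OUMVA"),
                       regime_map = NULL,
                       root_mode = c("theta", "separate"),
                       mserr = TRUE, name = NULL) {
  family <- match.arg(family)
  root_mode <- match.arg(root_mode)
  multi <- grepl("^OUM", family)
  if (multi) {
    if (is.null(regime_map)) stop_fmt("%s requires a regime map", family)
    if (length(unique(regime_map$regime)) < 2L)
      stop_fmt("%s requires >= 2 regimes", family)
  }
  structure(list(family = family, regime_map = regime_map,
                 root_mode = root_mode, mserr = isTRUE(mserr),
                 name = name %||% default_model_name(family, regime_map, root_mode)),
            class = "pt_model_spec")
}

default_model_name <- function(family, map, root_mode) {
  r <- if (is.null(map)) 1L else length(unique(map$regime))
  paste0(family, if (grepl("^OUM", family)) r else "",
         if (root_mode == "separate") "+root" else "")
}

# Free parameter counts entering AICc. Estimated quantities: the distinct
# alphas, the distinct betas, the optima (one per regime; BM1/OU1 have one
# mean-level parameter), and Z0 when the root is separate.
#   BM1 = 2 (beta, Z0); OU1 = 3 (alpha, beta, theta) or 4 with separate root;
#   OUM = 2 + r (+1); OUMV = 1 + 2r (+1); OUMA = 1 + 2r (+1); OUMVA = 3r (+1).
param_count <- function(family, n_regimes, root_mode) {
  r <- n_regimes
  k <- switch(family,
              BM1 = 2L,
              OU1 = 3L,
              OUM = 2L + r,
              OUMV = 1L + 2L * r,
              OUMA = 1L + 2L * r,
              OUMVA = 3L * r)
  if (root_mode == "separate" && family != "BM1") k <- k + 1L
  as.integer(k)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param lnL log-likelihood at the optimum.
#' @param k number of free parameters.
#' @param n sample size (number of tips).
#' @return AICc score.
#' @export
aicc <- function(lnL, k, n) {
  if (n <= k + 1) stop_fmt("AICc undefined: n (%d) <= k + 1 (%d)", n, k + 1)
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' Normalized relative likelihoods `exp(-Delta_m/2) / sum(exp(-Delta/2))`
#' with `Delta_m = AICc_m - min(AICc)`.
#'
#' @param scores numeric vector of AICc scores.
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(scores) {
  d <- scores - min(scores)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit a macroevolutionary model by maximum likelihood
#'
#' `alpha` and `beta` are optimised on the log scale with `n_starts` seeded
#' starting points whose attraction values span phylogenetic half-lives from
#' 1 Ma to ten times the tree depth. Conditional on `(alpha, beta)` the
#' optima/root are solved by GLS, `(W' V^-1 W)^-1 W' V^-1 y`, whose
#' conditional covariance supplies their standard errors.
#'
#' @param spec a `pt_model_spec` from [model_spec()].
#' @param tree calibrated `phylo`.
#' @param traits trait-vector `data.frame` (`taxon`, `value`, `se`) or named
#'   numeric vector.
#' @param n_starts number of optimiser starts (default 8).
#' @param seed integer seed for the start-point jitter.
#' @param alpha_bounds bounds on each attraction (1/Ma); the lower bound is
#'   kept strictly positive for numerical stability of `1/alpha` terms.
#' @return an object of class `pt_fit`: `lnL`, `k`, `n`, `aicc`, per-regime
#'   `alpha`/`beta`, optima `theta` with `se`, `Z0` (when separate), a
#'   `convergence` flag and the derived quantities of
#'   [derived_quantities()].
#' @export
fit_model <- function(spec, tree, traits, n_starts = 8, seed = 1,
                      alpha_bounds = c(1e-6, 10)) {
  stopifnot(inherits(spec, "pt_model_spec"))
  y <- trait_values(traits, tree)
  se <- if (spec$mserr) trait_se(traits, tree) else NULL
  if (spec$mserr && is.null(se)) se <- rep(0, length(y))
  n <- length(y)
  fam <- spec$family
  map <- if (fam %in% c("BM1", "OU1")) single_regime_map(tree, "all") else spec$regime_map
  regs <- regime_levels(tree, map)
  R <- length(regs)
  k <- param_count(fam, R, spec$root_mode)
  if (n < k + 2) stop_fmt("too few tips (%d) for %d parameters", n, k)
  depth <- max(node_depths(tree))
  S <- shared_times(tree)
  prep <- if (fam == "BM1") NULL else ou_prep(tree, map)
  se_al <- if (!is.null(se)) align_se(se, tree$tip.label) else NULL

  n_alpha <- if (fam %in% c("OUMA", "OUMVA")) R else if (fam == "BM1") 0L else 1L
  n_beta <- if (fam %in% c("OUMV", "OUMVA")) R else 1L

  expand <- function(par) {
    a <- if (n_alpha == 0L) stats::setNames(rep(0, R), regs)
         else stats::setNames(rep(exp(par[seq_len(n_alpha)]), length.out = R), regs)
    b <- stats::setNames(rep(exp(par[n_alpha + seq_len(n_beta)]), length.out = R), regs)
    list(alpha = a, beta = b)
  }

  gls_at <- function(par) {
    pr <- expand(par)
    V <- if (fam == "BM1") pr$beta[[1]] * S
         else ou_cov_fast(prep, unname(pr$alpha), unname(pr$beta))
    if (!is.null(se_al)) diag(V) <- diag(V) + se_al^2
    W <- if (fam == "BM1") {
      matrix(1, n, 1, dimnames = list(NULL, "Z0"))
    } else {
      Wf <- ou_weights_fast(prep, unname(pr$alpha))
      if (spec$root_mode == "theta") {
        Wf[, regs[1]] <- Wf[, regs[1]] + Wf[, "Z0"]
        Wf[, regs, drop = FALSE]
      } else Wf
    }
    L <- chol(V)
    Wt <- backsolve(L, W, transpose = TRUE)
    yt <- backsolve(L, y, transpose = TRUE)
    XtX <- crossprod(Wt)
    b <- solve(XtX, crossprod(Wt, yt))
    r <- yt - Wt %*% b
    lnL <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
    list(lnL = lnL, coef = stats::setNames(drop(b), colnames(W)),
         vcov = solve(XtX), pars = pr)
  }
  nll <- function(par) {
    out <- tryCatch(gls_at(par)$lnL, error = function(e) NA_real_)
    if (!is.finite(out)) return(1e10)
    -out
  }

  # seeded multi-start grid over half-lives and a variance-matched beta
  set.seed(seed)
  hl <- exp(seq(log(1), log(10 * depth), length.out = max(n_starts, 2)))
  b0 <- max(stats::var(y) / depth, 1e-10)
  np <- n_alpha + n_beta
  lower <- c(rep(log(alpha_bounds[1]), n_alpha), rep(log(b0) - 14, n_beta))
  upper <- c(rep(log(alpha_bounds[2]), n_alpha), rep(log(b0) + 14, n_beta))
  best <- NULL
  conv <- FALSE
  for (i in seq_len(n_starts)) {
    a0 <- log(log(2) / hl[((i - 1L) %% length(hl)) + 1L])
    start <- c(rep(a0, n_alpha) + stats::rnorm(n_alpha, 0, 0.2),
               rep(log(b0), n_beta) + stats::rnorm(n_beta, 0, 0.5))
    start <- pmin(pmax(start, lower), upper)
    opt <- tryCatch(
      stats::optim(start, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) next
    if (is.null(best) || opt$value < best$value - 1e-12) best <- opt
    if (opt$convergence == 0) conv <- TRUE
    if (np == 0L) break
  }
  if (fam == "BM1" && is.null(best)) { # pure 1-D in log beta
    opt <- stats::optim(log(b0), nll, method = "Brent",
                        lower = log(b0) - 20, upper = log(b0) + 20)
    best <- opt; conv <- TRUE
  }
  if (is.null(best))
    return(structure(list(spec = spec, convergence = FALSE, lnL = NA_real_,
                          k = k, n = n, aicc = NA_real_),
                     class = "pt_fit"))

  sol <- gls_at(best$par)
  coefs <- sol$coef
  ses_gls <- sqrt(diag(sol$vcov))
  names(ses_gls) <- names(coefs)
  # Observed-information standard errors over the full parameter vector
  # (log alpha, log beta, optima): the conditional GLS covariance understates
  # the optima's uncertainty because attraction and optimum estimates covary,
  # so the reported se comes from the inverse Hessian where it is computable.
  ses <- ses_gls
  if (np > 0L) {
    nll_full <- function(pall) {
      par <- pall[seq_len(np)]
      cf <- pall[-seq_len(np)]
      out <- tryCatch({
        pr <- expand(par)
        V <- if (fam == "BM1") pr$beta[[1]] * S
             else ou_cov_fast(prep, unname(pr$alpha), unname(pr$beta))
        if (!is.null(se_al)) diag(V) <- diag(V) + se_al^2
        W <- if (fam == "BM1") matrix(1, n, 1) else {
          Wf <- ou_weights_fast(prep, unname(pr$alpha))
          if (spec$root_mode == "theta") {
            Wf[, regs[1]] <- Wf[, regs[1]] + Wf[, "Z0"]
            Wf[, regs, drop = FALSE]
          } else Wf
        }
        -mvn_loglik(y, drop(W %*% cf), V)
      }, error = function(e) NA_real_)
      if (!is.finite(out)) 1e10 else out
    }
    hess <- tryCatch(
      stats::optimHess(c(best$par, unname(coefs)), nll_full),
      error = function(e) NULL)
    if (!is.null(hess)) {
      cv <- tryCatch(solve(hess), error = function(e) NULL)
      if (!is.null(cv)) {
        dg <- diag(cv)[-seq_len(np)]
        if (all(is.finite(dg)) && all(dg > 0))
          ses <- stats::setNames(sqrt(dg), names(coefs))
      }
    }
  }
  theta <- coefs[setdiff(names(coefs), "Z0")]
  fit <- structure(list(
    spec = spec, name = spec$name, family = fam,
    regimes = regs, n = n, k = k,
    lnL = sol$lnL, aicc = aicc(sol$lnL, k, n),
    alpha = sol$pars$alpha, beta = sol$pars$beta,
    theta = theta, se_theta = ses[names(theta)],
    se_theta_conditional = ses_gls[names(theta)],
    Z0 = if ("Z0" %in% names(coefs)) coefs[["Z0"]]
         else unname(coefs[regs[1]]),
    se_Z0 = if ("Z0" %in% names(coefs)) ses[["Z0"]]
            else unname(ses[regs[1]]),
    root_mode = spec$root_mode,
    convergence = conv), class = "pt_fit")
  fit$derived <- if (fam == "BM1") NULL else derived_quantities(fit)
  fit
}

#' Derived quantities of an OU fit
#'
#' Per regime: the phylogenetic half-life `ln(2)/alpha` (Ma, the time for
#' the process to erase half the phylogenetic covariance; infinite at
#' `alpha = 0`), the equivalent trend coefficient `mu = alpha * theta`
#' (log10(m)/Ma; the drift rate of the Brownian-with-trend limit as
#' `alpha -> 0`) with bounds `alpha * (theta +/- 2 se)`, and the optimum
#' back-transformed to metres, `10^theta`.
#'
#' @param fit a `pt_fit`, or a list with elements `alpha`, `theta`,
#'   `se_theta` (named per regime).
#' @return data.frame with one row per regime: `regime`, `alpha`,
#'   `half_life`, `theta`, `mu`, `mu_lo`, `mu_hi`, `theta_m`.
#' @export
derived_quantities <- function(fit) {
  a <- unlist(fit$alpha)
  th <- unlist(fit$theta)[names(a)]
  se <- unlist(fit$se_theta)[names(a)]
  data.frame(regime = names(a),
             alpha = unname(a),
             half_life = ifelse(a > 0, log(2) / a, Inf),
             theta = unname(th),
             mu = unname(a * th),
             mu_lo = unname(a * (th - 2 * se)),
             mu_hi = unname(a * (th + 2 * se)),
             theta_m = unname(10^th),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.pt_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, k = %d, n = %d, AICc = %.4f (%s)\n",
              x$name %||% x$family, x$lnL, x$k, x$n, x$aicc,
              if (isTRUE(x$convergence)) "converged" else "NOT converged"))
  if (!is.null(x$derived)) {
    cat("  per-regime estimates:\n")
    print(cbind(x$derived,
                beta = unlist(x$beta)[x$derived$regime],
                se_theta = unlist(x$se_theta)[x$derived$regime]),
          digits = 4)
    if (x$root_mode == "separate")
      cat(sprintf("  Z0 = %.4f (se %.4f)\n", x$Z0, x$se_Z0))
  }
  invisible(x)
}
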