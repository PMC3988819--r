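# Phylogenetic generalized least squares under Pagel's lambda.
#
# The correlation structure is C(lambda): the Brownian shared-path-time
# correlation matrix (s_ij / sqrt(T_i T_j)) with its off-diagonal entries
# multiplied by lambda -- the corPagel formulation, so lambda = 0 is exactly
# ordinary least squares on any tree, and lambda = 1 is pure Brownian
# correlation structure (on an ultrametric tree its slope equals the
# independent-contrasts regression slope through the origin). Intermediate
# or mildly out-of-[0,1] lambda is found by maximum likelihood on the
# profile likelihood, restricted to values keeping C(lambda) positive
# definite.

lambda_C <- function(C, lambda) {
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

pgls_profile <- function(X, y, C, lambda) {
  n <- length(y)
  Cl <- lambda_C(C, lambda)
  L <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  Xt <- backsolve(L, X, transpose = TRUE)
  yt <- backsolve(L, y, transpose = TRUE)
  XtX <- crossprod(Xt)
  b <- tryCatch(solve(XtX, crossprod(Xt, yt)), error = function(e) NULL)
  if (is.null(b)) return(NULL)
  r <- yt - Xt %*% b
  s2 <- sum(r^2) / n                      # ML error variance
  lnL <- -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(L))) + n)
  # GLS R^2 against the GLS-weighted intercept-only model
  ones <- backsolve(L, rep(1, n), transpose = TRUE)
  mu <- sum(ones * yt) / sum(ones^2)
  tss <- sum((yt - mu * ones)^2)
  list(coef = stats::setNames(drop(b), colnames(X)), lnL = lnL, sigma2 = s2,
       r2 = 1 - sum(r^2) / tss,
       resid_sd = sqrt(sum(r^2) / max(n - ncol(X), 1)),
       vcov_coef = s2 * n / max(n - ncol(X), 1) * solve(XtX))
}

#' Phylogenetic GLS regression with Pagel's lambda
#'
#' Fits `y ~ x` by GLS under the correlation structure `C(lambda)` on a
#' calibrated tree. `lambda_mode = "fixed0"` is ordinary least squares,
#' `"fixed1"` is Brownian (independent-contrasts) regression, `"ml"`
#' maximises the profile likelihood over a bounded lambda interval subject
#' to positive-definiteness.
#'
#' @param x,y named numeric vectors (names = taxa); only taxa present in
#'   both and on the tree are used (>= 3 required).
#' @param tree calibrated `phylo`.
#' @param lambda_mode `"fixed0"`, `"fixed1"` or `"ml"` (or a numeric lambda).
#' @param lambda_bounds search interval for `"ml"`; default `c(-0.2, 1.3)`,
#'   wide enough to expose mildly negative or >1 signal estimates.
#' @return object of class `pt_pgls`: `slope`, `intercept`, `lambda`,
#'   `lnL`, `aicc`, `r2`, `resid_sd`, `n`, coefficient covariance.
#' @export
pgls_fit <- function(x, y, tree, lambda_mode = c("ml", "fixed0", "fixed1"),
                     lambda_bounds = c(-0.2, 1.3)) {
  if (is.numeric(lambda_mode)) {
    lam_fixed <- lambda_mode
    lambda_mode <- "fixed"
  } else {
    lambda_mode <- match.arg(lambda_mode)
    lam_fixed <- switch(lambda_mode, fixed0 = 0, fixed1 = 1, ml = NA_real_)
  }
  taxa <- intersect(intersect(names(x)[!is.na(x)], names(y)[!is.na(y)]),
                    tree$tip.label)
  if (length(taxa) < 3L) stop_fmt("need >= 3 complete cases on the tree, got %d", length(taxa))
  tr <- ape::keep.tip(tree, taxa)
  S <- shared_times(tr)
  d <- sqrt(diag(S))
  C <- S / outer(d, d) # Brownian correlation structure
  xv <- x[tr$tip.label]; yv <- y[tr$tip.label]
  X <- cbind(intercept = 1, slope = xv)
  n <- length(yv)
  if (n <= 3L && lambda_mode == "ml")
    stop_fmt("too few cases (%d) to estimate lambda", n)

  if (lambda_mode == "ml") {
    f <- function(l) {
      p <- pgls_profile(X, yv, C, l)
      if (is.null(p)) -1e12 else p$lnL
    }
    op <- stats::optimize(f, interval = lambda_bounds, maximum = TRUE, tol = 1e-7)
    # guard against pd-failure plateaus at the boundary
    cand <- c(op$maximum, 0, 1)
    lam <- cand[which.max(vapply(cand, f, 0))]
    kpar <- 4L # intercept, slope, sigma2, lambda
  } else {
    lam <- lam_fixed
    kpar <- 3L
  }
  p <- pgls_profile(X, yv, C, lam)
  if (is.null(p)) stop_fmt("singular correlation structure at lambda = %.3f", lam)
  structure(list(slope = unname(p$coef["slope"]),
                 intercept = unname(p$coef["intercept"]),
                 lambda = lam, lambda_mode = lambda_mode,
                 lnL = p$lnL,
                 aicc = if (n > kpar + 1) aicc(p$lnL, kpar, n) else NA_real_,
                 r2 = p$r2, resid_sd = p$resid_sd,
                 sigma2 = p$sigma2, vcov = p$vcov_coef,
                 n = n, taxa = tr$tip.label),
            class = "pt_pgls")
}

#' @export
print.pt_pgls <- function(x, ...) {
  cat(sprintf("PGLS (lambda = %.3f, mode %s): slope %.4f, intercept %.4f, R2 %.3f, lnL %.3f, AICc %.3f, n %d\n",
              x$lambda, x$lambda_mode, x$slope, x$intercept, x$r2, x$lnL, x$aicc, x$n))
  invisible(x)
}

#' Predict from a PGLS fit
#' @param object a `pt_pgls`.
#' @param newdata numeric vector of predictor values.
#' @param ... unused.
#' @return numeric vector of predicted responses.
#' @export
predict.pt_pgls <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' Rank candidate predictors of a response on a tree
#'
#' Implements the lambda-selection protocol for wingspan estimation: for
#' each candidate predictor the non-phylogenetic (`lambda = 0`) and
#' phylogenetic (`lambda = 1`) regressions are fitted, the better one by
#' AICc is retained, and an independently ML-estimated lambda is reported
#' alongside. Predictors are ranked by the retained model's R-squared (ties
#' keep input order). The "mean standard estimate error" is the standard
#' deviation of (predicted - known) responses on the taxa used to fit.
#'
#' @param predictors named list of named numeric vectors (one per candidate).
#' @param y named numeric response vector.
#' @param tree calibrated `phylo`.
#' @return data.frame, one row per candidate, ordered by rank: `predictor`,
#'   `r2_nonphylo`, `aicc_nonphylo`, `r2_phylo`, `aicc_phylo`, `lambda_ml`,
#'   `retained` (`"phylo"`/`"nonphylo"`), `r2`, `n`, `msee`, `slope`,
#'   `intercept`.
#' @export
select_predictor <- function(predictors, y, tree) {
  if (!length(predictors)) stop_fmt("empty candidate predictor set")
  stopifnot(is.list(predictors), !is.null(names(predictors)))
  rows <- lapply(names(predictors), function(nm) {
    x <- predictors[[nm]]
    f0 <- pgls_fit(x, y, tree, "fixed0")
    f1 <- pgls_fit(x, y, tree, "fixed1")
    fml <- tryCatch(pgls_fit(x, y, tree, "ml"), error = function(e) NULL)
    retained <- if (is.na(f0$aicc) || is.na(f1$aicc)) {
      if (f1$lnL >= f0$lnL) "phylo" else "nonphylo"
    } else if (f1$aicc <= f0$aicc) "phylo" else "nonphylo"
    best <- if (retained == "phylo") f1 else f0
    known <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
    known <- intersect(known, best$taxa)
    pred <- predict(best, x[known])
    msee <- stats::sd(pred - y[known])
    data.frame(predictor = nm,
               r2_nonphylo = f0$r2, aicc_nonphylo = f0$aicc,
               r2_phylo = f1$r2, aicc_phylo = f1$aicc,
               lambda_ml = if (is.null(fml)) NA_real_ else fml$lambda,
               retained = retained, r2 = best$r2, n = best$n,
               msee = msee, slope = best$slope, intercept = best$intercept,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r2), , drop = FALSE] # stable: ties keep input order
  rownames(out) <- NULL
  out
}
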