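# Multi-regime Ornstein-Uhlenbeck machinery on non-ultrametric calibrated
# trees with a fixed (non-stationary) root.
#
# The trait follows dX = alpha_r (theta_r - X) dt + sqrt(beta_r) dW along
# each branch segment, with regime r given by a regime map. With the root
# state fixed at Z0 the model is Gaussian; all moments follow from a single
# root-to-tips pass over branch segments:
#   per node, Lambda = cumulative integral of alpha along the root path
#   (the "attraction load"), and Vacc = accumulated process variance.
# Then E[X_i] = Z0 e^{-Lambda_i} + sum over path segments of theta_r times
# its exponential weight, and for tips i,j with MRCA m,
#   Cov(X_i, X_j) = Vacc_m * exp(-(Lambda_i - Lambda_m)) *
#                            exp(-(Lambda_j - Lambda_m)),
# because deviations from the mean decay independently after divergence.
# Per-tip measurement error enters as diag(se^2).
#
# The segment structure and MRCA table depend only on (tree, painting), so
# they are precomputed once (ou_prep) and reused across the many likelihood
# evaluations of an optimisation.

# Precompute everything parameter-independent: segments flattened to a
# numeric matrix in root-to-tip order and the tip MRCA index matrix.
ou_prep <- function(tree, map) {
  validate_regime_map(tree, map)
  n <- ape::Ntip(tree)
  regs <- regime_levels(tree, map)
  pre <- rev(ape::postorder(tree))
  seg_by_edge <- split(seq_len(nrow(map)), map$edge)
  rows <- unlist(lapply(pre, function(e) {
    idx <- seg_by_edge[[as.character(e)]]
    idx[order(map$start[idx])]
  }), use.names = FALSE)
  segs <- cbind(parent = tree$edge[map$edge[rows], 1],
                child = tree$edge[map$edge[rows], 2],
                dt = map$end[rows] - map$start[rows],
                reg = match(map$regime[rows], regs))
  M <- ape::mrca(tree, full = FALSE)
  list(n = n, nn = n + tree$Nnode, root = n + 1L, segs = segs,
       regimes = regs, M = M, tips = tree$tip.label)
}

# per-node attraction load Lambda and accumulated variance Vacc
ou_moments_fast <- function(prep, alpha, beta) {
  Lam <- numeric(prep$nn)
  Vac <- numeric(prep$nn)
  s <- prep$segs
  cur_child <- -1L
  L <- V <- 0
  for (k in seq_len(nrow(s))) {
    p <- s[k, 1L]; ch <- s[k, 2L]
    if (ch != cur_child) { L <- Lam[p]; V <- Vac[p]; cur_child <- ch }
    a <- alpha[s[k, 4L]]; b <- beta[s[k, 4L]]; dt <- s[k, 3L]
    if (a > 1e-12) {
      f2 <- exp(-2 * a * dt)
      V <- V * f2 + b / (2 * a) * (1 - f2)
      L <- L + a * dt
    } else V <- V + b * dt
    Lam[ch] <- L
    Vac[ch] <- V
  }
  list(Lambda = Lam, Vacc = Vac)
}

# per-tip weights on (Z0, theta_r ...); rows sum to 1
ou_weights_fast <- function(prep, alpha) {
  R <- length(prep$regimes)
  W <- matrix(0, prep$nn, R + 1L)
  W[prep$root, 1L] <- 1
  s <- prep$segs
  cur_child <- -1L
  w <- NULL
  for (k in seq_len(nrow(s))) {
    p <- s[k, 1L]; ch <- s[k, 2L]
    if (ch != cur_child) { w <- W[p, ]; cur_child <- ch }
    a <- alpha[s[k, 4L]]
    f <- exp(-a * s[k, 3L])
    w <- w * f
    w[s[k, 4L] + 1L] <- w[s[k, 4L] + 1L] + (1 - f)
    W[ch, ] <- w
  }
  dimnames(W) <- list(NULL, c("Z0", prep$regimes))
  W <- W[seq_len(prep$n), , drop = FALSE]
  rownames(W) <- prep$tips
  W
}

ou_cov_fast <- function(prep, alpha, beta) {
  mom <- ou_moments_fast(prep, alpha, beta)
  Lt <- mom$Lambda[seq_len(prep$n)]
  V <- mom$Vacc[prep$M] * exp(-(outer(Lt, Lt, "+") - 2 * mom$Lambda[prep$M]))
  dim(V) <- c(prep$n, prep$n)
  dimnames(V) <- list(prep$tips, prep$tips)
  V
}

align_regime_pars <- function(x, regimes, what) {
  x <- unlist(x)
  if (is.null(names(x))) {
    if (length(x) == 1L) return(rep(x, length(regimes)))
    if (length(x) != length(regimes)) stop_fmt("%s length mismatch", what)
    return(x)
  }
  miss <- setdiff(regimes, names(x))
  if (length(miss)) stop_fmt("no %s for regime '%s'", what, miss[1])
  unname(x[regimes])
}

#' OU mean weights on the root state and regime optima
#'
#' For each tip the expected trait value is a convex combination of the root
#' state `Z0` and the regime optima `theta_r`:
#' `E[X_i] = w_i0 Z0 + sum_r w_ir theta_r`, with the `Z0` weight
#' `exp(-Lambda_i)` (`Lambda_i` the integral of `alpha` along the root-to-tip
#' path) and each path segment contributing `(1 - e^{-alpha dt})` discounted
#' by the attraction accumulated after it. Every row sums to 1.
#'
#' @param tree calibrated `phylo`.
#' @param map regime map (see [paint_clades()], [paint_eras()]).
#' @param alpha named vector of attraction strengths per regime (1/Ma,
#'   `>= 0`; 0 gives the Brownian limit in which the segment pulls nothing).
#' @return matrix `Ntip x (1 + n_regimes)`, columns `Z0` then the regime
#'   labels (basal regime first).
#' @export
ou_mean_weights <- function(tree, map, alpha) {
  prep <- ou_prep(tree, map)
  ou_weights_fast(prep, align_regime_pars(alpha, prep$regimes, "alpha"))
}

#' Analytic tip covariance of a multi-regime OU process
#'
#' Assembles the among-tip trait covariance implied by a regime map with
#' per-regime attraction `alpha` and Brownian variance `beta`, for a fixed
#' root state. With a shared `alpha` this reduces to
#' `V_ij = e^{-alpha (T_i + T_j - 2 s_ij)} * V_shared(s_ij)` where `s_ij` is
#' the root-to-MRCA shared time; with `alpha = 0` everywhere it reduces to
#' the Brownian `V_ij = beta * s_ij`.
#'
#' @inheritParams ou_mean_weights
#' @param beta named vector of Brownian variances per regime
#'   (log10(m)^2/Ma, > 0).
#' @param se optional per-tip standard errors (named or tip order); added to
#'   the diagonal as `se^2` (measurement error, `mserr`).
#' @return symmetric `Ntip x Ntip` covariance matrix (tip order).
#' @export
ou_covariance <- function(tree, map, alpha, beta, se = NULL) {
  prep <- ou_prep(tree, map)
  a <- align_regime_pars(alpha, prep$regimes, "alpha")
  b <- align_regime_pars(beta, prep$regimes, "beta")
  if (any(b <= 0)) stop_fmt("beta must be > 0")
  if (any(a < 0)) stop_fmt("alpha must be >= 0")
  V <- ou_cov_fast(prep, a, b)
  if (!is.null(se)) {
    se <- align_se(se, prep$tips)
    diag(V) <- diag(V) + se^2
  }
  V
}

align_se <- function(se, tips) {
  if (!is.null(names(se))) {
    miss <- setdiff(tips, names(se))
    if (length(miss)) stop_fmt("no se for tips: %s", paste(miss, collapse = ", "))
    se <- se[tips]
  } else if (length(se) == 1L) se <- rep(se, length(tips))
  if (length(se) != length(tips)) stop_fmt("se length mismatch")
  if (any(se < 0)) stop_fmt("negative se")
  se
}

#' Brownian-motion log-likelihood on a calibrated tree
#'
#' Multivariate normal log-density of the tip traits under Brownian motion:
#' mean `Z0`, covariance `beta * s_ij` with `s_ij` the root-to-MRCA shared
#' time, plus `diag(se^2)` if per-tip errors are supplied.
#'
#' @param tree calibrated `phylo`.
#' @param traits named numeric vector of tip values, or a trait-vector
#'   `data.frame` (`taxon`, `value`, `se`).
#' @param beta Brownian variance (> 0).
#' @param z0 root state.
#' @param se optional per-tip standard errors (taken from `traits` when it
#'   is a trait-vector data.frame).
#' @return log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, traits, beta, z0, se = NULL) {
  if (beta <= 0) stop_fmt("beta must be > 0")
  y <- trait_values(traits, tree)
  if (is.null(se)) se <- trait_se(traits, tree)
  S <- shared_times(tree)
  V <- beta * S
  if (!is.null(se)) diag(V) <- diag(V) + align_se(se, tree$tip.label)^2
  mvn_loglik(y, rep(z0, length(y)), V)
}

#' Shared path times of a calibrated tree
#' @param tree calibrated `phylo`.
#' @return `Ntip x Ntip` matrix of root-to-MRCA shared times `s_ij` (Ma);
#'   the diagonal holds root-to-tip times `T_i`.
#' @export
shared_times <- function(tree) {
  n <- ape::Ntip(tree)
  d <- node_depths(tree)
  M <- ape::mrca(tree, full = FALSE)
  S <- d[M]
  dim(S) <- c(n, n)
  dimnames(S) <- list(tree$tip.label, tree$tip.label)
  S
}

# Gaussian log-density via Cholesky; error on non-positive-definite V
mvn_loglik <- function(y, mu, V) {
  L <- tryCatch(chol(V), error = function(e)
    stop_fmt("covariance matrix not positive definite"))
  r <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
}

trait_values <- function(traits, tree) {
  if (is.data.frame(traits)) {
    y <- stats::setNames(traits$value, traits$taxon)
  } else y <- traits
  miss <- setdiff(tree$tip.label, names(y))
  if (length(miss)) stop_fmt("no trait value for tips: %s", paste(miss, collapse = ", "))
  y[tree$tip.label]
}

trait_se <- function(traits, tree) {
  if (is.data.frame(traits) && "se" %in% names(traits))
    return(stats::setNames(traits$se, traits$taxon)[tree$tip.label])
  NULL
}
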