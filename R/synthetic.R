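# Synthetic-data generator: trees, stratigraphic ranges and skeletal
# measurement tables with the statistical structure the analysis assumes,
# so every downstream stage is testable without a fossil compilation.

#' Define a simulation scenario
#'
#' Defaults emulate the pterosaur study system: a ~109-tip non-ultrametric
#' fossil tree spanning ~160 Ma, stage-level age uncertainty (2-10 Ma
#' windows), log10-scale wingspan evolution with a constrained basal regime
#' (strong attraction to a ~1 m optimum) switching at 145 Ma to a
#' weakly-attracted large-optimum regime (a sustained upward trend with
#' drift rate `mu = alpha * theta` of about 0.0076 log10(m)/Ma), per-tip
#' estimation error of 0.06 log10(m), and heavier missingness of distal
#' wing elements such that roughly a fifth of taxa have complete forelimbs.
#'
#' @param n_tips number of tree tips.
#' @param span_Ma root-to-deepest-tip time span (Ma).
#' @param scheme regime scheme: `"era_shift"` (regimes split at
#'   `boundary_Ma`), `"clade_shift"` (derived regime on a mid-depth clade)
#'   or `"single"`.
#' @param boundary_Ma era boundary (Ma before present) for `"era_shift"`.
#' @param alpha,beta,theta per-regime OU parameters, named `basal`/`derived`
#'   (only `basal` is used by `"single"`). Units: 1/Ma, log10(m)^2/Ma,
#'   log10(m).
#' @param Z0 root state (log10 m).
#' @param se_scale per-tip observation standard error (log10 m).
#' @param missingness named fractions in `[0,1]` per element column.
#' @param age_window range (Ma) of stratigraphic-window widths.
#' @param present_offset age (Ma) of the youngest possible tip; root age is
#'   `span_Ma + present_offset`.
#' @param seed integer master seed.
#' @return a list of class `pt_scenario`.
#' @export
sim_scenario <- function(n_tips = 109, span_Ma = 160,
                         scheme = c("era_shift", "clade_shift", "single"),
                         boundary_Ma = 145,
                         alpha = c(basal = 0.02, derived = 0.0056),
                         beta = c(basal = 8e-4, derived = 6e-4),
                         theta = c(basal = 0, derived = 1.35),
                         Z0 = 0, se_scale = 0.06,
                         missingness = default_missingness(),
                         age_window = c(2, 10),
                         present_offset = 66,
                         seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(n_tips >= 2, span_Ma > 0, all(beta > 0), all(alpha >= 0),
            se_scale >= 0, all(missingness >= 0 & missingness <= 1))
  structure(list(n_tips = n_tips, span_Ma = span_Ma, scheme = scheme,
                 boundary_Ma = boundary_Ma, alpha = alpha, beta = beta,
                 theta = theta, Z0 = Z0, se_scale = se_scale,
                 missingness = missingness, age_window = age_window,
                 present_offset = present_offset, seed = seed),
            class = "pt_scenario")
}

# Per-element deletion fractions: a preservational gradient, heaviest on the
# distal wing finger and on crania; tuned so the expected complete-forelimb
# fraction is ~0.20 of taxa (about 34 of 168).
default_missingness <- function() {
  c(skull = 0.40, mandible = 0.35, rostrum = 0.45,
    humerus = 0.08, ulna = 0.10, radius = 0.10, mcIV = 0.12,
    phIV1 = 0.15, phIV2 = 0.18, phIV3 = 0.22, phIV4 = 0.50)
}

# mean fractions of the wingspan sum contributed by each wing element
element_proportions <- function() {
  c(humerus = 0.086, ulna = 0.172, mcIV = 0.129,
    phIV1 = 0.216, phIV2 = 0.190, phIV3 = 0.155, phIV4 = 0.052)
}

#' Simulate a non-ultrametric fossil tree
#'
#' Forward birth-death simulation (via [ape::rlineage()]) retaining extinct
#' lineages, pruned to `n_tips` and rescaled so the deepest tip sits at
#' `span_Ma`; extinct tips give heterogeneous tip depths. When pruning, tips
#' are sampled stratified over equal-width depth bins, flattening the tip
#' age distribution the way fossil compilations sample more evenly through
#' time than a supercritical birth-death process would. `root.time` is set
#' to `span_Ma + present_offset`.
#'
#' @param n_tips number of tips (>= 2).
#' @param span_Ma total time span (Ma).
#' @param seed integer seed.
#' @param birth,death per-lineage rates (1/Ma) of the generating process;
#'   the default high-turnover pair spreads extinct tips through the span.
#' @param present_offset age of the deepest possible tip level (Ma).
#' @return calibrated `phylo` with `root.time`.
#' @export
simulate_tree <- function(n_tips, span_Ma, seed, birth = 0.12, death = 0.09,
                          present_offset = 66) {
  if (n_tips < 2) stop_fmt("n_tips must be >= 2")
  if (span_Ma <= 0) stop_fmt("span_Ma must be > 0")
  set.seed(seed)
  phy <- NULL
  for (try in 1:200) {
    cand <- ape::rlineage(birth, death, Tmax = span_Ma)
    if (!is.null(cand) && inherits(cand, "phylo") && ape::Ntip(cand) >= n_tips) {
      phy <- cand; break
    }
  }
  if (is.null(phy))
    stop_fmt("birth-death simulation failed to reach %d tips in 200 tries", n_tips)
  if (ape::Ntip(phy) > n_tips)
    phy <- ape::keep.tip(phy, stratified_tip_sample(phy, n_tips))
  phy$edge.length <- phy$edge.length * (span_Ma / max(node_depths(phy)))
  phy$tip.label <- sprintf("t%03d", seq_len(ape::Ntip(phy)))
  phy$node.label <- NULL
  phy$root.time <- span_Ma + present_offset
  phy
}

# sample n tips spread over equal-width tip-depth bins (fill shortfalls at
# random from the remainder)
stratified_tip_sample <- function(phy, n, n_bins = 8) {
  d <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  bin <- cut(d, breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  per <- ceiling(n / n_bins)
  keep <- unlist(lapply(split(seq_along(d), bin), function(idx)
    if (length(idx) <= per) idx else sample(idx, per)), use.names = FALSE)
  if (length(keep) > n) keep <- sample(keep, n)
  if (length(keep) < n)
    keep <- c(keep, sample(setdiff(seq_along(d), keep), n - length(keep)))
  phy$tip.label[keep]
}

scenario_regime_map <- function(tree, scenario) {
  switch(scenario$scheme,
    single = single_regime_map(tree, "basal"),
    era_shift = paint_eras(tree, scenario$boundary_Ma,
                           labels = c("basal", "derived")),
    clade_shift = {
      # derived regime = subtree whose stem is nearest 40% of the span deep
      d <- node_depths(tree)
      n <- ape::Ntip(tree)
      nodes <- (n + 2L):(n + tree$Nnode)
      sizes <- vapply(nodes, function(nd) length(tips_below(tree, nd)), 1L)
      ok <- nodes[sizes >= 3 & sizes <= n - 3]
      if (!length(ok)) stop_fmt("tree too small for a clade shift")
      target <- ok[which.min(abs(d[ok] - 0.4 * scenario$span_Ma))]
      paint_clades(tree, stats::setNames(
        list(tree$tip.label[tips_below(tree, target)]), "derived"),
        base_label = "basal")
    })
}

#' Simulate trait evolution on a painted tree
#'
#' Exact Ornstein-Uhlenbeck transition sampling per branch segment:
#' `X(end) ~ N(theta + (X(start) - theta) e^{-alpha dt},
#' (beta/2alpha)(1 - e^{-2 alpha dt}))`, with the Brownian limit
#' (mean `X(start)`, variance `beta dt`) when `alpha = 0`. Independent
#' `N(0, se^2)` observation noise is added when `se_scale > 0`.
#'
#' @param tree calibrated `phylo`.
#' @param scenario a `pt_scenario` (supplies the painting and parameters),
#'   or `NULL` if `map`/`alpha`/`beta`/`theta`/`Z0` are given directly.
#' @param map,alpha,beta,theta,Z0,se_scale overrides of the scenario fields.
#' @param n_rep number of independent replicate simulations.
#' @param seed integer seed.
#' @return for `n_rep = 1` a trait-vector `data.frame`; otherwise a
#'   `Ntip x n_rep` matrix of observed values (row names = tips).
#' @export
simulate_trait <- function(tree, scenario = NULL, map = NULL, alpha = NULL,
                           beta = NULL, theta = NULL, Z0 = NULL,
                           se_scale = NULL, n_rep = 1, seed = 1) {
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "pt_scenario"))
    map <- map %||% scenario_regime_map(tree, scenario)
    alpha <- alpha %||% scenario$alpha
    beta <- beta %||% scenario$beta
    theta <- theta %||% scenario$theta
    Z0 <- Z0 %||% scenario$Z0
    se_scale <- se_scale %||% scenario$se_scale
  }
  if (is.null(map)) stop_fmt("need a regime map (or a scenario)")
  se_scale <- se_scale %||% 0
  validate_regime_map(tree, map)
  regs <- unique(map$regime)
  alpha <- as.list(alpha); beta <- as.list(beta); theta <- as.list(theta)
  miss <- setdiff(regs, intersect(names(alpha), intersect(names(beta), names(theta))))
  if (length(miss)) stop_fmt("unparameterised regimes: %s", paste(miss, collapse = ", "))
  set.seed(seed)
  n <- ape::Ntip(tree)
  X <- matrix(NA_real_, n + tree$Nnode, n_rep)
  X[n + 1L, ] <- Z0
  segs <- split(map[c("start", "end", "regime")], map$edge)
  for (e in rev(ape::postorder(tree))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    s <- segs[[as.character(e)]]
    s <- s[order(s$start), , drop = FALSE]
    x <- X[p, ]
    for (k in seq_len(nrow(s))) {
      r <- s$regime[k]
      a <- alpha[[r]]; b <- beta[[r]]; th <- theta[[r]]
      dt <- s$end[k] - s$start[k]
      if (a > 1e-12) {
        f <- exp(-a * dt)
        m <- th + (x - th) * f
        v <- b / (2 * a) * (1 - f^2)
      } else {
        m <- x
        v <- b * dt
      }
      x <- stats::rnorm(n_rep, m, sqrt(v))
    }
    X[ch, ] <- x
  }
  obs <- X[seq_len(n), , drop = FALSE]
  if (se_scale > 0)
    obs <- obs + matrix(stats::rnorm(n * n_rep, 0, se_scale), n, n_rep)
  rownames(obs) <- tree$tip.label
  if (n_rep == 1L)
    return(data.frame(taxon = tree$tip.label, value = obs[, 1],
                      se = se_scale, provenance = "simulated",
                      row.names = NULL, stringsAsFactors = FALSE))
  obs
}

#' Delete measurements by independent Bernoulli draws
#'
#' @param table measurement table.
#' @param missingness named per-element deletion fractions in `[0,1]`.
#' @param seed integer seed.
#' @return the table with elements deleted.
#' @export
apply_missingness <- function(table, missingness, seed) {
  stopifnot(all(missingness >= 0 & missingness <= 1))
  set.seed(seed)
  for (el in intersect(names(missingness), names(table))) {
    if (missingness[[el]] <= 0) next
    drop <- stats::runif(nrow(table)) < missingness[[el]]
    table[[el]][drop] <- NA_real_
  }
  table
}

#' Build a skeletal measurement table from true wingspans
#'
#' Decomposes each taxon's true wingspan (log10 m) into the seven summed
#' wing elements with noisy proportions (so the elements sum exactly to the
#' wingspan before any deletion), and generates allometrically related
#' cranial elements and a radius. Proportion/allometry deviations for
#' phalanges, humerus, metacarpal and cranial elements evolve as Brownian
#' motion on the tree (so those predictors carry phylogenetic signal), while
#' ulna and radius deviations are independent noise (a functional rather
#' than phylogenetic correlation with wingspan). Juvenile/subadult taxa are
#' down-scaled and a minority of adults get a `rescale_factor > 1`.
#'
#' @param tree calibrated `phylo`.
#' @param true_log10_m named vector of true log10 wingspans (m).
#' @param seed integer seed.
#' @param status_probs probabilities of adult/subadult/juvenile.
#' @param prop_sd Brownian rate of log-proportion deviations (per Ma, on the
#'   natural-log scale).
#' @param iid_sd standard deviation of the ulna/radius independent noise.
#' @return measurement table `data.frame` (no missingness applied).
#' @export
simulate_measurements <- function(tree, true_log10_m, seed,
                                  status_probs = c(adult = 0.80, subadult = 0.12,
                                                   juvenile = 0.08),
                                  prop_sd = 0.03, iid_sd = 0.05) {
  set.seed(seed)
  taxa <- names(true_log10_m)
  nt <- length(taxa)
  W_mm <- 10^true_log10_m * 1000
  props <- element_proportions()
  bm_map <- single_regime_map(tree, "all")
  bm_dev <- function(rate, sd_seed) {
    simulate_trait(tree, map = bm_map, alpha = c(all = 0), beta = c(all = rate^2),
                   theta = c(all = 0), Z0 = 0, se_scale = 0,
                   n_rep = 2, seed = sd_seed)[taxa, 1]
  }
  # noisy proportions, renormalised so the wing elements sum exactly to the
  # wingspan; phylogenetically structured for the phalanges, metacarpal and
  # humerus, but independent for the ulna (functional correlation only)
  raw <- sapply(seq_along(props), function(i) {
    dev <- if (names(props)[i] == "ulna") stats::rnorm(nt, 0, iid_sd)
           else bm_dev(prop_sd, seed + 11 * i)
    props[i] * exp(dev)
  })
  colnames(raw) <- names(props)
  raw <- raw / rowSums(raw)
  out <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  for (el in names(props)) out[[el]] <- W_mm * raw[, el]
  # radius tracks the ulna with independent noise (functional correlation)
  out$radius <- out$ulna * 0.95 * exp(stats::rnorm(nt, 0, iid_sd * 0.5))
  # cranial allometry with phylogenetic deviations
  out$mandible <- 0.25 * W_mm^1.05 / 1000^0.05 * exp(bm_dev(0.05, seed + 101))
  out$skull <- out$mandible * 1.15 * exp(stats::rnorm(nt, 0, 0.05))
  out$rostrum <- out$skull * 0.55 * exp(stats::rnorm(nt, 0, 0.08))

  status <- sample(names(status_probs), nt, replace = TRUE, prob = status_probs)
  scale_im <- ifelse(status == "juvenile", 0.55,
                     ifelse(status == "subadult", 0.80, 1))
  rescale <- rep(1, nt)
  grown <- status == "adult" & stats::runif(nt) < 0.10
  rescale[grown] <- stats::runif(sum(grown), 1.05, 1.5)
  for (el in element_columns())
    out[[el]] <- out[[el]] * scale_im / rescale
  out$status <- status
  out$rescale_factor <- rescale
  out[c("taxon", element_columns(), "status", "rescale_factor")]
}

#' Simulate stratigraphic age ranges for the tips of a tree
#'
#' Each tip's true age is bracketed by a window of width drawn uniformly
#' from `window` (Ma), positioned uniformly around the true age (clamped at
#' 0), emulating stage-level age resolution.
#'
#' @param tree calibrated `phylo` with `root.time`.
#' @param window numeric length-2: range of window widths (Ma).
#' @param seed integer seed.
#' @return age table `data.frame` (`taxon`, `age_max`, `age_min`).
#' @export
simulate_ages <- function(tree, window = c(2, 10), seed = 1) {
  set.seed(seed)
  true_age <- tip_ages(tree)
  w <- stats::runif(length(true_age), window[1], window[2])
  u <- stats::runif(length(true_age))
  amax <- true_age + u * w
  amin <- pmax(amax - w, 0)
  data.frame(taxon = names(true_age), age_max = amax, age_min = amin,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a full synthetic study deposit
#'
#' Produces everything the pipeline reads: a cladogram (topology only, with
#' a few polytomies introduced to exercise random resolution), a skeletal
#' measurement table covering the tree tips plus `n_extra` off-tree taxa
#' (emulating measured species absent from the cladogram), a stratigraphic
#' age table, and the underlying truths for validation.
#'
#' @param scenario a `pt_scenario`.
#' @param n_extra number of measured taxa not placed on the cladogram.
#' @param n_polytomies number of internal nodes collapsed into polytomies.
#' @param dir optional directory; when given, `tree.nwk`,
#'   `measurements.csv` and `ages.csv` are written there so synthetic runs
#'   exercise the real parsers.
#' @return list with `cladogram`, `measurements`, `ages`, `true_tree`
#'   (calibrated, all taxa), `true_traits`, `paths` (when `dir` given).
#' @export
simulate_study <- function(scenario = sim_scenario(), n_extra = 59,
                           n_polytomies = 4, dir = NULL) {
  seed <- scenario$seed
  n_all <- scenario$n_tips + n_extra
  tree_all <- simulate_tree(n_all, scenario$span_Ma,
                            seed = derive_seed(seed, "tree"),
                            present_offset = scenario$present_offset)
  traits <- simulate_trait(tree_all, scenario,
                           seed = derive_seed(seed, "trait"))
  meas <- simulate_measurements(tree_all,
                                stats::setNames(traits$value, traits$taxon),
                                seed = derive_seed(seed, "elements"))
  meas <- apply_missingness(meas, scenario$missingness,
                            seed = derive_seed(seed, "missingness"))
  ages <- simulate_ages(tree_all, scenario$age_window,
                        seed = derive_seed(seed, "ages"))

  set.seed(derive_seed(seed, "prune"))
  keep <- sample(tree_all$tip.label, scenario$n_tips)
  clad <- ape::keep.tip(tree_all, keep)
  clad <- collapse_random_nodes(clad, n_polytomies,
                                seed = derive_seed(seed, "polytomy"))
  clad$edge.length <- NULL
  clad$root.time <- NULL

  out <- list(cladogram = clad, measurements = meas, ages = ages,
              true_tree = tree_all, true_traits = traits,
              scenario = scenario)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- list(tree = file.path(dir, "tree.nwk"),
                      measurements = file.path(dir, "measurements.csv"),
                      ages = file.path(dir, "ages.csv"))
    write_newick(clad, out$paths$tree)
    write_measurements(meas, out$paths$measurements)
    write_ages(ages, out$paths$ages)
  }
  out
}

collapse_random_nodes <- function(tree, n_polytomies, seed) {
  if (n_polytomies <= 0) return(tree)
  set.seed(seed)
  n <- ape::Ntip(tree)
  internal <- which(tree$edge[, 2] > n)
  pick <- sample(internal, min(n_polytomies, length(internal)))
  el <- tree$edge.length %||% rep(1, nrow(tree$edge))
  el[pick] <- 0
  tree$edge.length <- el
  tree <- ape::di2multi(tree, tol = 1e-9)
  tree
}
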