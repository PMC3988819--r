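# Shared fixtures and independent oracles, all built in code.

# canonical string form of a rooted topology (children sorted recursively)
canon_topology <- function(phy) {
  n <- ape::Ntip(phy)
  rec <- function(nd) {
    if (nd <= n) return(phy$tip.label[nd])
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    paste0("(", paste(sort(vapply(kids, rec, "")), collapse = ","), ")")
  }
  rec(n + 1L)
}

# fixed 4-tip non-ultrametric tree used by the Monte-Carlo oracle tests
fixture_tree4 <- function() {
  tr <- ape::read.tree(text = "((A:30,B:20):40,(C:50,D:60):25);")
  tr$root.time <- 90
  tr
}

# fixed 5-tip tree for brute-force Brownian density assembly
fixture_tree5 <- function() {
  tr <- ape::read.tree(text = "(((A:10,B:12):20,C:25):15,(D:30,E:28):22);")
  tr$root.time <- 60
  tr
}

# Euler-Maruyama simulation of dX = a(th - X)dt + sqrt(b) dW on one branch
em_simulate <- function(n_rep, t_total, a, b, th, x0, dt = 0.002) {
  x <- rep(x0, n_rep)
  for (i in seq_len(round(t_total / dt)))
    x <- x + a * (th - x) * dt + sqrt(b * dt) * stats::rnorm(n_rep)
  x
}

# brute-force BM covariance: enumerate root-to-tip paths edge by edge and
# accumulate shared durations, independently of shared_times()
brute_bm_cov <- function(tree, beta) {
  n <- ape::Ntip(tree)
  paths <- lapply(seq_len(n), function(tip) {
    p <- integer(0)
    nd <- tip
    while (nd != n + 1L) {
      e <- which(tree$edge[, 2] == nd)
      p <- c(p, e)
      nd <- tree$edge[e, 1]
    }
    p
  })
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n))
    V[i, j] <- beta * sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  V
}

# plain multivariate normal log-density (independent of the package path)
mvtnorm_logdens <- function(y, mu, V) {
  n <- length(y)
  -0.5 * (n * log(2 * pi) + determinant(V)$modulus[1] +
            drop(t(y - mu) %*% solve(V) %*% (y - mu)))
}

# parameter count a fitted multi-regime model actually reports
model_k_for_test <- function(family, map, tree, y) {
  fit_model(model_spec(family, regime_map = map, mserr = FALSE), tree, y,
            n_starts = 2)$k
}

# small measurement table with every wing element present
complete_measurements <- function(taxa = c("A", "B", "C", "D", "E", "F")) {
  n <- length(taxa)
  base <- c(humerus = 100, ulna = 200, mcIV = 150, phIV1 = 250, phIV2 = 220,
            phIV3 = 180, phIV4 = 60)
  out <- data.frame(taxon = taxa, stringsAsFactors = FALSE)
  sc <- seq(0.8, 1.8, length.out = n)
  for (el in names(base)) out[[el]] <- base[[el]] * sc
  out$skull <- 260 * sc
  out$mandible <- 240 * sc
  out$rostrum <- 140 * sc
  out$radius <- out$ulna * 0.95
  out$status <- "adult"
  out$rescale_factor <- 1
  out
}

# ultrametric tree over given taxa (for PGLS / contrasts oracles)
ultrametric_tree <- function(n = 6, seed = 42) {
  set.seed(seed)
  tr <- ape::rcoal(n, tip.label = LETTERS[seq_len(n)])
  tr$edge.length <- tr$edge.length * 50
  tr$root.time <- max(ape::node.depth.edgelength(tr))
  tr
}
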