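# Time-calibration of cladograms against stratigraphic tip ages.
#
# Convention used throughout the package: *ages* are Ma before present and
# *depths* are Ma measured forward from the root. A calibrated tree is a
# `phylo` with branch lengths in Ma plus a `root.time` element (age of the
# root, Ma before present, as in paleo-timescaling practice), so
#   age(node) = root.time - depth(node).
# All conversions go through node_depths()/tip_ages() to avoid sign bugs.

#' Node depths of a calibrated tree
#' @param tree calibrated `phylo` (branch lengths in Ma).
#' @return numeric vector over `1:(Ntip+Nnode)` of depth from the root (Ma).
#' @export
node_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ape::node.depth.edgelength(tree)
}

#' Tip ages (Ma before present) of a calibrated tree
#' @param tree calibrated `phylo` carrying `root.time`.
#' @return named numeric vector of tip ages.
#' @export
tip_ages <- function(tree) {
  if (is.null(tree$root.time)) stop_fmt("tree has no root.time; not a calibrated tree")
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  stats::setNames(tree$root.time - d, tree$tip.label)
}

#' Randomly resolve polytomies
#'
#' Each polytomous node is resolved by seeded sequential random attachment:
#' its child subtrees are repeatedly paired at random until the node is
#' binary. For a trichotomy the three labelled resolutions are
#' equiprobable; a k-way polytomy reaches every one of its (2k-3)!! labelled
#' resolutions. Deterministic under a fixed seed. Root trichotomies
#' (which ape treats as unrooted) are resolved like any other polytomy.
#'
#' @param cladogram `phylo`, possibly with polytomies, no branch lengths.
#' @param seed integer seed.
#' @return a fully bifurcating rooted `phylo`.
#' @export
resolve_polytomies <- function(cladogram, seed) {
  if (ape::is.binary.phylo(cladogram) && ape::is.rooted(cladogram))
    return(cladogram)
  set.seed(seed)
  n <- ape::Ntip(cladogram)
  kids_of <- split(cladogram$edge[, 2], cladogram$edge[, 1])
  build <- function(nd) {
    if (nd <= n) return(cladogram$tip.label[nd])
    subs <- vapply(kids_of[[as.character(nd)]], build, "")
    while (length(subs) > 2L) {
      pick <- sample.int(length(subs), 2L)
      subs <- c(subs[-pick], paste0("(", subs[pick[1]], ",", subs[pick[2]], ")"))
    }
    paste0("(", paste(subs, collapse = ","), ")")
  }
  phy <- ape::read.tree(text = paste0(build(n + 1L), ";"))
  phy$edge.length <- NULL
  phy
}

#' Draw tip ages uniformly within stratigraphic ranges
#'
#' Each taxon's age is drawn independently from
#' Uniform\[age_min, age_max\] (Ma before present).
#'
#' @param ages data.frame with `taxon`, `age_max`, `age_min`.
#' @param seed integer seed.
#' @return named numeric vector of sampled ages.
#' @export
sample_tip_ages <- function(ages, seed) {
  stopifnot(all(c("taxon", "age_max", "age_min") %in% names(ages)))
  if (any(ages$age_max < ages$age_min)) stop_fmt("age_max < age_min")
  set.seed(seed)
  stats::setNames(stats::runif(nrow(ages), ages$age_min, ages$age_max), ages$taxon)
}

# node ages implied by tip ages alone: every internal node as young as its
# oldest descendant tip allows (minimum node ages)
min_node_ages <- function(tree, tip_age) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  age <- numeric(n + m)
  age[seq_len(n)] <- tip_age[tree$tip.label]
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    age[p] <- max(age[p], age[ch])
  }
  age
}

ages_to_phylo <- function(tree, age) {
  tree$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  if (any(tree$edge.length < -1e-9)) stop_fmt("internal error: negative branch duration")
  tree$edge.length[tree$edge.length < 0] <- 0
  tree$root.time <- age[ape::Ntip(tree) + 1L]
  tree
}

#' Minimum-branch-length time calibration
#'
#' Node ages are initialised at the minimum values implied by the sampled tip
#' ages (each node as young as its oldest descendant tip), then a
#' tips-to-root pass enforces `parent_age >= child_age + min_bl` for every
#' branch, so all branch durations are at least `min_bl`. Tip ages are never
#' altered.
#'
#' @param cladogram binary `phylo` without branch lengths.
#' @param tip_age named vector of tip ages (Ma before present) covering all tips.
#' @param min_bl minimum branch duration in Ma (> 0); default 2.
#' @return calibrated `phylo` with `root.time`.
#' @export
#' @examples
#' cl <- read_newick("(A,B);")
#' tr <- calibrate_mbl(cl, c(A = 100, B = 100), min_bl = 2)
#' tr$root.time # 102
calibrate_mbl <- function(cladogram, tip_age, min_bl = 2) {
  if (!ape::is.binary.phylo(cladogram))
    stop_fmt("calibrate_mbl needs a binary tree; resolve polytomies first")
  if (min_bl <= 0) stop_fmt("min_bl must be > 0")
  miss <- setdiff(cladogram$tip.label, names(tip_age))
  if (length(miss)) stop_fmt("no tip age for: %s", paste(miss, collapse = ", "))
  n <- ape::Ntip(cladogram)
  age <- min_node_ages(cladogram, tip_age)
  po <- ape::reorder.phylo(cladogram, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    age[p] <- max(age[p], age[ch] + min_bl)
  }
  ages_to_phylo(cladogram, age)
}

#' 'Equal' time calibration
#'
#' Node ages are initialised at their minimum values (as in
#' [calibrate_mbl()]); each maximal run of zero-duration branches, together
#' with its first positive-duration ancestor branch, then has that ancestor's
#' duration redistributed equally across the run, by raising the intermediate
#' node ages. If a run reaches the root with no positive duration above it,
#' the root age is extended by `root_buffer` to supply duration; with
#' `root_buffer = 0` that situation is an error naming the path.
#'
#' @inheritParams calibrate_mbl
#' @param root_buffer extra duration (Ma) the root may be pushed back when a
#'   zero-length run reaches it; default 0.
#' @param tol durations below `tol` count as zero.
#' @return calibrated `phylo` with `root.time`; all durations > 0.
#' @export
calibrate_equal <- function(cladogram, tip_age, root_buffer = 0, tol = 1e-8) {
  if (!ape::is.binary.phylo(cladogram))
    stop_fmt("calibrate_equal needs a binary tree; resolve polytomies first")
  miss <- setdiff(cladogram$tip.label, names(tip_age))
  if (length(miss)) stop_fmt("no tip age for: %s", paste(miss, collapse = ", "))
  n <- ape::Ntip(cladogram)
  root <- n + 1L
  age <- min_node_ages(cladogram, tip_age)
  edge <- cladogram$edge
  parent_of <- integer(n + cladogram$Nnode)
  parent_of[edge[, 2]] <- edge[, 1]
  children_of <- split(edge[, 2], edge[, 1])
  buffer_used <- FALSE

  repeat {
    dur <- age[edge[, 1]] - age[edge[, 2]]
    zero <- which(dur <= tol)
    if (!length(zero)) break
    # topmost zero edge: one whose parent's incoming edge is positive or absent
    top <- NULL
    for (k in zero) {
      p <- edge[k, 1]
      if (p == root || (age[parent_of[p]] - age[p]) > tol) { top <- k; break }
    }
    p <- edge[top, 1]; c1 <- edge[top, 2]
    # follow the chain of zero edges downward from c1
    chain <- c(p, c1)
    node <- c1
    repeat {
      kids <- children_of[[as.character(node)]]
      if (is.null(kids)) break
      zk <- kids[(age[node] - age[kids]) <= tol]
      if (!length(zk)) break
      node <- zk[1]
      chain <- c(chain, node)
    }
    bottom <- chain[length(chain)]
    if (p == root) {
      if (!buffer_used && root_buffer > 0) {
        age[root] <- age[root] + root_buffer
        buffer_used <- TRUE
        top_age <- age[root]
        to_space <- chain[-c(1, length(chain))]
        k_seg <- length(to_space) + 1L
        anc_age <- top_age
      } else {
        path <- paste(c("root", node_label(cladogram, chain[-1])), collapse = " -> ")
        stop_fmt("cannot redistribute duration: zero-length path at the root (%s); set root_buffer > 0", path)
      }
    } else {
      anc <- parent_of[p]
      anc_age <- age[anc]
      to_space <- chain[-length(chain)] # p and intermediates get new ages
      k_seg <- length(to_space) + 1L
    }
    if (anc_age - age[bottom] <= tol) {
      path <- paste(node_label(cladogram, chain), collapse = " -> ")
      stop_fmt("cannot redistribute duration: no available duration on path %s", path)
    }
    step <- (anc_age - age[bottom]) / k_seg
    for (i in seq_along(to_space)) age[to_space[i]] <- anc_age - i * step
  }
  out <- ages_to_phylo(cladogram, age)
  if (any(out$edge.length <= 0)) stop_fmt("internal error: 'equal' left a non-positive branch")
  out
}

node_label <- function(tree, nodes) {
  n <- ape::Ntip(tree)
  ifelse(nodes <= n, tree$tip.label[nodes], paste0("node", nodes))
}

#' Generate replicate calibrated trees
#'
#' Convenience wrapper: resolves polytomies, samples tip ages and calibrates,
#' once per replicate, with child seeds derived from the master seed.
#'
#' @param cladogram `phylo`, possibly with polytomies.
#' @param ages stratigraphic age table (`taxon`, `age_max`, `age_min`).
#' @param n_trees number of replicate calibrations.
#' @param method `"mbl"` or `"equal"`.
#' @param min_bl minimum branch length for `"mbl"` (Ma).
#' @param root_buffer root buffer for `"equal"` (Ma).
#' @param seed master seed.
#' @return list of calibrated `phylo` objects.
#' @export
replicate_trees <- function(cladogram, ages, n_trees = 25, method = c("mbl", "equal"),
                            min_bl = 2, root_buffer = 10, seed = 1) {
  method <- match.arg(method)
  lapply(seq_len(n_trees), function(i) {
    phy <- resolve_polytomies(cladogram, derive_seed(seed, "resolve", i))
    ta <- sample_tip_ages(ages, derive_seed(seed, "tip_ages", i))
    if (method == "mbl") calibrate_mbl(phy, ta, min_bl = min_bl)
    else calibrate_equal(phy, ta, root_buffer = root_buffer)
  })
}
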