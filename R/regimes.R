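# Regime maps: paintings of macroevolutionary regime labels onto branch
# segments of a calibrated tree. A regime map is a data.frame with one row
# per branch segment: `edge` (row index into tree$edge), `start` and `end`
# (segment depths from the root, Ma, start < end) and `regime` (character).
# Segments tile every branch exactly.

#' Single-regime map covering the whole tree
#' @param tree calibrated `phylo`.
#' @param label regime label.
#' @return a regime map `data.frame`.
#' @export
single_regime_map <- function(tree, label = "all") {
  d <- node_depths(tree)
  data.frame(edge = seq_len(nrow(tree$edge)),
             start = d[tree$edge[, 1]],
             end = d[tree$edge[, 2]],
             regime = label,
             stringsAsFactors = FALSE)
}

#' Validate a regime map against its tree
#'
#' Checks that segments tile every branch exactly (no gaps or overlaps) and
#' that total painted duration equals total tree duration.
#'
#' @param tree calibrated `phylo`.
#' @param map regime map `data.frame`.
#' @param tol numeric tolerance (Ma).
#' @return `TRUE` invisibly; error otherwise.
#' @export
validate_regime_map <- function(tree, map, tol = 1e-8) {
  d <- node_depths(tree)
  need <- c("edge", "start", "end", "regime")
  if (!all(need %in% names(map))) stop_fmt("regime map needs columns %s", paste(need, collapse = ", "))
  for (e in seq_len(nrow(tree$edge))) {
    seg <- map[map$edge == e, , drop = FALSE]
    if (!nrow(seg)) stop_fmt("edge %d is unpainted", e)
    seg <- seg[order(seg$start), , drop = FALSE]
    p <- d[tree$edge[e, 1]]; ch <- d[tree$edge[e, 2]]
    if (abs(seg$start[1] - p) > tol || abs(seg$end[nrow(seg)] - ch) > tol)
      stop_fmt("segments of edge %d do not span the branch", e)
    if (nrow(seg) > 1 && any(abs(seg$start[-1] - seg$end[-nrow(seg)]) > tol))
      stop_fmt("gap or overlap in segments of edge %d", e)
    if (any(seg$end - seg$start <= -tol)) stop_fmt("negative segment on edge %d", e)
  }
  tot <- sum(map$end - map$start)
  if (abs(tot - sum(tree$edge.length)) > 1e-6 * max(1, sum(tree$edge.length)))
    stop_fmt("painted duration (%.6g) != total tree duration (%.6g)",
             tot, sum(tree$edge.length))
  invisible(TRUE)
}

#' Paint clade regimes onto a calibrated tree
#'
#' Each clade is defined by a set of tip labels; its regime covers every
#' branch of the subtree rooted at the tips' MRCA *plus* the clade's stem
#' branch (stem-inclusive painting, the usual convention for multi-regime OU
#' paintings; crown-only painting can be had by passing `stem = FALSE`).
#' Branches in no clade get `base_label`. Clades must be nested or disjoint;
#' a branch inside several nested clades takes the most exclusive one.
#'
#' @param tree calibrated `phylo`.
#' @param clades named list of character vectors of tip labels.
#' @param base_label label for residual (background) branches.
#' @param stem logical: include the stem branch of each clade (default TRUE).
#' @return a regime map `data.frame` (one segment per branch).
#' @export
paint_clades <- function(tree, clades, base_label = "basal", stem = TRUE) {
  stopifnot(is.list(clades), length(clades) >= 1, !is.null(names(clades)))
  n <- ape::Ntip(tree)
  tipsets <- lapply(clades, function(tt) {
    miss <- setdiff(tt, tree$tip.label)
    if (length(miss)) stop_fmt("clade tips not in tree: %s", paste(miss, collapse = ", "))
    sort(match(tt, tree$tip.label))
  })
  # nested-or-disjoint check, both on the defining tip sets and on the
  # realised descendant sets of the MRCAs
  desc <- lapply(tipsets, function(ti) {
    node <- if (length(ti) == 1L) ti else ape::getMRCA(tree, ti)
    tips_below(tree, node)
  })
  check_nesting <- function(sets) {
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i >= j) next
      ov <- length(intersect(sets[[i]], sets[[j]]))
      if (ov > 0 && ov < min(length(sets[[i]]), length(sets[[j]])))
        stop_fmt("clades '%s' and '%s' overlap without nesting",
                 names(clades)[i], names(clades)[j])
    }
  }
  check_nesting(tipsets)
  check_nesting(desc)
  # assign each edge the most exclusive containing clade
  ord <- order(vapply(desc, length, 1L)) # most exclusive first
  lab <- rep(base_label, nrow(tree$edge))
  for (i in rev(ord)) { # paint large clades first, small ones overwrite
    ti <- tipsets[[i]]
    node <- if (length(ti) == 1L) ti else ape::getMRCA(tree, ti)
    in_clade <- edges_below(tree, node, include_stem = stem)
    lab[in_clade] <- names(clades)[i]
  }
  m <- single_regime_map(tree)
  m$regime <- lab
  m
}

tips_below <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(node)
  kids <- tree$edge[edges_below(tree, node, include_stem = FALSE), 2]
  sort(kids[kids <= n])
}

edges_below <- function(tree, node, include_stem = TRUE) {
  keep <- logical(nrow(tree$edge))
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    ks <- which(tree$edge[, 1] == nd)
    keep[ks] <- TRUE
    stack <- c(stack, tree$edge[ks, 2])
  }
  if (include_stem) keep[which(tree$edge[, 2] == node)] <- TRUE
  which(keep)
}

#' Paint era regimes onto a calibrated tree
#'
#' Branches are split exactly at each time boundary they cross and segments
#' are labelled by the era containing them. Boundaries are given as ages (Ma
#' before present), strictly decreasing eras from oldest to youngest; a
#' boundary older than the root is ignored with a warning.
#'
#' @param tree calibrated `phylo` with `root.time`.
#' @param boundaries_Ma numeric vector of boundary ages (Ma before present).
#' @param labels optional character vector of era labels, length
#'   `length(boundaries) + 1`, oldest era first; default `era1`, `era2`, ...
#' @return a regime map `data.frame`.
#' @export
paint_eras <- function(tree, boundaries_Ma, labels = NULL) {
  if (is.null(tree$root.time)) stop_fmt("tree has no root.time")
  b <- sort(unique(boundaries_Ma), decreasing = TRUE) # oldest first
  drop <- b >= tree$root.time
  if (any(drop)) {
    warn_fmt("boundary at %s Ma is older than the root (%.3g Ma); ignored",
             paste(b[drop], collapse = ", "), tree$root.time)
    b <- b[!drop]
  }
  if (is.null(labels)) labels <- paste0("era", seq_len(length(b) + 1L))
  if (length(labels) != length(b) + 1L)
    stop_fmt("need %d era labels, got %d", length(b) + 1L, length(labels))
  cuts <- tree$root.time - b # boundary depths, increasing
  d <- node_depths(tree)
  segs <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    s <- d[tree$edge[e, 1]]; en <- d[tree$edge[e, 2]]
    inner <- cuts[cuts > s & cuts < en]
    pts <- c(s, inner, en)
    k <- length(pts) - 1L
    mid <- (pts[-1] + pts[-(k + 1L)]) / 2
    era <- findInterval(mid, cuts) + 1L
    segs[[e]] <- data.frame(edge = e, start = pts[-(k + 1L)], end = pts[-1],
                            regime = labels[era], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Regime labels present in a map (basal regime first)
#'
#' The basal regime is the one painted at the root (depth 0).
#' @param tree calibrated `phylo`.
#' @param map regime map.
#' @return character vector of regime labels, basal first.
#' @export
regime_levels <- function(tree, map) {
  root <- ape::Ntip(tree) + 1L
  root_edges <- which(tree$edge[, 1] == root)
  first <- map[map$edge %in% root_edges, , drop = FALSE]
  basal <- first$regime[which.min(first$start)]
  c(basal, setdiff(unique(map$regime), basal))
}

#' Write a regime map sidecar CSV
#' @param map regime map.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regime_map <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE)
  invisible(path)
}
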