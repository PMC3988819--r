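test_that("polytomy resolution is seeded, uniform on a trichotomy, exhaustive on a 4-way", {
  bin <- read_newick("((A,B),C);")
  expect_equal(canon_topology(resolve_polytomies(bin, 1)), canon_topology(bin))

  tri <- read_newick("(A,B,C);")
  expect_equal(canon_topology(resolve_polytomies(tri, 7)),
               canon_topology(resolve_polytomies(tri, 7)))
  tops <- vapply(1:3000, function(s) canon_topology(resolve_polytomies(tri, s)), "")
  freq <- table(tops) / 3000
  expect_equal(length(freq), 3L)
  # 1/3 each within ~4 binomial sd (sd ~ 0.0086)
  expect_true(all(abs(freq - 1 / 3) < 0.035))

  quad <- read_newick("(A,B,C,D);")
  tops4 <- unique(vapply(1:3000, function(s) canon_topology(resolve_polytomies(quad, s)), ""))
  expect_equal(length(tops4), 15L) # (2*4 - 3)!! labelled resolutions
  expect_true(ape::is.binary.phylo(resolve_polytomies(quad, 1)))
})

test_that("tip ages are uniform draws within the stratigraphic bounds", {
  ages <- data.frame(taxon = c("A", "B"), age_max = c(150, 152), age_min = c(150, 145))
  a1 <- sample_tip_ages(ages, 5)
  expect_identical(a1, sample_tip_ages(ages, 5))
  expect_equal(unname(a1["A"]), 150) # degenerate interval
  draws <- vapply(1:5000, function(s) sample_tip_ages(ages, s)["B"], 0)
  expect_true(all(draws >= 145 & draws <= 152))
  expect_equal(mean(draws), 148.5, tolerance = 0.01) # (145+152)/2, se ~ 0.03
})

test_that("mbl calibration matches the two-pass worked examples", {
  cherry <- read_newick("(A,B);")
  tr <- calibrate_mbl(cherry, c(A = 100, B = 100), min_bl = 2)
  expect_equal(tr$root.time, 102)
  expect_equal(sort(tr$edge.length), c(2, 2))

  nested <- read_newick("((A,B),C);")
  tr3 <- calibrate_mbl(nested, c(A = 100, B = 100, C = 100), min_bl = 2)
  d <- node_depths(tr3)
  ages <- tr3$root.time - d
  expect_equal(tr3$root.time, 104)
  expect_equal(sort(unique(round(ages[-(1:3)], 9))), c(102, 104))

  # staggered ages: each node pushed back just min_bl above its oldest child
  tr4 <- calibrate_mbl(nested, c(A = 100, B = 90, C = 80), min_bl = 2)
  expect_equal(tr4$root.time, 104) # (A,B) node at 102, root 2 Ma above it
  expect_equal(unname(tip_ages(tr4)[c("A", "B", "C")]), c(100, 90, 80))
  expect_error(calibrate_mbl(nested, c(A = 1, B = 1, C = 1), min_bl = 0), "min_bl")
})

test_that("mbl output always respects the minimum duration and tip ages", {
  for (s in 1:5) {
    clad <- simulate_tree(25, 120, seed = s)
    ages <- simulate_ages(clad, seed = s)
    clad$edge.length <- NULL
    ta <- sample_tip_ages(ages, s + 10)
    tr <- calibrate_mbl(clad, ta, min_bl = 2)
    expect_true(all(tr$edge.length >= 2 - 1e-9))
    expect_equal(tip_ages(tr)[names(ta)], ta, tolerance = 1e-9)
    expect_equal(canon_topology(tr), canon_topology(clad))
  }
})

test_that("'equal' calibration redistributes ancestor duration over zero runs", {
  # With minimum node ages the run of zero branches leading to the globally
  # oldest tip always reaches the root, so the root buffer supplies the
  # duration: 6 Ma shared over the 3-branch run root -> (AB,C) -> (A,B) -> A
  # as 2 + 2 + 2.
  clad <- read_newick("(((A,B),C),D);")
  ta <- c(A = 110, B = 90, C = 100, D = 104)
  expect_error(calibrate_equal(clad, ta), "root_buffer")
  tr <- calibrate_equal(clad, ta, root_buffer = 6)
  age <- tr$root.time - node_depths(tr)
  expect_equal(tr$root.time, 116)
  expect_equal(sort(age[-(1:4)]), c(112, 114, 116), tolerance = 1e-9)
  run_edges <- tr$edge.length[tr$edge.length < 12] # the redistributed run
  expect_equal(unique(round(run_edges, 9)), 2)
  expect_equal(length(run_edges), 3L)
  expect_true(all(tr$edge.length > 0))
  expect_equal(tip_ages(tr)[names(ta)], ta, tolerance = 1e-9)

  # structural invariants on a tree where several runs interact: strictly
  # positive durations, preserved tip ages and topology, root at the oldest
  # tip age plus the buffer
  ta2 <- c(A = 100, B = 90, C = 104, D = 110)
  tr2 <- calibrate_equal(clad, ta2, root_buffer = 6)
  expect_equal(tr2$root.time, 116)
  expect_equal(tip_ages(tr2)[names(ta2)], ta2, tolerance = 1e-9)
  expect_true(all(tr2$edge.length > 0))
  expect_equal(canon_topology(tr2), canon_topology(clad))
})

test_that("replicate calibrated trees are distinct under nondegenerate age ranges", {
  clad <- simulate_tree(20, 100, seed = 2)
  ages <- simulate_ages(clad, seed = 3)
  clad$edge.length <- NULL
  trees <- replicate_trees(clad, ages, n_trees = 6, method = "mbl", seed = 1)
  rt <- vapply(trees, `[[`, 0, "root.time")
  expect_equal(length(unique(rt)), 6L)
  expect_true(all(vapply(trees, function(t) all(t$edge.length >= 2 - 1e-9), TRUE)))
})

test_that("clade painting tiles the tree and respects nesting", {
  tr <- fixture_tree5()
  m1 <- paint_clades(tr, list(all = tr$tip.label))
  expect_equal(unique(m1$regime), "all")
  validate_regime_map(tr, m1)

  m2 <- paint_clades(tr, list(cladeAB = c("A", "B")))
  validate_regime_map(tr, m2)
  expect_equal(sum(m2$end - m2$start), sum(tr$edge.length))
  expect_setequal(unique(m2$regime), c("basal", "cladeAB"))
  # stem-inclusive: stem branch of (A,B) carries the clade label
  mrca_ab <- ape::getMRCA(tr, c("A", "B"))
  stem_edge <- which(tr$edge[, 2] == mrca_ab)
  expect_equal(m2$regime[m2$edge == stem_edge], "cladeAB")

  m3 <- paint_clades(tr, list(big = c("A", "B", "C"), small = c("A", "B")))
  expect_setequal(unique(m3$regime), c("basal", "big", "small"))
  expect_error(paint_clades(tr, list(x = c("A", "B"), y = c("B", "C"))),
               "overlap")
})

test_that("era painting splits branches exactly at boundaries", {
  tr <- fixture_tree4() # root.time 90
  # a boundary older than the root is ignored with a warning
  expect_warning(m0 <- paint_eras(tr, 95), "ignored")
  expect_equal(unique(m0$regime), "era1")

  m <- paint_eras(tr, 50, labels = c("old", "young")) # boundary depth 40
  validate_regime_map(tr, m)
  expect_equal(sum(m$end - m$start), sum(tr$edge.length))
  # the B pendant branch spans depths 40..60 entirely in 'young'
  # and the root->CD branch (depth 0..25) entirely in 'old'
  eB <- which(tr$edge[, 2] == which(tr$tip.label == "B"))
  expect_equal(m$regime[m$edge == eB], "young")
  # the A pendant branch spans depth 40..70: split 40..40? no: A depth 40..70
  eA <- which(tr$edge[, 2] == which(tr$tip.label == "A"))
  segA <- m[m$edge == eA, ]
  expect_equal(nrow(segA), 1L)
  # C pendant branch spans 25..75, crossing depth 40: two segments 15 + 35
  eC <- which(tr$edge[, 2] == which(tr$tip.label == "C"))
  segC <- m[m$edge == eC, ]
  expect_equal(sort(segC$end - segC$start), c(15, 35))
  expect_setequal(segC$regime, c("old", "young"))
})
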