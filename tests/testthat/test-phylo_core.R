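test_that("read_newick parses, validates, and reports structural errors", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tree_depth(tr), 2)
  expect_equal(unname(phylo_vcv(tr)["A", "B"]), 1)  # MRCA(A,B) at depth 1

  single <- read_newick("(A:1);")
  expect_equal(ape::Ntip(single), 1L)
  expect_equal(tree_depth(single), 1)

  uneven <- read_newick("((A:1,B:2):1,C:2);")
  expect_false(is_ultrametric_tree(uneven))
  expect_equal(unname(sort(tip_depths(uneven))), c(2, 2, 3))

  expect_error(read_newick("((A:1,B:1):1,C:2"), "unclosed")
  expect_error(read_newick("(A:1,B:1)):1;"), "offset 10")
  expect_error(read_newick("(A:1,B:1)"), "';'")
  expect_error(read_newick("((A:1,A:1):1,C:2);"), "duplicate tip labels")
  expect_error(read_newick("((A:1,B):1,C:2);"), "branch length")
})

test_that("rescale_depth scales to the target exactly and is idempotent", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  r1 <- rescale_depth(tr, 1)
  expect_equal(tree_depth(r1), 1)
  expect_equal(r1$edge.length, tr$edge.length / 2)
  expect_equal(rescale_depth(r1, 1), r1)
  expect_equal(rescale_depth(tr, 2), tr)
  expect_error(rescale_depth(tr, 0), "target")
  zero <- tr; zero$edge.length[] <- 0
  expect_error(rescale_depth(zero), "zero-depth")
})

test_that("phylo_vcv matches its definition and the path-enumeration oracle", {
  tr <- read_newick("((A:0.5,B:0.5):0.5,C:1);")
  expect_equal(unname(phylo_vcv(tr)),
               rbind(c(1, .5, 0), c(.5, 1, 0), c(0, 0, 1)))

  st <- star_tree(6, len = 2.5)
  expect_equal(unname(phylo_vcv(st)), 2.5 * diag(6))

  bal <- read_newick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  expect_equal(phylo_vcv(bal), naive_bm_cov(bal))
  for (seed in 1:5) {
    tr <- small_tree(7, seed)
    expect_equal(phylo_vcv(tr), naive_bm_cov(tr), tolerance = 1e-12)
  }
})

test_that("unit-depth vcv has unit diagonal; rescale commutes with vcv", {
  for (seed in 1:5) {
    tr <- small_tree(10, seed)
    C <- phylo_vcv(tr)
    expect_equal(unname(diag(C)), rep(1, 10))
    expect_lt(max(C[upper.tri(C)]), 1)
    big <- tr; big$edge.length <- big$edge.length * 7.3
    expect_equal(phylo_vcv(rescale_depth(big, 2)), 2 * C, tolerance = 1e-12)
  }
})

test_that("graft_missing_taxa places sisters, keeps ultrametricity, is seeded", {
  tr <- small_tree(8, seed = 4)
  expect_identical(graft_missing_taxa(tr, NULL), tr)
  expect_identical(graft_missing_taxa(tr, data.frame()[0, ]), tr)

  pl <- data.frame(new_tip = c("X", "Y"),
                   anchor_tips = c("t1;t2", "t5"))
  g1 <- graft_missing_taxa(tr, pl, seed = 11)
  expect_equal(ape::Ntip(g1), 10L)
  expect_true(is_ultrametric_tree(g1, tol = 1e-9))
  d <- tip_depths(g1)
  expect_lt(max(d) - min(d), 1e-9)
  # Y is bound as sister to its anchor: their MRCA is Y's parent
  mrca <- ape::getMRCA(g1, c("Y", "t5"))
  yi <- match("Y", g1$tip.label)
  expect_equal(g1$edge[g1$edge[, 2] == yi, 1], mrca)
  expect_identical(write_newick(graft_missing_taxa(tr, pl, seed = 11)),
                   write_newick(g1))
  expect_false(identical(write_newick(graft_missing_taxa(tr, pl, seed = 12)),
                         write_newick(g1)))
  expect_error(graft_missing_taxa(tr, data.frame(new_tip = "Z",
                                                 anchor_tips = "nosuch")),
               "nosuch")
})

test_that("grafting property: ultrametric, +1 tip per placement, across seeds", {
  tr <- small_tree(12, seed = 9)
  pl <- data.frame(new_tip = paste0("X", 1:4),
                   anchor_tips = c("t1", "t2;t3", "t4", "t5;t6;t7"))
  for (seed in 1:10) {
    g <- graft_missing_taxa(tr, pl, seed = seed)
    expect_equal(ape::Ntip(g), 16L)
    d <- tip_depths(g)
    expect_lt(max(d) - min(d), 1e-9)
    expect_true(all(g$edge.length > 0))
  }
})

test_that("paint_regimes: constant character, hand-run Fitch, pendant edges", {
  tr <- read_newick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  allw <- setNames(rep("woody", 4), c("A", "B", "C", "D"))
  p <- paint_regimes(tr, allw)
  expect_true(all(p$edge_states == "woody"))
  expect_equal(p$n_changes, 0L)

  # (H,H,W,W): cherries painted H and W; root set {H, W} -> majority tie ->
  # lexicographic first ("H"); one change on the W-cherry stem edge
  st <- setNames(c("H", "H", "W", "W"), c("A", "B", "C", "D"))
  p2 <- paint_regimes(tr, st)
  ntip <- 4L
  cherry_hw <- function(tips) {
    e <- which(tr$edge[, 2] %in% match(tips, tr$tip.label))
    unique(p2$edge_states[e])
  }
  expect_equal(cherry_hw(c("A", "B")), "H")
  expect_equal(cherry_hw(c("C", "D")), "W")
  expect_equal(p2$root_state, "H")
  expect_equal(p2$n_changes, 1L)
  expect_error(paint_regimes(tr, st[-1]), "missing tip states")
})

test_that("painting change count equals the exhaustive Fitch parsimony score", {
  set.seed(42)
  for (case in 1:20) {
    n <- sample(4:6, 1)
    tr <- small_tree(n, seed = 100 + case)
    st <- setNames(sample(c("H", "W"), n, replace = TRUE), tr$tip.label)
    if (length(unique(st)) == 1) st[1] <- setdiff(c("H", "W"), st[1])
    p <- paint_regimes(tr, st)
    expect_equal(p$n_changes, fitch_score_brute(tr, st))
    # pendant edges carry the observed tip state
    pend <- tr$edge[, 2] <= n
    expect_equal(p$edge_states[pend],
                 unname(st[tr$tip.label[tr$edge[pend, 2]]]))
  }
})
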