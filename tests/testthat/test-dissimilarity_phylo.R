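test_that("condensed distances follow the (2,1),(3,1),...(m,m-1) order", {
  S <- matrix(c(0, 0, 3, 4, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  d <- pairwise_euclidean_condensed(S)
  expect_equal(as.numeric(d), c(5, 0, 5))   # (b,a), (c,a), (c,b)
  expect_equal(attr(d, "Labels"), c("a", "b", "c"))

  same <- matrix(0, 2, 3)
  expect_equal(as.numeric(pairwise_euclidean_condensed(same)), 0)

  set.seed(3)
  expect_length(as.numeric(pairwise_euclidean_condensed(
    matrix(rnorm(30), 10, 3))), 45L)
  expect_error(pairwise_euclidean_condensed(matrix(c(0, NA, 1, 2), 2, 2)),
               "non-finite")
})

test_that("to_square places entries symmetrically and round-trips", {
  dm <- to_square(c(5, 0, 5), ids = c("a", "b", "c"))
  expect_equal(unname(dm),
               matrix(c(0, 5, 0, 5, 0, 5, 0, 5, 0), 3, 3))
  expect_equal(diag(dm), c(a = 0, b = 0, c = 0))
  expect_error(to_square(c(1, 2)), "triangular")
  expect_equal(to_square(numeric(0), ids = "only"),
               matrix(0, 1, 1, dimnames = list("only", "only")))
  set.seed(4)
  d <- stats::dist(matrix(rnorm(18), 6, 3))
  expect_equal(as.numeric(stats::as.dist(to_square(d))), as.numeric(d))
})

test_that("distance metric properties hold on random score matrices", {
  set.seed(9)
  for (rep in 1:10) {
    S <- matrix(rnorm(8 * 3), 8, 3)
    dm <- to_square(pairwise_euclidean_condensed(S))
    expect_equal(dm, t(dm))
    expect_true(all(diag(dm) == 0))
    for (i in 1:8) for (j in 1:8) for (l in 1:8) {
      expect_lte(dm[i, j], dm[i, l] + dm[l, j] + 1e-12)
    }
  }
})

test_that("upgma reproduces hand-executed merges", {
  # two taxa: single merge at half the dissimilarity
  t2 <- upgma(to_square(0.4, ids = c("a", "b")))
  expect_equal(t2$height, 0.2)
  expect_equal(cophenetic_distance(t2, "a", "b"), 0.4)

  # three taxa: {1,2} at height 1, then root at (8+8)/2/2 = 4
  dm <- to_square(c(2, 8, 8), ids = c("t1", "t2", "t3"))
  t3 <- upgma(dm)
  expect_equal(t3$height, c(1, 4))
  expect_equal(cophenetic_distance(t3, "t1", "t2"), 2)
  expect_equal(cophenetic_distance(t3, "t1", "t3"), 8)
  expect_equal(cophenetic_distance(t3, "t1", "t1"), 0)
  expect_error(cophenetic_distance(t3, "t1", "nope"), "unknown taxon")
})

test_that("upgma validates its input", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma(bad), "asymmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(upgma(neg), "negative")
  expect_error(upgma(matrix(0, 1, 1)), "at least 2")
})

test_that("upgma uses the size-weighted average update", {
  # after merging {a,b} (d=2), d({ab},c) = (6 + 10)/2 = 8 -> height 4;
  # then d({abc},e) = (2*20 + 1*35)/3 = 25 -> root at 12.5 (the
  # unweighted WPGMA update would give 27.5 -> 13.75 instead)
  dm <- to_square(c(2, 6, 20, 10, 20, 35), ids = c("a", "b", "c", "e"))
  tr <- upgma(dm)
  expect_equal(tr$height, c(1, 4, 12.5))
})

test_that("upgma is ultrametric with monotone heights on random inputs", {
  set.seed(21)
  for (rep in 1:15) {
    dm <- random_dissimilarity(sample(4:10, 1))
    tr <- upgma(dm)
    expect_true(all(diff(tr$height) >= -1e-12))
    expect_equal(2 * tr$height[1], min(dm[upper.tri(dm)]))
    phy <- as_phylo(tr)
    depths <- root_to_leaf_depths(phy)
    expect_equal(unname(depths), rep(max(tr$height), tr$m),
                 tolerance = 1e-10)
  }
})

test_that("upgma matches an independent average-linkage reference", {
  skip_if_not_installed("phangorn")
  set.seed(22)
  for (rep in 1:50) {
    dm <- random_dissimilarity(8)
    mine <- as_phylo(upgma(dm))
    ref <- phangorn::upgma(stats::as.dist(dm))
    expect_true(ape::all.equal.phylo(mine, ref, use.edge.length = TRUE,
                                     tolerance = 1e-8))
  }
})

test_that("tie-breaking picks the lowest index pair deterministically", {
  # d(1,2) == d(3,4): the (2,1) merge must happen first
  dm <- to_square(c(1, 5, 5, 5, 5, 1), ids = c("a", "b", "c", "e"))
  tr <- upgma(dm)
  expect_equal(tr$merge[1, ], c(-2L, -1L))
  expect_equal(tr$merge[2, ], c(-4L, -3L))
})

test_that("cut_tree extracts the k highest-split groups", {
  dm <- to_square(c(2, 8, 8), ids = c("t1", "t2", "t3"))
  tr <- upgma(dm)
  expect_equal(unname(cut_tree(tr, 2)), c(1L, 1L, 2L))
  expect_equal(unname(cut_tree(tr, 1)), c(1L, 1L, 1L))
  expect_equal(unname(cut_tree(tr, 3)), 1:3)
  expect_error(cut_tree(tr, 4), "\\[1, 3\\]")
})

test_that("newick export round-trips topology and branch lengths", {
  t2 <- upgma(to_square(0.4, ids = c("a", "b")))
  nwk <- write_newick(t2)
  phy <- read_newick(nwk)
  expect_setequal(phy$tip.label, c("a", "b"))
  expect_equal(sort(phy$edge.length), c(0.2, 0.2))

  dm3 <- to_square(c(2, 8, 8), ids = c("t1", "t2", "t3"))
  t3 <- upgma(dm3)
  phy3 <- read_newick(write_newick(t3))
  expect_true(ape::all.equal.phylo(phy3, as_phylo(t3),
                                   use.edge.length = TRUE,
                                   tolerance = 1e-10))
  cd <- as.matrix(stats::cophenetic(read_newick(write_newick(t3))))
  expect_equal(cd["t1", "t3"], 8, tolerance = 1e-10)

  set.seed(23)
  dm <- random_dissimilarity(9)
  tr <- upgma(dm)
  phy <- read_newick(write_newick(tr))
  expect_true(ape::all.equal.phylo(phy, as_phylo(tr),
                                   use.edge.length = TRUE,
                                   tolerance = 1e-10))
})

test_that("first merge cophenetic distance recovers the input minimum", {
  set.seed(24)
  for (rep in 1:10) {
    dm <- random_dissimilarity(7)
    tr <- upgma(dm)
    pair <- -tr$merge[1, ]   # both leaves at the first merge
    expect_equal(cophenetic_distance(tr, pair[1], pair[2]),
                 min(dm[upper.tri(dm)]), tolerance = 1e-12)
  }
})
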