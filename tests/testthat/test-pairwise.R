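test_that("information-to-distance transform follows the closed form", {
  expect_equal(info_to_distance(0), 1)
  expect_equal(info_to_distance(3, 0.5), 0.5)
  expect_equal(info_to_distance(99, 0.5), 0.1)
  expect_equal(info_to_distance(-0.01), 1)  # small negatives clipped
  # strictly decreasing
  v <- info_to_distance(c(0, 1, 5, 20))
  expect_true(all(diff(v) < 0))
})

test_that("complete linkage merges the closest pair first, heights monotone", {
  D <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3,
              dimnames = rep(list(c("a", "b", "c")), 2))
  cl <- cluster_genes(D)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))
  expect_equal(cl$merges$height[1], 0.1)
  expect_true(all(diff(cl$merges$height) >= 0))
  expect_match(cl$newick, "a|b")
  D2 <- matrix(c(0, .3, .3, 0), 2, dimnames = rep(list(c("g1", "g2")), 2))
  cl2 <- cluster_genes(D2)
  expect_equal(cl2$merges$height, 0.3)
  expect_error(cluster_genes(matrix(c(0, NA, NA, 0), 2)), "finite")
})

test_that("clustering is invariant to gene order", {
  set.seed(1)
  D <- matrix(runif(25, 0.2, 1), 5)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- rep(list(paste0("g", 1:5)), 2)
  perm <- c(4, 2, 5, 1, 3)
  cl1 <- cluster_genes(D)
  cl2 <- cluster_genes(D[perm, perm])
  expect_equal(sort(cl1$merges$height), sort(cl2$merges$height))
  # identical topology: compare induced cophenetic distances by gene name
  coph1 <- as.matrix(stats::cophenetic(cl1$hclust))
  coph2 <- as.matrix(stats::cophenetic(cl2$hclust))
  expect_equal(coph1, coph2[rownames(coph1), colnames(coph1)])
})

test_that("a gene paired with its copy scores like its auto-information", {
  hg <- make_half_grid(14)
  counts <- cbind(a = hg$x * 8, copy = hg$x * 8)
  pw <- pairwise_info(spatial_dataset(counts, hg$coords),
                      genes = c("a", "copy"), graph = "grid",
                      uncertainty = "none", bin_sizes = NULL,
                      max_iters = 300, seed = 4)
  auto <- pw$I["a", "a"]
  expect_gt(auto, 0)
  expect_equal(pw$I["a", "copy"], auto, tolerance = 0.1 * auto / auto)
  expect_equal(pw$I_sym, (pw$I + t(pw$I)) / 2)
  expect_equal(dim(pw$D), c(2L, 2L))
})

test_that("independent spatially-null genes carry near-zero pairwise information", {
  ds <- make_null_dataset(120, 2, seed = 5)
  pw <- pairwise_info(ds, genes = c("g1", "g2"), bin_sizes = NULL,
                      max_iters = 150, seed = 6)
  n <- 120
  expect_lt(abs(pw$I_sym["g1", "g2"]), 0.05 * n)
})

test_that("fewer than two genes is an error", {
  ds <- make_null_dataset(30, 2, seed = 7)
  expect_error(pairwise_info(ds, genes = "g1"), "two genes")
})

test_that("complementary patterns are invisible under the positivity constraint", {
  hg <- make_half_grid(14)
  counts <- cbind(left = hg$x * 8, right = (1 - hg$x) * 8)
  ds <- spatial_dataset(counts, hg$coords)
  pw <- pairwise_info(ds, genes = c("left", "right"), graph = "grid",
                      uncertainty = "none", bin_sizes = NULL,
                      max_iters = 300, seed = 9)
  # each gene alone is strongly spatial; the anti-correlated pair is not seen
  expect_gt(pw$I["left", "left"], 10)
  expect_lt(pw$I_sym["left", "right"], 0.25 * pw$I["left", "left"])
})
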