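test_that("Moran's I is -1 on the 4x4 checkerboard and matches brute force", {
  gg <- make_grid_graph(4)
  x <- (gg$coords[, 1] + gg$coords[, 2]) %% 2
  expect_equal(morans_i(x, gg$graph), -1)
  # independent brute force over the weight matrix
  brute <- function(x, g) {
    n <- g$n_cells
    W <- matrix(0, n, n)
    for (i in seq_len(n)) W[i, graph_neighbors(g, i)] <- 1
    z <- x - mean(x)
    (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
  }
  expect_equal(morans_i(x, gg$graph), brute(x, gg$graph))
  set.seed(1)
  y <- rnorm(16)
  expect_equal(morans_i(y, gg$graph), brute(y, gg$graph))
})

test_that("Moran's I agrees with the ape reference on a degree-regular graph", {
  # ape row-normalizes the weight matrix; on a degree-regular graph that is
  # a uniform rescaling, under which Moran's I is identical to binary weights
  set.seed(2)
  theta <- seq(0, 2 * pi, length.out = 41)[-41]
  coords <- cbind(cos(theta), sin(theta))
  g <- spatial_graph(coords, "knn", knn_m = 2)
  expect_true(all(g$degrees == 2))
  W <- matrix(0, 40, 40)
  for (i in 1:40) W[i, graph_neighbors(g, i)] <- 1
  x <- rnorm(40)
  ref <- ape::Moran.I(x, W, scaled = FALSE)
  expect_equal(morans_i(x, g), ref$observed, tolerance = 1e-10)
})

test_that("clique indicators give Moran 1 and Geary 0; constants give NA", {
  set.seed(3)
  cl <- make_two_cliques(3)
  expect_equal(morans_i(cl$membership, cl$graph), 1)
  expect_equal(gearys_c(cl$membership, cl$graph), 0)
  expect_true(is.na(morans_i(rep(2, 6), cl$graph)))
  expect_true(is.na(gearys_c(rep(2, 6), cl$graph)))
})

test_that("permutation nulls recover the known expectations", {
  set.seed(4)
  coords <- cbind(runif(100), runif(100))
  g <- spatial_graph(coords, "knn", knn_m = 5)
  x <- rnorm(100)
  mi <- replicate(1000, morans_i(sample(x), g))
  gc_ <- replicate(1000, gearys_c(sample(x), g))
  expect_equal(mean(mi), -1 / 99, tolerance = 0.003 / abs(1 / 99))
  expect_equal(mean(gc_), 1, tolerance = 0.01)
})

test_that("checkerboard alternation pushes Geary's C above 1", {
  gg <- make_grid_graph(4)
  x <- (gg$coords[, 1] + gg$coords[, 2]) %% 2
  expect_gt(gearys_c(x, gg$graph), 1)
})

test_that("PR-AUC is exact at both extremes and handles ties", {
  truth <- c(rep(TRUE, 5), rep(FALSE, 95))
  expect_equal(pr_auc(100:1, truth), 1)
  # reversed ranking: brute-force average precision of the worst ordering
  worst <- pr_auc(1:100, truth)
  brute <- mean(sapply(1:5, function(i) i / (95 + i)))
  expect_equal(worst, brute)
  # all-tied scores give precision = prevalence
  expect_equal(pr_auc(rep(1, 100), truth), 0.05)
  expect_error(pr_auc(1:4, rep(TRUE, 4)), "positive and one negative")
})

test_that("PR-AUC of random scores concentrates at the prevalence", {
  set.seed(5)
  truth <- c(rep(TRUE, 20), rep(FALSE, 180))
  vals <- replicate(200, pr_auc(rnorm(200), truth))
  expect_equal(mean(vals), 0.1, tolerance = 0.02 / 0.1)
})

test_that("PR-AUC is invariant to strictly monotone score transforms", {
  set.seed(6)
  s <- rnorm(50)
  truth <- s + rnorm(50) > 0.5
  expect_equal(pr_auc(s, truth), pr_auc(exp(s), truth))
  expect_equal(pr_auc(s, truth), pr_auc(rank(s), truth))
})

test_that("delta PR-AUC is zero at equality and bounded by the oracle", {
  set.seed(7)
  truth <- c(rep(TRUE, 10), rep(FALSE, 90))
  s <- rnorm(100)
  expect_equal(delta_pr_auc(s, s, truth), 0)
  expect_equal(delta_pr_auc(as.numeric(truth), s, truth),
               1 - pr_auc(s, truth))
})

test_that("baseline table ranks constant genes last and orients Geary", {
  ds <- make_null_dataset(50, 3, seed = 8)
  ds$counts[, 2] <- 7
  bl <- baseline_scores(ds)
  expect_true(is.na(bl$morans_i[2]))
  expect_equal(bl$rank_score[2], -Inf)
  blg <- baseline_scores(ds, statistic = "gearys_c")
  expect_equal(blg$rank_score[c(1, 3)], 2 - blg$gearys_c[c(1, 3)])
})
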