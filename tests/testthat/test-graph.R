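test_that("delaunay on a triangle gives the complete graph", {
  g <- spatial_graph(rbind(c(0, 0), c(1, 0), c(0.4, 1)), "delaunay")
  expect_equal(g$degrees, c(2L, 2L, 2L))
  expect_setequal(graph_neighbors(g, 1), c(2L, 3L))
})

test_that("radius graph on unit-square corners keeps sides, drops diagonals", {
  coords <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  g <- spatial_graph(coords, "radius", epsilon = 1.1)
  expect_equal(g$degrees, rep(2L, 4))
  # brute-force check: exactly the pairs at distance <= 1.1
  d <- as.matrix(dist(coords))
  for (i in 1:4)
    expect_setequal(graph_neighbors(g, i), which(d[i, ] <= 1.1 & d[i, ] > 0))
})

test_that("knn with m = 1 on two points yields a single symmetric edge", {
  g <- spatial_graph(rbind(c(0, 0), c(3, 4)), "knn", knn_m = 1)
  expect_equal(g$degrees, c(1L, 1L))
  expect_equal(graph_neighbors(g, 1), 2L)
  expect_equal(graph_neighbors(g, 2), 1L)
})

test_that("collinear points fall back to knn with a warning", {
  coords <- cbind(1:5, 2 * (1:5))
  expect_warning(g <- spatial_graph(coords, "delaunay"), "collinear")
  expect_true(all(g$degrees >= 1))
})

test_that("isolated nodes in radius mode are attached to a nearest neighbor", {
  coords <- rbind(c(0, 0), c(0.1, 0), c(5, 5))
  g <- spatial_graph(coords, "radius", epsilon = 0.5)
  expect_true(all(g$degrees >= 1))
  expect_equal(graph_neighbors(g, 3), 2L)
})

test_that("walk of length zero is the identity; forced moves are taken", {
  coords <- rbind(c(0, 0), c(1, 0))
  g <- spatial_graph(coords, "knn", knn_m = 1)
  w0 <- sample_walks(g, coords, k = 0)
  expect_equal(w0$end, 1:2)
  expect_equal(w0$dist, c(0, 0))
  w1 <- sample_walks(g, coords, k = 1)
  expect_equal(w1$end, c(2L, 1L))
  expect_equal(w1$dist, c(1, 1))
})

test_that("two-step walks on a 4-cycle split mass evenly over start and antipode", {
  coords <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  g <- spatial_graph(coords, "radius", epsilon = 1.1)
  set.seed(1)
  ends <- replicate(2500, sample_walks(g, coords, k = 2)$end)
  # enumeration: both 2-step walks from i end at i or the opposite corner,
  # each with probability 1/2
  antipode <- c(3L, 4L, 1L, 2L)
  for (i in 1:4) {
    p_start <- mean(ends[i, ] == i)
    p_anti <- mean(ends[i, ] == antipode[i])
    expect_equal(p_start, 0.5, tolerance = 0.05)
    expect_equal(p_start + p_anti, 1)
  }
})

test_that("implicit transition matrix is row-stochastic and mixes to the degree law", {
  set.seed(7)
  coords <- cbind(runif(10), runif(10))
  g <- spatial_graph(coords, "knn", knn_m = 3)
  P <- transition_matrix(g)
  expect_equal(unname(rowSums(P)), rep(1, 10))
  stationary <- g$degrees / sum(g$degrees)
  Pk <- P
  for (i in 2:200) Pk <- Pk %*% P
  # odd+even mix to dodge near-bipartite parity
  mixed <- (Pk + Pk %*% P) / 2
  for (i in 1:10)
    expect_equal(unname(mixed[i, ]), unname(stationary), tolerance = 0.01)
})

test_that("walk endpoints never leave the start's connected component", {
  coords <- rbind(cbind(runif(6), runif(6)), cbind(10 + runif(6), runif(6)))
  g <- spatial_graph(coords, "radius", epsilon = 2)
  set.seed(2)
  for (rep in 1:20) {
    w <- sample_walks(g, coords, k = 15)
    expect_true(all((w$start <= 6) == (w$end <= 6)))
  }
})

test_that("duplicate coordinates are tolerated with zero-length edges", {
  coords <- rbind(c(0, 0), c(0, 0), c(1, 0), c(0.5, 1))
  g <- spatial_graph(coords, "delaunay")
  expect_true(all(g$degrees >= 1))
  expect_true(2L %in% graph_neighbors(g, 1) || 1L %in% graph_neighbors(g, 2))
})
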