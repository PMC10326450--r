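test_that("collinear points split at the sorted midpoint multiple of k", {
  coords <- cbind(1:8, rep(0, 8))
  counts <- matrix(1, 8, 2)
  set.seed(1)
  bl <- bin_cells(coords, counts, 4)
  expect_length(bl$discarded, 0)
  groups <- split(bl$kept, bl$assignment)
  expect_setequal(vapply(groups, paste, collapse = ",", ""), c("1,2,3,4", "5,6,7,8"))
})

test_that("n mod k cells are discarded and every bin has exactly k members", {
  set.seed(2)
  coords <- cbind(runif(17), runif(17))
  bl <- bin_cells(coords, matrix(1, 17, 3), 4)
  expect_length(bl$discarded, 1)
  expect_equal(unname(table(bl$assignment)), rep(4L, 4), ignore_attr = TRUE)
  expect_setequal(c(bl$kept[order(bl$kept)], bl$discarded), 1:17)
})

test_that("bins on a 4x4 grid are spatially contiguous blocks", {
  coords <- as.matrix(expand.grid(x = 1:4, y = 1:4))
  set.seed(3)
  bl <- bin_cells(coords, matrix(1, 16, 1), 4)
  boxes <- lapply(split(seq_len(16), bl$assignment), function(idx) {
    xy <- coords[bl$kept[idx], , drop = FALSE]
    c(range(xy[, 1]), range(xy[, 2]))
  })
  # bounding boxes at the leaf level are interior-disjoint
  for (i in seq_along(boxes)) for (j in seq_along(boxes)) {
    if (i >= j) next
    a <- boxes[[i]]; b <- boxes[[j]]
    overlap_x <- min(a[2], b[2]) - max(a[1], b[1])
    overlap_y <- min(a[4], b[4]) - max(a[3], b[3])
    expect_true(overlap_x < 0 || overlap_y < 0)
  }
})

test_that("binned counts conserve totals over kept cells", {
  set.seed(4)
  coords <- cbind(runif(50), runif(50))
  counts <- matrix(rpois(50 * 3, 4), 50, 3)
  bl <- bin_cells(coords, counts, 8)
  expect_equal(colSums(bl$bin_counts), colSums(counts[bl$kept, ]))
  expect_equal(nrow(bl$bin_counts), 6)
})

test_that("bin stack carries the prescribed level weights", {
  ds <- make_null_dataset(120, 2, seed = 5)
  set.seed(5)
  levels <- build_bin_stack(ds)
  expect_equal(vapply(levels, `[[`, 1, "weight"), c(1, 4, 8, 16))
  expect_equal(nrow(levels[[2]]$counts), 30)
  empty <- build_bin_stack(ds, bin_sizes = NULL)
  expect_length(empty, 1)
  expect_equal(empty[[1]]$weight, 1)
})

test_that("oversized bin sizes are skipped with a warning, k > n is an error", {
  ds <- make_null_dataset(10, 2, seed = 6)
  set.seed(6)
  expect_warning(levels <- build_bin_stack(ds, bin_sizes = c(4, 16)), "skipped")
  expect_equal(vapply(levels, `[[`, 1, "weight"), c(1, 4))
  expect_error(bin_cells(cbind(1:5, 1:5), matrix(1, 5, 1), 7), "exceeds")
})
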