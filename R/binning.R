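#' Exact-size spatial binning with a modified kd-tree
#'
#' Partitions cells into spatially compact bins of exactly `k` cells. A
#' random `n %% k` cells are first discarded so the rest divide evenly; the
#' remainder are split recursively along alternating axes, cutting each
#' block at the multiple of `k` nearest its median so both halves stay
#' divisible by `k`. Equal-occupancy bins avoid the spurious spatial signal
#' that unequal bins would introduce. Bin counts are member sums; bin
#' coordinates are member centroids.
#'
#' @param coords cells x 2 coordinate matrix.
#' @param counts cells x genes count matrix.
#' @param k bin size (2 <= k <= n).
#' @return A `bin_level` list: `bin_size`, `assignment` (per kept cell, in
#'   input order), `kept` (indices of kept cells), `discarded`, `bin_counts`
#'   (bins x genes), `bin_coords` (bins x 2).
#' @export
bin_cells <- function(coords, counts, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- as.integer(k)
  if (k > n) stop(sprintf("bin size %d exceeds cell count %d", k, n))
  if (k < 2) stop("bin size must be >= 2")
  discard_n <- n %% k
  discarded <- if (discard_n > 0) sort(sample.int(n, discard_n)) else integer(0)
  kept <- setdiff(seq_len(n), discarded)

  # first split axis: the axis of larger coordinate range
  rng <- apply(coords[kept, , drop = FALSE], 2, function(v) diff(range(v)))
  first_axis <- if (rng[2] > rng[1]) 2L else 1L

  assignment <- integer(length(kept))
  next_bin <- 0L
  recurse <- function(idx, axis) {
    m <- length(idx)
    if (m == k) {
      next_bin <<- next_bin + 1L
      assignment[match(idx, kept)] <<- next_bin
      return(invisible(NULL))
    }
    # stable order along the axis, ties broken by cell index
    ord <- idx[order(coords[idx, axis], idx)]
    n_bins <- m %/% k
    left_bins <- round(n_bins / 2)
    left_bins <- min(max(left_bins, 1L), n_bins - 1L)
    cut <- left_bins * k
    other <- if (axis == 1L) 2L else 1L
    recurse(ord[seq_len(cut)], other)
    recurse(ord[(cut + 1L):m], other)
  }
  recurse(kept, first_axis)

  counts_kept <- counts[kept, , drop = FALSE]
  bin_counts <- rowsum(as.matrix(counts_kept), assignment)
  bin_coords <- rowsum(coords[kept, , drop = FALSE], assignment) / k
  structure(list(bin_size = k, assignment = assignment, kept = kept,
                 discarded = discarded, bin_counts = bin_counts,
                 bin_coords = bin_coords),
            class = "bin_level")
}

#' Assemble the multi-resolution training stack
#'
#' The training objective sums over the unbinned data (weight 1) plus one
#' binned level per entry of `bin_sizes`, each weighted by its bin size so
#' bins count in proportion to the cells they aggregate. Each level gets its
#' own spatial graph on the bin centroids. Bin sizes exceeding the number of
#' cells are skipped with a warning.
#'
#' @param dataset a [spatial_dataset()] (or count matrix with a `coords`
#'   attribute supplied separately).
#' @param bin_sizes ascending integer bin sizes; `NULL` or empty disables
#'   binning.
#' @param graph_method,graph_params how to build each level's graph; see
#'   [spatial_graph()].
#' @return List of levels; each has `counts`, `coords`, `graph`, `weight`,
#'   and for binned levels the underlying `bin_level`.
#' @export
build_bin_stack <- function(dataset, bin_sizes = c(4L, 8L, 16L),
                            graph_method = "delaunay", graph_params = list()) {
  counts <- dataset$counts
  coords <- dataset$coords
  n <- nrow(coords)
  make_graph <- function(xy) {
    # levels with very few bins cannot be triangulated; fall back to knn
    method <- if (nrow(xy) < 4 && graph_method == "delaunay") "knn" else graph_method
    do.call(spatial_graph, c(list(coords = xy, method = method), graph_params))
  }
  levels <- list(list(counts = counts, coords = coords,
                      graph = make_graph(coords), weight = 1, bin = NULL))
  for (k in bin_sizes) {
    if (k > n) {
      warning(sprintf("bin size %d exceeds n = %d cells; skipped", k, n))
      next
    }
    bl <- bin_cells(coords, counts, k)
    if (nrow(bl$bin_coords) < 2) {
      warning(sprintf("bin size %d leaves fewer than 2 bins; skipped", k))
      next
    }
    levels[[length(levels) + 1L]] <-
      list(counts = bl$bin_counts, coords = bl$bin_coords,
           graph = make_graph(bl$bin_coords), weight = as.numeric(k), bin = bl)
  }
  levels
}
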