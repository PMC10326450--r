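#' Build a spatial neighborhood graph
#'
#' Constructs the symmetric neighbor graph over cells that defines the
#' random-walk neighborhood distribution. From this graph, walks step to a
#' uniformly chosen neighbor, so the implicit transition probability from a
#' cell to each of its neighbors is 1/degree.
#'
#' Methods: `"delaunay"` (default for scattered cells; edges longer than the
#' `prune_quantile` quantile of edge lengths are pruned, since long
#' hull-spanning edges distort neighborhoods), `"knn"` (union-symmetrized
#' m-nearest-neighbor graph), `"radius"` (all pairs within `epsilon`), and
#' `"grid"` for array-based data, which links each cell to the cells one
#' lattice pitch away (4 neighbors on a square array, 6 on a hexagonal
#' Visium-style array).
#'
#' Isolated nodes (possible in radius mode or after pruning) are connected to
#' their single nearest neighbor so that walks are defined for every cell.
#' If the points are all collinear, Delaunay triangulation is undefined and
#' the builder falls back to the knn method with a warning.
#'
#' @param coords numeric matrix of cell coordinates (cells x 2).
#' @param method one of `"delaunay"`, `"knn"`, `"radius"`, `"grid"`.
#' @param epsilon neighborhood radius for `"radius"` mode (> 0).
#' @param knn_m number of nearest neighbors for `"knn"` mode.
#' @param grid `"square"` or `"hex"`; only used to sanity-check degrees in
#'   `"grid"` mode, which links cells within 1.05 lattice pitches.
#' @param prune_quantile quantile of Delaunay edge lengths above which edges
#'   are removed (set to 1 to disable pruning).
#' @return An object of class `spatial_graph`: adjacency in compressed form
#'   (`adj`, 1-based concatenated neighbor lists; `ptr`, offsets of length
#'   n+1), `degrees`, `n_cells`, `method`.
#' @export
spatial_graph <- function(coords, method = c("delaunay", "knn", "radius", "grid"),
                          epsilon = NULL, knn_m = 6L, grid = c("square", "hex"),
                          prune_quantile = 0.99) {
  method <- match.arg(method)
  grid <- match.arg(grid)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 1) stop("need at least one cell")

  edges <- switch(method,
    delaunay = {
      if (n < 3) stop("delaunay requires >= 3 cells")
      if (collinear_points(coords)) {
        warning("all points are collinear; falling back to knn graph")
        knn_edges(coords, min(knn_m, n - 1L))
      } else {
        delaunay_edges(coords, prune_quantile)
      }
    },
    knn = {
      if (knn_m < 1) stop("knn_m must be >= 1")
      knn_edges(coords, min(knn_m, n - 1L))
    },
    radius = {
      if (is.null(epsilon) || epsilon <= 0) stop("radius mode requires epsilon > 0")
      radius_edges(coords, epsilon)
    },
    grid = {
      pitch <- min_nonzero_dist(coords)
      radius_edges(coords, pitch * 1.05)
    })

  edges <- repair_isolated(edges, coords)
  adj_from_edges(edges, n, method)
}

collinear_points <- function(coords) {
  if (nrow(coords) < 3) return(TRUE)
  p0 <- coords[1, ]
  d <- sweep(coords[-1, , drop = FALSE], 2, p0)
  # reference displacement: the first nonzero one (guards duplicate points)
  ref <- which(rowSums(d^2) > 0)[1]
  if (is.na(ref)) return(TRUE)
  cross <- d[ref, 1] * d[, 2] - d[ref, 2] * d[, 1]
  scale <- max(abs(d)) ^ 2
  all(abs(cross) <= 1e-10 * max(scale, 1))
}

delaunay_edges <- function(coords, prune_quantile) {
  # deldir collapses exactly duplicated points; build on unique points and
  # attach each duplicate to its representative by a zero-length edge
  key <- paste(coords[, 1], coords[, 2], sep = "_")
  rep_idx <- match(key, key)
  uniq <- which(rep_idx == seq_along(rep_idx))
  dd <- deldir::deldir(coords[uniq, 1], coords[uniq, 2], suppressMsge = TRUE)
  e <- cbind(uniq[dd$delsgs$ind1], uniq[dd$delsgs$ind2])
  len <- sqrt(rowSums((coords[e[, 1], , drop = FALSE] -
                         coords[e[, 2], , drop = FALSE])^2))
  if (prune_quantile < 1) {
    # prune long hull-spanning edges; the median guard keeps the rule inert
    # on tiny or near-regular triangulations
    thr <- max(stats::quantile(len, prune_quantile, names = FALSE),
               1.5 * stats::median(len))
    e <- e[len <= thr, , drop = FALSE]
  }
  dup <- which(rep_idx != seq_along(rep_idx))
  if (length(dup)) e <- rbind(e, cbind(dup, rep_idx[dup]))
  e
}

knn_edges <- function(coords, m) {
  n <- nrow(coords)
  nn <- RANN::nn2(coords, k = min(m + 1L, n))$nn.idx
  # drop self-matches (first column under distinct points, but handle dupes)
  e <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- setdiff(nn[i, ], i)
    nb <- nb[seq_len(min(length(nb), m))]
    cbind(i, nb)
  }))
  e
}

radius_edges <- function(coords, eps) {
  n <- nrow(coords)
  # chunked pairwise distances to bound memory
  out <- vector("list", 0L)
  chunk <- max(1L, floor(2e7 / n))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    d2 <- outer(coords[idx, 1], coords[, 1], "-")^2 +
      outer(coords[idx, 2], coords[, 2], "-")^2
    hit <- which(d2 <= eps^2, arr.ind = TRUE)
    hit <- hit[idx[hit[, 1]] != hit[, 2], , drop = FALSE]
    if (nrow(hit)) out[[length(out) + 1L]] <- cbind(idx[hit[, 1]], hit[, 2])
  }
  if (!length(out)) return(matrix(integer(), 0, 2))
  do.call(rbind, out)
}

min_nonzero_dist <- function(coords) {
  nn <- RANN::nn2(coords, k = min(7L, nrow(coords)))$nn.dists
  pos <- nn[nn > 1e-12]
  if (!length(pos)) stop("all coordinates are identical")
  min(pos)
}

repair_isolated <- function(edges, coords) {
  n <- nrow(coords)
  present <- unique(c(edges[, 1], edges[, 2]))
  iso <- setdiff(seq_len(n), present)
  if (!length(iso)) return(edges)
  nn <- RANN::nn2(coords, coords[iso, , drop = FALSE], k = min(2L, n))$nn.idx
  mate <- vapply(seq_along(iso), function(i) {
    cand <- setdiff(nn[i, ], iso[i])
    if (length(cand)) cand[1] else if (iso[i] == 1L) 2L else 1L
  }, integer(1))
  rbind(edges, cbind(iso, mate))
}

adj_from_edges <- function(edges, n, method) {
  # symmetrize, drop self loops and duplicates
  e <- rbind(edges, edges[, 2:1, drop = FALSE])
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  e <- unique(e)
  if (n == 1L) {
    # a single cell has itself as the only (lazy) neighbor
    return(structure(list(n_cells = 1L, adj = 1L, ptr = c(1L, 2L),
                          degrees = 1L, method = method),
                     class = "spatial_graph"))
  }
  ord <- order(e[, 1], e[, 2])
  e <- e[ord, , drop = FALSE]
  deg <- tabulate(e[, 1], nbins = n)
  ptr <- c(1L, cumsum(deg) + 1L)
  structure(list(n_cells = n, adj = as.integer(e[, 2]), ptr = as.integer(ptr),
                 degrees = as.integer(deg), method = method),
            class = "spatial_graph")
}

#' @export
#' @method print spatial_graph
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph (%s): %d cells, %d edges, mean degree %.2f\n",
              x$method, x$n_cells, length(x$adj) / 2, mean(x$degrees)))
  invisible(x)
}

#' List the neighbors of a cell
#' @param graph a `spatial_graph`.
#' @param i cell index.
#' @return Integer vector of neighbor indices.
#' @export
graph_neighbors <- function(graph, i) {
  graph$adj[seq.int(graph$ptr[i], length.out = graph$degrees[i])]
}

#' Sample k-step random walks from every cell
#'
#' Draws one non-lazy uniform-neighbor random walk of length `k` from each
#' cell and returns start indices, endpoint indices, and the Euclidean
#' distance between each walk's start and end coordinates. The endpoint
#' distribution over many draws realizes the neighborhood distribution used
#' by the spatial information score.
#'
#' @param graph a `spatial_graph`.
#' @param coords the coordinates the graph was built on.
#' @param k walk length (>= 0; `k = 0` returns each cell itself).
#' @return A list with `start`, `end` (integer vectors) and `dist`.
#' @export
sample_walks <- function(graph, coords, k = 10L) {
  if (k < 0) stop("k must be >= 0")
  n <- graph$n_cells
  cur <- seq_len(n)
  if (k > 0) {
    for (s in seq_len(k)) {
      deg <- graph$degrees[cur]
      pick <- graph$ptr[cur] + pmin(floor(stats::runif(n) * deg), deg - 1)
      cur <- graph$adj[pick]
    }
  }
  d <- sqrt(rowSums((coords[seq_len(n), , drop = FALSE] -
                       coords[cur, , drop = FALSE])^2))
  list(start = seq_len(n), end = cur, dist = d)
}

#' Dense transition matrix of the uniform-neighbor walk
#'
#' Mostly a diagnostic/testing aid: the row-stochastic matrix whose entry
#' (i, j) is 1/degree(i) for each neighbor j of i.
#'
#' @param graph a `spatial_graph`.
#' @return n x n matrix with rows summing to 1.
#' @export
transition_matrix <- function(graph) {
  n <- graph$n_cells
  P <- matrix(0, n, n)
  for (i in seq_len(n))
    P[i, graph_neighbors(graph, i)] <- 1 / graph$degrees[i]
  P
}
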