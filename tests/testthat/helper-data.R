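# Small in-code fixtures shared across tests.

# iid negative-binomial counts at uniform random positions: spatially null.
make_null_dataset <- function(n_cells, n_genes, mu = 5, size = 4, seed = 1) {
  set.seed(seed)
  coords <- cbind(x = runif(n_cells), y = runif(n_cells))
  counts <- matrix(rnbinom(n_cells * n_genes, mu = mu, size = size),
                   n_cells, n_genes)
  colnames(counts) <- paste0("g", seq_len(n_genes))
  spatial_dataset(counts, coords)
}

# binary left/right gene on an m x m integer grid
make_half_grid <- function(m = 20) {
  gr <- expand.grid(x = seq_len(m), y = seq_len(m))
  coords <- as.matrix(gr)
  x <- as.numeric(gr$x <= m / 2)
  list(coords = coords, x = x,
       dataset = spatial_dataset(matrix(x, ncol = 1,
                                        dimnames = list(NULL, "half")),
                                 coords))
}

# dense 4 x 4 grid graph with rook adjacency (via the grid method)
make_grid_graph <- function(m = 4) {
  coords <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(m)))
  list(coords = coords, graph = spatial_graph(coords, "grid"))
}

# two tight cliques far apart, fully connected within each
make_two_cliques <- function(k = 3) {
  coords <- rbind(cbind(runif(k, 0, 0.1), runif(k, 0, 0.1)),
                  cbind(runif(k, 10, 10.1), runif(k, 10, 10.1)))
  list(coords = coords, graph = spatial_graph(coords, "radius", epsilon = 0.5),
       membership = rep(c(0, 1), each = k))
}
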