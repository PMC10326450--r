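#' Configure the cellular Potts spatial simulator
#'
#' Parameters of the lattice simulation used to generate labeled benchmark
#' data. Cells occupy sets of lattice sites, adhere according to a random
#' symmetric cell-type affinity matrix (entries uniform on
#' `adhesion_range`), are held near `target_area` by a quadratic penalty,
#' and migrate via an actin-inspired protrusion term (per-site activity
#' memory decaying from `max_act`, with energy bonus
#' `lambda_act * dGM / max_act` for copies from high- into low-activity
#' sites). Initial positions sit on a jittered grid with cell type assigned
#' by discretizing `sin(2 pi x p_x / L) + sin(2 pi y p_y / L)` into
#' equal-probability bands, producing ordered same-type blobs that grow
#' more disordered as `iterations` (Monte-Carlo sweeps of `L^2` copy
#' attempts) increases.
#'
#' @param n_cells number of cells.
#' @param n_types number of discrete cell types.
#' @param target_area target sites per cell.
#' @param lattice_size lattice side length `L`; default sized so cells fill
#'   about 60 percent of the lattice.
#' @param adhesion_range `(J_min, J_max)` for the random affinity matrix.
#' @param adhesion_medium cell-medium contact energy.
#' @param lambda_area area-constraint strength.
#' @param lambda_act,max_act protrusion strength and activity memory.
#' @param temperature Metropolis temperature.
#' @param iterations Monte-Carlo sweeps after the growth phase.
#' @param sine_periods per-axis periods of the type-assignment sine field.
#' @param seed RNG seed for positions, affinities and dynamics.
#' @return A `potts_config` list.
#' @export
potts_config <- function(n_cells = 2000L, n_types = 4L, target_area = 8L,
                         lattice_size = NULL, adhesion_range = c(2, 8),
                         adhesion_medium = 8, lambda_area = 3,
                         lambda_act = 10, max_act = 10, temperature = 1,
                         iterations = 100L, sine_periods = c(1.5, 1.5),
                         seed = 1L) {
  if (is.null(lattice_size))
    lattice_size <- ceiling(sqrt(n_cells * target_area / 0.6))
  stopifnot(n_cells * target_area <= lattice_size^2, iterations >= 0,
            n_types >= 2, target_area >= 1)
  structure(list(n_cells = as.integer(n_cells), n_types = as.integer(n_types),
                 target_area = as.integer(target_area),
                 lattice_size = as.integer(lattice_size),
                 adhesion_range = adhesion_range,
                 adhesion_medium = adhesion_medium, lambda_area = lambda_area,
                 lambda_act = lambda_act, max_act = max_act,
                 temperature = temperature, iterations = as.integer(iterations),
                 sine_periods = sine_periods, seed = as.integer(seed)),
            class = "potts_config")
}

#' Configure the negative-binomial expression simulator
#'
#' Per-gene baseline means are drawn log-normal(0, `baseline_logmean_sd`)
#' and scaled so the median per-cell library is `target_median_library`
#' counts (a sparse regime typical of imaging-based platforms). A random
#' subset of `n_svg` genes is spatially varying: their mean is perturbed
#' per cell type by a multiplicative factor `exp(N(0, effect_size^2))`.
#' Counts are negative binomial with dispersion `nb_dispersion` (variance
#' `mu + mu^2 / r`).
#'
#' @param n_genes,n_svg gene counts (`n_svg <= n_genes`).
#' @param nb_dispersion NB size parameter `r`.
#' @param effect_size standard deviation of per-type log-fold perturbations.
#' @param baseline_logmean_sd sd of baseline log-means.
#' @param target_median_library median counts per cell after scaling.
#' @param seed RNG seed for gene-level draws.
#' @return An `expr_config` list.
#' @export
expr_config <- function(n_genes = 8000L, n_svg = 1000L, nb_dispersion = 4,
                        effect_size = 0.5, baseline_logmean_sd = 1,
                        target_median_library = 200, seed = 1L) {
  stopifnot(n_svg <= n_genes, nb_dispersion > 0, effect_size >= 0)
  structure(list(n_genes = as.integer(n_genes), n_svg = as.integer(n_svg),
                 nb_dispersion = nb_dispersion, effect_size = effect_size,
                 baseline_logmean_sd = baseline_logmean_sd,
                 target_median_library = target_median_library,
                 seed = as.integer(seed)),
            class = "expr_config")
}

#' Simulate spatial expression data with a cellular Potts model
#'
#' Runs the lattice simulation of [potts_config()], takes cell centroids as
#' spatial coordinates and cell types as labels, and draws expression from
#' [expr_config()]. Ground truth is the `is_svg` label vector.
#'
#' @param potts a [potts_config()].
#' @param expr an [expr_config()].
#' @return A `sim_truth` list: `dataset` (a [spatial_dataset()] with cell
#'   types in `cell_labels`), `is_svg`, `params` (both configs plus the
#'   realized affinity matrix), `energy` (per-sweep total energy), `areas`,
#'   `initial_types` and the final `lattice` snapshot.
#' @export
simulate_potts <- function(potts = potts_config(), expr = expr_config()) {
  set.seed(potts$seed)
  L <- potts$lattice_size
  n <- potts$n_cells

  # jittered-grid seeding on unique lattice sites
  g <- ceiling(sqrt(n))
  spacing <- L / g
  pos <- expand.grid(gx = seq_len(g), gy = seq_len(g))[seq_len(n), ]
  jit <- spacing / 3
  px <- pmin(pmax(round((pos$gx - 0.5) * spacing + stats::runif(n, -jit, jit)), 1), L)
  py <- pmin(pmax(round((pos$gy - 0.5) * spacing + stats::runif(n, -jit, jit)), 1), L)
  site <- px + L * (py - 1)
  # resolve collisions deterministically: nudge to the next free site
  occ <- logical(L * L)
  for (i in seq_len(n)) {
    s <- site[i]
    while (occ[s]) s <- if (s < L * L) s + 1L else 1L
    occ[s] <- TRUE
    site[i] <- s
  }
  px <- (site - 1) %% L + 1
  py <- (site - 1) %/% L + 1

  # cell type from equal-probability bands of a sine field
  tfield <- sin(2 * pi * px * potts$sine_periods[1] / L) +
    sin(2 * pi * py * potts$sine_periods[2] / L)
  qs <- stats::quantile(tfield, probs = seq(0, 1, length.out = potts$n_types + 1))
  qs[1] <- -Inf
  qs[length(qs)] <- Inf
  types <- as.integer(cut(tfield, breaks = qs, labels = FALSE,
                          include.lowest = TRUE))

  # random symmetric affinity matrix
  Tn <- potts$n_types
  J <- matrix(0, Tn, Tn)
  J[upper.tri(J, diag = TRUE)] <- stats::runif(Tn * (Tn + 1) / 2,
                                               potts$adhesion_range[1],
                                               potts$adhesion_range[2])
  J <- J + t(J) - diag(diag(J))

  spin0 <- matrix(0L, L, L)
  spin0[cbind(px, py)] <- seq_len(n)
  run <- .potts_run_cpp(spin0, types, J, potts$adhesion_medium,
                        potts$lambda_area, potts$target_area,
                        potts$lambda_act, potts$max_act, potts$temperature,
                        potts$iterations, grow_rounds = 4L * potts$target_area)

  # centroids of final cell bodies
  idx <- which(run$spin > 0)
  cid <- run$spin[idx]
  sx <- (idx - 1) %% L + 1
  sy <- (idx - 1) %/% L + 1
  cx <- rowsum(as.numeric(sx), cid)[, 1] / tabulate(cid, n)
  cy <- rowsum(as.numeric(sy), cid)[, 1] / tabulate(cid, n)
  coords <- cbind(x = cx, y = cy)

  ex <- draw_nb_expression(types, expr)
  dataset <- spatial_dataset(ex$counts, coords,
                             cell_labels = paste0("type", types))
  structure(list(dataset = dataset, is_svg = ex$is_svg,
                 params = list(potts = unclass(potts), expr = unclass(expr),
                               J = J, generator = "potts"),
                 energy = run$energy, areas = run$areas,
                 initial_types = types, lattice = run$spin),
            class = "sim_truth")
}

# NB expression with per-type multiplicative perturbations for SVG genes.
draw_nb_expression <- function(types, expr) {
  set.seed(expr$seed)
  G <- expr$n_genes
  Tn <- max(types)
  mu <- stats::rlnorm(G, 0, expr$baseline_logmean_sd)
  is_svg <- logical(G)
  is_svg[sample.int(G, expr$n_svg)] <- TRUE
  eff <- matrix(1, Tn, G)
  if (expr$n_svg > 0 && expr$effect_size > 0)
    eff[, is_svg] <- exp(matrix(stats::rnorm(Tn * expr$n_svg, 0, expr$effect_size),
                                Tn))
  # scale so the median expected library is target_median_library
  lib_by_type <- as.numeric(eff %*% mu)
  scale <- expr$target_median_library / stats::median(lib_by_type[types])
  mu <- mu * scale
  n <- length(types)
  counts <- matrix(0L, n, G)
  block <- 1000L
  for (s in seq(1L, G, by = block)) {
    j <- s:min(G, s + block - 1L)
    m <- t(eff[types, j, drop = FALSE]) * mu[j] # genes x cells block
    counts[, j] <- t(matrix(stats::rnbinom(length(m), mu = m,
                                           size = expr$nb_dispersion),
                            nrow = length(j)))
  }
  colnames(counts) <- paste0("gene", seq_len(G))
  list(counts = counts, is_svg = is_svg)
}

#' Simulate streak / hotspot benchmark data
#'
#' Cells are uniform on the unit square; spatially varying genes have their
#' negative-binomial mean multiplied by `fold_change` inside a region
#' covering `region_fraction` of the area -- a vertical band centered at
#' x = 0.5 (`"streak"`) or a central disk (`"hotspot"`).
#'
#' @param n_cells number of cells.
#' @param pattern `"streak"` or `"hotspot"`.
#' @param region_fraction fraction of unit-square area in the region.
#' @param fold_change multiplicative effect inside the region (1 = null).
#' @param nb_mean,nb_dispersion baseline NB mean scale and dispersion;
#'   per-gene means vary log-normally around `nb_mean`.
#' @param n_genes,n_svg gene counts.
#' @param seed RNG seed.
#' @return A `sim_truth` list with `dataset`, `is_svg`, `in_region` and
#'   `params`.
#' @export
simulate_pattern <- function(n_cells = 5000L, pattern = c("streak", "hotspot"),
                             region_fraction = 0.2, fold_change = 3,
                             nb_mean = 2, nb_dispersion = 4,
                             n_genes = 1000L, n_svg = 100L, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(region_fraction > 0, region_fraction < 1, fold_change > 0,
            n_svg <= n_genes)
  set.seed(seed)
  coords <- cbind(x = stats::runif(n_cells), y = stats::runif(n_cells))
  inside <- if (pattern == "streak") {
    abs(coords[, "x"] - 0.5) <= region_fraction / 2
  } else {
    radius <- sqrt(region_fraction / pi)
    (coords[, "x"] - 0.5)^2 + (coords[, "y"] - 0.5)^2 <= radius^2
  }
  mu <- nb_mean * stats::rlnorm(n_genes, 0, 0.5)
  is_svg <- logical(n_genes)
  is_svg[sample.int(n_genes, n_svg)] <- TRUE
  m <- matrix(mu, n_cells, n_genes, byrow = TRUE)
  m[inside, is_svg] <- m[inside, is_svg] * fold_change
  counts <- matrix(stats::rnbinom(length(m), mu = m, size = nb_dispersion),
                   n_cells, n_genes)
  colnames(counts) <- paste0("gene", seq_len(n_genes))
  dataset <- spatial_dataset(counts, coords,
                             cell_labels = ifelse(inside, "region", "background"))
  structure(list(dataset = dataset, is_svg = is_svg, in_region = inside,
                 params = list(n_cells = n_cells, pattern = pattern,
                               region_fraction = region_fraction,
                               fold_change = fold_change, nb_mean = nb_mean,
                               nb_dispersion = nb_dispersion,
                               n_genes = n_genes, n_svg = n_svg, seed = seed,
                               generator = "pattern")),
            class = "sim_truth")
}

#' Type homophily of a cell arrangement
#'
#' Fraction of Delaunay-adjacent cell pairs sharing a type; a simple
#' measure of how spatially ordered the type arrangement is.
#'
#' @param coords cells x 2 coordinates.
#' @param types per-cell type labels.
#' @return Scalar in `[0, 1]`.
#' @export
type_homophily <- function(coords, types) {
  g <- spatial_graph(coords, "delaunay")
  i_idx <- rep.int(seq_len(g$n_cells), g$degrees)
  mean(types[i_idx] == types[g$adj])
}

#' Write a simulation to disk
#'
#' Writes `<prefix>_data.csv` (cell_id, x, y, one column per gene),
#' `<prefix>_truth.csv` (gene_id, is_svg) and `<prefix>_params.json`. The
#' parameter file is sufficient to regenerate the identical simulation via
#' [replay_sim()].
#'
#' @param sim a `sim_truth` from [simulate_potts()] or [simulate_pattern()].
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_truth"))
  ds <- sim$dataset
  tab <- data.frame(cell_id = ds$cell_ids, x = ds$coords[, 1],
                    y = ds$coords[, 2], as.data.frame(as.matrix(ds$counts)),
                    check.names = FALSE)
  data_path <- paste0(prefix, "_data.csv")
  utils::write.csv(tab, data_path, row.names = FALSE)
  truth_path <- paste0(prefix, "_truth.csv")
  utils::write.csv(data.frame(gene_id = ds$gene_ids, is_svg = sim$is_svg),
                   truth_path, row.names = FALSE)
  params_path <- paste0(prefix, "_params.json")
  jsonlite::write_json(sim$params, params_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data_path, truth_path, params_path))
}

#' Re-run a simulation from its parameter file
#'
#' @param params_path path to a `_params.json` written by [write_sim()].
#' @return A `sim_truth`, identical to the original for the same seed.
#' @export
replay_sim <- function(params_path) {
  p <- jsonlite::read_json(params_path, simplifyVector = TRUE)
  if (identical(p$generator, "potts")) {
    pc <- do.call(potts_config, p$potts[setdiff(names(p$potts), character(0))])
    ec <- do.call(expr_config, p$expr)
    simulate_potts(pc, ec)
  } else {
    do.call(simulate_pattern, p[setdiff(names(p), "generator")])
  }
}
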