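#' Construct a spatial expression dataset
#'
#' Bundles a cells-by-genes expression matrix with 2-D spatial coordinates and
#' optional per-cell/per-gene annotations. This is the universal input to
#' [spatinfo()], [pairwise_info()] and the baseline statistics.
#'
#' @param counts numeric matrix or `Matrix` sparse matrix, cells in rows,
#'   genes in columns; non-negative (integer counts unless a Gaussian
#'   posterior is supplied).
#' @param coords numeric matrix or data frame with two columns (x, y), one
#'   row per cell, in arbitrary Euclidean units. No rescaling is applied:
#'   the classifier's learned decay length absorbs the coordinate scale.
#' @param gene_ids,cell_ids optional character identifiers; defaults are
#'   taken from dimnames or generated.
#' @param posterior_mean,posterior_sd optional cells-by-genes matrices of
#'   posterior means and standard deviations for Gaussian-mode scoring;
#'   `posterior_sd` must be strictly positive.
#' @param cell_labels optional character vector of per-cell labels (cell
#'   type or region).
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(counts, coords, gene_ids = NULL, cell_ids = NULL,
                            posterior_mean = NULL, posterior_sd = NULL,
                            cell_labels = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L)
    stop("coords must have exactly 2 columns (x, y)")
  if (nrow(counts) != nrow(coords))
    stop(sprintf("cell count mismatch: counts has %d rows but coords has %d",
                 nrow(counts), nrow(coords)))
  if (any(!is.finite(coords)))
    stop(sprintf("non-finite coordinate at row %d",
                 which(rowSums(!is.finite(coords)) > 0)[1]))
  if (min_value(counts) < 0) stop("counts must be non-negative")
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  if (is.null(cell_ids)) cell_ids <- rownames(counts)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (length(gene_ids) != ncol(counts))
    stop("length(gene_ids) must equal ncol(counts)")
  if (length(cell_ids) != nrow(counts))
    stop("length(cell_ids) must equal nrow(counts)")
  if (!is.null(posterior_sd)) {
    if (is.null(posterior_mean)) stop("posterior_mean required with posterior_sd")
    if (!all(dim(posterior_mean) == dim(counts)) ||
        !all(dim(posterior_sd) == dim(counts)))
      stop("posterior matrices must be shape-matched to counts")
    if (min_value(posterior_sd) <= 0) stop("posterior_sd must be > 0 everywhere")
  }
  if (!is.null(cell_labels) && length(cell_labels) != nrow(counts))
    stop("cell_labels must have one entry per cell")
  zero <- col_sums(counts) == 0
  structure(list(counts = counts, coords = coords, gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids),
                 posterior_mean = posterior_mean, posterior_sd = posterior_sd,
                 cell_labels = cell_labels, all_zero = zero),
            class = "spatial_dataset")
}

# column sums / minimum that work for both base and Matrix matrices
col_sums <- function(m) if (inherits(m, "Matrix")) Matrix::colSums(m) else colSums(m)
row_sums <- function(m) if (inherits(m, "Matrix")) Matrix::rowSums(m) else rowSums(m)
min_value <- function(m) if (inherits(m, "Matrix")) min(m@x, 0) else min(m)

#' @export
#' @method print spatial_dataset
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  coordinate ranges: x [%.4g, %.4g], y [%.4g, %.4g]\n",
              min(x$coords[, 1]), max(x$coords[, 1]),
              min(x$coords[, 2]), max(x$coords[, 2])))
  if (any(x$all_zero))
    cat(sprintf("  %d gene(s) with all-zero counts (retained, flagged)\n",
                sum(x$all_zero)))
  if (!is.null(x$posterior_sd)) cat("  Gaussian posterior matrices attached\n")
  if (!is.null(x$cell_labels))
    cat(sprintf("  cell labels: %d distinct\n", length(unique(x$cell_labels))))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

#' Read a spatial expression dataset from disk
#'
#' Supports three layouts: `"table"`, a single delimited file holding
#' coordinate columns plus one column per gene; `"mtx"`, a MatrixMarket
#' sparse matrix with `features`/`barcodes` sidecar files and a separate
#' coordinate table; and `"gaussian"`, two delimited matrices of posterior
#' means and standard deviations plus a coordinate table.
#'
#' @param path main file: the dense table (`table` mode), the `.mtx` file
#'   (`mtx` mode), or the posterior-mean table (`gaussian` mode).
#' @param mode one of `"table"`, `"mtx"`, `"gaussian"`.
#' @param coords_path coordinate CSV with columns `cell_id,x,y` (modes `mtx`
#'   and `gaussian`).
#' @param features_path,barcodes_path sidecar files for `mtx` mode, one id
#'   per line (first column used).
#' @param sd_path posterior-sd table for `gaussian` mode.
#' @param coord_cols names (or indices) of the coordinate columns in `table`
#'   mode.
#' @param transpose set `TRUE` when the MTX file is genes-by-cells.
#' @param sep field separator for delimited files; guessed from the file
#'   extension by default.
#' @return A [spatial_dataset()].
#' @export
read_spatial_dataset <- function(path, mode = c("table", "mtx", "gaussian"),
                                 coords_path = NULL, features_path = NULL,
                                 barcodes_path = NULL, sd_path = NULL,
                                 coord_cols = c("x", "y"), transpose = FALSE,
                                 sep = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  guess_sep <- function(p) if (grepl("\\.tsv$|\\.txt$", p)) "\t" else ","
  if (mode == "table") {
    tab <- utils::read.table(path, header = TRUE,
                             sep = if (is.null(sep)) guess_sep(path) else sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    ci <- if (is.character(coord_cols)) match(coord_cols, names(tab)) else coord_cols
    if (any(is.na(ci))) stop("coordinate columns not found: ",
                             paste(coord_cols, collapse = ", "))
    coords <- as.matrix(tab[, ci, drop = FALSE])
    if (!is.numeric(coords)) {
      bad <- which(!vapply(tab[, ci, drop = FALSE], is.numeric, TRUE))
      badrow <- which(is.na(suppressWarnings(as.numeric(tab[[ci[bad[1]]]]))))[1]
      stop(sprintf("non-numeric coordinate in row %d", badrow))
    }
    id_col <- match("cell_id", names(tab))
    keep <- setdiff(seq_along(tab), c(ci, id_col))
    counts <- as.matrix(tab[, keep, drop = FALSE])
    cell_ids <- if (!is.na(id_col)) as.character(tab[[id_col]]) else NULL
    return(spatial_dataset(counts, coords, cell_ids = cell_ids))
  }
  coords_tab <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  coords <- as.matrix(coords_tab[, c("x", "y")])
  if (mode == "mtx") {
    m <- Matrix::readMM(path)
    if (transpose) m <- Matrix::t(m)
    feats <- utils::read.table(features_path, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    bcs <- utils::read.table(barcodes_path, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != nrow(coords))
      stop(sprintf("cell count mismatch: matrix has %d cells but coordinates have %d",
                   nrow(m), nrow(coords)))
    return(spatial_dataset(m, coords, gene_ids = feats, cell_ids = bcs))
  }
  # gaussian
  if (is.null(sd_path)) stop("gaussian mode requires sd_path")
  pm <- as.matrix(utils::read.table(path, header = TRUE,
                                    sep = if (is.null(sep)) guess_sep(path) else sep,
                                    check.names = FALSE))
  ps <- as.matrix(utils::read.table(sd_path, header = TRUE,
                                    sep = if (is.null(sep)) guess_sep(sd_path) else sep,
                                    check.names = FALSE))
  spatial_dataset(counts = pmax(pm, 0), coords = coords,
                  cell_ids = as.character(coords_tab$cell_id),
                  posterior_mean = pm, posterior_sd = ps)
}

#' Write gene-level results and optional per-cell saliency tables
#'
#' Writes `<prefix>_genes.csv` with columns gene_id, raw_score,
#' normalized_score, accuracy, p_value, q_value, sorted by normalized score
#' descending, and (optionally) `<prefix>_saliency.csv` in long format
#' (cell_id, gene_id, saliency) for the selected genes.
#'
#' @param fit a `spatinfo` fit object.
#' @param prefix output path prefix.
#' @param saliency_genes character vector of gene ids whose per-cell
#'   saliency should be written; `NULL` writes none.
#' @return Invisibly, the paths written.
#' @export
write_spatinfo_results <- function(fit, prefix, saliency_genes = NULL) {
  stopifnot(inherits(fit, "spatinfo"))
  sc <- fit$scores
  if (nrow(sc) == 0) stop("no results to write")
  sc <- sc[order(-sc$normalized_score), , drop = FALSE]
  gene_path <- paste0(prefix, "_genes.csv")
  utils::write.csv(sc[, c("gene_id", "raw_score", "normalized_score",
                          "accuracy", "p_value", "q_value")],
                   gene_path, row.names = FALSE)
  paths <- gene_path
  if (!is.null(saliency_genes) && length(saliency_genes)) {
    idx <- match(saliency_genes, colnames(fit$saliency))
    if (any(is.na(idx))) stop("unknown gene id: ",
                              paste(saliency_genes[is.na(idx)], collapse = ", "))
    long <- do.call(rbind, lapply(idx, function(j) {
      data.frame(cell_id = fit$cell_ids, gene_id = colnames(fit$saliency)[j],
                 saliency = fit$saliency[, j], stringsAsFactors = FALSE)
    }))
    sal_path <- paste0(prefix, "_saliency.csv")
    utils::write.csv(long, sal_path, row.names = FALSE)
    paths <- c(paths, sal_path)
  }
  invisible(paths)
}
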