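#' Spatial information between gene pairs
#'
#' Generalizes the per-gene score to ordered gene pairs: for pair (a, b) the
#' classifier sees gene a's expression at walk starts and gene b's at walk
#' ends; far pairs apply one shared permutation to both genes. The diagonal
#' is each gene's auto-information. Because the positivity constraint on the
#' classifier weights targets positive association, two genes expressed in
#' complementary regions score near zero (a documented limitation).
#'
#' The matrix is theoretically symmetric; residual asymmetry is Monte-Carlo
#' noise and is averaged out by the symmetrization `(I + t(I)) / 2`.
#'
#' @param object a [spatial_dataset()] or `spatinfo` fit-compatible matrix
#'   input (with `coords`).
#' @param genes character or integer vector of at least two genes,
#'   typically pre-filtered to high auto-information (see `min_auto_info`).
#' @param coords coordinates when `object` is a matrix.
#' @param min_auto_info optional filter: when `genes` is `NULL`, genes are
#'   scored by [spatinfo()] first and those with normalized score above this
#'   threshold are kept.
#' @param scale_exponent exponent `s` of the information-to-distance
#'   transform `D = (1 + I)^(-s)`.
#' @param ... further arguments passed to the trainer (as in [spatinfo()]):
#'   `graph`, `graph_params`, `walk_k`, `bin_sizes`, `uncertainty`,
#'   `max_iters`, `learning_rate`, `eval_rounds`, `seed`, ...
#' @return An object of class `pairwise_info`: `gene_ids`, `I` (ordered-pair
#'   normalized information), `I_sym`, `D`, `scale_exponent`.
#' @export
pairwise_info <- function(object, genes = NULL, coords = NULL,
                          min_auto_info = NULL, scale_exponent = 0.5, ...) {
  if (!inherits(object, "spatial_dataset")) {
    if (is.null(coords)) stop("coords required when object is a matrix")
    object <- spatial_dataset(object, coords)
  }
  dots <- list(...)
  if (is.null(genes)) {
    if (is.null(min_auto_info))
      stop("supply genes or min_auto_info")
    auto <- do.call(spatinfo, c(list(object = object), dots))
    genes <- auto$scores$gene_id[auto$scores$normalized_score > min_auto_info]
  }
  gidx <- resolve_genes(object, genes)
  if (length(gidx) < 2) stop("need at least two genes for pairwise information")

  args <- pairwise_train_args(object, dots)
  G <- length(gidx)
  I <- matrix(NA_real_, G, G,
              dimnames = list(object$gene_ids[gidx], object$gene_ids[gidx]))
  for (a in seq_len(G)) {
    for (b in seq_len(G)) {
      I[a, b] <- train_pair(args, gidx[a], gidx[b],
                            pair_id = (a - 1) * G + b)
    }
  }
  I_sym <- (I + t(I)) / 2
  structure(list(gene_ids = object$gene_ids[gidx], I = I, I_sym = I_sym,
                 D = info_to_distance(I_sym, scale_exponent),
                 scale_exponent = scale_exponent),
            class = "pairwise_info")
}

# Shared setup (graph, bin stack, configs) for all ordered pairs.
pairwise_train_args <- function(object, dots) {
  take <- function(name, default) if (!is.null(dots[[name]])) dots[[name]] else default
  sampler <- take("uncertainty", "gamma_poisson")
  if (!inherits(sampler, "sampler_config"))
    sampler <- sampler_config(match.arg(sampler, c("gamma_poisson",
                                                   "dirichlet_multinomial",
                                                   "gaussian", "none")))
  seed <- take("seed", NULL)
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  levels <- build_bin_stack(object, bin_sizes = take("bin_sizes", c(4L, 8L, 16L)),
                            graph_method = take("graph", "delaunay"),
                            graph_params = take("graph_params", list()))
  list(tmpl = lapply(levels, function(lv) level_template(lv, sampler, object)),
       cfg = list(max_iters = as.integer(take("max_iters", 1000L)),
                  learning_rate = take("learning_rate", 0.01),
                  beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                  convergence_window = as.integer(take("convergence_window", 100L)),
                  convergence_rtol = take("convergence_rtol", 1e-4),
                  eval_rounds = as.integer(take("eval_rounds", 10L)),
                  early_stop = isTRUE(take("early_stop", TRUE)),
                  positive_weights = !isTRUE(take("allow_negative_weights",
                                                  FALSE))),
       scfg = sampler_cfg_cpp(sampler, ncol(object$counts)),
       walk_k = as.integer(take("walk_k", 10L)), seed = seed)
}

train_pair <- function(args, ja, jb, pair_id) {
  if (!is.null(args$seed))
    set.seed(gene_substream(args$seed, pair_id))
  base_a <- gene_input(args$tmpl[[1]], ja)
  base_b <- gene_input(args$tmpl[[1]], jb)
  if (max(base_a) - min(base_a) < 1e-12 || max(base_b) - min(base_b) < 1e-12)
    return(0)
  lv_cpp <- lapply(args$tmpl, function(tm) {
    tm$xa <- gene_input(tm, ja)
    tm$xb <- gene_input(tm, jb)
    tm$paired <- ja != jb
    if (tm$gaussian) tm$aux <- as.numeric(tm$posterior_sd[, ja])
    tm
  })
  res <- .train_gene_cpp(lv_cpp, args$walk_k, args$cfg, args$scfg)
  normalize_scores(res$cell_scores)$normalized_score
}

#' Transform pairwise information to distances
#'
#' `D = (1 + I)^(-s)`: information 0 maps to distance 1 and distance decays
#' monotonically as information grows. Small negative information values
#' (Monte-Carlo noise) are clipped to 0.
#'
#' @param I_sym symmetric non-negative information matrix.
#' @param scale_exponent positive exponent `s` (default 0.5).
#' @return Distance matrix, same shape.
#' @export
info_to_distance <- function(I_sym, scale_exponent = 0.5) {
  (1 + pmax(I_sym, 0))^(-scale_exponent)
}

#' Cluster genes by pairwise spatial information
#'
#' Complete-linkage agglomerative clustering of the information-derived
#' distance matrix. The diagonal is zeroed (a gene is at distance 0 from
#' itself) before clustering.
#'
#' @param D symmetric non-negative distance matrix (e.g. from a
#'   [pairwise_info()] object's `$D`), or a `pairwise_info` object.
#' @return A list with the `hclust` tree, the `merge` table with `height`s,
#'   and the tree in `newick` format.
#' @export
cluster_genes <- function(D) {
  if (inherits(D, "pairwise_info")) D <- D$D
  if (any(!is.finite(D))) stop("non-finite distances")
  D <- as.matrix(D)
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc,
       merges = data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                           height = hc$height),
       newick = newick)
}

#' @export
#' @method print pairwise_info
print.pairwise_info <- function(x, ...) {
  cat(sprintf("pairwise_info: %d genes; symmetrized information range [%.3g, %.3g]\n",
              length(x$gene_ids), min(x$I_sym), max(x$I_sym)))
  invisible(x)
}
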