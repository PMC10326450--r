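#' Score spatial coherence of gene expression
#'
#' Fits, independently for every gene, a small distance-weighted classifier
#' that tries to distinguish expression pairs sampled from spatial
#' neighborhoods (endpoints of k-step random walks on a spatial graph) from
#' pairs sampled uniformly (the same walk indices after shuffling expression
#' across cells). The trained objective is a variational lower bound on the
#' Jensen-Shannon divergence between those two pair distributions: the
#' gene's *spatial information*. The bound decomposes over cells, giving a
#' per-cell saliency map, and the classifier's accuracy yields a binomial
#' test against random guessing.
#'
#' Training ascends the bound with Adam, optionally resampling expression
#' each iteration from a count posterior (see [sampler_config()]) and
#' jointly over a multi-resolution stack of exact-size spatial bins (see
#' [build_bin_stack()]); binned levels are auxiliary signal only, and all
#' reported quantities come from evaluation rounds on the unbinned data with
#' frozen parameters. Genes with constant input are skipped and reported at
#' the random-guessing baseline with p = 1.
#'
#' Each gene draws from its own seed substream derived from `seed`, so
#' results do not depend on gene order or batching, and are bit-for-bit
#' reproducible (exactly so in `"none"` uncertainty mode).
#'
#' @param object a [spatial_dataset()], or a cells x genes count matrix.
#' @param coords cells x 2 coordinate matrix (ignored when `object` is a
#'   `spatial_dataset`).
#' @param genes optional character or integer subset of genes to score.
#' @param graph graph construction method, see [spatial_graph()].
#' @param graph_params list of extra arguments for [spatial_graph()]
#'   (e.g. `epsilon`, `knn_m`, `grid`).
#' @param walk_k random-walk length defining the neighborhood scale.
#' @param bin_sizes ascending bin sizes for the training stack; `NULL`
#'   disables binning.
#' @param uncertainty count-uncertainty model, or a ready [sampler_config()].
#' @param max_iters,learning_rate Adam ascent budget and step size.
#' @param convergence_window,convergence_rtol early stopping: stop when the
#'   objective's moving-window average improves by less than
#'   `convergence_rtol` relative; disable with `early_stop = FALSE`.
#' @param early_stop logical.
#' @param eval_rounds number of fresh evaluation rounds used for the
#'   reported scores, saliency and accuracy.
#' @param allow_negative_weights drop the positivity constraint on the
#'   classifier weights, enabling detection of anti-correlated
#'   neighborhoods at some cost in power for the usual positive case.
#' @param seed integer master seed; `NULL` leaves the RNG stream untouched.
#' @param verbose print progress every 100 genes.
#' @return An object of class `spatinfo`: `scores` (data.frame with
#'   `gene_id`, `raw_score`, `normalized_score`, `accuracy`, `n_trials`,
#'   `p_value`, `q_value`, `n_iters`), `saliency` (cells x genes, in
#'   `[0, 1]`), `params` (genes x 5 fitted classifier parameters), the
#'   `graph`, and the call/configuration.
#' @seealso [pairwise_info()], [baseline_scores()], [simulate_potts()]
#' @examples
#' sim <- simulate_pattern(n_cells = 300, n_genes = 20, n_svg = 4, seed = 1)
#' fit <- spatinfo(sim$dataset, max_iters = 200, seed = 1)
#' head(summary(fit))
#' @export
spatinfo <- function(object, coords = NULL, genes = NULL,
                     graph = c("delaunay", "knn", "radius", "grid"),
                     graph_params = list(), walk_k = 10L,
                     bin_sizes = c(4L, 8L, 16L),
                     uncertainty = c("gamma_poisson", "dirichlet_multinomial",
                                     "gaussian", "none"),
                     max_iters = 1000L, learning_rate = 0.01,
                     convergence_window = 100L, convergence_rtol = 1e-4,
                     early_stop = TRUE, eval_rounds = 10L,
                     allow_negative_weights = FALSE, seed = NULL,
                     verbose = FALSE) {
  cl <- match.call()
  if (!inherits(object, "spatial_dataset")) {
    if (is.null(coords)) stop("coords required when object is a matrix")
    object <- spatial_dataset(object, coords)
  }
  graph <- match.arg(graph)
  sampler <- if (inherits(uncertainty, "sampler_config")) uncertainty
             else sampler_config(match.arg(uncertainty))
  if (sampler$model == "gaussian" && is.null(object$posterior_sd))
    stop("gaussian uncertainty requires posterior_mean/posterior_sd in the dataset")
  if (sampler$model == "gamma_poisson") {
    cm <- object$counts
    chk <- if (inherits(cm, "Matrix")) cm@x else cm
    if (any(chk != round(chk)))
      stop("gamma_poisson uncertainty requires integral counts")
  }
  stopifnot(max_iters >= 1, learning_rate > 0, eval_rounds >= 1)

  gidx <- resolve_genes(object, genes)
  n <- nrow(object$counts)

  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  levels <- build_bin_stack(object, bin_sizes = bin_sizes,
                            graph_method = graph, graph_params = graph_params)

  tmpl <- lapply(levels, function(lv) level_template(lv, sampler, object))
  cfg <- list(max_iters = as.integer(max_iters),
              learning_rate = learning_rate, beta1 = 0.9, beta2 = 0.999,
              adam_eps = 1e-8,
              convergence_window = as.integer(convergence_window),
              convergence_rtol = convergence_rtol,
              eval_rounds = as.integer(eval_rounds),
              early_stop = isTRUE(early_stop),
              positive_weights = !isTRUE(allow_negative_weights))
  scfg <- sampler_cfg_cpp(sampler, ncol(object$counts))

  G <- length(gidx)
  raw_score <- normalized <- accuracy <- p_value <- numeric(G)
  n_trials <- n_iters <- integer(G)
  saliency <- matrix(0, n, G,
                     dimnames = list(object$cell_ids, object$gene_ids[gidx]))
  params <- matrix(NA_real_, G, 5,
                   dimnames = list(object$gene_ids[gidx],
                                   c("w_s", "w_d", "b", "shift", "alpha")))

  for (gi in seq_len(G)) {
    j <- gidx[gi]
    if (!is.null(seed)) set.seed(gene_substream(seed, j))
    base <- gene_input(tmpl[[1]], j)
    if (max(base) - min(base) < 1e-12) {
      # constant expression: near/far distributions identical by construction
      raw_score[gi] <- log(0.25)
      normalized[gi] <- 0
      accuracy[gi] <- 0.5
      n_trials[gi] <- 0L
      p_value[gi] <- 1
      n_iters[gi] <- 0L
      next
    }
    lv_cpp <- lapply(tmpl, function(tm) {
      tm$xa <- gene_input(tm, j)
      tm$xb <- tm$xa
      tm$paired <- FALSE
      if (tm$gaussian) tm$aux <- as.numeric(tm$posterior_sd[, j])
      tm
    })
    res <- .train_gene_cpp(lv_cpp, as.integer(walk_k), cfg, scfg)
    ns <- normalize_scores(res$cell_scores)
    raw_score[gi] <- mean(res$cell_scores)
    normalized[gi] <- ns$normalized_score
    saliency[, gi] <- ns$saliency
    accuracy[gi] <- res$k_correct / res$n_trials
    n_trials[gi] <- as.integer(res$n_trials)
    p_value[gi] <- binomial_test(res$k_correct, res$n_trials)
    n_iters[gi] <- res$n_iters
    th <- res$theta
    eff <- if (allow_negative_weights) identity else softplus
    params[gi, ] <- c(eff(th[["raw_ws"]]), eff(th[["raw_wd"]]),
                      th[["b"]], th[["shift"]], exp(th[["log_alpha"]]))
    if (verbose && gi %% 100 == 0)
      message(sprintf("scored %d / %d genes", gi, G))
  }

  scores <- data.frame(gene_id = object$gene_ids[gidx], raw_score = raw_score,
                       normalized_score = normalized, accuracy = accuracy,
                       n_trials = n_trials, p_value = p_value,
                       q_value = adjust_pvalues(p_value), n_iters = n_iters,
                       stringsAsFactors = FALSE)
  structure(list(scores = scores, saliency = saliency, params = params,
                 graph = levels[[1]]$graph, coords = object$coords,
                 cell_ids = object$cell_ids,
                 config = list(graph = graph, graph_params = graph_params,
                               walk_k = walk_k, bin_sizes = bin_sizes,
                               sampler = sampler, max_iters = max_iters,
                               learning_rate = learning_rate,
                               convergence_window = convergence_window,
                               convergence_rtol = convergence_rtol,
                               early_stop = early_stop,
                               eval_rounds = eval_rounds,
                               allow_negative_weights = allow_negative_weights,
                               seed = seed),
                 call = cl),
            class = "spatinfo")
}

resolve_genes <- function(dataset, genes) {
  if (is.null(genes)) return(seq_along(dataset$gene_ids))
  if (is.character(genes)) {
    idx <- match(genes, dataset$gene_ids)
    if (any(is.na(idx))) stop("unknown gene id: ",
                              paste(genes[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(genes)
}

# Per-gene RNG substream: stable hash of the master seed and gene index so
# results are independent of gene order and batching. Kept below 2^31.
gene_substream <- function(seed, gene_index) {
  h <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(gene_index) * 16807
  as.integer(h %% 2147483647) + 1L
}

# Static (per-run) pieces of the C++ level list: graph, coords, aux.
level_template <- function(lv, sampler, dataset) {
  g <- lv$graph
  aux <- switch(sampler$model,
    gamma_poisson = size_factors(lv$counts),
    dirichlet_multinomial = as.numeric(row_sums(lv$counts)),
    gaussian = NULL, # filled per gene from posterior_sd
    none = numeric(g$n_cells))
  list(counts = lv$counts, adj = g$adj - 1L, ptr = g$ptr - 1L,
       cx = as.numeric(lv$coords[, 1]), cy = as.numeric(lv$coords[, 2]),
       weight = lv$weight, aux = aux, bin = lv$bin,
       gaussian = identical(sampler$model, "gaussian"),
       posterior_mean = if (identical(sampler$model, "gaussian"))
         bin_posterior(dataset$posterior_mean, lv$bin) else NULL,
       posterior_sd = if (identical(sampler$model, "gaussian"))
         bin_posterior_sd(dataset$posterior_sd, lv$bin) else NULL)
}

bin_posterior <- function(pm, bin) {
  if (is.null(bin)) return(pm)
  rowsum(pm[bin$kept, , drop = FALSE], bin$assignment)
}

bin_posterior_sd <- function(ps, bin) {
  if (is.null(bin)) return(ps)
  sqrt(rowsum(ps[bin$kept, , drop = FALSE]^2, bin$assignment))
}

gene_input <- function(tmpl, j) {
  if (tmpl$gaussian) {
    as.numeric(tmpl$posterior_mean[, j])
  } else {
    as.numeric(tmpl$counts[, j])
  }
}

sampler_cfg_cpp <- function(sampler, n_genes) {
  list(model = model_code(sampler$model), alpha0 = sampler$prior_shape,
       beta0 = sampler$prior_rate, alpha0d = sampler$dirichlet_prior,
       n_genes = as.numeric(n_genes), dm_scale = 1e4,
       resample_every = sampler$resample_every,
       transform = transform_code(sampler$transform))
}
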