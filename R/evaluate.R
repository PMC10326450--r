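#' Moran's I spatial autocorrelation
#'
#' Classical spatial autocorrelation with binary weights on the graph's
#' edges: `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i
#' (x_i - xbar)^2`. Returns `NA` for constant input (the statistic is
#' undefined, and flagging beats silently reporting 0).
#'
#' @param x per-cell numeric values.
#' @param graph a [spatial_graph()].
#' @return Scalar Moran's I, or `NA` for constant `x`.
#' @export
morans_i <- function(x, graph) {
  n <- graph$n_cells
  stopifnot(length(x) == n)
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom <= 0) return(NA_real_)
  i_idx <- rep.int(seq_len(n), graph$degrees)
  num <- sum(z[i_idx] * z[graph$adj])
  W <- length(graph$adj)
  (n / W) * num / denom
}

#' Geary's C spatial autocorrelation
#'
#' `C = ((n - 1) / (2 W)) * sum_ij w_ij (x_i - x_j)^2 / sum_i (x_i -
#' xbar)^2` with binary edge weights; 1 under the permutation null, below 1
#' for positive autocorrelation. `NA` for constant input.
#'
#' @inheritParams morans_i
#' @return Scalar Geary's C, or `NA` for constant `x`.
#' @export
gearys_c <- function(x, graph) {
  n <- graph$n_cells
  stopifnot(length(x) == n)
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom <= 0) return(NA_real_)
  i_idx <- rep.int(seq_len(n), graph$degrees)
  num <- sum((x[i_idx] - x[graph$adj])^2)
  W <- length(graph$adj)
  ((n - 1) / (2 * W)) * num / denom
}

#' Baseline autocorrelation scores for every gene
#'
#' Computes Moran's I and Geary's C per gene on log1p-transformed,
#' library-size-normalized counts (median library as reference), using the
#' same spatial graph as the information score. `rank_score` orients both
#' statistics so that higher means more spatially coherent (I itself, and
#' `2 - C`); genes with undefined statistics rank last.
#'
#' @param dataset a [spatial_dataset()].
#' @param graph optional pre-built [spatial_graph()]; defaults to Delaunay
#'   on the dataset coordinates.
#' @param statistic which statistic drives `rank_score`.
#' @return data.frame with `gene_id`, `morans_i`, `gearys_c`, `rank_score`.
#' @export
baseline_scores <- function(dataset, graph = NULL,
                            statistic = c("morans_i", "gearys_c")) {
  statistic <- match.arg(statistic)
  if (is.null(graph)) graph <- spatial_graph(dataset$coords, "delaunay")
  counts <- as.matrix(dataset$counts)
  sf <- size_factors(counts)
  norm <- log1p(counts / sf)
  mi <- apply(norm, 2, morans_i, graph = graph)
  gc_ <- apply(norm, 2, gearys_c, graph = graph)
  # a constant-count gene carries no expression signal even if library-size
  # normalization makes its values vary; flag rather than score it
  const <- apply(counts, 2, function(v) max(v) - min(v) == 0)
  mi[const] <- NA_real_
  gc_[const] <- NA_real_
  rank_score <- if (statistic == "morans_i") mi else 2 - gc_
  rank_score[is.na(rank_score)] <- -Inf
  data.frame(gene_id = dataset$gene_ids, morans_i = mi, gearys_c = gc_,
             rank_score = rank_score, stringsAsFactors = FALSE)
}

#' Area under the precision-recall curve
#'
#' Average precision of ranking genes by `scores` against boolean `truth`
#' (higher score = called more spatially varying). Computed as the
#' step-function sum over distinct score thresholds, so tied scores are
#' treated as one block. Its null value equals the prevalence of positives.
#'
#' @param scores per-gene numeric scores (larger = more spatial); `-Inf`
#'   allowed for "ranked last".
#' @param truth per-gene logical ground-truth labels.
#' @return Scalar PR-AUC in (0, 1].
#' @export
pr_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.logical(truth)
  if (!any(truth) || all(truth))
    stop("truth must contain at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  # block boundaries at distinct score values
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(t)[last_of_block]
  np <- seq_along(s)[last_of_block]
  precision <- tp / np
  recall <- tp / sum(truth)
  drec <- diff(c(0, recall))
  sum(drec * precision)
}

#' Improvement in PR-AUC over a baseline ranking
#'
#' `delta = pr_auc(method) - pr_auc(baseline)` on the same genes and truth;
#' positive values mean the method ranks true spatially varying genes
#' better than the baseline (conventionally Moran's I).
#'
#' @param method_scores,baseline_scores per-gene score vectors.
#' @param truth per-gene logical labels.
#' @return Scalar difference.
#' @export
delta_pr_auc <- function(method_scores, baseline_scores, truth) {
  pr_auc(method_scores, truth) - pr_auc(baseline_scores, truth)
}
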