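#' @export
#' @method print spatinfo
print.spatinfo <- function(x, ...) {
  sc <- x$scores
  cat(sprintf("spatinfo fit: %d genes x %d cells (graph: %s, walk length %d)\n",
              nrow(sc), nrow(x$saliency), x$config$graph, x$config$walk_k))
  cat(sprintf("  uncertainty model: %s; bin sizes: %s\n",
              x$config$sampler$model,
              if (length(x$config$bin_sizes)) paste(x$config$bin_sizes, collapse = ",")
              else "none"))
  cat(sprintf("  normalized score range: [%.3g, %.3g]; %d gene(s) with q < 0.05\n",
              min(sc$normalized_score), max(sc$normalized_score),
              sum(sc$q_value < 0.05)))
  top <- utils::head(sc[order(-sc$normalized_score), "gene_id"], 5)
  cat("  top genes:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a spatial information fit
#'
#' @param object a `spatinfo` fit.
#' @param ... unused.
#' @return The gene-level score table, sorted by normalized score
#'   descending.
#' @export
#' @method summary spatinfo
summary.spatinfo <- function(object, ...) {
  sc <- object$scores
  sc[order(-sc$normalized_score), , drop = FALSE]
}

#' Fitted classifier parameters
#'
#' @param object a `spatinfo` fit.
#' @param ... unused.
#' @return Genes x 5 matrix of effective parameters
#'   (`w_s`, `w_d`, `b`, `shift`, `alpha`); rows of skipped (constant)
#'   genes are `NA`.
#' @export
coef.spatinfo <- function(object, ...) object$params

#' Plot a gene's saliency map
#'
#' Draws the cells at their spatial coordinates, colored by the per-cell
#' saliency (normalized contribution to the gene's spatial information).
#'
#' @param x a `spatinfo` fit.
#' @param gene gene id or index to plot.
#' @param pch,cex passed to [graphics::plot()].
#' @param ... further graphical parameters.
#' @return Invisibly, the saliency vector plotted.
#' @export
plot.spatinfo <- function(x, gene = 1L, pch = 16, cex = 0.6, ...) {
  j <- if (is.character(gene)) match(gene, colnames(x$saliency)) else gene
  if (is.na(j) || j < 1 || j > ncol(x$saliency)) stop("unknown gene: ", gene)
  sal <- x$saliency[, j]
  pal <- grDevices::hcl.colors(100, "viridis")
  col <- pal[pmax(1L, ceiling(sal * 100))]
  graphics::plot(x$coords[, 1], x$coords[, 2], col = col, pch = pch, cex = cex,
                 xlab = "x", ylab = "y", asp = 1,
                 main = sprintf("%s saliency (score %.2f)",
                                colnames(x$saliency)[j],
                                x$scores$normalized_score[j]), ...)
  invisible(sal)
}
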