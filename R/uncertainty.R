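#' Configure posterior resampling of expression values
#'
#' During training, expression values can be redrawn from a per-cell-gene
#' posterior at every iteration so that the information score reflects the
#' uncertainty in sparse counts rather than treating them as exact.
#'
#' Models: `"gamma_poisson"` treats counts as absolute expression; the rate
#' posterior is Gamma(shape = `prior_shape` + count, rate = `prior_rate` +
#' size factor). `"dirichlet_multinomial"` treats per-cell totals as a
#' confounder and resamples proportions from the posterior Dirichlet (scaled
#' to counts per 10k). `"gaussian"` draws from supplied posterior
#' mean/standard-deviation matrices. `"none"` uses the transformed counts
#' deterministically.
#'
#' The default transform is `log1p` of the sampled rate/proportion (and of
#' the counts in `"none"` mode; `identity` for `"gaussian"`). A plain `log`
#' is available but not the default: under a weak Gamma prior, cells with
#' zero counts draw rates arbitrarily close to zero whose logs become
#' extreme negative outliers that dominate the per-gene standardization and
#' mask spatial signal. Sampled values are standardized per gene before
#' classification -- an affine change absorbed by the classifier weights
#' and shift.
#'
#' @param model one of `"gamma_poisson"`, `"dirichlet_multinomial"`,
#'   `"gaussian"`, `"none"`.
#' @param prior_shape,prior_rate Gamma prior hyperparameters (weakly
#'   informative defaults 0.1/0.1).
#' @param dirichlet_prior symmetric Dirichlet prior concentration.
#' @param resample_every redraw period in iterations (1 = every iteration).
#' @param transform `"log"`, `"log1p"` or `"identity"`; `NULL` picks the
#'   model-appropriate default above.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(model = c("gamma_poisson", "dirichlet_multinomial",
                                     "gaussian", "none"),
                           prior_shape = 0.1, prior_rate = 0.1,
                           dirichlet_prior = 0.01, resample_every = 1L,
                           transform = NULL) {
  model <- match.arg(model)
  stopifnot(prior_shape > 0, prior_rate > 0, dirichlet_prior > 0,
            resample_every >= 1)
  if (is.null(transform))
    transform <- switch(model, gaussian = "identity", "log1p")
  transform <- match.arg(transform, c("identity", "log1p", "log"))
  structure(list(model = model, prior_shape = prior_shape,
                 prior_rate = prior_rate, dirichlet_prior = dirichlet_prior,
                 resample_every = as.integer(resample_every),
                 transform = transform),
            class = "sampler_config")
}

transform_code <- function(tr) match(tr, c("identity", "log1p", "log")) - 1L
model_code <- function(m) match(m, c("none", "gamma_poisson",
                                     "dirichlet_multinomial", "gaussian")) - 1L

apply_transform <- function(x, tr) {
  switch(tr, identity = x, log1p = log1p(x), log = log(pmax(x, 1e-300)))
}

#' Size factors from library sizes
#'
#' Per-cell total count divided by the median total, so Gamma-Poisson rates
#' are on a normalized-expression scale.
#'
#' @param counts cells x genes count matrix.
#' @return Positive numeric vector, one per cell.
#' @export
size_factors <- function(counts) {
  tot <- row_sums(counts)
  med <- stats::median(tot)
  if (med <= 0) med <- 1
  sf <- tot / med
  sf[sf <= 0] <- min(sf[sf > 0], 1)
  sf
}

#' Draw expression from the Gamma-Poisson posterior
#'
#' For each cell/gene, draws a rate from Gamma(shape = `prior_shape` +
#' count, rate = `prior_rate` + size factor) and applies the configured
#' transform. Counts must be integral.
#'
#' @param counts cells x genes integer count matrix.
#' @param size_factors positive per-cell scale factors.
#' @param cfg a [sampler_config()].
#' @return Matrix of transformed posterior draws, same shape as `counts`.
#' @export
sample_expression_gp <- function(counts, size_factors = NULL,
                                 cfg = sampler_config("gamma_poisson")) {
  counts <- as.matrix(counts)
  if (any(counts != round(counts)))
    stop("Gamma-Poisson resampling requires integral counts")
  if (is.null(size_factors)) size_factors <- spatinfo::size_factors(counts)
  stopifnot(all(size_factors > 0), length(size_factors) == nrow(counts))
  shape <- cfg$prior_shape + counts
  rate <- cfg$prior_rate + size_factors # recycles down columns
  lam <- matrix(stats::rgamma(length(shape), shape = shape, rate = rate),
                nrow = nrow(counts), dimnames = dimnames(counts))
  apply_transform(lam, cfg$transform)
}

#' Draw expression proportions from the Dirichlet-Multinomial posterior
#'
#' Per cell, draws proportions over genes from Dirichlet(`dirichlet_prior` +
#' counts), scales to counts-per-10k, and applies the transform. Cells with
#' zero total count fall back to the prior alone (with a warning).
#'
#' @inheritParams sample_expression_gp
#' @return Matrix of transformed scaled proportions.
#' @export
sample_expression_dm <- function(counts,
                                 cfg = sampler_config("dirichlet_multinomial")) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  if (any(tot == 0))
    warning(sprintf("%d cell(s) with zero total count: proportions drawn from the prior alone",
                    sum(tot == 0)))
  g <- stats::rgamma(length(counts), shape = cfg$dirichlet_prior + counts, rate = 1)
  g <- matrix(g, nrow = nrow(counts), dimnames = dimnames(counts))
  p <- g / rowSums(g)
  apply_transform(p * 1e4, cfg$transform)
}

#' Draw expression from a Gaussian posterior
#'
#' Independent Normal(mean, sd) draws, identity transform. Used when an
#' upstream normalization method supplies posterior means and standard
#' deviations.
#'
#' @param posterior_mean,posterior_sd matrices of equal shape; `posterior_sd`
#'   must be strictly positive.
#' @return Matrix of draws.
#' @export
sample_expression_gaussian <- function(posterior_mean, posterior_sd) {
  if (is.null(posterior_sd)) stop("posterior_sd matrix is required")
  stopifnot(all(dim(posterior_mean) == dim(posterior_sd)))
  if (min(posterior_sd) <= 0) stop("posterior_sd must be > 0")
  matrix(stats::rnorm(length(posterior_mean), posterior_mean, posterior_sd),
         nrow = nrow(posterior_mean), dimnames = dimnames(posterior_mean))
}
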