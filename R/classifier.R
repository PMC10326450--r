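#' Numerically stable softplus
#' @param x numeric vector.
#' @return `log(1 + exp(x))` computed without overflow.
#' @export
softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

log_sigmoid <- function(x) -softplus(-x)

#' Construct classifier parameters
#'
#' The per-gene classifier is
#' `f(x, x', d) = exp(-d / alpha) * (w_s * |x + x' + shift| - w_d * |x - x'| + b)`
#' with the weights held positive through a softplus reparameterization
#' (`w_s = softplus(raw_ws)`, likewise `w_d`) and the distance-decay length
#' `alpha > 0` held positive through a log parameterization. The `w_s` term
#' rewards pairs that are jointly unusually low or high, the `w_d` term
#' penalizes dissimilar pairs, and `exp(-d / alpha)` discounts long walks
#' when spatial organization is local.
#'
#' @param raw_ws,raw_wd unconstrained weight parameters.
#' @param b bias.
#' @param shift additive shift inside the similarity term.
#' @param log_alpha log of the distance-decay length (coordinate units).
#' @return A `classifier_params` list with both raw and effective values.
#' @export
classifier_params <- function(raw_ws = log(expm1(0.1)), raw_wd = log(expm1(0.1)),
                              b = 0, shift = 0, log_alpha = 0) {
  structure(list(raw_ws = raw_ws, raw_wd = raw_wd, b = b, shift = shift,
                 log_alpha = log_alpha,
                 w_s = softplus(raw_ws), w_d = softplus(raw_wd),
                 alpha = exp(log_alpha)),
            class = "classifier_params")
}

#' @export
#' @method print classifier_params
print.classifier_params <- function(x, ...) {
  cat(sprintf("classifier_params: w_s = %.4g, w_d = %.4g, b = %.4g, shift = %.4g, alpha = %.4g\n",
              x$w_s, x$w_d, x$b, x$shift, x$alpha))
  invisible(x)
}

#' Evaluate the distance-weighted pair classifier
#'
#' @param theta a [classifier_params()], or any list carrying effective
#'   `w_s`, `w_d`, `b`, `shift`, `alpha`.
#' @param x,xp expression values at the walk start and end (vectors).
#' @param d walk Euclidean distance(s), `>= 0`.
#' @return The classifier logit(s) `f`.
#' @export
classify_pair <- function(theta, x, xp, d = 0) {
  stopifnot(all(d >= 0))
  exp(-d / theta$alpha) *
    (theta$w_s * abs(x + xp + theta$shift) - theta$w_d * abs(x - xp) + theta$b)
}

#' Jensen-Shannon lower-bound objective
#'
#' The variational bound on the Jensen-Shannon divergence between the
#' neighborhood pair distribution and the product of marginals: the mean
#' over cells of `-softplus(-f_near) - softplus(f_far)`, equivalently the
#' mean log probability the classifier assigns to the true near/far labels.
#' With an uninformative classifier (both logits 0) the value is
#' `-2 log 2 = log(0.25)`, and it approaches 0 under perfect classification.
#'
#' @param f_near,f_far equal-length logit vectors for neighborhood pairs and
#'   shuffled pairs.
#' @return Scalar mean objective (in nats, `<= 0` in expectation).
#' @export
js_objective <- function(f_near, f_far) {
  stopifnot(length(f_near) == length(f_far))
  mean(-softplus(-f_near) - softplus(f_far))
}

#' Normalize per-cell scores to saliency and a gene score
#'
#' Per-cell raw scores live in `[log 0.25, 0]` (random guessing to perfect
#' classification), occasionally dipping slightly below the floor through
#' Monte-Carlo noise. Saliency maps them affinely onto `[0, 1]` with
#' clipping; the gene-level normalized score is the sum of saliencies, in
#' `[0, n]`.
#'
#' @param raw numeric vector of per-cell raw scores.
#' @return List with `saliency` (per cell, in `[0, 1]`) and
#'   `normalized_score` (their sum).
#' @export
normalize_scores <- function(raw) {
  stopifnot(all(is.finite(raw)))
  floor_ <- log(0.25)
  sal <- pmin(pmax((raw - floor_) / (0 - floor_), 0), 1)
  list(saliency = sal, normalized_score = sum(sal))
}

#' One-sided binomial test against random guessing
#'
#' Upper-tail p value for the number of correctly classified pairs under the
#' null that the classifier guesses at random: `P(K >= k)` with
#' `K ~ Binomial(n, 0.5)`, computed from the survival function.
#'
#' @param k_correct number of correct classifications.
#' @param n_trials total classifications (0 allowed; gives p = 1).
#' @return p value in (0, 1].
#' @export
binomial_test <- function(k_correct, n_trials) {
  stopifnot(k_correct >= 0, k_correct <= n_trials)
  if (n_trials == 0) return(1)
  stats::pbinom(k_correct - 1, n_trials, 0.5, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' delegated to [stats::p.adjust()].
#'
#' @param p vector of p values in (0, 1].
#' @return q values, same length.
#' @export
adjust_pvalues <- function(p) stats::p.adjust(p, method = "BH")
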