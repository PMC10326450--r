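test_that("the pair classifier evaluates its closed form", {
  th <- list(w_s = 1, w_d = 1, b = 0, shift = 0, alpha = 1)
  expect_equal(classify_pair(th, 1, 1, 0), 2)
  expect_equal(classify_pair(th, 1, -1, 0), -2)
  expect_equal(classify_pair(th, 1, 1, 1), 2 * exp(-1))
  # vectorized and monotone in distance
  expect_equal(classify_pair(th, c(1, 1), c(1, 1), c(0, 2)),
               c(2, 2 * exp(-2)))
  expect_error(classify_pair(th, 1, 1, -1))
})

test_that("softplus reparameterization keeps the weights positive", {
  th <- classifier_params(raw_ws = -30, raw_wd = -30, log_alpha = -5)
  expect_gt(th$w_s, 0)
  expect_gt(th$w_d, 0)
  expect_gt(th$alpha, 0)
  expect_equal(classifier_params(raw_ws = log(expm1(2)))$w_s, 2)
})

test_that("the objective hits its baseline, limit, and a hand value", {
  expect_equal(js_objective(0, 0), -2 * log(2), tolerance = 1e-12)
  expect_equal(js_objective(1e4, -1e4), 0, tolerance = 1e-12)
  expect_equal(js_objective(1, -1), -2 * log1p(exp(-1)), tolerance = 1e-12)
  expect_equal(js_objective(1, -1), -0.62652, tolerance = 1e-5)
  # numerically stable far into the tails
  expect_true(is.finite(js_objective(-800, 800)))
})

test_that("score normalization maps the baseline to 0 and perfection to 1", {
  expect_equal(normalize_scores(log(0.25))$saliency, 0)
  expect_equal(normalize_scores(0)$saliency, 1)
  expect_equal(normalize_scores(-0.62652)$saliency, 0.54811, tolerance = 1e-4)
  # clipping covers numeric undershoot and the sum equals the gene score
  ns <- normalize_scores(c(log(0.25) - 0.01, -0.5, 0))
  expect_equal(ns$saliency[1], 0)
  expect_equal(ns$normalized_score, sum(ns$saliency))
})

test_that("binomial p values agree with direct tail summation", {
  expect_equal(binomial_test(10, 10), 2^-10)
  expect_equal(binomial_test(0, 25), 1)
  expect_equal(binomial_test(5, 10), 0.6230469, tolerance = 1e-7)
  expect_equal(binomial_test(0, 0), 1)
})

test_that("BH adjustment reproduces the hand-computed example", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.5, 0.04)
  expect_true(all(adjust_pvalues(p) >= p))
})

test_that("constant genes are skipped with a baseline result", {
  ds <- make_null_dataset(40, 2, seed = 11)
  ds$counts[, 1] <- 3
  fit <- spatinfo(ds, max_iters = 30, bin_sizes = NULL, seed = 1)
  expect_equal(fit$scores$normalized_score[1], 0)
  expect_equal(fit$scores$p_value[1], 1)
  expect_equal(fit$scores$raw_score[1], log(0.25))
  expect_true(all(fit$saliency[, 1] == 0))
  expect_gt(fit$scores$n_iters[2], 0)
})

test_that("identical seeds give bit-identical fits in deterministic mode", {
  ds <- make_null_dataset(60, 3, seed = 12)
  f1 <- spatinfo(ds, uncertainty = "none", max_iters = 60, seed = 42)
  f2 <- spatinfo(ds, uncertainty = "none", max_iters = 60, seed = 42)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$saliency, f2$saliency)
  expect_identical(coef(f1), coef(f2))
})

test_that("per-gene results do not depend on the gene subset scored", {
  ds <- make_null_dataset(60, 4, seed = 13)
  all_fit <- spatinfo(ds, max_iters = 40, seed = 5)
  sub_fit <- spatinfo(ds, genes = c("g3", "g1"), max_iters = 40, seed = 5)
  expect_equal(sub_fit$scores$raw_score,
               all_fit$scores$raw_score[c(3, 1)])
})

test_that("trained scores stay above the guessing floor and below zero", {
  ds <- make_null_dataset(150, 6, seed = 14)
  fit <- spatinfo(ds, max_iters = 150, seed = 2)
  expect_true(all(fit$scores$raw_score >= log(0.25) - 0.05))
  expect_true(all(fit$scores$raw_score <= 0))
  expect_true(all(fit$saliency >= 0 & fit$saliency <= 1))
  expect_equal(colSums(fit$saliency), fit$scores$normalized_score,
               ignore_attr = TRUE)
  expect_true(all(fit$scores$q_value >= fit$scores$p_value))
})

test_that("a strong spatial pattern is detected and a null is not", {
  hg <- make_half_grid(16)
  set.seed(3)
  null_gene <- rnbinom(nrow(hg$coords), mu = 5, size = 4)
  counts <- cbind(half = hg$x * 10, null = null_gene)
  ds <- spatial_dataset(counts, hg$coords)
  fit <- spatinfo(ds, graph = "grid", uncertainty = "none", bin_sizes = NULL,
                  seed = 8)
  expect_lt(fit$scores$p_value[1], 1e-6)
  expect_gt(fit$scores$p_value[2], 0.001)
  expect_gt(fit$scores$normalized_score[1],
            5 * fit$scores$normalized_score[2])
})

test_that("gaussian-mode scoring uses the posterior matrices", {
  hg <- make_half_grid(12)
  n <- nrow(hg$coords)
  set.seed(4)
  pm <- cbind(sig = hg$x * 3 + rnorm(n, 0, 0.1), noise = rnorm(n))
  ds <- spatial_dataset(counts = pmax(pm, 0), coords = hg$coords,
                        posterior_mean = pm,
                        posterior_sd = matrix(0.1, n, 2))
  fit <- spatinfo(ds, uncertainty = "gaussian", graph = "grid",
                  bin_sizes = NULL, max_iters = 300, seed = 6)
  expect_lt(fit$scores$p_value[1], 1e-4)
  expect_gt(fit$scores$normalized_score[1], fit$scores$normalized_score[2])
  expect_error(spatinfo(make_null_dataset(20, 2), uncertainty = "gaussian"),
               "posterior")
})

test_that("dropping the positivity constraint exposes anti-correlated neighborhoods", {
  # checkerboard: every neighbor is anti-correlated, so the constrained
  # classifier is nearly blind while the unconstrained one detects the gene
  m <- 16
  gr <- expand.grid(x = seq_len(m), y = seq_len(m))
  coords <- as.matrix(gr)
  x <- ((gr$x + gr$y) %% 2) * 6
  ds <- spatial_dataset(matrix(x, ncol = 1, dimnames = list(NULL, "stripe")),
                        coords)
  base <- spatinfo(ds, graph = "grid", walk_k = 1, uncertainty = "none",
                   bin_sizes = NULL, seed = 3)
  free <- spatinfo(ds, graph = "grid", walk_k = 1, uncertainty = "none",
                   bin_sizes = NULL, allow_negative_weights = TRUE, seed = 3)
  expect_gt(free$scores$normalized_score[1],
            2 * base$scores$normalized_score[1])
  expect_lt(coef(free)["stripe", "w_d"], 0)
})
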