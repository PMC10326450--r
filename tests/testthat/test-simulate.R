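test_that("iteration-zero lattices keep the ordered sine-band arrangement", {
  pc <- potts_config(n_cells = 500, iterations = 0, seed = 3)
  sim <- simulate_potts(pc, expr_config(n_genes = 20, n_svg = 4, seed = 3))
  # types live in balanced, spatially blocked bands
  expect_equal(length(sim$initial_types), 500)
  expect_true(max(table(sim$initial_types)) - min(table(sim$initial_types)) <= 2)
  expect_identical(sim$dataset$cell_labels, paste0("type", sim$initial_types))
  expect_gt(type_homophily(sim$dataset$coords, sim$initial_types), 0.55)
})

test_that("no cell is annihilated by the dynamics and areas stay positive", {
  pc <- potts_config(n_cells = 300, iterations = 100, seed = 4)
  sim <- simulate_potts(pc, expr_config(n_genes = 10, n_svg = 2, seed = 4))
  expect_equal(sort(unique(as.integer(sim$lattice[sim$lattice > 0]))), 1:300)
  expect_true(all(sim$areas >= 1))
  expect_equal(nrow(sim$dataset$coords), 300)
})

test_that("Metropolis dynamics lower the energy at low temperature", {
  pc <- potts_config(n_cells = 200, iterations = 30, temperature = 0.05,
                     lambda_act = 0, seed = 5)
  sim <- simulate_potts(pc, expr_config(n_genes = 5, n_svg = 1, seed = 5))
  expect_lt(sim$energy[30], sim$energy[1])
})

test_that("arrangements disorder slowly: homophily at 10 sweeps >= at 1000", {
  hom <- sapply(c(10, 1000), function(it) {
    pc <- potts_config(n_cells = 400, iterations = it, seed = 6)
    sim <- simulate_potts(pc, expr_config(n_genes = 5, n_svg = 1, seed = 6))
    type_homophily(sim$dataset$coords, sim$initial_types)
  })
  expect_gte(hom[1], hom[2])
  expect_gt(hom[2], 0.3)  # patterning persists
})

test_that("negative-binomial moments match mean + mean^2 / r", {
  sim <- simulate_pattern(n_cells = 20000, n_genes = 6, n_svg = 1,
                          fold_change = 1, nb_dispersion = 4, seed = 7)
  mu_hat <- colMeans(sim$dataset$counts)
  v_hat <- apply(sim$dataset$counts, 2, var)
  expect_equal(v_hat, mu_hat + mu_hat^2 / 4, tolerance = 0.1)
})

test_that("streak and hotspot regions cover the requested area", {
  sim <- simulate_pattern(n_cells = 10000, pattern = "streak",
                          region_fraction = 0.2, seed = 8)
  expect_equal(mean(sim$in_region), 0.2, tolerance = 0.012 / 0.2)
  hs <- simulate_pattern(n_cells = 10000, pattern = "hotspot",
                         region_fraction = 0.2, seed = 9)
  r <- sqrt(0.2 / pi)
  inside <- (hs$dataset$coords[, 1] - 0.5)^2 +
    (hs$dataset$coords[, 2] - 0.5)^2 <= r^2
  expect_equal(unname(hs$in_region), unname(inside))
  expect_equal(mean(hs$in_region), 0.2, tolerance = 0.012 / 0.2)
})

test_that("fold change one yields matched inside/outside distributions", {
  sim <- simulate_pattern(n_cells = 8000, n_genes = 4, n_svg = 2,
                          fold_change = 1, seed = 10)
  for (j in which(sim$is_svg)) {
    m_in <- mean(sim$dataset$counts[sim$in_region, j])
    m_out <- mean(sim$dataset$counts[!sim$in_region, j])
    expect_equal(m_in, m_out, tolerance = 0.1)
  }
})

test_that("effect size raises SVG expression contrast across types", {
  score_sep <- sapply(c(0, 1), function(es) {
    pc <- potts_config(n_cells = 300, iterations = 10, seed = 11)
    sim <- simulate_potts(pc, expr_config(n_genes = 40, n_svg = 10,
                                          effect_size = es, seed = 11))
    counts <- sim$dataset$counts
    types <- sim$initial_types
    f <- apply(counts[, sim$is_svg], 2, function(x) {
      s <- summary(stats::aov(x ~ factor(types)))
      s[[1]]$`F value`[1]
    })
    mean(f)
  })
  expect_gt(score_sep[2], score_sep[1] * 2)
})

test_that("simulations round-trip through disk and replay identically", {
  sim <- simulate_pattern(n_cells = 50, n_genes = 5, n_svg = 2, seed = 12)
  prefix <- file.path(withr::local_tempdir(), "sim")
  paths <- write_sim(sim, prefix)
  back <- read_spatial_dataset(paths[1], mode = "table")
  expect_equal(unname(back$counts), unname(sim$dataset$counts))
  truth <- read.csv(paths[2])
  expect_equal(nrow(truth), 5)
  expect_equal(truth$is_svg, sim$is_svg)
  again <- replay_sim(paths[3])
  expect_equal(again$dataset$counts, sim$dataset$counts)
  expect_equal(again$dataset$coords, sim$dataset$coords)
  pot <- simulate_potts(potts_config(n_cells = 80, iterations = 5, seed = 13),
                        expr_config(n_genes = 6, n_svg = 2, seed = 13))
  prefix2 <- file.path(withr::local_tempdir(), "pot")
  paths2 <- write_sim(pot, prefix2)
  pot2 <- replay_sim(paths2[3])
  expect_equal(pot2$dataset$counts, pot$dataset$counts)
  expect_equal(pot2$dataset$coords, pot$dataset$coords)
})
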