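# Exact oracle for the trained bound on small discrete datasets: enumerate the
# k-step walk pair distribution and the shuffled-pair distribution, then
# optimize the classifier by dense grid search with refinement.

# Tables of (value-index a, value-index b, distance, mass) for near and far
# pairs, for a gene with few distinct values on a small graph.
exact_pair_tables <- function(x, coords, graph, k) {
  n <- graph$n_cells
  z <- (x - mean(x)) / sd(x)
  vals <- sort(unique(z))
  ti <- match(z, vals)
  P <- transition_matrix(graph)
  Pk <- P
  if (k > 1) for (i in 2:k) Pk <- Pk %*% P
  d_ij <- as.matrix(dist(coords))
  mass <- Pk / n
  idx <- which(mass > 0, arr.ind = TRUE)
  self <- idx[, 1] == idx[, 2]
  tab <- data.frame(a = ti[idx[, 1]], b = ti[idx[, 2]],
                    d = round(d_ij[idx], 9), m = mass[idx], self = self)
  near <- stats::aggregate(m ~ a + b + d, tab, sum)

  # far pairs reuse the walk's (i, j, d); values come from a random
  # permutation: i == j gives one random cell's value twice, i != j a
  # without-replacement ordered pair
  nv <- length(vals)
  cnt <- tabulate(ti, nv)
  pv_distinct <- outer(cnt, cnt) - diag(cnt)
  pv_distinct <- pv_distinct / (n * (n - 1))
  dmass <- stats::aggregate(m ~ d + self, tab, sum)
  far <- do.call(rbind, lapply(seq_len(nrow(dmass)), function(r) {
    if (dmass$self[r]) {
      data.frame(a = seq_len(nv), b = seq_len(nv), d = dmass$d[r],
                 m = dmass$m[r] * cnt / n)
    } else {
      eg <- expand.grid(a = seq_len(nv), b = seq_len(nv))
      data.frame(a = eg$a, b = eg$b, d = dmass$d[r],
                 m = dmass$m[r] * pv_distinct[cbind(eg$a, eg$b)])
    }
  }))
  far <- stats::aggregate(m ~ a + b + d, far, sum)
  list(near = near, far = far, vals = vals)
}

# Expected per-pair objective for parameters theta on the exact tables.
exact_objective <- function(tabs, ws, wd, b, s, alpha) {
  f <- function(t) {
    exp(-t$d / alpha) * (ws * abs(tabs$vals[t$a] + tabs$vals[t$b] + s) -
                           wd * abs(tabs$vals[t$a] - tabs$vals[t$b]) + b)
  }
  sum(tabs$near$m * (-softplus(-f(tabs$near)))) +
    sum(tabs$far$m * (-softplus(f(tabs$far))))
}

# Dense grid search over (w_s, w_d, b, shift) with iterative refinement and a
# small profile grid over the decay length.
grid_search_optimum <- function(tabs, rounds = 4) {
  rng <- list(ws = c(0, 8), wd = c(0, 8), b = c(-8, 8), s = c(-4, 4))
  alphas <- c(2, 5, 10, 30, 1e6)
  best <- c(ws = 0.1, wd = 0.1, b = 0, s = 0, alpha = 10)
  bv <- -Inf
  for (round in seq_len(rounds)) {
    grd <- expand.grid(ws = seq(rng$ws[1], rng$ws[2], length.out = 9),
                       wd = seq(rng$wd[1], rng$wd[2], length.out = 9),
                       b = seq(rng$b[1], rng$b[2], length.out = 9),
                       s = seq(rng$s[1], rng$s[2], length.out = 9),
                       alpha = alphas)
    v <- mapply(function(ws, wd, b, s, a) exact_objective(tabs, ws, wd, b, s, a),
                grd$ws, grd$wd, grd$b, grd$s, grd$alpha)
    i <- which.max(v)
    if (v[i] > bv) {
      bv <- v[i]
      best <- unlist(grd[i, ])
    }
    for (p in names(rng)) {
      w <- diff(rng[[p]]) / 8
      rng[[p]] <- c(best[[p]] - w, best[[p]] + w)
    }
    rng$ws[1] <- max(rng$ws[1], 0)
    rng$wd[1] <- max(rng$wd[1], 0)
    alphas <- unique(pmax(best[["alpha"]] * c(0.5, 0.75, 1, 1.5, 2), 0.5))
  }
  list(value = bv, par = best)
}
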