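#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Numerically stable softplus log(1 + exp(x)).
static inline double softplus(double x) {
  if (x > 0.0) return x + log1p(std::exp(-x));
  return log1p(std::exp(x));
}

// log sigmoid(x) = -softplus(-x)
static inline double log_sigmoid(double x) { return -softplus(-x); }

static inline double sigmoid(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline double sgn(double x) { return (x > 0.0) - (x < 0.0); }

// One training/evaluation level: expression source, graph in CSR form, coords.
struct Level {
  int n;
  std::vector<double> xa;   // base input for gene a (counts / posterior mean)
  std::vector<double> xb;   // base input for gene b (== xa for auto-information)
  std::vector<double> aux;  // gp: size factor; dm: per-cell total count; gaussian: posterior sd
  std::vector<int> adj;     // concatenated 0-based neighbor lists
  std::vector<int> ptr;     // offsets, length n+1
  std::vector<double> cx, cy;
  double weight;
  bool paired;
  // working buffers
  std::vector<double> za, zb;     // sampled+transformed+standardized expression
  std::vector<int> endi, perm;
  std::vector<double> dist;
};

struct Sampler {
  int model;      // 0 none, 1 gamma-poisson, 2 dirichlet-multinomial, 3 gaussian
  double alpha0, beta0, alpha0d;
  double n_genes; // total genes, for the dm Beta marginal
  double dm_scale;
  int resample_every;
  int transform;  // 0 identity, 1 log1p, 2 log
};

static inline double apply_transform(double v, int tr) {
  if (tr == 1) return log1p(v);
  if (tr == 2) return std::log(v > 0.0 ? v : 1e-300);
  return v;
}

static void standardize(std::vector<double> &z) {
  const int n = (int)z.size();
  double m = 0.0;
  for (int i = 0; i < n; i++) m += z[i];
  m /= n;
  double s2 = 0.0;
  for (int i = 0; i < n; i++) { double d = z[i] - m; s2 += d * d; }
  double sd = std::sqrt(s2 / std::max(1, n - 1));
  if (sd < 1e-12) {
    for (int i = 0; i < n; i++) z[i] -= m;
  } else {
    for (int i = 0; i < n; i++) z[i] = (z[i] - m) / sd;
  }
}

static void sample_expression(const std::vector<double> &x,
                              const std::vector<double> &aux,
                              const Sampler &smp, std::vector<double> &z) {
  const int n = (int)x.size();
  z.resize(n);
  switch (smp.model) {
  case 1: // Gamma-Poisson posterior: Gamma(a0 + x, rate b0 + sf)
    for (int i = 0; i < n; i++) {
      double shape = smp.alpha0 + x[i];
      double rate = smp.beta0 + aux[i];
      z[i] = apply_transform(R::rgamma(shape, 1.0 / rate), smp.transform);
    }
    break;
  case 2: // Dirichlet-Multinomial: Beta marginal of the posterior Dirichlet
    for (int i = 0; i < n; i++) {
      double a = smp.alpha0d + x[i];
      double b = smp.alpha0d * (smp.n_genes - 1.0) + (aux[i] - x[i]);
      if (b <= 0.0) b = smp.alpha0d;
      z[i] = apply_transform(R::rbeta(a, b) * smp.dm_scale, smp.transform);
    }
    break;
  case 3: // Gaussian posterior
    for (int i = 0; i < n; i++)
      z[i] = apply_transform(x[i] + aux[i] * norm_rand(), smp.transform);
    break;
  default: // none: deterministic transform of the input
    for (int i = 0; i < n; i++) z[i] = apply_transform(x[i], smp.transform);
  }
  standardize(z);
}

// k-step uniform-neighbor random walk from every node; records endpoint and
// Euclidean start->end distance.
static void sample_walks(Level &lv, int k) {
  const int n = lv.n;
  lv.endi.resize(n);
  lv.dist.resize(n);
  for (int i = 0; i < n; i++) {
    int cur = i;
    for (int s = 0; s < k; s++) {
      int deg = lv.ptr[cur + 1] - lv.ptr[cur];
      if (deg <= 0) break; // isolated nodes are repaired upstream; safety only
      int j = (int)(unif_rand() * deg);
      if (j >= deg) j = deg - 1;
      cur = lv.adj[lv.ptr[cur] + j];
    }
    lv.endi[i] = cur;
    double dx = lv.cx[i] - lv.cx[cur];
    double dy = lv.cy[i] - lv.cy[cur];
    lv.dist[i] = std::sqrt(dx * dx + dy * dy);
  }
}

// Fisher-Yates shuffle of 0..n-1 using R's RNG.
static void draw_perm(std::vector<int> &perm, int n) {
  perm.resize(n);
  for (int i = 0; i < n; i++) perm[i] = i;
  for (int i = n - 1; i > 0; i--) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(perm[i], perm[j]);
  }
}

struct Theta {
  double raw_ws, raw_wd, b, shift, log_alpha;
};

// Accumulate the summed objective and (optionally) its gradient for one level.
// Near pairs: (za_i, zb_end_i); far pairs apply one permutation to both genes.
static double level_objective(Level &lv, const Theta &th, double grad[5],
                              bool want_grad, bool positive_weights) {
  const int n = lv.n;
  const double ws = positive_weights ? softplus(th.raw_ws) : th.raw_ws;
  const double wd = positive_weights ? softplus(th.raw_wd) : th.raw_wd;
  const double dws = positive_weights ? sigmoid(th.raw_ws) : 1.0;
  const double dwd = positive_weights ? sigmoid(th.raw_wd) : 1.0;
  const double alpha = std::exp(th.log_alpha);
  double obj = 0.0;
  for (int i = 0; i < n; i++) {
    const int e = lv.endi[i];
    const double decay = std::exp(-lv.dist[i] / alpha);
    // near
    {
      const double x = lv.za[i], xp = lv.zb[e];
      const double u = x + xp + th.shift, v = x - xp;
      const double g = ws * std::fabs(u) - wd * std::fabs(v) + th.b;
      const double f = decay * g;
      obj += -softplus(-f);
      if (want_grad) {
        const double df = sigmoid(-f) * lv.weight;
        grad[0] += df * decay * std::fabs(u) * dws;
        grad[1] -= df * decay * std::fabs(v) * dwd;
        grad[2] += df * decay;
        grad[3] += df * decay * ws * sgn(u);
        grad[4] += df * (lv.dist[i] / alpha) * f;
      }
    }
    // far
    {
      const double x = lv.za[lv.perm[i]], xp = lv.zb[lv.perm[e]];
      const double u = x + xp + th.shift, v = x - xp;
      const double g = ws * std::fabs(u) - wd * std::fabs(v) + th.b;
      const double f = decay * g;
      obj += -softplus(f);
      if (want_grad) {
        const double df = -sigmoid(f) * lv.weight;
        grad[0] += df * decay * std::fabs(u) * dws;
        grad[1] -= df * decay * std::fabs(v) * dwd;
        grad[2] += df * decay;
        grad[3] += df * decay * ws * sgn(u);
        grad[4] += df * (lv.dist[i] / alpha) * f;
      }
    }
  }
  return lv.weight * obj;
}

// Train the distance-weighted classifier for one gene (or one ordered gene
// pair) by stochastic gradient ascent on the Jensen-Shannon lower bound, then
// run frozen-parameter evaluation rounds on the unbinned level.
//
// levels: list of lists with fields xa, xb, aux, adj, ptr, cx, cy, weight.
// Returns raw per-cell scores, correct/trial counts and fitted parameters.
// [[Rcpp::export(name = ".train_gene_cpp")]]
List train_gene_cpp(List levels, int walk_k, List cfg, List sampler_cfg) {
  const int n_lev = levels.size();
  std::vector<Level> lv(n_lev);
  for (int l = 0; l < n_lev; l++) {
    List L = levels[l];
    NumericVector xa = L["xa"], xb = L["xb"], aux = L["aux"];
    NumericVector cx = L["cx"], cy = L["cy"];
    IntegerVector adj = L["adj"], ptr = L["ptr"];
    lv[l].n = xa.size();
    lv[l].xa.assign(xa.begin(), xa.end());
    lv[l].xb.assign(xb.begin(), xb.end());
    lv[l].paired = as<bool>(L["paired"]);
    lv[l].aux.assign(aux.begin(), aux.end());
    lv[l].adj.assign(adj.begin(), adj.end());
    lv[l].ptr.assign(ptr.begin(), ptr.end());
    lv[l].cx.assign(cx.begin(), cx.end());
    lv[l].cy.assign(cy.begin(), cy.end());
    lv[l].weight = as<double>(L["weight"]);
  }

  const int max_iters = as<int>(cfg["max_iters"]);
  const double lr = as<double>(cfg["learning_rate"]);
  const double b1 = as<double>(cfg["beta1"]), b2 = as<double>(cfg["beta2"]);
  const double adam_eps = as<double>(cfg["adam_eps"]);
  const int window = as<int>(cfg["convergence_window"]);
  const double rtol = as<double>(cfg["convergence_rtol"]);
  const int eval_rounds = as<int>(cfg["eval_rounds"]);
  const bool early_stop = as<bool>(cfg["early_stop"]);
  const bool positive_weights = as<bool>(cfg["positive_weights"]);

  Sampler smp;
  smp.model = as<int>(sampler_cfg["model"]);
  smp.alpha0 = as<double>(sampler_cfg["alpha0"]);
  smp.beta0 = as<double>(sampler_cfg["beta0"]);
  smp.alpha0d = as<double>(sampler_cfg["alpha0d"]);
  smp.n_genes = as<double>(sampler_cfg["n_genes"]);
  smp.dm_scale = as<double>(sampler_cfg["dm_scale"]);
  smp.resample_every = as<int>(sampler_cfg["resample_every"]);
  smp.transform = as<int>(sampler_cfg["transform"]);

  RNGScope rngscope;

  // Initialization: small positive weights, decay length at the scale of an
  // observed walk-distance batch on the unbinned level.
  sample_walks(lv[0], walk_k);
  double mean_d = 0.0;
  for (int i = 0; i < lv[0].n; i++) mean_d += lv[0].dist[i];
  mean_d /= lv[0].n;
  Theta th;
  th.raw_ws = th.raw_wd =
      positive_weights ? std::log(std::exp(0.1) - 1.0) : 0.1;
  th.b = 0.0;
  th.shift = 0.0;
  th.log_alpha = std::log(mean_d > 1e-12 ? mean_d : 1.0);

  double m[5] = {0, 0, 0, 0, 0}, v[5] = {0, 0, 0, 0, 0};
  std::vector<double> trace;
  trace.reserve(max_iters);
  int iters_run = 0;

  for (int it = 1; it <= max_iters; it++) {
    double grad[5] = {0, 0, 0, 0, 0};
    double obj = 0.0;
    for (int l = 0; l < n_lev; l++) {
      if (smp.model != 0) {
        if ((it - 1) % smp.resample_every == 0) {
          sample_expression(lv[l].xa, lv[l].aux, smp, lv[l].za);
          if (lv[l].paired)
            sample_expression(lv[l].xb, lv[l].aux, smp, lv[l].zb);
        }
      } else if (it == 1) {
        sample_expression(lv[l].xa, lv[l].aux, smp, lv[l].za);
        if (lv[l].paired) sample_expression(lv[l].xb, lv[l].aux, smp, lv[l].zb);
      }
      if (!lv[l].paired) lv[l].zb = lv[l].za;
      sample_walks(lv[l], walk_k);
      draw_perm(lv[l].perm, lv[l].n);
      obj += level_objective(lv[l], th, grad, true, positive_weights);
    }
    // Adam ascent
    const double bc1 = 1.0 - std::pow(b1, it), bc2 = 1.0 - std::pow(b2, it);
    double *par = &th.raw_ws;
    for (int p = 0; p < 5; p++) {
      m[p] = b1 * m[p] + (1.0 - b1) * grad[p];
      v[p] = b2 * v[p] + (1.0 - b2) * grad[p] * grad[p];
      par[p] += lr * (m[p] / bc1) / (std::sqrt(v[p] / bc2) + adam_eps);
    }
    trace.push_back(obj);
    iters_run = it;
    if (early_stop && it >= 2 * window) {
      double cur = 0.0, prev = 0.0;
      for (int t = it - window; t < it; t++) cur += trace[t];
      for (int t = it - 2 * window; t < it - window; t++) prev += trace[t];
      cur /= window;
      prev /= window;
      if (cur - prev < rtol * std::fabs(prev)) break;
    }
  }

  // Evaluation: frozen parameters, fresh draws, unbinned level only.
  Level &ev = lv[0];
  const int n = ev.n;
  std::vector<double> cell_score(n, 0.0);
  long long correct = 0, trials = 0;
  const double ws = positive_weights ? softplus(th.raw_ws) : th.raw_ws;
  const double wd = positive_weights ? softplus(th.raw_wd) : th.raw_wd;
  const double alpha = std::exp(th.log_alpha);
  for (int r = 0; r < eval_rounds; r++) {
    if (smp.model != 0) {
      sample_expression(ev.xa, ev.aux, smp, ev.za);
      if (ev.paired) sample_expression(ev.xb, ev.aux, smp, ev.zb);
    }
    if (!ev.paired) ev.zb = ev.za;
    sample_walks(ev, walk_k);
    draw_perm(ev.perm, n);
    for (int i = 0; i < n; i++) {
      const int e = ev.endi[i];
      const double decay = std::exp(-ev.dist[i] / alpha);
      double x = ev.za[i], xp = ev.zb[e];
      double fn = decay * (ws * std::fabs(x + xp + th.shift) -
                           wd * std::fabs(x - xp) + th.b);
      x = ev.za[ev.perm[i]];
      xp = ev.zb[ev.perm[e]];
      double ff = decay * (ws * std::fabs(x + xp + th.shift) -
                           wd * std::fabs(x - xp) + th.b);
      cell_score[i] += log_sigmoid(fn) + log_sigmoid(-ff);
      if (fn > 0.0) correct++;
      if (ff < 0.0) correct++;
      trials += 2;
    }
  }
  for (int i = 0; i < n; i++) cell_score[i] /= eval_rounds;

  return List::create(
      _["theta"] = NumericVector::create(
          _["raw_ws"] = th.raw_ws, _["raw_wd"] = th.raw_wd, _["b"] = th.b,
          _["shift"] = th.shift, _["log_alpha"] = th.log_alpha),
      _["cell_scores"] = NumericVector(cell_score.begin(), cell_score.end()),
      _["k_correct"] = (double)correct, _["n_trials"] = (double)trials,
      _["n_iters"] = iters_run,
      _["objective"] = trace.empty() ? NA_REAL : trace.back(),
      _["init_alpha"] = mean_d);
}
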