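// No-U-Turn sampler (Hoffman & Gelman 2014, Algorithm 6) with dual-averaging
// step-size adaptation and windowed diagonal mass-matrix estimation.
// Self-contained RNG (mt19937_64) so draws are reproducible from the seed
// independently of R's RNG state.

#include "ou_model.h"
#include <random>

namespace {

struct Rng {
  std::mt19937_64 eng;
  std::normal_distribution<double> norm{0.0, 1.0};
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  explicit Rng(std::uint64_t seed) : eng(seed) {}
  double rnorm() { return norm(eng); }
  double runif() { return unif(eng); }
};

struct Point {
  arma::vec q, p, g;
  double lp;
};

struct Sampler {
  Target* tgt;
  arma::vec minv;         // inverse mass (posterior variance estimate)
  int d;
  double max_dH = 1000.0;

  double joint(const Point& pt) const {
    return pt.lp - 0.5 * arma::dot(pt.p, minv % pt.p);
  }

  void leapfrog(Point& pt, double eps) const {
    pt.p += 0.5 * eps * pt.g;
    pt.q += eps * (minv % pt.p);
    pt.g = tgt->grad(pt.q);
    pt.lp = tgt->logp(pt.q);
    pt.p += 0.5 * eps * pt.g;
  }

  bool no_uturn(const Point& minus, const Point& plus) const {
    arma::vec dq = plus.q - minus.q;
    return arma::dot(dq, minv % minus.p) >= 0.0 &&
           arma::dot(dq, minv % plus.p) >= 0.0;
  }

  struct Tree {
    Point minus, plus, prop;
    double n = 0.0, alpha = 0.0;
    int nalpha = 0;
    bool s = true, div = false;
  };

  Tree build(const Point& from, double logu, int dir, int depth, double eps,
             double joint0, Rng& rng) {
    Tree t;
    if (depth == 0) {
      Point pt = from;
      leapfrog(pt, dir * eps);
      double j = std::isfinite(pt.lp) ? joint(pt) : -arma::datum::inf;
      t.minus = t.plus = t.prop = pt;
      t.n = (logu <= j) ? 1.0 : 0.0;
      t.div = !(logu < j + max_dH);
      t.s = !t.div;
      double a = std::exp(std::min(0.0, j - joint0));
      t.alpha = std::isfinite(a) ? a : 0.0;
      t.nalpha = 1;
      return t;
    }
    Tree t1 = build(from, logu, dir, depth - 1, eps, joint0, rng);
    if (!t1.s) return t1;
    Tree t2 = build(dir == 1 ? t1.plus : t1.minus, logu, dir, depth - 1, eps,
                    joint0, rng);
    t = t1;
    if (dir == 1) t.plus = t2.plus; else t.minus = t2.minus;
    double ntot = t1.n + t2.n;
    if (ntot > 0.0 && rng.runif() < t2.n / ntot) t.prop = t2.prop;
    t.n = ntot;
    t.alpha = t1.alpha + t2.alpha;
    t.nalpha = t1.nalpha + t2.nalpha;
    t.div = t1.div || t2.div;
    t.s = t2.s && no_uturn(t.minus, t.plus);
    return t;
  }

  double find_epsilon(const Point& init, Rng& rng) {
    double eps = 0.1;
    Point pt = init;
    pt.p.set_size(d);
    for (int i = 0; i < d; ++i) pt.p[i] = rng.rnorm() / std::sqrt(minv[i]);
    double j0 = joint(pt);
    Point pt1 = pt;
    leapfrog(pt1, eps);
    double dj = std::isfinite(pt1.lp) ? joint(pt1) - j0 : -arma::datum::inf;
    double a = dj > std::log(0.5) ? 1.0 : -1.0;
    for (int it = 0; it < 50; ++it) {
      if (a * dj <= -a * std::log(2.0)) break;
      eps *= std::pow(2.0, a);
      if (eps > 1e7 || eps < 1e-10) break;
      pt1 = pt;
      leapfrog(pt1, eps);
      dj = std::isfinite(pt1.lp) ? joint(pt1) - j0 : -arma::datum::inf;
    }
    return eps;
  }
};

} // namespace

// [[Rcpp::export]]
Rcpp::List nuts_sample_cpp(SEXP model_xptr, SEXP lp_fn, SEXP grad_fn,
                           arma::vec init, int iter, int warmup,
                           double adapt_delta, int max_depth, int seed) {
  // target: built-in OU model (external pointer) or R callback functions
  class RTarget : public Target {
  public:
    Rcpp::Function lp, gr;
    int d;
    RTarget(Rcpp::Function l, Rcpp::Function g, int d_) : lp(l), gr(g), d(d_) {}
    double logp(const arma::vec& q) {
      double v = Rcpp::as<double>(lp(q));
      return std::isnan(v) ? -arma::datum::inf : v;
    }
    arma::vec grad(const arma::vec& q) { return Rcpp::as<arma::vec>(gr(q)); }
    int npar() const { return d; }
  };

  Target* tgt;
  std::unique_ptr<RTarget> rt;
  if (model_xptr != R_NilValue) {
    Rcpp::XPtr<OUModel> xp(model_xptr);
    tgt = xp.get();
  } else {
    rt.reset(new RTarget(Rcpp::Function(lp_fn), Rcpp::Function(grad_fn),
                         init.n_elem));
    tgt = rt.get();
  }

  const int d = init.n_elem;
  Sampler smp;
  smp.tgt = tgt;
  smp.d = d;
  smp.minv = arma::vec(d, arma::fill::ones);
  Rng rng(static_cast<std::uint64_t>(seed) * 2862933555777941757ULL + 3037000493ULL);

  Point cur;
  cur.q = init;
  cur.g = tgt->grad(init);
  cur.lp = tgt->logp(init);
  if (!std::isfinite(cur.lp))
    Rcpp::stop("log posterior is not finite at the initial point");

  // dual averaging state
  double eps = smp.find_epsilon(cur, rng);
  double mu = std::log(10.0 * eps), logeps = std::log(eps), logepsbar = 0.0,
         Hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int awin = 0;  // iterations since dual-averaging restart

  // mass adaptation windows
  int fast1, term, win_start, win_size;
  if (warmup >= 150) { fast1 = 75; term = 50; win_size = 25; }
  else { fast1 = std::max(5, (int)(0.15 * warmup));
         term = std::max(5, (int)(0.1 * warmup));
         win_size = std::max(10, warmup - fast1 - term); }
  win_start = fast1;
  arma::vec wsum(d, arma::fill::zeros), wsum2(d, arma::fill::zeros);
  int wn = 0;

  const int keep = iter - warmup;
  arma::mat draws(std::max(keep, 0), d);
  arma::vec lp_out(std::max(keep, 0));
  Rcpp::IntegerVector divergent(std::max(keep, 0)), treedepth(std::max(keep, 0));
  Rcpp::NumericVector accept_out(std::max(keep, 0));
  int div_warmup = 0;

  for (int m = 0; m < iter; ++m) {
    // momentum refresh
    cur.p.set_size(d);
    for (int i = 0; i < d; ++i) cur.p[i] = rng.rnorm() / std::sqrt(smp.minv[i]);
    double joint0 = smp.joint(cur);
    double logu = joint0 + std::log(rng.runif());

    Point minus = cur, plus = cur, prop = cur;
    double n = 1.0, alpha_sum = 0.0;
    int nalpha = 0, depth = 0;
    bool sflag = true, divflag = false;
    while (sflag && depth < max_depth) {
      int dir = rng.runif() < 0.5 ? -1 : 1;
      Sampler::Tree t = smp.build(dir == 1 ? plus : minus, logu, dir, depth,
                                  eps, joint0, rng);
      if (dir == 1) plus = t.plus; else minus = t.minus;
      alpha_sum += t.alpha; nalpha += t.nalpha;
      divflag = divflag || t.div;
      if (t.s && rng.runif() < t.n / std::max(n, 1.0)) prop = t.prop;
      n += t.n;
      sflag = t.s && smp.no_uturn(minus, plus);
      ++depth;
    }
    cur.q = prop.q; cur.g = prop.g; cur.lp = prop.lp;
    double astat = nalpha > 0 ? alpha_sum / nalpha : 0.0;

    if (m < warmup) {
      if (divflag) ++div_warmup;
      // dual averaging
      ++awin;
      Hbar = (1.0 - 1.0 / (awin + t0)) * Hbar + (adapt_delta - astat) / (awin + t0);
      logeps = mu - std::sqrt((double)awin) / gamma * Hbar;
      double w = std::pow((double)awin, -kappa);
      logepsbar = w * logeps + (1.0 - w) * logepsbar;
      eps = std::exp(logeps);
      // mass window accumulation
      if (m >= win_start && m < warmup - term) {
        wsum += cur.q; wsum2 += cur.q % cur.q; ++wn;
        bool win_end = (wn >= win_size && (warmup - term - m) > 10) ||
                       (m == warmup - term - 1);
        if (win_end && wn >= 10) {
          arma::vec mean = wsum / wn;
          arma::vec var = (wsum2 - wn * (mean % mean)) / (wn - 1);
          smp.minv = var * ((double)wn / (wn + 5.0)) + 1e-3 * (5.0 / (wn + 5.0));
          wsum.zeros(); wsum2.zeros(); wn = 0;
          win_size *= 2;
          // restart step-size adaptation at the new metric
          eps = smp.find_epsilon(cur, rng);
          mu = std::log(10.0 * eps);
          logeps = std::log(eps); logepsbar = 0.0; Hbar = 0.0; awin = 0;
        }
      }
      if (m == warmup - 1) eps = std::exp(logepsbar);
    } else {
      int k = m - warmup;
      draws.row(k) = cur.q.t();
      lp_out[k] = cur.lp;
      divergent[k] = divflag ? 1 : 0;
      treedepth[k] = depth;
      accept_out[k] = astat;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("draws") = draws,
    Rcpp::Named("lp") = lp_out,
    Rcpp::Named("divergent") = divergent,
    Rcpp::Named("treedepth") = treedepth,
    Rcpp::Named("accept_stat") = accept_out,
    Rcpp::Named("step_size") = eps,
    Rcpp::Named("inv_mass") = smp.minv,
    Rcpp::Named("divergent_warmup") = div_warmup);
}
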