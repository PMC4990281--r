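#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Event codes shared with the R side:
// 0 init, 1 burst, 2 stage advance, 3 duplication, 4 division, 5 decay

namespace {

int pick_branch(const NumericVector& probs) {
  double u = unif_rand(), acc = 0.0;
  for (int i = 0; i < probs.size(); ++i) {
    acc += probs[i];
    if (u <= acc) return i;
  }
  return probs.size() - 1;
}

// discrete daughter allotment: mean x/2, variance alpha*x/4
double partition_discrete(double xd, double alpha) {
  long x = (long)(xd + 0.5);
  if (x <= 0) return 0.0;
  if (alpha <= 0.0) {
    long h = x / 2;
    if (x % 2 == 1 && unif_rand() < 0.5) ++h;
    return (double)h;
  }
  if (alpha <= 1.0) {
    if (unif_rand() < alpha) return R::rbinom((double)x, 0.5);
    long h = x / 2;
    if (x % 2 == 1 && unif_rand() < 0.5) ++h;
    return (double)h;
  }
  // over-dispersed: beta-binomial with intra-class rho = (alpha-1)/(x-1);
  // needs x >= 2 and alpha < x, otherwise fall back to binomial
  if (x < 2 || alpha >= (double)x) return R::rbinom((double)x, 0.5);
  double a = ((double)x - alpha) / (2.0 * (alpha - 1.0));
  double p = R::rbeta(a, a);
  return R::rbinom((double)x, p);
}

// continuous daughter allotment for the hybrid models
double partition_continuous(double x, double alpha, int constant_law) {
  if (x <= 0.0) return 0.0;
  if (constant_law) {
    // truncated normal, mean x/2, variance alpha
    if (alpha <= 0.0) return x / 2.0;
    double sd = std::sqrt(alpha), d;
    do { d = R::rnorm(x / 2.0, sd); } while (d < 0.0 || d > x);
    return d;
  }
  if (alpha <= 0.0) return x / 2.0;
  // gamma with mean x/2, variance alpha*x/4 (positively valued); truncated
  // to the mother level x (negligible mass there when x >> alpha)
  double d;
  do { d = R::rgamma(x / alpha, alpha / 2.0); } while (d > x);
  return d;
}

double draw_burst(int family, double bmean, double bpoint) {
  switch (family) {
  case 0: // geometric on {0,1,...} with mean bmean
    return R::rgeom(1.0 / (1.0 + bmean));
  case 1: // shifted geometric on {1,2,...} with mean bmean
    return 1.0 + R::rgeom(1.0 / bmean);
  default: // point mass
    return bpoint;
  }
}

struct TraceBuf {
  std::vector<double> t, x, phase, branch, step, event;
  void push(double tt, double xx, int ph, int br, int st, int ev) {
    t.push_back(tt); x.push_back(xx); phase.push_back(ph);
    branch.push_back(br); step.push_back(st); event.push_back(ev);
  }
};

} // namespace

// Event-driven exact simulation of a single-cell lineage.
// mode: 0 full (discrete bursts + noisy partitioning),
//       1 hybrid B (deterministic production, exact halving),
//       2 hybrid C (deterministic production, noisy partitioning)
// [[Rcpp::export]]
List sim_lineage_cpp(IntegerVector orders1, NumericVector probs1, double k1,
                     IntegerVector orders2, NumericVector probs2, double k2,
                     double f, double kx, double burst_mean,
                     int burst_family, double burst_point,
                     double alpha, int constant_law, int mode,
                     double gamma_x, int n_cycles, double x0) {
  const bool has_dup = orders2.size() > 0;
  const bool discrete = (mode == 0);
  TraceBuf tr;
  const R_xlen_t max_events = 200000000;

  double t = 0.0, x = x0;
  int phase = 1;
  int bi = pick_branch(probs1);
  int ord = orders1[bi], step = 1;
  double kc = k1;
  tr.push(t, x, phase, ord, step, 0);

  int cycles = 0;
  while (cycles < n_cycles) {
    if ((R_xlen_t)tr.t.size() > max_events)
      stop("event budget exceeded; reduce n_cycles or rates");
    double mult = (phase == 2) ? f : 1.0;
    double r_stage = ord * kc;
    double slope = discrete ? 0.0 : kx * mult * burst_mean;
    double dt; int ev;
    if (discrete) {
      double r_burst = kx * mult;
      double r_decay = gamma_x * x;
      double total = r_stage + r_burst + r_decay;
      dt = R::rexp(1.0 / total);
      double u = unif_rand() * total;
      ev = (u < r_burst) ? 1 : (u < r_burst + r_stage ? 2 : 5);
    } else {
      dt = R::rexp(1.0 / r_stage);
      ev = 2;
    }
    t += dt;
    x += slope * dt; // hybrid accumulation (0 in the full model)

    if (ev == 1) {        // burst
      x += draw_burst(burst_family, burst_mean, burst_point);
      tr.push(t, x, phase, ord, step, 1);
    } else if (ev == 5) { // decay of one molecule
      x -= 1.0;
      if (x < 0.0) x = 0.0;
      tr.push(t, x, phase, ord, step, 5);
    } else {              // stage advance
      if (step < ord) {
        ++step;
        tr.push(t, x, phase, ord, step, 2);
      } else if (phase == 1 && has_dup) {
        phase = 2; kc = k2;
        bi = pick_branch(probs2);
        ord = orders2[bi]; step = 1;
        tr.push(t, x, phase, ord, step, 3);
      } else {            // division
        if (mode == 0) x = partition_discrete(x, alpha);
        else if (mode == 1) x = x / 2.0;
        else x = partition_continuous(x, alpha, constant_law);
        phase = 1; kc = k1;
        bi = pick_branch(probs1);
        ord = orders1[bi]; step = 1;
        ++cycles;
        tr.push(t, x, phase, ord, step, 4);
      }
    }
  }
  return List::create(
    _["t"] = wrap(tr.t), _["x"] = wrap(tr.x),
    _["phase"] = wrap(tr.phase), _["branch"] = wrap(tr.branch),
    _["step"] = wrap(tr.step), _["event"] = wrap(tr.event));
}
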