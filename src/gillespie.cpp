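// Exact (direct-method) stochastic simulation of the bursty delayed
// negative-feedback her1/her7 clock. Mirrors the reference R
// implementation in R/sim_params.R; compiled because a single cell sees
// O(1e5-1e6) reaction events per run.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Params {
  double km, alpha, Bmax, pdcrit;
  int n_delay, hill_n;
  double tau_m, tau_p, kp1, kp7;
  double gm1, gm7, gp1, gp7, gp17;
  double kb, ku;
  bool shared_burst, deg_int;
};

Params unpack(const List& p) {
  Params q;
  q.km = p["km"]; q.alpha = p["alpha"]; q.Bmax = p["Bmax"];
  q.pdcrit = p["pdcrit"]; q.n_delay = p["n_delay"]; q.hill_n = p["hill_n"];
  q.tau_m = p["tau_m"]; q.tau_p = p["tau_p"];
  q.kp1 = p["kp1"]; q.kp7 = p["kp7"];
  q.gm1 = p["gamma_m1"]; q.gm7 = p["gamma_m7"];
  q.gp1 = p["gamma_p1"]; q.gp7 = p["gamma_p7"]; q.gp17 = p["gamma_p17"];
  q.kb = p["kb"]; q.ku = p["ku"];
  q.shared_burst = p["shared_burst_size"]; q.deg_int = p["degrade_intermediates"];
  return q;
}

int draw_burst(double mean_b) {
  if (mean_b <= 0.0) return 0;
  if (mean_b < 1.0) return (unif_rand() < mean_b) ? 1 : 0;
  return 1 + (int) R::rgeom(1.0 / mean_b);
}

// pick index i in [0, n) with weight w[i] from residual r (sum(w) > r >= 0)
int pick(const std::vector<int>& w, double rate, double& r) {
  for (size_t i = 0; i < w.size(); ++i) {
    double a = rate * w[i];
    if (r < a) return (int) i;
    r -= a;
  }
  return (int) w.size() - 1;  // numerical guard
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix sim_cell_cpp(List params) {
  Params p = unpack(params);
  double T0 = params["T0"], Tmax = params["Tmax"], dt = params["dt_obs"];
  const int n = p.n_delay;
  const double rate_m = p.tau_m > 0 ? n / p.tau_m : 0.0;
  const double rate_p = p.tau_p > 0 ? n / p.tau_p : 0.0;

  std::vector<int> m1c(n, 0), m7c(n, 0), p1c(n, 0), p7c(n, 0);
  long m1n = 0, m7n = 0, p1 = 0, p7 = 0, p17 = 0;
  long Sm1 = 0, Sm7 = 0, Sp1 = 0, Sp7 = 0;  // chain totals

  const int n_obs = (int) std::floor((Tmax - T0) / dt + 1e-9) + 1;
  NumericMatrix out(n_obs, 6);
  colnames(out) = CharacterVector::create("time", "m1n", "m7n",
                                          "p1", "p7", "p17");
  int obs = 0;
  double next_obs = T0;
  double t = 0.0;

  RNGScope scope;
  while (obs < n_obs) {
    double hill = 1.0 / (1.0 + std::pow((double) p17 / p.pdcrit, p.hill_n));
    double mean_b = p.Bmax * hill;

    double a_burst = p.km;  // km(1-alpha) + km(1-alpha) + km*alpha pieces below
    double a_m = rate_m * (Sm1 + Sm7);
    double a_tr = p.kp1 * m1n + p.kp7 * m7n;
    double a_pc = rate_p * (Sp1 + Sp7);
    double a_deg = p.gm1 * m1n + p.gm7 * m7n + p.gp1 * p1 + p.gp7 * p7 +
                   p.gp17 * p17;
    double a_dim = p.kb * (double) p1 * (double) p7 + p.ku * p17;
    double a_int = 0.0;
    if (p.deg_int)
      a_int = p.gm1 * Sm1 + p.gm7 * Sm7 + p.gp1 * Sp1 + p.gp7 * Sp7;
    // burst1 + burst7 + burst17 = km(1-a) + km(1-a) + km a = km(2-a)
    a_burst = p.km * (2.0 - p.alpha);
    double total = a_burst + a_m + a_tr + a_pc + a_deg + a_dim + a_int;

    double t_next;
    if (total <= 0.0) {
      t_next = R_PosInf;  // absorbing: only record remaining observations
    } else {
      t_next = t + exp_rand() / total;
    }

    while (obs < n_obs && next_obs <= t_next) {
      out(obs, 0) = next_obs;
      out(obs, 1) = m1n; out(obs, 2) = m7n;
      out(obs, 3) = p1; out(obs, 4) = p7; out(obs, 5) = p17;
      ++obs;
      next_obs += dt;
    }
    if (obs >= n_obs || !R_FINITE(t_next)) break;
    t = t_next;

    double r = unif_rand() * total;
    if (r < a_burst) {
      double a1 = p.km * (1.0 - p.alpha);
      auto push = [&](std::vector<int>& chain, long& mature, long& S, int b) {
        if (p.tau_m > 0) { chain[0] += b; S += b; } else mature += b;
      };
      if (r < a1) push(m1c, m1n, Sm1, draw_burst(mean_b));
      else if (r < 2 * a1) push(m7c, m7n, Sm7, draw_burst(mean_b));
      else {
        int b1 = draw_burst(mean_b);
        int b7 = p.shared_burst ? b1 : draw_burst(mean_b);
        push(m1c, m1n, Sm1, b1);
        push(m7c, m7n, Sm7, b7);
      }
    } else if (r < a_burst + a_m) {
      r -= a_burst;
      auto step = [&](std::vector<int>& chain, long& mature, long& S) {
        int i = pick(chain, rate_m, r);
        chain[i]--;
        if (i + 1 < n) chain[i + 1]++;
        else { mature++; S--; }
      };
      if (r < rate_m * Sm1) step(m1c, m1n, Sm1);
      else { r -= rate_m * Sm1; step(m7c, m7n, Sm7); }
    } else if (r < a_burst + a_m + a_tr) {
      r -= a_burst + a_m;
      auto feed = [&](std::vector<int>& chain, long& mono, long& S) {
        if (p.tau_p > 0) { chain[0]++; S++; } else mono++;
      };
      if (r < p.kp1 * m1n) feed(p1c, p1, Sp1);
      else feed(p7c, p7, Sp7);
    } else if (r < a_burst + a_m + a_tr + a_pc) {
      r -= a_burst + a_m + a_tr;
      auto step = [&](std::vector<int>& chain, long& mono, long& S) {
        int i = pick(chain, rate_p, r);
        chain[i]--;
        if (i + 1 < n) chain[i + 1]++;
        else { mono++; S--; }
      };
      if (r < rate_p * Sp1) step(p1c, p1, Sp1);
      else { r -= rate_p * Sp1; step(p7c, p7, Sp7); }
    } else if (r < a_burst + a_m + a_tr + a_pc + a_deg) {
      r -= a_burst + a_m + a_tr + a_pc;
      if (r < p.gm1 * m1n) m1n--;
      else if (r < p.gm1 * m1n + p.gm7 * m7n) m7n--;
      else if (r < p.gm1 * m1n + p.gm7 * m7n + p.gp1 * p1) p1--;
      else if (r < p.gm1 * m1n + p.gm7 * m7n + p.gp1 * p1 + p.gp7 * p7) p7--;
      else p17--;
    } else if (r < a_burst + a_m + a_tr + a_pc + a_deg + a_dim) {
      r -= a_burst + a_m + a_tr + a_pc + a_deg;
      if (r < p.kb * (double) p1 * (double) p7) { p1--; p7--; p17++; }
      else { p17--; p1++; p7++; }
    } else {
      r -= a_burst + a_m + a_tr + a_pc + a_deg + a_dim;
      auto degi = [&](std::vector<int>& chain, double g, long& S) {
        int i = pick(chain, g, r);
        chain[i]--; S--;
      };
      if (r < p.gm1 * Sm1) degi(m1c, p.gm1, Sm1);
      else if ((r -= p.gm1 * Sm1) < p.gm7 * Sm7) degi(m7c, p.gm7, Sm7);
      else if ((r -= p.gm7 * Sm7) < p.gp1 * Sp1) degi(p1c, p.gp1, Sp1);
      else { r -= p.gp1 * Sp1; degi(p7c, p.gp7, Sp7); }
    }
  }
  return out;
}
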