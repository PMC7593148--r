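// Individual-based engine for the circadian resource-competition model.
// All stochastic draws of a trial consume a single xorshift-free mt19937_64
// stream through the transforms below, so a (config, seed) pair fixes every
// trajectory byte-for-byte regardless of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

constexpr double kDeg2Rad = M_PI / 180.0;

struct TrialRng {
  std::mt19937_64 gen;
  explicit TrialRng(uint64_t seed) : gen(seed) {}
  // uniform double in [0, 1)
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int unif_int(int n) {
    int v = static_cast<int>(unif() * n);
    return v >= n ? n - 1 : v;
  }
  // Poisson via Knuth's product method (step means are ~1, so this is fast)
  int pois(double mean) {
    if (mean <= 0.0) return 0;
    double l = std::exp(-mean), p = 1.0;
    int k = 0;
    do {
      ++k;
      p *= unif();
    } while (p > l);
    return k - 1;
  }
  // standard normal via polar Marsaglia (no cached spare: keeps the draw
  // count per event deterministic and easy to document)
  double norm() {
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    return u * std::sqrt(-2.0 * std::log(s) / s);
  }
  template <typename T> void shuffle(std::vector<T>& x) {
    for (int i = static_cast<int>(x.size()) - 1; i > 0; --i) {
      int j = unif_int(i + 1);
      std::swap(x[i], x[j]);
    }
  }
};

inline double wrap_deg(double x) {
  double r = x - 360.0 * std::floor(x / 360.0);
  return r >= 360.0 ? r - 360.0 : r;
}

inline double circ_dist(double a, double b) {
  double d = std::fabs(wrap_deg(a) - wrap_deg(b));
  return d > 180.0 ? 360.0 - d : d;
}

inline double window_overlap(double p1, double p2, double width) {
  double d = circ_dist(p1, p2);
  return d >= width ? 0.0 : (width - d) / width;
}

// Closed form of the movement integral (degrees in, moves out):
// m = (M/360) * [(t1 - t0) + A * (180/pi) * (sin(t1 - phi) - sin(t0 - phi))]
inline double expected_moves_cpp(double amp, double phase, double t0,
                                 double t1, double m_total) {
  return (m_total / 360.0) *
         ((t1 - t0) + amp * (180.0 / M_PI) *
                          (std::sin((t1 - phase) * kDeg2Rad) -
                           std::sin((t0 - phase) * kDeg2Rad)));
}

// floor with carry; the 1e-9 snap guards exact-integer totals against
// losing a whole move to the last ulp of the float accumulation
inline int realize_moves_cpp(double expected, double& credit) {
  double tot = credit + expected;
  int moves = static_cast<int>(std::floor(tot + 1e-9));
  if (moves < 0) moves = 0;
  credit = tot - moves;
  if (credit < 0.0) credit = 0.0;
  return moves;
}

// circular mean of two angles with random-parent tie-break on antipodes
inline double circ_mean2(double p1, double p2, TrialRng& rng) {
  double c = std::cos(p1 * kDeg2Rad) + std::cos(p2 * kDeg2Rad);
  double s = std::sin(p1 * kDeg2Rad) + std::sin(p2 * kDeg2Rad);
  if (std::sqrt(c * c + s * s) < 1e-9) {
    return rng.unif() < 0.5 ? wrap_deg(p1) : wrap_deg(p2);
  }
  return wrap_deg(std::atan2(s, c) / kDeg2Rad);
}

struct Org {
  int sp;
  double amp, phase, energy, credit;
  int age, space;
};

struct SpeciesPars {
  int n0;
  double amp0, phase0, init_phase_sd, amp_sd, phase_sd_frac, S, k;
};

// ---- 2-means on the rows of the mating-window overlap matrix -------------

struct KmResult {
  std::vector<int> cl;  // 0/1 per point
  double wcss;
  bool ok;
};

KmResult lloyd_once(const std::vector<double>& M, int n, TrialRng& rng,
                    int iter_max, double tol) {
  KmResult res;
  res.cl.assign(n, 0);
  res.ok = false;
  // init: two distinct random rows as centroids
  int i1 = rng.unif_int(n);
  int i2 = rng.unif_int(n - 1);
  if (i2 >= i1) ++i2;
  std::vector<double> c1(M.begin() + (size_t)i1 * n, M.begin() + (size_t)(i1 + 1) * n);
  std::vector<double> c2(M.begin() + (size_t)i2 * n, M.begin() + (size_t)(i2 + 1) * n);
  std::vector<double> n1(n), n2(n), diff(n);
  std::vector<int> prev(n, -1);
  for (int it = 0; it < iter_max; ++it) {
    int cnt1 = 0, cnt2 = 0;
    std::fill(n1.begin(), n1.end(), 0.0);
    std::fill(n2.begin(), n2.end(), 0.0);
    // nearest-centroid assignment in hyperplane form:
    // d1 < d2  <=>  row . (c2 - c1) < (|c2|^2 - |c1|^2) / 2
    double q1 = 0.0, q2 = 0.0;
    for (int j = 0; j < n; ++j) {
      diff[j] = c2[j] - c1[j];
      q1 += c1[j] * c1[j];
      q2 += c2[j] * c2[j];
    }
    const double thresh = 0.5 * (q2 - q1);
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      const double* row = &M[(size_t)i * n];
      double proj = 0.0;
      for (int j = 0; j < n; ++j) proj += row[j] * diff[j];
      int cl = (proj > thresh) ? 1 : 0;  // strictly closer to c2
      if (cl != prev[i]) changed = true;
      prev[i] = cl;
      res.cl[i] = cl;
      if (cl == 1) {
        ++cnt2;
        for (int j = 0; j < n; ++j) n2[j] += row[j];
      } else {
        ++cnt1;
        for (int j = 0; j < n; ++j) n1[j] += row[j];
      }
    }
    if (cnt1 == 0 || cnt2 == 0) {
      // move the point farthest from the surviving centroid into the
      // empty cluster (keeps CGM defined for degenerate all-equal inputs)
      const std::vector<double>& cs = (cnt1 == 0) ? c2 : c1;
      int far = 0;
      double dmax = -1.0;
      for (int i = 0; i < n; ++i) {
        const double* row = &M[(size_t)i * n];
        double d = 0.0;
        for (int j = 0; j < n; ++j) {
          double a = row[j] - cs[j];
          d += a * a;
        }
        if (d > dmax) { dmax = d; far = i; }
      }
      int empty = (cnt1 == 0) ? 0 : 1;
      int full = 1 - empty;
      std::vector<double>& nf = (full == 0) ? n1 : n2;
      std::vector<double>& ne = (empty == 0) ? n1 : n2;
      const double* row = &M[(size_t)far * n];
      for (int j = 0; j < n; ++j) { nf[j] -= row[j]; ne[j] += row[j]; }
      res.cl[far] = empty;
      prev[far] = empty;
      changed = true;
      if (empty == 0) { cnt1 = 1; cnt2 = n - 1; } else { cnt2 = 1; cnt1 = n - 1; }
    }
    if (!changed && it > 0) break;
    double shift = 0.0;
    for (int j = 0; j < n; ++j) {
      double a = n1[j] / cnt1 - c1[j];
      double b = n2[j] / cnt2 - c2[j];
      shift += a * a + b * b;
      c1[j] = n1[j] / cnt1;
      c2[j] = n2[j] / cnt2;
    }
    if (shift < tol * tol) break;
  }
  res.wcss = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* row = &M[(size_t)i * n];
    const std::vector<double>& cc = (res.cl[i] == 0) ? c1 : c2;
    for (int j = 0; j < n; ++j) {
      double a = row[j] - cc[j];
      res.wcss += a * a;
    }
  }
  res.ok = true;
  return res;
}

void build_overlap(const std::vector<double>& phases, double width,
                   std::vector<double>& M) {
  int n = static_cast<int>(phases.size());
  M.assign((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    M[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double o = window_overlap(phases[i], phases[j], width);
      M[(size_t)i * n + j] = o;
      M[(size_t)j * n + i] = o;
    }
  }
}

double cgm_core(const std::vector<double>& phases, double width,
                TrialRng& rng, int nstart, int iter_max, double tol) {
  int n = static_cast<int>(phases.size());
  if (n < 2) return NA_REAL;
  std::vector<double> M;
  build_overlap(phases, width, M);
  KmResult best;
  best.ok = false;
  best.wcss = R_PosInf;
  for (int s = 0; s < nstart; ++s) {
    KmResult r = lloyd_once(M, n, rng, iter_max, tol);
    if (r.ok && r.wcss < best.wcss) best = r;
  }
  if (!best.ok) return NA_REAL;
  double sum = 0.0;
  long cnt = 0;
  for (int i = 0; i < n; ++i) {
    if (best.cl[i] != 0) continue;
    for (int j = 0; j < n; ++j) {
      if (best.cl[j] == 1) {
        sum += M[(size_t)i * n + j];
        ++cnt;
      }
    }
  }
  return cnt == 0 ? NA_REAL : sum / cnt;
}

// energy-proportional pair selection; returns {i, j} or {-1, -1} on failure
// (indices into the supplied pool). Assortative: partner weight is
// energy * mating-window overlap with the first parent; if every partner
// weight is zero the first parent is redrawn, up to 10 attempts in total.
std::pair<int, int> select_pair_core(const std::vector<double>& energy,
                                     const std::vector<double>& phase,
                                     const std::vector<int>& pool,
                                     bool assortative, double width,
                                     TrialRng& rng) {
  int m = static_cast<int>(pool.size());
  if (m < 2) return {-1, -1};
  double tot = 0.0;
  for (int i : pool) tot += energy[i];
  if (tot <= 0.0) return {-1, -1};
  int attempts = assortative ? 10 : 1;
  for (int a = 0; a < attempts; ++a) {
    // first parent ~ energy
    double u = rng.unif() * tot;
    int p1 = pool[m - 1];
    double acc = 0.0;
    for (int i : pool) {
      acc += energy[i];
      if (u < acc) { p1 = i; break; }
    }
    double wtot = 0.0;
    for (int i : pool) {
      if (i == p1) continue;
      double w = energy[i];
      if (assortative) w *= window_overlap(phase[p1], phase[i], width);
      wtot += w;
    }
    if (wtot <= 0.0) {
      if (!assortative) return {-1, -1};
      continue;  // retry with a fresh first parent
    }
    double u2 = rng.unif() * wtot;
    double acc2 = 0.0;
    int p2 = -1;
    for (int i : pool) {
      if (i == p1) continue;
      double w = energy[i];
      if (assortative) w *= window_overlap(phase[p1], phase[i], width);
      acc2 += w;
      if (u2 < acc2) { p2 = i; break; }
    }
    if (p2 < 0) {  // numeric edge: take last eligible
      for (int k = m - 1; k >= 0; --k) {
        int i = pool[k];
        if (i != p1 &&
            (!assortative || window_overlap(phase[p1], phase[i], width) > 0) &&
            energy[i] > 0) { p2 = i; break; }
      }
    }
    if (p2 >= 0) return {p1, p2};
  }
  return {-1, -1};
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_overlap_matrix(NumericVector phases, double width) {
  int n = phases.size();
  std::vector<double> ph(phases.begin(), phases.end());
  std::vector<double> M;
  build_overlap(ph, width, M);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = M[(size_t)i * n + j];
  return out;
}

// [[Rcpp::export]]
double cpp_cgm(NumericVector phases, double width, int seed, int nstart,
               int iter_max, double tol) {
  std::vector<double> ph(phases.begin(), phases.end());
  TrialRng rng(static_cast<uint64_t>(seed));
  return cgm_core(ph, width, rng, nstart, iter_max, tol);
}

// [[Rcpp::export]]
IntegerMatrix cpp_select_pairs(NumericVector energy, NumericVector phase,
                               bool assortative, double width, int n_pairs,
                               int seed) {
  std::vector<double> e(energy.begin(), energy.end());
  std::vector<double> p(phase.begin(), phase.end());
  std::vector<int> pool(e.size());
  for (size_t i = 0; i < e.size(); ++i) pool[i] = static_cast<int>(i);
  TrialRng rng(static_cast<uint64_t>(seed));
  IntegerMatrix out(n_pairs, 2);
  for (int k = 0; k < n_pairs; ++k) {
    auto pr = select_pair_core(e, p, pool, assortative, width, rng);
    if (pr.first < 0) {
      out(k, 0) = NA_INTEGER;
      out(k, 1) = NA_INTEGER;
    } else {
      out(k, 0) = pr.first + 1;
      out(k, 1) = pr.second + 1;
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_jump_samples(int from, int n_spaces, int n, int seed) {
  TrialRng rng(static_cast<uint64_t>(seed));
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    int ns = rng.unif_int(n_spaces - 1);
    if (ns >= from) ++ns;  // destination excludes the current space
    out[k] = ns;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_trial(List cfg, int seed) {
  // ---- unpack configuration ----
  const int n_spaces = as<int>(cfg["n_spaces"]);
  const int res_per_day = as<int>(cfg["resources_per_day"]);
  const int steps_per_day = as<int>(cfg["steps_per_day"]);
  const double m_total = as<double>(cfg["m_total"]);
  const double daily_cost = as<double>(cfg["daily_cost"]);
  const double e_orig = as<double>(cfg["e_orig"]);
  const int max_age = as<int>(cfg["max_age"]);
  const double r = as<double>(cfg["r"]);
  const double width = as<double>(cfg["window_width"]);
  const bool assortative = as<bool>(cfg["assortative"]);
  const bool stabilize = as<bool>(cfg["stabilize"]);
  const int horizon = as<int>(cfg["horizon_days"]);
  const double init_energy = as<double>(cfg["init_energy"]);
  const bool record_cgm = as<bool>(cfg["record_cgm"]);
  const bool poisson_births = as<bool>(cfg["poisson_births"]);
  const int km_nstart = as<int>(cfg["km_nstart"]);
  const int km_iter_max = as<int>(cfg["km_iter_max"]);
  const double km_tol = as<double>(cfg["km_tol"]);

  List sp_list = cfg["species"];
  const int nsp = sp_list.size();
  std::vector<SpeciesPars> sp(nsp);
  for (int s = 0; s < nsp; ++s) {
    List sc = sp_list[s];
    sp[s].n0 = as<int>(sc["n0"]);
    sp[s].amp0 = as<double>(sc["amplitude"]);
    sp[s].phase0 = as<double>(sc["phase"]);
    sp[s].init_phase_sd = as<double>(sc["init_phase_sd"]);
    sp[s].amp_sd = as<double>(sc["amp_sd"]);
    sp[s].phase_sd_frac = as<double>(sc["phase_sd_frac"]);
    sp[s].S = as<double>(sc["S"]);
    sp[s].k = as<double>(sc["k"]);
  }

  TrialRng rng(static_cast<uint64_t>(seed));
  const double deg_per_step = 360.0 / steps_per_day;
  const double step_cost = daily_cost / steps_per_day;
  const int res_per_step = res_per_day / steps_per_day;

  // ---- initial population ----
  std::vector<Org> pop;
  for (int s = 0; s < nsp; ++s) {
    for (int i = 0; i < sp[s].n0; ++i) {
      Org o;
      o.sp = s;
      o.amp = sp[s].amp0;
      o.phase = sp[s].phase0;
      if (sp[s].init_phase_sd > 0)
        o.phase = wrap_deg(o.phase + rng.norm() * sp[s].init_phase_sd);
      o.energy = init_energy;
      o.credit = 0.0;
      o.age = rng.unif_int(max_age);  // uniform 0 .. max_age-1
      o.space = rng.unif_int(n_spaces);
      pop.push_back(o);
    }
  }
  std::vector<int> grid(n_spaces, 0);
  std::vector<double> birth_credit(nsp, 0.0);

  // ---- per-day records (row 0 = initial state) ----
  const int nd = horizon + 1;
  IntegerMatrix rec_pop(nd, nsp);
  NumericMatrix rec_amp(nd, nsp), rec_pmean(nd, nsp), rec_psd(nd, nsp);
  NumericVector rec_cgm(nd, NA_REAL);
  NumericMatrix rec_res(nd, steps_per_day);
  NumericVector led_gain(nd, 0.0), led_cost(nd, 0.0), led_death(nd, 0.0),
      led_energy(nd, 0.0);
  IntegerVector led_added(nd, 0), led_consumed(nd, 0), led_births(nd, 0),
      led_failures(nd, 0), led_grid(nd, 0);

  auto record_day = [&](int d) {
    std::vector<double> cs(nsp, 0.0), sn(nsp, 0.0), am(nsp, 0.0);
    std::vector<int> cnt(nsp, 0);
    double etot = 0.0;
    for (const Org& o : pop) {
      ++cnt[o.sp];
      am[o.sp] += o.amp;
      cs[o.sp] += std::cos(o.phase * kDeg2Rad);
      sn[o.sp] += std::sin(o.phase * kDeg2Rad);
      etot += o.energy;
    }
    for (int s = 0; s < nsp; ++s) {
      rec_pop(d, s) = cnt[s];
      if (cnt[s] > 0) {
        rec_amp(d, s) = am[s] / cnt[s];
        double R = std::sqrt(cs[s] * cs[s] + sn[s] * sn[s]) / cnt[s];
        rec_pmean(d, s) = wrap_deg(std::atan2(sn[s], cs[s]) / kDeg2Rad);
        double Rc = std::max(R, 1e-12);
        rec_psd(d, s) =
            cnt[s] > 1 ? std::sqrt(-2.0 * std::log(Rc)) / kDeg2Rad : 0.0;
      } else {
        rec_amp(d, s) = NA_REAL;
        rec_pmean(d, s) = NA_REAL;
        rec_psd(d, s) = NA_REAL;
      }
    }
    led_energy[d] = etot;
    int g = 0;
    for (int v : grid) g += v;
    led_grid[d] = g;
    if (record_cgm) {
      std::vector<double> ph;
      ph.reserve(pop.size());
      for (const Org& o : pop) ph.push_back(o.phase);
      rec_cgm[d] =
          cgm_core(ph, width, rng, km_nstart, km_iter_max, km_tol);
    }
  };

  record_day(0);

  std::vector<int> order, pool;
  for (int d = 1; d <= horizon; ++d) {
    for (int s_in_day = 0; s_in_day < steps_per_day; ++s_in_day) {
      const double t0 = s_in_day * deg_per_step;
      const double t1 = t0 + deg_per_step;
      const double tmid = t0 + 0.5 * deg_per_step;

      // (1) resource input, uniform over spaces
      for (int i = 0; i < res_per_step; ++i) grid[rng.unif_int(n_spaces)]++;
      led_added[d] += res_per_step;

      // (2) movement + foraging in freshly shuffled order
      int n = static_cast<int>(pop.size());
      order.resize(n);
      for (int i = 0; i < n; ++i) order[i] = i;
      rng.shuffle(order);
      for (int idx : order) {
        Org& o = pop[idx];
        double m = expected_moves_cpp(o.amp, o.phase, t0, t1, m_total);
        int moves = realize_moves_cpp(m, o.credit);
        const double sS = sp[o.sp].S;
        for (int mv = 0; mv < moves; ++mv) {
          int ns = rng.unif_int(n_spaces - 1);
          if (ns >= o.space) ++ns;
          o.space = ns;
          if (grid[ns] > 0) {
            grid[ns]--;
            led_consumed[d]++;
            double gain =
                e_orig * (1.0 + sS * std::cos((tmid - o.phase) * kDeg2Rad));
            o.energy += gain;
            led_gain[d] += gain;
          }
        }
      }

      // (3) metabolism, flat per step
      for (Org& o : pop) o.energy -= step_cost;
      led_cost[d] += step_cost * n;

      // (4) cull energy-dead
      {
        size_t w = 0;
        for (size_t i = 0; i < pop.size(); ++i) {
          if (pop[i].energy > 0.0) {
            pop[w++] = pop[i];
          } else {
            led_death[d] += pop[i].energy;
          }
        }
        pop.resize(w);
      }

      // (5) reproduction; newborns join after the step
      std::vector<int> psz(nsp, 0);
      for (const Org& o : pop) ++psz[o.sp];
      int ptot = static_cast<int>(pop.size());
      std::vector<Org> newborns;
      std::vector<double> evec(pop.size()), pvec(pop.size());
      for (size_t i = 0; i < pop.size(); ++i) {
        evec[i] = pop[i].energy;
        pvec[i] = pop[i].phase;
      }
      for (int s = 0; s < nsp; ++s) {
        if (psz[s] == 0) continue;
        double r_adj = stabilize ? r * sp[s].k * ptot / psz[s] : r;
        double n_expected = psz[s] * r_adj * deg_per_step / 360.0;
        int nb;
        if (poisson_births) {
          // matings arrive as a constant-rate random stream: the realized
          // count per step is Poisson with the expected-progeny mean
          nb = rng.pois(n_expected);
        } else {
          birth_credit[s] += n_expected;
          nb = static_cast<int>(std::floor(birth_credit[s]));
          birth_credit[s] -= nb;
        }
        if (nb == 0) continue;
        pool.clear();
        for (size_t i = 0; i < pop.size(); ++i)
          if (pop[i].sp == s) pool.push_back(static_cast<int>(i));
        for (int b = 0; b < nb; ++b) {
          for (size_t i = 0; i < pop.size(); ++i) evec[i] = pop[i].energy;
          auto pr = select_pair_core(evec, pvec, pool, assortative, width, rng);
          if (pr.first < 0) {
            led_failures[d]++;
            continue;
          }
          Org& p1 = pop[pr.first];
          Org& p2 = pop[pr.second];
          Org ch;
          ch.sp = s;
          ch.energy = (p1.energy + p2.energy) / 3.0;
          p1.energy *= 2.0 / 3.0;
          p2.energy *= 2.0 / 3.0;
          double ma = 0.5 * (p1.amp + p2.amp);
          if (sp[s].amp_sd > 0) ma += rng.norm() * sp[s].amp_sd;
          ch.amp = std::min(1.0, std::max(0.0, ma));
          double mp = circ_mean2(p1.phase, p2.phase, rng);
          if (sp[s].phase_sd_frac > 0)
            mp += rng.norm() * sp[s].phase_sd_frac * 360.0;
          ch.phase = wrap_deg(mp);
          ch.age = 0;
          ch.credit = 0.0;
          ch.space = rng.unif_int(n_spaces);
          newborns.push_back(ch);
          led_births[d]++;
        }
      }
      for (const Org& o : newborns) pop.push_back(o);

      // snapshot of total grid resources at the step boundary
      int g = 0;
      for (int v : grid) g += v;
      rec_res(d, s_in_day) = g;
    }

    // (6) day boundary: aging and age cull, then the daily record
    {
      size_t w = 0;
      for (size_t i = 0; i < pop.size(); ++i) {
        pop[i].age += 1;
        if (pop[i].age < max_age) {
          pop[w++] = pop[i];
        } else {
          led_death[d] += pop[i].energy;
        }
      }
      pop.resize(w);
    }
    record_day(d);
  }

  // final per-organism snapshot
  int nfin = static_cast<int>(pop.size());
  IntegerVector fsp(nfin), fage(nfin);
  NumericVector famp(nfin), fphase(nfin), fenergy(nfin);
  for (int i = 0; i < nfin; ++i) {
    fsp[i] = pop[i].sp + 1;
    famp[i] = pop[i].amp;
    fphase[i] = pop[i].phase;
    fenergy[i] = pop[i].energy;
    fage[i] = pop[i].age;
  }
  IntegerVector grid_out(grid.begin(), grid.end());

  return List::create(
      _["pop"] = rec_pop, _["mean_amplitude"] = rec_amp,
      _["phase_mean"] = rec_pmean, _["phase_sd"] = rec_psd,
      _["cgm"] = rec_cgm, _["resources"] = rec_res,
      _["ledger"] = List::create(
          _["energy_gained"] = led_gain, _["metabolic_cost"] = led_cost,
          _["death_energy"] = led_death, _["total_energy"] = led_energy,
          _["resources_added"] = led_added,
          _["resources_consumed"] = led_consumed,
          _["grid_total"] = led_grid, _["births"] = led_births,
          _["birth_failures"] = led_failures),
      _["snapshot"] = List::create(_["species"] = fsp, _["amplitude"] = famp,
                                   _["phase"] = fphase,
                                   _["energy"] = fenergy, _["age"] = fage),
      _["grid"] = grid_out);
}
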