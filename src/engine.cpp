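// Fixed-step kinetic Monte-Carlo engine for bidirectional replication-fork
// propagation. Fork positions are advanced on a regular time grid (default
// 0.1 min) but firing-coverage checks and fork-fork meeting points are
// resolved by exact linear back-solution within a step, so segment
// boundaries carry no systematic discretisation error.
//
// Coordinates are kilobases, 0-based, half-open [a, b); chromosome ends are
// absorbing. Each cell uses its own counter-based RNG stream derived from
// the master seed, so ensembles are reproducible regardless of R's RNG
// state and independent of n_cells ordering.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[2];
  bool has_spare;
  double spare;
  explicit Rng(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t x = seed;
    s[0] = splitmix64(x);
    s[1] = splitmix64(x);
  }
  // xoroshiro128+
  uint64_t next() {
    uint64_t s0 = s[0], s1 = s[1];
    uint64_t r = s0 + s1;
    s1 ^= s0;
    s[0] = ((s0 << 55) | (s0 >> 9)) ^ s1 ^ (s1 << 14);
    s[1] = (s1 << 36) | (s1 >> 28);
    return r;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {  // Box-Muller, cached spare
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
  // truncated normal by resampling (atom-free truncation)
  double tnorm_lb(double mean, double sd, double lb, bool strict) {
    if (sd <= 0.0) return mean;
    for (int i = 0; i < 100000; ++i) {
      double v = mean + sd * norm();
      if (strict ? (v > lb) : (v >= lb)) return v;
    }
    return std::max(mean, lb) + 1e-9;  // pathological parameters
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
};

static inline uint64_t cell_seed(uint64_t master, uint64_t i) {
  uint64_t x = master ^ (0xD1B54A32D192ED03ULL * (i + 1));
  return splitmix64(x);
}

// --------------------------------------------------------------- model ----

struct Params {
  double mu_v, sd_v, sd_t;
  double t_exp;       // observation horizon (or cap in completion mode)
  bool to_completion;
  double p_end;       // per-minute fork termination probability
  bool use_mod;
  double cap_factor, ramp_scale, speed_scale;
  bool reeval_mod;    // re-evaluate the modifier each step (default: birth only)
  double dt;
};

struct ForkRec {
  int origin;     // 0-based index into the per-chromosome origin list
  int dir;        // +1 right, -1 left
  double v_base, v_eff;
  double birth, term;   // term = NA_REAL while active at horizon
  double x_start, x_end;
};

// one edge of a replication bubble
struct Edge {
  double pos;
  bool active;
  double v;        // effective speed (kb/min), >0
  double birth;
  double death;    // p_end lifetime limit (absolute time), INF if none
  int rec;         // index into fork records, -1 for chromosome boundary
};

struct Bubble { Edge left, right; };

struct ChromResult {
  std::vector<double> seg_l, seg_r;
  std::vector<int> status;          // 0 unlicensed 1 not-yet-fired 2 active 3 passive
  std::vector<ForkRec> forks;
  double completion;                // NA_REAL if unfinished
};

// distance to the nearest approaching (active, oncoming) fork; falls back to
// the chromosome end when none exists in that direction
static double approach_distance(const std::vector<Bubble> &bubs, double x,
                                int dir, double chrom_len, double t) {
  double best = dir > 0 ? (chrom_len - x) : x;
  for (size_t b = 0; b < bubs.size(); ++b) {
    if (dir > 0) {
      const Edge &e = bubs[b].left;   // left edges move leftward (toward us)
      if (e.active && e.pos > x) best = std::min(best, e.pos - x);
    } else {
      const Edge &e = bubs[b].right;
      if (e.active && e.pos < x) best = std::min(best, x - e.pos);
    }
  }
  return best;
}

static inline double mod_factor(double D, const Params &p) {
  double f = 1.0 + (p.cap_factor - 1.0) * std::min(1.0, D / p.ramp_scale);
  return std::min(p.cap_factor, f);
}

static inline double effective_speed(double base, double D, const Params &p) {
  double v = base * p.speed_scale;
  if (p.use_mod) v = std::min(v * mod_factor(D, p), p.cap_factor * p.mu_v);
  return v;
}

// is position x replicated at exact time t (edges extrapolated from their
// last committed position at time tnow backwards/forwards)?
static bool covered_at(const std::vector<Bubble> &bubs, double x,
                       double t, double tnow) {
  for (size_t b = 0; b < bubs.size(); ++b) {
    const Edge &L = bubs[b].left, &R = bubs[b].right;
    double lp = L.pos, rp = R.pos;
    if (L.active) lp = L.pos + L.v * (tnow - t);   // left edge moves left
    if (R.active) rp = R.pos - R.v * (tnow - t);
    if (t < L.birth && t < R.birth) continue;      // bubble not yet born
    if (x >= lp && x <= rp) return true;
  }
  return false;
}

// Simulate one chromosome of one cell. Origin arrays are the per-chromosome
// slices, sorted by position.
static ChromResult simulate_chrom(double chrom_len,
                                  const std::vector<double> &x,
                                  const std::vector<int> &licensed,
                                  const std::vector<double> &t0,
                                  const std::vector<double> &vl,
                                  const std::vector<double> &vr,
                                  const std::vector<double> &lifel,
                                  const std::vector<double> &lifer,
                                  const Params &p) {
  const int n = (int)x.size();
  ChromResult res;
  res.status.assign(n, 0);
  res.completion = NA_REAL;

  std::vector<Bubble> bubs;
  std::vector<int> fired(n, 0);
  // firing order within the horizon
  std::vector<int> ord;
  for (int i = 0; i < n; ++i) {
    if (licensed[i]) res.status[i] = 1;
    if (licensed[i] && t0[i] <= p.t_exp) ord.push_back(i);
  }
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return t0[a] < t0[b] || (t0[a] == t0[b] && x[a] < x[b]); });
  size_t next_fire = 0;

  double t = 0.0;
  double last_event = 0.0;
  bool done = (chrom_len <= 0);

  while (t < p.t_exp && !done) {
    double t2 = std::min(t + p.dt, p.t_exp);

    // --- fire origins due in (t, t2]; coverage checked at the exact t0
    while (next_fire < ord.size() && t0[ord[next_fire]] <= t2) {
      int i = ord[next_fire++];
      double tf = std::max(t0[i], 0.0);
      if (covered_at(bubs, x[i], tf, t)) { res.status[i] = 3; continue; }
      fired[i] = 1;
      res.status[i] = 2;
      double Dl = approach_distance(bubs, x[i], -1, chrom_len, t);
      double Dr = approach_distance(bubs, x[i], +1, chrom_len, t);
      double vle = effective_speed(vl[i], Dl, p);
      double vre = effective_speed(vr[i], Dr, p);
      Bubble nb;
      int rl = (int)res.forks.size();
      res.forks.push_back({i, -1, vl[i], vle, tf, NA_REAL, x[i], x[i]});
      res.forks.push_back({i, +1, vr[i], vre, tf, NA_REAL, x[i], x[i]});
      nb.left  = {x[i], true, vle, tf,
                  p.p_end > 0 ? tf + lifel[i] : R_PosInf, rl};
      nb.right = {x[i], true, vre, tf,
                  p.p_end > 0 ? tf + lifer[i] : R_PosInf, rl + 1};
      // born at the origin position; the common advance loop moves the new
      // edges from their exact birth time to the step boundary
      size_t k = 0;
      while (k < bubs.size() && bubs[k].left.pos < nb.left.pos) ++k;
      bubs.insert(bubs.begin() + k, nb);
    }

    // --- advance pre-existing edges to t2 (new bubbles were born advanced)
    for (size_t b = 0; b < bubs.size(); ++b) {
      Edge *ee[2] = {&bubs[b].left, &bubs[b].right};
      for (int s = 0; s < 2; ++s) {
        Edge &e = *ee[s];
        if (!e.active) continue;
        if (e.birth >= t2) continue;
        double from = std::max(t, e.birth);
        if (from >= t2) continue;
        double tstop = t2;
        // p_end death
        if (e.death < tstop) tstop = std::max(from, e.death);
        double dirsign = (s == 0) ? -1.0 : 1.0;
        double npos = e.pos + dirsign * e.v * (tstop - from);
        // chromosome ends absorb
        if (s == 0 && npos <= 0.0) {
          double treach = from + e.pos / e.v;
          e.pos = 0.0; e.active = false;
          res.forks[e.rec].term = treach; res.forks[e.rec].x_end = 0.0;
          last_event = std::max(last_event, treach);
          continue;
        }
        if (s == 1 && npos >= chrom_len) {
          double treach = from + (chrom_len - e.pos) / e.v;
          e.pos = chrom_len; e.active = false;
          res.forks[e.rec].term = treach; res.forks[e.rec].x_end = chrom_len;
          last_event = std::max(last_event, treach);
          continue;
        }
        e.pos = npos;
        if (tstop < t2) {  // died by p_end mid-step
          e.active = false;
          res.forks[e.rec].term = tstop;
          res.forks[e.rec].x_end = npos;
          last_event = std::max(last_event, tstop);
        }
      }
    }

    // --- optional per-step modifier re-evaluation
    if (p.use_mod && p.reeval_mod) {
      for (size_t b = 0; b < bubs.size(); ++b) {
        Edge *ee[2] = {&bubs[b].left, &bubs[b].right};
        for (int s = 0; s < 2; ++s) {
          Edge &e = *ee[s];
          if (!e.active || e.rec < 0) continue;
          int dir = (s == 0) ? -1 : +1;
          double D = approach_distance(bubs, e.pos, dir, chrom_len, t2);
          e.v = effective_speed(res.forks[e.rec].v_base, D, p);
          res.forks[e.rec].v_eff = e.v;  // last applied speed
        }
      }
    }

    // --- resolve collisions left to right until no overlaps remain
    bool merged = true;
    while (merged) {
      merged = false;
      for (size_t b = 0; b + 1 < bubs.size(); ++b) {
        Edge &Rn = bubs[b].right;        // right edge of left bubble
        Edge &Ln = bubs[b + 1].left;     // left edge of right bubble
        if (Rn.pos < Ln.pos) continue;
        // exact meeting within the step, by back-solving linear motion
        double overlap = Rn.pos - Ln.pos;
        double speed_sum = (Rn.active ? Rn.v : 0.0) + (Ln.active ? Ln.v : 0.0);
        double tm, pos;
        if (speed_sum > 0.0) {
          tm = t2 - overlap / speed_sum;
          pos = Rn.active ? (Rn.pos - Rn.v * (t2 - tm)) : Rn.pos;
        } else { tm = t2; pos = Rn.pos; }  // degenerate: static-static touch
        if (Rn.active) {
          Rn.active = false;
          res.forks[Rn.rec].term = tm; res.forks[Rn.rec].x_end = pos;
        }
        if (Ln.active) {
          Ln.active = false;
          res.forks[Ln.rec].term = tm; res.forks[Ln.rec].x_end = pos;
        }
        last_event = std::max(last_event, tm);
        // merge bubble b+1 into b (shared boundary owned once)
        bubs[b].right = bubs[b + 1].right;
        bubs.erase(bubs.begin() + b + 1);
        merged = true;
        break;
      }
    }

    // completion check
    if (bubs.size() == 1 && bubs[0].left.pos <= 0.0 &&
        bubs[0].right.pos >= chrom_len) {
      done = true;
      res.completion = last_event;
    }
    t = t2;
    if (!p.to_completion && t >= p.t_exp) break;
  }

  // mark passive: licensed, unfired, covered at horizon
  for (int i = 0; i < n; ++i) {
    if (res.status[i] == 1) {  // licensed, never fired
      for (size_t b = 0; b < bubs.size(); ++b)
        if (x[i] >= bubs[b].left.pos && x[i] <= bubs[b].right.pos) {
          res.status[i] = 3; break;
        }
    }
  }
  // close out still-active forks at the horizon
  for (size_t f = 0; f < res.forks.size(); ++f)
    if (ISNA(res.forks[f].term)) {
      const ForkRec &fr = res.forks[f];
      // final position from bubble edges
      for (size_t b = 0; b < bubs.size(); ++b) {
        if (bubs[b].left.rec == (int)f) res.forks[f].x_end = bubs[b].left.pos;
        if (bubs[b].right.rec == (int)f) res.forks[f].x_end = bubs[b].right.pos;
      }
      (void)fr;
    }
  for (size_t b = 0; b < bubs.size(); ++b) {
    res.seg_l.push_back(std::max(0.0, bubs[b].left.pos));
    res.seg_r.push_back(std::min(chrom_len, bubs[b].right.pos));
  }
  return res;
}

// ------------------------------------------------------------ programs ----

struct Program {
  std::vector<int> licensed;
  std::vector<double> t0, vl, vr, lifel, lifer;
};

static Program sample_program(Rng &rng, const std::vector<double> &comp,
                              const std::vector<double> &mu_t, const Params &p) {
  int n = (int)comp.size();
  Program pr;
  pr.licensed.resize(n); pr.t0.resize(n);
  pr.vl.resize(n); pr.vr.resize(n);
  pr.lifel.resize(n); pr.lifer.resize(n);
  double rate = p.p_end > 0 ? -std::log(1.0 - p.p_end) : 0.0;
  for (int i = 0; i < n; ++i) {
    pr.licensed[i] = rng.unif() < comp[i] ? 1 : 0;
    pr.t0[i] = rng.tnorm_lb(mu_t[i], p.sd_t, 0.0, false);
    pr.vl[i] = rng.tnorm_lb(p.mu_v, p.sd_v, 0.0, true);
    pr.vr[i] = rng.tnorm_lb(p.mu_v, p.sd_v, 0.0, true);
    pr.lifel[i] = rate > 0 ? rng.expo(rate) : R_PosInf;
    pr.lifer[i] = rate > 0 ? rng.expo(rate) : R_PosInf;
  }
  return pr;
}

// slice per chromosome and run the chromosome engine
static List run_cell(const NumericVector &chrom_len,
                     const IntegerVector &ori_chrom,
                     const NumericVector &ori_x,
                     const Program &pr, const Params &p,
                     bool record_forks) {
  int nchrom = chrom_len.size();
  int n = ori_x.size();
  NumericVector segs_chrom_l, segs_chrom_r;
  std::vector<int> segs_chrom;
  IntegerVector status(n);
  double completion = 0.0;
  bool unfinished = false;
  std::vector<double> fk_or, fk_dir, fk_vb, fk_ve, fk_b, fk_t, fk_xs, fk_xe;
  std::vector<int> fk_chrom;

  for (int c = 0; c < nchrom; ++c) {
    std::vector<double> x, t0, vl, vr, ll, lr, mt;
    std::vector<int> lic, idx;
    for (int i = 0; i < n; ++i)
      if (ori_chrom[i] == c) {
        idx.push_back(i);
        x.push_back(ori_x[i]); lic.push_back(pr.licensed[i]);
        t0.push_back(pr.t0[i]); vl.push_back(pr.vl[i]); vr.push_back(pr.vr[i]);
        ll.push_back(pr.lifel[i]); lr.push_back(pr.lifer[i]);
      }
    ChromResult cr = simulate_chrom(chrom_len[c], x, lic, t0, vl, vr, ll, lr, p);
    for (size_t k = 0; k < cr.seg_l.size(); ++k) {
      segs_chrom.push_back(c);
      segs_chrom_l.push_back(cr.seg_l[k]);
      segs_chrom_r.push_back(cr.seg_r[k]);
    }
    for (size_t k = 0; k < idx.size(); ++k) status[idx[k]] = cr.status[k];
    if (ISNA(cr.completion)) unfinished = true;
    else completion = std::max(completion, cr.completion);
    if (record_forks)
      for (size_t f = 0; f < cr.forks.size(); ++f) {
        const ForkRec &fr = cr.forks[f];
        fk_chrom.push_back(c);
        fk_or.push_back(idx[fr.origin] + 1);  // 1-based global origin index
        fk_dir.push_back(fr.dir); fk_vb.push_back(fr.v_base);
        fk_ve.push_back(fr.v_eff); fk_b.push_back(fr.birth);
        fk_t.push_back(fr.term); fk_xs.push_back(fr.x_start);
        fk_xe.push_back(fr.x_end);
      }
  }
  List out = List::create(
    _["seg_chrom"] = wrap(segs_chrom),
    _["seg_start"] = segs_chrom_l,
    _["seg_end"] = segs_chrom_r,
    _["status"] = status,
    _["completion"] = unfinished ? NA_REAL : completion);
  if (record_forks)
    out["forks"] = List::create(
      _["chrom"] = wrap(fk_chrom), _["origin"] = wrap(fk_or),
      _["dir"] = wrap(fk_dir), _["v_base"] = wrap(fk_vb),
      _["v_eff"] = wrap(fk_ve), _["birth"] = wrap(fk_b),
      _["term"] = wrap(fk_t), _["x_start"] = wrap(fk_xs),
      _["x_end"] = wrap(fk_xe));
  return out;
}

static Params make_params(List par) {
  Params p;
  p.mu_v = as<double>(par["mu_v"]);
  p.sd_v = std::sqrt(as<double>(par["var_v"]));
  p.sd_t = std::sqrt(as<double>(par["var_t"]));
  p.t_exp = as<double>(par["t_exp"]);
  p.to_completion = as<bool>(par["to_completion"]);
  p.p_end = as<double>(par["p_end"]);
  p.use_mod = as<bool>(par["use_mod"]);
  p.cap_factor = as<double>(par["cap_factor"]);
  p.ramp_scale = as<double>(par["ramp_scale"]);
  p.speed_scale = as<double>(par["speed_scale"]);
  p.reeval_mod = as<bool>(par["reeval_mod"]);
  p.dt = as<double>(par["dt"]);
  return p;
}

// [[Rcpp::export(name = ".sample_program_cpp")]]
List sample_program_cpp(NumericVector competence, NumericVector mu_t,
                        List par, double seed, double cell_index) {
  Params p = make_params(par);
  Rng rng(cell_seed((uint64_t)seed, (uint64_t)cell_index));
  Program pr = sample_program(rng,
      std::vector<double>(competence.begin(), competence.end()),
      std::vector<double>(mu_t.begin(), mu_t.end()), p);
  return List::create(
    _["licensed"] = wrap(pr.licensed), _["t0"] = wrap(pr.t0),
    _["v_left"] = wrap(pr.vl), _["v_right"] = wrap(pr.vr),
    _["life_left"] = wrap(pr.lifel), _["life_right"] = wrap(pr.lifer));
}

// [[Rcpp::export(name = ".replicate_program_cpp")]]
List replicate_program_cpp(NumericVector chrom_len, IntegerVector ori_chrom,
                           NumericVector ori_x, List program, List par,
                           bool record_forks) {
  Params p = make_params(par);
  Program pr;
  IntegerVector lic = program["licensed"];
  NumericVector t0 = program["t0"], vl = program["v_left"],
                vr = program["v_right"], ll = program["life_left"],
                lr = program["life_right"];
  pr.licensed.assign(lic.begin(), lic.end());
  pr.t0.assign(t0.begin(), t0.end());
  pr.vl.assign(vl.begin(), vl.end());
  pr.vr.assign(vr.begin(), vr.end());
  pr.lifel.assign(ll.begin(), ll.end());
  pr.lifer.assign(lr.begin(), lr.end());
  return run_cell(chrom_len, ori_chrom, ori_x, pr, p, record_forks);
}

// [[Rcpp::export(name = ".simulate_population_cpp")]]
List simulate_population_cpp(NumericVector chrom_len, IntegerVector ori_chrom,
                             NumericVector ori_x, NumericVector competence,
                             NumericVector mu_t, List par, int n_cells,
                             double seed, bool record_forks) {
  Params p = make_params(par);
  std::vector<double> comp(competence.begin(), competence.end());
  std::vector<double> mt(mu_t.begin(), mu_t.end());
  List cells(n_cells);
  for (int i = 0; i < n_cells; ++i) {
    Rng rng(cell_seed((uint64_t)seed, (uint64_t)(i + 1)));
    Program pr = sample_program(rng, comp, mt, p);
    cells[i] = run_cell(chrom_len, ori_chrom, ori_x, pr, p, record_forks);
  }
  return cells;
}

// Lean evaluation path for fitting: returns pooled track lengths, per-cell
// active-origin counts, and mean effective fork speed (for modifier
// calibration), without building per-cell R structures.
// [[Rcpp::export(name = ".simulate_tracks_cpp")]]
List simulate_tracks_cpp(NumericVector chrom_len, IntegerVector ori_chrom,
                         NumericVector ori_x, NumericVector competence,
                         NumericVector mu_t, List par, int n_cells,
                         double seed) {
  Params p = make_params(par);
  std::vector<double> comp(competence.begin(), competence.end());
  std::vector<double> mt(mu_t.begin(), mu_t.end());
  int nchrom = chrom_len.size();
  int n = ori_x.size();
  std::vector<double> tracks;
  NumericVector active(n_cells);
  double ve_sum = 0.0; long ve_n = 0;
  for (int i = 0; i < n_cells; ++i) {
    Rng rng(cell_seed((uint64_t)seed, (uint64_t)(i + 1)));
    Program pr = sample_program(rng, comp, mt, p);
    int nact = 0;
    for (int c = 0; c < nchrom; ++c) {
      std::vector<double> x, t0, vl, vr, ll, lr;
      std::vector<int> lic;
      for (int j = 0; j < n; ++j)
        if (ori_chrom[j] == c) {
          x.push_back(ori_x[j]); lic.push_back(pr.licensed[j]);
          t0.push_back(pr.t0[j]); vl.push_back(pr.vl[j]); vr.push_back(pr.vr[j]);
          ll.push_back(pr.lifel[j]); lr.push_back(pr.lifer[j]);
        }
      ChromResult cr = simulate_chrom(chrom_len[c], x, lic, t0, vl, vr, ll, lr, p);
      for (size_t k = 0; k < cr.seg_l.size(); ++k) {
        double len = cr.seg_r[k] - cr.seg_l[k];
        if (len > 0) tracks.push_back(len);
      }
      for (size_t k = 0; k < cr.status.size(); ++k)
        if (cr.status[k] == 2) ++nact;
      for (size_t f = 0; f < cr.forks.size(); ++f) {
        ve_sum += cr.forks[f].v_eff; ++ve_n;
      }
    }
    active[i] = nact;
  }
  return List::create(_["tracks"] = wrap(tracks), _["active"] = active,
                      _["mean_v_eff"] = ve_n ? ve_sum / ve_n : NA_REAL);
}
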