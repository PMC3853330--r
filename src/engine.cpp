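// Core stepping engine for the Teff/Treg/virus lattice model.
//
// All randomness is drawn from R's generator (unif_rand) so that a single
// set.seed() at the R level fixes the whole trajectory: one stream, one
// virtual patient per seed.  The per-step schedule is:
//   (1) pulse injection (Teff, Treg, virus Bernoulli trials, in that order)
//   (2) one turn per agent, agents taken in a freshly shuffled order; each
//       turn = species rule (activation / attack+duplication / suppression+
//       duplication) followed by a random Von Neumann move
//   (3) myelin recovery on damaged-but-nonzero patches
//   (4) life decrement and reaping
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

enum Species { TEFF = 1, TREG = 2, VIRUS = 3 };
enum CellState { RESTING = 0, ACTIVE = 1 };

struct Pars {
  int grid_size;
  double dt_hours;
  double init_mye, eat_mye, rec_mye;
  double eff_dup, p_t;
  double treg_radius, virus_radius;
  double mean_tregs;
  int patch_density;
  int hlife;
  double pulse_prob;
  bool per_day;       // pulse trials once per simulated day vs every step
  int agents_per_pulse;
  int steps_per_day;  // round(24 / dt_hours)
};

static Pars as_pars(List p) {
  Pars q;
  q.grid_size      = as<int>(p["grid_size"]);
  q.dt_hours       = as<double>(p["dt_hours"]);
  q.init_mye       = as<double>(p["init_mye"]);
  q.eat_mye        = as<double>(p["eat_mye"]);
  q.rec_mye        = as<double>(p["rec_mye"]);
  q.eff_dup        = as<double>(p["eff_dup"]);
  q.p_t            = as<double>(p["p_t"]);
  q.treg_radius    = as<double>(p["treg_radius"]);
  q.virus_radius   = as<double>(p["virus_radius"]);
  q.mean_tregs     = as<double>(p["mean_Tregs"]);
  q.patch_density  = as<int>(p["patch_density"]);
  q.hlife          = as<int>(p["hlife"]);
  q.pulse_prob     = as<double>(p["pulse_prob"]);
  q.per_day        = as<std::string>(p["pulse_mode"]) == "per_day";
  q.agents_per_pulse = as<int>(p["agents_per_pulse"]);
  q.steps_per_day  = (int) std::lround(24.0 / q.dt_hours);
  if (q.steps_per_day < 1) q.steps_per_day = 1;
  return q;
}

// uniform integer in {0, ..., n-1}
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;  // guard against unif_rand() returning values ~1
}

// torus min-image displacement distance for a 1-d offset
static inline int wrap_abs(int d, int g) {
  int a = std::abs(d) % g;
  return std::min(a, g - a);
}

struct World {
  Pars par;
  int step;
  std::vector<double> mye;                 // row-major grid_size^2
  std::vector<int> species, state, life, row, col;
  std::vector<char> alive;
  // per-patch occupancy tallies kept incrementally
  std::vector<int> occ_all, occ_virus, occ_teff_act, occ_treg_act;

  int g() const { return par.grid_size; }
  int idx(int r, int c) const { return r * g() + c; }

  void init_grids() {
    int n = g() * g();
    occ_all.assign(n, 0); occ_virus.assign(n, 0);
    occ_teff_act.assign(n, 0); occ_treg_act.assign(n, 0);
    for (size_t i = 0; i < species.size(); ++i)
      if (alive[i]) occ_add(i, +1);
  }
  void occ_add(size_t i, int d) {
    int p = idx(row[i], col[i]);
    occ_all[p] += d;
    if (species[i] == VIRUS) occ_virus[p] += d;
    else if (state[i] == ACTIVE) {
      if (species[i] == TEFF) occ_teff_act[p] += d;
      else occ_treg_act[p] += d;
    }
  }
  void set_state(size_t i, int s) { occ_add(i, -1); state[i] = s; occ_add(i, +1); }
  void kill(size_t i) { occ_add(i, -1); alive[i] = 0; }
  void move_to(size_t i, int r, int c) { occ_add(i, -1); row[i] = r; col[i] = c; occ_add(i, +1); }

  int draw_life() { return 1 + runif_int(2 * par.hlife); }

  void spawn(int sp, int st, int lf, int r, int c) {
    species.push_back(sp); state.push_back(st); life.push_back(lf);
    row.push_back(r); col.push_back(c); alive.push_back(1);
    occ_add(species.size() - 1, +1);
  }

  // random Von Neumann neighbour of (r, c)
  void vn_neighbor(int r, int c, int &nr, int &nc) {
    static const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
    int k = runif_int(4);
    nr = (r + dr[k] + g()) % g();
    nc = (c + dc[k] + g()) % g();
  }

  void move_agent(size_t i) {
    int nr, nc;
    vn_neighbor(row[i], col[i], nr, nc);
    move_to(i, nr, nc);
  }

  // disc of integer offsets with torus Euclidean distance <= radius,
  // sorted by distance (ascending) and grouped for nearest-first scans
  struct Disc { std::vector<int> dr, dc; std::vector<double> dist; };
  Disc make_disc(double radius) const {
    Disc d;
    int R = (int)std::floor(radius);
    std::vector<std::pair<double, std::pair<int,int> > > tmp;
    for (int a = -R; a <= R; ++a)
      for (int b = -R; b <= R; ++b) {
        double dd = std::sqrt((double)(wrap_abs(a, g()) * wrap_abs(a, g()) +
                                       wrap_abs(b, g()) * wrap_abs(b, g())));
        if (dd <= radius) tmp.push_back(std::make_pair(dd, std::make_pair(a, b)));
      }
    std::stable_sort(tmp.begin(), tmp.end());
    for (size_t k = 0; k < tmp.size(); ++k) {
      d.dist.push_back(tmp[k].first);
      d.dr.push_back(tmp[k].second.first);
      d.dc.push_back(tmp[k].second.second);
    }
    return d;
  }

  int count_in_disc(const Disc &d, const std::vector<int> &occ, int r, int c) const {
    int tot = 0;
    for (size_t k = 0; k < d.dr.size(); ++k) {
      int p = idx((r + d.dr[k] + g()) % g(), (c + d.dc[k] + g()) % g());
      tot += occ[p];
    }
    return tot;
  }

  // Nearest agent matching `occ` around (r, c); ties broken uniformly among
  // all agents at the minimal distance.  Returns -1 if none in the disc.
  int nearest_in_disc(const Disc &d, const std::vector<int> &occ,
                      int sp, int st, int r, int c) {
    double best = -1.0;
    for (size_t k = 0; k < d.dr.size(); ++k) {
      if (best >= 0 && d.dist[k] > best) break;
      int p = idx((r + d.dr[k] + g()) % g(), (c + d.dc[k] + g()) % g());
      if (occ[p] > 0) best = d.dist[k];
    }
    if (best < 0) return -1;
    // collect candidate agents at distance == best
    std::vector<int> cand;
    for (size_t i = 0; i < species.size(); ++i) {
      if (!alive[i] || species[i] != sp) continue;
      if (sp != VIRUS && state[i] != st) continue;
      double dd = std::sqrt((double)(wrap_abs(row[i] - r, g()) * wrap_abs(row[i] - r, g()) +
                                     wrap_abs(col[i] - c, g()) * wrap_abs(col[i] - c, g())));
      if (std::fabs(dd - best) < 1e-9) cand.push_back((int)i);
    }
    if (cand.empty()) return -1;  // unreachable if grids are consistent
    return cand[runif_int((int)cand.size())];
  }

  double p_e(double myelin, int treg_here) const {
    double m = myelin / par.init_mye;
    return par.eff_dup * m * m * (par.mean_tregs / (treg_here + par.mean_tregs));
  }

  // Bernoulli(prob), then the density gate; one relocation-retry with a
  // freshly recomputed probability.  Returns true if a newborn was created.
  bool attempt_duplication(size_t i, double prob, const Disc &treg_disc) {
    for (int attempt = 0; attempt < 2; ++attempt) {
      if (unif_rand() >= prob) return false;
      int p = idx(row[i], col[i]);
      if (occ_all[p] < par.patch_density) {
        int nr, nc;
        vn_neighbor(row[i], col[i], nr, nc);
        spawn(species[i], ACTIVE, draw_life(), nr, nc);
        life[i] = std::max(1, life[i] / 2);
        return true;
      }
      if (attempt == 1) break;
      move_agent(i);  // relocate and retry once
      prob = (species[i] == TEFF)
        ? p_e(mye[idx(row[i], col[i])],
              count_in_disc(treg_disc, occ_treg_act, row[i], col[i]))
        : par.p_t;
    }
    return false;
  }

  // resting T cell scans for the nearest virus; on contact both convert:
  // the virus disappears, the cell activates
  bool activate_by_virus(size_t i, const Disc &virus_disc) {
    int v = nearest_in_disc(virus_disc, occ_virus, VIRUS, -1, row[i], col[i]);
    if (v < 0) return false;
    kill((size_t)v);
    set_state(i, ACTIVE);
    return true;
  }

  bool teff_attack(size_t i) {
    int p = idx(row[i], col[i]);
    if (mye[p] <= 0) return false;
    mye[p] = std::max(0.0, mye[p] - par.eat_mye);
    return true;
  }

  bool treg_suppress(size_t i, const Disc &treg_disc) {
    int t = nearest_in_disc(treg_disc, occ_teff_act, TEFF, ACTIVE, row[i], col[i]);
    if (t < 0) return false;
    int tr = row[t], tc = col[t];
    kill((size_t)t);
    move_to(i, tr, tc);
    return true;
  }

  void pulse_phase() {
    bool trial_step = par.per_day ? (step % par.steps_per_day == 0) : true;
    if (!trial_step) return;
    const int sp[3] = {TEFF, TREG, VIRUS};
    for (int s = 0; s < 3; ++s) {
      if (unif_rand() < par.pulse_prob) {
        for (int k = 0; k < par.agents_per_pulse; ++k) {
          int r = runif_int(g()), c = runif_int(g());
          spawn(sp[s], RESTING, draw_life(), r, c);
        }
      }
    }
  }

  void recover_phase() {
    int n = g() * g();
    for (int p = 0; p < n; ++p)
      if (mye[p] > 0 && mye[p] < par.init_mye)
        mye[p] = std::min(par.init_mye, mye[p] + par.rec_mye);
  }

  int reap_phase() {
    int removed = 0;
    for (size_t i = 0; i < species.size(); ++i) {
      if (!alive[i]) continue;
      if (--life[i] <= 0) { kill(i); ++removed; }
    }
    // compact the agent arrays
    size_t w = 0;
    for (size_t i = 0; i < species.size(); ++i) {
      if (!alive[i]) continue;
      if (w != i) {
        species[w] = species[i]; state[w] = state[i]; life[w] = life[i];
        row[w] = row[i]; col[w] = col[i]; alive[w] = 1;
      }
      ++w;
    }
    species.resize(w); state.resize(w); life.resize(w);
    row.resize(w); col.resize(w); alive.resize(w);
    return removed;
  }

  void one_step(const Disc &treg_disc, const Disc &virus_disc) {
    pulse_phase();
    // shuffled turn order over agents present after the pulse phase
    size_t n0 = species.size();
    std::vector<int> order(n0);
    for (size_t i = 0; i < n0; ++i) order[i] = (int)i;
    for (size_t i = n0; i > 1; --i) {
      int j = runif_int((int)i);
      std::swap(order[i - 1], order[j]);
    }
    for (size_t k = 0; k < n0; ++k) {
      size_t i = (size_t)order[k];
      if (!alive[i]) continue;  // removed earlier this step (eaten/suppressed)
      if (species[i] == TEFF && state[i] == RESTING) {
        activate_by_virus(i, virus_disc);
      } else if (species[i] == TREG && state[i] == RESTING) {
        activate_by_virus(i, virus_disc);
      } else if (species[i] == TEFF) {           // active Teff
        if (teff_attack(i)) {
          double pr = p_e(mye[idx(row[i], col[i])],
                          count_in_disc(treg_disc, occ_treg_act, row[i], col[i]));
          attempt_duplication(i, pr, treg_disc);
        }
      } else if (species[i] == TREG) {           // active Treg
        if (treg_suppress(i, treg_disc))
          attempt_duplication(i, par.p_t, treg_disc);
      }
      if (alive[i]) move_agent(i);
    }
    recover_phase();
    reap_phase();
    ++step;
  }

  void damage(double &recov, double &unrecov) const {
    recov = 0.0; unrecov = 0.0;
    int n = g() * g();
    for (int p = 0; p < n; ++p) {
      if (mye[p] <= 0) unrecov += par.init_mye;
      else recov += par.init_mye - mye[p];
    }
  }

  void counts(int out[5]) const {
    for (int k = 0; k < 5; ++k) out[k] = 0;
    for (size_t i = 0; i < species.size(); ++i) {
      if (!alive[i]) continue;
      if (species[i] == TEFF) out[state[i] == RESTING ? 0 : 1]++;
      else if (species[i] == TREG) out[state[i] == RESTING ? 2 : 3]++;
      else out[4]++;
    }
  }
};

static World world_from_list(List w) {
  World x;
  x.par = as_pars(w["params"]);
  x.step = as<int>(w["step"]);
  NumericMatrix m = w["myelin"];
  int g = x.par.grid_size;
  if (m.nrow() != g || m.ncol() != g) stop("myelin matrix does not match grid_size");
  x.mye.resize(g * g);
  for (int r = 0; r < g; ++r)
    for (int c = 0; c < g; ++c) x.mye[r * g + c] = m(r, c);
  List ag = w["agents"];
  IntegerVector sp = ag["species"], st = ag["state"], lf = ag["life"],
                rr = ag["row"], cc = ag["col"];
  int n = sp.size();
  x.species.assign(sp.begin(), sp.end());
  x.state.assign(st.begin(), st.end());
  x.life.assign(lf.begin(), lf.end());
  x.row.assign(rr.begin(), rr.end());
  x.col.assign(cc.begin(), cc.end());
  x.alive.assign(n, 1);
  for (int i = 0; i < n; ++i) {
    if (x.row[i] < 0 || x.row[i] >= g || x.col[i] < 0 || x.col[i] >= g)
      stop("agent position off-lattice");
  }
  x.init_grids();
  return x;
}

static List world_to_list(const World &x, List params_in) {
  int g = x.par.grid_size;
  NumericMatrix m(g, g);
  for (int r = 0; r < g; ++r)
    for (int c = 0; c < g; ++c) m(r, c) = x.mye[r * g + c];
  int n = 0;
  for (size_t i = 0; i < x.species.size(); ++i) if (x.alive[i]) ++n;
  IntegerVector sp(n), st(n), lf(n), rr(n), cc(n);
  int k = 0;
  for (size_t i = 0; i < x.species.size(); ++i) {
    if (!x.alive[i]) continue;
    sp[k] = x.species[i]; st[k] = x.state[i]; lf[k] = x.life[i];
    rr[k] = x.row[i]; cc[k] = x.col[i]; ++k;
  }
  List ag = List::create(_["species"] = sp, _["state"] = st, _["life"] = lf,
                         _["row"] = rr, _["col"] = cc);
  return List::create(_["params"] = params_in, _["myelin"] = m,
                      _["agents"] = ag, _["step"] = x.step);
}

// [[Rcpp::export]]
List cpp_step(List world, int nsteps = 1) {
  World x = world_from_list(world);
  World::Disc td = x.make_disc(x.par.treg_radius);
  World::Disc vd = x.make_disc(x.par.virus_radius);
  for (int s = 0; s < nsteps; ++s) x.one_step(td, vd);
  return world_to_list(x, world["params"]);
}

// Full run: steps the world `steps` times recording populations and damage
// after every step (row 0 = initial state).
// [[Rcpp::export]]
List cpp_run(List world, int steps) {
  World x = world_from_list(world);
  World::Disc td = x.make_disc(x.par.treg_radius);
  World::Disc vd = x.make_disc(x.par.virus_radius);
  NumericMatrix ts(steps + 1, 9);
  int cnt[5]; double recov, unrecov;
  for (int s = 0; s <= steps; ++s) {
    if (s > 0) x.one_step(td, vd);
    x.counts(cnt);
    x.damage(recov, unrecov);
    ts(s, 0) = x.step;
    for (int k = 0; k < 5; ++k) ts(s, k + 1) = cnt[k];
    ts(s, 6) = recov; ts(s, 7) = unrecov; ts(s, 8) = recov + unrecov;
  }
  return List::create(_["ts"] = ts, _["world"] = world_to_list(x, world["params"]));
}

// --- granular rule entry points (1-based agent index) -----------------------

static size_t check_idx(const World &x, int i) {
  if (i < 1 || (size_t)i > x.species.size()) stop("agent index out of range");
  return (size_t)(i - 1);
}

// [[Rcpp::export]]
List cpp_move_agent(List world, int i) {
  World x = world_from_list(world);
  x.move_agent(check_idx(x, i));
  return world_to_list(x, world["params"]);
}

// [[Rcpp::export]]
List cpp_activate_by_virus(List world, int i) {
  World x = world_from_list(world);
  size_t k = check_idx(x, i);
  if (x.species[k] == VIRUS || x.state[k] != RESTING)
    stop("activate_by_virus requires a resting T cell");
  World::Disc vd = x.make_disc(x.par.virus_radius);
  bool ok = x.activate_by_virus(k, vd);
  List out = world_to_list(x, world["params"]);
  out.push_back(ok, "activated");
  return out;
}

// [[Rcpp::export]]
List cpp_teff_attack(List world, int i) {
  World x = world_from_list(world);
  size_t k = check_idx(x, i);
  if (x.species[k] != TEFF || x.state[k] != ACTIVE)
    stop("teff_attack requires an active Teff");
  bool ok = x.teff_attack(k);
  List out = world_to_list(x, world["params"]);
  out.push_back(ok, "attacked");
  return out;
}

// [[Rcpp::export]]
List cpp_treg_suppress(List world, int i) {
  World x = world_from_list(world);
  size_t k = check_idx(x, i);
  if (x.species[k] != TREG || x.state[k] != ACTIVE)
    stop("treg_suppress requires an active Treg");
  World::Disc td = x.make_disc(x.par.treg_radius);
  bool ok = x.treg_suppress(k, td);
  List out = world_to_list(x, world["params"]);
  out.push_back(ok, "suppressed");
  return out;
}

// [[Rcpp::export]]
List cpp_attempt_duplication(List world, int i, double prob) {
  if (prob < 0 || prob > 1) stop("prob must lie in [0, 1]");
  World x = world_from_list(world);
  size_t k = check_idx(x, i);
  if (x.state[k] != ACTIVE || x.species[k] == VIRUS)
    stop("attempt_duplication requires an active T cell");
  World::Disc td = x.make_disc(x.par.treg_radius);
  bool ok = x.attempt_duplication(k, prob, td);
  List out = world_to_list(x, world["params"]);
  out.push_back(ok, "duplicated");
  return out;
}

// [[Rcpp::export]]
List cpp_recover_myelin(List world) {
  World x = world_from_list(world);
  double before = 0, after = 0;
  for (size_t p = 0; p < x.mye.size(); ++p) before += x.mye[p];
  x.recover_phase();
  for (size_t p = 0; p < x.mye.size(); ++p) after += x.mye[p];
  List out = world_to_list(x, world["params"]);
  out.push_back(after - before, "recovered");
  return out;
}

// [[Rcpp::export]]
List cpp_decrement_life_and_reap(List world) {
  World x = world_from_list(world);
  int removed = x.reap_phase();
  List out = world_to_list(x, world["params"]);
  out.push_back(removed, "removed");
  return out;
}

// [[Rcpp::export]]
List cpp_pulse_events(List world) {
  World x = world_from_list(world);
  size_t before = x.species.size();
  x.pulse_phase();
  IntegerVector sp, n;
  // summarise newly introduced agents by species
  int per[4] = {0, 0, 0, 0};
  for (size_t i = before; i < x.species.size(); ++i) per[x.species[i]]++;
  for (int s = 1; s <= 3; ++s)
    if (per[s] > 0) { sp.push_back(s); n.push_back(per[s]); }
  List out = world_to_list(x, world["params"]);
  out.push_back(List::create(_["species"] = sp, _["count"] = n), "events");
  return out;
}

// [[Rcpp::export]]
int cpp_count_tregs_in_radius(List world, int row, int col, double radius) {
  World x = world_from_list(world);
  int g = x.par.grid_size;
  if (row < 0 || row >= g || col < 0 || col >= g) stop("position off-lattice");
  World::Disc d = x.make_disc(radius);
  return x.count_in_disc(d, x.occ_treg_act, row, col);
}

// [[Rcpp::export]]
int cpp_draw_initial_life(int hlife) {
  if (hlife < 1) stop("hlife must be >= 1");
  return 1 + runif_int(2 * hlife);
}
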