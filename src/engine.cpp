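// Daily-loop engine for the eco-genetic stream trout simulation.
//
// All stochastic draws use R's RNG (unif_rand / norm_rand / rpois / rbinom),
// so results are a pure function of the R-side seed. The exported helpers
// (eng_select_habitat_day, eng_grow, eng_survive_natural, eng_angling_day,
// eng_redd_day, ...) run the very same routines the full run uses, which is
// what the R-level operation wrappers call.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- parameters

struct TwoPt {
  // survival/catchability curve through two (driver, value) anchors on the
  // logistic scale: f(x) = plogis(a + b x)
  double a, b;
  double eval(double x) const { return 1.0 / (1.0 + std::exp(-(a + b * x))); }
};

static TwoPt make_twopt(double x1, double p1, double x2, double p2) {
  double l1 = std::log(p1 / (1.0 - p1));
  double l2 = std::log(p2 / (1.0 - p2));
  TwoPt f;
  f.b = (l2 - l1) / (x2 - x1);
  f.a = l1 - f.b * x1;
  return f;
}

struct TraitPar {
  double mean, va, ve, vmut;
};

struct Par {
  // bioenergetics
  double lw_a, lw_b, cmax_a, cmax_b, cmax_t_opt, cmax_t_sig;
  double resp_a, resp_b, resp_c, resp_d, e_food, e_fish, k_floor;
  double horizon;
  double swim_a, swim_b, swim_c, swim_d;
  // survival curves
  TwoPt s_temp, s_vel, s_strand, s_starv, s_terr, s_pisc;
  double terr_depth_b, terr_cover_b, pisc_min_length, pisc_ref_density;
  // genetics: emergence, mat_male, mat_female, neutral
  TraitPar tr[4];
  double g_floor_frac;
  // reproduction
  double spawn_start, spawn_end, p_spawn, k_spawn;
  double spawn_temp_lo, spawn_temp_hi, spawn_max_flow;
  double fec_a, fec_b, lambda_mates;
  double egg_bg;
  TwoPt egg_lo, egg_hi;
  double egg_dewater, egg_scour_flow, egg_scour, dd_emerge, hatch_frac;
  // fishing
  double exp_rate, min_ll, max_ll, season_start, season_end;
  double release_frac, noncompliance, hooking_mortality;
  double angling_efficiency, q_max;
  TwoPt q_curve;
  double reach_length_km;
  // experiment
  bool evolution;
  int census_doy, burn_in;
};

static double getp(const NumericVector& v, const std::string& nm) {
  CharacterVector nms = v.names();
  for (int i = 0; i < v.size(); ++i) {
    if (std::string(nms[i]) == nm) return v[i];
  }
  stop("missing parameter: " + nm);
  return NA_REAL;
}

static TwoPt get_curve(const NumericVector& v, const std::string& base) {
  return make_twopt(getp(v, base + "1"), getp(v, base + "2"),
                    getp(v, base + "3"), getp(v, base + "4"));
}

static Par read_par(const NumericVector& v) {
  Par p;
  p.lw_a = getp(v, "lw_a"); p.lw_b = getp(v, "lw_b");
  p.cmax_a = getp(v, "cmax_a"); p.cmax_b = getp(v, "cmax_b");
  p.cmax_t_opt = getp(v, "cmax_t_opt"); p.cmax_t_sig = getp(v, "cmax_t_sig");
  p.resp_a = getp(v, "resp_a"); p.resp_b = getp(v, "resp_b");
  p.resp_c = getp(v, "resp_c"); p.resp_d = getp(v, "resp_d");
  p.e_food = getp(v, "e_food"); p.e_fish = getp(v, "e_fish");
  p.k_floor = getp(v, "k_floor");
  p.horizon = getp(v, "fitness_horizon");
  p.swim_a = getp(v, "swim_a"); p.swim_b = getp(v, "swim_b");
  p.swim_c = getp(v, "swim_c"); p.swim_d = getp(v, "swim_d");
  p.s_temp = get_curve(v, "surv_temp");
  p.s_vel = get_curve(v, "surv_vel");
  p.s_strand = get_curve(v, "surv_strand");
  p.s_starv = get_curve(v, "surv_starv");
  p.s_terr = get_curve(v, "surv_terr");
  p.s_pisc = get_curve(v, "surv_pisc");
  p.terr_depth_b = getp(v, "terr_depth_b");
  p.terr_cover_b = getp(v, "terr_cover_b");
  p.pisc_min_length = getp(v, "pisc_min_length");
  p.pisc_ref_density = getp(v, "pisc_ref_density");
  const char* pre[4] = {"g_em_", "g_mm_", "g_mf_", "g_nt_"};
  for (int i = 0; i < 4; ++i) {
    std::string b(pre[i]);
    p.tr[i].mean = getp(v, b + "mean");
    p.tr[i].va = getp(v, b + "va");
    p.tr[i].ve = getp(v, b + "ve");
    p.tr[i].vmut = getp(v, b + "vmut");
  }
  p.g_floor_frac = getp(v, "g_floor_frac");
  p.spawn_start = getp(v, "spawn_start_doy");
  p.spawn_end = getp(v, "spawn_end_doy");
  p.p_spawn = getp(v, "p_spawn_daily");
  p.k_spawn = getp(v, "k_spawn");
  p.spawn_temp_lo = getp(v, "spawn_temp_lo");
  p.spawn_temp_hi = getp(v, "spawn_temp_hi");
  p.spawn_max_flow = getp(v, "spawn_max_flow");
  p.fec_a = getp(v, "fecundity_a"); p.fec_b = getp(v, "fecundity_b");
  p.lambda_mates = getp(v, "lambda_mates");
  p.egg_bg = getp(v, "egg_background");
  p.egg_lo = get_curve(v, "egg_temp_lo");
  p.egg_hi = get_curve(v, "egg_temp_hi");
  p.egg_dewater = getp(v, "egg_dewater");
  p.egg_scour_flow = getp(v, "egg_scour_flow");
  p.egg_scour = getp(v, "egg_scour");
  p.dd_emerge = getp(v, "dd_emerge");
  p.hatch_frac = getp(v, "hatch_frac");
  p.exp_rate = getp(v, "exp_rate");
  p.min_ll = getp(v, "min_ll"); p.max_ll = getp(v, "max_ll");
  p.season_start = getp(v, "season_start_doy");
  p.season_end = getp(v, "season_end_doy");
  p.release_frac = getp(v, "release_frac");
  p.noncompliance = getp(v, "noncompliance");
  p.hooking_mortality = getp(v, "hooking_mortality");
  p.angling_efficiency = getp(v, "angling_efficiency");
  p.q_max = getp(v, "q_max");
  {
    double l1 = getp(v, "q_anchor1"), l2 = getp(v, "q_anchor2");
    double f1 = getp(v, "q_anchor3"), f2 = getp(v, "q_anchor4");
    p.q_curve = make_twopt(l1, f1, l2, f2);
  }
  p.reach_length_km = getp(v, "reach_length_km");
  p.evolution = getp(v, "evolution") != 0.0;
  p.census_doy = (int)getp(v, "census_doy");
  p.burn_in = (int)getp(v, "burn_in");
  return p;
}

// ------------------------------------------------------------- bioenergetics

static inline double healthy_weight(const Par& p, double len) {
  return p.lw_a * std::pow(len, p.lw_b);
}

static inline double cmax_of(const Par& p, double wt, double temp) {
  double z = (temp - p.cmax_t_opt) / p.cmax_t_sig;
  return p.cmax_a * std::pow(wt, p.cmax_b) * std::exp(-z * z);
}

static inline double respiration(const Par& p, double wt, double temp,
                                 double vel) {
  return p.resp_a * std::pow(wt, p.resp_b) * std::exp(p.resp_c * temp) *
         (1.0 + p.resp_d * vel);
}

static inline double max_swim(const Par& p, double len, double temp) {
  return (p.swim_a + p.swim_b * len) * (p.swim_c + p.swim_d * temp);
}

// weight after one day given intake, and the projected length after h days of
// growth at today's rate (length never shrinks)
static inline double daily_dw(const Par& p, double wt, double intake,
                              double temp, double vel) {
  return (intake * p.e_food - respiration(p, wt, temp, vel)) / p.e_fish;
}

static inline double projected_length(const Par& p, double len, double wt,
                                      double dw, double h) {
  double wproj = wt + h * dw;
  if (wproj <= 0) return len;
  double lproj = std::pow(wproj / p.lw_a, 1.0 / p.lw_b);
  return lproj > len ? lproj : len;
}

// ------------------------------------------------------- survival components

// temperature and starvation depend only on the fish/day; the other four also
// depend on the cell. Terrestrial risk falls with depth and cover on the
// logit scale; piscivory applies to fish shorter than half the largest trout
// and scales with piscivore density.
static inline double surv_velocity(const Par& p, double len, double temp,
                                   double vel) {
  return p.s_vel.eval(vel / max_swim(p, len, temp));
}

static inline double surv_stranding(const Par& p, double len, double depth) {
  return p.s_strand.eval(depth / (len / 100.0));
}

static inline double surv_terrestrial(const Par& p, double len, double depth,
                                      double cover) {
  double base = p.s_terr.a + p.s_terr.b * len;
  double x = base + p.terr_depth_b * depth + p.terr_cover_b * cover;
  return 1.0 / (1.0 + std::exp(-x));
}

static inline double surv_piscivory(const Par& p, double len, double max_len,
                                    double pisc_density) {
  if (len >= 0.5 * max_len) return 1.0;
  double scale = pisc_density / p.pisc_ref_density;
  if (scale > 1.0) scale = 1.0;
  double s = p.s_pisc.eval(len);
  return 1.0 - (1.0 - s) * scale;
}

struct SixSurv {
  double s[6];  // temperature, velocity, stranding, starvation, terr, pisc
  double total() const {
    return s[0] * s[1] * s[2] * s[3] * s[4] * s[5];
  }
};

static SixSurv six_survival(const Par& p, double len, double k, double temp,
                            double depth, double vel, double cover,
                            double max_len, double pisc_density) {
  SixSurv out;
  out.s[0] = p.s_temp.eval(temp);
  out.s[1] = surv_velocity(p, len, temp, vel);
  out.s[2] = surv_stranding(p, len, depth);
  out.s[3] = p.s_starv.eval(k);
  out.s[4] = surv_terrestrial(p, len, depth, cover);
  out.s[5] = surv_piscivory(p, len, max_len, pisc_density);
  return out;
}

// --------------------------------------------------------------- population

struct Pop {
  std::vector<int> id, sex, age, cell;  // sex: 0 female, 1 male
  std::vector<double> len, wt, g[4], p_em, p_mat;
  std::vector<char> alive, spawned;
  std::vector<double> intake, dw;  // per-day scratch
  int next_id = 1;

  size_t size() const { return len.size(); }

  void reserve(size_t n) {
    id.reserve(n); sex.reserve(n); age.reserve(n); cell.reserve(n);
    len.reserve(n); wt.reserve(n);
    for (int t = 0; t < 4; ++t) g[t].reserve(n);
    p_em.reserve(n); p_mat.reserve(n);
    alive.reserve(n); spawned.reserve(n);
    intake.reserve(n); dw.reserve(n);
  }

  void add(int sx, int ag, double L, double W, const double gg[4],
           double pe, double pm) {
    id.push_back(next_id++); sex.push_back(sx); age.push_back(ag);
    cell.push_back(0);
    len.push_back(L); wt.push_back(W);
    for (int t = 0; t < 4; ++t) g[t].push_back(gg[t]);
    p_em.push_back(pe); p_mat.push_back(pm);
    alive.push_back(1); spawned.push_back(0);
    intake.push_back(0); dw.push_back(0);
  }

  void compact() {
    size_t j = 0;
    for (size_t i = 0; i < size(); ++i) {
      if (!alive[i]) continue;
      if (j != i) {
        id[j] = id[i]; sex[j] = sex[i]; age[j] = age[i]; cell[j] = cell[i];
        len[j] = len[i]; wt[j] = wt[i];
        for (int t = 0; t < 4; ++t) g[t][j] = g[t][i];
        p_em[j] = p_em[i]; p_mat[j] = p_mat[i];
        alive[j] = 1; spawned[j] = spawned[i];
        intake[j] = intake[i]; dw[j] = dw[i];
      }
      ++j;
    }
    id.resize(j); sex.resize(j); age.resize(j); cell.resize(j);
    len.resize(j); wt.resize(j);
    for (int t = 0; t < 4; ++t) g[t].resize(j);
    p_em.resize(j); p_mat.resize(j);
    alive.resize(j); spawned.resize(j);
    intake.resize(j); dw.resize(j);
  }
};

// dominance order: longer first, then heavier, then lower id
static std::vector<int> dominance_order(const Pop& pop) {
  std::vector<int> idx;
  idx.reserve(pop.size());
  for (size_t i = 0; i < pop.size(); ++i) {
    if (pop.alive[i]) idx.push_back((int)i);
  }
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (pop.len[a] != pop.len[b]) return pop.len[a] > pop.len[b];
    if (pop.wt[a] != pop.wt[b]) return pop.wt[a] > pop.wt[b];
    return pop.id[a] < pop.id[b];
  });
  return idx;
}

// ------------------------------------------------------------------ genetics

static void draw_genotype(const Par& p, const double mo[4],
                          const double fa[4], bool evolution, double out[4]) {
  for (int t = 0; t < 4; ++t) {
    double mean, sd;
    if (evolution) {
      mean = 0.5 * (mo[t] + fa[t]);
      sd = std::sqrt(p.tr[t].va / 2.0 + p.tr[t].vmut);
    } else {
      mean = p.tr[t].mean;
      sd = std::sqrt(p.tr[t].va);
    }
    double v = mean + (sd > 0 ? sd * norm_rand() : 0.0);
    if (p.tr[t].mean > 0) {
      double fl = p.g_floor_frac * p.tr[t].mean;
      if (v < fl) v = fl;
    }
    out[t] = v;
  }
}

static void express(const Par& p, const double gg[4], int sex, double& pe,
                    double& pm) {
  double sde = std::sqrt(p.tr[0].ve);
  pe = gg[0] + (sde > 0 ? sde * norm_rand() : 0.0);
  double fl = p.g_floor_frac * p.tr[0].mean;
  if (pe < fl) pe = fl;
  int t = (sex == 0) ? 2 : 1;  // 1 = mat_male, 2 = mat_female
  double sdm = std::sqrt(p.tr[t].ve);
  pm = gg[t] + (sdm > 0 ? sdm * norm_rand() : 0.0);
  double flm = p.g_floor_frac * p.tr[t].mean;
  if (pm < flm) pm = flm;
}

// --------------------------------------------------------------------- redds

struct Redd {
  int cell;
  int eggs, init_eggs, deaths, emerged;
  double dd;
  double mo[4];
  std::vector<std::array<double, 4>> fathers;
};

// one day of egg mortality + development for one redd; returns hatch count
static int redd_step(const Par& p, int& eggs, double& dd, int& deaths,
                     double temp, double depth, double flow) {
  if (eggs > 0) {
    double s = p.egg_bg * p.egg_lo.eval(temp) * p.egg_hi.eval(temp);
    if (depth <= 0) s *= p.egg_dewater;
    if (flow > p.egg_scour_flow) s *= p.egg_scour;
    int survive = (int)R::rbinom((double)eggs, s);
    deaths += eggs - survive;
    eggs = survive;
  }
  dd += temp > 0 ? temp : 0.0;
  int hatch = 0;
  if (dd >= p.dd_emerge && eggs > 0) {
    hatch = (int)std::ceil(p.hatch_frac * eggs);
    if (hatch > eggs) hatch = eggs;
    eggs -= hatch;
  }
  return hatch;
}

// ------------------------------------------------------- habitat + mortality

struct CellState {
  std::vector<double> depth, vel, cover, food_cap, food_rem, area;
  int n() const { return (int)depth.size(); }
};

// habitat selection + intake for one fish; returns chosen cell, fills
// intake/dw. Maximizes h*log(surv(cell-dependent)) + log(size factor); cell-
// independent survival factors do not change the argmax.
static int choose_cell(const Par& p, const CellState& cs, double len,
                       double wt, double pmat, double temp, double& intake_out,
                       double& dw_out) {
  int best = 0;
  double best_score = -1e300;
  double best_intake = 0, best_dw = 0;
  double cmax = cmax_of(p, wt, temp);
  double msw = max_swim(p, len, temp);
  double resp_base = p.resp_a * std::pow(wt, p.resp_b) *
                     std::exp(p.resp_c * temp);
  double blen = len / 100.0;  // body length in m for the stranding driver
  double terr_base = p.s_terr.a + p.s_terr.b * len;
  // the size factor min(1, projL/pmat) is 1 in every cell once the fish is at
  // or above its threshold (projected length never shrinks), so skip it then.
  bool mature = len >= pmat;
  // log(sf) = log(projL) - log(pmat), with log(projL) from the length-weight
  // inverse on the log scale (cheaper than pow, same quantity)
  double log_len = std::log(len);
  double log_lwa_b = std::log(p.lw_a) / p.lw_b;
  double log_pmat = std::log(pmat);
  for (int c = 0; c < cs.n(); ++c) {
    double rem = cs.food_rem[c];
    double intake = rem < cmax ? rem : cmax;
    if (intake < 0) intake = 0;
    double dw = (intake * p.e_food -
                 resp_base * (1.0 + p.resp_d * cs.vel[c])) / p.e_fish;
    double s_vel = p.s_vel.eval(cs.vel[c] / msw);
    double s_str = p.s_strand.eval(cs.depth[c] / blen);
    double x_terr = terr_base + p.terr_depth_b * cs.depth[c] +
                    p.terr_cover_b * cs.cover[c];
    double s_terr = 1.0 / (1.0 + std::exp(-x_terr));
    double score = p.horizon * std::log(s_vel * s_str * s_terr);
    if (!mature) {
      double wproj = wt + p.horizon * dw;
      double log_lp;  // log projected length, floored at current length
      if (wproj <= 0) {
        log_lp = log_len;
      } else {
        log_lp = std::log(wproj) / p.lw_b - log_lwa_b;
        if (log_lp < log_len) log_lp = log_len;
      }
      double log_sf = log_lp - log_pmat;
      if (log_sf < 0) score += log_sf;  // else sf = 1
    }
    if (score > best_score) {
      best_score = score;
      best = c;
      best_intake = intake;
      best_dw = dw;
    }
  }
  intake_out = best_intake;
  dw_out = best_dw;
  return best;
}

// apply one day of growth; length grows only while weight is at or above the
// healthy weight for the current length (so length is monotone)
static void grow_fish(const Par& p, double& len, double& wt, double dw,
                      double& k_out) {
  wt += dw;
  double wh = healthy_weight(p, len);
  double wmin = p.k_floor * wh;
  if (wt < wmin) wt = wmin;
  if (wt >= wh) {
    double nl = std::pow(wt / p.lw_a, 1.0 / p.lw_b);
    if (nl > len) len = nl;
  }
  k_out = wt / healthy_weight(p, len);
}

// six sequential Bernoulli survival draws in fixed order; returns 0 if the
// fish lives, else the 1-based index of the source that failed first
static int natural_death(const Par& p, const SixSurv& s) {
  for (int j = 0; j < 6; ++j) {
    if (unif_rand() > s.s[j]) return j + 1;
  }
  return 0;
}

// catchability: two-point logistic of length scaled to q_max
static inline double catchability(const Par& p, double len) {
  return p.q_max * p.q_curve.eval(len);
}

// one day of angling for one fish; events processed sequentially and stop at
// death. Returns 0 alive, 7 harvest, 8 illegal harvest, 9 hooking.
// Counters: captures, legal captures, illegal captures, keeps, illegal keeps,
// releases, hooking deaths.
static int angle_fish(const Par& p, double len, double pressure,
                      long long counters[7]) {
  double lam = pressure * catchability(p, len);
  if (lam <= 0) return 0;
  int ncap = (int)R::rpois(lam);
  for (int e = 0; e < ncap; ++e) {
    counters[0]++;
    bool is_legal = (len >= p.min_ll && len <= p.max_ll);
    bool released;
    if (is_legal) {
      counters[1]++;
      released = unif_rand() < p.release_frac;
      if (!released) {
        counters[3]++;
        return 7;
      }
    } else {
      counters[2]++;
      bool kept = unif_rand() < p.noncompliance;
      if (kept) {
        counters[4]++;
        return 8;
      }
      released = true;
    }
    counters[5]++;
    if (unif_rand() < p.hooking_mortality) {
      counters[6]++;
      return 9;
    }
  }
  return 0;
}

// --------------------------------------------------------- exported helpers

// [[Rcpp::export]]
NumericVector eng_two_point_logistic(NumericVector x, NumericVector anchors) {
  TwoPt f = make_twopt(anchors[0], anchors[1], anchors[2], anchors[3]);
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = f.eval(x[i]);
  return out;
}

// [[Rcpp::export]]
List eng_fitness_measure(double len, double wt, double k, double pmat,
                         double depth, double vel, double cover, double food,
                         double temp, double max_len, double pisc_density,
                         NumericVector par, double horizon) {
  Par p = read_par(par);
  double cmax = cmax_of(p, wt, temp);
  double intake = food < cmax ? food : cmax;
  if (intake < 0) intake = 0;
  double dw = daily_dw(p, wt, intake, temp, vel);
  double lp = projected_length(p, len, wt, dw, horizon);
  SixSurv s = six_survival(p, len, k, temp, depth, vel, cover, max_len,
                           pisc_density);
  double sf = lp / pmat;
  if (sf > 1.0) sf = 1.0;
  double fit = std::pow(s.total(), horizon) * sf;
  return List::create(_["fitness"] = fit, _["survival_daily"] = s.total(),
                      _["survival"] = NumericVector(s.s, s.s + 6),
                      _["intake"] = intake, _["dw"] = dw,
                      _["projected_length"] = lp, _["size_factor"] = sf);
}

// [[Rcpp::export]]
List eng_select_habitat_day(NumericVector len, NumericVector wt,
                            NumericVector pmat, IntegerVector id,
                            NumericVector depth, NumericVector vel,
                            NumericVector cover, NumericVector food,
                            double temp, NumericVector par) {
  Par p = read_par(par);
  int n = len.size(), nc = depth.size();
  CellState cs;
  cs.depth.assign(depth.begin(), depth.end());
  cs.vel.assign(vel.begin(), vel.end());
  cs.cover.assign(cover.begin(), cover.end());
  cs.food_rem.assign(food.begin(), food.end());
  cs.area.assign(nc, 0.0);
  // dominance order
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (len[a] != len[b]) return len[a] > len[b];
    if (wt[a] != wt[b]) return wt[a] > wt[b];
    return id[a] < id[b];
  });
  IntegerVector cell(n);
  NumericVector intake(n), dw(n);
  for (int r = 0; r < n; ++r) {
    int i = idx[r];
    double in_i, dw_i;
    int c = choose_cell(p, cs, len[i], wt[i], pmat[i], temp, in_i, dw_i);
    cell[i] = c + 1;
    intake[i] = in_i;
    dw[i] = dw_i;
    cs.food_rem[c] -= in_i;
    if (cs.food_rem[c] < 0) cs.food_rem[c] = 0;
  }
  return List::create(_["cell"] = cell, _["intake"] = intake, _["dw"] = dw,
                      _["food_remaining"] = NumericVector(cs.food_rem.begin(),
                                                          cs.food_rem.end()));
}

// [[Rcpp::export]]
List eng_grow(NumericVector len, NumericVector wt, NumericVector intake,
              double temp, NumericVector vel, NumericVector par) {
  Par p = read_par(par);
  int n = len.size();
  NumericVector L(n), W(n), K(n), dW(n);
  for (int i = 0; i < n; ++i) {
    double dw = daily_dw(p, wt[i], intake[i], temp, vel[i]);
    double l = len[i], w = wt[i], k;
    grow_fish(p, l, w, dw, k);
    L[i] = l; W[i] = w; K[i] = k; dW[i] = dw;
  }
  return List::create(_["length"] = L, _["weight"] = W, _["k"] = K,
                      _["dw"] = dW);
}

// [[Rcpp::export]]
IntegerVector eng_survive_natural(NumericVector len, NumericVector k,
                                  NumericVector depth, NumericVector vel,
                                  NumericVector cover, double temp,
                                  double max_len, double pisc_density,
                                  NumericVector par) {
  Par p = read_par(par);
  int n = len.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    SixSurv s = six_survival(p, len[i], k[i], temp, depth[i], vel[i],
                             cover[i], max_len, pisc_density);
    out[i] = natural_death(p, s);
  }
  return out;
}

// [[Rcpp::export]]
List eng_angling_day(NumericVector len, double pressure, NumericVector par) {
  Par p = read_par(par);
  int n = len.size();
  IntegerVector outcome(n);  // 0 alive, 7 harvest, 8 illegal, 9 hooking
  long long counters[7] = {0, 0, 0, 0, 0, 0, 0};
  for (int i = 0; i < n; ++i) {
    outcome[i] = angle_fish(p, len[i], pressure, counters);
  }
  return List::create(
      _["outcome"] = outcome, _["captures"] = (double)counters[0],
      _["legal_captures"] = (double)counters[1],
      _["illegal_captures"] = (double)counters[2],
      _["keeps"] = (double)counters[3],
      _["illegal_keeps"] = (double)counters[4],
      _["releases"] = (double)counters[5],
      _["hooking_deaths"] = (double)counters[6]);
}

// [[Rcpp::export]]
List eng_redd_day(int eggs, double dd, double temp, double depth, double flow,
                  NumericVector par) {
  Par p = read_par(par);
  int e = eggs, deaths = 0;
  double d = dd;
  int hatch = redd_step(p, e, d, deaths, temp, depth, flow);
  return List::create(_["eggs"] = e, _["dd"] = d, _["deaths"] = deaths,
                      _["hatch"] = hatch);
}

// [[Rcpp::export]]
NumericMatrix eng_inherit(NumericMatrix mother, NumericMatrix father,
                          NumericVector par, bool evolution) {
  Par p = read_par(par);
  int n = mother.nrow();
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    double mo[4], fa[4], gg[4];
    for (int t = 0; t < 4; ++t) {
      mo[t] = mother(i, t);
      fa[t] = father(i, t);
    }
    draw_genotype(p, mo, fa, evolution, gg);
    for (int t = 0; t < 4; ++t) out(i, t) = gg[t];
  }
  return out;
}

// --------------------------------------------------------------- main run

static const int N_REC = 38;

// record column layout (kept in sync with rec_names below and R accessors)
enum RecCol {
  REC_YEAR = 0,
  REC_DEN0, REC_DEN1, REC_DEN2, REC_DEN3P,
  REC_BIO0, REC_BIO1, REC_BIO2, REC_BIO3P,
  REC_W0, REC_W1, REC_W2, REC_W3P,
  REC_DEN_TOT, REC_BIO_TOT, REC_ADULT_JUV,
  REC_SP_DEN, REC_SP_AGE, REC_SP_BIO,
  REC_G_MM, REC_G_MF, REC_G_EM, REC_G_NT,
  REC_EGGS,
  REC_CAPT, REC_LEGCAPT, REC_ILLCAPT, REC_HARV, REC_ILLHARV, REC_REL, REC_HOOKD,
  REC_STOCK, REC_PRESS, REC_REALEXPR,
  REC_NCENSUS, REC_EMERGED, REC_DEATH_NAT, REC_DEATH_FISH
};

// [[Rcpp::export]]
List eng_run(NumericVector par, DataFrame cells, DataFrame env,
             DataFrame init_pop, int years) {
  Par p = read_par(par);

  // cells
  CellState cs;
  {
    NumericVector a = cells["area"], dc = cells["depth_coef"],
                  de = cells["depth_exp"], vc = cells["vel_coef"],
                  ve = cells["vel_exp"], cv = cells["cover"],
                  dp = cells["drift_prod"], sp = cells["search_prod"];
    int nc = a.size();
    cs.area.assign(a.begin(), a.end());
    cs.cover.assign(cv.begin(), cv.end());
    cs.depth.assign(nc, 0.0);
    cs.vel.assign(nc, 0.0);
    cs.food_cap.assign(nc, 0.0);
    cs.food_rem.assign(nc, 0.0);
  }
  NumericVector c_dcoef = cells["depth_coef"], c_dexp = cells["depth_exp"],
                c_vcoef = cells["vel_coef"], c_vexp = cells["vel_exp"],
                c_drift = cells["drift_prod"], c_search = cells["search_prod"];
  int nc = cs.n();
  double area_ha = 0;
  for (int c = 0; c < nc; ++c) area_ha += cs.area[c];
  area_ha /= 1e4;

  // environment
  NumericVector e_temp = env["temperature"], e_flow = env["flow"];
  IntegerVector e_doy = env["doy"];
  int ndays = e_temp.size();
  if (ndays < years * 365) stop("environment series shorter than the run");

  // population
  Pop pop;
  {
    NumericVector L = init_pop["length"], W = init_pop["weight"],
                  g0 = init_pop["g_emergence"], g1 = init_pop["g_mat_male"],
                  g2 = init_pop["g_mat_female"], g3 = init_pop["g_neutral"],
                  pe = init_pop["p_emergence"], pm = init_pop["p_mat_threshold"];
    IntegerVector ag = init_pop["age"];
    CharacterVector sx = init_pop["sex"];
    pop.reserve(L.size() * 3);
    for (int i = 0; i < L.size(); ++i) {
      double gg[4] = {g0[i], g1[i], g2[i], g3[i]};
      pop.add(std::string(sx[i]) == "F" ? 0 : 1, ag[i], L[i], W[i], gg,
              pe[i], pm[i]);
    }
  }

  std::vector<Redd> redds;
  NumericMatrix rec(years, N_REC);
  std::fill(rec.begin(), rec.end(), 0.0);

  // per-season / per-year accumulators
  long long counters[7] = {0, 0, 0, 0, 0, 0, 0};
  double stock = 0, pressure = 0;
  double sp_n = 0, sp_age = 0, sp_bio = 0, sp_gmm = 0, sp_gmf = 0,
         sp_gem = 0, sp_gnt = 0, sp_nf = 0, sp_nm = 0;
  long long eggs_laid = 0, emerged_y = 0, death_nat_y = 0, death_fish_y = 0;
  bool accounting_ok = true, eggs_ok = true;
  long long deaths_by_cause[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  double season_len = p.season_end - p.season_start + 1;

  std::vector<char> male_spawned(0);

  for (int day = 0; day < years * 365; ++day) {
    int doy = e_doy[day];
    int yr = day / 365;  // 0-based year index
    double temp = e_temp[day], flow = e_flow[day];
    bool fishing_year = (yr >= p.burn_in) && p.exp_rate > 0;
    // ExpR = 0 must follow the identical code path as no fishing at all, so
    // the harvestable-stock estimate below is computed (deterministically)
    // whenever the season starts after burn-in, regardless of ExpR.
    bool regulated_year = (yr >= p.burn_in);

    long long n_start = 0;
    for (size_t i = 0; i < pop.size(); ++i) n_start += pop.alive[i] ? 1 : 0;
    long long births_today = 0, deaths_today = 0;

    // new year bookkeeping
    if (doy == 1) {
      if (day > 0) {
        for (size_t i = 0; i < pop.size(); ++i) {
          if (pop.alive[i]) pop.age[i]++;
        }
      }
      for (int j = 0; j < 7; ++j) counters[j] = 0;
      emerged_y = 0; death_nat_y = 0; death_fish_y = 0;
      stock = 0; pressure = 0;
    }
    if (doy == (int)p.spawn_start) {
      for (size_t i = 0; i < pop.size(); ++i) pop.spawned[i] = 0;
      sp_n = sp_age = sp_bio = sp_gmm = sp_gmf = sp_gem = sp_gnt = 0;
      sp_nf = sp_nm = 0;
      eggs_laid = 0;
    }

    // update cells
    for (int c = 0; c < nc; ++c) {
      cs.depth[c] = c_dcoef[c] * std::pow(flow, c_dexp[c]);
      cs.vel[c] = c_vcoef[c] * std::pow(flow, c_vexp[c]);
      cs.food_cap[c] = c_drift[c] * cs.vel[c] * cs.area[c] +
                       c_search[c] * cs.area[c];
      cs.food_rem[c] = cs.food_cap[c];
    }

    // reach-level drivers
    double max_len = 0, pisc_n = 0;
    for (size_t i = 0; i < pop.size(); ++i) {
      if (!pop.alive[i]) continue;
      if (pop.len[i] > max_len) max_len = pop.len[i];
      if (pop.len[i] >= p.pisc_min_length) pisc_n += 1;
    }
    double pisc_density = pisc_n / area_ha;

    std::vector<int> order = dominance_order(pop);

    // (a) habitat selection, (b) growth
    for (int r = 0; r < (int)order.size(); ++r) {
      int i = order[r];
      double in_i, dw_i;
      int c = choose_cell(p, cs, pop.len[i], pop.wt[i], pop.p_mat[i], temp,
                          in_i, dw_i);
      pop.cell[i] = c;
      pop.intake[i] = in_i;
      pop.dw[i] = dw_i;
      cs.food_rem[c] -= in_i;
      if (cs.food_rem[c] < 0) cs.food_rem[c] = 0;
    }
    std::vector<double> kcond(pop.size(), 1.0);
    for (int r = 0; r < (int)order.size(); ++r) {
      int i = order[r];
      double k;
      grow_fish(p, pop.len[i], pop.wt[i], pop.dw[i], k);
      kcond[i] = k;
    }

    // (c) natural mortality
    for (int r = 0; r < (int)order.size(); ++r) {
      int i = order[r];
      SixSurv s = six_survival(p, pop.len[i], kcond[i], temp,
                               cs.depth[pop.cell[i]], cs.vel[pop.cell[i]],
                               cs.cover[pop.cell[i]], max_len, pisc_density);
      int cause = natural_death(p, s);
      if (cause > 0) {
        pop.alive[i] = 0;
        deaths_today++;
        death_nat_y++;
        deaths_by_cause[cause - 1]++;
      }
    }

    // (d) fishing
    if (regulated_year && doy == (int)p.season_start) {
      // harvestable stock: legal now, or projected to reach MinLL by season
      // end at today's realized growth rate in the assigned cell
      long long st = 0;
      for (size_t i = 0; i < pop.size(); ++i) {
        if (!pop.alive[i]) continue;
        if (pop.len[i] >= p.min_ll) {
          st++;
        } else {
          double lp = projected_length(p, pop.len[i], pop.wt[i], pop.dw[i],
                                       season_len);
          if (lp >= p.min_ll) st++;
        }
      }
      stock = (double)st;
      pressure = p.exp_rate * stock * p.angling_efficiency /
                 (p.reach_length_km * season_len);
    }
    if (fishing_year && doy >= (int)p.season_start &&
        doy <= (int)p.season_end && pressure > 0) {
      for (int r = 0; r < (int)order.size(); ++r) {
        int i = order[r];
        if (!pop.alive[i]) continue;
        int outcome = angle_fish(p, pop.len[i], pressure, counters);
        if (outcome > 0) {
          pop.alive[i] = 0;
          deaths_today++;
          death_fish_y++;
          deaths_by_cause[outcome - 1]++;
        }
      }
    }

    // (e) spawning
    if (doy >= (int)p.spawn_start && doy <= (int)p.spawn_end &&
        temp >= p.spawn_temp_lo && temp <= p.spawn_temp_hi &&
        flow < p.spawn_max_flow) {
      // mature males in dominance order (longest first)
      std::vector<int> males;
      for (int r = 0; r < (int)order.size(); ++r) {
        int i = order[r];
        if (pop.alive[i] && pop.sex[i] == 1 && pop.len[i] >= pop.p_mat[i]) {
          males.push_back(i);
        }
      }
      for (int r = 0; r < (int)order.size(); ++r) {
        int i = order[r];
        if (!pop.alive[i] || pop.sex[i] != 0) continue;
        if (pop.spawned[i]) continue;
        if (pop.len[i] < pop.p_mat[i]) continue;
        if (kcond[i] < p.k_spawn) continue;
        if (unif_rand() >= p.p_spawn) continue;
        if (males.empty()) continue;  // no mature male: no redd
        // fecundity with the egg size-number trade-off
        double ratio = p.tr[0].mean / pop.g[0][i];
        int eggs = (int)std::lround(p.fec_a * std::pow(pop.len[i], p.fec_b) *
                                    ratio * ratio * ratio);
        if (eggs <= 0) continue;
        Redd rd;
        rd.cell = pop.cell[i];
        rd.eggs = rd.init_eggs = eggs;
        rd.deaths = rd.emerged = 0;
        rd.dd = 0;
        for (int t = 0; t < 4; ++t) rd.mo[t] = pop.g[t][i];
        // largest male plus Poisson(lambda) smaller mature males
        std::vector<int> dads;
        dads.push_back(males[0]);
        if (males.size() > 1 && p.lambda_mates > 0) {
          int k = (int)R::rpois(p.lambda_mates);
          int avail = (int)males.size() - 1;
          if (k > avail) k = avail;
          // uniform sample without replacement from males[1..]
          std::vector<int> pool(males.begin() + 1, males.end());
          for (int d = 0; d < k; ++d) {
            int j = (int)std::floor(unif_rand() * pool.size());
            if (j >= (int)pool.size()) j = (int)pool.size() - 1;
            dads.push_back(pool[j]);
            pool.erase(pool.begin() + j);
          }
        }
        for (int d = 0; d < (int)dads.size(); ++d) {
          int m = dads[d];
          std::array<double, 4> fg;
          for (int t = 0; t < 4; ++t) fg[t] = pop.g[t][m];
          rd.fathers.push_back(fg);
          if (!pop.spawned[m]) {
            pop.spawned[m] = 1;
            sp_n += 1; sp_nm += 1;
            sp_age += pop.age[m];
            sp_bio += pop.wt[m];
            sp_gmm += pop.g[1][m];
            sp_gem += pop.g[0][m];
            sp_gnt += pop.g[3][m];
          }
        }
        pop.spawned[i] = 1;
        sp_n += 1; sp_nf += 1;
        sp_age += pop.age[i];
        sp_bio += pop.wt[i];
        sp_gmf += pop.g[2][i];
        sp_gem += pop.g[0][i];
        sp_gnt += pop.g[3][i];
        eggs_laid += eggs;
        redds.push_back(rd);
      }
    }

    // (f) redd development and emergence
    for (size_t rix = 0; rix < redds.size(); ++rix) {
      Redd& rd = redds[rix];
      int hatch = redd_step(p, rd.eggs, rd.dd, rd.deaths, temp,
                            cs.depth[rd.cell], flow);
      for (int h = 0; h < hatch; ++h) {
        int fidx = (int)std::floor(unif_rand() * rd.fathers.size());
        if (fidx >= (int)rd.fathers.size()) fidx = (int)rd.fathers.size() - 1;
        double gg[4];
        draw_genotype(p, rd.mo, rd.fathers[fidx].data(), p.evolution, gg);
        int sx = unif_rand() < 0.5 ? 0 : 1;
        double pe, pm;
        express(p, gg, sx, pe, pm);
        double L = pe;
        double W = healthy_weight(p, L);
        pop.add(sx, 0, L, W, gg, pe, pm);
        births_today++;
      }
      rd.emerged += hatch;
      emerged_y += hatch;
      if (rd.eggs == 0) {
        if (rd.deaths + rd.emerged != rd.init_eggs) eggs_ok = false;
      }
    }
    redds.erase(std::remove_if(redds.begin(), redds.end(),
                               [](const Redd& r) { return r.eggs == 0; }),
                redds.end());

    // recorders
    if (doy == p.census_doy) {
      double den[4] = {0, 0, 0, 0}, bio[4] = {0, 0, 0, 0},
             wts[4] = {0, 0, 0, 0};
      long long n_tot = 0;
      for (size_t i = 0; i < pop.size(); ++i) {
        if (!pop.alive[i]) continue;
        int a = pop.age[i];
        int cls = a >= 3 ? 3 : a;
        den[cls] += 1;
        bio[cls] += pop.wt[i];
        wts[cls] += pop.wt[i];
        n_tot++;
      }
      rec(yr, REC_YEAR) = yr + 1;
      double den_tot = 0, bio_tot = 0;
      for (int cl = 0; cl < 4; ++cl) {
        double mean_w = den[cl] > 0 ? wts[cl] / den[cl] : 0;
        rec(yr, REC_DEN0 + cl) = den[cl] / area_ha;
        rec(yr, REC_BIO0 + cl) = bio[cl] / 1000.0 / area_ha;
        rec(yr, REC_W0 + cl) = mean_w;
        den_tot += den[cl] / area_ha;
        bio_tot += bio[cl] / 1000.0 / area_ha;
      }
      rec(yr, REC_DEN_TOT) = den_tot;
      rec(yr, REC_BIO_TOT) = bio_tot;
      double juv = rec(yr, REC_BIO0) + rec(yr, REC_BIO1);
      double adu = rec(yr, REC_BIO2) + rec(yr, REC_BIO3P);
      rec(yr, REC_ADULT_JUV) = juv > 0 ? adu / juv : NA_REAL;
      rec(yr, REC_NCENSUS) = (double)n_tot;
    }
    if (doy == (int)p.spawn_end) {
      rec(yr, REC_SP_DEN) = sp_n / area_ha;
      rec(yr, REC_SP_AGE) = sp_n > 0 ? sp_age / sp_n : NA_REAL;
      rec(yr, REC_SP_BIO) = sp_bio / 1000.0 / area_ha;
      rec(yr, REC_G_MM) = sp_nm > 0 ? sp_gmm / sp_nm : NA_REAL;
      rec(yr, REC_G_MF) = sp_nf > 0 ? sp_gmf / sp_nf : NA_REAL;
      rec(yr, REC_G_EM) = sp_n > 0 ? sp_gem / sp_n : NA_REAL;
      rec(yr, REC_G_NT) = sp_n > 0 ? sp_gnt / sp_n : NA_REAL;
      rec(yr, REC_EGGS) = (double)eggs_laid / area_ha;
    }
    if (doy == (int)p.season_end) {
      rec(yr, REC_CAPT) = (double)counters[0];
      rec(yr, REC_LEGCAPT) = (double)counters[1];
      rec(yr, REC_ILLCAPT) = (double)counters[2];
      rec(yr, REC_HARV) = (double)counters[3];
      rec(yr, REC_ILLHARV) = (double)counters[4];
      rec(yr, REC_REL) = (double)counters[5];
      rec(yr, REC_HOOKD) = (double)counters[6];
      rec(yr, REC_STOCK) = stock;
      rec(yr, REC_PRESS) = pressure;
      rec(yr, REC_REALEXPR) = stock > 0 ? (double)counters[3] / stock : 0.0;
    }
    if (doy == 365) {
      rec(yr, REC_EMERGED) = (double)emerged_y;
      rec(yr, REC_DEATH_NAT) = (double)death_nat_y;
      rec(yr, REC_DEATH_FISH) = (double)death_fish_y;
    }

    // accounting closure: N(t+1) = N(t) + births - deaths
    long long n_end = 0;
    for (size_t i = 0; i < pop.size(); ++i) n_end += pop.alive[i] ? 1 : 0;
    if (n_end != n_start + births_today - deaths_today) accounting_ok = false;

    pop.compact();
  }

  // final population
  int n = (int)pop.size();
  NumericVector fL(n), fW(n), fg0(n), fg1(n), fg2(n), fg3(n), fpe(n), fpm(n);
  IntegerVector fid(n), fage(n);
  CharacterVector fsex(n);
  for (int i = 0; i < n; ++i) {
    fid[i] = pop.id[i];
    fsex[i] = pop.sex[i] == 0 ? "F" : "M";
    fage[i] = pop.age[i];
    fL[i] = pop.len[i];
    fW[i] = pop.wt[i];
    fg0[i] = pop.g[0][i]; fg1[i] = pop.g[1][i];
    fg2[i] = pop.g[2][i]; fg3[i] = pop.g[3][i];
    fpe[i] = pop.p_em[i]; fpm[i] = pop.p_mat[i];
  }
  DataFrame final_pop = DataFrame::create(
      _["id"] = fid, _["sex"] = fsex, _["age"] = fage, _["length"] = fL,
      _["weight"] = fW, _["g_emergence"] = fg0, _["g_mat_male"] = fg1,
      _["g_mat_female"] = fg2, _["g_neutral"] = fg3, _["p_emergence"] = fpe,
      _["p_mat_threshold"] = fpm);

  return List::create(_["records"] = rec, _["final_population"] = final_pop,
                      _["accounting_ok"] = accounting_ok,
                      _["egg_conservation_ok"] = eggs_ok,
                      _["deaths_by_cause"] = NumericVector(
                          deaths_by_cause, deaths_by_cause + 9),
                      _["area_ha"] = area_ha);
}
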