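#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include "rng.h"
using namespace Rcpp;

// Embodied foraging simulator: disk robots in a walled rectangular arena with
// a nest zone at one end (y = 0) and a food disk at the other (y = L).
// Behavioral states: 1 = searching, 2 = carrying food / laying trail
// (inbound), 3 = recruited / trail following (outbound).  Collision
// reactions Stay/Leave are read from the locus matching the robot's current
// state.  All randomness comes from per-robot xoshiro256++ streams plus one
// placement stream, all derived from the trial seed.

struct Params {
  double W, L;                 // field width / length (mm)
  double food_r, nest_r;       // food disk and nest zone radii (mm)
  double food_x, food_y;       // food centre
  double nest_x, nest_y;       // nest centre
  double light_r;              // food light detection radius (mm)
  double robot_r;              // robot body radius (mm)
  double speed;                // displacement per step (mm)
  int n_robots, n_steps;
  // pheromone grid
  double cell;
  int nx, ny;
  double deposit, evap, diff, thresh, follow_thresh;
  // behavior
  double sigma;                // S1 heading noise sd (rad/step)
  double steer_sigma;          // S2/S3 steering noise sd (rad/step)
  int stay_steps;
  double leave_dist;
  int trail_lost_steps;
  double sens_ahead, sens_side;
  double turn;                 // max steering turn (rad/step)
};

struct Robot {
  double x, y, h;
  int st;        // behavior state 1..3
  int stay;      // Stay steps remaining
  double leave;  // Leave distance remaining (mm)
  int lost;      // consecutive below-threshold trail readings
};

struct World {
  std::vector<Robot> rb;
  std::vector<double> ph;       // ny x nx, idx = iy * nx + ix
  std::vector<char> contact;    // n x n symmetric contact map
  std::vector<Xoshiro256> rng;  // n robot streams + 1 placement stream
  long long bouts, collisions;
  long long budget[3];
  int step;
  // scratch (not part of the serialized state)
  std::vector<double> buf;      // diffusion double-buffer
  double mass;                  // running total pheromone mass
};

static Params read_params(const List& cfg) {
  Params P;
  P.W = as<double>(cfg["field_width_mm"]);
  P.L = as<double>(cfg["field_length_mm"]);
  P.food_r = as<double>(cfg["food_diameter_mm"]) / 2.0;
  P.nest_r = as<double>(cfg["nest_diameter_mm"]) / 2.0;
  P.light_r = as<double>(cfg["food_light_radius_mm"]);
  P.robot_r = as<double>(cfg["robot_diameter_mm"]) / 2.0;
  double dt = as<double>(cfg["dt_s"]);
  P.speed = as<double>(cfg["robot_max_speed_mm_s"]) * dt;
  P.n_robots = as<int>(cfg["n_robots"]);
  P.n_steps = as<int>(cfg["n_steps"]);
  P.nest_x = P.W / 2.0; P.nest_y = 0.0;
  P.food_x = P.W / 2.0; P.food_y = P.L;
  P.cell = as<double>(cfg["grid_cell_mm"]);
  P.nx = (int)std::ceil(P.W / P.cell);
  P.ny = (int)std::ceil(P.L / P.cell);
  P.deposit = as<double>(cfg["deposit_amount_per_step"]);
  P.evap = as<double>(cfg["evaporation_coeff"]);
  P.diff = as<double>(cfg["diffusion_coeff"]);
  P.thresh = as<double>(cfg["detection_threshold"]);
  P.follow_thresh = as<double>(cfg["follow_threshold"]);
  P.sigma = as<double>(cfg["heading_noise_sd"]);
  P.steer_sigma = as<double>(cfg["steer_noise_sd"]);
  P.stay_steps = (int)std::lround(as<double>(cfg["stay_duration_s"]) / dt);
  P.leave_dist = as<double>(cfg["leave_distance_mm"]);
  P.trail_lost_steps = as<int>(cfg["trail_lost_steps"]);
  P.sens_ahead = as<double>(cfg["sensor_ahead_mm"]);
  P.sens_side = as<double>(cfg["sensor_side_mm"]);
  P.turn = as<double>(cfg["turn_rate_rad"]);
  return P;
}

static inline double wrap_angle(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a < -M_PI) a += 2.0 * M_PI;
  return a;
}

static inline int cell_index(const Params& P, double x, double y) {
  int ix = (int)(x / P.cell);
  int iy = (int)(y / P.cell);
  if (ix < 0) ix = 0; if (ix >= P.nx) ix = P.nx - 1;
  if (iy < 0) iy = 0; if (iy >= P.ny) iy = P.ny - 1;
  return iy * P.nx + ix;
}

static inline double ph_at(const World& w, const Params& P, double x, double y) {
  return w.ph[cell_index(P, x, y)];
}

static inline void clamp_walls(Robot& r, const Params& P) {
  double lo = P.robot_r;
  if (r.x < lo) r.x = lo;
  if (r.x > P.W - lo) r.x = P.W - lo;
  if (r.y < lo) r.y = lo;
  if (r.y > P.L - lo) r.y = P.L - lo;
}

static inline void steer_towards(Robot& r, double tx, double ty, double turn) {
  double want = std::atan2(ty - r.y, tx - r.x);
  double d = wrap_angle(want - r.h);
  if (d > turn) d = turn;
  if (d < -turn) d = -turn;
  r.h = wrap_angle(r.h + d);
}

// forward move with wall reflection (used by searching robots)
static inline void advance_reflect(Robot& r, const Params& P) {
  double nx_ = r.x + P.speed * std::cos(r.h);
  double ny_ = r.y + P.speed * std::sin(r.h);
  double lo = P.robot_r;
  if (nx_ < lo || nx_ > P.W - lo) r.h = wrap_angle(M_PI - r.h);
  if (ny_ < lo || ny_ > P.L - lo) r.h = wrap_angle(-r.h);
  r.x += P.speed * std::cos(r.h);
  r.y += P.speed * std::sin(r.h);
  clamp_walls(r, P);
}

// forward move with clamping (steered robots re-aim every tick)
static inline void advance_clamp(Robot& r, const Params& P) {
  r.x += P.speed * std::cos(r.h);
  r.y += P.speed * std::sin(r.h);
  clamp_walls(r, P);
}

// deposit, multiplicative evaporation, then 4-neighbour diffusion.  The
// evaporation factor is uniform, so it commutes with diffusion and both are
// fused into one buffered pass.
static void pheromone_step(std::vector<double>& ph, std::vector<double>& buf,
                           double& mass, const Params& P,
                           const std::vector<std::pair<int,double> >& deps) {
  for (size_t k = 0; k < deps.size(); ++k) {
    ph[deps[k].first] += deps[k].second;
    mass += deps[k].second;
  }
  if (mass <= 0.0) return;  // empty field is a fixed point
  const int n = P.nx * P.ny;
  if (P.diff > 0.0) {
    if ((int)buf.size() != n) buf.assign(n, 0.0);
    const double D = P.diff, E = P.evap;
    for (int iy = 0; iy < P.ny; ++iy) {
      const int row = iy * P.nx;
      const double* up = (iy > 0) ? &ph[row - P.nx] : 0;
      const double* dn = (iy < P.ny - 1) ? &ph[row + P.nx] : 0;
      for (int ix = 0; ix < P.nx; ++ix) {
        int idx = row + ix;
        double c = ph[idx], acc = 0.0;
        if (ix > 0)        acc += ph[idx - 1] - c;
        if (ix < P.nx - 1) acc += ph[idx + 1] - c;
        if (up)            acc += up[ix] - c;
        if (dn)            acc += dn[ix] - c;
        buf[idx] = E * (c + D * acc);
      }
    }
    ph.swap(buf);
  } else if (P.evap < 1.0) {
    for (int i = 0; i < n; ++i) ph[i] *= P.evap;
  }
  mass *= P.evap;
  if (mass < 1e-300) {
    mass = 0.0;
    std::fill(ph.begin(), ph.end(), 0.0);
  }
}

// collision reaction from the robot's own state locus: 0 = Stay, 1 = Leave
static inline void react(Robot& r, const Params& P, const int* g) {
  int allele = g[r.st - 1];
  if (allele == 0) { r.stay = P.stay_steps; r.leave = 0.0; }
  else             { r.leave = P.leave_dist; r.stay = 0; }
}

struct EventLog {
  std::vector<int> step;
  std::vector<int> robot;   // 1-based focal robot (or first of pair)
  std::vector<int> other;   // 1-based partner for collisions, NA (-1) for bouts
  std::vector<int> type;    // 1 = bout, 2 = collision
};

static void tick(World& w, const Params& P, const int* g, EventLog* log) {
  const int n = P.n_robots;
  std::vector<std::pair<int,double> > deps;

  // ---- motion ----
  for (int i = 0; i < n; ++i) {
    Robot& r = w.rb[i];
    w.budget[r.st - 1]++;
    double z = w.rng[i].normal();  // consumed every tick for stream stability
    if (r.stay > 0) { r.stay--; continue; }
    if (r.leave > 0.0) {
      // heading noise continues while reversing, so a yielding robot
      // re-approaches slightly offset instead of re-entering the same lane
      r.h = wrap_angle(r.h + P.steer_sigma * z);
      double d = std::min(P.speed, r.leave);
      r.x -= d * std::cos(r.h);
      r.y -= d * std::sin(r.h);
      r.leave -= d;
      clamp_walls(r, P);
      continue;
    }
    if (r.st == 1) {
      double dx = P.food_x - r.x, dy = P.food_y - r.y;
      if (std::sqrt(dx * dx + dy * dy) <= P.light_r)
        steer_towards(r, P.food_x, P.food_y, P.turn);
      else
        r.h = wrap_angle(r.h + P.sigma * z);
      advance_reflect(r, P);
    } else if (r.st == 2) {
      steer_towards(r, P.nest_x, P.nest_y, P.turn);
      r.h = wrap_angle(r.h + P.steer_sigma * z);
      advance_clamp(r, P);
      deps.push_back(std::make_pair(cell_index(P, r.x, r.y), P.deposit));
    } else {  // S3 trail following
      double dx = P.food_x - r.x, dy = P.food_y - r.y;
      if (std::sqrt(dx * dx + dy * dy) <= P.light_r) {
        steer_towards(r, P.food_x, P.food_y, P.turn);
        r.lost = 0;
      } else {
        double ca = std::cos(r.h), sa = std::sin(r.h);
        double lx = r.x + P.sens_ahead * ca - P.sens_side * sa;
        double ly = r.y + P.sens_ahead * sa + P.sens_side * ca;
        double rx = r.x + P.sens_ahead * ca + P.sens_side * sa;
        double ry = r.y + P.sens_ahead * sa - P.sens_side * ca;
        double cl = ph_at(w, P, lx, ly);
        double cr = ph_at(w, P, rx, ry);
        double here = ph_at(w, P, r.x, r.y);
        if (cl < P.follow_thresh && cr < P.follow_thresh && here < P.follow_thresh) {
          r.lost++;  // go straight, hoping to re-acquire
        } else {
          r.lost = 0;
          if (cl > cr)      r.h = wrap_angle(r.h + P.turn);
          else if (cr > cl) r.h = wrap_angle(r.h - P.turn);
        }
        // a recruited robot is outbound by definition: the nest beacon keeps
        // its heading pointed away from the nest while it tracks the trail
        double away = std::atan2(r.y - P.nest_y, r.x - P.nest_x);
        if (std::cos(r.h - away) < 0.0) {
          double d = wrap_angle(away - r.h);
          if (d > P.turn) d = P.turn;
          if (d < -P.turn) d = -P.turn;
          r.h = wrap_angle(r.h + d);
        }
      }
      r.h = wrap_angle(r.h + P.steer_sigma * z);
      advance_clamp(r, P);
    }
  }

  // ---- robot-robot collisions ----
  // one detection pass triggers reactions on new contacts and refreshes the
  // contact map; a robot already in contact with a partner does not
  // re-trigger until that contact is broken
  const double dia = 2.0 * P.robot_r;
  const double dia2 = dia * dia;
  bool overlap_found = false;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = w.rb[i].x - w.rb[j].x, dy = w.rb[i].y - w.rb[j].y;
      double d2 = dx * dx + dy * dy;
      bool touching = d2 <= dia2 * (1.0 + 1e-9);
      if (touching && !w.contact[i * n + j]) {
        w.collisions++;
        if (log) {
          log->step.push_back(w.step + 1);
          log->robot.push_back(i + 1);
          log->other.push_back(j + 1);
          log->type.push_back(2);
        }
        react(w.rb[i], P, g);
        react(w.rb[j], P, g);
      }
      w.contact[i * n + j] = touching ? 1 : 0;
      w.contact[j * n + i] = w.contact[i * n + j];
      if (d2 < dia2 - 1e-9) overlap_found = true;
    }
  }

  // resolve interpenetration: symmetric pairwise separation, iterated to
  // convergence (bounded), so bodies end at most in point contact
  if (overlap_found) {
    for (int pass = 0; pass < 40; ++pass) {
      bool any = false;
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
          double dx = w.rb[i].x - w.rb[j].x, dy = w.rb[i].y - w.rb[j].y;
          double d2 = dx * dx + dy * dy;
          if (d2 < dia2 - 1e-9) {
            double d = std::sqrt(d2);
            double ux, uy;
            if (d < 1e-9) { ux = 1.0; uy = 0.0; }  // coincident: deterministic axis
            else { ux = dx / d; uy = dy / d; }
            double shift = (dia - d) / 2.0;
            w.rb[i].x += ux * shift; w.rb[i].y += uy * shift;
            w.rb[j].x -= ux * shift; w.rb[j].y -= uy * shift;
            clamp_walls(w.rb[i], P);
            clamp_walls(w.rb[j], P);
            any = true;
          }
        }
      }
      if (!any) break;
    }
  }

  // ---- pheromone field ----
  pheromone_step(w.ph, w.buf, w.mass, P, deps);

  // ---- state transitions & bout counting ----
  const int p_allele = g[3];
  for (int i = 0; i < n; ++i) {
    Robot& r = w.rb[i];
    double dxf = P.food_x - r.x, dyf = P.food_y - r.y;
    bool at_food = std::sqrt(dxf * dxf + dyf * dyf) <= P.food_r + P.robot_r;
    double dxn = P.nest_x - r.x, dyn = P.nest_y - r.y;
    bool at_nest = std::sqrt(dxn * dxn + dyn * dyn) <= P.nest_r;
    double here = ph_at(w, P, r.x, r.y);
    if (r.st == 1) {
      if (at_food) {
        r.st = 2;
      } else if (p_allele == 1 && here >= P.thresh) {
        r.st = 3; r.lost = 0;
        // join the trail heading outbound (away from the nest beacon)
        if (std::fabs(dxn) > 1e-12 || std::fabs(dyn) > 1e-12)
          r.h = std::atan2(-dyn, -dxn);
      }
    } else if (r.st == 2) {
      if (at_nest) {
        w.bouts++;
        if (log) {
          log->step.push_back(w.step + 1);
          log->robot.push_back(i + 1);
          log->other.push_back(-1);
          log->type.push_back(1);
        }
        r.st = 1;
        if (p_allele == 1 && here >= P.thresh) {
          r.st = 3; r.lost = 0;
          if (std::fabs(dxn) > 1e-12 || std::fabs(dyn) > 1e-12)
            r.h = std::atan2(-dyn, -dxn);
        }
      }
    } else {  // S3
      if (at_food) { r.st = 2; r.lost = 0; }
      else if (r.lost >= P.trail_lost_steps) { r.st = 1; r.lost = 0; }
    }
  }
  w.step++;
}

static World make_world_internal(const Params& P, uint64_t seed) {
  World w;
  w.rb.resize(P.n_robots);
  w.ph.assign((size_t)P.nx * P.ny, 0.0);
  w.contact.assign((size_t)P.n_robots * P.n_robots, 0);
  w.rng.resize(P.n_robots + 1);
  SplitMix64 sm(seed);
  for (int i = 0; i <= P.n_robots; ++i) w.rng[i].seed_from(sm.next());
  Xoshiro256& place = w.rng[P.n_robots];
  double lo = P.robot_r;
  for (int i = 0; i < P.n_robots; ++i) {
    bool ok = false;
    double x = lo, y = lo;
    for (int tries = 0; tries < 1000 && !ok; ++tries) {
      x = lo + place.unif() * (P.W - 2 * lo);
      y = lo + place.unif() * (P.L - 2 * lo);
      ok = true;
      for (int j = 0; j < i; ++j) {
        double dx = x - w.rb[j].x, dy = y - w.rb[j].y;
        if (dx * dx + dy * dy < 4 * P.robot_r * P.robot_r) { ok = false; break; }
      }
    }
    w.rb[i].x = x;
    w.rb[i].y = y;
    w.rb[i].h = wrap_angle(place.unif() * 2.0 * M_PI - M_PI);
    w.rb[i].st = 1;
    w.rb[i].stay = 0;
    w.rb[i].leave = 0.0;
    w.rb[i].lost = 0;
  }
  w.bouts = 0;
  w.collisions = 0;
  w.budget[0] = w.budget[1] = w.budget[2] = 0;
  w.step = 0;
  w.mass = 0.0;
  return w;
}

static RawVector rng_to_raw(const World& w) {
  RawVector out(w.rng.size() * 32);
  std::memcpy(RAW(out), w.rng.data(), out.size());
  return out;
}

static List world_to_list(const World& w, const Params& P) {
  int n = P.n_robots;
  NumericVector x(n), y(n), h(n), leave(n);
  IntegerVector st(n), stay(n), lost(n);
  for (int i = 0; i < n; ++i) {
    x[i] = w.rb[i].x; y[i] = w.rb[i].y; h[i] = w.rb[i].h;
    st[i] = w.rb[i].st; stay[i] = w.rb[i].stay;
    leave[i] = w.rb[i].leave; lost[i] = w.rb[i].lost;
  }
  NumericMatrix ph(P.ny, P.nx);
  for (int iy = 0; iy < P.ny; ++iy)
    for (int ix = 0; ix < P.nx; ++ix)
      ph(iy, ix) = w.ph[iy * P.nx + ix];
  LogicalMatrix contact(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      contact(i, j) = w.contact[i * n + j] != 0;
  return List::create(
    _["x"] = x, _["y"] = y, _["heading"] = h, _["state"] = st,
    _["stay_timer"] = stay, _["leave_remaining"] = leave, _["trail_lost"] = lost,
    _["pheromone"] = ph, _["contact"] = contact,
    _["step"] = w.step,
    _["bouts"] = (double)w.bouts, _["collisions"] = (double)w.collisions,
    _["time_budget"] = NumericVector::create((double)w.budget[0],
                                             (double)w.budget[1],
                                             (double)w.budget[2]),
    _["rng_state"] = rng_to_raw(w));
}

static World list_to_world(const List& wl, const Params& P) {
  World w;
  int n = P.n_robots;
  NumericVector x = wl["x"], y = wl["y"], h = wl["heading"], leave = wl["leave_remaining"];
  IntegerVector st = wl["state"], stay = wl["stay_timer"], lost = wl["trail_lost"];
  if (x.size() != n) stop("world has %d robots but config expects %d", (int)x.size(), n);
  w.rb.resize(n);
  for (int i = 0; i < n; ++i) {
    w.rb[i].x = x[i]; w.rb[i].y = y[i]; w.rb[i].h = h[i];
    int s = st[i];
    if (s < 1 || s > 3) stop("unknown behavior_state %d for robot %d", s, i + 1);
    w.rb[i].st = s;
    w.rb[i].stay = stay[i]; w.rb[i].leave = leave[i]; w.rb[i].lost = lost[i];
  }
  NumericMatrix ph = wl["pheromone"];
  if (ph.nrow() != P.ny || ph.ncol() != P.nx) stop("pheromone grid dimensions do not match config");
  w.ph.assign((size_t)P.nx * P.ny, 0.0);
  w.mass = 0.0;
  for (int iy = 0; iy < P.ny; ++iy)
    for (int ix = 0; ix < P.nx; ++ix) {
      w.ph[iy * P.nx + ix] = ph(iy, ix);
      w.mass += ph(iy, ix);
    }
  LogicalMatrix contact = wl["contact"];
  w.contact.assign((size_t)n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      w.contact[i * n + j] = contact(i, j) ? 1 : 0;
  w.step = as<int>(wl["step"]);
  w.bouts = (long long)as<double>(wl["bouts"]);
  w.collisions = (long long)as<double>(wl["collisions"]);
  NumericVector tb = wl["time_budget"];
  w.budget[0] = (long long)tb[0]; w.budget[1] = (long long)tb[1]; w.budget[2] = (long long)tb[2];
  RawVector rs = wl["rng_state"];
  w.rng.resize(n + 1);
  if ((int)rs.size() != (n + 1) * 32) stop("rng_state has wrong length");
  std::memcpy(w.rng.data(), RAW(rs), rs.size());
  return w;
}

static void check_genotype(const IntegerVector& g) {
  if (g.size() != 4) stop("genotype must have 4 loci");
  for (int i = 0; i < 4; ++i)
    if (g[i] != 0 && g[i] != 1) stop("genotype loci must be 0 or 1");
}

// [[Rcpp::export]]
List cpp_make_world(List cfg, double seed) {
  Params P = read_params(cfg);
  World w = make_world_internal(P, (uint64_t)seed);
  return world_to_list(w, P);
}

// [[Rcpp::export]]
List cpp_step_world(List world, IntegerVector genotype, List cfg) {
  Params P = read_params(cfg);
  check_genotype(genotype);
  World w = list_to_world(world, P);
  tick(w, P, INTEGER(genotype), 0);
  return world_to_list(w, P);
}

// [[Rcpp::export]]
List cpp_simulate_trial(List cfg, IntegerVector genotype, double seed, bool log_events) {
  Params P = read_params(cfg);
  check_genotype(genotype);
  World w = make_world_internal(P, (uint64_t)seed);
  EventLog log;
  EventLog* lp = log_events ? &log : 0;
  for (int t = 0; t < P.n_steps; ++t) tick(w, P, INTEGER(genotype), lp);
  List out = List::create(
    _["bouts"] = (double)w.bouts,
    _["collisions"] = (double)w.collisions,
    _["time_budget"] = NumericVector::create(
        _["S1"] = (double)w.budget[0], _["S2"] = (double)w.budget[1],
        _["S3"] = (double)w.budget[2]),
    _["n_steps"] = P.n_steps);
  if (log_events) {
    out["events"] = DataFrame::create(
      _["step"] = wrap(log.step), _["robot"] = wrap(log.robot),
      _["other"] = wrap(log.other), _["type"] = wrap(log.type));
  }
  return out;
}

// One pheromone update applied to a free-standing field: deposits (x, y,
// amount in mm coordinates), then evaporation, then 4-neighbour diffusion.
// [[Rcpp::export]]
NumericMatrix cpp_update_pheromone(NumericMatrix field, NumericMatrix deposits, List cfg) {
  Params P = read_params(cfg);
  if (field.nrow() != P.ny || field.ncol() != P.nx)
    stop("field must be %d x %d for this config", P.ny, P.nx);
  std::vector<double> ph((size_t)P.nx * P.ny);
  for (int iy = 0; iy < P.ny; ++iy)
    for (int ix = 0; ix < P.nx; ++ix)
      ph[iy * P.nx + ix] = field(iy, ix);
  std::vector<std::pair<int,double> > deps;
  for (int k = 0; k < deposits.nrow(); ++k) {
    double x = deposits(k, 0), y = deposits(k, 1);
    if (x < 0 || x > P.W || y < 0 || y > P.L)
      stop("deposit at (%.1f, %.1f) lies outside the %g x %g field", x, y, P.W, P.L);
    deps.push_back(std::make_pair(cell_index(P, x, y), deposits(k, 2)));
  }
  std::vector<double> buf;
  double mass = 0.0;
  for (size_t i = 0; i < ph.size(); ++i) mass += ph[i];
  pheromone_step(ph, buf, mass, P, deps);
  NumericMatrix out(P.ny, P.nx);
  for (int iy = 0; iy < P.ny; ++iy)
    for (int ix = 0; ix < P.nx; ++ix)
      out(iy, ix) = ph[iy * P.nx + ix];
  return out;
}

// Derive a deterministic stream of sub-seeds from one master seed.
// [[Rcpp::export]]
NumericVector cpp_derive_seeds(double seed, int n) {
  SplitMix64 sm((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (double)(sm.next() >> 11);  // < 2^53
  return out;
}
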