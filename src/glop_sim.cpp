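// GLOP dyadic movement simulator: participant vector-field step, scripted
// opponent profiles, whole-trial simulation with collision freezing, and
// resynchronized trajectory prediction for posterior predictive checks.
// All random draws go through R's RNG (norm_rand/unif_rand) so results are
// reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Geom {
  double width, height, dist_max;
};

struct Config {
  int resolution;        // preference grid cells per axis
  double max_speed;      // participant speed cap, px/frame
  double motiv_gain;     // px of discrepancy -> px/frame of intended speed
  double collision_radius;
  bool attract;          // preference-gradient sign (true = attractive)
  double opponent_speed; // scripted opponent speed, px/frame
  double heading_noise_sd;  // radians
  double curious_distance;  // px standoff for the Curious profile
  double wander_persistence;
  double wander_margin;  // px from wall where Wandering starts steering away
};

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Radial lookup for the preference strength D(r)^s, which within a trial
// depends only on the cell's distance r to the opponent (d and s are fixed).
// Tabulated on a uniform grid over [0, dist_max] with linear interpolation;
// with 4096 bins (~0.5 px) the interpolation error is below 1e-6 relative,
// far under the movement-noise floor.
struct SpatialLUT {
  double step_inv;
  std::vector<double> v;
  void build(double d, double s, double dist_max, int n = 4096) {
    const double pref = d * dist_max;
    v.resize(n + 1);
    for (int k = 0; k <= n; k++) {
      const double r = k * dist_max / n;
      v[k] = std::pow((dist_max - std::fabs(r - pref)) / dist_max, s);
    }
    step_inv = n / dist_max;
  }
  inline double operator()(double r) const {
    double x = r * step_inv;
    int i = static_cast<int>(x);
    if (i >= static_cast<int>(v.size()) - 1) return v.back();
    const double f = x - i;
    return v[i] + (v[i + 1] - v[i]) * f;
  }
};

// v_spatial: preference-gradient resultant over a resolution^2 grid of cell
// centers.  Cell (i, j), 1-based, has center ((i-.5) w/res, (j-.5) h/res).
// D(g) = (dist_max - |dist(g, o) - d dist_max|) / dist_max, weight D^s,
// summand (g - p) when attractive (or (p - g) for the literal printed form),
// normalized by the number of cells.  When a lookup table is supplied the
// weight comes from it; otherwise it is computed exactly.
inline arma::vec2 spatial_vec(double px, double py, double ox, double oy,
                              double d, double s, const Geom &g,
                              const Config &cf,
                              const SpatialLUT *lut = nullptr) {
  const int res = cf.resolution;
  const double cw = g.width / res, ch = g.height / res;
  const double pref = d * g.dist_max;
  double sx = 0.0, sy = 0.0;
  for (int i = 0; i < res; i++) {
    const double cx = (i + 0.5) * cw;
    const double dx2 = (cx - ox) * (cx - ox);
    for (int j = 0; j < res; j++) {
      const double cy = (j + 0.5) * ch;
      const double r = std::sqrt(dx2 + (cy - oy) * (cy - oy));
      const double w =
          lut ? (*lut)(r)
              : std::pow((g.dist_max - std::fabs(r - pref)) / g.dist_max, s);
      sx += w * (cx - px);
      sy += w * (cy - py);
    }
  }
  const double n = static_cast<double>(res) * res;
  arma::vec2 out = {sx / n, sy / n};
  if (!cf.attract) out = -out;
  return out;
}

// One participant step.  Computes the preferred-distance, spatial-preference
// and pace-matching components, mixes them with the simplex weights, adds
// speed-scaled Gaussian variability, blends with the previous step through
// the autocorrelation weight, caps speed and clamps to the screen.
// params: d, w_d, w_s, w_p, a, s, v.  Consumes 2 normal draws when noisy.
inline void glop_step_core(arma::vec2 &p, arma::vec2 &p_prev_traj,
                           const arma::vec2 &o, const arma::vec2 &o_prev_traj,
                           const arma::vec &par, const Geom &g,
                           const Config &cf, bool noise,
                           const SpatialLUT *lut = nullptr) {
  const double d = par[0], w_d = par[1], w_s = par[2], w_p = par[3],
               a = par[4], s = par[5], v = par[6];
  arma::vec2 diff = o - p;
  const double dist = std::sqrt(diff[0] * diff[0] + diff[1] * diff[1]);
  arma::vec2 v_dist = {0.0, 0.0};
  if (dist > 0) {
    arma::vec2 t_hat = diff / dist;
    v_dist = (dist - d * g.dist_max) * t_hat;
  }
  arma::vec2 v_spatial = {0.0, 0.0};
  if (w_s > 0) v_spatial = spatial_vec(p[0], p[1], o[0], o[1], d, s, g, cf, lut);
  const arma::vec2 v_pace = o_prev_traj;
  // v_dist and v_spatial are position discrepancies in px; the control gain
  // converts them to an intended joystick velocity (px/frame) before mixing
  // with the pace component, which is already a per-frame velocity
  arma::vec2 v_motiv = cf.motiv_gain * (w_d * v_dist + w_s * v_spatial) +
                       w_p * v_pace;
  arma::vec2 v_var = {0.0, 0.0};
  if (noise) {
    const double sd = v * std::sqrt(v_motiv[0] * v_motiv[0] +
                                    v_motiv[1] * v_motiv[1]);
    v_var[0] = sd * norm_rand();
    v_var[1] = sd * norm_rand();
  }
  arma::vec2 v_traj = a * p_prev_traj + (1.0 - a) * (v_motiv + v_var);
  const double speed = std::sqrt(v_traj[0] * v_traj[0] + v_traj[1] * v_traj[1]);
  if (speed > cf.max_speed) v_traj *= cf.max_speed / speed;
  p[0] = clampd(p[0] + v_traj[0], 0.0, g.width);
  p[1] = clampd(p[1] + v_traj[1], 0.0, g.height);
  p_prev_traj = v_traj;
}

inline arma::vec2 rotate(const arma::vec2 &u, double ang) {
  const double c = std::cos(ang), s = std::sin(ang);
  return {c * u[0] - s * u[1], s * u[0] + c * u[1]};
}

// Scripted opponent step.  profile: 1 Aggressive, 2 Shy, 3 Curious,
// 4 Defensive, 5 Wandering.  Heading noise is a Gaussian rotation.
// Consumes 1 normal draw (profiles 1-4) or up to 1 normal draw (5).
inline void opponent_step_core(int profile, arma::vec2 &o,
                               arma::vec2 &o_prev_traj, double &heading,
                               const arma::vec2 &p,
                               const arma::vec2 &hidden_target, const Geom &g,
                               const Config &cf) {
  arma::vec2 step = {0.0, 0.0};
  const double sp = cf.opponent_speed;
  arma::vec2 diff = p - o;
  const double dist = std::sqrt(diff[0] * diff[0] + diff[1] * diff[1]);
  switch (profile) {
  case 1: { // Aggressive: straight at the participant
    if (dist > 0) step = sp * (diff / dist);
    step = rotate(step, cf.heading_noise_sd * norm_rand());
    break;
  }
  case 2: { // Shy: straight away
    if (dist > 0) step = -sp * (diff / dist);
    step = rotate(step, cf.heading_noise_sd * norm_rand());
    break;
  }
  case 3: { // Curious: distance-keeping (GLOP with w_d = 1 at a standoff)
    if (dist > 0) {
      arma::vec2 t_hat = diff / dist;
      arma::vec2 v = (dist - cf.curious_distance) * t_hat;
      const double mag = std::sqrt(v[0] * v[0] + v[1] * v[1]);
      step = (mag > sp) ? sp * (v / mag) : v;
    }
    step = rotate(step, cf.heading_noise_sd * norm_rand());
    break;
  }
  case 4: { // Defensive: hold the participant/hidden-target midpoint
    arma::vec2 mid = 0.5 * (p + hidden_target);
    arma::vec2 to_mid = mid - o;
    const double md = std::sqrt(to_mid[0] * to_mid[0] + to_mid[1] * to_mid[1]);
    if (md > 0) step = (md > sp) ? sp * (to_mid / md) : to_mid;
    step = rotate(step, cf.heading_noise_sd * norm_rand());
    break;
  }
  case 5: { // Wandering: persistent heading, steer off walls
    heading += (1.0 - cf.wander_persistence) * 10.0 * norm_rand();
    arma::vec2 dir = {std::cos(heading), std::sin(heading)};
    // blend toward screen center when close to a wall
    const double m = cf.wander_margin;
    if (o[0] < m || o[0] > g.width - m || o[1] < m || o[1] > g.height - m) {
      arma::vec2 to_c = {g.width / 2.0 - o[0], g.height / 2.0 - o[1]};
      const double cd = std::sqrt(to_c[0] * to_c[0] + to_c[1] * to_c[1]);
      if (cd > 0) {
        dir = 0.7 * (to_c / cd) + 0.3 * dir;
        const double dn = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1]);
        if (dn > 0) dir /= dn;
        heading = std::atan2(dir[1], dir[0]);
      }
    }
    step = sp * dir;
    break;
  }
  default:
    stop("unknown opponent profile code: %d", profile);
  }
  o[0] = clampd(o[0] + step[0], 0.0, g.width);
  o[1] = clampd(o[1] + step[1], 0.0, g.height);
  o_prev_traj = step;
}

Geom as_geom(const List &geom) {
  Geom g;
  g.width = as<double>(geom["width"]);
  g.height = as<double>(geom["height"]);
  g.dist_max = as<double>(geom["dist_max"]);
  return g;
}

Config as_config(const List &config) {
  Config cf;
  cf.resolution = as<int>(config["grid_resolution"]);
  cf.max_speed = as<double>(config["max_speed"]);
  cf.motiv_gain = as<double>(config["motiv_gain"]);
  cf.collision_radius = as<double>(config["collision_radius"]);
  cf.attract = as<std::string>(config["spatial_sign"]) == "attract";
  cf.opponent_speed = as<double>(config["opponent_speed"]);
  cf.heading_noise_sd = as<double>(config["heading_noise_sd"]);
  cf.curious_distance = as<double>(config["curious_distance"]);
  cf.wander_persistence = as<double>(config["wander_persistence"]);
  cf.wander_margin = as<double>(config["wander_margin"]);
  return cf;
}

} // namespace

// [[Rcpp::export]]
arma::vec cpp_spatial_vector(arma::vec p, arma::vec o, double d, double s,
                             List geom, List config) {
  Geom g = as_geom(geom);
  Config cf = as_config(config);
  arma::vec2 v = spatial_vec(p[0], p[1], o[0], o[1], d, s, g, cf);
  return arma::vec(v);
}

// [[Rcpp::export]]
List cpp_glop_step(arma::vec p, arma::vec p_prev_traj, arma::vec o,
                   arma::vec o_prev_traj, arma::vec params, List geom,
                   List config, bool noise) {
  Geom g = as_geom(geom);
  Config cf = as_config(config);
  arma::vec2 pp = {p[0], p[1]}, pt = {p_prev_traj[0], p_prev_traj[1]};
  arma::vec2 oo = {o[0], o[1]}, ot = {o_prev_traj[0], o_prev_traj[1]};
  RNGScope scope;
  glop_step_core(pp, pt, oo, ot, params, g, cf, noise);
  return List::create(_["position"] = NumericVector::create(pp[0], pp[1]),
                      _["prev_traj"] = NumericVector::create(pt[0], pt[1]));
}

// [[Rcpp::export]]
List cpp_opponent_step(int profile, arma::vec o, arma::vec o_prev_traj,
                       double heading, arma::vec p, arma::vec hidden_target,
                       List geom, List config) {
  Geom g = as_geom(geom);
  Config cf = as_config(config);
  arma::vec2 oo = {o[0], o[1]}, ot = {o_prev_traj[0], o_prev_traj[1]};
  arma::vec2 pp = {p[0], p[1]}, ht = {hidden_target[0], hidden_target[1]};
  RNGScope scope;
  opponent_step_core(profile, oo, ot, heading, pp, ht, g, cf);
  return List::create(_["position"] = NumericVector::create(oo[0], oo[1]),
                      _["prev_traj"] = NumericVector::create(ot[0], ot[1]),
                      _["heading"] = heading);
}

// Simulate one dyadic trial for n_frames frames.  Row t holds the state
// after t - 1 updates (row 1 is the starting state).  A collision (center
// distance below collision_radius) clears the alive flag and freezes both
// agents for the remaining frames.  Returns an n_frames x 5 matrix
// (p_x, p_y, o_x, o_y, alive).
// [[Rcpp::export]]
arma::mat cpp_simulate_trial(arma::vec params, int profile, arma::vec p_start,
                             arma::vec o_start, arma::vec hidden_target,
                             double wander_heading, int n_frames, List geom,
                             List config) {
  Geom g = as_geom(geom);
  Config cf = as_config(config);
  arma::mat out(n_frames, 5);
  arma::vec2 p = {p_start[0], p_start[1]}, o = {o_start[0], o_start[1]};
  arma::vec2 pt = {0.0, 0.0}, ot = {0.0, 0.0};
  arma::vec2 ht = {hidden_target[0], hidden_target[1]};
  double heading = wander_heading;
  SpatialLUT lut;
  const bool use_lut = params[2] > 0;
  if (use_lut) lut.build(params[0], params[5], g.dist_max);
  RNGScope scope;
  double dist0 = arma::norm(o - p);
  bool alive = dist0 >= cf.collision_radius;
  out.row(0) = arma::rowvec{p[0], p[1], o[0], o[1], alive ? 1.0 : 0.0};
  for (int t = 1; t < n_frames; t++) {
    if (alive) {
      // simultaneous update from the frame t-1 state: the participant reacts
      // to the opponent's position and most recent observed displacement
      arma::vec2 o_before = o, ot_before = ot;
      opponent_step_core(profile, o, ot, heading, p, ht, g, cf);
      glop_step_core(p, pt, o_before, ot_before, params, g, cf, true,
                     use_lut ? &lut : nullptr);
      if (arma::norm(o - p) < cf.collision_radius) alive = false;
    }
    out.row(t) = arma::rowvec{p[0], p[1], o[0], o[1], alive ? 1.0 : 0.0};
  }
  return out;
}

// Deterministic model prediction against an observed trial, resynchronized
// to the observed participant position (and displacement) every
// resync_every frames.  obs columns: p_x, p_y, o_x, o_y.  Movement noise is
// disabled so the prediction is the model's mean path.  Returns predicted
// positions and the mean squared pixel error within each segment.
// [[Rcpp::export]]
List cpp_predict_resync(arma::vec params, arma::mat obs, int resync_every,
                        List geom, List config) {
  Geom g = as_geom(geom);
  Config cf = as_config(config);
  const int L = obs.n_rows;
  SpatialLUT lut;
  const bool use_lut = params[2] > 0;
  if (use_lut) lut.build(params[0], params[5], g.dist_max);
  arma::mat pred(L, 2);
  pred.row(0) = obs.submat(0, 0, 0, 1);
  std::vector<double> seg_mse;
  int a = 0; // anchor frame (0-based)
  while (a < L - 1) {
    arma::vec2 p = {obs(a, 0), obs(a, 1)};
    arma::vec2 pt = {0.0, 0.0};
    if (a > 0)
      pt = {obs(a, 0) - obs(a - 1, 0), obs(a, 1) - obs(a - 1, 1)};
    const int seg_end = std::min(a + resync_every, L - 1);
    double acc = 0.0;
    int cnt = 0;
    for (int t = a + 1; t <= seg_end; t++) {
      arma::vec2 o = {obs(t - 1, 2), obs(t - 1, 3)};
      arma::vec2 ot = {0.0, 0.0};
      if (t - 1 > 0)
        ot = {obs(t - 1, 2) - obs(t - 2, 2), obs(t - 1, 3) - obs(t - 2, 3)};
      glop_step_core(p, pt, o, ot, params, g, cf, false,
                     use_lut ? &lut : nullptr);
      pred(t, 0) = p[0];
      pred(t, 1) = p[1];
      const double ex = p[0] - obs(t, 0), ey = p[1] - obs(t, 1);
      acc += ex * ex + ey * ey;
      cnt++;
    }
    seg_mse.push_back(acc / cnt);
    a = seg_end;
  }
  return List::create(_["predicted"] = pred,
                      _["segment_mse"] = NumericVector(seg_mse.begin(),
                                                       seg_mse.end()));
}
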