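// Core numerical kernels for the cyberslug package.
//
// The scalar decision-variable equations are defined once here and exported
// both as single-value R functions (the testable module surface) and reused
// verbatim inside the compiled trial loop, so the unit-tested formulas are
// the same code the batch experiments execute.
//
// Conventions: headings in degrees, counterclockwise positive; positions in
// cell units with x in [0, width), y in [0, height); odor grids are R
// matrices with rows = y and columns = x.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double kDegToRad = M_PI / 180.0;

// floor-based floating modulo with result in [0, m)
inline double fmod_floor(double v, double m) {
  double r = v - m * std::floor(v / m);
  if (r >= m) r -= m;
  if (r < 0.0) r += m;
  return r;
}

// numerically stable logistic
inline double sigmoid(double x) {
  if (x >= 0.0) {
    return 1.0 / (1.0 + std::exp(-x));
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

inline double wrap_coord(double v, double extent) {
  return fmod_floor(v, extent);
}

// reflecting boundary for non-torus arenas
inline double reflect_coord(double v, double extent) {
  if (extent <= 0.0) return 0.0;
  double period = 2.0 * extent;
  v = fmod_floor(v, period);
  if (v >= extent) v = period - v;
  if (v >= extent) v = std::nextafter(extent, 0.0);
  return v;
}

inline double wrap_delta(double d, double extent) {
  // shortest signed displacement on a circle of circumference `extent`
  d -= extent * std::round(d / extent);
  return d;
}

inline int cell_index(double v, int n) {
  int i = (int)std::floor(v);
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

// log-scaled sensor transduction: max(0, log10(c / floor))
inline double sensor_transform(double conc, double floor_conc) {
  if (conc <= floor_conc) return 0.0;
  return std::log10(conc / floor_conc);
}

inline double satiation_fn(double nutrition, double k4) {
  double d = 1.0 + k4 * std::exp(-4.0 * nutrition + 2.0);
  return 1.0 / (d * d);
}

inline double app_state_fn(double incentive, double satiation,
                           double prev_switch, double k5, double k6,
                           double k7, double baseline) {
  return baseline + sigmoid(k5 * incentive - k6 * satiation) +
         k7 * (prev_switch - 1.0);
}

inline double app_state_switch_fn(double app_state, double k8,
                                  double threshold) {
  return -2.0 * sigmoid(k8 * (app_state - threshold)) + 1.0;
}

inline double turn_angle_fn(double sw, double somatic_map, double k9) {
  return k9 * sw / (1.0 + std::exp(3.0 * somatic_map - sw));
}

inline double somatic_map_fn(double fl, double fr, double hl, double hr,
                             double k0) {
  double sns_flab = 0.5 * (fl + fr);
  double sns_hermi = 0.5 * (hl + hr);
  double F = sns_flab - sns_hermi;
  double H = sns_hermi - sns_flab;
  return (fl - fr) * sigmoid(k0 * F) + (hl - hr) * sigmoid(k0 * H);
}

inline void incentive_fn(double sns_betaine, double sns_hermi,
                         double sns_flab, double Vh, double Vf, double k1,
                         double k3, double& R_plus, double& R_minus,
                         double& incentive) {
  R_plus = sns_betaine / (1.0 + k1 * Vh * sns_hermi) + k3 * Vh * sns_hermi;
  R_minus = k3 * Vf * sns_flab;
  incentive = R_plus - R_minus;
}

inline double rw_update_fn(double V, double alpha, double beta, double lam) {
  return V + alpha * beta * (lam - V);
}

// ---- exported scalar surface ------------------------------------------------

// [[Rcpp::export(name = ".cpp_satiation")]]
double cpp_satiation(double nutrition, double k4) {
  return satiation_fn(nutrition, k4);
}

// [[Rcpp::export(name = ".cpp_app_state")]]
double cpp_app_state(double incentive, double satiation, double prev_switch,
                     double k5, double k6, double k7, double baseline) {
  return app_state_fn(incentive, satiation, prev_switch, k5, k6, k7, baseline);
}

// [[Rcpp::export(name = ".cpp_app_state_switch")]]
double cpp_app_state_switch(double app_state, double k8, double threshold) {
  return app_state_switch_fn(app_state, k8, threshold);
}

// [[Rcpp::export(name = ".cpp_turn_angle")]]
double cpp_turn_angle(double sw, double somatic_map, double k9) {
  return turn_angle_fn(sw, somatic_map, k9);
}

// [[Rcpp::export(name = ".cpp_somatic_map")]]
double cpp_somatic_map(double fl, double fr, double hl, double hr, double k0) {
  return somatic_map_fn(fl, fr, hl, hr, k0);
}

// [[Rcpp::export(name = ".cpp_incentive")]]
NumericVector cpp_incentive(double sns_betaine, double sns_hermi,
                            double sns_flab, double Vh, double Vf, double k1,
                            double k3) {
  double rp, rm, inc;
  incentive_fn(sns_betaine, sns_hermi, sns_flab, Vh, Vf, k1, k3, rp, rm, inc);
  return NumericVector::create(_["R_plus"] = rp, _["R_minus"] = rm,
                               _["incentive"] = inc);
}

// [[Rcpp::export(name = ".cpp_rw_update")]]
double cpp_rw_update(double V, double alpha, double beta, double lam) {
  return rw_update_fn(V, alpha, beta, lam);
}

// [[Rcpp::export(name = ".cpp_sensor_transform")]]
double cpp_sensor_transform(double conc, double floor_conc) {
  return sensor_transform(conc, floor_conc);
}

// ---- diffusion --------------------------------------------------------------

// One NetLogo-style `diffuse` step followed by multiplicative decay.
// Each cell gives `rate` of its content split equally among its 8 Moore
// neighbours; on a non-wrapping arena the shares that would leave the grid
// stay in place, so the operator conserves mass under both topologies.
static void diffuse_decay_inplace(std::vector<double>& f,
                                  std::vector<double>& buf, int H, int W,
                                  double rate, double decay, bool wrap) {
  const double share = rate / 8.0;
  const double keep_decay = 1.0 - decay;
  // buf <- sum over the 3x3 box (including centre); done separably:
  // vertical 3-sum into buf, then horizontal 3-sum of buf in place per row
  // via a temporary column copy. Column-major layout: index = y + H * x.
  static thread_local std::vector<double> vert;
  vert.resize(f.size());
  for (int x = 0; x < W; ++x) {
    const double* col = &f[(size_t)H * x];
    double* v = &vert[(size_t)H * x];
    for (int y = 0; y < H; ++y) {
      int ym = y - 1, yp = y + 1;
      double s = col[y];
      if (ym >= 0) s += col[ym];
      else if (wrap) s += col[H - 1];
      if (yp < H) s += col[yp];
      else if (wrap) s += col[0];
      v[y] = s;
    }
  }
  for (int x = 0; x < W; ++x) {
    int xm = x - 1, xp = x + 1;
    const double* v0 = &vert[(size_t)H * x];
    const double* vm = (xm >= 0) ? &vert[(size_t)H * xm]
                                 : (wrap ? &vert[(size_t)H * (W - 1)] : NULL);
    const double* vp = (xp < W) ? &vert[(size_t)H * xp]
                                : (wrap ? &vert[0] : NULL);
    double* b = &buf[(size_t)H * x];
    for (int y = 0; y < H; ++y) {
      double s = v0[y];
      if (vm) s += vm[y];
      if (vp) s += vp[y];
      b[y] = s;
    }
  }
  if (wrap) {
    for (size_t i = 0; i < f.size(); ++i) {
      // box sum minus centre = sum of the 8 neighbours
      double neigh = buf[i] - f[i];
      f[i] = keep_decay * ((1.0 - rate) * f[i] + share * neigh);
    }
  } else {
    // interior cells of the box sum are complete; edge cells received fewer
    // contributions, and symmetrically give fewer shares away: cell (x,y)
    // has nn(x,y) in-grid neighbours, keeps (8-nn)/8 of its outgoing share.
    for (int x = 0; x < W; ++x) {
      int nx = (x == 0 || x == W - 1) ? 1 : 2; // neighbour columns span
      for (int y = 0; y < H; ++y) {
        int ny = (y == 0 || y == H - 1) ? 1 : 2;
        int nn = (nx + 1) * (ny + 1) - 1; // in-grid Moore neighbours
        size_t i = (size_t)(y + H * x);
        double neigh = buf[i] - f[i];
        double kept = f[i] * (1.0 - rate) + f[i] * share * (8 - nn);
        f[i] = keep_decay * (kept + share * neigh);
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_diffuse_decay")]]
NumericMatrix cpp_diffuse_decay(NumericMatrix field, double rate, double decay,
                                bool wrap) {
  int H = field.nrow(), W = field.ncol();
  std::vector<double> f(field.begin(), field.end());
  std::vector<double> buf(f.size());
  diffuse_decay_inplace(f, buf, H, W, rate, decay, wrap);
  NumericMatrix out(H, W);
  std::copy(f.begin(), f.end(), out.begin());
  return out;
}

// ---- full trial loop --------------------------------------------------------

// Runs `n_steps` of the foraging simulation. All randomness comes from R's
// RNG (seed it with set.seed() before calling). Draw order per step is:
// one heading perturbation per prey, one wander draw if the agent is not
// engaged, then x/y/heading for each respawned prey.
// [[Rcpp::export(name = ".cpp_run_trial")]]
List cpp_run_trial(List cfg) {
  // arena
  const int W = as<int>(cfg["width"]);
  const int H = as<int>(cfg["height"]);
  const bool torus = as<bool>(cfg["wrap"]);
  const double diffusion_rate = as<double>(cfg["diffusion_rate"]);
  const double decay_rate = as<double>(cfg["decay_rate"]);
  const double prey_step = as<double>(cfg["prey_step_length"]);
  const double max_prey_turn = as<double>(cfg["max_prey_turn"]);
  const double emission = as<double>(cfg["prey_odor_emission"]);
  const double consumption_radius = as<double>(cfg["consumption_radius"]);
  // agent geometry / locomotion
  const double body_length = as<double>(cfg["body_length"]);
  const double sensor_distance = as<double>(cfg["sensor_distance"]);
  const double sensor_angle = as<double>(cfg["sensor_angle"]);
  const double agent_speed = as<double>(cfg["agent_speed"]);
  const double sensor_floor = as<double>(cfg["sensor_floor"]);
  const double engage_threshold = as<double>(cfg["engage_threshold"]);
  // constants
  const double k0 = as<double>(cfg["k0"]), k1 = as<double>(cfg["k1"]);
  const double k3 = as<double>(cfg["k3"]), k4 = as<double>(cfg["k4"]);
  const double k5 = as<double>(cfg["k5"]), k6 = as<double>(cfg["k6"]);
  const double k7 = as<double>(cfg["k7"]), k8 = as<double>(cfg["k8"]);
  const double k9 = as<double>(cfg["k9"]);
  const double switch_threshold = as<double>(cfg["switch_threshold"]);
  const double app_state_baseline = as<double>(cfg["app_state_baseline"]);
  const double nutrition_decay = as<double>(cfg["nutrition_decay"]);
  const double feed_gain = as<double>(cfg["feed_gain"]);
  const double alpha = as<double>(cfg["alpha"]);
  const double beta = as<double>(cfg["beta"]);
  const double lambda = as<double>(cfg["lambda"]);
  // scenario
  const int n_steps = as<int>(cfg["n_steps"]);
  const bool learning_enabled = as<bool>(cfg["learning_enabled"]);
  const bool satiation_enabled = as<bool>(cfg["satiation_enabled"]);
  const int trace_every = as<int>(cfg["trace_every"]);
  const double satiation_clamp = as<double>(cfg["satiation_clamp"]);

  // initial state (built in R so the RNG stream is shared)
  IntegerVector prey_species = clone(as<IntegerVector>(cfg["prey_species"]));
  NumericVector prey_x = clone(as<NumericVector>(cfg["prey_x"]));
  NumericVector prey_y = clone(as<NumericVector>(cfg["prey_y"]));
  NumericVector prey_h = clone(as<NumericVector>(cfg["prey_heading"]));
  const int n_prey = prey_species.size();
  double ax = as<double>(cfg["agent_x"]);
  double ay = as<double>(cfg["agent_y"]);
  double ah = as<double>(cfg["agent_heading"]);
  double nutrition = as<double>(cfg["nutrition"]);
  double Vh = as<double>(cfg["Vh"]);
  double Vf = as<double>(cfg["Vf"]);
  double prev_switch = as<double>(cfg["prev_switch"]);

  // odor fields: 0 = betaine, 1 = hermi, 2 = flab
  std::vector<double> field[3];
  std::vector<double> buf((size_t)W * H);
  for (int c = 0; c < 3; ++c) field[c].assign((size_t)W * H, 0.0);

  const double Wd = (double)W, Hd = (double)H;
  const double sens_r = sensor_distance * body_length;
  const double mouth_r = 0.5 * body_length;

  long counts[3] = {0, 0, 0};
  std::vector<int> consumed_step, consumed_species;

  int n_trace = (trace_every > 0) ? (n_steps / trace_every + 1) : 0;
  NumericMatrix trace(n_trace, 12);
  int trace_row = 0;

  RNGScope rng;

  for (int step = 1; step <= n_steps; ++step) {
    // (1) prey random walk
    for (int p = 0; p < n_prey; ++p) {
      double dturn = R::runif(-max_prey_turn, max_prey_turn);
      prey_h[p] += dturn;
      if (prey_step > 0.0) {
        double hr = prey_h[p] * kDegToRad;
        double nx = prey_x[p] + prey_step * std::cos(hr);
        double ny = prey_y[p] + prey_step * std::sin(hr);
        if (torus) {
          prey_x[p] = wrap_coord(nx, Wd);
          prey_y[p] = wrap_coord(ny, Hd);
        } else {
          prey_x[p] = reflect_coord(nx, Wd);
          prey_y[p] = reflect_coord(ny, Hd);
        }
      }
    }
    // (2) odor deposition, diffusion, decay
    for (int p = 0; p < n_prey; ++p) {
      int ix = cell_index(prey_x[p], W);
      int iy = cell_index(prey_y[p], H);
      size_t i = (size_t)(iy + H * ix);
      field[0][i] += emission; // betaine from every prey
      // species signature: hermi -> hermi channel; flab AND the Batesian
      // mimic fauxflab -> flab channel
      int chan = (prey_species[p] == 1) ? 1 : 2;
      field[chan][i] += emission;
    }
    for (int c = 0; c < 3; ++c)
      diffuse_decay_inplace(field[c], buf, H, W, diffusion_rate, decay_rate,
                            torus);
    // (3) sensors + somatic map
    double hr = ah * kDegToRad;
    double la = (ah + sensor_angle) * kDegToRad;
    double ra = (ah - sensor_angle) * kDegToRad;
    double lx = ax + sens_r * std::cos(la), ly = ay + sens_r * std::sin(la);
    double rx = ax + sens_r * std::cos(ra), ry = ay + sens_r * std::sin(ra);
    if (torus) {
      lx = wrap_coord(lx, Wd); ly = wrap_coord(ly, Hd);
      rx = wrap_coord(rx, Wd); ry = wrap_coord(ry, Hd);
    } else {
      lx = reflect_coord(lx, Wd); ly = reflect_coord(ly, Hd);
      rx = reflect_coord(rx, Wd); ry = reflect_coord(ry, Hd);
    }
    size_t li = (size_t)(cell_index(ly, H) + H * cell_index(lx, W));
    size_t ri = (size_t)(cell_index(ry, H) + H * cell_index(rx, W));
    double sns_bl = sensor_transform(field[0][li], sensor_floor);
    double sns_br = sensor_transform(field[0][ri], sensor_floor);
    double sns_hl = sensor_transform(field[1][li], sensor_floor);
    double sns_hr2 = sensor_transform(field[1][ri], sensor_floor);
    double sns_fl = sensor_transform(field[2][li], sensor_floor);
    double sns_fr = sensor_transform(field[2][ri], sensor_floor);
    double sns_betaine = 0.5 * (sns_bl + sns_br);
    double sns_hermi = 0.5 * (sns_hl + sns_hr2);
    double sns_flab = 0.5 * (sns_fl + sns_fr);
    double som_map = somatic_map_fn(sns_fl, sns_fr, sns_hl, sns_hr2, k0);
    // (4) incentive
    double R_plus, R_minus, inc;
    incentive_fn(sns_betaine, sns_hermi, sns_flab, Vh, Vf, k1, k3, R_plus,
                 R_minus, inc);
    // (5) satiation (clamped to a fixed hungry value when inactivated)
    double sat = satiation_enabled ? satiation_fn(nutrition, k4)
                                   : satiation_clamp;
    // (6) appetitive state, using the previous step's switch
    double app = app_state_fn(inc, sat, prev_switch, k5, k6, k7,
                              app_state_baseline);
    // (7) new approach-avoidance switch
    double sw = app_state_switch_fn(app, k8, switch_threshold);
    // (8) turn: decision turn when engaged with odor, wander otherwise
    bool engaged = (sns_betaine > engage_threshold) ||
                   (sns_hermi > engage_threshold) ||
                   (sns_flab > engage_threshold);
    double turn = engaged ? turn_angle_fn(sw, som_map, k9)
                          : R::runif(-1.0, 1.0);
    // (9) advance. The decision turn is a signed amplitude (negative in
    // approach, positive in avoidance); the somatic map supplies the side:
    // with the stimulus on the left (positive place code), an approach
    // turn rotates counterclockwise (toward it) and an avoidance turn
    // clockwise (away), and mirrored for a stimulus on the right.
    double dh = turn;
    if (engaged) dh = (som_map >= 0.0) ? -turn : turn;
    ah += dh;
    ah = fmod_floor(ah, 360.0);
    hr = ah * kDegToRad;
    {
      double nx = ax + agent_speed * std::cos(hr);
      double ny = ay + agent_speed * std::sin(hr);
      if (torus) { ax = wrap_coord(nx, Wd); ay = wrap_coord(ny, Hd); }
      else { ax = reflect_coord(nx, Wd); ay = reflect_coord(ny, Hd); }
    }
    // (10) consumption at the mouth, respawn, nutrition + learning
    double mx = ax + mouth_r * std::cos(hr);
    double my = ay + mouth_r * std::sin(hr);
    if (torus) { mx = wrap_coord(mx, Wd); my = wrap_coord(my, Hd); }
    int n_eaten = 0;
    for (int p = 0; p < n_prey; ++p) {
      double dx = prey_x[p] - mx, dy = prey_y[p] - my;
      if (torus) { dx = wrap_delta(dx, Wd); dy = wrap_delta(dy, Hd); }
      if (dx * dx + dy * dy <= consumption_radius * consumption_radius) {
        int sp = prey_species[p];
        counts[sp] += 1;
        consumed_step.push_back(step);
        consumed_species.push_back(sp);
        n_eaten += 1;
        if (learning_enabled) {
          if (sp == 1) Vh = rw_update_fn(Vh, alpha, beta, lambda);
          else if (sp == 0) Vf = rw_update_fn(Vf, alpha, beta, lambda);
          else Vf = rw_update_fn(Vf, alpha, beta, 0.0); // mimic: extinction
        }
        prey_x[p] = R::runif(0.0, Wd);
        prey_y[p] = R::runif(0.0, Hd);
        prey_h[p] = R::runif(0.0, 360.0);
      }
    }
    nutrition = nutrition * (1.0 - nutrition_decay) + feed_gain * n_eaten;
    prev_switch = sw;

    if (trace_every > 0 && (step % trace_every == 0) && trace_row < n_trace) {
      trace(trace_row, 0) = step;
      trace(trace_row, 1) = ax;
      trace(trace_row, 2) = ay;
      trace(trace_row, 3) = ah;
      trace(trace_row, 4) = nutrition;
      trace(trace_row, 5) = sat;
      trace(trace_row, 6) = inc;
      trace(trace_row, 7) = app;
      trace(trace_row, 8) = sw;
      trace(trace_row, 9) = turn;
      trace(trace_row, 10) = Vh;
      trace(trace_row, 11) = Vf;
      trace_row += 1;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["consumed_flab"] = (double)counts[0],
      _["consumed_hermi"] = (double)counts[1],
      _["consumed_fauxflab"] = (double)counts[2],
      _["consumed_step"] = wrap(consumed_step),
      _["consumed_species"] = wrap(consumed_species),
      _["Vh"] = Vh, _["Vf"] = Vf, _["nutrition"] = nutrition,
      _["agent_x"] = ax, _["agent_y"] = ay, _["agent_heading"] = ah,
      _["prev_switch"] = prev_switch);
  if (trace_every > 0) {
    out["trace"] = trace(Range(0, std::max(trace_row - 1, 0)), Range(0, 11));
  }
  return out;
}
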