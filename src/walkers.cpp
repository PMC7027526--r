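#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Resample a finely sampled polyline at equal Euclidean (chord) spacing dl.
// Vertices stay on the input polyline; marching guarantees |v_{i+1} - v_i| = dl
// to machine precision, which is the discretization contract of the fiber model.
// [[Rcpp::export]]
NumericMatrix resample_equal_chord(NumericVector x, NumericVector y, double dl) {
  int n = x.size();
  if (n < 2) stop("polyline needs at least two points");
  double total = 0.0;
  for (int i = 1; i < n; ++i) {
    double dx = x[i] - x[i - 1], dy = y[i] - y[i - 1];
    total += std::sqrt(dx * dx + dy * dy);
  }
  int cap = (int)(total / dl) + 2;
  std::vector<double> ox, oy;
  ox.reserve(cap); oy.reserve(cap);
  double px = x[0], py = y[0];
  ox.push_back(px); oy.push_back(py);
  int j = 0;
  double dl2 = dl * dl;
  while (true) {
    while (j + 1 < n) {
      double dx = x[j + 1] - px, dy = y[j + 1] - py;
      if (dx * dx + dy * dy >= dl2) break;
      ++j;
    }
    if (j + 1 >= n) break;
    // forward intersection of the circle |P' - P| = dl with segment j -> j+1
    double ax = x[j], ay = y[j];
    double ux = x[j + 1] - ax, uy = y[j + 1] - ay;
    double wx = ax - px, wy = ay - py;
    double A = ux * ux + uy * uy;
    double B = 2.0 * (wx * ux + wy * uy);
    double C = wx * wx + wy * wy - dl2;
    double disc = B * B - 4.0 * A * C;
    if (disc < 0) disc = 0;
    double t = (-B + std::sqrt(disc)) / (2.0 * A);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    px = ax + t * ux; py = ay + t * uy;
    ox.push_back(px); oy.push_back(py);
  }
  NumericMatrix out(ox.size(), 2);
  for (size_t i = 0; i < ox.size(); ++i) { out(i, 0) = ox[i]; out(i, 1) = oy[i]; }
  return out;
}

static inline double interp_at(const NumericVector& v, double dl, double s) {
  double u = s / dl;
  int j = (int)std::floor(u);
  if (j < 0) j = 0;
  int nmax = v.size() - 2;
  if (j > nmax) j = nmax;
  double f = u - j;
  return v[j] + f * (v[j + 1] - v[j]);
}

// 1D Gaussian diffusion in arc length, remapped through the discretized
// trajectory; transverse (y) and longitudinal (x) squared displacements are
// accumulated at save times. Uses R's RNG (set.seed on the R side).
// [[Rcpp::export]]
List mc_thin_fiber_cpp(NumericVector xv, NumericVector yv, double dl, double D0,
                       int n_particles, double dt, int n_steps, int save_every,
                       double s_min, double s_max) {
  int n_save = n_steps / save_every;
  NumericVector sum_y2(n_save), sum_y4(n_save), sum_x2(n_save);
  double L = (xv.size() - 1) * dl;
  double sd = std::sqrt(2.0 * D0 * dt);
  for (int k = 0; k < n_particles; ++k) {
    double s = s_min + unif_rand() * (s_max - s_min);
    double y0 = interp_at(yv, dl, s);
    double x0 = interp_at(xv, dl, s);
    int isave = 0;
    for (int step = 1; step <= n_steps; ++step) {
      s += norm_rand() * sd;
      if (s < 0) s = -s;                 // end reflections: hit with prob ~0
      else if (s > L) s = 2.0 * L - s;   // when margins are honoured
      if (step % save_every == 0) {
        double dy = interp_at(yv, dl, s) - y0;
        double dx = interp_at(xv, dl, s) - x0;
        double d2 = dy * dy;
        sum_y2[isave] += d2;
        sum_y4[isave] += d2 * d2;
        sum_x2[isave] += dx * dx;
        ++isave;
      }
    }
  }
  return List::create(_["sum_y2"] = sum_y2, _["sum_y4"] = sum_y4,
                      _["sum_x2"] = sum_x2);
}

// Phase accrual along thin-fiber walks: Phi_k = gamma * sum g(t) y_k(t) dt for
// each column of g (one waveform per column, sampled every dt).
// [[Rcpp::export]]
NumericMatrix mc_fiber_phases_cpp(NumericVector yv, double dl, double D0,
                                  int n_particles, double dt, NumericMatrix g,
                                  double gamma_eff, double s_min, double s_max) {
  int n_steps = g.nrow(), n_wave = g.ncol();
  double L = (yv.size() - 1) * dl;
  double sd = std::sqrt(2.0 * D0 * dt);
  NumericMatrix phi(n_particles, n_wave);
  for (int k = 0; k < n_particles; ++k) {
    double s = s_min + unif_rand() * (s_max - s_min);
    for (int step = 0; step < n_steps; ++step) {
      s += norm_rand() * sd;
      if (s < 0) s = -s;
      else if (s > L) s = 2.0 * L - s;
      double y = interp_at(yv, dl, s);
      for (int w = 0; w < n_wave; ++w) phi(k, w) += g(step, w) * y;
    }
    for (int w = 0; w < n_wave; ++w) phi(k, w) *= gamma_eff * dt;
  }
  return phi;
}

// Fixed-step 2D random walk inside the undulating strip
// |y - a sin(2 pi x / lambda)| <= d/2; steps crossing the boundary are
// rejected (walker stays). Transverse squared displacement at save times.
// [[Rcpp::export]]
List mc_strip_cpp(double d, double a, double lambda, int n_particles,
                  double dx, int n_steps, int save_every) {
  int n_save = n_steps / save_every;
  NumericVector sum_y2(n_save), sum_y4(n_save);
  double half = d / 2.0;
  double w0 = 2.0 * M_PI / lambda;
  for (int k = 0; k < n_particles; ++k) {
    double x = unif_rand() * lambda;
    double y = a * std::sin(w0 * x) + (unif_rand() - 0.5) * d;
    double y0 = y;
    int isave = 0;
    for (int step = 1; step <= n_steps; ++step) {
      double ang = 2.0 * M_PI * unif_rand();
      double xn = x + dx * std::cos(ang);
      double yn = y + dx * std::sin(ang);
      if (std::fabs(yn - a * std::sin(w0 * xn)) <= half) { x = xn; y = yn; }
      if (step % save_every == 0) {
        double dy = y - y0;
        double d2 = dy * dy;
        sum_y2[isave] += d2;
        sum_y4[isave] += d2 * d2;
        ++isave;
      }
    }
  }
  return List::create(_["sum_y2"] = sum_y2, _["sum_y4"] = sum_y4);
}
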