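#include <Rcpp.h>
using namespace Rcpp;

// Arena encoding shared with R: shape 0 = circle of radius R centred at the
// origin; shape 1 = rectangle [0, W] x [0, H]. All lengths in mm.

// Desired steering direction from the wall-bias term: no influence beyond
// twice the edge band (walls are only perceived nearby), toward the nearest
// wall between one and two band widths out, tangentially along it (in the
// sense closest to the current heading) once inside the band.
static inline bool wall_dir(int shape, double R, double W, double H, double band,
                            double x, double y, double hx, double hy,
                            double &wx, double &wy) {
  if (shape == 0) {
    double r = std::sqrt(x * x + y * y);
    if (r < 1e-9) return false;
    double d = R - r;
    if (d > 2 * band) return false;
    double ox = x / r, oy = y / r;
    if (d > band) { wx = ox; wy = oy; return true; }
    double tx = -oy, ty = ox;
    if (hx * tx + hy * ty < 0) { tx = -tx; ty = -ty; }
    wx = tx; wy = ty; return true;
  }
  double d = x; int w = 0;
  if (W - x < d) { d = W - x; w = 1; }
  if (y < d)     { d = y;     w = 2; }
  if (H - y < d) { d = H - y; w = 3; }
  if (d > 2 * band) return false;
  double ox, oy;
  switch (w) {
    case 0:  ox = -1; oy = 0; break;
    case 1:  ox = 1;  oy = 0; break;
    case 2:  ox = 0;  oy = -1; break;
    default: ox = 0;  oy = 1;  break;
  }
  if (d > band) { wx = ox; wy = oy; return true; }
  double tx = -oy, ty = ox;
  if (hx * tx + hy * ty < 0) { tx = -tx; ty = -ty; }
  wx = tx; wy = ty; return true;
}

// Specular-style reflection of an out-of-bounds position back into the
// arena; returns true when a reflection happened (callers then scatter the
// heading, emulating an avoidance turn rather than a billiard bounce).
static inline bool reflect_pos(int shape, double R, double W, double H,
                               double &x, double &y) {
  if (shape == 0) {
    double r = std::sqrt(x * x + y * y);
    if (r > R) {
      double rn = 2.0 * R - r;
      if (rn < 0) rn = 0;
      double s = (r > 0) ? rn / r : 0.0;
      x *= s; y *= s;
      return true;
    }
    return false;
  }
  bool refl = false;
  for (int it = 0; it < 8; ++it) {
    bool ok = true;
    if (x < 0)      { x = -x;         ok = false; refl = true; }
    else if (x > W) { x = 2 * W - x;  ok = false; refl = true; }
    if (y < 0)      { y = -y;         ok = false; refl = true; }
    else if (y > H) { y = 2 * H - y;  ok = false; refl = true; }
    if (ok) break;
  }
  if (x < 0) x = 0; if (x > W) x = W;
  if (y < 0) y = 0; if (y > H) y = H;
  return refl;
}

// heading of the inward wall normal at the nearest wall (collision-
// avoidance turn direction; symmetric tangentially so wall contacts do not
// drift the walk along the wall)
static inline double inward_normal(int shape, double R, double W, double H,
                                   double x, double y) {
  if (shape == 0) return std::atan2(-y, -x);
  double d = x; double ang = 0.0;            // left wall -> +x
  if (W - x < d) { d = W - x; ang = M_PI; }  // right -> -x
  if (y < d)     { d = y;     ang = M_PI_2; }      // bottom -> +y
  if (H - y < d) { d = H - y; ang = -M_PI_2; }     // top -> -y
  return ang;
}

static inline void blend(double &ux, double &uy, double bx, double by, double w) {
  ux = (1.0 - w) * ux + w * bx;
  uy = (1.0 - w) * uy + w * by;
  double n = std::sqrt(ux * ux + uy * uy);
  if (n > 1e-12) { ux /= n; uy /= n; }
}

// Correlated random walk for a single agent. speed/turn are pre-drawn in R
// (one entry per step) so the R RNG seed fully determines the path.
// [[Rcpp::export]]
List crw_path_cpp(double x0, double y0, double h0,
                  NumericVector speed, NumericVector turn, NumericVector scat,
                  double dt,
                  double kappa, double social_w, double social_x, double social_y,
                  int shape, double R, double W, double H, double band) {
  int n = speed.size();
  NumericVector x(n + 1), y(n + 1);
  x[0] = x0; y[0] = y0;
  double h = h0;
  for (int i = 0; i < n; ++i) {
    double hn = h + turn[i];
    double ux = std::cos(hn), uy = std::sin(hn);
    if (kappa > 0) {
      double wx, wy;
      if (wall_dir(shape, R, W, H, band, x[i], y[i], ux, uy, wx, wy))
        blend(ux, uy, wx, wy, kappa);
    }
    if (social_w > 0) {
      double sx = social_x - x[i], sy = social_y - y[i];
      double nr = std::sqrt(sx * sx + sy * sy);
      if (nr > 1e-9) blend(ux, uy, sx / nr, sy / nr, social_w);
    }
    double nx = x[i] + speed[i] * dt * ux;
    double ny = y[i] + speed[i] * dt * uy;
    bool refl = reflect_pos(shape, R, W, H, nx, ny);
    if (refl) {
      h = inward_normal(shape, R, W, H, nx, ny) + scat[i];
    } else {
      double dx = nx - x[i], dy = ny - y[i];
      h = (dx * dx + dy * dy > 1e-18) ? std::atan2(dy, dx) : hn;
    }
    x[i + 1] = nx; y[i + 1] = ny;
  }
  return List::create(_["x"] = x, _["y"] = y, _["h"] = h);
}

// k coupled agents; each heading is additionally steered toward the
// instantaneous group centroid with weight `cohesion`.
// [[Rcpp::export]]
List crw_shoal_cpp(NumericVector x0, NumericVector y0, NumericVector h0,
                   NumericMatrix speed, NumericMatrix turn, NumericMatrix scat,
                   double dt,
                   double kappa, double cohesion,
                   int shape, double R, double W, double H, double band) {
  int n = speed.nrow(), k = speed.ncol();
  NumericMatrix x(n + 1, k), y(n + 1, k);
  std::vector<double> h(k);
  for (int j = 0; j < k; ++j) { x(0, j) = x0[j]; y(0, j) = y0[j]; h[j] = h0[j]; }
  for (int i = 0; i < n; ++i) {
    double cx = 0, cy = 0;
    for (int j = 0; j < k; ++j) { cx += x(i, j); cy += y(i, j); }
    cx /= k; cy /= k;
    for (int j = 0; j < k; ++j) {
      double hn = h[j] + turn(i, j);
      double ux = std::cos(hn), uy = std::sin(hn);
      if (kappa > 0) {
        double wx, wy;
        if (wall_dir(shape, R, W, H, band, x(i, j), y(i, j), ux, uy, wx, wy))
          blend(ux, uy, wx, wy, kappa);
      }
      if (cohesion > 0) {
        double gx = cx - x(i, j), gy = cy - y(i, j);
        double nr = std::sqrt(gx * gx + gy * gy);
        if (nr > 1e-9) blend(ux, uy, gx / nr, gy / nr, cohesion);
      }
      double nx = x(i, j) + speed(i, j) * dt * ux;
      double ny = y(i, j) + speed(i, j) * dt * uy;
      bool refl = reflect_pos(shape, R, W, H, nx, ny);
      if (refl) {
        h[j] = inward_normal(shape, R, W, H, nx, ny) + scat(i, j);
      } else {
        double dx = nx - x(i, j), dy = ny - y(i, j);
        h[j] = (dx * dx + dy * dy > 1e-18) ? std::atan2(dy, dx) : hn;
      }
      x(i + 1, j) = nx; y(i + 1, j) = ny;
    }
  }
  return List::create(_["x"] = x, _["y"] = y, _["h"] = NumericVector(h.begin(), h.end()));
}
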