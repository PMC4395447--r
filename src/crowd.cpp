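#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double EPS = 1e-10;

static inline double det2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

static inline double wrap_diff(double dx, double period) {
  if (!std::isnan(period) && period > 0.0) {
    dx -= period * std::round(dx / period);
  }
  return dx;
}

// ---------------------------------------------------------------------------
// rasterization
// ---------------------------------------------------------------------------

// Even-odd rule point-in-polygon for one ring (open ring: last vertex joins first).
static bool point_in_ring(double px, double py, const NumericMatrix &ring) {
  int n = ring.nrow();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double xi = ring(i, 0), yi = ring(i, 1);
    double xj = ring(j, 0), yj = ring(j, 1);
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)) {
      inside = !inside;
    }
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_polygons(NumericVector px, NumericVector py,
                                     List polygons) {
  int n = px.size();
  LogicalVector out(n, false);
  for (int k = 0; k < polygons.size(); ++k) {
    NumericMatrix ring = polygons[k];
    if (ring.nrow() < 3) continue;
    for (int i = 0; i < n; ++i) {
      if (!out[i] && point_in_ring(px[i], py[i], ring)) out[i] = true;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// contiguous free space field
// ---------------------------------------------------------------------------

// occ: nx x ny occupancy lattice (true = obstacle cell). kernel: (2R+1)^2
// normalized weight stencil, zero outside the circular support. For each free
// cell the FS value is the kernel mass over the subset of support cells that
// are 4-connected-reachable from the center through free cells within the
// support window. Cells outside the lattice count as free.
// [[Rcpp::export]]
NumericMatrix cpp_fs_field(LogicalMatrix occ, NumericMatrix kernel) {
  int nx = occ.nrow(), ny = occ.ncol();
  int K = kernel.nrow();
  if (kernel.ncol() != K || K % 2 != 1)
    stop("kernel must be a square matrix with odd side length");
  int R = (K - 1) / 2;
  NumericMatrix fs(nx, ny);
  int W = 2 * R + 1;
  std::vector<char> visited(W * W);
  std::vector<int> stack;
  stack.reserve(W * W);
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      if (occ(i, j)) {
        fs(i, j) = NA_REAL;
        continue;
      }
      std::fill(visited.begin(), visited.end(), 0);
      stack.clear();
      int c0 = R * W + R;
      visited[c0] = 1;
      stack.push_back(c0);
      static const int DX[4] = {1, -1, 0, 0};
      static const int DY[4] = {0, 0, 1, -1};
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int di = cur / W - R, dj = cur % W - R;
        for (int d = 0; d < 4; ++d) {
          int ni = di + DX[d], nj = dj + DY[d];
          if (ni < -R || ni > R || nj < -R || nj > R) continue;
          int idx = (ni + R) * W + (nj + R);
          if (visited[idx]) continue;
          if (kernel(ni + R, nj + R) <= 0.0) continue;  // outside support
          int gi = i + ni, gj = j + nj;
          bool occupied = (gi >= 0 && gi < nx && gj >= 0 && gj < ny) &&
                          occ(gi, gj);
          if (occupied) continue;
          visited[idx] = 1;
          stack.push_back(idx);
        }
      }
      // sum in canonical column-major stencil order with extended-precision
      // accumulation (matching R's sum()), so the result does not depend on
      // the traversal order of the flood fill
      long double sum = 0.0L;
      for (int kc = 0; kc < W; ++kc) {
        for (int kr = 0; kr < W; ++kr) {
          if (visited[kr * W + kc]) sum += kernel(kr, kc);
        }
      }
      fs(i, j) = (double)sum;
    }
  }
  return fs;
}

// Bilinear interpolation of the FS lattice at world coordinates. Cell (i, j)
// has center (ox + (i + 0.5) cb, oy + (j + 0.5) cb). NA (occupied) corners
// are dropped and the remaining weights renormalized; if all four corners are
// occupied, the nearest positive FS within an expanding ring is returned
// (floor value for probe points grazing obstacle cells).
// [[Rcpp::export]]
NumericVector cpp_fs_bilinear(NumericMatrix fs, double ox, double oy,
                              double cb, NumericVector px, NumericVector py) {
  int nx = fs.nrow(), ny = fs.ncol();
  int n = px.size();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double gx = (px[q] - ox) / cb - 0.5;
    double gy = (py[q] - oy) / cb - 0.5;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
    double fx = gx - i0, fy = gy - j0;
    double wsum = 0.0, vsum = 0.0;
    for (int a = 0; a <= 1; ++a) {
      for (int b = 0; b <= 1; ++b) {
        int ii = std::min(std::max(i0 + a, 0), nx - 1);
        int jj = std::min(std::max(j0 + b, 0), ny - 1);
        double v = fs(ii, jj);
        if (NumericVector::is_na(v)) continue;
        double w = (a ? fx : 1.0 - fx) * (b ? fy : 1.0 - fy);
        wsum += w;
        vsum += w * v;
      }
    }
    if (wsum > 1e-12) {
      out[q] = vsum / wsum;
    } else {
      // all four corners occupied: expanding ring search for a free cell
      int ci = std::min(std::max((int)std::floor((px[q] - ox) / cb), 0), nx - 1);
      int cj = std::min(std::max((int)std::floor((py[q] - oy) / cb), 0), ny - 1);
      double best = NA_REAL;
      for (int r = 1; r < std::max(nx, ny) && NumericVector::is_na(best); ++r) {
        for (int ii = ci - r; ii <= ci + r; ++ii) {
          for (int jj = cj - r; jj <= cj + r; ++jj) {
            if (std::max(std::abs(ii - ci), std::abs(jj - cj)) != r) continue;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
            double v = fs(ii, jj);
            if (!NumericVector::is_na(v) && v > 0.0) {
              if (NumericVector::is_na(best) || v < best) best = v;
            }
          }
        }
      }
      out[q] = NumericVector::is_na(best) ? 1e-6 : best;
    }
  }
  return out;
}

// scalar bilinear FS lookup without R allocations (hot path of the filter)
static double fs_bilin_scalar(const NumericMatrix &fs, double ox, double oy,
                              double cb, double px, double py) {
  int nx = fs.nrow(), ny = fs.ncol();
  double gx = (px - ox) / cb - 0.5;
  double gy = (py - oy) / cb - 0.5;
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
  double fx = gx - i0, fy = gy - j0;
  double wsum = 0.0, vsum = 0.0;
  for (int a = 0; a <= 1; ++a) {
    for (int b = 0; b <= 1; ++b) {
      int ii = std::min(std::max(i0 + a, 0), nx - 1);
      int jj = std::min(std::max(j0 + b, 0), ny - 1);
      double v = fs(ii, jj);
      if (ISNAN(v)) continue;
      double w = (a ? fx : 1.0 - fx) * (b ? fy : 1.0 - fy);
      wsum += w;
      vsum += w * v;
    }
  }
  if (wsum > 1e-12) return vsum / wsum;
  // all four corners occupied: expanding ring search for the nearest free FS
  int ci = std::min(std::max((int)std::floor((px - ox) / cb), 0), nx - 1);
  int cj = std::min(std::max((int)std::floor((py - oy) / cb), 0), ny - 1);
  for (int r = 1; r < std::max(nx, ny); ++r) {
    double best = std::numeric_limits<double>::infinity();
    for (int ii = ci - r; ii <= ci + r; ++ii) {
      for (int jj = cj - r; jj <= cj + r; ++jj) {
        if (std::max(std::abs(ii - ci), std::abs(jj - cj)) != r) continue;
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
        double v = fs(ii, jj);
        if (!ISNAN(v) && v > 0.0 && v < best) best = v;
      }
    }
    if (std::isfinite(best)) return best;
  }
  return 1e-6;
}

// ---------------------------------------------------------------------------
// density filter
// ---------------------------------------------------------------------------

// Arc-sampled density-dependent correction of the preferred velocity, batch
// over all agents. Samples are evaluated in tie-break order (theta = 0, then
// by increasing |theta| with the negative offset first) and a sample replaces
// the incumbent only on strictly smaller goal cost.
// [[Rcpp::export]]
NumericMatrix cpp_filter_batch(NumericMatrix pos, NumericMatrix v0,
                               NumericVector pref_speed, NumericMatrix goal,
                               NumericVector width, NumericVector alpha,
                               NumericVector beta, NumericVector H,
                               double sigma, double lateral_scale,
                               double lookahead, double theta_max,
                               int n_samples, double tau,
                               double neighbor_radius, bool area_normalized,
                               bool seyfried, Nullable<NumericMatrix> fsmat,
                               double ox, double oy, double cb,
                               double period_x) {
  int n = pos.nrow();
  NumericMatrix out(n, 2);
  if (n_samples < 3 || n_samples % 2 == 0)
    stop("n_samples must be an odd integer >= 3");
  if (sigma <= 0) stop("sigma must be positive");
  int m = (n_samples - 1) / 2;
  double dtheta = theta_max / m;
  double pref_factor = area_normalized ? 1.0 / (2.0 * M_PI * sigma * sigma)
                                       : 1.0 / (2.0 * M_PI * sigma);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double ls2 = lateral_scale * lateral_scale;
  bool has_fs = fsmat.isNotNull();
  NumericMatrix fs;
  if (has_fs) fs = NumericMatrix(fsmat);

  // tie-break ordering of sample offsets
  std::vector<double> thetas;
  thetas.reserve(n_samples);
  thetas.push_back(0.0);
  for (int k = 1; k <= m; ++k) {
    thetas.push_back(-k * dtheta);
    thetas.push_back(k * dtheta);
  }

  double nr2 = neighbor_radius * neighbor_radius;
  std::vector<double> ndx, ndy;
  for (int i = 0; i < n; ++i) {
    double sp = pref_speed[i];
    double v0n = std::sqrt(v0(i, 0) * v0(i, 0) + v0(i, 1) * v0(i, 1));
    if (sp <= 0.0 || v0n < 1e-12) {
      out(i, 0) = 0.0;
      out(i, 1) = 0.0;
      continue;
    }
    double hx = v0(i, 0) / v0n, hy = v0(i, 1) / v0n;
    // neighbor displacements d_ij = p_i - p_j, thresholded at p_i
    ndx.clear();
    ndy.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = wrap_diff(pos(i, 0) - pos(j, 0), period_x);
      double dy = pos(i, 1) - pos(j, 1);
      if (dx * dx + dy * dy < nr2) {
        ndx.push_back(dx);
        ndy.push_back(dy);
      }
    }
    double scale = alpha[i] * H[i] * (1.0 + beta[i]);
    double best_cost = std::numeric_limits<double>::infinity();
    double best_vx = 0.0, best_vy = 0.0;
    for (size_t k = 0; k < thetas.size(); ++k) {
      double c = std::cos(thetas[k]), s = std::sin(thetas[k]);
      double vhx = c * hx - s * hy;
      double vhy = s * hx + c * hy;
      double rhoA = 0.0;
      for (size_t jj = 0; jj < ndx.size(); ++jj) {
        double dfor = ndx[jj] * vhx + ndy[jj] * vhy;
        double d2 = ndx[jj] * ndx[jj] + ndy[jj] * ndy[jj];
        double dprime2 = dfor * dfor + ls2 * (d2 - dfor * dfor);
        if (dprime2 < 0) dprime2 = 0;
        double e = dprime2 * inv2s2;
        if (e < 30.0) rhoA += pref_factor * std::exp(-e);
      }
      double fsval = 1.0;
      if (has_fs) {
        double qx = pos(i, 0) + vhx * lookahead;
        double qy = pos(i, 1) + vhy * lookahead;
        fsval = fs_bilin_scalar(fs, ox, oy, cb, qx, qy);
        if (fsval <= 0) fsval = 1e-6;
      }
      double rho = rhoA / fsval;
      double V;
      if (rho <= 0.0) {
        V = sp;
      } else {
        double S = seyfried ? 1.0 / (width[i] * rho) : width[i] / rho;
        double ratio = S / scale;
        V = std::min(sp, ratio * ratio);
      }
      double vx = vhx * V, vy = vhy * V;
      double ex = goal(i, 0) - (pos(i, 0) + vx * tau);
      double ey = goal(i, 1) - (pos(i, 1) + vy * tau);
      double cost = std::sqrt(ex * ex + ey * ey);
      if (cost < best_cost) {
        best_cost = cost;
        best_vx = vx;
        best_vy = vy;
      }
    }
    out(i, 0) = best_vx;
    out(i, 1) = best_vy;
  }
  return out;
}

// ---------------------------------------------------------------------------
// ORCA
// ---------------------------------------------------------------------------

struct Line {
  double px, py, dx, dy;
};

static bool linear_program1(const std::vector<Line> &lines, size_t lineNo,
                            double radius, double optx, double opty,
                            bool dirOpt, double &rx, double &ry) {
  const Line &ln = lines[lineNo];
  double dotProduct = ln.px * ln.dx + ln.py * ln.dy;
  double discriminant =
      dotProduct * dotProduct + radius * radius - (ln.px * ln.px + ln.py * ln.py);
  if (discriminant < 0.0) return false;
  double sqrtDisc = std::sqrt(discriminant);
  double tLeft = -dotProduct - sqrtDisc;
  double tRight = -dotProduct + sqrtDisc;
  for (size_t i = 0; i < lineNo; ++i) {
    double denominator = det2(ln.dx, ln.dy, lines[i].dx, lines[i].dy);
    double numerator = det2(lines[i].dx, lines[i].dy,
                            ln.px - lines[i].px, ln.py - lines[i].py);
    if (std::fabs(denominator) <= EPS) {
      if (numerator < 0.0) return false;
      continue;
    }
    double t = numerator / denominator;
    if (denominator >= 0.0) {
      tRight = std::min(tRight, t);
    } else {
      tLeft = std::max(tLeft, t);
    }
    if (tLeft > tRight) return false;
  }
  double t;
  if (dirOpt) {
    t = (optx * ln.dx + opty * ln.dy > 0.0) ? tRight : tLeft;
  } else {
    t = ln.dx * (optx - ln.px) + ln.dy * (opty - ln.py);
    if (t < tLeft) t = tLeft;
    else if (t > tRight) t = tRight;
  }
  rx = ln.px + t * ln.dx;
  ry = ln.py + t * ln.dy;
  return true;
}

static size_t linear_program2(const std::vector<Line> &lines, double radius,
                              double optx, double opty, bool dirOpt,
                              double &rx, double &ry) {
  if (dirOpt) {
    rx = optx * radius;
    ry = opty * radius;
  } else if (optx * optx + opty * opty > radius * radius) {
    double nrm = std::sqrt(optx * optx + opty * opty);
    rx = optx / nrm * radius;
    ry = opty / nrm * radius;
  } else {
    rx = optx;
    ry = opty;
  }
  for (size_t i = 0; i < lines.size(); ++i) {
    if (det2(lines[i].dx, lines[i].dy, lines[i].px - rx, lines[i].py - ry) >
        0.0) {
      double tx = rx, ty = ry;
      if (!linear_program1(lines, i, radius, optx, opty, dirOpt, rx, ry)) {
        rx = tx;
        ry = ty;
        return i;
      }
    }
  }
  return lines.size();
}

static void linear_program3(const std::vector<Line> &lines, size_t numObstLines,
                            size_t beginLine, double radius, double &rx,
                            double &ry) {
  double distance = 0.0;
  for (size_t i = beginLine; i < lines.size(); ++i) {
    if (det2(lines[i].dx, lines[i].dy, lines[i].px - rx, lines[i].py - ry) >
        distance) {
      std::vector<Line> projLines(lines.begin(),
                                  lines.begin() + numObstLines);
      for (size_t j = numObstLines; j < i; ++j) {
        Line nl;
        double determinant =
            det2(lines[i].dx, lines[i].dy, lines[j].dx, lines[j].dy);
        if (std::fabs(determinant) <= EPS) {
          if (lines[i].dx * lines[j].dx + lines[i].dy * lines[j].dy > 0.0)
            continue;  // parallel, same direction
          nl.px = 0.5 * (lines[i].px + lines[j].px);
          nl.py = 0.5 * (lines[i].py + lines[j].py);
        } else {
          double t = det2(lines[j].dx, lines[j].dy,
                          lines[i].px - lines[j].px,
                          lines[i].py - lines[j].py) /
                     determinant;
          nl.px = lines[i].px + t * lines[i].dx;
          nl.py = lines[i].py + t * lines[i].dy;
        }
        double ddx = lines[j].dx - lines[i].dx;
        double ddy = lines[j].dy - lines[i].dy;
        double nrm = std::sqrt(ddx * ddx + ddy * ddy);
        if (nrm <= EPS) continue;
        nl.dx = ddx / nrm;
        nl.dy = ddy / nrm;
        projLines.push_back(nl);
      }
      double tx = rx, ty = ry;
      if (linear_program2(projLines, radius, -lines[i].dy, lines[i].dx, true,
                          rx, ry) < projLines.size()) {
        rx = tx;
        ry = ty;
      }
      distance =
          det2(lines[i].dx, lines[i].dy, lines[i].px - rx, lines[i].py - ry);
    }
  }
}

// Pairwise ORCA line for agent i against agent j (responsibility shared
// half-half). Overlapping disks are resolved over dt instead of tauO.
static Line orca_pair_line(double pix, double piy, double pjx, double pjy,
                           double vix, double viy, double vjx, double vjy,
                           double ri, double rj, double tauO, double dt) {
  Line line;
  double rpx = pjx - pix, rpy = pjy - piy;       // relative position
  double rvx = vix - vjx, rvy = viy - vjy;       // relative velocity
  double distSq = rpx * rpx + rpy * rpy;
  double combR = ri + rj;
  double combR2 = combR * combR;
  double ux, uy;
  if (distSq > combR2) {
    double invTau = 1.0 / tauO;
    double wx = rvx - invTau * rpx, wy = rvy - invTau * rpy;
    double wLenSq = wx * wx + wy * wy;
    double dot1 = wx * rpx + wy * rpy;
    if (dot1 < 0.0 && dot1 * dot1 > combR2 * wLenSq) {
      double wLen = std::sqrt(wLenSq);
      double uwx = wx / wLen, uwy = wy / wLen;
      line.dx = uwy;
      line.dy = -uwx;
      ux = (combR * invTau - wLen) * uwx;
      uy = (combR * invTau - wLen) * uwy;
    } else {
      double leg = std::sqrt(distSq - combR2);
      if (det2(rpx, rpy, wx, wy) > 0.0) {
        line.dx = (rpx * leg - rpy * combR) / distSq;
        line.dy = (rpx * combR + rpy * leg) / distSq;
      } else {
        line.dx = -(rpx * leg + rpy * combR) / distSq;
        line.dy = -(-rpx * combR + rpy * leg) / distSq;
      }
      double dot2 = rvx * line.dx + rvy * line.dy;
      ux = dot2 * line.dx - rvx;
      uy = dot2 * line.dy - rvy;
    }
  } else {
    double invDt = 1.0 / dt;
    double wx = rvx - invDt * rpx, wy = rvy - invDt * rpy;
    double wLen = std::sqrt(wx * wx + wy * wy);
    double uwx, uwy;
    if (wLen > EPS) {
      uwx = wx / wLen;
      uwy = wy / wLen;
    } else {
      // coincident relative state: push along the (nonzero) center line,
      // or an arbitrary fixed direction if centers coincide exactly
      double d = std::sqrt(distSq);
      if (d > EPS) {
        uwx = -rpx / d;
        uwy = -rpy / d;
      } else {
        uwx = 1.0;
        uwy = 0.0;
      }
    }
    line.dx = uwy;
    line.dy = -uwx;
    ux = (combR * invDt - wLen) * uwx;
    uy = (combR * invDt - wLen) * uwy;
  }
  line.px = vix + 0.5 * ux;
  line.py = viy + 0.5 * uy;
  return line;
}

// [[Rcpp::export]]
List cpp_orca_pair_line(NumericVector pi_, NumericVector pj,
                        NumericVector vi, NumericVector vj, double ri,
                        double rj, double tauO, double dt) {
  double dx = pj[0] - pi_[0], dy = pj[1] - pi_[1];
  if (dx * dx + dy * dy < EPS * EPS)
    stop("agents have identical positions; relative geometry undefined");
  Line l = orca_pair_line(pi_[0], pi_[1], pj[0], pj[1], vi[0], vi[1], vj[0],
                          vj[1], ri, rj, tauO, dt);
  // outward-permitted normal is the direction rotated +90 degrees
  return List::create(
      _["point"] = NumericVector::create(l.px, l.py),
      _["direction"] = NumericVector::create(l.dx, l.dy),
      _["normal"] = NumericVector::create(-l.dy, l.dx));
}

// [[Rcpp::export]]
NumericVector cpp_orca_lp(NumericVector vpref, NumericMatrix lines_mat,
                          double max_speed, int num_obst) {
  std::vector<Line> lines(lines_mat.nrow());
  for (int i = 0; i < lines_mat.nrow(); ++i) {
    lines[i].px = lines_mat(i, 0);
    lines[i].py = lines_mat(i, 1);
    lines[i].dx = lines_mat(i, 2);
    lines[i].dy = lines_mat(i, 3);
  }
  double rx, ry;
  size_t fail =
      linear_program2(lines, max_speed, vpref[0], vpref[1], false, rx, ry);
  if (fail < lines.size()) {
    linear_program3(lines, (size_t)num_obst, fail, max_speed, rx, ry);
  }
  return NumericVector::create(rx, ry);
}

static double point_seg_nearest(double px, double py, double x1, double y1,
                                double x2, double y2, double &cx, double &cy) {
  double sx = x2 - x1, sy = y2 - y1;
  double len2 = sx * sx + sy * sy;
  double t = 0.0;
  if (len2 > EPS) {
    t = ((px - x1) * sx + (py - y1) * sy) / len2;
    t = std::min(std::max(t, 0.0), 1.0);
  }
  cx = x1 + t * sx;
  cy = y1 + t * sy;
  double dx = px - cx, dy = py - cy;
  return std::sqrt(dx * dx + dy * dy);
}

// New velocities for all agents under ORCA. Obstacle segments enter as
// linearized half-plane constraints from the nearest point on each nearby
// segment (full responsibility); agent constraints share responsibility
// half-half and are capped at the max_neighbors nearest agents.
// [[Rcpp::export]]
NumericMatrix cpp_orca_batch(NumericMatrix pos, NumericMatrix vel,
                             NumericMatrix vpref, NumericVector radius,
                             NumericVector max_speed, double tauO, double dt,
                             double neighbor_radius, int max_neighbors,
                             NumericMatrix segments, double tau_obst,
                             double period_x, double safety_margin) {
  int n = pos.nrow();
  int nseg = segments.nrow();
  NumericMatrix out(n, 2);
  double nr2 = neighbor_radius * neighbor_radius;
  std::vector<std::pair<double, int> > nb;
  for (int i = 0; i < n; ++i) {
    std::vector<Line> lines;
    // obstacle constraints first
    for (int sgi = 0; sgi < nseg; ++sgi) {
      double cx, cy;
      double d = point_seg_nearest(pos(i, 0), pos(i, 1), segments(sgi, 0),
                                   segments(sgi, 1), segments(sgi, 2),
                                   segments(sgi, 3), cx, cy);
      if (d > neighbor_radius || d < 1e-9) continue;
      double nx = (pos(i, 0) - cx) / d, ny = (pos(i, 1) - cy) / d;
      double ri = radius[i] + 0.5 * safety_margin;
      double b = (d > ri) ? -(d - ri) / tau_obst : (ri - d) / dt;
      Line l;
      l.px = b * nx;
      l.py = b * ny;
      l.dx = ny;
      l.dy = -nx;
      lines.push_back(l);
    }
    size_t numObstLines = lines.size();
    // nearest agents
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = wrap_diff(pos(j, 0) - pos(i, 0), period_x);
      double dy = pos(j, 1) - pos(i, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < nr2) nb.push_back(std::make_pair(d2, j));
    }
    std::sort(nb.begin(), nb.end());
    int keep = std::min((int)nb.size(), max_neighbors);
    for (int k = 0; k < keep; ++k) {
      int j = nb[k].second;
      double dx = wrap_diff(pos(j, 0) - pos(i, 0), period_x);
      double dy = pos(j, 1) - pos(i, 1);
      lines.push_back(orca_pair_line(0.0, 0.0, dx, dy, vel(i, 0), vel(i, 1),
                                     vel(j, 0), vel(j, 1),
                                     radius[i] + 0.5 * safety_margin,
                                     radius[j] + 0.5 * safety_margin, tauO,
                                     dt));
    }
    double rx, ry;
    size_t fail = linear_program2(lines, max_speed[i], vpref(i, 0),
                                  vpref(i, 1), false, rx, ry);
    if (fail < lines.size()) {
      linear_program3(lines, numObstLines, fail, max_speed[i], rx, ry);
    }
    out(i, 0) = rx;
    out(i, 1) = ry;
  }
  return out;
}

// ---------------------------------------------------------------------------
// social forces
// ---------------------------------------------------------------------------

// deterministic unit vector for coincident agent centers
static void hash_unit(int seed, int step, int i, int j, double &ux,
                      double &uy) {
  unsigned long long h = 1469598103934665603ULL;
  unsigned long long vals[4] = {(unsigned long long)(unsigned)seed,
                                (unsigned long long)(unsigned)step,
                                (unsigned long long)(unsigned)i,
                                (unsigned long long)(unsigned)j};
  for (int k = 0; k < 4; ++k) {
    h ^= vals[k];
    h *= 1099511628211ULL;
  }
  double ang = 2.0 * M_PI * ((h >> 11) % 1000000) / 1000000.0;
  ux = std::cos(ang);
  uy = std::sin(ang);
}

// Helbing-style accelerations: driving term plus exponential "social"
// repulsion, body force and sliding friction on contact, for agent-agent and
// agent-wall interactions.
// [[Rcpp::export]]
NumericMatrix cpp_sf_accel_batch(NumericMatrix pos, NumericMatrix vel,
                                 NumericMatrix vpref, NumericVector radius,
                                 NumericVector mass, double tauH, double A,
                                 double B, double bodyk, double kappa,
                                 double interaction_range,
                                 NumericMatrix segments, double period_x,
                                 int seed, int step) {
  int n = pos.nrow();
  int nseg = segments.nrow();
  NumericMatrix acc(n, 2);
  std::vector<double> fx(n, 0.0), fy(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = wrap_diff(pos(i, 0) - pos(j, 0), period_x);
      double dy = pos(i, 1) - pos(j, 1);
      double d = std::sqrt(dx * dx + dy * dy);
      double rij = radius[i] + radius[j];
      if (d > rij + interaction_range) continue;
      double nx, ny;
      if (d < 1e-9) {
        hash_unit(seed, step, i, j, nx, ny);
        d = 1e-9;
      } else {
        nx = dx / d;
        ny = dy / d;
      }
      double overlap = rij - d;
      double g = overlap > 0.0 ? overlap : 0.0;
      double fmag = A * std::exp(overlap / B) + bodyk * g;
      double tx = -ny, ty = nx;
      double dvt = (vel(j, 0) - vel(i, 0)) * tx + (vel(j, 1) - vel(i, 1)) * ty;
      double ffric = kappa * g * dvt;
      double fxi = fmag * nx + ffric * tx;
      double fyi = fmag * ny + ffric * ty;
      fx[i] += fxi;
      fy[i] += fyi;
      fx[j] -= fxi;
      fy[j] -= fyi;
    }
    for (int sgi = 0; sgi < nseg; ++sgi) {
      double cx, cy;
      double d = point_seg_nearest(pos(i, 0), pos(i, 1), segments(sgi, 0),
                                   segments(sgi, 1), segments(sgi, 2),
                                   segments(sgi, 3), cx, cy);
      if (d > radius[i] + interaction_range) continue;
      double nx, ny;
      if (d < 1e-9) {
        hash_unit(seed, step, i, n + sgi, nx, ny);
        d = 1e-9;
      } else {
        nx = (pos(i, 0) - cx) / d;
        ny = (pos(i, 1) - cy) / d;
      }
      double overlap = radius[i] - d;
      double g = overlap > 0.0 ? overlap : 0.0;
      double fmag = A * std::exp(overlap / B) + bodyk * g;
      double tx = -ny, ty = nx;
      double vt = vel(i, 0) * tx + vel(i, 1) * ty;
      fx[i] += fmag * nx - kappa * g * vt * tx;
      fy[i] += fmag * ny - kappa * g * vt * ty;
    }
  }
  for (int i = 0; i < n; ++i) {
    acc(i, 0) = (vpref(i, 0) - vel(i, 0)) / tauH + fx[i] / mass[i];
    acc(i, 1) = (vpref(i, 1) - vel(i, 1)) / tauH + fy[i] / mass[i];
  }
  return acc;
}

// ---------------------------------------------------------------------------
// collision score
// ---------------------------------------------------------------------------

static inline double interval_pen(double r0x, double r0y, double r1x,
                                  double r1y, double rij) {
  double dvx = r1x - r0x, dvy = r1y - r0y;
  double vv = dvx * dvx + dvy * dvy;
  double s = 0.0;
  if (vv > EPS) {
    s = -(r0x * dvx + r0y * dvy) / vv;
    s = std::min(std::max(s, 0.0), 1.0);
  }
  double mx = r0x + s * dvx, my = r0y + s * dvy;
  double dmin = std::sqrt(mx * mx + my * my);
  // endpoints can only be smaller at s in {0,1}, already covered by clamping
  double pen = rij - dmin;
  return pen > 0.0 ? pen : 0.0;
}

// x, y: frames x agents matrices (NA where an agent is absent). Returns the
// accumulated interval penetration together with the counts needed for the
// per-agent-per-interval normalization.
// [[Rcpp::export]]
List cpp_collision_score(NumericMatrix x, NumericMatrix y, NumericVector r,
                         double period_x) {
  int K = x.nrow(), n = x.ncol();
  if (K < 2) stop("need at least 2 frames");
  double total = 0.0;
  double agent_intervals = 0.0, pair_intervals = 0.0;
  NumericVector per_interval(K - 1);
  for (int k = 0; k + 1 < K; ++k) {
    std::vector<int> present;
    for (int i = 0; i < n; ++i) {
      if (!NumericVector::is_na(x(k, i)) && !NumericVector::is_na(x(k + 1, i)))
        present.push_back(i);
    }
    agent_intervals += present.size();
    double acc = 0.0;
    for (size_t a = 0; a < present.size(); ++a) {
      for (size_t b = a + 1; b < present.size(); ++b) {
        int i = present[a], j = present[b];
        double rij = r[i] + r[j];
        double r0x = wrap_diff(x(k, j) - x(k, i), period_x);
        double r0y = y(k, j) - y(k, i);
        double r1x = x(k + 1, j) - x(k + 1, i);
        double r1y = y(k + 1, j) - y(k + 1, i);
        if (!std::isnan(period_x) && period_x > 0.0) {
          r1x -= period_x * std::round((r1x - r0x) / period_x);
        }
        pair_intervals += 1.0;
        // cheap separating-axis reject: per-axis relative distance is linear
        if ((r0x > rij && r1x > rij) || (r0x < -rij && r1x < -rij)) continue;
        if ((r0y > rij && r1y > rij) || (r0y < -rij && r1y < -rij)) continue;
        double pen = interval_pen(r0x, r0y, r1x, r1y, rij);
        if (pen > 0.0) acc += pen;
      }
    }
    per_interval[k] = acc;
    total += acc;
  }
  return List::create(_["total"] = total,
                      _["agent_intervals"] = agent_intervals,
                      _["pair_intervals"] = pair_intervals,
                      _["n_intervals"] = K - 1,
                      _["per_interval"] = per_interval);
}
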