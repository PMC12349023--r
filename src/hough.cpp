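#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Gradient-voting circle transform (two-stage Hough):
//  1. Sobel gradients; pixels with gradient magnitude > grad_threshold are edges.
//  2. Each edge pixel votes along +/- its gradient direction for candidate
//     centers at radial distances [min_r, max_r] (full-resolution accumulator).
//  3. Local accumulator maxima with >= acc_threshold votes become candidates;
//     centers are refined to sub-pixel by the 3x3 vote centroid.
//  4. Greedy non-maximum suppression: candidates ordered by votes (desc),
//     ties by (y, x); a candidate is kept iff >= min_dist from all kept ones.
//  5. Radius per kept center: mode of radially-aligned edge distances in
//     [min_r, max_r], refined by the mean distance within +/-1 px of the mode.
//
// No polarity assumption: votes go both inward and outward, so cells darker
// or lighter than background are treated alike.

struct Cand {
  double v;     // votes
  int y, x;     // accumulator bin
  double fy, fx; // refined center
};

// [[Rcpp::export]]
DataFrame hough_circles_cpp(NumericMatrix gray, int min_r, int max_r,
                            double min_dist, double acc_threshold,
                            double grad_threshold) {
  const int H = gray.nrow(), W = gray.ncol();
  std::vector<int> ex, ey;
  std::vector<double> egx, egy;

  if (H >= 3 && W >= 3) {
    for (int y = 1; y < H - 1; ++y) {
      for (int x = 1; x < W - 1; ++x) {
        double gx = (gray(y - 1, x + 1) + 2.0 * gray(y, x + 1) + gray(y + 1, x + 1))
                  - (gray(y - 1, x - 1) + 2.0 * gray(y, x - 1) + gray(y + 1, x - 1));
        double gy = (gray(y + 1, x - 1) + 2.0 * gray(y + 1, x) + gray(y + 1, x + 1))
                  - (gray(y - 1, x - 1) + 2.0 * gray(y - 1, x) + gray(y - 1, x + 1));
        double mag = std::sqrt(gx * gx + gy * gy);
        if (mag > grad_threshold) {
          ex.push_back(x); ey.push_back(y);
          egx.push_back(gx / mag); egy.push_back(gy / mag);
        }
      }
    }
  }

  const size_t ne = ex.size();
  NumericMatrix acc(H, W);
  for (size_t i = 0; i < ne; ++i) {
    for (int s = -1; s <= 1; s += 2) {
      int px = INT_MIN, py = INT_MIN;
      for (int r = min_r; r <= max_r; ++r) {
        int cx = (int) std::lround(ex[i] + s * r * egx[i]);
        int cy = (int) std::lround(ey[i] + s * r * egy[i]);
        if (cx == px && cy == py) continue;  // same bin as previous radius
        px = cx; py = cy;
        if (cx >= 0 && cx < W && cy >= 0 && cy < H) acc(cy, cx) += 1.0;
      }
    }
  }

  // local maxima; on tie plateaus the lexicographically smallest (y, x) wins
  std::vector<Cand> cands;
  for (int y = 1; y < H - 1; ++y) {
    for (int x = 1; x < W - 1; ++x) {
      double v = acc(y, x);
      if (v < acc_threshold) continue;
      bool ismax = true;
      for (int dy = -1; dy <= 1 && ismax; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          if (dy == 0 && dx == 0) continue;
          double u = acc(y + dy, x + dx);
          if (u > v || (u == v && (dy < 0 || (dy == 0 && dx < 0)))) {
            ismax = false; break;
          }
        }
      }
      if (!ismax) continue;
      // sub-pixel refinement: vote centroid over the 3x3 neighbourhood
      double sw = 0.0, sx = 0.0, sy = 0.0;
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          double u = acc(y + dy, x + dx);
          sw += u; sx += u * (x + dx); sy += u * (y + dy);
        }
      }
      Cand c;
      c.v = v; c.y = y; c.x = x;
      c.fx = (sw > 0) ? sx / sw : (double) x;
      c.fy = (sw > 0) ? sy / sw : (double) y;
      cands.push_back(c);
    }
  }

  std::sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
    if (a.v != b.v) return a.v > b.v;
    if (a.y != b.y) return a.y < b.y;
    return a.x < b.x;
  });

  std::vector<Cand> kept;
  const double md2 = min_dist * min_dist;
  for (const Cand &c : cands) {
    bool ok = true;
    for (const Cand &k : kept) {
      double dx = c.fx - k.fx, dy = c.fy - k.fy;
      if (dx * dx + dy * dy < md2) { ok = false; break; }
    }
    if (ok) kept.push_back(c);
  }

  const int n = (int) kept.size();
  NumericVector out_x(n), out_y(n), out_r(n), out_v(n);
  std::vector<int> hist(max_r + 2, 0);
  for (int j = 0; j < n; ++j) {
    const double cx = kept[j].fx, cy = kept[j].fy;
    std::fill(hist.begin(), hist.end(), 0);
    for (size_t i = 0; i < ne; ++i) {
      double dx = ex[i] - cx, dy = ey[i] - cy;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < min_r - 1.0 || d > max_r + 1.0 || d <= 0.0) continue;
      // keep edges whose gradient is radially aligned with this center
      double cosang = (dx * egx[i] + dy * egy[i]) / d;
      if (std::fabs(cosang) < 0.8) continue;
      int b = (int) std::lround(d);
      if (b >= min_r && b <= max_r) hist[b]++;
    }
    int best = min_r;
    for (int r = min_r; r <= max_r; ++r)
      if (hist[r] > hist[best]) best = r;
    // refine: mean aligned-edge distance within +/-1 px of the modal radius
    double sd = 0.0; int cnt = 0;
    for (size_t i = 0; i < ne; ++i) {
      double dx = ex[i] - cx, dy = ey[i] - cy;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < best - 1.0 || d > best + 1.0 || d <= 0.0) continue;
      double cosang = (dx * egx[i] + dy * egy[i]) / d;
      if (std::fabs(cosang) < 0.8) continue;
      sd += d; cnt++;
    }
    double r = (cnt > 0) ? sd / cnt : (double) best;
    if (r < min_r) r = min_r;
    if (r > max_r) r = max_r;
    out_x[j] = cx; out_y[j] = cy; out_r[j] = r; out_v[j] = kept[j].v;
  }

  return DataFrame::create(_["center_x_px"] = out_x, _["center_y_px"] = out_y,
                           _["radius_px"] = out_r, _["votes"] = out_v);
}
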