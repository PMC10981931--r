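#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Scanline even-odd polygon rasterizer. Pixel (r, c) (0-based) is inside iff
// its center (x = c, y = r), nudged by +eps in both axes to break boundary
// ties deterministically, falls inside the polygon under the even-odd rule.
// Vertices are (x, y) in pixel coordinates.
// [[Rcpp::export(name = ".rasterize_polygon_cpp")]]
LogicalMatrix rasterize_polygon_cpp(NumericMatrix vertices, int height, int width) {
  const double eps = 1e-7;
  const int n = vertices.nrow();
  LogicalMatrix out(height, width);
  if (n < 3) return out;
  std::vector<double> xs(n), ys(n);
  for (int i = 0; i < n; ++i) { xs[i] = vertices(i, 0); ys[i] = vertices(i, 1); }
  std::vector<double> cross;
  for (int r = 0; r < height; ++r) {
    const double y = r + eps;
    cross.clear();
    for (int i = 0; i < n; ++i) {
      const int j = (i + 1) % n;
      const double y1 = ys[i], y2 = ys[j];
      // half-open rule avoids double counting shared vertices
      if ((y1 <= y && y < y2) || (y2 <= y && y < y1)) {
        cross.push_back(xs[i] + (y - y1) * (xs[j] - xs[i]) / (y2 - y1));
      }
    }
    if (cross.empty()) continue;
    std::sort(cross.begin(), cross.end());
    for (int c = 0; c < width; ++c) {
      const double x = c + eps;
      // count crossings strictly left of the (nudged) center
      int k = (int)(std::lower_bound(cross.begin(), cross.end(), x) - cross.begin());
      if (k % 2 == 1) out(r, c) = true;
    }
  }
  return out;
}

// 8- or 4-connected component labeling of a logical mask; labels 1..k in
// raster-scan discovery order (deterministic).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity = 8) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> nb;
  if (connectivity == 8) {
    nb = {{-1,-1},{-1,0},{-1,1},{0,-1},{0,1},{1,-1},{1,0},{1,1}};
  } else {
    nb = {{-1,0},{0,-1},{0,1},{1,0}};
  }
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push({r, c});
      while (!q.empty()) {
        auto p = q.front(); q.pop();
        for (auto &d : nb) {
          const int rr = p.first + d.first, cc = p.second + d.second;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push({rr, cc});
          }
        }
      }
    }
  }
  return lab;
}

static inline int nb8(const LogicalMatrix &m, int r, int c, int dr, int dc) {
  const int rr = r + dr, cc = c + dc;
  if (rr < 0 || rr >= m.nrow() || cc < 0 || cc >= m.ncol()) return 0;
  return m(rr, cc) ? 1 : 0;
}

// Zhang-Suen thinning to a 1-px-wide 8-connected skeleton.
// [[Rcpp::export(name = ".thin_cpp")]]
LogicalMatrix thin_cpp(LogicalMatrix input) {
  LogicalMatrix m = clone(input);
  const int H = m.nrow(), W = m.ncol();
  bool changed = true;
  std::vector<std::pair<int, int>> del;
  while (changed) {
    changed = false;
    for (int phase = 0; phase < 2; ++phase) {
      del.clear();
      for (int r = 0; r < H; ++r) {
        for (int c = 0; c < W; ++c) {
          if (!m(r, c)) continue;
          // neighbors p2..p9 clockwise from north
          int p[8] = {
            nb8(m, r, c, -1, 0), nb8(m, r, c, -1, 1), nb8(m, r, c, 0, 1),
            nb8(m, r, c, 1, 1),  nb8(m, r, c, 1, 0),  nb8(m, r, c, 1, -1),
            nb8(m, r, c, 0, -1), nb8(m, r, c, -1, -1)
          };
          int B = 0, A = 0;
          for (int i = 0; i < 8; ++i) {
            B += p[i];
            if (p[i] == 0 && p[(i + 1) % 8] == 1) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          if (phase == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          del.push_back({r, c});
        }
      }
      for (auto &d : del) m(d.first, d.second) = false;
      if (!del.empty()) changed = true;
    }
  }
  return m;
}

// Multi-source geodesic assignment inside a mask: every true pixel gets the
// (1-based) index of the nearest seed point by weighted Dijkstra on the
// 8-neighbor graph (axial steps 1, diagonal sqrt(2)), so cross-sections are
// perpendicular to the seed path rather than Chebyshev diagonals; distance
// ties go to the earlier seed. seeds: m x 2 matrix of 0-based (row, col).
// [[Rcpp::export(name = ".assign_nearest_seed_cpp")]]
IntegerMatrix assign_nearest_seed_cpp(LogicalMatrix mask, IntegerMatrix seeds) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix assign(H, W);
  std::vector<double> dist((size_t)H * W,
                           std::numeric_limits<double>::infinity());
  // (distance, seed index, pixel) min-heap; seed index in the key makes
  // tie-breaking deterministic (earlier seed wins at equal distance)
  typedef std::tuple<double, int, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
  for (int i = 0; i < seeds.nrow(); ++i) {
    const int r = seeds(i, 0), c = seeds(i, 1);
    if (r < 0 || r >= H || c < 0 || c >= W) stop("seed outside mask dimensions");
    const size_t id = (size_t)c * H + r;
    if (dist[id] > 0) {
      dist[id] = 0;
      pq.push(Node(0.0, i + 1, (int)id));
    }
  }
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double SQ2 = std::sqrt(2.0);
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    const double d = std::get<0>(nd);
    const int lab = std::get<1>(nd);
    const size_t id = (size_t)std::get<2>(nd);
    if (assign[id] != 0) continue;          // already settled
    if (d > dist[id]) continue;
    assign[id] = lab;
    const int r = (int)(id % H), c = (int)(id / H);
    for (int k = 0; k < 8; ++k) {
      const int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (!mask(rr, cc)) continue;
      const size_t nid = (size_t)cc * H + rr;
      if (assign[nid] != 0) continue;
      const double ndist = d + ((dr[k] != 0 && dc[k] != 0) ? SQ2 : 1.0);
      if (ndist <= dist[nid] + 1e-12) {
        dist[nid] = ndist;
        pq.push(Node(ndist, lab, (int)nid));
      }
    }
  }
  return assign;
}

// Separable Gaussian blur of a single channel (double matrix), reflect padding.
// [[Rcpp::export(name = ".gaussian_blur_cpp")]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto &v : k) v /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0) rr = -rr - 1;
        if (rr >= H) rr = 2 * H - rr - 1;
        acc += k[i + rad] * img(rr, c);
      }
      tmp(r, c) = acc;
    }
  }
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      double acc = 0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0) cc = -cc - 1;
        if (cc >= W) cc = 2 * W - cc - 1;
        acc += k[i + rad] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// Sweep a dense polyline (curve points at ~1 px spacing, 0-based (row, col))
// with a brush of diameter `width`. For each covered pixel returns the index
// of the nearest curve point, the distance to it, and the signed lateral
// offset (sign of the cross product of the local tangent with the offset).
// [[Rcpp::export(name = ".sweep_curve_cpp")]]
List sweep_curve_cpp(NumericMatrix curve, double width, int height, int wid) {
  const int m = curve.nrow();
  const double rad = width / 2.0, rad2 = rad * rad;
  IntegerMatrix idx(height, wid);
  NumericMatrix dist(height, wid), lat(height, wid);
  std::fill(dist.begin(), dist.end(), std::numeric_limits<double>::infinity());
  const int R = (int)std::ceil(rad);
  for (int i = 0; i < m; ++i) {
    const double cr = curve(i, 0), cc = curve(i, 1);
    // local tangent (central difference)
    const int i0 = std::max(0, i - 1), i1 = std::min(m - 1, i + 1);
    double tr = curve(i1, 0) - curve(i0, 0), tc = curve(i1, 1) - curve(i0, 1);
    const double tn = std::sqrt(tr * tr + tc * tc);
    if (tn > 0) { tr /= tn; tc /= tn; }
    const int rlo = std::max(0, (int)std::floor(cr - R)),
              rhi = std::min(height - 1, (int)std::ceil(cr + R)),
              clo = std::max(0, (int)std::floor(cc - R)),
              chi = std::min(wid - 1, (int)std::ceil(cc + R));
    for (int r = rlo; r <= rhi; ++r) {
      for (int c = clo; c <= chi; ++c) {
        const double dr = r - cr, dc = c - cc;
        const double d2 = dr * dr + dc * dc;
        if (d2 > rad2 || d2 >= dist(r, c) * dist(r, c)) continue;
        dist(r, c) = std::sqrt(d2);
        idx(r, c) = i + 1;
        const double crossp = tr * dc - tc * dr;
        lat(r, c) = (crossp >= 0 ? 1.0 : -1.0) * dist(r, c);
      }
    }
  }
  return List::create(_["index"] = idx, _["dist"] = dist, _["lateral"] = lat);
}
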