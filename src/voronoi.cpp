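#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Clipped Voronoi tessellation on the rectangle [0,w] x [0,h].
//
// Each cell is computed by successive half-plane clipping of the field
// rectangle against the perpendicular bisectors of (i, j), visiting the
// other generators in order of increasing distance and stopping once the
// next generator is farther than twice the cell's current circumradius
// (its bisector can no longer cut the polygon).  Edge provenance is
// tracked through the clips: every polygon edge carries the 0-based index
// of the generator whose bisector created it, or -1 for a stretch of the
// field boundary.  Shared bisector edges of positive length define the
// neighbor graph.
//
// Returns a list with one element per generator:
//   verts  - K x 2 matrix of polygon vertices (counter-clockwise)
//   labels - length-K integer vector, labels[k] is the source of the edge
//            from vertex k to vertex k+1 (wrapping), 0-based, -1 = border
// [[Rcpp::export]]
List voronoi_cells_cpp(NumericMatrix pts, double w, double h) {
  const int n = pts.nrow();
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = pts(i, 0); py[i] = pts(i, 1); }

  List out(n);
  std::vector<std::pair<double, int> > ord;
  ord.reserve(n);

  for (int i = 0; i < n; ++i) {
    ord.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = px[j] - px[i], dy = py[j] - py[i];
      ord.push_back(std::make_pair(dx * dx + dy * dy, j));
    }
    std::sort(ord.begin(), ord.end());

    std::vector<double> vx, vy, nvx, nvy;
    std::vector<int> lab, nlab;
    vx.push_back(0); vy.push_back(0);
    vx.push_back(w); vy.push_back(0);
    vx.push_back(w); vy.push_back(h);
    vx.push_back(0); vy.push_back(h);
    lab.assign(4, -1);

    double maxd2 = 0.0;
    for (size_t k = 0; k < vx.size(); ++k) {
      double dx = vx[k] - px[i], dy = vy[k] - py[i];
      double d2 = dx * dx + dy * dy;
      if (d2 > maxd2) maxd2 = d2;
    }

    for (size_t q = 0; q < ord.size(); ++q) {
      if (ord[q].first >= 4.0 * maxd2) break;  // bisector cannot reach
      const int j = ord[q].second;
      const double mx = 0.5 * (px[i] + px[j]), my = 0.5 * (py[i] + py[j]);
      const double ux = px[j] - px[i], uy = py[j] - py[i];

      const size_t K = vx.size();
      std::vector<double> dv(K);
      bool any_out = false;
      for (size_t k = 0; k < K; ++k) {
        dv[k] = (vx[k] - mx) * ux + (vy[k] - my) * uy;
        if (dv[k] > 0) any_out = true;
      }
      if (!any_out) continue;

      nvx.clear(); nvy.clear(); nlab.clear();
      for (size_t k = 0; k < K; ++k) {
        const size_t k2 = (k + 1) % K;
        const double da = dv[k], db = dv[k2];
        if (da <= 0) { nvx.push_back(vx[k]); nvy.push_back(vy[k]); nlab.push_back(lab[k]); }
        if ((da <= 0) != (db <= 0)) {
          const double t = da / (da - db);
          const double ix = vx[k] + t * (vx[k2] - vx[k]);
          const double iy = vy[k] + t * (vy[k2] - vy[k]);
          // leaving the half-plane: the new edge runs along the bisector;
          // entering it: the remainder of the original edge follows.
          nvx.push_back(ix); nvy.push_back(iy);
          nlab.push_back(da <= 0 ? j : lab[k]);
        }
      }
      vx.swap(nvx); vy.swap(nvy); lab.swap(nlab);

      maxd2 = 0.0;
      for (size_t k = 0; k < vx.size(); ++k) {
        double dx = vx[k] - px[i], dy = vy[k] - py[i];
        double d2 = dx * dx + dy * dy;
        if (d2 > maxd2) maxd2 = d2;
      }
    }

    // a vertex whose outgoing edge has zero length is merged away; the
    // surviving coincident vertex keeps the non-degenerate edge's label
    const size_t K = vx.size();
    std::vector<double> fx, fy; std::vector<int> flab;
    for (size_t k = 0; k < K; ++k) {
      const size_t kp = (k + 1) % K;
      double dx = vx[kp] - vx[k], dy = vy[kp] - vy[k];
      if (dx * dx + dy * dy > 1e-24) {
        fx.push_back(vx[k]); fy.push_back(vy[k]); flab.push_back(lab[k]);
      }
    }
    if (fx.size() < 3) { fx = vx; fy = vy; flab = lab; }

    NumericMatrix verts(fx.size(), 2);
    IntegerVector labels(fx.size());
    for (size_t k = 0; k < fx.size(); ++k) {
      verts(k, 0) = fx[k]; verts(k, 1) = fy[k]; labels[k] = flab[k];
    }
    out[i] = List::create(_["verts"] = verts, _["labels"] = labels);
  }
  return out;
}

// Edge lengths by label for one cell polygon: returns, for each unique
// non-negative label, the total length of its edges.  Used by the R side
// to apply the positive-length adjacency rule.
// [[Rcpp::export]]
List edge_lengths_cpp(NumericMatrix verts, IntegerVector labels) {
  const int K = verts.nrow();
  std::vector<int> ulab; std::vector<double> len;
  for (int k = 0; k < K; ++k) {
    const int k2 = (k + 1) % K;
    const int l = labels[k];
    if (l < 0) continue;
    const double dx = verts(k2, 0) - verts(k, 0);
    const double dy = verts(k2, 1) - verts(k, 1);
    const double d = std::sqrt(dx * dx + dy * dy);
    bool found = false;
    for (size_t q = 0; q < ulab.size(); ++q)
      if (ulab[q] == l) { len[q] += d; found = true; break; }
    if (!found) { ulab.push_back(l); len.push_back(d); }
  }
  return List::create(_["label"] = wrap(ulab), _["length"] = wrap(len));
}
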