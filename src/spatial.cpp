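#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// K nearest neighbours of each query row among the data rows, brute force
// with partial sort. Rows are points, columns are dimensions. Used both for
// spatial windows (2 columns) and marker-probability space (p columns).
// self_skip: when query and data are the same matrix, skip j == i.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix data, NumericMatrix query, int k,
                      bool self_skip) {
  const int n = data.nrow(), m = query.nrow(), d = data.ncol();
  if (k > (self_skip ? n - 1 : n))
    stop("k exceeds the number of candidate neighbours");
  IntegerMatrix out(m, k);
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < m; ++i) {
    int nc = 0;
    for (int j = 0; j < n; ++j) {
      if (self_skip && j == i) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = query(i, c) - data(j, c);
        s += diff * diff;
      }
      cand[nc++] = std::make_pair(s, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.begin() + nc);
    for (int q = 0; q < k; ++q) out(i, q) = cand[q].second + 1;  // 1-based
  }
  return out;
}

// Distance from each reference point to its nearest target point.
// self_skip: reference and target are the same point set (aligned rows).
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericVector rx, NumericVector ry,
                          NumericVector tx, NumericVector ty,
                          bool self_skip) {
  const int nr = rx.size(), nt = tx.size();
  NumericVector out(nr);
  for (int i = 0; i < nr; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nt; ++j) {
      if (self_skip && j == i) continue;
      double dx = rx[i] - tx[j], dy = ry[i] - ty[j];
      double s = dx * dx + dy * dy;
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Pairs of points within radius r: returned as a two-column (i, j) index
// matrix (1-based, both directions), the sparse neighbour graph used by the
// permutation interaction score.
// [[Rcpp::export]]
IntegerMatrix cpp_radius_pairs(NumericVector x, NumericVector y, double r) {
  const int n = x.size();
  const double r2 = r * r;
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy <= r2) {
        ii.push_back(i + 1); jj.push_back(j + 1);
        ii.push_back(j + 1); jj.push_back(i + 1);
      }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t q = 0; q < ii.size(); ++q) {
    out(q, 0) = ii[q];
    out(q, 1) = jj[q];
  }
  return out;
}

// Alpha-shape boundary points. An edge (i, j) with |ij| <= 2*alpha lies on
// the alpha-shape boundary iff one of the two circles of radius alpha
// through i and j contains no other point in its interior. Points incident
// to at least one boundary edge are flagged. Degenerate all-collinear input
// is handled by the caller (convex-hull fallback).
// [[Rcpp::export]]
LogicalVector cpp_alpha_edges(NumericVector x, NumericVector y,
                              double alpha) {
  const int n = x.size();
  LogicalVector edge(n, false);
  const double r2 = alpha * alpha;
  const double eps = 1e-9 * alpha;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d2 = dx * dx + dy * dy;
      if (d2 > 4.0 * r2 || d2 == 0.0) continue;
      double mx = 0.5 * (x[i] + x[j]), my = 0.5 * (y[i] + y[j]);
      double h = std::sqrt(std::max(0.0, r2 - 0.25 * d2));
      double d = std::sqrt(d2);
      // unit normal to the segment
      double ux = -dy / d, uy = dx / d;
      for (int side = 0; side < 2; ++side) {
        double cx = mx + (side == 0 ? h : -h) * ux;
        double cy = my + (side == 0 ? h : -h) * uy;
        bool empty = true;
        for (int q = 0; q < n; ++q) {
          if (q == i || q == j) continue;
          double qx = x[q] - cx, qy = y[q] - cy;
          if (qx * qx + qy * qy < r2 - eps) { empty = false; break; }
        }
        if (empty) { edge[i] = true; edge[j] = true; break; }
      }
      if (edge[i] && edge[j] && n > 2) continue;
    }
  }
  return edge;
}
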