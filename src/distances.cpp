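#include <Rcpp.h>
using namespace Rcpp;

// Classic DTW with absolute-difference local cost and symmetric steps
// (diagonal / up / left, each adding the local cost once). Returns the
// optimal total cost and the length of one optimal path (diagonal-preferring
// traceback) so callers can normalize by path length.
// [[Rcpp::export]]
List dtw_cost_cpp(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty series");
  NumericMatrix D(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::fabs(a[i] - b[j]);
      if (i == 0 && j == 0) D(i, j) = c;
      else if (i == 0) D(i, j) = D(i, j - 1) + c;
      else if (j == 0) D(i, j) = D(i - 1, j) + c;
      else D(i, j) = c + std::min(D(i - 1, j - 1),
                                  std::min(D(i - 1, j), D(i, j - 1)));
    }
  }
  // traceback, preferring diagonal on ties
  int i = n - 1, j = m - 1, len = 1;
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double dd = D(i - 1, j - 1), du = D(i - 1, j), dl = D(i, j - 1);
      if (dd <= du && dd <= dl) { --i; --j; }
      else if (du <= dl) { --i; }
      else { --j; }
    }
    ++len;
  }
  return List::create(_["cost"] = D(n - 1, m - 1), _["path_length"] = len);
}

// Symmetric Hausdorff distance between point sets given as (x, y) columns.
// [[Rcpp::export]]
double hausdorff_cpp(NumericVector ax, NumericVector ay,
                     NumericVector bx, NumericVector by) {
  int n = ax.size(), m = bx.size();
  double hab = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = ax[i] - bx[j], dy = ay[i] - by[j];
      double d = dx * dx + dy * dy;
      if (d < best) best = d;
    }
    if (best > hab) hab = best;
  }
  double hba = 0.0;
  for (int j = 0; j < m; ++j) {
    double best = R_PosInf;
    for (int i = 0; i < n; ++i) {
      double dx = ax[i] - bx[j], dy = ay[i] - by[j];
      double d = dx * dx + dy * dy;
      if (d < best) best = d;
    }
    if (best > hba) hba = best;
  }
  return std::sqrt(std::max(hab, hba));
}

static double point_segment_dist2(double px, double py,
                                  double x1, double y1,
                                  double x2, double y2) {
  double vx = x2 - x1, vy = y2 - y1;
  double L2 = vx * vx + vy * vy;
  double t = 0.0;
  if (L2 > 0.0) {
    t = ((px - x1) * vx + (py - y1) * vy) / L2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  double dx = px - (x1 + t * vx), dy = py - (y1 + t * vy);
  return dx * dx + dy * dy;
}

// One-sided segment-path distance: mean over points of A of the minimum
// Euclidean distance to any segment of trajectory B.
// [[Rcpp::export]]
double spd_cpp(NumericVector ax, NumericVector ay,
               NumericVector bx, NumericVector by) {
  int n = ax.size(), m = bx.size();
  if (m < 2) stop("trajectory B needs at least 2 points");
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j + 1 < m; ++j) {
      double d = point_segment_dist2(ax[i], ay[i], bx[j], by[j],
                                     bx[j + 1], by[j + 1]);
      if (d < best) best = d;
    }
    acc += std::sqrt(best);
  }
  return acc / n;
}

// One-sided nonlinear interdependence S(A|B) on delay-embedded series.
// emb_a / emb_b: rows = embedded points (same count), k neighbors,
// theiler: exclusion window on time-index distance.
// [[Rcpp::export]]
double nli_s_cpp(NumericMatrix emb_a, NumericMatrix emb_b,
                 int k, int theiler) {
  int n = emb_a.nrow(), d = emb_a.ncol();
  if (emb_b.nrow() != n) stop("embeddings must have equal length");
  std::vector<double> ratios;
  ratios.reserve(n);
  std::vector<std::pair<double,int> > da(n), db(n);
  for (int i = 0; i < n; ++i) {
    int na = 0, nb = 0;
    for (int j = 0; j < n; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double sa = 0.0, sb = 0.0;
      for (int c = 0; c < d; ++c) {
        double va = emb_a(i, c) - emb_a(j, c);
        double vb = emb_b(i, c) - emb_b(j, c);
        sa += va * va; sb += vb * vb;
      }
      da[na++] = std::make_pair(sa, j);
      db[nb++] = std::make_pair(sb, j);
    }
    if (na < k) continue;
    std::partial_sort(da.begin(), da.begin() + k, da.begin() + na);
    std::partial_sort(db.begin(), db.begin() + k, db.begin() + nb);
    double r_true = 0.0, r_cond = 0.0;
    for (int q = 0; q < k; ++q) {
      r_true += da[q].first;
      int jb = db[q].second;  // time index of B's q-th neighbor
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double v = emb_a(i, c) - emb_a(jb, c);
        s += v * v;
      }
      r_cond += s;
    }
    r_true /= k; r_cond /= k;
    if (r_cond > 0.0) ratios.push_back(r_true / r_cond);
    else ratios.push_back(1.0);  // exact coincidence: fully predictable
  }
  if (ratios.empty()) return NA_REAL;
  double acc = 0.0;
  for (size_t i = 0; i < ratios.size(); ++i) acc += ratios[i];
  return acc / ratios.size();
}
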