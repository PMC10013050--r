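#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger (algorithm 1) mutual information and
// conditional mutual information under the maximum norm, with a kd-tree for
// neighbour search and range counting. One-dimensional marginals use sorted
// arrays with binary search. All counts are strict (< eps), matching the
// KSG convention; the query point itself is never counted.

namespace {

typedef std::vector<const double*> Cols;

struct KDTree {
  int N, D;
  const Cols cols;
  std::vector<int> idx;
  struct Node { int dim; double split; int left, right, lo, hi; };
  std::vector<Node> nodes;
  static const int LEAF = 16;

  KDTree(const Cols& c, int n) : N(n), D((int)c.size()), cols(c), idx(n) {
    for (int i = 0; i < N; ++i) idx[i] = i;
    nodes.reserve(2 * (N / LEAF + 2));
    if (N > 0) build(0, N);
  }

  int build(int lo, int hi) {
    int me = (int)nodes.size();
    nodes.push_back(Node());
    if (hi - lo <= LEAF) {
      nodes[me].dim = -1; nodes[me].lo = lo; nodes[me].hi = hi;
      return me;
    }
    // split the widest dimension at its median
    int bd = 0; double bw = -1.0;
    for (int d = 0; d < D; ++d) {
      double mn = cols[d][idx[lo]], mx = mn;
      for (int i = lo + 1; i < hi; ++i) {
        double v = cols[d][idx[i]];
        if (v < mn) mn = v; else if (v > mx) mx = v;
      }
      if (mx - mn > bw) { bw = mx - mn; bd = d; }
    }
    int mid = (lo + hi) / 2;
    const double* cd = cols[bd];
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [cd](int a, int b) { return cd[a] < cd[b]; });
    nodes[me].dim = bd;
    nodes[me].split = cd[idx[mid]];
    nodes[me].lo = lo; nodes[me].hi = hi;
    int l = build(lo, mid);
    int r = build(mid, hi);
    nodes[me].left = l; nodes[me].right = r;
    return me;
  }

  inline double dist(const double* q, int p) const {
    double m = 0.0;
    for (int d = 0; d < D; ++d) {
      double v = std::fabs(q[d] - cols[d][p]);
      if (v > m) m = v;
    }
    return m;
  }

  // k nearest neighbours of q excluding point `self`; best holds the k
  // smallest distances, sorted ascending; returns kth distance.
  void knn(int node, const double* q, int self, int k, double* best) const {
    const Node& nd = nodes[node];
    if (nd.dim < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int p = idx[i];
        if (p == self) continue;
        double dv = dist(q, p);
        if (dv < best[k - 1]) {
          int j = k - 1;
          while (j > 0 && best[j - 1] > dv) { best[j] = best[j - 1]; --j; }
          best[j] = dv;
        }
      }
      return;
    }
    double gap = q[nd.dim] - nd.split;
    int nearC = gap < 0 ? nd.left : nd.right;
    int farC  = gap < 0 ? nd.right : nd.left;
    knn(nearC, q, self, k, best);
    if (std::fabs(gap) < best[k - 1]) knn(farC, q, self, k, best);
  }

  // number of points with max-norm distance strictly below eps, excluding
  // `self`.
  int count(int node, const double* q, int self, double eps) const {
    const Node& nd = nodes[node];
    if (nd.dim < 0) {
      int c = 0;
      for (int i = nd.lo; i < nd.hi; ++i) {
        int p = idx[i];
        if (p == self) continue;
        if (dist(q, p) < eps) ++c;
      }
      return c;
    }
    double gap = q[nd.dim] - nd.split;
    int nearC = gap < 0 ? nd.left : nd.right;
    int farC  = gap < 0 ? nd.right : nd.left;
    int c = count(nearC, q, self, eps);
    if (std::fabs(gap) < eps) c += count(farC, q, self, eps);
    return c;
  }
};

// strict-window count in a sorted 1-D array; excludes self when eps > 0
struct Sorted1D {
  std::vector<double> v;
  Sorted1D(const double* x, int n) : v(x, x + n) { std::sort(v.begin(), v.end()); }
  inline int count(double q, double eps) const {
    if (eps <= 0.0) return 0;
    int hi = (int)(std::lower_bound(v.begin(), v.end(), q + eps) - v.begin());
    int lo = (int)(std::upper_bound(v.begin(), v.end(), q - eps) - v.begin());
    return hi - lo - 1;  // subtract the query point itself
  }
};

struct Counter {
  const Cols cols;
  Sorted1D* s1;
  KDTree* tree;
  Counter(const Cols& c, int n) : cols(c), s1(NULL), tree(NULL) {
    if (cols.size() == 1) s1 = new Sorted1D(cols[0], n);
    else tree = new KDTree(cols, n);
  }
  ~Counter() { delete s1; delete tree; }
  inline int count(const std::vector<double>& qbuf, const std::vector<int>& dims,
                   int i, double eps) const {
    if (s1) return s1->count(qbuf[dims[0]], eps);
    // build sub-query in tree dimension order
    double q[64];
    for (size_t d = 0; d < dims.size(); ++d) q[d] = qbuf[dims[d]];
    if (eps <= 0.0) return 0;
    return tree->count(0, q, i, eps);
  }
};

struct Digamma {
  std::vector<double> tab;
  Digamma(int n) : tab(n + 2) {
    tab[1] = -0.5772156649015328606;
    for (int i = 1; i <= n; ++i) tab[i + 1] = tab[i] + 1.0 / i;
  }
  inline double operator()(int n) const { return tab[n]; }
};

// brute-force variant: exact same KSG counts via full distance passes,
// faster than the kd-tree for the moderate N of time-series work
double ksg_brute(const Cols& xc, const Cols& yc, const Cols& zc, int N, int k) {
  const int dx = (int)xc.size(), dy = (int)yc.size(), dz = (int)zc.size();
  Digamma dg(N + 1);
  std::vector<float> dxv(N), dyv(N), dzv(N), djv(N);
  std::vector<float> best(k);
  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) {
      float m = 0.0f;
      for (int d = 0; d < dx; ++d) {
        float v = (float)std::fabs(xc[d][i] - xc[d][j]);
        if (v > m) m = v;
      }
      dxv[j] = m;
      m = 0.0f;
      for (int d = 0; d < dy; ++d) {
        float v = (float)std::fabs(yc[d][i] - yc[d][j]);
        if (v > m) m = v;
      }
      dyv[j] = m;
      m = 0.0f;
      for (int d = 0; d < dz; ++d) {
        float v = (float)std::fabs(zc[d][i] - zc[d][j]);
        if (v > m) m = v;
      }
      dzv[j] = m;
      float a = dxv[j] > dyv[j] ? dxv[j] : dyv[j];
      djv[j] = a > dzv[j] ? a : dzv[j];
    }
    djv[i] = (float)R_PosInf;
    for (int b = 0; b < k; ++b) best[b] = (float)R_PosInf;
    float kth = best[k - 1];
    for (int j = 0; j < N; ++j) {
      float d = djv[j];
      if (d < kth) {
        int b = k - 1;
        while (b > 0 && best[b - 1] > d) { best[b] = best[b - 1]; --b; }
        best[b] = d;
        kth = best[k - 1];
      }
    }
    float eps = kth;
    if (!(eps > 0.0f) || !R_FINITE(eps)) continue;
    int nxz = 0, nyz = 0, nz = 0;
    for (int j = 0; j < N; ++j) {
      float axz = dxv[j] > dzv[j] ? dxv[j] : dzv[j];
      float ayz = dyv[j] > dzv[j] ? dyv[j] : dzv[j];
      nxz += (axz < eps);
      nyz += (ayz < eps);
      nz += (dzv[j] < eps);
    }
    nxz -= 1; nyz -= 1; nz -= 1;   // the point itself
    if (dz > 0) acc += dg(nxz + 1) + dg(nyz + 1) - dg(nz + 1);
    else acc += dg(nxz + 1) + dg(nyz + 1);
  }
  if (dz > 0) return dg(k) - acc / N;
  return dg(k) + dg(N) - acc / N;
}

// generic KSG CMI I(X; Y | Z); Z may be empty, giving KSG MI.
// All groups are lists of column pointers of length N.
double ksg_impl(const Cols& xc, const Cols& yc, const Cols& zc, int N, int k) {
  if (N <= 4096) return ksg_brute(xc, yc, zc, N, k);
  Cols joint;
  std::vector<int> dx, dy, dz, dxz, dyz;
  int pos = 0;
  for (size_t d = 0; d < xc.size(); ++d) { joint.push_back(xc[d]); dx.push_back(pos++); }
  for (size_t d = 0; d < yc.size(); ++d) { joint.push_back(yc[d]); dy.push_back(pos++); }
  for (size_t d = 0; d < zc.size(); ++d) { joint.push_back(zc[d]); dz.push_back(pos++); }
  dxz = dx; dxz.insert(dxz.end(), dz.begin(), dz.end());
  dyz = dy; dyz.insert(dyz.end(), dz.begin(), dz.end());
  const int D = (int)joint.size();
  if (k >= N) stop("k must be smaller than the number of samples");

  KDTree jt(joint, N);
  Cols xz, yz, zz;
  for (size_t d = 0; d < dxz.size(); ++d) xz.push_back(joint[dxz[d]]);
  for (size_t d = 0; d < dyz.size(); ++d) yz.push_back(joint[dyz[d]]);
  for (size_t d = 0; d < dz.size();  ++d) zz.push_back(joint[dz[d]]);
  Counter cxz(xz, N), cyz(yz, N);
  Counter* cz = zc.empty() ? NULL : new Counter(zz, N);

  Digamma dg(N + 1);
  std::vector<double> qbuf(D), best(k);
  std::vector<int> idxz(dxz.size()), idyz(dyz.size());
  for (size_t d = 0; d < dxz.size(); ++d) idxz[d] = dxz[d];
  for (size_t d = 0; d < dyz.size(); ++d) idyz[d] = dyz[d];

  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int d = 0; d < D; ++d) qbuf[d] = joint[d][i];
    for (int j = 0; j < k; ++j) best[j] = R_PosInf;
    jt.knn(0, qbuf.data(), i, k, best.data());
    double eps = best[k - 1];
    int nxz = cxz.count(qbuf, idxz, i, eps);
    int nyz = cyz.count(qbuf, idyz, i, eps);
    if (cz) {
      int nz = cz->count(qbuf, dz, i, eps);
      acc += dg(nxz + 1) + dg(nyz + 1) - dg(nz + 1);
    } else {
      acc += dg(nxz + 1) + dg(nyz + 1);
    }
  }
  double res;
  if (cz) { res = dg(k) - acc / N; delete cz; }
  else res = dg(k) + dg(N) - acc / N;
  return res;
}

Cols matCols(const NumericMatrix& m) {
  Cols c;
  for (int j = 0; j < m.ncol(); ++j) c.push_back(&m(0, j));
  return c;
}

// Shared per-step context for scanning many 1-D candidates against the
// same response and conditioning set. The (y, z) and (z) distance matrices
// do not depend on the candidate, so they are computed once; row-sorted
// copies provide O(log N) range counts. Each candidate evaluation then
// only needs an expanding two-pointer window over the candidate's sorted
// values.
struct StepCtx {
  int N, k, q;
  // distances stored as float: halves memory traffic of the random-access
  // row lookups, and KSG only compares distances (counts are integers)
  std::vector<float> dyz, dyzS;    // N x N, row-major; dyzS rows sorted
  std::vector<float> dz, dzS;      // only when q > 0
  Digamma dg;

  StepCtx(const double* y, const NumericMatrix& cond, int n, int kk)
    : N(n), k(kk), q(cond.ncol()), dg(n + 1) {
    dyz.resize((size_t)N * N);
    if (q > 0) dz.resize((size_t)N * N);
    for (int i = 0; i < N; ++i) {
      dyz[(size_t)i * N + i] = 0.0;
      if (q > 0) dz[(size_t)i * N + i] = 0.0;
      for (int j = i + 1; j < N; ++j) {
        double dzv = 0.0;
        for (int d = 0; d < q; ++d) {
          double v = std::fabs(cond(i, d) - cond(j, d));
          if (v > dzv) dzv = v;
        }
        double dyv = std::fabs(y[i] - y[j]);
        float dyzv = (float)(dyv > dzv ? dyv : dzv);
        dyz[(size_t)i * N + j] = dyzv;
        dyz[(size_t)j * N + i] = dyzv;
        if (q > 0) {
          dz[(size_t)i * N + j] = (float)dzv;
          dz[(size_t)j * N + i] = (float)dzv;
        }
      }
    }
    dyzS = dyz;
    for (int i = 0; i < N; ++i)
      std::sort(dyzS.begin() + (size_t)i * N, dyzS.begin() + (size_t)(i + 1) * N);
    if (q > 0) {
      dzS = dz;
      for (int i = 0; i < N; ++i)
        std::sort(dzS.begin() + (size_t)i * N, dzS.begin() + (size_t)(i + 1) * N);
    }
  }

  static int countSorted(const float* row, int N, float eps) {
    return (int)(std::lower_bound(row, row + N, eps) - row);
  }

  // CMI (or MI when q == 0) of a candidate given by its value per point:
  // value(i) = sortedVals[posBase[(i + shift) % N]] under a circular time
  // shift of the base candidate column. For wide conditioning sets the
  // kth-neighbour radius approaches the data range and the expanding
  // window degenerates into a branchy full scan, so a branchless
  // sequential pass over the distance rows is used instead.
  double eval(const std::vector<double>& sortedVals,
              const std::vector<int>& orderBase,
              const std::vector<int>& posBase, int shift) const {
    if (q >= 3) return evalBrute(sortedVals, orderBase, posBase, shift);
    double acc = 0.0;
    std::vector<double> best(k);
    for (int i = 0; i < N; ++i) {
      int ib = (i + shift) % N;
      int myPos = posBase[ib];
      double myVal = sortedVals[myPos];
      const float* drow = &dyz[(size_t)i * N];
      for (int b = 0; b < k; ++b) best[b] = R_PosInf;
      int l = myPos - 1, r = myPos + 1;
      for (;;) {
        double dl = l >= 0 ? myVal - sortedVals[l] : R_PosInf;
        double dr = r < N ? sortedVals[r] - myVal : R_PosInf;
        double dw = dl < dr ? dl : dr;
        if (dw >= best[k - 1]) break;
        int sidePos = dl < dr ? l-- : r++;
        int j = orderBase[sidePos] - shift; if (j < 0) j += N;
        double dj = drow[j];
        double joint = dj > dw ? dj : dw;
        if (joint < best[k - 1]) {
          int b = k - 1;
          while (b > 0 && best[b - 1] > joint) { best[b] = best[b - 1]; --b; }
          best[b] = joint;
        }
      }
      double eps = best[k - 1];
      if (!(eps > 0.0) || !R_FINITE(eps)) continue;  // degenerate; skip point
      int n1;
      if (q > 0) {
        // n_wz: expanding window while dw < eps, check dz < eps
        const float* zrow = &dz[(size_t)i * N];
        n1 = 0;
        int ll = myPos - 1, rr = myPos + 1;
        for (;;) {
          double dl = ll >= 0 ? myVal - sortedVals[ll] : R_PosInf;
          double dr = rr < N ? sortedVals[rr] - myVal : R_PosInf;
          double dw = dl < dr ? dl : dr;
          if (dw >= eps) break;
          int sidePos = dl < dr ? ll-- : rr++;
          int j = orderBase[sidePos] - shift; if (j < 0) j += N;
          if (zrow[j] < eps) ++n1;
        }
      } else {
        // n_w: plain 1-D window count
        int hi = (int)(std::lower_bound(sortedVals.begin(), sortedVals.end(),
                                        myVal + eps) - sortedVals.begin());
        int lo = (int)(std::upper_bound(sortedVals.begin(), sortedVals.end(),
                                        myVal - eps) - sortedVals.begin());
        n1 = hi - lo - 1;
      }
      float epsf = (float)eps;
      int n2 = countSorted(&dyzS[(size_t)i * N], N, epsf) - 1;
      if (q > 0) {
        int n3 = countSorted(&dzS[(size_t)i * N], N, epsf) - 1;
        acc += dg(n1 + 1) + dg(n2 + 1) - dg(n3 + 1);
      } else {
        acc += dg(n1 + 1) + dg(n2 + 1);
      }
    }
    if (q > 0) return dg(k) - acc / N;
    return dg(k) + dg(N) - acc / N;
  }

  double evalBrute(const std::vector<double>& sortedVals,
                   const std::vector<int>& orderBase,
                   const std::vector<int>& posBase, int shift) const {
    std::vector<float> wv(N);
    for (int r = 0; r < N; ++r) {
      int j = orderBase[r] - shift; if (j < 0) j += N;
      wv[j] = (float)sortedVals[r];
    }
    double acc = 0.0;
    std::vector<float> best(k);
    for (int i = 0; i < N; ++i) {
      float w0 = wv[i];
      const float* drow = &dyz[(size_t)i * N];
      for (int b = 0; b < k; ++b) best[b] = (float)R_PosInf;
      float kth = best[k - 1];
      for (int j = 0; j < N; ++j) {
        float dw = std::fabs(wv[j] - w0);
        float dj = drow[j];
        float d = dj > dw ? dj : dw;
        if (d < kth && j != i) {
          int b = k - 1;
          while (b > 0 && best[b - 1] > d) { best[b] = best[b - 1]; --b; }
          best[b] = d;
          kth = best[k - 1];
        }
      }
      float eps = kth;
      if (!(eps > 0.0f) || !R_FINITE(eps)) continue;
      const float* zrow = &dz[(size_t)i * N];
      int n1 = 0;
      for (int j = 0; j < N; ++j) {
        float dw = std::fabs(wv[j] - w0);
        float d = zrow[j] > dw ? zrow[j] : dw;
        n1 += (d < eps);
      }
      --n1;  // the point itself
      int n2 = countSorted(&dyzS[(size_t)i * N], N, eps) - 1;
      int n3 = countSorted(&dzS[(size_t)i * N], N, eps) - 1;
      acc += dg(n1 + 1) + dg(n2 + 1) - dg(n3 + 1);
    }
    return dg(k) - acc / N;
  }
};

void sortOrder(const double* w, int N, std::vector<double>& sortedVals,
               std::vector<int>& order, std::vector<int>& pos) {
  order.resize(N); sortedVals.resize(N); pos.resize(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [w](int a, int b) { return w[a] < w[b]; });
  for (int r = 0; r < N; ++r) { sortedVals[r] = w[order[r]]; pos[order[r]] = r; }
}

} // namespace

// [[Rcpp::export]]
double ksg_mi_cpp(NumericMatrix X, NumericMatrix Y, int k) {
  if (X.nrow() != Y.nrow()) stop("sample-size mismatch");
  Cols zc;
  return ksg_impl(matCols(X), matCols(Y), zc, X.nrow(), k);
}

// [[Rcpp::export]]
double ksg_cmi_cpp(NumericMatrix X, NumericMatrix Y, NumericMatrix Z, int k) {
  if (X.nrow() != Y.nrow()) stop("sample-size mismatch");
  Cols zc = Z.ncol() > 0 ? matCols(Z) : Cols();
  return ksg_impl(matCols(X), matCols(Y), zc, X.nrow(), k);
}

// CMI of every candidate column with y given the conditioning set.
// [[Rcpp::export]]
NumericVector scan_cmi_cpp(NumericVector y, NumericMatrix cands,
                           IntegerVector candIdx, NumericMatrix cond, int k) {
  const int N = y.size();
  StepCtx ctx(&y[0], cond, N, k);
  NumericVector out(candIdx.size());
  std::vector<double> sv; std::vector<int> order, pos;
  for (int q = 0; q < candIdx.size(); ++q) {
    sortOrder(&cands(0, candIdx[q] - 1), N, sv, order, pos);
    out[q] = ctx.eval(sv, order, pos, 0);
  }
  return out;
}

// All surrogate CMI values of the time-shift test (no early exit); used to
// estimate the null scale of the estimator at the first embedding step.
// [[Rcpp::export]]
NumericVector surrogate_vals_cpp(NumericVector y, NumericVector w,
                                 NumericMatrix cond, int k,
                                 IntegerVector shifts) {
  const int N = y.size();
  StepCtx ctx(&y[0], cond, N, k);
  std::vector<double> sv; std::vector<int> order, pos;
  sortOrder(&w[0], N, sv, order, pos);
  NumericVector out(shifts.size());
  for (int s = 0; s < shifts.size(); ++s) {
    int sh = ((shifts[s] % N) + N) % N;
    out[s] = ctx.eval(sv, order, pos, sh);
  }
  return out;
}

// Family-wise surrogate null for the first embedding step: each time shift
// is applied to every candidate column and the maximum MI over candidates
// is one draw of the max-statistic null (the observed first-step statistic
// is itself a maximum over candidates). Returns c(count, evaluated) with
// the same sequential early exit as the per-candidate test.
// [[Rcpp::export]]
IntegerVector surrogate_max_count_cpp(NumericVector y, NumericMatrix cands,
                                      IntegerVector candIdx, int k,
                                      IntegerVector shifts, double obs,
                                      int stopAt) {
  const int N = y.size();
  const int n = shifts.size();
  NumericMatrix cond(N, 0);
  StepCtx ctx(&y[0], cond, N, k);
  const int P = candIdx.size();
  std::vector<std::vector<double> > sv(P);
  std::vector<std::vector<int> > order(P), pos(P);
  for (int q = 0; q < P; ++q)
    sortOrder(&cands(0, candIdx[q] - 1), N, sv[q], order[q], pos[q]);
  int cnt = 0, done = 0;
  for (int s = 0; s < n; ++s) {
    int sh = ((shifts[s] % N) + N) % N;
    double mx = R_NegInf;
    for (int q = 0; q < P; ++q) {
      double v = ctx.eval(sv[q], order[q], pos[q], sh);
      if (v > mx) mx = v;
      if (mx >= obs) break;
    }
    ++done;
    if (mx >= obs) ++cnt;
    if (cnt >= stopAt) break;
    if (cnt + (n - done) < stopAt) break;
  }
  return IntegerVector::create(cnt, done);
}

// Sequential time-shift surrogate test: counts surrogate CMI values that
// reach `obs`, stopping as soon as the significance decision is settled
// (count >= stopAt, or too few draws remain to reach stopAt). Returns
// c(count, evaluated).
// [[Rcpp::export]]
IntegerVector surrogate_count_cpp(NumericVector y, NumericVector w,
                                  NumericMatrix cond, int k,
                                  IntegerVector shifts, double obs,
                                  int stopAt) {
  const int N = y.size();
  const int n = shifts.size();
  StepCtx ctx(&y[0], cond, N, k);
  std::vector<double> sv; std::vector<int> order, pos;
  sortOrder(&w[0], N, sv, order, pos);
  int cnt = 0, done = 0;
  for (int s = 0; s < n; ++s) {
    int sh = ((shifts[s] % N) + N) % N;
    double v = ctx.eval(sv, order, pos, sh);
    ++done;
    if (v >= obs) ++cnt;
    if (cnt >= stopAt) break;                 // decidedly not significant
    if (cnt + (n - done) < stopAt) break;     // decidedly significant
  }
  return IntegerVector::create(cnt, done);
}
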