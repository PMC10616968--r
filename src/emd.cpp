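#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- natural cubic spline through (t, y), evaluated at integer grid 0..n-1 ----
static void spline_eval(const std::vector<double>& t, const std::vector<double>& y,
                        int n, std::vector<double>& out) {
  int m = (int)t.size();
  if (m == 1) { std::fill(out.begin(), out.end(), y[0]); return; }
  if (m == 2) {
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = y[0] + slope * (i - t[0]);
    return;
  }
  // second-derivative formulation, natural boundary (M0 = Mm-1 = 0)
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), M(m);
  for (int i = 0; i < m - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 3.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  // evaluate
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double x = (double)i;
    while (seg < m - 2 && x > t[seg + 1]) ++seg;
    double dt = t[seg + 1] - t[seg];
    double A = (t[seg + 1] - x) / dt, B = (x - t[seg]) / dt;
    out[i] = A * y[seg] + B * y[seg + 1] +
      ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) * dt * dt / 6.0;
  }
}

// local extrema with plateau handling (plateau midpoint taken once)
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& imax, std::vector<int>& imin) {
  int n = (int)x.size();
  imax.clear(); imin.clear();
  int i = 1;
  while (i < n - 1) {
    if (x[i] == x[i + 1]) {            // plateau
      int j = i;
      while (j < n - 1 && x[j + 1] == x[i]) ++j;
      if (j < n - 1) {
        int c = (i + j) / 2;
        if (x[i] > x[i - 1] && x[i] > x[j + 1]) imax.push_back(c);
        else if (x[i] < x[i - 1] && x[i] < x[j + 1]) imin.push_back(c);
      }
      i = j + 1;
    } else {
      if (x[i] > x[i - 1] && x[i] > x[i + 1]) imax.push_back(i);
      else if (x[i] < x[i - 1] && x[i] < x[i + 1]) imin.push_back(i);
      ++i;
    }
  }
}

// assemble knots with end reflection (mirror up to two extrema about each end)
static void build_knots(const std::vector<int>& idx, const std::vector<double>& x,
                        int n, std::vector<double>& t, std::vector<double>& y) {
  t.clear(); y.clear();
  int m = (int)idx.size();
  int nref = std::min(2, m);
  for (int k = nref - 1; k >= 0; --k) {
    double tr = -(double)idx[k];
    if (tr < -1e-9) { t.push_back(tr); y.push_back(x[idx[k]]); }
  }
  for (int k = 0; k < m; ++k) { t.push_back((double)idx[k]); y.push_back(x[idx[k]]); }
  for (int k = 0; k < nref; ++k) {
    double tr = 2.0 * (n - 1) - (double)idx[m - 1 - k];
    if (tr > (double)(n - 1) + 1e-9) { t.push_back(tr); y.push_back(x[idx[m - 1 - k]]); }
  }
  // enforce strictly increasing (dedupe)
  std::vector<double> tt, yy;
  for (size_t k = 0; k < t.size(); ++k) {
    if (tt.empty() || t[k] > tt.back() + 1e-9) { tt.push_back(t[k]); yy.push_back(y[k]); }
  }
  t.swap(tt); y.swap(yy);
}

// one EMD of x; returns IMFs stacked row-wise and residue as last row.
static void emd_core(const std::vector<double>& xin, int max_imfs, int max_sifts,
                     double sd_tol, std::vector<std::vector<double> >& imfs,
                     std::vector<double>& residue) {
  int n = (int)xin.size();
  std::vector<double> r = xin, h(n), env_hi(n), env_lo(n), tmax, ymax, tmin, ymin;
  std::vector<int> imax, imin;
  imfs.clear();
  for (int k = 0; k < max_imfs; ++k) {
    find_extrema(r, imax, imin);
    if ((int)imax.size() + (int)imin.size() < 3) break;
    h = r;
    for (int s = 0; s < max_sifts; ++s) {
      find_extrema(h, imax, imin);
      if ((int)imax.size() < 2 || (int)imin.size() < 2) break;
      build_knots(imax, h, n, tmax, ymax);
      build_knots(imin, h, n, tmin, ymin);
      spline_eval(tmax, ymax, n, env_hi);
      spline_eval(tmin, ymin, n, env_lo);
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        double m = 0.5 * (env_hi[i] + env_lo[i]);
        num += m * m; den += h[i] * h[i];
        h[i] -= m;
      }
      if (den > 0 && num / den < sd_tol) break;
    }
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) r[i] -= h[i];
  }
  residue = r;
}

// [[Rcpp::export]]
List emd_cpp(NumericVector x, int max_imfs = 8, int max_sifts = 12,
             double sd_tol = 0.2) {
  std::vector<double> xin(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;
  std::vector<double> residue;
  emd_core(xin, max_imfs, max_sifts, sd_tol, imfs, residue);
  int n = x.size(), k = (int)imfs.size();
  NumericMatrix M(k, n);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < n; ++i) M(j, i) = imfs[j][i];
  return List::create(_["imfs"] = M, _["residue"] = NumericVector(residue.begin(), residue.end()));
}

// Complementary-pair EEMD: members come as x + w and x - w so the averaged
// decomposition reconstructs x exactly. Uses R's RNG (respects set.seed()).
// [[Rcpp::export]]
List eemd_cpp(NumericVector x, int n_ensembles, double noise_sd, int max_imfs,
              int max_sifts = 12, double sd_tol = 0.2) {
  int n = x.size();
  std::vector<double> xin(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;
  std::vector<double> residue;
  if (n_ensembles <= 1 || noise_sd <= 0.0) {
    emd_core(xin, max_imfs, max_sifts, sd_tol, imfs, residue);
    int k = (int)imfs.size();
    NumericMatrix M(k, n);
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < n; ++i) M(j, i) = imfs[j][i];
    return List::create(_["imfs"] = M,
                        _["residue"] = NumericVector(residue.begin(), residue.end()),
                        _["n_members"] = 1);
  }
  int n_pairs = (n_ensembles + 1) / 2;
  NumericMatrix acc(max_imfs, n);
  std::vector<double> res_acc(n, 0.0), xe(n);
  int members = 0;
  for (int p = 0; p < n_pairs; ++p) {
    NumericVector w = rnorm(n, 0.0, noise_sd);
    for (int sgn = 0; sgn < 2; ++sgn) {
      double s = sgn == 0 ? 1.0 : -1.0;
      for (int i = 0; i < n; ++i) xe[i] = xin[i] + s * w[i];
      emd_core(xe, max_imfs, max_sifts, sd_tol, imfs, residue);
      int k = (int)imfs.size();
      for (int j = 0; j < k; ++j)
        for (int i = 0; i < n; ++i) acc(j, i) += imfs[j][i];
      for (int i = 0; i < n; ++i) res_acc[i] += residue[i];
      ++members;
    }
  }
  for (int j = 0; j < max_imfs; ++j)
    for (int i = 0; i < n; ++i) acc(j, i) /= members;
  NumericVector res_out(n);
  for (int i = 0; i < n; ++i) res_out[i] = res_acc[i] / members;
  // drop trailing all-zero IMF rows
  int keep = max_imfs;
  while (keep > 0) {
    double ss = 0.0;
    for (int i = 0; i < n; ++i) ss += acc(keep - 1, i) * acc(keep - 1, i);
    if (ss > 0) break;
    --keep;
  }
  NumericMatrix M(keep, n);
  for (int j = 0; j < keep; ++j)
    for (int i = 0; i < n; ++i) M(j, i) = acc(j, i);
  return List::create(_["imfs"] = M, _["residue"] = res_out, _["n_members"] = members);
}

// Direct-form II transposed IIR filter with initial conditions.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x,
                             NumericVector zi) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(na, nb) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0), z(nz, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  for (int i = 0; i < std::min((int)zi.size(), nz); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}

// Median over rows for each column of a channels x samples matrix.
// [[Rcpp::export]]
NumericVector col_median_cpp(NumericMatrix X) {
  int nr = X.nrow(), nc = X.ncol();
  NumericVector out(nc);
  std::vector<double> buf(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) buf[i] = X(i, j);
    int mid = nr / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double m = buf[mid];
    if (nr % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
      m = 0.5 * (m + buf[mid - 1]);
    }
    out[j] = m;
  }
  return out;
}
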