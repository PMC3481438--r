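// Iterative solver for the anchored stationary system: ILU(0)-preconditioned
// BiCGSTAB with restarting and true-residual verification. The anchored
// matrix is a (negated) column-diagonally-dominant M-matrix on a truncated
// lattice; direct sparse factorizations suffer severe 3-D fill-in, while
// the zero-fill incomplete factorization captures the local transition
// structure well.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct CSR {
  int n;
  std::vector<int> ptr, col;
  std::vector<double> val;
};

CSR csc_to_csr(int n, const IntegerVector& Ap, const IntegerVector& Ai,
               const NumericVector& Ax) {
  CSR A;
  A.n = n;
  int nnz = Ax.size();
  A.ptr.assign(n + 1, 0);
  for (int k = 0; k < nnz; ++k) A.ptr[Ai[k] + 1]++;
  for (int r = 0; r < n; ++r) A.ptr[r + 1] += A.ptr[r];
  A.col.resize(nnz);
  A.val.resize(nnz);
  std::vector<int> next(A.ptr.begin(), A.ptr.end() - 1);
  for (int c = 0; c < n; ++c)
    for (int k = Ap[c]; k < Ap[c + 1]; ++k) {
      int dst = next[Ai[k]]++;
      A.col[dst] = c;
      A.val[dst] = Ax[k];
    }
  // sort rows by column index (insertion sort; rows are short)
  for (int r = 0; r < n; ++r)
    for (int k = A.ptr[r] + 1; k < A.ptr[r + 1]; ++k) {
      int c = A.col[k];
      double v = A.val[k];
      int m = k - 1;
      while (m >= A.ptr[r] && A.col[m] > c) {
        A.col[m + 1] = A.col[m];
        A.val[m + 1] = A.val[m];
        --m;
      }
      A.col[m + 1] = c;
      A.val[m + 1] = v;
    }
  return A;
}

struct ILU0 {
  CSR lu;
  std::vector<int> diag;
};

bool ilu0_factor(const CSR& A, ILU0& F) {
  F.lu = A;
  int n = A.n;
  F.diag.assign(n, -1);
  std::vector<int> pos(n, -1);
  for (int r = 0; r < n; ++r) {
    int rb = F.lu.ptr[r], re = F.lu.ptr[r + 1];
    for (int k = rb; k < re; ++k) pos[F.lu.col[k]] = k;
    for (int k = rb; k < re; ++k) {
      int c = F.lu.col[k];
      if (c >= r) break;
      int dc = F.diag[c];
      if (dc < 0 || F.lu.val[dc] == 0.0) {
        for (int k2 = rb; k2 < re; ++k2) pos[F.lu.col[k2]] = -1;
        return false;
      }
      double l = F.lu.val[k] / F.lu.val[dc];
      F.lu.val[k] = l;
      for (int kk = dc + 1; kk < F.lu.ptr[c + 1]; ++kk) {
        int p = pos[F.lu.col[kk]];
        if (p >= 0) F.lu.val[p] -= l * F.lu.val[kk];
      }
    }
    for (int k = rb; k < re; ++k)
      if (F.lu.col[k] == r) {
        F.diag[r] = k;
        break;
      }
    for (int k = rb; k < re; ++k) pos[F.lu.col[k]] = -1;
    if (F.diag[r] < 0 || F.lu.val[F.diag[r]] == 0.0) return false;
  }
  return true;
}

void ilu0_apply(const ILU0& F, std::vector<double>& x) {
  int n = F.lu.n;
  for (int r = 0; r < n; ++r) {
    double s = x[r];
    for (int k = F.lu.ptr[r]; k < F.diag[r]; ++k)
      s -= F.lu.val[k] * x[F.lu.col[k]];
    x[r] = s;
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = x[r];
    for (int k = F.diag[r] + 1; k < F.lu.ptr[r + 1]; ++k)
      s -= F.lu.val[k] * x[F.lu.col[k]];
    x[r] = s / F.lu.val[F.diag[r]];
  }
}

void spmv(const CSR& A, const std::vector<double>& x, std::vector<double>& y) {
  int n = A.n;
  for (int r = 0; r < n; ++r) {
    double s = 0;
    for (int k = A.ptr[r]; k < A.ptr[r + 1]; ++k) s += A.val[k] * x[A.col[k]];
    y[r] = s;
  }
}

double nrm2(const std::vector<double>& v) {
  double s = 0;
  for (double z : v) s += z * z;
  return std::sqrt(s);
}

}  // namespace

// [[Rcpp::export]]
List anchored_bicgstab(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                       int n, NumericVector bIn, double tol, int maxIter,
                       NumericVector x0) {
  CSR A = csc_to_csr(n, Ap, Ai, Ax);
  ILU0 F;
  if (!ilu0_factor(A, F)) return List::create(_["ok"] = false);
  std::vector<double> b(bIn.begin(), bIn.end());
  double bnorm = nrm2(b);
  if (bnorm == 0) bnorm = 1;
  std::vector<double> x(n, 0.0), r(n), r0(n), p(n), v(n), s(n), t(n), ph(n),
      sh(n);
  if (x0.size() == n) {
    for (int i = 0; i < n; ++i) x[i] = std::isfinite(x0[i]) ? x0[i] : 0.0;
  }
  int totIt = 0;
  bool converged = false;
  for (int restart = 0; restart < 60 && !converged && totIt < maxIter;
       ++restart) {
    spmv(A, x, t);
    for (int i = 0; i < n; ++i) r[i] = b[i] - t[i];
    double rn0 = nrm2(r) / bnorm;
    if (rn0 < tol) {
      converged = true;
      break;
    }
    r0 = r;
    double rho = 1, alpha = 1, omega = 1;
    std::fill(p.begin(), p.end(), 0.0);
    std::fill(v.begin(), v.end(), 0.0);
    for (int it = 0; it < 300 && totIt < maxIter; ++it, ++totIt) {
      double rho1 = 0;
      for (int i = 0; i < n; ++i) rho1 += r0[i] * r[i];
      if (rho1 == 0) break;
      if (it == 0)
        p = r;
      else {
        double beta = (rho1 / rho) * (alpha / omega);
        for (int i = 0; i < n; ++i) p[i] = r[i] + beta * (p[i] - omega * v[i]);
      }
      rho = rho1;
      ph = p;
      ilu0_apply(F, ph);
      spmv(A, ph, v);
      double r0v = 0;
      for (int i = 0; i < n; ++i) r0v += r0[i] * v[i];
      if (r0v == 0) break;
      alpha = rho / r0v;
      for (int i = 0; i < n; ++i) s[i] = r[i] - alpha * v[i];
      if (nrm2(s) / bnorm < tol) {
        for (int i = 0; i < n; ++i) x[i] += alpha * ph[i];
        converged = true;
        break;
      }
      sh = s;
      ilu0_apply(F, sh);
      spmv(A, sh, t);
      double tt = 0, ts = 0;
      for (int i = 0; i < n; ++i) {
        tt += t[i] * t[i];
        ts += t[i] * s[i];
      }
      if (tt == 0) break;
      omega = ts / tt;
      for (int i = 0; i < n; ++i) {
        x[i] += alpha * ph[i] + omega * sh[i];
        r[i] = s[i] - omega * t[i];
      }
      double rn = nrm2(r) / bnorm;
      if (rn < tol) {
        converged = true;
        break;
      }
      if (!std::isfinite(rn) || rn > 1e10) break;  // diverged: restart
      if (omega == 0) break;
    }
    if (converged) {
      spmv(A, x, t);
      for (int i = 0; i < n; ++i) r[i] = b[i] - t[i];
      if (nrm2(r) / bnorm >= tol * 100) converged = false;  // keep iterating
    }
    bool bad = false;
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(x[i])) {
        bad = true;
        break;
      }
    if (bad) std::fill(x.begin(), x.end(), 0.0);
  }
  spmv(A, x, t);
  for (int i = 0; i < n; ++i) r[i] = b[i] - t[i];
  double resid = nrm2(r) / bnorm;
  return List::create(_["ok"] = true,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["iters"] = totIt, _["resid"] = resid,
                      _["converged"] = converged || resid < tol * 100);
}
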