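#include <Rcpp.h>
using namespace Rcpp;

// Binary erosion/dilation inner loops.  Offsets (dr, dc) are the structuring
// element's cells relative to its origin; samples outside the image are
// background (false) for both operations.  Interior pixels (where every
// offset stays in bounds) run on precomputed linear offsets; the border
// runs with explicit bounds checks.

static LogicalMatrix morph_core(const LogicalMatrix& f,
                                const IntegerVector& dr,
                                const IntegerVector& dc,
                                const bool erode_mode) {
  const int nr = f.nrow(), nc = f.ncol(), m = dr.size();
  LogicalMatrix out(nr, nc);
  const int* fp = LOGICAL(f);
  int* op = LOGICAL(out);

  std::vector<int> rr(m), cc(m), lin(m);
  int rmin = 0, rmax = 0, cmin = 0, cmax = 0;
  for (int k = 0; k < m; ++k) {
    // dilation probes the reflected element: out(e) = any f(e - g)
    rr[k] = erode_mode ? dr[k] : -dr[k];
    cc[k] = erode_mode ? dc[k] : -dc[k];
    lin[k] = rr[k] + cc[k] * nr;
    rmin = std::min(rmin, rr[k]); rmax = std::max(rmax, rr[k]);
    cmin = std::min(cmin, cc[k]); cmax = std::max(cmax, cc[k]);
  }
  const int r0 = -rmin, r1 = nr - rmax;   // interior rows [r0, r1)
  const int c0 = -cmin, c1 = nc - cmax;

  for (int j = 0; j < nc; ++j) {
    const bool jin = (j >= c0 && j < c1);
    const int base = j * nr;
    for (int i = 0; i < nr; ++i) {
      bool acc = erode_mode;
      if (jin && i >= r0 && i < r1) {
        const int p = base + i;
        if (erode_mode) {
          for (int k = 0; k < m; ++k)
            if (!fp[p + lin[k]]) { acc = false; break; }
        } else {
          for (int k = 0; k < m; ++k)
            if (fp[p + lin[k]]) { acc = true; break; }
        }
      } else {
        for (int k = 0; k < m; ++k) {
          const int r = i + rr[k], c = j + cc[k];
          const bool inside = (r >= 0 && r < nr && c >= 0 && c < nc);
          const bool v = inside && fp[r + c * nr];
          if (erode_mode) { if (!v) { acc = false; break; } }
          else if (v) { acc = true; break; }
        }
      }
      op[base + i] = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_erode(const LogicalMatrix& f,
                        const IntegerVector& dr, const IntegerVector& dc) {
  return morph_core(f, dr, dc, true);
}

// [[Rcpp::export]]
LogicalMatrix cpp_dilate(const LogicalMatrix& f,
                         const IntegerVector& dr, const IntegerVector& dc) {
  return morph_core(f, dr, dc, false);
}

// Same-size 2-D cross-correlation with replicate (clamp-to-edge) borders.
// Kernel origin is its centre cell (odd sizes expected).

// [[Rcpp::export]]
NumericMatrix cpp_filter2(const NumericMatrix& x, const NumericMatrix& k) {
  const int nr = x.nrow(), nc = x.ncol();
  const int kr = k.nrow(), kc = k.ncol();
  const int or_ = kr / 2, oc = kc / 2;
  NumericMatrix out(nr, nc);
  const double* xp = REAL(x);
  const double* kp = REAL(k);
  double* op = REAL(out);

  const int nk = kr * kc;
  std::vector<int> lin(nk);
  std::vector<double> w(nk);
  for (int b = 0; b < kc; ++b)
    for (int a = 0; a < kr; ++a) {
      const int idx = a + b * kr;
      lin[idx] = (a - or_) + (b - oc) * nr;
      w[idx] = kp[idx];
    }
  const int r0 = or_, r1 = nr - (kr - 1 - or_);
  const int c0 = oc, c1 = nc - (kc - 1 - oc);

  for (int j = 0; j < nc; ++j) {
    const bool jin = (j >= c0 && j < c1);
    const int base = j * nr;
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      if (jin && i >= r0 && i < r1) {
        const int p = base + i;
        for (int t = 0; t < nk; ++t) acc += w[t] * xp[p + lin[t]];
      } else {
        for (int b = 0; b < kc; ++b) {
          int c = j + b - oc;
          if (c < 0) c = 0; else if (c >= nc) c = nc - 1;
          for (int a = 0; a < kr; ++a) {
            int r = i + a - or_;
            if (r < 0) r = 0; else if (r >= nr) r = nr - 1;
            acc += kp[a + b * kr] * xp[r + c * nr];
          }
        }
      }
      op[base + i] = acc;
    }
  }
  return out;
}
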