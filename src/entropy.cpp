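#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fuzzy membership of a template distance. conv 0 = gaussian_ratio
// exp(-(d/r)^n), conv 1 = chen_original exp(-d^n / r). Exponents larger
// than ~46 underflow below 1e-20 and are truncated to 0; the truncation
// error on any summed match quantity is < n_pairs * 1e-20, far below the
// 1e-10 oracle-agreement tolerance the package tests against.
static inline double fuzzy_weight(double d, double r, double nexp, int conv) {
  if (r <= 0.0) return (d == 0.0) ? 1.0 : 0.0;
  double a;
  if (conv == 0) {
    double q = d / r;
    a = (nexp == 2.0) ? q * q : std::pow(q, nexp);
  } else {
    a = ((nexp == 2.0) ? d * d : std::pow(d, nexp)) / r;
  }
  if (a > 46.0) return 0.0;
  return std::exp(-a);
}

// Summed match quantities at template lengths m and m+1 for one series.
// Templates are the N - m windows starting at 0..N-m-1 (the same count at
// both lengths); self-comparisons excluded; Chebyshev distance; for fuzzy
// entropy with demean = true each template is centred on its own mean
// before the distance is taken. Returns c(A, B): A = sum over ordered
// pairs of length-m match quantities, B = same at length m+1.
static void pair_sums(const double* x, int N, int m, double r,
                      bool fuzzy, double nexp, int conv, bool demean,
                      double& A, double& B) {
  int T = N - m;  // number of templates at both lengths
  A = 0.0;
  B = 0.0;
  if (T < 2) return;

  std::vector<double> mum, mum1;
  if (fuzzy && demean) {
    mum.resize(T);
    mum1.resize(T);
    double sm = 0.0;
    for (int k = 0; k < m; ++k) sm += x[k];
    for (int i = 0; i < T; ++i) {
      double sm1 = sm + x[i + m];
      mum[i] = sm / m;
      mum1[i] = sm1 / (m + 1);
      if (i + 1 < T) sm += x[i + m] - x[i];
    }
  }

  if (fuzzy && demean && nexp == 2.0 && conv == 0 && r > 0.0) {
    // hot path: quadratic-exponential membership on demeaned templates.
    // Demeaned template coordinates are laid out contiguously per template
    // so the pair loop touches memory linearly; the threshold is folded
    // into a reciprocal multiply and memberships below 1e-20 are skipped.
    const double rinv = 1.0 / r;
    std::vector<double> am(static_cast<size_t>(T) * m);
    std::vector<double> bm(static_cast<size_t>(T) * (m + 1));
    for (int i = 0; i < T; ++i) {
      for (int k = 0; k < m; ++k) am[static_cast<size_t>(i) * m + k] = x[i + k] - mum[i];
      for (int k = 0; k <= m; ++k) bm[static_cast<size_t>(i) * (m + 1) + k] = x[i + k] - mum1[i];
    }
    for (int i = 0; i < T - 1; ++i) {
      const double* ai = &am[static_cast<size_t>(i) * m];
      const double* bi = &bm[static_cast<size_t>(i) * (m + 1)];
      for (int j = i + 1; j < T; ++j) {
        const double* aj = &am[static_cast<size_t>(j) * m];
        const double* bj = &bm[static_cast<size_t>(j) * (m + 1)];
        double dm = 0.0, dm1 = 0.0;
        for (int k = 0; k < m; ++k) {
          double v = std::fabs(ai[k] - aj[k]);
          if (v > dm) dm = v;
        }
        for (int k = 0; k <= m; ++k) {
          double v = std::fabs(bi[k] - bj[k]);
          if (v > dm1) dm1 = v;
        }
        double qa = dm * rinv;  qa *= qa;
        double qb = dm1 * rinv; qb *= qb;
        if (qa <= 46.0) A += std::exp(-qa);
        if (qb <= 46.0) B += std::exp(-qb);
      }
    }
  } else if (fuzzy && demean) {
    for (int i = 0; i < T - 1; ++i) {
      for (int j = i + 1; j < T; ++j) {
        double dm = 0.0, dm1 = 0.0;
        for (int k = 0; k < m; ++k) {
          double v = std::fabs((x[i + k] - mum[i]) - (x[j + k] - mum[j]));
          if (v > dm) dm = v;
        }
        for (int k = 0; k <= m; ++k) {
          double v = std::fabs((x[i + k] - mum1[i]) - (x[j + k] - mum1[j]));
          if (v > dm1) dm1 = v;
        }
        A += fuzzy_weight(dm, r, nexp, conv);
        B += fuzzy_weight(dm1, r, nexp, conv);
      }
    }
  } else if (fuzzy) {
    for (int i = 0; i < T - 1; ++i) {
      for (int j = i + 1; j < T; ++j) {
        double dm = 0.0;
        for (int k = 0; k < m; ++k) {
          double v = std::fabs(x[i + k] - x[j + k]);
          if (v > dm) dm = v;
        }
        double v = std::fabs(x[i + m] - x[j + m]);
        double dm1 = (v > dm) ? v : dm;
        A += fuzzy_weight(dm, r, nexp, conv);
        B += fuzzy_weight(dm1, r, nexp, conv);
      }
    }
  } else {
    // hard-threshold counts (sample entropy); d(m+1) >= d(m) so a miss at
    // length m implies a miss at length m+1
    for (int i = 0; i < T - 1; ++i) {
      for (int j = i + 1; j < T; ++j) {
        double dm = 0.0;
        for (int k = 0; k < m; ++k) {
          double v = std::fabs(x[i + k] - x[j + k]);
          if (v > dm) dm = v;
        }
        if (dm <= r) {
          A += 1.0;
          double v = std::fabs(x[i + m] - x[j + m]);
          if ((v > dm ? v : dm) <= r) B += 1.0;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector entropy_sums_cpp(NumericVector x, int m, double r,
                               bool fuzzy, double nexp, int conv,
                               bool demean) {
  double A, B;
  pair_sums(x.begin(), x.size(), m, r, fuzzy, nexp, conv, demean, A, B);
  return NumericVector::create(A, B);
}

// Match-quantity sums for every offset coarse-grained series at scale tau.
// Row 1 = length-m sums, row 2 = length-(m+1) sums, one column per grain
// offset 0..tau-1. Grain k has length floor((N - k) / tau).
// [[Rcpp::export]]
NumericMatrix mse_sums_cpp(NumericVector x, int tau, int m, double r,
                           bool fuzzy, double nexp, int conv, bool demean) {
  int N = x.size();
  NumericMatrix out(2, tau);
  std::vector<double> grain;
  for (int k = 0; k < tau; ++k) {
    int L = (N - k) / tau;
    grain.resize(L);
    for (int l = 0; l < L; ++l) {
      double s = 0.0;
      int base = k + l * tau;
      for (int t = 0; t < tau; ++t) s += x[base + t];
      grain[l] = s / tau;
    }
    double A, B;
    pair_sums(grain.data(), L, m, r, fuzzy, nexp, conv, demean, A, B);
    out(0, k) = A;
    out(1, k) = B;
  }
  return out;
}
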