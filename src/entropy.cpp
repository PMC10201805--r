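#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Chebyshev (max-norm) distance between templates x[i..i+m-1] and x[j..j+m-1]
static inline double cheb(const double* x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(x[i + k] - x[j + k]);
    if (a > d) d = a;
  }
  return d;
}

// Pincus approximate entropy: Phi^m - Phi^{m+1}, self-matches included,
// N - m + 1 templates at dimension m. r in absolute units; r <= 0 means
// exact-match counting (degenerate constant-signal case).
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  int N = x.size();
  const double* p = REAL(x);
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int n_templ = N - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < n_templ; ++i) {
      int cnt = 0;
      for (int j = 0; j < n_templ; ++j) {
        double d = cheb(p, i, j, mm);
        if ((r > 0.0 && d <= r) || (r <= 0.0 && d == 0.0)) ++cnt;
      }
      acc += std::log((double)cnt / (double)n_templ);
    }
    phi[s] = acc / (double)n_templ;
  }
  return phi[0] - phi[1];
}

// Sample entropy pair counts: N - m templates at both dimensions,
// self-matches excluded. Returns c(B, A) = matched pairs at m and m+1.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int N = x.size();
  const double* p = REAL(x);
  int n_templ = N - m; // usable for both m and m+1 templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < n_templ; ++i) {
    for (int j = i + 1; j < n_templ; ++j) {
      double dm = cheb(p, i, j, m);
      bool match_m = (r > 0.0) ? (dm <= r) : (dm == 0.0);
      if (match_m) {
        B += 1.0;
        double d1 = std::fabs(p[i + m] - p[j + m]);
        double dm1 = d1 > dm ? d1 : dm;
        bool match_m1 = (r > 0.0) ? (dm1 <= r) : (dm1 == 0.0);
        if (match_m1) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}

// Fuzzy entropy: baseline-removed templates, exponential membership
// exp(-(d/r)^n), N - m templates at both dimensions, self-pairs excluded.
// Returns c(phi_m, phi_m1).
// [[Rcpp::export(name = ".fuzzyen_phi_cpp")]]
NumericVector fuzzyen_phi_cpp(NumericVector x, int m, double r, double n_exp) {
  int N = x.size();
  const double* p = REAL(x);
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int n_templ = N - m; // fixed across dimensions (Chen convention)
    // baseline-removed templates
    std::vector<double> t((size_t)n_templ * mm);
    for (int i = 0; i < n_templ; ++i) {
      double mu = 0.0;
      for (int k = 0; k < mm; ++k) mu += p[i + k];
      mu /= mm;
      for (int k = 0; k < mm; ++k) t[(size_t)i * mm + k] = p[i + k] - mu;
    }
    double acc = 0.0;
    for (int i = 0; i < n_templ; ++i) {
      for (int j = i + 1; j < n_templ; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double a = std::fabs(t[(size_t)i * mm + k] - t[(size_t)j * mm + k]);
          if (a > d) d = a;
        }
        double sim;
        if (r > 0.0) {
          sim = std::exp(-std::pow(d / r, n_exp));
        } else {
          sim = (d == 0.0) ? 1.0 : 0.0;
        }
        acc += sim;
      }
    }
    phi[s] = 2.0 * acc / ((double)n_templ * (double)(n_templ - 1));
  }
  return NumericVector::create(phi[0], phi[1]);
}
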