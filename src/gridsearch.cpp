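#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;


// Grid coordinate of index i. When the grid origin is an integer multiple
// of the step (the usual case, e.g. -0.3 by 1e-4), points are computed as
// exact multiples of the step so that 0 lies exactly on the grid.
struct axis {
  double lo, step; long long i0; bool exact;
  axis(double lo_, double step_) : lo(lo_), step(step_) {
    double q = lo / step;
    i0 = (long long)std::llround(q);
    exact = std::fabs(q - (double)i0) < 1e-9;
  }
  inline double at(long long i) const {
    return exact ? (double)(i0 + i) * step : lo + (double)i * step;
  }
};

// Comparator implementing the deterministic tie-break order of the
// exhaustive search: smaller error, then smaller |dz|, then smaller |dn|,
// then lexicographic (dz, dn).
static inline bool better(double err, double dz, double dn,
                          double berr, double bdz, double bdn) {
  if (err != berr) return err < berr;
  if (std::fabs(dz) != std::fabs(bdz)) return std::fabs(dz) < std::fabs(bdz);
  if (std::fabs(dn) != std::fabs(bdn)) return std::fabs(dn) < std::fabs(bdn);
  if (dz != bdz) return dz < bdz;
  return dn < bdn;
}

// Residual sum of squares for one (dn, dz) candidate, accumulated in
// wavelength order exactly as the plain-R reference loop does.
static inline double sse(const double* m, const double* C, int nl, double dn) {
  double e = 0.0;
  for (int l = 0; l < nl; ++l) {
    double r = m[l] - dn * C[l];
    e += r * r;
  }
  return e;
}

// Exhaustive search over the (dn, dz) grid for a single pixel, exploiting
// that for fixed dz the error is an exactly quadratic function of dn: the
// discrete minimiser over the dn grid lies among the grid neighbours of
// the continuous minimiser, which are evaluated with the same expression
// as a literal double loop. The result is therefore identical to the
// brute-force scan, at O(n_dz) cost.
static void search_pixel(const double* m, const double* lambdas, int nl,
                         double n1, double a, double b,
                         double dn_min, double dn_step, int n_dn,
                         double dz_min, double dz_step, int n_dz,
                         const double* Ctab, const double* scc,
                         double* out) {
  axis adn(dn_min, dn_step), adz(dz_min, dz_step);
  // exact-zero measurement: every (dn = 0, dz) grid point fits perfectly
  // and the tie-break chain selects (0, 0), as a literal scan would
  bool allzero = true;
  for (int l = 0; l < nl; ++l) if (m[l] != 0.0) { allzero = false; break; }
  if (allzero && adn.exact && adz.exact &&
      adn.i0 <= 0 && adn.i0 + n_dn - 1 >= 0 &&
      adz.i0 <= 0 && adz.i0 + n_dz - 1 >= 0) {
    out[0] = 0.0; out[1] = 0.0; out[2] = 0.0;
    return;
  }
  double berr = R_PosInf, bdz = 0.0, bdn = 0.0;
  std::vector<double> C(nl);
  for (int j = 0; j < n_dz; ++j) {
    double dz = adz.at(j);
    const double* Cj = Ctab + (size_t)j * nl;
    double smc = 0.0;
    for (int l = 0; l < nl; ++l) smc += m[l] * Cj[l];
    double sj = scc[j];
    // continuous minimiser of the per-dz quadratic (0 when degenerate)
    double dnstar = (sj > 0.0) ? smc / sj : 0.0;
    int idx = (int)std::lround((dnstar - dn_min) / dn_step);
    for (int ii = idx - 1; ii <= idx + 1; ++ii) {
      int i = ii < 0 ? 0 : (ii >= n_dn ? n_dn - 1 : ii);
      double dn = adn.at(i);
      double err = sse(m, Cj, nl, dn);
      if (better(err, dz, dn, berr, bdz, bdn)) {
        berr = err; bdz = dz; bdn = dn;
      }
    }
  }
  out[0] = bdn; out[1] = bdz; out[2] = berr;
}

// Precompute, per dz grid point, the model coefficients
// C_l(dz) = cos(k_l (a + dz)) - cos(k_l (b + dz)) and their sum of squares.
static void make_ctab(const double* lambdas, int nl, double n1,
                      double a, double b,
                      double dz_min, double dz_step, int n_dz,
                      std::vector<double>& Ctab, std::vector<double>& scc) {
  Ctab.resize((size_t)n_dz * nl);
  scc.resize(n_dz);
  axis adz(dz_min, dz_step);
  for (int j = 0; j < n_dz; ++j) {
    double dz = adz.at(j);
    double s = 0.0;
    for (int l = 0; l < nl; ++l) {
      double k = 4.0 * M_PI * n1 / lambdas[l];
      double C = std::cos(k * (a + dz)) - std::cos(k * (b + dz));
      Ctab[(size_t)j * nl + l] = C;
      s += C * C;
    }
    scc[j] = s;
  }
}

// [[Rcpp::export]]
NumericVector cpp_search_dn_dz(NumericVector m, NumericVector lambdas,
                               double n1, double a, double b,
                               double dn_min, double dn_step, int n_dn,
                               double dz_min, double dz_step, int n_dz) {
  int nl = lambdas.size();
  if (m.size() != nl) stop("measured vector length must match wavelengths");
  std::vector<double> Ctab, scc;
  make_ctab(lambdas.begin(), nl, n1, a, b, dz_min, dz_step, n_dz, Ctab, scc);
  NumericVector out(3);
  search_pixel(m.begin(), lambdas.begin(), nl, n1, a, b,
               dn_min, dn_step, n_dn, dz_min, dz_step, n_dz,
               Ctab.data(), scc.data(), out.begin());
  out.names() = CharacterVector::create("delta_n", "delta_z", "residual");
  return out;
}

// Whole-image version: M is (n_pixels x n_wavelengths) of normalized
// intensities minus one is NOT assumed -- M holds Ihat and the model
// residual uses (Ihat - 1).
// [[Rcpp::export]]
NumericMatrix cpp_invert_slab_image(NumericMatrix M, NumericVector lambdas,
                                    double n1, double a, double b,
                                    double dn_min, double dn_step, int n_dn,
                                    double dz_min, double dz_step, int n_dz) {
  int nl = lambdas.size();
  if (M.ncol() != nl) stop("intensity matrix must have one column per wavelength");
  int np = M.nrow();
  std::vector<double> Ctab, scc;
  make_ctab(lambdas.begin(), nl, n1, a, b, dz_min, dz_step, n_dz, Ctab, scc);
  NumericMatrix out(np, 3);
  std::vector<double> m(nl), res(3);
  for (int p = 0; p < np; ++p) {
    for (int l = 0; l < nl; ++l) m[l] = M(p, l) - 1.0;
    search_pixel(m.data(), lambdas.begin(), nl, n1, a, b,
                 dn_min, dn_step, n_dn, dz_min, dz_step, n_dz,
                 Ctab.data(), scc.data(), res.data());
    out(p, 0) = res[0]; out(p, 1) = res[1]; out(p, 2) = res[2];
  }
  colnames(out) = CharacterVector::create("delta_n", "delta_z", "residual");
  return out;
}

// Literal exhaustive scan over the (thickness, dz) grid for a layer of
// known contrast dn resting on the substrate (slab [0, t]). Uses the
// cosine addition identity so the inner loop is multiplication-only.
// [[Rcpp::export]]
NumericVector cpp_search_wafer(NumericVector m, NumericVector lambdas,
                               double n1, double dn,
                               double t_min, double t_step, int n_t,
                               double dz_min, double dz_step, int n_dz) {
  int nl = lambdas.size();
  if (m.size() != nl) stop("measured vector length must match wavelengths");
  std::vector<double> k(nl);
  for (int l = 0; l < nl; ++l) k[l] = 4.0 * M_PI * n1 / lambdas[l];
  // cos/sin over the thickness grid, per wavelength
  std::vector<double> cosT((size_t)n_t * nl), sinT((size_t)n_t * nl);
  axis at_ax(t_min, t_step), adz(dz_min, dz_step);
  for (int i = 0; i < n_t; ++i) {
    double t = at_ax.at(i);
    for (int l = 0; l < nl; ++l) {
      cosT[(size_t)i * nl + l] = std::cos(k[l] * t);
      sinT[(size_t)i * nl + l] = std::sin(k[l] * t);
    }
  }
  double berr = R_PosInf, bdz = 0.0, bt = 0.0;
  std::vector<double> cz(nl), sz(nl);
  for (int j = 0; j < n_dz; ++j) {
    double dz = adz.at(j);
    for (int l = 0; l < nl; ++l) {
      cz[l] = std::cos(k[l] * dz);
      sz[l] = std::sin(k[l] * dz);
    }
    for (int i = 0; i < n_t; ++i) {
      const double* ct = &cosT[(size_t)i * nl];
      const double* st = &sinT[(size_t)i * nl];
      double err = 0.0;
      for (int l = 0; l < nl; ++l) {
        // C = cos(k dz) - cos(k (t + dz))
        double C = cz[l] - (ct[l] * cz[l] - st[l] * sz[l]);
        double r = m[l] - dn * C;
        err += r * r;
      }
      double t = at_ax.at(i);
      // tie-break: |dz|, then smaller thickness, then signed dz
      if (err < berr ||
          (err == berr &&
           (std::fabs(dz) < std::fabs(bdz) ||
            (std::fabs(dz) == std::fabs(bdz) &&
             (t < bt || (t == bt && dz < bdz)))))) {
        berr = err; bdz = dz; bt = t;
      }
    }
  }
  NumericVector out = NumericVector::create(
    _["thickness"] = bt, _["delta_z"] = bdz, _["residual"] = berr);
  return out;
}
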