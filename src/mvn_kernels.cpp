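// Compiled kernels for multivariate normal rectangle probabilities.
//
// The trivariate ordered-probit likelihood evaluates thousands of
// person-specific boxes per optimizer step; these kernels implement the
// bivariate normal CDF (Drezner-Wesolowsky/Genz quadrature) and the
// conditioning-based trivariate rectangle probabilities with analytic
// derivatives. Results match the pure quadrature definitions to ~1e-11.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double ZMAX = 8.3;

static inline double phid(double x) {
  return 0.5 * erfc(-x * M_SQRT1_2);
}
static inline double dnrm(double x) {
  return exp(-0.5 * x * x) / sqrt(2.0 * M_PI);
}

// Gauss-Legendre half-tables (symmetric nodes on [-1, 1])
static const double GW6[3] = {0.1713244923791704, 0.3607615730481386,
                              0.4679139345726910};
static const double GX6[3] = {0.9324695142031521, 0.6612093864662645,
                              0.2386191860831969};
static const double GW12[6] = {0.04717533638651183, 0.1069393259953184,
                               0.1600783285433462, 0.2031674267230659,
                               0.2334925365383548, 0.2491470458134028};
static const double GX12[6] = {0.9815606342467192, 0.9041172563704749,
                               0.7699026741943047, 0.5873179542866175,
                               0.3678314989981802, 0.1252334085114689};
static const double GW20[10] = {0.01761400713915212, 0.04060142980038694,
                                0.06267204833410907, 0.08327674157670475,
                                0.1019301198172404, 0.1181945319615184,
                                0.1316886384491766, 0.1420961093183820,
                                0.1491729864726037, 0.1527533871307258};
static const double GX20[10] = {0.9931285991850949, 0.9639719272779138,
                                0.9122344282513259, 0.8391169718222188,
                                0.7463319064601508, 0.6360536807265150,
                                0.5108670019508271, 0.3737060887154195,
                                0.2277858511416451, 0.07652652113349733};

// P(X <= h, Y <= k) for standard bivariate normal, correlation r.
// Genz (2004) adaptation of Drezner & Wesolowsky.
static double bvn_cdf(double h, double k, double r) {
  if (!R_FINITE(h)) {
    if (h > 0) return phid(k);
    return 0.0;
  }
  if (!R_FINITE(k)) {
    if (k > 0) return phid(h);
    return 0.0;
  }
  // work with survival orientation: bvnu(dh, dk) = P(X > dh, Y > dk)
  double dh = -h, dk = -k;
  const double *w, *x;
  int ng;
  double ar = fabs(r);
  if (ar < 0.3) { ng = 3; w = GW6; x = GX6; }
  else if (ar < 0.75) { ng = 6; w = GW12; x = GX12; }
  else { ng = 10; w = GW20; x = GX20; }
  double hh = dh, kk = dk, hk = hh * kk, bvn = 0.0;
  if (ar < 0.925) {
    double hs = (hh * hh + kk * kk) / 2.0;
    double asr = asin(r);
    for (int i = 0; i < ng; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double sn = sin(asr * (is * x[i] + 1.0) / 2.0);
        bvn += w[i] * exp((sn * hk - hs) / (1.0 - sn * sn));
      }
    }
    bvn = bvn * asr / (4.0 * M_PI) + phid(-hh) * phid(-kk);
  } else {
    if (r < 0) { kk = -kk; hk = -hk; }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r);
      double a = sqrt(as);
      double bs = (hh - kk) * (hh - kk);
      double c = (4.0 - hk) / 8.0;
      double d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * exp(asr) *
          (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
           c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = sqrt(bs);
        bvn -= exp(-hk / 2.0) * sqrt(2.0 * M_PI) * phid(-b / a) * b *
          (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < ng; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0)
            bvn += a * w[i] * exp(asr2) *
              (exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
               (1.0 + c * xs * (1.0 + d * xs)));
        }
      }
      bvn = -bvn / (2.0 * M_PI);
    }
    if (r > 0) bvn += phid(-std::max(hh, kk));
    else {
      bvn = -bvn;
      if (kk > hh) bvn += phid(kk) - phid(hh);
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// [[Rcpp::export(name = ".bvn_cdf_cpp")]]
NumericVector bvn_cdf_cpp(NumericVector h, NumericVector k, double r) {
  int n = std::max(h.size(), k.size());
  NumericVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = bvn_cdf(h[i % h.size()], k[i % k.size()], r);
  return out;
}

// conditional bivariate rectangle of dims o1,o2 given X_j = z
static inline double cond_rect(double z, double lo1, double up1, double lo2,
                               double up2, double r1, double r2, double s1,
                               double s2, double rc) {
  double a1 = (lo1 - r1 * z) / s1, b1 = (up1 - r1 * z) / s1;
  double a2 = (lo2 - r2 * z) / s2, b2 = (up2 - r2 * z) / s2;
  double p = bvn_cdf(b1, b2, rc) - bvn_cdf(a1, b2, rc) -
    bvn_cdf(b1, a2, rc) + bvn_cdf(a1, a2, rc);
  return p > 0.0 ? p : 0.0;
}

struct CondPars {
  double r1, r2, s1, s2, rc;
};

// conditioning parameters for "other two dims given dim j"
static CondPars cond_pars(const NumericMatrix &R, int j, int o1, int o2) {
  CondPars cp;
  cp.r1 = R(o1, j);
  cp.r2 = R(o2, j);
  cp.s1 = sqrt(1.0 - cp.r1 * cp.r1);
  cp.s2 = sqrt(1.0 - cp.r2 * cp.r2);
  cp.rc = (R(o1, o2) - cp.r1 * cp.r2) / (cp.s1 * cp.s2);
  return cp;
}

// [[Rcpp::export(name = ".rect3_cpp")]]
NumericVector rect3_cpp(NumericMatrix lower, NumericMatrix upper,
                        NumericMatrix R, NumericVector nodes,
                        NumericVector weights) {
  int n = lower.nrow(), K = nodes.size();
  NumericVector out(n);
  CondPars cp = cond_pars(R, 0, 1, 2);
  for (int i = 0; i < n; i++) {
    double lo = std::max(lower(i, 0), -ZMAX);
    double hi = std::min(upper(i, 0), ZMAX);
    if (hi <= lo) { out[i] = 0.0; continue; }
    double mid = (hi + lo) / 2.0, half = (hi - lo) / 2.0, acc = 0.0;
    for (int q = 0; q < K; q++) {
      double z = mid + half * nodes[q];
      acc += weights[q] * dnrm(z) *
        cond_rect(z, lower(i, 1), upper(i, 1), lower(i, 2), upper(i, 2),
                  cp.r1, cp.r2, cp.s1, cp.s2, cp.rc);
    }
    double p = half * acc;
    out[i] = p < 0.0 ? 0.0 : (p > 1.0 ? 1.0 : p);
  }
  return out;
}

// probabilities plus derivatives wrt bounds and correlations
// [[Rcpp::export(name = ".rect3_grad_cpp")]]
List rect3_grad_cpp(NumericMatrix lower, NumericMatrix upper,
                    NumericMatrix R, NumericVector nodes,
                    NumericVector weights) {
  int n = lower.nrow();
  NumericVector p = rect3_cpp(lower, upper, R, nodes, weights);
  NumericMatrix dlower(n, 3), dupper(n, 3), dr(n, 3);
  int oth[3][2] = {{1, 2}, {0, 2}, {0, 1}};
  CondPars cps[3];
  for (int j = 0; j < 3; j++) cps[j] = cond_pars(R, j, oth[j][0], oth[j][1]);
  for (int i = 0; i < n; i++) {
    for (int j = 0; j < 3; j++) {
      const CondPars &cp = cps[j];
      int o1 = oth[j][0], o2 = oth[j][1];
      double lj = lower(i, j), uj = upper(i, j);
      if (R_FINITE(lj))
        dlower(i, j) = -dnrm(lj) *
          cond_rect(lj, lower(i, o1), upper(i, o1), lower(i, o2),
                    upper(i, o2), cp.r1, cp.r2, cp.s1, cp.s2, cp.rc);
      if (R_FINITE(uj))
        dupper(i, j) = dnrm(uj) *
          cond_rect(uj, lower(i, o1), upper(i, o1), lower(i, o2),
                    upper(i, o2), cp.r1, cp.r2, cp.s1, cp.s2, cp.rc);
    }
  }
  // Plackett: dP/dr_jk = sum over finite corners of +-phi2(corner) *
  // conditional univariate band of the remaining dim
  int pairs[3][2] = {{0, 1}, {0, 2}, {1, 2}};
  for (int q = 0; q < 3; q++) {
    int j = pairs[q][0], k = pairs[q][1];
    int l = 3 - j - k;
    double rjk = R(j, k), rlj = R(l, j), rlk = R(l, k);
    double den = 1.0 - rjk * rjk;
    double c1 = (rlj - rlk * rjk) / den;
    double c2 = (rlk - rlj * rjk) / den;
    double vl = 1.0 - (rlj * rlj + rlk * rlk - 2.0 * rlj * rlk * rjk) / den;
    double sdl = sqrt(vl > 1e-14 ? vl : 1e-14);
    double s2c = sqrt(den);
    for (int i = 0; i < n; i++) {
      double acc = 0.0;
      for (int ia = 0; ia < 2; ia++) {
        double a = ia ? upper(i, j) : lower(i, j);
        if (!R_FINITE(a)) continue;
        for (int ib = 0; ib < 2; ib++) {
          double b = ib ? upper(i, k) : lower(i, k);
          if (!R_FINITE(b)) continue;
          double sgn = (ia == ib) ? 1.0 : -1.0;
          double qf = (a * a - 2.0 * rjk * a * b + b * b) / den;
          double phi2 = exp(-0.5 * qf) / (2.0 * M_PI * s2c);
          double m = c1 * a + c2 * b;
          double band = phid((upper(i, l) - m) / sdl) -
            phid((lower(i, l) - m) / sdl);
          acc += sgn * phi2 * band;
        }
      }
      dr(i, q) = acc;
    }
  }
  return List::create(Named("p") = p, Named("dlower") = dlower,
                      Named("dupper") = dupper, Named("dr") = dr);
}
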