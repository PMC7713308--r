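// Hot path of the switching state-space sampler: one MCMC sweep over a
// single track segment. Latent positions are updated by systematic-scan
// single-site random-walk Metropolis (each site touches at most three
// process densities and its adjacent observations), then the discrete
// behavioural states are redrawn exactly by a forward-filter
// backward-sampling pass, and the sufficient statistics for the conjugate
// parameter updates are accumulated. Parameter draws themselves stay in R.
#include <Rcpp.h>
using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

// process log-density at time t (0-based, t >= 2) given persistence g and
// inverse covariance (p11, p12, p22) with log-determinant ldet
static inline double proc_ld(const double* lon, const double* lat, int t,
                             double g, double p11, double p12, double p22,
                             double ldet) {
  double elon = lon[t] - lon[t - 1] - g * (lon[t - 1] - lon[t - 2]);
  double elat = lat[t] - lat[t - 1] - g * (lat[t - 1] - lat[t - 2]);
  double q = elon * (p11 * elon + p12 * elat) + elat * (p12 * elon + p22 * elat);
  return -LOG2PI - 0.5 * ldet - 0.5 * q;
}

static inline double obs_ld(const double* lon, const double* lat, int i,
                            const int* k, const int* k2, const double* j,
                            const double* olon, const double* olat,
                            const double* slon, const double* slat,
                            const double* df) {
  double pl = (1.0 - j[i]) * lon[k[i]] + j[i] * lon[k2[i]];
  double pa = (1.0 - j[i]) * lat[k[i]] + j[i] * lat[k2[i]];
  return R::dt((olon[i] - pl) / slon[i], df[i], 1) - std::log(slon[i]) +
         R::dt((olat[i] - pa) / slat[i], df[i], 1) - std::log(slat[i]);
}

// [[Rcpp::export(name = ".hssm_sweep")]]
List hssm_sweep(NumericVector lon_, NumericVector lat_, IntegerVector b_,
                NumericVector obs_lon, NumericVector obs_lat,
                IntegerVector obs_k, IntegerVector obs_k2, NumericVector obs_j,
                NumericVector sc_lon, NumericVector sc_lat, NumericVector sc_df,
                IntegerVector site_ptr, IntegerVector site_obs,
                double g1, double g2,
                double p11, double p12, double p22, double ldet,
                double a1, double a2, NumericVector tau) {
  NumericVector lon = clone(lon_), lat = clone(lat_);
  IntegerVector b = clone(b_);
  IntegerVector acc_site(lon_.size());
  const int T = lon.size();
  double* L = lon.begin();
  double* A = lat.begin();
  const int* k = obs_k.begin();
  const int* k2 = obs_k2.begin();
  const double* j = obs_j.begin();
  const double* olon = obs_lon.begin();
  const double* olat = obs_lat.begin();
  const double* slon = sc_lon.begin();
  const double* slat = sc_lat.begin();
  const double* df = sc_df.begin();
  const double gam[2] = {g1, g2};
  int acc = 0;

  // ---- latent path: single-site Metropolis, systematic scan ----
  for (int t = 0; t < T; ++t) {
    double cl = L[t], ca = A[t];
    // per-site adapted scale; 10% of proposals take a 5x wider jump so the
    // path can hop between interpretations of heavy-tailed outlier fixes
    double sc = (R::unif_rand() < 0.1) ? 5.0 * tau[t] : tau[t];
    double pl = cl + R::norm_rand() * sc;
    double pa = ca + R::norm_rand() * sc;
    double delta = 0.0;
    int s0 = std::max(2, t), s1 = std::min(T - 1, t + 2);
    for (int s = s0; s <= s1; ++s)
      delta -= proc_ld(L, A, s, gam[b[s] - 1], p11, p12, p22, ldet);
    for (int i = site_ptr[t]; i < site_ptr[t + 1]; ++i)
      delta -= obs_ld(L, A, site_obs[i], k, k2, j, olon, olat, slon, slat, df);
    L[t] = pl; A[t] = pa;
    for (int s = s0; s <= s1; ++s)
      delta += proc_ld(L, A, s, gam[b[s] - 1], p11, p12, p22, ldet);
    for (int i = site_ptr[t]; i < site_ptr[t + 1]; ++i)
      delta += obs_ld(L, A, site_obs[i], k, k2, j, olon, olat, slon, slat, df);
    if (std::log(R::unif_rand()) < delta) {
      ++acc;
      acc_site[t] = 1;
    } else {
      L[t] = cl; A[t] = ca;
    }
  }

  // ---- discrete states: forward filter, backward sample ----
  // transition matrix rows: (stay transit, leave), (leave, stay ARS)
  double lp[2][2] = {{std::log(a1), std::log1p(-a1)},
                     {std::log1p(-a2), std::log(a2)}};
  double pi1 = (1.0 - a2) / ((1.0 - a1) + (1.0 - a2) + 1e-12);
  std::vector<double> f1(T), f2(T);
  f1[0] = std::log(pi1 + 1e-12);
  f2[0] = std::log(1.0 - pi1 + 1e-12);
  for (int t = 1; t < T; ++t) {
    double e1 = 0.0, e2 = 0.0;
    if (t >= 2) {
      e1 = proc_ld(L, A, t, g1, p11, p12, p22, ldet);
      e2 = proc_ld(L, A, t, g2, p11, p12, p22, ldet);
    }
    double a11 = f1[t - 1] + lp[0][0], a21 = f2[t - 1] + lp[1][0];
    double m1 = std::max(a11, a21);
    f1[t] = e1 + m1 + std::log(std::exp(a11 - m1) + std::exp(a21 - m1));
    double a12 = f1[t - 1] + lp[0][1], a22 = f2[t - 1] + lp[1][1];
    double m2 = std::max(a12, a22);
    f2[t] = e2 + m2 + std::log(std::exp(a12 - m2) + std::exp(a22 - m2));
  }
  {
    double m = std::max(f1[T - 1], f2[T - 1]);
    double p1 = std::exp(f1[T - 1] - m), p2 = std::exp(f2[T - 1] - m);
    b[T - 1] = (R::unif_rand() < p1 / (p1 + p2)) ? 1 : 2;
  }
  for (int t = T - 2; t >= 0; --t) {
    double l1 = f1[t] + lp[0][b[t + 1] - 1];
    double l2 = f2[t] + lp[1][b[t + 1] - 1];
    double m = std::max(l1, l2);
    double p1 = std::exp(l1 - m), p2 = std::exp(l2 - m);
    b[t] = (R::unif_rand() < p1 / (p1 + p2)) ? 1 : 2;
  }

  // ---- sufficient statistics for the conjugate updates ----
  double Ag[2] = {0, 0}, Mg[2] = {0, 0};
  double ss11 = 0, ss12 = 0, ss22 = 0;
  int nres = 0;
  int nstay[2] = {0, 0}, nleave[2] = {0, 0};
  for (int t = 2; t < T; ++t) {
    double dl = L[t] - L[t - 1], da = A[t] - A[t - 1];
    double pl = L[t - 1] - L[t - 2], pa = A[t - 1] - A[t - 2];
    int st = b[t] - 1;
    double Ppl = p11 * pl + p12 * pa, Ppa = p12 * pl + p22 * pa;
    Ag[st] += pl * Ppl + pa * Ppa;
    Mg[st] += dl * Ppl + da * Ppa;
    double el = dl - gam[st] * pl, ea = da - gam[st] * pa;
    ss11 += el * el; ss12 += el * ea; ss22 += ea * ea;
    ++nres;
  }
  for (int t = 1; t < T; ++t) {
    if (b[t - 1] == b[t]) ++nstay[b[t] - 1];
    else ++nleave[b[t - 1] - 1];
  }

  return List::create(_["lon"] = lon, _["lat"] = lat, _["b"] = b,
                      _["rate"] = double(acc) / T,
                      _["acc_site"] = acc_site,
                      _["A"] = NumericVector::create(Ag[0], Ag[1]),
                      _["M"] = NumericVector::create(Mg[0], Mg[1]),
                      _["SS"] = NumericVector::create(ss11, ss12, ss22),
                      _["nres"] = nres,
                      _["nstay"] = IntegerVector::create(nstay[0], nstay[1]),
                      _["nleave"] = IntegerVector::create(nleave[0], nleave[1]));
}
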