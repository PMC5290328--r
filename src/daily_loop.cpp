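// Daily water-balance inner loop. Mirrors the R reference engine in
// simulate_water_balance() operator for operator; the two engines are
// cross-checked in the test suite.
#include <Rcpp.h>
using namespace Rcpp;

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// [[Rcpp::export]]
List wb_daily_loop(const NumericVector& precip, const NumericVector& rain,
                   const NumericVector& snowfall, const NumericVector& tmean,
                   const NumericVector& pet, const IntegerVector& month,
                   const NumericVector& fc_mm, const NumericVector& sat_mm,
                   const NumericVector& resid_mm,
                   const NumericVector& evap_floor,
                   const NumericVector& evap_wt, const NumericVector& psi_sat,
                   const NumericVector& b, const NumericVector& thick10,
                   const NumericMatrix& roots, const NumericMatrix& crit_floor,
                   const NumericVector& crit_g, const NumericVector& icap_m,
                   const NumericVector& cover_m, const NumericMatrix& share_gm,
                   const NumericVector& hr_root, const NumericVector& w_init,
                   const LogicalVector& transp_on,
                   double wet_t, double demand_sat, double wet_e, double dry_e,
                   double melt_coef, double melt_temp, bool hr_on,
                   double hr_max_rate, double hr_coef) {
  const int n = precip.size(), nl = fc_mm.size(), ngr = roots.nrow();
  NumericMatrix theta_out(n, nl), transp_layer(n, nl), transp_group(n, ngr);
  NumericVector melt_v(n), swe_v(n), iloss_v(n), thru_v(n), evap_v(n),
      transp_v(n), drain_v(n), hrabs_v(n), stor_v(n);
  std::vector<double> w(w_init.begin(), w_init.end());
  std::vector<double> psi(nl), stress(nl), take(nl), wl(nl), flux(nl);
  double swe = 0.0;

  auto psi_of = [&](void) {
    for (int j = 0; j < nl; ++j) {
      double rel = w[j] / sat_mm[j];
      if (rel < 1e-9) rel = 1e-9;
      if (rel > 1.0) rel = 1.0;
      psi[j] = psi_sat[j] * std::pow(rel, -b[j]);
    }
  };

  for (int t = 0; t < n; ++t) {
    const int m = month[t] - 1;
    swe += snowfall[t];
    double melt = melt_coef * (tmean[t] > melt_temp ? tmean[t] - melt_temp : 0.0);
    if (melt > swe) melt = swe;
    swe -= melt;
    const double liquid = rain[t] + melt;

    double iloss = liquid < icap_m[m] ? liquid : icap_m[m];
    if (iloss > pet[t]) iloss = pet[t];
    const double thru = liquid - iloss;
    const double pet_rem = pet[t] - iloss;

    // cascading-bucket infiltration
    double remaining = thru;
    for (int j = 0; j < nl; ++j) {
      double deficit = fc_mm[j] - w[j];
      if (deficit < 0.0) deficit = 0.0;
      double ret = remaining < deficit ? remaining : deficit;
      w[j] += ret;
      remaining -= ret;
    }
    const double drain = remaining;

    psi_of();

    // bare-soil evaporation
    double evap = 0.0;
    const double pe = pet_rem * (1.0 - cover_m[m]);
    if (pe > 0.0) {
      for (int j = 0; j < nl; ++j) {
        if (evap_wt[j] <= 0.0) continue;
        double s = clamp01((psi[j] - dry_e) / (wet_e - dry_e));
        double tk = pe * evap_wt[j] * s;
        double avail = w[j] - evap_floor[j];
        if (avail < 0.0) avail = 0.0;
        if (tk > avail) tk = avail;
        w[j] -= tk;
        evap += tk;
      }
      psi_of();
    }

    // transpiration per group, compensatory weights from entry psi
    double transp_tot = 0.0;
    std::fill(take.begin(), take.end(), 0.0);
    const double pt = transp_on[t] ? pet_rem * cover_m[m] : 0.0;
    if (pt > 0.0) {
      for (int g = 0; g < ngr; ++g) {
        const double pot = pt * share_gm(m, g);
        if (pot <= 0.0) continue;
        double S = 0.0;
        for (int j = 0; j < nl; ++j) {
          double s = clamp01((psi[j] - crit_g[g]) / (wet_t - crit_g[g]));
          wl[j] = roots(g, j) * s;
          S += wl[j];
        }
        const double denom = S > demand_sat ? S : demand_sat;
        double gsum = 0.0;
        for (int j = 0; j < nl; ++j) {
          double tk = pot * wl[j] / denom;
          double avail = w[j] - crit_floor(g, j);
          if (avail < 0.0) avail = 0.0;
          if (tk > avail) tk = avail;
          w[j] -= tk;
          take[j] += tk;
          gsum += tk;
        }
        transp_group(t, g) = gsum;
        transp_tot += gsum;
      }
      psi_of();
    }

    // hydraulic redistribution: one vectorized pass over adjacent pairs
    double hr_abs = 0.0;
    if (hr_on && nl >= 2) {
      std::fill(flux.begin(), flux.end(), 0.0);
      bool any = false;
      for (int k = 0; k < nl - 1; ++k) {
        const double dpsi = psi[k] - psi[k + 1];
        const double adpsi = dpsi < 0.0 ? -dpsi : dpsi;
        if (adpsi < 1e-12) continue;
        double amt = hr_coef * adpsi * hr_root[k];
        if (amt > hr_max_rate) amt = hr_max_rate;
        const int donor = dpsi > 0.0 ? k : k + 1;
        const int recip = dpsi > 0.0 ? k + 1 : k;
        double cap1 = 0.5 * (w[donor] - resid_mm[donor]);
        if (cap1 < 0.0) cap1 = 0.0;
        double cap2 = 0.5 * (sat_mm[recip] - w[recip]);
        if (cap2 < 0.0) cap2 = 0.0;
        if (amt > cap1) amt = cap1;
        if (amt > cap2) amt = cap2;
        flux[donor] -= amt;
        flux[recip] += amt;
        any = true;
      }
      if (any) {
        for (int j = 0; j < nl; ++j) {
          w[j] += flux[j];
          hr_abs += flux[j] < 0.0 ? -flux[j] : flux[j];
        }
      }
    }

    double stor = 0.0;
    for (int j = 0; j < nl; ++j) {
      theta_out(t, j) = w[j] / thick10[j];
      transp_layer(t, j) = take[j];
      stor += w[j];
    }
    melt_v[t] = melt; swe_v[t] = swe; iloss_v[t] = iloss; thru_v[t] = thru;
    evap_v[t] = evap; transp_v[t] = transp_tot; drain_v[t] = drain;
    hrabs_v[t] = hr_abs; stor_v[t] = stor;
  }

  return List::create(
      _["theta"] = theta_out, _["transp_layer"] = transp_layer,
      _["transp_group"] = transp_group, _["melt"] = melt_v, _["swe"] = swe_v,
      _["iloss"] = iloss_v, _["thru"] = thru_v, _["evap"] = evap_v,
      _["transp"] = transp_v, _["drain"] = drain_v, _["hr_abs"] = hrabs_v,
      _["storage"] = stor_v);
}
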