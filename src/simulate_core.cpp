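#include <Rcpp.h>
using namespace Rcpp;

// Parameter slots, fixed order shared with R/crop_params.R (PARAM_ORDER)
enum {
  P_PLAN, P_CCS, P_DENSITY, P_CCX, P_CGC, P_CDC, P_KC, P_WP,
  P_BASET, P_UPPT, P_STBIO, P_SEN, P_YLD, P_HILEN, P_HI, P_MAT,
  P_ROOT, P_RTN, P_RTX, P_PEXUP, P_PEXLW, P_PEXHP,
  P_PSTO, P_PSEN, P_PSENSHP, P_ANAER, P_EVARDC,
  P_HINC, P_HINGSTO, P_HIPSFLO, P_N
};

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double ks_curve(double dep, double p_up, double p_lo,
                              double shape) {
  if (p_up >= p_lo) return dep <= p_up ? 1.0 : 0.0;
  double x = clampd((dep - p_up) / (p_lo - p_up), 0.0, 1.0);
  if (std::fabs(shape) < 1e-12) return 1.0 - x;
  return clampd(1.0 - (std::exp(shape * x) - 1.0) / (std::exp(shape) - 1.0),
                0.0, 1.0);
}

// Daily water-driven crop growth loop. Row 0 of the returned matrix is the
// initial state (day 0); the loop stops at maturity or the horizon.
// Column layout must match trajectory_columns() in R/simulate.R.
// [[Rcpp::export]]
NumericMatrix simulate_core_cpp(NumericVector par, int transplanted,
                                NumericVector tmin, NumericVector tmax,
                                NumericVector precip, NumericVector et0,
                                NumericVector irr,
                                NumericVector thick, NumericVector th_s,
                                NumericVector th_fc, NumericVector th_wp,
                                NumericVector tau, NumericVector theta_init,
                                int horizon, double ke) {
  if (par.size() != P_N) stop("parameter vector of wrong length");
  const int nl = thick.size();
  const int ncol = 5 + nl + 13;
  NumericMatrix out(horizon + 1, ncol);

  std::vector<double> theta(theta_init.begin(), theta_init.end());
  std::vector<double> top(nl), dz(nl), avail(nl);
  double depth_tot = 0.0;
  for (int l = 0; l < nl; ++l) { top[l] = depth_tot; depth_tot += thick[l]; }

  const double cc0 = par[P_CCS] * par[P_DENSITY] / 1e8;
  double cc = transplanted ? cc0 : 0.0;
  double gdd_cum = 0.0, biomass = 0.0, sen_tt = 0.0, cc_onset = 0.0;
  bool senescent = false;
  int last = 0;

  // day-0 row
  out(0, 0) = 0; out(0, 3) = cc; out(0, 4) = par[P_RTN];
  for (int l = 0; l < nl; ++l) out(0, 5 + l) = theta[l];
  for (int j = 0; j < 5; ++j) out(0, 5 + nl + 6 + j) = 1.0; // Ks columns

  for (int t = 1; t <= horizon; ++t) {
    double tlo = clampd(tmin[t], par[P_BASET], par[P_UPPT]);
    double thi = clampd(tmax[t], par[P_BASET], par[P_UPPT]);
    double g = (thi + tlo) / 2.0 - par[P_BASET];
    if (g < 0.0) g = 0.0;
    gdd_cum += g;

    double zr = par[P_RTN] + (par[P_RTX] - par[P_RTN]) *
                std::min(1.0, gdd_cum / par[P_ROOT]);
    if (zr > depth_tot) zr = depth_tot;

    double taw = 0.0, dr = 0.0, dzsum = 0.0, th_rz = 0.0, ts_rz = 0.0;
    for (int l = 0; l < nl; ++l) {
      double lo = top[l], hi = top[l] + thick[l];
      double d = std::max(0.0, std::min(hi, zr) - lo);
      dz[l] = d;
      taw += (th_fc[l] - th_wp[l]) / 100.0 * d * 1000.0;
      dr += std::max(0.0, th_fc[l] - theta[l]) / 100.0 * d * 1000.0;
      th_rz += theta[l] * d;
      ts_rz += th_s[l] * d;
      dzsum += d;
    }
    if (dzsum > 0.0) { th_rz /= dzsum; ts_rz /= dzsum; }
    else { th_rz = theta[0]; ts_rz = th_s[0]; }
    double pfrac = taw > 0.0 ? dr / taw : 0.0;

    double ks_exp = ks_curve(pfrac, par[P_PEXUP], par[P_PEXLW], par[P_PEXHP]);
    double ks_sto = ks_curve(pfrac, par[P_PSTO], 1.0, 0.0);
    double ks_sen = ks_curve(pfrac, par[P_PSEN], 1.0, par[P_PSENSHP]);
    double ks_aer = par[P_ANAER] <= 0.0 ? 1.0
      : clampd((ts_rz - th_rz) / par[P_ANAER], 0.0, 1.0);
    double ks_bio = par[P_STBIO] > 0.0 ? clampd(g / par[P_STBIO], 0.0, 1.0)
                                       : 1.0;

    // canopy development
    if (!senescent && gdd_cum >= par[P_SEN]) {
      senescent = true;
      cc_onset = cc;
      sen_tt = 0.0;
    }
    if (senescent) {
      sen_tt += g;
      cc = cc_onset * (1.0 - 0.05 *
           (std::exp((par[P_CDC] / par[P_CCX]) * sen_tt) - 1.0));
      if (cc < 0.0) cc = 0.0;
    } else if (gdd_cum >= par[P_PLAN]) {
      if (cc <= 0.0) cc = cc0;
      if (ks_sen < 1.0) {
        double dt = g * (1.0 - ks_sen);
        cc *= 1.0 - 0.05 * (std::exp((par[P_CDC] / par[P_CCX]) * dt) - 1.0);
        if (cc < 0.0) cc = 0.0;
      } else {
        double cge = ks_exp * par[P_CGC];
        if (cc <= par[P_CCX] / 2.0) cc *= std::exp(cge * g);
        else cc = par[P_CCX] - (par[P_CCX] - cc) * std::exp(-cge * g);
        cc = clampd(cc, 0.0, par[P_CCX]);
      }
    }

    // transpiration / evaporation split via the adjusted cover CC*
    double ccstar = clampd(1.72 * cc - cc * cc + 0.30 * cc * cc * cc,
                           0.0, 1.0);
    double late = senescent ? 1.0 - par[P_EVARDC] / 100.0 : 1.0;
    double tr_pot = ks_sto * ks_aer * par[P_KC] * ccstar * et0[t];
    double e_pot = ke * (1.0 - ccstar) * et0[t] * late;

    // soil water bucket: infiltration, drainage cascade, extraction
    double w0 = 0.0;
    for (int l = 0; l < nl; ++l) w0 += theta[l] / 100.0 * thick[l] * 1000.0;

    double inflow = precip[t] + irr[t];
    for (int l = 0; l < nl; ++l) {
      double cap = (th_s[l] - theta[l]) / 100.0 * thick[l] * 1000.0;
      if (cap < 0.0) cap = 0.0;
      double add = std::min(inflow, cap);
      theta[l] += add / (thick[l] * 10.0);
      inflow -= add;
    }
    double excess = inflow;

    double drainage = 0.0;
    for (int l = 0; l < nl; ++l) {
      double d = tau[l] * std::max(0.0, theta[l] - th_fc[l]) / 100.0 *
                 thick[l] * 1000.0;
      if (l < nl - 1) {
        double cap = (th_s[l + 1] - theta[l + 1]) / 100.0 *
                     thick[l + 1] * 1000.0;
        if (cap < 0.0) cap = 0.0;
        if (d > cap) d = cap;
        theta[l + 1] += d / (thick[l + 1] * 10.0);
      } else {
        drainage = d;
      }
      theta[l] -= d / (thick[l] * 10.0);
    }

    double floor_e = 0.5 * th_wp[0];
    double avail_e = std::max(0.0, theta[0] - floor_e) / 100.0 *
                     thick[0] * 1000.0;
    double kr = clampd((theta[0] - floor_e) / (th_fc[0] - floor_e), 0.0, 1.0);
    double e_act = std::min(e_pot * kr, avail_e);
    theta[0] -= e_act / (thick[0] * 10.0);

    double tot = 0.0;
    for (int l = 0; l < nl; ++l) {
      avail[l] = std::max(0.0, theta[l] - th_wp[l]) / 100.0 * dz[l] * 1000.0;
      tot += avail[l];
    }
    double tr_act = std::min(tr_pot, tot);
    if (tot > 0.0 && tr_act > 0.0)
      for (int l = 0; l < nl; ++l)
        theta[l] -= tr_act * avail[l] / tot / (thick[l] * 10.0);

    double w1 = 0.0;
    for (int l = 0; l < nl; ++l) w1 += theta[l] / 100.0 * thick[l] * 1000.0;
    double bal = (w1 - w0) - (precip[t] + irr[t] - e_act - tr_act -
                              drainage - excess);
    if (std::fabs(bal) > 1e-6)
      stop("soil water mass balance violated by %f mm", bal);

    biomass += ks_bio * par[P_WP] * (tr_act / et0[t]);
    double hif = clampd((gdd_cum - par[P_YLD]) / par[P_HILEN], 0.0, 1.0);
    double yield = hif * par[P_HI] * biomass;

    int c = 0;
    out(t, c++) = t; out(t, c++) = g; out(t, c++) = gdd_cum;
    out(t, c++) = cc; out(t, c++) = zr;
    for (int l = 0; l < nl; ++l) out(t, c++) = theta[l];
    out(t, c++) = dr; out(t, c++) = taw; out(t, c++) = tr_act;
    out(t, c++) = e_act; out(t, c++) = drainage; out(t, c++) = excess;
    out(t, c++) = ks_exp; out(t, c++) = ks_sto; out(t, c++) = ks_sen;
    out(t, c++) = ks_aer; out(t, c++) = ks_bio;
    out(t, c++) = biomass; out(t, c++) = yield;
    last = t;
    if (gdd_cum >= par[P_MAT]) break;
  }
  return out(Range(0, last), _);
}
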