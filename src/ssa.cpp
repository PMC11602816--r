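#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gillespie direct-method core for the dual-grid lattice model.
//
// Events and propensities (state n over K_A boxes, m over K_B boxes):
//   produce:   k1 into A-box 1 (rate k1/h_A per box volume h_A => k1)
//   A jump:    n_j * D_A/h_A^2 per available direction
//   B jump:    m_i * D_B/h_B^2 per available direction
//   react:     first-order  A_j -> B_i at k2 * W_ij * n_j
//              dimerization A_j+A_j -> B_i at (k2/h_A) * W_ij * n_j (n_j - 1)/2
//   degrade:   m_i * k3
//
// W is the K_B x K_A overlap-weight matrix (columns sum to 1); the total
// reaction rate out of A-box j is k2 n_j resp. (k2/h_A) n_j(n_j-1).
//
// Time-weighted first and second moments are accumulated lazily (per-box
// last-update times) so the per-event cost stays O(scan length).
//
// Uses R's RNG (unif_rand / exp_rand), so set.seed() governs reproducibility.

// [[Rcpp::export]]
List ssa_core(int KA, int KB, double L, double DA, double DB,
              double k1, double k2, double k3, int network,
              NumericMatrix W,
              IntegerVector n0, IntegerVector m0,
              double t_end, double burn_in,
              double record_interval, int nbatch) {
  const double hA = L / KA, hB = L / KB;
  const double dA = DA / (hA * hA), dB = DB / (hB * hB);
  const bool dimer = (network == 1);
  // dimerization: per-pair rate k2/h_A, so the total propensity in a box is
  // (k2/h_A) * n(n-1)/2, consistent with the Doi bridge k2 = 2 rho lambda
  const double c2 = dimer ? 0.5 * k2 / hA : k2;

  std::vector<long long> n(KA), m(KB);
  long long sumN = 0, sumM = 0, sumNN = 0;  // sumNN = sum n_j (n_j - 1)
  for (int j = 0; j < KA; ++j) { n[j] = n0[j]; sumN += n[j]; sumNN += n[j] * (n[j] - 1); }
  for (int i = 0; i < KB; ++i) { m[i] = m0[i]; sumM += m[i]; }

  // per-column nonzero targets of W with cumulative weights
  std::vector<std::vector<int> > wIdx(KA);
  std::vector<std::vector<double> > wCum(KA);
  for (int j = 0; j < KA; ++j) {
    double c = 0.0;
    for (int i = 0; i < KB; ++i) {
      if (W(i, j) > 0) { c += W(i, j); wIdx[j].push_back(i); wCum[j].push_back(c); }
    }
    if (!wCum[j].empty()) wCum[j].back() = 1.0;  // guard rounding
  }

  // lazy time-weighted moment accumulators
  std::vector<double> s1n(KA, 0.0), s2n(KA, 0.0), tln(KA, burn_in);
  std::vector<double> s1m(KB, 0.0), s2m(KB, 0.0), tlm(KB, burn_in);

  // batch means over [burn_in, t_end] for Monte-Carlo SEs
  const double T_eff = t_end - burn_in;
  const double batch_len = (nbatch > 0) ? T_eff / nbatch : T_eff;
  NumericVector batch_reac(nbatch > 0 ? nbatch : 1, 0.0);
  NumericVector batch_tot(nbatch > 0 ? nbatch : 1, 0.0);
  NumericVector batch_sumN(nbatch > 0 ? nbatch : 1, 0.0);
  NumericVector batch_sumM(nbatch > 0 ? nbatch : 1, 0.0);

  double acc_reac = 0.0, acc_totprop = 0.0;

  // snapshots
  int nsnap = 0, snap_cap = 0;
  if (record_interval > 0) snap_cap = (int)std::floor((t_end - burn_in) / record_interval) + 1;
  IntegerMatrix snap_n(snap_cap > 0 ? snap_cap : 1, KA);
  IntegerMatrix snap_m(snap_cap > 0 ? snap_cap : 1, KB);
  NumericVector snap_t(snap_cap > 0 ? snap_cap : 1);
  double next_rec = burn_in;

  double cnt_produce = 0, cnt_adiff = 0, cnt_bdiff = 0, cnt_react = 0, cnt_degrade = 0;

  double t = 0.0;
  RNGScope scope;

  // helper lambdas via macros to stay C++98-friendly with Rcpp attributes
  // (plain code below instead)

  while (t < t_end) {
    const double a_prod = k1;
    double bEndsA = (KA > 1) ? (double)(n[0] + n[KA - 1]) : 2.0 * (double)sumN;
    double bEndsB = (KB > 1) ? (double)(m[0] + m[KB - 1]) : 2.0 * (double)sumM;
    const double a_adiff = dA * (2.0 * (double)sumN - bEndsA);
    const double a_bdiff = dB * (2.0 * (double)sumM - bEndsB);
    const double a_react = dimer ? c2 * (double)sumNN : c2 * (double)sumN;
    const double a_degr = k3 * (double)sumM;
    const double a_tot = a_prod + a_adiff + a_bdiff + a_react + a_degr;

    double tau = (a_tot > 0) ? exp_rand() / a_tot : (t_end - t) + 1.0;
    double t_new = t + tau;
    if (t_new > t_end) t_new = t_end;

    // accumulate propensity time-averages over [t, t_new] inter burn_in
    double w0 = std::max(t, burn_in), w1 = t_new;
    if (w1 > w0) {
      double w = w1 - w0;
      acc_reac += w * (a_prod + a_react + a_degr);
      acc_totprop += w * a_tot;
      if (nbatch > 0) {
        // spread across batches (intervals are short relative to batches)
        int b0 = (int)std::floor((w0 - burn_in) / batch_len);
        int b1 = (int)std::floor((w1 - burn_in) / batch_len);
        if (b0 >= nbatch) b0 = nbatch - 1;
        if (b1 >= nbatch) b1 = nbatch - 1;
        if (b0 == b1) {
          batch_reac[b0] += w * (a_prod + a_react + a_degr);
          batch_tot[b0] += w * a_tot;
          batch_sumN[b0] += w * (double)sumN;
          batch_sumM[b0] += w * (double)sumM;
        } else {
          for (int b = b0; b <= b1; ++b) {
            double lo = burn_in + b * batch_len, hi = lo + batch_len;
            double ww = std::min(hi, w1) - std::max(lo, w0);
            if (ww <= 0) continue;
            batch_reac[b] += ww * (a_prod + a_react + a_degr);
            batch_tot[b] += ww * a_tot;
            batch_sumN[b] += ww * (double)sumN;
            batch_sumM[b] += ww * (double)sumM;
          }
        }
      }
    }

    // snapshots strictly inside (state holds on [t, t_new))
    while (snap_cap > 0 && next_rec <= t_new && next_rec <= t_end && nsnap < snap_cap) {
      for (int j = 0; j < KA; ++j) snap_n(nsnap, j) = (int)n[j];
      for (int i = 0; i < KB; ++i) snap_m(nsnap, i) = (int)m[i];
      snap_t[nsnap] = next_rec;
      ++nsnap;
      next_rec += record_interval;
    }

    if (t_new >= t_end || a_tot <= 0) { t = t_end; break; }
    t = t_new;

    // choose event
    double u = unif_rand() * a_tot;
    if (u < a_prod) {
      // production into A-box 1
      double tl = std::max(tln[0], burn_in);
      if (t > tl) { double w = t - tl; s1n[0] += w * n[0]; s2n[0] += w * (double)n[0] * n[0]; }
      tln[0] = t;
      sumNN += 2 * n[0];  // (n+1)n - n(n-1) = 2n
      n[0] += 1; sumN += 1;
      cnt_produce += 1;
    } else if ((u -= a_prod) < a_adiff) {
      // A diffusion: pick box with rate n_j * dA * ndir
      double v = u / dA;  // in units of molecule-directions
      int j = 0;
      for (; j < KA; ++j) {
        double r = (double)n[j] * ((j == 0 || j == KA - 1) ? ((KA > 1) ? 1.0 : 0.0) : 2.0);
        if (v < r) break;
        v -= r;
      }
      if (j >= KA) j = KA - 1;
      int dir;
      if (j == 0) dir = +1;
      else if (j == KA - 1) dir = -1;
      else dir = (v < (double)n[j]) ? -1 : +1;
      int j2 = j + dir;
      double tl = std::max(tln[j], burn_in);
      if (t > tl) { double w = t - tl; s1n[j] += w * n[j]; s2n[j] += w * (double)n[j] * n[j]; }
      tln[j] = t;
      tl = std::max(tln[j2], burn_in);
      if (t > tl) { double w = t - tl; s1n[j2] += w * n[j2]; s2n[j2] += w * (double)n[j2] * n[j2]; }
      tln[j2] = t;
      sumNN += -2 * n[j] + 2 + 2 * n[j2];  // moving one molecule j -> j2
      n[j] -= 1; n[j2] += 1;
      cnt_adiff += 1;
    } else if ((u -= a_adiff) < a_bdiff) {
      double v = u / dB;
      int i = 0;
      for (; i < KB; ++i) {
        double r = (double)m[i] * ((i == 0 || i == KB - 1) ? ((KB > 1) ? 1.0 : 0.0) : 2.0);
        if (v < r) break;
        v -= r;
      }
      if (i >= KB) i = KB - 1;
      int dir;
      if (i == 0) dir = +1;
      else if (i == KB - 1) dir = -1;
      else dir = (v < (double)m[i]) ? -1 : +1;
      int i2 = i + dir;
      double tl = std::max(tlm[i], burn_in);
      if (t > tl) { double w = t - tl; s1m[i] += w * m[i]; s2m[i] += w * (double)m[i] * m[i]; }
      tlm[i] = t;
      tl = std::max(tlm[i2], burn_in);
      if (t > tl) { double w = t - tl; s1m[i2] += w * m[i2]; s2m[i2] += w * (double)m[i2] * m[i2]; }
      tlm[i2] = t;
      m[i] -= 1; m[i2] += 1;
      cnt_bdiff += 1;
    } else if ((u -= a_bdiff) < a_react) {
      // conversion / dimerization out of A-box j into B-box i ~ W[, j]
      double v = u / c2;
      int j = 0;
      for (; j < KA; ++j) {
        double r = dimer ? (double)n[j] * (n[j] - 1) : (double)n[j];
        if (v < r) break;
        v -= r;
      }
      if (j >= KA) j = KA - 1;
      double u2 = unif_rand();
      int i = wIdx[j].back();
      for (size_t q = 0; q < wCum[j].size(); ++q) {
        if (u2 <= wCum[j][q]) { i = wIdx[j][q]; break; }
      }
      double tl = std::max(tln[j], burn_in);
      if (t > tl) { double w = t - tl; s1n[j] += w * n[j]; s2n[j] += w * (double)n[j] * n[j]; }
      tln[j] = t;
      tl = std::max(tlm[i], burn_in);
      if (t > tl) { double w = t - tl; s1m[i] += w * m[i]; s2m[i] += w * (double)m[i] * m[i]; }
      tlm[i] = t;
      if (dimer) {
        sumNN += (n[j] - 2) * (n[j] - 3) - n[j] * (n[j] - 1);
        n[j] -= 2; sumN -= 2;
      } else {
        sumNN += -2 * (n[j] - 1);
        n[j] -= 1; sumN -= 1;
      }
      m[i] += 1; sumM += 1;
      cnt_react += 1;
    } else {
      // degradation
      u -= a_react;
      double v = u / k3;
      int i = 0;
      for (; i < KB; ++i) {
        if (v < (double)m[i]) break;
        v -= (double)m[i];
      }
      if (i >= KB) i = KB - 1;
      double tl = std::max(tlm[i], burn_in);
      if (t > tl) { double w = t - tl; s1m[i] += w * m[i]; s2m[i] += w * (double)m[i] * m[i]; }
      tlm[i] = t;
      m[i] -= 1; sumM -= 1;
      cnt_degrade += 1;
    }
  }

  // flush moment accumulators to t_end
  for (int j = 0; j < KA; ++j) {
    double tl = std::max(tln[j], burn_in);
    if (t_end > tl) { double w = t_end - tl; s1n[j] += w * n[j]; s2n[j] += w * (double)n[j] * n[j]; }
  }
  for (int i = 0; i < KB; ++i) {
    double tl = std::max(tlm[i], burn_in);
    if (t_end > tl) { double w = t_end - tl; s1m[i] += w * m[i]; s2m[i] += w * (double)m[i] * m[i]; }
  }

  NumericVector mean_n(KA), var_n(KA), mean_m(KB), var_m(KB);
  for (int j = 0; j < KA; ++j) {
    mean_n[j] = s1n[j] / T_eff;
    var_n[j] = s2n[j] / T_eff - mean_n[j] * mean_n[j];
  }
  for (int i = 0; i < KB; ++i) {
    mean_m[i] = s1m[i] / T_eff;
    var_m[i] = s2m[i] / T_eff - mean_m[i] * mean_m[i];
  }
  if (nbatch > 0) {
    for (int b = 0; b < nbatch; ++b) {
      batch_reac[b] /= batch_len; batch_tot[b] /= batch_len;
      batch_sumN[b] /= batch_len; batch_sumM[b] /= batch_len;
    }
  }

  IntegerVector n_out(KA), m_out(KB);
  for (int j = 0; j < KA; ++j) n_out[j] = (int)n[j];
  for (int i = 0; i < KB; ++i) m_out[i] = (int)m[i];

  List snaps = R_NilValue;
  if (snap_cap > 0) {
    snaps = List::create(
      _["t"] = snap_t[Range(0, std::max(nsnap - 1, 0))],
      _["n"] = snap_n(Range(0, std::max(nsnap - 1, 0)), _),
      _["m"] = snap_m(Range(0, std::max(nsnap - 1, 0)), _),
      _["count"] = nsnap);
  }

  return List::create(
    _["mean_n"] = mean_n, _["var_n"] = var_n,
    _["mean_m"] = mean_m, _["var_m"] = var_m,
    _["mean_reac_propensity"] = acc_reac / T_eff,
    _["mean_total_propensity"] = acc_totprop / T_eff,
    _["batch_reac"] = batch_reac, _["batch_total"] = batch_tot,
    _["batch_sumN"] = batch_sumN, _["batch_sumM"] = batch_sumM,
    _["event_counts"] = NumericVector::create(
      _["produce"] = cnt_produce, _["diffuse_A"] = cnt_adiff,
      _["diffuse_B"] = cnt_bdiff, _["react"] = cnt_react,
      _["degrade"] = cnt_degrade),
    _["n_final"] = n_out, _["m_final"] = m_out,
    _["snapshots"] = snaps);
}
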