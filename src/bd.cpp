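#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Particle-based Brownian dynamics on [0, L] with reflecting boundaries.
//
// Per time step dt:
//   1. every particle moves by N(0, 2 D dt), reflected into [0, L]
//   2. production: Poisson(k1 dt) new A at the source (x = 0 or uniform on
//      the first A-compartment)
//   3. first-order network: each A converts to B in place w.p. 1 - exp(-k2 dt)
//      dimerization: each unordered A-pair within distance rho fires w.p.
//      1 - exp(-lambda dt); pairs processed in random order, a consumed
//      particle invalidates its remaining pairs; product B at the midpoint
//      (or at one reactant's position)
//   4. each B removed w.p. 1 - exp(-k3 dt)
//
// Time-weighted (weight dt) histograms on the A- and B-grids accumulate the
// stationary profiles after burn-in; batch means give Monte-Carlo SEs.

static inline double reflect01(double x, double L) {
  if (x >= 0.0 && x <= L) return x;
  const double period = 2.0 * L;
  double p = x - period * std::floor(x / period);  // in [0, 2L)
  return (p <= L) ? p : period - p;
}

// [[Rcpp::export]]
List bd_core(double L, double DA, double DB,
             double k1, double k2, double k3, int network,
             double lambda, double rho,
             double dt, double t_end, double burn_in,
             int KA, int KB, int source_mode, int product_mode,
             NumericVector a0, NumericVector b0, int nbatch) {
  const bool dimer = (network == 1);
  const double sigA = std::sqrt(2.0 * DA * dt), sigB = std::sqrt(2.0 * DB * dt);
  const double p2 = dimer ? 0.0 : 1.0 - std::exp(-k2 * dt);
  const double pl = dimer ? 1.0 - std::exp(-lambda * dt) : 0.0;
  const double p3 = 1.0 - std::exp(-k3 * dt);
  const double hA = L / KA, hB = L / KB;

  std::vector<double> ax(a0.begin(), a0.end()), bx(b0.begin(), b0.end());

  std::vector<double> histA(KA, 0.0), histB(KB, 0.0);
  // per-bin batch accumulators for SEs
  std::vector<double> batA(KA, 0.0), batB(KB, 0.0);
  std::vector<double> seA1(KA, 0.0), seA2(KA, 0.0), seB1(KB, 0.0), seB2(KB, 0.0);
  double totA1 = 0.0, totA2 = 0.0, totB1 = 0.0, totB2 = 0.0;
  double batTotA = 0.0, batTotB = 0.0;
  double accA = 0.0, accB = 0.0;

  const long nsteps = (long)std::ceil(t_end / dt);
  const long burn_steps = (long)std::ceil(burn_in / dt);
  const long meas_steps = nsteps - burn_steps;
  const long batch_steps = (nbatch > 0) ? std::max(meas_steps / nbatch, 1L) : meas_steps;
  int batches_done = 0;
  long in_batch = 0;

  std::vector<int> order, alive;
  std::vector<std::pair<int, int> > pairs;
  std::vector<int> idx;

  RNGScope scope;

  for (long s = 0; s < nsteps; ++s) {
    // 1. diffusion with reflection
    for (size_t p = 0; p < ax.size(); ++p) ax[p] = reflect01(ax[p] + sigA * norm_rand(), L);
    for (size_t p = 0; p < bx.size(); ++p) bx[p] = reflect01(bx[p] + sigB * norm_rand(), L);

    // 2. production
    int nnew = (int)R::rpois(k1 * dt);
    for (int q = 0; q < nnew; ++q)
      ax.push_back(source_mode == 1 ? unif_rand() * hA : 0.0);

    // 3. reactions
    if (!dimer) {
      for (size_t p = 0; p < ax.size();) {
        if (unif_rand() < p2) {
          bx.push_back(ax[p]);
          ax[p] = ax.back(); ax.pop_back();
        } else ++p;
      }
    } else if (ax.size() >= 2) {
      // sorted sweep for candidate pairs within rho
      size_t na = ax.size();
      idx.resize(na);
      for (size_t p = 0; p < na; ++p) idx[p] = (int)p;
      std::sort(idx.begin(), idx.end(),
                [&](int a, int b) { return ax[a] < ax[b]; });
      pairs.clear();
      for (size_t p = 0; p < na; ++p) {
        for (size_t q = p + 1; q < na; ++q) {
          if (ax[idx[q]] - ax[idx[p]] > rho) break;
          pairs.push_back(std::make_pair(idx[p], idx[q]));
        }
      }
      if (!pairs.empty()) {
        // random processing order (Fisher-Yates)
        for (size_t p = pairs.size() - 1; p > 0; --p) {
          size_t q = (size_t)(unif_rand() * (p + 1));
          if (q > p) q = p;
          std::swap(pairs[p], pairs[q]);
        }
        alive.assign(na, 1);
        std::vector<int> dead;
        for (size_t p = 0; p < pairs.size(); ++p) {
          int i = pairs[p].first, j = pairs[p].second;
          if (!alive[i] || !alive[j]) continue;
          if (unif_rand() < pl) {
            alive[i] = alive[j] = 0;
            double xb;
            if (product_mode == 1) xb = ax[i];
            else if (product_mode == 2) xb = ax[j];
            else xb = 0.5 * (ax[i] + ax[j]);
            bx.push_back(xb);
          }
        }
        // compact survivors
        size_t w = 0;
        for (size_t p = 0; p < na; ++p) if (alive[p]) ax[w++] = ax[p];
        ax.resize(w);
      }
    }

    // 4. degradation
    for (size_t p = 0; p < bx.size();) {
      if (unif_rand() < p3) { bx[p] = bx.back(); bx.pop_back(); }
      else ++p;
    }

    // 5. accumulate
    if (s >= burn_steps) {
      for (size_t p = 0; p < ax.size(); ++p) {
        int k = (int)(ax[p] / hA); if (k >= KA) k = KA - 1;
        histA[k] += dt; batA[k] += dt;
      }
      for (size_t p = 0; p < bx.size(); ++p) {
        int k = (int)(bx[p] / hB); if (k >= KB) k = KB - 1;
        histB[k] += dt; batB[k] += dt;
      }
      accA += dt * (double)ax.size(); accB += dt * (double)bx.size();
      batTotA += dt * (double)ax.size(); batTotB += dt * (double)bx.size();
      if (++in_batch == batch_steps && batches_done < nbatch) {
        double bl = batch_steps * dt;
        for (int k = 0; k < KA; ++k) {
          double v = batA[k] / bl; seA1[k] += v; seA2[k] += v * v; batA[k] = 0.0;
        }
        for (int k = 0; k < KB; ++k) {
          double v = batB[k] / bl; seB1[k] += v; seB2[k] += v * v; batB[k] = 0.0;
        }
        double va = batTotA / bl, vb = batTotB / bl;
        totA1 += va; totA2 += va * va; totB1 += vb; totB2 += vb * vb;
        batTotA = batTotB = 0.0;
        ++batches_done; in_batch = 0;
      }
    }
  }

  const double T_eff = meas_steps * dt;
  NumericVector countsA(KA), countsB(KB), seAv(KA), seBv(KB);
  for (int k = 0; k < KA; ++k) countsA[k] = histA[k] / T_eff;
  for (int k = 0; k < KB; ++k) countsB[k] = histB[k] / T_eff;
  int nb = std::max(batches_done, 1);
  for (int k = 0; k < KA; ++k) {
    double mu = seA1[k] / nb, v = seA2[k] / nb - mu * mu;
    seAv[k] = (nb > 1) ? std::sqrt(std::max(v, 0.0) / (nb - 1)) : NA_REAL;
  }
  for (int k = 0; k < KB; ++k) {
    double mu = seB1[k] / nb, v = seB2[k] / nb - mu * mu;
    seBv[k] = (nb > 1) ? std::sqrt(std::max(v, 0.0) / (nb - 1)) : NA_REAL;
  }
  double muA = totA1 / nb, muB = totB1 / nb;
  double seTotA = (nb > 1) ? std::sqrt(std::max(totA2 / nb - muA * muA, 0.0) / (nb - 1)) : NA_REAL;
  double seTotB = (nb > 1) ? std::sqrt(std::max(totB2 / nb - muB * muB, 0.0) / (nb - 1)) : NA_REAL;

  return List::create(
    _["mean_counts_A"] = countsA,  // time-averaged particle count per A-bin
    _["mean_counts_B"] = countsB,
    _["se_counts_A"] = seAv, _["se_counts_B"] = seBv,
    _["A_total"] = accA / T_eff, _["B_total"] = accB / T_eff,
    _["A_total_se"] = seTotA, _["B_total_se"] = seTotB,
    _["n_batches"] = batches_done,
    _["x_final_A"] = NumericVector(ax.begin(), ax.end()),
    _["x_final_B"] = NumericVector(bx.begin(), bx.end()));
}
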