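#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) of the 8-reaction
// two-gene cascade. Propensities are the concentration-space fluxes
// evaluated at (M/Omega, P/Omega) and multiplied by Omega; all nonlinear
// arguments therefore live in concentration units, so the macroscopic limit
// reproduces the deterministic model.
//
// mode: 0 = unlimited, 1 = shared, 2 = orthogonal.
// clamp (length 2, NaN = off): opposing mRNA *concentration* frozen at its
// mean inside each gene's translation partition (shared mode only); all
// other occurrences of the mRNAs stay live.
//
// Randomness comes from R's RNG (GetRNGstate via RNGScope in the wrapper),
// so set.seed() gives bit-exact reproducibility.

static inline void propensities(const double *x, const double *pr, int mode,
                                const double *clamp, double *a) {
  const double km01 = pr[0], km1 = pr[1], kp1 = pr[2], dm1 = pr[3],
               dp1 = pr[4], I1 = pr[5], Jm1 = pr[6], Jp1 = pr[7],
               km02 = pr[8], km2 = pr[9], kp2 = pr[10], dm2 = pr[11],
               dp2 = pr[12], I2 = pr[13], Jm2 = pr[14], Jp2 = pr[15],
               n = pr[16], Kg = pr[17], Omega = pr[18];
  const double m1 = x[0] / Omega, p1 = x[1] / Omega, m2 = x[2] / Omega;
  const double R1 = I1;
  const double Kgn = std::pow(Kg, n);
  const double R2 = I2 * Kgn / (std::pow(p1, n) + Kgn);
  double Zm1 = 1.0, Zm2 = 1.0, Zp1 = 1.0, Zp2 = 1.0;
  if (mode == 1) {
    Zm1 = Zm2 = 1.0 + R1 / Jm1 + R2 / Jm2;
    const double m2_in_1 = ISNAN(clamp[1]) ? m2 : clamp[1];
    const double m1_in_2 = ISNAN(clamp[0]) ? m1 : clamp[0];
    Zp1 = 1.0 + m1 / Jp1 + m2_in_1 / Jp2;
    Zp2 = 1.0 + m1_in_2 / Jp1 + m2 / Jp2;
  } else if (mode == 2) {
    Zm1 = 1.0 + R1 / Jm1;
    Zm2 = 1.0 + R2 / Jm2;
    Zp1 = 1.0 + m1 / Jp1;
    Zp2 = 1.0 + m2 / Jp2;
  }
  a[0] = Omega * (km01 + km1 * R1) / Zm1; // M1 birth
  a[1] = dm1 * x[0];                      // M1 death
  a[2] = kp1 * x[0] / Zp1;                // P1 birth (= Omega*kp1*m1/Zp1)
  a[3] = dp1 * x[1];                      // P1 death
  a[4] = Omega * (km02 + km2 * R2) / Zm2; // M2 birth
  a[5] = dm2 * x[2];                      // M2 death
  a[6] = kp2 * x[2] / Zp2;                // P2 birth
  a[7] = dp2 * x[3];                      // P2 death
}

static const int SPECIES[8] = {0, 0, 1, 1, 2, 2, 3, 3};
static const int DELTA[8]   = {+1, -1, +1, -1, +1, -1, +1, -1};

// [[Rcpp::export(name = ".ssa_run")]]
List ssa_run(NumericVector par, int mode, NumericVector init,
             double t_end, double dt, NumericVector clamp,
             bool record_events = false, double max_events = 2e9) {
  RNGScope scope;
  double x[4] = {init[0], init[1], init[2], init[3]};
  double a[8];
  const int n_grid = (int)std::floor(t_end / dt) + 1;
  IntegerMatrix grid_counts(record_events ? 1 : n_grid, 4);
  NumericVector grid_times(record_events ? 1 : n_grid);
  std::vector<double> ev_t;
  std::vector<int> ev_x[4];

  double t = 0.0;
  long long n_events = 0;
  int gi = 0; // next grid index to fill
  if (record_events) {
    ev_t.push_back(0.0);
    for (int k = 0; k < 4; ++k) ev_x[k].push_back((int)x[k]);
  }
  while (t < t_end && n_events < (long long)max_events) {
    propensities(x, REAL(par), mode, REAL(clamp), a);
    double atot = 0.0;
    for (int k = 0; k < 8; ++k) atot += a[k];
    double t_next;
    if (atot <= 0.0) {
      t_next = t_end + dt; // absorbing state: hold to the end
    } else {
      t_next = t + R::exp_rand() / atot;
    }
    if (!record_events) {
      while (gi < n_grid && gi * dt <= t_next && gi * dt <= t_end) {
        grid_times[gi] = gi * dt;
        for (int k = 0; k < 4; ++k) grid_counts(gi, k) = (int)x[k];
        ++gi;
      }
    }
    if (t_next > t_end || atot <= 0.0) break;
    t = t_next;
    double u = R::unif_rand() * atot, acc = 0.0;
    int ch = 7;
    for (int k = 0; k < 8; ++k) {
      acc += a[k];
      if (u <= acc) { ch = k; break; }
    }
    x[SPECIES[ch]] += DELTA[ch];
    ++n_events;
    if (record_events) {
      ev_t.push_back(t);
      for (int k = 0; k < 4; ++k) ev_x[k].push_back((int)x[k]);
    }
  }
  if (!record_events) {
    while (gi < n_grid) { // trailing grid points after last event
      grid_times[gi] = gi * dt;
      for (int k = 0; k < 4; ++k) grid_counts(gi, k) = (int)x[k];
      ++gi;
    }
    colnames(grid_counts) = CharacterVector::create("M1", "P1", "M2", "P2");
    return List::create(_["times"] = grid_times, _["counts"] = grid_counts,
                        _["n_events"] = (double)n_events);
  }
  const int ne = (int)ev_t.size();
  IntegerMatrix counts(ne, 4);
  NumericVector times(ne);
  for (int i = 0; i < ne; ++i) {
    times[i] = ev_t[i];
    for (int k = 0; k < 4; ++k) counts(i, k) = ev_x[k][i];
  }
  colnames(counts) = CharacterVector::create("M1", "P1", "M2", "P2");
  return List::create(_["times"] = times, _["counts"] = counts,
                      _["n_events"] = (double)n_events);
}

// Propensity vector at a single state, for cross-checking the R-level
// channel builder against the simulator's internal kernel.
// [[Rcpp::export(name = ".ssa_propensities")]]
NumericVector ssa_propensities(NumericVector par, int mode,
                               NumericVector state, NumericVector clamp) {
  double a[8];
  double x[4] = {state[0], state[1], state[2], state[3]};
  propensities(x, REAL(par), mode, REAL(clamp), a);
  NumericVector out(8);
  for (int k = 0; k < 8; ++k) out[k] = a[k];
  out.names() = CharacterVector::create("m1_birth", "m1_death", "p1_birth",
                                        "p1_death", "m2_birth", "m2_death",
                                        "p2_birth", "p2_death");
  return out;
}
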