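// Lagged-flux Euler integration of the holobiont DEB model.
//
// State is carried as log host biomass and symbiont:host biomass ratios;
// the model's specific rates depend only on those ratios, so this is exactly
// the multiplicative Euler update while immune to overflow during sustained
// exponential growth. Flux formulas mirror compute_fluxes() in R/fluxes.R
// (the R evaluator is the reference; parity is enforced by tests).
#include <Rcpp.h>
using namespace Rcpp;

// host parameter order
enum { N_NH, N_NX, J_HT0, SIGMA_NH, SIGMA_CH, J_XM, K_X, J_NM, K_N,
       K_CO2, J_HGM, Y_C, N_HOST_PAR };
// symbiont parameter order (rows of sp)
enum { N_NS, J_ST0, SIGMA_NS, SIGMA_CS, Y_CL, A_STAR, K_NPQ, K_ROS,
       J_CPM, J_SGM, B_BLEACH, N_SYM_PAR };
// flux column order (matches host_flux_names / sym_flux_names in R)
enum { F_JX, F_JN, F_JHG, F_JHT, F_RNH, F_RHON, F_JEC, F_JCO2, F_RCH, F_A,
       N_HOST_FLUX };
enum { G_JL, G_RCS, G_JCP, G_JEL, G_JNPQ, G_CROS, G_RNS, G_JSG, G_RHOC,
       G_JST, N_SYM_FLUX };

static inline double su1(double m, double x) {
  if (x <= 0.0) return 0.0;
  return 1.0 / (1.0 / m + 1.0 / x);
}

static inline double su2(double m, double x, double y) {
  if (x <= 0.0 || y <= 0.0) return 0.0;
  return 1.0 / (1.0 / m + 1.0 / x + 1.0 / y - 1.0 / (x + y));
}

// [[Rcpp::export(name = ".run_loop_cpp")]]
List run_loop_cpp(double lH0, NumericVector s0,
                  NumericVector hostf0, NumericMatrix symf0,
                  double light, double din, double prey,
                  NumericVector hp, NumericMatrix sp,
                  double dt, int n_steps, int record_stride,
                  int watch, double watch_share) {
  const int n = s0.size();
  if (symf0.nrow() != n || symf0.ncol() != N_SYM_FLUX)
    stop("initial symbiont flux matrix has wrong shape");
  if (sp.nrow() != N_SYM_PAR || sp.ncol() != n)
    stop("symbiont parameter matrix has wrong shape");

  const int ncol = 2 + n + N_HOST_FLUX + N_SYM_FLUX * n;
  const int max_rec = n_steps / record_stride + 3;
  NumericMatrix out(max_rec, ncol);
  int n_rec = 0;
  double stopped_time = -1.0;

  std::vector<double> s(s0.begin(), s0.end());
  double lH = lH0;
  std::vector<double> lag_rhoC(n), lag_jSG(n), lag_cROS(n);
  for (int i = 0; i < n; ++i) {
    lag_rhoC[i] = symf0(i, G_RHOC);
    lag_jSG[i] = symf0(i, G_JSG);
    lag_cROS[i] = symf0(i, G_CROS);
  }

  std::vector<double> hostf(N_HOST_FLUX);
  std::vector< std::vector<double> > symf(n, std::vector<double>(N_SYM_FLUX));
  for (int f = 0; f < N_HOST_FLUX; ++f) hostf[f] = hostf0[f];
  for (int i = 0; i < n; ++i)
    for (int f = 0; f < N_SYM_FLUX; ++f) symf[i][f] = symf0(i, f);

  // host fluxes independent of state
  const double j_X = hp[J_XM] * prey / (prey + hp[K_X]);
  const double j_N = hp[J_NM] * din / (din + hp[K_N]);
  const double j_HT = hp[J_HT0];
  const double r_NH = hp[SIGMA_NH] * hp[N_NH] * j_HT;
  const double nitrogen_in = (j_N + hp[N_NX] * j_X + r_NH) / hp[N_NH];
  const double yC = hp[Y_C];

  auto record = [&](double t) {
    if (n_rec >= max_rec) stop("internal error: record buffer overflow");
    int c = 0;
    out(n_rec, c++) = t;
    out(n_rec, c++) = lH;
    for (int i = 0; i < n; ++i) out(n_rec, c++) = s[i];
    for (int f = 0; f < N_HOST_FLUX; ++f) out(n_rec, c++) = hostf[f];
    for (int i = 0; i < n; ++i)
      for (int f = 0; f < N_SYM_FLUX; ++f) out(n_rec, c++) = symf[i][f];
    ++n_rec;
  };

  record(0.0);

  for (int k = 1; k <= n_steps; ++k) {
    double stot = 0.0;
    for (int i = 0; i < n; ++i) stot += s[i];

    const double A = 1.26 + 1.39 * std::exp(-6.48 * stot);
    double shared_c = 0.0;
    for (int i = 0; i < n; ++i) shared_c += lag_rhoC[i] * s[i];
    const double carbon_in = yC * (shared_c + j_X);
    const double j_HG = su2(hp[J_HGM], carbon_in, nitrogen_in);
    const double rho_N = std::max(
        j_N + hp[N_NX] * j_X + r_NH - hp[N_NH] * j_HG, 0.0);
    const double j_eC = std::max(j_X + shared_c - j_HG / yC, 0.0);
    const double j_CO2 = hp[K_CO2] * j_eC;
    const double r_CH = hp[SIGMA_CH] * (j_HT + (1.0 - yC) * j_HG / yC);
    const double co2_share = stot > 0.0 ? (j_CO2 + r_CH) / stot : 0.0;
    const double rhoN_share = stot > 0.0 ? rho_N / stot : 0.0;

    hostf[F_JX] = j_X; hostf[F_JN] = j_N; hostf[F_JHG] = j_HG;
    hostf[F_JHT] = j_HT; hostf[F_RNH] = r_NH; hostf[F_RHON] = rho_N;
    hostf[F_JEC] = j_eC; hostf[F_JCO2] = j_CO2; hostf[F_RCH] = r_CH;
    hostf[F_A] = A;

    const double fH = 1.0 + (j_HG - j_HT) * dt;
    if (fH <= 0.0)
      stop("host biomass became nonpositive at day %f", k * dt);

    for (int i = 0; i < n; ++i) {
      const double j_L = A * light * sp(A_STAR, i);
      const double r_CS = sp(SIGMA_CS, i) *
          (sp(J_ST0, i) + (1.0 - yC) * lag_jSG[i] / yC);
      const double j_CP = su2(sp(J_CPM, i), sp(Y_CL, i) * j_L,
                              co2_share + r_CS) / lag_cROS[i];
      const double j_eL = std::max(j_L - j_CP / sp(Y_CL, i), 0.0);
      const double j_NPQ = su1(sp(K_NPQ, i), j_eL);
      const double c_ROS = 1.0 + std::max(j_eL - j_NPQ, 0.0) / sp(K_ROS, i);
      const double r_NS = sp(SIGMA_NS, i) * sp(N_NS, i) * sp(J_ST0, i);
      const double j_SG = su2(sp(J_SGM, i), yC * j_CP,
                              (rhoN_share + r_NS) / sp(N_NS, i));
      const double rho_C = j_CP - j_SG / yC;
      const double j_ST = sp(J_ST0, i) * (1.0 + sp(B_BLEACH, i) *
                                          (c_ROS - 1.0));

      symf[i][G_JL] = j_L; symf[i][G_RCS] = r_CS; symf[i][G_JCP] = j_CP;
      symf[i][G_JEL] = j_eL; symf[i][G_JNPQ] = j_NPQ;
      symf[i][G_CROS] = c_ROS; symf[i][G_RNS] = r_NS;
      symf[i][G_JSG] = j_SG; symf[i][G_RHOC] = rho_C; symf[i][G_JST] = j_ST;

      lag_rhoC[i] = rho_C; lag_jSG[i] = j_SG; lag_cROS[i] = c_ROS;

      const double fS = 1.0 + (j_SG - j_ST) * dt;
      s[i] = fS > 0.0 ? s[i] * fS / fH : 0.0;
      if (!std::isfinite(s[i]))
        stop("symbiont state became non-finite at day %f", k * dt);
    }

    lH += std::log(fH);
    if (!std::isfinite(lH) && lH > 0)
      stop("host state became non-finite at day %f", k * dt);

    const double t = k * dt;
    bool tripped = false;
    if (watch >= 0) {
      double stot_new = 0.0;
      for (int i = 0; i < n; ++i) stot_new += s[i];
      if (stot_new > 0.0 && s[watch] / stot_new >= watch_share) {
        tripped = true;
        stopped_time = t;
      }
    }
    if (tripped || k == n_steps || k % record_stride == 0)
      record(t);
    if (tripped) break;
  }

  return List::create(_["mat"] = out(Range(0, n_rec - 1), _),
                      _["stopped_time"] = stopped_time);
}
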