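#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Model codes: 1 = M1, 2 = M2, 3 = M3, 4 = M4a, 5 = M4b, 6 = M4c, 7 = M5.
// Free-parameter vectors arrive in the canonical order defined by
// model_spec() on the R side:
//   M1:  alpha_reinf, tau_reinf
//   M2:  alpha_reinf, tau_reinf, tau_stim
//   M3:  alpha_rew, alpha_pun, tau_reinf
//   M4a: alpha_rew, alpha_pun, tau_reinf, tau_loc
//   M4b: alpha_rew, alpha_pun, tau_reinf, tau_stim
//   M4c: alpha_rew, alpha_pun, tau_reinf, tau_stim, tau_loc
//   M5:  rho, phi, beta

struct Pars {
  double arew, apun, treinf, tstim, tloc, rho, phi, beta;
};

static Pars map_pars(int model, const double *x) {
  Pars p;
  p.arew = p.apun = p.treinf = p.tstim = p.tloc = p.rho = p.phi = 0.0;
  p.beta = 1.0; // fixed at 1 for models 1-4c
  switch (model) {
  case 1: p.arew = p.apun = x[0]; p.treinf = x[1]; break;
  case 2: p.arew = p.apun = x[0]; p.treinf = x[1]; p.tstim = x[2]; break;
  case 3: p.arew = x[0]; p.apun = x[1]; p.treinf = x[2]; break;
  case 4: p.arew = x[0]; p.apun = x[1]; p.treinf = x[2]; p.tloc = x[3]; break;
  case 5: p.arew = x[0]; p.apun = x[1]; p.treinf = x[2]; p.tstim = x[3]; break;
  case 6: p.arew = x[0]; p.apun = x[1]; p.treinf = x[2]; p.tstim = x[3];
          p.tloc = x[4]; break;
  case 7: p.rho = x[0]; p.phi = x[1]; p.beta = x[2]; break;
  default: Rcpp::stop("unknown model code");
  }
  return p;
}

// Softmax log-probability of the chosen side given the two Q values.
static inline double log_softmax2(double qc, double qo, double beta) {
  double a = beta * qc, b = beta * qo;
  double m = a > b ? a : b;
  return a - (m + std::log(std::exp(a - m) + std::exp(b - m)));
}

// Trial-loop session log-likelihood. Stimuli are coded 0/1, sides 0 = left,
// 1 = right; state (V, stickiness indicators, EWA experience weights) is
// reset at session start only and persists across the two runs.
static double session_ll(int model, const Pars &p,
                         const int *stim_left, const int *chosen_stim,
                         const int *reinf, int nt) {
  double V[2] = {0.5, 0.5};
  double n[2] = {1.0, 1.0};
  int prev_stim = -1, prev_side = -1;
  double ll = 0.0;
  for (int t = 0; t < nt; ++t) {
    int sl = stim_left[t], sr = 1 - sl;
    double Ql, Qr;
    if (model == 7) { Ql = V[sl]; Qr = V[sr]; }
    else            { Ql = p.treinf * V[sl]; Qr = p.treinf * V[sr]; }
    if (prev_stim >= 0) {
      if (sl == prev_stim) Ql += p.tstim; else Qr += p.tstim;
      if (prev_side == 0)  Ql += p.tloc;  else Qr += p.tloc;
    }
    int cs = chosen_stim[t];
    int side = (cs == sl) ? 0 : 1;
    ll += (side == 0) ? log_softmax2(Ql, Qr, p.beta)
                      : log_softmax2(Qr, Ql, p.beta);
    double R = (double) reinf[t];
    if (model == 7) {
      double nold = n[cs];
      double nnew = nold * p.rho + 1.0;
      V[cs] = (p.phi * nold * V[cs] + R) / nnew;
      n[cs] = nnew;
    } else {
      double lr = (R > 0.5) ? p.arew : p.apun;
      V[cs] += lr * (R - V[cs]);
    }
    prev_stim = cs;
    prev_side = side;
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_session_loglik(int model, NumericVector pars,
                          IntegerVector stim_left, IntegerVector chosen_stim,
                          IntegerVector reinf) {
  Pars p = map_pars(model, pars.begin());
  return session_ll(model, p, stim_left.begin(), chosen_stim.begin(),
                    reinf.begin(), stim_left.size());
}

// ---------------------------------------------------------------------------
// Hierarchical model internals.
//
// `dat` (built by build_hierarchical_model() in R) contains:
//   model      : int model code
//   P          : number of free parameters
//   family     : int vector, 0 = beta, 1 = gamma(shape, rate), 2 = normal
//   h1, h2     : prior hyperparameters per parameter
//   lo, hi     : support bounds used to clamp subject-level values
//   sigma_scale: half-normal scale of the inter-subject SD prior
//   S          : number of subjects; C: number of cells (9)
//   sessions   : list of list(stim_left, chosen_stim, reinf)
//   sess_subj, sess_cell : 0-based indices per session
//
// theta layout: mu[p, c] at p*C + c; delta[p, s] at P*C + p*S + s;
// sigma[p] at P*C + P*S + p.

struct HModel {
  int model, P, S, C;
  std::vector<int> family;
  std::vector<double> h1, h2, lo, hi, sscale;
  std::vector<std::vector<int> > sl, cs, rf;
  std::vector<int> subj, cell;
  std::vector<std::vector<int> > by_cell, by_subj;
};

static HModel parse_model(List dat) {
  HModel m;
  m.model = as<int>(dat["model"]);
  m.P = as<int>(dat["P"]);
  m.S = as<int>(dat["S"]);
  m.C = as<int>(dat["C"]);
  m.family = as<std::vector<int> >(dat["family"]);
  m.h1 = as<std::vector<double> >(dat["h1"]);
  m.h2 = as<std::vector<double> >(dat["h2"]);
  m.lo = as<std::vector<double> >(dat["lo"]);
  m.hi = as<std::vector<double> >(dat["hi"]);
  m.sscale = as<std::vector<double> >(dat["sigma_scale"]);
  List sess = dat["sessions"];
  m.subj = as<std::vector<int> >(dat["sess_subj"]);
  m.cell = as<std::vector<int> >(dat["sess_cell"]);
  int K = sess.size();
  m.sl.resize(K); m.cs.resize(K); m.rf.resize(K);
  for (int k = 0; k < K; ++k) {
    List s = sess[k];
    m.sl[k] = as<std::vector<int> >(s["stim_left"]);
    m.cs[k] = as<std::vector<int> >(s["chosen_stim"]);
    m.rf[k] = as<std::vector<int> >(s["reinf"]);
  }
  m.by_cell.resize(m.C);
  m.by_subj.resize(m.S);
  for (int k = 0; k < K; ++k) {
    m.by_cell[m.cell[k]].push_back(k);
    m.by_subj[m.subj[k]].push_back(k);
  }
  return m;
}

static inline double clampd(double x, double lo, double hi) {
  if (x < lo) return lo;
  if (x > hi) return hi;
  return x;
}

static double mu_logprior(const HModel &m, int p, double x) {
  switch (m.family[p]) {
  case 0:
    if (x <= 0.0 || x >= 1.0) return R_NegInf;
    return R::dbeta(x, m.h1[p], m.h2[p], 1);
  case 1:
    if (x <= 0.0) return R_NegInf;
    return R::dgamma(x, m.h1[p], 1.0 / m.h2[p], 1); // h2 is a rate
  default:
    return R::dnorm(x, m.h1[p], m.h2[p], 1);
  }
}

// log density of a half-normal(0, scale) evaluated at s > 0
static inline double halfnorm_ld(double s, double scale) {
  if (s <= 0.0) return R_NegInf;
  return M_LN2 + R::dnorm(s, 0.0, scale, 1);
}

static double sess_ll_at(const HModel &m, const double *theta, int k) {
  int P = m.P, C = m.C, S = m.S;
  std::vector<double> x(P);
  for (int p = 0; p < P; ++p) {
    double v = theta[p * C + m.cell[k]] + theta[P * C + p * S + m.subj[k]];
    x[p] = clampd(v, m.lo[p], m.hi[p]);
  }
  Pars pp = map_pars(m.model, x.data());
  return session_ll(m.model, pp, m.sl[k].data(), m.cs[k].data(),
                    m.rf[k].data(), (int) m.sl[k].size());
}

static double joint_ld(const HModel &m, const double *theta) {
  int P = m.P, C = m.C, S = m.S;
  double lp = 0.0;
  for (int p = 0; p < P; ++p) {
    double sig = theta[P * C + P * S + p];
    double hs = halfnorm_ld(sig, m.sscale[p]);
    if (!R_FINITE(hs)) return R_NegInf;
    lp += hs;
    for (int c = 0; c < C; ++c) {
      double mp = mu_logprior(m, p, theta[p * C + c]);
      if (!R_FINITE(mp)) return R_NegInf;
      lp += mp;
    }
    for (int s = 0; s < S; ++s)
      lp += R::dnorm(theta[P * C + p * S + s], 0.0, sig, 1);
  }
  for (size_t k = 0; k < m.sl.size(); ++k) lp += sess_ll_at(m, theta, k);
  return lp;
}

// [[Rcpp::export]]
double cpp_joint_logdens(NumericVector theta, List dat) {
  HModel m = parse_model(dat);
  return joint_ld(m, theta.begin());
}

// [[Rcpp::export]]
NumericVector cpp_joint_logdens_mat(NumericMatrix thetas, List dat) {
  HModel m = parse_model(dat);
  int n = thetas.nrow();
  NumericVector out(n);
  std::vector<double> row(thetas.ncol());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < thetas.ncol(); ++j) row[j] = thetas(i, j);
    out[i] = joint_ld(m, row.data());
  }
  return out;
}

// Adaptive random-walk Metropolis-within-Gibbs over all scalars.
// Step sizes adapt in batches of 50 during warmup toward a 0.44
// acceptance rate (Roberts & Rosenthal); they are frozen afterwards.
// Uses R's RNG, so chains are reproducible via set.seed() on the R side.
// [[Rcpp::export]]
List cpp_sample_chain(List dat, int warmup, int draws, int thin,
                      NumericVector init, NumericVector step_init) {
  HModel m = parse_model(dat);
  int P = m.P, C = m.C, S = m.S;
  int D = P * C + P * S + P;
  int K = (int) m.sl.size();
  std::vector<double> theta(init.begin(), init.end());
  std::vector<double> lstep(D);
  for (int j = 0; j < D; ++j) lstep[j] = std::log(step_init[j]);

  // cached per-session log-likelihoods
  std::vector<double> llk(K);
  for (int k = 0; k < K; ++k) llk[k] = sess_ll_at(m, theta.data(), k);

  std::vector<int> acc(D, 0), tries(D, 0);
  std::vector<long> acc_tot(D, 0), tries_tot(D, 0);
  std::vector<double> lscale(P, std::log(0.3));
  std::vector<int> scale_acc(P, 0), scale_tries(P, 0);
  int n_keep = draws / thin;
  NumericMatrix out(n_keep, D);
  int kept = 0, batch = 0;

  int total = warmup + draws;
  std::vector<double> newll;
  for (int it = 0; it < total; ++it) {
    for (int j = 0; j < D; ++j) {
      double cur = theta[j];
      double prop = cur + std::exp(lstep[j]) * norm_rand();
      double dlp = 0.0;
      bool reject = false;
      const std::vector<int> *affected = 0;
      if (j < P * C) {                     // cell mean
        int p = j / C, c = j % C;
        double lp0 = mu_logprior(m, p, cur), lp1 = mu_logprior(m, p, prop);
        if (!R_FINITE(lp1)) reject = true; else dlp += lp1 - lp0;
        if (!reject) affected = &m.by_cell[c];
      } else if (j < P * C + P * S) {      // subject deviation
        int p = (j - P * C) / S, s = (j - P * C) % S;
        double sig = theta[P * C + P * S + p];
        dlp += R::dnorm(prop, 0.0, sig, 1) - R::dnorm(cur, 0.0, sig, 1);
        affected = &m.by_subj[s];
      } else {                             // inter-subject SD
        int p = j - P * C - P * S;
        if (prop <= 0.0) reject = true;
        else {
          dlp += halfnorm_ld(prop, m.sscale[p]) - halfnorm_ld(cur, m.sscale[p]);
          for (int s = 0; s < S; ++s) {
            double d = theta[P * C + p * S + s];
            dlp += R::dnorm(d, 0.0, prop, 1) - R::dnorm(d, 0.0, cur, 1);
          }
        }
      }
      if (!reject && affected) {
        theta[j] = prop;
        newll.clear();
        for (size_t a = 0; a < affected->size(); ++a) {
          int k = (*affected)[a];
          double l = sess_ll_at(m, theta.data(), k);
          newll.push_back(l);
          dlp += l - llk[k];
        }
        theta[j] = cur;
      }
      ++tries[j];
      if (!reject && (dlp >= 0.0 || unif_rand() < std::exp(dlp))) {
        theta[j] = prop;
        ++acc[j];
        if (affected)
          for (size_t a = 0; a < affected->size(); ++a)
            llk[(*affected)[a]] = newll[a];
      }
    }
    // Scale move per parameter: jointly multiply sigma_p and all of that
    // parameter's subject deviations by exp(eps). This traverses the
    // half-normal funnel that coordinate-wise updates cross slowly. The
    // delta-prior ratio and the transformation Jacobian combine to a
    // single +eps term; only the likelihood needs recomputing.
    for (int p = 0; p < P; ++p) {
      int js = P * C + P * S + p;
      double eps = std::exp(lscale[p]) * norm_rand();
      double k = std::exp(eps);
      double sig = theta[js];
      double dlp = halfnorm_ld(sig * k, m.sscale[p]) -
                   halfnorm_ld(sig, m.sscale[p]) + eps;
      for (int s = 0; s < S; ++s) theta[P * C + p * S + s] *= k;
      theta[js] *= k;
      newll.resize(K);
      for (int kk = 0; kk < K; ++kk) {
        newll[kk] = sess_ll_at(m, theta.data(), kk);
        dlp += newll[kk] - llk[kk];
      }
      ++scale_tries[p];
      if (dlp >= 0.0 || unif_rand() < std::exp(dlp)) {
        ++scale_acc[p];
        for (int kk = 0; kk < K; ++kk) llk[kk] = newll[kk];
      } else {
        for (int s = 0; s < S; ++s) theta[P * C + p * S + s] /= k;
        theta[js] /= k;
      }
    }
    // adapt during warmup
    if (it < warmup && ((it + 1) % 50 == 0)) {
      ++batch;
      double gain = std::min(0.25, 1.0 / std::sqrt((double) batch));
      for (int j = 0; j < D; ++j) {
        double rate = tries[j] ? (double) acc[j] / tries[j] : 0.0;
        lstep[j] += (rate > 0.44 ? gain : -gain);
        acc_tot[j] += acc[j]; tries_tot[j] += tries[j];
        acc[j] = 0; tries[j] = 0;
      }
      for (int p = 0; p < P; ++p) {
        double rate = scale_tries[p] ? (double) scale_acc[p] / scale_tries[p]
                                     : 0.0;
        lscale[p] += (rate > 0.3 ? gain : -gain);
        scale_acc[p] = 0; scale_tries[p] = 0;
      }
    }
    if (it >= warmup && ((it - warmup + 1) % thin == 0) && kept < n_keep) {
      for (int j = 0; j < D; ++j) out(kept, j) = theta[j];
      ++kept;
    }
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector arate(D), stepv(D);
  for (int j = 0; j < D; ++j) {
    long a = acc_tot[j] + acc[j], t = tries_tot[j] + tries[j];
    arate[j] = t ? (double) a / t : NA_REAL;
    stepv[j] = std::exp(lstep[j]);
  }
  return List::create(_["draws"] = out, _["accept_rate"] = arate,
                      _["step"] = stepv);
}

// ---------------------------------------------------------------------------
// In-silico task + agent simulator (fast path used by the cohort module).
//
// Consumes R's RNG in exactly the order documented for generate_session():
// per run: one uniform for the initially correct stimulus, one per sequence
// start for the criterion; per trial: side assignment, choice, and (only on
// correct choices) the misleading-feedback draw. generate_session() with
// policy_from_model() reproduces these sessions draw for draw.
// [[Rcpp::export]]
List cpp_simulate_session(int model, NumericVector pars, int n_runs,
                          int seq_per_run, int crit_min, int crit_max,
                          double p_misleading, int max_trials) {
  Pars p = map_pars(model, pars.begin());
  int cap = n_runs * max_trials;
  IntegerVector run(cap), seq(cap), stim_left(cap), correct(cap),
      chosen(cap), side(cap), reinf(cap);
  LogicalVector misl(cap);
  std::vector<int> revpts, crits;
  int t_all = 0;
  double V[2] = {0.5, 0.5};
  double n[2] = {1.0, 1.0};
  int prev_stim = -1, prev_side = -1;
  int range = crit_max - crit_min + 1;
  for (int r = 0; r < n_runs; ++r) {
    int cor = (unif_rand() < 0.5) ? 0 : 1;
    int s = 1;
    int crit = crit_min + std::min(range - 1, (int)(unif_rand() * range));
    crits.push_back(crit);
    int cum = 0, t_run = 0;
    bool run_done = false;
    while (!run_done) {
      int sl = (unif_rand() < 0.5) ? 0 : 1;
      int sr = 1 - sl;
      double Ql, Qr;
      if (model == 7) { Ql = V[sl]; Qr = V[sr]; }
      else            { Ql = p.treinf * V[sl]; Qr = p.treinf * V[sr]; }
      if (prev_stim >= 0) {
        if (sl == prev_stim) Ql += p.tstim; else Qr += p.tstim;
        if (prev_side == 0)  Ql += p.tloc;  else Qr += p.tloc;
      }
      double pl = 1.0 / (1.0 + std::exp(p.beta * (Qr - Ql)));
      int ch_side = (unif_rand() < pl) ? 0 : 1;
      int cs = (ch_side == 0) ? sl : sr;
      int R = 0; bool ml = false;
      if (cs == cor) {
        if (unif_rand() < p_misleading) { R = 0; ml = true; }
        else R = 1;
      }
      run[t_all] = r; seq[t_all] = s; stim_left[t_all] = sl;
      correct[t_all] = cor; chosen[t_all] = cs; side[t_all] = ch_side;
      reinf[t_all] = R; misl[t_all] = ml;
      ++t_all; ++t_run;
      // agent learning
      double Rd = (double) R;
      if (model == 7) {
        double nold = n[cs], nnew = nold * p.rho + 1.0;
        V[cs] = (p.phi * nold * V[cs] + Rd) / nnew;
        n[cs] = nnew;
      } else {
        double lr = (R > 0) ? p.arew : p.apun;
        V[cs] += lr * (Rd - V[cs]);
      }
      prev_stim = cs; prev_side = ch_side;
      // task bookkeeping
      if (cs == cor) ++cum;
      if (cum >= crit) {
        if (s == seq_per_run) run_done = true;
        else if (t_run >= max_trials) run_done = true; // cap hit: no reversal
        else {
          cor = 1 - cor;
          revpts.push_back(t_all);
          ++s;
          crit = crit_min + std::min(range - 1, (int)(unif_rand() * range));
          crits.push_back(crit);
          cum = 0;
        }
      }
      if (!run_done && t_run >= max_trials) run_done = true;
    }
  }
  Range idx(0, t_all - 1);
  return List::create(
      _["run"] = run[idx], _["sequence"] = seq[idx],
      _["stim_left"] = stim_left[idx], _["correct_stim"] = correct[idx],
      _["chosen_stim"] = chosen[idx], _["chosen_side"] = side[idx],
      _["reinforcement"] = reinf[idx], _["misleading"] = misl[idx],
      _["reversal_points"] = wrap(revpts), _["criteria_used"] = wrap(crits));
}
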