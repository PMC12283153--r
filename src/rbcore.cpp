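// Fast path for the Rao-Blackwellized particle sweep and the EM
// sufficient-statistics smoothing pass. The R implementations in
// R/kalman.R and R/saem.R are the readable reference versions; tests
// cross-check the two routes on small instances.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double MU0_4PI = 1e-7;

// smooth tangential orientation field (local azimuthal direction)
static inline vec azim_ori(const vec& r) {
  double nxy = std::sqrt(r(0) * r(0) + r(1) * r(1));
  vec o(3, fill::zeros);
  if (nxy < 1e-12) { o(0) = 1.0; return o; }
  o(0) = -r(1) / nxy; o(1) = r(0) / nxy;
  return o;
}

// Sarvas magnetometer lead field of one dipole, projected on sensor
// normals; allocation-free scalar arithmetic (hot path of the sweep)
static void sarvas_one(const vec& r0v, const vec& qv,
                       const mat& spos, const mat& sori, vec& out) {
  const uword M = spos.n_rows;
  const double x0 = r0v(0), y0 = r0v(1), z0 = r0v(2);
  const double qx = qv(0), qy = qv(1), qz = qv(2);
  const double cx = qy * z0 - qz * y0;   // q x r0
  const double cy = qz * x0 - qx * z0;
  const double cz = qx * y0 - qy * x0;
  for (uword m = 0; m < M; ++m) {
    const double rx = spos(m, 0), ry = spos(m, 1), rz = spos(m, 2);
    const double ax = rx - x0, ay = ry - y0, az = rz - z0;
    const double na = std::sqrt(ax * ax + ay * ay + az * az);
    const double nr = std::sqrt(rx * rx + ry * ry + rz * rz);
    const double r0r = x0 * rx + y0 * ry + z0 * rz;
    const double F = na * (nr * na + nr * nr - r0r);
    const double adr = ax * rx + ay * ry + az * rz;
    const double c1 = na * na / nr + adr / na + 2.0 * na + 2.0 * nr;
    const double c2 = na + 2.0 * nr + adr / na;
    const double gx = c1 * rx - c2 * x0;
    const double gy = c1 * ry - c2 * y0;
    const double gz = c1 * rz - c2 * z0;
    const double cdr = cx * rx + cy * ry + cz * rz;
    const double s = MU0_4PI / (F * F);
    const double Bx = s * (F * cx - cdr * gx);
    const double By = s * (F * cy - cdr * gy);
    const double Bz = s * (F * cz - cdr * gz);
    out(m) = Bx * sori(m, 0) + By * sori(m, 1) + Bz * sori(m, 2);
  }
}

// [[Rcpp::export]]
arma::mat gain_sarvas_cpp(const arma::mat& loc, const arma::mat& ori,
                          const arma::mat& spos, const arma::mat& sori) {
  const uword Ns = loc.n_rows, M = spos.n_rows;
  mat G(M, Ns);
  vec col(M);
  for (uword j = 0; j < Ns; ++j) {
    sarvas_one(loc.row(j).t(), ori.row(j).t(), spos, sori, col);
    G.col(j) = col;
  }
  return G;
}

// gain evaluation dispatch
// mode 0: Sarvas with analytic azimuthal orientations
// mode 1: fixed gain matrix (location-independent; testing hook)
// mode 2: nearest-grid-point column lookup from an imported gain
struct GainCtx {
  int mode;
  const mat* spos; const mat* sori;
  const mat* Gfixed;
  const mat* grid_pos; const mat* grid_gain;
  double scale;  // gain is divided by this (internal standardization)
};

static void eval_gain(const GainCtx& ctx, const vec& rvec, mat& G) {
  const uword Ns = rvec.n_elem / 3;
  if (ctx.mode == 1) { G = (*ctx.Gfixed) / ctx.scale; return; }
  if (ctx.mode == 2) {
    const mat& gp = *ctx.grid_pos;
    for (uword j = 0; j < Ns; ++j) {
      vec r = rvec.subvec(3 * j, 3 * j + 2);
      uword best = 0; double bd = datum::inf;
      for (uword g = 0; g < gp.n_rows; ++g) {
        double d = std::pow(gp(g, 0) - r(0), 2) + std::pow(gp(g, 1) - r(1), 2) +
                   std::pow(gp(g, 2) - r(2), 2);
        if (d < bd) { bd = d; best = g; }
      }
      G.col(j) = ctx.grid_gain->col(best) / ctx.scale;
    }
    return;
  }
  vec col(ctx.spos->n_rows);
  for (uword j = 0; j < Ns; ++j) {
    vec r = rvec.subvec(3 * j, 3 * j + 2);
    sarvas_one(r, azim_ori(r), *ctx.spos, *ctx.sori, col);
    G.col(j) = col / ctx.scale;
  }
}

// RB Kalman measurement update with E = sig2*I, via Woodbury on the
// Ns-dimensional source block. On entry (mu, P) hold the PREDICTED
// moments; on exit the filtered ones. Returns the incremental loglik.
static double rb_step_update(const vec& y, const mat& G, double sig2,
                             vec& mu, mat& P) {
  const uword Ns = G.n_cols, M = G.n_rows;
  mat Pq = P.submat(0, 0, Ns - 1, Ns - 1);
  vec e = y - G * mu.head(Ns);
  mat C = G.t() * G;                       // Ns x Ns
  mat Mt = eye(Ns, Ns) + (C * Pq) / sig2;  // I + s^-2 C D
  vec u = G.t() * e;
  vec w = solve(Mt, u, solve_opts::fast);
  vec Sinv_e = e / sig2 - (G * (Pq * w)) / (sig2 * sig2);
  double ld, sign;
  log_det(ld, sign, Mt);
  double logdetS = (double)M * std::log(sig2) + ld;
  double quad = dot(e, Sinv_e);
  if (!std::isfinite(quad) || !std::isfinite(ld))
    Rcpp::stop("non-finite innovation in RB Kalman update");
  double ll = -0.5 * ((double)M * std::log(2.0 * datum::pi) + logdetS + quad);
  mat Pcol = P.cols(0, Ns - 1);            // n x Ns
  vec g = G.t() * Sinv_e;                  // Ns
  mat Q = C / sig2 - (C * (Pq * solve(Mt, C, solve_opts::fast))) / (sig2 * sig2);
  Q = 0.5 * (Q + Q.t());
  mu += Pcol * g;
  P -= Pcol * Q * Pcol.t();
  P = 0.5 * (P + P.t());
  return ll;
}

// full predict + update step
static double rb_step(const vec& y, const mat& G, const mat& A, const mat& V,
                      double sig2, vec& mu, mat& P) {
  vec mup = A * mu;
  mat Pp = A * P * A.t() + V;
  mu = mup;
  P = 0.5 * (Pp + Pp.t());
  return rb_step_update(y, G, sig2, mu, P);
}

static uword categorical_draw(const vec& w) {
  double u = R::runif(0.0, 1.0) * accu(w);
  double c = 0.0;
  for (uword i = 0; i < w.n_elem; ++i) {
    c += w(i);
    if (u <= c) return i;
  }
  return w.n_elem - 1;
}

static void systematic_resample(const vec& w, uvec& idx) {
  const uword N = idx.n_elem;
  double u0 = R::runif(0.0, 1.0) / (double)N;
  double c = w(0);
  uword i = 0;
  for (uword j = 0; j < N; ++j) {
    double u = u0 + (double)j / (double)N;
    while (u > c && i + 1 < w.n_elem) { ++i; c += w(i); }
    idx(j) = i;
  }
}

// Conditional particle filter with ancestor sampling over source-location
// trajectories, Rao-Blackwellized over the companion-form amplitudes.
// ybar: T x M (trial-averaged data), ref: T x 3Ns reference trajectory.
// Returns trajectories (cube T x 3Ns x Np), final weights, per-step ESS,
// a log-likelihood trace and the index sampled for the next reference.
// [[Rcpp::export]]
Rcpp::List cpfas_sweep_cpp(const arma::mat& ybar, const arma::mat& ref,
                           const arma::mat& Atil, const arma::mat& Vtil,
                           double sig2, const arma::vec& mu0,
                           const arma::mat& P0, int Np, double a, double h2,
                           const arma::mat& XiChol, int gain_mode,
                           const arma::mat& spos, const arma::mat& sori,
                           double gain_scale, const arma::mat& Gfixed,
                           const arma::mat& grid_pos,
                           const arma::mat& grid_gain) {
  const uword T = ybar.n_rows, M = ybar.n_cols;
  const uword d = ref.n_cols, Ns = d / 3, n = Atil.n_rows;
  if (Np < 1) Rcpp::stop("Np must be >= 1");
  GainCtx ctx{gain_mode, &spos, &sori, &Gfixed, &grid_pos, &grid_gain,
              gain_scale};
  const uword NP = (uword)Np;
  mat loc(d, NP);                       // current locations
  mat mu(n, NP);                        // RB filter means
  cube P(n, n, NP);                     // RB filter covariances
  vec logw(NP), w(NP);
  cube loc_hist(d, NP, T);
  umat anc(NP, T, fill::zeros);
  vec ess(T), llt(T);
  mat G(M, Ns);
  const double h = std::sqrt(std::max(h2, 0.0));

  // t = 1: spawn particles around the reference start
  for (uword i = 0; i < NP; ++i) {
    if (i == NP - 1) loc.col(i) = ref.row(0).t();
    else loc.col(i) = ref.row(0).t() + XiChol * randn<vec>(d);
    mu.col(i) = mu0;
    P.slice(i) = P0;
    eval_gain(ctx, loc.col(i), G);
    vec m = mu.col(i);
    mat Pi = P.slice(i);
    logw(i) = rb_step(ybar.row(0).t(), G, Atil, Vtil, sig2, m, Pi);
    mu.col(i) = m; P.slice(i) = Pi;
  }
  double mx = logw.max();
  if (!std::isfinite(mx)) Rcpp::stop("all particle weights vanished at step 1");
  w = exp(logw - mx);
  llt(0) = mx + std::log(accu(w) / (double)NP);
  w /= accu(w);
  ess(0) = 1.0 / dot(w, w);
  loc_hist.slice(0) = loc;

  mat newloc(d, NP), newmu(n, NP);
  cube newP(n, n, NP);
  for (uword t = 1; t < T; ++t) {
    vec rbar = loc * w;                  // weighted particle mean
    mat m_kernel(d, NP);
    for (uword i = 0; i < NP; ++i)
      m_kernel.col(i) = a * loc.col(i) + (1.0 - a) * rbar;

    uvec anc_t(NP);
    if (NP > 1) {
      uvec idx(NP - 1);
      systematic_resample(w, idx);
      anc_t.head(NP - 1) = idx;
    }
    // ancestor sampling for the reference particle: transition-kernel weights
    vec rstar = ref.row(t).t();
    if (h2 > 0) {
      vec law(NP);
      for (uword i = 0; i < NP; ++i) {
        vec z = solve(trimatl(XiChol), rstar - m_kernel.col(i));
        law(i) = std::log(w(i) + 1e-300) - 0.5 * dot(z, z) / h2;
      }
      law -= law.max();
      anc_t(NP - 1) = categorical_draw(exp(law));
    } else {
      anc_t(NP - 1) = NP - 1;  // degenerate kernel: keep the reference line
    }

    for (uword i = 0; i < NP; ++i) {
      uword ai = anc_t(i);
      if (i == NP - 1) newloc.col(i) = rstar;
      else newloc.col(i) = m_kernel.col(ai) + h * (XiChol * randn<vec>(d));
      vec m = mu.col(ai);
      mat Pi = P.slice(ai);
      eval_gain(ctx, newloc.col(i), G);
      logw(i) = rb_step(ybar.row(t).t(), G, Atil, Vtil, sig2, m, Pi);
      newmu.col(i) = m;
      newP.slice(i) = Pi;
    }
    loc = newloc; mu = newmu; P = newP;
    mx = logw.max();
    if (!std::isfinite(mx))
      Rcpp::stop("all particle weights vanished at step %d (max log-weight %f)",
                 (int)(t + 1), mx);
    w = exp(logw - mx);
    llt(t) = mx + std::log(accu(w) / (double)NP);
    w /= accu(w);
    ess(t) = 1.0 / dot(w, w);
    anc.col(t) = anc_t;
    loc_hist.slice(t) = loc;
  }

  // reconstruct surviving trajectories by backward ancestry tracing
  cube traj(T, d, NP);
  for (uword i = 0; i < NP; ++i) {
    uword idx = i;
    for (uword t = T; t-- > 0;) {
      traj.subcube(t, 0, i, t, d - 1, i) = loc_hist.slice(t).col(idx).t();
      if (t > 0) idx = anc(idx, t);
    }
  }
  uword next_ref = categorical_draw(w);
  return Rcpp::List::create(
      Rcpp::Named("traj") = traj, Rcpp::Named("weights") = w,
      Rcpp::Named("ess") = ess, Rcpp::Named("loglik") = accu(llt),
      Rcpp::Named("loglik_steps") = llt,
      Rcpp::Named("next_ref") = (int)next_ref + 1);
}

// Per-particle, per-trial Kalman filtering + RTS smoothing along given
// location trajectories, accumulating the EM sufficient statistics
// Phi, Psi, Sigma, Z, Ups and the particle/time-averaged gain Gbar.
// trials: cube T x M x J. traj: cube T x 3Ns x Np. w: final sweep weights.
// [[Rcpp::export]]
Rcpp::List suffstats_cpp(const arma::cube& trials, const arma::cube& traj,
                         const arma::vec& w, const arma::mat& Atil,
                         const arma::mat& Vtil, double sig2,
                         const arma::vec& mu0, const arma::mat& P0,
                         int gain_mode, const arma::mat& spos,
                         const arma::mat& sori, double gain_scale,
                         const arma::mat& Gfixed, const arma::mat& grid_pos,
                         const arma::mat& grid_gain, int max_smooth = 0) {
  const uword T = trials.n_slices > 0 ? trials.n_rows : 0;
  const uword M = trials.n_cols, J = trials.n_slices;
  const uword d = traj.n_cols, Ns = d / 3, n = Atil.n_rows;
  const uword NP = traj.n_slices;
  GainCtx ctx{gain_mode, &spos, &sori, &Gfixed, &grid_pos, &grid_gain,
              gain_scale};

  mat Phi(n, n, fill::zeros), Psi(n, n, fill::zeros), Sig(n, n, fill::zeros);
  mat Ups(M, n, fill::zeros), Gbar(M, Ns, fill::zeros);
  mat Z(M, M, fill::zeros);
  for (uword j = 0; j < J; ++j) Z += trials.slice(j).t() * trials.slice(j);

  cube Gs(M, Ns, T);
  mat mup(n, T), muf(n, T);
  cube Pp(n, n, T), Pf(n, n, T);
  double loglik = 0.0;

  // Gbar: unweighted average over every particle and time point
  {
    mat G(M, Ns);
    for (uword i = 0; i < NP; ++i)
      for (uword t = 0; t < T; ++t) {
        vec rv = vectorise(traj.subcube(t, 0, i, t, d - 1, i));
        eval_gain(ctx, rv, G);
        Gbar += G / ((double)NP * (double)T);
      }
  }

  // optionally collapse the weighted set to max_smooth equally weighted
  // representatives (weight-proportional systematic resampling) before the
  // expensive per-particle smoothing pass
  uvec sm_idx(NP);
  vec sm_w(NP);
  uword n_sm = 0;
  for (uword i = 0; i < NP; ++i)
    if (w(i) >= 1e-14) { sm_idx(n_sm) = i; sm_w(n_sm) = w(i); ++n_sm; }
  if (max_smooth > 0 && n_sm > (uword)max_smooth) {
    uvec idx((uword)max_smooth);
    systematic_resample(w, idx);
    n_sm = (uword)max_smooth;
    sm_idx.head(n_sm) = idx;
    sm_w.head(n_sm).fill(1.0 / (double)n_sm);
  }

  for (uword s = 0; s < n_sm; ++s) {
    const uword i = sm_idx(s);
    const double wi = sm_w(s);
    for (uword t = 0; t < T; ++t) {
      vec rv = vectorise(traj.subcube(t, 0, i, t, d - 1, i));
      mat G(M, Ns);
      eval_gain(ctx, rv, G);
      Gs.slice(t) = G;
    }
    for (uword j = 0; j < J; ++j) {
      vec mu = mu0;
      mat P = P0;
      for (uword t = 0; t < T; ++t) {
        vec mup_t = Atil * mu;
        mat Pp_t = Atil * P * Atil.t() + Vtil;
        Pp_t = 0.5 * (Pp_t + Pp_t.t());
        mup.col(t) = mup_t;
        Pp.slice(t) = Pp_t;
        mu = mup_t; P = Pp_t;
        double ll = rb_step_update(trials.slice(j).row(t).t(), Gs.slice(t),
                                   sig2, mu, P);
        muf.col(t) = mu;
        Pf.slice(t) = P;
        loglik += wi * ll;
      }
      // RTS backward pass with accumulation
      vec ms = muf.col(T - 1);
      mat Ps = Pf.slice(T - 1);
      Phi += wi * (Ps + ms * ms.t());
      Ups += wi * (trials.slice(j).row(T - 1).t() * ms.t());
      for (uword t = T - 1; t-- > 0;) {
        // smooth step t (filtered) given t+1 (smoothed)
        mat Jg;
        bool ok = solve(Jg, Pp.slice(t + 1), Atil * Pf.slice(t),
                        solve_opts::no_approx);
        if (ok) Jg = Jg.t();
        else Jg = Pf.slice(t) * Atil.t() * pinv(Pp.slice(t + 1));
        vec ms_new = muf.col(t) + Jg * (ms - mup.col(t + 1));
        mat Ps_new = Pf.slice(t) + Jg * (Ps - Pp.slice(t + 1)) * Jg.t();
        Ps_new = 0.5 * (Ps_new + Ps_new.t());
        mat L1 = Ps * Jg.t();  // cov(x_{t+1}, x_t | y)
        Psi += wi * (L1 + ms * ms_new.t());
        Sig += wi * (Ps_new + ms_new * ms_new.t());
        ms = ms_new; Ps = Ps_new;
        Phi += wi * (Ps + ms * ms.t());
        Ups += wi * (trials.slice(j).row(t).t() * ms.t());
      }
      // pair t = 1 with the smoothed initial state
      mat Jg;
      bool ok = solve(Jg, Pp.slice(0), Atil * P0, solve_opts::no_approx);
      if (ok) Jg = Jg.t();
      else Jg = P0 * Atil.t() * pinv(Pp.slice(0));
      vec m0 = mu0 + Jg * (ms - mup.col(0));
      mat P0s = P0 + Jg * (Ps - Pp.slice(0)) * Jg.t();
      P0s = 0.5 * (P0s + P0s.t());
      mat L1 = Ps * Jg.t();
      Psi += wi * (L1 + ms * m0.t());
      Sig += wi * (P0s + m0 * m0.t());
    }
  }
  Phi = 0.5 * (Phi + Phi.t());
  Sig = 0.5 * (Sig + Sig.t());
  return Rcpp::List::create(
      Rcpp::Named("Phi") = Phi, Rcpp::Named("Psi") = Psi,
      Rcpp::Named("Sigma") = Sig, Rcpp::Named("Z") = Z,
      Rcpp::Named("Ups") = Ups, Rcpp::Named("Gbar") = Gbar,
      Rcpp::Named("loglik") = loglik);
}

// Smoothed amplitude means along one location path (per trial).
// Returns cube T x Ns x J of smoothed current-amplitude means.
// [[Rcpp::export]]
arma::cube smooth_amplitudes_cpp(const arma::cube& trials,
                                 const arma::mat& path, const arma::mat& Atil,
                                 const arma::mat& Vtil, double sig2,
                                 const arma::vec& mu0, const arma::mat& P0,
                                 int gain_mode, const arma::mat& spos,
                                 const arma::mat& sori, double gain_scale,
                                 const arma::mat& Gfixed,
                                 const arma::mat& grid_pos,
                                 const arma::mat& grid_gain) {
  const uword T = trials.n_rows, M = trials.n_cols, J = trials.n_slices;
  const uword d = path.n_cols, Ns = d / 3, n = Atil.n_rows;
  GainCtx ctx{gain_mode, &spos, &sori, &Gfixed, &grid_pos, &grid_gain,
              gain_scale};
  cube Gs(M, Ns, T);
  for (uword t = 0; t < T; ++t) {
    mat G(M, Ns);
    eval_gain(ctx, path.row(t).t(), G);
    Gs.slice(t) = G;
  }
  cube out(T, Ns, J);
  mat mup(n, T), muf(n, T);
  cube Pp(n, n, T), Pf(n, n, T);
  for (uword j = 0; j < J; ++j) {
    vec mu = mu0;
    mat P = P0;
    for (uword t = 0; t < T; ++t) {
      vec mup_t = Atil * mu;
      mat Pp_t = Atil * P * Atil.t() + Vtil;
      Pp_t = 0.5 * (Pp_t + Pp_t.t());
      mup.col(t) = mup_t; Pp.slice(t) = Pp_t;
      mu = mup_t; P = Pp_t;
      rb_step_update(trials.slice(j).row(t).t(), Gs.slice(t), sig2, mu, P);
      muf.col(t) = mu; Pf.slice(t) = P;
    }
    vec ms = muf.col(T - 1);
    mat Ps = Pf.slice(T - 1);
    out.subcube(T - 1, 0, j, T - 1, Ns - 1, j) = ms.head(Ns).t();
    for (uword t = T - 1; t-- > 0;) {
      mat Jg;
      bool ok = solve(Jg, Pp.slice(t + 1), Atil * Pf.slice(t),
                      solve_opts::no_approx);
      if (ok) Jg = Jg.t();
      else Jg = Pf.slice(t) * Atil.t() * pinv(Pp.slice(t + 1));
      vec ms_new = muf.col(t) + Jg * (ms - mup.col(t + 1));
      mat Ps_new = Pf.slice(t) + Jg * (Ps - Pp.slice(t + 1)) * Jg.t();
      ms = ms_new; Ps = 0.5 * (Ps_new + Ps_new.t());
      out.subcube(t, 0, j, t, Ns - 1, j) = ms.head(Ns).t();
    }
  }
  return out;
}
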