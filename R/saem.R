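#' Accumulate EM sufficient statistics from smoothed moments
#'
#' Reference (pure R) implementation of the sufficient statistics consumed by
#' the M-step:
#' \deqn{\Phi = \sum_{t,j,i} w_i (P_{t|T} + \mu_{t|T}\mu_{t|T}^\top),\quad
#'       \Psi = \sum w_i (P_{t,t-1|T} + \mu_{t|T}\mu_{t-1|T}^\top),\quad
#'       \Sigma = \sum w_i (P_{t-1|T} + \mu_{t-1|T}\mu_{t-1|T}^\top),}
#' \eqn{Z = \sum_{t,j} y y^\top}, \eqn{\Upsilon = \sum_{t,j} y \sum_i w_i
#' \mu_{t|T}^\top}, and the particle/time-averaged gain
#' \eqn{\bar G = (N_p T)^{-1} \sum_{t,i} G(r^i_t)} (unweighted). The `t = 1`
#' lag pairs with the smoothed initial state. The SAEM fast path computes the
#' same quantities in compiled code; tests cross-check the two.
#'
#' @param smoothed list over particles; element `i` is a list over trials of
#'   [rts_smooth()] outputs along particle `i`'s trajectory.
#' @param weights normalized particle weights.
#' @param gains list over particles of gain matrices (`M x N_s`, or a list of
#'   length `T` for time-varying locations).
#' @param trials `J x T x M` data array (or `T x M` matrix for one trial).
#' @return object of class `suff_stats` with `Phi`, `Psi`, `Sigma`, `Z`,
#'   `Ups`, `Gbar`.
#' @export
compute_suffstats <- function(smoothed, weights, gains, trials) {
  if (is.matrix(trials)) trials <- array(trials, c(1, dim(trials)))
  J <- dim(trials)[1]; T <- dim(trials)[2]; M <- dim(trials)[3]
  Np <- length(smoothed)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must be normalized")
  n <- ncol(smoothed[[1]][[1]]$smooth_mean)
  ns <- smoothed[[1]][[1]]$n_sources
  Phi <- Psi <- Sig <- matrix(0, n, n)
  Ups <- matrix(0, M, n)
  Gbar <- matrix(0, M, ns)
  Z <- matrix(0, M, M)
  for (j in seq_len(J)) Z <- Z + crossprod(matrix(trials[j, , ], T, M))
  for (i in seq_len(Np)) {
    gi <- gains[[i]]
    gl <- if (is.list(gi)) gi else rep(list(gi), T)
    for (t in seq_len(T)) Gbar <- Gbar + gl[[t]] / (Np * T)
    wi <- weights[i]
    for (j in seq_len(J)) {
      sm <- smoothed[[i]][[j]]
      if (nrow(sm$smooth_mean) != T) stop("smoothed moments shape mismatch")
      y <- matrix(trials[j, , ], T, M)
      for (t in seq_len(T)) {
        mt <- sm$smooth_mean[t, ]
        Phi <- Phi + wi * (sm$smooth_cov[, , t] + tcrossprod(mt))
        Ups <- Ups + wi * (y[t, ] %o% mt)
        mprev <- if (t == 1) sm$mean0 else sm$smooth_mean[t - 1, ]
        Pprev <- if (t == 1) sm$cov0 else sm$smooth_cov[, , t - 1]
        Psi <- Psi + wi * (sm$lag1_cov[, , t] + mt %o% mprev)
        Sig <- Sig + wi * (Pprev + tcrossprod(mprev))
      }
    }
  }
  new_suffstats(Phi, Psi, Sig, Z, Ups, Gbar)
}

new_suffstats <- function(Phi, Psi, Sigma, Z, Ups, Gbar) {
  if (any(!is.finite(Phi)) || any(!is.finite(Psi)) || any(!is.finite(Sigma)) ||
      any(!is.finite(Z)) || any(!is.finite(Ups)) || any(!is.finite(Gbar)))
    stop("non-finite sufficient statistics")
  structure(list(Phi = (Phi + t(Phi)) / 2, Psi = Psi,
                 Sigma = (Sigma + t(Sigma)) / 2, Z = Z, Ups = Ups,
                 Gbar = Gbar),
            class = "suff_stats")
}

#' Stochastic-approximation update of the running sufficient statistics
#'
#' Blockwise convex combination \eqn{S_k = (1-\zeta) S_{k-1} + \zeta S_k}.
#'
#' @param S_prev,S_new `suff_stats` objects (`S_prev = NULL` acts as zero).
#' @param zeta step size in (0, 1].
#' @return `suff_stats`.
#' @export
sa_update <- function(S_prev, S_new, zeta) {
  if (zeta <= 0 || zeta > 1) stop("`zeta` must be in (0, 1]")
  stopifnot(inherits(S_new, "suff_stats"))
  if (is.null(S_prev)) S_prev <- lapply(unclass(S_new), function(x) x * 0)
  out <- Map(function(a, b) (1 - zeta) * a + zeta * b,
             unclass(S_prev)[names(unclass(S_new))], unclass(S_new))
  structure(out, class = "suff_stats")
}

#' SAEM step-size schedule
#'
#' \eqn{\zeta_k = 1} for `k <= K0` (burn-in), then
#' \eqn{\zeta_k = (k - K0)^{-\gamma}} with \eqn{\gamma \in (0.5, 1]}, which
#' satisfies \eqn{\sum_k \zeta_k = \infty} and \eqn{\sum_k \zeta_k^2 <
#' \infty}.
#'
#' @param k iteration index (vectorized).
#' @param K0 burn-in length.
#' @param gamma decay exponent in (0.5, 1].
#' @return step sizes.
#' @export
zeta_schedule <- function(k, K0, gamma) {
  if (gamma <= 0.5 || gamma > 1) stop("`gamma` must be in (0.5, 1]")
  ifelse(k <= K0, 1, pmax(k - K0, 1)^(-gamma))
}

#' Closed-form M-step for MVAR coefficients, process noise and sensor noise
#'
#' Maximizes the complete-data expected log-likelihood given the accumulated
#' sufficient statistics: the free top block-row of the companion matrix is
#' \eqn{[A_1 \ldots A_P] = \Psi_{top} \Sigma^{-1}}, the (diagonal) process
#' noise is \eqn{V = \mathrm{diag}[(\Phi - \Psi\Sigma^{-1}\Psi^\top)]_{top}
#' / (JT)}, and
#' \eqn{\sigma_m^2 = \mathrm{tr}(Z - \Upsilon\tilde G^\top - \tilde
#' G\Upsilon^\top + \tilde G \Phi \tilde G^\top) / (MJT)} with
#' \eqn{\tilde G = [\bar G\; 0]}.
#'
#' @param S `suff_stats`.
#' @param J,T trial and sample counts behind `S`.
#' @param n_sources,order model dimensions.
#' @param ridge relative ridge added to `Sigma` when it is numerically
#'   singular (logged via a warning).
#' @return list with `model` ([mvar_model()] with diagonal `V`), `A_tilde`,
#'   `V`, `sigma_m2`.
#' @export
mstep_closed <- function(S, J, T, n_sources, order, ridge = 1e-10) {
  stopifnot(inherits(S, "suff_stats"))
  ns <- n_sources; n <- ns * order
  M <- nrow(S$Z)
  Sig <- S$Sigma
  B <- tryCatch(t(solve(Sig, t(S$Psi))), error = function(e) NULL)
  if (is.null(B)) {
    warning("singular Sigma in M-step; ridge fallback applied")
    Sig <- Sig + ridge * mean(diag(Sig)) * diag(n)
    B <- t(solve(Sig, t(S$Psi)))
  }
  Arow <- B[1:ns, , drop = FALSE]
  resid <- S$Phi - B %*% t(S$Psi)
  vdiag <- diag(resid)[1:ns] / (J * T)
  # variance floor: relative to the state scale so standardized and raw
  # amplitude units are both safe
  vfloor <- 1e-12 * max(mean(diag(S$Phi)) / (J * T), 1e-300)
  if (any(vdiag < vfloor)) {
    warning("process-noise variance floored in M-step")
    vdiag <- pmax(vdiag, vfloor)
  }
  Gb <- S$Gbar
  Phi_tt <- S$Phi[1:ns, 1:ns, drop = FALSE]
  Ups_top <- S$Ups[, 1:ns, drop = FALSE]
  sm2 <- (sum(diag(S$Z)) - 2 * sum(Ups_top * Gb) +
            sum((Gb %*% Phi_tt) * Gb)) / (M * J * T)
  if (sm2 < vfloor * 1e-6) {
    warning("sensor-noise variance floored in M-step")
    sm2 <- vfloor * 1e-6
  }
  coeffs <- lapply(seq_len(order), function(p)
    Arow[, ((p - 1) * ns + 1):(p * ns), drop = FALSE])
  model <- mvar_model(coeffs, diag(vdiag, ns))
  list(model = model, A_tilde = to_companion(model)$A_tilde,
       V = diag(vdiag, ns), sigma_m2 = sm2)
}

#' Gradient M-step for the sensor- and brain-noise variances
#'
#' Under the brain-noise measurement model
#' \eqn{E = \sigma_m^2 I + \sigma_b^2 G G^\top} the noise update has no
#' closed form; this routine ascends the measurement part of the expected
#' complete-data log-likelihood,
#' \eqn{-(JT/2)\log\det(2\pi E) - \tfrac12 \mathrm{tr}(E^{-1} W)} with
#' \eqn{W = Z - \Upsilon_{top}\bar G^\top - \bar G\Upsilon_{top}^\top +
#' \bar G \Phi_{tt} \bar G^\top}, by gradient ascent in
#' \eqn{(\log\sigma_m^2, \log\sigma_b^2)} with backtracking halving.
#' With `fix_b2 = TRUE` and `sigma_b2 = 0` the maximizer is the closed-form
#' \eqn{\mathrm{tr}(W)/(MJT)}.
#'
#' @param S `suff_stats`.
#' @param J,T counts behind `S`.
#' @param n_sources model dimension.
#' @param sigma_m2,sigma_b2 starting values (> 0; `sigma_b2 = 0` allowed only
#'   with `fix_b2 = TRUE`).
#' @param gain_ref `M x K` reference gain whose outer product carries the
#'   projected brain noise.
#' @param fix_b2 hold `sigma_b2` fixed (optimize `sigma_m2` only).
#' @param max_iter,tol ascent iteration cap and gradient-norm tolerance.
#' @return list with `sigma_m2`, `sigma_b2`, `value` (objective), `grad_norm`,
#'   `iterations`.
#' @export
mstep_noise <- function(S, J, T, n_sources, sigma_m2, sigma_b2, gain_ref,
                        fix_b2 = FALSE, max_iter = 500L, tol = 1e-9) {
  stopifnot(inherits(S, "suff_stats"))
  ns <- n_sources
  M <- nrow(S$Z)
  W <- S$Z - S$Ups[, 1:ns, drop = FALSE] %*% t(S$Gbar) -
    S$Gbar %*% t(S$Ups[, 1:ns, drop = FALSE]) +
    S$Gbar %*% S$Phi[1:ns, 1:ns, drop = FALSE] %*% t(S$Gbar)
  W <- (W + t(W)) / 2
  eg <- eigen(tcrossprod(gain_ref), symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  wt <- diag(t(eg$vectors) %*% W %*% eg$vectors)
  obj <- function(m2, b2) {
    d <- m2 + b2 * lam
    -0.5 * J * T * (M * log(2 * pi) + sum(log(d))) - 0.5 * sum(wt / d)
  }
  grad <- function(m2, b2) {
    d <- m2 + b2 * lam
    gm <- -0.5 * J * T * sum(1 / d) + 0.5 * sum(wt / d^2)
    gb <- -0.5 * J * T * sum(lam / d) + 0.5 * sum(wt * lam / d^2)
    c(gm * m2, if (fix_b2) 0 else gb * b2)  # chain rule: log-parameters
  }
  if (sigma_m2 <= 0) stop("sigma_m2 must be > 0")
  if (!fix_b2 && sigma_b2 <= 0) sigma_b2 <- sigma_m2 * 1e-4
  lm2 <- log(sigma_m2); lb2 <- log(max(sigma_b2, 1e-300))
  b2_of <- function(lb2) if (fix_b2 && sigma_b2 == 0) 0 else exp(lb2)
  f <- obj(exp(lm2), b2_of(lb2))
  it <- 0L; gnorm <- Inf
  repeat {
    it <- it + 1L
    g <- grad(exp(lm2), b2_of(lb2))
    if (any(!is.finite(g)))
      stop("non-finite gradient in noise M-step at (",
           exp(lm2), ", ", b2_of(lb2), ")")
    gnorm <- sqrt(sum(g^2))
    if (gnorm < tol * max(1, abs(f)) || it > max_iter) break
    step <- min(1, 1 / gnorm) * 0.5
    ok <- FALSE
    for (bt in 1:60) {
      lm2_new <- lm2 + step * g[1]
      lb2_new <- lb2 + step * g[2]
      f_new <- obj(exp(lm2_new), b2_of(lb2_new))
      if (is.finite(f_new) && f_new > f) { ok <- TRUE; break }
      step <- step / 2
    }
    if (!ok) break  # no ascent direction left at machine precision
    lm2 <- lm2_new; lb2 <- lb2_new; f <- f_new
  }
  list(sigma_m2 = exp(lm2), sigma_b2 = b2_of(lb2), value = f,
       grad_norm = gnorm, iterations = it)
}

#' BIC model-order selection for the amplitude MVAR model
#'
#' Fits a least-squares MVAR model at every order in `p_range` and evaluates
#' \deqn{\mathrm{BIC}(P) = -2 LL + K_P \log(JT), \qquad
#'       K_P = N_s^2 P + N_s + 1,}
#' where `LL` is the Gaussian process log-likelihood of the fitted model
#' (diagonal process noise; the free-parameter count covers the coefficient
#' matrices, the diagonal of `V`, and one noise variance).
#'
#' @param series `J x T x N_s` array (or `T x N_s` matrix) of amplitude time
#'   courses.
#' @param p_range candidate orders, a subset of 1..20.
#' @return list with `order` (argmin), `table` (data.frame with P, loglik,
#'   K_P, BIC).
#' @export
bic_select <- function(series, p_range = 1:20) {
  if (length(p_range) == 0) stop("empty order range")
  if (any(p_range < 1 | p_range > 20)) stop("orders must lie in [1, 20]")
  if (is.matrix(series)) series <- array(series, c(1, dim(series)))
  J <- dim(series)[1]; T <- dim(series)[2]; ns <- dim(series)[3]
  rows <- lapply(sort(unique(p_range)), function(P) {
    fit <- fit_mvar_ls(series, P)
    ll <- mvar_process_loglik(series, fit)
    K <- ns^2 * P + ns + 1
    data.frame(P = P, loglik = ll, K = K, BIC = -2 * ll + K * log(J * T))
  })
  tab <- do.call(rbind, rows)
  list(order = tab$P[which.min(tab$BIC)], table = tab)
}

# Gaussian log-likelihood of the MVAR process part (diagonal V), pooled over
# trials; conditioning on the first P samples of each trial.
mvar_process_loglik <- function(series, model) {
  if (is.matrix(series)) series <- array(series, c(1, dim(series)))
  J <- dim(series)[1]; T <- dim(series)[2]; ns <- dim(series)[3]
  P <- model$order
  v <- pmax(diag(model$proc_noise), 1e-300)
  ll <- 0
  for (j in seq_len(J)) {
    q <- matrix(series[j, , ], T, ns)
    for (t in (P + 1):T) {
      pred <- rep(0, ns)
      for (p in seq_len(P)) pred <- pred + model$coeffs[[p]] %*% q[t - p, ]
      r <- q[t, ] - as.numeric(pred)
      ll <- ll - 0.5 * sum(log(2 * pi * v) + r^2 / v)
    }
  }
  ll
}

#' Control settings for [fit_joint()]
#'
#' @param n_particles particles in the CPF-AS sweep (paper-scale default 500;
#'   desk-scale studies use 48-64).
#' @param n_iter SAEM iteration budget.
#' @param K0_frac fraction of the budget spent in the `zeta = 1` burn-in.
#' @param gamma step-size decay exponent in (0.5, 1].
#' @param delta Liu-West discount in (0, 1].
#' @param kernel_sd isotropic kernel spread (m) per location coordinate.
#' @param noise_model `"iid"` sensor noise, or `"brain"` adding the
#'   white-brain-noise term `sigma_b2 * G G^T` (noise variances then updated
#'   by [mstep_noise()]).
#' @param tol,tol_window early stop when the relative parameter change stays
#'   below `tol` for `tol_window` consecutive iterations (after burn-in).
#' @param max_smooth cap on the number of particles carried through the
#'   per-particle RTS smoothing pass; when more particles carry weight, the
#'   set is collapsed by weight-proportional systematic resampling to this
#'   many equally weighted representatives (0 = no cap). A pure
#'   computational device: the collapsed set is an unbiased resampling of
#'   the full weighted set.
#' @param verbose print a progress line every 25 iterations.
#' @return list of control settings.
#' @export
joint_control <- function(n_particles = 500L, n_iter = 300L, K0_frac = 0.3,
                          gamma = 0.7, delta = 0.98, kernel_sd = 0.005,
                          noise_model = c("iid", "brain"), tol = 1e-4,
                          tol_window = 20L, max_smooth = 16L,
                          verbose = FALSE) {
  list(n_particles = as.integer(n_particles), n_iter = as.integer(n_iter),
       K0_frac = K0_frac, gamma = gamma, delta = delta,
       kernel_sd = kernel_sd, noise_model = match.arg(noise_model),
       tol = tol, tol_window = as.integer(tol_window),
       max_smooth = as.integer(max_smooth), verbose = verbose)
}

#' Joint SAEM estimation of source locations, amplitudes and connectivity
#'
#' The top-level fitter: iterates a Rao-Blackwellized CPF-AS sweep over
#' source-location trajectories (E-step sampling), per-particle/per-trial RTS
#' smoothing into sufficient statistics, the stochastic-approximation
#' average, and closed-form/gradient M-steps for the MVAR coefficients and
#' noise variances. Data are standardized internally (sensor scale and gain
#' scale) and all outputs are returned in the original units.
#'
#' @param trials `J x T x M` sensor data array (or `T x M` matrix for a
#'   single trial).
#' @param n_sources number of sources to estimate (1-5 recommended).
#' @param order MVAR model order `P`.
#' @param geometry [make_geometry()] object (analytic forward model); or
#'   supply `gain_grid` for an imported lead field.
#' @param control [joint_control()] list.
#' @param fixed_locations optional `N_s x 3` true/known locations: bypasses
#'   the particle sweep entirely and runs exact (Kalman) EM at those
#'   locations.
#' @param reference optional `N_s x 3` initial locations for the reference
#'   trajectory (default: MCMV scan of the trial-averaged data).
#' @param gain_grid optional imported grid gain (list with `gain`,
#'   `positions`) used instead of the analytic model.
#' @return object of class `joint_fit`: `$mvar` (fitted [mvar_model()]),
#'   `$locations` (list with `estimate` `N_s x 3`, `spread`), `$amplitudes`
#'   (`J x T x N_s` smoothed means), `$noise` (`sigma_m2`, `sigma_b2`),
#'   `$loglik` (per-iteration trace), `$ess_min`, `$param_trace`
#'   (per-iteration parameter norms), `$iterations`, `$control`.
#' @export
fit_joint <- function(trials, n_sources, order = 2, geometry = NULL,
                      control = joint_control(), fixed_locations = NULL,
                      reference = NULL, gain_grid = NULL) {
  if (is.matrix(trials)) trials <- array(trials, c(1, dim(trials)))
  J <- dim(trials)[1]; T <- dim(trials)[2]; M <- dim(trials)[3]
  ns <- n_sources; n <- ns * order
  if (ns < 1) stop("n_sources must be >= 1")
  ybar <- apply(trials, c(2, 3), mean)

  # internal standardization: G' = G/gs, y' = y/ys
  if (!is.null(gain_grid)) {
    gs <- median(sqrt(colSums(gain_grid$gain^2)))
    Ggrid_raw <- gain_grid$gain
    grid_pos <- gain_grid$positions
  } else {
    stopifnot(inherits(geometry, "head_geometry"))
    Ggrid_raw <- grid_gain(geometry)
    gs <- median(sqrt(colSums(Ggrid_raw^2)))
    grid_pos <- geometry$grid$positions
  }
  ys <- stats::sd(ybar)
  if (!is.finite(ys) || ys == 0) ys <- 1
  trials_s <- trials / ys
  ybar_s <- ybar / ys

  # reference locations
  if (!is.null(fixed_locations)) {
    loc0 <- as.matrix(fixed_locations)
  } else if (!is.null(reference)) {
    loc0 <- as.matrix(reference)
  } else {
    scan_gain <- Ggrid_raw
    C <- crossprod(ybar) / T
    C <- C + reg_lambda(C, M) * diag(M)
    loc0 <- mai_scan(C, diag(M), scan_gain, ns, positions = grid_pos)$locations
  }
  ref <- matrix(t(loc0), T, 3 * ns, byrow = TRUE)

  ctx <- if (!is.null(gain_grid)) gain_context(grid = gain_grid, scale = gs)
         else gain_context(geometry = geometry, scale = gs)

  # theta init: A = 0; V from a least-squares amplitude projection;
  # sigma_m2 at 10% of the per-trial data variance
  G0 <- gain_eval(ctx, as.numeric(t(loc0)))
  qhat <- t(pseudo_inverse(crossprod(G0)) %*% t(G0) %*% t(ybar_s))
  v0 <- mean(apply(qhat, 2, var))
  if (!is.finite(v0) || v0 <= 0) v0 <- 1
  model <- mvar_model(rep(list(matrix(0, ns, ns)), order), diag(v0, ns))
  cf <- to_companion(model)
  sm2 <- 0.1 * mean(apply(matrix(aperm(trials_s, c(2, 1, 3)), J * T, M), 2, var))
  if (!is.finite(sm2) || sm2 <= 0) sm2 <- 0.1
  sb2 <- 0
  Ggrid_s <- Ggrid_raw / gs
  brain <- control$noise_model == "brain"
  if (brain) sb2 <- sm2 / mean(rowSums(Ggrid_s^2))

  K0 <- ceiling(control$K0_frac * control$n_iter)
  a <- (3 * control$delta - 1) / (2 * control$delta)
  h2 <- 1 - a^2
  XiChol <- diag(control$kernel_sd, 3 * ns)
  S_run <- NULL
  trace_ll <- numeric(0)
  trace_par <- matrix(NA_real_, control$n_iter, 4,
                      dimnames = list(NULL, c("max_abs_A", "tr_V",
                                              "sigma_m2", "sigma_b2")))
  ess_min <- numeric(0)
  stable_count <- 0L
  trials_cube <- aperm(trials_s, c(2, 3, 1))  # T x M x J for the C++ core
  last_system <- NULL
  k_stop <- control$n_iter
  par_old <- NULL

  for (k in seq_len(control$n_iter)) {
    mu0 <- rep(0, n)
    P0 <- default_init_cov(cf$A_tilde, cf$V_tilde)
    # effective iid noise seen by the RB filter (brain noise folded in)
    sig_eff <- sm2 + if (brain) sb2 * mean(rowSums(Ggrid_s^2)) else 0
    if (is.null(fixed_locations)) {
      sw <- cpfas_sweep_cpp(ybar_s, ref, cf$A_tilde, cf$V_tilde, sig_eff / J,
                            mu0, P0, control$n_particles, a, h2, XiChol,
                            ctx$mode, ctx$spos, ctx$sori, ctx$scale,
                            ctx$Gfixed, ctx$grid_pos, ctx$grid_gain)
      traj <- sw$traj
      w <- as.numeric(sw$weights)
      ref <- matrix(traj[, , sw$next_ref], T, 3 * ns)
      trace_ll <- c(trace_ll, sw$loglik)
      ess_min <- c(ess_min, min(sw$ess))
      last_system <- sw
    } else {
      traj <- array(ref, c(T, 3 * ns, 1))
      w <- 1
      trace_ll <- c(trace_ll, NA_real_)
    }
    St <- suffstats_cpp(trials_cube, traj, w, cf$A_tilde, cf$V_tilde,
                        sig_eff, mu0, P0, ctx$mode, ctx$spos, ctx$sori,
                        ctx$scale, ctx$Gfixed, ctx$grid_pos, ctx$grid_gain,
                        control$max_smooth)
    Sk <- new_suffstats(St$Phi, St$Psi, St$Sigma, St$Z, St$Ups, St$Gbar)
    if (!is.null(fixed_locations)) trace_ll[k] <- St$loglik
    zeta <- zeta_schedule(k, K0, control$gamma)
    S_run <- sa_update(S_run, Sk, zeta)
    ms <- mstep_closed(S_run, J, T, ns, order)
    model <- ms$model; cf <- to_companion(model)
    if (brain) {
      up <- mstep_noise(S_run, J, T, ns, sigma_m2 = ms$sigma_m2,
                        sigma_b2 = sb2, gain_ref = Ggrid_s)
      sm2 <- up$sigma_m2; sb2 <- up$sigma_b2
    } else {
      sm2 <- ms$sigma_m2
    }
    trace_par[k, ] <- c(max(abs(unlist(model$coeffs))),
                        sum(diag(model$proc_noise)), sm2, sb2)
    par_new <- c(unlist(model$coeffs), diag(model$proc_noise), sm2, sb2)
    if (!is.null(par_old)) {
      rel <- max(abs(par_new - par_old)) / max(max(abs(par_old)), 1e-12)
      stable_count <- if (rel < control$tol) stable_count + 1L else 0L
      if (k > K0 && stable_count >= control$tol_window) { k_stop <- k; break }
    }
    par_old <- par_new
    if (control$verbose && k %% 25 == 0)
      message(sprintf("iter %4d  loglik %.2f  zeta %.3f", k, trace_ll[k], zeta))
  }

  # location summary: particle- and time-averaged weighted mean
  if (is.null(fixed_locations)) {
    tm <- apply(last_system$traj, c(2, 3), mean)      # (3ns) x Np time means
    est_vec <- as.numeric(tm %*% last_system$weights)
    dev2 <- sweep(tm, 1, est_vec)^2
    spread_vec <- sqrt(as.numeric(dev2 %*% last_system$weights))
    loc_est <- matrix(est_vec, ns, 3, byrow = TRUE)
    loc_spread <- matrix(spread_vec, ns, 3, byrow = TRUE)
    final_path <- matrix(est_vec, T, 3 * ns, byrow = TRUE)
  } else {
    loc_est <- as.matrix(fixed_locations)
    loc_spread <- matrix(0, ns, 3)
    final_path <- ref
  }

  mu0 <- rep(0, n)
  P0 <- default_init_cov(cf$A_tilde, cf$V_tilde)
  sig_eff <- sm2 + if (brain) sb2 * mean(rowSums(Ggrid_s^2)) else 0
  amps <- smooth_amplitudes_cpp(trials_cube, final_path, cf$A_tilde,
                                cf$V_tilde, sig_eff, mu0, P0, ctx$mode,
                                ctx$spos, ctx$sori, ctx$scale, ctx$Gfixed,
                                ctx$grid_pos, ctx$grid_gain)
  amps <- aperm(amps, c(3, 1, 2))  # J x T x Ns

  # undo the internal standardization: q' = q * gs / ys
  amp_scale <- ys / gs
  model_out <- mvar_model(model$coeffs, model$proc_noise * amp_scale^2)
  structure(list(
    mvar = model_out,
    locations = list(estimate = loc_est, spread = loc_spread),
    amplitudes = amps * amp_scale,
    noise = list(sigma_m2 = sm2 * ys^2,
                 sigma_b2 = sb2 * amp_scale^2),
    loglik = trace_ll, ess_min = ess_min, iterations = k_stop,
    param_trace = trace_par[seq_len(k_stop), , drop = FALSE],
    reference_init = loc0,
    scaling = list(data = ys, gain = gs),
    control = control, n_sources = ns, order = order,
    dims = c(J = J, T = T, M = M)),
    class = "joint_fit")
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("joint state-space fit: %d sources, order %d, %d iterations\n",
              x$n_sources, x$order, x$iterations))
  cat("  locations (m):\n")
  print(round(x$locations$estimate, 4))
  cat(sprintf("  sigma_m2 = %.3e, sigma_b2 = %.3e\n",
              x$noise$sigma_m2, x$noise$sigma_b2))
  invisible(x)
}
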