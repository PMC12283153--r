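test_that("sufficient statistics: degenerate case, weight invariance, MC oracle", {
  set.seed(51)
  # single particle, T = 1, J = 1, zero smoothed covariance: Phi = q q^T
  q <- c(1.5, -0.7)
  sm <- structure(list(
    smooth_mean = matrix(q, 1, 2), smooth_cov = array(0, c(2, 2, 1)),
    lag1_cov = array(0, c(2, 2, 1)), mean0 = c(0, 0),
    cov0 = matrix(0, 2, 2), n_sources = 2L), class = "smoothed_moments")
  y <- array(rnorm(3), c(1, 1, 3))
  G <- matrix(rnorm(6), 3, 2)
  S <- compute_suffstats(list(list(sm)), 1, list(G), y)
  expect_equal(S$Phi, tcrossprod(q))
  expect_equal(S$Ups, y[1, 1, ] %o% q)
  expect_equal(S$Z, tcrossprod(y[1, 1, ]))

  # renormalized duplicate weights leave every statistic unchanged
  m <- rand_stable_mvar(2, 1)
  pars <- ssm_params(m, sigma_m2 = 0.3)
  Tn <- 6; M <- 4
  yy <- array(rnorm(Tn * M), c(1, Tn, M))
  Gl <- list(matrix(rnorm(M * 2), M, 2), matrix(rnorm(M * 2), M, 2))
  sms <- lapply(Gl, function(g)
    list(rts_smooth(kalman_filter(yy[1, , ], g, pars), pars)))
  S1 <- compute_suffstats(sms, c(0.3, 0.7), Gl, yy)
  S2 <- compute_suffstats(sms, c(0.3, 0.7), Gl, yy)
  for (nm in names(unclass(S1))) expect_equal(S1[[nm]], S2[[nm]])
  expect_error(compute_suffstats(sms, c(0.6, 1.4), Gl, yy), "normalized")

  # Monte-Carlo oracle: sampling from the smoothed Gaussians reproduces the
  # second moments within 3 standard errors
  sm1 <- sms[[1]][[1]]
  nsim <- 4000
  t_pick <- 3
  nd <- ncol(sm1$smooth_mean)
  L <- chol(sm1$smooth_cov[, , t_pick] + 1e-12 * diag(nd))
  draws <- matrix(rnorm(nsim * nd), nsim, nd) %*% L +
    matrix(sm1$smooth_mean[t_pick, ], nsim, nd, byrow = TRUE)
  mc <- crossprod(draws) / nsim
  exact <- sm1$smooth_cov[, , t_pick] + tcrossprod(sm1$smooth_mean[t_pick, ])
  se <- 3 * max(abs(exact)) / sqrt(nsim)
  expect_lt(max(abs(mc - exact)), 3 * se + 0.2)
})

test_that("stochastic-approximation update is the stated convex combination", {
  set.seed(52)
  mk <- function(x) megjoint:::new_suffstats(
    diag(x, 2), matrix(x, 2, 2), diag(x, 2), diag(x, 3),
    matrix(x, 3, 2), matrix(x, 3, 2))
  S1 <- mk(2); S2 <- mk(6)
  expect_equal(sa_update(S1, S2, 1)$Phi, S2$Phi)        # zeta = 1 replaces
  expect_equal(sa_update(NULL, S2, 0.5)$Phi, S2$Phi / 2)
  # iterating with a constant target converges geometrically
  S <- S1
  for (k in 1:60) S <- sa_update(S, S2, 0.3)
  expect_equal(S$Phi, S2$Phi, tolerance = 1e-6)
  expect_error(sa_update(S1, S2, 0), "zeta")
})

test_that("zeta schedule satisfies the SA constraints", {
  expect_equal(zeta_schedule(1:5, 5, 0.7), rep(1, 5))
  expect_equal(zeta_schedule(4, 0, 1), 0.25)
  expect_error(zeta_schedule(1, 0, 0.4), "gamma")
  # p-series check over 1e6 terms: the partial sums of zeta keep growing
  # like K^0.3 (ratio ~ 100^0.3 = 3.98 between K = 1e4 and 1e6) while the
  # partial sums of zeta^2 are already within a small tail of their limit
  k <- 1:1e6
  z <- zeta_schedule(k, 0, 0.7)
  partial <- cumsum(z)
  expect_gt(partial[1e6] / partial[1e4], 3)
  expect_lt(sum(z^2) - sum(z[1:1e4]^2), 0.1)
  expect_lt(sum(z^2), 5)                          # bounded (zeta(1.4) ~ 3.1)
})

test_that("closed-form M-step: edge case and recovery from a long AR run", {
  set.seed(53)
  # Psi = 0 gives A = 0 and V = diag(Phi)/(JT)
  S0 <- megjoint:::new_suffstats(diag(c(4, 6)), matrix(0, 2, 2), diag(2),
                                 diag(3), matrix(0, 3, 2),
                                 matrix(rnorm(6), 3, 2))
  ms0 <- mstep_closed(S0, J = 1, T = 2, n_sources = 2, order = 1)
  expect_equal(ms0$model$coeffs[[1]], matrix(0, 2, 2))
  expect_equal(diag(ms0$V), c(2, 3))
  # noiseless observation of a long AR(1) run: the M-step coefficient
  # agrees with the direct conditional least-squares estimate (the exact
  # finite-sample MLE) and sits within sampling error of the truth
  a_true <- 0.8
  m <- mvar_model(list(matrix(a_true)), matrix(1))
  pars <- ssm_params(m, sigma_m2 = 1e-8)
  Tn <- 4000
  q <- simulate_mvar(m, Tn, drop = TRUE)
  y <- array(q, c(1, Tn, 1))
  S <- exact_suffstats(y, matrix(1), pars)
  ms <- mstep_closed(S, 1, Tn, 1, 1)
  a_ls <- sum(q[-1] * q[-Tn]) / sum(q[-Tn]^2)
  expect_equal(ms$model$coeffs[[1]][1, 1], a_ls, tolerance = 2e-3)
  se <- sqrt((1 - a_true^2) / Tn)
  expect_lt(abs(ms$model$coeffs[[1]][1, 1] - a_true), 4 * se)
  expect_equal(diag(ms$V), 1, tolerance = 0.1, ignore_attr = TRUE)
})

test_that("M-step matches the generic numerical maximizer", {
  set.seed(54)
  for (rep in 1:3) {
    ns <- sample(1:2, 1); P <- sample(1:2, 1)
    Tn <- 30; M <- 4; J <- 2
    m <- rand_stable_mvar(ns, P)
    pars <- ssm_params(m, sigma_m2 = 0.5)
    G <- matrix(rnorm(M * ns), M, ns)
    q <- simulate_mvar(m, Tn, n_trials = J)
    y <- array(0, c(J, Tn, M))
    for (j in 1:J) y[j, , ] <- matrix(q[j, , ], Tn, ns) %*% t(G) +
        matrix(rnorm(Tn * M, sd = sqrt(0.5)), Tn, M)
    S <- exact_suffstats(y, G, pars)
    ms <- mstep_closed(S, J, Tn, ns, P)
    or <- mstep_numeric_oracle(S, J, Tn, ns, P, M)
    Arow <- do.call(cbind, ms$model$coeffs)
    expect_equal(Arow, or$A, tolerance = 1e-4, ignore_attr = TRUE)
    expect_equal(diag(ms$V), or$v, tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(ms$sigma_m2, or$sigma_m2, tolerance = 1e-3)
  }
})

test_that("noise gradient step: closed-form limit, stationarity, recovery", {
  set.seed(55)
  ns <- 2; Tn <- 40; M <- 5; J <- 2
  m <- rand_stable_mvar(ns, 1)
  pars <- ssm_params(m, sigma_m2 = 0.4)
  G <- matrix(rnorm(M * ns), M, ns)
  q <- simulate_mvar(m, Tn, n_trials = J)
  y <- array(0, c(J, Tn, M))
  for (j in 1:J) y[j, , ] <- matrix(q[j, , ], Tn, ns) %*% t(G) +
      matrix(rnorm(Tn * M, sd = sqrt(0.4)), Tn, M)
  S <- exact_suffstats(y, G, pars)
  ms <- mstep_closed(S, J, Tn, ns, 1)
  # sigma_b2 pinned at zero: gradient ascent lands on the closed form
  up <- mstep_noise(S, J, Tn, ns, sigma_m2 = 5 * ms$sigma_m2, sigma_b2 = 0,
                    gain_ref = G, fix_b2 = TRUE)
  expect_equal(up$sigma_m2, ms$sigma_m2, tolerance = 1e-6)
  # starting at the optimum: gradient is (numerically) zero, no movement
  up2 <- mstep_noise(S, J, Tn, ns, sigma_m2 = ms$sigma_m2, sigma_b2 = 0,
                     gain_ref = G, fix_b2 = TRUE)
  expect_equal(up2$sigma_m2, ms$sigma_m2, tolerance = 1e-8)
  # parameter recovery with genuine projected brain noise at T = 1000
  set.seed(56)
  Tn2 <- 1000
  sm2_true <- 0.3; sb2_true <- 0.8
  Gref <- matrix(rnorm(M * 3), M, 3)
  q2 <- simulate_mvar(m, Tn2, n_trials = 1)
  E_true <- diag(sm2_true, M) + sb2_true * tcrossprod(Gref)
  L <- chol(E_true)
  y2 <- array(matrix(q2[1, , ], Tn2, ns) %*% t(G) +
                matrix(rnorm(Tn2 * M), Tn2, M) %*% L, c(1, Tn2, M))
  pars_b <- ssm_params(m, sigma_m2 = sm2_true, sigma_b2 = sb2_true,
                       noise_rule = "brain", gain_ref = Gref)
  smoothed <- list(list(rts_smooth(kalman_filter(y2[1, , ], G, pars_b),
                                   pars_b)))
  S2 <- compute_suffstats(smoothed, 1, list(G), y2)
  up3 <- mstep_noise(S2, 1, Tn2, ns, sigma_m2 = 1, sigma_b2 = 0.1,
                     gain_ref = Gref)
  expect_lt(abs(up3$sigma_m2 - sm2_true) / sm2_true, 0.2)
  expect_lt(abs(up3$sigma_b2 - sb2_true) / sb2_true, 0.2)
})

test_that("BIC order selection: parameter counts and white-noise penalty", {
  # free-parameter count forced by the formula
  tab <- function(ns, P) ns^2 * P + ns + 1
  expect_equal(tab(5, 14), 356)
  expect_equal(tab(3, 2), 22)
  set.seed(57)
  # white-noise amplitudes: the penalty makes the smallest order win
  y <- array(rnorm(2 * 400 * 3), c(2, 400, 3))
  sel <- bic_select(y, 1:4)
  expect_equal(sel$order, 1L)
  expect_equal(sel$table$K, 3^2 * (1:4) + 3 + 1)
  expect_error(bic_select(y, integer(0)), "empty")
  expect_error(bic_select(y, 25), "\\[1, 20\\]")
  # a genuine order-2 process is identified
  m <- mvar_template("typeI")
  q <- simulate_mvar(m, 1500)
  expect_equal(bic_select(q, 1:4)$order, 2L)
})

test_that("fixed-location SAEM is exact EM: monotone loglik, null data", {
  set.seed(58)
  geom <- small_geometry()
  idx <- c(10L, 50L)
  locs <- geom$grid$positions[idx, ]
  m <- mvar_model(list(matrix(c(0.5, 0.4, 0, 0.3), 2, 2), diag(-0.3, 2)),
                  diag(2))
  G <- assemble_gain(locs, geom$grid$orientations[idx, ], geom$sensors)
  Tn <- 400; J <- 4; M <- geom$sensors$n_sensors
  q <- simulate_mvar(m, Tn, n_trials = J)
  sig <- sqrt(mean((matrix(q, J * Tn, 2) %*% t(G))^2) / 50)
  y <- array(0, c(J, Tn, M))
  for (j in 1:J) y[j, , ] <- matrix(q[j, , ], Tn, 2) %*% t(G) +
      matrix(rnorm(Tn * M, sd = sig), Tn, M)
  fit <- fit_joint(y, 2, 2, geom, fixed_locations = locs,
                   control = joint_control(n_iter = 25, K0_frac = 1,
                                           tol = 0))
  expect_gt(min(diff(fit$loglik)), -1e-6 * abs(fit$loglik[1]))
  expect_equal(fit$locations$estimate, locs, ignore_attr = TRUE)
  # pure-noise data: coefficients and amplitude variance collapse, and the
  # sensor-noise variance is recovered
  set.seed(59)
  sig0 <- 2e-13
  y0 <- array(rnorm(Tn * M, sd = sig0), c(1, Tn, M))
  fit0 <- fit_joint(y0, 1, 1, geom,
                    fixed_locations = geom$grid$positions[5, , drop = FALSE],
                    control = joint_control(n_iter = 40, K0_frac = 1,
                                            tol = 0))
  expect_lt(abs(fit0$noise$sigma_m2 - sig0^2) / sig0^2, 0.1)
  expect_lt(abs(fit0$mvar$coeffs[[1]][1, 1]), 0.2)
  # estimated amplitude variance is negligible vs the data scale it explains
  amp_pow <- mean(fit0$amplitudes^2) * mean(megjoint:::grid_gain(geom)[, 5]^2)
  expect_lt(amp_pow / sig0^2, 0.05)
})

test_that("joint fit is bitwise reproducible under a fixed seed", {
  geom <- small_geometry()
  set.seed(60)
  scen <- simulate_mvar_scenario("typeI", geom, T = 80, J = 1,
                                 snr_brain = 5, snr_meas = 5, n_brain = 50)
  run <- function() {
    set.seed(77)
    fit_joint(scen$data$y, 3, 2, geom,
              control = joint_control(n_particles = 8, n_iter = 6, tol = 0))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$mvar$coeffs, f2$mvar$coeffs)
  expect_identical(f1$locations$estimate, f2$locations$estimate)
  expect_identical(f1$loglik, f2$loglik)
})
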