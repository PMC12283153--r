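test_that("conjugate-Gaussian closed forms and degenerate cases", {
  # static scalar state (A = 1, V = 0), prior N(0, 1), one obs, unit noise:
  # posterior N(y/2, 1/2)
  m <- mvar_model(list(matrix(1)), matrix(0))
  pars <- ssm_params(m, sigma_m2 = 1)
  y <- matrix(0.8, 1, 1)
  kf <- kalman_filter(y, matrix(1), pars, init_mean = 0, init_cov = matrix(1))
  expect_equal(kf$filt_mean[1, 1], 0.4, tolerance = 1e-12)
  expect_equal(kf$filt_cov[1, 1, 1], 0.5, tolerance = 1e-12)
  expect_equal(kf$loglik, dnorm(0.8, 0, sqrt(2), log = TRUE),
               tolerance = 1e-12)

  # zero gain: no information, filtered mean stays at the prior mean
  m2 <- mvar_model(list(matrix(0.7)), matrix(0))
  pars2 <- ssm_params(m2, sigma_m2 = 1)
  kf2 <- kalman_filter(matrix(rnorm(5), 5, 1), matrix(0), pars2,
                       init_mean = 2, init_cov = matrix(1))
  expect_equal(kf2$filt_mean[, 1], 2 * 0.7^(1:5), tolerance = 1e-12)
})

test_that("smoother handles constant state and uninformative data", {
  # identity dynamics, zero process noise: all smoothed means equal and the
  # one-lag covariance equals the smoothed variance
  m <- mvar_model(list(matrix(1)), matrix(0))
  pars <- ssm_params(m, sigma_m2 = 1)
  y <- matrix(rnorm(6, mean = 1), 6, 1)
  kf <- kalman_filter(y, matrix(1), pars, init_mean = 0, init_cov = matrix(1))
  sm <- suppressMessages(rts_smooth(kf, pars))
  expect_lt(diff(range(sm$smooth_mean)), 1e-10)
  expect_equal(sm$lag1_cov[1, 1, 6], sm$smooth_cov[1, 1, 6],
               tolerance = 1e-8)
  # near-infinite noise: smoothed mean follows the prior dynamics
  pars_n <- ssm_params(mvar_model(list(matrix(0.5)), matrix(0)),
                       sigma_m2 = 1e12)
  kf_n <- kalman_filter(y, matrix(1), pars_n, init_mean = 3,
                        init_cov = matrix(1e-12))
  sm_n <- suppressMessages(rts_smooth(kf_n, pars_n))
  expect_equal(sm_n$smooth_mean[, 1], 3 * 0.5^(1:6), tolerance = 1e-4)
})

test_that("filter and smoother match batch Gaussian conditioning", {
  set.seed(31)
  for (rep in 1:4) {
    ns <- sample(1:2, 1); P <- sample(1:2, 1); Tn <- sample(3:7, 1)
    M <- sample(2:5, 1)
    m <- rand_stable_mvar(ns, P)
    cf <- to_companion(m)
    s2 <- rexp(1) + 0.1
    pars <- ssm_params(cf, sigma_m2 = s2)
    gains <- lapply(seq_len(Tn), function(t) matrix(rnorm(M * ns), M, ns))
    y <- matrix(rnorm(Tn * M), Tn, M)
    n <- ns * P
    mu0 <- rnorm(n); P0 <- crossprod(matrix(rnorm(n * n), n)) + diag(n)
    kf <- kalman_filter(y, gains, pars, mu0, P0)
    sm <- rts_smooth(kf, pars)
    or <- batch_gaussian_oracle(y, gains, cf$A_tilde, cf$V_tilde,
                                diag(s2, M), mu0, P0)
    expect_equal(kf$loglik, or$loglik, tolerance = 1e-10)
    for (t in seq_len(Tn)) {
      i <- t * n + 1:n
      expect_equal(sm$smooth_mean[t, ], or$mean[i], tolerance = 1e-8)
      expect_equal(sm$smooth_cov[, , t], or$cov[i, i, drop = FALSE][, , drop = TRUE],
                   tolerance = 1e-8, ignore_attr = TRUE)
      ip <- (t - 1) * n + 1:n
      expect_equal(sm$lag1_cov[, , t],
                   matrix(or$cov[i, ip], n, n), tolerance = 1e-8,
                   ignore_attr = TRUE)
      flt <- batch_filter_oracle(y, gains, cf$A_tilde, cf$V_tilde,
                                 diag(s2, M), mu0, P0, t)
      expect_equal(kf$filt_mean[t, ], flt$mean, tolerance = 1e-8)
      expect_equal(kf$filt_cov[, , t], matrix(flt$cov, n, n),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("smoothing reduces variance and loglik is scale-invariant", {
  set.seed(32)
  m <- rand_stable_mvar(2, 2)
  cf <- to_companion(m)
  pars <- ssm_params(cf, sigma_m2 = 0.5)
  Tn <- 8; M <- 4
  G <- matrix(rnorm(M * 2), M, 2)
  y <- matrix(rnorm(Tn * M), Tn, M)
  kf <- kalman_filter(y, G, pars)
  sm <- rts_smooth(kf, pars)
  for (t in 1:Tn)
    expect_true(all(diag(sm$smooth_cov[, , t]) <=
                      diag(kf$filt_cov[, , t]) + 1e-10))
  # joint rescaling of (y, G, sqrt(E)) shifts loglik only by the Jacobian
  c2 <- 7
  pars_s <- ssm_params(cf, sigma_m2 = 0.5 * c2^2)
  kf_s <- kalman_filter(y * c2, G * c2, pars_s)
  expect_equal(kf_s$loglik, kf$loglik - Tn * M * log(c2), tolerance = 1e-8)
})

test_that("noise_scale implements trial averaging and errors are raised", {
  set.seed(33)
  m <- rand_stable_mvar(1, 1)
  pars <- ssm_params(m, sigma_m2 = 0.4)
  y <- matrix(rnorm(5), 5, 1)
  G <- matrix(1.2)
  kf_direct <- kalman_filter(y, G, pars, noise_scale = 1 / 4)
  pars_quarter <- ssm_params(m, sigma_m2 = 0.1)
  kf_manual <- kalman_filter(y, G, pars_quarter)
  expect_equal(kf_direct$loglik, kf_manual$loglik, tolerance = 1e-12)
  expect_error(kalman_filter(y, G, pars, noise_scale = 0))
  p_bad <- ssm_params(m, sigma_m2 = 1)
  p_bad$sigma_m2 <- 0
  expect_error(kalman_filter(y, G, p_bad), "sigma_m2")
})
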