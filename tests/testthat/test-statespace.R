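test_that("companion form has the forced block structure and round-trips", {
  A1 <- matrix(c(0.5, 0, 0, 0.3), 2, 2)
  A2 <- matrix(c(0.1, 0, 0, 0.1), 2, 2)
  m <- mvar_model(list(A1, A2), diag(2))
  cf <- to_companion(m)
  expect_equal(dim(cf$A_tilde), c(4, 4))
  expect_equal(cf$A_tilde[1:2, 1:2], A1)
  expect_equal(cf$A_tilde[1:2, 3:4], A2)
  expect_equal(cf$A_tilde[3:4, 1:2], diag(2))
  expect_equal(cf$A_tilde[3:4, 3:4], matrix(0, 2, 2))
  expect_equal(cf$V_tilde[1:2, 1:2], diag(2))
  expect_equal(cf$V_tilde[3:4, 3:4], matrix(0, 2, 2))

  # P = 1: companion matrix is A1 itself
  m1 <- mvar_model(list(A1), diag(2))
  expect_equal(to_companion(m1)$A_tilde, A1)

  # round trips on random stable models
  set.seed(11)
  for (i in 1:5) {
    ns <- sample(1:3, 1); P <- sample(1:3, 1)
    m <- rand_stable_mvar(ns, P)
    m2 <- from_companion(to_companion(m))
    expect_equal(m2$coeffs, m$coeffs)
    expect_equal(m2$proc_noise, m$proc_noise)
  }
})

test_that("mvar_model validates inputs", {
  expect_error(mvar_model(list(matrix(0, 2, 3)), diag(2)), "square")
  expect_error(mvar_model(list(diag(2), diag(3)), diag(2)), "square")
  expect_error(mvar_model(list(diag(2)), matrix(c(1, 2, 0, 1), 2)),
               "symmetric")
  expect_error(mvar_model(list(diag(2)), diag(c(-1, 1))), "nonnegative")
})

test_that("spectral radius and stability flag", {
  expect_equal(spectral_radius(mvar_model(list(matrix(0.9)), matrix(1)))$radius,
               0.9)
  expect_true(spectral_radius(mvar_model(list(matrix(0.9)), matrix(1)))$stable)
  expect_false(spectral_radius(mvar_model(list(matrix(1.0)), matrix(1)))$stable)
  # strictly lower-triangular coupling at lag 1, zero lag 2: the companion
  # spectrum is the diagonal (block-triangular argument)
  A1 <- matrix(c(0.6, 0.4, 0, 0.3), 2, 2)  # column-major: lower triangular
  m <- mvar_model(list(A1, matrix(0, 2, 2)), diag(2))
  expect_equal(spectral_radius(m)$radius, 0.6, tolerance = 1e-12)
})

test_that("stationary covariance solves the Lyapunov equation", {
  # scalar closed form: gamma = v / (1 - a^2)
  m <- mvar_model(list(matrix(0.9)), matrix(1))
  expect_equal(stationary_covariance(m)[1, 1], 1 / (1 - 0.81),
               tolerance = 1e-12)
  # A = 0: Gamma = V_tilde
  m0 <- mvar_model(list(matrix(0, 2, 2)), diag(c(2, 3)))
  expect_equal(stationary_covariance(m0), to_companion(m0)$V_tilde)
  # random stable model satisfies the fixed-point identity and matches a
  # long simulation within Monte-Carlo error
  set.seed(21)
  m <- rand_stable_mvar(2, 2, radius_max = 0.8)
  G <- stationary_covariance(m)
  cf <- to_companion(m)
  expect_equal(G, cf$A_tilde %*% G %*% t(cf$A_tilde) + cf$V_tilde,
               tolerance = 1e-10)
  q <- simulate_mvar(m, 40000, drop = TRUE)
  emp <- cov(cbind(q[-1, ], q[-nrow(q), ]))
  expect_equal(emp, G, tolerance = 0.15)
  expect_error(stationary_covariance(mvar_model(list(matrix(1.1)), matrix(1))),
               "stable")
})

test_that("simulation refuses unstable models and matches trial shape", {
  expect_error(simulate_mvar(mvar_model(list(matrix(1.2)), matrix(1)), 100),
               "unstable")
  set.seed(4)
  m <- rand_stable_mvar(2, 1)
  q <- simulate_mvar(m, 50, n_trials = 3)
  expect_equal(dim(q), c(3, 50, 2))
})

test_that("ssm_params builds the measurement covariance by rule", {
  m <- rand_stable_mvar(2, 1)
  p_iid <- ssm_params(m, sigma_m2 = 0.5)
  expect_equal(meas_noise_cov(p_iid, 4), diag(0.5, 4))
  G <- matrix(rnorm(8), 4, 2)
  p_brain <- ssm_params(m, sigma_m2 = 0.5, sigma_b2 = 2,
                        noise_rule = "brain", gain_ref = G)
  expect_equal(meas_noise_cov(p_brain, 4), diag(0.5, 4) + 2 * tcrossprod(G))
  expect_error(ssm_params(m, sigma_m2 = 0.5, noise_rule = "brain"),
               "gain_ref")
  expect_error(ssm_params(m, sigma_m2 = -1), "nonnegative")
})

test_that("MVAR JSON serialization round-trips", {
  set.seed(9)
  m <- rand_stable_mvar(3, 2)
  js <- mvar_to_json(m)
  m2 <- mvar_from_json(js)
  expect_equal(m2$coeffs, m$coeffs, tolerance = 1e-12)
  expect_equal(m2$proc_noise, m$proc_noise, tolerance = 1e-12)
  f <- tempfile(fileext = ".json")
  mvar_to_json(m, f)
  expect_equal(mvar_from_json(f)$coeffs, m$coeffs, tolerance = 1e-12)
})
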