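test_that("shrinkage kernel follows the Liu-West rule", {
  set.seed(41)
  locs <- matrix(rnorm(30), 10, 3)
  w <- runif(10); w <- w / sum(w)
  Xi <- diag(3)
  # delta = 1: no shrinkage
  k1 <- shrinkage_kernel(locs, w, 1, Xi)
  expect_equal(k1$h2, 0)
  expect_equal(k1$m, locs)
  # delta = 0.95: direct arithmetic from the stated rule
  k2 <- shrinkage_kernel(locs, w, 0.95, Xi)
  expect_equal(k2$a, (3 * 0.95 - 1) / (2 * 0.95), tolerance = 1e-12)
  expect_equal(k2$h2, 1 - k2$a^2, tolerance = 1e-12)
  rbar <- as.numeric(t(locs) %*% w)
  expect_equal(k2$m[3, ], k2$a * locs[3, ] + (1 - k2$a) * rbar,
               tolerance = 1e-12)
  # identical particles are fixed points for any delta
  same <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  k3 <- shrinkage_kernel(same, rep(0.2, 5), 0.9, Xi)
  expect_equal(k3$m, same)
  expect_error(shrinkage_kernel(locs, w, 0, Xi), "delta")
  expect_error(shrinkage_kernel(locs, w, 1.2, Xi), "delta")
})

test_that("N_p = 1 sweep returns the reference exactly (conditioning)", {
  set.seed(42)
  geom <- small_geometry()
  m <- rand_stable_mvar(2, 2)
  pars <- ssm_params(m, sigma_m2 = 0.5)
  Tn <- 12
  loc <- geom$grid$positions[c(5, 40), ]
  ref <- matrix(t(loc), Tn, 6, byrow = TRUE)
  y <- matrix(rnorm(Tn * geom$sensors$n_sensors), Tn)
  ps <- cpfas_sweep(y, pars, ref, n_particles = 1, geometry = geom)
  expect_equal(matrix(ps$traj[, , 1], Tn, 6), ref, tolerance = 0)
  expect_equal(ps$weights, 1)
  # RB loglik along the pinned path equals the plain Kalman loglik
  G <- assemble_gain(loc, NULL, geom$sensors)
  kf <- kalman_filter(y, G, pars, init_mean = rep(0, 4),
                      init_cov = megjoint:::default_init_cov(
                        to_companion(m)$A_tilde, to_companion(m)$V_tilde))
  expect_equal(ps$loglik, kf$loglik, tolerance = 1e-8)
})

test_that("location-independent gain gives uniform weights", {
  set.seed(43)
  m <- rand_stable_mvar(1, 1)
  pars <- ssm_params(m, sigma_m2 = 1)
  Tn <- 10; M <- 6; Np <- 20
  ref <- matrix(0.01, Tn, 3)
  G <- matrix(rnorm(M), M, 1)
  y <- matrix(rnorm(Tn * M), Tn, M)
  ps <- cpfas_sweep(y, pars, ref, n_particles = Np, gain_fixed = G)
  expect_equal(ps$weights, rep(1 / Np, Np), tolerance = 1e-12)
  expect_equal(ps$ess, rep(Np, Tn), tolerance = 1e-8)
})

test_that("sweep concentrates near the truth in a high-SNR toy", {
  set.seed(44)
  geom <- small_geometry()
  true_idx <- 20L
  loc <- geom$grid$positions[true_idx, , drop = FALSE]
  G <- assemble_gain(loc, geom$grid$orientations[true_idx, , drop = FALSE],
                     geom$sensors)
  m <- mvar_model(list(matrix(0.6)), matrix(1))
  Tn <- 60
  q <- simulate_mvar(m, Tn, drop = TRUE)
  sig <- sqrt(mean((q %*% t(G))^2) / 400)
  y <- q %*% t(G) + matrix(rnorm(Tn * nrow(G), sd = sig), Tn)
  pars <- ssm_params(m, sigma_m2 = sig^2)
  errs <- replicate(5, {
    ps <- cpfas_sweep(y, pars, matrix(loc, Tn, 3, byrow = TRUE),
                      n_particles = 24, geometry = geom)
    tm <- apply(ps$traj, c(2, 3), mean)
    est <- as.numeric(tm %*% ps$weights)
    sqrt(sum((est - as.numeric(loc))^2))
  })
  expect_lt(max(errs), 0.002)  # within 2 mm of the truth
  # ESS is finite and positive throughout
  ps <- cpfas_sweep(y, pars, matrix(loc, Tn, 3, byrow = TRUE),
                    n_particles = 24, geometry = geom)
  expect_true(all(is.finite(ps$ess)) && all(ps$ess >= 1))
})

test_that("init_reference builds a constant trajectory from the MCMV scan", {
  set.seed(45)
  geom <- small_geometry()
  idx <- 13L
  G <- assemble_gain(geom$grid$positions[idx, , drop = FALSE],
                     geom$grid$orientations[idx, , drop = FALSE],
                     geom$sensors)
  q <- matrix(rnorm(200), 200, 1)
  y <- q %*% t(G)  # noise-free single on-grid source
  ref <- init_reference(y, geom, 1)
  expect_equal(attr(ref, "locations")[1, ], geom$grid$positions[idx, ],
               tolerance = 1e-12)
  expect_equal(unname(apply(ref, 2, function(col) diff(range(col)))),
               rep(0, 3))
  # user-supplied override bypasses the scan
  ov <- matrix(c(0.01, 0.02, 0.03), 1)
  ref2 <- init_reference(y, geom, 1, override = ov)
  expect_equal(attr(ref2, "locations"), ov)
})
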