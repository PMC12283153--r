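test_that("regularization constant is 5% of the mean eigenvalue", {
  expect_equal(reg_lambda(diag(7)), 0.05)
  expect_equal(reg_lambda(2 * diag(13)), 0.10)
  expect_message(l0 <- reg_lambda(matrix(0, 3, 3)), "zero-trace")
  expect_equal(l0, 0)
})

test_that("NAI scan: identity case and single-source recovery", {
  geom <- small_geometry()
  G <- grid_gain(geom)
  M <- geom$sensors$n_sensors
  # C = N: the index is identically 1
  sc <- nai_scan(diag(M), diag(M), G, 1, geom$grid$positions)
  expect_equal(sc$index, rep(1, ncol(G)), tolerance = 1e-10)
  # single on-grid noiseless source: top NAI at the true grid point
  set.seed(81)
  idx <- 30L
  q <- rnorm(300)
  C <- tcrossprod(G[, idx]) * var(q) + 1e-6 * mean(G[, idx]^2) * diag(M)
  sc2 <- nai_scan(C + reg_lambda(C) * diag(M), diag(M), G, 1,
                  geom$grid$positions)
  expect_equal(sc2$order[1], idx)
})

test_that("MAI scan reduces to NAI for one source and is zero when C = N", {
  geom <- small_geometry()
  G <- grid_gain(geom)
  M <- geom$sensors$n_sensors
  set.seed(82)
  C <- crossprod(matrix(rnorm(4 * M), 4, M)) / 4 + diag(M)
  nai <- nai_scan(C, diag(M), G, 1, geom$grid$positions)
  mai <- mai_scan(C, diag(M), G, 1, geom$grid$positions)
  expect_equal(order(mai$index), order(nai$index))
  expect_equal(mai$order[1], nai$order[1])
  mai0 <- mai_scan(diag(M), diag(M), G, 2, geom$grid$positions)
  expect_lt(max(abs(mai0$index[is.finite(mai0$index)])), 1e-8)
})

test_that("MCMV localizes fully correlated sources where LCMV fails", {
  set.seed(83)
  geom <- small_geometry()
  G <- grid_gain(geom)
  M <- geom$sensors$n_sensors
  idx <- c(10L, 55L)
  # perfectly correlated pair: classic LCMV failure mode
  q <- rnorm(2000)
  Y <- outer(q, G[, idx[1]] + G[, idx[2]])
  Y <- Y + matrix(rnorm(length(Y), sd = 0.02 * sd(Y)), nrow(Y))
  C <- crossprod(Y) / nrow(Y)
  C <- C + reg_lambda(C) * diag(M)
  mai <- mai_scan(C, diag(M), G, 2, geom$grid$positions)
  spacing <- 0.02
  d_mai <- source_localization_error(geom$grid$positions[idx, ],
                                     mai$locations)$max
  expect_lt(d_mai, spacing)
})

test_that("spatial filter has unit gain and recovers noise-free sources", {
  set.seed(84)
  geom <- small_geometry()
  G <- grid_gain(geom)
  M <- geom$sensors$n_sensors
  Gs <- G[, c(3, 33), drop = FALSE]
  C <- crossprod(matrix(rnorm(6 * M), 6, M)) + diag(M)
  CinvG <- solve(C, Gs)
  Fm <- solve(crossprod(Gs, CinvG)) %*% t(CinvG)
  expect_equal(Fm %*% Gs, diag(2), tolerance = 1e-10, ignore_attr = TRUE)
  q <- matrix(rnorm(100 * 2), 100, 2)
  y <- q %*% t(Gs)
  s <- extract_timeseries(y, Gs, C)
  expect_equal(s[1, , ], q, tolerance = 1e-8)
  sp <- extract_timeseries(y, Gs[, 2:1], C)
  expect_equal(sp[1, , ], q[, 2:1], tolerance = 1e-8)
})

test_that("least-squares MVAR fit: exact recovery and consistency", {
  set.seed(85)
  # a noiseless scalar AR(1) trajectory is fitted exactly
  a <- 0.9
  q <- matrix(a^(0:80), ncol = 1)
  fit0 <- fit_mvar_ls(rbind(q), 1)
  expect_equal(fit0$coeffs[[1]][1, 1], a, tolerance = 1e-8)
  # stochastic MVAR recovery with persistent excitation
  m2 <- rand_stable_mvar(2, 2, radius_max = 0.8, vdiag = c(1, 1))
  q2 <- simulate_mvar(m2, 3000, n_trials = 2)
  fit2 <- fit_mvar_ls(q2, 2)
  expect_equal(fit2$coeffs[[1]], m2$coeffs[[1]], tolerance = 0.2)
  # white noise: coefficients shrink with T
  w <- array(rnorm(10000 * 2), c(1, 10000, 2))
  fitw <- fit_mvar_ls(w, 1)
  expect_lt(max(abs(fitw$coeffs[[1]])), 0.05)
  expect_error(fit_mvar_ls(array(rnorm(20), c(1, 10, 2)), 12), "smaller")
})

test_that("scan maps export to TSV", {
  geom <- small_geometry()
  G <- grid_gain(geom)
  M <- geom$sensors$n_sensors
  set.seed(87)
  C <- crossprod(matrix(rnorm(4 * M), 4, M)) + diag(M)
  sc <- nai_scan(C, diag(M), G, 2, geom$grid$positions)
  f <- tempfile(fileext = ".tsv")
  write_scan_tsv(sc, geom$grid$positions, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(geom$grid$positions))
  expect_equal(which(tab$selected), sort(sc$order))
  expect_equal(tab$index, unname(sc$index), tolerance = 1e-6)
})

test_that("two-step pipeline end-to-end on an easy scenario", {
  set.seed(86)
  geom <- small_geometry()
  scen <- simulate_mvar_scenario("typeI", geom, T = 400, J = 1,
                                 snr_brain = 10, snr_meas = 5, n_brain = 60)
  for (variant in c("mcmv", "lcmv")) {
    ts <- twostep_pipeline(scen$data$y, geom, 3, 2, variant)
    expect_equal(dim(ts$series), c(1, 400, 3))
    sle <- source_localization_error(scen$truth$locations, ts$locations)
    expect_lt(sle$max, 0.03)
    # the true 1 -> 2 link carries visible gPDC mass after matching
    asg <- sle$assignment
    expect_gt(max(ts$gpdc$values[, asg[2], asg[1]]), 0.1)
  }
  # determinism: identical inputs give identical outputs
  t1 <- twostep_pipeline(scen$data$y, geom, 3, 2, "mcmv")
  t2 <- twostep_pipeline(scen$data$y, geom, 3, 2, "mcmv")
  expect_identical(t1$locations, t2$locations)
  expect_identical(t1$model$coeffs, t2$model$coeffs)
})
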