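# shared fixtures and independent oracles, built in code

# random stable MVAR model: draw coefficients and shrink until the
# companion spectral radius is below `radius_max`
rand_stable_mvar <- function(ns, P, radius_max = 0.95, vdiag = NULL) {
  repeat {
    coeffs <- lapply(seq_len(P), function(p)
      matrix(rnorm(ns * ns, sd = 0.4 / p), ns, ns))
    m <- mvar_model(coeffs, diag(if (is.null(vdiag)) rexp(ns) + 0.2
                                 else vdiag, ns))
    sr <- spectral_radius(m)$radius
    if (sr < radius_max) return(m)
    coeffs <- lapply(coeffs, function(a) a * radius_max / (sr * 1.05))
    m <- mvar_model(coeffs, m$proc_noise)
    if (spectral_radius(m)$stable) return(m)
  }
}

# small reusable geometry (cheap gain evaluations)
small_geometry <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_geometry(n_sensors = 24L, n_grid = 64L)
    cache
  }
})

# batch joint-Gaussian oracle: stacks states x_0..x_T and observations,
# conditions the joint Gaussian exactly. Independent of the recursive
# filter/smoother implementation.
batch_gaussian_oracle <- function(y, gains, A, V, E, mu0, P0) {
  T <- nrow(y); M <- ncol(y); n <- nrow(A); ns <- ncol(gains[[1]])
  nx <- (T + 1) * n
  mu <- numeric(nx); S <- matrix(0, nx, nx)
  mu[1:n] <- mu0; S[1:n, 1:n] <- P0
  for (t in 1:T) {
    i <- t * n + 1:n; ip <- (t - 1) * n + 1:n
    mu[i] <- A %*% mu[ip]
    cross <- S[1:(t * n), ip, drop = FALSE] %*% t(A)
    S[1:(t * n), i] <- cross; S[i, 1:(t * n)] <- t(cross)
    S[i, i] <- A %*% S[ip, ip] %*% t(A) + V
  }
  H <- matrix(0, T * M, nx)
  for (t in 1:T)
    H[(t - 1) * M + 1:M, t * n + 1:n] <- cbind(gains[[t]],
                                               matrix(0, M, n - ns))
  Sy <- H %*% S %*% t(H) + kronecker(diag(T), E)
  Sxy <- S %*% t(H)
  yv <- as.numeric(t(y))
  K <- Sxy %*% solve(Sy)
  mpost <- as.numeric(mu + K %*% (yv - H %*% mu))
  Spost <- S - K %*% t(Sxy)
  ll <- -0.5 * (length(yv) * log(2 * pi) +
                  as.numeric(determinant(Sy)$modulus) +
                  sum((yv - H %*% mu) * solve(Sy, yv - H %*% mu)))
  list(mean = mpost, cov = Spost, loglik = ll, n = n)
}

# conditioning-on-prefix version (filtered moments at step t)
batch_filter_oracle <- function(y, gains, A, V, E, mu0, P0, t_obs) {
  or <- batch_gaussian_oracle(y[seq_len(t_obs), , drop = FALSE],
                              gains[seq_len(t_obs)], A, V, E, mu0, P0)
  n <- or$n
  i <- t_obs * n + 1:n
  list(mean = or$mean[i], cov = or$cov[i, i])
}

# numerical maximizer of the expected complete-data log-likelihood, used as
# the independent oracle for the closed-form M-step
mstep_numeric_oracle <- function(S, J, T, ns, P, M) {
  Qneg <- function(par) {
    A <- matrix(par[1:(ns * ns * P)], ns, ns * P)
    v <- exp(par[ns * ns * P + 1:ns])
    s2 <- exp(par[length(par)])
    Phi_t <- S$Phi[1:ns, 1:ns, drop = FALSE]
    Psi_t <- S$Psi[1:ns, , drop = FALSE]
    Rm <- Phi_t - Psi_t %*% t(A) - A %*% t(Psi_t) + A %*% S$Sigma %*% t(A)
    W <- S$Z - S$Ups[, 1:ns, drop = FALSE] %*% t(S$Gbar) -
      S$Gbar %*% t(S$Ups[, 1:ns, drop = FALSE]) +
      S$Gbar %*% Phi_t %*% t(S$Gbar)
    -(-J * T / 2 * sum(log(2 * pi * v)) - 0.5 * sum(diag(Rm) / v) -
        M * J * T / 2 * log(2 * pi * s2) - 0.5 * sum(diag(W)) / s2)
  }
  p0 <- c(rep(0, ns * ns * P), log(diag(S$Phi)[1:ns] / (J * T)),
          log(sum(diag(S$Z)) / (M * J * T)))
  opt <- optim(p0, Qneg, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  list(A = matrix(opt$par[1:(ns * ns * P)], ns, ns * P),
       v = exp(opt$par[ns * ns * P + 1:ns]),
       sigma_m2 = exp(opt$par[length(p0)]))
}

# exact sufficient statistics of a small system via R Kalman + RTS
exact_suffstats <- function(y, G, params) {
  J <- dim(y)[1]
  smoothed <- list(lapply(seq_len(J), function(j)
    rts_smooth(kalman_filter(y[j, , ], G, params), params)))
  compute_suffstats(smoothed, 1, list(G), y)
}
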