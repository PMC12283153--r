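#' Kalman filter for the conditionally linear amplitude states
#'
#' Runs the standard predict/update recursions for the companion-form state
#' \eqn{\tilde q_t} under observation matrix
#' \eqn{H_t = [G(r_t)\; 0 \cdots 0]} and measurement noise
#' `E * noise_scale`, accumulating the marginal log-likelihood
#' \eqn{\sum_t \log N(y_t \mid H_t \mu_{t|1:t-1},\, H_t P_{t|1:t-1} H_t^\top + E\,s)}.
#' The Joseph-form covariance update is used and covariances are symmetrized
#' each step. `noise_scale = 1/J` implements filtering of data averaged over
#' `J` trials.
#'
#' @param y `T x M` observation matrix.
#' @param gains a single `M x N_s` gain matrix, or a list of length `T` of
#'   such matrices (time-varying source locations).
#' @param params [ssm_params()].
#' @param init_mean,init_cov prior mean / covariance of the state at `t = 0`
#'   (before the first prediction). Defaults: zero mean and the stationary
#'   covariance when the dynamics are stable, otherwise a broad diagonal.
#' @param noise_scale positive scalar multiplying the measurement-noise
#'   covariance.
#' @return object of class `kalman_moments`: `pred_mean`/`filt_mean`
#'   (`T x n`), `pred_cov`/`filt_cov` (`n x n x T`), `loglik`, plus the prior
#'   (`init_mean`, `init_cov`) and the inputs needed by [rts_smooth()].
#' @export
kalman_filter <- function(y, gains, params, init_mean = NULL, init_cov = NULL,
                          noise_scale = 1) {
  stopifnot(inherits(params, "ssm_params"), noise_scale > 0)
  y <- as.matrix(y)
  T <- nrow(y); M <- ncol(y)
  A <- params$companion$A_tilde; V <- params$companion$V_tilde
  n <- nrow(A); ns <- params$companion$n_sources
  if (params$sigma_m2 <= 0) stop("sigma_m2 must be > 0 to evaluate a likelihood")
  gl <- if (is.list(gains)) gains else rep(list(gains), T)
  if (length(gl) != T) stop("`gains` list must have length T = ", T)
  if (nrow(gl[[1]]) != M || ncol(gl[[1]]) != ns)
    stop("gain must be ", M, "x", ns)
  E <- meas_noise_cov(params, M) * noise_scale

  if (is.null(init_mean)) init_mean <- rep(0, n)
  if (is.null(init_cov)) {
    cf <- params$companion
    sr <- max(Mod(eigen(A, only.values = TRUE)$values))
    init_cov <- if (sr < 1) {
      G <- solve(diag(n * n) - kronecker(A, A), as.vector(V))
      (matrix(G, n, n) + t(matrix(G, n, n))) / 2
    } else diag(max(diag(V), 1) * 1e3, n)
  }

  pred_mean <- matrix(0, T, n); filt_mean <- matrix(0, T, n)
  pred_cov <- array(0, dim = c(n, n, T)); filt_cov <- array(0, dim = c(n, n, T))
  mu <- as.numeric(init_mean); P <- init_cov
  loglik <- 0
  for (t in seq_len(T)) {
    mu_p <- as.numeric(A %*% mu)
    P_p <- A %*% P %*% t(A) + V
    P_p <- (P_p + t(P_p)) / 2
    H <- cbind(gl[[t]], matrix(0, M, n - ns))
    S <- H %*% P_p %*% t(H) + E
    S <- (S + t(S)) / 2
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop("non-positive-definite innovation covariance at step ", t)
    e <- y[t, ] - as.numeric(H %*% mu_p)
    Sinv_e <- backsolve(ch, forwardsolve(t(ch), e))
    loglik <- loglik - 0.5 * (M * log(2 * pi) + 2 * sum(log(diag(ch))) +
                                sum(e * Sinv_e))
    K <- P_p %*% t(H) %*% backsolve(ch, forwardsolve(t(ch), diag(M)))
    mu <- mu_p + as.numeric(K %*% e)
    IKH <- diag(n) - K %*% H
    P <- IKH %*% P_p %*% t(IKH) + K %*% E %*% t(K)  # Joseph form
    P <- (P + t(P)) / 2
    pred_mean[t, ] <- mu_p; pred_cov[, , t] <- P_p
    filt_mean[t, ] <- mu; filt_cov[, , t] <- P
  }
  structure(list(pred_mean = pred_mean, pred_cov = pred_cov,
                 filt_mean = filt_mean, filt_cov = filt_cov,
                 loglik = loglik, init_mean = as.numeric(init_mean),
                 init_cov = init_cov, n_sources = ns),
            class = "kalman_moments")
}

#' Rauch-Tung-Striebel smoother with one-lag covariances
#'
#' Backward recursion with smoother gain
#' \eqn{J_t = P_{t|1:t} \tilde A^\top P_{t+1|1:t}^{-1}}; the one-lag smoothed
#' cross-covariance is obtained from the smoother-gain identity
#' \eqn{P_{t,t-1|1:T} = P_{t|1:T} J_{t-1}^\top}. At `t = T` the smoothed
#' moments equal the filtered ones. A singular predicted covariance triggers
#' a pseudo-inverse fallback (reported via a message).
#'
#' @param filt [kalman_filter()] output.
#' @param params the same [ssm_params()] used for filtering.
#' @return object of class `smoothed_moments`: `smooth_mean` (`T x n`),
#'   `smooth_cov` (`n x n x T`), `lag1_cov` (`n x n x T`; slice `t` holds
#'   `cov(x_t, x_{t-1} | y_{1:T})`, with `t = 1` pairing the initial state),
#'   and the smoothed initial state `mean0`, `cov0`.
#' @export
rts_smooth <- function(filt, params) {
  stopifnot(inherits(filt, "kalman_moments"), inherits(params, "ssm_params"))
  A <- params$companion$A_tilde
  T <- nrow(filt$filt_mean); n <- ncol(filt$filt_mean)
  sm <- matrix(0, T, n); sc <- array(0, dim = c(n, n, T))
  l1 <- array(0, dim = c(n, n, T))
  Jlist <- vector("list", T)  # J_t maps smoothing at t+1 back to t; J_0 stored last
  sm[T, ] <- filt$filt_mean[T, ]; sc[, , T] <- filt$filt_cov[, , T]
  used_pinv <- FALSE
  smoother_gain <- function(Pf, Pp) {
    X <- tryCatch(t(solve(Pp, A %*% Pf)), error = function(e) NULL)
    if (is.null(X)) {
      used_pinv <<- TRUE
      X <- Pf %*% t(A) %*% pseudo_inverse(Pp)
    }
    X
  }
  for (t in seq(T - 1, 0)) {
    Pf <- if (t == 0) filt$init_cov else filt$filt_cov[, , t]
    mf <- if (t == 0) filt$init_mean else filt$filt_mean[t, ]
    Pp1 <- filt$pred_cov[, , t + 1]
    J <- smoother_gain(Pf, Pp1)
    ms1 <- sm[t + 1, ]; Ps1 <- sc[, , t + 1]
    m <- mf + as.numeric(J %*% (ms1 - filt$pred_mean[t + 1, ]))
    P <- Pf + J %*% (Ps1 - Pp1) %*% t(J)
    P <- (P + t(P)) / 2
    l1[, , t + 1] <- Ps1 %*% t(J)  # cov(x_{t+1}, x_t | y_{1:T})
    if (t == 0) { mean0 <- m; cov0 <- P } else { sm[t, ] <- m; sc[, , t] <- P }
  }
  if (used_pinv) message("rts_smooth: singular predicted covariance; pseudo-inverse fallback used")
  structure(list(smooth_mean = sm, smooth_cov = sc, lag1_cov = l1,
                 mean0 = mean0, cov0 = cov0, n_sources = filt$n_sources),
            class = "smoothed_moments")
}

pseudo_inverse <- function(S, tol = 1e-12) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  keep <- ev$values > tol * max(abs(ev$values), 1e-300)
  if (!any(keep)) return(matrix(0, nrow(S), ncol(S)))
  ev$vectors[, keep, drop = FALSE] %*%
    (t(ev$vectors[, keep, drop = FALSE]) / ev$values[keep])
}
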