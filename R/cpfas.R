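# --- gain context -----------------------------------------------------------
# Internal descriptor telling the C++ core how to evaluate G(r):
#   "sphere": analytic Sarvas gain with the smooth azimuthal orientation field
#   "fixed" : a constant, location-independent gain (testing hook)
#   "grid"  : nearest-neighbour lookup in an imported grid gain
gain_context <- function(geometry = NULL, gain_fixed = NULL,
                         grid = NULL, scale = 1) {
  if (!is.null(gain_fixed)) {
    mode <- 1L
    ctx <- list(mode = mode, spos = matrix(0, 1, 3), sori = matrix(0, 1, 3),
                Gfixed = as.matrix(gain_fixed), grid_pos = matrix(0, 1, 3),
                grid_gain = matrix(0, 1, 1), scale = scale)
  } else if (!is.null(grid)) {
    ctx <- list(mode = 2L, spos = matrix(0, 1, 3), sori = matrix(0, 1, 3),
                Gfixed = matrix(0, 1, 1), grid_pos = as.matrix(grid$positions),
                grid_gain = as.matrix(grid$gain), scale = scale)
  } else {
    stopifnot(inherits(geometry, "head_geometry"))
    ctx <- list(mode = 0L, spos = geometry$sensors$positions,
                sori = geometry$sensors$orientations,
                Gfixed = matrix(0, 1, 1), grid_pos = matrix(0, 1, 3),
                grid_gain = matrix(0, 1, 1), scale = scale)
  }
  ctx
}

# evaluate the context's gain at a stacked location vector (R side)
gain_eval <- function(ctx, rvec) {
  ns <- length(rvec) / 3
  loc <- matrix(rvec, ns, 3, byrow = TRUE)
  if (ctx$mode == 1L) return(ctx$Gfixed / ctx$scale)
  if (ctx$mode == 2L) {
    cols <- vapply(seq_len(ns), function(j) {
      d2 <- rowSums((ctx$grid_pos - matrix(loc[j, ], nrow(ctx$grid_pos), 3,
                                           byrow = TRUE))^2)
      which.min(d2)
    }, integer(1))
    return(ctx$grid_gain[, cols, drop = FALSE] / ctx$scale)
  }
  gain_sarvas_cpp(loc, azimuthal_orientation(loc), ctx$spos, ctx$sori) / ctx$scale
}

#' Liu-West shrinkage kernel for static source locations
#'
#' Computes the kernel locations used to propose particle moves for the
#' (truly static) source locations: with discount `delta` in (0, 1],
#' `a = (3*delta - 1) / (2*delta)`, `h^2 = 1 - a^2`, and kernel location
#' `m_i = a * r_i + (1 - a) * rbar` where `rbar` is the current weighted
#' particle mean. `delta = 1` gives `h^2 = 0` and `m_i = r_i` (no shrinkage).
#'
#' @param locations `N_p x d` particle locations (stacked 3-vectors).
#' @param weights length-`N_p` normalized weights.
#' @param delta discount factor in (0, 1].
#' @param spread `d x d` kernel spread matrix `Xi` (the proposal covariance
#'   is `h^2 * Xi`).
#' @return list with `a`, `h2`, `m` (`N_p x d` kernel locations), `spread`.
#' @export
shrinkage_kernel <- function(locations, weights, delta, spread) {
  if (delta <= 0 || delta > 1) stop("`delta` must be in (0, 1]")
  locations <- as.matrix(locations)
  stopifnot(length(weights) == nrow(locations),
            nrow(spread) == ncol(locations))
  w <- weights / sum(weights)
  a <- (3 * delta - 1) / (2 * delta)
  h2 <- 1 - a^2
  rbar <- as.numeric(t(locations) %*% w)
  m <- a * locations + (1 - a) * matrix(rbar, nrow(locations),
                                        ncol(locations), byrow = TRUE)
  list(a = a, h2 = h2, m = m, spread = spread)
}

#' One Rao-Blackwellized CPF-AS sweep over source-location trajectories
#'
#' Runs a conditional particle filter with ancestor sampling: particle `N_p`
#' is pinned to the reference trajectory with its ancestor resampled; the
#' remaining particles are propagated through the Liu-West shrinkage kernel
#' and weighted by the Rao-Blackwellized predictive likelihood of the
#' trial-averaged data (each particle carrying its own Kalman filter over the
#' amplitudes, with measurement noise `sigma_m2 / J`). Systematic resampling
#' is applied at every step.
#'
#' @param y_avg `T x M` trial-averaged sensor data.
#' @param params [ssm_params()] (current SAEM parameter estimate).
#' @param reference `T x (3 N_s)` reference location trajectory.
#' @param n_particles number of particles `N_p >= 1`.
#' @param geometry [make_geometry()] object (analytic spherical gain), or
#'   `NULL` when `gain_fixed`/`gain_grid` is given.
#' @param n_trials trial count `J` behind `y_avg` (noise scale `1/J`).
#' @param kernel list with `delta` (discount, default 0.98) and `sd`
#'   (isotropic kernel spread in meters, default 0.005).
#' @param gain_fixed optional constant `M x N_s` gain (location-independent).
#' @param gain_grid optional imported grid gain: list with `gain`,
#'   `positions` (nearest-neighbour evaluation).
#' @param init_mean,init_cov prior moments for the amplitude state.
#' @return object of class `particle_system`: `traj` (`T x d x N_p` array),
#'   `weights`, `ess` (per step), `loglik`, `next_ref` (index of the
#'   trajectory sampled as the next reference).
#' @export
cpfas_sweep <- function(y_avg, params, reference, n_particles, geometry = NULL,
                        n_trials = 1, kernel = list(delta = 0.98, sd = 0.005),
                        gain_fixed = NULL, gain_grid = NULL,
                        init_mean = NULL, init_cov = NULL) {
  stopifnot(inherits(params, "ssm_params"), n_particles >= 1)
  y_avg <- as.matrix(y_avg)
  reference <- as.matrix(reference)
  if (nrow(reference) != nrow(y_avg))
    stop("reference trajectory length must equal T")
  d <- ncol(reference)
  delta <- if (is.null(kernel$delta)) 0.98 else kernel$delta
  if (delta <= 0 || delta > 1) stop("`delta` must be in (0, 1]")
  ksd <- if (is.null(kernel$sd)) 0.005 else kernel$sd
  a <- (3 * delta - 1) / (2 * delta)
  h2 <- 1 - a^2
  XiChol <- diag(ksd, d)
  A <- params$companion$A_tilde; V <- params$companion$V_tilde
  n <- nrow(A)
  if (is.null(init_mean)) init_mean <- rep(0, n)
  if (is.null(init_cov)) init_cov <- default_init_cov(A, V)
  ctx <- gain_context(geometry, gain_fixed, gain_grid)
  res <- cpfas_sweep_cpp(y_avg, reference, A, V,
                         params$sigma_m2 / n_trials, init_mean, init_cov,
                         as.integer(n_particles), a, h2, XiChol,
                         ctx$mode, ctx$spos, ctx$sori, ctx$scale,
                         ctx$Gfixed, ctx$grid_pos, ctx$grid_gain)
  structure(list(traj = res$traj, weights = as.numeric(res$weights),
                 ess = as.numeric(res$ess), loglik = res$loglik,
                 next_ref = res$next_ref, delta = delta, kernel_sd = ksd),
            class = "particle_system")
}

default_init_cov <- function(A, V) {
  n <- nrow(A)
  sr <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (sr < 1) {
    G <- solve(diag(n * n) - kronecker(A, A), as.vector(V))
    (matrix(G, n, n) + t(matrix(G, n, n))) / 2
  } else diag(max(diag(V), 1) * 1e3, n)
}

#' @export
print.particle_system <- function(x, ...) {
  dm <- dim(x$traj)
  cat(sprintf("particle system: %d particles, T = %d, %d location coords\n",
              dm[3], dm[1], dm[2]))
  cat(sprintf("  min/median ESS: %.1f / %.1f, sweep loglik %.3f\n",
              min(x$ess), median(x$ess), x$loglik))
  invisible(x)
}

#' Initialize the reference trajectory from an MCMV scan
#'
#' Scans the candidate grid with the iterative multi-source activity index
#' (MCMV beamformer, [mai_scan()]) on the covariance of the trial-averaged
#' data and returns a constant-in-time trajectory at the selected locations.
#'
#' @param y_avg `T x M` trial-averaged data.
#' @param geometry [make_geometry()] object.
#' @param n_sources number of sources to locate.
#' @param noise_cov `M x M` noise covariance for the scan (default identity).
#' @param gain optional precomputed `M x N_grid` grid gain.
#' @param override optional user-supplied `N_s x 3` locations bypassing the
#'   scan entirely.
#' @return `T x (3 N_s)` trajectory matrix with attribute `"locations"`.
#' @export
init_reference <- function(y_avg, geometry, n_sources, noise_cov = NULL,
                           gain = NULL, override = NULL) {
  y_avg <- as.matrix(y_avg)
  T <- nrow(y_avg); M <- ncol(y_avg)
  if (!is.null(override)) {
    loc <- as.matrix(override)
    stopifnot(nrow(loc) == n_sources, ncol(loc) == 3)
  } else {
    if (is.null(gain)) gain <- grid_gain(geometry)
    C <- crossprod(y_avg) / T
    C <- C + reg_lambda(C, M) * diag(M)
    if (is.null(noise_cov)) noise_cov <- diag(M)
    scan <- mai_scan(C, noise_cov, gain, n_sources,
                     positions = geometry$grid$positions)
    loc <- scan$locations
  }
  ref <- matrix(t(loc), T, 3 * n_sources, byrow = TRUE)
  attr(ref, "locations") <- loc
  ref
}
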