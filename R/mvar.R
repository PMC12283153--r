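#' Multivariate autoregressive (MVAR) model
#'
#' Container for an order-`P` MVAR model on `N_s` sources,
#' \deqn{q_t = \sum_{p=1}^P A_p q_{t-p} + v_t, \quad v_t \sim N(0, V),}
#' the connectivity object used throughout the package: entry `(i, j)` of
#' `A_p` encodes the lagged influence of source `j` on source `i`.
#'
#' @param coeffs list of `P` square `N_s x N_s` coefficient matrices.
#' @param proc_noise `N_s x N_s` symmetric positive-semidefinite process-noise
#'   covariance `V` (amplitude units squared).
#' @return an object of class `mvar_model` with fields `n_sources`, `order`,
#'   `coeffs`, `proc_noise`.
#' @examples
#' m <- mvar_model(list(diag(0.5, 2), diag(0.1, 2)), diag(2))
#' spectral_radius(m)
#' @export
mvar_model <- function(coeffs, proc_noise) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  if (!is.list(coeffs) || length(coeffs) < 1L)
    stop("`coeffs` must be a non-empty list of square matrices")
  ns <- nrow(coeffs[[1]])
  for (a in coeffs) {
    if (!is.matrix(a) || nrow(a) != ns || ncol(a) != ns)
      stop("all coefficient matrices must be square with matching dimension")
  }
  if (!is.matrix(proc_noise) || nrow(proc_noise) != ns || ncol(proc_noise) != ns)
    stop("`proc_noise` must be ", ns, "x", ns)
  if (max(abs(proc_noise - t(proc_noise))) > 1e-8 * max(1, max(abs(proc_noise))))
    stop("`proc_noise` must be symmetric")
  if (any(diag(proc_noise) < 0))
    stop("`proc_noise` must have nonnegative diagonal")
  structure(
    list(n_sources = ns, order = length(coeffs),
         coeffs = lapply(coeffs, unname),
         proc_noise = unname((proc_noise + t(proc_noise)) / 2)),
    class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("MVAR model: %d sources, order %d\n", x$n_sources, x$order))
  sr <- spectral_radius(x)
  cat(sprintf("  spectral radius %.4f (%s)\n", sr$radius,
              if (sr$stable) "stable" else "NOT stable"))
  invisible(x)
}

#' Companion-form reformulation of an MVAR model
#'
#' Stacks the order-`P` model into the first-order form
#' \eqn{\tilde q_t = \tilde A \tilde q_{t-1} + \tilde v_t}, where the top
#' block-row of `A_tilde` is `[A_1 ... A_P]`, the sub-diagonal blocks are
#' identities, and `V_tilde` carries `V` in its top-left block.
#'
#' @param model an [mvar_model()].
#' @return object of class `companion_form` with fields `A_tilde`, `V_tilde`,
#'   `n_sources`, `order`; the current amplitudes are the top `N_s` entries of
#'   the stacked state.
#' @export
to_companion <- function(model) {
  stopifnot(inherits(model, "mvar_model"))
  ns <- model$n_sources; p <- model$order; n <- ns * p
  A <- matrix(0, n, n)
  for (k in seq_len(p)) A[1:ns, ((k - 1) * ns + 1):(k * ns)] <- model$coeffs[[k]]
  if (p > 1) A[(ns + 1):n, 1:(n - ns)] <- diag(n - ns)
  V <- matrix(0, n, n)
  V[1:ns, 1:ns] <- model$proc_noise
  structure(list(A_tilde = A, V_tilde = V, n_sources = ns, order = p),
            class = "companion_form")
}

#' Invert the companion-form stacking back to an MVAR model
#'
#' @param cf a `companion_form` object (or a bare `A_tilde` matrix with
#'   `n_sources` supplied).
#' @param proc_noise optional `N_s x N_s` process noise overriding the
#'   top-left block of `V_tilde`.
#' @return an [mvar_model()]; `from_companion(to_companion(m))` equals `m`.
#' @export
from_companion <- function(cf, proc_noise = NULL) {
  stopifnot(inherits(cf, "companion_form"))
  ns <- cf$n_sources; p <- cf$order
  coeffs <- lapply(seq_len(p), function(k)
    cf$A_tilde[1:ns, ((k - 1) * ns + 1):(k * ns), drop = FALSE])
  V <- if (is.null(proc_noise)) cf$V_tilde[1:ns, 1:ns, drop = FALSE] else proc_noise
  mvar_model(coeffs, V)
}

#' Spectral radius and stability flag of an MVAR model
#'
#' @param model an [mvar_model()] or `companion_form`.
#' @return list with `radius` (max modulus eigenvalue of the companion matrix)
#'   and `stable` (`TRUE` iff radius < 1).
#' @export
spectral_radius <- function(model) {
  A <- if (inherits(model, "companion_form")) model$A_tilde
       else to_companion(model)$A_tilde
  r <- max(Mod(eigen(A, only.values = TRUE)$values))
  list(radius = r, stable = r < 1)
}

#' Stationary covariance of the stacked MVAR state
#'
#' Solves the discrete Lyapunov equation
#' \eqn{\Gamma = \tilde A \Gamma \tilde A^\top + \tilde V} by vectorization;
#' the top-left `N_s` block is the stationary lag-0 covariance of the
#' amplitudes.
#'
#' @param model an [mvar_model()] (must be stable).
#' @return the `(N_s P) x (N_s P)` stationary covariance matrix.
#' @export
stationary_covariance <- function(model) {
  sr <- spectral_radius(model)
  if (!sr$stable) stop("model is not stable (spectral radius ",
                       format(sr$radius), "); no stationary covariance")
  cf <- if (inherits(model, "companion_form")) model else to_companion(model)
  A <- cf$A_tilde; V <- cf$V_tilde; n <- nrow(A)
  G <- solve(diag(n * n) - kronecker(A, A), as.vector(V))
  G <- matrix(G, n, n)
  (G + t(G)) / 2
}

#' Simulate amplitude time series from a stable MVAR model
#'
#' Draws Gaussian innovations and iterates the recursion after a burn-in, so
#' the returned series is (approximately) stationary. Stability is enforced:
#' simulation from an unstable model is refused.
#'
#' @param model stable [mvar_model()].
#' @param T number of retained time samples.
#' @param n_trials number of independent trials.
#' @param burnin discarded initial samples per trial.
#' @return array `n_trials x T x N_s` (drops to `T x N_s` matrix if
#'   `n_trials == 1` and `drop = TRUE`).
#' @param drop drop the trial dimension for a single trial.
#' @export
simulate_mvar <- function(model, T, n_trials = 1L, burnin = 200L, drop = FALSE) {
  stopifnot(inherits(model, "mvar_model"), T >= 1)
  if (!spectral_radius(model)$stable)
    stop("refusing to simulate from an unstable MVAR model")
  ns <- model$n_sources; p <- model$order
  L <- chol_psd(model$proc_noise)
  out <- array(0, dim = c(n_trials, T, ns))
  total <- T + burnin
  for (j in seq_len(n_trials)) {
    q <- matrix(0, total + p, ns)
    innov <- matrix(rnorm(total * ns), total, ns) %*% t(L)
    for (t in seq_len(total)) {
      tt <- t + p
      acc <- innov[t, ]
      for (k in seq_len(p)) acc <- acc + model$coeffs[[k]] %*% q[tt - k, ]
      q[tt, ] <- acc
    }
    out[j, , ] <- q[(p + burnin + 1):(p + total), , drop = FALSE]
  }
  if (drop && n_trials == 1L) out[1, , , drop = TRUE] else out
}

# Cholesky factor (lower) tolerant of PSD matrices with zero eigenvalues.
chol_psd <- function(S) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  ev$vectors %*% diag(sqrt(d), length(d))
}

#' State-space parameter bundle
#'
#' Collects the companion-form dynamics with the measurement-noise model:
#' either isotropic sensor noise `E = sigma_m2 * I` (rule `"iid"`) or sensor
#' noise plus white brain noise projected through a reference gain,
#' `E = sigma_m2 * I + sigma_b2 * G G^T` (rule `"brain"`).
#'
#' @param companion `companion_form` (or an [mvar_model()], converted).
#' @param sigma_m2 sensor-noise variance (squared measurement units), > 0
#'   whenever a likelihood is evaluated.
#' @param sigma_b2 brain-noise variance (amplitude units squared), >= 0.
#' @param noise_rule `"iid"` or `"brain"`.
#' @param gain_ref reference gain matrix (`M x K`) for the `"brain"` rule.
#' @return object of class `ssm_params`.
#' @export
ssm_params <- function(companion, sigma_m2, sigma_b2 = 0,
                       noise_rule = c("iid", "brain"), gain_ref = NULL) {
  noise_rule <- match.arg(noise_rule)
  if (inherits(companion, "mvar_model")) companion <- to_companion(companion)
  stopifnot(inherits(companion, "companion_form"))
  if (sigma_m2 < 0 || sigma_b2 < 0) stop("noise variances must be nonnegative")
  if (noise_rule == "brain" && is.null(gain_ref))
    stop("`gain_ref` required for the brain-noise rule")
  structure(list(companion = companion, sigma_m2 = sigma_m2,
                 sigma_b2 = sigma_b2, noise_rule = noise_rule,
                 gain_ref = gain_ref),
            class = "ssm_params")
}

#' Measurement-noise covariance implied by an `ssm_params` object
#'
#' @param params `ssm_params`.
#' @param M number of channels.
#' @return `M x M` covariance matrix `E`.
#' @export
meas_noise_cov <- function(params, M) {
  stopifnot(inherits(params, "ssm_params"))
  E <- diag(params$sigma_m2, M)
  if (params$noise_rule == "brain" && params$sigma_b2 > 0) {
    G <- params$gain_ref
    if (nrow(G) != M) stop("gain_ref has ", nrow(G), " rows; expected ", M)
    E <- E + params$sigma_b2 * tcrossprod(G)
  }
  E
}

#' Serialize an MVAR model to JSON
#'
#' @param model [mvar_model()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when writing to file).
#' @export
mvar_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "mvar_model"))
  doc <- list(n_sources = model$n_sources, order = model$order,
              coeffs = model$coeffs, proc_noise = model$proc_noise)
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize an MVAR model from JSON
#'
#' @param x JSON string or path to a JSON file.
#' @return [mvar_model()].
#' @export
mvar_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyMatrix = TRUE)
  coeffs <- doc$coeffs
  if (is.array(coeffs) && length(dim(coeffs)) == 3)
    coeffs <- lapply(seq_len(dim(coeffs)[1]), function(k) coeffs[k, , , drop = TRUE])
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  coeffs <- lapply(coeffs, function(a) matrix(unlist(a), doc$n_sources, doc$n_sources))
  mvar_model(coeffs, matrix(unlist(doc$proc_noise), doc$n_sources, doc$n_sources))
}
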