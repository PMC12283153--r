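#' Covariance regularization constant
#'
#' \eqn{\lambda = 0.05\,\mathrm{trace}(C)/M}; the regularized covariance is
#' `C + lambda * I`. A zero-trace input yields `lambda = 0` (degenerate,
#' reported via a message).
#'
#' @param C `M x M` data covariance.
#' @param M number of channels (defaults to `nrow(C)`).
#' @return the scalar regularization parameter.
#' @export
reg_lambda <- function(C, M = nrow(C)) {
  lam <- 0.05 * sum(diag(C)) / M
  if (lam == 0) message("reg_lambda: zero-trace covariance, lambda = 0")
  lam
}

# greedy peak picking with a minimum-separation rule
pick_peaks <- function(values, positions, n, min_sep) {
  ord <- order(values, decreasing = TRUE)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) == n) break
    if (length(sel) == 0 ||
        all(sqrt(rowSums((positions[sel, , drop = FALSE] -
                          matrix(positions[i, ], length(sel), 3,
                                 byrow = TRUE))^2)) >= min_sep))
      sel <- c(sel, i)
  }
  if (length(sel) < n)
    stop("fewer than ", n, " separated peaks found in the scan")
  sel
}

#' LCMV source scan via the neural activity index
#'
#' For every grid point `g`, \eqn{\mathrm{NAI}(g) = (g^\top N^{-1} g) /
#' (g^\top C^{-1} g)}; the `n_sources` largest peaks are selected subject to
#' a minimum-separation rule (default 2 cm).
#'
#' @param C regularized `M x M` data covariance.
#' @param N `M x M` noise covariance.
#' @param gain `M x N_grid` grid gain matrix.
#' @param n_sources number of sources to select.
#' @param positions `N_grid x 3` grid positions.
#' @param min_sep minimum peak separation (m).
#' @return object of class `scan_result`: `index` (per grid point), `order`
#'   (selected indices), `locations`, `gain_sub`.
#' @export
nai_scan <- function(C, N, gain, n_sources, positions, min_sep = 0.02) {
  M <- nrow(C)
  Cinv_g <- tryCatch(solve(C, gain), error = function(e)
    stop("singular covariance in NAI scan: ", conditionMessage(e)))
  Ninv_g <- solve(N, gain)
  idx <- colSums(gain * Ninv_g) / colSums(gain * Cinv_g)
  sel <- pick_peaks(idx, positions, n_sources, min_sep)
  structure(list(index = idx, order = sel,
                 locations = positions[sel, , drop = FALSE],
                 gain_sub = gain[, sel, drop = FALSE], variant = "lcmv"),
            class = "scan_result")
}

#' Iterative MCMV source scan via the multi-source activity index
#'
#' Grows the source set greedily: with `H` holding the already-fixed gain
#' columns plus one candidate,
#' \eqn{\mathrm{MAI}(H) = \mathrm{tr}[(H^\top N^{-1} H)(H^\top C^{-1}
#' H)^{-1}] - n}; at each step only the new candidate is scanned and
#' previously selected sources stay fixed. With one source the ranking
#' coincides with [nai_scan()]. No separation rule is needed by
#' construction (a repeated column is rank-deficient and skipped).
#'
#' @inheritParams nai_scan
#' @return `scan_result` (with `index` holding the last iteration's MAI map;
#'   unvisited/skipped candidates are `-Inf`).
#' @export
mai_scan <- function(C, N, gain, n_sources, positions) {
  M <- nrow(C)
  Cinv_G <- solve(C, gain)
  Ninv_G <- solve(N, gain)
  sel <- integer(0)
  idx <- rep(-Inf, ncol(gain))
  for (s in seq_len(n_sources)) {
    idx[] <- -Inf
    for (g in seq_len(ncol(gain))) {
      if (g %in% sel) next
      cols <- c(sel, g)
      Sm <- crossprod(gain[, cols, drop = FALSE], Cinv_G[, cols, drop = FALSE])
      Tm <- crossprod(gain[, cols, drop = FALSE], Ninv_G[, cols, drop = FALSE])
      val <- tryCatch(sum(diag(Tm %*% solve(Sm))) - length(cols),
                      error = function(e) NA_real_)
      if (is.na(val)) next  # rank-deficient candidate set: skipped
      idx[g] <- val
    }
    if (!any(is.finite(idx))) stop("MAI scan found no admissible candidate")
    sel <- c(sel, which.max(idx))
  }
  structure(list(index = idx, order = sel,
                 locations = positions[sel, , drop = FALSE],
                 gain_sub = gain[, sel, drop = FALSE], variant = "mcmv"),
            class = "scan_result")
}

#' Export a beamformer scan map to TSV
#'
#' One row per grid point: position and scan-index value (NAI or the final
#' MAI map), with the selected sources flagged.
#'
#' @param scan [nai_scan()] / [mai_scan()] result.
#' @param positions `N_grid x 3` grid positions used for the scan.
#' @param path output path.
#' @export
write_scan_tsv <- function(scan, positions, path) {
  stopifnot(inherits(scan, "scan_result"))
  df <- data.frame(x = positions[, 1], y = positions[, 2],
                   z = positions[, 3], index = scan$index,
                   selected = seq_len(nrow(positions)) %in% scan$order)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Beamformer spatial-filter time-series extraction
#'
#' Unit-gain filter \eqn{F = (G^\top C^{-1} G)^{-1} G^\top C^{-1}} applied
#' per time point (`s_t = F y_t`), so `F %*% G_sub` is the identity.
#'
#' @param trials `J x T x M` array (or `T x M` matrix).
#' @param G_sub `M x N_s` selected gain columns (full column rank).
#' @param C_reg regularized `M x M` covariance.
#' @return `J x T x N_s` array of source time courses.
#' @export
extract_timeseries <- function(trials, G_sub, C_reg) {
  if (is.matrix(trials)) trials <- array(trials, c(1, dim(trials)))
  J <- dim(trials)[1]; T <- dim(trials)[2]; M <- dim(trials)[3]
  CinvG <- solve(C_reg, G_sub)
  A <- crossprod(G_sub, CinvG)
  if (rcond_sym(A) < 1e-14) stop("rank-deficient gain subset in extraction")
  Ft <- CinvG %*% solve(A)              # t(F): M x Ns
  ns <- ncol(G_sub)
  out <- array(0, dim = c(J, T, ns))
  for (j in seq_len(J)) out[j, , ] <- matrix(trials[j, , ], T, M) %*% Ft
  out
}

rcond_sym <- function(A) {
  ev <- abs(eigen((A + t(A)) / 2, only.values = TRUE)$values)
  min(ev) / max(ev)
}

#' Least-squares MVAR fit (pooled across trials)
#'
#' Stacks the lagged regression over all trials and solves it by least
#' squares; the residual covariance is returned as `V`. An ill-conditioned
#' regressor matrix triggers a small ridge with a warning.
#'
#' @param series `J x T x N_s` array or `T x N_s` matrix.
#' @param order MVAR order (`T` must exceed `order * N_s + 1` per trial).
#' @return [mvar_model()].
#' @export
fit_mvar_ls <- function(series, order) {
  if (is.matrix(series)) series <- array(series, c(1, dim(series)))
  J <- dim(series)[1]; T <- dim(series)[2]; ns <- dim(series)[3]
  if (order >= T) stop("`order` must be smaller than the trial length")
  if (T <= order * ns + 1) stop("trial length too short for order ", order)
  nobs <- J * (T - order)
  X <- matrix(0, nobs, ns * order)
  Y <- matrix(0, nobs, ns)
  row <- 1L
  for (j in seq_len(J)) {
    q <- matrix(series[j, , ], T, ns)
    for (t in (order + 1):T) {
      X[row, ] <- as.numeric(t(q[t - seq_len(order), , drop = FALSE]))
      Y[row, ] <- q[t, ]
      row <- row + 1L
    }
  }
  XtX <- crossprod(X)
  B <- tryCatch(solve(XtX, crossprod(X, Y)), error = function(e) NULL)
  if (is.null(B)) {
    warning("ill-conditioned MVAR regression; ridge fallback applied")
    B <- solve(XtX + 1e-8 * mean(diag(XtX)) * diag(ncol(X)), crossprod(X, Y))
  }
  resid <- Y - X %*% B
  V <- crossprod(resid) / nobs
  coeffs <- lapply(seq_len(order), function(p)
    t(B[((p - 1) * ns + 1):(p * ns), , drop = FALSE]))
  mvar_model(coeffs, (V + t(V)) / 2)
}

#' Two-step beamformer + MVAR connectivity pipeline
#'
#' The conventional comparison pipeline: regularize the data covariance,
#' scan for sources (LCMV/NAI or MCMV/MAI), extract unit-gain filter time
#' series, fit an MVAR model by least squares, and compute the gPDC
#' spectrum.
#'
#' @param trials `J x T x M` array (or `T x M` matrix).
#' @param geometry [make_geometry()] object (or pass `gain` + `positions`).
#' @param n_sources number of sources.
#' @param order MVAR order.
#' @param variant `"lcmv"` or `"mcmv"`.
#' @param noise_cov `M x M` noise covariance for the scan (default identity).
#' @param gain,positions optional precomputed grid gain/positions.
#' @param freqs gPDC frequency grid.
#' @return list with `locations`, `model`, `gpdc`, `scan`, `series`.
#' @export
twostep_pipeline <- function(trials, geometry = NULL, n_sources, order,
                             variant = c("mcmv", "lcmv"), noise_cov = NULL,
                             gain = NULL, positions = NULL, freqs = NULL) {
  variant <- match.arg(variant)
  if (is.matrix(trials)) trials <- array(trials, c(1, dim(trials)))
  J <- dim(trials)[1]; T <- dim(trials)[2]; M <- dim(trials)[3]
  if (is.null(gain)) {
    stopifnot(inherits(geometry, "head_geometry"))
    gain <- grid_gain(geometry)
    positions <- geometry$grid$positions
  }
  flat <- matrix(aperm(trials, c(2, 1, 3)), J * T, M)
  C <- crossprod(flat) / (J * T)
  C_reg <- C + reg_lambda(C, M) * diag(M)
  if (is.null(noise_cov)) noise_cov <- diag(M)
  scan <- if (variant == "lcmv")
    nai_scan(C_reg, noise_cov, gain, n_sources, positions)
  else mai_scan(C_reg, noise_cov, gain, n_sources, positions)
  series <- extract_timeseries(trials, scan$gain_sub, C_reg)
  model <- fit_mvar_ls(series, order)
  list(locations = scan$locations, model = model,
       gpdc = gpdc(model, freqs), scan = scan, series = series,
       variant = variant)
}
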