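#' Generalized partial directed coherence of an MVAR model
#'
#' Frequency-domain directed-influence measure: with
#' \eqn{\bar A(f) = I - \sum_p A_p e^{-i 2\pi f p}} and
#' \eqn{\sigma_i^2 = V_{ii}},
#' \deqn{\mathrm{gPDC}_{ij}(f) = \frac{|\bar A_{ij}(f)| / \sigma_i}
#'   {\sqrt{\sum_k |\bar A_{kj}(f)|^2 / \sigma_k^2}},}
#' so entry `(f, i, j)` quantifies the influence of source `j` on source `i`
#' at normalized frequency `f`, and every column satisfies
#' \eqn{\sum_i \mathrm{gPDC}_{ij}(f)^2 = 1}.
#'
#' @param model [mvar_model()] with positive-diagonal process noise.
#' @param freqs normalized frequencies in (0, 0.5); default 64 evenly spaced
#'   points.
#' @return object of class `gpdc_spectrum`: `freqs`, `values`
#'   (`F x N_s x N_s` array).
#' @export
gpdc <- function(model, freqs = NULL) {
  stopifnot(inherits(model, "mvar_model"))
  sig2 <- diag(model$proc_noise)
  if (any(sig2 <= 0)) stop("gPDC requires strictly positive V diagonal")
  if (is.null(freqs)) freqs <- seq(0, 0.5, length.out = 66)[2:65]
  ns <- model$n_sources
  vals <- array(0, dim = c(length(freqs), ns, ns))
  sig <- sqrt(sig2)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    Abar <- diag(ns) + 0i
    for (p in seq_len(model$order))
      Abar <- Abar - model$coeffs[[p]] * exp(-2i * pi * f * p)
    num <- abs(Abar) / sig                 # row-wise 1/sigma_i
    den <- sqrt(colSums(num^2))
    vals[fi, , ] <- sweep(num, 2, den, "/")
  }
  structure(list(freqs = freqs, values = vals, n_sources = ns),
            class = "gpdc_spectrum")
}

#' @export
print.gpdc_spectrum <- function(x, ...) {
  cat(sprintf("gPDC spectrum: %d sources, %d frequencies in [%.3f, %.3f]\n",
              x$n_sources, length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

# per-channel phase randomization preserving the amplitude spectrum
phase_randomize <- function(x) {
  T <- length(x)
  X <- fft(x)
  half <- floor((T - 1) / 2)
  if (half >= 1) {
    ph <- runif(half, 0, 2 * pi)
    X[2:(half + 1)] <- Mod(X[2:(half + 1)]) * exp(1i * ph)
    X[T:(T - half + 1)] <- Conj(X[2:(half + 1)])
  }
  Re(fft(X, inverse = TRUE)) / T
}

#' Surrogate-based significance mask for gPDC
#'
#' Tests the gPDC of the MVAR model fitted to `source_ts` against causal
#' Fourier-transform surrogates: each surrogate phase-randomizes every
#' channel independently (amplitude spectra preserved, cross-channel causal
#' structure destroyed), refits the MVAR model at the same order and
#' recomputes gPDC. An observed entry is significant where it exceeds the
#' per-entry empirical `(1 - alpha)` quantile of the surrogate distribution.
#'
#' @param source_ts `T x N_s` matrix or `J x T x N_s` array of source time
#'   courses.
#' @param order MVAR order for fitting.
#' @param n_surr number of surrogates (default 100).
#' @param alpha significance level (default 0.01); `n_surr >= 1/alpha`
#'   recommended.
#' @param freqs frequency grid passed to [gpdc()].
#' @param observed_model optional [mvar_model()] whose gPDC is tested
#'   instead of a least-squares refit of `source_ts` (used to test the SAEM
#'   maximum-likelihood estimate against the surrogate null).
#' @return list with `significant` (`F x N_s x N_s` logical), `observed`
#'   ([gpdc()] of the data fit), `thresholds` (per-entry quantiles).
#' @export
gpdc_significance <- function(source_ts, order, n_surr = 100L, alpha = 0.01,
                              freqs = NULL, observed_model = NULL) {
  if (n_surr < 1) stop("`n_surr` must be >= 1")
  if (is.matrix(source_ts)) source_ts <- array(source_ts, c(1, dim(source_ts)))
  J <- dim(source_ts)[1]; T <- dim(source_ts)[2]; ns <- dim(source_ts)[3]
  if (T <= order * ns + 1) stop("time series too short for order ", order)
  obs_fit <- if (is.null(observed_model)) fit_mvar_ls(source_ts, order)
             else observed_model
  obs <- gpdc(obs_fit, freqs)
  surr_vals <- array(0, dim = c(n_surr, length(obs$freqs), ns, ns))
  for (s in seq_len(n_surr)) {
    sur <- source_ts
    for (j in seq_len(J)) for (c in seq_len(ns))
      sur[j, , c] <- phase_randomize(source_ts[j, , c])
    sfit <- fit_mvar_ls(sur, order)
    surr_vals[s, , , ] <- gpdc(sfit, obs$freqs)$values
  }
  # empirical (1 - alpha) quantile as an order statistic of the surrogates
  k <- min(n_surr, ceiling((1 - alpha) * n_surr))
  thr <- apply(surr_vals, c(2, 3, 4), function(v) sort(v, partial = k)[k])
  list(significant = obs$values > thr, observed = obs, thresholds = thr)
}

#' Coefficient summary matrix and binarized connectivity
#'
#' The weight matrix is the elementwise maximum of `|A_p|` across lags,
#' normalized by its off-diagonal maximum; links are declared where the
#' normalized off-diagonal weight exceeds `threshold` (default 0.05, i.e. 5%
#' of the maximum). The diagonal never contributes to the normalization nor
#' to the binary matrix.
#'
#' @param model [mvar_model()].
#' @param threshold binarization threshold in (0, 1).
#' @return object of class `connectivity_summary`: `weights` (normalized),
#'   `binary` (logical), `threshold`.
#' @export
summarize_and_binarize <- function(model, threshold = 0.05) {
  stopifnot(inherits(model, "mvar_model"))
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  ns <- model$n_sources
  W <- Reduce(pmax, lapply(model$coeffs, abs))
  off <- W; diag(off) <- 0
  mx <- max(off)
  Wn <- if (mx > 0) W / mx else W
  B <- Wn > threshold
  diag(B) <- FALSE
  structure(list(weights = Wn, binary = B, threshold = threshold),
            class = "connectivity_summary")
}

#' Export a gPDC spectrum (with optional significance) to long-format TSV
#'
#' Columns: `freq`, `from`, `to`, `value`, `significant`.
#'
#' @param spectrum [gpdc()] output.
#' @param path output path.
#' @param significant optional logical array matching `spectrum$values`.
#' @export
write_gpdc_tsv <- function(spectrum, path, significant = NULL) {
  stopifnot(inherits(spectrum, "gpdc_spectrum"))
  ns <- spectrum$n_sources
  grid <- expand.grid(fi = seq_along(spectrum$freqs), to = seq_len(ns),
                      from = seq_len(ns))
  df <- data.frame(freq = spectrum$freqs[grid$fi], from = grid$from,
                   to = grid$to,
                   value = spectrum$values[cbind(grid$fi, grid$to, grid$from)])
  df$significant <- if (is.null(significant)) NA
    else significant[cbind(grid$fi, grid$to, grid$from)]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
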