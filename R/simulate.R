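#' Unit-variance pink-noise series
#'
#' Independent series with a 1/f amplitude-shaped spectrum, generated by
#' frequency-domain filtering of white Gaussian noise and normalized to unit
#' empirical variance.
#'
#' @param n_series number of independent series.
#' @param T series length (>= 64).
#' @return `n_series x T` matrix.
#' @export
pink_noise <- function(n_series, T) {
  if (T < 64) stop("pink noise requires T >= 64")
  freqs <- c(1, seq_len(floor(T / 2)))  # DC amplitude tied to f = 1 bin
  out <- matrix(0, n_series, T)
  for (s in seq_len(n_series)) {
    X <- fft(rnorm(T))
    shape <- numeric(T)
    half <- floor(T / 2)
    shape[1] <- 1
    for (k in seq_len(half)) {
      a <- 1 / sqrt(k)
      shape[k + 1] <- a
      shape[T - k + 1] <- a
    }
    x <- Re(fft(X * shape, inverse = TRUE)) / T
    out[s, ] <- (x - mean(x)) / sd(x)
  }
  out
}

#' Scale brain noise and draw measurement noise to requested SNRs
#'
#' Deterministic rescaling: the brain-noise component is scaled so that
#' \deqn{\mathrm{SNR}_{brain} = \mathrm{tr}\sum_t y^s_t (y^s_t)^\top /
#'       \mathrm{tr}\sum_t y^b_t (y^b_t)^\top}
#' holds exactly, and the white sensor noise is scaled so that
#' \deqn{\mathrm{SNR}_{meas} = \mathrm{tr}\sum_t (y^s_t + y^b_t)(\cdot)^\top
#'       / \mathrm{tr}\sum_t e_t e_t^\top} holds exactly. `snr_brain = Inf`
#' yields zero brain noise.
#'
#' @param y_s signal component (`J x T x M` array or `T x M` matrix).
#' @param y_b_raw unscaled brain-noise component, same shape.
#' @param snr_brain,snr_meas requested power ratios (> 0).
#' @return list with `y_b`, `e_n`, `snr_brain_realized`, `snr_meas_realized`.
#' @export
scale_to_snr <- function(y_s, y_b_raw, snr_brain, snr_meas) {
  p_s <- sum(y_s^2)
  if (p_s == 0) stop("zero-power signal component")
  if (is.infinite(snr_brain)) {
    y_b <- y_b_raw * 0
  } else {
    if (snr_brain <= 0) stop("snr_brain must be > 0")
    p_b <- sum(y_b_raw^2)
    if (p_b == 0) stop("zero-power brain-noise component")
    y_b <- y_b_raw * sqrt(p_s / (snr_brain * p_b))
  }
  if (snr_meas <= 0) stop("snr_meas must be > 0")
  e_raw <- array(rnorm(length(y_s)), dim = if (is.null(dim(y_s))) length(y_s)
                                           else dim(y_s))
  p_sb <- sum((y_s + y_b)^2)
  e_n <- e_raw * sqrt(p_sb / (snr_meas * sum(e_raw^2)))
  list(y_b = y_b, e_n = e_n,
       snr_brain_realized = if (is.infinite(snr_brain)) Inf
                            else p_s / sum(y_b^2),
       snr_meas_realized = p_sb / sum(e_n^2))
}

#' Default second-order coefficient template for the simulation scenarios
#'
#' Damped-oscillator self-dynamics (lag-1 coefficient 0.5, lag-2 coefficient
#' -0.3 on every diagonal) plus unidirectional couplings of 0.4 at lag 1 on
#' the scenario's links: Type-I couples source 1 to source 2 only (source 3
#' independent); Type-II chains 1 to 2 to 3. The template is verified stable.
#'
#' @param scenario_type `"typeI"` or `"typeII"`.
#' @param n_sources number of sources (default 3).
#' @param coupling lag-1 coupling strength.
#' @param proc_sd innovation standard deviation.
#' @return stable [mvar_model()].
#' @export
mvar_template <- function(scenario_type = c("typeI", "typeII"),
                          n_sources = 3L, coupling = 0.4, proc_sd = 1) {
  scenario_type <- match.arg(scenario_type)
  ns <- n_sources
  A1 <- diag(0.5, ns); A2 <- diag(-0.3, ns)
  if (scenario_type == "typeI") {
    A1[2, 1] <- coupling
  } else {
    A1[2, 1] <- coupling
    A1[3, 2] <- coupling
  }
  m <- mvar_model(list(A1, A2), diag(proc_sd^2, ns))
  stopifnot(spectral_radius(m)$stable)
  m
}

# sample n distinct grid indices with pairwise separation >= min_sep
place_sources <- function(positions, n, min_sep, max_tries = 2000L) {
  for (try in seq_len(max_tries)) {
    idx <- sample(nrow(positions), n)
    d <- as.matrix(dist(positions[idx, , drop = FALSE]))
    if (all(d[upper.tri(d)] >= min_sep)) return(idx)
  }
  stop("could not place ", n, " sources at >= ", min_sep, " m separation")
}

#' Simulate an MVAR-driven MEG scenario (Type-I / Type-II)
#'
#' Places three dipoles at random candidate-grid locations at least
#' `min_sep` apart, simulates their amplitudes from the second-order
#' coefficient template ([mvar_template()]), projects them through the
#' spherical forward model, adds pink brain noise from `n_brain` random
#' shell locations scaled to `snr_brain`, and white sensor noise scaled to
#' `snr_meas` (both via [scale_to_snr()]). The sensor data decompose exactly
#' as `y = y_s + y_b + e_n`.
#'
#' @param scenario_type `"typeI"` (1 -> 2, source 3 independent) or
#'   `"typeII"` (1 -> 2 -> 3).
#' @param geometry [make_geometry()] object.
#' @param T samples per trial (default 1000).
#' @param J number of trials (default 1).
#' @param snr_brain,snr_meas requested SNRs (defaults 3 and 5).
#' @param n_brain number of brain-noise source locations (default 500).
#' @param min_sep minimum pairwise source separation (m, default 0.03).
#' @param burnin MVAR burn-in samples.
#' @return object of class `sim_scenario`: `$truth` (model, locations,
#'   orientations, grid indices, binary connectivity), `$data` (`y`,
#'   components `y_s`, `y_b`, `e_n`, realized SNRs), dims and settings.
#' @export
simulate_mvar_scenario <- function(scenario_type = c("typeI", "typeII"),
                                   geometry = make_geometry(), T = 1000L,
                                   J = 1L, snr_brain = 3, snr_meas = 5,
                                   n_brain = 500L, min_sep = 0.03,
                                   burnin = 200L) {
  scenario_type <- match.arg(scenario_type)
  stopifnot(inherits(geometry, "head_geometry"))
  model <- mvar_template(scenario_type)
  ns <- model$n_sources
  idx <- place_sources(geometry$grid$positions, ns, min_sep)
  locs <- geometry$grid$positions[idx, , drop = FALSE]
  oris <- geometry$grid$orientations[idx, , drop = FALSE]
  G <- assemble_gain(locs, oris, geometry$sensors)
  M <- geometry$sensors$n_sensors
  q <- simulate_mvar(model, T, n_trials = J, burnin = burnin)
  y_s <- array(0, dim = c(J, T, M))
  for (j in seq_len(J)) y_s[j, , ] <- matrix(q[j, , ], T, ns) %*% t(G)
  # pink brain noise from random shell locations (independent across trials)
  y_b_raw <- array(0, dim = c(J, T, M))
  bpos <- fibonacci_cap(n_brain, geometry$grid_radius, 0.15 * pi, 0.5 * pi)
  bpos <- bpos[sample(n_brain), , drop = FALSE]  # decouple from grid order
  Gb <- assemble_gain(bpos, azimuthal_orientation(bpos), geometry$sensors)
  for (j in seq_len(J)) y_b_raw[j, , ] <- t(Gb %*% pink_noise(n_brain, T))
  sc <- scale_to_snr(y_s, y_b_raw, snr_brain, snr_meas)
  y <- y_s + sc$y_b + sc$e_n
  truth_binary <- summarize_and_binarize(model, 0.05)$binary
  structure(list(
    truth = list(model = model, locations = locs, orientations = oris,
                 grid_index = idx, binary = truth_binary,
                 amplitudes = q),
    data = list(y = y, y_s = y_s, y_b = sc$y_b, e_n = sc$e_n,
                snr_brain_realized = sc$snr_brain_realized,
                snr_meas_realized = sc$snr_meas_realized),
    scenario_type = scenario_type, T = T, J = J,
    snr_brain = snr_brain, snr_meas = snr_meas,
    geometry = geometry),
    class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("%s scenario: %d sources, T = %d, J = %d, SNR_brain = %s, SNR_meas = %s\n",
              x$scenario_type, nrow(x$truth$locations), x$T, x$J,
              format(x$snr_brain), format(x$snr_meas)))
  invisible(x)
}

# evoked-response waveform templates: superposed Gaussian bumps standing in
# for measured cortical responses (peaks near 120/170/250 ms)
evoked_templates <- function(T, sfreq) {
  tt <- (seq_len(T) - 1) / sfreq
  bump <- function(center, width, amp) amp * exp(-0.5 * ((tt - center) / width)^2)
  rbind(bump(0.120, 0.015, 1.0) + bump(0.250, 0.040, 0.4),
        bump(0.170, 0.020, 0.9) + bump(0.300, 0.050, 0.35),
        bump(0.140, 0.018, 0.7) + bump(0.220, 0.035, 0.5))
}

#' Simulate a multi-subject evoked-response scenario
#'
#' Three active sources carry smooth evoked-like waveforms (superposed
#' Gaussian bumps; a synthetic stand-in for measured cortical responses)
#' plus `n_quiet` quiet sources; per subject, amplitudes are scaled
#' uniformly in `[0.75, 1.25]` and waveforms circularly shifted within
#' +/- 100 ms. Brain noise comes from `n_brain` random shell locations at
#' `snr_brain = 1` and white sensor noise at `snr_meas = 3` by default.
#'
#' @param geometry [make_geometry()] object.
#' @param n_subjects number of simulated subjects.
#' @param T samples per trial; default 154 (0.7 s at 220 Hz).
#' @param sfreq sampling rate (Hz).
#' @param J trials per subject (default 40).
#' @param n_quiet quiet (zero-amplitude) sources appended to the truth.
#' @param snr_brain,snr_meas noise settings (defaults 1 and 3).
#' @param n_brain brain-noise locations (default 2000).
#' @param amp_range amplitude scaling range.
#' @param shift_ms maximal circular shift (ms).
#' @param min_sep source separation (m).
#' @return list of per-subject `sim_scenario`-like objects (class
#'   `evoked_scenario` elements) with `$truth$waveforms`, `$truth$scale`,
#'   `$truth$shift` recorded.
#' @export
make_evoked_scenario <- function(geometry = make_geometry(), n_subjects = 1L,
                                 T = 154L, sfreq = 220, J = 40L,
                                 n_quiet = 2L, snr_brain = 1, snr_meas = 3,
                                 n_brain = 2000L, amp_range = c(0.75, 1.25),
                                 shift_ms = 100, min_sep = 0.03) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  shift_max <- round(shift_ms / 1000 * sfreq)
  if (shift_max >= T) stop("circular shift exceeds the trial length")
  tmpl <- evoked_templates(T, sfreq)
  n_active <- nrow(tmpl)
  M <- geometry$sensors$n_sensors
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    idx <- place_sources(geometry$grid$positions, n_active + n_quiet, min_sep)
    locs <- geometry$grid$positions[idx, , drop = FALSE]
    oris <- geometry$grid$orientations[idx, , drop = FALSE]
    G <- assemble_gain(locs[seq_len(n_active), , drop = FALSE],
                       oris[seq_len(n_active), , drop = FALSE],
                       geometry$sensors)
    scale <- runif(n_active, amp_range[1], amp_range[2])
    shift <- sample(seq(-shift_max, shift_max), n_active, replace = TRUE)
    wav <- tmpl
    for (i in seq_len(n_active)) {
      w <- tmpl[i, ] * scale[i]
      k <- shift[i] %% T
      wav[i, ] <- if (k == 0) w else c(w[(T - k + 1):T], w[1:(T - k)])
    }
    y_s <- array(0, dim = c(J, T, M))
    sig <- t(wav) %*% t(G)                 # T x M, identical across trials
    for (j in seq_len(J)) y_s[j, , ] <- sig
    bpos <- fibonacci_cap(n_brain, geometry$grid_radius, 0.15 * pi, 0.5 * pi)
    Gb <- assemble_gain(bpos, azimuthal_orientation(bpos), geometry$sensors)
    y_b_raw <- array(0, dim = c(J, T, M))
    for (j in seq_len(J)) y_b_raw[j, , ] <- t(Gb %*% pink_noise(n_brain, T))
    sc <- scale_to_snr(y_s, y_b_raw, snr_brain, snr_meas)
    out[[s]] <- structure(list(
      truth = list(locations = locs, orientations = oris, grid_index = idx,
                   waveforms = wav, scale = scale, shift = shift,
                   n_active = n_active, n_quiet = n_quiet),
      data = list(y = y_s + sc$y_b + sc$e_n, y_s = y_s, y_b = sc$y_b,
                  e_n = sc$e_n,
                  snr_brain_realized = sc$snr_brain_realized,
                  snr_meas_realized = sc$snr_meas_realized),
      T = T, J = J, sfreq = sfreq, snr_brain = snr_brain,
      snr_meas = snr_meas, geometry = geometry),
      class = "evoked_scenario")
  }
  out
}
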