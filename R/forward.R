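#' Sensor array for a spherical-conductor magnetometer model
#'
#' @param positions `M x 3` sensor positions (meters, head frame with the
#'   conductor sphere centered at the origin); all strictly outside the
#'   conductor.
#' @param orientations `M x 3` unit magnetometer normals.
#' @param conductor_radius radius of the homogeneous conducting sphere (m).
#' @return object of class `sensor_array`.
#' @export
sensor_array <- function(positions, orientations, conductor_radius) {
  positions <- as.matrix(positions); orientations <- as.matrix(orientations)
  stopifnot(ncol(positions) == 3, ncol(orientations) == 3,
            nrow(positions) == nrow(orientations), conductor_radius > 0)
  nrm <- sqrt(rowSums(orientations^2))
  if (any(abs(nrm - 1) > 1e-12)) stop("sensor orientations must be unit norm")
  if (any(sqrt(rowSums(positions^2)) <= conductor_radius))
    stop("all sensors must lie strictly outside the conductor sphere")
  structure(list(positions = unname(positions),
                 orientations = unname(orientations),
                 conductor_radius = conductor_radius,
                 n_sensors = nrow(positions)),
            class = "sensor_array")
}

# Smooth tangential orientation field: the local azimuthal direction.
# Used for every candidate source location so the gain is a continuous
# function of position; a stand-in for cortical-normal orientations.
azimuthal_orientation <- function(loc) {
  loc <- rbind(loc)
  out <- t(apply(loc, 1, function(r) {
    nxy <- sqrt(r[1]^2 + r[2]^2)
    if (nxy < 1e-12) return(c(1, 0, 0))
    c(-r[2], r[1], 0) / nxy
  }))
  unname(out)
}

#' Magnetometer lead field of a current dipole in a conducting sphere
#'
#' Analytic (Sarvas) magnetic field of a current dipole inside a homogeneous
#' conducting sphere centered at the origin, projected onto the magnetometer
#' orientations. Linear in the dipole moment; a radial dipole or a dipole at
#' the origin produces an identically zero field.
#'
#' @param location 3-vector, dipole location (m), inside the conductor.
#' @param orientation 3-vector, dipole moment direction (unit vector).
#' @param sensors [sensor_array()].
#' @param moment dipole moment magnitude (A m); default 1 (unit dipole).
#' @return length-`M` vector of sensor readings (T per unit moment).
#' @export
sarvas_leadfield <- function(location, orientation, sensors, moment = 1) {
  stopifnot(inherits(sensors, "sensor_array"), length(location) == 3)
  r0 <- as.numeric(location)
  if (sqrt(sum(r0^2)) >= sensors$conductor_radius)
    stop("source location must be strictly inside the conductor sphere")
  q <- as.numeric(orientation) * moment
  spos <- sensors$positions; sori <- sensors$orientations
  mu0_4pi <- 1e-7
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  out <- numeric(nrow(spos))
  for (m in seq_len(nrow(spos))) {
    r <- spos[m, ]
    a <- r - r0
    na <- sqrt(sum(a^2)); nr <- sqrt(sum(r^2))
    if (na < 1e-9) stop("source coincides with sensor ", m)
    Fs <- na * (nr * na + nr^2 - sum(r0 * r))
    adr <- sum(a * r)
    gradF <- (na^2 / nr + adr / na + 2 * na + 2 * nr) * r -
      (na + 2 * nr + adr / na) * r0
    B <- mu0_4pi / Fs^2 * (Fs * qxr0 - sum(qxr0 * r) * gradF)
    out[m] <- sum(B * sori[m, ])
  }
  out
}

#' Assemble the gain (lead-field) matrix for a set of dipoles
#'
#' Column `j` is the [sarvas_leadfield()] of source `j`; the gain is a
#' continuous function of each source location.
#'
#' @param locations `N_s x 3` dipole locations (m).
#' @param orientations `N_s x 3` unit dipole orientations, or `NULL` to use
#'   the package's smooth azimuthal tangential field.
#' @param sensors [sensor_array()].
#' @return `M x N_s` gain matrix.
#' @export
assemble_gain <- function(locations, orientations = NULL, sensors) {
  locations <- rbind(locations)
  if (nrow(locations) < 1) stop("at least one source is required")
  if (is.null(orientations)) orientations <- azimuthal_orientation(locations)
  orientations <- rbind(orientations)
  stopifnot(nrow(orientations) == nrow(locations))
  vapply(seq_len(nrow(locations)), function(j)
    sarvas_leadfield(locations[j, ], orientations[j, ], sensors),
    numeric(sensors$n_sensors))
}

# Deterministic quasi-uniform points on a spherical cap via a Fibonacci
# lattice, restricted to colatitudes [theta_min, theta_max].
fibonacci_cap <- function(n, radius, theta_min, theta_max) {
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  cmin <- cos(theta_max); cmax <- cos(theta_min)
  z <- cmax - (i / n) * (cmax - cmin)
  theta <- acos(z)
  phi <- golden * (seq_len(n) - 1)
  cbind(radius * sin(theta) * cos(phi),
        radius * sin(theta) * sin(phi),
        radius * z)
}

#' Build a spherical-head measurement geometry
#'
#' Places `n_sensors` radially oriented magnetometers quasi-uniformly on the
#' upper part of a sphere of radius `sensor_radius` and a candidate source
#' grid with tangential (azimuthal) orientations on a shell of radius
#' `grid_radius` strictly inside the conductor. Deterministic for a given
#' configuration; `seed` adds a small reproducible jitter to the grid when
#' nonzero jitter is requested.
#'
#' @param n_sensors number of magnetometers (default 102, a typical
#'   whole-head magnetometer count).
#' @param conductor_radius conductor sphere radius (m).
#' @param sensor_radius sensor shell radius (m); must exceed
#'   `conductor_radius`.
#' @param n_grid number of candidate source locations.
#' @param grid_radius source shell radius (m); must be below
#'   `conductor_radius`.
#' @param seed optional integer seed for the jitter.
#' @param jitter standard deviation (m) of isotropic tangent-plane jitter
#'   applied to grid points (0 = none).
#' @return object of class `head_geometry`: `$sensors` ([sensor_array()]),
#'   `$grid` (list with `positions`, `orientations`), and the radii.
#' @export
make_geometry <- function(n_sensors = 102L, conductor_radius = 0.09,
                          sensor_radius = 0.12, n_grid = 302L,
                          grid_radius = 0.07, seed = NULL, jitter = 0) {
  if (sensor_radius <= conductor_radius)
    stop("`sensor_radius` must exceed `conductor_radius`")
  if (grid_radius >= conductor_radius)
    stop("`grid_radius` must be below `conductor_radius`")
  spos <- fibonacci_cap(n_sensors, sensor_radius, 0, 0.55 * pi)
  sori <- spos / sqrt(rowSums(spos^2))
  sens <- sensor_array(spos, sori, conductor_radius)
  # keep the grid off the pole (azimuthal field singular there)
  gpos <- fibonacci_cap(n_grid, grid_radius, 0.15 * pi, 0.5 * pi)
  if (jitter > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    gpos <- gpos + matrix(rnorm(3 * n_grid, sd = jitter), ncol = 3)
    gpos <- gpos / sqrt(rowSums(gpos^2)) * grid_radius
  }
  gori <- azimuthal_orientation(gpos)
  structure(list(sensors = sens,
                 grid = list(positions = unname(gpos), orientations = gori),
                 conductor_radius = conductor_radius,
                 sensor_radius = sensor_radius,
                 grid_radius = grid_radius),
            class = "head_geometry")
}

#' @export
print.head_geometry <- function(x, ...) {
  cat(sprintf("head geometry: %d sensors (r = %.3f m), %d grid points (r = %.3f m), conductor r = %.3f m\n",
              x$sensors$n_sensors, x$sensor_radius, nrow(x$grid$positions),
              x$grid_radius, x$conductor_radius))
  invisible(x)
}

#' Gain matrix over the candidate grid
#'
#' @param geometry [make_geometry()] output.
#' @return `M x N_grid` matrix of lead fields, one column per grid point.
#' @export
grid_gain <- function(geometry) {
  stopifnot(inherits(geometry, "head_geometry"))
  assemble_gain(geometry$grid$positions, geometry$grid$orientations,
                geometry$sensors)
}

#' Export a gain matrix with its grid to TSV
#'
#' Plain-text interchange format for externally computed lead fields: three
#' `#`-prefixed header lines (format tag, channel count, grid size) followed
#' by one row per grid point (`x y z ox oy oz g_1 ... g_M`).
#'
#' @param gain `M x N_grid` gain matrix.
#' @param positions `N_grid x 3` source positions (m).
#' @param orientations `N_grid x 3` unit orientations.
#' @param path output file path.
#' @export
write_gain_tsv <- function(gain, positions, orientations, path) {
  M <- nrow(gain); ng <- ncol(gain)
  stopifnot(nrow(positions) == ng, nrow(orientations) == ng)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# megjoint gain v1",
               paste0("# n_channels\t", M),
               paste0("# n_grid\t", ng)), con)
  tab <- cbind(positions, orientations, t(gain))
  write.table(format(tab, digits = 17), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import a gain matrix from TSV
#'
#' @param path file written by [write_gain_tsv()] (or by an external tool
#'   following the same 3-line-header layout).
#' @return list with `gain` (`M x N_grid`), `positions`, `orientations`.
#' @export
read_gain_tsv <- function(path) {
  hdr <- readLines(path, n = 3)
  if (!startsWith(hdr[1], "#")) stop("missing 3-line header in ", path)
  M <- as.integer(strsplit(hdr[2], "\t")[[1]][2])
  ng <- as.integer(strsplit(hdr[3], "\t")[[1]][2])
  tab <- unname(as.matrix(read.table(path, skip = 3, sep = "\t")))
  if (nrow(tab) != ng || ncol(tab) != 6 + M) stop("gain table shape mismatch")
  list(gain = t(tab[, -(1:6), drop = FALSE]),
       positions = unname(tab[, 1:3, drop = FALSE]),
       orientations = unname(tab[, 4:6, drop = FALSE]))
}
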