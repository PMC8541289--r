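#' Time-lapse acquisition parameters
#'
#' Parameters of the emulated video acquisition: 2-minute time lapses at
#' 500 ms frame interval, 4x objective pixel size 1.63 um/pixel, ~20 tracked
#' particles, 1 pixel localization noise.
#'
#' @param frame_interval_s Frame interval (s).
#' @param duration_s Acquisition duration (s).
#' @param pixel_size_um Pixel size (um/pixel).
#' @param noise_px Localization noise standard deviation (pixels).
#' @param n_particles Number of tracked particles.
#' @return An object of class `baw_acquisition`.
#' @export
acquisition_spec <- function(frame_interval_s = 0.5, duration_s = 120,
                             pixel_size_um = 1.63, noise_px = 1,
                             n_particles = 20) {
  if (any(c(frame_interval_s, duration_s, pixel_size_um) <= 0) ||
      noise_px < 0 || n_particles < 1) {
    stop("acquisition parameters must be positive (noise may be zero)")
  }
  if (duration_s / frame_interval_s < 2) {
    stop("duration/frame interval must yield at least 3 frames")
  }
  structure(
    list(frame_interval_s = frame_interval_s, duration_s = duration_s,
         pixel_size_um = pixel_size_um, noise_px = noise_px,
         n_particles = n_particles),
    class = "baw_acquisition")
}

#' Generate synthetic tracked trajectories
#'
#' Forward-simulates the transverse closed-form path for `n_particles`
#' particles under a known energy density, sampled at the acquisition frame
#' interval, with Gaussian localization noise and optional quantization to
#' the pixel grid. Initial positions are drawn uniformly over
#' `(0.05 w, 0.45 w) + (0.55 w, 0.95 w)` — tracked beads start near the walls
#' and move inward, and the node band is excluded. Output is in the
#' [load_trajectories()] schema; the generating parameters travel along as a
#' manifest attribute.
#'
#' @param true_Eac Generating acoustic energy density (J/m^3, >= 0).
#' @param species A [baw_species()].
#' @param medium A [baw_medium()].
#' @param geometry A [baw_geometry()].
#' @param acq An [acquisition_spec()].
#' @param seed RNG seed (integer).
#' @param quantize Quantize observed positions to the pixel grid
#'   (default TRUE).
#' @param path Optional CSV path; when given, the table is written there and
#'   a JSON manifest (same path with extension `.manifest.json`) records all
#'   generating parameters.
#' @return A data frame `particle_id`, `t` (s), `y` (m), invisibly when
#'   `path` is given; attribute `manifest` holds the generating parameters.
#' @export
generate_trajectories <- function(true_Eac, species, medium, geometry,
                                  acq = acquisition_spec(), seed = 1,
                                  quantize = TRUE, path = NULL) {
  stopifnot(inherits(acq, "baw_acquisition"))
  if (!is.finite(true_Eac) || true_Eac < 0) stop("true_Eac must be >= 0")
  set.seed(seed)
  w <- geometry$width
  field <- resonant_drive(geometry, medium, Eac = true_Eac)
  times <- seq(0, acq$duration_s, by = acq$frame_interval_s)
  px <- acq$pixel_size_um * 1e-6
  n <- acq$n_particles
  # uniform over both half channels, outside the extreme 5% near the walls
  # and outside the node band
  lower <- stats::runif(n) < 0.5
  y0 <- ifelse(lower,
               stats::runif(n, 0.05 * w, 0.45 * w),
               stats::runif(n, 0.55 * w, 0.95 * w))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    y <- transverse_path(y0[i], times, species, medium, field, geometry)
    if (acq$noise_px > 0) {
      y <- y + stats::rnorm(length(y), sd = acq$noise_px * px)
    }
    if (quantize) y <- round(y / px) * px
    y <- pmin(pmax(y, 0), w)
    rows[[i]] <- data.frame(particle_id = i, t = times, y = y)
  }
  out <- do.call(rbind, rows)
  manifest <- list(true_Eac = true_Eac, seed = seed, quantize = quantize,
                   species = species$label, radius_m = species$radius,
                   width_m = w,
                   frame_interval_s = acq$frame_interval_s,
                   duration_s = acq$duration_s,
                   pixel_size_um = acq$pixel_size_um,
                   noise_px = acq$noise_px, n_particles = n)
  attr(out, "manifest") <- manifest
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    jsonlite::write_json(manifest, sub("\\.csv$", ".manifest.json", path),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' Uniform inlet ensemble
#'
#' Draws `n` entry positions uniformly over the inlet cross-section.
#'
#' @param n Number of particles (>= 0).
#' @param geometry A [baw_geometry()].
#' @param seed Optional RNG seed; when `NULL` the current RNG state is used
#'   (so callers that seeded already stay reproducible).
#' @return A matrix with columns `y`, `z` (m) and `n` rows.
#' @export
generate_inlet_ensemble <- function(n, geometry, seed = NULL) {
  stopifnot(inherits(geometry, "baw_geometry"))
  if (n < 0) stop("n must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  cbind(y = stats::runif(n, 0, geometry$width),
        z = stats::runif(n, 0, geometry$height))
}

#' Synthetic outlet absorbance readout
#'
#' Emulates a UV-Vis style readout of the outlet partition: per-outlet
#' signals proportional to the particle counts with multiplicative lognormal
#' noise of the given coefficient of variation. The ratio
#' `central / (central + side)` of the readouts is the UV-Vis style focusing
#' fraction.
#'
#' @param partition A [simulate_population()] result (its first species'
#'   tally is read), or a list with `central` and `side` counts.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 for a noiseless readout).
#' @param seed RNG seed.
#' @return A list `central`, `side` (noisy signal levels) and
#'   `focusing_fraction` (their ratio estimator), `NA` when both are zero.
#' @export
generate_outlet_readout <- function(partition, noise_cv = 0.05, seed = 1) {
  if (inherits(partition, "baw_outlet_partition")) {
    central <- partition$tally$central[1]
    side <- partition$tally$side[1]
  } else {
    central <- partition$central; side <- partition$side
  }
  if (central < 0 || side < 0) stop("counts must be non-negative")
  set.seed(seed)
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (noise_cv == 0) {
    s_c <- central; s_s <- side
  } else {
    sdlog <- sqrt(log(1 + noise_cv^2))
    # mean-one lognormal factors
    f <- stats::rlnorm(2, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    s_c <- central * f[1]; s_s <- side * f[2]
  }
  frac <- if (s_c + s_s > 0) s_c / (s_c + s_s) else NA_real_
  list(central = s_c, side = s_s, focusing_fraction = frac)
}
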