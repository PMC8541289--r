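#' Fluid medium properties
#'
#' Constructs a `baw_medium` object describing the suspension medium of an
#' acoustofluidic device. Compressibility and sound speed must be mutually
#' consistent with `beta = 1/(rho * c^2)`; if `compressibility` is omitted it
#' is derived from the density and sound speed.
#'
#' @param density Mass density \eqn{\rho_m} (kg/m^3).
#' @param sound_speed Speed of sound \eqn{c_m} (m/s).
#' @param viscosity Dynamic viscosity \eqn{\eta_m} (Pa s).
#' @param compressibility Isentropic compressibility \eqn{\beta_m} (1/Pa).
#'   Defaults to `1/(density * sound_speed^2)`. If supplied, it must agree
#'   with that relation within 1%.
#' @param label Optional text label.
#'
#' @return An object of class `baw_medium`: a list with fields `density`,
#'   `compressibility`, `viscosity`, `sound_speed`, `label`.
#'
#' @examples
#' water_medium()
#' @export
baw_medium <- function(density, sound_speed, viscosity,
                       compressibility = NULL, label = "medium") {
  stopifnot(is.numeric(density), is.numeric(sound_speed), is.numeric(viscosity))
  if (any(!is.finite(c(density, sound_speed, viscosity))) ||
      density <= 0 || sound_speed <= 0 || viscosity <= 0) {
    stop("medium properties must be finite and strictly positive")
  }
  beta_derived <- 1 / (density * sound_speed^2)
  if (is.null(compressibility)) {
    compressibility <- beta_derived
  } else {
    if (!is.finite(compressibility) || compressibility <= 0) {
      stop("compressibility must be finite and strictly positive")
    }
    if (abs(compressibility - beta_derived) / beta_derived > 0.01) {
      stop(sprintf(
        "compressibility %.4g /Pa inconsistent with 1/(rho*c^2) = %.4g /Pa (> 1%%)",
        compressibility, beta_derived))
    }
  }
  structure(
    list(density = density, compressibility = compressibility,
         viscosity = viscosity, sound_speed = sound_speed, label = label),
    class = "baw_medium")
}

#' Water at 20 degrees C
#'
#' Default suspension medium: density 998 kg/m^3, sound speed 1481 m/s,
#' viscosity 1.002e-3 Pa s, compressibility derived (~4.57e-10 /Pa).
#'
#' @return A [baw_medium()] object.
#' @export
water_medium <- function() {
  baw_medium(density = 998, sound_speed = 1481, viscosity = 1.002e-3,
             label = "water (20 C)")
}

#' @export
print.baw_medium <- function(x, ...) {
  cat(sprintf("<baw_medium> %s\n", x$label))
  cat(sprintf("  density        %.4g kg/m^3\n", x$density))
  cat(sprintf("  sound speed    %.4g m/s\n", x$sound_speed))
  cat(sprintf("  viscosity      %.4g Pa.s\n", x$viscosity))
  cat(sprintf("  compressibility %.4g /Pa\n", x$compressibility))
  invisible(x)
}

#' Particle species
#'
#' Describes a population of spherical beads or cells by radius, density and
#' compressibility. Volume is derived as \eqn{V_p = (4/3)\pi a_0^3} (it can be
#' supplied explicitly but must agree with the radius to 1e-12 relative).
#'
#' @param radius Particle radius \eqn{a_0} (m).
#' @param density Particle density \eqn{\rho_p} (kg/m^3).
#' @param compressibility Particle compressibility \eqn{\beta_p} (1/Pa).
#' @param volume Particle volume (m^3); derived from the radius by default.
#' @param label Text label for reports.
#'
#' @return An object of class `baw_species`.
#' @examples
#' polystyrene_species(4e-6)  # 4 um polystyrene bead
#' @export
baw_species <- function(radius, density, compressibility,
                        volume = NULL, label = "particle") {
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  if (!is.finite(compressibility) || compressibility <= 0) {
    stop("compressibility must be positive")
  }
  v_derived <- (4 / 3) * pi * radius^3
  if (is.null(volume)) {
    volume <- v_derived
  } else if (abs(volume - v_derived) / v_derived > 1e-12) {
    stop("volume inconsistent with (4/3) pi a0^3")
  }
  structure(
    list(radius = radius, volume = volume, density = density,
         compressibility = compressibility, label = label),
    class = "baw_species")
}

#' Polystyrene bead species
#'
#' Convenience constructor for polystyrene microspheres (density 1050 kg/m^3,
#' compressibility 2.16e-10 /Pa).
#'
#' @param diameter Bead diameter (m).
#' @param label Text label; defaults to the diameter in micrometres.
#' @return A [baw_species()] object.
#' @export
polystyrene_species <- function(diameter, label = NULL) {
  if (is.null(label)) label <- sprintf("%g um polystyrene", diameter * 1e6)
  baw_species(radius = diameter / 2, density = 1050,
              compressibility = 2.16e-10, label = label)
}

#' @export
print.baw_species <- function(x, ...) {
  cat(sprintf("<baw_species> %s\n", x$label))
  cat(sprintf("  radius  %.4g um   density %.4g kg/m^3   compressibility %.4g /Pa\n",
              x$radius * 1e6, x$density, x$compressibility))
  invisible(x)
}

#' Resonator channel geometry
#'
#' Rectangular straight-channel geometry of a transversal BAW resonator. The
#' transverse coordinate y runs from 0 at the left wall to `width` at the
#' right wall; the pressure node of the half-wave mode sits at `width/2`.
#'
#' @param width Channel width \eqn{w_{ch}} (m); the standing wave spans it.
#' @param height Channel height/depth (m).
#' @param length Channel length along the flow (m).
#' @param band_fraction Central-outlet band width as a fraction of the channel
#'   width (default 1/3): particles within `band_fraction*width/2` of the node
#'   count as focused.
#'
#' @return An object of class `baw_geometry`.
#' @examples
#' device_geometry()  # the 190 x 95 um x 40 mm reference channel
#' @export
baw_geometry <- function(width, height, length, band_fraction = 1 / 3) {
  if (any(!is.finite(c(width, height, length))) ||
      width <= 0 || height <= 0 || length <= 0) {
    stop("geometry dimensions must be finite and positive")
  }
  if (!is.finite(band_fraction) || band_fraction <= 0 || band_fraction >= 1) {
    stop("band_fraction must lie in (0, 1)")
  }
  structure(
    list(width = width, height = height, length = length,
         band_fraction = band_fraction),
    class = "baw_geometry")
}

#' Reference device geometry
#'
#' The silicon-chip channel used throughout the examples: 190 um wide,
#' 95 um deep, 40 mm long, central outlet band of width w/3.
#'
#' @return A [baw_geometry()] object.
#' @export
device_geometry <- function() {
  baw_geometry(width = 190e-6, height = 95e-6, length = 40e-3)
}

#' @export
print.baw_geometry <- function(x, ...) {
  cat(sprintf("<baw_geometry> %.4g x %.4g um cross-section, %.4g mm long, band %.3g\n",
              x$width * 1e6, x$height * 1e6, x$length * 1e3, x$band_fraction))
  invisible(x)
}

#' Acoustic drive field
#'
#' Bundles the actuation parameters of the standing-wave field: frequency,
#' wavelength/wavenumber and the acoustic energy density `Eac` (J/m^3) or,
#' equivalently, the pressure amplitude `p0` (Pa), linked by
#' \eqn{E_{ac} = p_0^2 \beta_m / 4}. A peak-to-peak drive voltage may be
#' attached together with a quadratic calibration constant `kappa_V`
#' such that `Eac = kappa_V * Vpp^2` (see [eac_from_voltage()]).
#'
#' By default the wavelength is the medium wavelength `cm/f`. For a resonator
#' driven at a measured resonance that differs from the ideal half-wave
#' frequency of the fabricated width, pass `wavelength` explicitly (typically
#' `2 * width`); a warning notes the mismatch with `cm/f`.
#'
#' @param frequency Actuation frequency f (Hz).
#' @param medium A [baw_medium()]; needed to derive the wavelength and to link
#'   energy density and pressure amplitude.
#' @param Eac Acoustic energy density (J/m^3, equivalently Pa). One of `Eac`,
#'   `p0`, `Vpp` must be given (or `Eac = 0` default).
#' @param p0 Pressure amplitude (Pa).
#' @param Vpp Peak-to-peak drive voltage (V), mapped through `kappa_V`.
#' @param kappa_V Voltage calibration constant (J/m^3/V^2). Default calibrated
#'   so that 52.92 V corresponds to 7.25 J/m^3.
#' @param wavelength Acoustic wavelength (m); default `medium$sound_speed /
#'   frequency`.
#'
#' @return An object of class `baw_drive` with fields `frequency`, `omega`,
#'   `wavelength`, `wavenumber`, `Eac`, `p0`, `Vpp`, `kappa_V`, and the bound
#'   `medium`.
#' @examples
#' drive_field(4.623e6, water_medium(), Eac = 7.25)
#' @export
drive_field <- function(frequency, medium = water_medium(), Eac = NULL,
                        p0 = NULL, Vpp = NULL, kappa_V = default_kappa_V(),
                        wavelength = NULL) {
  stopifnot(inherits(medium, "baw_medium"))
  if (!is.finite(frequency) || frequency <= 0) stop("frequency must be positive")
  lambda_med <- medium$sound_speed / frequency
  if (is.null(wavelength)) {
    wavelength <- lambda_med
  } else if (abs(wavelength - lambda_med) / lambda_med > 1e-9) {
    warning(sprintf(
      "wavelength %.4g m overrides the medium wavelength cm/f = %.4g m (off-resonance mode shape)",
      wavelength, lambda_med))
  }
  if (is.null(Eac) && is.null(p0) && !is.null(Vpp)) {
    Eac <- eac_from_voltage(Vpp, kappa_V)
  }
  if (is.null(Eac) && is.null(p0)) Eac <- 0
  if (is.null(Eac)) Eac <- energy_density_from_pressure(p0, medium)
  if (!is.finite(Eac) || Eac < 0) stop("Eac must be non-negative")
  p0_derived <- pressure_amplitude(Eac, medium)
  if (is.null(p0)) {
    p0 <- p0_derived
  } else if (p0_derived > 0 && abs(p0 - p0_derived) / p0_derived > 1e-9) {
    stop("p0 and Eac are inconsistent with Eac = p0^2 * beta_m / 4")
  }
  structure(
    list(frequency = frequency, omega = 2 * pi * frequency,
         wavelength = wavelength, wavenumber = 2 * pi / wavelength,
         Eac = Eac, p0 = p0, Vpp = Vpp, kappa_V = kappa_V, medium = medium),
    class = "baw_drive")
}

#' Geometry-consistent resonant drive field
#'
#' Builds the ideal half-wave drive for a given channel: wavelength
#' `2 * width`, frequency `cm / (2 * width)`, so the pressure node falls on
#' the channel centre and `k = pi / width`.
#'
#' @param geometry A [baw_geometry()].
#' @param medium A [baw_medium()].
#' @inheritParams drive_field
#' @return A [drive_field()] object.
#' @export
resonant_drive <- function(geometry, medium = water_medium(), Eac = NULL,
                           p0 = NULL, Vpp = NULL, kappa_V = default_kappa_V()) {
  stopifnot(inherits(geometry, "baw_geometry"))
  f <- medium$sound_speed / (2 * geometry$width)
  drive_field(f, medium, Eac = Eac, p0 = p0, Vpp = Vpp, kappa_V = kappa_V,
              wavelength = 2 * geometry$width)
}

#' @export
print.baw_drive <- function(x, ...) {
  cat(sprintf("<baw_drive> f = %.4g MHz, lambda = %.4g um, Eac = %.4g J/m^3, p0 = %.4g kPa\n",
              x$frequency / 1e6, x$wavelength * 1e6, x$Eac, x$p0 / 1e3))
  invisible(x)
}

# half-wave consistency check shared by force/path/simulation code
check_half_wave <- function(field, geometry, tol = 1e-6) {
  if (abs(field$wavelength - 2 * geometry$width) / (2 * geometry$width) > tol) {
    stop(sprintf(
      "drive wavelength %.6g m is not the half-wave mode of a %.6g m wide channel (need lambda = 2*width); use resonant_drive()",
      field$wavelength, 2 * geometry$width))
  }
  invisible(TRUE)
}
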