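#' Acoustic contrast factor
#'
#' The dimensionless contrast factor
#' \deqn{\phi = \frac{5\rho_p - 2\rho_m}{2\rho_p + \rho_m} - \frac{\beta_p}{\beta_m}}
#' determines whether a particle migrates to the pressure node (\eqn{\phi > 0})
#' or the anti-node (\eqn{\phi < 0}) of a standing wave.
#'
#' @param species A [baw_species()].
#' @param medium A [baw_medium()].
#' @return The contrast factor (dimensionless scalar).
#' @examples
#' contrast_factor(polystyrene_species(4e-6), water_medium())
#' @export
contrast_factor <- function(species, medium) {
  stopifnot(inherits(species, "baw_species"), inherits(medium, "baw_medium"))
  rp <- species$density; rm_ <- medium$density
  (5 * rp - 2 * rm_) / (2 * rp + rm_) -
    species$compressibility / medium$compressibility
}

#' Transverse acoustic radiation force
#'
#' Primary radiation force on a compressible sphere in the half-wave standing
#' pressure field, at transverse position `y` measured from the left wall
#' (anti-node). With `x = y - w/2` the distance from the node,
#' \deqn{F_R = -\frac{\pi p_0^2 V_p \beta_m}{2\lambda}\,\phi\,
#'   \sin\!\left(\frac{4\pi x}{\lambda}\right)
#'   = V_p k E_{ac} \phi \sin(2 k y),}
#' positive toward the node for positive-contrast particles on the left half.
#' The medium compressibility \eqn{\beta_m} enters the prefactor (the
#' scattering coefficient of the incident field), which makes the force
#' consistent with the closed-form transverse path and with
#' \eqn{E_{ac} = p_0^2\beta_m/4}.
#'
#' @param y Transverse position(s) in `[0, width]` (m); vectorised.
#' @param species A [baw_species()].
#' @param medium A [baw_medium()].
#' @param field A [drive_field()] with `lambda = 2 * width` (half-wave mode).
#' @param geometry A [baw_geometry()].
#' @return Signed transverse force (N), same length as `y`.
#' @export
radiation_force <- function(y, species, medium, field, geometry) {
  stopifnot(inherits(field, "baw_drive"), inherits(geometry, "baw_geometry"))
  check_half_wave(field, geometry)
  if (any(!is.finite(y)) || any(y < 0) || any(y > geometry$width)) {
    stop("y must lie inside the channel [0, width]")
  }
  if (!is.finite(field$Eac)) stop("drive field carries no energy density")
  phi <- contrast_factor(species, medium)
  k <- field$wavenumber
  x <- y - geometry$width / 2
  # -(pi p0^2 Vp beta_m / (2 lambda)) phi sin(4 pi x / lambda); the prefactor
  # equals Vp * k * Eac via Eac = p0^2 beta_m / 4
  -(pi * field$p0^2 * species$volume * medium$compressibility /
      (2 * field$wavelength)) * phi * sin(2 * k * x)
}

#' Stokes drag force
#'
#' Viscous drag on a small sphere, \eqn{F_D = -6\pi\eta_m a_0 v_p}, opposing
#' the particle velocity.
#'
#' @param velocity Particle velocity (m/s); vectorised.
#' @param species A [baw_species()].
#' @param medium A [baw_medium()].
#' @return Signed drag force (N).
#' @export
stokes_drag <- function(velocity, species, medium) {
  stopifnot(inherits(species, "baw_species"), inherits(medium, "baw_medium"))
  if (any(!is.finite(velocity))) stop("velocity must be finite")
  -6 * pi * medium$viscosity * species$radius * velocity
}

#' Critical particle diameter for node focusing
#'
#' Below this diameter, drag from boundary-driven (Rayleigh) acoustic
#' streaming outweighs the radiation force and particles are stirred rather
#' than focused. The balance equates the maximum acoustophoretic velocity
#' \eqn{(2\phi/9\eta_m) k a^2 E_{ac}} with the maximum Rayleigh slip speed
#' \eqn{(3/8) U^2/c_m = (3/2) E_{ac}/(\rho_m c_m)}; the energy density
#' cancels, leaving
#' \deqn{2 a_c = \sqrt{\frac{27\,\eta_m}{2\pi\,\phi\,\rho_m\,f}}.}
#' The diameter shrinks as the frequency or the contrast factor grows.
#'
#' @param phi Acoustic contrast factor (> 0; see [contrast_factor()]).
#' @param medium A [baw_medium()].
#' @param field A [drive_field()] (only the frequency is used).
#' @return Critical diameter \eqn{2a_c} (m).
#' @examples
#' medium <- water_medium()
#' phi <- contrast_factor(polystyrene_species(4e-6), medium)
#' critical_diameter(phi, medium, drive_field(4.623e6, medium)) * 1e6  # um
#' @export
critical_diameter <- function(phi, medium, field) {
  stopifnot(inherits(medium, "baw_medium"), inherits(field, "baw_drive"))
  if (!is.finite(phi) || phi <= 0) {
    stop("critical diameter requires a positive contrast factor (node-focusing regime)")
  }
  sqrt(27 * medium$viscosity / (2 * pi * phi * medium$density * field$frequency))
}

# exponential focusing rate (1/s) of the transverse path:
# d/dt ln tan(k y) = (4 phi / 9 eta) (k r)^2 Eac
focusing_rate <- function(species, medium, field) {
  phi <- contrast_factor(species, medium)
  (4 * phi / (9 * medium$viscosity)) *
    (field$wavenumber * species$radius)^2 * field$Eac
}

#' Closed-form transverse particle path
#'
#' Overdamped balance of radiation force and Stokes drag yields the
#' transverse path toward the pressure node at `w/2`:
#' \deqn{y(t) = \frac{1}{k}\arctan\!\left\{\tan(k y_0)\,
#'   \exp\!\left[\frac{4\phi}{9\eta_m}(k r)^2 E_{ac}\, t\right]\right\}}
#' for \eqn{y_0 \in (0, w/2]}; starting positions in the upper half channel
#' are handled by reflection about the node. Walls (`y0 = 0` or `w`) are
#' unstable equilibria and are returned unchanged with a warning.
#'
#' @param y0 Initial transverse position (m, scalar).
#' @param t Time(s) since field on (s); vectorised.
#' @param species A [baw_species()].
#' @param medium A [baw_medium()].
#' @param field A [drive_field()]; its wavenumber must be the half-wave mode
#'   of the channel (`k = pi / width`).
#' @param geometry A [baw_geometry()].
#' @return Positions `y(t)` (m), same length as `t`.
#' @export
transverse_path <- function(y0, t, species, medium, field, geometry) {
  stopifnot(inherits(geometry, "baw_geometry"))
  check_half_wave(field, geometry)
  w <- geometry$width
  if (!is.finite(y0) || y0 < 0 || y0 > w) stop("y0 must lie in [0, width]")
  if (any(t < 0)) stop("t must be non-negative")
  if (y0 == 0 || y0 == w) {
    warning("y0 sits on a pressure anti-node (unstable equilibrium); returning y0")
    return(rep(y0, length(t)))
  }
  k <- field$wavenumber
  A <- focusing_rate(species, medium, field)
  reflect <- y0 > w / 2
  yh <- if (reflect) w - y0 else y0
  yt <- atan(tan(k * yh) * exp(A * t)) / k
  # atan() maps through the node continuously; tan(k*w/2) is +Inf so the node
  # itself is the t -> Inf limit
  if (yh == w / 2) yt <- rep(w / 2, length(t))
  if (reflect) w - yt else yt
}

#' Acoustic energy density from a transverse displacement
#'
#' Inverts the closed-form transverse path: given that a particle moved from
#' `y0` to `yt` (both on the same half channel, `yt` nearer the node) in time
#' `t`,
#' \deqn{E_{ac} = \frac{9\eta_m}{4\phi (k r)^2 t}
#'   \ln\!\frac{\tan(k\,y_t)}{\tan(k\,y_0)}.}
#'
#' @param y0,yt Initial and final transverse positions (m), strictly inside
#'   one half channel (neither on a wall nor exactly at the node).
#' @param t Elapsed time (s, > 0).
#' @param species A [baw_species()].
#' @param medium A [baw_medium()].
#' @param field A [drive_field()] providing the half-wave wavenumber.
#' @param geometry A [baw_geometry()].
#' @return Energy density Eac (J/m^3); 0 when `yt == y0`.
#' @export
energy_density_from_displacement <- function(y0, yt, t, species, medium,
                                             field, geometry) {
  check_half_wave(field, geometry)
  w <- geometry$width
  k <- field$wavenumber
  if (t <= 0) stop("t must be positive")
  fold <- function(y) if (y > w / 2) w - y else y
  if ((y0 > w / 2) != (yt > w / 2)) {
    stop("y0 and yt must lie on the same half channel")
  }
  y0h <- fold(y0); yth <- fold(yt)
  if (any(c(y0h, yth) <= 0) || any(c(y0h, yth) >= w / 2)) {
    stop("positions exactly on a wall or on the node are degenerate for tan(k y)")
  }
  if (yth == y0h) return(0)
  if (yth < y0h) stop("motion away from the node: yt must be nearer the node than y0")
  phi <- contrast_factor(species, medium)
  (9 * medium$viscosity / (4 * phi * (k * species$radius)^2 * t)) *
    log(tan(k * yth) / tan(k * y0h))
}

#' Pressure amplitude from acoustic energy density
#'
#' \deqn{p_a = \sqrt{4 E_{ac} \rho_m c_m^2} = 2 c_m \sqrt{E_{ac}\rho_m},}
#' i.e. \eqn{E_{ac} = p_a^2/(4\rho_m c_m^2) = p_a^2 \beta_m / 4}.
#'
#' @param Eac Acoustic energy density (J/m^3, >= 0); vectorised.
#' @param medium A [baw_medium()].
#' @return Pressure amplitude (Pa).
#' @examples
#' pressure_amplitude(7.25, water_medium()) / 1e6  # ~0.252 MPa
#' @export
pressure_amplitude <- function(Eac, medium) {
  stopifnot(inherits(medium, "baw_medium"))
  if (any(!is.finite(Eac)) || any(Eac < 0)) stop("Eac must be non-negative")
  2 * medium$sound_speed * sqrt(Eac * medium$density)
}

#' Acoustic energy density from pressure amplitude
#'
#' Inverse of [pressure_amplitude()]: \eqn{E_{ac} = p_a^2/(4\rho_m c_m^2)}.
#'
#' @param p0 Pressure amplitude (Pa, >= 0); vectorised.
#' @param medium A [baw_medium()].
#' @return Energy density (J/m^3).
#' @export
energy_density_from_pressure <- function(p0, medium) {
  stopifnot(inherits(medium, "baw_medium"))
  if (any(!is.finite(p0)) || any(p0 < 0)) stop("p0 must be non-negative")
  p0^2 / (4 * medium$density * medium$sound_speed^2)
}

#' Half-wave design width of the channel
#'
#' The transversal-resonator design rule: the channel width equals half the
#' acoustic wavelength in the medium at the working frequency,
#' \eqn{w_{ch} = c_m / (2 f)}.
#'
#' @param medium A [baw_medium()].
#' @param frequency Working frequency (Hz); vectorised.
#' @return Channel width (m).
#' @examples
#' design_width(baw_medium(998, 1497, 1e-3), 4e6) * 1e6  # ~187 um
#' @export
design_width <- function(medium, frequency) {
  stopifnot(inherits(medium, "baw_medium"))
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    stop("frequency must be positive")
  }
  medium$sound_speed / (2 * frequency)
}

#' Default voltage-to-energy-density calibration
#'
#' Quadratic calibration constant (J/m^3/V^2) anchored so that a 52.92 V
#' peak-to-peak drive corresponds to 7.25 J/m^3, the condition under which
#' the energy density of the reference device was measured.
#'
#' @return kappa_V (J/m^3/V^2).
#' @export
default_kappa_V <- function() 7.25 / 52.92^2

#' Acoustic energy density from drive voltage
#'
#' Energy density scales with the square of the drive amplitude:
#' `Eac = kappa_V * Vpp^2`.
#'
#' @param Vpp Peak-to-peak voltage (V, >= 0); vectorised.
#' @param kappa_V Calibration constant (J/m^3/V^2), see [default_kappa_V()].
#' @return Energy density (J/m^3).
#' @export
eac_from_voltage <- function(Vpp, kappa_V = default_kappa_V()) {
  if (any(!is.finite(Vpp)) || any(Vpp < 0)) stop("Vpp must be non-negative")
  if (!is.finite(kappa_V) || kappa_V <= 0) stop("kappa_V must be positive")
  kappa_V * Vpp^2
}
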