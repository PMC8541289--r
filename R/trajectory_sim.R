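#' Particle injection rate from concentration and flow rate
#'
#' Number of particles entering the channel per second for a suspension of
#' the given concentration pumped at the given flow rate:
#' `ceiling(concentration * flow_rate / 60000)` with the concentration in
#' particles/mL and the flow rate in uL/min (the ceiling keeps fractional
#' rates conservative, e.g. 28.4/s rounds to 29/s).
#'
#' @param concentration Particle concentration (particles/mL); vectorised.
#' @param flow_rate_ul_min Volumetric flow rate (uL/min).
#' @return Integer injection rate (particles/s).
#' @examples
#' injection_rate(5.68e6, 3)  # 284
#' injection_rate(5.68e5, 3)  # 29
#' @export
injection_rate <- function(concentration, flow_rate_ul_min) {
  if (any(concentration < 0) || any(flow_rate_ul_min < 0)) {
    stop("concentration and flow rate must be non-negative")
  }
  as.integer(ceiling(concentration * flow_rate_ul_min / 60000))
}

#' Laminar axial velocity profile of a rectangular duct
#'
#' Pressure-driven (Poiseuille) flow profile in a rectangular channel of
#' width `w` (coordinate y) and height `h` (coordinate z), as the standard
#' Fourier cosh/sin series truncated at `n_terms` odd terms, scaled so the
#' integral of the profile over the cross-section equals the volumetric flow
#' rate. No-slip at all four walls.
#'
#' @param geometry A [baw_geometry()].
#' @param flow_rate_ul_min Volumetric flow rate (uL/min).
#' @param n_terms Number of odd series terms (default 11).
#' @return A function `f(y, z)` returning the axial velocity (m/s),
#'   vectorised over positions; it carries attributes `mean_velocity` and
#'   `flow_rate` (m^3/s).
#' @export
axial_velocity_profile <- function(geometry, flow_rate_ul_min, n_terms = 11) {
  stopifnot(inherits(geometry, "baw_geometry"))
  if (flow_rate_ul_min < 0) stop("flow rate must be non-negative")
  w <- geometry$width; h <- geometry$height
  Q <- flow_rate_ul_min * 1e-9 / 60  # m^3/s
  odd <- seq(1, by = 2, length.out = n_terms)
  shape <- function(y, z) {
    if (any(y < 0 | y > w | z < 0 | z > h)) {
      stop("point outside the cross-section")
    }
    u <- numeric(length(y) * 0 + max(length(y), length(z)))
    for (n in odd) {
      a <- n * pi / h
      # cosh ratio written via exp to stay finite for large arguments
      arg1 <- a * (y - w / 2); arg2 <- a * w / 2
      ratio <- exp(abs(arg1) - arg2) * (1 + exp(-2 * abs(arg1))) /
        (1 + exp(-2 * arg2))
      u <- u + (1 / n^3) * (1 - ratio) * sin(a * z)
    }
    u
  }
  # normalise the shape so the cross-section integral equals Q
  yq <- seq(0, w, length.out = 101); zq <- seq(0, h, length.out = 101)
  s <- outer(yq, zq, shape)
  wy <- rep(1, 101); wy[c(1, 101)] <- 0.5
  integral <- (w / 100) * (h / 100) * as.numeric(t(wy) %*% s %*% wy)
  scale <- if (integral > 0) Q / integral else 0
  f <- function(y, z) scale * shape(y, z)
  attr(f, "mean_velocity") <- if (w * h > 0) Q / (w * h) else 0
  attr(f, "flow_rate") <- Q
  f
}

# acoustophoretic transverse velocity: radiation force / Stokes drag
acoustophoretic_velocity <- function(y, species, medium, field, geometry) {
  A <- focusing_rate(species, medium, field)
  k <- field$wavenumber
  (A / (2 * k)) * sin(2 * k * y)
}

# Vectorised RK4 advance of a particle ensemble through the channel.
# state: list(x, y, z, t, active); returns state + exit records.
advance_ensemble <- function(y, z, x, species, medium, field, geometry,
                             axial, streaming = NULL, dt = NULL,
                             t_max = 600, t0 = 0, record = NULL) {
  w <- geometry$width; h <- geometry$height; L <- geometry$length
  # finite particle size: the centre cannot approach a wall closer than one
  # radius, which also keeps near-wall particles off the zero-velocity plane
  off <- min(species$radius, w / 4, h / 4)
  k <- field$wavenumber
  A <- focusing_rate(species, medium, field)
  vmax <- abs(A) / (2 * k)
  if (is.null(dt)) {
    # per-step transverse displacement below w/100
    dt <- if (vmax > 0) min(0.02, (w / 100) / vmax) else 0.02
  }
  n <- length(y)
  active <- rep(TRUE, n)
  exit_y <- rep(NA_real_, n); exit_t <- rep(NA_real_, n)
  t <- t0
  vel <- function(yy, zz) {
    vy <- (A / (2 * k)) * sin(2 * k * yy)
    vz <- numeric(length(yy))
    if (!is.null(streaming)) {
      sv <- streaming_velocity_at(cbind(pmin(pmax(yy, 0), w),
                                        pmin(pmax(zz, 0), h)), streaming)
      vy <- vy + sv[, 1]; vz <- vz + sv[, 2]
    }
    vx <- axial(pmin(pmax(yy, 0), w), pmin(pmax(zz, 0), h))
    list(vx = vx, vy = vy, vz = vz)
  }
  halvings <- 0
  while (any(active) && t < t_max - 1e-12) {
    ia <- which(active)
    ya <- y[ia]; za <- z[ia]; xa <- x[ia]
    k1 <- vel(ya, za)
    step <- dt
    m1 <- max(abs(k1$vy))
    if (m1 * step > w / 100) step <- (w / 100) / m1
    k2 <- vel(ya + step / 2 * k1$vy, za + step / 2 * k1$vz)
    k3 <- vel(ya + step / 2 * k2$vy, za + step / 2 * k2$vz)
    k4 <- vel(ya + step * k3$vy, za + step * k3$vz)
    dy <- step / 6 * (k1$vy + 2 * k2$vy + 2 * k3$vy + k4$vy)
    dz <- step / 6 * (k1$vz + 2 * k2$vz + 2 * k3$vz + k4$vz)
    dx <- step / 6 * (k1$vx + 2 * k2$vx + 2 * k3$vx + k4$vx)
    # overshoot guard: a transverse step must not cross the node by more
    # than it approached it (monotone convergence of the overdamped path)
    over <- abs(dy) > w / 50
    if (any(over)) {
      halvings <- halvings + 1
      if (halvings > 60) stop("step-size instability: halving cap reached")
      dt <- dt / 2
      next
    }
    y[ia] <- pmin(pmax(ya + dy, off), w - off)
    z[ia] <- pmin(pmax(za + dz, off), h - off)
    x[ia] <- xa + dx
    t <- t + step
    if (!is.null(record)) record(t, ia, y[ia], z[ia], x[ia])
    done <- x[ia] >= L
    if (any(done)) {
      id <- ia[done]
      exit_y[id] <- y[id]; exit_t[id] <- t
      active[id] <- FALSE
    }
  }
  list(y = y, z = z, x = x, t = t, active = active,
       exit_y = exit_y, exit_t = exit_t)
}

#' Simulate a single particle through the channel
#'
#' Integrates the overdamped transport of one particle: transverse
#' acoustophoretic drift (radiation force balanced by Stokes drag), optional
#' streaming-flow drag, and axial advection by the duct Poiseuille profile.
#' Explicit RK4 with automatic step-size reduction near the node.
#'
#' @param y0,z0 Entry position in the cross-section (m).
#' @param species A [baw_species()].
#' @param medium A [baw_medium()].
#' @param field A [drive_field()] (half-wave mode of the geometry).
#' @param geometry A [baw_geometry()].
#' @param flow_rate_ul_min Flow rate (uL/min); 0 for a stationary fluid.
#' @param streaming Optional [solve_streaming()] solution whose interpolated
#'   velocity is added to the particle velocity.
#' @param dt Time step (s); default adapts so a step moves less than
#'   width/100 transversely.
#' @param t_max Simulation horizon (s).
#' @param sample_dt Interval at which the trajectory is recorded (s).
#' @return A list with `trajectory` (data frame `t`, `x`, `y`, `z`), `exited`
#'   (logical), `exit_y`, `exit_t`.
#' @export
simulate_particle <- function(y0, z0, species, medium, field, geometry,
                              flow_rate_ul_min = 0, streaming = NULL,
                              dt = NULL, t_max = 120, sample_dt = 0.1) {
  check_half_wave(field, geometry)
  axial <- axial_velocity_profile(geometry, flow_rate_ul_min)
  rec_t <- numeric(0); rec_x <- numeric(0); rec_y <- numeric(0); rec_z <- numeric(0)
  last <- -Inf
  record <- function(t, ia, y, z, x) {
    if (t - last >= sample_dt) {
      rec_t <<- c(rec_t, t); rec_x <<- c(rec_x, x)
      rec_y <<- c(rec_y, y); rec_z <<- c(rec_z, z)
      last <<- t
    }
  }
  st <- advance_ensemble(y0, z0, 0, species, medium, field, geometry,
                         axial, streaming, dt, t_max, record = record)
  traj <- data.frame(t = c(0, rec_t), x = c(0, rec_x),
                     y = c(y0, rec_y), z = c(z0, rec_z))
  list(trajectory = traj, exited = !st$active,
       exit_y = st$exit_y, exit_t = st$exit_t)
}

#' Simulate a particle population and tally the outlet partition
#'
#' Injects `n` particles per species with entry positions drawn uniformly
#' over the inlet cross-section, advances each species' ensemble with the
#' vectorised overdamped integrator, and partitions exits between the central
#' outlet band (width `band_fraction * width` around the node) and the side
#' outlets. Mixed populations are treated as independent, non-interacting
#' species. Reproducible for a given seed.
#'
#' @param species A [baw_species()] or list of them.
#' @param n Particles per species (scalar or vector matching `species`).
#' @param medium A [baw_medium()].
#' @param field A [drive_field()] (half-wave mode of the geometry).
#' @param geometry A [baw_geometry()].
#' @param flow_rate_ul_min Flow rate (uL/min).
#' @param streaming Optional [solve_streaming()] solution.
#' @param seed RNG seed (integer).
#' @param t_max Simulation horizon per particle (s).
#' @param dt Optional fixed time step (s).
#' @return An object of class `baw_outlet_partition`: per-species data frame
#'   `tally` (`species`, `central`, `side`, `in_transit`), vectors of exit
#'   positions, and the simulation parameters.
#' @export
simulate_population <- function(species, n, medium, field, geometry,
                                flow_rate_ul_min, streaming = NULL,
                                seed = 1, t_max = 600, dt = NULL) {
  check_half_wave(field, geometry)
  if (inherits(species, "baw_species")) species <- list(species)
  n <- rep_len(n, length(species))
  set.seed(seed)
  axial <- axial_velocity_profile(geometry, flow_rate_ul_min)
  w <- geometry$width
  band <- geometry$band_fraction * w / 2
  tally <- data.frame(species = vapply(species, `[[`, "", "label"),
                      central = 0L, side = 0L, in_transit = 0L)
  exit_positions <- vector("list", length(species))
  for (s in seq_along(species)) {
    if (n[s] == 0) { exit_positions[[s]] <- numeric(0); next }
    pos <- generate_inlet_ensemble(n[s], geometry)
    st <- advance_ensemble(pos[, "y"], pos[, "z"], numeric(n[s]),
                           species[[s]], medium, field, geometry,
                           axial, streaming, dt, t_max)
    exited <- !st$active
    ey <- st$exit_y[exited]
    tally$central[s] <- sum(abs(ey - w / 2) <= band)
    tally$side[s] <- sum(abs(ey - w / 2) > band)
    tally$in_transit[s] <- sum(st$active)
    exit_positions[[s]] <- ey
  }
  structure(
    list(tally = tally, exit_positions = exit_positions,
         band_fraction = geometry$band_fraction, seed = seed,
         flow_rate_ul_min = flow_rate_ul_min, Eac = field$Eac,
         t_max = t_max, n = n),
    class = "baw_outlet_partition")
}

#' @export
print.baw_outlet_partition <- function(x, ...) {
  cat("<baw_outlet_partition>\n")
  df <- x$tally
  df$fraction <- ifelse(df$central + df$side > 0,
                        df$central / (df$central + df$side), NA)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Focusing fraction by central-band counting
#'
#' Fraction of transverse positions within the central node band,
#' `|y - w/2| <= band_fraction * w / 2` — the image-analysis focusing metric.
#'
#' @param y Transverse positions (m).
#' @param geometry A [baw_geometry()] (provides width and band fraction).
#' @return Fraction in `[0, 1]`, or `NA` with a warning for empty input.
#' @export
focusing_fraction_band <- function(y, geometry) {
  stopifnot(inherits(geometry, "baw_geometry"))
  if (length(y) == 0) {
    warning("no positions supplied; focusing fraction undefined")
    return(NA_real_)
  }
  band <- geometry$band_fraction * geometry$width / 2
  mean(abs(y - geometry$width / 2) <= band)
}

#' Focusing fraction by outlet partition
#'
#' Per-species ratio of particles collected at the central outlet to all
#' particles collected at the outlets — the outlet (UV-Vis style) focusing
#' metric, with counts standing in for absorbance.
#'
#' @param partition A [simulate_population()] result.
#' @return Named numeric vector of per-species fractions (`NA` with a warning
#'   for a species with no exits).
#' @export
focusing_fraction_outlet <- function(partition) {
  stopifnot(inherits(partition, "baw_outlet_partition"))
  df <- partition$tally
  total <- df$central + df$side
  if (any(total == 0)) warning("species with zero exited particles: fraction undefined")
  out <- ifelse(total > 0, df$central / total, NA_real_)
  names(out) <- df$species
  out
}
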