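#' First-order acoustic field of the half-wave mode
#'
#' Analytic standing-wave solution of the Helmholtz equation
#' \eqn{\nabla^2 p = -(\omega^2/c^2) p} on the channel cross-section for the
#' ideal transversal half-wave resonance: pressure anti-nodes on the side
#' walls, node on the centre line,
#' \deqn{p_1(y) = p_a \cos(k y), \qquad
#'   v_1(y) = i\,\frac{p_a}{\rho_m c_m}\,\sin(k y),}
#' with `k = pi / width`. The axial and vertical first-order velocity
#' components vanish for this mode.
#'
#' @param field A [drive_field()] with `wavelength = 2 * width`
#'   (use [resonant_drive()]).
#' @param geometry A [baw_geometry()].
#' @param medium A [baw_medium()].
#' @param ny,nz Grid resolution across the width and height (>= 32 x 16).
#' @return An object of class `baw_first_order`: grids `y`, `z`, complex
#'   matrices `p`, `u1` (axial), `v1` (transverse), `w1` (vertical) of size
#'   `ny x nz`, plus `omega`, `c`, `k`, `pa`.
#' @export
first_order_field <- function(field, geometry, medium = field$medium,
                              ny = 128, nz = 64) {
  stopifnot(inherits(field, "baw_drive"), inherits(geometry, "baw_geometry"))
  check_half_wave(field, geometry)
  if (ny < 32 || nz < 16) stop("grid must be at least 32 x 16")
  y <- seq(0, geometry$width, length.out = ny)
  z <- seq(0, geometry$height, length.out = nz)
  k <- pi / geometry$width
  pa <- field$p0
  U <- pa / (medium$density * medium$sound_speed)
  p <- outer(complex(real = pa * cos(k * y)), rep(1 + 0i, nz))
  v1 <- outer(complex(imaginary = U * sin(k * y)), rep(1 + 0i, nz))
  zero <- matrix(0 + 0i, ny, nz)
  structure(
    list(y = y, z = z, p = p, u1 = zero, v1 = v1, w1 = zero,
         omega = field$omega, c = medium$sound_speed, k = k, pa = pa,
         U = U, geometry = geometry),
    class = "baw_first_order")
}

#' Discrete Helmholtz residual of a first-order field
#'
#' Maximum of \eqn{|\partial_{yy} p + (\omega/c)^2 p|} over interior columns,
#' normalised by \eqn{k^2 \max|p|}; second-order small in the grid spacing for
#' the analytic mode. Used for grid-convergence checks. The effective
#' wavenumber of the stored mode (`k = pi/width`) is used, consistent with
#' the stored field.
#'
#' @param f1 A [first_order_field()] object.
#' @return Relative residual (dimensionless scalar).
#' @export
helmholtz_residual <- function(f1) {
  stopifnot(inherits(f1, "baw_first_order"))
  p <- f1$p[, 1]
  h <- f1$y[2] - f1$y[1]
  i <- 2:(length(p) - 1)
  lap <- (p[i - 1] - 2 * p[i] + p[i + 1]) / h^2
  res <- lap + f1$k^2 * p[i]
  max(Mod(res)) / (f1$k^2 * max(Mod(p)))
}

#' Limiting (slip) velocity of boundary-driven streaming
#'
#' Evaluates the limiting-velocity formulas of the slip method on the walls
#' of the cross-section: with `q_y = u1 d(v1*)/dx + v1 d(v1*)/dy`,
#' \deqn{v_L = -\frac{1}{4\omega}\,\mathrm{Re}\Big\{q_y +
#'   v_1^*\big[(2+i)\,\nabla\!\cdot\!\mathbf{v}_1 - (2+3i)\,
#'   \partial_z w_1\big]\Big\},}
#' and analogously for the axial component with `u1`. Each component is
#' paired with its own conjugate velocity. For the analytic half-wave field
#' (`v1 = iU sin(ky)`, `u1 = w1 = 0`) this reduces to the classical Rayleigh
#' slip \eqn{v_L = -(3/8)(U^2/c)\sin(2ky)} on the top and bottom walls, and
#' the side-wall slip vanishes identically.
#'
#' @param f1 A [first_order_field()] object.
#' @return An object of class `baw_limiting_velocity`: `y`, `z`,
#'   `vL_bottom`, `vL_top` (length `ny`, tangential-y slip on the horizontal
#'   walls), `wL_left`, `wL_right` (length `nz`, tangential-z slip on the
#'   side walls), and the intermediate `qy` profile.
#' @export
limiting_velocity <- function(f1) {
  stopifnot(inherits(f1, "baw_first_order"))
  y <- f1$y
  h <- y[2] - y[1]
  v1 <- f1$v1[, 1]            # y-profile (z-independent for this mode)
  n <- length(v1)
  dv1_dy <- complex(real = numeric(n))
  i <- 2:(n - 1)
  dv1_dy[i] <- (v1[i + 1] - v1[i - 1]) / (2 * h)
  dv1_dy[1] <- (-3 * v1[1] + 4 * v1[2] - v1[3]) / (2 * h)
  dv1_dy[n] <- (3 * v1[n] - 4 * v1[n - 1] + v1[n - 2]) / (2 * h)
  # du1/dx = dw1/dz = 0 for the analytic transversal mode
  div1 <- dv1_dy
  qy <- f1$u1[, 1] * 0 + v1 * Conj(dv1_dy)
  vL <- -(1 / (4 * f1$omega)) *
    Re(qy + Conj(v1) * ((2 + 1i) * div1 - (2 + 3i) * 0))
  wL <- numeric(length(f1$z))  # w1 = 0 so side-wall tangential slip vanishes
  structure(
    list(y = y, z = f1$z, vL_bottom = vL, vL_top = vL,
         wL_left = wL, wL_right = wL, qy = qy,
         U = f1$U, c = f1$c, k = f1$k, geometry = f1$geometry),
    class = "baw_limiting_velocity")
}

# Coupled streamfunction-vorticity assembly for 2D Stokes flow on the
# rectangle with tangential slip on the walls. Unknowns are psi and omega on
# the full ny x nz node grid; interior rows enforce  lap(psi) + omega = 0 and
# lap(omega) = 0, boundary rows enforce psi = 0 and a Thom-type wall-vorticity
# closure carrying the slip.
#' Solve the boundary-driven streaming flow in the cross-section
#'
#' Second-order (streaming) Stokes flow \eqn{\nabla p_2 = \mu \nabla^2 v_2},
#' \eqn{\nabla\cdot v_2 = 0} on the rectangular cross-section, driven by the
#' limiting-velocity slip imposed as the tangential wall boundary condition
#' (no penetration through the walls). Solved as one sparse linear system in
#' streamfunction-vorticity form; the velocity derived from the streamfunction
#' is discretely divergence-free by construction.
#'
#' @param lv A [limiting_velocity()] object (its grid sets the resolution).
#' @param geometry A [baw_geometry()].
#' @param medium A [baw_medium()] (viscosity, used for the diagnostic
#'   second-order pressure).
#' @return An object of class `baw_streaming`: grids `y`, `z`; matrices
#'   `psi`, `v2y`, `v2z`, `p2` (`ny x nz`); `mu`.
#' @export
solve_streaming <- function(lv, geometry = lv$geometry,
                            medium = water_medium()) {
  stopifnot(inherits(lv, "baw_limiting_velocity"))
  y <- lv$y; z <- lv$z
  ny <- length(y); nz <- length(z)
  N <- ny * nz
  # nondimensionalize (lengths by the width, velocities by the peak slip) so
  # the streamfunction and vorticity unknowns are both O(1) in the solve
  L <- diff(range(y))
  V <- max(abs(c(lv$vL_bottom, lv$vL_top, lv$wL_left, lv$wL_right)))
  if (V == 0) {
    zero <- matrix(0, ny, nz)
    return(structure(
      list(y = y, z = z, psi = zero, v2y = zero, v2z = zero, p2 = zero,
           mu = medium$viscosity, geometry = geometry),
      class = "baw_streaming"))
  }
  hy <- (y[2] - y[1]) / L; hz <- (z[2] - z[1]) / L
  sb <- lv$vL_bottom / V; st <- lv$vL_top / V
  sl <- lv$wL_left / V; sr <- lv$wL_right / V
  idx <- function(i, j) (j - 1) * ny + i       # psi index
  odx <- function(i, j) N + (j - 1) * ny + i   # omega index

  rhs <- numeric(2 * N)
  g <- expand.grid(i = 2:(ny - 1), j = 2:(nz - 1))
  ii <- g$i; jj <- g$j
  cy <- 1 / hy^2; cz <- 1 / hz^2; cc <- -2 * cy - 2 * cz
  r1 <- idx(ii, jj); r2 <- odx(ii, jj)
  # interior rows: lap(psi) + omega = 0 and lap(omega) = 0
  trip <- list(
    cbind(r1, idx(ii, jj), cc),
    cbind(r1, idx(ii - 1, jj), cy), cbind(r1, idx(ii + 1, jj), cy),
    cbind(r1, idx(ii, jj - 1), cz), cbind(r1, idx(ii, jj + 1), cz),
    cbind(r1, odx(ii, jj), 1),
    cbind(r2, odx(ii, jj), cc),
    cbind(r2, odx(ii - 1, jj), cy), cbind(r2, odx(ii + 1, jj), cy),
    cbind(r2, odx(ii, jj - 1), cz), cbind(r2, odx(ii, jj + 1), cz))
  # boundary: psi = 0 everywhere on walls
  bi <- c(1:ny, 1:ny, rep(1, nz - 2), rep(ny, nz - 2))
  bj <- c(rep(1, ny), rep(nz, ny), 2:(nz - 1), 2:(nz - 1))
  trip <- c(trip, list(cbind(idx(bi, bj), idx(bi, bj), 1)))
  # wall-vorticity closures (row = omega eq at the wall node).
  # v2y = dpsi/dz, v2z = -dpsi/dy; on each wall psi = 0 along the wall, the
  # normal derivative of psi equals the tangential slip, and a second-order
  # Taylor step to the first interior node gives Thom's formula with slip.
  iw <- 2:(ny - 1)
  rb <- odx(iw, 1)   # bottom z = 0: dpsi/dz = vL_bottom
  rt <- odx(iw, nz)  # top z = H:    dpsi/dz = vL_top
  trip <- c(trip, list(
    cbind(rb, rb, 1), cbind(rb, idx(iw, 2), 2 / hz^2),
    cbind(rt, rt, 1), cbind(rt, idx(iw, nz - 1), 2 / hz^2)))
  rhs[rb] <- 2 * sb[iw] / hz
  rhs[rt] <- -2 * st[iw] / hz
  jw <- 2:(nz - 1)
  rl <- odx(1, jw)   # left y = 0:  v2z = -dpsi/dy = wL_left
  rr <- odx(ny, jw)  # right y = W
  trip <- c(trip, list(
    cbind(rl, rl, 1), cbind(rl, idx(2, jw), 2 / hy^2),
    cbind(rr, rr, 1), cbind(rr, idx(ny - 1, jw), 2 / hy^2)))
  rhs[rl] <- -2 * sl[jw] / hy
  rhs[rr] <- 2 * sr[jw] / hy
  # corner vorticity is not referenced by any interior stencil; pin to 0
  rc <- odx(c(1, ny, 1, ny), c(1, 1, nz, nz))
  trip <- c(trip, list(cbind(rc, rc, 1)))

  trip <- do.call(rbind, trip)
  A <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(2 * N, 2 * N))
  sol <- as.numeric(Matrix::solve(A, rhs))
  psi <- matrix(sol[1:N], ny, nz) * V * L   # back to dimensional units

  hy <- y[2] - y[1]; hz <- z[2] - z[1]

  # velocities from the streamfunction (central differences, one-sided at walls)
  ddz <- function(m) {
    out <- m * 0
    out[, 2:(nz - 1)] <- (m[, 3:nz] - m[, 1:(nz - 2)]) / (2 * hz)
    out[, 1] <- (-3 * m[, 1] + 4 * m[, 2] - m[, 3]) / (2 * hz)
    out[, nz] <- (3 * m[, nz] - 4 * m[, nz - 1] + m[, nz - 2]) / (2 * hz)
    out
  }
  ddy <- function(m) {
    out <- m * 0
    out[2:(ny - 1), ] <- (m[3:ny, ] - m[1:(ny - 2), ]) / (2 * hy)
    out[1, ] <- (-3 * m[1, ] + 4 * m[2, ] - m[3, ]) / (2 * hy)
    out[ny, ] <- (3 * m[ny, ] - 4 * m[ny - 1, ] + m[ny - 2, ]) / (2 * hy)
    out
  }
  v2y <- ddz(psi)
  v2z <- -ddy(psi)

  # diagnostic second-order pressure: integrate grad p2 = mu lap(v2) from the
  # origin (line integral along z = 0 then along z); approximate, for export
  lap <- function(m) {
    out <- m * 0
    out[2:(ny - 1), ] <- (m[3:ny, ] - 2 * m[2:(ny - 1), ] + m[1:(ny - 2), ]) / hy^2
    out[, 2:(nz - 1)] <- out[, 2:(nz - 1)] +
      (m[, 3:nz] - 2 * m[, 2:(nz - 1)] + m[, 1:(nz - 2)]) / hz^2
    out
  }
  mu <- medium$viscosity
  gy <- mu * lap(v2y); gz <- mu * lap(v2z)
  p2 <- matrix(0, ny, nz)
  p2[, 1] <- c(0, cumsum((gy[-1, 1] + gy[-ny, 1]) / 2 * hy))
  for (i in 1:ny) {
    p2[i, ] <- p2[i, 1] + c(0, cumsum((gz[i, -1] + gz[i, -nz]) / 2 * hz))
  }

  structure(
    list(y = y, z = z, psi = psi, v2y = v2y, v2z = v2z, p2 = p2, mu = mu,
         geometry = geometry),
    class = "baw_streaming")
}

#' Maximum discrete divergence of a streaming solution
#'
#' Central-difference divergence of `(v2y, v2z)` at interior nodes,
#' normalised by `max|v2| * k`. Zero to rounding for a streamfunction-derived
#' field.
#'
#' @param sol A [solve_streaming()] solution.
#' @return Relative divergence (dimensionless scalar).
#' @export
streaming_divergence <- function(sol) {
  stopifnot(inherits(sol, "baw_streaming"))
  ny <- length(sol$y); nz <- length(sol$z)
  hy <- sol$y[2] - sol$y[1]; hz <- sol$z[2] - sol$z[1]
  i <- 2:(ny - 1); j <- 2:(nz - 1)
  div <- (sol$v2y[i + 1, j] - sol$v2y[i - 1, j]) / (2 * hy) +
    (sol$v2z[i, j + 1] - sol$v2z[i, j - 1]) / (2 * hz)
  vmax <- max(sqrt(sol$v2y^2 + sol$v2z^2))
  k <- pi / (sol$y[ny] - sol$y[1])
  if (vmax == 0) return(0)
  max(abs(div)) / (vmax * k)
}

#' Interpolate the streaming velocity at a point
#'
#' Bilinear interpolation of the solved second-order velocity field; exact at
#' grid nodes.
#'
#' @param point Numeric vector `c(y, z)` (m), or a 2-column matrix of points.
#' @param sol A [solve_streaming()] solution.
#' @return For a single point, `c(vy, vz)` (m/s); for a matrix of points, a
#'   2-column matrix.
#' @export
streaming_velocity_at <- function(point, sol) {
  stopifnot(inherits(sol, "baw_streaming"))
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  y <- pts[, 1]; z <- pts[, 2]
  yr <- range(sol$y); zr <- range(sol$z)
  if (any(y < yr[1] - 1e-15) || any(y > yr[2] + 1e-15) ||
      any(z < zr[1] - 1e-15) || any(z > zr[2] + 1e-15)) {
    stop("point outside the cross-section")
  }
  out <- cbind(bilinear_interp(sol$y, sol$z, sol$v2y, y, z),
               bilinear_interp(sol$y, sol$z, sol$v2z, y, z))
  colnames(out) <- c("vy", "vz")
  if (is.matrix(point)) out else drop(out)
}

# vectorised bilinear interpolation on a regular grid
bilinear_interp <- function(xg, zg, m, x, z) {
  nx <- length(xg); nz <- length(zg)
  hx <- xg[2] - xg[1]; hz <- zg[2] - zg[1]
  ix <- pmin(pmax(floor((x - xg[1]) / hx) + 1, 1), nx - 1)
  iz <- pmin(pmax(floor((z - zg[1]) / hz) + 1, 1), nz - 1)
  tx <- (x - xg[ix]) / hx
  tz <- (z - zg[iz]) / hz
  m[cbind(ix, iz)] * (1 - tx) * (1 - tz) +
    m[cbind(ix + 1, iz)] * tx * (1 - tz) +
    m[cbind(ix, iz + 1)] * (1 - tx) * tz +
    m[cbind(ix + 1, iz + 1)] * tx * tz
}

#' Export a streaming solution as a data frame
#'
#' Long-format grid table `(y, z, v2y, v2z, p2)` suitable for CSV export or
#' plotting.
#'
#' @param sol A [solve_streaming()] solution.
#' @return A data frame with one row per grid node.
#' @export
streaming_grid <- function(sol) {
  stopifnot(inherits(sol, "baw_streaming"))
  g <- expand.grid(y = sol$y, z = sol$z)
  data.frame(y = g$y, z = g$z,
             v2y = as.vector(sol$v2y), v2z = as.vector(sol$v2z),
             p2 = as.vector(sol$p2))
}
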