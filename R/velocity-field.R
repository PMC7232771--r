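#' Build a synthetic surface velocity field
#'
#' Compose a stationary surface current field from streamfunction-based
#' components — Gaussian gyres, solid-body gyres, zonal jets, uniform drift
#' and smoothed random eddy noise — evaluated at cell centers and zeroed on
#' land. All components are derived from a scalar streamfunction by central
#' differencing, so the interior flow is divergence-free by construction
#' (discretely exact: the central-difference divergence of a
#' central-difference curl cancels identically).
#'
#' Component descriptors (lists with a `type` field):
#' \describe{
#'   \item{gyre}{Gaussian eddy: `center_km = c(x, y)`, `radius_km`,
#'     `amplitude` (m/s peak swirl speed scale).}
#'   \item{solid_body}{rigid rotation: `center_km`, `omega` (rad/s);
#'     speed grows linearly with radius and vanishes at the center.}
#'   \item{jet}{zonal jet: `y_km` center line, `width_km`, `amplitude`
#'     (m/s peak eastward speed).}
#'   \item{uniform}{constant drift: `u`, `v` (m/s).}
#'   \item{noise}{smoothed random eddies: `amplitude` (m/s speed scale),
#'     `smooth` (number of 3x3 smoothing passes, default 4).}
#' }
#'
#' @param grid a [SeascapeGrid-class].
#' @param components list of descriptors as above.
#' @param seed RNG seed used by noise components; the field is reproducible.
#' @param seasonalWindow integer months (metadata; default April-September).
#' @return A [VelocityField-class] with u, v in m/s.
#' @export
makeVelocityField <- function(grid, components = list(), seed = 1L,
                              seasonalWindow = 4:9) {
  nx <- nrow(grid@landMask); ny <- ncol(grid@landMask)
  cs <- grid@cellSizeKm
  xc <- (seq_len(nx) - 0.5) * cs
  yc <- (seq_len(ny) - 0.5) * cs
  X <- matrix(rep(xc, ny), nx, ny)
  Y <- matrix(rep(yc, each = nx), nx, ny)

  # streamfunction in units (m/s) * km, so d(psi)/d(km) is m/s
  psi <- matrix(0, nx, ny)
  u <- matrix(0, nx, ny)
  v <- matrix(0, nx, ny)
  kn <- 0L
  for (cmp in components) {
    amp <- cmp$amplitude %||% cmp$omega %||% max(abs(c(cmp$u %||% 0, cmp$v %||% 0)))
    if (!all(is.finite(amp))) stop("component amplitudes must be finite")
    psi <- psi + switch(cmp$type,
      gyre = {
        r2 <- (X - cmp$center_km[1])^2 + (Y - cmp$center_km[2])^2
        cmp$amplitude * cmp$radius_km * exp(-r2 / (2 * cmp$radius_km^2))
      },
      solid_body = {
        r2 <- (X - cmp$center_km[1])^2 + (Y - cmp$center_km[2])^2
        500 * cmp$omega * r2  # u = -1000*omega*(y-cy) m/s, v = +1000*omega*(x-cx)
      },
      jet = {
        w <- cmp$width_km
        z <- (Y - cmp$y_km) / (w * sqrt(2))
        -cmp$amplitude * w * sqrt(pi / 2) * (2 * pnorm(z * sqrt(2)) - 1)
      },
      uniform = -(cmp$u %||% 0) * Y + (cmp$v %||% 0) * X,
      noise = {
        kn <- kn + 1L
        raw <- with_seed(sub_seed(seed, kn), matrix(rnorm(nx * ny), nx, ny))
        for (s in seq_len(cmp$smooth %||% 4)) raw <- smooth3x3(raw)
        uv <- psi_to_uv(raw, cs)
        spd <- max(sqrt(uv$u^2 + uv$v^2), 1e-12)
        raw * (cmp$amplitude / spd)
      },
      stop("unknown velocity component type: ", cmp$type)
    )
  }
  uv <- psi_to_uv(psi, cs)
  u <- uv$u; v <- uv$v
  u[grid@landMask] <- 0
  v[grid@landMask] <- 0
  new("VelocityField", u = u, v = v, seasonalWindow = as.integer(seasonalWindow))
}

# u = -dpsi/dy, v = dpsi/dx; central differences inside, one-sided at edges.
psi_to_uv <- function(psi, cellSizeKm) {
  nx <- nrow(psi); ny <- ncol(psi)
  dx <- matrix(0, nx, ny); dy <- matrix(0, nx, ny)
  if (nx >= 3) dx[2:(nx - 1), ] <- (psi[3:nx, ] - psi[1:(nx - 2), ]) / (2 * cellSizeKm)
  dx[1, ] <- (psi[2, ] - psi[1, ]) / cellSizeKm
  dx[nx, ] <- (psi[nx, ] - psi[nx - 1, ]) / cellSizeKm
  if (ny >= 3) dy[, 2:(ny - 1)] <- (psi[, 3:ny] - psi[, 1:(ny - 2)]) / (2 * cellSizeKm)
  dy[, 1] <- (psi[, 2] - psi[, 1]) / cellSizeKm
  dy[, ny] <- (psi[, ny] - psi[, ny - 1]) / cellSizeKm
  list(u = -dy, v = dx)
}

smooth3x3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  p <- matrix(0, nx + 2, ny + 2)
  p[2:(nx + 1), 2:(ny + 1)] <- m
  p[1, ] <- p[2, ]; p[nx + 2, ] <- p[nx + 1, ]
  p[, 1] <- p[, 2]; p[, ny + 2] <- p[, ny + 1]
  out <- matrix(0, nx, ny)
  for (di in 0:2) for (dj in 0:2) {
    out <- out + p[di + seq_len(nx), dj + seq_len(ny)]
  }
  out / 9
}

#' Discrete divergence of a velocity field
#'
#' Central-difference divergence (1/s) on interior cells; used to verify that
#' streamfunction-derived fields are non-divergent. Units: velocities are
#' m/s, cell size km, so the raw value is scaled by 1/1000.
#'
#' @param field a [VelocityField-class].
#' @param cellSizeKm grid cell size in km.
#' @return Matrix of divergence values, `NA` on the boundary ring.
#' @export
fieldDivergence <- function(field, cellSizeKm) {
  u <- field@u; v <- field@v
  nx <- nrow(u); ny <- ncol(u)
  div <- matrix(NA_real_, nx, ny)
  if (nx >= 3 && ny >= 3) {
    div[2:(nx - 1), 2:(ny - 1)] <-
      (u[3:nx, 2:(ny - 1)] - u[1:(nx - 2), 2:(ny - 1)]) / (2 * cellSizeKm) +
      (v[2:(nx - 1), 3:ny] - v[2:(nx - 1), 1:(ny - 2)]) / (2 * cellSizeKm)
  }
  div / 1000
}

setMethod("show", "VelocityField", function(object) {
  spd <- sqrt(object@u^2 + object@v^2)
  cat(sprintf("VelocityField: %d x %d cells, max speed %.3f m/s, months %s\n",
              nrow(object@u), ncol(object@u), max(spd),
              paste(range(object@seasonalWindow), collapse = "-")))
})
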