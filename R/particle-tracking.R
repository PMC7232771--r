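#' Release schedule for dispersal simulations
#'
#' Desk-scale stand-in for a full larval release protocol: particles are
#' released from every habitat cell at each monthly release inside the
#' reproductive window (April-September by default), drift passively in the
#' surface layer for the dispersive-phase duration (5 days by default) and
#' then settle.
#'
#' @param months integer release months (metadata; default `4:9`).
#' @param particlesPerCell particles released per habitat cell per release.
#' @param pldDays drift duration in days (> 0).
#' @param dtS integration time step in seconds.
#' @param driftLayer label of the drift layer (metadata; 2-D model).
#' @return A list of class `"ReleaseSchedule"`.
#' @export
releaseSchedule <- function(months = 4:9, particlesPerCell = 50, pldDays = 5,
                            dtS = 3600, driftLayer = "surface 0-2 m") {
  stopifnot(pldDays > 0, particlesPerCell >= 1, dtS > 0)
  structure(list(months = as.integer(months),
                 particlesPerCell = as.integer(particlesPerCell),
                 pldDays = pldDays, dtS = dtS, driftLayer = driftLayer),
            class = "ReleaseSchedule")
}

# Vectorized velocity lookup (km/s) at positions, by bilinear interpolation
# of the cell-centered m/s components.
velocity_at <- function(grid, field, x, y) {
  list(u = bilinear(field@u, x, y, grid@cellSizeKm) / 1000,
       v = bilinear(field@v, x, y, grid@cellSizeKm) / 1000)
}

#' Advect particles through a velocity field
#'
#' Fixed-step fourth-order Runge-Kutta integration with bilinear velocity
#' interpolation. Any step whose endpoint falls on a land cell is cancelled
#' and the particle holds position for that step (stick-in-place; simple and
#' direction-unbiased). A step ending outside the domain marks the particle
#' as lost and freezes it.
#'
#' `advectParticle` integrates a single particle and returns its end
#' position; `advectParticles` is the vectorized core used by
#' [runDispersal()].
#'
#' @param grid a [SeascapeGrid-class].
#' @param field a [VelocityField-class].
#' @param start numeric `c(x_km, y_km)` start position (must be a sea cell).
#' @param starts two-column matrix of start positions (km).
#' @param pldDays drift duration (days).
#' @param dtS time step (s); `pldDays * 86400` need not be an exact multiple,
#'   the final partial step is shortened.
#' @return `advectParticle`: numeric `c(x_km, y_km)`. `advectParticles`: a
#'   list with `x`, `y` (end positions) and `lost` (logical).
#' @export
advectParticle <- function(grid, field, start, pldDays = 5, dtS = 3600) {
  cell <- cell_of(start[1], start[2], nrow(grid@landMask), ncol(grid@landMask),
                  grid@cellSizeKm)
  if (is.na(cell) || grid@landMask[cell]) {
    stop("start position must lie in a sea cell")
  }
  res <- advectParticles(grid, field, matrix(start, 1, 2), pldDays, dtS)
  c(x_km = res$x, y_km = res$y)
}

#' @rdname advectParticle
#' @export
advectParticles <- function(grid, field, starts, pldDays = 5, dtS = 3600) {
  nx <- nrow(grid@landMask); ny <- ncol(grid@landMask)
  cs <- grid@cellSizeKm
  xmax <- nx * cs; ymax <- ny * cs
  x <- starts[, 1]; y <- starts[, 2]
  lost <- rep(FALSE, length(x))
  total <- pldDays * 86400
  nStep <- ceiling(total / dtS - 1e-9)
  for (s in seq_len(nStep)) {
    dt <- min(dtS, total - (s - 1) * dtS)
    act <- !lost
    if (!any(act)) break
    xa <- x[act]; ya <- y[act]
    k1 <- velocity_at(grid, field, xa, ya)
    k2 <- velocity_at(grid, field, xa + 0.5 * dt * k1$u, ya + 0.5 * dt * k1$v)
    k3 <- velocity_at(grid, field, xa + 0.5 * dt * k2$u, ya + 0.5 * dt * k2$v)
    k4 <- velocity_at(grid, field, xa + dt * k3$u, ya + dt * k3$v)
    xn <- xa + dt / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
    yn <- ya + dt / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
    out <- xn < 0 | xn > xmax | yn < 0 | yn > ymax
    celln <- cell_of(pmin(pmax(xn, 0), xmax), pmin(pmax(yn, 0), ymax), nx, ny, cs)
    onLand <- !out & grid@landMask[celln]
    keepX <- ifelse(onLand, xa, xn)   # cancelled step: hold position
    keepY <- ifelse(onLand, ya, yn)
    x[act] <- ifelse(out, xa, keepX)
    y[act] <- ifelse(out, ya, keepY)
    lostNow <- rep(FALSE, length(x)); lostNow[act] <- out
    lost <- lost | lostNow
  }
  list(x = x, y = y, lost = lost)
}

#' Run a dispersal simulation over a release schedule
#'
#' Releases `particlesPerCell` particles from every habitat cell at each
#' release (uniform sub-cell jitter, seeded), advects each for the
#' dispersive-phase duration, and applies the settlement rule: a particle
#' ending in a habitat cell settles there; one ending in sea but non-habitat
#' snaps to the nearest habitat cell within one cell radius (else it is
#' lost); a particle carried out of the domain is lost.
#'
#' @param grid a [SeascapeGrid-class] with non-empty habitat.
#' @param field a [VelocityField-class].
#' @param schedule a [releaseSchedule()].
#' @param seed RNG seed; the ensemble is fully reproducible.
#' @return A [ParticleEnsemble-class].
#' @export
runDispersal <- function(grid, field, schedule = releaseSchedule(), seed = 1L) {
  hab <- habitatCells(grid)
  if (length(hab) == 0L) stop("empty habitat: nothing to release")
  nx <- nrow(grid@landMask); ny <- ncol(grid@landMask)
  cs <- grid@cellSizeKm
  ij <- cell_to_ij(hab, nx)
  nRel <- length(schedule$months)
  ppc <- schedule$particlesPerCell
  nPer <- length(hab) * ppc

  pieces <- vector("list", nRel)
  for (r in seq_len(nRel)) {
    src <- rep(hab, each = ppc)
    jit <- with_seed(sub_seed(seed, r), matrix(runif(2 * nPer), nPer, 2))
    sx <- (rep(ij[, "ix"], each = ppc) - 1 + jit[, 1]) * cs
    sy <- (rep(ij[, "iy"], each = ppc) - 1 + jit[, 2]) * cs
    res <- advectParticles(grid, field, cbind(sx, sy),
                           schedule$pldDays, schedule$dtS)
    dest <- settle(grid, res$x, res$y, res$lost)
    pieces[[r]] <- data.frame(
      src_cell = src, release = r, end_x = res$x, end_y = res$y,
      dest_cell = dest, lost = is.na(dest))
  }
  parts <- do.call(rbind, pieces)
  parts$particle_id <- seq_len(nrow(parts))
  parts <- parts[, c("particle_id", "src_cell", "release", "end_x", "end_y",
                     "dest_cell", "lost")]
  released <- setNames(rep(ppc * nRel, length(hab)), as.character(hab))
  new("ParticleEnsemble", particles = parts, released = released)
}

# Settlement rule: habitat end cell -> settle there; sea non-habitat -> snap
# to the nearest habitat cell among the 8 neighbours (ties broken by lowest
# cell id); otherwise lost (NA).
settle <- function(grid, x, y, lost) {
  nx <- nrow(grid@landMask); ny <- ncol(grid@landMask)
  cs <- grid@cellSizeKm
  cell <- cell_of(x, y, nx, ny, cs)
  dest <- rep(NA_integer_, length(x))
  ok <- !lost & !is.na(cell)
  inHab <- ok & grid@habitatMask[pmax(cell, 1)] & ok
  dest[inHab] <- cell[inHab]
  need <- which(ok & !inHab)
  if (length(need)) {
    ij <- cell_to_ij(cell[need], nx)
    for (k in seq_along(need)) {
      i <- ij[k, "ix"]; j <- ij[k, "iy"]
      best <- NA_integer_; bestD <- Inf
      for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
        cid <- (jj - 1) * nx + ii
        if (!grid@habitatMask[cid]) next
        d <- (x[need[k]] - (ii - 0.5) * cs)^2 + (y[need[k]] - (jj - 0.5) * cs)^2
        if (d < bestD - 1e-12 || (abs(d - bestD) <= 1e-12 && cid < best)) {
          best <- cid; bestD <- d
        }
      }
      dest[need[k]] <- best
    }
  }
  dest
}

#' Summarize a particle ensemble as a normalized connectivity matrix
#'
#' Element `(i, j)` is the number of particles released at habitat cell `i`
#' that settled at cell `j`, divided by the number released from `i`. Rows
#' sum to at most 1; the deficit is the lost fraction.
#'
#' @param ensemble a [ParticleEnsemble-class].
#' @param grid the [SeascapeGrid-class] used for the release.
#' @return A single-generation [ConnectivityMatrix-class] over habitat cells.
#' @export
ensembleToConnectivity <- function(ensemble, grid) {
  hab <- habitatCells(grid)
  ids <- as.character(hab)
  rel <- ensemble@released[ids]
  if (any(is.na(rel)) || any(rel == 0)) {
    stop("every habitat cell must have released particles")
  }
  p <- ensemble@particles
  m <- matrix(0, length(hab), length(hab), dimnames = list(ids, ids))
  settled <- p[!p$lost, , drop = FALSE]
  if (nrow(settled)) {
    tab <- table(factor(settled$src_cell, levels = hab),
                 factor(settled$dest_cell, levels = hab))
    m <- unclass(tab) / as.numeric(rel)
    dimnames(m) <- list(ids, ids)
  }
  new("ConnectivityMatrix", probs = m, rawProbs = m, generations = 1L,
      symmetrization = "none")
}

setMethod("show", "ParticleEnsemble", function(object) {
  p <- object@particles
  cat(sprintf("ParticleEnsemble: %d particles from %d cells (%.1f%% settled)\n",
              nrow(p), length(object@released), 100 * mean(!p$lost)))
})
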