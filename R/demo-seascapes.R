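#' Synthetic channel seascape with coastal sites
#'
#' A compact study system used throughout the examples and calibration
#' analyses: an elongated land-bounded channel with a coastal habitat
#' fringe, an along-channel jet plus a basin gyre and weak eddy noise, a
#' monotone salinity decline along the channel, and `nSites` site samples
#' evenly spaced along the southern coast. Everything is deterministic given
#' `fieldSeed`.
#'
#' @param nSites number of site samples along the southern coast.
#' @param nx,ny,cellSizeKm grid dimensions (cells) and cell size (km).
#' @param fieldSeed seed for the eddy-noise component.
#' @return list with `grid` ([SeascapeGrid-class]), `field`
#'   ([VelocityField-class]) and `sites` (site metadata data.frame with a
#'   `cell` column mapping each site to its habitat cell).
#' @export
channelSeascape <- function(nSites = 20, nx = 44, ny = 9, cellSizeKm = 5,
                            fieldSeed = 7L) {
  grid <- buildGrid(list(
    nx = nx, ny = ny, cell_size_km = cellSizeKm,
    land = list(border = TRUE),
    depth = list(mode = "coastal", slope_m_per_km = 4, max_depth = 60)
  ))
  grid <- assignEnvironment(grid, "salinity", "x", 25, 5)
  grid <- assignEnvironment(grid, "temperature", "y", 16, 13)
  field <- makeVelocityField(grid, list(
    list(type = "jet", y_km = ny * cellSizeKm / 2, width_km = 2 * cellSizeKm,
         amplitude = 0.06),
    list(type = "gyre", center_km = c(nx * cellSizeKm / 2, ny * cellSizeKm / 2),
         radius_km = nx * cellSizeKm / 6, amplitude = 0.05),
    list(type = "noise", amplitude = 0.03, smooth = 4)
  ), seed = fieldSeed)

  hab <- habitatCells(grid)
  ij <- cell_to_ij(hab, nx)
  south <- hab[ij[, "iy"] == 2L]
  south <- south[order(cell_to_ij(south, nx)[, "ix"])]
  if (nSites > length(south)) stop("more sites than southern coastal cells")
  cells <- south[round(seq(1, length(south), length.out = nSites))]
  cc <- cellCenters(grid, cells)
  t <- seq(0, 1, length.out = nSites)
  sites <- data.frame(
    site_id = sprintf("S%02d", seq_len(nSites)),
    region = paste0("R", as.integer(cut(t, 4, labels = FALSE,
                                        include.lowest = TRUE))),
    x_km = cc[, 1], y_km = cc[, 2],
    salinity_psu = grid@salinityPsu[cells],
    temp_C = grid@temperatureC[cells],
    coast_dist_km = cc[, 1] - min(cc[, 1]),
    mpa = as.integer(seq_len(nSites) %% 2L),
    cell = cells
  )
  list(grid = grid, field = field, sites = sites)
}

#' Linear colonization-chain demography fixture
#'
#' A one-dimensional stepping-stone system for serial-founder experiments: a
#' tridiagonal nearest-neighbour connectivity matrix over `d` demes (self
#' weight `selfW`, each neighbour `(1 - selfW) / 2`), a site table whose
#' salinity declines linearly along the chain (the colonization front moves
#' into progressively fresher water), and covariates with independent
#' variation (meandering coastline distance, random temperatures,
#' alternating MPA flags).
#'
#' @param d number of demes.
#' @param selfW self-retention weight of the connectivity rows.
#' @param seed seed for the covariate jitter.
#' @return list with `conn` (matrix), `sites` (data.frame) and
#'   `founderOrder` (1..d).
#' @export
colonizationChain <- function(d = 20, selfW = 0.8, seed = 1L) {
  m <- diag(selfW, d)
  side <- (1 - selfW) / 2
  for (i in seq_len(d - 1)) {
    m[i, i + 1] <- side
    m[i + 1, i] <- side
  }
  m[1, 1] <- selfW + side
  m[d, d] <- selfW + side
  jit <- with_seed(seed, list(
    step = exp(rnorm(d, 0, 0.45)),
    ts = rnorm(d, 15, 1.5), tw = rnorm(d, 3, 1.5)
  ))
  coast <- cumsum(c(0, 50 * jit$step[-1]))
  sites <- data.frame(
    site_id = sprintf("D%02d", seq_len(d)),
    region = "chain",
    x_km = seq(0, by = 50, length.out = d), y_km = 0,
    salinity_psu = seq(25, 6, length.out = d),
    temp_C = round(jit$ts, 2),
    winter_temp_C = round(jit$tw, 2),
    coast_dist_km = round(coast, 1),
    mpa = as.integer(seq_len(d) %% 2L)
  )
  list(conn = m, sites = sites, founderOrder = seq_len(d))
}
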