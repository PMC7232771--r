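#' Synthetic 31-site Baltic-style sampling layout
#'
#' A synthetic site metadata table emulating a basin-wide sampling campaign:
#' 31 sites in five broad regions — W (western entrance area, 9 sites), SBA
#' (south-western basin coast, 6), SBO (north-western basin coast, 2), FBO
#' (north-eastern coast, 7) and GFE (eastern gulf, 7) — with 14 of 31 sites
#' (45%) flagged as marine protected areas, a monotone salinity decline from
#' the entrance into the inner basins, and coastline distance measured from
#' the entrance. All values are synthetic; no field data are included.
#'
#' @return data.frame with `site_id`, `region`, `x_km`, `y_km`,
#'   `salinity_psu`, `winter_salinity_psu`, `temp_C`, `winter_temp_C`,
#'   `coast_dist_km`, `mpa`.
#' @export
balticSiteLayout <- function() {
  counts <- c(W = 9L, SBA = 6L, SBO = 2L, FBO = 7L, GFE = 7L)
  region <- rep(names(counts), counts)
  id <- unlist(lapply(counts, seq_len), use.names = FALSE)
  siteId <- paste0(region, "-", id)
  n <- length(siteId)
  # along-coast path from the entrance (W-1) to the inner gulf (GFE-7)
  coast <- cumsum(c(0, rep(c(60, 75, 55, 80, 65, 70), length.out = n - 1)))
  t <- coast / max(coast)
  x <- 80 + 900 * t
  y <- 150 + 350 * sin(pi * t) * ifelse(region %in% c("SBO", "FBO"), 1.4, 1.0)
  sal <- 26 - 21 * t            # 26 psu at the entrance down to ~5 psu
  mpa <- integer(n)
  mpa[seq(1, n, by = 2)][1:14] <- 1L
  data.frame(
    site_id = siteId, region = region,
    x_km = round(x, 1), y_km = round(y, 1),
    salinity_psu = round(sal, 2),
    winter_salinity_psu = round(sal * 0.93 + 0.4, 2),
    temp_C = round(17 - 4 * t, 2),
    winter_temp_C = round(4 - 2.5 * t, 2),
    coast_dist_km = round(coast, 1),
    mpa = mpa
  )
}

#' Place site samples on a seascape grid
#'
#' Deterministically picks `count` habitat cells spread along the habitat
#' extent (ordered by x then y), labels them into `nRegions` contiguous
#' regions along the x axis, and reads salinity/temperature off the grid
#' fields. Alternating sites are flagged as MPAs.
#'
#' @param grid a [SeascapeGrid-class].
#' @param count number of sites.
#' @param nRegions number of region labels.
#' @return site metadata data.frame (`site_id`, `region`, `x_km`, `y_km`,
#'   `salinity_psu`, `temp_C`, `coast_dist_km`, `mpa`, `cell`).
#' @export
placeSites <- function(grid, count = 25, nRegions = 5) {
  hab <- habitatCells(grid)
  if (count > length(hab)) stop("more sites requested than habitat cells")
  cc <- cellCenters(grid, hab)
  ord <- order(cc[, 1], cc[, 2])
  pick <- ord[round(seq(1, length(hab), length.out = count))]
  cells <- hab[pick]
  cc <- cc[pick, , drop = FALSE]
  regionIdx <- as.integer(cut(rank(cc[, 1], ties.method = "first"),
                              breaks = nRegions, labels = FALSE))
  region <- paste0("R", regionIdx)
  data.frame(
    site_id = sprintf("S%02d", seq_len(count)),
    region = region,
    x_km = cc[, 1], y_km = cc[, 2],
    salinity_psu = grid@salinityPsu[cells],
    temp_C = grid@temperatureC[cells],
    coast_dist_km = cc[, 1] - min(cc[, 1]),
    mpa = as.integer(seq_len(count) %% 2L),
    cell = cells
  )
}
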