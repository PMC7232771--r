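#' Build a synthetic seascape grid
#'
#' Construct a [SeascapeGrid-class] from a declarative configuration: grid
#' dimensions and cell size, a land description (an optional land border plus
#' rectangular land blocks), and a depth model. Habitat is defined as every
#' sea cell whose mean depth is below the habitat depth limit (30 m by
#' default), the depth rule commonly used for shallow-water hard-bottom taxa.
#'
#' The depth model is one of `list(mode = "constant", value = <m>)`,
#' `list(mode = "matrix", values = <nx x ny depths>)`, or
#' `list(mode = "coastal", slope_m_per_km = <m/km>, max_depth = <m>)`, the
#' last deepening linearly with distance from the nearest land cell so that
#' habitat forms a coastal fringe.
#'
#' @param config a list with elements `nx`, `ny`, `cell_size_km`, `depth`
#'   (see above), optional `land = list(border = TRUE/FALSE, blocks =
#'   list(c(x0, x1, y0, y1), ...))` (cell-index rectangles, inclusive),
#'   and optional `habitat_depth_limit` (m, default 30).
#' @return A [SeascapeGrid-class]; salinity and temperature are initialised
#'   to zero and filled by [assignEnvironment()].
#' @examples
#' g <- buildGrid(list(nx = 10, ny = 6, cell_size_km = 5,
#'                     depth = list(mode = "constant", value = 10)))
#' sum(habitatCells(g))
#' @export
buildGrid <- function(config) {
  nx <- config$nx; ny <- config$ny
  if (is.null(nx) || is.null(ny) || nx < 2 || ny < 2) {
    stop("grid dimensions must be at least 2 x 2")
  }
  cellSizeKm <- config$cell_size_km
  if (is.null(cellSizeKm) || cellSizeKm <= 0) stop("cell_size_km must be positive")
  limit <- config$habitat_depth_limit %||% 30
  if (limit <= 0) stop("habitat depth limit must be positive")

  land <- matrix(FALSE, nx, ny)
  lc <- config$land
  if (!is.null(lc)) {
    if (isTRUE(lc$border)) {
      land[1, ] <- TRUE; land[nx, ] <- TRUE
      land[, 1] <- TRUE; land[, ny] <- TRUE
    }
    for (b in lc$blocks %||% list()) {
      b <- as.numeric(b)
      land[max(1, b[1]):min(nx, b[2]), max(1, b[3]):min(ny, b[4])] <- TRUE
    }
  }
  if (all(land)) stop("empty habitat: land covers all cells")

  dc <- config$depth
  if (is.null(dc)) stop("a depth model is required")
  depth <- matrix(NA_real_, nx, ny)
  sea <- !land
  if (identical(dc$mode, "constant")) {
    depth[sea] <- dc$value
  } else if (identical(dc$mode, "coastal")) {
    depth[sea] <- pmin(dc$slope_m_per_km * land_distance_km(land, cellSizeKm)[sea],
                       dc$max_depth %||% Inf)
  } else if (identical(dc$mode, "matrix")) {
    vals <- matrix(as.numeric(unlist(dc$values)), nx, ny)
    depth[sea] <- vals[sea]
  } else {
    stop("unknown depth mode: ", dc$mode)
  }

  habitat <- sea & !is.na(depth) & depth < limit
  if (!any(habitat)) {
    stop("empty habitat: no sea cell shallower than ", limit, " m")
  }
  zeros <- matrix(0, nx, ny)
  new("SeascapeGrid", cellSizeKm = cellSizeKm, landMask = land, depthM = depth,
      habitatMask = habitat, salinityPsu = zeros, temperatureC = zeros,
      habitatDepthLimit = limit)
}

# Distance (km) from each cell center to the nearest land cell center; cells
# in an all-sea domain are measured from the domain edge instead, so a
# coastal depth model still produces a shallow fringe.
land_distance_km <- function(land, cellSizeKm) {
  nx <- nrow(land); ny <- ncol(land)
  ix <- matrix(rep(seq_len(nx), ny), nx, ny)
  iy <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  if (!any(land)) {
    edge <- pmin(ix - 0.5, nx - ix + 0.5, iy - 0.5, ny - iy + 0.5)
    return(edge * cellSizeKm)
  }
  lnd <- which(land)
  lx <- ((lnd - 1) %% nx) + 1
  ly <- ((lnd - 1) %/% nx) + 1
  d2 <- outer(as.vector(ix), lx, function(a, b) (a - b)^2) +
        outer(as.vector(iy), ly, function(a, b) (a - b)^2)
  matrix(sqrt(apply(d2, 1, min)) * cellSizeKm, nx, ny)
}

#' Assign a monotone environmental gradient to a seascape grid
#'
#' Fill the salinity and/or temperature field with a linear gradient between
#' two endpoint values along the `x` or `y` axis, emulating the large-scale
#' brackish gradients of semi-enclosed seas. Values vary monotonically from
#' `from` at the low-coordinate end to `to` at the high-coordinate end.
#'
#' @param grid a [SeascapeGrid-class].
#' @param field `"salinity"` or `"temperature"`.
#' @param axis `"x"` or `"y"`.
#' @param from,to finite endpoint values.
#' @return The grid with the field replaced.
#' @export
assignEnvironment <- function(grid, field = c("salinity", "temperature"),
                              axis = c("x", "y"), from, to) {
  field <- match.arg(field)
  axis <- match.arg(axis)
  stopifnot(is.finite(from), is.finite(to))
  nx <- nrow(grid@landMask); ny <- ncol(grid@landMask)
  if (axis == "x") {
    frac <- if (nx == 1) 0 else (seq_len(nx) - 1) / (nx - 1)
    vals <- matrix(rep(from + frac * (to - from), ny), nx, ny)
  } else {
    frac <- if (ny == 1) 0 else (seq_len(ny) - 1) / (ny - 1)
    vals <- matrix(rep(from + frac * (to - from), each = nx), nx, ny)
  }
  if (field == "salinity") grid@salinityPsu <- vals else grid@temperatureC <- vals
  validObject(grid)
  grid
}

#' @rdname accessors
#' @export
setMethod("gridDims", "SeascapeGrid", function(x) {
  c(nx = nrow(x@landMask), ny = ncol(x@landMask))
})

#' @rdname accessors
#' @export
setMethod("habitatCells", "SeascapeGrid", function(x) which(x@habitatMask))

#' @param cells optional integer cell ids; default all cells.
#' @rdname accessors
#' @export
setMethod("cellCenters", "SeascapeGrid", function(x, cells = NULL) {
  nx <- nrow(x@landMask)
  if (is.null(cells)) cells <- seq_along(x@landMask)
  ij <- cell_to_ij(cells, nx)
  cbind(x_km = (ij[, "ix"] - 0.5) * x@cellSizeKm,
        y_km = (ij[, "iy"] - 0.5) * x@cellSizeKm)
})

setMethod("show", "SeascapeGrid", function(object) {
  d <- gridDims(object)
  cat(sprintf(
    "SeascapeGrid: %d x %d cells of %.1f km (%d sea, %d habitat < %g m)\n",
    d["nx"], d["ny"], object@cellSizeKm, sum(!object@landMask),
    sum(object@habitatMask), object@habitatDepthLimit))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
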