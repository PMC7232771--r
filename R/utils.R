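# Internal helpers: seeded evaluation, interpolation, small utilities.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1031L + k * 7919) %% 2147483629)
}

# Cell id (1-based column-major linear index) containing planar positions
# (km). Positions outside the domain return NA.
cell_of <- function(x, y, nx, ny, cellSizeKm) {
  ix <- floor(x / cellSizeKm) + 1
  iy <- floor(y / cellSizeKm) + 1
  ix[x == nx * cellSizeKm] <- nx  # right/top edges belong to the last cell
  iy[y == ny * cellSizeKm] <- ny
  ok <- !is.na(ix) & ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer((iy[ok] - 1) * nx + ix[ok])
  out
}

cell_to_ij <- function(cell, nx) {
  ix <- ((cell - 1) %% nx) + 1
  iy <- ((cell - 1) %/% nx) + 1
  cbind(ix = ix, iy = iy)
}

# Bilinear interpolation of a cell-centered field at arbitrary positions (km).
# Coordinates outside the center lattice are clamped to its edge, so the
# field extends constantly past the outermost cell centers.
bilinear <- function(f, x, y, cellSizeKm) {
  nx <- nrow(f); ny <- ncol(f)
  cx <- pmin(pmax(x / cellSizeKm + 0.5, 1), nx)
  cy <- pmin(pmax(y / cellSizeKm + 0.5, 1), ny)
  i0 <- pmin(floor(cx), nx - 1); i0 <- pmax(i0, 1)
  j0 <- pmin(floor(cy), ny - 1); j0 <- pmax(j0, 1)
  tx <- cx - i0; ty <- cy - j0
  idx <- function(i, j) (j - 1) * nx + i
  f00 <- f[idx(i0, j0)]; f10 <- f[idx(i0 + 1, j0)]
  f01 <- f[idx(i0, j0 + 1)]; f11 <- f[idx(i0 + 1, j0 + 1)]
  (1 - tx) * (1 - ty) * f00 + tx * (1 - ty) * f10 +
    (1 - tx) * ty * f01 + tx * ty * f11
}

# Upper-triangle (i < j) vector of a square matrix.
upper_vec <- function(m) m[upper.tri(m)]

as_conn_matrix <- function(x) {
  if (is(x, "ConnectivityMatrix")) x@probs else as.matrix(x)
}

check_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  invisible(m)
}

check_symmetric <- function(m, what = "matrix", tol = 1e-9) {
  check_square(m, what)
  if (max(abs(m - t(m))) > tol) {
    stop(what, " must be symmetric (symmetrize it first)", call. = FALSE)
  }
  invisible(m)
}
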