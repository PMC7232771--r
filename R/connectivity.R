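#' Construct a ConnectivityMatrix from a plain matrix
#'
#' @param m square nonnegative matrix; dimnames (if any) become node ids.
#' @param generations generation count the matrix represents.
#' @param symmetrization symmetrization mode already applied, if any.
#' @return A [ConnectivityMatrix-class].
#' @export
connectivityMatrix <- function(m, generations = 1L, symmetrization = "none") {
  m <- as.matrix(m)
  check_square(m, "connectivity matrix")
  if (is.null(rownames(m))) {
    ids <- as.character(seq_len(nrow(m)))
    dimnames(m) <- list(ids, ids)
  }
  new("ConnectivityMatrix", probs = pmin(m, 1), rawProbs = m,
      generations = as.integer(generations), symmetrization = symmetrization)
}

#' @param raw return the raw accumulated matrix instead of the capped one.
#' @rdname accessors
#' @export
setMethod("connProbs", "ConnectivityMatrix", function(x, raw = FALSE) {
  if (raw) x@rawProbs else x@probs
})

#' @rdname accessors
#' @export
setMethod("nodeIds", "ConnectivityMatrix", function(x) rownames(x@probs))

#' @rdname accessors
#' @export
setMethod("generations", "ConnectivityMatrix", function(x) x@generations)

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf(
    "ConnectivityMatrix: %d nodes, G = %d, symmetrization = %s\n  row sums (capped): [%.3g, %.3g]\n",
    nrow(object@probs), object@generations, object@symmetrization,
    min(rowSums(object@probs)), max(rowSums(object@probs))))
})

#' Multigenerational stepping-stone connectivity
#'
#' Accumulate dispersal over `G` generations by summing matrix powers:
#' `S_G = M + M^2 + ... + M^G`, computed by iterated multiplication. `M^g`
#' carries the probability of a lineage following any g-step route through
#' intermediate nodes, so the sum captures stepping-stone connectivity over
#' all routes of up to `G` generations. Both the raw sum and its elementwise
#' cap at 1 are kept; the capped form (a probability-like quantity) is the
#' default downstream.
#'
#' @param M a single-generation [ConnectivityMatrix-class] (or plain matrix).
#' @param G number of generations (>= 1); 64 spans basin-scale stepping-stone
#'   dispersal at a mean per-generation displacement of a few tens of km.
#' @return A [ConnectivityMatrix-class] with `generations = G`; access the
#'   raw sum with `connProbs(x, raw = TRUE)`.
#' @export
multigenConnectivity <- function(M, G = 64L) {
  if (is(M, "ConnectivityMatrix")) {
    if (M@generations != 1L) stop("M must be a single-generation matrix")
    m <- M@probs
  } else {
    m <- as.matrix(M)
  }
  check_square(m, "connectivity matrix")
  G <- as.integer(G)
  if (G < 1L) stop("G must be at least 1")
  acc <- m
  pow <- m
  for (g in seq_len(G - 1L)) {
    pow <- pow %*% m
    acc <- acc + pow
  }
  new("ConnectivityMatrix", probs = pmin(acc, 1), rawProbs = acc,
      generations = G, symmetrization = "none")
}

#' @rdname symmetrize
#' @export
setMethod("symmetrize", "matrix", function(x, mode = c("mean", "min", "max")) {
  mode <- match.arg(mode)
  check_square(x, "matrix")
  out <- switch(mode,
    mean = (x + t(x)) / 2,
    min = pmin(x, t(x)),
    max = pmax(x, t(x)))
  diag(out) <- diag(x)
  out
})

#' @rdname symmetrize
#' @export
setMethod("symmetrize", "ConnectivityMatrix", function(x, mode = c("mean", "min", "max")) {
  mode <- match.arg(mode)
  new("ConnectivityMatrix",
      probs = symmetrize(x@probs, mode),
      rawProbs = symmetrize(x@rawProbs, mode),
      generations = x@generations, symmetrization = mode)
})

#' @rdname logConnectivity
#' @export
setMethod("logConnectivity", "matrix", function(x, offset = 1e-50) {
  if (any(x < 0)) stop("connectivity entries must be nonnegative")
  log10(x + offset)
})

#' @rdname logConnectivity
#' @export
setMethod("logConnectivity", "ConnectivityMatrix", function(x, offset = 1e-50) {
  logConnectivity(x@probs, offset)
})

#' Aggregate cell-level connectivity to site level
#'
#' Site pair `(a, b)` receives the mean of the cell-level matrix over all
#' source cells of `a` crossed with all destination cells of `b`. Sites are
#' mapped to their nearest habitat cells within a search radius.
#'
#' @param M a cell-level [ConnectivityMatrix-class].
#' @param siteCells named list: site id -> integer vector of habitat cell ids
#'   (as found in `nodeIds(M)`), each non-empty. See [mapSitesToCells()].
#' @param raw aggregate the raw matrix instead of the capped one.
#' @return A [ConnectivityMatrix-class] over sites (raw and capped slots both
#'   aggregated).
#' @export
siteConnectivity <- function(M, siteCells, raw = FALSE) {
  ids <- nodeIds(M)
  idx <- lapply(siteCells, function(cells) {
    i <- match(as.character(cells), ids)
    if (length(i) == 0L || any(is.na(i))) {
      stop("every site must map to at least one habitat cell present in M")
    }
    i
  })
  agg <- function(m) {
    s <- length(idx)
    out <- matrix(0, s, s, dimnames = list(names(idx), names(idx)))
    for (a in seq_len(s)) for (b in seq_len(s)) {
      out[a, b] <- mean(m[idx[[a]], idx[[b]]])
    }
    out
  }
  new("ConnectivityMatrix", probs = agg(M@probs), rawProbs = agg(M@rawProbs),
      generations = M@generations, symmetrization = M@symmetrization)
}

#' Map site coordinates to habitat cells
#'
#' Assign each site its nearest habitat cell (by cell-center distance),
#' erroring when none lies within the search radius.
#'
#' @param grid a [SeascapeGrid-class].
#' @param sites data.frame with `site_id`, `x_km`, `y_km`.
#' @param radiusKm maximum site-to-cell-center distance.
#' @return Named list of integer cell ids, one per site.
#' @export
mapSitesToCells <- function(grid, sites, radiusKm = 2 * grid@cellSizeKm) {
  hab <- habitatCells(grid)
  cc <- cellCenters(grid, hab)
  out <- lapply(seq_len(nrow(sites)), function(k) {
    d <- sqrt((cc[, 1] - sites$x_km[k])^2 + (cc[, 2] - sites$y_km[k])^2)
    if (min(d) > radiusKm) {
      stop("site ", sites$site_id[k], " has no habitat cell within ",
           radiusKm, " km")
    }
    hab[which.min(d)]
  })
  names(out) <- sites$site_id
  out
}

#' Read/write dense connectivity CSV
#'
#' Dense CSV with node ids as header row and first column; a YAML sidecar
#' (`<path>.meta.yaml`) records the generation count and symmetrization mode.
#'
#' @param x a [ConnectivityMatrix-class].
#' @param path CSV file path.
#' @return `readConnectivityCsv` returns a [ConnectivityMatrix-class].
#' @export
writeConnectivityCsv <- function(x, path) {
  df <- data.frame(node_id = nodeIds(x), x@probs, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(generations = x@generations,
                        symmetrization = x@symmetrization,
                        capped = TRUE),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname writeConnectivityCsv
#' @export
readConnectivityCsv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df$node_id, colnames(df)[-1])
  metaPath <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(metaPath)) yaml::read_yaml(metaPath) else list()
  new("ConnectivityMatrix", probs = pmin(m, 1), rawProbs = m,
      generations = as.integer(meta$generations %||% 1L),
      symmetrization = meta$symmetrization %||% "none")
}
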