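#' @import methods
#' @importFrom stats cor lm pchisq pf quantile rbinom rnorm runif sd setNames
#'   fisher.test cmdscale as.dist coef anova drop1 complete.cases pnorm ave
#' @importFrom utils head read.csv write.csv
#' @importFrom tools md5sum
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' SeascapeGrid: a discretized coastal domain
#'
#' Regular planar grid of square cells holding a land/sea mask, mean depth,
#' a habitat mask (sea cells shallower than the habitat depth limit), and
#' environmental fields (salinity, temperature). Cells are indexed by their
#' R-native linear index over the `(nx, ny)` cell matrix; the center of cell
#' `(ix, iy)` lies at `((ix - 0.5) * cellSizeKm, (iy - 0.5) * cellSizeKm)`.
#' Geometry is planar; the domain is abstract, not georeferenced.
#'
#' @slot cellSizeKm positive cell edge length in km.
#' @slot landMask logical `nx x ny` matrix, `TRUE` on land.
#' @slot depthM numeric matrix of mean cell depth (m), `NA` on land.
#' @slot habitatMask logical matrix: sea cells with depth below the limit.
#' @slot salinityPsu,temperatureC numeric environmental fields (psu, deg C).
#' @slot habitatDepthLimit depth cutoff (m) defining habitat, default 30.
#'
#' @export
setClass("SeascapeGrid",
  representation(
    cellSizeKm = "numeric",
    landMask = "matrix",
    depthM = "matrix",
    habitatMask = "matrix",
    salinityPsu = "matrix",
    temperatureC = "matrix",
    habitatDepthLimit = "numeric"
  )
)

setValidity("SeascapeGrid", function(object) {
  msgs <- character()
  d <- dim(object@landMask)
  for (sl in c("depthM", "habitatMask", "salinityPsu", "temperatureC")) {
    if (!identical(dim(slot(object, sl)), d)) {
      msgs <- c(msgs, sprintf("slot '%s' must have the same shape as landMask", sl))
    }
  }
  if (length(object@cellSizeKm) != 1L || !is.finite(object@cellSizeKm) ||
      object@cellSizeKm <= 0) {
    msgs <- c(msgs, "cellSizeKm must be a single positive number")
  }
  if (length(msgs) == 0L) {
    if (any(object@habitatMask & object@landMask)) {
      msgs <- c(msgs, "habitat cells must be sea cells")
    }
    sea <- !object@landMask
    if (any(sea & !is.finite(object@depthM))) {
      msgs <- c(msgs, "depth must be finite on sea cells")
    } else if (any(object@depthM[sea] < 0)) {
      msgs <- c(msgs, "depth must be nonnegative on sea cells")
    }
    hab <- object@habitatMask
    if (any(hab) && any(object@depthM[hab] >= object@habitatDepthLimit)) {
      msgs <- c(msgs, "habitat cells must be shallower than habitatDepthLimit")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' VelocityField: surface current components on a SeascapeGrid
#'
#' Horizontal velocity components (m/s) at cell centers, zero on land.
#' The field is stationary in time; the seasonal release window lives in the
#' release schedule, and `seasonalWindow` here is descriptive metadata only.
#'
#' @slot u,v numeric matrices (m/s), same shape as the grid.
#' @slot seasonalWindow integer months the field is meant to represent.
#'
#' @export
setClass("VelocityField",
  representation(u = "matrix", v = "matrix", seasonalWindow = "integer")
)

setValidity("VelocityField", function(object) {
  if (!identical(dim(object@u), dim(object@v))) {
    return("u and v must have the same shape")
  }
  if (!all(is.finite(object@u)) || !all(is.finite(object@v))) {
    return("velocity components must be finite everywhere")
  }
  TRUE
})

#' ParticleEnsemble: released, settled and lost particles
#'
#' One row per particle: source habitat cell, release index, trajectory end
#' position (km), destination habitat cell (`NA` when lost) and the lost flag.
#'
#' @slot particles data.frame with columns `particle_id`, `src_cell`,
#'   `release`, `end_x`, `end_y`, `dest_cell`, `lost`.
#' @slot released named integer vector: particles released per source cell.
#'
#' @export
setClass("ParticleEnsemble",
  representation(particles = "data.frame", released = "integer")
)

setValidity("ParticleEnsemble", function(object) {
  need <- c("particle_id", "src_cell", "release", "end_x", "end_y",
            "dest_cell", "lost")
  if (!all(need %in% names(object@particles))) {
    return(paste("particles must have columns:", paste(need, collapse = ", ")))
  }
  p <- object@particles
  if (any(p$lost & !is.na(p$dest_cell))) {
    return("lost particles cannot have a destination cell")
  }
  if (any(!p$lost & is.na(p$dest_cell))) {
    return("non-lost particles must have a destination cell")
  }
  TRUE
})

#' ConnectivityMatrix: normalized source-to-destination dispersal probabilities
#'
#' Square nonnegative matrix whose `(i, j)` element is the probability that a
#' propagule released at node `i` settles at node `j`. Single-generation rows
#' sum to at most 1 (the deficit is the lost fraction). Multigenerational
#' accumulations keep both the raw matrix-power sum and its elementwise cap at
#' 1; the capped form is the default downstream because the quantity is read
#' as a dispersal probability.
#'
#' @slot probs the default (capped) matrix, dimnames = node ids.
#' @slot rawProbs the raw accumulated matrix (equals `probs` for G = 1).
#' @slot generations integer generation count G.
#' @slot symmetrization one of "none", "min", "max", "mean".
#'
#' @export
setClass("ConnectivityMatrix",
  representation(
    probs = "matrix",
    rawProbs = "matrix",
    generations = "integer",
    symmetrization = "character"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  m <- object@probs
  if (nrow(m) != ncol(m)) return("connectivity matrix must be square")
  if (!identical(dim(m), dim(object@rawProbs))) {
    return("probs and rawProbs must have the same shape")
  }
  if (any(m < 0) || any(object@rawProbs < 0)) {
    return("connectivity entries must be nonnegative")
  }
  if (any(m > 1 + 1e-9)) {
    return("capped connectivity entries must be at most 1")
  }
  if (object@generations == 1L && object@symmetrization == "none" &&
      any(rowSums(object@rawProbs) > 1 + 1e-9)) {
    return("single-generation rows must sum to at most 1")
  }
  if (!object@symmetrization %in% c("none", "min", "max", "mean")) {
    return("symmetrization must be one of none/min/max/mean")
  }
  TRUE
})

#' ClusterAssignment: a barrier-delimited partition of habitat nodes
#'
#' @slot labels integer cluster label per node, named by node id.
#' @slot threshold the mean crossing-probability threshold theta.
#' @slot strengths data.frame of per-cluster-pair mean crossing probabilities.
#' @slot K number of clusters.
#'
#' @export
setClass("ClusterAssignment",
  representation(
    labels = "integer",
    threshold = "numeric",
    strengths = "data.frame",
    K = "integer"
  )
)

setValidity("ClusterAssignment", function(object) {
  if (any(is.na(object@labels))) return("every node must be labeled")
  if (length(object@threshold) != 1L || object@threshold <= 0) {
    return("threshold must be a single positive number")
  }
  if (nrow(object@strengths) > 0 &&
      any(object@strengths$mean_crossing > object@threshold + 1e-12)) {
    return("all inter-cluster mean crossing probabilities must be <= threshold")
  }
  TRUE
})

#' GenotypeDataset: diploid biallelic genotypes grouped into site samples
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]. The single assay
#' `"dosage"` holds alt-allele dosages (0/1/2, `NA` for missing calls) with
#' loci as rows and individuals as columns; `colData` carries the individual
#' to site mapping; the site metadata table (coordinates, region, salinity,
#' temperature, MPA flag) is stored in `metadata(x)$siteTable`.
#'
#' @export
setClass("GenotypeDataset", contains = "SummarizedExperiment")

setValidity("GenotypeDataset", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'dosage' is required")
  }
  g <- SummarizedExperiment::assay(object, "dosage")
  bad <- !is.na(g) & !(g %in% c(0, 1, 2))
  if (any(bad)) return("dosages must be 0, 1, 2 or NA")
  if (!"site" %in% names(SummarizedExperiment::colData(object))) {
    return("colData must contain a 'site' column")
  }
  st <- S4Vectors::metadata(object)$siteTable
  if (is.null(st) || !"site_id" %in% names(st)) {
    return("metadata(x)$siteTable with a site_id column is required")
  }
  sites <- unique(as.character(SummarizedExperiment::colData(object)$site))
  if (!all(sites %in% st$site_id)) {
    return("every individual's site must appear in the site table")
  }
  TRUE
})

#' MantelResult: a matrix-correlation permutation test result
#'
#' @slot r Pearson correlation of the off-diagonal (upper-triangle) vectors.
#' @slot p two-sided permutation p-value with the +1 correction.
#' @slot nPerm number of permutations used.
#' @slot seed RNG seed (NA when an explicit permutation set was supplied).
#' @slot degenerate TRUE when one off-diagonal vector was constant.
#'
#' @export
setClass("MantelResult",
  representation(r = "numeric", p = "numeric", nPerm = "integer",
                 seed = "numeric", degenerate = "logical")
)

#' RegressionResult: an OLS fit with ANOVA table and VIF screening record
#'
#' @slot coefficients data.frame: term, estimate, se, t, p.
#' @slot r2,adjR2 coefficient of determination (plain and adjusted).
#' @slot anovaTable per-factor marginal F tests (drop-one).
#' @slot vif named variance inflation factors of the retained predictors.
#' @slot dropped predictors removed by the VIF screen, in drop order.
#' @slot n number of observations.
#'
#' @export
setClass("RegressionResult",
  representation(
    coefficients = "data.frame",
    r2 = "numeric",
    adjR2 = "numeric",
    anovaTable = "data.frame",
    vif = "numeric",
    dropped = "character",
    n = "integer"
  )
)
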