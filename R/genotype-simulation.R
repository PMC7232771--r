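#' Demography configuration for the stepping-stone genotype simulator
#'
#' Free parameters of the Wright-Fisher stepping-stone model (no field
#' estimates exist for them; they are simulation knobs, not inferences).
#'
#' @param N diploid effective size per deme.
#' @param m migration fraction in `[0, 1]`: the share of each deme's gamete
#'   pool drawn from donor demes each generation.
#' @param nLoci number of independent biallelic loci.
#' @param nGenerations generations simulated.
#' @param nIndPerSite diploid individuals sampled per site at the end.
#' @param initFreqRange range of the uniform ancestral allele frequencies;
#'   the default `[0.1, 0.9]` avoids immediate fixation.
#' @param missingRate probability a genotype call is masked as missing
#'   (default 0; 0.2 mimics an 80% call-rate dataset).
#' @param founderSchedule optional serial-founder (colonization-front) plan:
#'   `list(order = <deme indices in colonization order>, interval = <gens
#'   between colonizations>, founderSize = <diploid founders>)`. Each deme is
#'   founded from the previous deme in the order through a founder
#'   bottleneck; repeated bottlenecks erode heterozygosity along the front.
#' @param seed RNG seed.
#' @return A list of class `"DemographyConfig"`.
#' @export
demographyConfig <- function(N = 100L, m = 0.1, nLoci = 1000L,
                             nGenerations = 200L, nIndPerSite = 20L,
                             initFreqRange = c(0.1, 0.9), missingRate = 0,
                             founderSchedule = NULL, seed = 1L) {
  stopifnot(N >= 1, m >= 0, m <= 1, nLoci >= 1, nGenerations >= 1,
            missingRate >= 0, missingRate < 1)
  structure(list(N = as.integer(N), m = m, nLoci = as.integer(nLoci),
                 nGenerations = as.integer(nGenerations),
                 nIndPerSite = as.integer(nIndPerSite),
                 initFreqRange = initFreqRange, missingRate = missingRate,
                 founderSchedule = founderSchedule, seed = seed),
            class = "DemographyConfig")
}

#' Simulate genotypes under connectivity-driven stepping-stone demography
#'
#' Diploid Wright-Fisher simulation on the demes defined by a site table,
#' with migration structured by a dispersal connectivity matrix. Each
#' generation a deme draws a fraction `m` of its gamete pool from donor
#' demes in proportion to its column-normalized incoming connectivity (the
#' source-to-destination matrix is converted to an immigration mixture so
#' sampling stays well defined when rows lose mass to open boundaries), the
#' remainder locally; allele frequencies then drift by binomial sampling of
#' `2N` gametes. Ancestral frequencies are shared across demes, drawn
#' uniformly from `initFreqRange`. Loci are independent; there is no
#' mutation or selection.
#'
#' With a `founderSchedule`, demes are colonized serially: deme `k` in the
#' order is founded at generation `(k - 1) * interval` from the previous
#' deme through a bottleneck of `founderSize` diploid founders;
#' not-yet-colonized demes neither receive nor donate migrants.
#'
#' At the end, `nIndPerSite` individuals per deme are sampled assuming
#' Hardy-Weinberg proportions, optionally masked at `missingRate`.
#'
#' @param conn a site-level single-generation [ConnectivityMatrix-class] or
#'   square matrix; node order must match `sites` rows.
#' @param demo a [demographyConfig()].
#' @param sites site metadata data.frame (`site_id`, `x_km`, `y_km`,
#'   `region`, `salinity_psu`, `temp_C`, `mpa`).
#' @return A [GenotypeDataset-class].
#' @export
simulateGenotypes <- function(conn, demo, sites) {
  m <- as_conn_matrix(conn)
  check_square(m, "connectivity matrix")
  d <- nrow(m)
  if (nrow(sites) != d) stop("sites rows must match connectivity nodes")
  mig <- demo$m

  # immigration mixture: W[j, i] = P(migrant into j came from i)
  colsum <- colSums(m)
  isolated <- mig > 0 & colsum == 0
  if (any(isolated)) {
    warning("deme(s) with no incoming connectivity treated as isolated: ",
            paste(sites$site_id[isolated], collapse = ", "))
  }
  W <- t(m) / ifelse(colsum == 0, 1, colsum)  # W[j, i]; rows sum to 1 (or 0)

  L <- demo$nLoci
  fs <- demo$founderSchedule
  p <- with_seed(sub_seed(demo$seed, 1L),
                 runif(L, demo$initFreqRange[1], demo$initFreqRange[2]))
  P <- matrix(rep(p, each = d), d, L)

  colonized <- rep(TRUE, d)
  colTime <- rep(0L, d)
  if (!is.null(fs)) {
    ord <- fs$order
    interval <- fs$interval %||% 5L
    colonized <- rep(FALSE, d)
    colonized[ord[1]] <- TRUE
    colTime[ord] <- (seq_along(ord) - 1L) * interval
    P[!colonized, ] <- NA_real_
  }

  genSeed <- sub_seed(demo$seed, 2L)
  P <- with_seed(genSeed, {
    for (g in seq_len(demo$nGenerations)) {
      if (!is.null(fs)) {
        newly <- which(!colonized & colTime == g - 1L & seq_len(d) %in% fs$order)
        for (j in newly) {
          src <- fs$order[match(j, fs$order) - 1L]
          nf <- 2L * (fs$founderSize %||% 5L)
          P[j, ] <- rbinom(L, nf, P[src, ]) / nf
          colonized[j] <- TRUE
        }
      }
      act <- which(colonized)
      Pact <- P[act, , drop = FALSE]
      if (mig > 0 && length(act) > 1L) {
        Wact <- W[act, act, drop = FALSE]
        rs <- rowSums(Wact)
        ok <- rs > 0
        Wact[ok, ] <- Wact[ok, , drop = FALSE] / rs[ok]
        inc <- Wact %*% Pact
        eff <- ifelse(ok, mig, 0)
        Pmig <- (1 - eff) * Pact + eff * inc
      } else {
        Pmig <- Pact
      }
      P[act, ] <- matrix(rbinom(length(Pmig), 2L * demo$N, as.vector(Pmig)),
                         nrow(Pmig), ncol(Pmig)) / (2 * demo$N)
    }
    P
  })
  if (any(!colonized)) {
    warning("deme(s) never colonized within the simulated generations: ",
            paste(sites$site_id[!colonized], collapse = ", "))
    P[!colonized, ] <- 0
  }

  nInd <- demo$nIndPerSite
  geno <- with_seed(sub_seed(demo$seed, 3L), {
    g <- matrix(0L, L, d * nInd)
    for (j in seq_len(d)) {
      cols <- (j - 1L) * nInd + seq_len(nInd)
      g[, cols] <- matrix(rbinom(L * nInd, 2L, rep(P[j, ], nInd)), L, nInd)
    }
    g
  })
  if (demo$missingRate > 0) {
    mask <- with_seed(sub_seed(demo$seed, 4L),
                      matrix(runif(length(geno)) < demo$missingRate,
                             nrow(geno), ncol(geno)))
    geno[mask] <- NA_integer_
  }
  indSite <- rep(as.character(sites$site_id), each = nInd)
  indId <- paste0(indSite, "_", rep(seq_len(nInd), d))
  lociId <- sprintf("L%05d", seq_len(L))
  genotypeDataset(geno, indSite, sites, individualIds = indId, lociIds = lociId)
}

#' Assemble a GenotypeDataset
#'
#' @param dosage integer matrix, loci x individuals, values 0/1/2/NA.
#' @param indSites character vector: site id of each individual (column).
#' @param sites site metadata data.frame with at least `site_id`.
#' @param individualIds,lociIds optional dimnames.
#' @return A [GenotypeDataset-class].
#' @export
genotypeDataset <- function(dosage, indSites, sites, individualIds = NULL,
                            lociIds = NULL) {
  dosage <- as.matrix(dosage)
  if (!is.null(individualIds)) colnames(dosage) <- individualIds
  if (!is.null(lociIds)) rownames(dosage) <- lociIds
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0(indSites, "_", stats::ave(
      seq_along(indSites), indSites, FUN = seq_along))
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("L%05d", seq_len(nrow(dosage)))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    colData = S4Vectors::DataFrame(site = as.character(indSites),
                                   row.names = colnames(dosage)),
    metadata = list(siteTable = as.data.frame(sites))
  )
  new("GenotypeDataset", se)
}

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeDataset", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setMethod("siteTable", "GenotypeDataset", function(x)
  S4Vectors::metadata(x)$siteTable)

#' @rdname accessors
#' @export
setMethod("siteOf", "GenotypeDataset", function(x)
  as.character(SummarizedExperiment::colData(x)$site))

setMethod("show", "GenotypeDataset", function(object) {
  g <- dosages(object)
  cat(sprintf(
    "GenotypeDataset: %d loci x %d individuals in %d sites (%.1f%% missing)\n",
    nrow(g), ncol(g), length(unique(siteOf(object))), 100 * mean(is.na(g))))
})
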