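# Per-site, per-locus sufficient statistics: non-missing sample size n,
# alt-allele frequency p, observed heterozygote proportion h.
site_locus_stats <- function(x) {
  g <- dosages(x)
  sites <- siteOf(x)
  uniq <- unique(sites)
  L <- nrow(g)
  n <- p <- h <- matrix(0, length(uniq), L, dimnames = list(uniq, rownames(g)))
  for (k in seq_along(uniq)) {
    gs <- g[, sites == uniq[k], drop = FALSE]
    nk <- rowSums(!is.na(gs))
    n[k, ] <- nk
    p[k, ] <- ifelse(nk > 0, rowSums(gs, na.rm = TRUE) / (2 * nk), NA_real_)
    h[k, ] <- ifelse(nk > 0, rowSums(gs == 1L, na.rm = TRUE) / nk, NA_real_)
  }
  list(sites = uniq, n = n, p = p, h = h)
}

#' Per-locus allele frequencies for one site
#'
#' Sample alt-allele frequency `p = (alt dosage sum) / (2 * non-missing
#' individuals)` per locus; loci with no calls at the site are flagged.
#'
#' @param x a [GenotypeDataset-class].
#' @param site a site id present in the dataset.
#' @return data.frame with `locus`, `p_alt`, `n_alleles`, `all_missing`.
#' @export
alleleFreqs <- function(x, site) {
  sites <- siteOf(x)
  if (!site %in% sites) stop("unknown site: ", site)
  g <- dosages(x)[, sites == site, drop = FALSE]
  n <- rowSums(!is.na(g))
  data.frame(
    locus = rownames(g),
    p_alt = ifelse(n > 0, rowSums(g, na.rm = TRUE) / (2 * n), NA_real_),
    n_alleles = 2L * n,
    all_missing = n == 0L,
    row.names = NULL
  )
}

#' Per-site genetic diversity: He, Ho and FIS
#'
#' Per locus, unbiased expected heterozygosity
#' `He = (2n / (2n - 1)) * (1 - p^2 - q^2)` (Nei's small-sample correction,
#' `n` = non-missing individuals) and observed heterozygosity `Ho` = the
#' heterozygote fraction. Site-level `He` and `Ho` are means over all loci
#' (monomorphic loci contribute 0); `FIS = 1 - Ho/He` is averaged over
#' polymorphic loci only. Near-zero FIS indicates within-site panmixia.
#'
#' @param x a [GenotypeDataset-class]; every site needs >= 2 individuals.
#' @return data.frame with `site_id`, `n_ind`, `He`, `Ho`, `FIS`.
#' @export
siteDiversity <- function(x) {
  st <- site_locus_stats(x)
  nInd <- table(siteOf(x))[st$sites]
  if (any(nInd < 2)) {
    stop("site(s) with fewer than 2 individuals: ",
         paste(st$sites[nInd < 2], collapse = ", "))
  }
  out <- lapply(seq_along(st$sites), function(k) {
    n <- st$n[k, ]; p <- st$p[k, ]; h <- st$h[k, ]
    ok <- n > 0
    n <- n[ok]; p <- p[ok]; h <- h[ok]
    he <- (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
    poly <- he > 0
    fis <- if (any(poly)) mean(1 - h[poly] / he[poly]) else NA_real_
    data.frame(site_id = st$sites[k], n_ind = as.integer(nInd[k]),
               He = mean(he), Ho = mean(h), FIS = fis)
  })
  do.call(rbind, out)
}

# Weir-Cockerham (1984) two-sample variance components per locus, from the
# per-site sufficient statistics. Returns a, b, c vectors over loci.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Pairwise multilocus FST (Weir-Cockerham 1984)
#'
#' For each site pair, the ratio-of-averages estimator
#' `theta = sum_l a_l / sum_l (a_l + b_l + c_l)` over loci genotyped in both
#' samples (with at least 2 called individuals on each side). Estimates are
#' not clamped, so slightly negative values can occur at low differentiation;
#' clamp to zero only when a true distance is needed (e.g. before MDS).
#'
#' @param x a [GenotypeDataset-class] with >= 2 sites.
#' @return A list with `fst` (symmetric matrix, diagonal 0) and `nLoci`
#'   (per-pair loci used).
#' @export
pairwiseFst <- function(x) {
  st <- site_locus_stats(x)
  s <- length(st$sites)
  if (s < 2L) stop("pairwise FST needs at least 2 sites")
  fst <- matrix(0, s, s, dimnames = list(st$sites, st$sites))
  nl <- matrix(0L, s, s, dimnames = list(st$sites, st$sites))
  for (i in seq_len(s - 1)) for (j in (i + 1):s) {
    ok <- st$n[i, ] >= 2 & st$n[j, ] >= 2
    comp <- wc_components(st$n[i, ok], st$n[j, ok], st$p[i, ok], st$p[j, ok],
                          st$h[i, ok], st$h[j, ok])
    denom <- sum(comp$a + comp$b + comp$c)
    if (sum(ok) == 0L || denom == 0) {
      stop("no shared polymorphic loci for pair ",
           st$sites[i], " / ", st$sites[j])
    }
    fst[i, j] <- fst[j, i] <- sum(comp$a) / denom
    nl[i, j] <- nl[j, i] <- sum(ok)
  }
  list(fst = fst, nLoci = nl)
}

#' Genic differentiation exact test for a site pair
#'
#' Per locus, a two-sided Fisher exact test on the 2x2 allele-count table
#' (ref/alt by site); loci monomorphic across both samples are skipped.
#' Per-locus p-values are combined across loci with Fisher's method
#' (`-2 * sum(log p)` against chi-square with `2L` df), assuming independent
#' loci.
#'
#' @param x a [GenotypeDataset-class].
#' @param siteA,siteB site ids.
#' @return list with `perLocus` (data.frame `locus`, `p`) and `combinedP`.
#' @export
genicTest <- function(x, siteA, siteB) {
  fa <- alleleFreqs(x, siteA)
  fb <- alleleFreqs(x, siteB)
  altA <- round(fa$p_alt * fa$n_alleles); refA <- fa$n_alleles - altA
  altB <- round(fb$p_alt * fb$n_alleles); refB <- fb$n_alleles - altB
  keep <- which(fa$n_alleles > 0 & fb$n_alleles > 0 &
                (altA + altB > 0) & (refA + refB > 0))
  if (length(keep) == 0L) stop("no testable (polymorphic) loci for this pair")
  p <- vapply(keep, function(l) {
    fisher.test(matrix(c(refA[l], altA[l], refB[l], altB[l]), 2, 2))$p.value
  }, numeric(1))
  combined <- pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
  list(perLocus = data.frame(locus = fa$locus[keep], p = p),
       combinedP = combined)
}

#' Individual identity-by-state distance matrix
#'
#' Per pair of individuals, per-locus IBS is `1 - |d1 - d2| / 2` on shared
#' non-missing loci, and the distance is `1 - mean(IBS)`.
#'
#' @param x a [GenotypeDataset-class] with >= 2 individuals.
#' @return symmetric distance matrix over individuals, diagonal 0.
#' @export
ibsDistance <- function(x) {
  g <- dosages(x)
  n <- ncol(g)
  if (n < 2L) stop("IBS distance needs at least 2 individuals")
  d <- matrix(0, n, n, dimnames = list(colnames(g), colnames(g)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- !is.na(g[, i]) & !is.na(g[, j])
    if (!any(shared)) stop("individuals ", colnames(g)[i], " and ",
                           colnames(g)[j], " share no called loci")
    ibs <- 1 - abs(g[shared, i] - g[shared, j]) / 2
    d[i, j] <- d[j, i] <- 1 - mean(ibs)
  }
  d
}

#' Metric (classical) multidimensional scaling of a distance matrix
#'
#' Classical scaling via double centering and eigen-decomposition
#' (`stats::cmdscale`), with negative entries (possible for unclamped FST)
#' clamped to zero first. Variance explained per axis is each positive
#' eigenvalue's share of the positive-eigenvalue total. Coordinates are
#' deterministic up to axis sign.
#'
#' @param m symmetric matrix with zero diagonal (small negative entries
#'   allowed; they are clamped).
#' @param k number of axes requested; truncated with a warning if it exceeds
#'   the number of positive eigenvalues.
#' @return list with `points` (n x k'), `eig`, `varExplained`.
#' @export
metricMDS <- function(m, k = 2) {
  check_symmetric(m, "distance matrix", tol = 1e-8)
  m <- pmax(m, 0)
  diag(m) <- 0
  fit <- cmdscale(as.dist(m), k = min(k, nrow(m) - 1), eig = TRUE)
  pos <- fit$eig[fit$eig > 1e-12]
  kEff <- min(k, length(pos))
  if (kEff < k) {
    warning("only ", kEff, " positive eigenvalue(s); axes truncated")
  }
  pts <- fit$points
  if (is.null(dim(pts)) || ncol(pts) == 0) {
    pts <- matrix(0, nrow(m), kEff, dimnames = list(rownames(m), NULL))
  } else {
    pts <- pts[, seq_len(min(kEff, ncol(pts))), drop = FALSE]
  }
  if (kEff == 0) pts <- matrix(0, nrow(m), 0, dimnames = list(rownames(m), NULL))
  list(points = pts, eig = fit$eig,
       varExplained = if (length(pos)) (pos / sum(pos))[seq_len(kEff)] else numeric(0))
}
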