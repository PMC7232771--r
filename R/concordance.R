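#' Mantel permutation test between two symmetric matrices
#'
#' Pearson correlation `r` of the upper-triangle vectors, with significance
#' from jointly permuting the rows and columns of `B`. The p-value is
#' two-sided with the add-one correction:
#' `p = (1 + #\{|r_perm| >= |r_obs|\}) / (nPerm + 1)`.
#'
#' If either off-diagonal vector is constant, the correlation is undefined
#' and a degenerate result (NA statistic and p-value, `degenerate = TRUE`)
#' is returned.
#'
#' @param A,B symmetric matrices with identical shape and node order.
#' @param nPerm number of random permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @param perms optional explicit permutation set (matrix, one permutation of
#'   `1:n` per row), e.g. all `n!` orderings for an exhaustive test; then
#'   `p = mean(|r_perm| >= |r_obs|)` over the supplied set and `seed` is
#'   ignored.
#' @return A [MantelResult-class].
#' @export
mantelTest <- function(A, B, nPerm = 9999L, seed = 1L, perms = NULL) {
  check_symmetric(A, "A"); check_symmetric(B, "B")
  if (!identical(dim(A), dim(B))) stop("A and B must have the same shape")
  if (is.null(perms) && nPerm < 1) stop("nPerm must be at least 1")
  va <- upper_vec(A)
  vb <- upper_vec(B)
  if (sd(va) == 0 || sd(vb) == 0) {
    return(new("MantelResult", r = NA_real_, p = NA_real_,
               nPerm = 0L, seed = NA_real_, degenerate = TRUE))
  }
  rObs <- cor(va, vb)
  n <- nrow(B)
  perm_r <- function(idx) {
    vbp <- upper_vec(B[idx, idx])
    if (sd(vbp) == 0) return(0)
    cor(va, vbp)
  }
  eps <- 1e-12
  if (!is.null(perms)) {
    rs <- apply(perms, 1, perm_r)
    p <- mean(abs(rs) >= abs(rObs) - eps)
    return(new("MantelResult", r = rObs, p = p, nPerm = nrow(perms),
               seed = NA_real_, degenerate = FALSE))
  }
  rs <- with_seed(seed, vapply(seq_len(nPerm), function(k)
    perm_r(sample.int(n)), numeric(1)))
  p <- (1 + sum(abs(rs) >= abs(rObs) - eps)) / (nPerm + 1)
  new("MantelResult", r = rObs, p = p, nPerm = as.integer(nPerm),
      seed = as.numeric(seed), degenerate = FALSE)
}

setMethod("show", "MantelResult", function(object) {
  if (object@degenerate) {
    cat("MantelResult: degenerate (constant off-diagonal vector)\n")
  } else {
    cat(sprintf("MantelResult: r = %.4f, p = %.4g (%d permutations)\n",
                object@r, object@p, object@nPerm))
  }
})

#' Two-group isolation-by-distance regression
#'
#' Splits site pairs into those containing at least one flagged site versus
#' the rest, and fits ordinary least squares `FST ~ log-connectivity`
#' separately per group. Flagging the genetically isolated sites exposes
#' distinct IBD relationships (different intercepts/slopes) between pairs
#' touching them and all remaining pairs.
#'
#' @param fst symmetric FST matrix with site ids as dimnames.
#' @param logconn symmetric log-connectivity matrix, same order.
#' @param flaggedSites character vector of site ids (possibly empty); with an
#'   empty flag set, the "rest" group is simply all pairs.
#' @return list with elements `flagged` and `rest`, each `NULL` (group
#'   skipped, with a warning, when it has < 3 pairs) or a list with `slope`,
#'   `intercept`, `r2`, `p`, `n`; plus `pairs`, the per-pair data.
#' @export
ibdRegression <- function(fst, logconn, flaggedSites = character()) {
  check_symmetric(fst, "fst"); check_symmetric(logconn, "logconn")
  if (!identical(dim(fst), dim(logconn))) stop("matrices must match")
  ids <- rownames(fst) %||% as.character(seq_len(nrow(fst)))
  ut <- which(upper.tri(fst), arr.ind = TRUE)
  pairs <- data.frame(
    site_a = ids[ut[, 1]], site_b = ids[ut[, 2]],
    fst = fst[ut], logconn = logconn[ut],
    flagged = ids[ut[, 1]] %in% flaggedSites | ids[ut[, 2]] %in% flaggedSites
  )
  fit_group <- function(d, label) {
    if (nrow(d) < 3) {
      warning("group '", label, "' has fewer than 3 pairs; skipped")
      return(NULL)
    }
    f <- lm(fst ~ logconn, data = d)
    s <- summary(f)
    list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
         r2 = s$r.squared,
         p = unname(s$coefficients[2, 4]), n = nrow(d))
  }
  flagged <- if (any(pairs$flagged)) {
    fit_group(pairs[pairs$flagged, ], "flagged")
  } else NULL
  rest <- fit_group(pairs[!pairs$flagged, ], "rest")
  list(flagged = flagged, rest = rest, pairs = pairs)
}

# Variance inflation factors via auxiliary regressions: VIF_j = 1/(1 - R2_j)
# where R2_j is from regressing predictor j on the others. Handles exact
# collinearity (R2 = 1 -> Inf).
vif_aux <- function(X) {
  if (ncol(X) < 2L) return(setNames(rep(1, ncol(X)), colnames(X)))
  vapply(seq_len(ncol(X)), function(j) {
    f <- lm(X[, j] ~ X[, -j, drop = FALSE])
    # suppress the perfect-fit warning: R2 = 1 is exactly the signal sought
    r2 <- suppressWarnings(summary(f)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(X))
}

#' Heterozygosity-environment multiple regression with VIF screening
#'
#' Models per-site expected heterozygosity as a function of site covariates
#' (e.g. salinity, temperature, MPA status, coastline distance). Predictors
#' are first screened for collinearity: while any variance inflation factor
#' is at or above `vifLimit` (default 3), the predictor with the highest VIF
#' is dropped. The retained model is fit by OLS and each term is tested with
#' a marginal (drop-one) F test.
#'
#' @param diversity output of [siteDiversity()] (needs `site_id`, `He`).
#' @param env data.frame with `site_id` and predictor columns.
#' @param predictors predictor column names; default all non-`site_id`
#'   columns of `env`.
#' @param vifLimit drop predictors with VIF at or above this value.
#' @return A [RegressionResult-class].
#' @export
envRegression <- function(diversity, env,
                          predictors = setdiff(names(env), "site_id"),
                          vifLimit = 3) {
  d <- merge(diversity[, c("site_id", "He")], env, by = "site_id")
  d <- d[complete.cases(d[, c("He", predictors)]), ]
  keep <- predictors
  if (nrow(d) < length(keep) + 2) {
    stop("need at least p + 2 sites for p predictors")
  }
  repeat {
    X <- as.matrix(d[, keep, drop = FALSE])
    constant <- apply(X, 2, function(c) sd(c) == 0)
    if (any(constant)) { keep <- keep[!constant]; next }
    v <- vif_aux(X)
    if (length(keep) < 2L || max(v) < vifLimit) break
    worst <- names(v)[which.max(v)]
    keep <- setdiff(keep, worst)
  }
  if (length(keep) == 0L) stop("no predictors left after VIF screening")
  fml <- stats::as.formula(paste("He ~", paste(keep, collapse = " + ")))
  fit <- lm(fml, data = d)
  if (fit$df.residual == 0 || any(is.na(coef(fit)))) {
    stop("design is rank deficient after screening")
  }
  s <- summary(fit)
  dr <- drop1(fit, test = "F")
  anovaTable <- data.frame(
    term = rownames(dr)[-1],
    F = dr$`F value`[-1],
    p = dr$`Pr(>F)`[-1]
  )
  coefs <- data.frame(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, 1],
    se = s$coefficients[, 2],
    t = s$coefficients[, 3],
    p = s$coefficients[, 4],
    row.names = NULL
  )
  new("RegressionResult",
      coefficients = coefs, r2 = s$r.squared, adjR2 = s$adj.r.squared,
      anovaTable = anovaTable,
      vif = vif_aux(as.matrix(d[, keep, drop = FALSE])),
      dropped = setdiff(predictors, keep), n = nrow(d))
}

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult: n = %d, R2 = %.3f (adj %.3f)\n",
              object@n, object@r2, object@adjR2))
  if (length(object@dropped)) {
    cat("  dropped by VIF screen:", paste(object@dropped, collapse = ", "), "\n")
  }
  print(object@anovaTable, row.names = FALSE)
})

#' Within- and between-region FST summaries
#'
#' Summaries of the pairwise FST distribution per region (within) and per
#' region pair (between): pair count, mean, SD and quartiles — the tabular
#' counterpart of regional FST boxplots. Regions with fewer than 2 sites have
#' no within-region entry.
#'
#' @param fst symmetric FST matrix with site ids as dimnames.
#' @param regions named character vector: site id -> region label (every site
#'   must be labeled).
#' @return list with data.frames `within` (`region`, `n`, `mean`, `sd`,
#'   `q25`, `median`, `q75`) and `between` (`region_a`, `region_b`, ...).
#' @export
regionFstSummary <- function(fst, regions) {
  check_symmetric(fst, "fst")
  ids <- rownames(fst)
  if (is.null(ids)) stop("fst must have site ids as dimnames")
  if (!all(ids %in% names(regions))) stop("every site must have a region label")
  reg <- regions[ids]
  ut <- which(upper.tri(fst), arr.ind = TRUE)
  ra <- reg[ut[, 1]]; rb <- reg[ut[, 2]]
  vals <- fst[ut]
  summ <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), mean = mean(v), sd = sd(v),
               q25 = q[1], median = q[2], q75 = q[3])
  }
  uniq <- sort(unique(reg))
  within <- do.call(rbind, lapply(uniq, function(r) {
    v <- vals[ra == r & rb == r]
    if (length(v) == 0) return(NULL)
    cbind(region = r, summ(v))
  }))
  betweenPairs <- if (length(uniq) >= 2) utils::combn(uniq, 2) else
    matrix(character(), 2, 0)
  between <- do.call(rbind, lapply(seq_len(ncol(betweenPairs)), function(k) {
    r1 <- betweenPairs[1, k]; r2 <- betweenPairs[2, k]
    v <- vals[(ra == r1 & rb == r2) | (ra == r2 & rb == r1)]
    if (length(v) == 0) return(NULL)
    cbind(region_a = r1, region_b = r2, summ(v))
  }))
  list(within = within %||% data.frame(), between = between %||% data.frame())
}
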