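sym_mat <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

test_that("Mantel statistic and p behave correctly on identical matrices", {
  set.seed(41)
  A <- sym_mat(runif(15), 6)
  res <- mantelTest(A, A, nPerm = 99, seed = 2)
  expect_equal(res@r, 1)
  expect_equal(res@p, 1 / 100)
})

test_that("Mantel p matches exhaustive enumeration on 4x4 matrices", {
  set.seed(42)
  A <- sym_mat(runif(6), 4)
  B <- sym_mat(runif(6), 4)
  perms <- all_perms(4)
  res <- mantelTest(A, B, perms = perms)
  # independent enumeration, coded directly
  va <- A[upper.tri(A)]
  rObs <- cor(va, B[upper.tri(B)])
  rs <- apply(perms, 1, function(ix) cor(va, B[ix, ix][upper.tri(B)]))
  expect_equal(res@r, rObs)
  expect_equal(res@p, mean(abs(rs) >= abs(rObs) - 1e-12))
  # a joint relabeling of both matrices leaves the result unchanged
  ix <- c(3, 1, 4, 2)
  res2 <- mantelTest(A[ix, ix], B[ix, ix], perms = perms)
  expect_equal(res2@r, res@r)
  expect_equal(res2@p, res@p)
})

test_that("Mantel degenerates gracefully and agrees with vegan on r", {
  A <- sym_mat(rep(0.3, 10), 5)
  B <- sym_mat(runif(10), 5)
  res <- mantelTest(A, B, nPerm = 9)
  expect_true(res@degenerate)
  expect_true(is.na(res@r))

  skip_if_not_installed("vegan")
  set.seed(43)
  X <- sym_mat(runif(45), 10)
  Y <- sym_mat(runif(45), 10)
  rPkg <- mantelTest(X, Y, nPerm = 9, seed = 1)@r
  rVegan <- unname(vegan::mantel(as.dist(X), as.dist(Y), permutations = 9)$statistic)
  expect_equal(rPkg, rVegan, tolerance = 1e-12)
})

test_that("IBD regression splits pairs by flagged sites and recovers fits", {
  n <- 8
  ids <- paste0("S", 1:n)
  set.seed(44)
  lc <- sym_mat(-runif(choose(n, 2), 2, 10), n)
  dimnames(lc) <- list(ids, ids)

  # all pairs on one exact line, empty flag set: single fit with R2 = 1
  fst1 <- -0.004 * lc
  dimnames(fst1) <- dimnames(lc)
  r1 <- suppressWarnings(ibdRegression(fst1, lc))
  expect_null(r1$flagged)
  expect_equal(r1$rest$r2, 1)
  expect_equal(r1$rest$slope, -0.004)
  expect_equal(r1$rest$n, choose(n, 2))

  # two constructed lines with distinct intercepts, split by flag
  flagged <- c("S1", "S2")
  isFlagPair <- outer(ids %in% flagged, ids %in% flagged, `|`)
  fst2 <- -0.004 * lc + ifelse(isFlagPair, 0.05, 0.01)
  diag(fst2) <- 0
  dimnames(fst2) <- dimnames(lc)
  r2 <- suppressWarnings(ibdRegression(fst2, lc, flagged))
  expect_equal(r2$flagged$r2, 1)
  expect_equal(r2$rest$r2, 1)
  expect_equal(r2$flagged$intercept, 0.05)
  expect_equal(r2$rest$intercept, 0.01)
  expect_equal(r2$flagged$n + r2$rest$n, choose(n, 2))

  # empty flag set reduces to the plain all-pairs regression
  plain <- lm(fst ~ logconn, data = r1$pairs)
  expect_equal(r1$rest$slope, unname(coef(plain)[2]))

  # tiny groups are skipped with a warning
  expect_warning(
    ibdRegression(fst2[1:2, 1:2], lc[1:2, 1:2]),
    "fewer than 3")
})

test_that("environment regression screens collinear predictors and fits OLS", {
  set.seed(45)
  n <- 24
  env <- data.frame(
    site_id = paste0("S", 1:n),
    salinity_psu = seq(25, 5, length.out = n),
    temp_C = rnorm(n, 15, 1),
    mpa = rep(0:1, n / 2)
  )
  div <- data.frame(site_id = env$site_id,
                    He = 0.01 * env$salinity_psu + 0.05)
  fit <- suppressWarnings(envRegression(div, env))
  expect_equal(fit@r2, 1)
  sal <- fit@anovaTable[fit@anovaTable$term == "salinity_psu", ]
  expect_lt(sal$p, 1e-12)
  expect_equal(length(fit@dropped), 0L)

  # orthogonal standardized (mean-centered) predictors have VIF 1
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  env2 <- data.frame(site_id = env$site_id, a = X[, 1], b = X[, 2], c = X[, 3])
  div2 <- data.frame(site_id = env$site_id,
                     He = 0.3 + 0.1 * X[, 1] + rnorm(n, 0, 0.01))
  fit2 <- envRegression(div2, env2)
  expect_equal(unname(fit2@vif), rep(1, 3), tolerance = 1e-8)

  # a duplicated predictor is dropped by the VIF screen
  env3 <- cbind(env, salinity_dup = env$salinity_psu)
  div3 <- data.frame(site_id = env$site_id,
                     He = 0.01 * env$salinity_psu + rnorm(n, 0, 0.005))
  fit3 <- envRegression(div3, env3)
  expect_length(intersect(c("salinity_psu", "salinity_dup"), fit3@dropped), 1L)
  expect_true(all(fit3@vif < 3))
})

test_that("regional FST summaries count pairs correctly", {
  layout <- balticSiteLayout()
  n <- nrow(layout)
  expect_equal(n, 31L)
  set.seed(46)
  fst <- sym_mat(runif(choose(n, 2), 0, 0.07), n)
  dimnames(fst) <- list(layout$site_id, layout$site_id)
  reg <- regionFstSummary(fst, setNames(layout$region, layout$site_id))
  expect_equal(sum(reg$within$n) + sum(reg$between$n), choose(31, 2))

  # single region: between-region table is empty
  one <- regionFstSummary(fst[1:5, 1:5],
                          setNames(rep("W", 5), layout$site_id[1:5]))
  expect_equal(nrow(one$between), 0L)
  expect_equal(one$within$n, choose(5, 2))

  expect_error(regionFstSummary(fst, setNames(layout$region[-1],
                                              layout$site_id[-1])),
               "region label")
})
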