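# Shared fixtures and independent oracles, all built in code.

# Flat all-sea grid.
flat_grid <- function(nx = 10, ny = 8, cell = 5, depth = 10) {
  buildGrid(list(nx = nx, ny = ny, cell_size_km = cell,
                 depth = list(mode = "constant", value = depth)))
}

# Grid whose habitat is exactly the given cells (everything else too deep).
habitat_grid <- function(nx, ny, cell, habitatCells, shallow = 10, deep = 50) {
  d <- matrix(deep, nx, ny)
  d[habitatCells] <- shallow
  buildGrid(list(nx = nx, ny = ny, cell_size_km = cell,
                 depth = list(mode = "matrix", values = d)))
}

# Tiny genotype dataset from per-site dosage matrices (loci x individuals).
toy_dataset <- function(...) {
  mats <- list(...)
  sites <- names(mats)
  dosage <- do.call(cbind, mats)
  genotypeDataset(dosage, rep(sites, vapply(mats, ncol, integer(1))),
                  data.frame(site_id = sites))
}

# --- Weir-Cockerham theta oracle: nested-ANOVA mean squares evaluated by
# explicit loops over allele copies (independent of the closed-form path).
oracle_wc_theta <- function(g1, g2) {
  A <- 0; D <- 0
  for (l in seq_len(nrow(g1))) {
    d1 <- g1[l, !is.na(g1[l, ])]; d2 <- g2[l, !is.na(g2[l, ])]
    if (length(d1) < 2 || length(d2) < 2) next
    n <- c(length(d1), length(d2)); N <- sum(n); r <- 2
    p <- c(mean(d1) / 2, mean(d2) / 2)
    ybar <- sum(n * p) / N
    SSG <- 0; SSI <- 0
    for (k in 1:2) {
      for (d in (if (k == 1) d1 else d2)) {
        copies <- c(rep(0, 2 - d), rep(1, d))
        SSG <- SSG + sum((copies - d / 2)^2)
        SSI <- SSI + 2 * (d / 2 - p[k])^2
      }
    }
    SSP <- sum(2 * n * (p - ybar)^2)
    MSG <- SSG / N; MSI <- SSI / (N - r); MSP <- SSP / (r - 1)
    nc <- (N - sum(n^2) / N) / (r - 1)
    a <- (MSP - MSI) / (2 * nc)
    b <- (MSI - MSG) / 2
    A <- A + a; D <- D + a + b + MSG
  }
  A / D
}

# --- classical-scaling oracle: double centering + eigen, by hand.
oracle_cmds <- function(d, k) {
  n <- nrow(d)
  B <- -0.5 * d^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))  # sequential sweeps add the grand mean back
  e <- eigen(B, symmetric = TRUE)
  e$vectors[, 1:k, drop = FALSE] %*% diag(sqrt(pmax(e$values[1:k], 0)), k)
}

# --- all permutations of 1..n (recursive, n small).
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# --- set partitions of n elements as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(a, k) {
    if (length(a) == n) { out[[length(out) + 1]] <<- a; return() }
    for (v in seq_len(k + 1)) rec(c(a, v), max(k, v))
  }
  rec(integer(0), 0L)
  out
}

partition_feasible <- function(m, lab, theta) {
  K <- max(lab)
  if (K < 2) return(TRUE)
  for (a in 1:(K - 1)) for (b in (a + 1):K) {
    if (mean(m[lab == a, lab == b, drop = FALSE]) > theta) return(FALSE)
  }
  TRUE
}

# Finest feasible partition by exhaustive search (unique on the instances
# used in tests; see the clustering tests for the instance class).
oracle_finest_partition <- function(m, theta) {
  ps <- Filter(function(p) partition_feasible(m, p, theta), all_partitions(nrow(m)))
  ps[[which.max(vapply(ps, max, integer(1)))]]
}

canon_partition <- function(lab) as.integer(factor(lab, levels = unique(lab)))

# Random symmetric block matrix with strong within-block connectivity and
# weak between-block noise (dimnames 1..n).
block_matrix <- function(n, k, within = c(0.1, 0.3), between = c(0, 0.0008)) {
  blk <- sort(sample.int(k, n, replace = TRUE))
  while (length(unique(blk)) < k) blk <- sort(sample.int(k, n, replace = TRUE))
  m <- matrix(runif(n * n, between[1], between[2]), n, n)
  for (c in seq_len(k)) {
    idx <- which(blk == c)
    m[idx, idx] <- runif(length(idx)^2, within[1], within[2])
  }
  m <- symmetrize(m, "mean")
  diag(m) <- 0.5
  dimnames(m) <- list(seq_len(n), seq_len(n))
  list(m = m, blocks = blk)
}
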