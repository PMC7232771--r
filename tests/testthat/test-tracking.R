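test_that("advection matches analytic trajectories", {
  g <- flat_grid(20, 8, cell = 5)   # 100 x 40 km
  f0 <- makeVelocityField(g, list())
  expect_equal(advectParticle(g, f0, c(12, 17)), c(x_km = 12, y_km = 17))

  # uniform 0.1 m/s for 5 days: 0.1 * 432000 s = 43.2 km east
  fu <- makeVelocityField(g, list(list(type = "uniform", u = 0.1)))
  end <- advectParticle(g, fu, c(2, 20), pldDays = 5, dtS = 3600)
  expect_equal(unname(end), c(45.2, 20), tolerance = 1e-9)

  expect_error(advectParticle(
    buildGrid(list(nx = 4, ny = 4, cell_size_km = 5,
                   land = list(blocks = list(c(1, 2, 1, 4))),
                   depth = list(mode = "constant", value = 10))),
    f0, c(2, 2)), "sea cell")
})

test_that("RK4 conserves the orbit radius of a solid-body rotation", {
  g <- flat_grid(40, 40, cell = 5)
  f <- makeVelocityField(g, list(
    list(type = "solid_body", center_km = c(100, 100), omega = 1e-5)))
  start <- c(140, 100)
  end <- advectParticle(g, f, start, pldDays = 5, dtS = 3600)
  r0 <- 40
  r1 <- sqrt(sum((end - c(100, 100))^2))
  expect_lt(abs(r1 - r0) / r0, 1e-3)
})

test_that("halving the time step barely moves RK4 endpoints on smooth fields", {
  g <- flat_grid(30, 30, cell = 5)
  f <- makeVelocityField(g, list(
    list(type = "gyre", center_km = c(75, 75), radius_km = 40, amplitude = 0.2)))
  start <- c(95, 60)
  e1 <- advectParticle(g, f, start, pldDays = 5, dtS = 3600)
  e2 <- advectParticle(g, f, start, pldDays = 5, dtS = 1800)
  scale <- sqrt(sum((e1 - start)^2))
  expect_lt(sqrt(sum((e1 - e2)^2)) / scale, 1e-6)
})

test_that("stationary particles settle where they were released", {
  g <- buildGrid(list(nx = 3, ny = 3, cell_size_km = 5,
                      land = list(border = TRUE),
                      depth = list(mode = "constant", value = 10)))
  expect_equal(habitatCells(g), 5L)
  f <- makeVelocityField(g, list())
  ens <- runDispersal(g, f, releaseSchedule(months = 5, particlesPerCell = 100),
                      seed = 2)
  p <- ens@particles
  expect_equal(nrow(p), 100)
  expect_true(all(!p$lost))
  expect_true(all(p$dest_cell == 5L))
})

test_that("uniform flow crossing one cell per PLD moves settlement one cell east", {
  # habitat: cells (2,2) and (3,2) of a 6x3 all-sea grid, 10 km cells
  hab <- c(8L, 9L)  # column-major ids for (2,2), (3,2)
  g <- habitat_grid(6, 3, 10, hab)
  expect_equal(habitatCells(g), hab)
  u <- 10000 / (5 * 86400)  # one 10-km cell per 5-day PLD
  f <- makeVelocityField(g, list(list(type = "uniform", u = u)))
  ens <- runDispersal(g, f, releaseSchedule(months = 5, particlesPerCell = 200),
                      seed = 4)
  p <- ens@particles
  from1 <- p[p$src_cell == 8L, ]
  expect_gte(mean(from1$dest_cell == 9L, na.rm = TRUE) *
               mean(!from1$lost), 0.95)
})

test_that("particles advected across the open boundary are lost, never settled", {
  g <- flat_grid(6, 4, cell = 5)  # open boundaries, all habitat
  f <- makeVelocityField(g, list(list(type = "uniform", u = 1)))  # 432 km / PLD
  ens <- runDispersal(g, f, releaseSchedule(months = 5, particlesPerCell = 10),
                      seed = 1)
  p <- ens@particles
  expect_true(all(p$lost))
  expect_true(all(is.na(p$dest_cell)))
  # conservation: settled + lost = released, per source cell
  rel <- ens@released
  settled <- table(factor(p$src_cell[!p$lost], levels = names(rel)))
  lost <- table(factor(p$src_cell[p$lost], levels = names(rel)))
  expect_equal(as.integer(settled + lost), unname(rel))
})

test_that("ensemble counts normalize to dispersal probabilities", {
  hab <- c(8L, 9L)
  g <- habitat_grid(6, 3, 10, hab)
  parts <- data.frame(
    particle_id = 1:100,
    src_cell = rep(8L, 100),
    release = 1L,
    end_x = 15, end_y = 15,
    dest_cell = c(rep(9L, 60), rep(8L, 20), rep(NA_integer_, 20)),
    lost = c(rep(FALSE, 80), rep(TRUE, 20)))
  ens <- new("ParticleEnsemble", particles = parts,
             released = c(`8` = 100L, `9` = 25L))
  # give cell 9 some particles too so normalization is defined
  extra <- data.frame(particle_id = 101:125, src_cell = 9L, release = 1L,
                      end_x = 25, end_y = 15, dest_cell = 9L, lost = FALSE)
  ens@particles <- rbind(parts, extra)
  conn <- ensembleToConnectivity(ens, g)
  m <- connProbs(conn)
  expect_equal(m["8", "8"], 0.2)
  expect_equal(m["8", "9"], 0.6)
  expect_equal(sum(m["8", ]), 0.8)
  expect_equal(m["9", "9"], 1)

  ens@released <- c(`8` = 100L, `9` = 0L)
  expect_error(ensembleToConnectivity(ens, g), "released")
})

test_that("dispersal is reproducible by seed and rows stay within [0, 1]", {
  ch <- channelSeascape(nSites = 6, nx = 16, ny = 7)
  sch <- releaseSchedule(months = c(5, 7), particlesPerCell = 15)
  e1 <- runDispersal(ch$grid, ch$field, sch, seed = 9)
  e2 <- runDispersal(ch$grid, ch$field, sch, seed = 9)
  expect_identical(e1@particles, e2@particles)
  m <- connProbs(ensembleToConnectivity(e1, ch$grid))
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(rowSums(m) <= 1 + 1e-12))
})

test_that("a mirror-symmetric flow yields mirror-symmetric connectivity", {
  # v depends only on y: the system is invariant under x-reflection
  g <- flat_grid(8, 8, cell = 5)
  f <- makeVelocityField(g, list(list(type = "uniform", v = 0.02)))
  ens <- runDispersal(g, f, releaseSchedule(months = 5:7, particlesPerCell = 40),
                      seed = 6)
  m <- connProbs(ensembleToConnectivity(ens, g))
  nx <- 8
  mirror <- function(cell) {
    ij <- cbind(((cell - 1) %% nx) + 1, ((cell - 1) %/% nx) + 1)
    as.character((ij[, 2] - 1) * nx + (nx - ij[, 1] + 1))
  }
  ids <- rownames(m)
  mm <- m[mirror(as.numeric(ids)), mirror(as.numeric(ids))]
  n <- 40 * 3
  expect_lt(max(abs(m - mm)), 3 / sqrt(n))
})
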