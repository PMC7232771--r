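test_that("habitat is the intersection of sea and the depth rule", {
  g <- flat_grid(40, 30, cell = 5, depth = 10)
  expect_true(all(g@habitatMask))

  expect_error(
    buildGrid(list(nx = 40, ny = 30, cell_size_km = 5,
                   depth = list(mode = "constant", value = 50))),
    "empty habitat")

  # top half land: habitat confined to sea cells
  g2 <- buildGrid(list(nx = 10, ny = 10, cell_size_km = 5,
                       land = list(blocks = list(c(1, 10, 6, 10))),
                       depth = list(mode = "constant", value = 10)))
  expect_false(any(g2@habitatMask & g2@landMask))
  expect_true(all(which(g2@habitatMask) %in% which(!g2@landMask)))
  expect_equal(sum(g2@habitatMask), 50)

  # depth exactly at the limit is not habitat (strict inequality)
  g3 <- buildGrid(list(nx = 4, ny = 4, cell_size_km = 5,
                       habitat_depth_limit = 30,
                       depth = list(mode = "constant", value = 29.9)))
  expect_true(all(g3@habitatMask))
  expect_error(buildGrid(list(nx = 1, ny = 5, cell_size_km = 5,
                              depth = list(mode = "constant", value = 10))),
               "at least 2 x 2")
  expect_error(buildGrid(list(nx = 4, ny = 4, cell_size_km = 5,
                              land = list(blocks = list(c(1, 4, 1, 4))),
                              depth = list(mode = "constant", value = 10))),
               "empty habitat")
})

test_that("cell geometry uses cell centers at (i - 0.5) * cell size", {
  g <- flat_grid(4, 3, cell = 10)
  expect_equal(unname(gridDims(g)), c(4, 3))
  cc <- cellCenters(g, cells = c(1, 4, 12))
  expect_equal(cc[, "x_km"], c(5, 35, 35))
  expect_equal(cc[, "y_km"], c(5, 5, 25))
})

test_that("environmental gradients are monotone between the endpoints", {
  g <- flat_grid(10, 6)
  g <- assignEnvironment(g, "salinity", "x", from = 25, to = 3)
  s <- g@salinityPsu
  expect_equal(max(s), 25)
  expect_equal(min(s), 3)
  expect_true(all(apply(s, 2, function(row) all(diff(row) < 0))))

  gc <- assignEnvironment(g, "salinity", "x", from = 7, to = 7)
  expect_true(all(gc@salinityPsu == 7))

  gr <- assignEnvironment(g, "salinity", "x", from = 3, to = 25)
  expect_equal(gr@salinityPsu, s[nrow(s):1, ])
  expect_equal(range(gr@salinityPsu), range(s))

  gy <- assignEnvironment(g, "temperature", "y", from = 16, to = 12)
  expect_true(all(apply(gy@temperatureC, 1, function(col) all(diff(col) < 0))))
})

test_that("velocity fields are zero for zero components and on land", {
  g <- buildGrid(list(nx = 12, ny = 10, cell_size_km = 5,
                      land = list(blocks = list(c(1, 12, 1, 2))),
                      depth = list(mode = "constant", value = 10)))
  f0 <- makeVelocityField(g, list())
  expect_true(all(f0@u == 0) && all(f0@v == 0))

  fz <- makeVelocityField(g, list(
    list(type = "gyre", center_km = c(30, 30), radius_km = 15, amplitude = 0)))
  expect_true(all(fz@u == 0) && all(fz@v == 0))

  fn <- makeVelocityField(g, list(list(type = "noise", amplitude = 0.05)),
                          seed = 3)
  expect_true(all(fn@u[g@landMask] == 0) && all(fn@v[g@landMask] == 0))
  expect_true(any(fn@u != 0))
  # reproducible by seed
  fn2 <- makeVelocityField(g, list(list(type = "noise", amplitude = 0.05)),
                           seed = 3)
  expect_identical(fn@u, fn2@u)
})

test_that("solid-body gyre speed vanishes at the center and grows linearly", {
  g <- flat_grid(21, 21, cell = 2)
  ctr <- c(21, 21)  # center of cell (11, 11)
  f <- makeVelocityField(g, list(
    list(type = "solid_body", center_km = ctr, omega = 1e-5)))
  spd <- sqrt(f@u^2 + f@v^2)
  expect_equal(spd[11, 11], 0)
  # |v| = 1000 * omega * r (m/s, r in km)
  expect_equal(spd[15, 11], 1e-2 * 8, tolerance = 1e-10)
  expect_equal(spd[11, 16], 1e-2 * 10, tolerance = 1e-10)
})

test_that("streamfunction components are discretely divergence-free", {
  g <- flat_grid(30, 30, cell = 5)
  f <- makeVelocityField(g, list(
    list(type = "gyre", center_km = c(75, 75), radius_km = 30, amplitude = 0.1),
    list(type = "jet", y_km = 75, width_km = 20, amplitude = 0.08),
    list(type = "noise", amplitude = 0.03)), seed = 11)
  div <- fieldDivergence(f, 5)
  umax <- max(sqrt(f@u^2 + f@v^2))
  expect_lt(max(abs(div[3:28, 3:28])), 1e-8 * umax)
})
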