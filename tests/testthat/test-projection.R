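# A small fitted setting reused across projection tests: toy data whose
# predictors are laid out as raster layers.
projFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- smallGrid(20)
      set.seed(44)
      v1 <- matrix(rnorm(400), 20, 20)
      v2 <- matrix(rnorm(400), 20, 20)
      stack <- rasterStack(list(rasterLayer(g, v1, name = "x1"),
                                rasterLayer(g, v2, name = "x2")))
      pres <- randomPoints(60, g, seed = 1)
      pa <- randomPoints(80, g, seed = 2)
      # make response depend on x1 so models have signal
      rc <- cellOf(pres$lon, pres$lat, g)
      keep <- v1[cbind(rc$row + 1, rc$col + 1)] > -0.3
      mm <- assembleModelMatrix(pres[keep, ], pa, stack)
      cache <<- list(g = g, stack = stack, mm = mm,
                     rf = fitAlgorithm("RF", mm, seed = 1))
    }
    cache
  }
})

test_that("projection over a constant stack is a constant map", {
  fx <- projFixture()
  const <- rasterStack(list(rasterLayer(fx$g, 0.3, name = "x1"),
                            rasterLayer(fx$g, -0.1, name = "x2")))
  map <- projectMap(fx$rf, const)
  v <- as.vector(layerValues(map))
  expect_equal(length(unique(v)), 1)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("projecting the training stack reproduces the training-case scores", {
  fx <- projFixture()
  map <- projectMap(fx$rf, fx$stack)
  scores <- predictScores(fx$rf, fx$mm)
  # look up each training case's cell in the projected map
  v <- as.vector(layerValues(map))
  # reconstruct case cells from the predictor values (unique per cell here)
  idx <- match(paste(fx$mm$x1, fx$mm$x2),
               paste(as.vector(layerValues(getLayer(fx$stack, "x1"))),
                     as.vector(layerValues(getLayer(fx$stack, "x2")))))
  expect_equal(v[idx], scores, tolerance = 1e-12)
})

test_that("SRE projections are binary and missing layers are named", {
  fx <- projFixture()
  sre <- fitAlgorithm("SRE", fx$mm, params = list(alpha = 0.05))
  map <- projectMap(sre, fx$stack)
  expect_true(all(layerValues(map) %in% c(0, 1)))
  half <- rasterStack(list(rasterLayer(fx$g, 0, name = "x1")))
  expect_error(projectMap(fx$rf, half), "x2")
})

test_that("nodata cells propagate to the projection", {
  fx <- projFixture()
  v <- layerValues(getLayer(fx$stack, "x1"))
  v[5, 5] <- NA
  stack <- rasterStack(list(rasterLayer(fx$g, v, name = "x1"),
                            getLayer(fx$stack, "x2")))
  map <- projectMap(fx$rf, stack)
  expect_true(is.na(layerValues(map)[5, 5]))
  expect_equal(sum(is.na(layerValues(map))), 1)
})

# Stack with HPV layers for the substitution scenarios.
hpvFixture <- function() {
  g <- smallGrid(15)
  set.seed(50)
  sites <- randomPoints(8, g, seed = 50)
  env <- rasterLayer(g, matrix(rnorm(225), 15, 15), name = "env_01")
  hpv <- buildHpvLayers(
    occurrenceRecords(sites$lon, sites$lat, 2000, 2007), g, 2012,
    periods = c(10, 5), capacities = c("P", "C", "D"))
  list(g = g, sites = sites,
       stack = rasterStack(c(list(env_01 = env), hpv)))
}

test_that("identity substitution leaves HPV layers bit-identical", {
  fx <- hpvFixture()
  sub <- forecastStack(fx$stack, fx$sites)
  expect_setequal(attr(sub, "substituted"),
                  c("10.P", "10.C", "10.D", "5.P", "5.C", "5.D"))
  for (nm in attr(sub, "substituted")) {
    expect_identical(layerValues(getLayer(sub, nm)),
                     layerValues(getLayer(fx$stack, nm)), info = nm)
  }
  # and the environmental layer is untouched
  expect_identical(layerValues(getLayer(sub, "env_01")),
                   layerValues(getLayer(fx$stack, "env_01")))
})

test_that("adding current sites can only shrink distance layers", {
  fx <- hpvFixture()
  more <- rbind(fx$sites, randomPoints(5, fx$g, seed = 51))
  sub <- forecastStack(fx$stack, more)
  expect_true(all(layerValues(getLayer(sub, "5.D")) <=
                    layerValues(getLayer(fx$stack, "5.D")) + 1e-9))
  env_only <- rasterStack(list(getLayer(fx$stack, "env_01")))
  expect_error(forecastStack(env_only, fx$sites), "no HPV")
})

test_that("the potential scenario sets distance to the fill and counts to saturation", {
  fx <- hpvFixture()
  pot <- potentialStack(fx$stack, fill = 0)
  expect_true(all(layerValues(getLayer(pot, "5.D")) == 0))
  expect_true(all(layerValues(getLayer(pot, "10.D")) == 0))
  expect_true(all(layerValues(getLayer(pot, "5.P")) == 1))
  expect_true(all(layerValues(getLayer(pot, "10.C")) == 1))
  expect_error(potentialStack(fx$stack, fill = -5), "non-negative")

  # substitution equals a manually built constant-HPV stack
  manual <- fx$stack@layers
  for (nm in c("10.P", "10.C", "5.P", "5.C")) {
    manual[[nm]] <- rasterLayer(fx$g, 1, name = nm)
  }
  for (nm in c("10.D", "5.D")) manual[[nm]] <- rasterLayer(fx$g, 0, name = nm)
  for (nm in names(manual)) {
    expect_identical(layerValues(getLayer(pot, nm)),
                     layerValues(manual[[nm]]), info = nm)
  }
})

test_that("difference maps are exact cell-wise subtractions within [-1, 1]", {
  g <- smallGrid(10)
  set.seed(52)
  a <- rasterLayer(g, matrix(runif(100), 10, 10), name = "f")
  b <- rasterLayer(g, matrix(runif(100), 10, 10), name = "c")
  em <- emergenceMap(a, b)
  expect_equal(layerValues(em), layerValues(a) - layerValues(b))
  expect_true(all(layerValues(em) >= -1 & layerValues(em) <= 1))
  expect_true(all(layerValues(emergenceMap(a, a)) == 0))

  un <- unsaturationMap(a, b)
  expect_equal(layerValues(un), layerValues(a) - layerValues(b))
  expect_equal(layerName(un), "unsaturation")

  g2 <- smallGrid(12)
  c2 <- rasterLayer(g2, matrix(0, 12, 12))
  expect_error(emergenceMap(a, c2), "different grids")
})

test_that("thresholding a probability map yields the super-threshold cell centers", {
  g <- gridSpec(0, 0, 3, 3, resolution = 1)
  v <- matrix(c(0.9, 0.1, 0.1, 0.1, 0.8, 0.1, 0.1, 0.1, 0.2), 3, 3)
  sites <- thresholdToSites(rasterLayer(g, v), 0.5)
  expect_equal(nrow(sites), 2)
  rc <- cellOf(sites$lon, sites$lat, g)
  got <- sort((rc$row + 1) + rc$col * 3)
  expect_equal(got, sort(which(as.vector(v) >= 0.5)))
})
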