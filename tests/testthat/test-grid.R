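test_that("cellOf follows the half-open north-west convention", {
  g <- gridSpec(0, 0, 10, 10, resolution = 1)
  expect_equal(unlist(cellOf(0, 10 - 1e-9, g)), c(row = 0, col = 0))
  expect_equal(unlist(cellOf(0 + 1.5, 10 - 2.5, g)), c(row = 2, col = 1))
  # shared edges belong to the cell to the east/south
  expect_equal(unlist(cellOf(3, 10, g)), c(row = 0, col = 3))
  expect_equal(unlist(cellOf(3, 7, g)), c(row = 3, col = 3))
  expect_error(cellOf(10, 5, g), "outside")
  expect_error(cellOf(5, 0, g), "outside")
})

test_that("cellOf agrees with a loop-based assignment on random points", {
  g <- smallGrid(10)
  pts <- randomPoints(1000, g, seed = 42)
  got <- cellOf(pts$lon, pts$lat, g)
  idx <- sample(nrow(pts), 60)  # oracle is O(cells) per point; spot-check
  for (i in idx) {
    expect_equal(unname(unlist(got[i, ])),
                 oracleCellOf(pts$lon[i], pts$lat[i], g))
  }
  # and full agreement with the vectorized arithmetic re-derived per point
  for (i in seq_len(nrow(pts))) {
    expect_equal(got$col[i], floor((pts$lon[i] - g@xmin) / resolutionOf(g)))
    expect_equal(got$row[i], floor((g@ymax - pts$lat[i]) / resolutionOf(g)))
  }
})

test_that("rasterizeCount tallies points per cell and conserves the total", {
  g <- gridSpec(0, 0, 5, 5, resolution = 1)
  pts <- data.frame(lon = c(0.5, 0.6, 0.7, 3.5), lat = c(4.5, 4.4, 4.3, 1.5))
  cnt <- rasterizeCount(pts, g)
  expect_equal(layerValues(cnt)[1, 1], 3)
  expect_equal(layerValues(cnt)[4, 4], 1)
  expect_equal(sum(layerValues(cnt)), 4)

  empty <- rasterizeCount(data.frame(lon = numeric(0), lat = numeric(0)), g)
  expect_true(all(layerValues(empty) == 0))

  g2 <- smallGrid(20)
  pts2 <- randomPoints(200, g2, seed = 7)
  got <- layerValues(rasterizeCount(pts2, g2))
  want <- matrix(0, 20, 20)
  for (i in seq_len(200)) {
    rc <- oracleCellOf(pts2$lon[i], pts2$lat[i], g2)
    want[rc[1] + 1, rc[2] + 1] <- want[rc[1] + 1, rc[2] + 1] + 1
  }
  expect_equal(got, want)
})

test_that("rasterizeCount can drop or refuse outside points", {
  g <- gridSpec(0, 0, 5, 5, resolution = 1)
  pts <- data.frame(lon = c(0.5, 7), lat = c(0.5, 1))
  expect_error(rasterizeCount(pts, g), "outside")
  expect_warning(cnt <- rasterizeCount(pts, g, drop_outside = TRUE), "dropped")
  expect_equal(sum(layerValues(cnt)), 1)
})

test_that("toPresence binarizes counts, preserves NA and is idempotent", {
  g <- gridSpec(0, 0, 3, 1, resolution = 1)
  cnt <- rasterLayer(g, matrix(c(0, 1, 5), 1, 3))
  expect_equal(as.vector(layerValues(toPresence(cnt))), c(0, 1, 1))

  zeros <- rasterLayer(g, matrix(0, 1, 3))
  expect_true(all(layerValues(toPresence(zeros)) == 0))

  withNA <- rasterLayer(g, matrix(c(NA, 2, 0), 1, 3))
  expect_equal(as.vector(layerValues(toPresence(withNA))), c(NA, 1, 0))

  neg <- rasterLayer(g, matrix(c(-1, 0, 1), 1, 3))
  expect_error(toPresence(neg), "negative")

  g2 <- smallGrid(15)
  cnt2 <- rasterizeCount(randomPoints(60, g2, seed = 3), g2)
  p1 <- toPresence(cnt2)
  expect_equal(sum(layerValues(p1)), sum(layerValues(cnt2) > 0))
  expect_equal(layerValues(toPresence(p1)), layerValues(p1))
})

test_that("distanceToNearest is zero at a site's cell center and matches the closed form", {
  g <- smallGrid(10)
  ctr <- cellCenters(g)
  one <- data.frame(lon = ctr$lon[35], lat = ctr$lat[35])
  d <- layerValues(distanceToNearest(one, g))
  expect_equal(as.vector(d)[35], 0)
  # half the cell diagonal bounds the distance inside an occupied cell
  halfdiag <- oracleHaversine(0, 52, 1 / 120, 52 + 1 / 120) / 2
  expect_lt(as.vector(d)[35], halfdiag)

  # neighbouring cell on the same parallel: exactly the haversine of one
  # cell's longitude offset at that latitude
  i_east <- 35 + dim(g)[1]
  expect_equal(as.vector(d)[i_east],
               oracleHaversine(ctr$lon[35], ctr$lat[35],
                               ctr$lon[i_east], ctr$lat[i_east]),
               tolerance = 1e-9)
})

test_that("distanceToNearest matches the exhaustive all-pairs oracle", {
  g <- smallGrid(20)
  pts <- randomPoints(10, g, seed = 11)
  got <- layerValues(distanceToNearest(pts, g))
  want <- oracleDistanceGrid(pts, g)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("distance layers are monotone under point addition and union is pointwise min", {
  g <- smallGrid(15)
  a <- randomPoints(5, g, seed = 1)
  b <- randomPoints(4, g, seed = 2)
  dA <- distanceToNearest(a, g)
  dAB <- distanceToNearest(rbind(a, b), g)
  expect_true(all(layerValues(dAB) <= layerValues(dA) + 1e-9))
  dB <- distanceToNearest(b, g)
  expect_equal(layerValues(dAB),
               pmin(layerValues(dA), layerValues(dB)),
               tolerance = 1e-12)
  expect_error(distanceToNearest(data.frame(lon = numeric(0),
                                            lat = numeric(0)), g),
               "at least one site")
})

test_that("grid and raster validity guards reject inconsistent objects", {
  expect_error(gridSpec(10, 0, 0, 10), "xmax")
  g <- gridSpec(0, 0, 5, 5, resolution = 1)
  expect_error(rasterLayer(g, matrix(0, 2, 5)), "5 x 5")
})

test_that("ASCII grid round-trips a layer including nodata cells", {
  g <- smallGrid(8)
  v <- matrix(rnorm(64), 8, 8)
  v[3, 5] <- NA
  lay <- rasterLayer(g, v, name = "band")
  path <- tempfile(fileext = ".asc")
  writeAsciiGrid(lay, path, digits = 15)
  back <- readAsciiGrid(path)
  expect_equal(layerValues(back), v, tolerance = 1e-12)
  expect_equal(dim(gridOf(back)), dim(g))
  expect_true(is.na(layerValues(back)[3, 5]))
})

test_that("point tables round-trip through CSV and GeoJSON", {
  pts <- data.frame(lon = c(17.1, 17.2), lat = c(52.3, 52.4),
                    onset_year = c(1985L, 2000L), id = c("a", "b"))
  p1 <- tempfile(fileext = ".csv")
  writePointsCSV(pts, p1)
  expect_equal(readPointsCSV(p1), pts)
  p2 <- tempfile(fileext = ".geojson")
  writePointsGeoJSON(pts, p2)
  back <- readPointsGeoJSON(p2)
  expect_equal(back$lon, pts$lon)
  expect_equal(back$onset_year, pts$onset_year)
})
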