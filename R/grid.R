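# Grid geometry, point rasterization and the three HPV information-capacity
# transforms (presence / count / distance).

# Mean Earth radius in meters used for every great-circle distance in the
# package (simulation, HPV construction, deduplication).
EARTH_RADIUS_M <- 6371008.8

#' Great-circle distance in meters
#'
#' Haversine distance on a spherical Earth (radius 6,371,008.8 m), the single
#' distance metric used throughout the package. Vectorized over both ends.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees; recycled.
#' @return numeric vector of distances in meters.
#' @export
haversineMeters <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  geosphere::distHaversine(
    cbind(rep_len(lon1, n), rep_len(lat1, n)),
    cbind(rep_len(lon2, n), rep_len(lat2, n)),
    r = EARTH_RADIUS_M
  )
}

#' Locate points on the grid
#'
#' Maps lon/lat points to 0-based (row, col) cell indices. Row 0 is the
#' northernmost row; `col = floor((lon - xmin)/resolution)`. Cells are
#' half-open: a point on a shared edge belongs to the cell to its east/south,
#' so the valid domain is `lon in [xmin, xmax)` and `lat in (ymin, ymax]`.
#'
#' @param lon,lat numeric vectors, degrees.
#' @param grid a [GridSpec-class].
#' @return data.frame with columns `row`, `col` (0-based integers).
#' @examples
#' g <- gridSpec(0, 0, 10, 10, resolution = 1)
#' cellOf(0, 10 - 1e-9, g)  # (0, 0): north-west corner cell
#' @export
cellOf <- function(lon, lat, grid) {
  stopifnot(is(grid, "GridSpec"))
  bad <- lon < grid@xmin | lon >= grid@xmax | lat <= grid@ymin | lat > grid@ymax
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "point (lon %.6f, lat %.6f) is outside the grid extent lon [%g, %g), lat (%g, %g]",
      lon[i], lat[i], grid@xmin, grid@xmax, grid@ymin, grid@ymax))
  }
  col <- floor((lon - grid@xmin) / grid@resolution)
  row <- floor((grid@ymax - lat) / grid@resolution)
  # guard against floating-point spill on the interior edges
  col <- pmin(pmax(as.integer(col), 0L), grid@ncols - 1L)
  row <- pmin(pmax(as.integer(row), 0L), grid@nrows - 1L)
  data.frame(row = row, col = col)
}

# 1-based linear cell index in R's column-major matrix order.
cellIndex <- function(row0, col0, grid) {
  (row0 + 1L) + col0 * grid@nrows
}

#' Cell-center coordinates
#'
#' @param grid a [GridSpec-class].
#' @return data.frame `lon`, `lat` for every cell, in column-major matrix
#'   order (cell index `row + (col-1)*nrows`).
#' @export
cellCenters <- function(grid) {
  rows <- seq_len(grid@nrows)
  cols <- seq_len(grid@ncols)
  lat <- grid@ymax - (rows - 0.5) * grid@resolution
  lon <- grid@xmin + (cols - 0.5) * grid@resolution
  data.frame(lon = rep(lon, each = grid@nrows),
             lat = rep(lat, times = grid@ncols))
}

#' Rasterize points as per-cell counts
#'
#' The lowest-level HPV build step: the number of occurrence sites falling in
#' each grid cell (information capacity "Count").
#'
#' @param points data.frame with columns `lon`, `lat`.
#' @param grid a [GridSpec-class].
#' @param drop_outside if `TRUE`, points outside the extent are dropped with
#'   a warning instead of raising an error.
#' @param name layer label.
#' @return A [RasterLayer-class] of non-negative integer counts; the cell sum
#'   equals the number of retained points.
#' @export
rasterizeCount <- function(points, grid, drop_outside = FALSE, name = "count") {
  stopifnot(is(grid, "GridSpec"))
  lon <- points$lon; lat <- points$lat
  if (drop_outside) {
    keep <- lon >= grid@xmin & lon < grid@xmax & lat > grid@ymin & lat <= grid@ymax
    if (any(!keep)) {
      warning(sum(!keep), " point(s) outside the grid extent dropped")
      lon <- lon[keep]; lat <- lat[keep]
    }
  }
  vals <- matrix(0, grid@nrows, grid@ncols)
  if (length(lon)) {
    rc <- cellOf(lon, lat, grid)
    idx <- cellIndex(rc$row, rc$col, grid)
    tab <- tabulate(idx, nbins = grid@nrows * grid@ncols)
    vals[] <- tab
  }
  rasterLayer(grid, vals, name = name)
}

#' Convert a count layer to presence/absence
#'
#' Information capacity "Presence": 1 where at least one site falls in the
#' cell, 0 elsewhere; `NA` cells are preserved.
#'
#' @param count_layer a [RasterLayer-class] of non-negative counts.
#' @param name layer label.
#' @return A [RasterLayer-class] with values in `{0, 1, NA}`.
#' @export
toPresence <- function(count_layer, name = "presence") {
  stopifnot(is(count_layer, "RasterLayer"))
  v <- count_layer@values
  if (any(v < 0, na.rm = TRUE)) {
    stop("count layer contains negative values; cannot convert to presence")
  }
  out <- ifelse(is.na(v), NA_real_, as.numeric(v > 0))
  rasterLayer(count_layer@grid, matrix(out, nrow(v), ncol(v)),
              name = name, nodata = count_layer@nodata)
}

#' Distance to the nearest occurrence site
#'
#' Information capacity "Distance": the great-circle distance in meters from
#' every cell center to the nearest of the given sites. This is the
#' highest-capacity HPV transform and the core predictor of the method.
#'
#' @param points data.frame with columns `lon`, `lat`; must be non-empty
#'   (an empty site set leaves the distance undefined — for the potential
#'   range scenario use [potentialStack()] instead).
#' @param grid a [GridSpec-class].
#' @param name layer label.
#' @return A [RasterLayer-class] of distances in meters.
#' @export
distanceToNearest <- function(points, grid, name = "distance") {
  stopifnot(is(grid, "GridSpec"))
  if (is.null(points) || nrow(points) == 0L) {
    stop("distanceToNearest() requires at least one site; ",
         "distance to an empty site set is undefined")
  }
  ctr <- cellCenters(grid)
  d <- rep(Inf, nrow(ctr))
  for (i in seq_len(nrow(points))) {
    d <- pmin(d, haversineMeters(ctr$lon, ctr$lat,
                                 points$lon[i], points$lat[i]))
  }
  rasterLayer(grid, matrix(d, grid@nrows, grid@ncols), name = name)
}

#' Elementwise minimum of two raster layers
#'
#' @param a,b [RasterLayer-class] objects on the same grid.
#' @param name layer label.
#' @return A [RasterLayer-class].
#' @export
layerMin <- function(a, b, name = a@name) {
  stopifnot(identical(a@grid, b@grid))
  rasterLayer(a@grid, pmin(a@values, b@values), name = name)
}
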