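#' @import methods
NULL

#' GridSpec: a regular longitude/latitude grid
#'
#' Defines the geometry every raster layer in the package shares: a regular
#' unprojected lon/lat grid (EPSG:4326). The default resolution of 1/120
#' degree corresponds to roughly 1 x 1 km cells at mid latitudes, the grain
#' at which occurrence sites are rasterized.
#'
#' Cells are half-open: a cell owns its western and northern edges, so a
#' point lying on a shared edge belongs to the cell to its east/south.
#' Row 0 (0-based, see [cellOf()]) is the northernmost row.
#'
#' @slot xmin,ymin,xmax,ymax numeric, grid extent in degrees.
#' @slot resolution numeric, cell size in degrees (default 1/120).
#' @slot nrows,ncols integer, grid dimensions.
#'
#' @seealso [gridSpec()] for the user-facing constructor.
#' @export
setClass("GridSpec",
  representation(
    xmin = "numeric", ymin = "numeric", xmax = "numeric", ymax = "numeric",
    resolution = "numeric", nrows = "integer", ncols = "integer"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
      object@resolution <= 0) {
    msg <- c(msg, "resolution must be a single positive number")
  }
  if (object@xmax <= object@xmin) msg <- c(msg, "xmax must exceed xmin")
  if (object@ymax <= object@ymin) msg <- c(msg, "ymax must exceed ymin")
  if (length(msg) == 0L) {
    nc <- round((object@xmax - object@xmin) / object@resolution)
    nr <- round((object@ymax - object@ymin) / object@resolution)
    if (object@ncols != nc) {
      msg <- c(msg, sprintf("ncols (%d) inconsistent with extent/resolution (%d)",
                            object@ncols, nc))
    }
    if (object@nrows != nr) {
      msg <- c(msg, sprintf("nrows (%d) inconsistent with extent/resolution (%d)",
                            object@nrows, nr))
    }
    if (object@nrows < 1L || object@ncols < 1L) {
      msg <- c(msg, "grid must have at least one row and column")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param xmin,ymin,xmax,ymax extent in degrees lon/lat.
#' @param resolution cell size in degrees; default `1/120` (~1 km).
#' @return A [GridSpec-class] object; `nrows`/`ncols` are derived from the
#'   extent and resolution.
#' @examples
#' g <- gridSpec(17, 51, 17 + 200/120, 51 + 200/120)
#' dim(g)  # 200 x 200
#' @export
gridSpec <- function(xmin, ymin, xmax, ymax, resolution = 1 / 120) {
  new("GridSpec",
    xmin = as.numeric(xmin), ymin = as.numeric(ymin),
    xmax = as.numeric(xmax), ymax = as.numeric(ymax),
    resolution = as.numeric(resolution),
    nrows = as.integer(round((ymax - ymin) / resolution)),
    ncols = as.integer(round((xmax - xmin) / resolution))
  )
}

#' RasterLayer: one named band of values over a GridSpec
#'
#' Values are stored as an `nrows x ncols` matrix with row 1 the
#' northernmost row (matching [cellOf()] row 0). Missing cells are `NA` in
#' memory; the `nodata` slot records the sentinel used when the layer is
#' written to disk ([writeAsciiGrid()]).
#'
#' @slot grid a [GridSpec-class].
#' @slot name character label (e.g. `"5.D"` for a 5-year distance HPV).
#' @slot values numeric matrix.
#' @slot nodata numeric scalar, on-disk sentinel for missing cells.
#' @export
setClass("RasterLayer",
  representation(
    grid = "GridSpec", name = "character",
    values = "matrix", nodata = "numeric"
  )
)

setValidity("RasterLayer", function(object) {
  msg <- character()
  if (!identical(dim(object@values),
                 c(object@grid@nrows, object@grid@ncols))) {
    msg <- c(msg, sprintf(
      "values matrix is %d x %d but grid is %d x %d",
      nrow(object@values), ncol(object@values),
      object@grid@nrows, object@grid@ncols))
  }
  if (length(object@name) != 1L) msg <- c(msg, "name must be length 1")
  if (length(object@nodata) != 1L) msg <- c(msg, "nodata must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a RasterLayer
#'
#' @param grid a [GridSpec-class].
#' @param values numeric matrix (`nrows x ncols`, row 1 = north) or a single
#'   number to fill the grid.
#' @param name layer label.
#' @param nodata sentinel written for `NA` cells on disk; default -9999.
#' @return A [RasterLayer-class].
#' @export
rasterLayer <- function(grid, values, name = "layer", nodata = -9999) {
  if (length(values) == 1L) {
    values <- matrix(as.numeric(values), grid@nrows, grid@ncols)
  }
  new("RasterLayer", grid = grid, name = as.character(name),
      values = values, nodata = as.numeric(nodata))
}

#' RasterStack: named layers sharing one grid
#'
#' @slot grid the shared [GridSpec-class].
#' @slot layers named list of [RasterLayer-class] objects.
#' @export
setClass("RasterStack",
  representation(grid = "GridSpec", layers = "list")
)

setValidity("RasterStack", function(object) {
  msg <- character()
  if (length(object@layers)) {
    if (is.null(names(object@layers)) || anyNA(names(object@layers)) ||
        any(names(object@layers) == "")) {
      msg <- c(msg, "all layers must be named")
    }
    ok <- vapply(object@layers, function(l) {
      is(l, "RasterLayer") && identical(l@grid, object@grid)
    }, logical(1))
    if (!all(ok)) msg <- c(msg, "all layers must be RasterLayers on the shared grid")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RasterStack
#'
#' @param layers a list of [RasterLayer-class] objects; names default to the
#'   layers' own names.
#' @return A [RasterStack-class].
#' @export
rasterStack <- function(layers) {
  if (length(layers) == 0L) stop("rasterStack() needs at least one layer")
  if (is.null(names(layers))) {
    names(layers) <- vapply(layers, function(l) l@name, character(1))
  }
  new("RasterStack", grid = layers[[1L]]@grid, layers = layers)
}

#' StudyBundle: everything one synthetic (or real) study needs
#'
#' Produced by [makeStudy()]: the environmental predictor stack, the true
#' suitability surface that drove the simulation, the study-area mask, the
#' dated census records, the later response-snapshot presences, and the
#' full yearly occupancy history of the simulated invasion (used for
#' ground-truth checks of forecasts).
#'
#' @slot env a [RasterStack-class] of environmental predictors.
#' @slot suitability [RasterLayer-class], true occupancy probability.
#' @slot mask [RasterLayer-class], 1 = inside study area.
#' @slot census data.frame of dated [occurrence records][occurrenceRecords].
#' @slot response data.frame of presence points (lon, lat) at the response year.
#' @slot occupancy named list: year -> integer vector of occupied cell indices.
#' @slot landscapeConfig,invasionConfig the generating configurations.
#' @export
setClass("StudyBundle",
  representation(
    env = "RasterStack", suitability = "RasterLayer", mask = "RasterLayer",
    census = "data.frame", response = "data.frame", occupancy = "list",
    landscapeConfig = "list", invasionConfig = "list"
  )
)

setValidity("StudyBundle", function(object) {
  msg <- character()
  if (!identical(object@suitability@grid, object@env@grid)) {
    msg <- c(msg, "suitability grid differs from env grid")
  }
  if (!identical(object@mask@grid, object@env@grid)) {
    msg <- c(msg, "mask grid differs from env grid")
  }
  need <- c("id", "lon", "lat", "onset_year", "census_year")
  if (nrow(object@census) && !all(need %in% names(object@census))) {
    msg <- c(msg, "census must have columns id, lon, lat, onset_year, census_year")
  }
  if (length(msg)) msg else TRUE
})
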