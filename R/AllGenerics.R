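#' @rdname GridSpec-class
#' @param x a `GridSpec` or `RasterLayer`.
#' @export
setMethod("dim", "GridSpec", function(x) c(x@nrows, x@ncols))

#' @rdname RasterLayer-class
#' @param x a `RasterLayer`.
#' @export
setMethod("dim", "RasterLayer", function(x) dim(x@values))

#' Accessors for grid and raster objects
#'
#' `gridOf()` returns the [GridSpec-class] an object lives on;
#' `layerValues()` the value matrix of a layer (row 1 = north);
#' `layerName()` its label; `resolutionOf()` the cell size in degrees;
#' `nLayers()` / `layerNames()` the size and names of a stack.
#'
#' @param x a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))
#' @rdname accessors
#' @export
setMethod("gridOf", "RasterLayer", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridOf", "RasterStack", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridOf", "GridSpec", function(x) x)
#' @rdname accessors
#' @export
setMethod("gridOf", "StudyBundle", function(x) x@env@grid)

#' @rdname accessors
#' @export
setGeneric("layerValues", function(x) standardGeneric("layerValues"))
#' @rdname accessors
#' @export
setMethod("layerValues", "RasterLayer", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("layerName", function(x) standardGeneric("layerName"))
#' @rdname accessors
#' @export
setMethod("layerName", "RasterLayer", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("resolutionOf", function(x) standardGeneric("resolutionOf"))
#' @rdname accessors
#' @export
setMethod("resolutionOf", "GridSpec", function(x) x@resolution)
#' @rdname accessors
#' @export
setMethod("resolutionOf", "RasterLayer", function(x) x@grid@resolution)

#' @rdname accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))
#' @rdname accessors
#' @export
setMethod("nLayers", "RasterStack", function(x) length(x@layers))

#' @rdname accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname accessors
#' @export
setMethod("layerNames", "RasterStack", function(x) names(x@layers))

#' @rdname accessors
#' @param name layer name.
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))
#' @rdname accessors
#' @export
setMethod("getLayer", "RasterStack", function(x, name) {
  if (!name %in% names(x@layers)) {
    stop("no layer named '", name, "' in stack (have: ",
         paste(names(x@layers), collapse = ", "), ")")
  }
  x@layers[[name]]
})

#' Study bundle accessors
#'
#' @param x a [StudyBundle-class].
#' @return `envStack()` the environmental [RasterStack-class];
#'   `censusRecords()` the dated occurrence records; `responsePresences()`
#'   the response-year presence points; `studyMask()` the mask layer;
#'   `occupancyAt()` the occupied cell indices at a given year.
#' @name study-accessors
NULL

#' @rdname study-accessors
#' @export
setGeneric("envStack", function(x) standardGeneric("envStack"))
#' @rdname study-accessors
#' @export
setMethod("envStack", "StudyBundle", function(x) x@env)

#' @rdname study-accessors
#' @export
setGeneric("censusRecords", function(x) standardGeneric("censusRecords"))
#' @rdname study-accessors
#' @export
setMethod("censusRecords", "StudyBundle", function(x) x@census)

#' @rdname study-accessors
#' @export
setGeneric("responsePresences", function(x) standardGeneric("responsePresences"))
#' @rdname study-accessors
#' @export
setMethod("responsePresences", "StudyBundle", function(x) x@response)

#' @rdname study-accessors
#' @export
setGeneric("studyMask", function(x) standardGeneric("studyMask"))
#' @rdname study-accessors
#' @export
setMethod("studyMask", "StudyBundle", function(x) x@mask)

#' @rdname study-accessors
#' @param year integer year.
#' @export
setGeneric("occupancyAt", function(x, year) standardGeneric("occupancyAt"))
#' @rdname study-accessors
#' @export
setMethod("occupancyAt", "StudyBundle", function(x, year) {
  key <- as.character(year)
  if (!key %in% names(x@occupancy)) {
    stop("no occupancy snapshot recorded for year ", year)
  }
  x@occupancy[[key]]
})

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", object@nrows, "x", object@ncols, "cells at",
      format(object@resolution, digits = 6), "deg\n")
  cat("  extent: lon [", object@xmin, ",", object@xmax, "], lat [",
      object@ymin, ",", object@ymax, "]\n")
})

setMethod("show", "RasterLayer", function(object) {
  v <- object@values
  cat("RasterLayer '", object@name, "' (", nrow(v), " x ", ncol(v), ")\n",
      sep = "")
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat(sprintf("  values: min %.4g, median %.4g, max %.4g; %d NA cells\n",
                min(fin), stats::median(fin), max(fin), sum(is.na(v))))
  } else {
    cat("  all cells NA\n")
  }
})

setMethod("show", "RasterStack", function(object) {
  cat("RasterStack with", length(object@layers), "layer(s):",
      paste(names(object@layers), collapse = ", "), "\n")
  show(object@grid)
})

setMethod("show", "StudyBundle", function(object) {
  cat("StudyBundle\n")
  show(object@env@grid)
  cat("  env layers:", length(object@env@layers),
      "| census records:", nrow(object@census),
      "| response presences:", nrow(object@response), "\n")
  yrs <- names(object@occupancy)
  if (length(yrs)) {
    cat("  occupancy history:", yrs[1L], "-", yrs[length(yrs)], "\n")
  }
})
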