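# Plain-text raster and point I/O. Rasters use the ESRI ASCII grid format
# (.asc): a 6-line header followed by rows of values, north row first, which
# matches the in-memory matrix orientation. Coordinates are EPSG:4326 lon/lat.

#' Write a raster layer as an ESRI ASCII grid
#'
#' @param layer a [RasterLayer-class].
#' @param path output file path (conventionally `.asc`).
#' @param digits significant digits to print; default 10.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(layer, path, digits = 10) {
  stopifnot(is(layer, "RasterLayer"))
  g <- layer@grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", g@ncols),
    paste("nrows", g@nrows),
    paste("xllcorner", format(g@xmin, digits = 15)),
    paste("yllcorner", format(g@ymin, digits = 15)),
    paste("cellsize", format(g@resolution, digits = 15)),
    paste("NODATA_value", format(layer@nodata, digits = 15))
  ), con)
  v <- layer@values
  v[is.na(v)] <- layer@nodata
  for (r in seq_len(nrow(v))) {
    writeLines(paste(formatC(v[r, ], digits = digits, format = "g"),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param name layer label; defaults to the file name without extension.
#' @return A [RasterLayer-class]; nodata cells become `NA`.
#' @export
readAsciiGrid <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  res <- hdr$cellsize
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nrows * ncols) {
    stop("ASCII grid ", path, ": expected ", nrows * ncols,
         " values, found ", length(vals))
  }
  m <- matrix(vals, nrows, ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  g <- gridSpec(hdr$xllcorner, hdr$yllcorner,
                hdr$xllcorner + ncols * res, hdr$yllcorner + nrows * res,
                resolution = res)
  rasterLayer(g, m, name = name, nodata = hdr$nodata_value)
}

#' Read and write point tables
#'
#' Points travel as CSV with columns `lon`, `lat` and optionally
#' `onset_year`, `census_year`, `id`, or as GeoJSON Point features with the
#' extra columns as properties.
#'
#' @param points data.frame with at least `lon` and `lat`.
#' @param path file path.
#' @return the read functions return a data.frame; the write functions
#'   return `path` invisibly.
#' @name point-io
NULL

#' @rdname point-io
#' @export
writePointsCSV <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname point-io
#' @export
readPointsCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname point-io
#' @export
writePointsGeoJSON <- function(points, path) {
  props <- setdiff(names(points), c("lon", "lat"))
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(points$lon[i], points$lat[i])),
      properties = as.list(points[i, props, drop = FALSE])
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname point-io
#' @export
readPointsGeoJSON <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    stop(path, " is not a GeoJSON FeatureCollection")
  }
  rows <- lapply(fc$features, function(f) {
    cc <- unlist(f$geometry$coordinates)
    c(list(lon = cc[1L], lat = cc[2L]), f$properties)
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(out) <- NULL
  out
}

# Run expr with a temporarily seeded RNG, restoring the caller's stream.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' One master seed spawns named per-stage seeds (simulate / pa / split / fit /
#' meta ...), so pipeline stages can be re-run independently yet
#' reproducibly. The derivation is a fixed integer hash of the stage name,
#' kept below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
deriveSeed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483629)
}
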