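# Pseudoabsence sampling and model-matrix assembly. Presence-only response
# data are amended with randomly placed pseudoabsences (background cells
# treated as absences); predictor values are extracted at every point's cell.

#' Sample pseudoabsences
#'
#' Draws `n` cells uniformly without replacement from the eligible cells of
#' the study mask — cells with a positive, non-missing mask value that do not
#' contain a presence — and returns their centers as points. One
#' pseudoabsence per cell, matching the analysis grain.
#'
#' @param mask a [RasterLayer-class]; eligible cells have value > 0.
#' @param n number of pseudoabsences (default 1000).
#' @param presences data.frame of presence points (`lon`, `lat`) whose cells
#'   are excluded; `NULL` to exclude nothing.
#' @param seed integer seed; the draw is deterministic given it.
#' @return data.frame of points `lon`, `lat` with attribute `cells` (the
#'   sampled cell indices).
#' @export
samplePseudoabsences <- function(mask, n = 1000, presences = NULL, seed = 1) {
  stopifnot(is(mask, "RasterLayer"), n >= 0)
  v <- as.vector(mask@values)
  eligible <- which(!is.na(v) & v > 0)
  if (!is.null(presences) && nrow(presences)) {
    rc <- cellOf(presences$lon, presences$lat, mask@grid)
    eligible <- setdiff(eligible, cellIndex(rc$row, rc$col, mask@grid))
  }
  if (n == 0L) {
    out <- data.frame(lon = numeric(0), lat = numeric(0))
    attr(out, "cells") <- integer(0)
    return(out)
  }
  if (length(eligible) < n) {
    stop("only ", length(eligible), " eligible cells for ", n,
         " pseudoabsences")
  }
  cells <- withSeed(seed, sort(sample(eligible, n)))
  ctr <- cellCenters(mask@grid)
  out <- data.frame(lon = ctr$lon[cells], lat = ctr$lat[cells])
  attr(out, "cells") <- cells
  out
}

#' Assemble the model matrix
#'
#' One row per point; predictor columns are the stack layer values extracted
#' at each point's cell, the binary `response` is 1 for presences and 0 for
#' pseudoabsences, and `role` tags each row's provenance. Rows with any
#' missing predictor are dropped and the count reported via a message and
#' the `"n_dropped_nodata"` attribute.
#'
#' @param presences,pseudoabsences data.frames of points (`lon`, `lat`).
#' @param stack a [RasterStack-class] of predictors (environmental + HPV).
#' @param drop_outside if `TRUE`, points outside the grid are dropped with a
#'   logged count instead of raising an error.
#' @return data.frame with the predictor columns, `response` and `role`;
#'   attributes: `predictors` (stable column order), `n_dropped_nodata`,
#'   `n_dropped_outside`.
#' @export
assembleModelMatrix <- function(presences, pseudoabsences, stack,
                                drop_outside = FALSE) {
  stopifnot(is(stack, "RasterStack"))
  grid <- stack@grid
  pts <- rbind(
    data.frame(lon = presences$lon, lat = presences$lat,
               response = rep(1, nrow(presences))),
    data.frame(lon = pseudoabsences$lon, lat = pseudoabsences$lat,
               response = rep(0, nrow(pseudoabsences)))
  )
  n_outside <- 0L
  inside <- pts$lon >= grid@xmin & pts$lon < grid@xmax &
    pts$lat > grid@ymin & pts$lat <= grid@ymax
  if (any(!inside)) {
    if (!drop_outside) {
      stop(sum(!inside), " point(s) fall outside the predictor grid")
    }
    n_outside <- sum(!inside)
    message(n_outside, " point(s) outside the grid dropped")
    pts <- pts[inside, , drop = FALSE]
  }
  rc <- cellOf(pts$lon, pts$lat, grid)
  idx <- cellIndex(rc$row, rc$col, grid)
  pred_names <- layerNames(stack)
  pred <- vapply(pred_names,
                 function(nm) as.vector(getLayer(stack, nm)@values)[idx],
                 numeric(nrow(pts)))
  pred <- matrix(pred, nrow = nrow(pts),
                 dimnames = list(NULL, pred_names))
  mm <- data.frame(pred, check.names = FALSE)
  mm$response <- pts$response
  mm$role <- ifelse(pts$response == 1, "presence", "pseudoabsence")
  complete <- stats::complete.cases(mm[, pred_names, drop = FALSE])
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message(n_dropped, " case(s) with missing predictor values dropped")
    mm <- mm[complete, , drop = FALSE]
  }
  rownames(mm) <- NULL
  attr(mm, "predictors") <- pred_names
  attr(mm, "n_dropped_nodata") <- n_dropped
  attr(mm, "n_dropped_outside") <- n_outside
  mm
}

#' Predictor names of a model matrix
#'
#' @param mm a model matrix from [assembleModelMatrix()].
#' @return character vector of predictor column names in stable order.
#' @export
predictorNames <- function(mm) {
  p <- attr(mm, "predictors")
  if (is.null(p)) setdiff(names(mm), c("response", "role")) else p
}
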