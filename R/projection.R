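# Spatial projection of fitted models and the HPV-substitution scenarios:
# current map, short-term forecast (distance to *current* sites), potential
# range (zero/low distance everywhere), and the emergence / unsaturation
# difference maps.

# HPV layers are recognized by their "<period>.<capacity>" names.
hpvLayerInfo <- function(stack) {
  nm <- layerNames(stack)
  m <- regmatches(nm, regexec("^([0-9]+)\\.([PCD])$", nm))
  keep <- lengths(m) == 3L
  data.frame(name = nm[keep],
             period = as.integer(vapply(m[keep], `[`, character(1), 2L)),
             capacity = vapply(m[keep], `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

#' Project a model over a predictor stack
#'
#' Scores every grid cell with the model, using the stack's layer values as
#' the predictor row of that cell. Cells with any missing predictor are
#' `NA` in the output.
#'
#' @param scorer an `sdmScorer` (single model or [ensembleScorer()]).
#' @param stack a [RasterStack-class] whose layer names cover the model's
#'   predictors.
#' @param name output layer label.
#' @return a probability [RasterLayer-class] in `[0, 1]` (binary for SRE).
#' @export
projectMap <- function(scorer, stack, name = "projection") {
  stopifnot(is(stack, "RasterStack"))
  preds <- if (inherits(scorer, "sreModel")) scorer$predictors else {
    stopifnot(inherits(scorer, "sdmScorer"))
    scorer$predictors
  }
  missing <- setdiff(preds, layerNames(stack))
  if (length(missing)) {
    stop("stack lacks predictor layer(s): ", paste(missing, collapse = ", "))
  }
  grid <- stack@grid
  nd <- data.frame(lapply(stats::setNames(preds, preds), function(nm) {
    as.vector(getLayer(stack, nm)@values)
  }), check.names = FALSE)
  out <- rep(NA_real_, nrow(nd))
  complete <- stats::complete.cases(nd)
  if (any(complete)) {
    out[complete] <- predictScores(scorer, nd[complete, , drop = FALSE])
  }
  rasterLayer(grid, matrix(out, grid@nrows, grid@ncols), name = name)
}

#' Substitute HPV layers with the current distribution
#'
#' The short-term forecast scenario: every HPV layer in the stack is
#' recomputed from the *current* sites — distance layers become the distance
#' to the nearest current site, count and presence layers the rasterization
#' of the current sites. Projecting a model over the result is read as the
#' map at (present + minimal recentness of the HPV set).
#'
#' @param stack a [RasterStack-class] containing HPV layers
#'   (`"<period>.<P|C|D>"`).
#' @param current_sites data.frame of points (`lon`, `lat`).
#' @return a new [RasterStack-class] with an attribute `substituted` listing
#'   the replaced layers.
#' @export
forecastStack <- function(stack, current_sites) {
  info <- hpvLayerInfo(stack)
  if (nrow(info) == 0L) {
    stop("stack contains no HPV layers to substitute")
  }
  layers <- stack@layers
  cnt <- rasterizeCount(current_sites, stack@grid)
  dst <- NULL
  for (i in seq_len(nrow(info))) {
    nm <- info$name[i]
    layers[[nm]] <- switch(info$capacity[i],
      C = rasterLayer(stack@grid, cnt@values, name = nm),
      P = rasterLayer(stack@grid, toPresence(cnt)@values, name = nm),
      D = {
        if (is.null(dst)) dst <- distanceToNearest(current_sites, stack@grid)
        rasterLayer(stack@grid, dst@values, name = nm)
      })
  }
  out <- new("RasterStack", grid = stack@grid, layers = layers)
  attr(out, "substituted") <- info$name
  attr(out, "substitution") <- "from-current"
  out
}

#' Substitute HPV layers with saturating constants
#'
#' The potential-range scenario: distance layers are set to a constant low
#' or zero value and count/presence layers to a saturating constant, so the
#' projection reads as the probability of final space infilling —
#' occurrence probability were propagule pressure no longer limiting.
#'
#' @param stack a [RasterStack-class] containing HPV layers.
#' @param fill constant for distance layers, meters (default 0).
#' @param presence_fill,count_fill constants for presence and count layers
#'   (defaults 1 and 1).
#' @return a new [RasterStack-class] with substitution attributes.
#' @export
potentialStack <- function(stack, fill = 0, presence_fill = 1,
                           count_fill = 1) {
  if (fill < 0) stop("distance fill must be non-negative")
  info <- hpvLayerInfo(stack)
  if (nrow(info) == 0L) {
    stop("stack contains no HPV layers to substitute")
  }
  layers <- stack@layers
  for (i in seq_len(nrow(info))) {
    nm <- info$name[i]
    const <- switch(info$capacity[i], D = fill, P = presence_fill,
                    C = count_fill)
    layers[[nm]] <- rasterLayer(stack@grid, const, name = nm)
  }
  out <- new("RasterStack", grid = stack@grid, layers = layers)
  attr(out, "substituted") <- info$name
  attr(out, "substitution") <- "constant"
  out
}

differenceLayer <- function(a, b, name) {
  stopifnot(is(a, "RasterLayer"), is(b, "RasterLayer"))
  if (!identical(a@grid, b@grid)) {
    stop("maps are on different grids; cannot subtract")
  }
  rasterLayer(a@grid, a@values - b@values, name = name)
}

#' New-site-emergence map
#'
#' Pointwise forecast probability minus current probability; positive cells
#' are where new sites are expected to emerge over the forecast span.
#'
#' @param forecast_map,current_map probability [RasterLayer-class] maps on
#'   one grid.
#' @return a difference [RasterLayer-class] in `[-1, 1]`.
#' @export
emergenceMap <- function(forecast_map, current_map) {
  differenceLayer(forecast_map, current_map, "emergence")
}

#' Unsaturation map
#'
#' Pointwise potential probability minus current probability; positive cells
#' are suitable but not yet reached — the unsaturated part of the range.
#'
#' @param potential_map,current_map probability [RasterLayer-class] maps on
#'   one grid.
#' @return a difference [RasterLayer-class] in `[-1, 1]`.
#' @export
unsaturationMap <- function(potential_map, current_map) {
  differenceLayer(potential_map, current_map, "unsaturation")
}

#' Threshold a probability map into pseudo-sites
#'
#' Used by iterated forecasting: cells at or above the threshold become
#' sites (their centers), feeding the next round of HPV substitution.
#'
#' @param prob_map probability [RasterLayer-class].
#' @param threshold cutoff in `[0, 1]` (typically the ensemble's TSS-optimal
#'   threshold).
#' @return data.frame of points `lon`, `lat`.
#' @export
thresholdToSites <- function(prob_map, threshold) {
  v <- as.vector(prob_map@values)
  cells <- which(!is.na(v) & v >= threshold)
  ctr <- cellCenters(prob_map@grid)
  data.frame(lon = ctr$lon[cells], lat = ctr$lat[cells])
}
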