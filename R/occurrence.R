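# Dated-occurrence bookkeeping and HPV layer / variant construction.
#
# A population site is a row: id, lon, lat, onset_year (earliest known
# existence) and census_year (year the site was verified present). Historical
# proximity variables are built by subsetting these records to those already
# present a given number of years before the response snapshot, then
# rasterizing with one of three information-capacity transforms.

#' Build a dated occurrence record table
#'
#' @param lon,lat coordinates in degrees.
#' @param onset_year earliest year the population is known to have existed.
#' @param census_year year the site was verified present; defaults to
#'   `onset_year` when the site was first found at the census.
#' @param id site labels; autogenerated when missing.
#' @return data.frame with columns `id`, `lon`, `lat`, `onset_year`,
#'   `census_year`. Rows with `onset_year > census_year` are rejected.
#' @export
occurrenceRecords <- function(lon, lat, onset_year,
                              census_year = onset_year, id = NULL) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n)
  lat <- rep_len(lat, n)
  onset_year <- rep_len(as.integer(onset_year), n)
  census_year <- rep_len(as.integer(census_year), n)
  if (any(onset_year > census_year)) {
    stop("onset_year must not exceed census_year")
  }
  if (is.null(id)) id <- sprintf("site_%04d", seq_len(n))
  data.frame(id = as.character(id), lon = lon, lat = lat,
             onset_year = onset_year, census_year = census_year,
             stringsAsFactors = FALSE)
}

#' Decennial onset estimation
#'
#' When only the decade of a population's onset is known, the onset year is
#' coarsened to the middle year of that decade (1970-1979 becomes 1975).
#'
#' @param decade_start first year of the decade; must be divisible by 10.
#' @return `decade_start + 5`.
#' @examples
#' decennialOnset(1970)  # 1975
#' @export
decennialOnset <- function(decade_start) {
  if (any(decade_start %% 10 != 0)) {
    stop("decade_start must be divisible by 10 (got ",
         paste(decade_start[decade_start %% 10 != 0], collapse = ", "), ")")
  }
  as.integer(decade_start + 5)
}

#' Merge populations closer than a radius
#'
#' Sites farther than `radius` from every other site are treated as separate
#' populations; closer ones are merged. Merging follows single-linkage
#' clustering at the radius (chains of pairwise-close sites form one
#' population). The merged record keeps the earliest onset year, the latest
#' census year and the centroid location.
#'
#' @param records occurrence record data.frame (see [occurrenceRecords()]).
#' @param radius linkage radius in meters; default 500.
#' @return deduplicated occurrence record data.frame.
#' @export
dedupePopulations <- function(records, radius = 500) {
  stopifnot(radius > 0)
  n <- nrow(records)
  if (n <= 1L) return(records)
  d <- geosphere::distm(cbind(records$lon, records$lat),
                        fun = function(p1, p2) {
                          geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M)
                        })
  # single-linkage components at the radius via hclust + cutree
  cl <- stats::cutree(stats::hclust(stats::as.dist(d), method = "single"),
                      h = radius)
  merged <- lapply(split(seq_len(n), cl), function(ix) {
    sub <- records[ix, , drop = FALSE]
    rep <- sub[which.min(sub$onset_year), , drop = FALSE]
    rep$lon <- mean(sub$lon)
    rep$lat <- mean(sub$lat)
    rep$onset_year <- min(sub$onset_year)
    rep$census_year <- max(sub$census_year)
    rep
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out[order(match(out$id, records$id)), , drop = FALSE]
}

#' Subset records by minimal recentness
#'
#' Keeps the sites already existing `recentness` years before the response
#' snapshot, i.e. those with `onset_year <= response_year - recentness`.
#' When the recentness equals the lag between response and census years this
#' returns every censused record.
#'
#' @param records occurrence record data.frame.
#' @param response_year year of the response snapshot.
#' @param recentness minimal recentness in years (5, 10 or 25 in the standard
#'   variant set).
#' @return the qualifying subset of `records`.
#' @examples
#' r <- occurrenceRecords(c(17.2, 17.4), c(52.1, 52.2), c(1985, 2005), 2007)
#' subsetByRecentness(r, 2012, 10)  # onset <= 2002: only the 1985 site
#' @export
subsetByRecentness <- function(records, response_year, recentness) {
  records[records$onset_year <= response_year - recentness, , drop = FALSE]
}

#' Build historical proximity variable layers
#'
#' For each requested time period `p` and information capacity `k`, subsets
#' the records to those existing `p` years before `response_year` and
#' rasterizes them: `P` presence/absence, `C` site count, `D` distance in
#' meters to the nearest site. Layers are named `"<p>.<k>"` (e.g. `"5.D"`).
#'
#' @param records occurrence record data.frame.
#' @param grid a [GridSpec-class].
#' @param response_year year of the response snapshot.
#' @param periods integer vector of minimal recentness values.
#' @param capacities subset of `c("P", "C", "D")`.
#' @param drop_outside passed to [rasterizeCount()].
#' @return named list of [RasterLayer-class] objects. A period with no
#'   qualifying site is an error for capacity `D` (distance undefined) and a
#'   zero layer with a warning for `P`/`C`.
#' @export
buildHpvLayers <- function(records, grid, response_year, periods,
                           capacities = c("C", "D"), drop_outside = FALSE) {
  stopifnot(all(capacities %in% c("P", "C", "D")))
  layers <- list()
  for (p in sort(unique(periods), decreasing = TRUE)) {
    sub <- subsetByRecentness(records, response_year, p)
    cnt <- rasterizeCount(sub[, c("lon", "lat")], grid,
                          drop_outside = drop_outside,
                          name = paste0(p, ".C"))
    for (k in capacities) {
      nm <- paste0(p, ".", k)
      if (k == "C") {
        if (nrow(sub) == 0L) {
          warning("no sites qualify for period ", p, "; '", nm,
                  "' is an all-zero layer")
        }
        layers[[nm]] <- cnt
      } else if (k == "P") {
        if (nrow(sub) == 0L) {
          warning("no sites qualify for period ", p, "; '", nm,
                  "' is an all-zero layer")
        }
        layers[[nm]] <- toPresence(cnt, name = nm)
      } else {
        if (nrow(sub) == 0L) {
          stop("no sites qualify for period ", p,
               "; distance layer '", nm, "' is undefined")
        }
        layers[[nm]] <- distanceToNearest(sub[, c("lon", "lat")], grid,
                                          name = nm)
      }
    }
  }
  layers
}

# The six time-period combinations that, crossed with the four capacity
# codes, give the 24 standard HPV variants.
PERIOD_COMBOS <- list(c(5L), c(10L), c(25L), c(10L, 5L), c(25L, 10L),
                      c(25L, 10L, 5L))
CAPACITY_CODES <- c("P", "C", "D", "CD")
CONTROL_LABEL <- "No HPV"

#' Format / parse HPV variant labels
#'
#' A variant label concatenates its time periods (descending) and its
#' capacity code: `"5.P"`, `"25.10.5.CD"`. The control variant is
#' `"No HPV"`. `parseVariantLabel()` inverts `formatVariantLabel()`.
#'
#' @param periods integer vector of time periods (years).
#' @param capacity_code one of `"P"`, `"C"`, `"D"`, `"CD"`, `"control"`.
#' @param label a variant label.
#' @return `formatVariantLabel()` a character label;
#'   `parseVariantLabel()` a list with `label`, `periods`, `capacities`,
#'   `capacity_code`, `minimal_recentness`, `n_periods`.
#' @export
formatVariantLabel <- function(periods, capacity_code) {
  if (identical(capacity_code, "control") || length(periods) == 0L) {
    return(CONTROL_LABEL)
  }
  paste(c(sort(unique(periods), decreasing = TRUE), capacity_code),
        collapse = ".")
}

#' @rdname formatVariantLabel
#' @export
parseVariantLabel <- function(label) {
  if (identical(label, CONTROL_LABEL)) {
    return(list(label = CONTROL_LABEL, periods = integer(0),
                capacities = character(0), capacity_code = "control",
                minimal_recentness = "control", n_periods = "control"))
  }
  parts <- strsplit(label, ".", fixed = TRUE)[[1L]]
  code <- parts[length(parts)]
  if (!code %in% CAPACITY_CODES) {
    stop("malformed variant label '", label, "': capacity code '", code,
         "' is not one of ", paste(CAPACITY_CODES, collapse = ", "))
  }
  periods <- as.integer(parts[-length(parts)])
  if (anyNA(periods) || length(periods) == 0L) {
    stop("malformed variant label '", label, "': bad period list")
  }
  caps <- if (code == "CD") c("C", "D") else code
  list(label = label, periods = sort(periods, decreasing = TRUE),
       capacities = caps, capacity_code = code,
       minimal_recentness = as.character(min(periods)),
       n_periods = as.character(length(periods)))
}

#' Enumerate the standard HPV variant set
#'
#' The factorial design of the predictor sets: every combination of the four
#' capacity codes (`P`, `C`, `D`, `CD`) with the six time-period combinations
#' `{5}`, `{10}`, `{25}`, `{10,5}`, `{25,10}`, `{25,10,5}` — 24 HPV variants —
#' plus the `"No HPV"` control with environmental predictors only.
#'
#' @return data.frame (the variant registry) with columns `label`,
#'   `capacity_code`, `minimal_recentness`, `n_periods` and a list column
#'   `periods`.
#' @examples
#' v <- enumerateVariants()
#' nrow(v)  # 25
#' @export
enumerateVariants <- function() {
  rows <- list(data.frame(label = CONTROL_LABEL, capacity_code = "control",
                          minimal_recentness = "control", n_periods = "control",
                          stringsAsFactors = FALSE))
  periods <- list(integer(0))
  for (code in CAPACITY_CODES) {
    for (pc in PERIOD_COMBOS) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = formatVariantLabel(pc, code),
        capacity_code = code,
        minimal_recentness = as.character(min(pc)),
        n_periods = as.character(length(pc)),
        stringsAsFactors = FALSE)
      periods[[length(periods) + 1L]] <- pc
    }
  }
  out <- do.call(rbind, rows)
  out$periods <- periods
  rownames(out) <- NULL
  out
}

#' Look up one variant in the registry
#'
#' @param label variant label.
#' @param registry variant registry from [enumerateVariants()].
#' @return the registry row (with its `periods` entry) for `label`.
#' @export
variantInfo <- function(label, registry = enumerateVariants()) {
  i <- match(label, registry$label)
  if (is.na(i)) stop("unknown variant label '", label, "'")
  registry[i, , drop = FALSE]
}
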