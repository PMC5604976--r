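# Independent oracles and small fixtures used across the suite. The oracles
# are deliberately naive (explicit loops, closed forms) and share no code
# with the implementation paths they check.

# Closed-form haversine, written out from the formula.
oracleHaversine <- function(lon1, lat1, lon2, lat2, R = 6371008.8) {
  toRad <- pi / 180
  dlat <- (lat2 - lat1) * toRad
  dlon <- (lon2 - lon1) * toRad
  a <- sin(dlat / 2)^2 + cos(lat1 * toRad) * cos(lat2 * toRad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# Loop-based cell assignment: scan all cells for the one whose half-open
# bounds contain the point.
oracleCellOf <- function(lon, lat, grid) {
  res <- resolutionOf(grid)
  nr <- dim(grid)[1]; nc <- dim(grid)[2]
  for (r in 0:(nr - 1)) {
    north <- grid@ymax - r * res
    south <- north - res
    if (lat <= north && lat > south) {
      for (c in 0:(nc - 1)) {
        west <- grid@xmin + c * res
        if (lon >= west && lon < west + res) return(c(r, c))
      }
    }
  }
  stop("point not in any cell")
}

# Exhaustive all-pairs distance-to-nearest over cell centers.
oracleDistanceGrid <- function(points, grid) {
  ctr <- cellCenters(grid)
  vals <- numeric(nrow(ctr))
  for (i in seq_len(nrow(ctr))) {
    vals[i] <- min(oracleHaversine(ctr$lon[i], ctr$lat[i],
                                   points$lon, points$lat))
  }
  matrix(vals, dim(grid)[1], dim(grid)[2])
}

# Iterative label propagation: merge clusters until no pair of clusters
# holds points within the radius.
oracleClusterCount <- function(lon, lat, radius) {
  n <- length(lon)
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (labels[i] != labels[j] &&
          oracleHaversine(lon[i], lat[i], lon[j], lat[j]) <= radius) {
        labels[labels == labels[j]] <- labels[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(labels))
}

# Exhaustive threshold-scan TSS using table() bookkeeping.
oracleTSS <- function(scores, labels, step = 0.001) {
  best <- -Inf; best_t <- NA
  for (t in seq(0, 1, by = step)) {
    pred <- as.integer(scores >= t)
    tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
    tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
    tss <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (tss > best) { best <- tss; best_t <- t }
  }
  list(tss = best, threshold = best_t)
}

# Trapezoidal AUC from the explicit ROC curve.
oracleAUC <- function(scores, labels) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- spec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pred <- scores >= ths[i]
    sens[i] <- sum(pred & labels == 1) / sum(labels == 1)
    spec[i] <- sum(!pred & labels == 0) / sum(labels == 0)
  }
  fpr <- 1 - spec
  sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
}

# Small grid fixture: n x n cells at 1/120 degree near latitude 52.
smallGrid <- function(n = 20) {
  gridSpec(17, 52, 17 + n / 120, 52 + n / 120, resolution = 1 / 120)
}

randomPoints <- function(n, grid, seed = 1) {
  set.seed(seed)
  eps <- resolutionOf(grid) * 1e-6
  data.frame(
    lon = runif(n, grid@xmin, grid@xmax - eps),
    lat = runif(n, grid@ymin + eps, grid@ymax))
}

# A small, quick study on a 60x60 grid for unit tests (cached per session).
tinyStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- gridSpec(17, 52, 17.5, 52.5, resolution = 1 / 120)
      cache <<- makeStudy(landscapeConfig(grid = g, seed = 5),
                          invasionConfig(seed = 5))
    }
    cache
  }
})

# A perfectly separable toy model matrix: response = 1 iff x1 > 0.
toyMatrix <- function(n = 200, seed = 1) {
  set.seed(seed)
  x1 <- c(runif(n / 2, 0.5, 2), runif(n / 2, -2, -0.5))
  mm <- data.frame(x1 = x1, x2 = rnorm(n), x3 = rnorm(n),
                   response = as.numeric(x1 > 0),
                   role = ifelse(x1 > 0, "presence", "pseudoabsence"))
  attr(mm, "predictors") <- c("x1", "x2", "x3")
  mm
}
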