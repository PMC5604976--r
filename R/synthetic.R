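# Synthetic study generator: spatially autocorrelated environmental
# landscapes and a dispersal-limited invasion that produces dated occurrence
# records (a field-census analogue) plus a later response snapshot. It stands
# in for real census/response data so the whole HPV pipeline can be exercised
# and tested offline.

#' Landscape generator configuration
#'
#' Defaults describe a 200 x 200 cell study area (~1.7 x 1.7 degrees at
#' 1/120-degree resolution, centered near latitude 52, i.e. Central European
#' conditions) with 8 standardized, spatially autocorrelated environmental
#' layers. True habitat suitability is a logistic function of a weighted sum
#' of the layers; the default weights make roughly the top tenth of the area
#' clearly suitable, so the simulated invasion stays patchy and
#' dispersal-limited rather than filling the grid.
#'
#' @param grid a [GridSpec-class]; default 200 x 200 at 1/120 degree centered
#'   at (17.8 E, 52 N).
#' @param n_env_layers number of environmental layers (default 8).
#' @param autocorrelation_scale Gaussian smoothing scale in cells (default 15).
#' @param suitability_weights numeric weights over the layers; default gives
#'   four informative layers and four nuisance layers.
#' @param suitability_intercept logistic intercept (default -3.5, i.e. a
#'   baseline establishment probability of about 0.03 per propagule; with
#'   the default weights the environment modulates this weakly, so the
#'   invasion is limited by dispersal rather than by habitat and much
#'   suitable area stays unreached at the census — the regime HPV
#'   predictors are designed for).
#' @param seed integer RNG seed.
#' @return a classed list of settings.
#' @export
landscapeConfig <- function(grid = NULL, n_env_layers = 8,
                            autocorrelation_scale = 15,
                            suitability_weights = NULL,
                            suitability_intercept = -3.5,
                            seed = 3) {
  if (is.null(grid)) {
    grid <- gridSpec(17.8 - 100 / 120, 52 - 100 / 120,
                     17.8 + 100 / 120, 52 + 100 / 120, resolution = 1 / 120)
  }
  stopifnot(n_env_layers >= 1, autocorrelation_scale >= 1)
  if (is.null(suitability_weights)) {
    suitability_weights <- rep(0, n_env_layers)
    base <- c(0.4, -0.3, 0.2, 0.15)
    suitability_weights[seq_len(min(4, n_env_layers))] <-
      base[seq_len(min(4, n_env_layers))]
  }
  stopifnot(length(suitability_weights) == n_env_layers)
  if (any(!is.finite(suitability_weights)) ||
      !is.finite(suitability_intercept)) {
    stop("suitability weights and intercept must be finite")
  }
  structure(list(
    grid = grid, n_env_layers = as.integer(n_env_layers),
    autocorrelation_scale = autocorrelation_scale,
    suitability_weights = suitability_weights,
    suitability_intercept = suitability_intercept,
    seed = as.integer(seed)
  ), class = "landscapeConfig")
}

#' Invasion simulator configuration
#'
#' Emulates an invasion with separate near- and long-distance dispersal: each
#' extant site emits a few propagules per year whose dispersal distance is
#' exponential with a short mean, with a small probability of a uniform
#' long-distance jump; a propagule establishes with probability equal to the
#' habitat suitability of the cell it lands in. Populations are persistent by
#' default (the modelled species holds sites for decades). Onset years before
#' `decennial_noise_before` are coarsened to mid-decade, emulating records
#' whose exact onset year is unknown.
#'
#' @param n_initial_foci number of initial foci (default 5).
#' @param start_year,census_year,response_year invasion start, field-census
#'   and response-snapshot years (defaults 1980, 2007, 2012).
#' @param events_per_site_per_year propagule events per extant site per year
#'   (default 3).
#' @param kernel_mean_km mean of the exponential short-distance kernel in km
#'   (default 2).
#' @param p_long_distance probability a propagule takes the long-distance
#'   path (default 0.01).
#' @param long_distance_max_km maximum of the uniform long-distance kernel
#'   (default 100).
#' @param persistence_prob yearly site survival probability (default 1).
#' @param decennial_noise_before onsets earlier than this year are coarsened
#'   decennially; `NA` disables (default 1997).
#' @param seed integer RNG seed.
#' @return a classed list of settings.
#' @export
invasionConfig <- function(n_initial_foci = 5, start_year = 1980,
                           census_year = 2007, response_year = 2012,
                           events_per_site_per_year = 3,
                           kernel_mean_km = 2.0, p_long_distance = 0.01,
                           long_distance_max_km = 100,
                           persistence_prob = 1.0,
                           decennial_noise_before = 1997, seed = 3) {
  stopifnot(start_year < census_year, census_year < response_year,
            p_long_distance >= 0, p_long_distance <= 1,
            persistence_prob >= 0, persistence_prob <= 1,
            kernel_mean_km > 0, long_distance_max_km > 0,
            n_initial_foci >= 1, events_per_site_per_year >= 1)
  structure(list(
    n_initial_foci = as.integer(n_initial_foci),
    start_year = as.integer(start_year),
    census_year = as.integer(census_year),
    response_year = as.integer(response_year),
    events_per_site_per_year = as.integer(events_per_site_per_year),
    kernel_mean_km = kernel_mean_km, p_long_distance = p_long_distance,
    long_distance_max_km = long_distance_max_km,
    persistence_prob = persistence_prob,
    decennial_noise_before = decennial_noise_before,
    seed = as.integer(seed)
  ), class = "invasionConfig")
}

# Row-normalized Gaussian band matrix; row-normalization keeps the smoother
# mass-preserving at the grid boundary.
gaussBand <- function(n, sigma) {
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K / rowSums(K)
}

#' Generate a synthetic environmental landscape
#'
#' Each layer is white noise smoothed with a separable Gaussian kernel
#' (sd = `autocorrelation_scale / 2` cells) and z-scored, giving standardized
#' spatially autocorrelated fields whose empirical variogram rises out to
#' roughly the configured scale. True suitability is
#' `logistic(intercept + sum(weights * layers))`.
#'
#' @param config a [landscapeConfig()].
#' @return list with `env` (a [RasterStack-class] of layers `env_01`, ...)
#'   and `suitability` (a [RasterLayer-class] with values in (0, 1)).
#'   Deterministic given `config$seed`.
#' @export
generateLandscape <- function(config) {
  stopifnot(inherits(config, "landscapeConfig"))
  g <- config$grid
  withSeed(config$seed, {
    sigma <- config$autocorrelation_scale / 2
    Br <- gaussBand(g@nrows, sigma)
    Bc <- gaussBand(g@ncols, sigma)
    layers <- vector("list", config$n_env_layers)
    lin <- matrix(config$suitability_intercept, g@nrows, g@ncols)
    for (i in seq_len(config$n_env_layers)) {
      z <- matrix(stats::rnorm(g@nrows * g@ncols), g@nrows, g@ncols)
      s <- Br %*% z %*% t(Bc)
      s <- (s - mean(s)) / stats::sd(s)
      nm <- sprintf("env_%02d", i)
      layers[[i]] <- rasterLayer(g, s, name = nm)
      lin <- lin + config$suitability_weights[i] * s
    }
    names(layers) <- vapply(layers, layerName, character(1))
    list(env = rasterStack(layers),
         suitability = rasterLayer(g, stats::plogis(lin),
                                   name = "suitability"))
  })
}

#' Simulate a dispersal-limited invasion
#'
#' Seeds foci in high-suitability cells at `start_year`, then each year every
#' extant site emits propagules (exponential short-distance kernel, rare
#' uniform long-distance jumps, uniform bearing); a propagule landing in an
#' unoccupied in-grid cell establishes a new site with probability equal to
#' that cell's suitability, and the year of first occupation is recorded as
#' the site's onset. Events landing outside the grid are lost (absorbing
#' boundary).
#'
#' @param landscape output of [generateLandscape()].
#' @param config an [invasionConfig()].
#' @param end_year last simulated year; default `config$response_year`.
#'   Simulating past the response year provides ground truth for forecast
#'   checks.
#' @return list with `census` (occurrence records verified at the census
#'   year, onsets decennially coarsened where configured), `response`
#'   (presence points at the response year), `occupancy` (year ->
#'   occupied cell indices) and `onsets` (true onset year per currently
#'   occupied cell). Deterministic given `config$seed`.
#' @export
simulateInvasion <- function(landscape, config, end_year = NULL) {
  stopifnot(inherits(config, "invasionConfig"))
  if (is.null(end_year)) end_year <- config$response_year
  stopifnot(end_year >= config$response_year)
  grid <- landscape$suitability@grid
  suit <- as.vector(landscape$suitability@values)
  ctr <- cellCenters(grid)
  withSeed(config$seed, {
    pool <- which(suit > stats::quantile(suit, 0.8))
    if (length(pool) == 0L) {
      stop("no cells with suitability above the 0.8 quantile; ",
           "cannot place invasion foci")
    }
    # introductions succeed where habitat is good: sample foci from the
    # high-suitability pool proportionally to suitability
    cells <- sample(pool, min(config$n_initial_foci, length(pool)),
                    prob = suit[pool])
    onset <- rep(config$start_year, length(cells))
    occupancy <- list()
    occupancy[[as.character(config$start_year)]] <- sort(cells)
    census <- NULL
    for (year in seq(config$start_year + 1L, end_year)) {
      n_sites <- length(cells)
      if (n_sites > 0L) {
        nev <- n_sites * config$events_per_site_per_year
        src <- cells[sample.int(n_sites, nev, replace = TRUE)]
        long <- stats::runif(nev) < config$p_long_distance
        dist_m <- ifelse(long,
                         stats::runif(nev, 0, config$long_distance_max_km * 1000),
                         stats::rexp(nev, 1 / (config$kernel_mean_km * 1000)))
        brg <- stats::runif(nev, 0, 360)
        dest <- geosphere::destPoint(cbind(ctr$lon[src], ctr$lat[src]),
                                     brg, dist_m, r = EARTH_RADIUS_M)
        inside <- dest[, 1] >= grid@xmin & dest[, 1] < grid@xmax &
          dest[, 2] > grid@ymin & dest[, 2] <= grid@ymax
        if (any(inside)) {
          rc <- cellOf(dest[inside, 1], dest[inside, 2], grid)
          cand <- cellIndex(rc$row, rc$col, grid)
          cand <- cand[!(cand %in% cells)]
          est <- cand[stats::runif(length(cand)) < suit[cand]]
          new_cells <- unique(est)
          if (length(new_cells)) {
            cells <- c(cells, new_cells)
            onset <- c(onset, rep(year, length(new_cells)))
          }
        }
      }
      if (config$persistence_prob < 1 && length(cells)) {
        live <- stats::runif(length(cells)) < config$persistence_prob
        cells <- cells[live]
        onset <- onset[live]
      }
      occupancy[[as.character(year)]] <- sort(cells)
      if (year == config$census_year) {
        census <- data.frame(cell = cells, onset = onset)
      }
    }
    if (is.null(census)) stop("census year precedes the first simulated year")
    cen_onset <- census$onset
    if (is.finite(config$decennial_noise_before)) {
      old <- cen_onset < config$decennial_noise_before
      cen_onset[old] <- decennialOnset(10L * (cen_onset[old] %/% 10L))
    }
    census_rec <- occurrenceRecords(
      lon = ctr$lon[census$cell], lat = ctr$lat[census$cell],
      onset_year = pmin(cen_onset, config$census_year),
      census_year = config$census_year)
    census_rec$cell <- census$cell
    resp_cells <- occupancy[[as.character(config$response_year)]]
    response <- data.frame(lon = ctr$lon[resp_cells],
                           lat = ctr$lat[resp_cells], cell = resp_cells)
    list(census = census_rec, response = response,
         occupancy = occupancy,
         onsets = stats::setNames(onset, cells))
  })
}

#' Generate a complete synthetic study
#'
#' One call that yields everything the downstream modules need: the
#' environmental stack, true suitability, an all-inclusive study mask, the
#' dated census records, the response-year presences and the yearly
#' occupancy history.
#'
#' @param landscape_config a [landscapeConfig()].
#' @param invasion_config an [invasionConfig()].
#' @param extra_years years to keep simulating past the response year so
#'   forecasts can be checked against ground truth (default 5).
#' @return a [StudyBundle-class].
#' @export
makeStudy <- function(landscape_config = landscapeConfig(),
                      invasion_config = invasionConfig(),
                      extra_years = 5) {
  land <- generateLandscape(landscape_config)
  sim <- simulateInvasion(land, invasion_config,
                          end_year = invasion_config$response_year + extra_years)
  grid <- land$suitability@grid
  new("StudyBundle",
      env = land$env, suitability = land$suitability,
      mask = rasterLayer(grid, 1, name = "mask"),
      census = sim$census, response = sim$response,
      occupancy = sim$occupancy,
      landscapeConfig = unclass(landscape_config),
      invasionConfig = unclass(invasion_config))
}

#' Write / read a study bundle as a directory of text files
#'
#' Layout: `env_XX.asc`, `suitability.asc`, `mask.asc` (ESRI ASCII grids),
#' `census.csv`, `response.csv`, `occupancy.csv` (year, cell) and
#' `config.yaml` holding both generating configurations.
#'
#' @param bundle a [StudyBundle-class].
#' @param dir directory path (created if missing).
#' @return `writeStudyBundle()` returns `dir` invisibly;
#'   `readStudyBundle()` returns the reconstructed [StudyBundle-class].
#' @export
writeStudyBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "StudyBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in layerNames(bundle@env)) {
    writeAsciiGrid(getLayer(bundle@env, nm),
                   file.path(dir, paste0(nm, ".asc")), digits = 15)
  }
  writeAsciiGrid(bundle@suitability, file.path(dir, "suitability.asc"),
                 digits = 15)
  writeAsciiGrid(bundle@mask, file.path(dir, "mask.asc"), digits = 15)
  writePointsCSV(bundle@census, file.path(dir, "census.csv"))
  writePointsCSV(bundle@response, file.path(dir, "response.csv"))
  occ <- do.call(rbind, lapply(names(bundle@occupancy), function(y) {
    cells <- bundle@occupancy[[y]]
    if (length(cells) == 0L) return(NULL)
    data.frame(year = as.integer(y), cell = cells)
  }))
  utils::write.csv(occ, file.path(dir, "occupancy.csv"), row.names = FALSE)
  cfg <- list(landscape = bundle@landscapeConfig,
              invasion = bundle@invasionConfig)
  cfg$landscape$grid <- list(
    xmin = bundle@env@grid@xmin, ymin = bundle@env@grid@ymin,
    xmax = bundle@env@grid@xmax, ymax = bundle@env@grid@ymax,
    resolution = bundle@env@grid@resolution)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"),
                   precision = 15)
  invisible(dir)
}

#' @rdname writeStudyBundle
#' @export
readStudyBundle <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  g <- cfg$landscape$grid
  grid <- gridSpec(g$xmin, g$ymin, g$xmax, g$ymax, resolution = g$resolution)
  env_files <- sort(list.files(dir, pattern = "^env_\\d+\\.asc$"))
  layers <- lapply(env_files, function(f) readAsciiGrid(file.path(dir, f)))
  occ_df <- utils::read.csv(file.path(dir, "occupancy.csv"))
  occupancy <- lapply(split(occ_df$cell, occ_df$year), as.integer)
  lc <- cfg$landscape
  lc$grid <- grid
  lc <- do.call(landscapeConfig, lc)
  ic <- do.call(invasionConfig, cfg$invasion)
  new("StudyBundle",
      env = rasterStack(layers),
      suitability = readAsciiGrid(file.path(dir, "suitability.asc")),
      mask = readAsciiGrid(file.path(dir, "mask.asc")),
      census = readPointsCSV(file.path(dir, "census.csv")),
      response = readPointsCSV(file.path(dir, "response.csv")),
      occupancy = occupancy,
      landscapeConfig = unclass(lc), invasionConfig = unclass(ic))
}
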