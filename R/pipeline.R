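# End-to-end workflow: build the predictor stack for a variant, run the
# factorial model experiment, meta-model the melted results, and write all
# artifacts with a manifest. These functions back the command-line script in
# inst/scripts/hpvsdm.R.

#' Build the predictor stack for one HPV variant
#'
#' Environmental layers plus the variant's HPV layers, built from the dated
#' census records at the study's response year. The control variant returns
#' the environmental stack unchanged.
#'
#' @param study a [StudyBundle-class].
#' @param variant_label variant label (see [enumerateVariants()]).
#' @param registry variant registry.
#' @return a [RasterStack-class].
#' @export
buildVariantStack <- function(study, variant_label,
                              registry = enumerateVariants()) {
  info <- variantInfo(variant_label, registry)
  layers <- envStack(study)@layers
  if (info$capacity_code != "control") {
    hpv <- buildHpvLayers(censusRecords(study), gridOf(study),
                          response_year = study@invasionConfig$response_year,
                          periods = info$periods[[1L]],
                          capacities = parseVariantLabel(variant_label)$capacities)
    layers <- c(layers, hpv)
  }
  new("RasterStack", grid = gridOf(study), layers = layers)
}

#' Run the factorial variant experiment on one study
#'
#' Samples one pseudoabsence set, then for every requested variant builds
#' the predictor stack, assembles the model matrix, cross-validates the
#' single-model algorithms and builds the TSS-gated ensembles. Variants
#' where no single model passes the gate contribute single-model rows only.
#'
#' @param study a [StudyBundle-class].
#' @param variants character vector of variant labels (default: all 25).
#' @param algorithms algorithms to fit (default all seven).
#' @param n_pa pseudoabsences per set (default 1000).
#' @param pa_sets number of independent pseudoabsence sets (default 1).
#' @param n_repetitions split repetitions (default 3).
#' @param eval_fraction held-out fraction (default 0.2).
#' @param gate ensemble TSS gate (default 0.7).
#' @param seed master seed (pseudoabsence and split/fit seeds derive from it).
#' @param registry variant registry.
#' @return list with `results` (all single + ensemble rows, with `pa_set`
#'   ids), `cvs` (named list of `sdmCV` objects per variant, for the first
#'   pseudoabsence set) and `pseudoabsences` (list of point sets).
#' @export
runVariantExperiment <- function(study, variants = enumerateVariants()$label,
                                 algorithms = SDM_ALGORITHMS, n_pa = 1000,
                                 pa_sets = 1, n_repetitions = 3,
                                 eval_fraction = 0.2, gate = 0.7, seed = 1,
                                 registry = enumerateVariants()) {
  pas <- lapply(seq_len(pa_sets), function(k) {
    samplePseudoabsences(studyMask(study), n = n_pa,
                         presences = responsePresences(study),
                         seed = deriveSeed(seed, paste0("pa", k)))
  })
  results <- list()
  cvs <- list()
  for (v in variants) {
    stack <- buildVariantStack(study, v, registry)
    for (k in seq_len(pa_sets)) {
      mm <- assembleModelMatrix(responsePresences(study), pas[[k]], stack)
      cv <- crossValidate(mm, algorithms = algorithms,
                          n_repetitions = n_repetitions,
                          eval_fraction = eval_fraction,
                          seed = deriveSeed(seed, paste0("fit.", v, ".", k)),
                          variant_label = v, pa_set = k)
      if (k == 1L) cvs[[v]] <- cv
      results[[length(results) + 1L]] <- cv$results
      ens <- tryCatch(buildEnsemble(cv, gate = gate),
                      error = function(e) NULL)
      if (!is.null(ens)) {
        ens$n_members <- NULL
        results[[length(results) + 1L]] <- ens
      }
    }
  }
  list(results = do.call(rbind, results), cvs = cvs, pseudoabsences = pas)
}

#' Pipeline run configuration
#'
#' One master seed spawns named per-stage seeds so every stage is
#' independently reproducible; all settings are recorded in the output
#' manifest.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param landscape a [landscapeConfig()].
#' @param invasion an [invasionConfig()].
#' @param variants variant labels to fit.
#' @param algorithms algorithms to fit.
#' @param n_pa pseudoabsences per set.
#' @param pa_sets number of independent pseudoabsence sets.
#' @param n_repetitions split repetitions.
#' @param eval_fraction held-out fraction.
#' @param gate ensemble TSS gate.
#' @param projection_variant variant whose ensemble is projected in the
#'   scenario maps.
#' @param meta_p,meta_iter meta-model significance level and iterations.
#' @return a classed list.
#' @export
runConfig <- function(out_dir, seed = 1,
                      landscape = landscapeConfig(seed = deriveSeed(seed, "landscape")),
                      invasion = invasionConfig(seed = deriveSeed(seed, "invasion")),
                      variants = c("No HPV", "5.D", "10.D", "25.D",
                                   "5.P", "10.P", "25.P"),
                      algorithms = c("RF", "GBM", "SRE"),
                      n_pa = 1000, pa_sets = 1, n_repetitions = 3,
                      eval_fraction = 0.2,
                      gate = 0.7, projection_variant = "5.D",
                      meta_p = 0.01, meta_iter = 100) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 landscape = landscape, invasion = invasion,
                 variants = variants, algorithms = algorithms,
                 n_pa = n_pa, pa_sets = pa_sets,
                 n_repetitions = n_repetitions,
                 eval_fraction = eval_fraction, gate = gate,
                 projection_variant = projection_variant,
                 meta_p = meta_p, meta_iter = meta_iter),
            class = "runConfig")
}

#' Run the full pipeline and write artifacts
#'
#' Simulate a study, build HPV variants, fit and ensemble the models, melt
#' the results, run the shadow-feature meta-model, project the scenario
#' maps for one variant, and write everything under `config$out_dir`:
#' `study/` (the bundle), `variants.csv`, `results.csv`, `melted.csv`,
#' `importance.csv`, `maps/*.asc` and `manifest.json`.
#'
#' @param config a [runConfig()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory objects (`study`,
#'   `experiment`, `melted`, `importance`, `maps`).
#' @export
runStudyPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("simulating study ...")
  study <- makeStudy(config$landscape, config$invasion)
  writeStudyBundle(study, file.path(config$out_dir, "study"))

  registry <- enumerateVariants()
  reg_out <- registry
  reg_out$periods <- vapply(registry$periods, paste, character(1),
                            collapse = ".")
  utils::write.csv(reg_out, file.path(config$out_dir, "variants.csv"),
                   row.names = FALSE)

  say("fitting ", length(config$variants), " variants x ",
      length(config$algorithms), " algorithms ...")
  exp <- runVariantExperiment(study, variants = config$variants,
                              algorithms = config$algorithms,
                              n_pa = config$n_pa, pa_sets = config$pa_sets,
                              n_repetitions = config$n_repetitions,
                              eval_fraction = config$eval_fraction,
                              gate = config$gate, seed = config$seed,
                              registry = registry)
  utils::write.csv(exp$results, file.path(config$out_dir, "results.csv"),
                   row.names = FALSE)

  say("meta-modelling ...")
  melted <- meltResults(exp$results, registry)
  utils::write.csv(melted, file.path(config$out_dir, "melted.csv"),
                   row.names = FALSE)
  importance <- tryCatch(
    borutaImportance(melted, p = config$meta_p, max_iter = config$meta_iter,
                     seed = deriveSeed(config$seed, "meta")),
    error = function(e) NULL)
  if (!is.null(importance)) {
    utils::write.csv(attributeRanking(importance),
                     file.path(config$out_dir, "importance.csv"),
                     row.names = FALSE)
  }

  say("projecting scenarios for variant ", config$projection_variant, " ...")
  maps <- list()
  pv <- config$projection_variant
  cv <- exp$cvs[[pv]]
  scorer <- tryCatch(ensembleScorer(cv, gate = config$gate),
                     error = function(e) NULL)
  if (!is.null(scorer)) {
    map_dir <- file.path(config$out_dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    stack <- buildVariantStack(study, pv, registry)
    maps$current <- projectMap(scorer, stack, name = "current")
    fstack <- forecastStack(stack, responsePresences(study))
    maps$forecast <- projectMap(scorer, fstack, name = "forecast")
    pstack <- potentialStack(stack)
    maps$potential <- projectMap(scorer, pstack, name = "potential")
    maps$emergence <- emergenceMap(maps$forecast, maps$current)
    maps$unsaturation <- unsaturationMap(maps$potential, maps$current)
    for (nm in names(maps)) {
      writeAsciiGrid(maps[[nm]], file.path(map_dir, paste0(nm, ".asc")))
    }
  } else {
    say("no single model passed the gate for ", pv, "; skipping maps")
  }

  manifest <- list(
    seed = config$seed,
    derived_seeds = list(pa = deriveSeed(config$seed, "pa1"),
                         meta = deriveSeed(config$seed, "meta")),
    variants = config$variants, algorithms = config$algorithms,
    n_pa = config$n_pa, pa_sets = config$pa_sets,
    n_repetitions = config$n_repetitions,
    eval_fraction = config$eval_fraction, gate = config$gate,
    n_census_records = nrow(censusRecords(study)),
    n_response_presences = nrow(responsePresences(study)),
    n_result_rows = nrow(exp$results),
    grid = list(nrows = gridOf(study)@nrows, ncols = gridOf(study)@ncols,
                resolution = gridOf(study)@resolution))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(study = study, experiment = exp, melted = melted,
                 importance = importance, maps = maps))
}
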