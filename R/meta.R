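# Meta-modelling of what drives model quality: melt all model evaluations
# into a long table annotated with HPV set attributes, then run a
# shadow-feature random-forest importance analysis that classifies each
# attribute as Confirmed / Tentative / Rejected.

#' Melt model results into the meta-model table
#'
#' One row per model evaluation, annotated with the four design attributes —
#' the algorithm used, the information-capacity combination (`P`, `C`, `D`,
#' `CD` or `control`), the minimal recentness of the time periods included
#' (5, 10, 25 or `control`) and the number of time periods (1, 2, 3 or
#' `control`) — plus the single/ensemble group. TSS is z-scored within each
#' group (`tss_std`), so single and ensemble models are comparable on one
#' scale.
#'
#' @param results data.frame of model results ([crossValidate()] /
#'   [buildEnsemble()] rows, row-bound).
#' @param registry variant registry from [enumerateVariants()].
#' @return data.frame with columns `tss`, `tss_std`, `algorithm`,
#'   `capacity_code`, `minimal_recentness`, `n_periods`, `group` (factors
#'   where categorical). Unconverged rows are dropped.
#' @export
meltResults <- function(results, registry = enumerateVariants()) {
  unknown <- setdiff(unique(results$variant), registry$label)
  if (length(unknown)) {
    stop("variant(s) not in the registry: ", paste(unknown, collapse = ", "))
  }
  res <- results[is.finite(results$tss), , drop = FALSE]
  i <- match(res$variant, registry$label)
  out <- data.frame(
    tss = res$tss,
    algorithm = factor(res$algorithm),
    capacity_code = factor(registry$capacity_code[i],
                           levels = c("P", "C", "D", "CD", "control")),
    minimal_recentness = factor(registry$minimal_recentness[i],
                                levels = c("5", "10", "25", "control")),
    n_periods = factor(registry$n_periods[i],
                       levels = c("1", "2", "3", "control")),
    group = factor(res$group, levels = c("single", "ensemble")),
    variant = res$variant,
    stringsAsFactors = FALSE)
  out$tss_std <- stats::ave(out$tss, out$group, FUN = function(v) {
    if (length(v) < 2L || stats::sd(v) == 0) return(v * 0)
    (v - mean(v)) / stats::sd(v)
  })
  droplevels(out)
}

#' Shadow-feature (Boruta-style) attribute importance
#'
#' Each iteration appends a permuted "shadow" copy of every candidate
#' attribute, fits a random-forest regressor of the response on attributes
#' plus shadows, and records each attribute's importance Z-score (mean
#' permutation importance over trees divided by its standard deviation). An
#' iteration scores a "hit" for an attribute when its Z exceeds the maximum
#' shadow Z. After all iterations the hit count is tested against
#' Binomial(iterations, 1/2): significantly high at `p` means Confirmed,
#' significantly low means Rejected, otherwise Tentative.
#'
#' @param table melted results from [meltResults()], or any data.frame.
#' @param attributes candidate attribute columns; default the five design
#'   attributes present in `table`.
#' @param response response column name (default `"tss_std"`).
#' @param p significance level of the binomial test (default 0.01).
#' @param max_iter number of shadow iterations (default 100).
#' @param ntree trees per forest (default 200).
#' @param seed integer seed; the whole report is deterministic given it.
#' @return an `importanceReport`: data.frame with one row per attribute
#'   (`attribute`, `mean_z`, `hits`, `iterations`, `status`), plus
#'   attributes `p` and `seed`.
#' @export
borutaImportance <- function(table,
                             attributes = intersect(
                               c("algorithm", "capacity_code",
                                 "minimal_recentness", "n_periods", "group"),
                               names(table)),
                             response = "tss_std", p = 0.01,
                             max_iter = 100, ntree = 200, seed = 1) {
  stopifnot(length(attributes) >= 2, nrow(table) >= 50)
  y <- table[[response]]
  if (!is.numeric(y) || stats::sd(y) == 0) {
    stop("response '", response, "' is degenerate (zero variance)")
  }
  x <- table[, attributes, drop = FALSE]
  x[] <- lapply(x, function(col) if (is.character(col)) factor(col) else col)
  n <- nrow(x)
  zsum <- stats::setNames(numeric(length(attributes)), attributes)
  hits <- stats::setNames(integer(length(attributes)), attributes)
  withSeed(seed, {
    for (it in seq_len(max_iter)) {
      shadows <- lapply(x, function(col) col[sample.int(n)])
      names(shadows) <- paste0("shadow_", attributes)
      df <- data.frame(x, shadows, check.names = FALSE)
      rf <- randomForest::randomForest(x = df, y = y, ntree = ntree,
                                       importance = TRUE)
      z <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
      az <- z[attributes]
      sz <- z[paste0("shadow_", attributes)]
      zsum <- zsum + az
      hits <- hits + as.integer(az > max(sz))
    }
  })
  status <- vapply(hits, function(h) {
    p_hi <- stats::pbinom(h - 1L, max_iter, 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(h, max_iter, 0.5)
    if (p_hi < p) "Confirmed" else if (p_lo < p) "Rejected" else "Tentative"
  }, character(1))
  report <- data.frame(attribute = attributes,
                       mean_z = zsum / max_iter,
                       hits = hits, iterations = max_iter,
                       status = status, stringsAsFactors = FALSE,
                       row.names = NULL)
  attr(report, "p") <- p
  attr(report, "seed") <- seed
  class(report) <- c("importanceReport", "data.frame")
  report
}

#' Rank attributes by mean importance Z-score
#'
#' The meta-model summary table: attributes sorted by mean Z-score,
#' descending, with their significance status; ties break alphabetically by
#' attribute name.
#'
#' @param report an `importanceReport` from [borutaImportance()].
#' @return the report rows in rank order with a `rank` column.
#' @export
attributeRanking <- function(report) {
  stopifnot(inherits(report, "importanceReport") || is.data.frame(report))
  ord <- order(-report$mean_z, report$attribute)
  out <- report[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
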