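# Single-model fitting (7 algorithms behind one scorer contract), TSS/ROC
# evaluation at optimized thresholds, stratified cross-validation and
# TSS-gated ensemble construction with six combination statistics.

#' The seven single-model algorithms
#' @export
SDM_ALGORITHMS <- c("ANN", "CTA", "FDA", "GBM", "MARS", "RF", "SRE")

#' Ensemble combination methods
#' @export
ENSEMBLE_METHODS <- c("EMmean", "EMwmean", "EMmedian", "EMca",
                      "EMciInf", "EMciSup")

#' Describe one algorithm run
#'
#' @param name one of `SDM_ALGORITHMS`.
#' @param params named list of hyperparameter overrides.
#' @param seed integer seed for stochastic learners.
#' @return a classed list.
#' @export
algorithmSpec <- function(name, params = list(), seed = 1) {
  name <- match.arg(name, SDM_ALGORITHMS)
  if (name == "SRE") {
    alpha <- params$alpha %||% 0.025
    if (alpha < 0 || alpha >= 0.5) stop("SRE alpha must be in [0, 0.5)")
  }
  structure(list(name = name, params = params, seed = as.integer(seed)),
            class = "algorithmSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Surface range envelope
#'
#' The classic presence-only envelope classifier: for each predictor the
#' envelope is the `[alpha, 1 - alpha]` quantile interval of the presence
#' values; a case is predicted present (score 1) iff it lies inside every
#' envelope, else absent (score 0).
#'
#' @param presence_rows data.frame of predictor values at presence cases.
#' @param alpha tail quantile trimmed from each end (default 0.025).
#' @return a classed envelope model with a `predict` contract via
#'   [predictScores()].
#' @export
fitSRE <- function(presence_rows, alpha = 0.025) {
  stopifnot(nrow(presence_rows) >= 2, alpha >= 0, alpha < 0.5)
  env <- lapply(presence_rows, function(x) {
    stats::quantile(x, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  })
  structure(list(envelope = env, alpha = alpha,
                 predictors = names(presence_rows)),
            class = "sreModel")
}

predictSRE <- function(model, newdata) {
  inside <- rep(TRUE, nrow(newdata))
  for (nm in model$predictors) {
    e <- model$envelope[[nm]]
    inside <- inside & newdata[[nm]] >= e[1L] & newdata[[nm]] <= e[2L]
  }
  as.numeric(inside)
}

# Hinge-basis expansion shared by the MARS and FDA stand-ins: per predictor a
# linear term plus paired hinges max(0, x - k) / max(0, k - x) at interior
# quantile knots of the training data.
hingeBasisDef <- function(train, predictors, probs = c(0.25, 0.5, 0.75)) {
  knots <- lapply(predictors, function(nm) {
    unique(stats::quantile(train[[nm]], probs, names = FALSE, na.rm = TRUE))
  })
  names(knots) <- predictors
  list(predictors = predictors, knots = knots)
}

hingeBasisExpand <- function(def, data) {
  cols <- list()
  for (nm in def$predictors) {
    x <- data[[nm]]
    cols[[paste0(nm, "::lin")]] <- x
    for (k in def$knots[[nm]]) {
      cols[[sprintf("%s::h+%.6g", nm, k)]] <- pmax(x - k, 0)
      cols[[sprintf("%s::h-%.6g", nm, k)]] <- pmax(k - x, 0)
    }
  }
  do.call(cbind, cols)
}

#' Fit one algorithm and return a probability scorer
#'
#' All seven algorithms are fitted behind one contract: the result scores any
#' new case in `[0, 1]` via [predictScores()]. RF, GBM, CTA and ANN are
#' standard classifiers (randomForest, xgboost, rpart, nnet); MARS is an
#' adaptive hinge-basis expansion with a cross-validated lasso-logistic fit;
#' FDA is a linear discriminant on the same hinge basis; SRE is the surface
#' range envelope (binary score). Fits are deterministic given `seed`.
#'
#' @param algorithm one of `SDM_ALGORITHMS`, or an [algorithmSpec()].
#' @param mm model matrix from [assembleModelMatrix()] (both classes present).
#' @param seed integer seed.
#' @param params named list of hyperparameter overrides (`ntree`, `nrounds`,
#'   `max_depth`, `eta`, `size`, `decay`, `maxit`, `alpha`, ...).
#' @return an object of class `sdmScorer` with fields `algorithm`,
#'   `predictors`, `converged`.
#' @export
fitAlgorithm <- function(algorithm, mm, seed = 1, params = list()) {
  if (inherits(algorithm, "algorithmSpec")) {
    params <- utils::modifyList(algorithm$params, params)
    seed <- algorithm$seed
    algorithm <- algorithm$name
  }
  algorithm <- match.arg(algorithm, SDM_ALGORITHMS)
  preds <- predictorNames(mm)
  y <- mm$response
  if (length(unique(y)) < 2L) {
    stop("model matrix contains a single response class; cannot fit")
  }
  x <- mm[, preds, drop = FALSE]
  fit <- NULL
  predict_fun <- NULL
  converged <- TRUE
  err <- tryCatch({
    withSeed(seed, {
      if (algorithm == "RF") {
        fit <- randomForest::randomForest(
          x = x, y = factor(y, levels = c(0, 1)),
          ntree = params$ntree %||% 200)
        predict_fun <- function(fit, nd) {
          unname(stats::predict(fit, nd, type = "prob")[, "1"])
        }
      } else if (algorithm == "GBM") {
        dm <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
        fit <- xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        max_depth = params$max_depth %||% 3,
                        eta = params$eta %||% 0.1,
                        nthread = 1),
          data = dm, nrounds = params$nrounds %||% 100, verbose = 0)
        predict_fun <- function(fit, nd) {
          stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(nd)))
        }
      } else if (algorithm == "CTA") {
        df <- data.frame(x, .y = factor(y, levels = c(0, 1)),
                         check.names = FALSE)
        fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                            control = rpart::rpart.control(
                              cp = params$cp %||% 0.01,
                              minsplit = params$minsplit %||% 20))
        predict_fun <- function(fit, nd) {
          unname(stats::predict(fit, nd, type = "prob")[, "1"])
        }
      } else if (algorithm == "ANN") {
        ctr <- vapply(x, mean, numeric(1))
        scl <- vapply(x, stats::sd, numeric(1))
        scl[scl == 0 | !is.finite(scl)] <- 1
        xs <- scale(as.matrix(x), center = ctr, scale = scl)
        net <- nnet::nnet(xs, y, size = params$size %||% 5,
                          decay = params$decay %||% 0.01,
                          maxit = params$maxit %||% 200,
                          entropy = TRUE, trace = FALSE)
        fit <- list(net = net, center = ctr, scale = scl)
        predict_fun <- function(fit, nd) {
          nds <- scale(as.matrix(nd), center = fit$center, scale = fit$scale)
          as.numeric(stats::predict(fit$net, nds, type = "raw"))
        }
      } else if (algorithm == "MARS") {
        def <- hingeBasisDef(x, preds)
        basis <- hingeBasisExpand(def, x)
        keep <- apply(basis, 2, stats::sd) > 1e-10
        basis <- basis[, keep, drop = FALSE]
        foldid <- sample(rep_len(1:5, nrow(basis)))
        cvfit <- glmnet::cv.glmnet(basis, y, family = "binomial",
                                   foldid = foldid, nlambda = 50)
        fit <- list(def = def, keep = keep, cvfit = cvfit)
        predict_fun <- function(fit, nd) {
          b <- hingeBasisExpand(fit$def, nd)[, fit$keep, drop = FALSE]
          as.numeric(stats::predict(fit$cvfit, b, s = "lambda.min",
                                    type = "response"))
        }
      } else if (algorithm == "FDA") {
        def <- hingeBasisDef(x, preds)
        basis <- hingeBasisExpand(def, x)
        keep <- apply(basis, 2, stats::sd) > 1e-10
        basis <- basis[, keep, drop = FALSE]
        lfit <- suppressWarnings(
          MASS::lda(basis, grouping = factor(y, levels = c(0, 1))))
        fit <- list(def = def, keep = keep, lda = lfit)
        predict_fun <- function(fit, nd) {
          b <- hingeBasisExpand(fit$def, nd)[, fit$keep, drop = FALSE]
          unname(stats::predict(fit$lda, b)$posterior[, "1"])
        }
      } else { # SRE
        fit <- fitSRE(x[y == 1, , drop = FALSE],
                      alpha = params$alpha %||% 0.025)
        predict_fun <- function(fit, nd) predictSRE(fit, nd)
      }
    })
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(err)) {
    converged <- FALSE
    predict_fun <- function(fit, nd) rep(NA_real_, nrow(nd))
  }
  structure(list(algorithm = algorithm, predictors = preds, fit = fit,
                 predict_fun = predict_fun, converged = converged,
                 error = err),
            class = "sdmScorer")
}

#' Score new cases with a fitted model
#'
#' @param scorer an `sdmScorer` from [fitAlgorithm()] or [ensembleScorer()],
#'   or an envelope model from [fitSRE()].
#' @param newdata data.frame containing the scorer's predictor columns.
#' @return numeric scores in `[0, 1]` (clipped against minor numerical
#'   spill from individual learners).
#' @export
predictScores <- function(scorer, newdata) {
  if (inherits(scorer, "sreModel")) {
    missing <- setdiff(scorer$predictors, names(newdata))
    if (length(missing)) {
      stop("newdata lacks predictor(s): ", paste(missing, collapse = ", "))
    }
    return(predictSRE(scorer, newdata))
  }
  stopifnot(inherits(scorer, "sdmScorer"))
  missing <- setdiff(scorer$predictors, names(newdata))
  if (length(missing)) {
    stop("newdata lacks predictor(s): ", paste(missing, collapse = ", "))
  }
  s <- scorer$predict_fun(scorer$fit,
                          newdata[, scorer$predictors, drop = FALSE])
  pmin(pmax(s, 0), 1)
}

#' True skill statistic at the optimal threshold
#'
#' `TSS(t) = sensitivity(t) + specificity(t) - 1` with cases predicted
#' present when `score >= t`. The maximum is taken over the threshold grid
#' `0, 0.001, ..., 1`; ties resolve to the smallest threshold.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels binary labels (0/1); both classes must be present.
#' @param step threshold grid step (default 0.001).
#' @return list with `tss`, `threshold`, `sensitivity`, `specificity`.
#' @export
evaluateTSS <- function(scores, labels, step = 0.001) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class; TSS is undefined")
  }
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  ths <- seq(0, 1, by = step)
  sens <- vapply(ths, function(t) mean(sp >= t), numeric(1))
  spec <- vapply(ths, function(t) mean(sn < t), numeric(1))
  tss <- sens + spec - 1
  i <- which.max(tss)
  list(tss = tss[i], threshold = ths[i],
       sensitivity = sens[i], specificity = spec[i])
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with ties averaged.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
evaluateROC <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class; ROC is undefined")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Qualitative TSS category
#'
#' Bins a TSS value: below 0.4 "moderate or below", 0.4-0.6 "good", above
#' 0.6 and below 0.7 "very good", and at or above 0.7 "ensemble-eligible" —
#' the gate a single model must pass to enter an ensemble.
#'
#' @param tss numeric TSS values in `[-1, 1]`.
#' @return character vector of categories.
#' @export
classifyTssQuality <- function(tss) {
  if (any(tss < -1 | tss > 1, na.rm = TRUE)) {
    stop("TSS values must lie in [-1, 1]")
  }
  ifelse(tss < 0.4, "moderate or below",
         ifelse(tss <= 0.6, "good",
                ifelse(tss < 0.7, "very good", "ensemble-eligible")))
}

#' Cross-validate the single-model algorithms on one variant
#'
#' For each repetition a stratified random split holds out `eval_fraction`
#' of each class for evaluation; every algorithm is fitted on the
#' calibration part and evaluated with TSS and ROC on the held-out part.
#'
#' @param mm model matrix from [assembleModelMatrix()].
#' @param algorithms character vector of algorithms (default all seven).
#' @param n_repetitions number of split repetitions (default 3).
#' @param eval_fraction held-out fraction in `(0, 0.5]` (default 0.2).
#' @param seed master seed; per-repetition and per-algorithm seeds are
#'   derived from it.
#' @param variant_label label recorded in the results.
#' @param pa_set pseudoabsence-set id recorded in the results.
#' @return an object of class `sdmCV`: list with `results` (one row per
#'   algorithm x repetition: variant, algorithm, pa_set, repetition, group
#'   `"single"`, tss, roc, threshold, converged) and `reps` (per repetition:
#'   held-out indices, per-algorithm held-out scores, thresholds, scorers).
#' @export
crossValidate <- function(mm, algorithms = SDM_ALGORITHMS,
                          n_repetitions = 3, eval_fraction = 0.2,
                          seed = 1, variant_label = "variant", pa_set = 1L) {
  stopifnot(eval_fraction > 0, eval_fraction <= 0.5)
  algorithms <- match.arg(algorithms, SDM_ALGORITHMS, several.ok = TRUE)
  y <- mm$response
  rows <- list()
  reps <- list()
  for (r in seq_len(n_repetitions)) {
    test_idx <- withSeed(deriveSeed(seed, paste0("split", r)), {
      unlist(lapply(split(seq_along(y), y), function(ix) {
        sample(ix, max(1L, round(length(ix) * eval_fraction)))
      }), use.names = FALSE)
    })
    train <- mm[-test_idx, , drop = FALSE]
    attr(train, "predictors") <- predictorNames(mm)
    test <- mm[test_idx, , drop = FALSE]
    scores <- list()
    thresholds <- list()
    scorers <- list()
    for (alg in algorithms) {
      sc <- fitAlgorithm(alg, train,
                         seed = deriveSeed(seed, paste0(alg, ".", r)))
      scorers[[alg]] <- sc
      if (sc$converged) {
        s <- predictScores(sc, test)
        ev <- evaluateTSS(s, test$response)
        roc <- evaluateROC(s, test$response)
        scores[[alg]] <- s
        thresholds[[alg]] <- ev$threshold
        rows[[length(rows) + 1L]] <- data.frame(
          variant = variant_label, algorithm = alg, pa_set = pa_set,
          repetition = r, group = "single", ensemble_method = NA_character_,
          tss = ev$tss, roc = roc, threshold = ev$threshold,
          converged = TRUE, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          variant = variant_label, algorithm = alg, pa_set = pa_set,
          repetition = r, group = "single", ensemble_method = NA_character_,
          tss = NA_real_, roc = NA_real_, threshold = NA_real_,
          converged = FALSE, stringsAsFactors = FALSE)
      }
    }
    reps[[r]] <- list(test_idx = test_idx, scores = scores,
                      thresholds = thresholds, scorers = scorers,
                      labels = test$response)
  }
  structure(list(results = do.call(rbind, rows), reps = reps,
                 variant = variant_label, pa_set = pa_set, seed = seed),
            class = "sdmCV")
}

combineMembers <- function(score_mat, tss, thresholds, method) {
  m <- ncol(score_mat)
  switch(method,
    EMmean = rowMeans(score_mat),
    EMwmean = {
      w <- tss / sum(tss)
      as.numeric(score_mat %*% w)
    },
    EMmedian = apply(score_mat, 1, stats::median),
    EMca = {
      bin <- sweep(score_mat, 2, thresholds, ">=")
      rowMeans(bin)
    },
    EMciInf = {
      mu <- rowMeans(score_mat)
      se <- if (m > 1) apply(score_mat, 1, stats::sd) / sqrt(m) else 0
      pmin(pmax(mu - 1.96 * se, 0), 1)
    },
    EMciSup = {
      mu <- rowMeans(score_mat)
      se <- if (m > 1) apply(score_mat, 1, stats::sd) / sqrt(m) else 0
      pmin(pmax(mu + 1.96 * se, 0), 1)
    },
    stop("unknown ensemble method '", method, "'")
  )
}

#' Build TSS-gated ensembles from cross-validated single models
#'
#' Members are the single models whose held-out TSS reaches the gate
#' (default 0.7). Six combination statistics are computed per repetition on
#' the held-out scores: unweighted mean, TSS-proportional weighted mean,
#' pointwise median, committee averaging (mean of member predictions
#' binarized at each member's TSS-optimal threshold) and the lower/upper
#' normal-approximation confidence bounds of the member mean
#' (`mean -/+ 1.96 sd/sqrt(m)`, clipped to `[0, 1]`). Each ensemble is then
#' itself evaluated with TSS and ROC on the held-out cases.
#'
#' @param cv an `sdmCV` from [crossValidate()].
#' @param gate TSS gate for membership (default 0.7).
#' @param methods subset of `ENSEMBLE_METHODS`.
#' @return data.frame of ensemble `ModelResult` rows (group `"ensemble"`,
#'   `ensemble_method` filled, `algorithm` set to the method name). Errors
#'   if no repetition has any member passing the gate.
#' @export
buildEnsemble <- function(cv, gate = 0.7, methods = ENSEMBLE_METHODS) {
  stopifnot(inherits(cv, "sdmCV"))
  methods <- match.arg(methods, ENSEMBLE_METHODS, several.ok = TRUE)
  singles <- cv$results[cv$results$group == "single" & cv$results$converged, ]
  rows <- list()
  any_members <- FALSE
  for (r in seq_along(cv$reps)) {
    rep <- cv$reps[[r]]
    sr <- singles[singles$repetition == r & singles$tss >= gate, ]
    if (nrow(sr) == 0L) next
    any_members <- TRUE
    algs <- sr$algorithm
    score_mat <- do.call(cbind, rep$scores[algs])
    tss <- sr$tss[match(algs, sr$algorithm)]
    thr <- unlist(rep$thresholds[algs])
    for (method in methods) {
      s <- combineMembers(score_mat, tss, thr, method)
      ev <- evaluateTSS(s, rep$labels)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = cv$variant, algorithm = method, pa_set = cv$pa_set,
        repetition = r, group = "ensemble", ensemble_method = method,
        tss = ev$tss, roc = evaluateROC(s, rep$labels),
        threshold = ev$threshold, converged = TRUE,
        n_members = length(algs), stringsAsFactors = FALSE)
    }
  }
  if (!any_members) {
    stop("empty ensemble: no single model reached the TSS >= ", gate, " gate")
  }
  do.call(rbind, rows)
}

#' Combine gate-passing members into one projectable scorer
#'
#' Collects every converged single model whose held-out TSS reaches the gate
#' (across repetitions) and returns a scorer that applies the chosen
#' combination statistic to the members' predictions, usable anywhere an
#' `sdmScorer` is (notably [projectMap()]).
#'
#' @param cv an `sdmCV` from [crossValidate()].
#' @param gate TSS gate (default 0.7).
#' @param method one of `ENSEMBLE_METHODS` (default `"EMwmean"`).
#' @return an `sdmScorer`.
#' @export
ensembleScorer <- function(cv, gate = 0.7, method = "EMwmean") {
  stopifnot(inherits(cv, "sdmCV"))
  method <- match.arg(method, ENSEMBLE_METHODS)
  singles <- cv$results[cv$results$group == "single" & cv$results$converged &
                          cv$results$tss >= gate, ]
  if (nrow(singles) == 0L) {
    stop("empty ensemble: no single model reached the TSS >= ", gate, " gate")
  }
  members <- list()
  for (i in seq_len(nrow(singles))) {
    r <- singles$repetition[i]
    alg <- singles$algorithm[i]
    members[[length(members) + 1L]] <- list(
      scorer = cv$reps[[r]]$scorers[[alg]],
      tss = singles$tss[i],
      threshold = singles$threshold[i])
  }
  preds <- members[[1L]]$scorer$predictors
  fit <- list(members = members, method = method)
  predict_fun <- function(fit, nd) {
    score_mat <- vapply(fit$members,
                        function(m) predictScores(m$scorer, nd),
                        numeric(nrow(nd)))
    score_mat <- matrix(score_mat, nrow = nrow(nd))
    combineMembers(score_mat,
                   vapply(fit$members, `[[`, numeric(1), "tss"),
                   vapply(fit$members, `[[`, numeric(1), "threshold"),
                   fit$method)
  }
  structure(list(algorithm = method, predictors = preds, fit = fit,
                 predict_fun = predict_fun, converged = TRUE, error = NULL),
            class = "sdmScorer")
}
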