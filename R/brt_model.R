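#' Boosted-regression-trees configuration
#'
#' Settings of the stagewise Bernoulli-deviance boosting used for the
#' occurrence-state models.  Defaults follow the standard ecological BRT
#' guidelines: small shrinkage, moderately deep interaction trees, and
#' stochastic bagging.
#'
#' @param learning_rate shrinkage applied to each tree, in (0, 1\].
#' @param tree_complexity maximum interaction depth of each tree (>= 1).
#' @param bag_fraction fraction of rows resampled (without replacement) per
#'   tree, in (0, 1\].
#' @param n_folds number of cross-validation folds (>= 2), stratified by
#'   class.
#' @param step_size trees added per increment of the stepwise search.
#' @param max_trees cap on the number of trees explored.
#' @param patience increments past the holdout-deviance minimum before the
#'   search stops.
#' @param seed integer seed controlling folds and bagging.
#' @return A `brt_config` list.
#' @export
brt_config <- function(learning_rate = 0.001, tree_complexity = 5,
                       bag_fraction = 0.75, n_folds = 10, step_size = 50,
                       max_trees = 10000, patience = 5, seed = 1L) {
  if (learning_rate <= 0 || learning_rate > 1)
    stop_input("learning_rate must be in (0, 1]")
  if (tree_complexity < 1) stop_input("tree_complexity must be >= 1")
  if (bag_fraction <= 0 || bag_fraction > 1)
    stop_input("bag_fraction must be in (0, 1]")
  if (n_folds < 2) stop_input("n_folds must be >= 2")
  if (step_size < 1 || max_trees < step_size)
    stop_input("need step_size >= 1 and max_trees >= step_size")
  structure(list(learning_rate = learning_rate,
                 tree_complexity = as.integer(tree_complexity),
                 bag_fraction = bag_fraction, n_folds = as.integer(n_folds),
                 step_size = as.integer(step_size),
                 max_trees = as.integer(max_trees),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "brt_config")
}

# Rank-based area under the ROC curve (Mann-Whitney; ties count 0.5).
roc_auc_impl <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted 0.5.  Invariant to any
#' strictly monotone transform of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\]; `NA` if only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop_input("scores and labels must have equal length")
  roc_auc_impl(scores, as.numeric(labels))
}

#' Mean cross-validated AUC over folds
#'
#' The headline performance metric: the mean over folds of the rank-based
#' AUC of each fold's holdout predictions.  Folds containing a single class
#' are skipped with a warning.
#'
#' @param fold_predictions list of per-fold lists with elements `scores` and
#'   `labels` (each labelled row scored exactly once as holdout).
#' @return Mean holdout AUC.
#' @export
cross_validated_auc <- function(fold_predictions) {
  aucs <- vapply(fold_predictions, function(f)
    roc_auc_impl(f$scores, as.numeric(f$labels)), numeric(1))
  if (anyNA(aucs)) {
    warning(sprintf("%d fold(s) contained a single class and were skipped",
                    sum(is.na(aucs))))
    aucs <- aucs[!is.na(aucs)]
  }
  if (!length(aucs)) stop_input("no fold with both classes")
  mean(aucs)
}

# Per-predictor split-gain totals rescaled to percentages.  Parses the text
# model dump directly (xgb.importance mishandles single-feature models in
# some xgboost builds, and the dump is version-stable).
relative_influence_of <- function(model, feature_names) {
  dump <- xgboost::xgb.dump(model, with_stats = TRUE)
  splits <- grep("\\[.*\\].*gain=", dump, value = TRUE)  # split nodes only
  rel <- stats::setNames(numeric(length(feature_names)), feature_names)
  if (!length(splits)) {
    warning("model contains no splits; relative influence undefined (all 0)")
    return(rel)
  }
  feat <- sub("^.*\\[([^<]+)<.*$", "\\1", splits)
  gain <- as.numeric(sub("^.*gain=([-0-9.eE+]+),.*$", "\\1", splits))
  tot <- tapply(gain, feat, sum)
  rel[names(tot)] <- 100 * tot / sum(tot)
  rel
}

# Mean Bernoulli deviance of predicted probabilities.
bernoulli_deviance <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

# Stratified fold assignment: classes shuffled separately, folds recycled.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      rows <- which(y == cls)
      rows <- rows[sample.int(length(rows))]
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  fold
}

xgb_params <- function(config, seed) {
  list(objective = "binary:logistic", eta = config$learning_rate,
       max_depth = config$tree_complexity, subsample = config$bag_fraction,
       nthread = 1, seed = seed, min_child_weight = 1, lambda = 0,
       tree_method = "exact")
}

#' Fit a BRT with stepwise tree-count selection
#'
#' Stagewise Bernoulli-deviance boosting (backed by xgboost: shrinkage
#' `learning_rate`, trees of depth <= `tree_complexity`, per-tree bagging at
#' `bag_fraction`) with the tree count chosen by a stepwise search: trees are
#' added `step_size` at a time to `n_folds` class-stratified
#' cross-validation models, the mean holdout deviance is recorded at each
#' increment, and the search stops once the deviance minimum has not improved
#' for `patience` increments (or at `max_trees`).  The selected count is the
#' argmin of the recorded mean holdout deviance; a final model with that many
#' trees is then fitted on all rows.
#'
#' @param predictors data frame of numeric predictors for the labelled
#'   patches (a `patch_id` column, if present, is dropped).
#' @param response 0/1 occurrence-state vector.
#' @param config a [brt_config()].
#' @return A `brt_fit` object: `n_trees`, `auc_train`, `auc_cv`, `fold_auc`,
#'   `relative_influence` (percentages summing to 100), `deviance_trace`,
#'   `cv_predictions`, `folds`, the fitted xgboost `model`, the training
#'   matrix and config.
#' @export
fit_brt_step <- function(predictors, response, config = brt_config()) {
  stopifnot(inherits(config, "brt_config"))
  X <- predictors
  X$patch_id <- NULL
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(response)
  if (anyNA(y) || anyNA(X)) stop_input("predictors/response must not contain NA")
  if (length(unique(y)) < 2L)
    stop_input("response has a single class; cannot fit")
  if (nrow(X) < config$n_folds)
    stop_input("need at least n_folds labelled patches")
  fold <- stratified_folds(y, config$n_folds, config$seed)
  k <- config$n_folds
  dfold <- lapply(seq_len(k), function(f)
    xgboost::xgb.DMatrix(X[fold != f, , drop = FALSE], label = y[fold != f]))
  boosters <- vector("list", k)
  cv_pred <- numeric(length(y))
  best <- list(dev = Inf, chunk = 0L, pred = NULL)
  trace <- list()
  chunk <- 0L; since_best <- 0L
  repeat {
    chunk <- chunk + 1L
    for (f in seq_len(k)) {
      boosters[[f]] <- xgboost::xgb.train(
        params = xgb_params(config, derive_seed(config$seed, f)),
        data = dfold[[f]], nrounds = config$step_size, verbose = 0,
        xgb_model = boosters[[f]])
      ho <- fold == f
      cv_pred[ho] <- predict(boosters[[f]], X[ho, , drop = FALSE])
    }
    dev <- mean(vapply(seq_len(k), function(f)
      bernoulli_deviance(cv_pred[fold == f], y[fold == f]), numeric(1)))
    trace[[chunk]] <- data.frame(chunk = chunk,
                                 trees = chunk * config$step_size,
                                 mean_holdout_deviance = dev)
    if (dev < best$dev) {
      best <- list(dev = dev, chunk = chunk, pred = cv_pred)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    if (since_best >= config$patience ||
        chunk * config$step_size >= config$max_trees) break
  }
  n_trees <- best$chunk * config$step_size
  fold_auc <- vapply(seq_len(k), function(f)
    roc_auc_impl(best$pred[fold == f], y[fold == f]), numeric(1))
  bad <- is.na(fold_auc)
  if (any(bad))
    warning(sprintf("%d fold(s) contained a single class and were skipped",
                    sum(bad)))
  auc_cv <- mean(fold_auc[!bad])
  dall <- xgboost::xgb.DMatrix(X, label = y)
  final <- xgboost::xgb.train(params = xgb_params(config, config$seed),
                              data = dall, nrounds = n_trees, verbose = 0)
  auc_train <- roc_auc_impl(predict(final, X), y)
  rel <- relative_influence_of(final, colnames(X))
  structure(list(n_trees = n_trees, auc_train = auc_train, auc_cv = auc_cv,
                 fold_auc = fold_auc, relative_influence = rel,
                 deviance_trace = do.call(rbind, trace),
                 cv_predictions = best$pred, folds = fold, model = final,
                 X = X, y = y, config = config),
            class = "brt_fit")
}

#' @export
print.brt_fit <- function(x, ...) {
  cat(sprintf("<brt_fit> %d trees; AUC-cv %.3f, training AUC %.3f\n",
              x$n_trees, x$auc_cv, x$auc_train))
  inf <- sort(x$relative_influence, decreasing = TRUE)
  cat("  relative influence (%):",
      paste(sprintf("%s %.1f", names(inf), inf), collapse = ", "), "\n")
  invisible(x)
}

#' Relative influence of the predictors
#'
#' Per predictor, the total split-improvement accumulated over all trees of
#' the fitted model, rescaled to sum to 100.  Predictors never used in a
#' split have influence 0.
#'
#' @param fit a [fit_brt_step()] result.
#' @return Named numeric vector of percentages.
#' @export
variable_importance <- function(fit) {
  stopifnot(inherits(fit, "brt_fit"))
  fit$relative_influence
}

#' Centered partial-dependence curve
#'
#' For `grid_size` values spanning the predictor's observed range, the mean
#' model score (link scale) with that predictor fixed and all other
#' predictors at their observed joint values; the curve is centered by
#' subtracting its mean over the grid.
#'
#' @param fit a [fit_brt_step()] result.
#' @param predictor predictor name.
#' @param grid_size number of evaluation points.
#' @return Data frame `predictor`, `value`, `fit` (centered, mean zero over
#'   the grid).
#' @export
partial_dependence <- function(fit, predictor, grid_size = 25) {
  stopifnot(inherits(fit, "brt_fit"))
  if (!predictor %in% colnames(fit$X))
    stop_input("unknown predictor '%s'", predictor)
  rng <- range(fit$X[, predictor])
  grid <- if (rng[1L] == rng[2L]) rep(rng[1L], grid_size)
          else seq(rng[1L], rng[2L], length.out = grid_size)
  f <- vapply(grid, function(v) {
    Xg <- fit$X
    Xg[, predictor] <- v
    mean(predict(fit$model, Xg, outputmargin = TRUE))
  }, numeric(1))
  data.frame(predictor = predictor, value = grid, fit = f - mean(f))
}

#' Replicate BRT fits with derived seeds
#'
#' Runs `n_replicates` independent fits differing only in the stochastic
#' elements (fold assignment and bagging, via per-replicate derived seeds)
#' and collates their AUC-cv, training AUC, tree counts and relative
#' influences.
#'
#' @inheritParams fit_brt_step
#' @param n_replicates number of replicate fits (>= 1).
#' @return A `brt_replicates` object: `replicates` (one row per fit with an
#'   influence column per predictor) and `summary` (means and SDs).
#' @export
run_brt_replicates <- function(predictors, response, config = brt_config(),
                               n_replicates = 100) {
  if (n_replicates < 1) stop_input("n_replicates must be >= 1")
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    fit <- fit_brt_step(predictors, response, cfg)
    rows[[i]] <- cbind(
      data.frame(replicate = i, seed = cfg$seed, auc_cv = fit$auc_cv,
                 auc_train = fit$auc_train, n_trees = fit$n_trees),
      as.data.frame(as.list(fit$relative_influence)))
  }
  reps <- do.call(rbind, rows)
  infl_cols <- setdiff(names(reps),
                       c("replicate", "seed", "auc_cv", "auc_train", "n_trees"))
  summary <- list(
    n_replicates = n_replicates,
    mean_auc_cv = mean(reps$auc_cv), sd_auc_cv = stats::sd(reps$auc_cv),
    mean_auc_train = mean(reps$auc_train),
    mean_n_trees = mean(reps$n_trees),
    mean_influence = colMeans(reps[, infl_cols, drop = FALSE])
  )
  structure(list(replicates = reps, summary = summary, config = config),
            class = "brt_replicates")
}

#' @export
print.brt_replicates <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<brt_replicates> %d fits; AUC-cv %.3f +/- %.3f, mean %d trees\n",
    s$n_replicates, s$mean_auc_cv, s$sd_auc_cv, round(s$mean_n_trees)))
  invisible(x)
}

#' Write replicate results, partial dependence and a run manifest
#'
#' @param replicates a [run_brt_replicates()] result.
#' @param fit optional single [fit_brt_step()] for partial-dependence output.
#' @param stem output path stem.
#' @param grid_size partial-dependence grid size.
#' @export
write_brt_results <- function(replicates, fit = NULL, stem,
                              grid_size = 25) {
  utils::write.csv(replicates$replicates, paste0(stem, "_replicates.csv"),
                   row.names = FALSE)
  if (!is.null(fit)) {
    pd <- do.call(rbind, lapply(colnames(fit$X), partial_dependence,
                                fit = fit, grid_size = grid_size))
    utils::write.csv(pd, paste0(stem, "_partial_dependence.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(config = unclass(replicates$config),
         n_replicates = replicates$summary$n_replicates,
         seeds = replicates$replicates$seed),
    paste0(stem, "_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
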