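#' Random-forest configuration
#'
#' Regression-forest settings used for variance attribution across grouping
#' criteria. The pipeline default of 5,000 trees matches common practice for
#' stable permutation importances; tests and desk runs use fewer.
#'
#' @param n_trees number of trees (default 5000).
#' @param mtry features tried per split; default `ceiling(p / 3)`, the
#'   regression convention (resolved at fit time).
#' @param min_node_size minimum node size (default 5).
#' @param seed integer seed; fixes bootstrap and permutation draws.
#' @param response_encoding how group labels become a numeric response:
#'   `"auto"` (default: 0/1 for two-level criteria, one-vs-rest for
#'   multi-level ones), `"binary"` (0/1, two levels only),
#'   `"integer_codes"` (factor codes as numbers; imposes an arbitrary
#'   ordering on unordered levels), or `"one_vs_rest"` (one forest per
#'   level, results averaged).
#' @return object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 5000, mtry = NULL, min_node_size = 5,
                          seed = 1,
                          response_encoding = c("auto", "binary",
                                                "integer_codes",
                                                "one_vs_rest")) {
  structure(list(n_trees = check_count(n_trees, "n_trees", 1L),
                 mtry = if (!is.null(mtry)) check_count(mtry, "mtry", 1L),
                 min_node_size = check_count(min_node_size, "min_node_size", 1L),
                 seed = check_seed(seed),
                 response_encoding = match.arg(response_encoding)),
            class = "forest_config")
}

#' Fit a bagged regression forest with OOB error and importance
#'
#' Each tree is grown on a bootstrap sample; splits are chosen among `mtry`
#' random features minimizing within-node variance. The out-of-bag (OOB)
#' prediction of a sample averages the trees whose bootstrap missed it;
#' `r_squared = 1 - MSE_oob / Var(y)` with the population variance.
#' Permutation importances are computed per tree on its OOB set.
#'
#' @param X samples x features numeric matrix or data.frame.
#' @param y numeric response (group labels pre-encoded), `n >= 10`.
#' @param config a [forest_config()].
#' @return object of class `forest_result`: `r_squared`, `oob_mse`,
#'   `importance` (feature -> %IncMSE), `top_k` (features ranked by
#'   importance), and the underlying `randomForest` fit.
#' @export
fit_forest <- function(X, y, config = forest_config()) {
  stopifnot(inherits(config, "forest_config"))
  X <- as.matrix(X)
  if (!is.numeric(y) || length(y) != nrow(X))
    stop_invalid("y must be numeric with one value per row of X")
  n <- nrow(X); p <- ncol(X)
  if (n < 10L) stop_invalid("need at least 10 samples")
  pop_var <- mean((y - mean(y))^2)
  if (pop_var == 0) stop_invalid("constant response: Var(y) = 0")
  mtry <- min(config$mtry %||% ceiling(p / 3), p)
  ## encoded group labels have few unique values by design; muffle the
  ## engine's regression-mode caution about that
  rf <- with_seed(config$seed, withCallingHandlers(
    randomForest::randomForest(
      x = X, y = y, ntree = config$n_trees, mtry = mtry,
      nodesize = config$min_node_size, importance = TRUE),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  pred <- rf$predicted
  no_oob <- is.na(pred)
  if (any(no_oob))
    warning(sum(no_oob), " sample(s) with no OOB tree excluded from MSE")
  oob_mse <- mean((y[!no_oob] - pred[!no_oob])^2)
  ## raw permutation importance: mean over trees of the increase in that
  ## tree's OOB MSE after permuting the feature; normalized by the ensemble
  ## OOB MSE to a percent scale (0 exactly for features never split on)
  raw <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  pct <- 100 * raw / oob_mse
  structure(list(r_squared = 1 - oob_mse / pop_var, oob_mse = oob_mse,
                 importance = pct,
                 importance_scaled = randomForest::importance(
                   rf, type = 1, scale = TRUE)[, 1],
                 top_k = names(sort(pct, decreasing = TRUE)),
                 rf = rf, config = config),
            class = "forest_result")
}

#' @export
print.forest_result <- function(x, ...) {
  cat(sprintf("Regression forest (%d trees): R2 = %.3f, OOB MSE = %.4g\n",
              x$config$n_trees, x$r_squared, x$oob_mse))
  top <- utils::head(x$top_k, 5)
  cat("  top features (%IncMSE):",
      paste(sprintf("%s (%.1f)", top, x$importance[top]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Permutation importance of a fitted forest
#'
#' Percent increase in OOB mean squared error when a feature's out-of-bag
#' values are permuted, as stored at fit time. `scaled = TRUE` returns the
#' SD-scaled variant (raw increase divided by its standard error across
#' trees) used by some toolchains.
#'
#' @param forest a `forest_result` from [fit_forest()].
#' @param scaled return the SD-scaled importance instead of the raw percent.
#' @return named numeric vector, one value per feature.
#' @export
permutation_importance <- function(forest, scaled = FALSE) {
  stopifnot(inherits(forest, "forest_result"))
  if (scaled) forest$importance_scaled else forest$importance
}

encode_response <- function(f, encoding) {
  f <- factor(f)
  if (nlevels(f) < 2L) stop_invalid("grouping has a single level")
  switch(encoding,
         binary = {
           if (nlevels(f) != 2L)
             stop_invalid("binary encoding needs exactly 2 levels")
           as.numeric(f) - 1
         },
         integer_codes = as.numeric(f),
         stop_invalid("unknown response encoding"))
}

#' Compare grouping criteria by random-forest variance explained
#'
#' Fits one regression forest per grouping criterion (e.g. culture medium,
#' phylogenetic clade, isolation source) with the profile columns as
#' predictors and the encoded group labels as the response, and ranks the
#' criteria by OOB `R^2` — the criterion whose labels the profiles predict
#' best dominates the data. By default two-level criteria use 0/1 encoding
#' and multi-level criteria one-vs-rest (one forest per level, `R^2` and
#' importances averaged), because integer-coding unordered levels imposes an
#' arbitrary ordering that dilutes real group signal; `integer_codes` is
#' available as an explicit alternative.
#'
#' @param profile samples x features matrix or [feature_table].
#' @param metadata data.frame with one row per sample (matched to profile
#'   row names via its `sample_id` column, or positionally).
#' @param groupings character vector of metadata columns to compare.
#' @param config a [forest_config()]; the same seed is used for every
#'   criterion so identical groupings give identical results.
#' @param top_k number of top features reported per model (default 10).
#' @return object of class `grouping_comparison`: `table` (one row per
#'   grouping, ordered by decreasing `r_squared`) and `results` (named list
#'   of `forest_result`s or one-vs-rest aggregates).
#' @export
compare_groupings <- function(profile, metadata, groupings,
                              config = forest_config(), top_k = 10) {
  if (inherits(profile, "feature_table")) {
    metadata <- metadata %||% profile$sample_meta
    profile <- profile$abundance
  }
  profile <- as.matrix(profile)
  if (!is.null(metadata$sample_id) && !is.null(rownames(profile))) {
    if (!all(rownames(profile) %in% metadata$sample_id))
      stop_invalid("profile rows missing from metadata")
    metadata <- metadata[match(rownames(profile), metadata$sample_id), ,
                         drop = FALSE]
  }
  missing <- setdiff(groupings, names(metadata))
  if (length(missing))
    stop_invalid("grouping(s) absent from metadata: ",
                 paste(missing, collapse = ", "))
  results <- list()
  rows <- list()
  for (grp in groupings) {
    f <- factor(metadata[[grp]])
    if (nlevels(f) < 2L)
      stop_invalid("grouping '", grp, "' has a single level")
    encoding <- config$response_encoding
    if (encoding == "auto")
      encoding <- if (nlevels(f) == 2L) "binary" else "one_vs_rest"
    if (encoding == "one_vs_rest") {
      fits <- lapply(levels(f), function(lv)
        fit_forest(profile, as.numeric(f == lv), config))
      r2 <- mean(vapply(fits, `[[`, numeric(1), "r_squared"))
      imp <- rowMeans(vapply(fits, `[[`,
                             numeric(ncol(profile)), "importance"))
      res <- list(r_squared = r2,
                  oob_mse = mean(vapply(fits, `[[`, numeric(1), "oob_mse")),
                  importance = imp,
                  top_k = names(sort(imp, decreasing = TRUE)),
                  fits = fits)
    } else {
      if (encoding == "binary" && nlevels(f) > 2L) encoding <- "integer_codes"
      y <- encode_response(f, encoding)
      res <- fit_forest(profile, y, config)
    }
    results[[grp]] <- res
    rows[[grp]] <- data.frame(
      grouping = grp, n_levels = nlevels(f), r_squared = res$r_squared,
      oob_mse = res$oob_mse,
      top_features = paste(utils::head(res$top_k, top_k), collapse = ","),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$r_squared), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, results = results, config = config),
            class = "grouping_comparison")
}

#' @export
print.grouping_comparison <- function(x, ...) {
  cat("Random-forest variance attribution (ranked by OOB R2):\n")
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  %d. %-10s R2 = %6.3f (%d levels)\n", i,
                x$table$grouping[i], x$table$r_squared[i],
                x$table$n_levels[i]))
  invisible(x)
}
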