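# Random-forest training on the assembled feature matrix.

.target_col <- function(target) paste0("label_", target)

.target_levels <- function(target) {
  .class_levels(match.arg(target, c("de", "survival", "cnv")))
}

# rows usable for a target: encoded features + non-missing labels
.eval_data <- function(fm, target) {
  stopifnot(inherits(fm, "metonco_features"))
  col <- .target_col(target)
  if (!col %in% names(fm$data)) {
    abort(paste0("feature matrix carries no '", col,
                 "' labels; assemble with labels = build_label_set(...)"),
          class = "metoncokit_config_error")
  }
  cats <- fm$schema$feature[fm$schema$type == "categorical"]
  if (length(cats) && is.null(fm$code_maps)) fm <- encode_categoricals(fm)
  keep <- !is.na(fm$data[[col]])
  data <- fm$data[keep, , drop = FALSE]
  list(
    x = as.data.frame(data[, fm$schema$feature, drop = FALSE]),
    y = as.character(data[[col]]),
    meta = data[, intersect(c("gene", "cell_line"), names(data)), drop = FALSE],
    group = if ("gene" %in% names(data)) data$gene else
      as.character(seq_len(nrow(data))),
    schema = fm$schema,
    levels = .target_levels(target),
    code_maps = fm$code_maps
  )
}

# fit a seeded forest; y may be missing some of `levels`
.fit_forest <- function(x, y, levels, ntree, mtry, seed) {
  yf <- droplevels(factor(y, levels = levels))
  if (nlevels(yf) < 2L) {
    abort("training labels contain fewer than two classes",
          class = "metoncokit_config_error")
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  randomForest::randomForest(x = x, y = yf, ntree = ntree, mtry = mtry,
                             importance = FALSE)
}

# class + probability predictions with all `levels` columns present
.predict_forest <- function(forest, x, levels) {
  cls <- as.character(predict(forest, x, type = "response"))
  pr <- predict(forest, x, type = "prob")
  probs <- matrix(0, nrow(x), length(levels),
                  dimnames = list(NULL, levels))
  probs[, colnames(pr)] <- pr
  list(class = cls, prob = probs)
}

#' Train a random-forest tumor-fitness classifier
#'
#' Encodes categoricals, robust-scales all features, rebalances classes by
#' random oversampling, and fits a seeded random forest on every labelled
#' row of the chosen target. Defaults: 500 trees, `sqrt(n_features)`
#' variables per split, unlimited depth.
#'
#' @param fm A `metonco_features` object with labels attached.
#' @param target `"de"`, `"cnv"` or `"survival"`.
#' @param ntree Number of trees.
#' @param mtry Variables tried per split; default `sqrt(n_features)`.
#' @param seed Integer seed controlling oversampling and forest growth;
#'   identical (data, hyperparameters, seed) give identical predictions.
#' @param oversample Rebalance classes before fitting (default `TRUE`).
#' @return A `metonco_forest`: the fitted forest plus the schema, target,
#'   class levels, scaling parameters and code maps needed to score new data.
#' @export
train_tumor_forest <- function(fm, target = c("de", "cnv", "survival"),
                               ntree = 500, mtry = NULL, seed = 1,
                               oversample = TRUE) {
  target <- match.arg(target)
  cats <- fm$schema$feature[fm$schema$type == "categorical"]
  if (length(cats) && is.null(fm$code_maps)) fm <- encode_categoricals(fm)
  if (is.null(fm$scaling)) fm <- robust_scale(fm)
  ed <- .eval_data(fm, target)
  x <- ed$x; y <- ed$y
  if (oversample) {
    os <- random_oversample(x, y, seed = seed)
    x <- os$data; y <- os$labels
  }
  forest <- .fit_forest(x, y, ed$levels, ntree, mtry, seed)
  structure(
    list(forest = forest, schema = fm$schema, target = target,
         levels = ed$levels,
         hyperparameters = list(ntree = ntree, mtry = forest$mtry),
         seed = seed, scaling = fm$scaling, code_maps = fm$code_maps),
    class = "metonco_forest"
  )
}

#' @export
print.metonco_forest <- function(x, ...) {
  cat("<metonco_forest> target: ", x$target, "; ",
      x$hyperparameters$ntree, " trees, mtry ", x$hyperparameters$mtry,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Predict tumor-fitness classes for new rows
#'
#' @param object A `metonco_forest`.
#' @param newdata A `metonco_features` object or a data frame containing the
#'   schema's feature columns on the original (unscaled) scale; categorical
#'   strings are encoded with the stored maps (an unseen category is an
#'   error naming the column).
#' @param type `"class"` for labels, `"prob"` for a class-probability matrix.
#' @param ... Unused.
#' @return Character labels or a numeric probability matrix.
#' @export
predict.metonco_forest <- function(object, newdata, type = c("class", "prob"),
                                   ...) {
  type <- match.arg(type)
  df <- if (inherits(newdata, "metonco_features")) newdata$data else
    as.data.frame(newdata)
  miss <- setdiff(object$schema$feature, names(df))
  if (length(miss)) {
    abort(paste0("newdata lacks feature column(s): ",
                 paste(miss, collapse = ", ")),
          class = "metoncokit_lookup_error")
  }
  df <- .apply_code_maps(df, object$code_maps)
  df <- .robust_scale_df(df, object$schema$feature, object$scaling)$data
  out <- .predict_forest(object$forest, df[, object$schema$feature,
                                           drop = FALSE], object$levels)
  if (type == "class") out$class else out$prob
}

#' Gini feature importances of a trained forest
#'
#' Mean decrease in Gini node impurity per feature, normalised to sum to one,
#' with dense ranks (1 = most important). When the training feature matrix is
#' supplied, each feature's correlation direction with the target (`'+'`,
#' `'~'`, `'-'`; see [feature_target_correlation()]) is appended.
#'
#' @param object A `metonco_forest`.
#' @param fm Optional `metonco_features` used to attach correlation signs.
#' @param cutoff Absolute Pearson correlation above which a direction is
#'   called (default 0.6).
#' @return A tibble `feature`, `category`, `gini`, `importance`, `rank`
#'   (and `sign` when `fm` is given), ordered by rank.
#' @export
feature_importance <- function(object, fm = NULL, cutoff = 0.6) {
  stopifnot(inherits(object, "metonco_forest"))
  imp <- randomForest::importance(object$forest, type = 2)
  out <- tibble(feature = rownames(imp), gini = as.numeric(imp[, 1])) %>%
    left_join(object$schema, by = "feature") %>%
    mutate(importance = .data$gini / sum(.data$gini),
           rank = rank(-.data$gini, ties.method = "first")) %>%
    select("feature", "category", "gini", "importance", "rank") %>%
    arrange(.data$rank)
  if (!is.null(fm)) {
    signs <- feature_target_correlation(fm, object$target, cutoff = cutoff)
    out <- out %>% left_join(signs[c("feature", "r", "sign")], by = "feature")
  }
  out
}

#' @export
#' @method tidy metonco_forest
tidy.metonco_forest <- function(x, ...) feature_importance(x, ...)

#' @export
#' @method glance metonco_forest
glance.metonco_forest <- function(x, ...) {
  conf <- x$forest$confusion
  tibble(target = x$target, ntree = x$hyperparameters$ntree,
         mtry = x$hyperparameters$mtry,
         oob_error = mean(x$forest$err.rate[x$hyperparameters$ntree,
                                            "OOB"]),
         n_features = nrow(x$schema), n_train = sum(conf[, seq_len(nrow(conf))]))
}

#' Grid-search forest hyperparameters by cross-validation
#'
#' Evaluates each (ntree, mtry, maxnodes) combination with stratified k-fold
#' cross-validation and reports the grid with the best row first, so the
#' performance of the best parameters is explicit.
#'
#' @param fm A `metonco_features` object with labels.
#' @param target Classification target.
#' @param ntree,mtry Vectors of candidate values (`NA` in `mtry` means the
#'   `sqrt(n_features)` default).
#' @param k,seed Cross-validation folds and seed.
#' @return A tibble of grid points with `accuracy`, sorted best first.
#' @export
tune_forest <- function(fm, target = c("de", "cnv", "survival"),
                        ntree = c(200, 500), mtry = NA,
                        k = 5, seed = 1) {
  target <- match.arg(target)
  grid <- tidyr::expand_grid(ntree = ntree, mtry = mtry)
  acc <- purrr::pmap_dbl(grid, function(ntree, mtry) {
    ev <- k_fold_cv(fm, target, k = k, seed = seed, ntree = ntree,
                    mtry = if (is.na(mtry)) NULL else mtry)
    ev$metrics$accuracy
  })
  grid %>% mutate(accuracy = acc) %>% arrange(dplyr::desc(.data$accuracy))
}
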