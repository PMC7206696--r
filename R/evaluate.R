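# Validation schemes, confusion-matrix metrics, permutation significance,
# correlation-direction calls, and gene-level aggregation.
#
# All schemes share one leakage-safe fold fit: robust scaling is fitted on
# the training rows only and applied to the evaluation rows, and random
# oversampling touches the training rows only. `paper_mode = TRUE` instead
# scales and oversamples the pooled data before splitting, reproducing the
# resample-first workflow for comparison; it is not the default because
# duplicated rows then straddle the split and inflate accuracy.

# indices (with repeats) that rebalance `labels` to the majority count
.oversample_indices <- function(labels, seed) {
  tab <- table(labels)
  target <- max(tab)
  set.seed(seed)
  extra <- unlist(lapply(names(tab), function(cl) {
    need <- target - tab[[cl]]
    if (need == 0) return(integer(0))
    sample(which(labels == cl), need, replace = TRUE)
  }))
  c(seq_along(labels), extra)
}

# paper-mode preparation: scale, then oversample the POOLED rows before any
# split, so resampled copies straddle train/test (the leaky comparison mode)
.paper_mode_pool <- function(ed, seed) {
  ed$x <- .robust_scale_df(ed$x, names(ed$x))$data
  idx <- .oversample_indices(ed$y, seed)
  ed$x <- ed$x[idx, , drop = FALSE]
  ed$y <- ed$y[idx]
  ed$meta <- ed$meta[idx, , drop = FALSE]
  # paper mode splits at row level: duplicated copies may straddle the split
  ed$group <- as.character(seq_along(idx))
  ed$prepared <- TRUE
  ed
}

# fit on train indices, predict on test indices; returns predictions tibble.
# When ed$prepared is TRUE the data are already scaled/rebalanced (paper
# mode) and no per-fold preparation happens.
.fit_eval_split <- function(ed, train_idx, test_idx, ntree, mtry, seed) {
  if (isTRUE(ed$prepared)) {
    x_train <- ed$x[train_idx, , drop = FALSE]
    y_train <- ed$y[train_idx]
    x_test <- ed$x[test_idx, , drop = FALSE]
  } else {
    sc <- .robust_scale_df(ed$x[train_idx, , drop = FALSE], names(ed$x))
    x_train <- sc$data
    y_train <- ed$y[train_idx]
    os <- random_oversample(x_train, y_train, seed = seed)
    x_train <- os$data; y_train <- os$labels
    x_test <- .robust_scale_df(ed$x[test_idx, , drop = FALSE],
                               names(ed$x), sc$params)$data
  }
  y_test <- ed$y[test_idx]
  meta <- ed$meta[test_idx, , drop = FALSE]
  forest <- .fit_forest(x_train, y_train, ed$levels, ntree, mtry, seed)
  pred <- .predict_forest(forest, x_test, ed$levels)
  out <- as_tibble(meta)
  out$truth <- y_test
  out$pred <- pred$class
  probs <- as_tibble(as.data.frame(pred$prob))
  names(probs) <- paste0("prob_", names(probs))
  bind_cols(out, probs)
}

.confusion_from_predictions <- function(pred, levels) {
  table(truth = factor(pred$truth, levels = levels),
        pred = factor(pred$pred, levels = levels))
}

.new_eval <- function(pred, levels, scheme, target, seed, extra = list()) {
  cm <- .confusion_from_predictions(pred, levels)
  scores <- as.matrix(pred[paste0("prob_", levels)])
  colnames(scores) <- levels
  metrics <- compute_metrics(cm, truth = pred$truth, scores = scores)
  structure(c(list(confusion = cm, metrics = metrics, predictions = pred,
                   scheme = scheme, target = target, seed = seed,
                   levels = levels), extra),
            class = "metonco_eval")
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest TP/TN/FP/FN per class give per-class precision, recall
#' (sensitivity), specificity and F1, macro-averaged across classes;
#' accuracy is the diagonal fraction; MCC is the multiclass covariance form
#' (zero by convention when a marginal is degenerate). When per-row class
#' probability `scores` and `truth` are supplied, a one-vs-rest AUROC is
#' computed per class from the rank statistic and macro-averaged over
#' classes present in the truth.
#'
#' @param confusion A square class-by-class count matrix (rows = truth,
#'   columns = predicted).
#' @param truth Optional character vector of true classes (for AUROC).
#' @param scores Optional numeric matrix of class probabilities, one column
#'   per class (for AUROC).
#' @return A list: `accuracy`, `by_class` (tibble of per-class metrics),
#'   `precision`, `recall`, `specificity`, `f1` (macro averages), `mcc`,
#'   `auroc` (`NA` without scores), `n`.
#' @export
compute_metrics <- function(confusion, truth = NULL, scores = NULL) {
  cm <- as.matrix(confusion)
  if (!nrow(cm) || sum(cm) == 0) {
    abort("empty confusion matrix", class = "metoncokit_config_error")
  }
  stopifnot(nrow(cm) == ncol(cm))
  classes <- rownames(cm)
  n <- sum(cm)
  rate <- function(num, den) ifelse(den == 0, 0, num / den)
  by_class <- purrr::map_dfr(seq_along(classes), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- n - tp - fn - fp
    precision <- rate(tp, tp + fp)
    recall <- rate(tp, tp + fn)
    tibble(class = classes[k], tp = tp, fp = fp, fn = fn, tn = tn,
           precision = precision, recall = recall,
           specificity = rate(tn, tn + fp),
           f1 = rate(2 * precision * recall, precision + recall))
  })
  # multiclass MCC, covariance form
  tvec <- rowSums(cm); pvec <- colSums(cm); c_diag <- sum(diag(cm))
  denom <- sqrt((n^2 - sum(pvec^2)) * (n^2 - sum(tvec^2)))
  mcc <- if (denom == 0) 0 else (c_diag * n - sum(pvec * tvec)) / denom
  auroc <- NA_real_
  if (!is.null(scores) && !is.null(truth)) {
    aucs <- vapply(classes, function(cl) {
      pos <- truth == cl
      if (!any(pos) || all(pos)) return(NA_real_)
      r <- rank(scores[, cl])
      (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
        (sum(pos) * sum(!pos))
    }, numeric(1))
    auroc <- mean(aucs, na.rm = TRUE)
  }
  list(accuracy = c_diag / n, by_class = by_class,
       precision = mean(by_class$precision), recall = mean(by_class$recall),
       specificity = mean(by_class$specificity), f1 = mean(by_class$f1),
       mcc = mcc, auroc = auroc, n = n)
}

# Stratified fold assignment over grouping units (genes): all rows of a unit
# land in the same fold, so a gene's replicated cell-line rows never straddle
# a split; within each class, shuffled units are dealt round-robin. Units are
# stratified by their first row's label. With one row per unit this reduces
# to plain stratified row assignment.
.stratified_folds <- function(y, groups, k, seed) {
  uid <- unique(groups)
  ulab <- y[match(uid, groups)]
  counts <- table(ulab)
  if (any(counts < k)) {
    abort(paste0("class '", names(counts)[which.min(counts)], "' has only ",
                 min(counts), " unit(s); use k <= ", min(counts)),
          class = "metoncokit_config_error")
  }
  ufold <- setNames(integer(length(uid)), uid)
  set.seed(seed)
  for (cl in unique(ulab)) {
    idx <- sample(which(ulab == cl))
    ufold[idx] <- rep_len(seq_len(k), length(idx))
  }
  unname(ufold[groups])
}

# stratified test subset: units allocated per class by largest remainder so
# the held-out unit count is exactly round(fraction * n_units)
.stratified_split <- function(y, groups, fraction, seed) {
  uid <- unique(groups)
  ulab <- y[match(uid, groups)]
  n_test <- round(fraction * length(uid))
  classes <- sort(unique(ulab))
  counts <- vapply(classes, function(cl) sum(ulab == cl), numeric(1))
  exact <- counts * n_test / length(uid)
  base <- floor(exact)
  rem <- n_test - sum(base)
  if (rem > 0) {
    order_by_frac <- order(exact - base, decreasing = TRUE)
    base[order_by_frac[seq_len(rem)]] <- base[order_by_frac[seq_len(rem)]] + 1
  }
  set.seed(seed)
  test_units <- unlist(lapply(seq_along(classes), function(i) {
    sample(uid[ulab == classes[i]], base[i])
  }))
  sort(which(groups %in% test_units))
}

#' Stratified k-fold cross-validation
#'
#' Splits the labelled rows into k stratified folds; for each fold the model
#' is trained on the remaining folds (scaling and oversampling fitted there
#' only) and scored on the held-out fold. Out-of-fold predictions are pooled
#' into a single confusion matrix. Folds are grouped by gene: all of a
#' gene's cell-line rows land in the same fold, since a gene's static
#' features repeat across its rows and splitting them across folds would let
#' the forest memorise gene identity rather than learn the signal
#' (`paper_mode` reverts to row-level splitting).
#'
#' @param fm A `metonco_features` object with labels.
#' @param target `"de"`, `"cnv"` or `"survival"`.
#' @param k Number of folds (default 10); every class must have at least `k`
#'   labelled genes.
#' @param seed Integer seed controlling folds, oversampling and forests.
#' @param ntree,mtry Forest hyperparameters (see [train_tumor_forest()]).
#' @param paper_mode Scale and oversample before splitting (leaky; for
#'   comparison only).
#' @return A `metonco_eval` report: confusion matrix, metric bundle,
#'   per-row predictions with class probabilities, and the scheme metadata.
#' @export
k_fold_cv <- function(fm, target = c("de", "cnv", "survival"), k = 10,
                      seed = 1, ntree = 500, mtry = NULL,
                      paper_mode = FALSE) {
  target <- match.arg(target)
  ed <- .eval_data(fm, target)
  if (paper_mode) ed <- .paper_mode_pool(ed, seed)
  fold <- .stratified_folds(ed$y, ed$group, k, seed)
  pred <- purrr::map_dfr(seq_len(k), function(i) {
    .fit_eval_split(ed, which(fold != i), which(fold == i),
                    ntree, mtry, seed = seed + i)
  })
  .new_eval(pred, ed$levels, "kfold", target, seed, extra = list(k = k))
}

#' Stratified holdout validation
#'
#' Keeps a stratified `fraction` of the labelled rows (default 30%) aside as
#' validation data, trains on the remainder, and scores the held-out rows.
#' Like [k_fold_cv()], the split is grouped by gene.
#'
#' @inheritParams k_fold_cv
#' @param fraction Held-out fraction (default 0.3); the held-out gene count
#'   is exactly `round(fraction * n_genes)`.
#' @return A `metonco_eval` report.
#' @export
holdout_validation <- function(fm, target = c("de", "cnv", "survival"),
                               fraction = 0.3, seed = 1, ntree = 500,
                               mtry = NULL, paper_mode = FALSE) {
  target <- match.arg(target)
  ed <- .eval_data(fm, target)
  if (paper_mode) ed <- .paper_mode_pool(ed, seed)
  test_idx <- .stratified_split(ed$y, ed$group, fraction, seed)
  train_idx <- setdiff(seq_along(ed$y), test_idx)
  pred <- .fit_eval_split(ed, train_idx, test_idx, ntree, mtry, seed = seed)
  .new_eval(pred, ed$levels, "holdout", target, seed,
            extra = list(fraction = fraction))
}

#' Leave-one-cell-line-out validation
#'
#' Systematically removes each cell line: the model is trained on all other
#' cell lines' rows and evaluated on the held-out line.
#'
#' @inheritParams k_fold_cv
#' @return A named list of `metonco_eval` reports, one per cell line.
#' @export
leave_one_cell_line_out <- function(fm, target = c("de", "cnv", "survival"),
                                    seed = 1, ntree = 500, mtry = NULL) {
  target <- match.arg(target)
  ed <- .eval_data(fm, target)
  lines <- sort(unique(ed$meta$cell_line))
  if (length(lines) < 2L) {
    abort("leave-one-cell-line-out needs at least two cell lines",
          class = "metoncokit_config_error")
  }
  reports <- lapply(seq_along(lines), function(i) {
    test_idx <- which(ed$meta$cell_line == lines[i])
    pred <- .fit_eval_split(ed, setdiff(seq_along(ed$y), test_idx), test_idx,
                            ntree, mtry, seed = seed + i)
    .new_eval(pred, ed$levels, "loco", target, seed,
              extra = list(cell_line = lines[i]))
  })
  setNames(reports, lines)
}

#' Leave-one-feature-set-out validation
#'
#' Retrains with each feature category (topological, dynamic, biochemical)
#' dropped in turn and reports the cross-validated performance without it,
#' quantifying the impact of that category. Categories with no features are
#' skipped with a warning.
#'
#' @inheritParams k_fold_cv
#' @return A tibble `category`, `n_features`, `accuracy`, `f1`, `mcc`, with
#'   the full per-category `metonco_eval` reports in the `reports` attribute.
#' @export
leave_one_feature_set_out <- function(fm, target = c("de", "cnv", "survival"),
                                      k = 10, seed = 1, ntree = 500,
                                      mtry = NULL) {
  target <- match.arg(target)
  cats <- c("topological", "dynamic", "biochemical")
  reports <- list()
  rows <- list()
  for (cat in cats) {
    drop_feats <- fm$schema$feature[fm$schema$category == cat]
    if (!length(drop_feats)) {
      warn(paste0("feature category '", cat, "' has no features; skipped"))
      next
    }
    fm2 <- fm
    fm2$schema <- fm$schema[fm$schema$category != cat, , drop = FALSE]
    fm2$data <- fm$data[, setdiff(names(fm$data), drop_feats), drop = FALSE]
    if (!is.null(fm2$scaling)) {
      fm2$scaling <- fm2$scaling[!fm2$scaling$feature %in% drop_feats, ,
                                 drop = FALSE]
    }
    ev <- k_fold_cv(fm2, target, k = k, seed = seed, ntree = ntree,
                    mtry = mtry)
    reports[[cat]] <- ev
    rows[[cat]] <- tibble(category = cat, n_features = length(drop_feats),
                          accuracy = ev$metrics$accuracy,
                          f1 = ev$metrics$f1, mcc = ev$metrics$mcc)
  }
  out <- bind_rows(rows)
  attr(out, "reports") <- reports
  out
}

#' Permutation significance of classifier accuracy
#'
#' Builds a null distribution of accuracy by refitting the full evaluation
#' pipeline on randomly shuffled labels, then reports the Z-score of the
#' observed accuracy against that null, the upper-tailed normal-fit p value,
#' and the empirical p value `(1 + #{null >= observed}) / (n_iter + 1)` (the
#' empirical p is the safer of the two when the null is skewed).
#'
#' @inheritParams k_fold_cv
#' @param n_iter Number of label shuffles (default 1000; at least 2).
#' @param scheme Evaluation scheme for both the observed and null accuracies:
#'   `"holdout"` (default, one split per iteration) or `"kfold"`.
#' @param fraction,k Scheme parameters.
#' @return A `metonco_permutation`: observed accuracy, null mean/sd, z_score,
#'   p_normal, p_empirical, and the null accuracy vector.
#' @export
permutation_significance <- function(fm, target = c("de", "cnv", "survival"),
                                     n_iter = 1000, seed = 1,
                                     scheme = c("holdout", "kfold"),
                                     fraction = 0.3, k = 10, ntree = 500,
                                     mtry = NULL, paper_mode = FALSE) {
  target <- match.arg(target)
  scheme <- match.arg(scheme)
  if (n_iter < 2) {
    abort("n_iter must be at least 2", class = "metoncokit_config_error")
  }
  run_once <- function(fmx, s) {
    ev <- if (scheme == "holdout") {
      holdout_validation(fmx, target, fraction = fraction, seed = s,
                         ntree = ntree, mtry = mtry, paper_mode = paper_mode)
    } else {
      k_fold_cv(fmx, target, k = k, seed = s, ntree = ntree, mtry = mtry,
                paper_mode = paper_mode)
    }
    ev$metrics$accuracy
  }
  observed <- run_once(fm, seed)
  col <- .target_col(target)
  null_acc <- vapply(seq_len(n_iter), function(i) {
    fmi <- fm
    lab <- fmi$data[[col]]
    ok <- !is.na(lab)
    set.seed(seed + i)
    fmi$data[[col]][ok] <- sample(lab[ok])
    run_once(fmi, seed + i)
  }, numeric(1))
  z <- (observed - mean(null_acc)) / sd(null_acc)
  structure(
    list(observed = observed, null_mean = mean(null_acc),
         null_sd = sd(null_acc), z_score = z,
         p_normal = pnorm(z, lower.tail = FALSE),
         p_empirical = (1 + sum(null_acc >= observed)) / (n_iter + 1),
         null_accuracy = null_acc, n_iter = n_iter, scheme = scheme,
         target = target, seed = seed),
    class = "metonco_permutation"
  )
}

#' @export
print.metonco_permutation <- function(x, ...) {
  cat("<metonco_permutation> observed accuracy ", format(x$observed),
      " vs null ", format(x$null_mean), " +/- ", format(x$null_sd),
      " (", x$n_iter, " shuffles)\n  z = ", format(x$z_score),
      ", normal-fit p = ", format(x$p_normal),
      ", empirical p = ", format(x$p_empirical), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method glance metonco_permutation
glance.metonco_permutation <- function(x, ...) {
  tibble(target = x$target, scheme = x$scheme, observed = x$observed,
         null_mean = x$null_mean, null_sd = x$null_sd, z_score = x$z_score,
         p_normal = x$p_normal, p_empirical = x$p_empirical,
         n_iter = x$n_iter)
}

#' Correlation direction between each feature and the target
#'
#' Encodes the ternary classes ordinally (decreased = -1, neutral = 0,
#' increased = +1) and computes the Pearson correlation of every feature
#' against the encoding. Directions are called at |R| > `cutoff` (default
#' 0.6): `'+'`, `'-'`, otherwise `'~'`. Zero-variance features get `'~'`
#' with a warning.
#'
#' @inheritParams k_fold_cv
#' @param cutoff Absolute correlation cutoff for a direction call.
#' @return A tibble `feature`, `r`, `sign`.
#' @export
feature_target_correlation <- function(fm, target = c("de", "cnv", "survival"),
                                       cutoff = 0.6) {
  target <- match.arg(target)
  ed <- .eval_data(fm, target)
  yord <- .encode_class(ed$y, ed$levels)
  rs <- vapply(names(ed$x), function(col) {
    x <- ed$x[[col]]
    if (sd(x) == 0) {
      warn(paste0("feature '", col, "' has zero variance; sign '~'"))
      return(NA_real_)
    }
    cor(x, yord)
  }, numeric(1))
  tibble(feature = names(ed$x), r = unname(rs)) %>%
    mutate(sign = dplyr::case_when(
      is.na(.data$r) ~ "~",
      .data$r > cutoff ~ "+",
      .data$r < -cutoff ~ "-",
      TRUE ~ "~"
    ))
}

#' Aggregate per-cell-line rows to one summary row per gene
#'
#' Predicted labels are combined by plurality vote across a gene's cell
#' lines; on a tie for the top count the label falls back to the class of
#' the median ordinal encoding (so an UP/DOWN conflict resolves to NEUTRAL).
#' Numeric columns are summarised by their median.
#'
#' @param data A data frame with a `gene` column, a label column, and any
#'   numeric columns to summarise.
#' @param label_col Name of the label column (default `"pred"`).
#' @param levels Class levels in ordinal order; defaults to the levels found.
#' @return A tibble with one row per gene.
#' @export
gene_level_aggregate <- function(data, label_col = "pred", levels = NULL) {
  data <- as_tibble(data)
  stopifnot("gene" %in% names(data), label_col %in% names(data))
  if (is.null(levels)) {
    found <- unique(data[[label_col]])
    levels <- if (all(found %in% .class_levels("de"))) .class_levels("de")
    else if (all(found %in% .class_levels("cnv"))) .class_levels("cnv")
    else sort(found)
  }
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  vote <- function(labs) {
    tab <- sort(table(labs), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) {
      .decode_class(round(median(.encode_class(labs, levels))), levels)
    } else {
      names(tab)[1]
    }
  }
  data %>%
    group_by(.data$gene) %>%
    summarise(!!label_col := vote(.data[[label_col]]),
              across(all_of(num_cols), median),
              n_rows = dplyr::n(), .groups = "drop")
}

#' @export
print.metonco_eval <- function(x, ...) {
  cat("<metonco_eval> scheme: ", x$scheme, "; target: ", x$target,
      "; n = ", x$metrics$n, "\n  accuracy ", format(x$metrics$accuracy),
      ", macro F1 ", format(x$metrics$f1), ", MCC ", format(x$metrics$mcc),
      ", AUROC ", format(x$metrics$auroc), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @export
#' @method tidy metonco_eval
tidy.metonco_eval <- function(x, ...) x$metrics$by_class

#' @export
#' @method glance metonco_eval
glance.metonco_eval <- function(x, ...) {
  tibble(scheme = x$scheme, target = x$target, n = x$metrics$n,
         accuracy = x$metrics$accuracy, precision = x$metrics$precision,
         recall = x$metrics$recall, specificity = x$metrics$specificity,
         f1 = x$metrics$f1, mcc = x$metrics$mcc, auroc = x$metrics$auroc,
         seed = x$seed)
}

#' Serialise an evaluation report to JSON
#'
#' @param x A `metonco_eval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(x, path) {
  stopifnot(inherits(x, "metonco_eval"))
  out <- list(scheme = x$scheme, target = x$target, seed = x$seed,
              confusion = as.data.frame.matrix(unclass(x$confusion)),
              metrics = x$metrics[c("accuracy", "precision", "recall",
                                    "specificity", "f1", "mcc", "auroc", "n")],
              by_class = x$metrics$by_class)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
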