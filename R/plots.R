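# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_col
#'   geom_point geom_vline geom_histogram geom_jitter labs coord_flip
#'   scale_fill_gradient theme_minimal stat_summary facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a confusion matrix as a heatmap
#'
#' @param object A `metonco_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot metonco_eval
autoplot.metonco_eval <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot(df, aes(x = .data$pred, y = .data$truth, fill = .data$Freq)) +
    geom_tile() +
    geom_text(aes(label = .data$Freq)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted class", y = "true class", fill = "rows",
         title = paste0(object$scheme, " validation, target ", object$target,
                        " (accuracy ",
                        sprintf("%.3f", object$metrics$accuracy), ")")) +
    theme_minimal()
}

#' Plot Gini feature importances
#'
#' @param object A `metonco_forest`.
#' @param top Number of top-ranked features to show (default 10).
#' @param fm Optional feature matrix to annotate correlation signs.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot metonco_forest
autoplot.metonco_forest <- function(object, top = 10, fm = NULL, ...) {
  imp <- feature_importance(object, fm = fm)
  imp <- head(imp, top)
  lab <- if ("sign" %in% names(imp)) {
    paste0(imp$feature, " [", imp$sign, "]")
  } else {
    imp$feature
  }
  imp$label <- factor(lab, levels = rev(lab))
  ggplot(imp, aes(x = .data$label, y = .data$importance,
                  fill = .data$category)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "normalised Gini importance",
         title = paste0("top ", nrow(imp), " features, target ",
                        object$target)) +
    theme_minimal()
}

#' Plot the permutation-null accuracy distribution
#'
#' @param object A `metonco_permutation`.
#' @param ... Unused.
#' @return A ggplot with the observed accuracy as a vertical line.
#' @export
#' @method autoplot metonco_permutation
autoplot.metonco_permutation <- function(object, ...) {
  df <- tibble(accuracy = object$null_accuracy)
  ggplot(df, aes(x = .data$accuracy)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed, colour = "firebrick",
               linewidth = 1) +
    labs(x = "null accuracy (shuffled labels)", y = "count",
         title = sprintf("observed %.3f, empirical p = %.4g",
                         object$observed, object$p_empirical)) +
    theme_minimal()
}

#' Per-class distribution of a feature
#'
#' Jittered per-row feature values split by ternary class, with the class
#' median marked — the per-feature view used to read off how a feature
#' separates increased, neutral and decreased genes.
#'
#' @param fm A `metonco_features` object with labels.
#' @param feature Feature column to plot.
#' @param target `"de"`, `"cnv"` or `"survival"`.
#' @return A ggplot.
#' @export
plot_feature_distribution <- function(fm, feature,
                                      target = c("de", "cnv", "survival")) {
  target <- match.arg(target)
  stopifnot(feature %in% fm$schema$feature)
  col <- .target_col(target)
  df <- fm$data[!is.na(fm$data[[col]]), c(feature, col)]
  names(df) <- c("value", "class")
  df$class <- factor(df$class, levels = .target_levels(target))
  ggplot(df, aes(x = .data$class, y = .data$value)) +
    geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
    stat_summary(fun = median, geom = "point", shape = 18, size = 4,
                 colour = "firebrick") +
    labs(x = NULL, y = feature, title = paste0(feature, " by ", target,
                                               " class")) +
    theme_minimal()
}
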