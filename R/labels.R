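# Ternary tumor-fitness labels from omics tables.
#
# Three targets, each labelled per gene by explicit threshold rules:
#   survival — Cox hazard ratio + p value per cohort, reconciled by plurality
#   CNV      — per-sample gain/loss calls (COSMIC-style clauses), then a
#              gain/loss ratio per gene
#   DE       — median tumor-vs-normal log2 fold change against +/- 2

#' Label a single survival record
#'
#' `UPREG` when the hazard ratio is at least `up_threshold` with `p <= alpha`
#' (higher activity, worse survival); `DOWNREG` when it is at most
#' `down_threshold` with `p <= alpha`; `NEUTRAL` for intermediate hazard
#' ratios or non-significant tests. Vectorised over `hr` and `p`.
#'
#' @param hr Hazard ratio(s), >= 0.
#' @param p Cox test p value(s) in `[0, 1]`.
#' @param up_threshold,down_threshold Hazard-ratio cutoffs (defaults 1.33 and
#'   0.75; the alternative published pairs 0.5/2.0 and 0.90/1.10 can be
#'   supplied here).
#' @param alpha Significance level (default 0.05, inclusive).
#' @return Character vector of `"UPREG"`, `"NEUTRAL"`, `"DOWNREG"`.
#' @export
label_survival_record <- function(hr, p, up_threshold = 1.33,
                                  down_threshold = 0.75, alpha = 0.05) {
  if (any(hr < 0, na.rm = TRUE)) {
    abort("hazard ratio must be non-negative", class = "metoncokit_parse_error")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p value must lie in [0, 1]", class = "metoncokit_parse_error")
  }
  dplyr::case_when(
    hr >= up_threshold & p <= alpha ~ "UPREG",
    hr <= down_threshold & p <= alpha ~ "DOWNREG",
    TRUE ~ "NEUTRAL"
  )
}

#' Reconcile multiple class calls for one gene
#'
#' Returns the strictly most frequent class; any tie for the top count —
#' including direct conflicts — yields `NEUTRAL`.
#'
#' @param labels Non-empty character vector of class calls.
#' @return A single class string.
#' @export
reconcile_labels <- function(labels) {
  if (!length(labels)) {
    abort("cannot reconcile an empty set of labels",
          class = "metoncokit_parse_error")
  }
  tab <- sort(table(labels), decreasing = TRUE)
  if (length(tab) > 1L && tab[1] == tab[2]) return("NEUTRAL")
  names(tab)[1]
}

#' Classify one CNV sample as gain, loss, or neither
#'
#' COSMIC-style total-copy-number calls relative to average genome ploidy:
#' `GAIN` when ploidy <= 2.7 and CN >= 5, or ploidy > 2.7 and CN >= 9;
#' `LOSS` when ploidy <= 2.7 and CN = 0, or ploidy > 2.7 and
#' CN < ploidy - `loss_offset`; otherwise `NONE`. The clauses are checked in
#' that order (GAIN first). Vectorised.
#'
#' @param total_copy_number Non-negative integer copy number(s).
#' @param genome_ploidy Positive average genome ploidy.
#' @param loss_offset Offset subtracted from ploidy in the high-ploidy LOSS
#'   clause (default 2.7).
#' @return Character vector of `"GAIN"`, `"LOSS"`, `"NONE"`.
#' @export
classify_cnv_sample <- function(total_copy_number, genome_ploidy,
                                loss_offset = 2.7) {
  if (any(genome_ploidy <= 0, na.rm = TRUE)) {
    abort("genome ploidy must be positive", class = "metoncokit_parse_error")
  }
  if (any(total_copy_number < 0, na.rm = TRUE)) {
    abort("total copy number must be non-negative",
          class = "metoncokit_parse_error")
  }
  dplyr::case_when(
    genome_ploidy <= 2.7 & total_copy_number >= 5 ~ "GAIN",
    genome_ploidy > 2.7 & total_copy_number >= 9 ~ "GAIN",
    genome_ploidy <= 2.7 & total_copy_number == 0 ~ "LOSS",
    genome_ploidy > 2.7 & total_copy_number < genome_ploidy - loss_offset ~ "LOSS",
    TRUE ~ "NONE"
  )
}

#' Label one gene from its CNV sample records
#'
#' Samples are first classified by [classify_cnv_sample()]; the gene-level
#' call uses the gain/loss ratio (#GAIN / #LOSS): `NEUTRAL` when fewer than
#' `min_measurements` samples were measured (all records count, including
#' `NONE` calls) or when the ratio lies in `[low, high]`; `GAIN` when the
#' ratio exceeds `high` (a gene with gains and no losses has ratio +Inf);
#' `LOSS` when it is below `low`. A gene with neither gains nor losses is
#' `NEUTRAL`.
#'
#' @param samples Data frame of records for a single gene with columns
#'   `total_copy_number` and `genome_ploidy` (and optionally `gene`, which
#'   must then be constant).
#' @param min_measurements Minimum sample count for a non-neutral call.
#' @param low,high Inclusive ratio bounds of the neutral band.
#' @return A single class string.
#' @export
label_cnv_gene <- function(samples, min_measurements = 5,
                           low = 0.5, high = 2.0) {
  samples <- as_tibble(samples)
  if ("gene" %in% names(samples) && length(unique(samples$gene)) > 1L) {
    abort("label_cnv_gene() expects records for a single gene",
          class = "metoncokit_consistency_error")
  }
  if (nrow(samples) < min_measurements) return("NEUTRAL")
  calls <- classify_cnv_sample(samples$total_copy_number,
                               samples$genome_ploidy)
  n_gain <- sum(calls == "GAIN")
  n_loss <- sum(calls == "LOSS")
  if (n_gain == 0 && n_loss == 0) return("NEUTRAL")
  ratio <- if (n_loss == 0) Inf else n_gain / n_loss
  if (ratio > high) "GAIN" else if (ratio < low) "LOSS" else "NEUTRAL"
}

#' Label one gene from tumor-vs-normal log2 fold changes
#'
#' The median over replicate measurements is the gene's value: `UPREG` at
#' `up` (default 2) or above, `DOWNREG` at `down` (default -2) or below,
#' otherwise `NEUTRAL`.
#'
#' @param values Non-empty numeric vector of log2 fold changes.
#' @param up,down Inclusive cutoffs.
#' @return A single class string.
#' @export
label_differential_expression <- function(values, up = 2, down = -2) {
  if (!length(values)) {
    abort("no fold-change values supplied", class = "metoncokit_parse_error")
  }
  if (any(!is.finite(values))) {
    abort("fold-change values must be finite", class = "metoncokit_parse_error")
  }
  m <- median(values)
  if (m >= up) "UPREG" else if (m <= down) "DOWNREG" else "NEUTRAL"
}

#' Assemble the per-gene ternary label set from omics tables
#'
#' Applies the three labelling rules table-wide and joins the results per
#' gene, with supporting counts as provenance. Genes absent from a table get
#' `NA` for that target (they are dropped later when that target is used for
#' training, mirroring the removal of genes with missing values).
#'
#' @param survival Data frame `gene`, `cohort`, `hazard_ratio`, `p_value`.
#' @param cnv Data frame `gene`, `sample`, `total_copy_number`,
#'   `genome_ploidy`.
#' @param de Data frame `gene`, `log2_fold_change`.
#' @param genes Genes to label; defaults to the union across tables.
#' @param thresholds Optional named list overriding rule parameters:
#'   `hr_up`, `hr_down`, `alpha`, `cnv_min_measurements`, `cnv_low`,
#'   `cnv_high`, `de_up`, `de_down`.
#' @return A tibble `gene`, `de_label`, `cnv_label`, `survival_label`,
#'   `n_de_values`, `n_cnv_samples`, `n_survival_records`.
#' @export
build_label_set <- function(survival, cnv, de, genes = NULL,
                            thresholds = list()) {
  th <- modifyList(list(hr_up = 1.33, hr_down = 0.75, alpha = 0.05,
                        cnv_min_measurements = 5, cnv_low = 0.5,
                        cnv_high = 2.0, de_up = 2, de_down = -2),
                   thresholds)
  survival <- as_tibble(survival); cnv <- as_tibble(cnv); de <- as_tibble(de)
  if (is.null(genes)) {
    genes <- sort(unique(c(survival$gene, cnv$gene, de$gene)))
  }
  sv <- survival %>%
    mutate(call = label_survival_record(.data$hazard_ratio, .data$p_value,
                                        th$hr_up, th$hr_down, th$alpha)) %>%
    group_by(.data$gene) %>%
    summarise(survival_label = reconcile_labels(.data$call),
              n_survival_records = dplyr::n(), .groups = "drop")
  cv <- cnv %>%
    group_by(.data$gene) %>%
    summarise(cnv_label = label_cnv_gene(dplyr::pick(dplyr::everything()),
                                         th$cnv_min_measurements,
                                         th$cnv_low, th$cnv_high),
              n_cnv_samples = dplyr::n(), .groups = "drop")
  dx <- de %>%
    group_by(.data$gene) %>%
    summarise(de_label = label_differential_expression(.data$log2_fold_change,
                                                       th$de_up, th$de_down),
              n_de_values = dplyr::n(), .groups = "drop")
  tibble(gene = genes) %>%
    left_join(dx, by = "gene") %>%
    left_join(cv, by = "gene") %>%
    left_join(sv, by = "gene") %>%
    mutate(n_de_values = tidyr::replace_na(.data$n_de_values, 0L),
           n_cnv_samples = tidyr::replace_na(.data$n_cnv_samples, 0L),
           n_survival_records = tidyr::replace_na(.data$n_survival_records, 0L)) %>%
    select("gene", "de_label", "cnv_label", "survival_label",
           "n_de_values", "n_cnv_samples", "n_survival_records")
}

#' Write a label set as TSV
#'
#' @param labels Tibble from [build_label_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_set <- function(labels, path) {
  readr::write_tsv(labels, path)
  invisible(path)
}
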