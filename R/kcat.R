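#' Read enzyme turnover-number records from TSV
#'
#' Expects columns `gene`, `substrate`, `kcat` (turnover number in 1/s).
#' Records with non-positive or missing kcat are rejected at parse with a
#' warning naming how many were dropped.
#'
#' @param path Path to a TSV file.
#' @return A tibble of validated records.
#' @export
read_kcat <- function(path) {
  rec <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("gene", "substrate", "kcat"), names(rec))
  if (length(miss)) {
    abort(paste0("kcat table missing column(s): ", paste(miss, collapse = ", ")),
          class = "metoncokit_parse_error")
  }
  bad <- !is.finite(rec$kcat) | rec$kcat <= 0
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad), " kcat record(s) with non-positive or ",
                "missing values"))
    rec <- rec[!bad, ]
  }
  rec
}

#' Curate turnover-number features per gene
#'
#' Enzyme catalytic rates span many orders of magnitude, so the feature is
#' the base-2 logarithm. A gene with several measurements (different
#' substrates) gets the median of its per-record `log2(kcat)` values; a gene
#' in the universe with no measurement is imputed with the median of the
#' per-gene medians across all measured genes.
#'
#' @param records A data frame with columns `gene` and `kcat` (> 0), e.g.
#'   from [read_kcat()].
#' @param gene_universe Non-empty character vector of genes that need a
#'   feature value.
#' @return A tibble `gene`, `log2_kcat`, `imputed`, one row per universe
#'   gene, ordered as `gene_universe`.
#' @export
curate_kcat <- function(records, gene_universe) {
  if (!length(gene_universe)) {
    abort("gene universe is empty", class = "metoncokit_config_error")
  }
  records <- as_tibble(records)
  if (any(records$kcat <= 0)) {
    abort("kcat records must be positive; run read_kcat() to reject them",
          class = "metoncokit_parse_error")
  }
  per_gene <- records %>%
    filter(.data$gene %in% gene_universe) %>%
    group_by(.data$gene) %>%
    summarise(log2_kcat = median(log2(.data$kcat)), .groups = "drop")
  if (!nrow(per_gene)) {
    abort("no kcat records overlap the gene universe; imputation median undefined",
          class = "metoncokit_config_error")
  }
  fallback <- median(per_gene$log2_kcat)
  tibble(gene = gene_universe) %>%
    left_join(per_gene, by = "gene") %>%
    mutate(imputed = is.na(.data$log2_kcat),
           log2_kcat = ifelse(.data$imputed, fallback, .data$log2_kcat))
}

#' Read a cell-line expression table from TSV
#'
#' Expects columns `gene`, `cell_line`, `value` (normalised expression, used
#' as provided). Set `log2 = TRUE` to log-transform (values must then be
#' positive).
#'
#' @param path Path to a TSV file.
#' @param log2 Apply a log2 transform to `value`.
#' @return A tibble with one row per (gene, cell line).
#' @export
read_expression <- function(path, log2 = FALSE) {
  ex <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("gene", "cell_line", "value"), names(ex))
  if (length(miss)) {
    abort(paste0("expression table missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "metoncokit_parse_error")
  }
  if (anyDuplicated(ex[c("gene", "cell_line")])) {
    abort("expression table has duplicate (gene, cell_line) entries",
          class = "metoncokit_parse_error")
  }
  if (log2) ex$value <- log2(ex$value)
  ex
}
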