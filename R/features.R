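# Feature-matrix assembly: one row per (gene, cell line), columns defined by
# a schema that assigns each feature to the topological, dynamic or
# biochemical category. Static features repeat across a gene's cell lines;
# only expression varies within a gene.

#' Build a feature schema
#'
#' @param feature Character vector of unique feature (column) names.
#' @param category One of `"topological"`, `"dynamic"`, `"biochemical"` per
#'   feature.
#' @param type `"numeric"` or `"categorical"` per feature.
#' @return A tibble with columns `feature`, `category`, `type`.
#' @export
feature_schema <- function(feature, category, type) {
  stopifnot(!anyDuplicated(feature),
            all(category %in% c("topological", "dynamic", "biochemical")),
            all(type %in% c("numeric", "categorical")))
  tibble(feature = feature, category = category, type = type)
}

# infer schema from assembled column names
.infer_schema <- function(cols) {
  cat_of <- function(x) {
    dplyr::case_when(
      grepl("^(media_dist_|biomass_dist_)", x) ~ "topological",
      x %in% c("media_epicenter", "biomass_epicenter", "total_epicenter",
               "subsystem", "subnetwork") ~ "topological",
      grepl("^flux_", x) ~ "dynamic",
      TRUE ~ "biochemical"
    )
  }
  feature_schema(cols, cat_of(cols),
                 ifelse(cols %in% c("subsystem", "subnetwork"),
                        "categorical", "numeric"))
}

# dominant subsystem per gene: most frequent over the gene's reactions,
# lexicographically smallest on ties (deterministic)
.gene_subsystems <- function(model) {
  purrr::map_dfr(model$genes, function(g) {
    ids <- .gene_reaction_ids(model, g)
    subs <- model$reactions$subsystem[match(ids, model$reactions$id)]
    subs <- subs[nzchar(subs)]
    if (!length(subs)) return(tibble(gene = g, subsystem = "none"))
    tab <- sort(table(subs), decreasing = TRUE)
    top <- names(tab)[tab == tab[1]]
    tibble(gene = g, subsystem = sort(top)[1])
  })
}

#' Assemble the gene-by-cell-line feature matrix
#'
#' Joins the per-gene feature sources (topology profiles, knockout flux
#' deltas, curated kcat, the gene's dominant pathway) with per-(gene, cell
#' line) expression into one row per gene and cell line. Static features are
#' repeated across a gene's cell lines. Genes missing from any source are
#' dropped with a message, mirroring the removal of genes with missing
#' values. Ternary labels, when supplied, are attached as `label_de`,
#' `label_cnv`, `label_survival` columns (genes may carry `NA` for targets
#' they lack).
#'
#' @param distances Tibble from [distance_profiles()].
#' @param knockout Tibble from [knockout_feature_table()] or a compatible
#'   gene-by-`flux_*` table.
#' @param kcat Tibble from [curate_kcat()].
#' @param expression Tibble `gene`, `cell_line`, `value`.
#' @param model Optional `metabolic_model`; when given, each gene's dominant
#'   `subsystem` is added as a categorical topological feature.
#' @param labels Optional tibble from [build_label_set()].
#' @return A `metonco_features` object: list with `data` (tibble), `schema`,
#'   `code_maps` (`NULL` until [encode_categoricals()]), `scaling` (`NULL`
#'   until [robust_scale()]).
#' @export
assemble_feature_matrix <- function(distances, knockout, kcat, expression,
                                    model = NULL, labels = NULL) {
  distances <- as_tibble(distances)
  knockout <- as_tibble(knockout) %>% select(-any_of("feasible"))
  kcat <- as_tibble(kcat) %>% select(-any_of("imputed"))
  expression <- as_tibble(expression) %>% rename(expression = "value")
  sources <- list(topology = distances$gene, flux = knockout$gene,
                  kcat = kcat$gene, expression = unique(expression$gene))
  keep <- Reduce(intersect, sources)
  if (!length(keep)) {
    abort("no gene is present in every feature source",
          class = "metoncokit_consistency_error")
  }
  dropped <- setdiff(unique(unlist(sources)), keep)
  if (length(dropped)) {
    inform(paste0("dropping ", length(dropped),
                  " gene(s) with missing values: ",
                  paste(head(sort(dropped), 10), collapse = ", "),
                  if (length(dropped) > 10) ", ..." else ""))
  }
  static <- distances %>%
    inner_join(knockout, by = "gene") %>%
    inner_join(kcat, by = "gene")
  if (!is.null(model)) {
    static <- static %>% inner_join(.gene_subsystems(model), by = "gene")
  }
  data <- expression %>%
    filter(.data$gene %in% keep) %>%
    inner_join(static, by = "gene") %>%
    arrange(.data$gene, .data$cell_line)
  feat_cols <- setdiff(names(data), c("gene", "cell_line"))
  # column order: topological, dynamic, biochemical
  schema <- .infer_schema(feat_cols) %>%
    arrange(factor(.data$category,
                   c("topological", "dynamic", "biochemical")))
  data <- data %>% select("gene", "cell_line", all_of(schema$feature))
  if (!is.null(labels)) {
    lab <- as_tibble(labels) %>%
      select("gene", label_de = "de_label", label_cnv = "cnv_label",
             label_survival = "survival_label")
    data <- data %>% left_join(lab, by = "gene")
  }
  structure(list(data = data, schema = schema, code_maps = NULL,
                 scaling = NULL),
            class = "metonco_features")
}

#' @export
print.metonco_features <- function(x, ...) {
  cat("<metonco_features> ", nrow(x$data), " rows (",
      length(unique(x$data$gene)), " genes x ",
      length(unique(x$data$cell_line)), " cell lines), ",
      nrow(x$schema), " features (",
      paste(capture_counts(x$schema$category), collapse = ", "), ")\n",
      if (!is.null(x$code_maps)) "  categoricals encoded\n" else "",
      if (!is.null(x$scaling)) "  robust-scaled\n" else "", sep = "")
  invisible(x)
}

capture_counts <- function(x) {
  tab <- table(x)
  paste0(names(tab), ": ", as.integer(tab))
}

#' @export
#' @method tidy metonco_features
tidy.metonco_features <- function(x, ...) x$data

#' Encode categorical features as integer codes
#'
#' Each distinct string of a categorical feature gets a stable integer code
#' in lexicographic order (0-based); the reversible map is stored on the
#' object so predictions can be mapped back. Applying the stored maps to new
#' data containing an unseen category is an error naming the column.
#'
#' @param fm A `metonco_features` object.
#' @return The object with categorical columns replaced by integer codes and
#'   `code_maps` filled.
#' @export
encode_categoricals <- function(fm) {
  stopifnot(inherits(fm, "metonco_features"))
  cats <- fm$schema$feature[fm$schema$type == "categorical"]
  maps <- list()
  for (col in cats) {
    levels <- sort(unique(fm$data[[col]]))
    maps[[col]] <- setNames(seq_along(levels) - 1L, levels)
    fm$data[[col]] <- as.integer(maps[[col]][fm$data[[col]]])
  }
  fm$code_maps <- maps
  fm
}

#' Decode integer codes back to category strings
#'
#' @param fm An encoded `metonco_features` object.
#' @return The object with original category strings restored and
#'   `code_maps` cleared.
#' @export
decode_categoricals <- function(fm) {
  stopifnot(inherits(fm, "metonco_features"), !is.null(fm$code_maps))
  for (col in names(fm$code_maps)) {
    map <- fm$code_maps[[col]]
    fm$data[[col]] <- names(map)[match(fm$data[[col]], map)]
  }
  fm$code_maps <- NULL
  fm
}

# apply stored code maps to a plain data frame (prediction path)
.apply_code_maps <- function(df, maps) {
  for (col in names(maps)) {
    if (!col %in% names(df)) next
    if (is.numeric(df[[col]])) next  # already encoded
    unseen <- setdiff(unique(df[[col]]), names(maps[[col]]))
    if (length(unseen)) {
      abort(paste0("unseen category in column '", col, "': ",
                   paste(unseen, collapse = ", ")),
            class = "metoncokit_lookup_error")
    }
    df[[col]] <- as.integer(maps[[col]][df[[col]]])
  }
  df
}

# low-level robust scaling of a data frame over given columns; params is a
# tibble(feature, center, scale); when NULL it is fitted (median / IQR with
# zero-IQR divisors replaced by 1)
.robust_scale_df <- function(df, cols, params = NULL) {
  if (is.null(params)) {
    params <- purrr::map_dfr(cols, function(col) {
      qs <- quantile(df[[col]], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- qs[3] - qs[1]
      tibble(feature = col, center = qs[2],
             scale = if (iqr == 0) 1 else iqr)
    })
  }
  for (i in seq_len(nrow(params))) {
    col <- params$feature[i]
    df[[col]] <- (df[[col]] - params$center[i]) / params$scale[i]
  }
  list(data = df, params = params)
}

#' Robust-scale numeric features
#'
#' Centers each numeric feature at its median and divides by its
#' interquartile range (Q3 - Q1, linear-interpolation quantiles); features
#' with zero IQR are centered only (divisor 1). Scaling parameters are
#' stored for exact inversion with [inverse_scale()]. Categorical features
#' must be encoded first and are scaled as their integer codes, matching the
#' encode-then-scale order of the assembly pipeline.
#'
#' @param fm A `metonco_features` object (encoded if it has categoricals).
#' @param params Optional previously fitted parameters (tibble `feature`,
#'   `center`, `scale`) to apply instead of fitting, e.g. to scale evaluation
#'   rows with training-fold parameters.
#' @return The object with scaled feature columns and `scaling` filled.
#' @export
robust_scale <- function(fm, params = NULL) {
  stopifnot(inherits(fm, "metonco_features"))
  cats <- fm$schema$feature[fm$schema$type == "categorical"]
  if (length(cats) && is.null(fm$code_maps)) {
    abort("encode categorical features before scaling",
          class = "metoncokit_config_error")
  }
  out <- .robust_scale_df(fm$data, fm$schema$feature, params)
  fm$data <- out$data
  fm$scaling <- out$params
  fm
}

#' Invert robust scaling
#'
#' @param fm A scaled `metonco_features` object.
#' @return The object with original feature values restored (to floating
#'   point accuracy) and `scaling` cleared.
#' @export
inverse_scale <- function(fm) {
  stopifnot(inherits(fm, "metonco_features"), !is.null(fm$scaling))
  for (i in seq_len(nrow(fm$scaling))) {
    col <- fm$scaling$feature[i]
    fm$data[[col]] <- fm$data[[col]] * fm$scaling$scale[i] +
      fm$scaling$center[i]
  }
  fm$scaling <- NULL
  fm
}

#' Randomly oversample minority classes
#'
#' Samples minority-class rows with replacement (seeded) until every class
#' matches the majority count. All original rows are retained; only copies
#' are added. Intended for training data only — resampling before a
#' train/evaluation split leaks duplicated rows across the split and
#' inflates accuracy (see the `paper_mode` flag of the evaluation
#' functions).
#'
#' @param data A data frame of training rows.
#' @param labels Class label per row (length `nrow(data)`), with at least two
#'   distinct classes.
#' @param seed Integer seed for the resampling draw.
#' @return A list with `data` (rebalanced rows) and `labels`.
#' @export
random_oversample <- function(data, labels, seed = 1) {
  labels <- as.character(labels)
  stopifnot(nrow(data) == length(labels))
  if (length(unique(labels)) < 2L) {
    abort("oversampling needs at least two classes",
          class = "metoncokit_config_error")
  }
  idx <- .oversample_indices(labels, seed)
  list(data = data[idx, , drop = FALSE], labels = labels[idx])
}

#' Write a feature matrix as TSV with a JSON sidecar
#'
#' The TSV holds the data rows; the sidecar records the schema, categorical
#' code maps and scaling parameters needed to interpret or invert them.
#'
#' @param fm A `metonco_features` object.
#' @param path Output TSV path; the sidecar is written to
#'   `paste0(path, ".meta.json")`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "metonco_features"))
  readr::write_tsv(fm$data, path)
  meta <- list(schema = fm$schema,
               code_maps = fm$code_maps,
               scaling = fm$scaling)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
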