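# End-to-end orchestration: features -> labels -> assembly -> training ->
# evaluation -> importance, under a single config, with every output stamped
# by the config hash and seed so reruns are byte-identical.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)),
          class = "metoncokit_pipeline_error", parent = e)
  })
}

#' Default pipeline configuration
#'
#' Returns the full default config as a named list; [run_pipeline()] deep-
#' merges a user config over it. Sections: `simulate` (fixture spec
#' arguments; set to `NULL` and fill `paths` to run on files), `paths`
#' (model/table files), `target`, `flux_source` (`"table"` uses a supplied
#' knockout-flux table, `"fba"` recomputes deletions by linear programming),
#' `thresholds` (label-rule overrides), `forest` (`ntree`, `mtry`),
#' `validation` (`scheme` in kfold/holdout/loco/lofso, `k`, `fraction`,
#' `permutation`, `n_iter`), `mode` (`paper_mode`, `absolute_deltas`), and
#' `seed`.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    simulate = list(),
    paths = NULL,
    target = "de",
    flux_source = "table",
    thresholds = list(),
    forest = list(ntree = 500, mtry = NULL),
    validation = list(scheme = "kfold", k = 10, fraction = 0.3,
                      permutation = FALSE, n_iter = 1000),
    mode = list(paper_mode = FALSE, absolute_deltas = FALSE),
    seed = 1
  )
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  modifyList(default_config(), config, keep.null = TRUE)
}

# read model + omics tables from config$paths
.load_inputs <- function(paths) {
  need <- c("model", "kcat", "expression", "survival", "cnv", "de")
  miss <- setdiff(need, names(paths))
  if (length(miss)) {
    abort(paste0("paths config missing: ", paste(miss, collapse = ", ")),
          class = "metoncokit_config_error")
  }
  tsv <- function(p) readr::read_tsv(p, show_col_types = FALSE)
  tables <- list(kcat = tsv(paths$kcat), expression = tsv(paths$expression),
                 survival = tsv(paths$survival), cnv = tsv(paths$cnv),
                 de = tsv(paths$de))
  if (!is.null(paths$knockout_flux)) {
    tables$knockout_flux <- tsv(paths$knockout_flux)
  }
  list(model = read_metabolic_model(paths$model), tables = tables)
}

#' Run the full per-cancer pipeline
#'
#' Executes the stages in order — input generation or loading, topology
#' profiles, knockout-flux features, kcat curation, ternary labelling,
#' matrix assembly, training, the configured validation scheme, feature
#' importance and correlation directions — and writes every artifact to
#' `out_dir`. Any stage error aborts with the failing stage named; outputs
#' written before the failure are retained for debugging. Reruns with an
#' identical config produce byte-identical files.
#'
#' @param config A config list (see [default_config()]) or the path to a
#'   YAML file holding one.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the model, tables, feature matrix, labels,
#'   trained forest, evaluation report(s), importance table and manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("metonco_run_")) {
  cfg <- .load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, config_hash = rlang::hash(cfg),
                   seed = cfg$seed)

  if (!is.null(cfg$paths)) {
    inputs <- .stage("load", .load_inputs(cfg$paths))
    model <- inputs$model
    tables <- inputs$tables
  } else {
    spec <- .stage("simulate",
                   do.call(fixture_spec,
                           modifyList(cfg$simulate, list(seed = cfg$seed),
                                      keep.null = TRUE)))
    model <- .stage("simulate", generate_toy_model(spec))
    tables <- .stage("simulate", generate_omics_tables(model, spec))
    readr::write_tsv(tables$truth, file.path(out_dir, "truth.tsv"))
  }

  profiles <- .stage("topology", distance_profiles(model))
  knockout <- .stage("flux", {
    if (cfg$flux_source == "fba" || is.null(tables$knockout_flux)) {
      knockout_feature_table(model, absolute = cfg$mode$absolute_deltas)
    } else {
      tables$knockout_flux
    }
  })
  kcatf <- .stage("kcat", curate_kcat(tables$kcat, model$genes))
  labels <- .stage("label",
                   build_label_set(tables$survival, tables$cnv, tables$de,
                                   genes = model$genes,
                                   thresholds = cfg$thresholds))
  write_label_set(labels, file.path(out_dir, "labels.tsv"))

  fm <- .stage("assemble",
               assemble_feature_matrix(profiles, knockout, kcatf,
                                       tables$expression, model = model,
                                       labels = labels))
  write_feature_matrix(fm, file.path(out_dir, "feature_matrix.tsv"))

  forest <- .stage("train",
                   train_tumor_forest(fm, cfg$target,
                                      ntree = cfg$forest$ntree,
                                      mtry = cfg$forest$mtry,
                                      seed = cfg$seed))

  val <- cfg$validation
  evaluation <- .stage("evaluate", switch(
    val$scheme,
    kfold = k_fold_cv(fm, cfg$target, k = val$k, seed = cfg$seed,
                      ntree = cfg$forest$ntree, mtry = cfg$forest$mtry,
                      paper_mode = cfg$mode$paper_mode),
    holdout = holdout_validation(fm, cfg$target, fraction = val$fraction,
                                 seed = cfg$seed, ntree = cfg$forest$ntree,
                                 mtry = cfg$forest$mtry,
                                 paper_mode = cfg$mode$paper_mode),
    loco = leave_one_cell_line_out(fm, cfg$target, seed = cfg$seed,
                                   ntree = cfg$forest$ntree,
                                   mtry = cfg$forest$mtry),
    lofso = leave_one_feature_set_out(fm, cfg$target, k = val$k,
                                      seed = cfg$seed,
                                      ntree = cfg$forest$ntree,
                                      mtry = cfg$forest$mtry),
    abort(paste0("unknown validation scheme '", val$scheme, "'"),
          class = "metoncokit_config_error")
  ))
  if (inherits(evaluation, "metonco_eval")) {
    write_eval_json(evaluation, file.path(out_dir, "evaluation.json"))
  } else if (is.data.frame(evaluation)) {
    readr::write_tsv(evaluation, file.path(out_dir, "evaluation.tsv"))
  } else {
    for (nm in names(evaluation)) {
      write_eval_json(evaluation[[nm]],
                      file.path(out_dir, paste0("evaluation_", nm, ".json")))
    }
  }

  permutation <- NULL
  if (isTRUE(val$permutation)) {
    permutation <- .stage("permutation",
                          permutation_significance(fm, cfg$target,
                                                   n_iter = val$n_iter,
                                                   seed = cfg$seed,
                                                   ntree = cfg$forest$ntree))
    jsonlite::write_json(glance(permutation),
                         file.path(out_dir, "permutation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  importance <- .stage("importance", feature_importance(forest, fm = fm))
  readr::write_tsv(importance, file.path(out_dir, "importance.tsv"))
  correlation <- .stage("importance", feature_target_correlation(fm, cfg$target))
  readr::write_tsv(correlation, file.path(out_dir, "correlation.tsv"))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, tables = tables, features = fm,
                 labels = labels, forest = forest, evaluation = evaluation,
                 permutation = permutation, importance = importance,
                 correlation = correlation, manifest = manifest,
                 out_dir = out_dir))
}

#' Pool per-cancer feature matrices into a pan-cancer matrix
#'
#' Concatenates the rows of several assembled matrices. The cancer id is
#' kept as a `cancer` metadata column; set `include_cancer_id = TRUE` to
#' expose it to the classifier as an additional categorical feature
#' (category `"context"`). All matrices must share the same feature schema.
#'
#' @param fms Named list of `metonco_features` objects (names = cancer ids).
#' @param include_cancer_id Expose the cancer id as a feature.
#' @return A pooled `metonco_features` object.
#' @export
combine_cancers <- function(fms, include_cancer_id = FALSE) {
  stopifnot(length(fms) >= 2L, !is.null(names(fms)))
  schemas <- lapply(fms, function(f) f$schema)
  if (!all(vapply(schemas[-1], identical, logical(1), schemas[[1]]))) {
    abort("per-cancer matrices have differing schemas",
          class = "metoncokit_consistency_error")
  }
  data <- purrr::imap_dfr(fms, function(f, id) {
    mutate(f$data, cancer = id)
  })
  schema <- schemas[[1]]
  if (include_cancer_id) {
    schema <- bind_rows(schema,
                        tibble(feature = "cancer", category = "context",
                               type = "categorical"))
  }
  structure(list(data = data, schema = schema, code_maps = NULL,
                 scaling = NULL),
            class = "metonco_features")
}
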