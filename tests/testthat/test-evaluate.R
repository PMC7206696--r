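# Metrics, validation schemes, permutation significance, correlations,
# gene-level aggregation.

fixture_sets <- new.env()
get_fixture <- function(name, builder) {
  if (is.null(fixture_sets[[name]])) fixture_sets[[name]] <- builder()
  fixture_sets[[name]]
}

signal_fm <- function() {
  get_fixture("signal", function() {
    make_fixture_matrix(seed = 3, n_genes = 30, n_reactions = 32,
                        n_metabolites = 25, n_cell_lines = 2)$fm
  })
}

noise_fm <- function() {
  get_fixture("noise", function() {
    make_fixture_matrix(seed = 13, n_genes = 30, n_reactions = 32,
                        n_metabolites = 25, n_cell_lines = 2,
                        signal_features = character(0), effect_size = 0,
                        label_noise = 0)$fm
  })
}

test_that("metric bundle agrees with an independent formula oracle", {
  set.seed(5)
  classes <- c("DOWNREG", "NEUTRAL", "UPREG")
  truth <- sample(classes, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.6, truth, sample(classes, 200, replace = TRUE))
  cm <- table(truth = factor(truth, classes), pred = factor(pred, classes))
  got <- compute_metrics(cm)
  want <- oracle_metrics(truth, pred, classes)
  for (metric in names(want)) {
    expect_equal(got[[metric]], want[[metric]], tolerance = 1e-12,
                 info = metric)
  }
  # confusion row sums equal per-class truth counts
  expect_equal(unname(rowSums(cm)),
               unname(sapply(classes, function(cl) sum(truth == cl))))
})

test_that("metric conventions hold in degenerate cases", {
  classes <- c("DOWNREG", "NEUTRAL", "UPREG")
  perfect <- diag(c(10, 12, 8))
  dimnames(perfect) <- list(classes, classes)
  m <- compute_metrics(perfect)
  expect_equal(m$accuracy, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$f1, 1)
  # single-class predictions: recall (1,0,0)-pattern, MCC 0 by convention
  one_class <- matrix(0, 3, 3, dimnames = list(classes, classes))
  one_class[, 1] <- c(10, 10, 10)
  m2 <- compute_metrics(one_class)
  expect_equal(m2$by_class$recall, c(1, 0, 0))
  expect_equal(m2$mcc, 0)
  # a uniform random confusion matrix has MCC about 0
  set.seed(1)
  unif <- matrix(rpois(9, 2000), 3, 3, dimnames = list(classes, classes))
  expect_lt(abs(compute_metrics(unif)$mcc), 0.05)
  expect_error(compute_metrics(matrix(0, 3, 3,
                                      dimnames = list(classes, classes))),
               class = "metoncokit_config_error")
})

test_that("one-vs-rest AUROC matches pROC on random scores", {
  set.seed(8)
  classes <- c("DOWNREG", "NEUTRAL", "UPREG")
  truth <- sample(classes, 120, replace = TRUE)
  scores <- matrix(runif(360), 120, 3, dimnames = list(NULL, classes))
  scores <- scores / rowSums(scores)
  pred <- classes[max.col(scores)]
  cm <- table(truth = factor(truth, classes), pred = factor(pred, classes))
  got <- compute_metrics(cm, truth = truth, scores = scores)$auroc
  want <- mean(vapply(classes, function(cl) {
    as.numeric(pROC::auc(pROC::roc(truth == cl, scores[, cl],
                                   quiet = TRUE, direction = "<")))
  }, numeric(1)))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("cross-validation separates planted signal and is deterministic", {
  fm <- signal_fm()
  ev <- k_fold_cv(fm, "de", k = 5, seed = 1, ntree = 150)
  expect_gt(ev$metrics$accuracy, 0.7)
  expect_equal(sum(ev$confusion), nrow(ev$predictions))
  # fold assignment and forests depend only on the seed
  ev2 <- k_fold_cv(fm, "de", k = 5, seed = 1, ntree = 150)
  expect_identical(ev$predictions, ev2$predictions)
  ev3 <- k_fold_cv(fm, "de", k = 5, seed = 2, ntree = 150)
  expect_false(identical(ev$predictions$pred, ev3$predictions$pred))
  # a class with fewer genes than folds is refused with advice
  expect_error(k_fold_cv(fm, "de", k = 50), "use k",
               class = "metoncokit_config_error")
})

test_that("holdout splits are stratified, disjoint, and sized as requested", {
  fm <- signal_fm()                        # 30 genes x 2 lines
  ev <- holdout_validation(fm, "de", fraction = 0.3, seed = 4, ntree = 150)
  # 9 of 30 genes -> 18 of 60 rows held out
  expect_equal(ev$metrics$n, 18)
  held_genes <- unique(ev$predictions$gene)
  expect_equal(length(held_genes), round(0.3 * 30))
  # held-out genes never contribute training rows (grouped split)
  expect_lt(length(intersect(held_genes,
                             setdiff(unique(fm$data$gene), held_genes))), 1)
  expect_gt(ev$metrics$accuracy, 0.6)
})

test_that("leave-one-cell-line-out returns one report per line", {
  fm <- signal_fm()
  reports <- leave_one_cell_line_out(fm, "de", seed = 1, ntree = 100)
  expect_named(reports, c("CL1", "CL2"))
  for (r in reports) {
    expect_s3_class(r, "metonco_eval")
    expect_equal(length(unique(r$predictions$cell_line)), 1)
    expect_equal(r$metrics$n, 30)
  }
  one_line <- fm
  one_line$data <- dplyr::filter(one_line$data, .data$cell_line == "CL1")
  expect_error(leave_one_cell_line_out(one_line, "de"),
               class = "metoncokit_config_error")
})

test_that("leave-one-feature-set-out pinpoints the signal-bearing category", {
  fm <- signal_fm()
  out <- leave_one_feature_set_out(fm, "de", k = 5, seed = 1, ntree = 150)
  expect_setequal(out$category, c("topological", "dynamic", "biochemical"))
  # planted signal lives in the dynamic flux columns: dropping them hurts
  # most, dropping the inert categories hardly matters
  acc <- stats::setNames(out$accuracy, out$category)
  expect_lt(acc["dynamic"], acc["topological"] - 0.1)
  expect_lt(acc["dynamic"], acc["biochemical"] - 0.1)
  reports <- attr(out, "reports")
  expect_s3_class(reports$dynamic, "metonco_eval")
})

test_that("permutation significance has the right tail behaviour", {
  fm <- signal_fm()
  ps <- permutation_significance(fm, "de", n_iter = 30, seed = 2,
                                 scheme = "holdout", ntree = 100)
  # planted signal: observed accuracy beats every shuffled accuracy
  expect_lt(ps$p_empirical, 0.1)
  expect_gt(ps$z_score, 2)
  expect_equal(length(ps$null_accuracy), 30)
  expect_error(permutation_significance(fm, "de", n_iter = 1),
               class = "metoncokit_config_error")
  # an observation below the null mean has p above one half
  fake <- ps
  fake$observed <- ps$null_mean - 2 * ps$null_sd
  expect_gt((1 + sum(fake$null_accuracy >= fake$observed)) /
              (fake$n_iter + 1), 0.5)
})

test_that("correlation directions recover constructed relationships", {
  fm <- noise_fm()
  levels <- c("DOWNREG", "NEUTRAL", "UPREG")
  enc <- match(fm$data$label_de, levels) - 2
  fm$data$expression <- enc                     # exactly the encoded class
  fm$data$log2_kcat <- -enc                     # exactly the negation
  out <- feature_target_correlation(fm, "de")
  expect_equal(out$sign[out$feature == "expression"], "+")
  expect_equal(out$r[out$feature == "expression"], 1)
  expect_equal(out$sign[out$feature == "log2_kcat"], "-")
  # independent noise features stay uncalled
  noise_signs <- out$sign[grepl("^flux_", out$feature)]
  expect_true(all(noise_signs == "~"))
  # zero-variance features warn and yield '~'
  fm$data$total_epicenter <- 1
  expect_warning(out2 <- feature_target_correlation(fm, "de"),
                 "zero variance")
  expect_equal(out2$sign[out2$feature == "total_epicenter"], "~")
})

test_that("gene-level aggregation votes by plurality with median fallback", {
  df <- tibble::tibble(
    gene = c("a", "a", "a", "b", "b", "c"),
    pred = c("UPREG", "UPREG", "NEUTRAL", "UPREG", "DOWNREG", "DOWNREG"),
    score = c(1, 2, 3, 10, 20, 5)
  )
  out <- gene_level_aggregate(df)
  expect_equal(out$pred[out$gene == "a"], "UPREG")       # plurality
  expect_equal(out$pred[out$gene == "b"], "NEUTRAL")     # tie -> median code
  expect_equal(out$pred[out$gene == "c"], "DOWNREG")     # single row
  expect_equal(out$score[out$gene == "a"], 2)            # median value
  expect_equal(out$n_rows[out$gene == "b"], 2)
  # permutation of rows does not change the result
  out2 <- gene_level_aggregate(df[sample(nrow(df)), ])
  expect_equal(dplyr::arrange(out2, .data$gene), dplyr::arrange(out, .data$gene))
})

test_that("evaluation reports serialise to JSON and tidy to tibbles", {
  fm <- signal_fm()
  ev <- holdout_validation(fm, "de", seed = 1, ntree = 100)
  f <- withr::local_tempfile(fileext = ".json")
  write_eval_json(ev, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$metrics$accuracy, ev$metrics$accuracy)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(glance(ev)), 1)
})
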