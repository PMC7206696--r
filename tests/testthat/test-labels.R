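# Ternary labelling rules: boundary behaviour, reconciliation, totality.

test_that("survival labels respect the hazard-ratio and significance boundaries", {
  cases <- list(
    list(hr = 1.33, p = 0.05, exp = "UPREG"),    # both boundaries inclusive
    list(hr = 0.75, p = 0.04, exp = "DOWNREG"),
    list(hr = 2.5, p = 0.2, exp = "NEUTRAL"),    # non-significant
    list(hr = 1.32, p = 0.01, exp = "NEUTRAL"),  # below the up threshold
    list(hr = 0.76, p = 0.01, exp = "NEUTRAL"),
    list(hr = 0.75, p = 0.051, exp = "NEUTRAL"),
    list(hr = 10, p = 0.05, exp = "UPREG"),
    list(hr = 0, p = 0.001, exp = "DOWNREG")
  )
  for (cs in cases) {
    expect_equal(label_survival_record(cs$hr, cs$p), cs$exp,
                 info = paste("hr", cs$hr, "p", cs$p))
  }
  # alternative published threshold pairs are honoured
  expect_equal(label_survival_record(1.9, 0.01, up_threshold = 2,
                                     down_threshold = 0.5), "NEUTRAL")
  expect_equal(label_survival_record(1.12, 0.01, up_threshold = 1.10,
                                     down_threshold = 0.90), "UPREG")
  expect_error(label_survival_record(-1, 0.5),
               class = "metoncokit_parse_error")
})

test_that("label reconciliation is plurality with ties neutral", {
  expect_equal(reconcile_labels(c("UPREG", "UPREG", "NEUTRAL")), "UPREG")
  expect_equal(reconcile_labels(c("UPREG", "DOWNREG")), "NEUTRAL")
  expect_equal(reconcile_labels("NEUTRAL"), "NEUTRAL")
  expect_equal(reconcile_labels(c("DOWNREG", "DOWNREG", "UPREG", "NEUTRAL")),
               "DOWNREG")
  expect_error(reconcile_labels(character(0)),
               class = "metoncokit_parse_error")
  # permutation invariance
  set.seed(1)
  labs <- sample(c("UPREG", "NEUTRAL", "DOWNREG"), 9, replace = TRUE)
  for (i in 1:5) {
    expect_equal(reconcile_labels(sample(labs)), reconcile_labels(labs))
  }
})

test_that("CNV sample calls follow the ploidy-conditional clauses", {
  cases <- list(
    list(cn = 5, pl = 2.0, exp = "GAIN"),   # low-ploidy gain edge
    list(cn = 4, pl = 2.0, exp = "NONE"),
    list(cn = 9, pl = 3.0, exp = "GAIN"),   # high-ploidy gain edge
    list(cn = 8, pl = 3.0, exp = "NONE"),
    list(cn = 0, pl = 2.0, exp = "LOSS"),   # low-ploidy loss is total loss
    list(cn = 1, pl = 2.0, exp = "NONE"),
    list(cn = 0, pl = 3.0, exp = "LOSS"),   # 0 < 3.0 - 2.7
    list(cn = 1, pl = 4.0, exp = "LOSS"),   # 1 < 4.0 - 2.7
    list(cn = 2, pl = 4.0, exp = "NONE"),   # 2 >= 1.3
    list(cn = 3, pl = 2.0, exp = "NONE"),
    list(cn = 5, pl = 2.7, exp = "GAIN")    # boundary ploidy counts as low
  )
  for (cs in cases) {
    expect_equal(classify_cnv_sample(cs$cn, cs$pl), cs$exp,
                 info = paste("cn", cs$cn, "ploidy", cs$pl))
  }
  expect_error(classify_cnv_sample(2, 0), class = "metoncokit_parse_error")
  expect_error(classify_cnv_sample(-1, 2), class = "metoncokit_parse_error")
})

test_that("gain and loss clauses never both fire on a realistic grid", {
  grid <- expand.grid(cn = 0:15, pl = seq(1, 6, by = 0.1))
  gain <- (grid$pl <= 2.7 & grid$cn >= 5) | (grid$pl > 2.7 & grid$cn >= 9)
  loss <- (grid$pl <= 2.7 & grid$cn == 0) |
    (grid$pl > 2.7 & grid$cn < grid$pl - 2.7)
  expect_false(any(gain & loss))
  # and the vectorised classifier is total: one class per grid point
  calls <- classify_cnv_sample(grid$cn, grid$pl)
  expect_true(all(calls %in% c("GAIN", "LOSS", "NONE")))
})

test_that("gene-level CNV labels follow the gain/loss ratio rules", {
  rec <- function(n_gain, n_loss, n_none) {
    tibble::tibble(
      gene = "g",
      sample = paste0("s", seq_len(n_gain + n_loss + n_none)),
      total_copy_number = c(rep(6, n_gain), rep(0, n_loss), rep(2, n_none)),
      genome_ploidy = 2.0
    )
  }
  expect_equal(label_cnv_gene(rec(2, 1, 0)), "NEUTRAL")  # only 3 measurements
  expect_equal(label_cnv_gene(rec(6, 1, 3)), "GAIN")     # ratio 6 > 2
  expect_equal(label_cnv_gene(rec(2, 2, 6)), "NEUTRAL")  # ratio 1
  expect_equal(label_cnv_gene(rec(1, 6, 3)), "LOSS")     # ratio 1/6 < 0.5
  expect_equal(label_cnv_gene(rec(5, 0, 1)), "GAIN")     # Inf ratio
  expect_equal(label_cnv_gene(rec(0, 0, 6)), "NEUTRAL")  # no calls at all
  expect_equal(label_cnv_gene(rec(4, 2, 0)), "NEUTRAL")  # ratio 2 inclusive
  expect_equal(label_cnv_gene(rec(2, 4, 0)), "NEUTRAL")  # ratio 0.5 inclusive
  mixed <- dplyr::mutate(rec(3, 3, 0), gene = rep(c("a", "b"), 3))
  expect_error(label_cnv_gene(mixed), class = "metoncokit_consistency_error")
})

test_that("differential-expression labels use the median against +/- 2", {
  expect_equal(label_differential_expression(2.0), "UPREG")
  expect_equal(label_differential_expression(c(-2.5, -1.9, -2.1)), "DOWNREG")
  expect_equal(label_differential_expression(0), "NEUTRAL")
  expect_equal(label_differential_expression(c(1.9, 1.99)), "NEUTRAL")
  expect_equal(label_differential_expression(-2), "DOWNREG")
  expect_error(label_differential_expression(numeric(0)),
               class = "metoncokit_parse_error")
  expect_error(label_differential_expression(c(1, NA)),
               class = "metoncokit_parse_error")
})

test_that("labels are total and monotone under fuzzing", {
  set.seed(42)
  hr <- runif(300, 0, 5)
  p <- runif(300)
  labs <- label_survival_record(hr, p)
  expect_true(all(labs %in% c("UPREG", "NEUTRAL", "DOWNREG")))
  # raising hr at significant p never moves UPREG to DOWNREG
  sig <- p <= 0.05
  labs2 <- label_survival_record(hr + runif(300, 0, 2), p)
  expect_false(any(labs[sig] == "UPREG" & labs2[sig] == "DOWNREG"))
  # DE is total over random finite inputs
  de <- vapply(1:100, function(i) {
    label_differential_expression(rnorm(sample(1:5, 1), sd = 3))
  }, character(1))
  expect_true(all(de %in% c("UPREG", "NEUTRAL", "DOWNREG")))
})

test_that("the label-set table joins all three targets with provenance", {
  lst <- make_fixture_matrix(seed = 7, n_genes = 12, n_reactions = 14,
                             n_metabolites = 14, n_cell_lines = 2)
  ls <- lst$labels
  expect_equal(nrow(ls), 12)
  expect_true(all(c("de_label", "cnv_label", "survival_label",
                    "n_de_values", "n_cnv_samples",
                    "n_survival_records") %in% names(ls)))
  expect_true(all(ls$de_label %in% c("UPREG", "NEUTRAL", "DOWNREG")))
  expect_true(all(ls$cnv_label %in% c("GAIN", "NEUTRAL", "LOSS")))
  expect_true(all(ls$n_cnv_samples >= 0))
})
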