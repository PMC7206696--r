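# Seeded synthetic fixtures: toy metabolic models and omics tables with
# planted, recoverable structure, so the full pipeline is exercisable
# without any external data.

#' Specify a synthetic fixture
#'
#' Describes the toy model (sizes, component counts) and the planted signal
#' (which features separate the classes, by how much, and how much label
#' noise is applied). The defaults give a model of about 40 metabolites and
#' 60 genes observed in 5 cell lines — 300 feature rows — with 5 designated
#' knockout-flux features separated by 2 robust-scale units between adjacent
#' classes and a 5% label-flip rate.
#'
#' @param n_metabolites Total metabolite count (media + biomass + internal).
#' @param n_reactions Internal (gene-associated) reaction count.
#' @param n_genes Distinct gene count; genes are assigned to reactions
#'   cyclically, so `n_genes <= n_reactions`.
#' @param n_media,n_biomass Media and biomass component counts.
#' @param n_cell_lines Cell lines in the expression table.
#' @param n_subsystems Distinct pathway labels on internal reactions.
#' @param signal_features Feature columns carrying planted class separation;
#'   defaults to the first five knockout-flux columns. Allowed names:
#'   `flux_s<k>` columns, `expression`, `log2_kcat`.
#' @param effect_size Mean separation between adjacent classes on the signal
#'   features, in units of the unit-variance feature noise (> 0 whenever
#'   signal features are designated; 0 disables the signal).
#' @param label_noise Probability that a gene's emitted label (per target
#'   table) is flipped to another class; must be below 0.5.
#' @param seed Integer seed for all draws.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(n_metabolites = 40, n_reactions = 70, n_genes = 60,
                         n_media = 3, n_biomass = 4, n_cell_lines = 5,
                         n_subsystems = 8,
                         signal_features = paste0("flux_s", 1:5),
                         effect_size = 2, label_noise = 0.05, seed = 1) {
  spec <- list(n_metabolites = n_metabolites, n_reactions = n_reactions,
               n_genes = n_genes, n_media = n_media, n_biomass = n_biomass,
               n_cell_lines = n_cell_lines, n_subsystems = n_subsystems,
               signal_features = signal_features, effect_size = effect_size,
               label_noise = label_noise, seed = seed)
  counts <- c(n_metabolites, n_reactions, n_genes, n_media, n_biomass,
              n_cell_lines, n_subsystems)
  if (any(counts < 1)) {
    abort("all fixture counts must be positive",
          class = "metoncokit_config_error")
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    abort("label_noise must lie in [0, 0.5)",
          class = "metoncokit_config_error")
  }
  if (length(signal_features) && effect_size <= 0) {
    abort("effect_size must be positive when signal features are designated",
          class = "metoncokit_config_error")
  }
  if (n_genes > n_reactions) {
    abort("n_genes cannot exceed n_reactions",
          class = "metoncokit_config_error")
  }
  if (n_metabolites < n_media + n_biomass + 1) {
    abort("n_metabolites must exceed n_media + n_biomass",
          class = "metoncokit_config_error")
  }
  bad_sig <- setdiff(signal_features,
                     c(paste0("flux_s", seq_len(n_subsystems)),
                       "expression", "log2_kcat"))
  if (length(bad_sig)) {
    abort(paste0("unknown signal feature(s): ",
                 paste(bad_sig, collapse = ", ")),
          class = "metoncokit_config_error")
  }
  structure(spec, class = "fixture_spec")
}

#' Generate a toy constraint-based model
#'
#' Builds a connected, guaranteed-feasible toy network: one exchange
#' (source) reaction per media component, a chain of single-gene internal
#' reactions routing each media component towards every biomass component,
#' extra random internal reactions for topological variety (a fraction of
#' them reversible), and a biomass reaction consuming all biomass
#' components. Internal reactions carry subsystem labels `s1..s<k>` and
#' single-gene associations `g1..g<n>` assigned cyclically. Generation is
#' fully seeded; an infeasible draw (which the construction makes rare) is
#' regenerated with a shifted seed up to 10 times before erroring.
#'
#' @param spec A [fixture_spec()].
#' @return A validated, feasible `metabolic_model` (wild-type biomass flux
#'   strictly positive).
#' @export
generate_toy_model <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  for (try in 0:9) {
    model <- .draw_toy_model(spec, spec$seed + try * 7919)
    wt <- wild_type_flux(model)
    if (wt$status == "optimal" && wt$objective_value > 1e-6) return(model)
  }
  abort("could not draw a feasible toy model in 10 attempts",
        class = "metoncokit_config_error")
}

.draw_toy_model <- function(spec, seed) {
  set.seed(seed)
  n_int <- spec$n_metabolites - spec$n_media - spec$n_biomass
  media <- paste0("med", seq_len(spec$n_media), "_e")
  internal <- paste0("x", seq_len(n_int), "_c")
  biomass <- paste0("bio", seq_len(spec$n_biomass), "_c")
  mets <- tibble(
    id = c(media, internal, biomass),
    name = c(media, internal, biomass),
    compartment = c(rep("e", spec$n_media), rep("c", n_int + spec$n_biomass))
  )
  rxn <- function(id, re, pr, rev = FALSE, lb = if (rev) -10 else 0, ub = 10,
                  sub = "", gpr = "") {
    tibble(id = id, reversible = rev, lower_bound = lb, upper_bound = ub,
           subsystem = sub, gene_association = gpr,
           reactants = list(re), products = list(pr))
  }
  none <- setNames(numeric(0), character(0))
  exch <- purrr::map_dfr(seq_along(media), function(i) {
    rxn(paste0("EX_", i), none, setNames(1, media[i]), sub = "exchange")
  })
  subs <- paste0("s", seq_len(spec$n_subsystems))
  gene_of <- function(i) paste0("g", (i - 1L) %% spec$n_genes + 1L)
  rows <- list()
  ri <- 0L
  # backbone: route a media metabolite to each biomass component through
  # 1-2 internal hops so every biomass precursor is producible
  for (j in seq_len(spec$n_biomass)) {
    src <- media[(j - 1L) %% spec$n_media + 1L]
    hops <- sample(1:2, 1)
    chain <- c(src, sample(internal, hops), biomass[j])
    for (h in seq_len(length(chain) - 1L)) {
      ri <- ri + 1L
      rows[[ri]] <- rxn(paste0("R", ri), setNames(1, chain[h]),
                        setNames(1, chain[h + 1L]),
                        sub = sample(subs, 1), gpr = gene_of(ri))
    }
  }
  # extra random internal reactions among existing metabolites
  pool <- c(media, internal, biomass)
  while (ri < spec$n_reactions) {
    ri <- ri + 1L
    from <- sample(pool, 1)
    to <- sample(setdiff(pool, from), 1)
    rows[[ri]] <- rxn(paste0("R", ri), setNames(1, from), setNames(1, to),
                      rev = runif(1) < 0.2,
                      sub = sample(subs, 1), gpr = gene_of(ri))
  }
  biomass_rxn <- rxn("BIOMASS", setNames(rep(1, spec$n_biomass), biomass),
                     none, ub = 1000, sub = "biomass")
  rxns <- bind_rows(exch, bind_rows(rows), biomass_rxn)
  metabolic_model(mets, rxns, "BIOMASS",
                  biomass_components = biomass, media_components = media,
                  genes = paste0("g", seq_len(spec$n_genes)))
}

# planted ternary labels per gene, balanced classes, seeded
.planted_labels <- function(spec, levels = c("DOWNREG", "NEUTRAL", "UPREG")) {
  set.seed(spec$seed + 1)
  tibble(gene = paste0("g", seq_len(spec$n_genes)),
         label = sample(rep_len(levels, spec$n_genes)))
}

.flip_labels <- function(labels, noise, levels, seed) {
  set.seed(seed)
  flip <- runif(length(labels)) < noise
  out <- labels
  out[flip] <- vapply(labels[flip], function(l) {
    sample(setdiff(levels, l), 1)
  }, character(1))
  out
}

#' Generate synthetic omics tables with planted signal
#'
#' Draws balanced planted ternary labels per gene, then emits every table
#' the pipeline ingests, constructed so that the labelling rules recover the
#' (noise-flipped) planted labels exactly:
#' survival records whose hazard ratio and p value reproduce the label under
#' the 1.33/0.75, alpha = 0.05 rule; CNV sample records whose gain/loss
#' ratio reproduces it under the COSMIC clauses; fold changes whose median
#' reproduces it under the +/- 2 rule. Designated signal features are
#' shifted by `effect_size` times the label's ordinal sign (+1 increased,
#' 0 neutral, -1 decreased) on top of unit Gaussian noise; all other numeric
#' features are independent noise. Label flips (`label_noise`) are applied
#' independently per target table, after the features are drawn from the
#' true planted label.
#'
#' @param model A toy model from [generate_toy_model()] (supplies gene ids
#'   and subsystem labels).
#' @param spec The [fixture_spec()] used to generate `model`.
#' @return A named list of tibbles — `kcat`, `expression`, `survival`,
#'   `cnv`, `de`, `knockout_flux` — plus `truth` (the planted label per
#'   gene) and `spec`.
#' @export
generate_omics_tables <- function(model, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  genes <- paste0("g", seq_len(spec$n_genes))
  truth <- .planted_labels(spec)
  sig <- .encode_class(truth$label, c("DOWNREG", "NEUTRAL", "UPREG"))
  shift <- function(feature) {
    if (feature %in% spec$signal_features) sig * spec$effect_size else 0
  }

  set.seed(spec$seed + 2)
  # kcat: 1-3 substrate records per gene around a gene-level log2 center
  kcat_center <- 5 + shift("log2_kcat") + rnorm(spec$n_genes)
  kcat <- purrr::map_dfr(seq_along(genes), function(i) {
    k <- sample(1:3, 1)
    tibble(gene = genes[i], substrate = paste0("sub", seq_len(k)),
           kcat = 2^(kcat_center[i] + rnorm(k, 0, 0.3)))
  })

  set.seed(spec$seed + 3)
  lines <- paste0("CL", seq_len(spec$n_cell_lines))
  expression <- tidyr::expand_grid(gene = genes, cell_line = lines) %>%
    mutate(value = rnorm(dplyr::n()) +
             rep(shift("expression"), each = spec$n_cell_lines))

  # knockout-flux feature table: one column per subsystem; designated
  # columns carry the planted separation, the rest are noise
  set.seed(spec$seed + 4)
  flux_cols <- paste0("flux_s", seq_len(spec$n_subsystems))
  flux <- tibble(gene = genes)
  for (col in flux_cols) {
    flux[[col]] <- rnorm(spec$n_genes) + shift(col)
  }

  # survival: 1-3 cohorts per gene, every record consistent with the label
  surv_label <- .flip_labels(truth$label, spec$label_noise,
                             c("DOWNREG", "NEUTRAL", "UPREG"),
                             spec$seed + 5)
  set.seed(spec$seed + 6)
  survival <- purrr::map_dfr(seq_along(genes), function(i) {
    k <- sample(1:3, 1)
    lab <- surv_label[i]
    hr <- switch(lab,
      UPREG = pmax(1.35, exp(rnorm(k, log(1.8), 0.15))),
      DOWNREG = pmin(0.74, exp(rnorm(k, log(0.55), 0.15))),
      NEUTRAL = runif(k, 0.80, 1.25))
    p <- if (lab == "NEUTRAL") runif(k, 0.06, 0.8) else runif(k, 0.001, 0.049)
    tibble(gene = genes[i], cohort = paste0("cohort", seq_len(k)),
           hazard_ratio = hr, p_value = p)
  })

  # CNV: sample records whose gain/loss ratio reproduces the label
  cnv_levels <- c("LOSS", "NEUTRAL", "GAIN")
  cnv_label <- .flip_labels(.decode_class(sig, cnv_levels), spec$label_noise,
                            cnv_levels, spec$seed + 7)
  set.seed(spec$seed + 8)
  cnv <- purrr::map_dfr(seq_along(genes), function(i) {
    lab <- cnv_label[i]
    if (lab == "GAIN") {
      n_gain <- sample(5:8, 1); n_loss <- sample(0:1, 1); n_none <- sample(0:2, 1)
    } else if (lab == "LOSS") {
      n_loss <- sample(5:8, 1); n_gain <- sample(0:1, 1); n_none <- sample(0:2, 1)
    } else if (runif(1) < 0.2) {
      # occasionally exercise the under-measured (< 5 samples) clause
      n_gain <- sample(0:2, 1); n_loss <- 0; n_none <- sample(1:2, 1)
    } else {
      n_gain <- sample(1:3, 1); n_loss <- n_gain; n_none <- sample(1:3, 1)
    }
    cn <- c(sample(5:8, n_gain, replace = TRUE),
            rep(0, n_loss),
            rep(2, n_none))
    k <- length(cn)
    tibble(gene = genes[i], sample = paste0("S", seq_len(k)),
           total_copy_number = cn,
           genome_ploidy = round(runif(k, 1.9, 2.5), 2))
  })

  # DE: replicate fold changes whose median reproduces the label
  de_label <- .flip_labels(truth$label, spec$label_noise,
                           c("DOWNREG", "NEUTRAL", "UPREG"), spec$seed + 9)
  set.seed(spec$seed + 10)
  de <- purrr::map_dfr(seq_along(genes), function(i) {
    k <- sample(1:3, 1)
    vals <- switch(de_label[i],
      UPREG = runif(k, 2.2, 4),
      DOWNREG = runif(k, -4, -2.2),
      NEUTRAL = runif(k, -1.5, 1.5))
    tibble(gene = genes[i], log2_fold_change = vals)
  })

  list(kcat = kcat, expression = expression, survival = survival,
       cnv = cnv, de = de, knockout_flux = flux, truth = truth, spec = spec)
}

#' Write a fixture to disk for exact replay
#'
#' Writes the toy model (JSON dialect), the five omics TSVs, the
#' knockout-flux TSV, the planted truth, and a manifest recording the spec
#' and seed.
#'
#' @param model A `metabolic_model`.
#' @param tables Output of [generate_omics_tables()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(model, tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model_json(model, file.path(dir, "model.json"))
  for (nm in c("kcat", "expression", "survival", "cnv", "de",
               "knockout_flux", "truth")) {
    readr::write_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(unclass(tables$spec),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
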