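# Flux balance analysis with total-flux minimisation.
#
# Stage 1 maximises biomass flux subject to steady state (S v = 0) and flux
# bounds. Stage 2 fixes biomass at its optimum (minus a 1e-9 slack against
# numerical infeasibility) and minimises the summed absolute flux, with each
# flux split into non-negative forward and backward parts. The stage-2
# solution is the reported one: a single, reproducible flux distribution.

# stoichiometric matrix: metabolites x reactions, products positive
.stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions
  S <- matrix(0, length(mets), nrow(rxns),
              dimnames = list(mets, rxns$id))
  for (i in seq_len(nrow(rxns))) {
    re <- rxns$reactants[[i]]
    pr <- rxns$products[[i]]
    if (length(re)) S[names(re), i] <- S[names(re), i] - re
    if (length(pr)) S[names(pr), i] <- S[names(pr), i] + pr
  }
  S
}

.flux_solution <- function(flux, objective, status) {
  structure(list(reaction_flux = flux, objective_value = objective,
                 status = status),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status,
      "; biomass flux: ", format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy flux_solution
tidy.flux_solution <- function(x, ...) {
  tibble(reaction = names(x$reaction_flux), flux = unname(x$reaction_flux))
}

# core two-stage solve over explicit bounds (lb, ub named by reaction id)
.two_stage_fba <- function(model, lb, ub, tol = 1e-9, zero_tol = 1e-9) {
  S <- .stoich_matrix(model)
  n <- ncol(S)
  bio <- match(model$biomass_reaction_id, colnames(S))
  obj1 <- numeric(n); obj1[bio] <- 1
  s1 <- simplex_solve(obj1, S, rep(0, nrow(S)), lb, ub, maximize = TRUE,
                      tol = tol)
  if (s1$status != "optimal") {
    return(.flux_solution(setNames(rep(NA_real_, n), colnames(S)),
                          NA_real_, "infeasible"))
  }
  mu <- s1$value
  if (lb[bio] < 0) {
    abort("biomass reaction must be irreversible (lower bound >= 0)",
          class = "metoncokit_config_error")
  }
  # split v = f - b; minimise sum(f) + sum(b) at (near-)optimal biomass
  lo_f <- pmax(lb, 0); hi_f <- pmax(ub, 0)
  lo_b <- pmax(-ub, 0); hi_b <- pmax(-lb, 0)
  lo_f[bio] <- max(lo_f[bio], mu - 1e-9)
  if (hi_f[bio] < lo_f[bio]) hi_f[bio] <- lo_f[bio]
  Aeq <- cbind(S, -S)
  s2 <- simplex_solve(rep(1, 2 * n), Aeq, rep(0, nrow(S)),
                      c(lo_f, lo_b), c(hi_f, hi_b), maximize = FALSE,
                      tol = tol)
  if (s2$status != "optimal") {
    # stage 1 proved feasibility; fall back to its vertex solution
    v <- s1$x
  } else {
    v <- s2$x[seq_len(n)] - s2$x[n + seq_len(n)]
  }
  v[abs(v) < zero_tol] <- 0
  .flux_solution(setNames(v, colnames(S)), unname(v[bio]), "optimal")
}

#' Wild-type flux distribution of a model
#'
#' Runs flux balance analysis, then resolves the usual degeneracy of the
#' optimal flux space by minimising the sum of absolute fluxes at the optimal
#' biomass value (parsimonious FBA). The result is deterministic for a given
#' model.
#'
#' @param model A `metabolic_model` with a bounded feasible region.
#' @param tol Solver pivoting tolerance.
#' @return A `flux_solution`: named `reaction_flux` vector, `objective_value`
#'   (biomass flux) and `status` (`"optimal"` or `"infeasible"`). Fluxes with
#'   magnitude below 1e-9 are reported as exactly zero.
#' @export
wild_type_flux <- function(model, tol = 1e-9) {
  .two_stage_fba(model, setNames(model$reactions$lower_bound,
                                 model$reactions$id),
                 setNames(model$reactions$upper_bound, model$reactions$id),
                 tol = tol)
}

#' Flux distribution after a single-gene deletion
#'
#' Reactions whose gene association evaluates inactive with the gene deleted
#' have their bounds clamped to zero; the two-stage procedure of
#' [wild_type_flux()] is then re-run. A deletion that leaves no feasible
#' steady state returns status `"infeasible"` with an all-zero flux map
#' (a lethal deletion carries no steady-state flux).
#'
#' @param model A `metabolic_model`.
#' @param gene A gene id present in `model$genes`.
#' @param tol Solver pivoting tolerance.
#' @return A `flux_solution`.
#' @export
knockout_flux <- function(model, gene, tol = 1e-9) {
  if (!gene %in% model$genes) {
    abort(paste0("unknown gene '", gene, "'"),
          class = "metoncokit_lookup_error")
  }
  lb <- setNames(model$reactions$lower_bound, model$reactions$id)
  ub <- setNames(model$reactions$upper_bound, model$reactions$id)
  off <- !vapply(model$reactions$gene_association, evaluate_gpr,
                 logical(1), deleted = gene)
  lb[off] <- 0
  ub[off] <- 0
  sol <- .two_stage_fba(model, lb, ub, tol = tol)
  if (sol$status == "infeasible") {
    sol$reaction_flux[] <- 0
    sol$objective_value <- 0
  }
  sol
}

#' Mean flux change per subsystem between two flux solutions
#'
#' For each subsystem of the model, the mean over its member reactions of the
#' knockout-minus-wild-type flux difference. Differences are signed by
#' default so the direction of flux rewiring is preserved; set
#' `absolute = TRUE` for magnitudes. Subsystems with no member reactions get
#' a delta of zero.
#'
#' @param model A `metabolic_model`.
#' @param wild,ko `flux_solution`s over the same reaction set.
#' @param gene Optional gene id recorded in the output row.
#' @param absolute Use `abs(v_ko - v_wt)` instead of the signed difference.
#' @return A one-row tibble: `gene`, `feasible`, then one `flux_*` column per
#'   model subsystem (names sanitised to valid column names).
#' @export
subsystem_flux_deltas <- function(model, wild, ko, gene = NA_character_,
                                  absolute = FALSE) {
  if (!identical(sort(names(wild$reaction_flux)),
                 sort(names(ko$reaction_flux)))) {
    abort("wild-type and knockout solutions cover different reaction sets",
          class = "metoncokit_consistency_error")
  }
  diffs <- ko$reaction_flux[names(wild$reaction_flux)] - wild$reaction_flux
  if (absolute) diffs <- abs(diffs)
  subs <- model$subsystem_list
  vals <- vapply(subs, function(s) {
    members <- model$reactions$id[model$reactions$subsystem == s]
    if (!length(members)) return(0)
    mean(diffs[members])
  }, numeric(1))
  cols <- setNames(as.list(vals), paste0("flux_", gsub("[^A-Za-z0-9]+", "_", subs)))
  as_tibble(c(list(gene = gene, feasible = ko$status == "optimal"), cols))
}

#' Knockout flux features for a set of genes
#'
#' Runs [knockout_flux()] for each gene against a shared wild-type solution
#' and stacks the per-subsystem mean flux differences into a gene-by-subsystem
#' feature table (the "dynamic" feature category). A gene that disables no
#' reaction yields all-zero deltas.
#'
#' @param model A `metabolic_model`.
#' @param genes Genes to delete; defaults to all model genes.
#' @param absolute Passed to [subsystem_flux_deltas()].
#' @param wild Optional precomputed wild-type `flux_solution`.
#' @return A tibble with one row per gene: `gene`, `feasible`, `flux_*`
#'   columns.
#' @export
knockout_feature_table <- function(model, genes = model$genes,
                                   absolute = FALSE, wild = NULL) {
  if (is.null(wild)) wild <- wild_type_flux(model)
  if (wild$status != "optimal") {
    abort("wild-type model is infeasible", class = "metoncokit_config_error")
  }
  purrr::map_dfr(genes, function(g) {
    ko <- knockout_flux(model, g)
    subsystem_flux_deltas(model, wild, ko, gene = g, absolute = absolute)
  })
}

#' Write knockout flux features as TSV
#'
#' @param features Tibble from [knockout_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_knockout_features <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}
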