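# Independent oracles used across the test suite.

# ---- breadth-first search oracle (hand-rolled, independent of igraph) ----
# edges: data.frame(from, to); returns hop count or Inf
bfs_distance <- function(edges, source, target, vertices) {
  if (!source %in% vertices || !target %in% vertices) return(Inf)
  if (source == target) return(0)
  adj <- split(edges$to, edges$from)
  dist <- setNames(rep(Inf, length(vertices)), vertices)
  dist[source] <- 0
  queue <- source
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        if (w == target) return(unname(dist[w]))
        queue <- c(queue, w)
      }
    }
  }
  unname(dist[target])
}

# edge list of a model under the construction rules (independent of
# metabolite_graph): reactant x product per reaction, both ways if reversible
model_edges <- function(model) {
  out <- list()
  for (i in seq_len(nrow(model$reactions))) {
    from <- names(model$reactions$reactants[[i]])
    to <- names(model$reactions$products[[i]])
    if (!length(from) || !length(to)) next
    g <- expand.grid(from = from, to = to, stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- g
    if (model$reactions$reversible[i]) {
      out[[length(out) + 1]] <- data.frame(from = g$to, to = g$from)
    }
  }
  if (!length(out)) return(data.frame(from = character(0), to = character(0)))
  unique(do.call(rbind, out))
}

# ---- linear-programming oracle (scipy HiGHS via python) ----
# problems: list of list(obj, Aeq (matrix), beq, lb, ub, maximize)
# returns list of list(status, value, x)
.lp_oracle_py <- '
import json, sys
import numpy as np
from scipy.optimize import linprog

with open(sys.argv[1]) as fh:
    problems = json.load(fh)
out = []
for p in problems:
    c = np.asarray(p["obj"], float)
    sign = -1.0 if p["maximize"] else 1.0
    A = np.asarray(p["Aeq"], float).reshape(len(p["beq"]), len(c))
    bounds = list(zip(p["lb"], p["ub"]))
    res = linprog(sign * c, A_eq=A, b_eq=np.asarray(p["beq"], float),
                  bounds=bounds, method="highs")
    if res.status == 0:
        out.append({"status": "optimal", "value": float(np.dot(c, res.x)),
                    "x": [float(v) for v in res.x]})
    elif res.status == 2:
        out.append({"status": "infeasible", "value": None, "x": None})
    else:
        out.append({"status": "failed", "value": None, "x": None})
with open(sys.argv[2], "w") as fh:
    json.dump(out, fh)
'

solve_lp_oracle <- function(problems) {
  stopifnot(nzchar(Sys.which("python")))
  script <- tempfile(fileext = ".py")
  writeLines(.lp_oracle_py, script)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  payload <- lapply(problems, function(p) {
    list(obj = p$obj, Aeq = as.numeric(t(p$Aeq)), beq = p$beq,
         lb = p$lb, ub = p$ub, maximize = isTRUE(p$maximize))
  })
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(script, infile, outfile),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}

# stoichiometric matrix + bounds of a model (test-local reimplementation)
model_lp_parts <- function(model, lb = NULL, ub = NULL) {
  mets <- model$metabolites$id
  rxns <- model$reactions
  S <- matrix(0, length(mets), nrow(rxns), dimnames = list(mets, rxns$id))
  for (i in seq_len(nrow(rxns))) {
    re <- rxns$reactants[[i]]; pr <- rxns$products[[i]]
    if (length(re)) S[names(re), i] <- S[names(re), i] - re
    if (length(pr)) S[names(pr), i] <- S[names(pr), i] + pr
  }
  list(S = S,
       lb = if (is.null(lb)) setNames(rxns$lower_bound, rxns$id) else lb,
       ub = if (is.null(ub)) setNames(rxns$upper_bound, rxns$id) else ub,
       bio = match(model$biomass_reaction_id, colnames(S)))
}

# two-stage (max biomass, then min total |v|) problems for the oracle:
# returns the pair of LP problem definitions; stage 2 needs stage 1 result
oracle_stage1_problem <- function(parts) {
  n <- ncol(parts$S)
  obj <- numeric(n); obj[parts$bio] <- 1
  list(obj = obj, Aeq = parts$S, beq = rep(0, nrow(parts$S)),
       lb = unname(parts$lb), ub = unname(parts$ub), maximize = TRUE)
}

oracle_stage2_problem <- function(parts, mu) {
  n <- ncol(parts$S)
  lo <- pmax(parts$lb, 0); hi <- pmax(parts$ub, 0)
  lob <- pmax(-parts$ub, 0); hib <- pmax(-parts$lb, 0)
  lo[parts$bio] <- max(lo[parts$bio], mu - 1e-9)
  if (hi[parts$bio] < lo[parts$bio]) hi[parts$bio] <- lo[parts$bio]
  list(obj = rep(1, 2 * n), Aeq = cbind(parts$S, -parts$S),
       beq = rep(0, nrow(parts$S)),
       lb = unname(c(lo, lob)), ub = unname(c(hi, hib)), maximize = FALSE)
}

# ---- metric formula oracle (straight loops, independent code path) ----
oracle_metrics <- function(truth, pred, classes) {
  n <- length(truth)
  acc <- mean(truth == pred)
  per <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- n - tp - fp - fn
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    list(precision = prec, recall = rec,
         specificity = if (tn + fp == 0) 0 else tn / (tn + fp),
         f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
  })
  tvec <- sapply(classes, function(cl) sum(truth == cl))
  pvec <- sapply(classes, function(cl) sum(pred == cl))
  cdiag <- sum(truth == pred)
  den <- sqrt((n^2 - sum(pvec^2)) * (n^2 - sum(tvec^2)))
  mcc <- if (den == 0) 0 else (cdiag * n - sum(pvec * tvec)) / den
  list(accuracy = acc,
       precision = mean(sapply(per, `[[`, "precision")),
       recall = mean(sapply(per, `[[`, "recall")),
       specificity = mean(sapply(per, `[[`, "specificity")),
       f1 = mean(sapply(per, `[[`, "f1")),
       mcc = mcc)
}

# ---- shared small fixtures ----
# linear chain model: med -> x1 -> ... -> bio, one gene per internal reaction
chain_model <- function(n_internal = 2, ub = 10) {
  internal <- if (n_internal > 0) paste0("x", seq_len(n_internal), "_c") else character(0)
  mets <- tibble::tibble(
    id = c("med1_e", internal, "bio1_c"),
    name = c("med1_e", internal, "bio1_c"),
    compartment = c("e", rep("c", n_internal + 1))
  )
  chain <- c("med1_e", internal, "bio1_c")
  none <- stats::setNames(numeric(0), character(0))
  rxn <- function(id, re, pr, sub, gpr = "", lb = 0, hi = ub) {
    tibble::tibble(id = id, reversible = FALSE, lower_bound = lb,
                   upper_bound = hi, subsystem = sub,
                   gene_association = gpr,
                   reactants = list(re), products = list(pr))
  }
  rxns <- rxn("EX_1", none, stats::setNames(1, "med1_e"), "exchange")
  for (h in seq_len(length(chain) - 1)) {
    rxns <- dplyr::bind_rows(
      rxns, rxn(paste0("R", h), stats::setNames(1, chain[h]),
                stats::setNames(1, chain[h + 1]), "core",
                gpr = paste0("g", h), hi = 100))
  }
  rxns <- dplyr::bind_rows(
    rxns, rxn("BIOMASS", stats::setNames(1, "bio1_c"), none, "biomass",
              hi = 1000))
  metabolic_model(mets, rxns, "BIOMASS", biomass_components = "bio1_c",
                  media_components = "med1_e")
}

# small labelled feature matrix built through the full synthetic pipeline
make_fixture_matrix <- function(seed = 3, ...) {
  spec <- fixture_spec(seed = seed, ...)
  model <- generate_toy_model(spec)
  tables <- generate_omics_tables(model, spec)
  kcatf <- curate_kcat(tables$kcat, model$genes)
  labels <- build_label_set(tables$survival, tables$cnv, tables$de,
                            genes = model$genes)
  profiles <- distance_profiles(model)
  fm <- suppressMessages(
    assemble_feature_matrix(profiles, tables$knockout_flux, kcatf,
                            tables$expression, model = model,
                            labels = labels))
  list(spec = spec, model = model, tables = tables, labels = labels,
       fm = fm)
}
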