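#' Build the directed metabolite graph of a model
#'
#' Every irreversible reaction contributes one unweighted edge from each
#' reactant to each product; reversible reactions contribute both directions.
#' Parallel edges arising from different reactions are collapsed (hop counts
#' are unaffected). All model metabolites are vertices, so disconnected
#' metabolites are represented and simply unreachable.
#'
#' @param model A `metabolic_model`.
#' @param exclude Optional metabolite ids to drop from the graph before edge
#'   construction (e.g., currency metabolites such as protons or water). No
#'   metabolite is excluded by default.
#' @return An `igraph` directed simple graph whose vertex names are
#'   metabolite ids.
#' @export
metabolite_graph <- function(model, exclude = character(0)) {
  rxns <- model$reactions
  edges <- purrr::map_dfr(seq_len(nrow(rxns)), function(i) {
    from <- setdiff(names(rxns$reactants[[i]]), exclude)
    to <- setdiff(names(rxns$products[[i]]), exclude)
    if (!length(from) || !length(to)) return(tibble(from = character(0),
                                                    to = character(0)))
    fwd <- tidyr::expand_grid(from = from, to = to)
    if (rxns$reversible[i]) {
      bind_rows(fwd, tibble(from = fwd$to, to = fwd$from))
    } else {
      fwd
    }
  })
  edges <- distinct(edges)
  verts <- setdiff(model$metabolites$id, exclude)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

# reaction ids whose gene association mentions `gene` (boolean structure
# ignored for topology)
.gene_reaction_ids <- function(model, gene) {
  hits <- vapply(model$reactions$gene_association,
                 function(g) gene %in% gpr_genes(g), logical(1))
  model$reactions$id[hits]
}

# union of product metabolite ids over the gene's reactions
.gene_products <- function(model, gene) {
  ids <- .gene_reaction_ids(model, gene)
  if (!length(ids)) {
    abort(paste0("gene '", gene, "' appears in no gene association"),
          class = "metoncokit_lookup_error")
  }
  idx <- match(ids, model$reactions$id)
  unique(unlist(lapply(model$reactions$products[idx], names)))
}

#' Shortest-path distance between a gene and a model component
#'
#' A gene's network position is anchored at the product metabolites of the
#' reactions it catalyses. In the `to_gene_products` direction (used for
#' media components) the distance is the minimum hop count from the component
#' to any such product; in the `from_gene_products` direction (used for
#' biomass components) it is the minimum hop count from any product to the
#' component. For genes catalysing several reactions the shortest path over
#' all of them is taken.
#'
#' @param model A `metabolic_model`.
#' @param graph Metabolite graph from [metabolite_graph()].
#' @param gene Gene id; must appear in at least one gene association.
#' @param component Metabolite id of a media or biomass component.
#' @param direction `"to_gene_products"` (component to products) or
#'   `"from_gene_products"` (products to component).
#' @return A non-negative integer hop count, or `Inf` when unreachable.
#' @export
gene_component_distance <- function(model, graph, gene, component,
                                    direction = c("to_gene_products",
                                                  "from_gene_products")) {
  direction <- match.arg(direction)
  products <- .gene_products(model, gene)
  vn <- igraph::V(graph)$name
  products <- intersect(products, vn)
  if (!length(products) || !component %in% vn) return(Inf)
  d <- if (direction == "to_gene_products") {
    igraph::distances(graph, v = component, to = products, mode = "out")
  } else {
    igraph::distances(graph, v = component, to = products, mode = "in")
  }
  min(d)
}

#' Epicenter scores for one gene
#'
#' Computes the shortest-path distance from every media component to the
#' gene's reaction products, and from those products to every biomass
#' component, then sums each set: the media epicenter, the biomass epicenter,
#' and their total. Unreachable components enter the sums at a finite
#' sentinel so that scores stay ordinal while penalising disconnection.
#'
#' @param model A `metabolic_model`.
#' @param graph Metabolite graph from [metabolite_graph()].
#' @param gene Gene id.
#' @param unreachable Sentinel distance substituted for unreachable
#'   components; defaults to the number of metabolites plus one (one more
#'   than any realisable hop count).
#' @return A one-row tibble: `gene`, one `media_dist_*` column per media
#'   component, one `biomass_dist_*` column per biomass component, and
#'   `media_epicenter`, `biomass_epicenter`, `total_epicenter`.
#' @export
epicenter_scores <- function(model, graph, gene, unreachable = NULL) {
  distance_profiles(model, genes = gene, graph = graph,
                    unreachable = unreachable)
}

#' Distance profiles and epicenter scores for many genes
#'
#' Vectorised form of [epicenter_scores()]: one row per gene.
#'
#' @inheritParams epicenter_scores
#' @param genes Gene ids to profile; defaults to all model genes.
#' @return A tibble with one row per gene (see [epicenter_scores()]).
#' @export
distance_profiles <- function(model, genes = model$genes,
                              graph = metabolite_graph(model),
                              unreachable = NULL) {
  if (is.null(unreachable)) unreachable <- nrow(model$metabolites) + 1
  vn <- igraph::V(graph)$name
  media <- model$media_components
  biomass <- model$biomass_components
  # media x vertex (paths out of the component) and biomass x vertex (paths
  # into the component) hop-count matrices, computed once
  dist_from <- function(comps, mode) {
    present <- comps %in% vn
    d <- matrix(Inf, length(comps), length(vn),
                dimnames = list(comps, vn))
    if (any(present)) {
      d[comps[present], ] <- igraph::distances(graph, v = comps[present],
                                               to = vn, mode = mode)
    }
    d
  }
  d_med <- dist_from(media, "out")
  d_bio <- dist_from(biomass, "in")
  safe <- function(x) gsub("[^A-Za-z0-9]+", "_", x)
  purrr::map_dfr(genes, function(g) {
    products <- intersect(.gene_products(model, g), vn)
    comp_min <- function(d) {
      if (!length(products)) return(rep(Inf, nrow(d)))
      apply(d[, products, drop = FALSE], 1, min)
    }
    md <- comp_min(d_med)
    bd <- comp_min(d_bio)
    md[!is.finite(md)] <- unreachable
    bd[!is.finite(bd)] <- unreachable
    row <- c(list(gene = g),
             setNames(as.list(md), paste0("media_dist_", safe(media))),
             setNames(as.list(bd), paste0("biomass_dist_", safe(biomass))),
             list(media_epicenter = sum(md),
                  biomass_epicenter = sum(bd),
                  total_epicenter = sum(md) + sum(bd)))
    as_tibble(row)
  })
}

#' Write distance profiles as TSV
#'
#' @param profiles Tibble from [distance_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_profiles <- function(profiles, path) {
  readr::write_tsv(profiles, path)
  invisible(path)
}
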