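#' Construct a constraint-based metabolic model
#'
#' Bundles metabolites, bounded reactions with gene associations, and the
#' declared biomass/media component sets into a validated model object. This is
#' the container every downstream stage (metabolite graph, flux balance
#' analysis, feature assembly) consumes.
#'
#' @param metabolites A data frame with columns `id`, `name`, `compartment`.
#' @param reactions A data frame with columns `id`, `reversible`,
#'   `lower_bound`, `upper_bound`, `subsystem`, `gene_association` (a boolean
#'   expression string over gene ids, possibly empty), and list-columns
#'   `reactants` and `products`, each entry a named numeric vector of positive
#'   stoichiometric coefficients keyed by metabolite id.
#' @param biomass_reaction_id Id of the growth pseudo-reaction.
#' @param biomass_components Metabolite ids entering the biomass objective.
#' @param media_components Metabolite ids supplied by the growth medium.
#' @param genes Optional character vector of gene ids; defaults to the union of
#'   all genes appearing in gene associations.
#'
#' @return An object of class `metabolic_model`: a list with elements
#'   `metabolites`, `reactions` (tibbles), `genes`, `biomass_reaction_id`,
#'   `biomass_components`, `media_components` and `subsystem_list` (sorted
#'   distinct reaction subsystems).
#' @seealso [read_metabolic_model()], [metabolite_graph()], [wild_type_flux()]
#' @export
metabolic_model <- function(metabolites, reactions, biomass_reaction_id,
                            biomass_components, media_components,
                            genes = NULL) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  stopifnot(all(c("id", "name", "compartment") %in% names(metabolites)),
            all(c("id", "reversible", "lower_bound", "upper_bound",
                  "subsystem", "gene_association", "reactants", "products")
                %in% names(reactions)))
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gene_association, gpr_genes))))
  }
  model <- structure(
    list(
      metabolites = metabolites,
      reactions = reactions,
      genes = as.character(genes),
      biomass_reaction_id = biomass_reaction_id,
      biomass_components = as.character(biomass_components),
      media_components = as.character(media_components),
      subsystem_list = sort(unique(reactions$subsystem[nzchar(reactions$subsystem)]))
    ),
    class = "metabolic_model"
  )
  validate_model(model)
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique metabolite ids, non-empty
#' compartments, resolvable species references, consistent flux bounds and
#' reversibility flags, a resolvable biomass reaction, and resolvable
#' biomass/media components. Errors are classed so callers can distinguish
#' parse problems (`metoncokit_parse_error`) from configuration problems
#' (`metoncokit_config_error`).
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly unchanged, if valid.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    abort("duplicate metabolite ids", class = "metoncokit_parse_error")
  }
  if (any(!nzchar(mets$compartment))) {
    abort("metabolite with empty compartment", class = "metoncokit_parse_error")
  }
  if (anyDuplicated(rxns$id)) {
    abort("duplicate reaction ids", class = "metoncokit_parse_error")
  }
  for (i in seq_len(nrow(rxns))) {
    refs <- c(names(rxns$reactants[[i]]), names(rxns$products[[i]]))
    bad <- setdiff(refs, mets$id)
    if (length(bad)) {
      abort(
        paste0("reaction '", rxns$id[i], "' references unknown metabolite(s): ",
               paste(bad, collapse = ", ")),
        class = "metoncokit_parse_error"
      )
    }
    coefs <- c(rxns$reactants[[i]], rxns$products[[i]])
    if (length(coefs) && any(coefs <= 0)) {
      abort(paste0("reaction '", rxns$id[i], "' has non-positive stoichiometry"),
            class = "metoncokit_parse_error")
    }
  }
  if (any(rxns$lower_bound > rxns$upper_bound)) {
    abort("reaction with lower_bound > upper_bound",
          class = "metoncokit_parse_error")
  }
  if (any(rxns$reversible != (rxns$lower_bound < 0))) {
    abort("reversible flag inconsistent with lower_bound < 0",
          class = "metoncokit_parse_error")
  }
  if (!model$biomass_reaction_id %in% rxns$id) {
    abort(paste0("biomass reaction '", model$biomass_reaction_id,
                 "' not found in model"),
          class = "metoncokit_config_error")
  }
  bad_bio <- setdiff(model$biomass_components, mets$id)
  bad_med <- setdiff(model$media_components, mets$id)
  if (length(bad_bio) || length(bad_med)) {
    abort(paste0("unresolvable component(s): ",
                 paste(c(bad_bio, bad_med), collapse = ", ")),
          class = "metoncokit_config_error")
  }
  gpr_all <- unique(unlist(lapply(rxns$gene_association, gpr_genes)))
  missing_genes <- setdiff(gpr_all, model$genes)
  if (length(missing_genes)) {
    abort(paste0("gene(s) in associations but not in gene set: ",
                 paste(missing_genes, collapse = ", ")),
          class = "metoncokit_parse_error")
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ", length(x$genes), " genes\n",
      "  biomass: ", x$biomass_reaction_id,
      " (", length(x$biomass_components), " components); media: ",
      length(x$media_components), " components; ",
      length(x$subsystem_list), " subsystems\n", sep = "")
  invisible(x)
}

#' Read a metabolic model from SBML or the toy JSON dialect
#'
#' Dispatches on file extension: `.json` is parsed as the toy-model dialect
#' (see [write_model_json()]); anything else is parsed as SBML Level 3 with
#' the flux-bounds and gene-association (fbc) extensions.
#'
#' @param path Path to the model document.
#' @param ... Passed to [parse_model_sbml()] for SBML input.
#' @return A validated `metabolic_model`.
#' @export
read_metabolic_model <- function(path, ...) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    parse_model_json(path)
  } else {
    parse_model_sbml(path, ...)
  }
}

#' Parse the toy-model JSON dialect
#'
#' The dialect is a single JSON object with keys `metabolites` (array of
#' `{id, name, compartment}`), `reactions` (array of `{id, reactants,
#' products, reversible, lower_bound, upper_bound, subsystem,
#' gene_association}`, where `reactants`/`products` are objects mapping
#' metabolite id to positive coefficient), `biomass_reaction`,
#' `biomass_components` and `media_components`.
#'
#' @param path Path to a JSON document.
#' @return A validated `metabolic_model`.
#' @export
parse_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("metabolites", "reactions", "biomass_reaction",
            "biomass_components", "media_components")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    abort(paste0("model document missing key(s): ", paste(miss, collapse = ", ")),
          class = "metoncokit_parse_error")
  }
  mets <- purrr::map_dfr(doc$metabolites, function(m) {
    tibble(id = m$id %||% abort("metabolite without id",
                                class = "metoncokit_parse_error"),
           name = m$name %||% m$id,
           compartment = m$compartment %||% "c")
  })
  side <- function(x) {
    if (is.null(x) || !length(x)) return(setNames(numeric(0), character(0)))
    setNames(vapply(x, as.numeric, numeric(1)), names(x))
  }
  rxns <- purrr::map_dfr(doc$reactions, function(r) {
    lb <- as.numeric(r$lower_bound %||% 0)
    ub <- as.numeric(r$upper_bound %||% 1000)
    tibble(id = r$id %||% abort("reaction without id",
                                class = "metoncokit_parse_error"),
           reversible = as.logical(r$reversible %||% (lb < 0)),
           lower_bound = lb, upper_bound = ub,
           subsystem = as.character(r$subsystem %||% ""),
           gene_association = as.character(r$gene_association %||% ""),
           reactants = list(side(r$reactants)),
           products = list(side(r$products)))
  })
  metabolic_model(mets, rxns,
                  biomass_reaction_id = doc$biomass_reaction,
                  biomass_components = unlist(doc$biomass_components),
                  media_components = unlist(doc$media_components))
}

#' Write a model in the toy JSON dialect
#'
#' Inverse of [parse_model_json()]: a model written and re-read round-trips to
#' an identical object.
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  side <- function(x) if (length(x)) as.list(x) else structure(list(), names = character(0))
  doc <- list(
    metabolites = purrr::pmap(model$metabolites, function(id, name, compartment) {
      list(id = id, name = name, compartment = compartment)
    }),
    reactions = purrr::pmap(model$reactions, function(id, reversible, lower_bound,
                                                      upper_bound, subsystem,
                                                      gene_association,
                                                      reactants, products) {
      list(id = id, reactants = side(reactants), products = side(products),
           reversible = reversible, lower_bound = lower_bound,
           upper_bound = upper_bound, subsystem = subsystem,
           gene_association = gene_association)
    }),
    biomass_reaction = model$biomass_reaction_id,
    biomass_components = as.list(model$biomass_components),
    media_components = as.list(model$media_components)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Parse an SBML Level 3 model with fbc extensions
#'
#' A minimal reader for SBML documents carrying flux bounds (via fbc bound
#' parameters or reaction-level attributes) and gene-product associations.
#' Reaction subsystems are taken from a `SUBSYSTEM:` line in the reaction
#' notes when present. The biomass reaction defaults to the active fbc
#' objective; biomass components default to the biomass reaction's reactants;
#' media components default to metabolites touched by exchange (single-sided)
#' reactions.
#'
#' @param path Path to an SBML file.
#' @param biomass_reaction_id Override for the biomass reaction id.
#' @param biomass_components,media_components Optional overrides for the
#'   declared component sets.
#' @return A validated `metabolic_model`.
#' @export
parse_model_sbml <- function(path, biomass_reaction_id = NULL,
                             biomass_components = NULL,
                             media_components = NULL) {
  doc <- xml2::read_xml(path)
  q <- function(node, xp) xml2::xml_find_all(node, xp)
  attr1 <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) NULL else v
  }
  sp <- q(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (!length(sp)) {
    abort("SBML document has no species", class = "metoncokit_parse_error")
  }
  mets <- purrr::map_dfr(sp, function(s) {
    tibble(id = xml2::xml_attr(s, "id"),
           name = attr1(s, "name") %||% xml2::xml_attr(s, "id"),
           compartment = attr1(s, "compartment") %||% "c")
  })
  pars <- q(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))
  # map fbc geneProduct ids to labels when present
  gps <- q(doc, ".//*[local-name()='geneProduct']")
  gp_map <- setNames(
    ifelse(is.na(xml2::xml_attr(gps, "label")),
           xml2::xml_attr(gps, "id"), xml2::xml_attr(gps, "label")),
    xml2::xml_attr(gps, "id"))

  assoc_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      return(if (!is.na(ref) && ref %in% names(gp_map)) gp_map[[ref]] else ref)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, assoc_to_string, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx_nodes <- q(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  side_of <- function(rn, which) {
    refs <- q(rn, paste0("./*[local-name()='", which,
                         "']/*[local-name()='speciesReference']"))
    if (!length(refs)) return(setNames(numeric(0), character(0)))
    coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    coef[is.na(coef)] <- 1
    setNames(coef, xml2::xml_attr(refs, "species"))
  }
  rxns <- purrr::map_dfr(rx_nodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    rev <- identical(attr1(rn, "reversible"), "true")
    lb_ref <- attr1(rn, "lowerFluxBound")
    ub_ref <- attr1(rn, "upperFluxBound")
    lb <- if (!is.null(lb_ref) && lb_ref %in% names(parval)) parval[[lb_ref]]
          else if (rev) -1000 else 0
    ub <- if (!is.null(ub_ref) && ub_ref %in% names(parval)) parval[[ub_ref]]
          else 1000
    assoc_node <- q(rn, ".//*[local-name()='geneProductAssociation']/*")
    gpr <- if (length(assoc_node)) assoc_to_string(assoc_node[[1]]) else ""
    notes <- xml2::xml_text(q(rn, ".//*[local-name()='notes']"))
    sub <- ""
    if (length(notes)) {
      m <- regmatches(notes[1],
                      regexpr("SUBSYSTEM:[ \t]*[^<\n]*", notes[1]))
      if (length(m)) sub <- trimws(sub("SUBSYSTEM:\\s*", "", m))
    }
    tibble(id = id, reversible = lb < 0, lower_bound = lb, upper_bound = ub,
           subsystem = sub, gene_association = gpr,
           reactants = list(side_of(rn, "listOfReactants")),
           products = list(side_of(rn, "listOfProducts")))
  })

  if (is.null(biomass_reaction_id)) {
    fo <- q(doc, ".//*[local-name()='fluxObjective']")
    if (length(fo)) {
      biomass_reaction_id <- xml2::xml_attr(fo[[1]], "reaction")
    } else {
      hit <- grep("biomass", rxns$id, ignore.case = TRUE, value = TRUE)
      if (!length(hit)) {
        abort("no biomass reaction declared (no fbc objective, no id match)",
              class = "metoncokit_config_error")
      }
      biomass_reaction_id <- hit[1]
    }
  }
  if (is.null(biomass_components)) {
    i <- match(biomass_reaction_id, rxns$id)
    biomass_components <- if (!is.na(i)) names(rxns$reactants[[i]]) else character(0)
  }
  if (is.null(media_components)) {
    one_sided <- vapply(seq_len(nrow(rxns)), function(i) {
      xor(length(rxns$reactants[[i]]) == 0, length(rxns$products[[i]]) == 0)
    }, logical(1))
    one_sided[match(biomass_reaction_id, rxns$id)] <- FALSE
    media_components <- sort(unique(unlist(
      lapply(which(one_sided), function(i) {
        c(names(rxns$reactants[[i]]), names(rxns$products[[i]]))
      }))))
  }
  metabolic_model(mets, rxns, biomass_reaction_id,
                  biomass_components, media_components)
}
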