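# Metabolite graph construction and shortest-path epicenter scores.

test_that("edge construction follows the reactant-to-product rule", {
  mets <- tibble::tibble(id = c("A", "B", "C"), name = c("A", "B", "C"),
                         compartment = "c")
  rxn <- function(id, re, pr, rev = FALSE) {
    tibble::tibble(id = id, reversible = rev,
                   lower_bound = if (rev) -10 else 0, upper_bound = 10,
                   subsystem = "s", gene_association = "g1",
                   reactants = list(re), products = list(pr))
  }
  none <- stats::setNames(numeric(0), character(0))
  base <- dplyr::bind_rows(
    rxn("EX", none, c(A = 1)),
    rxn("BIO", c(C = 1), none)
  )

  # irreversible A + B -> C gives exactly A->C and B->C
  m1 <- metabolic_model(mets, dplyr::bind_rows(base, rxn("R1", c(A = 1, B = 1), c(C = 1))),
                        "BIO", "C", "A")
  g1 <- metabolite_graph(m1)
  el <- igraph::as_data_frame(g1)
  expect_setequal(paste(el$from, el$to), c("A C", "B C"))

  # reversible A <-> B gives both directions
  m2 <- metabolic_model(mets, dplyr::bind_rows(base, rxn("R1", c(A = 1), c(B = 1), rev = TRUE)),
                        "BIO", "C", "A")
  el2 <- igraph::as_data_frame(metabolite_graph(m2))
  expect_setequal(paste(el2$from, el2$to), c("A B", "B A"))

  # a model whose reactions are all one-sided has no edges
  m3 <- metabolic_model(mets, base, "BIO", "C", "A")
  expect_equal(igraph::ecount(metabolite_graph(m3)), 0)
})

test_that("edge count matches the combinatorial formula with duplicates collapsed", {
  for (seed in 1:5) {
    spec <- fixture_spec(seed = seed, n_metabolites = 15, n_reactions = 14,
                         n_genes = 7, signal_features = character(0),
                         effect_size = 0)
    model <- generate_toy_model(spec)
    g <- metabolite_graph(model)
    pairs <- unlist(lapply(seq_len(nrow(model$reactions)), function(i) {
      from <- names(model$reactions$reactants[[i]])
      to <- names(model$reactions$products[[i]])
      if (!length(from) || !length(to)) return(character(0))
      fwd <- as.vector(outer(from, to, paste))
      if (model$reactions$reversible[i]) c(fwd, as.vector(outer(to, from, paste)))
      else fwd
    }))
    expect_equal(igraph::ecount(g), length(unique(pairs)))
  }
})

test_that("distances match an independent breadth-first-search oracle", {
  for (seed in 1:10) {
    spec <- fixture_spec(seed = 200 + seed,
                         n_metabolites = sample(10:30, 1),
                         n_reactions = sample(12:28, 1), n_genes = 8,
                         n_media = 2, n_biomass = 3,
                         signal_features = character(0), effect_size = 0)
    model <- generate_toy_model(spec)
    g <- metabolite_graph(model)
    edges <- model_edges(model)
    verts <- model$metabolites$id
    for (gene in sample(model$genes, 3)) {
      prods <- unique(unlist(lapply(
        which(vapply(model$reactions$gene_association,
                     function(x) gene %in% gpr_genes(x), logical(1))),
        function(i) names(model$reactions$products[[i]]))))
      for (comp in c(model$media_components, model$biomass_components[1])) {
        d_med <- gene_component_distance(model, g, gene, comp,
                                         "to_gene_products")
        exp_med <- min(vapply(prods, function(p) {
          bfs_distance(edges, comp, p, verts)
        }, numeric(1)))
        expect_equal(d_med, exp_med, info = paste(seed, gene, comp, "media"))
        d_bio <- gene_component_distance(model, g, gene, comp,
                                         "from_gene_products")
        exp_bio <- min(vapply(prods, function(p) {
          bfs_distance(edges, p, comp, verts)
        }, numeric(1)))
        expect_equal(d_bio, exp_bio, info = paste(seed, gene, comp, "biomass"))
      }
    }
  }
})

test_that("chain distances follow the worked single-path examples", {
  # med -> x1 -> x2 -> bio ; gene g1 catalyses med -> x1
  model <- chain_model(n_internal = 2)
  g <- metabolite_graph(model)
  # media direction: distance from med to g1 product x1 is 1
  expect_equal(gene_component_distance(model, g, "g1", "med1_e",
                                       "to_gene_products"), 1)
  # biomass direction: x1 -> x2 -> bio is 2 hops
  expect_equal(gene_component_distance(model, g, "g1", "bio1_c",
                                       "from_gene_products"), 2)
})

test_that("epicenter sums recompute from the per-component distances", {
  lst <- make_fixture_matrix(seed = 5, n_metabolites = 20, n_reactions = 18,
                             n_genes = 9, n_media = 2, n_biomass = 3,
                             signal_features = character(0), effect_size = 0)
  dp <- distance_profiles(lst$model)
  med_cols <- grep("^media_dist_", names(dp), value = TRUE)
  bio_cols <- grep("^biomass_dist_", names(dp), value = TRUE)
  expect_equal(length(med_cols), 2)
  expect_equal(length(bio_cols), 3)
  expect_equal(dp$media_epicenter, rowSums(dp[med_cols]))
  expect_equal(dp$biomass_epicenter, rowSums(dp[bio_cols]))
  expect_equal(dp$total_epicenter, dp$media_epicenter + dp$biomass_epicenter)
  expect_true(all(as.matrix(dp[c(med_cols, bio_cols)]) >= 0))
})

test_that("unreachable components enter sums at the sentinel value", {
  # med -> x1 -> bio, but an isolated metabolite is declared in biomass
  mets <- tibble::tibble(id = c("m_e", "x_c", "b_c", "iso_c"),
                         name = id <- c("m_e", "x_c", "b_c", "iso_c"),
                         compartment = c("e", "c", "c", "c"))
  none <- stats::setNames(numeric(0), character(0))
  rxns <- dplyr::bind_rows(
    tibble::tibble(id = "EX", reversible = FALSE, lower_bound = 0,
                   upper_bound = 10, subsystem = "exchange",
                   gene_association = "",
                   reactants = list(none), products = list(c(m_e = 1))),
    tibble::tibble(id = "R1", reversible = FALSE, lower_bound = 0,
                   upper_bound = 10, subsystem = "core",
                   gene_association = "g1",
                   reactants = list(c(m_e = 1)), products = list(c(x_c = 1))),
    tibble::tibble(id = "R2", reversible = FALSE, lower_bound = 0,
                   upper_bound = 10, subsystem = "core",
                   gene_association = "g2",
                   reactants = list(c(x_c = 1)), products = list(c(b_c = 1))),
    tibble::tibble(id = "BIO", reversible = FALSE, lower_bound = 0,
                   upper_bound = 100, subsystem = "biomass",
                   gene_association = "",
                   reactants = list(c(b_c = 1)), products = list(none))
  )
  model <- metabolic_model(mets, rxns, "BIO",
                           biomass_components = c("b_c", "iso_c"),
                           media_components = "m_e")
  g <- metabolite_graph(model)
  sentinel <- nrow(model$metabolites) + 1
  prof <- epicenter_scores(model, g, "g1")
  expect_equal(prof$biomass_dist_iso_c, sentinel)
  expect_equal(prof$biomass_epicenter,
               prof$biomass_dist_b_c + sentinel)
  # configurable sentinel
  prof2 <- epicenter_scores(model, g, "g1", unreachable = 99)
  expect_equal(prof2$biomass_dist_iso_c, 99)
  # raw distance lookup reports Inf
  expect_equal(gene_component_distance(model, g, "g1", "iso_c",
                                       "from_gene_products"), Inf)
})

test_that("adding a reversible duplicate reaction never increases distances", {
  for (seed in 1:5) {
    spec <- fixture_spec(seed = 300 + seed, n_metabolites = 15,
                         n_reactions = 14, n_genes = 7, n_media = 2,
                         n_biomass = 2, signal_features = character(0),
                         effect_size = 0)
    model <- generate_toy_model(spec)
    dp1 <- distance_profiles(model)
    # duplicate a random irreversible internal reaction as reversible
    irrev <- which(!model$reactions$reversible &
                     lengths(model$reactions$reactants) > 0 &
                     lengths(model$reactions$products) > 0)
    set.seed(seed)
    i <- sample(irrev, 1)
    dup <- model$reactions[i, ]
    dup$id <- "DUP"
    dup$reversible <- TRUE
    dup$lower_bound <- -10
    model2 <- metabolic_model(model$metabolites,
                              dplyr::bind_rows(model$reactions, dup),
                              model$biomass_reaction_id,
                              model$biomass_components,
                              model$media_components)
    dp2 <- distance_profiles(model2, genes = model$genes)
    dist_cols <- grep("_dist_", names(dp1), value = TRUE)
    expect_true(all(as.matrix(dp2[dist_cols]) <= as.matrix(dp1[dist_cols])))
  }
})

test_that("a gene absent from every association raises a lookup error", {
  model <- chain_model()
  g <- metabolite_graph(model)
  expect_error(gene_component_distance(model, g, "ghost", "med1_e",
                                       "to_gene_products"),
               class = "metoncokit_lookup_error")
})
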