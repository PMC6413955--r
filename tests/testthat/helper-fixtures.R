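# Shared fixtures. Pipeline runs on the default 20-cell fixture are
# memoized per (mode, seed, medium variant): several test files reuse them
# and each run costs a few LP batches.

toy_net <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- make_toy_network()
    net
  }
})

chain_net <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- make_toy_network("chain")
    net
  }
})

# the spec's counting example: 5 metabolites / 8 internal / 3 exchanges
counting_net <- function() {
  template_network(
    metabolites = c("a_e", "a", "b", "c", "biomass_met"),
    reactions = list(
      list(id = "T1", stoich = c(a_e = -1, a = 1)),
      list(id = "R1", stoich = c(a = -1, b = 1), gpr = "g1 and g2"),
      list(id = "R2", stoich = c(a = -1, b = 1), gpr = "g3"),
      list(id = "R3", stoich = c(b = -1, c = 1), reversible = TRUE,
           gpr = "g1 or g4"),
      list(id = "R4", stoich = c(b = -2, c = 1), gpr = "(g1 and g2) or g5"),
      list(id = "R5", stoich = c(c = -1, a = 1)),
      list(id = "R6", stoich = c(c = -2, b = 1)),
      list(id = "BIOMASS", stoich = c(c = -1, biomass_met = 1), gpr = "g6"),
      list(id = "EX_a", stoich = c(a_e = -1), reversible = TRUE),
      list(id = "EX_c", stoich = c(c = -1), reversible = TRUE),
      list(id = "EX_biomass", stoich = c(biomass_met = -1))
    ),
    biomass_reaction_id = "BIOMASS")
}

# random structural network (no LP use): for dimension-formula properties
random_structural_net <- function(m_int = NULL, n_int = NULL, n_ext = NULL) {
  m_int <- if (is.null(m_int)) sample(2:8, 1) else m_int
  n_int <- if (is.null(n_int)) sample(2:10, 1) else n_int
  n_ext <- if (is.null(n_ext)) sample(1:min(4, m_int), 1) else n_ext
  mets <- c(paste0("m", seq_len(m_int)), "biomass_met")
  ex_species <- c(sample(paste0("m", seq_len(m_int)), n_ext - 1), "biomass_met")
  rxns <- lapply(seq_len(n_int - 1), function(i) {
    pair <- sample(mets, 2)
    list(id = paste0("r", i),
         stoich = stats::setNames(c(-1, 1), pair),
         reversible = stats::runif(1) < 0.3)
  })
  rxns <- c(rxns, list(list(
    id = "BIOMASS",
    stoich = stats::setNames(c(-1, 1), c(sample(setdiff(mets, "biomass_met"), 1),
                                         "biomass_met")))))
  ex <- lapply(ex_species, function(sp) {
    list(id = paste0("EX_", sp), stoich = stats::setNames(-1, sp),
         reversible = TRUE)
  })
  template_network(metabolites = mets, reactions = c(rxns, ex),
                   biomass_reaction_id = "BIOMASS")
}

fixture_run_cache <- new.env(parent = emptyenv())

# memoized pipeline run on the default 20-cell fixture
fixture_run <- function(mode = "scFBA", seed = 7, palm_uptake = FALSE,
                        n_cells = 20) {
  key <- paste(mode, seed, palm_uptake, n_cells, sep = "|")
  if (!is.null(fixture_run_cache[[key]])) return(fixture_run_cache[[key]])
  net <- toy_net()
  data <- simulate_expression(net, fixture_spec(n_cells = n_cells, seed = seed))
  medium <- if (palm_uptake) {
    toy_medium(n_cells, extra_uptake = c(palm_e = 100))
  } else {
    toy_medium(n_cells)
  }
  cfg <- run_config(model = net, expression = data, medium = medium,
                    mode = mode, min_genes = 1, seed = seed)
  res <- suppressWarnings(run_pipeline(cfg))
  res$truth <- attr(data, "labels")
  res$data <- data
  fixture_run_cache[[key]] <- res
  res
}

expect_close <- function(actual, expected, tol = 1e-9) {
  testthat::expect_lt(abs(actual - expected), tol)
}
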