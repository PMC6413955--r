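test_that("assembled matrix matches the population size formula", {
  # the worked example: M=5, N=8, N_ext=3, n_cells=4, N_blood=2 -> 22 x 46
  net <- counting_net()
  model <- build_population_model(net, 4,
                                  blood_metabolites = c("a_e", "biomass_met"))
  expect_equal(dim(model$S), c(4 * 5 + 2, 4 * (8 + 3) + 2))
  # randomized structural property
  set.seed(99)
  for (i in 1:25) {
    rnet <- random_structural_net()
    nc <- sample(1:6, 1)
    m <- build_population_model(rnet, nc)
    M <- n_metabolites(rnet); N <- n_internal(rnet); Nx <- n_exchanges(rnet)
    Nb <- length(m$blood_species)
    expect_equal(dim(m$S), c(nc * M + Nb, nc * (N + Nx) + Nb))
  }
})

test_that("cooperation and blood columns carry the stated stoichiometry", {
  net <- toy_net()
  model <- build_population_model(net, 3)
  # cooperation column for (cell 2, glucose): -1 at the cell row, +1 at TME
  col <- model$S[, "EX_glc_cell2"]
  nz <- col[col != 0]
  expect_equal(sort(unname(nz)), c(-1, 1))
  expect_setequal(names(nz), c("glc_e_cell2", "glc_e_TME"))
  # all blood-backed cooperation columns: exactly 2 nonzeros; blood: exactly 1
  coop <- model$columns$col[model$columns$kind == "cooperation" &
                              model$columns$species %in% model$blood_species]
  expect_true(all(Matrix::colSums(model$S[, coop, drop = FALSE] != 0) == 2))
  blood <- model$columns$col[model$columns$kind == "blood"]
  expect_true(all(Matrix::colSums(model$S[, blood, drop = FALSE] != 0) == 1))
  # each cell block replicates the template stoichiometry
  for (rid in c("GLYC", "BIOMASS")) {
    st <- net$reactions[[rid]]$stoich
    for (cc in 1:3) {
      col <- model$S[, paste0(rid, "_cell", cc)]
      got <- col[col != 0]
      expect_equal(got[paste0(names(st), "_cell", cc)],
                   stats::setNames(unname(st), paste0(names(st), "_cell", cc)))
    }
  }
})

test_that("species without a blood exchange are closed, not dangling", {
  net <- toy_net()
  model <- build_population_model(net, 2,
                                  blood_metabolites = c("glc_e", "o2_e"))
  # biomass is auto-added
  expect_true("biomass_met" %in% model$blood_species)
  closed <- model$columns$col[model$columns$kind == "cooperation" &
                                !model$columns$species %in% model$blood_species]
  expect_true(length(closed) > 0)
  expect_true(all(model$lb[closed] == 0 & model$ub[closed] == 0))
  expect_error(build_population_model(net, 2, blood_metabolites = "unobtainium"),
               "no exchanged counterpart")
})

test_that("a 1-cell population equals the template (LP oracle)", {
  net <- chain_net()
  model <- build_population_model(net, 1)
  model <- apply_medium(model, medium_spec(uptake = c(n_e = 10), n_pop = 1))
  sol <- optimize_population(model, need_x = FALSE)
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  # independent oracle on the same LP
  orc <- oracle_optimize(model)
  expect_equal(sol$objective_value, orc$objective, tolerance = 1e-7)
})

test_that("the medium scales, closes and opens blood exchanges as specified", {
  net <- toy_net()
  model <- build_population_model(net, 34)
  medium <- toy_medium(n_pop = 34)
  m <- apply_medium(model, medium)
  # population uptake bound = N_pop * 100 nmol/h
  expect_equal(unname(m$lb["B_glc_e"]), -3400)
  expect_equal(unname(m$ub["B_glc_e"]), 0)       # uptake-only species
  expect_equal(unname(m$lb["B_lac_e"]), 0)       # secretable
  expect_true(is.infinite(m$ub["B_lac_e"]))
  expect_equal(unname(m$ub["B_biomass_met"]), Inf)
  expect_equal(unname(m$lb["B_palm_e"]), 0)      # not in medium: closed
  expect_equal(unname(m$ub["B_palm_e"]), 0)
  # closing oxygen: omit it from the uptake set
  m2 <- apply_medium(model, medium_spec(uptake = c(glc_e = 100), n_pop = 34))
  expect_equal(unname(m2$lb["B_o2_e"]), 0)
  expect_equal(unname(m2$ub["B_o2_e"]), 0)
  expect_error(apply_medium(model, medium_spec(uptake = c(nope = 1), n_pop = 1)),
               "without a blood exchange")
})
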