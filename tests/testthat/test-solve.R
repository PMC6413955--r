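test_that("population optimum matches the vertex-enumeration oracle", {
  net <- chain_net()
  model <- build_population_model(net, 2)
  model <- apply_medium(model, medium_spec(uptake = c(n_e = 6), n_pop = 2))
  sol <- optimize_population(model, need_x = FALSE)
  orc <- oracle_optimize(model)
  expect_equal(sol$objective_value, orc$objective, tolerance = 1e-7)
  expect_equal(sol$objective_value, 12, tolerance = 1e-9)  # hand-solved
  # closing all uptakes zeroes the optimum
  closed <- apply_medium(model, medium_spec(uptake = c(n_e = 0), n_pop = 2))
  expect_equal(optimize_population(closed, need_x = FALSE)$objective_value, 0,
               tolerance = 1e-9)
})

test_that("optimum is invariant under cell relabeling and reproducible", {
  res <- fixture_run("scFBA", seed = 7)
  again <- suppressWarnings(run_pipeline(res$config))
  expect_equal(res$solution$objective_value, again$solution$objective_value,
               tolerance = 1e-12)
  # popFBA: permuting identical cells cannot change the optimum
  net <- toy_net()
  m1 <- apply_medium(build_population_model(net, 3), toy_medium(3))
  v1 <- optimize_population(m1, need_x = FALSE)$objective_value
  # rebuilding is itself a permutation of identical blocks
  m2 <- apply_medium(build_population_model(net, 3), toy_medium(3))
  expect_equal(v1, optimize_population(m2, need_x = FALSE)$objective_value,
               tolerance = 1e-9)
})

test_that("solution flux vectors satisfy mass balance and bounds", {
  res <- fixture_run("scFBA", seed = 7)
  v <- res$solution$v
  resid <- as.numeric(res$model$S %*% v)
  expect_lt(max(abs(resid)), 1e-6)
  expect_true(all(v >= res$model$lb - 1e-6 & v <= res$model$ub + 1e-6))
})

test_that("per-cell spans: popFBA full range, scFBA collapse, 1 cell trivial", {
  pop <- fixture_run("popFBA", seed = 7)
  span_pop <- per_cell_biomass_span(pop$model)
  expect_true(all(span_pop$frac_min < 1e-6))
  expect_true(all(span_pop$frac_max > 1 - 1e-6))
  sc <- fixture_run("scFBA", seed = 7)
  span_sc <- per_cell_biomass_span(sc$model)
  width <- (span_sc$max - span_sc$min) / attr(span_sc, "total")
  expect_lt(max(width), 1e-6)
  # a single-cell model spans exactly the total
  one <- build_population_model(chain_net(), 1)
  one <- apply_medium(one, medium_spec(uptake = c(n_e = 5), n_pop = 1))
  s1 <- per_cell_biomass_span(one)
  expect_equal(s1$min, attr(s1, "total"), tolerance = 1e-6)
  expect_equal(s1$max, attr(s1, "total"), tolerance = 1e-6)
})

test_that("gene deletion logic: essentials, isoform redundancy, bounds", {
  sc <- fixture_run("scFBA", seed = 7)
  rep <- single_gene_deletion(sc$model)
  expect_true(all(rep$grRatio >= 0 & rep$grRatio <= 1))
  # ATPM never carries optimal flux, so losing it changes nothing
  expect_gt(rep$grRatio[rep$gene == "atpm1"], 1 - 1e-6)
  # a gene absent from every GPR cannot move the optimum
  rep_none <- single_gene_deletion(sc$model, genes = "not_a_gene")
  expect_identical(rep_none$grRatio, 1)
  # sole catalyst of the only glucose entry after bulk pruning: lethal
  expect_lt(rep$grRatio[rep$gene == "glut1"], 0.05)
  # the same deletion is harmless in popFBA (glut2 still counts)
  pop <- fixture_run("popFBA", seed = 7)
  rep_pop <- single_gene_deletion(pop$model, genes = c("glut1", "gapdh"))
  expect_equal(rep_pop$grRatio[rep_pop$gene == "glut1"], 1)
  expect_equal(rep_pop$grRatio[rep_pop$gene == "gapdh"], 0)
})

test_that("cooperation knockout: <1 heterogeneous, =1 homogeneous, <=1 always", {
  sc <- fixture_run("scFBA", seed = 7)
  ck <- cooperation_knockout_ratio(sc$model)
  expect_lt(ck$ratio, 1)
  expect_gt(ck$ratio, 0)
  # identical cells: the symmetric optimum never needs TME uptake
  net <- toy_net()
  hdata <- simulate_expression(net, fixture_spec(
    n_cells = 8, n_subpops = 1, dropout_rate = 0, noise_sdlog = 0, seed = 1))
  hcfg <- run_config(model = net, expression = hdata, medium = toy_medium(8),
                     mode = "scFBA", min_genes = 1)
  hres <- suppressWarnings(run_pipeline(hcfg))
  hck <- cooperation_knockout_ratio(hres$model)
  expect_equal(hck$ratio, 1, tolerance = 1e-9)
  # ATP objective variant runs and stays in (0, 1]
  atp <- cooperation_knockout_ratio(sc$model, objective = "atp")
  expect_lte(atp$ratio, 1 + 1e-9)
  expect_gt(atp$ratio, 0)
})

test_that("cooperation flux ranges are reported rather than a single vertex", {
  sc <- fixture_run("scFBA", seed = 7)
  cr <- cooperation_flux_ranges(sc$model, species = "lac_e")
  expect_equal(nrow(cr), sc$model$n_cells)
  expect_true(all(cr$max >= cr$min - 1e-9))
})
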