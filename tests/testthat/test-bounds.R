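chain_model <- function(n_cells = 1, uptake = 10) {
  model <- build_population_model(chain_net(), n_cells)
  apply_medium(model, medium_spec(uptake = c(n_e = uptake),
                                  n_pop = n_cells))
}

test_that("capacities solve the linear chain by hand (FVA oracle)", {
  # uptake <= 10 feeding T -> C1 -> BIOMASS: every step has capacity 10
  m <- chain_model(1, uptake = 10)
  caps <- compute_flux_capacities(m)
  for (rid in c("T", "C1", "BIOMASS", "EX_n", "EX_biomass")) {
    expect_equal(caps$F[caps$template_id == rid], 10, tolerance = 1e-9,
                 info = rid)
  }
  # backward extreme of the uptake cooperation is the uptake bound
  expect_equal(caps$f_backward[caps$template_id == "EX_n"], -10,
               tolerance = 1e-9)
  # unreachable reaction: closed uptake gives zero capacity everywhere
  m0 <- apply_medium(build_population_model(chain_net(), 1),
                     medium_spec(uptake = c(n_e = 0), n_pop = 1))
  caps0 <- compute_flux_capacities(m0)
  expect_true(all(caps0$F[caps0$template_id %in%
                            c("T", "C1", "BIOMASS")] == 0))
})

test_that("an isolated reversible loop is bounded by template defaults", {
  net <- template_network(
    metabolites = c("u_e", "p", "q"),
    reactions = list(
      list(id = "L1", stoich = c(p = -1, q = 1), reversible = TRUE,
           lb = -7, ub = 7, gpr = "gl1"),
      list(id = "L2", stoich = c(q = -1, p = 1), reversible = TRUE,
           lb = -7, ub = 7, gpr = "gl2"),
      list(id = "EX_u", stoich = c(u_e = -1), reversible = TRUE)))
  m <- apply_medium(build_population_model(net, 1),
                    medium_spec(uptake = c(u_e = 0), n_pop = 1))
  caps <- compute_flux_capacities(m)
  expect_equal(caps$F[caps$template_id == "L1"], 7, tolerance = 1e-9)
})

test_that("capacity remapping reproduces the stated arithmetic exactly", {
  # U = eps + (F - eps) * share
  eps <- 1e-3
  expect_identical(eps + (100 - eps) * 0.25, 25.00075)
  m <- chain_model(2, uptake = 50)
  caps <- compute_flux_capacities(m)
  ras <- structure(list(
    ras = matrix(c(1, 3), 1, 2, dimnames = list("C1", c("c1", "c2"))),
    normalized = NULL, scored_reactions = "C1"), class = "ras_matrix")
  bounded <- apply_ras_bounds(m, caps, ras, epsilon = eps)
  FC1 <- caps$F[caps$template_id == "C1"]       # = 100 (both cells' uptake)
  expect_equal(unname(bounded$ub["C1_cell1"]), eps + (FC1 - eps) * 0.25)
  expect_equal(unname(bounded$ub["C1_cell2"]), eps + (FC1 - eps) * 0.75)
  # irreversible: L = 0
  expect_equal(unname(bounded$lb["C1_cell1"]), 0)
  # unscored reactions keep capacity bounds
  expect_equal(unname(bounded$ub["T_cell1"]),
               caps$F[caps$template_id == "T"])
})

test_that("zero shares get the epsilon floor and reversibility uses -U", {
  net <- toy_net()
  n <- 4
  model <- apply_medium(build_population_model(net, n), toy_medium(n))
  caps <- compute_flux_capacities(model)
  ras0 <- structure(list(
    ras = matrix(0, 2, n, dimnames = list(c("LDH", "GLUT"), paste0("c", 1:n))),
    normalized = NULL, scored_reactions = c("LDH", "GLUT")),
    class = "ras_matrix")
  b <- apply_ras_bounds(model, caps, ras0, epsilon = 1e-3)
  expect_equal(unname(b$ub[paste0("LDH_cell", 1:n)]), rep(1e-3, n))
  # LDH is reversible: lower bound mirrors the upper
  expect_equal(unname(b$lb[paste0("LDH_cell", 1:n)]), rep(-1e-3, n))
  # GLUT is irreversible: floor above, zero below
  expect_equal(unname(b$lb[paste0("GLUT_cell", 1:n)]), rep(0, n))
  # epsilon larger than a zero capacity: clamped with a warning
  expect_warning(apply_ras_bounds(model, within(caps, F[1] <- 0), ras0),
                 "clamped")
})

test_that("bound conservation: sum_c U - F = (n_cells - 1) * eps exactly", {
  eps <- 1e-3
  n <- 5
  m <- chain_model(n, uptake = 20)
  caps <- compute_flux_capacities(m)
  shares <- c(0.1, 0.2, 0.3, 0.15, 0.25)
  ras <- structure(list(
    ras = matrix(shares, 1, n, dimnames = list("C1", paste0("c", 1:n))),
    normalized = NULL, scored_reactions = "C1"), class = "ras_matrix")
  b <- apply_ras_bounds(m, caps, ras, epsilon = eps)
  U <- b$ub[paste0("C1_cell", 1:n)]
  FC1 <- caps$F[caps$template_id == "C1"]
  expect_lt(abs(sum(U) - FC1 - (n - 1) * eps), 1e-12)
})

test_that("raising one cell's share never lowers its bound (monotonicity)", {
  m <- chain_model(3, uptake = 30)
  caps <- compute_flux_capacities(m)
  mk <- function(v) structure(list(
    ras = matrix(v, 1, 3, dimnames = list("C1", paste0("c", 1:3))),
    normalized = NULL, scored_reactions = "C1"), class = "ras_matrix")
  u1 <- apply_ras_bounds(m, caps, mk(c(1, 1, 2)), epsilon = 1e-3)$ub["C1_cell1"]
  u2 <- apply_ras_bounds(m, caps, mk(c(2, 1, 2)), epsilon = 1e-3)$ub["C1_cell1"]
  expect_gte(u2, u1)
})
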