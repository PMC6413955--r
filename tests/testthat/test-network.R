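test_that("template constructor counts and classifies as the file states", {
  net <- counting_net()
  expect_equal(n_metabolites(net), 5)
  expect_equal(n_internal(net), 8)
  expect_equal(n_exchanges(net), 3)
  # single-participant rule assigns EX_* (and nothing else) to the exchanges
  expect_setequal(net$exchanges, c("EX_a", "EX_c", "EX_biomass"))
  expect_identical(net$biomass_reaction_id, "BIOMASS")
  expect_error(template_network(metabolites = "a",
                                reactions = list(list(id = "r",
                                                      stoich = c(zz = 1)))),
               "unknown metabolites")
})

test_that("SBML write -> read round-trips metabolites, reactions and GPRs", {
  for (net in list(toy_net(), chain_net(), counting_net())) {
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml_network(net, path)
    back <- read_sbml_network(path)
    expect_setequal(back$metabolites, net$metabolites)
    expect_setequal(names(back$reactions), names(net$reactions))
    expect_setequal(back$exchanges, net$exchanges)
    expect_identical(back$biomass_reaction_id, net$biomass_reaction_id)
    for (id in names(net$reactions)) {
      a <- net$reactions[[id]]; b <- back$reactions[[id]]
      expect_equal(a$stoich[sort(names(a$stoich))],
                   b$stoich[sort(names(b$stoich))])
      expect_identical(a$reversible, b$reversible)
      expect_equal(c(a$lb, a$ub), c(b$lb, b$ub))
      fmt <- function(g) if (is.null(g)) "" else format(g)
      expect_identical(fmt(a$gpr), fmt(b$gpr))
    }
  }
})

test_that("an independent SBML reader (cobrapy) agrees on the toy model", {
  path <- withr::local_tempfile(fileext = ".xml")
  net <- toy_net()
  write_sbml_network(net, path)
  out <- withr::local_tempfile(fileext = ".json")
  script <- sprintf(
    "import json, cobra; m = cobra.io.read_sbml_model(%s)\njson.dump({'mets': len(m.metabolites), 'rxns': len(m.reactions), 'genes': len(m.genes), 'gprs': sum(1 for r in m.reactions if r.gene_reaction_rule)}, open(%s, 'w'))",
    deparse(path), deparse(out))
  res <- system2(scfba:::lp_python(), c("-c", shQuote(script)),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  got <- jsonlite::fromJSON(out)
  expect_equal(got$mets, n_metabolites(net))
  expect_equal(got$rxns, length(net$reactions))
  expect_equal(got$genes, length(network_genes(net)))
  expect_equal(got$gprs, sum(!vapply(net$reactions,
                                     function(r) is.null(r$gpr), logical(1))))
})

test_that("legacy notes-dialect GPRs and kinetic-law bounds are read", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfSpecies>',
    '<species id="x" compartment="c"/>',
    '<species id="x_b" compartment="e" boundaryCondition="true"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R1" reversible="true">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: ga1 or (ga2 and ga3)</p></body></notes>',
    '<listOfReactants><speciesReference species="x_b"/></listOfReactants>',
    '<listOfProducts><speciesReference species="x"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-42"/>',
    '<parameter id="UPPER_BOUND" value="99"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '<reaction id="EX_x" reversible="false">',
    '<listOfReactants><speciesReference species="x"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), path)
  net <- read_sbml_network(path)
  expect_identical(net$metabolites, "x")  # boundary species dropped
  r1 <- net$reactions[["R1"]]
  expect_identical(format(r1$gpr), "ga1 or ga2 and ga3")
  expect_equal(c(r1$lb, r1$ub), c(-42, 99))
  expect_true(r1$reversible)
  # R1 lost its boundary partner, so it now touches one metabolite: both
  # reactions classify as exchanges
  expect_setequal(net$exchanges, c("R1", "EX_x"))
})

test_that("gene id mapping and GPR exclusion behave at load time", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml_network(chain_net(), path)
  mapped <- read_sbml_network(path, gene_map = data.frame(
    from = c("t1", "c1a"), to = c("HGNC:1", "HGNC:2")))
  expect_setequal(gpr_genes(mapped$reactions[["C1"]]$gpr), c("HGNC:2", "c1b"))
  excl <- read_sbml_network(path, gpr_excluded = "BIOMASS")
  expect_null(excl$reactions[["BIOMASS"]]$gpr)
  expect_identical(excl$gpr_excluded, "BIOMASS")
  expect_error(read_sbml_network(path, gpr_excluded = "nope"),
               "unknown reactions")
  expect_error(read_sbml_network("missing-file.xml"), "not found")
})

test_that("gene deletion uses false-logic, drops orphans, and composes", {
  net <- counting_net()
  # AND rule: deleting one subunit removes the reaction
  expect_false("R1" %in% names(delete_genes(net, "g1")$reactions))
  # OR rule: the surviving isoform keeps the reaction
  expect_true("R3" %in% names(delete_genes(net, "g1")$reactions))
  # empty deletion is the identity
  expect_identical(delete_genes(net, character()), net)
  # no-GPR reactions are never touched
  expect_true(all(c("T1", "R5", "R6") %in%
                    names(delete_genes(net, paste0("g", 1:6))$reactions)))
  # composability: delete(G1 u G2) == delete(delete(G1), G2)
  set.seed(3)
  all_genes <- network_genes(net)
  for (i in 1:10) {
    g1 <- sample(all_genes, 2)
    g2 <- sample(all_genes, 2)
    a <- delete_genes(net, union(g1, g2))
    b <- delete_genes(delete_genes(net, g1), g2)
    expect_setequal(names(a$reactions), names(b$reactions))
    expect_setequal(a$metabolites, b$metabolites)
  }
  # orphan metabolites are dropped
  tiny <- template_network(
    metabolites = c("x", "y"),
    reactions = list(list(id = "A", stoich = c(x = -1, y = 1), gpr = "gA"),
                     list(id = "EX_x", stoich = c(x = -1), reversible = TRUE)))
  reduced <- delete_genes(tiny, "gA")
  expect_identical(reduced$metabolites, "x")
  expect_setequal(names(reduced$reactions), "EX_x")
})

test_that("disabled_reactions mirrors deletion and JSON dump is faithful", {
  net <- counting_net()
  expect_setequal(disabled_reactions(net, "g1"), "R1")
  expect_setequal(disabled_reactions(net, c("g3", "g1")), c("R1", "R2"))
  expect_length(disabled_reactions(net, "not_a_gene"), 0)
  dump <- network_to_json(net)
  expect_equal(length(dump$reactions), length(net$reactions))
  expect_identical(dump$biomass_reaction_id, "BIOMASS")
})
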