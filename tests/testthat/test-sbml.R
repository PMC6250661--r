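round_trip <- function(model) {
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  write_sbml_model(model, path)
  read_sbml_model(path)
}

test_that("SBML round-trip preserves the toy models exactly", {
  for (m in list(make_toy1(), make_toy2())) {
    m2 <- round_trip(m)
    expect_identical(m2$reactions$id, m$reactions$id)
    expect_identical(m2$reactions$lb, m$reactions$lb)
    expect_identical(m2$reactions$ub, m$reactions$ub)
    expect_identical(m2$biomass_id, m$biomass_id)
    expect_identical(m2$genes, m$genes)
    expect_identical(m2$gpr, m$gpr)
    expect_equal(as.matrix(m2$S[rownames(m$S), ]), as.matrix(m$S))
  }
})

test_that("bounds survive the round-trip at full double precision", {
  rx <- data.frame(id = c("EX_A", "R1", "BIOMASS"),
                   lb = c(0, -1 / 3, 0),
                   ub = c(1e-7 + pi, 987654321.123456, 1000),
                   gpr = "", stringsAsFactors = FALSE)
  st <- list(EX_A = c(A = 1), R1 = c(A = -1, B = 1), BIOMASS = c(B = -1))
  m <- metabolic_model(rx, st, "BIOMASS", id = "awkward")
  m2 <- round_trip(m)
  expect_identical(m2$reactions$lb, m$reactions$lb)
  expect_identical(m2$reactions$ub, m$reactions$ub)
})

test_that("GPR trees survive the round-trip including nesting", {
  rx <- data.frame(id = c("EX_A", "R1", "R2", "BIOMASS"),
                   lb = 0, ub = c(5, 10, 10, 1000),
                   gpr = c("", "(g1 and g2) or g3",
                           "g4 and (g5 or (g6 and g7))", ""),
                   stringsAsFactors = FALSE)
  st <- list(EX_A = c(A = 1), R1 = c(A = -1, B = 1), R2 = c(A = -1, B = 1),
             BIOMASS = c(B = -1))
  m <- metabolic_model(rx, st, "BIOMASS")
  m2 <- round_trip(m)
  expect_identical(m2$gpr, m$gpr)
})

test_that("biomass reaction is recovered from the fbc active objective", {
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  write_sbml_model(make_toy1(), path)
  m <- read_sbml_model(path)                      # no biomass_id given
  expect_identical(m$biomass_id, "BIOMASS")
})

test_that("legacy COBRA SBML (notes + kinetic-law bounds) is readable", {
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="legacy">',
    '<listOfSpecies>',
    '<species id="A" compartment="c"/>',
    '<species id="B" compartment="c"/>',
    '<species id="A_b" compartment="e" boundaryCondition="true"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="EX_A" reversible="false">',
    '<listOfReactants><speciesReference species="A_b"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/>',
    '<parameter id="UPPER_BOUND" value="7"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '<reaction id="R1" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: ga or gb</p></body></notes>',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts>',
    '</reaction>',
    '<reaction id="BIOMASS" reversible="false">',
    '<listOfReactants><speciesReference species="B"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '</model>',
    '</sbml>'), path)
  m <- read_sbml_model(path, biomass_id = "BIOMASS")
  expect_identical(m$reactions$ub[m$reactions$id == "EX_A"], 7)
  # boundary species excluded from mass balance -> EX_A is an exchange
  expect_false("A_b" %in% rownames(m$S))
  expect_true("EX_A" %in% exchange_reactions(m))
  # notes-based GPR parsed; default bounds applied to R1
  expect_identical(m$gpr[["R1"]], parse_gpr("ga or gb"))
  expect_identical(m$reactions$ub[m$reactions$id == "R1"], 1000)
  expect_equal(fba(m)$objective, 7)
})

test_that("random synthetic networks survive the SBML round-trip", {
  for (topo in c("linear", "branched", "currency")) {
    m <- make_random_network(synthetic_spec(topology = topo, seed = 7))$model
    m2 <- round_trip(m)
    expect_identical(m2$reactions[names(m2$reactions) != "gpr"],
                     m$reactions[names(m$reactions) != "gpr"])
    expect_identical(m2$gpr, m$gpr)
    expect_equal(as.matrix(m2$S[rownames(m$S), ]), as.matrix(m$S))
    expect_equal(fba(m2)$objective, fba(m)$objective)
  }
})
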