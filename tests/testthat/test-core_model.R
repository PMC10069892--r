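test_that("elemental formulas parse in Hill notation with charge stripping", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("C10H16N5O13P3"),
               c(C = 10, H = 16, N = 5, O = 13, P = 3))
  expect_equal(parse_formula("C6H11O9P-2"), c(C = 6, H = 11, O = 9, P = 1))
  expect_equal(element_count("CO2"), 1)
  expect_equal(element_count("H3N", "C"), 0)
  # generic groups make atom counts undefined
  expect_null(parse_formula("C10H12R"))
  expect_null(parse_formula("XC4"))
  expect_null(parse_formula(NA))
  expect_true(is.na(element_count(NA)))
})

test_that("biomass carbon fraction counts substrate carbon minus returned carbon", {
  mets <- mk_mets(list("glc_c", "c", "C6H12O6"), list("gly_c", "c", "C2H5NO2"),
                  list("atp_c", "c", NA), list("biomass_c", "c", NA))
  rxns <- list(rx("BIO", c(glc_c = -2, gly_c = -1, biomass_c = 1)),
               rx("EX_BIO", c(biomass_c = -1)))
  m <- mk_model("bio_demo", mets, rxns, c(BIO = 1))
  cf <- biomass_carbon_fraction(m, "BIO")
  expect_equal(cf$value, 14)  # 2 x 6 + 1 x 2
  expect_length(cf$skipped_metabolites, 0)

  rxns2 <- list(rx("BIO", c(glc_c = -1, atp_c = -1, biomass_c = 1)),
                rx("EX_BIO", c(biomass_c = -1)))
  m2 <- mk_model("bio_demo2", mets, rxns2, c(BIO = 1))
  cf2 <- biomass_carbon_fraction(m2, "BIO")
  expect_equal(cf2$value, 6)
  expect_equal(cf2$skipped_metabolites, "atp_c")

  # all substrates formula-less -> undefined
  rxns3 <- list(rx("BIO", c(atp_c = -1, biomass_c = 1)),
                rx("EX_BIO", c(biomass_c = -1)))
  m3 <- mk_model("bio_demo3", mets, rxns3, c(BIO = 1))
  expect_error(biomass_carbon_fraction(m3, "BIO"), "carbon fraction undefined")

  # toy model ground truth
  tp <- toy_day()
  expect_equal(biomass_carbon_fraction(tp$model)$value,
               tp$ground_truth$biomass_carbon)

  # scaling the stoichiometry scales the per-unit-flux carbon proportionally
  m4 <- m
  m4$stoichiometry$BIO <- m$stoichiometry$BIO * 3
  expect_equal(biomass_carbon_fraction(m4, "BIO")$value, 42)
})

test_that("exchange and transport roles are detected structurally", {
  tp <- toy_day()$model
  rxn <- tp$reactions
  expect_true(all(rxn$is_exchange[rxn$id %in% c("EX_CO2", "EX_PHOTON",
                                                "EX_BIOMASS")]))
  expect_true(all(rxn$is_transport[rxn$id %in% c("T_CO2_HC", "T_CO2_MC",
                                                 "AAC_M")]))
  expect_false(any(rxn$is_transport[rxn$id %in% c("RBC_C", "GDC", "BIOMASS")]))
  expect_false(any(rxn$is_exchange[rxn$id %in% c("T_CO2_HC", "PGD")]))
})

test_that("SBML round-trips through the tabular dialect bit-exactly", {
  tp <- generate_toyplant(toy_model_spec(include_futile_loop = TRUE))
  f <- tempfile(fileext = ".xml")
  write_sbml(tp$model, f, ec_in_notes = c("PDH", "OGDH"))
  m <- read_sbml(f)
  expect_equal(m$reactions$id, tp$model$reactions$id)
  expect_equal(m$reactions$lower_bound, tp$model$reactions$lower_bound)
  expect_equal(m$reactions$upper_bound, tp$model$reactions$upper_bound)
  for (r in m$reactions$id) {
    a <- tp$model$stoichiometry[[r]]
    b <- m$stoichiometry[[r]][names(a)]
    expect_equal(unname(b), unname(a), tolerance = 1e-12)
  }
  # EC harvested from notes for the reactions written without CV terms
  expect_equal(m$ec_numbers[["PDH"]], "1.2.4.1")
  expect_equal(m$ec_numbers[["GDC"]], "1.4.4.2")

  d <- tempfile()
  write_tabular(m, d)
  m2 <- read_tabular(d)
  expect_identical(m$id, m2$id)
  expect_equal(m$metabolites, m2$metabolites)
  expect_equal(m$reactions, m2$reactions)
  expect_identical(names(m$stoichiometry), names(m2$stoichiometry))
  for (r in names(m$stoichiometry)) {
    expect_identical(m$stoichiometry[[r]], m2$stoichiometry[[r]])
  }
  expect_identical(m$objective, m2$objective)
  expect_identical(m$ec_numbers, m2$ec_numbers)
})

test_that("tabular writer preserves unicode names and handles empty models", {
  mets <- mk_mets(list("A_c", "c", "C2H4O2"))
  rxns <- list(rx("EX_A", c(A_c = -1), lb = -5))
  m <- mk_model("uni", mets, rxns, c(EX_A = 1))
  m$reactions$name <- "acetate ⇄ milieu extérieur"
  d <- tempfile()
  write_tabular(m, d)
  m2 <- read_tabular(d)
  expect_identical(m2$reactions$name, m$reactions$name)

  empty <- metabolic_model(
    "empty",
    data.frame(id = character(0), name = character(0),
               compartment = character(0), formula = character(0),
               is_boundary = logical(0), stringsAsFactors = FALSE),
    data.frame(id = character(0), name = character(0),
               lower_bound = numeric(0), upper_bound = numeric(0),
               stringsAsFactors = FALSE),
    stats::setNames(list(), character(0)))
  d2 <- tempfile()
  write_tabular(empty, d2)
  e2 <- read_tabular(d2)
  expect_equal(nrow(e2$reactions), 0)
  # a model without reactions is valid but unusable for FBA
  expect_error(fba(e2), "empty objective")
})

test_that("SBML reader defaults missing bounds with a warning and handles kinetic-law bounds", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="mini">',
    '<listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="A_c" compartment="c"/>',
    '<species id="A_b" compartment="c" boundaryCondition="true"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R_nobounds" reversible="true">',
    '<listOfReactants><speciesReference species="A_b"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A_c"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R_kinetic" reversible="false">',
    '<listOfReactants><speciesReference species="A_c"/></listOfReactants>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/>',
    '<parameter id="UPPER_BOUND" value="42.5"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>')
  f <- tempfile(fileext = ".xml")
  writeLines(sbml, f)
  expect_warning(m <- read_sbml(f), "defaulting")
  expect_equal(m$reactions$lower_bound[m$reactions$id == "R_nobounds"], -1000)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "R_nobounds"], 1000)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "R_kinetic"], 42.5)
  expect_true(m$metabolites$is_boundary[m$metabolites$id == "A_b"])

  # user-supplied EC mapping is the last fallback
  m2 <- suppressWarnings(read_sbml(f, ec_mapping = data.frame(
    reaction = "R_kinetic", ec = "1.1.1.1", stringsAsFactors = FALSE)))
  expect_equal(m2$ec_numbers[["R_kinetic"]], "1.1.1.1")

  # empty model element: valid, zero reactions
  f2 <- tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
               '<model id="void"/></sbml>'), f2)
  m3 <- read_sbml(f2)
  expect_equal(nrow(m3$reactions), 0)
  expect_error(fba(m3), "empty objective")
  # parse failure carries context
  f3 <- tempfile(fileext = ".xml")
  writeLines("<sbml><model>", f3)
  expect_error(read_sbml(f3), "parse failure")
})

test_that("model validation catches structural violations", {
  mets <- mk_mets(list("A_c", "c", "C2H4O2"))
  expect_error(mk_model("bad", mets,
                        list(rx("R1", c(A_c = -1, Z_c = 1))), c(R1 = 1)),
               "unknown metabolites")
  expect_error(mk_model("bad2", mets,
                        list(rx("R1", c(A_c = -1), lb = 5, ub = 1)), c(R1 = 1)),
               "lower_bound")
  expect_error(mk_model("bad3", mets, list(rx("R1", c(A_c = -1))),
                        c(NOPE = 1)), "unknown reactions")
})

test_that("non-exchange toy reactions are carbon balanced from formulas", {
  for (fixt in list(toy_day(), toy_night(),
                    generate_random_variant(n_extra_reactions = 20, seed = 7))) {
    m <- fixt$model
    bal <- element_balance(m, "C")
    keep <- !m$reactions$is_exchange
    expect_true(all(abs(bal[keep]) < 1e-9, na.rm = TRUE),
                label = paste("carbon balance of", m$id))
  }
})
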