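sbml_wrap <- function(...) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
         'level="3" version="1"><model id="m">', paste0(...), "</model></sbml>")
}
MML <- 'xmlns="http://www.w3.org/1998/Math/MathML"'

test_that("local parameters are substituted by value on import", {
  doc <- sbml_wrap(
    '<listOfCompartments><compartment id="c" size="2" constant="true"/></listOfCompartments>',
    '<listOfSpecies><species id="X" compartment="c" initialConcentration="1" boundaryCondition="false" constant="false"/></listOfSpecies>',
    '<listOfReactions><reaction id="r1" reversible="false">',
    '<listOfReactants><speciesReference species="X" stoichiometry="1" constant="true"/></listOfReactants>',
    '<kineticLaw><math ', MML, '><apply><times/><ci>k</ci><ci>X</ci></apply></math>',
    '<listOfLocalParameters><localParameter id="k" value="3"/></listOfLocalParameters>',
    '</kineticLaw></reaction></listOfReactions>')
  imp <- import_sbml(doc)
  expect_equal(imp$model$species$compartment, 2)
  r <- imp$model$reactions[[1]]
  expect_equal(r$type, "X")
  expect_equal(r$rate, "3*[X]")
  # dynamics: d[X]/dt = -3*X/V = -1.5 at X = 1
  sys <- build_system(imp$model)
  expect_equal(sys$rhs(1), -1.5)
})

test_that("user-defined functions are inlined into kinetic laws", {
  doc <- sbml_wrap(
    '<listOfFunctionDefinitions><functionDefinition id="f">',
    '<math ', MML, '><lambda><bvar><ci>a</ci></bvar>',
    '<apply><times/><cn>2</cn><ci>a</ci></apply></lambda></math>',
    '</functionDefinition></listOfFunctionDefinitions>',
    '<listOfCompartments><compartment id="c" size="1" constant="true"/></listOfCompartments>',
    '<listOfSpecies><species id="X" compartment="c" initialConcentration="4"/></listOfSpecies>',
    '<listOfReactions><reaction id="r1">',
    '<listOfProducts><speciesReference species="X" stoichiometry="1"/></listOfProducts>',
    '<kineticLaw><math ', MML, '><apply><ci>f</ci><ci>X</ci></apply></math>',
    '</kineticLaw></reaction></listOfReactions>')
  imp <- import_sbml(doc)
  expect_equal(imp$model$reactions[[1]]$rate, "2*[X]")
  fn_row <- imp$report[imp$report$construct == "functionDefinition", ]
  expect_equal(fn_row$status, "supported")
})

test_that("unsupported constructs land in the dropped partition", {
  doc <- sbml_wrap(
    '<listOfCompartments><compartment id="c" size="1"/></listOfCompartments>',
    '<listOfSpecies><species id="X" compartment="c" initialConcentration="1"/></listOfSpecies>',
    '<listOfRules><algebraicRule><math ', MML,
    '><apply><minus/><ci>X</ci><cn>1</cn></apply></math></algebraicRule></listOfRules>')
  imp <- import_sbml(doc)
  dr <- imp$report[imp$report$status == "dropped", ]
  expect_true(any(dr$construct == "algebraicRule"))
  expect_match(dr$reason[dr$construct == "algebraicRule"], "unsupported")
  expect_error(import_sbml(doc, strict = TRUE), "unsupported SBML construct")
})

test_that("assignment and rate rules are translated", {
  doc <- sbml_wrap(
    '<listOfCompartments><compartment id="c" size="1"/></listOfCompartments>',
    '<listOfSpecies><species id="X" compartment="c" initialConcentration="0"/></listOfSpecies>',
    '<listOfParameters><parameter id="a" value="2" constant="true"/>',
    '<parameter id="b" constant="false"/>',
    '<parameter id="z" value="1" constant="false"/></listOfParameters>',
    '<listOfRules>',
    '<assignmentRule variable="b"><math ', MML,
    '><apply><times/><ci>a</ci><cn>3</cn></apply></math></assignmentRule>',
    '<rateRule variable="z"><math ', MML,
    '><apply><minus/><ci>z</ci></apply></math></rateRule>',
    '</listOfRules>')
  imp <- import_sbml(doc)
  vals <- resolve_parameters(imp$model)
  expect_equal(unname(vals["b"]), 6)
  # rate rule target became a state with dz/dt = -z
  expect_true("z" %in% imp$model$species$name)
  sys <- build_system(imp$model)
  iz <- match("z", sys$species_order)
  x <- sys$x0; x[iz] <- 2
  expect_equal(sys$rhs(unname(x))[iz], -2)
})

test_that("every source construct appears in exactly one report row", {
  doc <- export_sbml(fixtures("toggle_switch"))
  imp <- import_sbml(doc)
  expect_true(all(imp$report$status %in% c("supported", "dropped")))
  # one row per species, parameter, compartment, reaction
  expect_equal(sum(imp$report$construct == "species"), 7)
  expect_equal(sum(imp$report$construct == "reaction"), 5 + 5)  # + degradations
})

test_that("export counts reactions and degradation extras correctly", {
  m <- fixtures("toggle_switch")
  doc <- export_sbml(m)
  ns <- xml2::xml_ns_strip(doc)
  rx <- xml2::xml_find_all(ns, ".//listOfReactions/reaction")
  degrading <- sum(m$species$degradation > 0)
  expect_equal(length(rx), 5 + degrading)
  # species with d = 0 get no degradation reaction
  ids <- xml2::xml_attr(rx, "id")
  expect_false(any(ids %in% c("deg_X1", "deg_X2")))
  expect_true("deg_GFP" %in% ids)
})

test_that("dependent parameters export as assignment rules and re-import", {
  m <- parse_netlist(c(".parameters", "a 2", "b a*3",
                       ".species", "X 1 0",
                       ".reactions", "Cx {X} {b}", ".simulation"))
  imp <- import_sbml(export_sbml(m))
  vals <- resolve_parameters(imp$model)
  expect_equal(unname(vals["b"]), 6)
  sys <- build_system(imp$model)
  expect_equal(sys$rhs(1), 6)
})

test_that("export/import round-trip preserves the dynamics of all fixtures", {
  set.seed(202)
  for (nm in fixture_names) {
    m <- fixtures(nm)
    imp <- import_sbml(export_sbml(m))
    s1 <- build_system(m)
    s2 <- build_system(imp$model)
    expect_setequal(s2$species_order, s1$species_order)
    reorder <- match(s1$species_order, s2$species_order)
    worst <- 0
    for (k in 1:100) {
      x <- stats::setNames(runif(length(s1$species_order), 0, 10),
                           s1$species_order)
      a <- s1$rhs(unname(x[s1$species_order]))
      b <- s2$rhs(unname(x[s2$species_order]))
      worst <- max(worst, max(abs(a - b[reorder]) / pmax(abs(a), 1e-8)))
    }
    expect_lt(worst, 1e-9)
  }
})

test_that("identifiers are sanitized to SId form with a mapping table", {
  doc <- sbml_wrap(
    '<listOfCompartments><compartment id="c" size="1"/></listOfCompartments>',
    '<listOfSpecies><species id="bad-name" compartment="c" initialConcentration="1"/></listOfSpecies>')
  imp <- import_sbml(doc)
  expect_equal(imp$model$species$name, "bad_name")
  expect_equal(unname(imp$id_map[["bad-name"]]), "bad_name")
})
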