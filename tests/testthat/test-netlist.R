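test_that("reaction lines parse per the type table", {
  m <- parse_netlist(c(
    ".parameters", "vmax 1", "km 0.5",
    ".species", "S 1", "P 0", "E 2",
    ".reactions", "E1 {S} {P} {E} {vmax,km}",
    ".simulation"))
  expect_equal(length(m$reactions), 1)
  r <- m$reactions[[1]]
  expect_equal(r$type, "E")
  expect_equal(nrow(r$reactants), 1)
  expect_equal(nrow(r$products), 1)
  expect_equal(r$modifiers, "E")
  expect_equal(length(r$params), 2)
  expect_equal(r$params$v_max, "vmax")
  expect_equal(r$params$K_m, "km")
})

test_that("empty sections and absent-list zeros are accepted", {
  m <- parse_netlist(c(".parameters", ".species", "S 1", ".reactions",
                       ".simulation"))
  expect_equal(length(m$reactions), 0)
  expect_equal(nrow(m$species), 1)
  # a transcription with no regulators: both regulator arguments are 0
  m2 <- parse_netlist(c(".parameters", ".species", "mX", ".reactions",
                        "T1 {mX} 0 0 {5}", ".simulation"))
  r <- m2$reactions[[1]]
  expect_equal(r$activators, character(0))
  expect_equal(r$repressors, character(0))
  expect_equal(r$params$k_TR, "5")
})

test_that("stoichiometry prefixes, braces and quoted rates tokenize", {
  m <- parse_netlist(c(
    ".parameters", "k 1",
    ".species", "A 1", "B 1", "C 0",
    ".reactions",
    "Bdim {2*A,B} {C} {k,0}",
    "Xc {A} {C} 0 'k*[A]^2/(1+[A])'",
    ".simulation"))
  expect_equal(m$reactions[[1]]$reactants$stoich, c(2L, 1L))
  expect_equal(m$reactions[[2]]$rate, "k*[A]^2/(1+[A])")
})

test_that("comments, blank lines and passthrough are handled", {
  m <- parse_netlist(c(
    "* title comment", "",
    ".parameters", "k 2 ; a rate", "",
    ".species", "S 1 0 ; observed",
    ".reactions",
    "$Rload out 0 1k",
    ".simulation"))
  expect_equal(m$parameters$comment, "a rate")
  expect_equal(m$species$initial, 1)
  expect_equal(m$passthrough, "Rload out 0 1k")
})

test_that("format errors name the offending line", {
  expect_error(parse_netlist(c(".reactions", "Q1 {A} {B} {1}")),
               "unknown reaction-type letter")
  expect_error(parse_netlist(c(".species", "S", ".reactions", "E1 {S} {1}")),
               "takes 3 argument")
  expect_error(parse_netlist(c(".species", "S", ".reactions",
                               "H1 {S} {S} {1,2}")),
               "needs \\{v_max,K,n\\}")
  expect_error(parse_netlist(c(".species", "A", ".reactions",
                               "C1 {Missing} {1}")),
               "undeclared species")
  expect_error(parse_netlist(c("A 1")), "before any section")
})

test_that("case-insensitively duplicated names are rejected", {
  expect_error(parse_netlist(c(".species", "abc 1", "ABC 2")),
               "duplicate species")
  expect_error(parse_netlist(c(".parameters", "k 1", ".species", "K 2")),
               "parameter and species")
})

test_that("numeric literals accept engineering suffixes", {
  expect_equal(parse_spice_number("2.5u"), 2.5e-6)
  expect_equal(parse_spice_number("3k"), 3000)
  expect_equal(parse_spice_number("-1.2e-3"), -0.0012)
  expect_true(is.na(parse_spice_number("oops")))
  m <- parse_netlist(c(".parameters", "kon 10k", "koff 2*kon",
                       ".species", ".reactions", ".simulation"))
  v <- resolve_parameters(m)
  expect_equal(unname(v["kon"]), 1e4)
  expect_equal(unname(v["koff"]), 2e4)
})

test_that("parameters resolve through dependency chains", {
  m <- parse_netlist(c(".parameters", "a 2", "b a*3",
                       ".species", ".reactions", ".simulation"))
  expect_equal(resolve_parameters(m), c(a = 2, b = 6))
  m2 <- parse_netlist(c(".parameters", "k 1e-3", "kon 10*k", "koff kon/2",
                        ".species", ".reactions", ".simulation"))
  expect_equal(resolve_parameters(m2), c(k = 0.001, kon = 0.01, koff = 0.005))
})

test_that("cyclic and dangling parameter definitions error", {
  m <- parse_netlist(c(".parameters", "a b", "b a",
                       ".species", ".reactions", ".simulation"))
  err <- tryCatch(resolve_parameters(m), error = function(e) conditionMessage(e))
  expect_match(err, "cyclic")
  expect_match(err, "a")
  expect_match(err, "b")
  expect_error(resolve_parameters(
    parse_netlist(c(".parameters", "a nosuch*2",
                    ".species", ".reactions", ".simulation"))),
    "undefined")
})

test_that("parameter resolution is declaration-order independent", {
  base <- c("a 2", "b a*3", "c b+a", "d c^2/b")
  ref <- resolve_parameters(parse_netlist(c(".parameters", base,
                                            ".species", ".reactions",
                                            ".simulation")))
  set.seed(42)
  for (i in 1:5) {
    shuffled <- sample(base)
    v <- resolve_parameters(parse_netlist(c(".parameters", shuffled,
                                            ".species", ".reactions",
                                            ".simulation")))
    expect_equal(v[names(ref)], ref)
  }
})

test_that("write/parse round-trips are the identity on all fixtures", {
  for (nm in fixture_names) {
    m <- fixtures(nm)
    expect_model_equal(parse_netlist(write_netlist(m)), m)
  }
  # and on generated models with a fixed seed
  g <- gen_random_pathway(10, 16, seed = 7)
  expect_model_equal(parse_netlist(write_netlist(g)), g)
  g2 <- gen_repressilator_grn(5)
  expect_model_equal(parse_netlist(write_netlist(g2)), g2)
  # empty model
  e <- bsp_model()
  expect_model_equal(parse_netlist(write_netlist(e)), e)
})

test_that("the toggle-switch netlist text reparses to 7 species / 5 reactions", {
  txt <- write_netlist(fixtures("toggle_switch"))
  m <- parse_netlist(txt)
  expect_equal(nrow(m$species), 7)
  expect_equal(length(m$reactions), 5)
})

test_that("directive grammar is validated", {
  expect_error(parse_netlist(c(".species", "S", ".simulation", "PULSE S 1 2")),
               "PULSE takes")
  expect_error(parse_netlist(c(".simulation", "NOSUCH 1")), "unknown simulation")
  expect_error(parse_netlist(c(".species", "S", ".simulation",
                               "TIMECOURSE 10", "STEADY")),
               "at most one analysis")
  m <- parse_netlist(c(".species", "S", ".simulation",
                       "WAVEFORM S {0,1,5,0.5,9,0}"))
  expect_equal(m$directives[[1]]$args$times, c(0, 5, 9))
  expect_equal(m$directives[[1]]$args$values, c(1, 0.5, 0))
  expect_error(parse_netlist(c(".species", "S", ".simulation",
                               "WAVEFORM S {5,1,2,0}")),
               "increasing")
})
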