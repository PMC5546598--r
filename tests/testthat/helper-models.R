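# Small models built in code for the unit and property tests.

# single species, constant production beta and decay d
beta_d_model <- function(beta = 2, d = 0.5, x0 = 0) {
  parse_netlist(c(
    ".parameters", paste("beta", beta), paste("d", d),
    ".species", paste("X", x0, d),
    ".reactions", "Cprod {X} {beta}",
    ".simulation"))
}

# pure first-order decay
decay_model <- function(d = 0.5, x0 = 10) {
  parse_netlist(c(".parameters", ".species", paste("X", x0, d),
                  ".reactions", ".simulation"))
}

# closed diffusion pair A <-> B
diffusion_pair <- function(D = 0.5, a0 = 4, b0 = 1, va = 1, vb = 1) {
  parse_netlist(c(
    ".parameters", paste("Dc", D),
    ".species", paste("A", a0, 0, va), paste("B", b0, 0, vb),
    ".reactions", "Fab {A} {B} {Dc}",
    ".simulation"))
}

# closed binding system A + B <-> C (mass conservation fixture)
binding_model <- function(kon = 2, koff = 0.5) {
  parse_netlist(c(
    ".parameters", paste("kon", kon), paste("koff", koff),
    ".species", "A 3", "B 2", "C 0.5",
    ".reactions", "Bbind {A,B} {C} {kon,koff}",
    ".simulation"))
}

# linear production cascade X1 -> X2 -> X3 via translation-type links
linear_chain_model <- function() {
  parse_netlist(c(
    ".parameters", "beta 3", "k12 2", "k23 4",
    ".species", "X1 0 1", "X2 0 2", "X3 0 4",
    ".reactions",
    "Cin {X1} {beta}",
    "La {X2} {X1} {k12}",
    "Lb {X3} {X2} {k23}",
    ".simulation"))
}

# hand-coded rhs of the self-inhibited enzymatic loop (the independent
# oracle for the network-assembly equivalence tests)
self_inhibited_rhs_oracle <- function(x, alpha = 1, Vmax = 2, Km = 1, KP = 1,
                                      nB = 2, dS = 0.1, dP = 0.2) {
  S <- x[["S"]]; P <- x[["P"]]
  enz <- Vmax * S / (Km + S) * KP^nB / (KP^nB + P^nB)
  c(S = alpha - enz - dS * S, P = enz - dP * P)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rel_err <- function(a, b, floor = 1e-12) max(abs(a - b) / pmax(abs(b), floor))

expect_model_equal <- function(a, b) {
  expect_equal(a$parameters, b$parameters)
  expect_equal(a$species, b$species)
  expect_equal(length(a$reactions), length(b$reactions))
  for (i in seq_along(a$reactions)) {
    ra <- a$reactions[[i]]; rb <- b$reactions[[i]]
    expect_equal(ra$name, rb$name)
    expect_equal(ra$type, rb$type)
    expect_equal(ra$reactants, rb$reactants)
    expect_equal(ra$products, rb$products)
    expect_equal(ra$modifiers, rb$modifiers)
    expect_equal(ra$activators, rb$activators)
    expect_equal(ra$repressors, rb$repressors)
    expect_equal(ra$rate, rb$rate)
    pa <- ra$params[!startsWith(names(ra$params) %||% character(), ".")]
    pb <- rb$params[!startsWith(names(rb$params) %||% character(), ".")]
    expect_equal(pa, pb)
  }
  expect_equal(length(a$directives), length(b$directives))
  for (i in seq_along(a$directives)) {
    expect_equal(a$directives[[i]]$kind, b$directives[[i]]$kind)
    expect_equal(a$directives[[i]]$args, b$directives[[i]]$args)
  }
  expect_equal(a$passthrough, b$passthrough)
}

fixture_names <- c("self_inhibited", "toggle_switch", "penicillin_bio",
                   "band_detector", "and_gate")
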