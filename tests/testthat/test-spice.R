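deck_lines <- function(deck) unclass(deck)

# controlled/fixed source lines: behavioral B devices plus C-reaction
# current sources (stimulus devices IPULSE/IPWL/IAC excluded)
count_deck_sources <- function(deck) {
  l <- deck_lines(deck)
  sum(grepl("^B", l)) + sum(grepl("^IC", l))
}

test_that("species map to capacitors and degradation to 1/d resistors", {
  m <- parse_netlist(c(".parameters", ".species", "S 2 0.25 3",
                       ".reactions", ".simulation"))
  deck <- to_spice(m)
  l <- deck_lines(deck)
  expect_true(any(grepl("^CS S 0 3 ic=2$", l)))
  expect_true(any(grepl("^RS S 0 4$", l)))  # 1/0.25
  # d = 0: no resistor
  m0 <- parse_netlist(c(".species", "S 1 0"))
  expect_false(any(grepl("^RS", deck_lines(to_spice(m0)))))
  expect_equal(sum(grepl("^CS", deck_lines(to_spice(m0)))), 1)
})

test_that("diffusion becomes a single 1/D resistor between the nodes", {
  deck <- to_spice(diffusion_pair(D = 0.5))
  l <- deck_lines(deck)
  rline <- l[grepl("^RFFAB", l)]
  expect_length(rline, 1)
  expect_equal(strsplit(rline, "\\s+")[[1]][2:4], c("A", "B", "2"))
})

test_that("reactions emit N+M opposed behavioral sources", {
  deck <- to_spice(binding_model())
  l <- deck_lines(deck)
  b <- l[grepl("^BBBIND", l)]
  expect_length(b, 3)  # 2 reactants + 1 product
  toks <- strsplit(b, "\\s+")
  # reactant sources pull from the node, product sources push into it
  expect_equal(toks[[1]][2:3], c("A", "0"))
  expect_equal(toks[[2]][2:3], c("B", "0"))
  expect_equal(toks[[3]][2:3], c("0", "C"))
  expr <- sub(".*I=\\{(.*)\\}$", "\\1", b[1])
  expect_match(expr, "V\\(A\\)", fixed = FALSE)
  expect_match(expr, "V\\(B\\)", fixed = FALSE)
})

test_that("toggle-switch decks carry the expected source counts", {
  full <- to_spice(fixtures("toggle_switch"))
  expect_equal(count_deck_sources(full),
               as.integer(count_sources(build_system(fixtures("toggle_switch")))))
  pruned <- to_spice(fixtures("toggle_switch"), prune = TRUE)
  expect_equal(count_deck_sources(pruned), 5)
  expect_equal(sum(grepl("^C", deck_lines(pruned)) &
                     !grepl("^\\.", deck_lines(pruned))), 5)  # 5 nodes
  expect_equal(deck_lint(pruned), character(0))
})

test_that("directives translate to analyses, stimuli and controls", {
  m <- parse_netlist(c(
    ".parameters", ".species", "S 0 1", "G 0 1",
    ".reactions", "Cs {G} {2}",
    ".simulation", "FIX S 2", "TIMECOURSE 10 101", "PLOT {G}"))
  l <- deck_lines(to_spice(m))
  expect_true(any(grepl("^VFIXS S 0 DC 2$", l)))
  expect_true(any(grepl("^\\.tran ", l)))
  expect_true(any(grepl("^plot v\\(G\\)$", l)))
  expect_equal(l[length(l)], ".end")
  expect_equal(l[1], "* biospice generated netlist")
  # sweep -> .dc with a source on the swept node
  msw <- parse_netlist(c(".species", "A 0 0", "G 0 1", ".reactions",
                         "Hx {A} {G} {1,1,2}",
                         ".simulation", "SWEEP A {0,10,11}"))
  lsw <- deck_lines(to_spice(msw))
  expect_true(any(grepl("^VSWEEPA A 0 DC 0$", lsw)))
  expect_true(any(grepl("^\\.dc VSWEEPA 0 10 1$", lsw)))
})

test_that("passthrough lines are echoed verbatim into the deck", {
  m <- parse_netlist(c(".species", "S 1 0", ".reactions",
                       "$Rext S 0 1k", ".simulation"))
  expect_true(any(deck_lines(to_spice(m)) == "Rext S 0 1k"))
})

test_that("deck generation is deterministic and lint catches defects", {
  a <- to_spice(fixtures("band_detector"))
  b <- to_spice(fixtures("band_detector"))
  expect_identical(deck_lines(a), deck_lines(b))
  expect_equal(deck_lint(a), character(0))
  broken <- c(deck_lines(a)[-length(deck_lines(a))], ".tran 1 10", ".end")
  expect_true("multiple analyses" %in% deck_lint(broken))
  floating <- c("* t", "CS S 0 1 ic=0", "BX1_Q Q 0 I={V(S)}", ".tran 1 10", ".end")
  expect_match(paste(deck_lint(floating), collapse = "; "), "undeclared node 'Q'")
  noend <- c("* t", "CS S 0 1 ic=0")
  expect_true("missing .end" %in% deck_lint(noend))
})
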