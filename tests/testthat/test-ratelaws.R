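mk <- function(...) bsp_reaction(...)

test_that("binding rate follows mass action with signed reverse term", {
  r <- mk("B1", reactants = data.frame(species = c("R1", "R2"), stoich = c(1, 1)),
          products = data.frame(species = "P", stoich = 2),
          params = list(k_on = 2, k_off = 1))
  conc <- c(R1 = 3, R2 = 4, P = 5)
  expect_equal(rate_binding(r, conc), 2 * 12 - 1 * 25)  # = -1
  # zero reactant, irreversible -> zero rate
  r0 <- mk("B2", reactants = "A", products = "P",
           params = list(k_on = 5, k_off = 0))
  expect_equal(rate_binding(r0, c(A = 0, P = 7)), 0)
  # detailed balance: at [P]^nP / prod [R]^nR = k_on/k_off the rate vanishes
  req <- mk("B3", reactants = "A", products = "P",
            params = list(k_on = 3, k_off = 1.5))
  expect_equal(rate_binding(req, c(A = 2, P = 4)), 0)
  expect_error(rate_binding(r0, c(A = -1, P = 0)), "negative concentration")
})

test_that("enzymatic rate half-saturates at K_m and saturates at v_max*[E]", {
  r <- mk("E1", reactants = "S", products = "P", modifiers = "E",
          params = list(v_max = 3, K_m = 2))
  expect_equal(rate_enzymatic(r, c(S = 0, P = 0, E = 1.5)), 0)
  expect_equal(rate_enzymatic(r, c(S = 2, P = 0, E = 1.5)), 3 * 1.5 / 2)
  # increasing in S, bounded by v_max*[E]
  s_grid <- c(0.1, 1, 10, 100, 1e4)
  v <- vapply(s_grid, function(s) rate_enzymatic(r, c(S = s, P = 0, E = 1.5)), 0)
  expect_true(all(diff(v) > 0))
  expect_true(all(v < 3 * 1.5))
  expect_error(rate_enzymatic(mk("E2", reactants = "S", products = "P",
                                 modifiers = "E",
                                 params = list(v_max = 1, K_m = -1)),
                              c(S = 1, P = 0, E = 1)),
               "K_m")
})

test_that("diffusion rate is linear in the gradient and antisymmetric", {
  r <- mk("F1", reactants = "Xa", products = "Xb", params = list(D = 0.5))
  expect_equal(rate_diffusion(r, c(Xa = 4, Xb = 1)), 1.5)
  expect_equal(rate_diffusion(r, c(Xa = 2, Xb = 2)), 0)
  rswap <- mk("F2", reactants = "Xb", products = "Xa", params = list(D = 0.5))
  for (pair in list(c(1, 3), c(0, 5), c(2.5, 2.5))) {
    cc <- c(Xa = pair[1], Xb = pair[2])
    expect_equal(rate_diffusion(rswap, cc), -rate_diffusion(r, cc))
  }
})

test_that("Hill rate half-maxes at K and switches for large n", {
  r <- mk("H1", reactants = "R", products = "P",
          params = list(v_max = 4, K = 2, n = 3))
  expect_equal(rate_hill(r, c(R = 2, P = 0)), 2, tolerance = 1e-12)
  expect_equal(rate_hill(r, c(R = 0, P = 0)), 0)
  rsteep <- mk("H2", reactants = "R", products = "P",
               params = list(v_max = 4, K = 2, n = 60))
  expect_equal(rate_hill(rsteep, c(R = 3, P = 0)), 4, tolerance = 1e-6)
})

test_that("translation rate is linear in mRNA", {
  r <- mk("L1", products = "Prot", modifiers = "mX", params = list(k_TL = 3))
  expect_equal(rate_translation(r, c(mX = 2, Prot = 0)), 6)
  expect_equal(rate_translation(r, c(mX = 0, Prot = 0)), 0)
  expect_equal(rate_translation(r, c(mX = 4, Prot = 0)),
               2 * rate_translation(r, c(mX = 2, Prot = 0)))
})

test_that("pump rate multiplies Hill factors over its regulators", {
  r0 <- mk("P1", reactants = "A", products = "B", params = list(v_max = 7))
  expect_equal(rate_pump(r0, c(A = 1, B = 1)), 7)
  r1 <- mk("P2", reactants = "A", products = "B", modifiers = "M",
           params = list(v_max = 7, K = 2, n = 2))
  expect_equal(rate_pump(r1, c(A = 1, B = 1, M = 2)), 3.5, tolerance = 1e-12)
  expect_equal(rate_pump(r1, c(A = 1, B = 1, M = 0)), 0)
  bad <- mk("P3", reactants = "A", products = "B", modifiers = c("M", "N"),
            params = list(v_max = 1, K = 2, n = 2))
  expect_error(rate_pump(bad, c(A = 1, B = 1, M = 1, N = 1)), "pair per regulator")
})

test_that("transcription covers constitutive, repressed and activated promoters", {
  r0 <- mk("T0", products = "mX", params = list(k_TR = 6))
  expect_equal(rate_transcription(r0, c(mX = 0)), 6)
  rrep <- mk("T1", products = "mX", repressors = "R",
             params = list(k_TR = 6, KR = 2, nR = 1))
  expect_equal(rate_transcription(rrep, c(mX = 0, R = 2)), 3, tolerance = 1e-12)
  ract <- mk("T2", products = "mX", activators = "A",
             params = list(k_TR = 6, KA = 2, nA = 1))
  expect_equal(rate_transcription(ract, c(mX = 0, A = 2)), 3, tolerance = 1e-12)
  # activator absent -> silent promoter (numerator is the activator sum)
  expect_equal(rate_transcription(ract, c(mX = 0, A = 0)), 0)
})

test_that("custom rates reproduce built-in laws and reject bad input", {
  rx <- mk("X1", reactants = "S", products = "P",
           rate = "veff*[S]/(km+[S])")
  re <- mk("E9", reactants = "S", products = "P", modifiers = "E",
           params = list(v_max = 2, K_m = 0.7))
  params <- c(veff = 2 * 1.3, km = 0.7)
  for (s in c(0, 0.5, 3, 40)) {
    expect_equal(rate_custom(rx, c(S = s, P = 0), params),
                 rate_enzymatic(re, c(S = s, P = 0, E = 1.3)),
                 tolerance = 1e-12)
  }
  expect_equal(rate_custom(mk("X2", rate = "0"), c(S = 1), c()), 0)
  # the product-inhibition factor halves the rate at [P] = K_P
  rinh <- mk("X3", reactants = "S", products = "P",
             rate = "Vmax*[S]/(Km+[S])*KP^nB/(KP^nB+[P]^nB)")
  pars <- c(Vmax = 2, Km = 1, KP = 1.5, nB = 2)
  v_free <- rate_custom(rinh, c(S = 2, P = 0), pars)
  v_half <- rate_custom(rinh, c(S = 2, P = 1.5), pars)
  expect_equal(v_half, v_free / 2, tolerance = 1e-12)
  expect_error(rate_custom(mk("X4", rate = "k*[Nope]"), c(S = 1), c(k = 1)),
               "unknown species")
  expect_error(rate_custom(mk("X5", rate = "nope*[S]"), c(S = 1), c(k = 1)),
               "unknown parameter")
  expect_error(bsp_parse_expr("sin([S])"), "unsupported function")
})

test_that("all rates stay finite on random nonnegative inputs", {
  set.seed(11)
  reactions <- list(
    mk("Bz", reactants = c("A", "B"), products = "C",
       params = list(k_on = 2, k_off = 0.3)),
    mk("Ez", reactants = "A", products = "B", modifiers = "C",
       params = list(v_max = 1, K_m = 0.2)),
    mk("Fz", reactants = "A", products = "B", params = list(D = 1.2)),
    mk("Hz", reactants = "A", products = "B",
       params = list(v_max = 2, K = 0.5, n = 2.5)),
    mk("Lz", products = "B", modifiers = "A", params = list(k_TL = 0.7)),
    mk("Pz", reactants = "A", products = "B", modifiers = "C",
       params = list(v_max = 1, K = 1, n = 1.5)),
    mk("Tz", products = "A", activators = "B", repressors = "C",
       params = list(k_TR = 3, KA = 1, nA = 2, KR = 1, nR = 2)),
    mk("Xz", reactants = "A", products = "B",
       rate = "exp(-[A])*ln(1+[B])+sqrt([C])"))
  for (i in 1:50) {
    conc <- c(A = runif(1, 0, 100), B = runif(1, 0, 100), C = runif(1, 0, 100))
    for (r in reactions) expect_true(is.finite(reaction_rate(r, conc)))
  }
  # irreversible binding is nonnegative
  rb <- mk("Bnn", reactants = c("A", "B"), products = "C",
           params = list(k_on = 2, k_off = 0))
  for (i in 1:20) {
    conc <- c(A = runif(1, 0, 10), B = runif(1, 0, 10), C = runif(1, 0, 10))
    expect_gte(rate_binding(rb, conc), 0)
  }
})
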