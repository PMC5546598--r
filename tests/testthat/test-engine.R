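test_that("steady state matches closed forms", {
  # beta/d
  x <- steady_state(build_system(beta_d_model(beta = 2, d = 0.5)))
  expect_equal(unname(x[["X"]]), 4, tolerance = 1e-10)
  expect_lt(attr(x, "residual"), 1e-10)
  # all-zero model stays at its initial state
  m0 <- parse_netlist(c(".species", "A 1.5", "B 0", ".reactions"))
  expect_equal(as.numeric(steady_state(build_system(m0))), c(1.5, 0))
  # linear cascade X1 -> X2 -> X3, solved by hand
  xs <- steady_state(build_system(linear_chain_model()))
  expect_equal(unname(xs[c("X1", "X2", "X3")]), c(3, 3, 3), tolerance = 1e-9)
})

test_that("self-inhibited steady state satisfies the flux-balance identity", {
  sys <- build_system(fixtures("self_inhibited"))
  x <- steady_state(sys)
  S <- x[["S"]]; P <- x[["P"]]
  enz <- 2 * S / (1 + S) * 1 / (1 + P^2)
  expect_lt(abs(1 - enz - 0.1 * S), 1e-10)  # alpha = flux + dS*S
  expect_lt(abs(enz - 0.2 * P), 1e-10)
})

test_that("multistart search finds the right number of stable states", {
  # monostable beta/d
  ss <- find_stable_states(build_system(beta_d_model(2, 0.5)), 8, seed = 1)
  expect_equal(nrow(ss), 1)
  expect_equal(ss$X, 4, tolerance = 1e-8)
  # linear cascade: single state at the hand solution
  ss2 <- find_stable_states(build_system(linear_chain_model()), 8, seed = 1)
  expect_equal(nrow(ss2), 1)
  expect_equal(unname(unlist(ss2[1, c("X1", "X2", "X3")])), c(3, 3, 3),
               tolerance = 1e-7)
  # search is deterministic given the seed
  sys <- build_system(fixtures("toggle_switch"))
  a <- find_stable_states(sys, 12, seed = 5)
  b <- find_stable_states(sys, 12, seed = 5)
  expect_equal(a, b)
})

test_that("transient simulation matches the decay closed form", {
  sys <- build_system(decay_model(d = 0.5, x0 = 10))
  tc <- time_course(sys, t_end = 10, n_points = 101)
  expect_lt(rel_err(tc$X, 10 * exp(-0.5 * tc$time), floor = 1e-8), 1e-6)
})

test_that("diffusion-only pairs conserve total mass along the trajectory", {
  sys <- build_system(diffusion_pair(D = 0.5, va = 1, vb = 1))
  tc <- time_course(sys, t_end = 20, n_points = 51)
  expect_lt(max(abs(tc$A + tc$B - 5)) / 5, 1e-9)
})

test_that("long-horizon transients land on the steady state", {
  for (model in list(beta_d_model(2, 0.5), fixtures("self_inhibited"))) {
    sys <- build_system(model)
    xs <- steady_state(sys)
    tc <- time_course(sys, t_end = 400, n_points = 51)
    end <- as.numeric(tc[nrow(tc), -1])
    expect_lt(max(abs(end - xs) / pmax(abs(xs), 1e-6)), 1e-6)
  }
})

test_that("pulse and waveform stimuli drive the state and restart cleanly", {
  sys <- build_system(decay_model(d = 1, x0 = 0))
  # constant source of 2 between t=1 and t=3: x rises toward 2, then decays
  p <- bsp_directive("PULSE", species = "X", delay = 1, length = 2,
                     height = 2, frequency = 0)
  tc <- time_course(sys, stimuli = list(p), t_end = 6, n_points = 121)
  expect_equal(tc$X[tc$time <= 1], rep(0, sum(tc$time <= 1)), tolerance = 1e-9)
  x3 <- tc$X[tc$time == 3]
  expect_equal(x3, 2 * (1 - exp(-2)), tolerance = 1e-6)
  expect_equal(tc$X[tc$time == 6], x3 * exp(-3), tolerance = 1e-6)
  # periodic pulse: frequency 0.5 -> two activations within t_end = 4
  pp <- bsp_directive("PULSE", species = "X", delay = 0, length = 0.5,
                      height = 2, frequency = 0.5)
  tcp <- time_course(sys, stimuli = list(pp), t_end = 4, n_points = 161)
  expect_gt(tcp$X[which.min(abs(tcp$time - 2.25))],
            tcp$X[which.min(abs(tcp$time - 1.9))])
})

test_that("DC sweep warm-starts and detects hysteresis only where it exists", {
  # inert input: flat line at beta/d
  m <- parse_netlist(c(".parameters", ".species", "X 0 0.5", "U 0 0",
                       ".reactions", "Cp {X} {2}", ".simulation"))
  sw <- dc_sweep(build_system(m), "U", c(0, 1, 2, 5))
  expect_equal(sw$X, rep(4, 4), tolerance = 1e-9)
  # Hill reporter driven by its clamped activator: half plateau at K
  mh <- parse_netlist(c(".parameters",
                        ".species", "A 0 0", "G 0 1",
                        ".reactions", "Hrep {A} {G} {4,2,2}",
                        ".simulation"))
  sysh <- build_system(mh)
  swh <- dc_sweep(sysh, "A", c(0, 2, 1000))
  plateau <- swh$G[3]
  expect_equal(swh$G[2], plateau / 2, tolerance = 1e-3)
  # band detector: no hysteresis (forward == reverse)
  bd <- build_system(fixtures("band_detector"))
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 25))
  fwd <- dc_sweep(bd, "AHL", grid)
  rev <- dc_sweep(bd, "AHL", base::rev(grid))
  expect_lt(max(abs(fwd$GFP - base::rev(rev$GFP)) /
                  pmax(abs(fwd$GFP), 1e-9)), 1e-6)
  # toggle switch swept through its bistable region: hysteresis appears
  # (sweeping I2, the enzyme erasing R1, flips state 0 -> 1 on the way
  # up; the reverse branch stays in state 1)
  tg <- build_system(fixtures("toggle_switch"))
  tgrid <- seq(0, 3, length.out = 13)
  f <- dc_sweep(tg, "I2", tgrid)
  r <- dc_sweep(tg, "I2", base::rev(tgrid))
  expect_gt(max(abs(f$R1 - base::rev(r$R1))), 1)
})

test_that("band detector output peaks at intermediate input only", {
  bd <- build_system(fixtures("band_detector"))
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 31))
  sw <- dc_sweep(bd, "AHL", grid)
  g <- sw$GFP
  k <- which.max(g)
  expect_gt(k, 1); expect_lt(k, length(g))
  expect_gt(max(g), 100 * g[1])
  expect_gt(max(g), 100 * g[length(g)])
  expect_true(all(diff(g[1:k]) > 0))
  expect_true(all(diff(g[k:length(g)]) < 0))
})

test_that("transfer function matches the one-pole closed form", {
  d <- 0.5
  sys <- build_system(decay_model(d = d, x0 = 0))
  w <- 10^seq(-2, 2, length.out = 33)
  tf <- transfer_function(sys, "X", "X", w)
  expect_lt(max(abs(tf$magnitude - 1 / sqrt(d^2 + w^2))), 1e-9)
  tf0 <- transfer_function(sys, "X", "X", 1e-9)
  expect_equal(tf0$magnitude, 1 / d, tolerance = 1e-9)        # DC gain
  tfd <- transfer_function(sys, "X", "X", d)
  expect_equal(tfd$magnitude, (1 / d) / sqrt(2), tolerance = 1e-9)  # -3 dB
  expect_lt(tf$magnitude[length(w)], 1e-2 * tf$magnitude[1])  # roll-off
})

test_that("transfer function agrees with a sinusoid-driven transient", {
  d <- 0.5; wdrive <- 1
  sys <- build_system(decay_model(d = d, x0 = 0))
  tf <- transfer_function(sys, "X", "X", wdrive)
  # brute-force oracle: drive dx/dt = -d x + sin(w t), measure the
  # steady oscillation amplitude
  sol <- deSolve::ode(y = 0, times = seq(0, 80, 0.02),
                      func = function(t, y, p) list(-d * y + sin(wdrive * t)),
                      rtol = 1e-10, atol = 1e-12)
  late <- sol[sol[, 1] > 60, 2]
  amp <- (max(late) - min(late)) / 2
  expect_lt(abs(amp - tf$magnitude) / amp, 0.02)
})

test_that("truth tables cover combinations in Gray order", {
  # k=1 on an inert-input model: both segments identical
  m <- parse_netlist(c(".parameters", ".species", "X 0 0.5", "U 0 1",
                       ".reactions", "Cp {X} {2}", ".simulation"))
  tt <- truth_table(build_system(m), "U", on_level = 1, segment = 60)
  expect_equal(nrow(tt$table), 2)
  expect_equal(tt$table$X[1], tt$table$X[2], tolerance = 1e-6)
  # k=2: 4 segments over 4*segment horizon, one bit flips per edge
  ag <- build_system(fixtures("and_gate"))
  tt2 <- truth_table(ag, c("InA", "InB"), on_level = 10, segment = 40)
  expect_equal(nrow(tt2$table), 4)
  expect_equal(max(tt2$result$time), 160)
  bits <- as.matrix(tt2$table[, c("in_InA", "in_InB")])
  expect_true(all(rowSums(abs(diff(bits))) == 1))
  # AND gate: output high only in the (1,1) segment
  thr <- max(tt2$table$OutP) / 2
  on <- tt2$table$OutP > thr
  expect_equal(on, bits[, 1] == 1 & bits[, 2] == 1)
})

test_that("run_model dispatches on the embedded analysis directive", {
  res <- run_model(fixtures("band_detector"))
  expect_s3_class(res, "bsp_result")
  expect_equal(attr(res, "axis_kind"), "sweep")
  st <- run_model(beta_d_model(2, 0.5))
  expect_equal(st$X, 4, tolerance = 1e-9)
  tcm <- fixtures("self_inhibited")
  expect_equal(attr(run_model(tcm), "axis_kind"), "time")
})
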