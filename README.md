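# biospice

Circuit-style modeling and simulation of biochemical reaction networks
in R.

`biospice` treats a biochemical system the way an analog circuit
simulator treats a circuit. The analogy maps concentration to node
voltage and molecule flux to current: every chemical species is a node
with a capacitor (its compartment volume) storing "charge"
(molecules), natural degradation is a leak resistor of value `1/d`,
and every reaction is a set of controlled current sources — one per
reactant (sign −) and one per product (sign +) — whose common value is
the reaction's rate law. Kirchhoff's current law at each node then
reproduces the familiar ODE system

```
d[X]/dt = ( Σ_reactions  sign · stoich · v(reaction)  −  d_X·[X] ) / V_X
```

The package provides, around that core:

* **A compact netlist language** for biochemical systems — four
  sections (`.parameters`, `.species`, `.reactions`, `.simulation`),
  one line per object, SPICE-style comments and engineering suffixes.
  The first letter of a reaction name selects its rate law:

  | letter | reaction | rate law |
  |---|---|---|
  | `B` | binding | `k_on·Π[R_k]^nR_k − k_off·Π[P_k]^nP_k` |
  | `C` | constant production | `β` |
  | `D` | simple decay | `d·[X]` |
  | `E` | enzymatic | `v_max·[E]·[S]/(K_m+[S])` |
  | `F` | passive diffusion | `D·([X]_A − [X]_B)` |
  | `H` | Hill-controlled | `v_max·[R]^n/(K^n+[R]^n)` |
  | `L` | mRNA translation | `k_TL·[mRNA]` |
  | `P` | pump | `v_max·Π_j [M_j]^n_j/(K_j^n_j+[M_j]^n_j)` |
  | `T` | DNA transcription | `k_TR·num/(1+Σ_act+Σ_rep)` (Hill occupancy) |
  | `X` | custom | any quoted expression over `[species]` and parameters |

* **A multi-analysis engine**: operating point (damped Newton with a
  pseudo-transient fallback), multistart stable-state search, stiff
  transient simulation with pulse/waveform stimuli, DC sweeps with
  continuation, small-signal transfer functions (Bode analysis around
  the operating point) and truth-table logic runs in Gray-code order.
* **SBML Level 3 import/export** (Level 2 accepted on import), with
  kinetic-law MathML translation, local-parameter substitution,
  function inlining, assignment/rate rules, and an import report that
  partitions every construct into supported/dropped.
* **An NGSPICE netlist exporter** applying the device mapping above
  (behavioral `B` sources for rate laws, `1/D` resistors for
  diffusion, `.TRAN/.DC/.AC` for the analyses).
* **Benchmark generators**: repressilator-ring gene regulatory
  networks of any odd size (`2n+2` species and reactions) and random
  enzymatic pathways with feedback/feedforward edges, plus built-in
  fixture circuits (toggle switch, band detector, AND gate, a
  penicillin-biosensor reaction stage, a self-inhibited enzymatic
  loop).

Results come back as tibbles with `tidy()`, `glance()` and
`autoplot()` methods, so everything composes with the tidyverse.

## Worked example: a bistable toggle switch

Two genes repress each other; enzymes `I1`/`I2` erase one repressor or
the other; a GFP readout reports the state.

```r
library(biospice)

model <- fixtures("toggle_switch")
model_summary(model)
#> # A tibble: 1 × 5
#>   n_species n_reactions n_parameters n_directives types
#>       <int>       <int>        <int>        <int> <chr>
#> 1         7           5            7            2 ET

sys <- build_system(model)
count_sources(sys, prune_inert = TRUE)
#> [1] 5
#> attr(,"nodes")
#> [1] 5

find_stable_states(sys, n_starts = 32, seed = 0)
#> # A tibble: 2 × 8
#>      R1     R2    I1    I2   GFP    X1    X2  residual
#>   <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>     <dbl>
#> 1 9.90  0.101      0     0 0.101     0    0   1.42e-11
#> 2 0.101 9.90       0     0 9.90      0    0   2.55e-11
```

The two rows are the memory states: "0" (`R1` high, GFP off) and "1"
(`R2` and GFP high, mirror-symmetric concentrations). A pulse of the
erasing enzyme flips the memory:

```r
state1 <- c(R1 = 0.101, R2 = 9.90, I1 = 0, I2 = 0, GFP = 9.90, X1 = 0, X2 = 0)
pulse <- bsp_directive("PULSE", species = "I1", delay = 10, length = 20,
                       height = 2, frequency = 0)
tc <- time_course(sys, stimuli = list(pulse), t_end = 300, x0 = state1)
tail(tc[, c("time", "R1", "R2", "GFP")], 1)
#>    time    R1    R2    GFP
#> 1   300  9.90 0.101  0.101      # switched to state "0"
autoplot(tc, species = c("R1", "R2", "GFP"))
```

Export the same model for other tools:

```r
export_sbml(model, "toggle.xml")       # SBML Level 3
write_spice(to_spice(model), "toggle.cir")  # NGSPICE deck
```

A command-line front end wrapping these functions is installed at
`system.file("cli", "biospice.R", package = "biospice")` with
subcommands `simulate`, `to-sbml`, `from-sbml`, `to-spice` and `bench`.

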