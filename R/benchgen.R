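# Benchmark generators and the fixture models used across the test
# suite: a self-inhibited enzymatic loop, a genetic toggle switch, a
# penicillin-biosensor reaction stage, a band detector and an AND gate,
# plus scalable repressilator-ring GRNs and random metabolic pathways.
#
# Kinetic constants are package defaults chosen to sit inside the
# qualitative regime each fixture is meant to exhibit (bistability,
# sustained oscillation, band-pass response, ...); see the methods
# vignette for the rationale behind each value.

#' Generate a repressilator-ring gene regulatory network
#'
#' A ring of `n_genes` (odd) genes, each transcribed into an mRNA
#' (repressed by the previous gene's protein) and translated into its
#' protein, plus one reporter gene (mRNA + protein) repressed by gene
#' 1's protein: `2*n_genes + 2` species and as many reactions.
#' Default kinetics sit in the classic oscillatory regime of the
#' mRNA-protein repressilator (strong maximal transcription, Hill
#' coefficient 2, protein/mRNA lifetime ratio 0.2).
#'
#' @param n_genes odd integer >= 3.
#' @param k_TR maximal transcription rate.
#' @param k_TL translation rate per mRNA.
#' @param KR,nR repression Hill constant and coefficient.
#' @param d_mRNA,d_protein degradation rates.
#' @return a [bsp_model()].
#' @export
gen_repressilator_grn <- function(n_genes, k_TR = 216, k_TL = 0.2, KR = 1,
                                  nR = 2, d_mRNA = 1, d_protein = 0.2) {
  if (n_genes < 3 || n_genes %% 2 == 0)
    stop("n_genes must be an odd integer >= 3 (even rings do not oscillate)",
         call. = FALSE)
  params <- tibble::tibble(
    name = c("kTR", "kTL", "KR", "nR"),
    expression = as.character(c(k_TR, k_TL, KR, nR)),
    comment = c("max transcription rate", "translation rate per mRNA",
                "repression Hill constant", "repression Hill coefficient"))
  genes <- seq_len(n_genes)
  mrna <- paste0("mRNA", genes)
  prot <- paste0("P", genes)
  species <- tibble::tibble(
    name = c(mrna, prot, "mRNArep", "Prep"),
    initial = c(ifelse(genes == 1, 5, 0), rep(0, n_genes), 0, 0),
    degradation = c(rep(d_mRNA, n_genes), rep(d_protein, n_genes),
                    d_mRNA, d_protein),
    compartment = 1)
  reactions <- list()
  for (i in genes) {
    prev <- prot[if (i == 1) n_genes else i - 1]
    reactions[[length(reactions) + 1]] <-
      bsp_reaction(paste0("Ttx", i), products = mrna[i], repressors = prev,
                   params = list(k_TR = "kTR", KR = "KR", nR = "nR"))
    reactions[[length(reactions) + 1]] <-
      bsp_reaction(paste0("Ltl", i), products = prot[i], modifiers = mrna[i],
                   params = list(k_TL = "kTL"))
  }
  reactions[[length(reactions) + 1]] <-
    bsp_reaction("Ttxrep", products = "mRNArep", repressors = prot[1],
                 params = list(k_TR = "kTR", KR = "KR", nR = "nR"))
  reactions[[length(reactions) + 1]] <-
    bsp_reaction("Ltlrep", products = "Prep", modifiers = "mRNArep",
                 params = list(k_TL = "kTL"))
  bsp_model(parameters = params, species = species, reactions = reactions,
            directives = list(bsp_directive("TIMECOURSE", t_end = 200,
                                            n_points = 401L),
                              bsp_directive("PLOT", species = "Prep")))
}

#' Generate a random metabolic pathway
#'
#' `n_species` species on a linear chain of `n_species` enzymatic
#' reactions (the last one a pure sink), fed by a constant source into
#' species 1, plus `n_reactions - n_species` extra feedback/feedforward
#' enzymatic reactions between uniformly drawn ordered species pairs.
#' Every enzymatic reaction is catalyzed by a uniformly drawn species
#' of the pathway (Michaelis--Menten).  Generation is reproducible from
#' `seed`.
#'
#' @param n_species number of species `N >= 2`.
#' @param n_reactions number of enzymatic reactions `M >= N`.
#' @param seed RNG seed.
#' @param source_rate constant influx into species 1.
#' @param v_max,K_m shared enzymatic kinetics.
#' @return a [bsp_model()].
#' @export
gen_random_pathway <- function(n_species, n_reactions, seed = 0,
                               source_rate = 1, v_max = 1, K_m = 1) {
  stopifnot(n_species >= 2, n_reactions >= n_species)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sp <- paste0("S", seq_len(n_species))
  # first-order dilution on every node bounds the total mass, so the
  # source-driven pathway always has a (nontrivial) steady state even
  # when the saturable enzymatic sink alone could not absorb the influx
  species <- tibble::tibble(name = sp, initial = 1, degradation = 0.1,
                            compartment = 1)
  params <- tibble::tibble(name = c("src", "vmax", "km"),
                           expression = as.character(c(source_rate, v_max, K_m)),
                           comment = c("chain influx", "enzymatic v_max",
                                       "enzymatic K_m"))
  reactions <- list(bsp_reaction("Cin", products = sp[1],
                                 params = list(beta = "src")))
  add_e <- function(name, from, to) {
    bsp_reaction(name, reactants = sp[from],
                 products = if (is.na(to)) NULL else sp[to],
                 modifiers = sp[sample.int(n_species, 1)],
                 params = list(v_max = "vmax", K_m = "km"))
  }
  for (i in seq_len(n_species)) {
    reactions[[length(reactions) + 1]] <-
      add_e(paste0("Echain", i), i, if (i < n_species) i + 1 else NA)
  }
  for (j in seq_len(n_reactions - n_species)) {
    pair <- sample.int(n_species, 2, replace = FALSE)
    reactions[[length(reactions) + 1]] <-
      add_e(paste0("Extra", j), pair[1], pair[2])
  }
  bsp_model(parameters = params, species = species, reactions = reactions,
            directives = list(bsp_directive("STEADY")))
}

# ---- fixtures --------------------------------------------------------

.fixture_self_inhibited <- function() {
  params <- tibble::tibble(
    name = c("alpha", "Vmax", "Km", "KP", "nB", "dS", "dP"),
    expression = c("1", "2", "1", "1", "2", "0.1", "0.2"),
    comment = c("constant production of S", "max enzymatic rate",
                "Michaelis constant", "inhibition Hill constant",
                "inhibition Hill number", "S degradation", "P degradation"))
  species <- tibble::tibble(name = c("S", "P"), initial = c(0, 0),
                            degradation = c(0.1, 0.2), compartment = 1)
  reactions <- list(
    bsp_reaction("Cprod", products = "S", params = list(beta = "alpha")),
    bsp_reaction("Xenz", reactants = "S", products = "P",
                 rate = "Vmax*[S]/(Km+[S])*KP^nB/(KP^nB+[P]^nB)"))
  bsp_model(parameters = params, species = species, reactions = reactions,
            directives = list(bsp_directive("TIMECOURSE", t_end = 100,
                                            n_points = 201L),
                              bsp_directive("PLOT", species = c("S", "P"))))
}

# Symmetric bistable toggle: two mutually repressing genes (R1, R2),
# enzymes I1/I2 that convert the high repressor into inert X1/X2, and a
# GFP readout repressed by R1.  nR = 2 and v/(d*K) = 10 guarantee
# bistability; injecting I1 erases R2 (flips "1" -> "0"), I2 erases R1.
.fixture_toggle_switch <- function() {
  params <- tibble::tibble(
    name = c("kTR", "KRt", "nRt", "dR", "vE", "KmE", "dI"),
    expression = c("1", "1", "2", "0.1", "5", "1", "1"),
    comment = c("max transcription rate", "repression Hill constant",
                "repression Hill number", "repressor/GFP degradation",
                "enzymatic v_max", "enzymatic K_m", "enzyme degradation"))
  species <- tibble::tibble(
    name = c("R1", "R2", "I1", "I2", "GFP", "X1", "X2"),
    initial = c(10, 0, 0, 0, 0, 0, 0),
    degradation = c(0.1, 0.1, 1, 1, 0.1, 0, 0),
    compartment = 1)
  reactions <- list(
    bsp_reaction("Ttx1", products = "R2", repressors = "R1",
                 params = list(k_TR = "kTR", KR = "KRt", nR = "nRt")),
    bsp_reaction("Ttx2", products = "R1", repressors = "R2",
                 params = list(k_TR = "kTR", KR = "KRt", nR = "nRt")),
    bsp_reaction("Ecv1", reactants = "R2", products = "X2", modifiers = "I1",
                 params = list(v_max = "vE", K_m = "KmE")),
    bsp_reaction("Ecv2", reactants = "R1", products = "X1", modifiers = "I2",
                 params = list(v_max = "vE", K_m = "KmE")),
    bsp_reaction("Ttx5", products = "GFP", repressors = "R1",
                 params = list(k_TR = "kTR", KR = "KRt", nR = "nRt")))
  bsp_model(parameters = params, species = species, reactions = reactions,
            directives = list(bsp_directive("TIMECOURSE", t_end = 200,
                                            n_points = 401L),
                              bsp_directive("PLOT", species = "GFP")))
}

# Reaction stage of a penicillin biosensor: penicillin hydrolysis at an
# enzyme-coated surface releases protons, buffered by phosphate and
# exchanged with a large, well-stirred chamber through a gel membrane.
# 5 species (Pen, Pcl, H, B, BH) instantiated in the chamber and at two
# sensor surfaces + the chamber-only penicillinase: 16 species,
# 1 enzymatic + 10 diffusion + 3 binding reactions.  pH is a derived
# output (-log10[H]); volumes make the chamber 100x each surface film.
.fixture_penicillin <- function() {
  comps <- c("ch", "s1", "s2")
  base <- c("Pen", "Pcl", "H", "B", "BH")
  nm <- function(s, c) paste0(s, "_", c)
  species <- tibble::tibble(
    name = c(as.vector(outer(base, comps, nm)), "Enz"),
    initial = 0, degradation = 0, compartment = 1)
  vols <- c(ch = 1, s1 = 0.01, s2 = 0.01)
  for (c in comps) {
    species$compartment[species$name %in% nm(base, c)] <- vols[[c]]
    species$initial[species$name == nm("H", c)] <- 6.31e-8  # pH = buffer pKa
    species$initial[species$name == nm("B", c)] <- 5e-3
    species$initial[species$name == nm("BH", c)] <- 5e-3
  }
  species$initial[species$name == "Pen_ch"] <- 2e-3
  species$compartment[species$name == "Enz"] <- 1
  species$initial[species$name == "Enz"] <- 1e-6

  params <- tibble::tibble(
    name = c("vmaxE", "KmE", "Dpen", "Dsol", "konB", "koffB"),
    expression = c("1e5", "1e-4", "0.5", "0.2", "1e8", "6.31"),
    comment = c("penicillinase turnover", "penicillinase K_m",
                "gel-membrane diffusion constant for penicillin",
                "gel-membrane diffusion constant for ions/buffer",
                "phosphate protonation k_on (pKa 7.2)",
                "phosphate protonation k_off"))
  reactions <- list(
    bsp_reaction("Ehydrolysis", reactants = nm("Pen", "s1"),
                 products = c(nm("Pcl", "s1"), nm("H", "s1")),
                 modifiers = "Enz", params = list(v_max = "vmaxE", K_m = "KmE")))
  for (s in base) for (surf in c("s1", "s2")) {
    reactions[[length(reactions) + 1]] <-
      bsp_reaction(paste0("Fdiff_", s, "_", surf),
                   reactants = nm(s, "ch"), products = nm(s, surf),
                   params = list(D = if (s == "Pen") "Dpen" else "Dsol"))
  }
  for (c in comps) {
    reactions[[length(reactions) + 1]] <-
      bsp_reaction(paste0("Bbuffer_", c),
                   reactants = c(nm("H", c), nm("B", c)),
                   products = nm("BH", c),
                   params = list(k_on = "konB", k_off = "koffB"))
  }
  bsp_model(parameters = params, species = species, reactions = reactions,
            directives = list(bsp_directive("TIMECOURSE", t_end = 400,
                                            n_points = 401L),
                              bsp_directive("PLOT",
                                            species = c(nm("H", "s1"),
                                                        nm("H", "s2")))))
}

# Band detector: GFP only at intermediate input.  The output promoter
# is constitutive and repressed by two branches: Rlo, itself repressed
# by the input at a low threshold (so present only at LOW input), and
# Rhi, activated by the input at a high threshold (present only at
# HIGH input).  Both branches off -> band of expression in between.
.fixture_band_detector <- function() {
  params <- tibble::tibble(
    name = c("kTRb", "kTLb", "Klo", "Khi", "KRb", "nH", "dm", "dp"),
    expression = c("10", "1", "0.03", "10", "1", "2", "1", "0.2"),
    comment = c("max transcription", "translation rate",
                "input threshold shutting the low branch",
                "input threshold switching on the high branch",
                "branch repression constant", "Hill coefficient",
                "mRNA degradation", "protein degradation"))
  species <- tibble::tibble(
    name = c("AHL", "mRlo", "Rlo", "mRhi", "Rhi", "mGFP", "GFP"),
    initial = 0, degradation = c(0, 1, 0.2, 1, 0.2, 1, 0.2), compartment = 1)
  reactions <- list(
    bsp_reaction("TtxRlo", products = "mRlo", repressors = "AHL",
                 params = list(k_TR = "kTRb", KR = "Klo", nR = "nH")),
    bsp_reaction("LtlRlo", products = "Rlo", modifiers = "mRlo",
                 params = list(k_TL = "kTLb")),
    bsp_reaction("TtxRhi", products = "mRhi", activators = "AHL",
                 params = list(k_TR = "kTRb", KA = "Khi", nA = "nH")),
    bsp_reaction("LtlRhi", products = "Rhi", modifiers = "mRhi",
                 params = list(k_TL = "kTLb")),
    bsp_reaction("TtxGFP", products = "mGFP", repressors = c("Rlo", "Rhi"),
                 params = list(k_TR = "kTRb", KR = c("KRb", "KRb"),
                               nR = c("nH", "nH"))),
    bsp_reaction("LtlGFP", products = "GFP", modifiers = "mGFP",
                 params = list(k_TL = "kTLb")))
  bsp_model(parameters = params, species = species, reactions = reactions,
            directives = list(bsp_directive("SWEEP", species = "AHL",
                                            from = 1e-3, to = 1e3,
                                            npoints = 61L, scale = "log"),
                              bsp_directive("PLOT", species = "GFP")))
}

# Two-input AND gate: the output promoter is activated by input A and
# repressed by NotB, a constitutive protein that input B shuts off.
# Output is high only when both A and B are present.
.fixture_and_gate <- function() {
  params <- tibble::tibble(
    name = c("kTRa", "kTLa", "KAa", "KRnb", "KRb", "nH2", "dma", "dpa"),
    expression = c("10", "1", "1", "0.2", "1", "2", "1", "0.5"),
    comment = c("max transcription", "translation rate",
                "A activation constant", "NotB repression constant (strong)",
                "B repression of NotB", "Hill coefficient",
                "mRNA degradation", "protein degradation"))
  species <- tibble::tibble(
    name = c("InA", "InB", "mNotB", "NotB", "mOut", "OutP"),
    initial = 0, degradation = c(1, 1, 1, 0.5, 1, 0.5), compartment = 1)
  reactions <- list(
    bsp_reaction("TtxNotB", products = "mNotB", repressors = "InB",
                 params = list(k_TR = "kTRa", KR = "KRb", nR = "nH2")),
    bsp_reaction("LtlNotB", products = "NotB", modifiers = "mNotB",
                 params = list(k_TL = "kTLa")),
    bsp_reaction("TtxOut", products = "mOut", activators = "InA",
                 repressors = "NotB",
                 params = list(k_TR = "kTRa", KA = "KAa", nA = "nH2",
                               KR = "KRnb", nR = "nH2")),
    bsp_reaction("LtlOut", products = "OutP", modifiers = "mOut",
                 params = list(k_TL = "kTLa")))
  bsp_model(parameters = params, species = species, reactions = reactions,
            directives = list(bsp_directive("TRUTHTABLE",
                                            inputs = c("InA", "InB"),
                                            on_level = 10, segment = 40),
                              bsp_directive("PLOT", species = "OutP")))
}

#' Built-in fixture models
#'
#' Named small models exercising every reaction type and analysis:
#' `self_inhibited` (constant production + product-inhibited enzymatic
#' conversion), `toggle_switch` (bistable mutual repression with enzyme
#' erasure and a GFP readout; 7 species, 5 reactions),
#' `penicillin_bio` (the reaction stage of a penicillin biosensor:
#' 16 species, 1 enzymatic + 10 diffusion + 3 binding reactions),
#' `band_detector` (incoherent feedforward band-pass) and `and_gate`
#' (two-input transcriptional AND).
#'
#' @param name optional fixture name; omit for the full named list.
#' @return a [bsp_model()], or a named list of all fixtures.
#' @export
fixtures <- function(name = NULL) {
  all <- list(self_inhibited = .fixture_self_inhibited,
              toggle_switch = .fixture_toggle_switch,
              penicillin_bio = .fixture_penicillin,
              band_detector = .fixture_band_detector,
              and_gate = .fixture_and_gate)
  if (is.null(name)) return(lapply(all, function(f) f()))
  if (!name %in% names(all))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(all), collapse = ", "), call. = FALSE)
  all[[name]]()
}

#' pH trace from a proton concentration series
#'
#' Derived output for the biosensor fixture: `pH = -log10([H+]/1 mol/l)`,
#' computed at reporting time (protons stay a state variable).
#'
#' @param result a [time_course()] result.
#' @param species proton species column.
#' @return tibble with `time` and `pH`.
#' @export
ph_trace <- function(result, species = "H_s1") {
  tibble::tibble(time = result$time, pH = -log10(pmax(result[[species]], 1e-300)))
}
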