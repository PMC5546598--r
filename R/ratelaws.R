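# Reaction-rate laws for each reaction type.
#
# All rates are in concentration/time, evaluated at nonnegative
# concentrations.  Hill terms guard x = 0 explicitly so that 0^0 never
# arises: a regulator at zero concentration contributes factor 0 (for
# n > 0) before any power is taken.

# x^n with the zero guard used by every Hill-type term.
.hill_pow <- function(x, n) if (x <= 0) 0 else x^n

# Resolve a reaction's parameter entries (numbers or parameter
# formulas) to numerics against resolved model parameters.
.rparams <- function(r, params = numeric()) {
  lapply(r$params, function(v) {
    if (!is.character(v)) return(v)
    vapply(v, bsp_eval_scalar, 0, params = params, USE.NAMES = FALSE)
  })
}

.conc <- function(conc, sp) {
  out <- conc[sp]
  if (anyNA(out))
    stop(sprintf("missing concentration(s): %s",
                 paste(sp[is.na(out)], collapse = ", ")), call. = FALSE)
  if (any(out < 0))
    stop(sprintf("negative concentration for: %s",
                 paste(sp[out < 0], collapse = ", ")), call. = FALSE)
  unname(out)
}

#' Rate laws for individual reactions
#'
#' Evaluate the rate of one reaction at a set of concentrations:
#' * `rate_binding()` — mass action,
#'   \eqn{v = k_{on}\prod_k [R_k]^{nR_k} - k_{off}\prod_k [P_k]^{nP_k}};
#'   `k_off = 0` encodes an irreversible reaction.
#' * `rate_enzymatic()` — Michaelis–Menten,
#'   \eqn{v = v_{max}[E][S]/(K_m+[S])}; several listed enzymes act as
#'   the sum of their concentrations, an empty enzyme list means the
#'   rate is per unit enzyme.
#' * `rate_diffusion()` — passive diffusion \eqn{v = D([X]_A - [X]_B)},
#'   positive from the first (in) species to the second (out) species.
#' * `rate_hill()` — \eqn{v = v_{max}[R]^n/(K^n+[R]^n)}.
#' * `rate_translation()` — \eqn{v = k_{TL}[mRNA]}.
#' * `rate_pump()` — \eqn{v = v_{max}\prod_j [M_j]^{n_j}/(K_j^{n_j}+[M_j]^{n_j})};
#'   with no regulators the pump runs at `v_max`.
#' * `rate_transcription()` — promoter occupancy form
#'   \eqn{v = k_{TR}\,\mathrm{num}/(1+\sum_j([A_j]/KA_j)^{nA_j}+\sum_j([R_j]/KR_j)^{nR_j})}
#'   with \eqn{\mathrm{num}=\sum_j([A_j]/KA_j)^{nA_j}} when activators are
#'   declared and 1 (constitutive promoter) otherwise, so a
#'   repressor-only promoter reduces to the usual inhibitory Hill law.
#' * `rate_custom()` — evaluates the reaction's quoted expression, with
#'   species in brackets (`[S]`) and parameters bare.
#' * `reaction_rate()` — dispatches on the reaction's type (including
#'   `C`, constant production at `beta`, and `D`, linear decay `d*[X]`).
#'
#' @param r a [bsp_reaction()] of the matching type.
#' @param conc named numeric vector of concentrations; must cover every
#'   species the reaction references.
#' @param params named numeric vector of resolved model parameters (see
#'   [resolve_parameters()]), needed when the reaction's kinetic
#'   parameters are given as formulas.
#' @return the scalar rate (concentration/time).
#' @name ratelaws
NULL

#' @rdname ratelaws
#' @export
rate_binding <- function(r, conc, params = numeric()) {
  p <- .rparams(r, params)
  rc <- .conc(conc, r$reactants$species)
  pc <- .conc(conc, r$products$species)
  fwd <- p$k_on * prod(rc^r$reactants$stoich)
  rev <- if (p$k_off > 0 && nrow(r$products) > 0)
    p$k_off * prod(pc^r$products$stoich) else 0
  fwd - rev
}

#' @rdname ratelaws
#' @export
rate_enzymatic <- function(r, conc, params = numeric()) {
  p <- .rparams(r, params)
  if (p$K_m <= 0) stop("enzymatic reaction: K_m must be > 0", call. = FALSE)
  S <- .conc(conc, r$reactants$species[1])
  E <- if (length(r$modifiers) > 0) sum(.conc(conc, r$modifiers)) else 1
  p$v_max * E * S / (p$K_m + S)
}

#' @rdname ratelaws
#' @export
rate_diffusion <- function(r, conc, params = numeric()) {
  p <- .rparams(r, params)
  A <- .conc(conc, r$reactants$species[1])
  B <- .conc(conc, r$products$species[1])
  p$D * (A - B)
}

#' @rdname ratelaws
#' @export
rate_hill <- function(r, conc, params = numeric()) {
  p <- .rparams(r, params)
  if (p$K <= 0) stop("Hill reaction: K must be > 0", call. = FALSE)
  R <- .conc(conc, r$reactants$species[1])
  Rn <- .hill_pow(R, p$n)
  p$v_max * Rn / (p$K^p$n + Rn)
}

#' @rdname ratelaws
#' @export
rate_translation <- function(r, conc, params = numeric()) {
  p <- .rparams(r, params)
  p$k_TL * .conc(conc, r$modifiers[1])
}

#' @rdname ratelaws
#' @export
rate_pump <- function(r, conc, params = numeric()) {
  p <- .rparams(r, params)
  if (length(p$K) != length(r$modifiers) || length(p$n) != length(r$modifiers))
    stop("pump: one (K_j, n_j) pair per regulator required", call. = FALSE)
  v <- p$v_max
  for (j in seq_along(r$modifiers)) {
    if (p$K[j] <= 0) stop("pump: K_j must be > 0", call. = FALSE)
    M <- .conc(conc, r$modifiers[j])
    Mn <- .hill_pow(M, p$n[j])
    v <- v * Mn / (p$K[j]^p$n[j] + Mn)
  }
  v
}

#' @rdname ratelaws
#' @export
rate_transcription <- function(r, conc, params = numeric()) {
  p <- .rparams(r, params)
  if (length(p$KA) != length(r$activators) || length(p$KR) != length(r$repressors))
    stop("transcription: one (K, n) pair per regulator required", call. = FALSE)
  if (any(c(p$KA, p$KR) <= 0))
    stop("transcription: Hill constants must be > 0", call. = FALSE)
  act <- 0
  for (j in seq_along(r$activators))
    act <- act + .hill_pow(.conc(conc, r$activators[j]) / p$KA[j], p$nA[j])
  rep <- 0
  for (j in seq_along(r$repressors))
    rep <- rep + .hill_pow(.conc(conc, r$repressors[j]) / p$KR[j], p$nR[j])
  num <- if (length(r$activators) > 0) act else 1
  p$k_TR * num / (1 + act + rep)
}

#' @rdname ratelaws
#' @export
rate_custom <- function(r, conc, params = numeric()) {
  ex <- if (!is.null(r$compiled_rate)) r$compiled_rate else bsp_parse_expr(r$rate)
  unknown <- setdiff(ex$species, names(conc))
  if (length(unknown) > 0)
    stop(sprintf("custom rate '%s' references unknown species: %s",
                 r$rate, paste(unknown, collapse = ", ")), call. = FALSE)
  unknown_p <- setdiff(ex$params, names(params))
  if (length(unknown_p) > 0)
    stop(sprintf("custom rate '%s' references unknown parameter(s): %s",
                 r$rate, paste(unknown_p, collapse = ", ")), call. = FALSE)
  bsp_eval_expr(ex, conc = conc, params = params)
}

#' @rdname ratelaws
#' @export
reaction_rate <- function(r, conc, params = numeric()) {
  switch(r$type,
    B = rate_binding(r, conc, params),
    C = .rparams(r, params)$beta,
    D = .rparams(r, params)$d * .conc(conc, r$reactants$species[1]),
    E = rate_enzymatic(r, conc, params),
    F = rate_diffusion(r, conc, params),
    H = rate_hill(r, conc, params),
    L = rate_translation(r, conc, params),
    P = rate_pump(r, conc, params),
    T = rate_transcription(r, conc, params),
    X = rate_custom(r, conc, params))
}
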