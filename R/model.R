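# The central model container: parameters, species, reactions,
# simulation directives and raw passthrough lines.

.reaction_types <- c(B = "binding", C = "constant_production", D = "decay",
                     E = "enzymatic", F = "diffusion", H = "hill",
                     L = "translation", P = "pump", T = "transcription",
                     X = "custom")

.directive_kinds <- c("FIX", "PULSE", "WAVEFORM", "TRANSFUNC", "TRUTHTABLE",
                      "STEADY", "SWEEP", "TIMECOURSE", "PLOT", "PLOTALL")

.analysis_kinds <- c("TRANSFUNC", "TRUTHTABLE", "STEADY", "SWEEP", "TIMECOURSE")

#' Construct a reaction
#'
#' The first letter of `name` selects the reaction type: `B` binding,
#' `C` constant production, `D` simple decay, `E` enzymatic
#' (Michaelis--Menten), `F` passive diffusion, `H` Hill-controlled,
#' `L` mRNA translation, `P` pump, `T` DNA transcription, `X` custom rate.
#'
#' @param name reaction identifier; its first letter is the type.
#' @param reactants,products data frames with columns `species` and
#'   `stoich`, or character vectors (stoichiometry 1).
#' @param modifiers character vector of species that shape the rate but
#'   carry no flux (enzymes, pump regulators).  For `T` reactions use
#'   `activators`/`repressors` instead.
#' @param params named list of kinetic parameters for the type; entries
#'   may be numbers or parameter-expression strings.
#' @param activators,repressors transcription-factor species (`T` only).
#' @param rate custom rate expression string (`X` only).
#' @return an object of class `bsp_reaction`.
#' @export
bsp_reaction <- function(name, reactants = NULL, products = NULL,
                         modifiers = character(), params = list(),
                         activators = character(), repressors = character(),
                         rate = NULL) {
  type <- toupper(substr(name, 1, 1))
  if (!type %in% names(.reaction_types))
    stop(sprintf("unknown reaction type letter '%s' in reaction '%s'", type, name),
         call. = FALSE)
  as_part <- function(x) {
    if (is.null(x)) return(tibble::tibble(species = character(), stoich = integer()))
    if (is.character(x)) return(tibble::tibble(species = x, stoich = rep(1L, length(x))))
    tibble::tibble(species = as.character(x$species), stoich = as.integer(x$stoich))
  }
  # canonical parameter layout: per-regulator slots always present
  if (type == "T") {
    for (f in c("KA", "nA", "KR", "nR"))
      if (is.null(params[[f]])) params[[f]] <- character()
    params <- params[c("k_TR", "KA", "nA", "KR", "nR")]
  }
  if (type == "P") {
    for (f in c("K", "n")) if (is.null(params[[f]])) params[[f]] <- character()
    params <- params[c("v_max", "K", "n")]
  }
  if (type == "B" && is.null(params$k_off) && !is.null(params$k_on))
    params$k_off <- "0"
  r <- structure(list(name = name, type = type,
                      reactants = as_part(reactants), products = as_part(products),
                      modifiers = as.character(modifiers), params = params,
                      activators = as.character(activators),
                      repressors = as.character(repressors),
                      rate = rate),
                 class = "bsp_reaction")
  if (any(c(r$reactants$stoich, r$products$stoich) < 1))
    stop(sprintf("reaction '%s': stoichiometries must be positive integers", name),
         call. = FALSE)
  r
}

#' Construct a simulation directive
#'
#' @param kind one of `FIX`, `PULSE`, `WAVEFORM`, `TRANSFUNC`, `TRUTHTABLE`,
#'   `STEADY`, `SWEEP`, `TIMECOURSE`, `PLOT`, `PLOTALL`.
#' @param ... kind-specific arguments (see the netlist format vignette).
#' @return an object of class `bsp_directive`.
#' @export
bsp_directive <- function(kind, ...) {
  kind <- toupper(kind)
  if (!kind %in% .directive_kinds)
    stop(sprintf("unknown directive kind '%s'", kind), call. = FALSE)
  structure(list(kind = kind, args = list(...)), class = "bsp_directive")
}

#' Construct a model
#'
#' The central exchange object: ordered parameter definitions, species
#' with initial concentration / degradation rate / compartment volume,
#' typed reactions, simulation directives and raw passthrough lines for
#' the SPICE exporter.
#'
#' @param parameters tibble with columns `name`, `expression`, `comment`.
#' @param species tibble with columns `name`, `initial`, `degradation`,
#'   `compartment`.
#' @param reactions list of [bsp_reaction()] objects.
#' @param directives list of [bsp_directive()] objects.
#' @param passthrough character vector of raw simulator lines.
#' @return an object of class `bsp_model`.
#' @export
bsp_model <- function(parameters = NULL, species = NULL, reactions = list(),
                      directives = list(), passthrough = character()) {
  if (is.null(parameters))
    parameters <- tibble::tibble(name = character(), expression = character(),
                                 comment = character())
  if (is.null(species))
    species <- tibble::tibble(name = character(), initial = double(),
                              degradation = double(), compartment = double())
  m <- structure(list(parameters = tibble::as_tibble(parameters),
                      species = tibble::as_tibble(species),
                      reactions = reactions, directives = directives,
                      passthrough = as.character(passthrough)),
                 class = "bsp_model")
  validate_model(m)
}

#' Validate a model's internal consistency
#'
#' Checks name uniqueness (case-insensitive, so the SPICE export stays
#' safe), disjoint species/parameter namespaces, nonnegative initial
#' concentrations and degradation rates, positive compartment volumes,
#' reaction cross-references and per-type parameter completeness.
#'
#' @param model a [bsp_model()].
#' @return the model, invisibly unchanged, or an error.
#' @export
validate_model <- function(model) {
  p <- model$parameters; s <- model$species
  if (anyDuplicated(tolower(p$name)))
    stop("duplicate parameter names (case-insensitive): ",
         paste(p$name[duplicated(tolower(p$name))], collapse = ", "), call. = FALSE)
  if (anyDuplicated(tolower(s$name)))
    stop("duplicate species names (case-insensitive): ",
         paste(s$name[duplicated(tolower(s$name))], collapse = ", "), call. = FALSE)
  clash <- intersect(tolower(p$name), tolower(s$name))
  if (length(clash) > 0)
    stop("names used both as parameter and species: ",
         paste(clash, collapse = ", "), call. = FALSE)
  if (any(s$initial < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
  if (any(s$degradation < 0)) stop("degradation rates must be >= 0", call. = FALSE)
  if (any(s$compartment <= 0)) stop("compartment volumes must be > 0", call. = FALSE)
  for (r in model$reactions) .validate_reaction(r, s$name)
  invisible(model)
}

.reaction_species <- function(r) {
  unique(c(r$reactants$species, r$products$species, r$modifiers,
           r$activators, r$repressors))
}

.validate_reaction <- function(r, declared) {
  unknown <- setdiff(.reaction_species(r), declared)
  if (length(unknown) > 0)
    stop(sprintf("reaction '%s' references undeclared species: %s",
                 r$name, paste(unknown, collapse = ", ")), call. = FALSE)
  need <- switch(r$type,
    B = c("k_on", "k_off"), C = "beta", D = "d", E = c("v_max", "K_m"),
    F = "D", H = c("v_max", "K", "n"), L = "k_TL",
    P = "v_max", T = "k_TR", X = character())
  missing <- setdiff(need, names(r$params))
  if (length(missing) > 0)
    stop(sprintf("reaction '%s' (type %s) is missing parameter(s): %s",
                 r$name, r$type, paste(missing, collapse = ", ")), call. = FALSE)
  if (r$type == "P") {
    nm <- length(r$modifiers)
    if (length(r$params$K %||% numeric()) != nm ||
        length(r$params$n %||% numeric()) != nm)
      stop(sprintf("reaction '%s': pump needs one (K_j, n_j) pair per regulator", r$name),
           call. = FALSE)
  }
  if (r$type == "T") {
    if (length(r$params$KA %||% numeric()) != length(r$activators) ||
        length(r$params$nA %||% numeric()) != length(r$activators) ||
        length(r$params$KR %||% numeric()) != length(r$repressors) ||
        length(r$params$nR %||% numeric()) != length(r$repressors))
      stop(sprintf("reaction '%s': transcription needs one (K, n) pair per regulator",
                   r$name), call. = FALSE)
  }
  if (r$type == "X" && (is.null(r$rate) || !nzchar(r$rate)))
    stop(sprintf("reaction '%s': custom reaction needs a rate expression", r$name),
         call. = FALSE)
  if (r$type == "E" && nrow(r$reactants) > 1)
    stop(sprintf("reaction '%s': enzymatic reactions support a single substrate", r$name),
         call. = FALSE)
  invisible(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bsp_model <- function(x, ...) {
  cat(sprintf("<bsp_model> %d parameter(s), %d species, %d reaction(s), %d directive(s)\n",
              nrow(x$parameters), nrow(x$species), length(x$reactions),
              length(x$directives)))
  if (length(x$reactions) > 0) {
    tt <- table(vapply(x$reactions, `[[`, "", "type"))
    cat("  reactions by type:",
        paste(sprintf("%s=%d", names(tt), as.integer(tt)), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
print.bsp_reaction <- function(x, ...) {
  side <- function(df) paste(ifelse(df$stoich > 1, paste0(df$stoich, "*", df$species),
                                    df$species), collapse = " + ")
  cat(sprintf("<bsp_reaction %s [%s]> %s -> %s\n", x$name, .reaction_types[[x$type]],
              side(x$reactants), side(x$products)))
  invisible(x)
}

#' Number of species and reactions of a model
#'
#' @param model a [bsp_model()].
#' @return a one-row tibble with counts by category.
#' @export
model_summary <- function(model) {
  tt <- vapply(model$reactions, `[[`, "", "type")
  tibble::tibble(n_species = nrow(model$species),
                 n_reactions = length(model$reactions),
                 n_parameters = nrow(model$parameters),
                 n_directives = length(model$directives),
                 types = paste(sort(unique(tt)), collapse = ""))
}
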