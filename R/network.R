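# Assembly of a model into the equivalent dynamical network.
#
# Under the circuit analogy each species is a charge-storage node
# (capacitor = compartment volume), natural degradation is a leak
# (resistor), and each reaction contributes one signed controlled
# source per reactant (-stoich) and per product (+stoich); modifiers
# shape rates but carry no flux.  The assembled right-hand side is
#   d[X]/dt = (sum of signed stoich * rate  -  d_X * [X]) / V_X
# with FIX-directive species algebraically clamped (derivative zeroed).

# Species whose concentration enters the reaction's rate.
.rate_deps <- function(r) {
  switch(r$type,
    B = unique(c(r$reactants$species,
                 if (!is.null(r$params$.koff_pos) && r$params$.koff_pos)
                   r$products$species)),
    C = character(),
    D = r$reactants$species,
    E = unique(c(r$reactants$species[1], r$modifiers)),
    F = c(r$reactants$species[1], r$products$species[1]),
    H = r$reactants$species[1],
    L = r$modifiers[1],
    P = r$modifiers,
    T = unique(c(r$activators, r$repressors)),
    X = r$compiled_rate$species)
}

# Compile a custom-rate expression into a fast function of the state
# vector: species symbols become x[i] lookups, parameters are folded in.
.compile_expr_fn <- function(ex, sp_index, params) {
  subs <- function(lang) {
    if (is.call(lang)) {
      for (i in seq_along(lang)[-1]) lang[[i]] <- subs(lang[[i]])
      return(lang)
    }
    if (is.symbol(lang)) {
      nm <- as.character(lang)
      if (startsWith(nm, ".S.")) {
        sp <- sub("^\\.S\\.", "", nm)
        return(call("[", as.symbol("x"), sp_index[[sp]]))
      }
      if (nm %in% names(params)) return(params[[nm]])
    }
    lang
  }
  body <- subs(ex$lang)
  env <- .bsp_eval_env()
  f <- function(x) NULL
  body(f) <- body
  environment(f) <- env
  f
}

# Build the per-reaction rate closure over state positions.
.compile_rate <- function(r, sp_index, params) {
  p <- .rparams(r, params)
  ri <- sp_index[r$reactants$species]; rs <- r$reactants$stoich
  pi <- sp_index[r$products$species];  ps <- r$products$stoich
  mi <- sp_index[r$modifiers]
  switch(r$type,
    B = {
      kon <- p$k_on; koff <- p$k_off
      if (koff > 0 && length(pi) > 0)
        function(x) kon * prod(x[ri]^rs) - koff * prod(x[pi]^ps)
      else
        function(x) kon * prod(x[ri]^rs)
    },
    C = { beta <- p$beta; function(x) beta },
    D = { d <- p$d; i <- ri[1]; function(x) d * x[i] },
    E = {
      vmax <- p$v_max; Km <- p$K_m; i <- ri[1]
      if (Km <= 0) stop(sprintf("reaction '%s': K_m must be > 0", r$name), call. = FALSE)
      if (length(mi) > 0) function(x) vmax * sum(x[mi]) * x[i] / (Km + x[i])
      else function(x) vmax * x[i] / (Km + x[i])
    },
    F = { D <- p$D; a <- ri[1]; b <- pi[1]; function(x) D * (x[a] - x[b]) },
    H = {
      vmax <- p$v_max; K <- p$K; n <- p$n; i <- ri[1]
      if (K <= 0) stop(sprintf("reaction '%s': K must be > 0", r$name), call. = FALSE)
      Kn <- K^n
      function(x) { Rn <- if (x[i] <= 0) 0 else x[i]^n; vmax * Rn / (Kn + Rn) }
    },
    L = { kTL <- p$k_TL; i <- mi[1]; function(x) kTL * x[i] },
    P = {
      vmax <- p$v_max; K <- p$K; n <- p$n
      if (any(K <= 0)) stop(sprintf("reaction '%s': K_j must be > 0", r$name), call. = FALSE)
      Kn <- K^n
      function(x) {
        m <- x[mi]; mn <- ifelse(m <= 0, 0, m^n)
        vmax * prod(mn / (Kn + mn))
      }
    },
    T = {
      kTR <- p$k_TR
      ai <- sp_index[r$activators]; KA <- p$KA; nA <- p$nA
      rj <- sp_index[r$repressors]; KR <- p$KR; nR <- p$nR
      if (any(c(KA, KR) <= 0))
        stop(sprintf("reaction '%s': Hill constants must be > 0", r$name), call. = FALSE)
      has_act <- length(ai) > 0
      function(x) {
        act <- if (has_act) {
          w <- x[ai] / KA; sum(ifelse(w <= 0, 0, w^nA))
        } else 0
        rep <- if (length(rj) > 0) {
          w <- x[rj] / KR; sum(ifelse(w <= 0, 0, w^nR))
        } else 0
        kTR * (if (has_act) act else 1) / (1 + act + rep)
      }
    },
    X = .compile_expr_fn(r$compiled_rate, sp_index, params))
}

#' Assemble a model into its dynamical network
#'
#' Resolves parameters, compiles every reaction's rate law and builds
#' the ODE right-hand side: one signed source term per reactant and per
#' product of each reaction, a leak term `-d*[X]` per species, all
#' divided by the compartment volume.  Species named in `FIX`
#' directives are clamped (state held, derivative zeroed).
#'
#' @param model a validated [bsp_model()].
#' @param clamps optional tibble with columns `species`, `value`
#'   overriding the model's `FIX` directives.
#' @return an object of class `bsp_system` with elements
#'   `species_order`, `x0`, `rhs(x, t)`, `volumes`, `degradation`,
#'   `clamped`, `params` and per-reaction source-term bookkeeping.
#' @export
build_system <- function(model, clamps = NULL) {
  validate_model(model)
  params <- resolve_parameters(model)
  sp <- model$species$name
  n <- length(sp)
  sp_index <- stats::setNames(seq_len(n), sp)
  x0 <- stats::setNames(model$species$initial, sp)
  dvec <- model$species$degradation
  Vvec <- model$species$compartment

  if (is.null(clamps)) {
    fx <- Filter(function(d) d$kind == "FIX", model$directives)
    clamps <- tibble::tibble(
      species = vapply(fx, function(d) d$args$species, ""),
      value = vapply(fx, function(d) d$args$value, 0))
  }
  unknown <- setdiff(clamps$species, sp)
  if (length(unknown) > 0)
    stop("FIX references unknown species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  clamp_idx <- unname(sp_index[clamps$species])
  clamp_val <- clamps$value
  x0[clamp_idx] <- clamp_val

  reactions <- lapply(model$reactions, function(r) {
    unknown <- setdiff(.reaction_species(r), sp)
    if (length(unknown) > 0)
      stop(sprintf("reaction '%s' references unknown species: %s",
                   r$name, paste(unknown, collapse = ", ")), call. = FALSE)
    if (r$type == "X") {
      r$compiled_rate <- bsp_parse_expr(r$rate)
      bad <- setdiff(r$compiled_rate$species, sp)
      if (length(bad) > 0)
        stop(sprintf("custom rate of '%s' references unknown species: %s",
                     r$name, paste(bad, collapse = ", ")), call. = FALSE)
      badp <- setdiff(r$compiled_rate$params, names(params))
      if (length(badp) > 0)
        stop(sprintf("custom rate of '%s' references unknown parameter(s): %s",
                     r$name, paste(badp, collapse = ", ")), call. = FALSE)
    }
    if (r$type == "B") {
      p <- .rparams(r, params)
      r$params$.koff_pos <- p$k_off > 0
    }
    r
  })

  rate_fns <- lapply(reactions, .compile_rate, sp_index = sp_index, params = params)
  # net signed stoichiometry per state index (a species appearing on
  # both sides of one reaction must accumulate, not overwrite)
  tgt <- lapply(reactions, function(r) {
    idx <- unname(c(sp_index[r$reactants$species], sp_index[r$products$species]))
    coef <- c(-r$reactants$stoich, r$products$stoich)
    u <- unique(idx)
    list(idx = u, coef = vapply(u, function(i) sum(coef[idx == i]), 0))
  })
  tgt_idx <- lapply(tgt, `[[`, "idx")
  tgt_coef <- lapply(tgt, `[[`, "coef")
  deps <- lapply(reactions, .rate_deps)

  nclamp <- length(clamp_idx)
  rhs <- function(x, t = 0) {
    xp <- pmax(x, 0)
    if (nclamp) xp[clamp_idx] <- clamp_val
    dx <- numeric(n)
    for (k in seq_along(rate_fns)) {
      v <- rate_fns[[k]](xp)
      ti <- tgt_idx[[k]]
      dx[ti] <- dx[ti] + tgt_coef[[k]] * v
    }
    dx <- (dx - dvec * xp) / Vvec
    if (nclamp) dx[clamp_idx] <- 0
    dx
  }

  structure(list(model = model, params = params,
                 species_order = sp, x0 = x0,
                 volumes = stats::setNames(Vvec, sp),
                 degradation = stats::setNames(dvec, sp),
                 clamped = tibble::tibble(species = clamps$species, value = clamp_val),
                 reactions = reactions, rate_fns = rate_fns,
                 tgt_idx = tgt_idx, tgt_coef = tgt_coef, deps = deps,
                 rhs = rhs),
            class = "bsp_system")
}

#' @export
print.bsp_system <- function(x, ...) {
  cat(sprintf("<bsp_system> %d state(s), %d reaction(s), %d clamped\n",
              length(x$species_order), length(x$reactions), nrow(x$clamped)))
  invisible(x)
}

# Species referenced by any simulation directive (treated as observed:
# they are retained by pruning even when inert, like a fluorescent
# readout).
.directive_species <- function(model) {
  out <- character()
  for (d in model$directives) {
    a <- d$args
    out <- c(out, a$species, a$input, a$output, a$inputs)
  }
  unique(out[!is.na(out)])
}

#' Inert species of an assembled system
#'
#' A species is inert when its concentration appears in no reaction's
#' rate expression (a degradation leak counts: it gives the node
#' self-dynamics), it is not referenced by any simulation directive and
#' it is not clamped: a pure accumulator that integrates flux but
#' influences nothing, so it (and its attached sources) can be removed
#' without changing the dynamics of the rest.  Accumulators fed by a
#' nonzero flux have no finite operating point, which is why the
#' steady-state analyses exclude them.
#'
#' @param system a [build_system()] result.
#' @return character vector of inert species names.
#' @export
inert_species <- function(system) {
  active <- unique(unlist(system$deps))
  keep <- unique(c(active, .directive_species(system$model),
                   system$clamped$species,
                   system$species_order[system$degradation > 0]))
  setdiff(system$species_order, keep)
}

#' Count controlled-source terms of a system
#'
#' Counts the nonlinear controlled sources of the equivalent circuit:
#' every reactant and product of a reaction contributes one signed
#' source, constant production one fixed source per product, while
#' decay and passive diffusion map to resistors (leaks) and are not
#' counted.  With `prune_inert = TRUE`, [inert_species()] and the
#' sources attached to them are removed first.
#'
#' @param system a [build_system()] result.
#' @param prune_inert remove inert species before counting?
#' @return integer source count; the retained node count is attached as
#'   attribute `"nodes"`.
#' @export
count_sources <- function(system, prune_inert = FALSE) {
  drop <- if (prune_inert) inert_species(system) else character()
  keep <- setdiff(system$species_order, drop)
  n <- 0L
  for (r in system$reactions) {
    if (r$type %in% c("D", "F")) next
    parts <- if (r$type == "C") r$products$species
             else c(r$reactants$species, r$products$species)
    n <- n + sum(parts %in% keep)
  }
  structure(n, nodes = length(keep))
}

#' Jacobian of the assembled right-hand side
#'
#' Central finite differences with step `max(1e-8, 1e-6*|x_j|)`;
#' clamped rows (and columns into clamped states) are zero.
#'
#' @param system a [build_system()] result.
#' @param state numeric state vector in `species_order` (named vectors
#'   are reordered).
#' @return the `n x n` Jacobian matrix `J[i,j] = d(dx_i/dt)/dx_j`.
#' @export
system_jacobian <- function(system, state = system$x0) {
  sp <- system$species_order
  n <- length(sp)
  if (!is.null(names(state))) state <- state[sp]
  state <- unname(state)
  if (length(state) != n)
    stop("state length does not match species_order", call. = FALSE)
  f0 <- system$rhs(state)
  if (any(!is.finite(f0)))
    stop("non-finite right-hand side at the evaluation state", call. = FALSE)
  J <- matrix(0, n, n, dimnames = list(sp, sp))
  clamped <- match(system$clamped$species, sp)
  for (j in seq_len(n)) {
    if (j %in% clamped) next
    h <- max(1e-8, 1e-6 * abs(state[j]))
    xp <- state; xm <- state
    if (state[j] - h >= 0) {
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    } else {
      # stay inside the nonnegative orthant (the rhs guard would bias a
      # centered stencil straddling zero)
      xp[j] <- state[j] + 2 * h; xm[j] <- state[j]
    }
    J[, j] <- (system$rhs(xp) - system$rhs(xm)) / (2 * h)
  }
  if (length(clamped) > 0) J[clamped, ] <- 0
  J
}
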