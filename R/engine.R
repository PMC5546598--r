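# Analysis engine: steady state, multistability search, transient
# simulation with stimuli, DC sweep with continuation, small-signal
# transfer function and truth-table logic runs.
#
# Defaults follow stiff-solver practice: implicit integration (lsoda,
# switching to the sparse lsodes above 50 states), rtol 1e-8,
# atol 1e-12, and a steady-state residual tolerance of 1e-10 on the
# max-norm of the right-hand side.

.free_idx <- function(system) {
  setdiff(seq_along(system$species_order),
          match(system$clamped$species, system$species_order))
}

.ode_method <- function(n) if (n > 50) "lsodes" else "lsoda"

#' Steady state of a system
#'
#' Damped Newton iteration from `x0`; if Newton stalls, falls back to
#' pseudo-transient integration (integrating the ODE over growing
#' horizons) followed by a Newton polish.  Clamped species retain their
#' clamp values; free states are kept nonnegative.  Pure-accumulator
#' [inert_species()] integrate incoming flux indefinitely and have no
#' finite operating point, so they are excluded from the residual and
#' reported at their start value.
#'
#' @param system a [build_system()] result.
#' @param x0 starting state (defaults to the model's initial
#'   concentrations).
#' @param atol convergence tolerance on `max |rhs|`.
#' @param max_iter Newton iteration budget.
#' @return the steady state as a named numeric vector with attribute
#'   `"residual"`.
#' @export
steady_state <- function(system, x0 = system$x0, atol = 1e-10, max_iter = 100) {
  sp <- system$species_order
  n <- length(sp)
  if (!is.null(names(x0))) x0 <- x0[sp]
  x <- unname(pmax(x0, 0))
  clamped <- match(system$clamped$species, sp)
  if (length(clamped) > 0) x[clamped] <- system$clamped$value
  free <- setdiff(.free_idx(system), match(inert_species(system), sp))
  if (length(free) == 0 || n == 0)
    return(structure(stats::setNames(x, sp), residual = 0))

  newton <- function(x, iters) {
    f <- system$rhs(x)
    best <- x; best_res <- max(abs(f[free]))
    for (it in seq_len(iters)) {
      if (best_res <= atol) break
      J <- system_jacobian(system, x)[free, free, drop = FALSE]
      step <- tryCatch(solve(J, -f[free]), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      lambda <- 1; improved <- FALSE
      for (k in 1:30) {
        xt <- x; xt[free] <- pmax(xt[free] + lambda * step, 0)
        ft <- system$rhs(xt)
        if (all(is.finite(ft)) && max(abs(ft[free])) < max(abs(f[free]))) {
          x <- xt; f <- ft; improved <- TRUE; break
        }
        lambda <- lambda / 2
      }
      if (!improved) break
      if (max(abs(f[free])) < best_res) { best <- x; best_res <- max(abs(f[free])) }
    }
    list(x = best, res = best_res)
  }

  out <- newton(x, max_iter)
  if (out$res > atol) {
    # pseudo-transient fallback: march the ODE toward the attractor
    y <- out$x
    horizon <- 1
    for (stage in 1:12) {
      sol <- tryCatch(
        suppressWarnings(
          deSolve::ode(y = y, times = c(0, horizon),
                       func = function(t, y, p) list(system$rhs(y, t)),
                       method = .ode_method(n), rtol = 1e-8, atol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(sol) && nrow(sol) == 2 && all(is.finite(sol[2, -1]))) {
        y <- pmax(as.numeric(sol[2, -1]), 0)
        if (length(clamped) > 0) y[clamped] <- system$clamped$value
      }
      polished <- newton(y, 25)
      if (polished$res <= atol) { out <- polished; break }
      if (polished$res < out$res) out <- polished
      horizon <- horizon * 4
    }
  }
  if (out$res > atol)
    stop(sprintf("steady state did not converge: best residual %.3e > %.0e",
                 out$res, atol), call. = FALSE)
  structure(stats::setNames(out$x, sp), residual = out$res)
}

#' Locate the stable steady states of a system
#'
#' Runs [steady_state()] from the model's initial state plus `n_starts`
#' random starts, log-uniform over `range` scaled by the largest
#' initial concentration (or 1), deduplicates the solutions and keeps
#' those whose Jacobian eigenvalues (clamped and [inert_species()]
#' dimensions excluded) all have real part below `-1e-9 * ||J||`;
#' marginal states are reported unstable.
#'
#' @param system a [build_system()] result.
#' @param n_starts number of random starts.
#' @param seed RNG seed; the search is deterministic given
#'   `(model, seed)`.
#' @param range log-uniform sampling range (before scaling).
#' @return a tibble with one row per stable state (columns = species)
#'   and a `residual` column.
#' @export
find_stable_states <- function(system, n_starts = 32, seed = 0,
                               range = c(1e-3, 1e3)) {
  sp <- system$species_order
  n <- length(sp)
  # inert accumulator species have identically zero Jacobian columns and
  # rows that only integrate flux: they contribute spurious zero
  # eigenvalues and start-dependent offsets, so the stability test and
  # deduplication run on the pruned state space
  inert <- match(inert_species(system), sp)
  free <- setdiff(.free_idx(system), inert)
  live <- setdiff(seq_len(n), inert)
  scale <- max(system$x0, 1)
  starts <- list(system$x0)
  if (n_starts >= 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    for (i in seq_len(n_starts)) {
      u <- stats::runif(n, log(range[1]), log(range[2]))
      starts[[i + 1]] <- stats::setNames(scale * exp(u), sp)
    }
  }
  sols <- list()
  for (s in starts) {
    x <- tryCatch(steady_state(system, s), error = function(e) NULL)
    if (is.null(x)) next
    dup <- any(vapply(sols, function(y)
      all(abs(x[live] - y[live]) <=
            1e-6 * pmax(abs(x[live]), abs(y[live])) + 1e-9), TRUE))
    if (!dup) sols[[length(sols) + 1]] <- x
  }
  stable <- Filter(function(x) {
    J <- system_jacobian(system, x)[free, free, drop = FALSE]
    if (length(J) == 0) return(TRUE)
    ev <- eigen(J, only.values = TRUE)$values
    all(Re(ev) < -1e-9 * norm(J, "I"))
  }, sols)
  out <- if (length(stable) == 0) {
    m <- matrix(numeric(), 0, n, dimnames = list(NULL, sp))
    tibble::as_tibble(as.data.frame(m))
  } else {
    tibble::as_tibble(do.call(rbind, lapply(stable, function(x) as.data.frame(t(x)))))
  }
  out$residual <- vapply(stable, function(s) attr(s, "residual"), 0)
  out
}

# ---- stimuli ---------------------------------------------------------

# Convert PULSE/WAVEFORM directives into a per-species source function
# s(t) (amount/time) and the list of discontinuity times.
.build_stimuli <- function(system, stimuli, t_end) {
  sp <- system$species_order
  n <- length(sp)
  funs <- list(); breaks <- numeric()
  for (d in stimuli) {
    if (inherits(d, "bsp_directive") && d$kind %in% c("PULSE", "WAVEFORM")) {
      a <- d$args
      i <- match(a$species, sp)
      if (is.na(i)) stop(sprintf("stimulus references unknown species '%s'", a$species),
                         call. = FALSE)
      if (d$kind == "PULSE") {
        delay <- a$delay; len <- a$length; h <- a$height; fr <- a$frequency
        if (fr > 0 && len > 1 / fr)
          stop("PULSE length exceeds the period", call. = FALSE)
        funs[[length(funs) + 1]] <- local({
          i <- i; delay <- delay; len <- len; h <- h; fr <- fr
          function(t, s) {
            tt <- if (fr > 0 && t >= delay) (t - delay) %% (1 / fr) else t - delay
            if (tt >= 0 && tt < len) s[i] <- s[i] + h
            s
          }
        })
        if (fr > 0) {
          k <- 0:floor(max(0, t_end - delay) * fr)
          breaks <- c(breaks, delay + k / fr, delay + k / fr + len)
        } else breaks <- c(breaks, delay, delay + len)
      } else {
        tm <- a$times; vv <- a$values
        funs[[length(funs) + 1]] <- local({
          i <- i; tm <- tm; vv <- vv
          function(t, s) {
            j <- findInterval(t, tm)
            if (j >= 1) s[i] <- s[i] + vv[j]
            s
          }
        })
        breaks <- c(breaks, tm)
      }
    } else if (inherits(d, "bsp_directive")) {
      # FIX handled at build time; analysis/control directives ignored here
      next
    } else stop("stimuli must be bsp_directive objects", call. = FALSE)
  }
  clamped <- match(system$clamped$species, sp)
  source_at <- function(t) {
    s <- numeric(n)
    for (f in funs) s <- f(t, s)
    if (length(clamped) > 0) s[clamped] <- 0
    s
  }
  list(source = source_at, breaks = sort(unique(breaks[breaks > 0 & breaks < t_end])),
       active = length(funs) > 0)
}

#' Transient simulation
#'
#' Integrates the stiff ODE from the per-species initial concentrations
#' with `PULSE`/`WAVEFORM` stimuli added as time-dependent molecule
#' sources.  The integrator restarts at every stimulus discontinuity;
#' output is reported on a uniform grid.
#'
#' @param system a [build_system()] result.
#' @param stimuli list of stimulus [bsp_directive()]s (`PULSE`,
#'   `WAVEFORM`); defaults to those found in the model.
#' @param t_end horizon (> 0).
#' @param n_points reporting-grid size.
#' @param x0 initial state override.
#' @param rtol,atol integrator tolerances.
#' @return a `bsp_result` tibble: `time` plus one column per species.
#' @export
time_course <- function(system, stimuli = NULL, t_end, n_points = 201,
                        x0 = system$x0, rtol = 1e-8, atol = 1e-12) {
  stopifnot(t_end > 0, n_points >= 2)
  sp <- system$species_order
  n <- length(sp)
  if (is.null(stimuli))
    stimuli <- Filter(function(d) d$kind %in% c("PULSE", "WAVEFORM"),
                      system$model$directives)
  st <- .build_stimuli(system, stimuli, t_end)
  V <- unname(system$volumes)
  func <- if (st$active) {
    function(t, y, p) list(system$rhs(y, t) + st$source(t) / V)
  } else {
    function(t, y, p) list(system$rhs(y, t))
  }
  if (!is.null(names(x0))) x0 <- x0[sp]
  y <- unname(x0)
  clamped <- match(system$clamped$species, sp)
  if (length(clamped) > 0) y[clamped] <- system$clamped$value

  report <- seq(0, t_end, length.out = n_points)
  bounds <- unique(sort(c(0, st$breaks, t_end)))
  rows <- matrix(NA_real_, n_points, n, dimnames = list(NULL, sp))
  rows[1, ] <- y
  method <- .ode_method(n)
  for (b in seq_len(length(bounds) - 1)) {
    a <- bounds[b]; z <- bounds[b + 1]
    rpt <- report[report > a & report <= z]
    times <- unique(sort(c(a, rpt, z)))
    sol <- deSolve::ode(y = y, times = times, func = func, method = method,
                        rtol = rtol, atol = atol)
    if (nrow(sol) < length(times) || any(!is.finite(sol[nrow(sol), -1])))
      stop(sprintf("integration failed near t = %.6g", sol[nrow(sol), 1]),
           call. = FALSE)
    if (length(rpt) > 0) {
      ridx <- match(rpt, times)
      rows[match(rpt, report), ] <- sol[ridx, -1, drop = FALSE]
    }
    y <- as.numeric(sol[nrow(sol), -1])
  }
  new_bsp_result(tibble::tibble(time = report, !!!as.data.frame(rows)),
                 axis_kind = "time")
}

#' DC sweep: steady states along an input grid
#'
#' Clamps `input_species` at each grid value and computes the steady
#' state, warm-starting each point from the previous solution
#' (continuation).  Failed points are reported as `NA`.
#'
#' @param system a [build_system()] result.
#' @param input_species species to clamp and sweep.
#' @param grid nonempty vector of nonnegative clamp values.
#' @return a `bsp_result` tibble: the swept input plus per-species
#'   steady values; failed grid points carry `NA` rows.
#' @export
dc_sweep <- function(system, input_species, grid) {
  stopifnot(length(grid) >= 1, all(grid >= 0))
  sp <- system$species_order
  if (!input_species %in% sp)
    stop(sprintf("unknown sweep species '%s'", input_species), call. = FALSE)
  base_clamps <- system$clamped[system$clamped$species != input_species, ]
  out <- matrix(NA_real_, length(grid), length(sp), dimnames = list(NULL, sp))
  warm <- system$x0
  failed <- integer()
  for (g in seq_along(grid)) {
    clamps <- rbind(base_clamps,
                    tibble::tibble(species = input_species, value = grid[g]))
    sysg <- build_system(system$model, clamps = clamps)
    x <- tryCatch(steady_state(sysg, warm), error = function(e) NULL)
    if (is.null(x)) { failed <- c(failed, g); next }
    out[g, ] <- x
    warm <- x
  }
  res <- new_bsp_result(
    tibble::tibble(!!input_species := grid,
                   !!!as.data.frame(out[, setdiff(sp, input_species), drop = FALSE])),
    axis_kind = "sweep", meta = list(failed_points = failed))
  res
}

#' Small-signal transfer function (Bode analysis)
#'
#' Linearizes the system at its steady state and evaluates
#' \eqn{H(j\omega) = e_{out}^T (j\omega I - J)^{-1} b} over a frequency
#' grid, where `b` is a unit molecule-source at the input node (scaled
#' by the input compartment volume); with
#' `input_convention = "concentration"` the input column of the inverse
#' is taken instead (unit concentration perturbation).
#'
#' @param system a [build_system()] result.
#' @param input_species,output_species node names.
#' @param omega angular-frequency grid (rad/time).
#' @param input_convention `"source"` (default) or `"concentration"`.
#' @param x0 starting state for the steady-state search.
#' @return a `bsp_result` tibble with columns `omega`, `magnitude`,
#'   `phase` (radians), `magnitude_db`, `phase_deg`.
#' @export
transfer_function <- function(system, input_species, output_species, omega,
                              input_convention = c("source", "concentration"),
                              x0 = system$x0) {
  input_convention <- match.arg(input_convention)
  sp <- system$species_order
  for (s in c(input_species, output_species))
    if (!s %in% sp) stop(sprintf("unknown species '%s'", s), call. = FALSE)
  xs <- steady_state(system, x0)
  free <- .free_idx(system)
  if (!match(input_species, sp) %in% free || !match(output_species, sp) %in% free)
    stop("transfer function input/output must be unclamped species", call. = FALSE)
  J <- system_jacobian(system, xs)[free, free, drop = FALSE]
  iin <- match(match(input_species, sp), free)
  iout <- match(match(output_species, sp), free)
  b <- numeric(length(free))
  b[iin] <- if (input_convention == "source")
    1 / system$volumes[[input_species]] else 1
  Ieye <- diag(length(free))
  H <- vapply(omega, function(w) {
    A <- 1i * w * Ieye - J
    h <- tryCatch(solve(A, b)[iout], error = function(e) NA_complex_)
    h
  }, complex(1))
  new_bsp_result(tibble::tibble(omega = omega,
                                magnitude = Mod(H), phase = Arg(H),
                                magnitude_db = 20 * log10(Mod(H)),
                                phase_deg = Arg(H) * 180 / pi),
                 axis_kind = "frequency",
                 meta = list(steady_state = xs, input = input_species,
                             output = output_species))
}

#' Truth-table analysis
#'
#' Drives each input species with a constant molecule source at
#' `on_level` or 0 over `2^k` segments covering every Boolean input
#' combination in Gray-code order (one input flips per segment edge),
#' runs one continuous transient, and reports each species' value at
#' the end of each segment.
#'
#' @param system a [build_system()] result.
#' @param inputs input species (1 to 16).
#' @param on_level source level (concentration/time) for logic 1.
#' @param segment duration of each segment.
#' @param n_points_per_segment reporting density.
#' @return a list of class `bsp_truthtable`: `$result` (the transient
#'   `bsp_result`) and `$table` (one row per combination: input bits
#'   plus end-of-segment species values).
#' @export
truth_table <- function(system, inputs, on_level, segment,
                        n_points_per_segment = 25) {
  k <- length(inputs)
  stopifnot(k >= 1, k <= 16, on_level > 0, segment > 0)
  sp <- system$species_order
  unknown <- setdiff(inputs, sp)
  if (length(unknown) > 0)
    stop("unknown truth-table inputs: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ncomb <- 2^k
  gray <- bitwXor(0:(ncomb - 1), (0:(ncomb - 1)) %/% 2)
  bits <- t(vapply(gray, function(g) as.integer(intToBits(g))[seq_len(k)],
                   integer(k)))
  bits <- matrix(bits, ncol = k)  # row = segment, col = input
  t_end <- ncomb * segment
  stimuli <- lapply(seq_len(k), function(j) {
    bsp_directive("WAVEFORM", species = inputs[j],
                  times = (seq_len(ncomb) - 1) * segment,
                  values = on_level * bits[, j])
  })
  res <- time_course(system, stimuli = stimuli, t_end = t_end,
                     n_points = ncomb * n_points_per_segment + 1)
  ends <- seq_len(ncomb) * segment
  eidx <- vapply(ends, function(tt) which.min(abs(res$time - tt)), 0L)
  tab <- tibble::as_tibble(cbind(
    stats::setNames(as.data.frame(bits), paste0("in_", inputs)),
    as.data.frame(tibble::as_tibble(res)[eidx, sp, drop = FALSE])))
  structure(list(result = res, table = tab, inputs = inputs,
                 on_level = on_level, segment = segment),
            class = "bsp_truthtable")
}

#' @export
print.bsp_truthtable <- function(x, ...) {
  cat(sprintf("<bsp_truthtable> %d input(s), %d segment(s) of %g time units\n",
              length(x$inputs), nrow(x$table), x$segment))
  print(x$table)
  invisible(x)
}

#' Run the analysis directive embedded in a model
#'
#' Builds the system and dispatches on the model's analysis directive
#' (`STEADY`, `TIMECOURSE`, `SWEEP`, `TRANSFUNC` or `TRUTHTABLE`),
#' applying its stimulus directives.  Models without an analysis
#' directive default to `STEADY`.
#'
#' @param model a [bsp_model()].
#' @param ... overrides passed to the dispatched engine function.
#' @return the engine result (a `bsp_result`, steady-state tibble or
#'   `bsp_truthtable`).
#' @export
run_model <- function(model, ...) {
  system <- build_system(model)
  ana <- Filter(function(d) d$kind %in% .analysis_kinds, model$directives)
  if (length(ana) == 0) {
    x <- steady_state(system, ...)
    return(tibble::as_tibble(as.data.frame(t(x))))
  }
  d <- ana[[1]]; a <- d$args
  switch(d$kind,
    STEADY = {
      x <- steady_state(system, ...)
      tibble::as_tibble(as.data.frame(t(x)))
    },
    TIMECOURSE = time_course(system, t_end = a$t_end, n_points = a$n_points, ...),
    SWEEP = {
      grid <- if (a$scale == "log")
        exp(seq(log(a$from), log(a$to), length.out = a$npoints))
      else seq(a$from, a$to, length.out = a$npoints)
      dc_sweep(system, a$species, grid, ...)
    },
    TRANSFUNC = transfer_function(system, a$input, a$output,
                                  omega = exp(seq(log(a$wmin), log(a$wmax),
                                                  length.out = a$npoints)), ...),
    TRUTHTABLE = truth_table(system, a$inputs, a$on_level, a$segment, ...))
}
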