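# Reading and writing the biospice netlist format.
#
# A netlist is a line-oriented UTF-8 text file with four dot-keyword
# sections (case-insensitive): .parameters, .species, .reactions and
# .simulation.  Lines starting with `*` are comments, text after `;` is
# an inline comment, and lines starting with `$` are raw simulator lines
# passed through verbatim to the SPICE exporter.  Multi-valued fields
# are comma-separated lists between braces, `{A,2*B}`; a literal `0`
# stands for an empty list where the reaction type allows one.

# Split a line into blank-separated tokens, keeping {...} and '...'
# groups together.
.tokenize_line <- function(line, lineno) {
  chars <- strsplit(line, "")[[1]]
  tokens <- character(); buf <- character()
  depth <- 0L; in_quote <- FALSE
  flush <- function() {
    if (length(buf) > 0) tokens <<- c(tokens, paste(buf, collapse = ""))
    buf <<- character()
  }
  for (ch in chars) {
    if (in_quote) {
      buf <- c(buf, ch)
      if (ch == "'") in_quote <- FALSE
    } else if (ch == "'") {
      buf <- c(buf, ch); in_quote <- TRUE
    } else if (ch == "{") {
      depth <- depth + 1L; buf <- c(buf, ch)
    } else if (ch == "}") {
      depth <- depth - 1L; buf <- c(buf, ch)
      if (depth < 0) stop(sprintf("line %d: unbalanced '}'", lineno), call. = FALSE)
    } else if (grepl("^\\s$", ch) && depth == 0L) {
      flush()
    } else {
      buf <- c(buf, ch)
    }
  }
  if (in_quote) stop(sprintf("line %d: unterminated quote", lineno), call. = FALSE)
  if (depth != 0L) stop(sprintf("line %d: unbalanced '{'", lineno), call. = FALSE)
  flush()
  tokens
}

# Parse a brace list "{a,b,c}" (or bare single token, or literal 0 ->
# empty) into a character vector of items.
.parse_list <- function(token, lineno, allow_empty = TRUE) {
  token <- trimws(token)
  if (token == "0") {
    if (!allow_empty)
      stop(sprintf("line %d: this argument may not be empty", lineno), call. = FALSE)
    return(character())
  }
  if (startsWith(token, "{")) {
    inner <- trimws(substr(token, 2, nchar(token) - 1))
    if (!nzchar(inner)) return(character())
    return(trimws(strsplit(inner, ",")[[1]]))
  }
  token
}

# A species list item may carry an integer stoichiometry prefix `n*Name`.
.parse_species_list <- function(token, lineno) {
  items <- .parse_list(token, lineno)
  if (length(items) == 0)
    return(tibble::tibble(species = character(), stoich = integer()))
  sp <- character(length(items)); st <- integer(length(items))
  for (i in seq_along(items)) {
    m <- regmatches(items[i], regexec("^(?:([0-9]+)\\*)?([A-Za-z_][A-Za-z0-9_]*)$",
                                      items[i]))[[1]]
    if (length(m) == 0)
      stop(sprintf("line %d: cannot parse species item '%s'", lineno, items[i]),
           call. = FALSE)
    st[i] <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    sp[i] <- m[3]
  }
  tibble::tibble(species = sp, stoich = st)
}

# Expected positional argument layout after the reaction name, per type.
# Each entry: argument roles before the final parameter list.
.reaction_args <- list(
  B = c("reactants", "products"),
  C = c("products"),
  D = c("reactants"),
  E = c("reactants", "products", "modifiers"),
  F = c("reactants", "products"),      # in species, out species
  H = c("reactants", "products"),
  L = c("products", "modifiers"),      # proteins, mRNAs
  P = c("reactants", "products", "modifiers"),
  T = c("products", "activators", "repressors"),
  X = c("reactants", "products", "modifiers")
)

# Map the final parameter token list onto the type's named layout.
.assign_params <- function(type, vals, r, lineno) {
  n <- length(vals)
  bad <- function(msg) stop(sprintf("line %d: %s", lineno, msg), call. = FALSE)
  switch(type,
    B = { if (n < 1 || n > 2) bad("binding needs {k_on[,k_off]}")
          list(k_on = vals[1], k_off = if (n == 2) vals[2] else "0") },
    C = { if (n != 1) bad("constant production needs {beta}")
          list(beta = vals[1]) },
    D = { if (n != 1) bad("decay needs {d}")
          list(d = vals[1]) },
    E = { if (n != 2) bad("enzymatic reaction needs {v_max,K_m}")
          list(v_max = vals[1], K_m = vals[2]) },
    F = { if (n != 1) bad("diffusion needs {D}")
          list(D = vals[1]) },
    H = { if (n != 3) bad("Hill reaction needs {v_max,K,n}")
          list(v_max = vals[1], K = vals[2], n = vals[3]) },
    L = { if (n != 1) bad("translation needs {k_TL}")
          list(k_TL = vals[1]) },
    P = { nm <- length(r$modifiers)
          if (n != 1 + 2 * nm)
            bad(sprintf("pump with %d regulator(s) needs {v_max%s}", nm,
                        strrep(",K_j,n_j", nm)))
          list(v_max = vals[1],
               K = if (nm) vals[1 + 2 * seq_len(nm) - 1] else character(),
               n = if (nm) vals[1 + 2 * seq_len(nm)] else character()) },
    T = { na <- length(r$activators); nr <- length(r$repressors)
          if (n != 1 + 2 * (na + nr))
            bad(sprintf("transcription with %d activator(s)/%d repressor(s) needs {k_TR%s%s}",
                        na, nr, strrep(",KA_j,nA_j", na), strrep(",KR_j,nR_j", nr)))
          list(k_TR = vals[1],
               KA = if (na) vals[1 + 2 * seq_len(na) - 1] else character(),
               nA = if (na) vals[1 + 2 * seq_len(na)] else character(),
               KR = if (nr) vals[1 + 2 * na + 2 * seq_len(nr) - 1] else character(),
               nR = if (nr) vals[1 + 2 * na + 2 * seq_len(nr)] else character()) },
    bad(sprintf("unknown reaction type '%s'", type)))
}

.parse_reaction_line <- function(tokens, lineno) {
  name <- tokens[1]
  type <- toupper(substr(name, 1, 1))
  if (!type %in% names(.reaction_types))
    stop(sprintf("line %d: unknown reaction-type letter '%s' in '%s'",
                 lineno, type, name), call. = FALSE)
  roles <- .reaction_args[[type]]
  args <- tokens[-1]
  if (length(args) != length(roles) + 1L)
    stop(sprintf("line %d: reaction '%s' (type %s) takes %d argument(s) plus parameters, got %d",
                 lineno, name, type, length(roles), length(args)), call. = FALSE)
  fields <- list(reactants = NULL, products = NULL, modifiers = character(),
                 activators = character(), repressors = character())
  for (i in seq_along(roles)) {
    role <- roles[i]
    if (role %in% c("reactants", "products")) {
      fields[[role]] <- .parse_species_list(args[i], lineno)
    } else {
      fields[[role]] <- .parse_species_list(args[i], lineno)$species
    }
  }
  last <- args[length(args)]
  if (type == "X") {
    if (!grepl("^'.*'$", last))
      stop(sprintf("line %d: custom reaction rate must be between simple quotes", lineno),
           call. = FALSE)
    rate <- substr(last, 2, nchar(last) - 1)
    r <- bsp_reaction(name, fields$reactants, fields$products,
                      modifiers = fields$modifiers, rate = rate)
  } else {
    vals <- .parse_list(last, lineno)
    r0 <- list(modifiers = fields$modifiers, activators = fields$activators,
               repressors = fields$repressors)
    params <- .assign_params(type, vals, r0, lineno)
    params <- lapply(params, as.character)
    r <- bsp_reaction(name, fields$reactants, fields$products,
                      modifiers = fields$modifiers, params = params,
                      activators = fields$activators, repressors = fields$repressors)
  }
  r
}

.num_or_stop <- function(tok, lineno, what) {
  v <- parse_spice_number(tok)
  if (is.na(v))
    stop(sprintf("line %d: %s must be a number, got '%s'", lineno, what, tok),
         call. = FALSE)
  v
}

.parse_directive_line <- function(tokens, lineno) {
  kind <- toupper(tokens[1])
  args <- tokens[-1]
  bad <- function(msg) stop(sprintf("line %d: %s", lineno, msg), call. = FALSE)
  num <- function(i, what) .num_or_stop(args[i], lineno, what)
  switch(kind,
    FIX = { if (length(args) != 2) bad("FIX takes: species value")
            bsp_directive("FIX", species = args[1], value = num(2, "FIX value")) },
    PULSE = { if (length(args) != 5)
                bad("PULSE takes: species delay length height frequency")
              bsp_directive("PULSE", species = args[1], delay = num(2, "delay"),
                            length = num(3, "length"), height = num(4, "height"),
                            frequency = num(5, "frequency")) },
    WAVEFORM = { if (length(args) != 2) bad("WAVEFORM takes: species {t1,v1,t2,v2,...}")
                 vals <- vapply(.parse_list(args[2], lineno), .num_or_stop,
                                0, lineno = lineno, what = "WAVEFORM value",
                                USE.NAMES = FALSE)
                 if (length(vals) %% 2 != 0 || length(vals) == 0)
                   bad("WAVEFORM list must be (time,value) pairs")
                 tm <- vals[seq(1, length(vals), 2)]
                 if (any(tm < 0) || any(diff(tm) <= 0))
                   bad("WAVEFORM times must be nonnegative and increasing")
                 bsp_directive("WAVEFORM", species = args[1], times = tm,
                               values = vals[seq(2, length(vals), 2)]) },
    TRANSFUNC = { if (length(args) < 2 || length(args) > 3)
                    bad("TRANSFUNC takes: input output [{wmin,wmax,npoints}]")
                  grid <- c(1e-3, 1e3, 61)
                  if (length(args) == 3) {
                    grid <- vapply(.parse_list(args[3], lineno), .num_or_stop, 0,
                                   lineno = lineno, what = "TRANSFUNC grid",
                                   USE.NAMES = FALSE)
                    if (length(grid) != 3) bad("TRANSFUNC grid is {wmin,wmax,npoints}")
                  }
                  bsp_directive("TRANSFUNC", input = args[1], output = args[2],
                                wmin = grid[1], wmax = grid[2],
                                npoints = as.integer(grid[3])) },
    TRUTHTABLE = { if (length(args) != 3)
                     bad("TRUTHTABLE takes: {inputs} on_level segment")
                   bsp_directive("TRUTHTABLE",
                                 inputs = .parse_list(args[1], lineno, allow_empty = FALSE),
                                 on_level = num(2, "on_level"),
                                 segment = num(3, "segment")) },
    STEADY = { if (length(args) != 0) bad("STEADY takes no arguments")
               bsp_directive("STEADY") },
    SWEEP = { if (length(args) != 2) bad("SWEEP takes: species {min,max,npoints[,log]}")
              g <- .parse_list(args[2], lineno)
              if (!length(g) %in% c(3, 4)) bad("SWEEP grid is {min,max,npoints[,log]}")
              scale <- if (length(g) == 4) tolower(g[4]) else "lin"
              if (!scale %in% c("lin", "log")) bad("SWEEP scale must be lin or log")
              bsp_directive("SWEEP", species = args[1],
                            from = .num_or_stop(g[1], lineno, "SWEEP min"),
                            to = .num_or_stop(g[2], lineno, "SWEEP max"),
                            npoints = as.integer(.num_or_stop(g[3], lineno, "SWEEP npoints")),
                            scale = scale) },
    TIMECOURSE = { if (length(args) < 1 || length(args) > 2)
                     bad("TIMECOURSE takes: t_end [n_points]")
                   bsp_directive("TIMECOURSE", t_end = num(1, "t_end"),
                                 n_points = if (length(args) == 2)
                                   as.integer(num(2, "n_points")) else 201L) },
    PLOT = { if (length(args) != 1) bad("PLOT takes: {species,...}")
             bsp_directive("PLOT", species = .parse_list(args[1], lineno,
                                                         allow_empty = FALSE)) },
    PLOTALL = { if (length(args) != 0) bad("PLOTALL takes no arguments")
                bsp_directive("PLOTALL") },
    bad(sprintf("unknown simulation directive '%s'", kind)))
}

#' Parse a biospice netlist
#'
#' Reads the four-section netlist text (`.parameters`, `.species`,
#' `.reactions`, `.simulation`) into a [bsp_model()].  Comment lines
#' start with `*`, inline comments follow `;`, raw simulator lines are
#' prefixed with `$` and collected verbatim.
#'
#' @param text netlist source: a single string or a character vector of
#'   lines.
#' @return a validated [bsp_model()].
#' @seealso [read_netlist()] to parse from a file, [write_netlist()] for
#'   the inverse.
#' @export
#' @examples
#' m <- parse_netlist(c(
#'   ".parameters", "kcat 2.5 ; turnover", "km 0.5",
#'   ".species", "S 10 0", "P 0 0.1", "Enz 1 0",
#'   ".reactions", "Ecat {S} {P} {Enz} {kcat,km}",
#'   ".simulation", "TIMECOURSE 50", "PLOT {P}"))
#' model_summary(m)
parse_netlist <- function(text) {
  if (length(text) == 1 && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  section <- NA_character_
  params <- list(); species <- list(); reactions <- list()
  directives <- list(); passthrough <- character()
  for (i in seq_along(text)) {
    raw <- text[i]
    line <- trimws(raw)
    if (!nzchar(line) || startsWith(line, "*")) next
    if (startsWith(line, "$")) {
      passthrough <- c(passthrough, trimws(substring(line, 2)))
      next
    }
    # inline comments: text after ';' outside quotes.  In the
    # parameters section the comment is a declared (optional) field and
    # is kept; everywhere else it is discarded.
    comment <- ""
    if (grepl(";", line)) {
      chars <- strsplit(line, "")[[1]]
      inq <- FALSE
      for (j in seq_along(chars)) {
        if (chars[j] == "'") inq <- !inq
        if (chars[j] == ";" && !inq) {
          comment <- trimws(substring(line, j + 1))
          line <- trimws(substr(line, 1, j - 1))
          break
        }
      }
      if (!nzchar(line)) next
    }
    if (startsWith(line, ".")) {
      sec <- tolower(sub("^\\.", "", strsplit(line, "\\s+")[[1]][1]))
      if (!sec %in% c("parameters", "species", "reactions", "simulation"))
        stop(sprintf("line %d: unknown section '.%s'", i, sec), call. = FALSE)
      section <- sec
      next
    }
    if (is.na(section))
      stop(sprintf("line %d: content before any section header", i), call. = FALSE)
    tokens <- .tokenize_line(line, i)
    if (length(tokens) == 0) next
    if (section == "parameters") {
      if (length(tokens) < 2)
        stop(sprintf("line %d: parameter needs a name and a value", i), call. = FALSE)
      params[[length(params) + 1]] <-
        tibble::tibble(name = tokens[1], expression = tokens[2],
                       comment = if (length(tokens) > 2)
                         paste(tokens[-(1:2)], collapse = " ") else comment)
    } else if (section == "species") {
      if (length(tokens) < 1 || length(tokens) > 4)
        stop(sprintf("line %d: species takes: name [initial] [degradation] [volume]", i),
             call. = FALSE)
      species[[length(species) + 1]] <-
        tibble::tibble(name = tokens[1],
                       initial = if (length(tokens) >= 2)
                         .num_or_stop(tokens[2], i, "initial concentration") else 0,
                       degradation = if (length(tokens) >= 3)
                         .num_or_stop(tokens[3], i, "degradation rate") else 0,
                       compartment = if (length(tokens) >= 4)
                         .num_or_stop(tokens[4], i, "compartment volume") else 1)
    } else if (section == "reactions") {
      reactions[[length(reactions) + 1]] <- .parse_reaction_line(tokens, i)
    } else {
      directives[[length(directives) + 1]] <- .parse_directive_line(tokens, i)
    }
  }
  m <- bsp_model(parameters = if (length(params)) dplyr::bind_rows(params) else NULL,
                 species = if (length(species)) dplyr::bind_rows(species) else NULL,
                 reactions = reactions, directives = directives,
                 passthrough = passthrough)
  n_analysis <- sum(vapply(m$directives, function(d) d$kind %in% .analysis_kinds, TRUE))
  if (n_analysis > 1)
    stop("at most one analysis directive (STEADY/SWEEP/TIMECOURSE/TRANSFUNC/TRUTHTABLE) per run",
         call. = FALSE)
  m
}

#' Read a biospice netlist file
#'
#' @param path file path.
#' @return a [bsp_model()].
#' @export
read_netlist <- function(path) parse_netlist(readLines(path, warn = FALSE))

#' Resolve parameter definitions to numeric values
#'
#' Parameters may be literals or arithmetic formulas over other
#' parameters; they are evaluated in a topological order of the
#' dependency graph, so declaration order does not matter for an acyclic
#' set.  Cyclic definitions are an error naming the cycle members.
#'
#' @param model a [bsp_model()].
#' @return a named numeric vector, one value per parameter.
#' @export
#' @examples
#' m <- parse_netlist(c(".parameters", "k 1e-3", "kon 10*k", "koff kon/2",
#'                      ".species", ".reactions", ".simulation"))
#' resolve_parameters(m)
resolve_parameters <- function(model) {
  p <- model$parameters
  n <- nrow(p)
  if (n == 0) return(stats::setNames(numeric(), character()))
  exprs <- vector("list", n)
  deps <- vector("list", n)
  for (i in seq_len(n)) {
    v <- parse_spice_number(p$expression[i])
    if (!is.na(v)) {
      exprs[[i]] <- v; deps[[i]] <- character()
    } else {
      ex <- bsp_parse_expr(p$expression[i])
      if (length(ex$species) > 0)
        stop(sprintf("parameter '%s': species references are not allowed", p$name[i]),
             call. = FALSE)
      unknown <- setdiff(ex$params, p$name)
      if (length(unknown) > 0)
        stop(sprintf("parameter '%s' references undefined name(s): %s",
                     p$name[i], paste(unknown, collapse = ", ")), call. = FALSE)
      exprs[[i]] <- ex; deps[[i]] <- ex$params
    }
  }
  names(deps) <- p$name
  # Kahn's algorithm
  indeg <- vapply(deps, length, 0L)
  order <- character(); queue <- p$name[indeg == 0]
  remaining <- deps
  while (length(queue) > 0) {
    nm <- queue[1]; queue <- queue[-1]
    order <- c(order, nm)
    remaining[[nm]] <- NULL
    for (other in names(remaining)) {
      remaining[[other]] <- setdiff(remaining[[other]], nm)
      if (length(remaining[[other]]) == 0) {
        queue <- c(queue, other)
        remaining[[other]] <- character()
        remaining[other] <- NULL
      }
    }
  }
  if (length(order) < n) {
    cyc <- setdiff(p$name, order)
    # narrow to members actually on a cycle (reachable from themselves)
    on_cycle <- cyc[vapply(cyc, function(s) {
      seen <- character(); stack <- deps[[s]]
      while (length(stack) > 0) {
        cur <- stack[1]; stack <- stack[-1]
        if (cur == s) return(TRUE)
        if (!cur %in% seen) { seen <- c(seen, cur); stack <- c(stack, deps[[cur]]) }
      }
      FALSE
    }, TRUE)]
    if (length(on_cycle) == 0) on_cycle <- cyc
    stop(sprintf("cyclic parameter definition involving: %s",
                 paste(sort(on_cycle), collapse = ", ")), call. = FALSE)
  }
  vals <- stats::setNames(numeric(n), p$name)
  idx <- stats::setNames(seq_len(n), p$name)
  for (nm in order) {
    ex <- exprs[[idx[[nm]]]]
    vals[[nm]] <- if (is.numeric(ex)) ex else bsp_eval_expr(ex, params = vals)
    if (!is.finite(vals[[nm]]))
      stop(sprintf("parameter '%s' does not evaluate to a finite number", nm),
           call. = FALSE)
  }
  vals
}

# ---- writer ----------------------------------------------------------

.fmt_num <- function(x) {
  if (length(x) == 0) return(character())
  vapply(x, function(v) format(v, digits = 15, scientific = NA, trim = TRUE), "")
}

.fmt_species_list <- function(df) {
  if (is.null(df) || nrow(df) == 0) return("0")
  items <- ifelse(df$stoich > 1, paste0(df$stoich, "*", df$species), df$species)
  paste0("{", paste(items, collapse = ","), "}")
}

.fmt_name_list <- function(x) {
  if (length(x) == 0) return("0")
  paste0("{", paste(x, collapse = ","), "}")
}

.fmt_params <- function(r) {
  p <- lapply(r$params, as.character)
  vals <- switch(r$type,
    B = c(p$k_on, p$k_off),
    C = p$beta, D = p$d,
    E = c(p$v_max, p$K_m),
    F = p$D,
    H = c(p$v_max, p$K, p$n),
    L = p$k_TL,
    P = c(p$v_max, as.vector(rbind(p$K, p$n))),
    T = c(p$k_TR, as.vector(rbind(p$KA, p$nA)), as.vector(rbind(p$KR, p$nR))))
  paste0("{", paste(vals, collapse = ","), "}")
}

#' Serialize a model to biospice netlist text
#'
#' The inverse of [parse_netlist()]: `parse_netlist(write_netlist(m))`
#' is structurally equal to `m`.
#'
#' @param model a [bsp_model()].
#' @param path optional file path; when given the text is also written
#'   to disk.
#' @return the netlist as a character vector of lines, invisibly when
#'   `path` is given.
#' @export
write_netlist <- function(model, path = NULL) {
  out <- c(".parameters")
  p <- model$parameters
  for (i in seq_len(nrow(p))) {
    out <- c(out, paste0(p$name[i], " ", p$expression[i],
                         if (nzchar(p$comment[i])) paste0(" ; ", p$comment[i]) else ""))
  }
  out <- c(out, ".species")
  s <- model$species
  for (i in seq_len(nrow(s))) {
    out <- c(out, paste(s$name[i], .fmt_num(s$initial[i]), .fmt_num(s$degradation[i]),
                        .fmt_num(s$compartment[i])))
  }
  out <- c(out, ".reactions")
  for (r in model$reactions) {
    roles <- .reaction_args[[r$type]]
    args <- vapply(roles, function(role) {
      if (role %in% c("reactants", "products")) .fmt_species_list(r[[role]])
      else .fmt_name_list(r[[role]])
    }, "")
    last <- if (r$type == "X") paste0("'", r$rate, "'") else .fmt_params(r)
    out <- c(out, paste(c(r$name, args, last), collapse = " "))
  }
  out <- c(out, ".simulation")
  for (d in model$directives) out <- c(out, .fmt_directive(d))
  if (length(model$passthrough) > 0)
    out <- c(out, paste0("$", model$passthrough))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

.fmt_directive <- function(d) {
  a <- d$args
  switch(d$kind,
    FIX = paste("FIX", a$species, .fmt_num(a$value)),
    PULSE = paste("PULSE", a$species, .fmt_num(a$delay), .fmt_num(a$length),
                  .fmt_num(a$height), .fmt_num(a$frequency)),
    WAVEFORM = paste("WAVEFORM", a$species,
                     paste0("{", paste(as.vector(rbind(.fmt_num(a$times),
                                                       .fmt_num(a$values))),
                                       collapse = ","), "}")),
    TRANSFUNC = paste("TRANSFUNC", a$input, a$output,
                      paste0("{", .fmt_num(a$wmin), ",", .fmt_num(a$wmax), ",",
                             a$npoints, "}")),
    TRUTHTABLE = paste("TRUTHTABLE", .fmt_name_list(a$inputs),
                       .fmt_num(a$on_level), .fmt_num(a$segment)),
    STEADY = "STEADY",
    SWEEP = paste("SWEEP", a$species,
                  paste0("{", .fmt_num(a$from), ",", .fmt_num(a$to), ",",
                         a$npoints, ",", a$scale, "}")),
    TIMECOURSE = paste("TIMECOURSE", .fmt_num(a$t_end), a$n_points),
    PLOT = paste("PLOT", .fmt_name_list(a$species)),
    PLOTALL = "PLOTALL")
}
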