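# NGSPICE-compatible netlist generation.
#
# Device mapping: each species is a node with a capacitor to ground
# valued by its compartment (initial concentration as `ic=`), natural
# degradation is a resistor of value 1/d, every reactant/product of a
# reaction gets one behavioral current source (B dialect, `I={...}`)
# carrying the rate expression with opposite signs on the two sides,
# passive diffusion collapses to a single resistor of value 1/D between
# the two nodes, constant production is a DC current source, FIX a
# voltage source, PULSE a pulsed current source.  Analyses map to
# .TRAN/.DC/.AC and PLOT/PLOTALL to control statements.

.spice_fmt <- function(x) trimws(formatC(x, digits = 12, format = "g"))

# node name for a species: uppercased, N_ prefix on reserved collisions
.spice_nodes <- function(species) {
  reserved <- c("GND", "VDD", "VSS", "TIME", "TEMP")
  up <- toupper(species)
  nodes <- ifelse(up %in% reserved, paste0("N_", up), up)
  if (anyDuplicated(nodes))
    stop("species names collide case-insensitively in SPICE node space: ",
         paste(species[duplicated(nodes) | duplicated(nodes, fromLast = TRUE)],
               collapse = ", "), call. = FALSE)
  stats::setNames(nodes, species)
}

# rate expression (package grammar, numeric parameters already usable
# via .param) -> NGSPICE behavioral expression with V(node) references
.spice_expr <- function(src, nodes) {
  out <- src
  for (sp in names(nodes))
    out <- gsub(paste0("\\[", sp, "\\]"), paste0("V(", nodes[[sp]], ")"), out)
  # dialect: ln -> log, log10 -> log10, pow/min/max/sqrt/exp exist
  out <- gsub("\\bln\\(", "log(", out)
  if (grepl("\\[", out))
    stop(sprintf("unresolved species reference in expression '%s'", src),
         call. = FALSE)
  out
}

#' Generate an NGSPICE netlist from a model
#'
#' @param model a [bsp_model()].
#' @param prune drop [inert_species()] nodes (and the sources attached
#'   to them) before emitting the deck?
#' @return an object of class `bsp_deck`: a character vector of netlist
#'   lines (title first, `.end` last).
#' @export
to_spice <- function(model, prune = FALSE) {
  validate_model(model)
  params <- resolve_parameters(model)  # also validates resolvability
  if (prune) {
    drop <- inert_species(build_system(model))
    model$species <- model$species[!model$species$name %in% drop, ]
    model$reactions <- lapply(model$reactions, function(r) {
      r$reactants <- r$reactants[!r$reactants$species %in% drop, ]
      r$products <- r$products[!r$products$species %in% drop, ]
      r
    })
  }
  sp <- model$species
  nodes <- .spice_nodes(sp$name)
  lines <- c("* biospice generated netlist")
  if (any(nodes != toupper(sp$name)) || any(toupper(sp$name) != sp$name)) {
    lines <- c(lines, "* node mapping:",
               paste0("*   ", sp$name, " -> ", nodes[sp$name]))
  }
  p <- model$parameters
  if (nrow(p) > 0)
    lines <- c(lines, paste0(".param ", p$name, "=",
                             vapply(p$expression, .expand_suffixes, "")))

  # species: capacitor (+ ic), degradation resistor
  for (i in seq_len(nrow(sp))) {
    nd <- nodes[[sp$name[i]]]
    lines <- c(lines, sprintf("C%s %s 0 %s ic=%s", nd, nd,
                              .spice_fmt(sp$compartment[i]),
                              .spice_fmt(sp$initial[i])))
    if (sp$degradation[i] > 0)
      lines <- c(lines, sprintf("R%s %s 0 %s", nd, nd,
                                .spice_fmt(1 / sp$degradation[i])))
  }

  # reactions
  for (r in model$reactions) {
    rp <- .rparams(r, params)
    if (r$type == "F") {
      a <- nodes[[r$reactants$species[1]]]; b <- nodes[[r$products$species[1]]]
      lines <- c(lines, sprintf("RF%s %s %s %s", toupper(r$name), a, b,
                                .spice_fmt(1 / rp$D)))
      next
    }
    if (r$type == "D") {
      nd <- nodes[[r$reactants$species[1]]]
      lines <- c(lines, sprintf("RD%s %s 0 %s", toupper(r$name), nd,
                                .spice_fmt(1 / rp$d)))
      next
    }
    if (r$type == "C") {
      for (i in seq_len(nrow(r$products))) {
        nd <- nodes[[r$products$species[i]]]
        lines <- c(lines, sprintf("I%s_%s 0 %s DC %s", toupper(r$name), nd, nd,
                                  .spice_fmt(rp$beta * r$products$stoich[i])))
      }
      next
    }
    expr <- .spice_expr(.reaction_formula(r), nodes)
    emit <- function(df, sign) {
      for (i in seq_len(nrow(df))) {
        nd <- nodes[[df$species[i]]]
        coef <- df$stoich[i]
        body <- if (coef == 1) expr else sprintf("%d*(%s)", coef, expr)
        # B source current flows from node 1 through the source to node 2
        if (sign > 0)
          lines <<- c(lines, sprintf("B%s_%s 0 %s I={%s}", toupper(r$name), nd,
                                     nd, body))
        else
          lines <<- c(lines, sprintf("B%s_%s %s 0 I={%s}", toupper(r$name), nd,
                                     nd, body))
      }
    }
    emit(r$reactants, -1)
    emit(r$products, +1)
  }

  # stimulus directives -> devices; analysis -> simulation statement
  analysis <- character(); controls <- character()
  plotted <- character()
  for (d in model$directives) {
    a <- d$args
    switch(d$kind,
      FIX = {
        nd <- nodes[[a$species]]
        lines <- c(lines, sprintf("VFIX%s %s 0 DC %s", nd, nd, .spice_fmt(a$value)))
      },
      PULSE = {
        nd <- nodes[[a$species]]
        per <- if (a$frequency > 0) .spice_fmt(1 / a$frequency) else "1e30"
        lines <- c(lines, sprintf(
          "IPULSE%s 0 %s PULSE(0 %s %s 1e-9 1e-9 %s %s)", nd, nd,
          .spice_fmt(a$height), .spice_fmt(a$delay), .spice_fmt(a$length), per))
      },
      WAVEFORM = {
        nd <- nodes[[a$species]]
        pw <- paste(vapply(seq_along(a$times), function(k)
          paste(.spice_fmt(a$times[k]), .spice_fmt(a$values[k])), ""),
          collapse = " ")
        lines <- c(lines, sprintf("IPWL%s 0 %s PWL(%s)", nd, nd, pw))
      },
      TIMECOURSE = analysis <- c(analysis,
        sprintf(".tran %s %s uic", .spice_fmt(a$t_end / max(a$n_points - 1, 1)),
                .spice_fmt(a$t_end))),
      SWEEP = {
        nd <- nodes[[a$species]]
        lines <- c(lines, sprintf("VSWEEP%s %s 0 DC %s", nd, nd, .spice_fmt(a$from)))
        analysis <- c(analysis, sprintf(".dc VSWEEP%s %s %s %s", nd,
                                        .spice_fmt(a$from), .spice_fmt(a$to),
                                        .spice_fmt((a$to - a$from) /
                                                     max(a$npoints - 1, 1))))
      },
      TRANSFUNC = {
        nd <- nodes[[a$input]]
        lines <- c(lines, sprintf("IAC%s 0 %s DC 0 AC 1", nd, nd))
        analysis <- c(analysis, sprintf(".ac dec %d %s %s",
                                        max(1L, a$npoints %/% 7L),
                                        .spice_fmt(a$wmin / (2 * pi)),
                                        .spice_fmt(a$wmax / (2 * pi))))
        plotted <- c(plotted, a$output)
      },
      TRUTHTABLE = {
        k <- length(a$inputs)
        for (j in seq_len(k)) {
          nd <- nodes[[a$inputs[j]]]
          per <- a$segment * 2^j
          lines <- c(lines, sprintf(
            "IPULSE%s 0 %s PULSE(0 %s %s 1e-9 1e-9 %s %s)", nd, nd,
            .spice_fmt(a$on_level), .spice_fmt(per / 2), .spice_fmt(per / 2),
            .spice_fmt(per)))
        }
        analysis <- c(analysis, sprintf(".tran %s %s uic",
                                        .spice_fmt(a$segment / 20),
                                        .spice_fmt(a$segment * 2^k)))
      },
      PLOT = plotted <- c(plotted, a$species),
      PLOTALL = plotted <- c(plotted, sp$name),
      STEADY = analysis <- c(analysis, ".op"))
  }
  if (length(plotted) > 0)
    controls <- c(".control", "run",
                  paste("plot", paste0("v(", nodes[unique(plotted)], ")",
                                       collapse = " ")),
                  ".endc")
  lines <- c(lines, model$passthrough, analysis, controls, ".end")
  structure(lines, class = "bsp_deck")
}

#' @export
print.bsp_deck <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' Write a SPICE deck to a file
#'
#' @param deck a [to_spice()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_spice <- function(deck, path) {
  writeLines(unclass(deck), path)
  invisible(path)
}

#' Lint a generated SPICE deck
#'
#' Structural checks on a generated netlist: a single analysis
#' statement, `.end` present and last, every device node declared as a
#' species node (capacitor line) or ground, no floating sources.
#'
#' @param deck a [to_spice()] result (or character vector of lines).
#' @return a character vector of findings; empty when the deck is clean.
#' @export
deck_lint <- function(deck) {
  lines <- unclass(deck)
  findings <- character()
  body <- lines[!startsWith(lines, "*")]
  ends <- which(trimws(tolower(body)) == ".end")
  if (length(ends) == 0) findings <- c(findings, "missing .end")
  else if (ends[length(ends)] != length(body))
    findings <- c(findings, ".end is not the last statement")
  n_analysis <- sum(grepl("^\\.(tran|dc|ac|op)\\b", tolower(body)))
  if (n_analysis > 1) findings <- c(findings, "multiple analyses")
  # declared nodes: capacitor lines "Cxxx NODE 0 ..."
  caps <- body[grepl("^C", body)]
  declared <- c("0", vapply(strsplit(caps, "\\s+"), function(t) t[2], ""))
  two_node <- body[grepl("^(R|B|I|V)", body) & !grepl("^\\.", body)]
  for (ln in two_node) {
    t <- strsplit(ln, "\\s+")[[1]]
    if (length(t) < 3) next
    for (nd in t[2:3])
      if (!nd %in% declared)
        findings <- c(findings, sprintf("device '%s' references undeclared node '%s'",
                                        t[1], nd))
  }
  unique(findings)
}
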