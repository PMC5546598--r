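# SBML (Level 3 Version 1) import and export, built on xml2.
#
# Import accepts Level 2 and Level 3 core documents.  Kinetic-law
# MathML is translated into the package's expression grammar; reaction-
# local parameters are substituted by value, user-defined functions are
# inlined, parameter assignment rules become dependent parameter
# definitions and species-referencing assignment rules are inlined into
# every formula that uses them (dynamically equivalent).  Unsupported
# constructs (units, algebraic rules, events, ...) are partitioned into
# the report's `dropped` list; nothing is silently ignored.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

# ---- MathML reading --------------------------------------------------

.mathml_cn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  txts <- xml2::xml_contents(node)
  if (!is.na(type) && type %in% c("e-notation", "rational")) {
    parts <- trimws(xml2::xml_text(txts[xml2::xml_name(txts) != "sep"]))
    parts <- parts[nzchar(parts)]
    a <- as.numeric(parts[1]); b <- as.numeric(parts[2])
    return(if (type == "e-notation") a * 10^b else a / b)
  }
  as.numeric(trimws(xml2::xml_text(node)))
}

# MathML content element -> R call/symbol/number.
.mathml_to_lang <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1) stop("malformed <math> element", call. = FALSE)
    return(.mathml_to_lang(kids[[1]]))
  }
  if (nm == "cn") return(.mathml_cn(node))
  if (nm == "ci") return(as.symbol(trimws(xml2::xml_text(node))))
  if (nm == "csymbol") {
    url <- xml2::xml_attr(node, "definitionURL")
    if (!is.na(url) && grepl("time", url)) return(as.symbol(".time"))
    stop(sprintf("unsupported csymbol '%s'", trimws(xml2::xml_text(node))),
         call. = FALSE)
  }
  if (nm == "pi") return(pi)
  if (nm == "exponentiale") return(exp(1))
  if (nm != "apply")
    stop(sprintf("unsupported MathML element <%s>", nm), call. = FALSE)
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  args <- kids[-1]
  # <log> and <root> carry qualifier children
  qual <- NULL
  if (length(args) > 0 && xml2::xml_name(args[[1]]) %in% c("logbase", "degree")) {
    qual <- .mathml_to_lang(xml2::xml_child(args[[1]]))
    args <- args[-1]
  }
  al <- lapply(seq_along(args), function(i) .mathml_to_lang(args[[i]]))
  nary <- function(fn) Reduce(function(a, b) call(fn, a, b), al)
  switch(op,
    plus = if (length(al) == 0) 0 else nary("+"),
    times = if (length(al) == 0) 1 else nary("*"),
    minus = if (length(al) == 1) call("-", al[[1]]) else call("-", al[[1]], al[[2]]),
    divide = call("/", al[[1]], al[[2]]),
    power = call("^", al[[1]], al[[2]]),
    exp = call("exp", al[[1]]),
    ln = call("ln", al[[1]]),
    log = {
      base <- qual %||% 10
      if (is.numeric(base) && base == 10) call("log10", al[[1]])
      else if (is.numeric(base) && abs(base - exp(1)) < 1e-12) call("ln", al[[1]])
      else call("/", call("ln", al[[1]]), call("ln", base))
    },
    root = {
      deg <- qual %||% 2
      if (is.numeric(deg) && deg == 2) call("sqrt", al[[1]])
      else call("^", al[[1]], call("/", 1, deg))
    },
    min = nary("min"),
    max = nary("max"),
    ci = {  # function invocation: first child is <ci>fname</ci>
      fname <- trimws(xml2::xml_text(kids[[1]]))
      as.call(c(as.symbol(fname), al))
    },
    stop(sprintf("unsupported MathML operator <%s>", op), call. = FALSE))
}

# Walk a lang object applying a symbol substitution map (symbol ->
# lang/number) and inlining user-defined functions.
.lang_substitute <- function(lang, submap = list(), fundefs = list()) {
  rec <- function(x) {
    if (is.call(x)) {
      fn <- x[[1]]
      if (is.symbol(fn) && as.character(fn) %in% names(fundefs)) {
        fd <- fundefs[[as.character(fn)]]
        actual <- lapply(as.list(x)[-1], rec)
        if (length(actual) != length(fd$args))
          stop(sprintf("function '%s' called with %d argument(s), expects %d",
                       as.character(fn), length(actual), length(fd$args)),
               call. = FALSE)
        local_map <- stats::setNames(actual, fd$args)
        return(.lang_substitute(fd$body, c(local_map, submap), fundefs))
      }
      for (i in seq_along(x)[-1]) x[[i]] <- rec(x[[i]])
      return(x)
    }
    if (is.symbol(x)) {
      nm <- as.character(x)
      if (nm %in% names(submap)) return(submap[[nm]])
    }
    x
  }
  rec(lang)
}

.lang_symbols <- function(lang) {
  out <- character()
  rec <- function(x) {
    if (is.call(x)) for (a in as.list(x)[-1]) rec(a)
    else if (is.symbol(x)) out <<- c(out, as.character(x))
  }
  rec(lang)
  unique(out)
}

# lang -> source string in the package grammar, bracketing species ids.
.lang_to_src <- function(lang, species = character()) {
  prec <- c(`+` = 1, `-` = 1, `*` = 2, `/` = 2, `^` = 3)
  rec <- function(x, parent_prec = 0) {
    if (is.numeric(x)) {
      if (x < 0) return(paste0("(", format(x, digits = 17, trim = TRUE), ")"))
      return(format(x, digits = 17, trim = TRUE))
    }
    if (is.symbol(x)) {
      nm <- as.character(x)
      return(if (nm %in% species) paste0("[", nm, "]") else nm)
    }
    fn <- as.character(x[[1]])
    if (fn == "(") return(rec(x[[2]], parent_prec))
    if (fn %in% names(prec)) {
      if (fn == "-" && length(x) == 2) {
        s <- paste0("-", rec(x[[2]], 3))
        return(if (parent_prec > 1) paste0("(", s, ")") else s)
      }
      p <- prec[[fn]]
      s <- paste0(rec(x[[2]], p), fn, rec(x[[3]], p + (fn %in% c("-", "/", "^"))))
      return(if (p < parent_prec) paste0("(", s, ")") else s)
    }
    paste0(fn, "(", paste(vapply(as.list(x)[-1], rec, "", 0), collapse = ","), ")")
  }
  rec(lang)
}

# ---- MathML writing --------------------------------------------------

.lang_to_mathml <- function(lang, species = character()) {
  rec <- function(x) {
    if (is.numeric(x)) return(paste0("<cn> ", format(x, digits = 17, trim = TRUE),
                                     " </cn>"))
    if (is.symbol(x)) return(paste0("<ci> ", as.character(x), " </ci>"))
    fn <- as.character(x[[1]])
    if (fn == "(") return(rec(x[[2]]))
    args <- vapply(as.list(x)[-1], rec, "")
    op <- switch(fn,
      `+` = "plus", `-` = "minus", `*` = "times", `/` = "divide",
      `^` = "power", pow = "power", exp = "exp", ln = "ln",
      log10 = NULL, sqrt = NULL, min = "min", max = "max",
      stop(sprintf("cannot export function '%s' to MathML", fn), call. = FALSE))
    if (fn == "log10")
      return(paste0("<apply><log/><logbase><cn> 10 </cn></logbase>",
                    args[1], "</apply>"))
    if (fn == "sqrt")
      return(paste0("<apply><root/>", args[1], "</apply>"))
    paste0("<apply><", op, "/>", paste(args, collapse = ""), "</apply>")
  }
  paste0('<math xmlns="', .MATHML_NS, '">', rec(lang), "</math>")
}

# ---- identifier sanitization ----------------------------------------

.sanitize_sid <- function(ids) {
  out <- gsub("[^A-Za-z0-9_]", "_", ids)
  bad <- !grepl("^[A-Za-z_]", out)
  out[bad] <- paste0("x_", out[bad])
  while (anyDuplicated(out)) {
    d <- duplicated(out)
    out[d] <- paste0(out[d], "_")
  }
  out
}

# ---- export ----------------------------------------------------------

# Build the rate-law expression string for a typed reaction, using the
# reaction's parameter entries verbatim (parameter names stay symbolic,
# numbers are inlined).
.reaction_formula <- function(r) {
  p <- lapply(r$params, as.character)
  ref <- function(s) paste0("[", s, "]")
  powered <- function(df) paste(
    ifelse(df$stoich > 1, paste0(ref(df$species), "^", df$stoich),
           ref(df$species)), collapse = "*")
  hill <- function(sp, K, n)
    sprintf("(%s/%s)^%s", ref(sp), K, n)
  switch(r$type,
    B = {
      fwd <- paste0(p$k_on, "*", powered(r$reactants))
      koff_num <- parse_spice_number(p$k_off)
      if (!is.na(koff_num) && koff_num == 0) fwd
      else paste0(fwd, "-", p$k_off, "*", powered(r$products))
    },
    C = p$beta,
    D = paste0(p$d, "*", ref(r$reactants$species[1])),
    E = {
      S <- ref(r$reactants$species[1])
      E <- if (length(r$modifiers) > 0)
        paste0("(", paste(vapply(r$modifiers, ref, ""), collapse = "+"), ")*")
      else ""
      sprintf("%s*%s%s/(%s+%s)", p$v_max, E, S, p$K_m, S)
    },
    F = sprintf("%s*(%s-%s)", p$D, ref(r$reactants$species[1]),
                ref(r$products$species[1])),
    H = {
      R <- ref(r$reactants$species[1])
      sprintf("%s*%s^%s/(%s^%s+%s^%s)", p$v_max, R, p$n, p$K, p$n, R, p$n)
    },
    L = paste0(p$k_TL, "*", ref(r$modifiers[1])),
    P = {
      terms <- vapply(seq_along(r$modifiers), function(j) {
        M <- ref(r$modifiers[j])
        sprintf("(%s^%s/(%s^%s+%s^%s))", M, p$n[j], p$K[j], p$n[j], M, p$n[j])
      }, "")
      paste(c(p$v_max, terms), collapse = "*")
    },
    T = {
      act <- vapply(seq_along(r$activators), function(j)
        hill(r$activators[j], p$KA[j], p$nA[j]), "")
      rep <- vapply(seq_along(r$repressors), function(j)
        hill(r$repressors[j], p$KR[j], p$nR[j]), "")
      den <- paste(c("1", act, rep), collapse = "+")
      num <- if (length(act) > 0) paste0("(", paste(act, collapse = "+"), ")")
             else "1"
      sprintf("%s*%s/(%s)", p$k_TR, num, den)
    },
    X = r$rate)
}

#' Export a model to SBML
#'
#' Writes an SBML Level 3 Version 1 document: literal parameters become
#' SBML parameters, dependent parameters become assignment rules,
#' species carry their initial concentration and compartment, each
#' reaction is exported with its participants and a MathML kinetic law
#' built from its type, and every species with a nonzero degradation
#' rate gains an extra first-order degradation reaction (SBML has no
#' native degradation field).  Simulation directives are not
#' representable in SBML and are omitted; passthrough lines trigger a
#' warning.
#'
#' @param model a [bsp_model()].
#' @param path optional file path to write to.
#' @return an `xml2` document, invisibly when `path` is given.
#' @export
export_sbml <- function(model, path = NULL) {
  validate_model(model)
  if (length(model$passthrough) > 0)
    warning("passthrough lines are not representable in SBML and were dropped",
            call. = FALSE)
  sp <- model$species
  vols <- sort(unique(sp$compartment))
  comp_id <- stats::setNames(paste0("comp", seq_along(vols)), as.character(vols))

  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="1">', .SBML_NS),
    '<model id="model">',
    "<listOfCompartments>",
    sprintf('<compartment id="%s" size="%s" constant="true"/>',
            comp_id, format(vols, digits = 17, trim = TRUE)),
    "</listOfCompartments>")

  if (nrow(sp) > 0) {
    lines <- c(lines, "<listOfSpecies>",
      sprintf(paste0('<species id="%s" compartment="%s" initialConcentration="%s"',
                     ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
                     ' constant="false"/>'),
              sp$name, comp_id[as.character(sp$compartment)],
              format(sp$initial, digits = 17, trim = TRUE)),
      "</listOfSpecies>")
  }

  p <- model$parameters
  is_literal <- !is.na(vapply(p$expression, parse_spice_number, 0))
  rules <- character()
  if (nrow(p) > 0) {
    plines <- character()
    for (i in seq_len(nrow(p))) {
      if (is_literal[i]) {
        plines <- c(plines, sprintf('<parameter id="%s" value="%s" constant="true"/>',
                                    p$name[i],
                                    format(parse_spice_number(p$expression[i]),
                                           digits = 17, trim = TRUE)))
      } else {
        plines <- c(plines, sprintf('<parameter id="%s" constant="false"/>', p$name[i]))
        ex <- bsp_parse_expr(p$expression[i])
        rules <- c(rules, sprintf('<assignmentRule variable="%s">%s</assignmentRule>',
                                  p$name[i], .lang_to_mathml(ex$lang)))
      }
    }
    lines <- c(lines, "<listOfParameters>", plines, "</listOfParameters>")
  }
  if (length(rules) > 0)
    lines <- c(lines, "<listOfRules>", rules, "</listOfRules>")

  rxn_xml <- function(id, reactants, products, modifiers, formula_src) {
    ex <- bsp_parse_expr(formula_src)
    # species symbols were bracketed in the source; in MathML they are
    # plain <ci>, so rewrite .S.X symbols back to X
    lang <- if (length(ex$species) == 0) ex$lang else
      .lang_substitute(ex$lang,
        submap = stats::setNames(lapply(ex$species, function(s) as.symbol(s)),
                                 paste0(".S.", ex$species)))
    refs <- function(df, tag) {
      if (is.null(df) || nrow(df) == 0) return(character())
      c(sprintf("<listOf%ss>", tag),
        sprintf('<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                df$species, df$stoich),
        sprintf("</listOf%ss>", tag))
    }
    mods <- if (length(modifiers) > 0)
      c("<listOfModifiers>",
        sprintf('<modifierSpeciesReference species="%s"/>', modifiers),
        "</listOfModifiers>") else character()
    c(sprintf('<reaction id="%s" reversible="true" fast="false">', id),
      refs(reactants, "Reactant"), refs(products, "Product"), mods,
      "<kineticLaw>", .lang_to_mathml(lang), "</kineticLaw>", "</reaction>")
  }

  rlines <- character()
  for (r in model$reactions) {
    mods <- unique(c(r$modifiers, r$activators, r$repressors))
    rlines <- c(rlines, rxn_xml(r$name, r$reactants, r$products, mods,
                                .reaction_formula(r)))
  }
  for (i in seq_len(nrow(sp))) {
    if (sp$degradation[i] > 0) {
      rlines <- c(rlines, rxn_xml(
        paste0("deg_", sp$name[i]),
        tibble::tibble(species = sp$name[i], stoich = 1L), NULL, character(),
        sprintf("%s*[%s]", format(sp$degradation[i], digits = 17, trim = TRUE),
                sp$name[i])))
    }
  }
  if (length(rlines) > 0)
    lines <- c(lines, "<listOfReactions>", rlines, "</listOfReactions>")
  lines <- c(lines, "</model>", "</sbml>")
  doc <- xml2::read_xml(paste(lines, collapse = "\n"))
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

# ---- import ----------------------------------------------------------

#' Import an SBML document
#'
#' Translates an SBML Level 2/3 core document into a [bsp_model()]:
#' global parameters, species with compartment volumes, and one custom
#' (`X`-type) reaction per SBML reaction whose rate expression is the
#' kinetic law with reaction-local parameters substituted by value and
#' user-defined functions inlined.  Parameter assignment rules become
#' dependent parameter definitions; assignment rules that reference
#' species are inlined into every formula using them; rate rules become
#' extra source reactions.  Boundary-condition species are clamped via
#' `FIX` directives.  Unsupported constructs (unit definitions,
#' algebraic rules, events, ...) are listed in the report's `dropped`
#' partition; with `strict = TRUE` they raise an error instead.
#'
#' @param x an SBML file path, XML string or `xml2` document.
#' @param strict error on unsupported constructs instead of dropping?
#' @return a list with elements `model` (a [bsp_model()]) and `report`
#'   (an `ImportReport` tibble with columns `construct`, `id`,
#'   `status`, `reason`).
#' @export
import_sbml <- function(x, strict = FALSE) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  doc <- xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("no <model> element found", call. = FALSE)

  report <- list()
  note <- function(construct, id, status, reason = "") {
    if (strict && status == "dropped")
      stop(sprintf("unsupported SBML construct: %s '%s' (%s)", construct, id, reason),
           call. = FALSE)
    report[[length(report) + 1]] <<-
      tibble::tibble(construct = construct, id = id, status = status,
                     reason = reason)
  }

  att <- function(node, a, default = NA_character_) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) default else v
  }
  natt <- function(node, a, default = NA_real_) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) default else as.numeric(v)
  }

  # compartments
  comp_nodes <- xml2::xml_find_all(mdl, ".//listOfCompartments/compartment")
  comp_size <- stats::setNames(
    vapply(comp_nodes, function(n) { s <- natt(n, "size", NA); if (is.na(s)) 1 else s }, 0),
    vapply(comp_nodes, function(n) att(n, "id"), ""))
  for (id in names(comp_size)) note("compartment", id, "supported")

  # raw id tables (sanitized)
  sp_nodes <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  sp_ids_raw <- vapply(sp_nodes, function(n) att(n, "id"), "")
  par_nodes <- xml2::xml_find_all(mdl, "./listOfParameters/parameter")
  par_ids_raw <- vapply(par_nodes, function(n) att(n, "id"), "")
  all_raw <- c(sp_ids_raw, par_ids_raw)
  all_clean <- .sanitize_sid(all_raw)
  idmap <- stats::setNames(all_clean, all_raw)
  clean <- function(id) if (id %in% names(idmap)) idmap[[id]] else id

  # function definitions
  fundefs <- list()
  for (fd in xml2::xml_find_all(mdl, ".//listOfFunctionDefinitions/functionDefinition")) {
    id <- att(fd, "id")
    lam <- xml2::xml_find_first(fd, ".//lambda")
    ok <- tryCatch({
      bvars <- vapply(xml2::xml_find_all(lam, "./bvar/ci"),
                      function(n) trimws(xml2::xml_text(n)), "")
      kids <- xml2::xml_children(lam)
      body_node <- kids[[length(kids)]]
      fundefs[[id]] <- list(args = bvars, body = .mathml_to_lang(body_node))
      TRUE
    }, error = function(e) FALSE)
    note("functionDefinition", id, if (ok) "supported" else "dropped",
         if (ok) "inlined at call sites" else "unparseable lambda")
  }

  # events / algebraic rules / units -> dropped
  for (n in xml2::xml_find_all(mdl, ".//listOfEvents/event"))
    note("event", att(n, "id", "(anonymous)"), "dropped",
         "events are not representable in the netlist model")
  for (n in xml2::xml_find_all(mdl, ".//listOfRules/algebraicRule"))
    note("algebraicRule", "(anonymous)", "dropped", "algebraic rule: unsupported")
  for (n in xml2::xml_find_all(mdl, ".//listOfUnitDefinitions/unitDefinition"))
    note("unitDefinition", att(n, "id"), "dropped", "unit definitions are ignored")

  # rename raw document ids to sanitized ones inside a formula
  rename_ids <- function(lang) {
    syms <- .lang_symbols(lang)
    ren <- syms[syms %in% names(idmap) & syms != idmap[syms]]
    if (length(ren) == 0) return(lang)
    .lang_substitute(lang,
      submap = stats::setNames(lapply(unname(idmap[ren]), as.symbol), ren))
  }

  # assignment rules: sanitized variable -> lang (functions inlined)
  assign_rules <- list()
  for (n in xml2::xml_find_all(mdl, ".//listOfRules/assignmentRule")) {
    v <- att(n, "variable")
    lang <- tryCatch(
      rename_ids(.lang_substitute(.mathml_to_lang(xml2::xml_find_first(n, "./math")),
                                  fundefs = fundefs)),
      error = function(e) NULL)
    if (is.null(lang) || ".time" %in% .lang_symbols(lang)) {
      note("assignmentRule", v, "dropped", "time-dependent or unparseable rule")
    } else {
      assign_rules[[clean(v)]] <- lang
      note("assignmentRule", v, "supported", "inlined into referencing formulas")
    }
  }
  # topological inlining of chained rules; cyclic sets rejected
  if (length(assign_rules) > 0) {
    for (pass in seq_len(length(assign_rules) + 1)) {
      changed <- FALSE
      for (v in names(assign_rules)) {
        syms <- intersect(.lang_symbols(assign_rules[[v]]), names(assign_rules))
        if (v %in% syms)
          stop(sprintf("cyclic assignment rules involving '%s'", v), call. = FALSE)
        if (length(syms) > 0) {
          assign_rules[[v]] <- .lang_substitute(assign_rules[[v]],
                                                submap = assign_rules[syms])
          changed <- TRUE
        }
      }
      if (!changed) break
      if (pass > length(assign_rules))
        stop("cyclic assignment rules detected", call. = FALSE)
    }
  }

  # species
  species <- tibble::tibble(name = character(), initial = double(),
                            degradation = double(), compartment = double())
  directives <- list()
  for (n in sp_nodes) {
    id <- att(n, "id")
    comp <- att(n, "compartment")
    vol <- if (comp %in% names(comp_size)) comp_size[[comp]] else 1
    conc <- natt(n, "initialConcentration", NA)
    if (is.na(conc)) {
      amt <- natt(n, "initialAmount", NA)
      conc <- if (is.na(amt)) 0 else amt / vol
    }
    if (clean(id) %in% names(assign_rules)) {
      note("species", id, "supported", "concentration set by assignment rule (inlined)")
      next
    }
    species <- dplyr::bind_rows(species,
      tibble::tibble(name = clean(id), initial = max(conc, 0),
                     degradation = 0, compartment = vol))
    boundary <- identical(att(n, "boundaryCondition"), "true") ||
      identical(att(n, "constant"), "true")
    if (boundary) {
      directives[[length(directives) + 1]] <-
        bsp_directive("FIX", species = clean(id), value = max(conc, 0))
      note("species", id, "supported", "boundary condition -> FIX clamp")
    } else note("species", id, "supported")
  }
  sp_clean <- species$name

  # global parameters
  parameters <- tibble::tibble(name = character(), expression = character(),
                               comment = character())
  rate_rule_targets <- vapply(
    xml2::xml_find_all(mdl, ".//listOfRules/rateRule"),
    function(n) att(n, "variable"), "")
  for (n in par_nodes) {
    id <- att(n, "id")
    if (clean(id) %in% names(assign_rules)) {
      ex_lang <- assign_rules[[clean(id)]]
      # parameter rules may only reference parameters; species refs force inlining
      if (length(intersect(.lang_symbols(ex_lang), sp_clean)) > 0) {
        note("parameter", id, "supported",
             "assignment rule references species; inlined into formulas")
        next
      }
      parameters <- dplyr::bind_rows(parameters,
        tibble::tibble(name = clean(id), expression = .lang_to_src(ex_lang),
                       comment = "assignment rule"))
      note("parameter", id, "supported", "assignment rule -> dependent parameter")
      next
    }
    if (id %in% rate_rule_targets) {
      # becomes a pseudo-species integrated by a rate rule
      v0 <- natt(n, "value", 0)
      species <- dplyr::bind_rows(species,
        tibble::tibble(name = clean(id), initial = max(v0, 0), degradation = 0,
                       compartment = 1))
      sp_clean <- species$name
      note("parameter", id, "supported", "rate rule target -> state variable")
      next
    }
    v <- natt(n, "value", NA)
    if (is.na(v)) {
      note("parameter", id, "dropped", "no value and no supported rule")
      next
    }
    parameters <- dplyr::bind_rows(parameters,
      tibble::tibble(name = clean(id), expression = format(v, digits = 17, trim = TRUE),
                     comment = ""))
    note("parameter", id, "supported")
  }

  # formula post-processing shared by reactions and rate rules:
  # substitute reaction-local parameters (raw ids), inline functions,
  # rename document ids to sanitized ones, then inline assignment rules
  inline_all <- function(lang, locals = list()) {
    lang <- .lang_substitute(lang, submap = locals, fundefs = fundefs)
    lang <- rename_ids(lang)
    .lang_substitute(lang, submap = assign_rules)
  }

  reactions <- list()
  for (n in xml2::xml_find_all(mdl, ".//listOfReactions/reaction")) {
    id <- att(n, "id")
    part <- function(xp) {
      nodes <- xml2::xml_find_all(n, xp)
      if (length(nodes) == 0)
        return(tibble::tibble(species = character(), stoich = integer()))
      st <- vapply(nodes, function(m) { s <- natt(m, "stoichiometry", 1); s }, 0)
      if (any(abs(st - round(st)) > 1e-9))
        stop(sprintf("reaction '%s': non-integer stoichiometry unsupported", id),
             call. = FALSE)
      tibble::tibble(species = vapply(nodes, function(m) clean(att(m, "species")), ""),
                     stoich = as.integer(round(st)))
    }
    kl <- xml2::xml_find_first(n, "./kineticLaw")
    if (inherits(kl, "xml_missing")) {
      note("reaction", id, "dropped", "no kinetic law")
      next
    }
    locals <- list()
    for (lp in xml2::xml_find_all(kl, "./listOfLocalParameters/localParameter | ./listOfParameters/parameter"))
      locals[[att(lp, "id")]] <- natt(lp, "value", 0)
    lang <- tryCatch(
      inline_all(.mathml_to_lang(xml2::xml_find_first(kl, "./math")), locals),
      error = function(e) e)
    if (inherits(lang, "error") || ".time" %in% .lang_symbols(lang)) {
      note("reaction", id, "dropped",
           if (inherits(lang, "error")) conditionMessage(lang)
           else "kinetic law depends on time")
      next
    }
    mods <- vapply(xml2::xml_find_all(n, "./listOfModifiers/modifierSpeciesReference"),
                   function(m) clean(att(m, "species")), "")
    mods <- intersect(mods, sp_clean)
    reactions[[length(reactions) + 1]] <- bsp_reaction(
      paste0("X_", clean(id)),
      reactants = part("./listOfReactants/speciesReference"),
      products = part("./listOfProducts/speciesReference"),
      modifiers = mods,
      rate = .lang_to_src(lang, species = sp_clean))
    note("reaction", id, "supported")
  }

  # rate rules -> one source reaction adding the rule's value to the target
  for (n in xml2::xml_find_all(mdl, ".//listOfRules/rateRule")) {
    v <- att(n, "variable")
    lang <- tryCatch(
      inline_all(.mathml_to_lang(xml2::xml_find_first(n, "./math"))),
      error = function(e) e)
    if (inherits(lang, "error") || ".time" %in% .lang_symbols(lang) ||
        !clean(v) %in% species$name) {
      note("rateRule", v, "dropped", "time-dependent, unparseable or unknown target")
      next
    }
    vol <- species$compartment[species$name == clean(v)]
    if (vol != 1)  # rhs divides flux by volume; rate rules are d[X]/dt directly
      lang <- call("*", lang, vol)
    reactions[[length(reactions) + 1]] <- bsp_reaction(
      paste0("X_rate_", clean(v)), products = clean(v),
      rate = .lang_to_src(lang, species = sp_clean))
    note("rateRule", v, "supported", "extra derivative contribution")
  }

  model <- bsp_model(parameters = parameters, species = species,
                     reactions = reactions, directives = directives)
  rep <- if (length(report) > 0) dplyr::bind_rows(report)
         else tibble::tibble(construct = character(), id = character(),
                             status = character(), reason = character())
  list(model = model, report = rep, id_map = idmap)
}
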