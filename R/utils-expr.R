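# Numeric literals and rate/parameter expressions shared by the parser,
# the rate-law evaluator and the exporters.

# Engineering suffixes accepted on numeric literals (SPICE convention).
.bsp_suffixes <- c(k = 1e3, m = 1e-3, u = 1e-6, n = 1e-9, p = 1e-12)

#' Parse a numeric literal with SPICE engineering suffixes
#'
#' Accepts plain and scientific notation plus the suffixes `k` (1e3),
#' `m` (1e-3), `u` (1e-6), `n` (1e-9) and `p` (1e-12), e.g. `"2.5u"`.
#'
#' @param x a character scalar.
#' @return a double, or `NA` if `x` is not a numeric literal.
#' @export
parse_spice_number <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^([+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)([kmunp]?)$", x))[[1]]
  if (length(m) == 0) return(NA_real_)
  v <- as.numeric(m[2])
  if (nzchar(m[3])) v <- v * .bsp_suffixes[[m[3]]]
  v
}

# Rewrite engineering-suffixed literals inside an expression string into
# plain scientific notation so the R parser can read it.
.expand_suffixes <- function(text) {
  gsub("(?<![A-Za-z0-9_.])([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)([kmunp])(?![A-Za-z0-9_])",
       "(\\1*1\\2)", text, perl = TRUE) |>
    (\(s) {
      # second pass: the injected "1k" style literal -> numeric
      for (sf in names(.bsp_suffixes)) {
        s <- gsub(paste0("\\*1", sf, "\\)"),
                  paste0("*", format(.bsp_suffixes[[sf]], scientific = TRUE), ")"), s)
      }
      s
    })()
}

# Functions allowed inside rate/parameter expressions, mapped to their R
# equivalents.  `pow(a,b)` becomes `a^b`, `ln` is the natural log.
.bsp_funs <- c("exp", "ln", "log10", "pow", "min", "max", "sqrt")

.bsp_eval_env <- function() {
  e <- new.env(parent = baseenv())
  e$exp <- exp; e$ln <- log; e$log10 <- log10
  e$pow <- function(a, b) a^b
  e$min <- min; e$max <- max; e$sqrt <- sqrt
  e
}

# Species references are written `[Name]`; internally they become the
# symbol `.S.Name` so the expression is valid R.
.species_ref_to_sym <- function(text) {
  gsub("\\[([A-Za-z_][A-Za-z0-9_]*)\\]", ".S.\\1", text)
}

.sym_to_species_ref <- function(text) {
  gsub("\\.S\\.([A-Za-z_][A-Za-z0-9_]*)", "[\\1]", text)
}

#' Parse a rate or parameter expression
#'
#' Grammar: `+ - * / ^`, parentheses, the functions
#' `exp, ln, log10, pow, min, max, sqrt`, species concentrations written
#' in brackets (`[S]`) and parameters as bare identifiers.
#'
#' @param text expression source.
#' @return an object of class `bsp_expr`: the parsed R call plus the
#'   species and parameter names it references.
#' @keywords internal
bsp_parse_expr <- function(text) {
  src <- text
  text <- .species_ref_to_sym(.expand_suffixes(text))
  lang <- tryCatch(str2lang(text), error = function(e) {
    stop(sprintf("cannot parse expression '%s': %s", src, conditionMessage(e)),
         call. = FALSE)
  })
  syms <- character(); funs <- character()
  walk <- function(x) {
    if (is.call(x)) {
      fn <- as.character(x[[1]])
      funs <<- c(funs, fn)
      for (a in as.list(x)[-1]) walk(a)
    } else if (is.symbol(x)) {
      syms <<- c(syms, as.character(x))
    } else if (!is.numeric(x)) {
      stop(sprintf("unsupported token in expression '%s'", src), call. = FALSE)
    }
  }
  walk(lang)
  bad <- setdiff(unique(funs), c("+", "-", "*", "/", "^", "(", .bsp_funs))
  if (length(bad) > 0) {
    stop(sprintf("unsupported function(s) %s in expression '%s'",
                 paste0("'", bad, "'", collapse = ", "), src), call. = FALSE)
  }
  syms <- unique(syms)
  species <- sub("^\\.S\\.", "", syms[startsWith(syms, ".S.")])
  params <- syms[!startsWith(syms, ".S.")]
  structure(list(src = src, lang = lang, species = species, params = params),
            class = "bsp_expr")
}

# Evaluate a parsed expression given concentrations and parameter values.
bsp_eval_expr <- function(ex, conc = numeric(), params = numeric()) {
  e <- .bsp_eval_env()
  if (length(params)) for (nm in names(params)) assign(nm, params[[nm]], envir = e)
  if (length(conc))  for (nm in names(conc))  assign(paste0(".S.", nm), conc[[nm]], envir = e)
  v <- eval(ex$lang, envir = e)
  if (!is.finite(v)) {
    if (is.nan(v) || is.infinite(v))
      stop(sprintf("expression '%s' evaluated to a non-finite value", ex$src),
           call. = FALSE)
  }
  v
}

# Evaluate a numeric-or-formula field (no species refs allowed) against
# resolved parameter values.
bsp_eval_scalar <- function(text, params = numeric()) {
  v <- parse_spice_number(text)
  if (!is.na(v)) return(v)
  ex <- bsp_parse_expr(text)
  if (length(ex$species) > 0)
    stop(sprintf("species references not allowed in '%s'", text), call. = FALSE)
  missing <- setdiff(ex$params, names(params))
  if (length(missing) > 0)
    stop(sprintf("undefined parameter(s) %s in '%s'",
                 paste(missing, collapse = ", "), text), call. = FALSE)
  bsp_eval_expr(ex, params = params)
}
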