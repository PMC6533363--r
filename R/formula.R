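#' Parse a chemical formula into element counts
#'
#' Understands element symbols, integer multipliers and (possibly nested)
#' parentheses, e.g. `"Au(OH)4"` -> c(Au = 1, O = 4, H = 4). Charge is *not*
#' part of the formula string; it is stored separately on the species.
#'
#' @param formula a single formula string. The empty string (used for the
#'   electron pseudo-species) yields an empty count vector.
#' @return named numeric vector of element counts.
#' @export
#' @examples
#' parse_formula("Au(OH)4")
#' parse_formula("S2O3")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (formula == "") return(stats::setNames(numeric(0), character(0)))
  parse_chunk(formula)
}

# recursive descent over one chunk; multiplies nested groups
parse_chunk <- function(s) {
  counts <- numeric(0)
  add <- function(el, n) {
    counts[el] <<- (if (el %in% names(counts)) counts[[el]] else 0) + n
  }
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      depth <- 1L; j <- i
      while (depth > 0L) {
        j <- j + 1L
        if (j > n) stop("unbalanced parenthesis in formula: ", s)
        cj <- substr(s, j, j)
        if (cj == "(") depth <- depth + 1L
        if (cj == ")") depth <- depth - 1L
      }
      inner <- parse_chunk(substr(s, i + 1L, j - 1L))
      mult <- regmatches(substr(s, j + 1L, n), regexpr("^[0-9]+", substr(s, j + 1L, n)))
      k <- if (length(mult)) as.numeric(mult) else 1
      for (el in names(inner)) add(el, inner[[el]] * k)
      i <- j + 1L + (if (length(mult)) nchar(mult) else 0L)
    } else {
      m <- regmatches(substr(s, i, n), regexpr("^[A-Z][a-z]?[0-9]*", substr(s, i, n)))
      if (!length(m)) stop("cannot parse formula at '", substr(s, i, n), "' in: ", s)
      el <- regmatches(m, regexpr("^[A-Z][a-z]?", m))
      num <- sub("^[A-Z][a-z]?", "", m)
      add(el, if (nzchar(num)) as.numeric(num) else 1)
      i <- i + nchar(m)
    }
  }
  counts
}

#' Define a chemical species
#'
#' A species carries its elemental composition, charge, phase, and optional
#' standard-state properties. Solids and liquid water are assigned unit
#' activity by the predominance calculations; `dGf` (standard Gibbs energy of
#' formation, kJ mol-1) is required only for species that take part in
#' pH-Eh diagram construction.
#'
#' @param name identifier used in reaction equations (e.g. `"Au(OH)4-"`).
#' @param formula formula string understood by [parse_formula()]; `""` for the
#'   electron pseudo-species.
#' @param charge signed integer charge.
#' @param phase one of `"solid"`, `"liquid"`, `"gas"`, `"aqueous"`.
#' @param dGf,dHf,S0 optional standard-state Gibbs energy / enthalpy of
#'   formation (kJ mol-1) and entropy (J mol-1 K-1).
#' @return object of class `thermo_species`.
#' @export
thermo_species <- function(name, formula, charge = 0, phase = "aqueous",
                           dGf = NA_real_, dHf = NA_real_, S0 = NA_real_) {
  phase <- match.arg(phase, c("solid", "liquid", "gas", "aqueous"))
  elements <- parse_formula(formula)
  if (any(elements <= 0)) stop("element counts must be positive: ", name)
  structure(
    list(name = name, formula = formula, elements = elements,
         charge = charge, phase = phase, dGf = dGf, dHf = dHf, S0 = S0),
    class = "thermo_species"
  )
}

#' @export
print.thermo_species <- function(x, ...) {
  cat(sprintf("species %s [%s] charge %+d", x$name, x$phase, x$charge))
  if (!is.na(x$dGf)) cat(sprintf(", dGf = %.2f kJ/mol", x$dGf))
  cat("\n")
  invisible(x)
}
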