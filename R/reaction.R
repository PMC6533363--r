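#' Construct a reaction from signed stoichiometric coefficients
#'
#' Reactants carry negative coefficients, products positive. Electrons are an
#' ordinary pseudo-species named `"e-"` (no elements, charge -1), so half
#' reactions balance like any other reaction.
#'
#' @param stoich named numeric vector of signed coefficients over species
#'   names; coefficients may be fractional.
#' @param logK base-10 equilibrium constant at 298 K, or `NA` until derived.
#' @param n_electrons moles of electrons transferred (0 for non-redox).
#'   Defaults to `|coefficient of "e-"|` when electrons appear explicitly.
#' @param label free-text description.
#' @return object of class `thermo_reaction`.
#' @export
#' @examples
#' r <- reaction(c("Au(s)" = -1, "O2-" = -1, "H+" = -4, "Au3+" = 1, "H2O" = 2),
#'               logK = 2.74, label = "superoxide oxidation of gold")
reaction <- function(stoich, logK = NA_real_, n_electrons = NULL, label = "") {
  stopifnot(is.numeric(stoich), !is.null(names(stoich)), all(nzchar(names(stoich))))
  stoich <- stoich[abs(stoich) > 1e-12]
  if (anyDuplicated(names(stoich)))
    stoich <- tapply(stoich, names(stoich), sum)[unique(names(stoich))]
  if (is.null(n_electrons))
    n_electrons <- if ("e-" %in% names(stoich)) abs(stoich[["e-"]]) else 0
  structure(
    list(stoich = stoich, logK = logK, n_electrons = n_electrons, label = label),
    class = "thermo_reaction"
  )
}

#' @export
print.thermo_reaction <- function(x, ...) {
  cat(format_reaction(x))
  if (!is.na(x$logK)) cat(sprintf("   logK = %.2f", x$logK))
  cat("\n")
  invisible(x)
}

#' Render a reaction as an equation string
#' @param rxn a `thermo_reaction`.
#' @return single string, e.g. `"Au(s) + O2- + 4 H+ = Au3+ + 2 H2O"`.
#' @export
format_reaction <- function(rxn) {
  side <- function(v) {
    if (!length(v)) return("(nothing)")
    coefs <- vapply(abs(v), format, character(1), trim = TRUE)
    paste(ifelse(abs(abs(v) - 1) < 1e-12, names(v),
                 paste(coefs, names(v))),
          collapse = " + ")
  }
  s <- rxn$stoich
  paste(side(s[s < 0]), "=", side(s[s > 0]))
}

#' Parse an equation string into a reaction
#'
#' The equation dialect uses `" + "` (spaces required) to separate terms and
#' `"="` between sides, so species names themselves may contain `"+"`
#' (`"Au3+"`, `"H+"`). A term is an optional coefficient (integer or decimal,
#' e.g. `0.75`) separated from the species name by a space.
#'
#' @param equation e.g. `"Au(s) + 0.75 O2(aq) + 3 H+ = Au3+ + 1.5 H2O"`.
#' @inheritParams reaction
#' @return object of class `thermo_reaction`.
#' @export
parse_equation <- function(equation, logK = NA_real_, n_electrons = NULL,
                           label = equation) {
  sides <- strsplit(equation, "=", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("equation must contain exactly one '=': ", equation)
  term <- function(txt, sign) {
    txt <- trimws(txt)
    m <- regmatches(txt, regexpr("^[0-9]*\\.?[0-9]+(?=\\s)", txt, perl = TRUE))
    coef <- if (length(m)) as.numeric(m) else 1
    name <- trimws(if (length(m)) substring(txt, nchar(m) + 1L) else txt)
    if (!nzchar(name)) stop("empty species name in term: '", txt, "'")
    stats::setNames(sign * coef, name)
  }
  parts <- function(s, sign) {
    toks <- strsplit(trimws(s), " + ", fixed = TRUE)[[1]]
    unlist(lapply(toks, term, sign = sign))
  }
  reaction(c(parts(sides[1], -1), parts(sides[2], +1)),
           logK = logK, n_electrons = n_electrons, label = label)
}

#' Check element and charge balance of a reaction
#'
#' Electrons (`"e-"`) are treated as carrying charge -1 and no elements. The
#' empty reaction is balanced by definition.
#'
#' @param rxn a `thermo_reaction`.
#' @param species a species database: a list of [thermo_species()] (or the
#'   `$species` component of [read_thermo_db()]), indexed by name. Every
#'   species in the reaction must be defined.
#' @param tol numerical tolerance on the deltas.
#' @return list with `element_delta` (named numeric, product minus reactant
#'   totals), `charge_delta`, and logical `ok`.
#' @export
check_balance <- function(rxn, species, tol = 1e-9) {
  stopifnot(inherits(rxn, "thermo_reaction"))
  missing <- setdiff(names(rxn$stoich), names(species))
  if (length(missing))
    stop("unknown species in reaction: ", paste(missing, collapse = ", "))
  eldelta <- numeric(0)
  chdelta <- 0
  for (nm in names(rxn$stoich)) {
    sp <- species[[nm]]
    co <- rxn$stoich[[nm]]
    for (el in names(sp$elements)) {
      eldelta[el] <- (if (el %in% names(eldelta)) eldelta[[el]] else 0) +
        co * sp$elements[[el]]
    }
    chdelta <- chdelta + co * sp$charge
  }
  list(element_delta = eldelta, charge_delta = chdelta,
       ok = all(abs(eldelta) < tol) && abs(chdelta) < tol)
}

#' Combine reactions by Hess's law
#'
#' Stoichiometries add with the given multipliers and cancel exactly; the
#' equilibrium constant of the result is the multiplier-weighted sum of the
#' inputs' log K values (log K is additive under reaction combination).
#'
#' @param terms list of `list(rxn, mult)` pairs (or two-element unnamed lists);
#'   multipliers may be negative or fractional.
#' @return a `thermo_reaction` with combined stoichiometry and logK. Electron
#'   count is recomputed from any surviving explicit `"e-"` coefficient.
#' @export
#' @examples
#' r5 <- parse_equation("H2O = H+ + OH-", logK = -14)
#' combine_reactions(list(list(r5, 1), list(r5, -1))) # empty reaction, logK 0
combine_reactions <- function(terms) {
  stopifnot(is.list(terms), length(terms) >= 1L)
  stoich <- numeric(0)
  logK <- 0
  labels <- character(0)
  for (tm in terms) {
    rxn <- tm[[1]]; mult <- tm[[2]]
    stopifnot(inherits(rxn, "thermo_reaction"), is.numeric(mult))
    if (is.na(rxn$logK))
      stop("cannot combine: reaction without logK (", rxn$label, ")")
    for (nm in names(rxn$stoich)) {
      stoich[nm] <- (if (nm %in% names(stoich)) stoich[[nm]] else 0) +
        mult * rxn$stoich[[nm]]
    }
    logK <- logK + mult * rxn$logK
    labels <- c(labels, sprintf("%g x (%s)", mult, rxn$label))
  }
  reaction(stoich, logK = logK, label = paste(labels, collapse = " + "))
}

#' Partition the Gibbs energy of a whole reaction between two half reactions
#'
#' Verifies that the two half reactions sum (with electron cancellation) to
#' the whole reaction, then returns the Gibbs energy of the unknown half as
#' the difference `dG(rxn) - dG(known half)` (Gibbs energies are additive).
#'
#' @param rxn the whole reaction (`thermo_reaction`).
#' @param half_known,half_other the two half reactions; their stoichiometries
#'   must add up to `rxn` once electrons cancel.
#' @param dG_rxn Gibbs energy of the whole reaction, kJ mol-1.
#' @param dG_known Gibbs energy of `half_known`, kJ mol-1.
#' @param tol tolerance for the stoichiometric sum check.
#' @return Gibbs energy of `half_other`, kJ mol-1.
#' @export
half_reaction_split <- function(rxn, half_known, half_other, dG_rxn, dG_known,
                                tol = 1e-9) {
  summed <- numeric(0)
  for (h in list(half_known, half_other)) {
    for (nm in names(h$stoich)) {
      summed[nm] <- (if (nm %in% names(summed)) summed[[nm]] else 0) + h$stoich[[nm]]
    }
  }
  summed <- summed[abs(summed) > tol]
  target <- rxn$stoich[abs(rxn$stoich) > tol]
  same <- setequal(names(summed), names(target)) &&
    all(abs(summed[names(target)] - target) < tol)
  if (!same)
    stop("half reactions do not sum to the whole reaction: ",
         format_reaction(reaction(if (length(summed)) summed else c("e-" = 0))))
  dG_rxn - dG_known
}
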