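#' Gibbs energy of reaction from enthalpy and entropy
#'
#' `dG = dH - T * dS / 1000` (the entropy term is converted from J to kJ).
#'
#' @param dH reaction enthalpy, kJ mol-1.
#' @param dS reaction entropy, J mol-1 K-1.
#' @param const a [thermo_constants()] set; its `T` is used.
#' @return Gibbs energy of reaction, kJ mol-1.
#' @export
#' @examples
#' delta_g_from_hs(-122.82, -359.74) # -15.62
delta_g_from_hs <- function(dH, dS, const = thermo_constants()) {
  stopifnot(is.finite(dH), is.finite(dS))
  dH - const$T * dS / 1000
}

#' Convert between Gibbs energy and equilibrium constant
#'
#' `dG = -2.303 R T logK`, with dG in kJ mol-1. The two functions are exact
#' inverses of each other.
#'
#' @param dG Gibbs energy of reaction, kJ mol-1.
#' @param logK base-10 equilibrium constant.
#' @param const a [thermo_constants()] set.
#' @return `logk_from_delta_g`: logK; `delta_g_from_logk`: dG in kJ mol-1.
#' @export
#' @examples
#' logk_from_delta_g(-15.62) # ~2.74
logk_from_delta_g <- function(dG, const = thermo_constants()) {
  -dG / const$lnK_factor
}

#' @rdname logk_from_delta_g
#' @export
delta_g_from_logk <- function(logK, const = thermo_constants()) {
  -logK * const$lnK_factor
}

#' Convert between half-reaction Gibbs energy and standard potential
#'
#' `dG0 = -n F E0` with F in kJ V-1 per electron equivalent. The sign
#' convention follows the reaction exactly as written: the potential of the
#' gold oxidation half reaction `Au(s) - 3 e- = Au3+` is -1.52 V, giving
#' `dG0 = +440 kJ mol-1`.
#'
#' @param n moles of electrons transferred (> 0).
#' @param E0 standard potential, V.
#' @param dG Gibbs energy, kJ mol-1.
#' @param const a [thermo_constants()] set.
#' @return `gibbs_from_potential`: dG in kJ mol-1; `potential_from_gibbs`: E0 in V.
#' @export
#' @examples
#' gibbs_from_potential(3, -1.52)   # +440.0
#' potential_from_gibbs(-455.62, 3) # 1.57
gibbs_from_potential <- function(n, E0, const = thermo_constants()) {
  stopifnot(n > 0)
  -n * const$F_kj * E0
}

#' @rdname gibbs_from_potential
#' @export
potential_from_gibbs <- function(dG, n, const = thermo_constants()) {
  if (!isTRUE(n > 0)) stop("n must be a positive electron count")
  -dG / (n * const$F_kj)
}

#' pH-Eh boundary line of a redox half reaction
#'
#' For a half reaction with `h` protons and `n` electrons on the reactant side
#' (e.g. `O2- + 4 H+ + 3 e- = 2 H2O`), mass action gives
#' `logK = h * pH + n * pe`, and with `pe = F/(2.303 R T) * Eh` the boundary is
#' the straight line `h * pH + (n * F / (2.303 R T)) * Eh = logK`. For n = 3 at
#' 298 K the Eh coefficient evaluates to 50.7 V-1.
#'
#' @param logK equilibrium constant of the half reaction (log10).
#' @param n_electrons electrons transferred (> 0).
#' @param h proton stoichiometric coefficient (reactant side positive).
#' @param const a [thermo_constants()] set.
#' @return object of class `boundary_line`: list with `ph_coeff`, `eh_coeff`
#'   (V-1), `rhs` (= logK) and a function `eh_at_ph(pH)` solving for Eh.
#' @export
#' @examples
#' b <- nernst_boundary(79.84, n_electrons = 3, h = 4)
#' b$eh_at_ph(c(0, 14)) # 1.57, 0.47
nernst_boundary <- function(logK, n_electrons, h, const = thermo_constants()) {
  if (!isTRUE(n_electrons > 0))
    stop("not a redox boundary: n_electrons must be > 0")
  eh_coeff <- n_electrons * const$F_kj / const$lnK_factor
  structure(
    list(ph_coeff = h, eh_coeff = eh_coeff, rhs = logK,
         eh_at_ph = function(pH) (logK - h * pH) / eh_coeff),
    class = "boundary_line"
  )
}

#' @export
print.boundary_line <- function(x, ...) {
  cat(sprintf("%.2f = %g pH + %.1f Eh  (Eh at pH 0: %.2f V; at pH 14: %.2f V)\n",
              x$rhs, x$ph_coeff, x$eh_coeff, x$eh_at_ph(0), x$eh_at_ph(14)))
  invisible(x)
}

#' The gold / superoxide thermodynamic derivation chain
#'
#' Runs the full derivation from a handful of tabulated inputs to every
#' reaction constant used in the pH-Eh modelling of superoxide-driven gold
#' oxidation: reaction enthalpy and entropy of the superoxide oxidation of
#' gold to Au3+ give its Gibbs energy and logK; combination with the
#' Au(OH)4- complexation and water dissociation reactions gives the logK of
#' the overall superoxide and dissolved-oxygen oxidation reactions; the
#' half-reaction split against the Au/Au3+ couple gives the superoxide/water
#' couple's Gibbs energy, logK, standard potential, and its pH-Eh boundary
#' line with endpoints at pH 0 and pH 14.
#'
#' @param dH_rxn3,dS_rxn3 enthalpy (kJ mol-1) and entropy (J mol-1 K-1) of
#'   `Au(s) + O2- + 4 H+ = Au3+ + 2 H2O`.
#' @param logK4 logK of `Au3+ + 4 OH- = Au(OH)4-`.
#' @param logK5 logK of water dissociation.
#' @param logK6 logK of `Au(s) + 0.75 O2(aq) + 3 H+ = Au3+ + 1.5 H2O`.
#' @param E0_au standard potential of `Au(s) - 3 e- = Au3+` as written
#'   (oxidation direction), V.
#' @param n electrons transferred in the gold couple.
#' @param const a [thermo_constants()] set.
#' @return named list: `dG_rxn3`, `logK_rxn3`, `logK_rxn1`, `logK_rxn2`,
#'   `dG_au_couple`, `dG_o2_couple`, `logK0_o2_couple`, `E0_o2_couple`,
#'   `boundary` (a [nernst_boundary()] line), `eh_ph0`, `eh_ph14`.
#' @export
#' @examples
#' chain <- gold_superoxide_chain()
#' round(chain$logK_rxn1, 2) # -1.91
gold_superoxide_chain <- function(dH_rxn3 = -122.82, dS_rxn3 = -359.74,
                                  logK4 = 51.35, logK5 = -14.00,
                                  logK6 = -11.44, E0_au = -1.52, n = 3,
                                  const = thermo_constants()) {
  dG3 <- delta_g_from_hs(dH_rxn3, dS_rxn3, const)
  logK3 <- logk_from_delta_g(dG3, const)
  # rxn1 = rxn3 + rxn4 + 4 * rxn5 : Au(s) + O2- + 2 H2O = Au(OH)4-
  logK1 <- logK3 + logK4 + 4 * logK5
  # rxn2 = rxn6 + rxn4 + 4 * rxn5 : Au(s) + 0.75 O2(aq) + 2.5 H2O = Au(OH)4- + H+
  logK2 <- logK6 + logK4 + 4 * logK5
  dG_au <- gibbs_from_potential(n, E0_au, const)
  dG_o2 <- dG3 - dG_au
  logK0 <- logk_from_delta_g(dG_o2, const)
  E0_o2 <- potential_from_gibbs(dG_o2, n, const)
  line <- nernst_boundary(logK0, n_electrons = n, h = 4, const = const)
  list(dG_rxn3 = dG3, logK_rxn3 = logK3, logK_rxn1 = logK1, logK_rxn2 = logK2,
       dG_au_couple = dG_au, dG_o2_couple = dG_o2, logK0_o2_couple = logK0,
       E0_o2_couple = E0_o2, boundary = line,
       eh_ph0 = line$eh_at_ph(0), eh_ph14 = line$eh_at_ph(14))
}
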