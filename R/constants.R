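#' Physical constants used throughout the thermodynamic calculations
#'
#' Returns the constant set used by every Gibbs energy / equilibrium constant /
#' electrode potential conversion in the package. The defaults deliberately use
#' the rounded values common in geochemistry textbooks (T = 298 K rather than
#' 298.15, the factor 2.303 rather than ln 10 = 2.302585...), because the
#' printed reaction constants this package reproduces were computed with them.
#' Both are configurable for users who want the unrounded arithmetic.
#'
#' @param R gas constant, J mol-1 K-1.
#' @param F_kj Faraday constant expressed in kJ V-1 per mole of electrons.
#' @param T temperature, K.
#' @param ln10 the decadic conversion factor ("2.303").
#'
#' @return An object of class `thermo_constants`: a named list with fields
#'   `R`, `F_kj`, `T`, `ln10` and the derived `lnK_factor` =
#'   `ln10 * R * T / 1000` (kJ mol-1 per log10 unit).
#' @export
#' @examples
#' tc <- thermo_constants()
#' tc$lnK_factor # ~5.706 kJ per log10 unit at 298 K
thermo_constants <- function(R = 8.314, F_kj = 96.49, T = 298, ln10 = 2.303) {
  stopifnot(is.finite(R), is.finite(F_kj), is.finite(T), T > 0, ln10 > 0)
  structure(
    list(R = R, F_kj = F_kj, T = T, ln10 = ln10,
         lnK_factor = ln10 * R * T / 1000),
    class = "thermo_constants"
  )
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat(sprintf(
    "thermo_constants: R = %g J/mol/K, F = %g kJ/V/eq, T = %g K, ln10 = %g\n",
    x$R, x$F_kj, x$T, x$ln10))
  invisible(x)
}
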