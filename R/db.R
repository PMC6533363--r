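#' Read a species/reaction thermodynamic database
#'
#' The database is plain tab-separated text: one file of species (columns
#' `name`, `formula`, `charge`, `phase`, `dGf`, `dHf`, `S0`, `source`) and one
#' of reactions (columns `id`, `equation`, `logK`, `n_electrons`, `E0`,
#' `source`). Equation strings use the dialect of [parse_equation()] and may
#' carry fractional coefficients (`"0.75 O2(aq)"`). The package ships a
#' default database seeded with the reaction constants of the
#' superoxide-driven gold oxidation model plus standard formation free
#' energies for the carbonate, sulfur and gold species used by the pH-Eh
#' diagrams.
#'
#' @param species_file,reactions_file paths to the TSV files; defaults are the
#'   shipped database under `inst/extdata`.
#' @return object of class `thermo_db`: list with `species` (named list of
#'   [thermo_species()]), `reactions` (named list of [thermo_reaction][reaction]
#'   objects keyed by id), and the raw tables `species_table`,
#'   `reactions_table`.
#' @export
#' @examples
#' db <- read_thermo_db()
#' db$reactions$R3
read_thermo_db <- function(
    species_file = system.file("extdata", "thermo_species.tsv", package = "aurox"),
    reactions_file = system.file("extdata", "thermo_reactions.tsv", package = "aurox")) {
  st <- utils::read.delim(species_file, stringsAsFactors = FALSE,
                          na.strings = "NA", quote = "\"")
  rt <- utils::read.delim(reactions_file, stringsAsFactors = FALSE,
                          na.strings = "NA", quote = "")
  species <- stats::setNames(vector("list", nrow(st)), st$name)
  for (i in seq_len(nrow(st))) {
    species[[i]] <- thermo_species(
      name = st$name[i], formula = st$formula[i], charge = st$charge[i],
      phase = st$phase[i], dGf = st$dGf[i], dHf = st$dHf[i], S0 = st$S0[i])
  }
  reactions <- stats::setNames(vector("list", nrow(rt)), rt$id)
  for (i in seq_len(nrow(rt))) {
    reactions[[i]] <- parse_equation(
      rt$equation[i], logK = rt$logK[i], n_electrons = rt$n_electrons[i],
      label = rt$id[i])
  }
  structure(list(species = species, reactions = reactions,
                 species_table = st, reactions_table = rt),
            class = "thermo_db")
}

#' @export
print.thermo_db <- function(x, ...) {
  cat(sprintf("thermo_db: %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  invisible(x)
}

#' Gibbs energy of formation lookup
#' @param db a `thermo_db`.
#' @param name species name.
#' @return dGf in kJ mol-1; errors if the species is unknown or has no value.
#' @keywords internal
species_dgf <- function(db, name) {
  sp <- db$species[[name]]
  if (is.null(sp)) stop("unknown species: ", name)
  if (is.na(sp$dGf)) stop("no Gibbs energy of formation for species: ", name)
  sp$dGf
}
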