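# Two-stage pH-Eh predominance (Pourbaix) diagrams for gold.
#
# Stage 1 speciates the ligand subsystem (carbonate or sulfur species at a
# fixed total activity); stage 2 speciates gold against the locally
# predominant ligand species. All reactions are balanced automatically from
# species formulas over the basis {H+, e-, H2O, reference species}, and their
# equilibrium constants derive from tabulated Gibbs energies of formation.
# Unit activity is assumed for solids and liquid water; no ionic-strength
# corrections are applied.

#' Convert Eh (V) to the dimensionless pe scale
#' @param Eh redox potential, V.
#' @param const a [thermo_constants()] set; `pe = F/(2.303 R T) * Eh`.
#' @return pe values (16.91 per volt at 298 K with the default constants).
#' @export
eh_to_pe <- function(Eh, const = thermo_constants()) {
  Eh * const$F_kj / const$lnK_factor
}

#' Convert a mass-fraction solubility level to a log10 molal activity
#'
#' Mass fractions are interpreted per kilogram of water (density 1 kg L-1)
#' and converted with the molar mass of gold (196.97 g mol-1):
#' 1 ppb = 1e-6 g kg-1 -> log a = -8.29. A numeric argument is treated as a
#' direct activity override and returned as log10 of it (so `1e-6` -> -6
#' exactly, matching the decade convention of the diagram captions).
#'
#' @param level `"ppt"`, `"ppb"`, `"ppm"`, or a numeric activity.
#' @param molar_mass g mol-1 of the dissolved element (gold by default).
#' @return log10 activity.
#' @export
#' @examples
#' mass_fraction_to_log_activity("ppb") # -8.29
mass_fraction_to_log_activity <- function(level, molar_mass = 196.97) {
  if (is.numeric(level)) return(log10(level))
  frac <- switch(level,
                 ppm = 1e-3, ppb = 1e-6, ppt = 1e-9,
                 stop("unknown solubility level: ", level))
  log10(frac / molar_mass)
}

#' Define a pH-Eh predominance system
#'
#' @param ligand `"carbon"` (bicarbonate-dominated, total activity 0.01) or
#'   `"sulfur"` (thiosulfate/sulfate/sulfide, total activity 0.01).
#' @param au_levels named numeric vector of log10 dissolved-gold activities at
#'   which solubility contours are drawn, ordered ppm -> ppt (strictly
#'   decreasing). Defaults to the decade values -6, -9, -12; use
#'   [mass_fraction_to_log_activity()] for exact mass-fraction conversions.
#' @param ph_range,eh_range diagram extent (pH units; volts).
#' @param ph_step,eh_step grid steps (> 0).
#' @param ligand_activity total activity of the ligand subsystem.
#' @param db a [read_thermo_db()] database supplying formation free energies.
#' @param const a [thermo_constants()] set.
#' @return object of class `pourbaix_system`.
#' @export
pourbaix_system <- function(ligand = c("carbon", "sulfur"),
                            au_levels = c(ppm = -6, ppb = -9, ppt = -12),
                            ph_range = c(0, 14), eh_range = c(-0.8, 1.6),
                            ph_step = 0.05, eh_step = 0.005,
                            ligand_activity = 0.01,
                            db = read_thermo_db(),
                            const = thermo_constants()) {
  ligand <- match.arg(ligand)
  stopifnot(ph_step > 0, eh_step > 0, ligand_activity > 0)
  if (is.null(names(au_levels))) names(au_levels) <- paste0("L", seq_along(au_levels))
  if (any(diff(au_levels) >= 0))
    stop("au_levels must be strictly decreasing when ordered ppm -> ppt")
  sets <- if (ligand == "carbon") {
    list(element = "C", ref = "HCO3-",
         aqueous = c("CH4(aq)", "CO2(aq)", "HCO3-", "CO3-2"),
         solids = "C(s)",
         au_aqueous = c("Au3+", "Au+", "AuOH(aq)", "Au(OH)2-", "Au(OH)4-"))
  } else {
    list(element = "S", ref = "SO4-2",
         aqueous = c("H2S(aq)", "HS-", "S2O3-2", "HSO4-", "SO4-2"),
         solids = "S(s)",
         au_aqueous = c("Au3+", "Au+", "AuOH(aq)", "Au(OH)2-", "Au(OH)4-",
                        "AuHS(aq)", "Au(HS)2-"))
  }
  for (nm in c(sets$aqueous, sets$solids, sets$au_aqueous, "Au(s)", "H2O"))
    species_dgf(db, nm) # fail early, naming the species, if data are missing
  structure(
    c(sets,
      list(ligand = ligand, au_levels = au_levels, ph_range = ph_range,
           eh_range = eh_range, ph_step = ph_step, eh_step = eh_step,
           log_ligand_activity = log10(ligand_activity), db = db,
           const = const)),
    class = "pourbaix_system")
}

# Balance `1 base + nuL ligand + w H2O + h H+ + n e- = species` from formulas
# and return the coefficients plus the reaction logK (from dGf). `base` counts
# the conserved element once per nu_base; ligand supplies `ligand_element`.
dissolution_coeffs <- function(db, species, base, element,
                               ligand = NULL, ligand_element = NULL,
                               const = thermo_constants()) {
  el <- function(sp, e) if (e %in% names(sp$elements)) sp$elements[[e]] else 0
  sp <- db$species[[species]]; bs <- db$species[[base]]
  if (is.null(sp)) stop("unknown species: ", species)
  nu_base <- el(sp, element) / el(bs, element)
  nu_L <- 0; lg <- NULL
  if (!is.null(ligand) && !is.null(ligand_element) &&
      el(sp, ligand_element) > 0 && !identical(ligand, base)) {
    lg <- db$species[[ligand]]
    nu_L <- el(sp, ligand_element) / el(lg, ligand_element)
  }
  O <- el(sp, "O") - nu_base * el(bs, "O") - (if (nu_L) nu_L * el(lg, "O") else 0)
  w <- O
  H <- el(sp, "H") - nu_base * el(bs, "H") - (if (nu_L) nu_L * el(lg, "H") else 0)
  h <- H - 2 * w
  zc <- sp$charge - nu_base * bs$charge - (if (nu_L) nu_L * lg$charge else 0)
  n <- h - zc
  dG <- species_dgf(db, species) - nu_base * species_dgf(db, base) -
    (if (nu_L) nu_L * species_dgf(db, ligand) else 0) -
    w * species_dgf(db, "H2O")
  list(nu_base = nu_base, nu_L = nu_L, w = w, h = h, n = n,
       logK = -dG / const$lnK_factor)
}

# log10 activity of a species at (pH, pe), given log activities of its base
# and ligand sources. Vectorized over pH/pe.
log_activity_from_coeffs <- function(cf, pH, pe, log_a_base, log_a_L = 0) {
  cf$logK + cf$nu_base * log_a_base + cf$nu_L * log_a_L - cf$h * pH - cf$n * pe
}

#' Predominant ligand-subsystem species at given pH-Eh points
#'
#' At fixed total ligand activity, returns the member of the carbon (CH4,
#' C(s), CO2(aq), HCO3-, CO3--) or sulfur (H2S, HS-, S(s), S2O3--, HSO4-,
#' SO4--) set with the highest equilibrium activity. Solids (graphite,
#' elemental sulfur) predominate where they are supersaturated with respect to
#' the best aqueous species at the total activity. Ties break by database
#' order, deterministically.
#'
#' @param system a [pourbaix_system()].
#' @param pH,Eh equal-length numeric vectors.
#' @return character vector of species names.
#' @export
ligand_predominance <- function(system, pH, Eh) {
  pe <- eh_to_pe(Eh, system$const)
  pick_predominant(system, pH, pe,
                   aqueous = system$aqueous, solids = system$solids,
                   ref = system$ref, element = system$element,
                   log_total = system$log_ligand_activity)
}

pick_predominant <- function(system, pH, pe, aqueous, solids, ref, element,
                             log_total, tol = 1e-9) {
  db <- system$db; const <- system$const
  cfa <- lapply(aqueous, dissolution_coeffs, db = db, base = ref,
                element = element, const = const)
  cfs <- lapply(solids, dissolution_coeffs, db = db, base = ref,
                element = element, const = const)
  npts <- length(pH)
  if (length(aqueous) == 1L && !length(solids))
    return(rep(aqueous, npts))
  best_viol <- rep(Inf, npts)
  best_idx <- rep(1L, npts)
  solid_idx <- rep(0L, npts)
  for (p in seq_along(aqueous)) {
    la_ref <- (log_total - cfa[[p]]$logK + cfa[[p]]$h * pH + cfa[[p]]$n * pe) /
      cfa[[p]]$nu_base
    viol <- rep(-Inf, npts)
    for (q in seq_along(aqueous)) {
      if (q == p) next
      la_q <- log_activity_from_coeffs(cfa[[q]], pH, pe, la_ref)
      viol <- pmax(viol, la_q - log_total)
    }
    take <- viol < best_viol - tol
    if (any(take)) {
      best_viol[take] <- viol[take]
      best_idx[take] <- p
      # supersaturation of solids under this candidate's reference activity
      si_best <- rep(-Inf, npts)
      si_which <- rep(0L, npts)
      for (s in seq_along(solids)) {
        si <- log_activity_from_coeffs(cfs[[s]], pH, pe, la_ref)
        upd <- si > si_best
        si_best[upd] <- si[upd]
        si_which[upd] <- s
      }
      solid_idx[take] <- ifelse(si_best[take] > tol, si_which[take], 0L)
    }
  }
  out <- aqueous[best_idx]
  sol <- solid_idx > 0L
  out[sol] <- solids[solid_idx[sol]]
  out
}

#' Predominant gold species at given pH-Eh points
#'
#' Dissolved gold species activities are computed in equilibrium with metallic
#' gold at unit activity; ligand-bearing complexes are balanced against the
#' locally predominant ligand species at the subsystem's total activity (unit
#' activity if that species is a solid). Metallic gold `Au(s)` is returned
#' where no dissolved species reaches the activity `10^log_a_au`; otherwise
#' the dissolved species of highest activity wins (database order on ties).
#'
#' @param system a [pourbaix_system()].
#' @param pH,Eh equal-length numeric vectors.
#' @param log_a_au log10 dissolved-gold activity threshold.
#' @param ligand_label optional precomputed [ligand_predominance()] labels.
#' @return character vector of species names.
#' @export
au_predominance <- function(system, pH, Eh, log_a_au, ligand_label = NULL) {
  pe <- eh_to_pe(Eh, system$const)
  if (is.null(ligand_label)) ligand_label <- ligand_predominance(system, pH, Eh)
  la <- au_log_activities(system, pH, pe, ligand_label)
  best <- max.col(t(la), ties.method = "first") # species x pts -> per-point argmax
  maxla <- la[cbind(best, seq_along(pH))]
  out <- system$au_aqueous[best]
  out[maxla < log_a_au] <- "Au(s)"
  out
}

# matrix (species x points) of log activities of dissolved gold species
au_log_activities <- function(system, pH, pe, ligand_label) {
  db <- system$db; const <- system$const
  npts <- length(pH)
  la <- matrix(-Inf, nrow = length(system$au_aqueous), ncol = npts)
  for (lab in unique(ligand_label)) {
    idx <- which(ligand_label == lab)
    lsp <- db$species[[lab]]
    log_a_L <- if (lsp$phase %in% c("solid", "liquid")) 0 else
      system$log_ligand_activity
    for (i in seq_along(system$au_aqueous)) {
      cf <- dissolution_coeffs(db, system$au_aqueous[i], base = "Au(s)",
                               element = "Au", ligand = lab,
                               ligand_element = system$element, const = const)
      la[i, idx] <- log_activity_from_coeffs(cf, pH[idx], pe[idx], 0, log_a_L)
    }
  }
  la
}

#' Build a full two-stage predominance field
#'
#' Evaluates ligand and gold predominance over the system grid, one gold label
#' set per solubility level, and attaches the water-stability window and the
#' superoxide/water boundary line as overlays. Deterministic for a fixed
#' database and grid.
#'
#' @param system a [pourbaix_system()].
#' @return object of class `predominance_field`: list with `ph`, `eh` (grid
#'   axes), `ligand_labels` (pH x Eh character matrix), `au_labels` (named
#'   list of matrices, one per activity level), `overlays` (named list of
#'   `data.frame(ph, eh)` polylines) and the `system`.
#' @export
build_diagram <- function(system) {
  ph <- seq(system$ph_range[1], system$ph_range[2], by = system$ph_step)
  eh <- seq(system$eh_range[1], system$eh_range[2], by = system$eh_step)
  grid_ph <- rep(ph, times = length(eh))
  grid_eh <- rep(eh, each = length(ph))
  lig <- ligand_predominance(system, grid_ph, grid_eh)
  au <- lapply(system$au_levels, function(lv)
    matrix(au_predominance(system, grid_ph, grid_eh, lv, ligand_label = lig),
           nrow = length(ph)))
  chain <- gold_superoxide_chain(const = system$const)
  e_o2 <- 237.13 * 2 / (2 * 2 * system$const$F_kj) # O2 + 4H+ + 4e- = 2H2O
  slope <- system$const$lnK_factor / system$const$F_kj
  overlays <- list(
    superoxide_water = data.frame(ph = range(ph),
                                  eh = chain$boundary$eh_at_ph(range(ph))),
    o2_window = data.frame(ph = range(ph), eh = e_o2 - slope * range(ph)),
    h2_window = data.frame(ph = range(ph), eh = -slope * range(ph))
  )
  structure(list(ph = ph, eh = eh,
                 ligand_labels = matrix(lig, nrow = length(ph)),
                 au_labels = au, overlays = overlays, system = system),
            class = "predominance_field")
}

#' @export
print.predominance_field <- function(x, ...) {
  cat(sprintf(
    "predominance_field (%s system): %d x %d grid, levels %s\n",
    x$system$ligand, length(x$ph), length(x$eh),
    paste(names(x$system$au_levels), collapse = "/")))
  cat("ligand fields:", paste(unique(as.vector(x$ligand_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Extract boundary segments between unequal neighboring labels
#'
#' Scans the label grid for horizontally and vertically adjacent cells with
#' different labels and returns the shared cell edges as line segments.
#'
#' @param field a [build_diagram()] result.
#' @param stage `"ligand"` or the name of an activity level (e.g. `"ppb"`).
#' @return data.frame with columns `ph0`, `eh0`, `ph1`, `eh1`, `label_a`,
#'   `label_b` (one row per cell edge on the boundary).
#' @export
field_boundaries <- function(field, stage = "ligand") {
  labs <- if (stage == "ligand") field$ligand_labels else field$au_labels[[stage]]
  if (is.null(labs)) stop("unknown stage: ", stage)
  ph <- field$ph; eh <- field$eh
  hs <- field$system$ph_step / 2; vs <- field$system$eh_step / 2
  out <- list()
  # vertical boundaries: differing neighbors along pH
  d <- labs[-1, , drop = FALSE] != labs[-nrow(labs), , drop = FALSE]
  ij <- which(d, arr.ind = TRUE)
  if (nrow(ij)) {
    mid <- (ph[ij[, 1]] + ph[ij[, 1] + 1]) / 2
    ij2 <- ij; ij2[, 1] <- ij2[, 1] + 1L
    out[[1]] <- data.frame(ph0 = mid, eh0 = eh[ij[, 2]] - vs,
                           ph1 = mid, eh1 = eh[ij[, 2]] + vs,
                           label_a = labs[ij], label_b = labs[ij2])
  }
  # horizontal boundaries: differing neighbors along Eh
  d <- labs[, -1, drop = FALSE] != labs[, -ncol(labs), drop = FALSE]
  ij <- which(d, arr.ind = TRUE)
  if (nrow(ij)) {
    mid <- (eh[ij[, 2]] + eh[ij[, 2] + 1]) / 2
    ij2 <- ij; ij2[, 2] <- ij2[, 2] + 1L
    out[[2]] <- data.frame(ph0 = ph[ij[, 1]] - hs, eh0 = mid,
                           ph1 = ph[ij[, 1]] + hs, eh1 = mid,
                           label_a = labs[ij], label_b = labs[ij2])
  }
  if (!length(out)) return(data.frame(ph0 = numeric(0), eh0 = numeric(0),
                                      ph1 = numeric(0), eh1 = numeric(0),
                                      label_a = character(0),
                                      label_b = character(0)))
  do.call(rbind, out)
}

#' Export a predominance field as tabular text
#'
#' Writes `<prefix>_grid.tsv` (one row per grid cell: pH, Eh, ligand label and
#' one gold label column per activity level) and `<prefix>_boundaries.tsv`
#' (boundary segments for the ligand stage and every gold level).
#'
#' @param field a [build_diagram()] result.
#' @param prefix output path prefix.
#' @param header optional provenance comment lines (prefixed with `#`).
#' @return invisibly, the two file paths.
#' @export
export_diagram <- function(field, prefix, header = character(0)) {
  grid <- data.frame(ph = rep(field$ph, times = length(field$eh)),
                     eh = rep(field$eh, each = length(field$ph)),
                     ligand = as.vector(field$ligand_labels))
  for (nm in names(field$au_labels))
    grid[[paste0("au_", nm)]] <- as.vector(field$au_labels[[nm]])
  bounds <- do.call(rbind, lapply(
    c("ligand", names(field$au_labels)),
    function(st) cbind(stage = st, field_boundaries(field, st))))
  paths <- paste0(prefix, c("_grid.tsv", "_boundaries.tsv"))
  write_tsv_with_header(grid, paths[1], header)
  write_tsv_with_header(bounds, paths[2], header)
  invisible(paths)
}

write_tsv_with_header <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read back an exported predominance grid
#' @param path a `*_grid.tsv` written by [export_diagram()].
#' @return data.frame of the grid table (comment lines skipped).
#' @export
read_diagram_grid <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @export
plot.predominance_field <- function(x, level = names(x$au_labels)[1], ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting predominance fields")
  grid <- data.frame(ph = rep(x$ph, times = length(x$eh)),
                     eh = rep(x$eh, each = length(x$ph)),
                     species = as.vector(x$au_labels[[level]]))
  ov <- do.call(rbind, lapply(names(x$overlays), function(nm)
    cbind(line = nm, x$overlays[[nm]])))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$ph, y = .data$eh)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$species)) +
    ggplot2::geom_line(data = ov,
                       ggplot2::aes(group = .data$line, linetype = .data$line)) +
    ggplot2::labs(x = "pH", y = "Eh (V)",
                  title = sprintf("Au predominance, %s system (%s)",
                                  x$system$ligand, level))
}
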