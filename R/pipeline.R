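# End-to-end driver: simulate -> analyze -> report for the thermodynamic,
# predominance-diagram, kinetics and ecology tracks. All randomness funnels
# through one seed; every output file carries a provenance header.

#' Run the analysis pipeline
#'
#' Executes one or all analysis tracks and writes a machine-readable results
#' file (`results.json`), a human-readable `summary.txt`, and per-track
#' tables into the output directory. Tracks operate on synthetic data
#' generated from the configured scenarios unless input files are supplied.
#'
#' @param config either a path to a YAML configuration file or a list.
#'   Recognized fields: `track` (`"thermo"`, `"pourbaix"`, `"kinetics"`,
#'   `"ecology"` or `"all"`), `seed` (integer), `outdir`, and optional
#'   per-track overrides: `kinetics$series_file` (tidy TSV with columns
#'   condition, replicate, time_h, au3_uM or absorbance, ph),
#'   `kinetics$curve_file` (TSV conc_uM/absorbance), `kinetics$windows`,
#'   `ecology$counts_file`/`meta_file`/`taxonomy_file`, `ecology$threshold`,
#'   `ecology$min_prevalence`, `pourbaix$ph_step`/`eh_step`.
#' @return invisibly, the results list (also written as JSON).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("missing input file: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(track = "all", seed = 1L, outdir = "aurox_results",
         kinetics = list(), ecology = list(), pourbaix = list()),
    config)
  tracks <- if (identical(cfg$track, "all"))
    c("thermo", "pourbaix", "kinetics", "ecology") else cfg$track
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  header <- provenance_header(cfg)
  results <- list(seed = cfg$seed)
  for (tr in tracks) {
    results[[tr]] <- tryCatch(
      switch(tr,
             thermo = track_thermo(cfg, header),
             pourbaix = track_pourbaix(cfg, header),
             kinetics = track_kinetics(cfg, header),
             ecology = track_ecology(cfg, header),
             stop("unknown track: ", tr)),
      error = function(e) stop("stage '", tr, "' failed: ", conditionMessage(e),
                               call. = FALSE))
  }
  jsonlite::write_json(results, file.path(cfg$outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(paste0("# ", header), format_summary(results)),
             file.path(cfg$outdir, "summary.txt"))
  invisible(results)
}

provenance_header <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- cfg[setdiff(names(cfg), "outdir")] # hash the analysis config only
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  c(sprintf("aurox %s", as.character(utils::packageVersion("aurox"))),
    sprintf("seed=%d", as.integer(cfg$seed)),
    sprintf("config_md5=%s", unname(tools::md5sum(tmp))))
}

track_thermo <- function(cfg, header) {
  chain <- gold_superoxide_chain()
  tab <- data.frame(
    quantity = c("dG_rxn3_kJ", "logK_rxn3", "logK_rxn1", "logK_rxn2",
                 "dG_au_couple_kJ", "dG_o2_couple_kJ", "logK0_o2_couple",
                 "E0_o2_couple_V", "eh_ph0_V", "eh_ph14_V"),
    value = c(chain$dG_rxn3, chain$logK_rxn3, chain$logK_rxn1, chain$logK_rxn2,
              chain$dG_au_couple, chain$dG_o2_couple, chain$logK0_o2_couple,
              chain$E0_o2_couple, chain$eh_ph0, chain$eh_ph14))
  write_tsv_with_header(tab, file.path(cfg$outdir, "thermo_chain.tsv"), header)
  db <- read_thermo_db()
  balance_ok <- vapply(db$reactions,
                       function(r) check_balance(r, db$species)$ok, logical(1))
  c(as.list(stats::setNames(tab$value, tab$quantity)),
    list(all_reactions_balanced = all(balance_ok)))
}

track_pourbaix <- function(cfg, header) {
  out <- list()
  for (lig in c("carbon", "sulfur")) {
    sys <- pourbaix_system(
      lig,
      ph_step = cfg$pourbaix$ph_step %||% 0.05,
      eh_step = cfg$pourbaix$eh_step %||% 0.005)
    field <- build_diagram(sys)
    export_diagram(field, file.path(cfg$outdir, paste0("pourbaix_", lig)),
                   header)
    out[[lig]] <- list(
      ligand_fields = sort(unique(as.vector(field$ligand_labels))),
      au_fields = lapply(field$au_labels,
                         function(m) sort(unique(as.vector(m)))))
  }
  out
}

track_kinetics <- function(cfg, header) {
  kc <- cfg$kinetics
  curve_tab <- if (!is.null(kc$curve_file)) {
    if (!file.exists(kc$curve_file)) stop("missing input file: ", kc$curve_file)
    utils::read.delim(kc$curve_file, comment.char = "#")
  } else gen_standard_curve(seed = cfg$seed)
  curve <- fit_standard_curve(curve_tab$conc_uM, curve_tab$absorbance)
  series <- if (!is.null(kc$series_file)) {
    if (!file.exists(kc$series_file)) stop("missing input file: ", kc$series_file)
    read_microcosm_tsv(kc$series_file, curve)
  } else gen_microcosm(microcosm_scenario_anomaly(), seed = cfg$seed)
  w1 <- kc$window1 %||% c(0, 45)
  w2 <- kc$window2 %||% c(191, 453)
  wc <- kc$correlation_window %||% c(45, 191)
  f1 <- fit_phase_rate(series, w1)
  f2 <- fit_phase_rate(series, w2)
  corr <- correlate_au3_ph(series, wc, tails = kc$tails %||% 2)
  pox <- percent_oxidized(series)
  write_tsv_with_header(as.data.frame(series),
                        file.path(cfg$outdir, "kinetics_series.tsv"), header)
  list(curve_slope = curve$slope, curve_intercept = curve$intercept,
       curve_r2 = curve$r2,
       rate_phase1_uM_h = f1$rate, rate_phase2_uM_h = f2$rate,
       au3_ph_r = corr$r, au3_ph_p = corr$p,
       t_max_h = pox$t_max, percent_oxidized = pox$percent)
}

track_ecology <- function(cfg, header) {
  ec <- cfg$ecology
  tab <- if (!is.null(ec$counts_file)) {
    read_otu_tsv(ec$counts_file, ec$meta_file, ec$taxonomy_file)
  } else gen_otu_table(community_scenario(), seed = cfg$seed)
  div <- diversity_table(tab)
  write_tsv_with_header(div, file.path(cfg$outdir, "ecology_diversity.tsv"),
                        header)
  anom <- tab$site_meta$area == "anomaly"
  hs <- classify_hotspots(tab$site_meta$au[anom])
  cor_anom <- diversity_gold_correlation(tab, anom)
  cor_ref <- diversity_gold_correlation(tab, !anom)
  nets <- lapply(c(anomaly = "anomaly", reference = "reference"), function(ar) {
    sel <- tab$site_meta$area == ar
    net <- build_network(tab, min_prevalence = ec$min_prevalence %||% 7,
                         threshold = ec$threshold %||% 0.8, sites = sel)
    export_network(net, file.path(cfg$outdir, paste0("network_", ar)), header)
    mods <- if (nrow(net$edges)) greedy_modules(net) else
      list(n_modules = 0L, Q = NA_real_)
    cent <- stress_centrality(net)
    list(n_nodes = length(net$nodes), n_edges = nrow(net$edges),
         n_modules = mods$n_modules, modularity_Q = mods$Q,
         top_stress_node = names(cent)[which.max(cent)],
         top_stress = max(cent))
  })
  list(hotspot_threshold = hs$threshold, n_hotspots = sum(hs$hotspot),
       anomaly_r = cor_anom$r, anomaly_p = cor_anom$p,
       anomaly_significant = cor_anom$significant,
       reference_r = cor_ref$r, reference_p = cor_ref$p,
       reference_significant = cor_ref$significant,
       network = nets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_summary <- function(res) {
  unlist(lapply(names(res), function(nm) {
    v <- res[[nm]]
    if (!is.list(v)) return(sprintf("%s: %s", nm, format(v)))
    c(paste0("[", nm, "]"),
      vapply(names(v), function(k) {
        val <- v[[k]]
        sprintf("  %s = %s", k,
                if (is.list(val)) jsonlite::toJSON(val, auto_unbox = TRUE)
                else paste(format(val, digits = 6), collapse = ", "))
      }, character(1)))
  }))
}

#' Read a tidy microcosm TSV (condition, replicate, time_h, au3_uM or
#' absorbance, ph) and summarize replicates into a series
#' @param path TSV path (comment lines `#` allowed).
#' @param curve optional [fit_standard_curve()] used to invert an
#'   `absorbance` column when `au3_uM` is absent.
#' @return a [microcosm_series()] of replicate means.
#' @export
read_microcosm_tsv <- function(path, curve = NULL) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.delim(path, comment.char = "#")
  if (is.null(df$au3_uM)) {
    if (is.null(curve) || is.null(df$absorbance))
      stop("series file needs au3_uM, or absorbance plus a standard curve")
    df$au3_uM <- as.numeric(absorbance_to_au3(curve, df$absorbance))
  }
  agg <- stats::aggregate(cbind(au3_uM, ph) ~ time_h, data = df, FUN = mean)
  sds <- stats::aggregate(au3_uM ~ time_h, data = df, FUN = stats::sd)
  total <- if (!is.null(df$total_au)) df$total_au[1] else 40
  microcosm_series(agg$time_h, agg$au3_uM, ph = agg$ph, au3_sd = sds$au3_uM,
                   condition = as.character(df$condition[1]),
                   replicates = max(as.integer(df$replicate)),
                   total_au = total)
}

#' Read a site x OTU TSV plus metadata/taxonomy TSVs
#'
#' Accepts a plain table (first column = site id) or a Mothur shared-style
#' header (`label`, `Group`, `numOtus`, then OTU columns).
#'
#' @param counts_file sites x OTUs TSV.
#' @param meta_file site metadata TSV (`site`, `area`, `au`, ...).
#' @param taxonomy_file optional taxonomy TSV (`otu`, `phylum`, `order`).
#' @return an [otu_table()].
#' @export
read_otu_tsv <- function(counts_file, meta_file, taxonomy_file = NULL) {
  for (f in c(counts_file, meta_file))
    if (!file.exists(f)) stop("missing input file: ", f)
  ct <- utils::read.delim(counts_file, comment.char = "#", check.names = FALSE)
  if (all(c("label", "Group", "numOtus") %in% names(ct))) {
    rownames(ct) <- ct$Group
    ct <- ct[, setdiff(names(ct), c("label", "Group", "numOtus")), drop = FALSE]
  } else {
    rownames(ct) <- ct[[1]]
    ct <- ct[, -1, drop = FALSE]
  }
  meta <- utils::read.delim(meta_file, comment.char = "#")
  tax <- if (!is.null(taxonomy_file))
    utils::read.delim(taxonomy_file, comment.char = "#") else NULL
  otu_table(as.matrix(ct), meta, tax)
}
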