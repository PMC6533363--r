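# Seeded generators producing microcosm series, calibration tables, site x OTU
# tables and toy graphs with the statistical structure the analyses assume.
# All generators are pure functions of (scenario, seed): the same seed yields
# an identical table. Each returns its inputs in a `truth` attribute so tests
# can measure parameter recovery.

#' Default gold-anomaly fungal microcosm scenario
#'
#' Piecewise-linear Au(III) trajectory emulating a fungal microcosm built from
#' gold-anomaly soil spiked with 40 uM metallic gold: a fast first oxidation
#' phase (0-45 h at 0.19 uM h-1), a rise to the 13.44 uM maximum (33.6% of the
#' pool) at 119 h, partial Au(III) depletion to 9 uM by 191 h, a slow second
#' phase (191-453 h at 0.01 uM h-1), and a decline to the 5.68 uM
#' reference-microcosm plateau by 693 h. pH co-varies linearly with Au(III)
#' inside the 45-191 h rate-change window.
#'
#' @param noise_sd replicate noise on Au(III), uM.
#' @return a scenario list for [gen_microcosm()].
#' @export
microcosm_scenario_anomaly <- function(noise_sd = 0.3) {
  list(
    condition = "gold-anomaly fungal",
    sampling_times = c(0, 17, 45, 119, 191, 310, 453, 693),
    phase_windows = list(c(0, 45, 0.19), c(45, 119, 0.0661),
                         c(119, 191, -0.0617), c(191, 453, 0.01),
                         c(453, 693, -0.02475)),
    start_au3 = 0, noise_sd = noise_sd, replicates = 3, total_au = 40,
    ph_base = 6.2, ph_window = c(45, 191), ph_coupling = 0.12,
    ph_noise_sd = 0.02)
}

#' Reference-area fungal microcosm scenario
#'
#' Slow oxidation (0.07 uM h-1 over 0-45 h) rising to a stable plateau near
#' 5.68 uM, with pH independent of Au(III).
#'
#' @inheritParams microcosm_scenario_anomaly
#' @return a scenario list for [gen_microcosm()].
#' @export
microcosm_scenario_reference <- function(noise_sd = 0.3) {
  list(
    condition = "reference fungal",
    sampling_times = c(0, 17, 45, 119, 191, 310, 453, 693),
    phase_windows = list(c(0, 45, 0.07), c(45, 119, 0.0342)),
    start_au3 = 0, noise_sd = noise_sd, replicates = 3, total_au = 40,
    ph_base = 6.0, ph_window = NULL, ph_coupling = 0, ph_noise_sd = 0.02)
}

# noiseless trajectory: linear inside windows, held flat between/after them
piecewise_au3 <- function(scenario, times) {
  level <- function(t) {
    v <- scenario$start_au3
    for (w in scenario$phase_windows) {
      if (t <= w[1]) break
      v <- v + w[3] * (min(t, w[2]) - w[1])
    }
    v
  }
  vapply(times, level, numeric(1))
}

#' Generate a replicate microcosm time series
#'
#' Au(III) follows the scenario's piecewise-linear windows (held constant
#' between windows), plus independent Gaussian replicate noise clipped at
#' zero; pH co-varies linearly with the noiseless Au(III) trajectory inside
#' the scenario's coupling window and stays at its baseline outside it.
#'
#' @param scenario a scenario list (see [microcosm_scenario_anomaly()]);
#'   windows must be ordered and non-overlapping and `noise_sd >= 0`.
#' @param seed integer seed.
#' @return a [microcosm_series()] of replicate means (with `au3_sd`), plus
#'   attributes `replicate_table` (tidy per-replicate data.frame) and `truth`
#'   (the scenario and seed).
#' @export
gen_microcosm <- function(scenario, seed = 1) {
  ws <- do.call(rbind, scenario$phase_windows)
  stopifnot(all(ws[, 1] < ws[, 2]), scenario$noise_sd >= 0,
            !is.unsorted(ws[, 1]))
  if (nrow(ws) > 1 && any(ws[-1, 1] < ws[-nrow(ws), 2] - 1e-9))
    stop("phase windows overlap")
  times <- scenario$sampling_times
  mu <- piecewise_au3(scenario, times)
  withr_seed(seed, {
    reps <- lapply(seq_len(scenario$replicates), function(r)
      pmax(mu + stats::rnorm(length(times), 0, scenario$noise_sd), 0))
    ph_mu <- rep(scenario$ph_base, length(times))
    if (!is.null(scenario$ph_window)) {
      inw <- times >= scenario$ph_window[1] & times <= scenario$ph_window[2]
      ph_mu[inw] <- scenario$ph_base +
        scenario$ph_coupling * (mu[inw] - mu[which(inw)[1]])
    }
    ph <- ph_mu + stats::rnorm(length(times), 0, scenario$ph_noise_sd)
  })
  repmat <- do.call(cbind, reps)
  series <- microcosm_series(
    times = times, au3 = rowMeans(repmat), ph = ph,
    au3_sd = apply(repmat, 1, stats::sd),
    condition = scenario$condition, replicates = scenario$replicates,
    total_au = scenario$total_au)
  attr(series, "replicate_table") <- data.frame(
    condition = scenario$condition,
    replicate = rep(seq_len(scenario$replicates), each = length(times)),
    time_h = rep(times, scenario$replicates),
    au3_uM = as.vector(repmat),
    ph = rep(ph, scenario$replicates))
  attr(series, "truth") <- c(scenario, list(seed = seed, au3_noiseless = mu))
  series
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a colorimetric calibration table
#'
#' @param slope,intercept true line (AU uM-1, AU).
#' @param noise_sd Gaussian absorbance noise, AU (>= 0).
#' @param concs standard concentrations, uM.
#' @param seed integer seed.
#' @return data.frame `conc_uM`, `absorbance` with a `truth` attribute.
#' @export
gen_standard_curve <- function(slope = 0.02, intercept = 0.01, noise_sd = 0,
                               concs = c(2, 3, 10, 20, 30), seed = 1) {
  stopifnot(noise_sd >= 0)
  withr_seed(seed, {
    a <- slope * concs + intercept + stats::rnorm(length(concs), 0, noise_sd)
  })
  structure(data.frame(conc_uM = concs, absorbance = a),
            truth = list(slope = slope, intercept = intercept,
                         noise_sd = noise_sd, seed = seed))
}

#' Default two-area community scenario
#'
#' Emulates the 19-site two-area field design: 10 anomaly sites whose gold
#' concentrations are lognormal with median 3.54 ng g-1 and a heavy hotspot
#' tail, 9 reference sites with lower, narrower gold levels; site diversity is
#' coupled to gold in the anomaly area only.
#'
#' @param coupling_anomaly,coupling_reference target Pearson correlation
#'   between the latent site diversity and gold in each area (in [-1, 1]).
#' @param n_anomaly,n_reference sites per area.
#' @param n_otus number of OTUs.
#' @param reads sequencing depth per site.
#' @param dispersion Dirichlet overdispersion of the compositions (larger =
#'   less compositional noise).
#' @return a scenario list for [gen_otu_table()].
#' @export
community_scenario <- function(coupling_anomaly = 0.9, coupling_reference = 0,
                               n_anomaly = 10, n_reference = 9, n_otus = 40,
                               reads = 5000, dispersion = 500) {
  stopifnot(abs(coupling_anomaly) <= 1, abs(coupling_reference) <= 1,
            n_anomaly > 0, n_reference > 0, n_otus > 1)
  list(coupling_anomaly = coupling_anomaly,
       coupling_reference = coupling_reference,
       n_anomaly = n_anomaly, n_reference = n_reference, n_otus = n_otus,
       reads = reads, dispersion = dispersion,
       au_meanlog_anomaly = log(3.54), au_sdlog_anomaly = 1.1,
       au_meanlog_reference = log(1.5), au_sdlog_reference = 0.5,
       div_base = 4, div_slope = 0.45, div_noise_frac = 1)
}

# geometric-series composition whose inverse Simpson index equals `target`
geometric_composition <- function(target, n_otus) {
  if (target >= n_otus) stop("infeasible diversity target (>= number of OTUs)")
  if (target <= 1) return(c(1, rep(0, n_otus - 1)))
  f <- function(theta) {
    p <- theta^(seq_len(n_otus) - 1)
    p <- p / sum(p)
    1 / sum(p^2) - target
  }
  theta <- stats::uniroot(f, c(1e-8, 1 - 1e-10), tol = 1e-12)$root
  p <- theta^(seq_len(n_otus) - 1)
  p / sum(p)
}

#' Generate a two-area site x OTU table with per-site geochemistry
#'
#' Gold concentrations are lognormal per area (the anomaly scaled to the
#' design median of 3.54 ng g-1 with a heavy hotspot tail). In the coupled
#' area each site's target inverse Simpson diversity increases linearly with
#' gold, attenuated by Gaussian noise so the latent diversity-gold Pearson
#' correlation equals the scenario coupling; in the uncoupled area the target
#' diversity is drawn independently. Site compositions are geometric-series
#' abundance profiles tuned to the target diversity, perturbed with Dirichlet
#' (gamma-normalized) dispersion and sampled as multinomial counts. A
#' high-prevalence "Hypocreales-like" order is seeded among the most abundant
#' OTUs; remaining OTUs receive arbitrary order/phylum labels.
#'
#' @param scenario a [community_scenario()].
#' @param seed integer seed.
#' @return an [otu_table()] with a `truth` attribute recording the scenario,
#'   seed, per-site gold and latent target diversities.
#' @export
gen_otu_table <- function(scenario, seed = 1) {
  s <- scenario
  n <- s$n_anomaly + s$n_reference
  area <- rep(c("anomaly", "reference"), c(s$n_anomaly, s$n_reference))
  withr_seed(seed, {
    au_a <- stats::rlnorm(s$n_anomaly, s$au_meanlog_anomaly, s$au_sdlog_anomaly)
    # rescale so the realized anomaly median sits at the design median
    au_a <- au_a * exp(s$au_meanlog_anomaly) / stats::median(au_a)
    au_r <- stats::rlnorm(s$n_reference, s$au_meanlog_reference,
                          s$au_sdlog_reference)
    au <- c(au_a, au_r)
    latent <- function(gold, coupling) {
      z <- as.vector(scale(gold))
      if (all(!is.finite(z))) z <- rep(0, length(gold))
      eps <- stats::rnorm(length(gold))
      mix <- coupling * z + sqrt(1 - coupling^2) * eps * s$div_noise_frac
      s$div_base + s$div_slope * stats::sd(gold) * mix
    }
    div_a <- latent(au_a, s$coupling_anomaly)
    div_r <- latent(au_r, s$coupling_reference)
    target <- pmin(pmax(c(div_a, div_r), 1.2), s$n_otus * 0.8)
    counts <- t(vapply(target, function(tg) {
      p <- geometric_composition(tg, s$n_otus)
      gam <- stats::rgamma(s$n_otus, shape = p * s$dispersion)
      if (sum(gam) == 0) gam <- p
      stats::rmultinom(1, s$reads, gam / sum(gam))[, 1]
    }, integer(s$n_otus)))
    ph <- stats::rnorm(n, 5.6, 0.3)
  })
  sites <- sprintf("%s%02d", ifelse(area == "anomaly", "GA", "RA"),
                   c(seq_len(s$n_anomaly), seq_len(s$n_reference)))
  rownames(counts) <- sites
  colnames(counts) <- sprintf("OTU%03d", seq_len(s$n_otus))
  orders <- c("Hypocreales", "Pleosporales", "Capnodiales", "Chaetothyriales",
              "Agaricales", "Eurotiales", "Russulales", "Helotiales",
              "Atheliales", "Dothideales")
  phyla <- c(rep("Ascomycota", 4), "Basidiomycota", "Ascomycota",
             "Basidiomycota", "Ascomycota", "Basidiomycota", "Ascomycota")
  idx <- rep(seq_along(orders), length.out = s$n_otus)
  taxonomy <- data.frame(otu = colnames(counts), phylum = phyla[idx],
                         order = orders[idx])
  meta <- data.frame(site = sites, area = area, au = au, ph = ph)
  tab <- otu_table(counts, meta, taxonomy)
  attr(tab, "truth") <- c(s, list(seed = seed, target_diversity = target))
  tab
}

#' Deterministic toy graphs for centrality and modularity oracles
#'
#' @param motif `"path"`, `"star"`, `"clique"`, `"two_cliques"`, or
#'   `"custom"` (supply `edges`).
#' @param n motif size (path length, leaf count, clique size).
#' @param edges data.frame `from`/`to` for `motif = "custom"`.
#' @return a `cooccurrence_network`.
#' @export
#' @examples
#' gen_toy_network("path", n = 3)
gen_toy_network <- function(motif = c("path", "star", "clique", "two_cliques",
                                      "custom"),
                            n = 3, edges = NULL) {
  motif <- match.arg(motif)
  lab <- function(i) letters[i]
  e <- switch(motif,
    path = data.frame(from = lab(seq_len(n - 1)), to = lab(seq_len(n - 1) + 1)),
    star = data.frame(from = "center", to = paste0("leaf", seq_len(n))),
    clique = {
      pr <- utils::combn(n, 2)
      data.frame(from = lab(pr[1, ]), to = lab(pr[2, ]))
    },
    two_cliques = {
      pr <- utils::combn(n, 2)
      rbind(data.frame(from = lab(pr[1, ]), to = lab(pr[2, ])),
            data.frame(from = lab(pr[1, ] + n), to = lab(pr[2, ] + n)))
    },
    custom = {
      if (is.null(edges)) stop("custom motif requires an edge list")
      edges
    })
  network_from_edges(e)
}
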