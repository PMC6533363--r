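---
title: "Methods: modelling superoxide-driven gold oxidation and its microbial context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling superoxide-driven gold oxidation and its microbial context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aurox)
```

aurox models how fungi in auriferous soils can oxidize metallic gold under
Earth-surface conditions, and how that geochemical capability shows up in the
soil microbiome. This vignette documents the model, the numerical choices, the
synthetic-data generators, and the limits of each — i.e. everything a reviewer
would want to know before trusting a number the package prints.

## 1. The thermodynamic core

### Model

All equilibrium arithmetic runs at standard state and 298 K through four
conversions:

* $\Delta_r G = \Delta_r H - T\,\Delta_r S$,
* $\Delta_r G = -2.303\,R\,T\,\log K$,
* $\Delta G^\circ = -n F E^\circ$, with $F = 96.49$ kJ V$^{-1}$ per electron
  equivalent,
* the Nernst boundary of a half reaction with $h$ protons and $n$ electrons:
  $h\,\mathrm{pH} + \tfrac{nF}{2.303RT}\,Eh = \log K$.

Reactions are first-class objects: signed stoichiometric vectors over species
names, with electrons as an explicit pseudo-species. `combine_reactions()`
implements Hess's law ($\log K$ is additive under reaction combination) with
exact cancellation, and `check_balance()` verifies element and charge balance
of every reaction against the species database before it is used.

### Why T = 298 and the literal 2.303

`thermo_constants()` deliberately defaults to the rounded constants common in
the geochemical literature (298 K rather than 298.15, the factor 2.303 rather
than $\ln 10 = 2.302585\ldots$), because the published reaction constants this
package reproduces were computed with them; with the unrounded values the
derived constants drift by more than their printed precision. Both are
configurable.

```{r}
chain <- gold_superoxide_chain()
round(unlist(chain[c("dG_rxn3", "logK_rxn3", "logK_rxn1", "logK_rxn2",
                     "dG_au_couple", "dG_o2_couple", "logK0_o2_couple",
                     "E0_o2_couple", "eh_ph0", "eh_ph14")]), 3)
```

The chain starts from the enthalpy and entropy of
$\mathrm{Au(s)} + \mathrm{O_2^-} + 4\mathrm{H^+} = \mathrm{Au^{3+}} +
2\mathrm{H_2O}$, combines it with the $\mathrm{Au(OH)_4^-}$ complexation and
water-dissociation reactions, splits it against the $\mathrm{Au^0/Au^{3+}}$
couple ($E^\circ = -1.52$ V as an oxidation), and ends with the
superoxide/water couple and its pH–Eh boundary line
$4\,\mathrm{pH} + 50.7\,Eh = \log K^0$.

## 2. pH–Eh predominance diagrams

### Two-stage engine

`build_diagram()` evaluates a rectangular pH–Eh grid in two stages:

1. **Ligand subsystem.** The carbon set
   ($\mathrm{CH_4, C(s), CO_2, HCO_3^-, CO_3^{2-}}$) or sulfur set
   ($\mathrm{H_2S, HS^-, S(s), S_2O_3^{2-}, HSO_4^-, SO_4^{2-}}$) is speciated
   at a fixed total activity (0.01 by default). For each candidate species the
   engine assumes it holds the total activity, computes every other member's
   equilibrium activity, and keeps the candidate whose worst violation of the
   total-activity cap is smallest; graphite or elemental sulfur replace the
   winner where they are supersaturated. This self-consistency scan avoids a
   full speciation solve while agreeing with one wherever a single species
   dominates — exactly the regime a predominance diagram displays.
2. **Gold.** Dissolved gold species
   ($\mathrm{Au^{3+}, Au^+, AuOH, Au(OH)_2^-, Au(OH)_4^-}$, plus
   $\mathrm{AuHS}$ and $\mathrm{Au(HS)_2^-}$ in the sulfur system) are
   computed in equilibrium with metallic gold at unit activity, with
   ligand-bearing complexes balanced against the locally predominant ligand
   species. A cell is labelled `Au(s)` when no dissolved species reaches the
   solubility contour under consideration.

All dissolution reactions are balanced automatically from species formulas
over the basis $\{\mathrm{H^+}, e^-, \mathrm{H_2O}, \text{reference}\}$, and
their $\log K$ values derive from tabulated standard Gibbs energies of
formation (`inst/extdata/thermo_species.tsv`; CODATA/NBS values for the
ligand species, gold species anchored to the reaction constants of the model).
Activity coefficients are taken as unity: these are predominance maps, not
solubility predictions in brines.

### Solubility contours

The default contour levels are the decade activities $10^{-6}$, $10^{-9}$,
$10^{-12}$ (named ppm/ppb/ppt following the convention that labels diagram
contours by the nearest mass fraction). `mass_fraction_to_log_activity()`
performs the exact conversion (1 ppb of Au = $10^{-6}$ g kg$^{-1}$ water
$\rightarrow \log a = -8.29$) for users who want mass-fraction-exact contours.
Because a region immobile at the lowest contour is immobile at every higher
one, the `Au(s)` fields nest — a property the test suite checks on every
build.

```{r}
sys <- pourbaix_system("sulfur", ph_step = 0.5, eh_step = 0.05)
field <- build_diagram(sys)
table(field$au_labels$ppb)
```

The default grid (0.05 pH $\times$ 0.005 V over pH 0–14, Eh $-0.8$ to 1.6 V)
builds in a few seconds; both step sizes are configurable.

## 3. Microcosm kinetics

The kinetics module is ordinary least squares all the way down, matching how
such assays are analyzed in practice:

* `fit_standard_curve()` regresses absorbance (654 nm) on Au(III)
  concentration over standards at 2, 3, 10, 20 and 30 µM;
  `absorbance_to_au3()` inverts the line, clipping inferred concentrations
  below zero (blank-level noise) and reporting how many were clipped.
* `fit_phase_rate()` estimates a linear oxidation rate over a user-chosen time
  window. Windows are an analyst's choice, not an algorithm's: the headline
  anomaly scenario uses 0–45 h for the fast phase and 191–453 h for the slow
  phase. `find_breakpoint()` offers a descriptive two-segment SSE search for
  users who want the change point estimated.
* `correlate_au3_ph()` computes Pearson's r between Au(III) and pH inside a
  window with the exact t transform; with three time points that is one
  degree of freedom, so p-values near 0.07 at $|r| > 0.99$ are expected — the
  test is honest about how little data it sees.
* `percent_oxidized()` reports the Au(III) maximum as a percentage of the
  spiked gold pool and flags apparent values above 100%.

```{r}
s <- gen_microcosm(microcosm_scenario_anomaly(), seed = 1)
fit_phase_rate(s, c(0, 45))
fit_phase_rate(s, c(191, 453))
percent_oxidized(s)$percent
```

## 4. Community ecology

`inverse_simpson()`, `berger_parker()` (dominance form, with a reciprocal
option) and `chao1()` (bias-corrected branch when no doubletons are observed)
are implemented directly — they are two-line estimators whose correctness the
tests pin to hand-computed values and, for inverse Simpson, to vegan.

`classify_hotspots()` applies the field rule that an anomaly site is a gold
hotspot when its concentration is at least 1.5 times the anomaly median; the
rule is scale-equivariant. `diversity_gold_correlation()` tests the
diversity–gold association per area with Pearson's exact t test at
$\alpha = 0.1$, the significance level appropriate to n = 9–10 sites.

Co-occurrence networks (`build_network()`) aggregate counts to taxonomic
order, keep taxa present in at least 7 sites, convert to relative abundances,
and join pairs whose absolute Pearson correlation reaches 0.8. Modules come
from a hand-written greedy agglomerative modularity maximizer with a
deterministic lexicographic tie-break, and `stress_centrality()` counts the
shortest paths through each node via breadth-first path counting — both are
validated in the tests against exhaustive oracles (all partitions, explicit
path enumeration) on small graphs. Greedy modularity is approximate: on a
six-node path it stops at Q = 0.26 although Q = 0.30 is attainable, which is
the expected behaviour of the algorithm, not a defect.

## 5. Synthetic data

Because the raw assay and sequencing data behind the motivating study are not
redistributable, every analysis stage is exercised against seeded generators
whose *parameters are recoverable*:

* `gen_microcosm()` draws replicate Gaussian noise around a piecewise-linear
  Au(III) trajectory (held flat between windows, clipped at zero), with pH
  co-varying linearly with Au(III) inside a designated window. The default
  anomaly scenario rises at 0.19 µM h$^{-1}$, peaks at 33.6% of the 40 µM
  pool at 119 h, and creeps at 0.01 µM h$^{-1}$ in the second phase; the
  reference scenario rises at 0.07 µM h$^{-1}$ to a 5.68 µM plateau.
* `gen_otu_table()` emulates the 19-site two-area field design: anomaly gold
  is lognormal rescaled to a median of 3.54 ng g$^{-1}$ with a heavy hotspot
  tail; latent site diversity is coupled to gold at a target correlation in
  the anomaly area (0.9 by default) and uncoupled in the reference area;
  compositions are geometric series tuned by root-finding to hit each site's
  target inverse Simpson index, perturbed with Dirichlet dispersion and
  sampled as multinomial reads.
* `gen_standard_curve()` and `gen_toy_network()` provide calibration tables
  and the classic graph motifs (path, star, clique, two cliques) used as
  oracle cases.

All generators are pure functions of (scenario, seed) — they save and restore
the caller's RNG state — and attach a `truth` attribute recording their
parameters, so tests measure recovery rather than memorized outputs.

Two statistical honesty notes. First, with 10 sites the null sampling
distribution of a correlation coefficient is wide
($P(|r| < 0.3) \approx 0.64$), so an uncoupled area *cannot* show $|r| < 0.3$
"almost always"; the tests check the null behaviour against its exact
distribution instead. Second, the joint pattern
significant-anomaly/non-significant-reference is bounded by the reference
area's false-positive rate ($1 - \alpha = 0.9$); at the default coupling the
measured recovery over 200 seeds is about 0.94.

## 6. The pipeline

`run_pipeline()` chains simulate → analyze → report for the thermodynamic,
diagram, kinetics and ecology tracks from a single declarative configuration
(a YAML file or list), funnels all randomness through one seed, and stamps
every output file with a provenance header (package version, seed, config
hash). Identical seeds give byte-identical output bundles. A thin command-line
wrapper lives in `inst/cli/aurox.R`.

## Limitations

* Standard state, 298 K, unit activity coefficients; no ionic strength or
  temperature corrections.
* The predominance engine maps the *most abundant* species; it is not a full
  speciation or reactive-transport solver.
* Generators emulate design structure (phases, coupling, hotspot tails), not
  read-level sequencing artefacts or soil geostatistics.
* Greedy modularity does not guarantee the optimal partition, and
  stress/modularity statistics are computed on unweighted, unsigned edges.
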