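# Alpha diversity, gold-hotspot classification, and diversity-gold
# correlation for site x OTU count tables with per-site geochemistry.

#' Inverse Simpson diversity
#'
#' `1 / sum(p_i^2)` over relative abundances; an effective-species-number
#' measure, >= 1, bounded above by the observed richness.
#'
#' @param counts non-negative count vector for one site (total > 0).
#' @return the index.
#' @export
#' @examples
#' inverse_simpson(c(10, 10, 10, 10)) # 4
inverse_simpson <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty site: no positive counts")
  p <- counts / sum(counts)
  1 / sum(p^2)
}

#' Berger-Parker dominance
#'
#' Relative abundance of the single most abundant taxon, `n_max / N`
#' (dominance form, as reported by Mothur). Set `reciprocal = TRUE` for the
#' `N / n_max` diversity form.
#'
#' @param counts non-negative count vector (total > 0).
#' @param reciprocal return the reciprocal (diversity) form.
#' @return dominance in (0, 1], or its reciprocal.
#' @export
berger_parker <- function(counts, reciprocal = FALSE) {
  N <- sum(counts)
  if (N <= 0) stop("empty site: no positive counts")
  d <- max(counts) / N
  if (reciprocal) 1 / d else d
}

#' Chao1 nonparametric richness estimate
#'
#' `S_obs + f1^2 / (2 f2)` from singleton (`f1`) and doubleton (`f2`) counts,
#' switching to the bias-corrected form `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`
#' when no doubletons are observed.
#'
#' @param counts non-negative integer count vector (total > 0).
#' @return estimated richness.
#' @export
#' @examples
#' chao1(c(3, 3, 3, 1, 1, 2)) # 6 observed, f1 = 2, f2 = 1 -> 8
chao1 <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty site: no positive counts")
  S <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) S + f1^2 / (2 * f2) else S + f1 * (f1 - 1) / 2
}

#' Assemble a site x OTU table with site metadata and taxonomy
#'
#' @param counts site x OTU matrix of non-negative integers with row (site)
#'   and column (OTU) names; analyzed sites must have positive totals.
#' @param site_meta data.frame with one row per site (matched by `site`
#'   column or row names): `area` (`"anomaly"` or `"reference"`), `au`
#'   (ng g-1), optionally `ph` and other geochemistry.
#' @param taxonomy optional data.frame with `otu`, `phylum`, `order`
#'   (unlisted OTUs are labeled `"unclassified"`).
#' @return object of class `otu_table`: list with `counts`, `site_meta`,
#'   `taxonomy`.
#' @export
otu_table <- function(counts, site_meta, taxonomy = NULL) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            all(counts >= 0))
  if (any(rowSums(counts) <= 0)) stop("all analyzed sites need positive totals")
  if (is.null(site_meta$site)) site_meta$site <- rownames(site_meta)
  if (!all(rownames(counts) %in% site_meta$site))
    stop("site metadata missing for some sites")
  site_meta <- site_meta[match(rownames(counts), site_meta$site), , drop = FALSE]
  if (is.null(taxonomy))
    taxonomy <- data.frame(otu = colnames(counts), phylum = "unclassified",
                           order = "unclassified")
  missing <- setdiff(colnames(counts), taxonomy$otu)
  if (length(missing))
    taxonomy <- rbind(taxonomy,
                      data.frame(otu = missing, phylum = "unclassified",
                                 order = "unclassified"))
  structure(list(counts = counts, site_meta = site_meta, taxonomy = taxonomy),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d sites x %d OTUs (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(table(x$site_meta$area)),
                            table(x$site_meta$area)), collapse = ", ")))
  invisible(x)
}

#' Per-site alpha diversity summary
#'
#' @param table an [otu_table()].
#' @return data.frame with one row per site: `site`, `area`, `au`,
#'   `inverse_simpson`, `berger_parker`, `chao1`, `richness`.
#' @export
diversity_table <- function(table) {
  cnt <- table$counts
  data.frame(
    site = rownames(cnt),
    area = table$site_meta$area,
    au = table$site_meta$au,
    inverse_simpson = apply(cnt, 1, inverse_simpson),
    berger_parker = apply(cnt, 1, berger_parker),
    chao1 = apply(cnt, 1, chao1),
    richness = rowSums(cnt > 0),
    row.names = NULL)
}

#' Classify gold hotspots within the anomaly area
#'
#' A site is a hotspot when its gold concentration is greater than or equal to
#' 1.5 times the median gold concentration of the anomaly sites. The rule is
#' scale-equivariant: rescaling all concentrations rescales the threshold and
#' leaves the labels unchanged.
#'
#' @param au gold concentrations of the anomaly sites, ng g-1 (no missing
#'   values; at least one site).
#' @param fold threshold multiplier (1.5 by default).
#' @return list with `threshold` (ng g-1), `hotspot` (logical vector), and
#'   `median`.
#' @export
#' @examples
#' classify_hotspots(c(2, 3.54, 6, 40, 1))
classify_hotspots <- function(au, fold = 1.5) {
  if (!length(au) || anyNA(au)) stop("gold values missing")
  med <- stats::median(au)
  thr <- fold * med
  list(threshold = thr, hotspot = au >= thr, median = med)
}

#' Correlation between site diversity and in situ gold concentration
#'
#' Pearson correlation between per-site inverse Simpson diversity and gold
#' concentration within a site group, with the p-value from the exact t
#' transform and a significance flag at the analysis alpha (0.1).
#'
#' @param table an [otu_table()].
#' @param sites logical or character selector of the sites to include (e.g.
#'   anomaly sites, or hotspots); at least three sites.
#' @param tails 1 (directional, following the sign of r) or 2.
#' @param alpha significance level for the flag.
#' @return list with `r`, `p`, `n`, `significant`.
#' @export
diversity_gold_correlation <- function(table, sites, tails = 2, alpha = 0.1) {
  if (is.character(sites)) sites <- rownames(table$counts) %in% sites
  cnt <- table$counts[sites, , drop = FALSE]
  au <- table$site_meta$au[sites]
  if (nrow(cnt) < 3) stop("fewer than three sites in group")
  div <- apply(cnt, 1, inverse_simpson)
  if (stats::sd(div) == 0 || stats::sd(au) == 0)
    stop("zero variance in diversity or gold within the group")
  alt <- if (tails == 2) "two.sided" else
    if (stats::cor(div, au) >= 0) "greater" else "less"
  ct <- stats::cor.test(div, au, alternative = alt, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(cnt),
       significant = ct$p.value < alpha)
}
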