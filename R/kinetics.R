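# Microcosm Au(III) oxidation kinetics: TMB colorimetric calibration,
# phase-wise linear rates, Au(III)-pH correlation, percent of spiked gold
# oxidized.

# r-squared without summary.lm (which warns on exact fits); NA when the
# response is constant
r_squared <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum(stats::residuals(fit)^2) / sst
}

#' Fit a colorimetric standard curve
#'
#' Ordinary least squares of absorbance (654 nm) on Au(III) concentration.
#'
#' @param concs concentrations, uM (at least two distinct values).
#' @param abs_values absorbances, AU; same length as `concs`.
#' @return object of class `standard_curve`: list with `slope` (AU uM-1),
#'   `intercept` (AU), `r2`, and the input data.
#' @export
#' @examples
#' fit_standard_curve(c(2, 3, 10, 20, 30), 0.02 * c(2, 3, 10, 20, 30) + 0.01)
fit_standard_curve <- function(concs, abs_values) {
  stopifnot(length(concs) == length(abs_values), length(concs) >= 2)
  if (length(unique(concs)) < 2)
    stop("all concentrations identical; cannot fit a standard curve")
  fit <- stats::lm(abs_values ~ concs)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = r_squared(fit, abs_values),
         concentrations = concs, absorbances = abs_values),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: A = %.4g * c + %.4g (r2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r2, length(x$concentrations)))
  invisible(x)
}

#' Invert a standard curve: absorbance to Au(III) concentration
#'
#' `(A - intercept) / slope`; inferred concentrations below zero are clipped
#' to zero and counted in the `n_clipped` attribute (measurement noise can
#' push blank-level absorbances below the intercept).
#'
#' @param curve a [fit_standard_curve()] result.
#' @param A absorbance(s), AU.
#' @return concentrations, uM, with attribute `n_clipped`.
#' @export
absorbance_to_au3 <- function(curve, A) {
  if (abs(curve$slope) < 1e-12) stop("standard curve has zero slope")
  conc <- (A - curve$intercept) / curve$slope
  n_clipped <- sum(conc < 0)
  if (n_clipped > 0)
    warning(n_clipped, " inferred concentration(s) below zero clipped to 0")
  structure(pmax(conc, 0), n_clipped = n_clipped)
}

#' Assemble a microcosm time series
#'
#' @param times sampling times, h (strictly increasing).
#' @param au3 mean Au(III) concentration over replicates, uM (>= 0).
#' @param ph mean pH at each time (optional, needed for [correlate_au3_ph()]).
#' @param au3_sd replicate standard deviation, uM (optional).
#' @param condition label, e.g. `"GA6F+cs"`.
#' @param replicates replicate count (>= 1).
#' @param total_au total spiked gold, uM (> 0).
#' @return object of class `microcosm_series` (a data.frame with metadata
#'   attributes).
#' @export
microcosm_series <- function(times, au3, ph = NULL, au3_sd = NULL,
                             condition = "", replicates = 1, total_au = 40) {
  stopifnot(all(diff(times) > 0), all(au3 >= 0), replicates >= 1, total_au > 0)
  df <- data.frame(time_h = times, au3_uM = au3)
  if (!is.null(ph)) df$ph <- ph
  if (!is.null(au3_sd)) df$au3_sd <- au3_sd
  structure(df, condition = condition, replicates = replicates,
            total_au = total_au,
            class = c("microcosm_series", "data.frame"))
}

#' Phase-wise linear oxidation rate
#'
#' OLS slope of Au(III) concentration against time over a user-specified
#' window of observed times (the linear phases are identified by inspection of
#' the trajectory, or with [find_breakpoint()]).
#'
#' @param series a [microcosm_series()].
#' @param window `c(t_start, t_end)` in hours; observations with
#'   `t_start <= t <= t_end` enter the fit (at least two required).
#' @return object of class `phase_fit`: list with `window`, `rate` (uM h-1),
#'   `intercept` (uM), `r2`, `n`.
#' @export
fit_phase_rate <- function(series, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  sel <- series$time_h >= window[1] & series$time_h <= window[2]
  if (sum(sel) < 2) stop("fewer than two observations inside the window")
  fit <- stats::lm(au3_uM ~ time_h, data = series[sel, , drop = FALSE])
  structure(
    list(window = window, rate = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = r_squared(fit, series$au3_uM[sel]), n = sum(sel)),
    class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat(sprintf("phase_fit %g-%g h: rate = %.4g uM/h (n = %d, r2 = %s)\n",
              x$window[1], x$window[2], x$rate, x$n,
              ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2))))
  invisible(x)
}

#' Two-segment breakpoint search
#'
#' Grid search over interior observed times for the single breakpoint that
#' minimizes the summed squared error of two independent line fits. A
#' descriptive convenience, not used by any headline statistic.
#'
#' @param series a [microcosm_series()].
#' @return list with `breakpoint` (h) and the two [fit_phase_rate()] fits.
#' @export
find_breakpoint <- function(series) {
  t <- series$time_h
  if (length(t) < 4) stop("need at least four observations for a breakpoint search")
  cand <- t[2:(length(t) - 1)]
  sse <- vapply(cand, function(b) {
    f1 <- fit_phase_rate(series, c(min(t), b))
    f2 <- fit_phase_rate(series, c(b, max(t)))
    pred <- function(f, tt) f$intercept + f$rate * tt
    sum((series$au3_uM[t <= b] - pred(f1, t[t <= b]))^2) +
      sum((series$au3_uM[t >= b] - pred(f2, t[t >= b]))^2)
  }, numeric(1))
  b <- cand[which.min(sse)]
  list(breakpoint = b,
       phase1 = fit_phase_rate(series, c(min(t), b)),
       phase2 = fit_phase_rate(series, c(b, max(t))))
}

#' Pearson correlation between Au(III) and pH over a time window
#'
#' Pearson's r with the p-value from the exact t transform on n - 2 degrees of
#' freedom; one-tailed p-values supported for directional hypotheses.
#'
#' @param series a [microcosm_series()] carrying a `ph` column.
#' @param window `c(t_start, t_end)`, h; at least three points required.
#' @param tails 1 or 2; for `tails = 1` the alternative follows the sign of
#'   the observed correlation.
#' @return list with `r`, `p`, `n`, `df`.
#' @export
correlate_au3_ph <- function(series, window = range(series$time_h), tails = 2) {
  if (is.null(series$ph)) stop("series has no pH column")
  sel <- series$time_h >= window[1] & series$time_h <= window[2]
  if (sum(sel) < 3) stop("fewer than three observations inside the window")
  x <- series$au3_uM[sel]; y <- series$ph[sel]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in Au(III) or pH inside the window")
  alt <- if (tails == 2) "two.sided" else
    if (stats::cor(x, y) >= 0) "greater" else "less"
  ct <- stats::cor.test(x, y, alternative = alt, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(sel),
       df = unname(ct$parameter))
}

#' Maximum fraction of the spiked gold pool recovered as Au(III)
#'
#' @param series a [microcosm_series()] with a `total_au` attribute (uM).
#' @return list with `t_max` (h, time of the Au(III) maximum), `percent`
#'   (100 * max(au3) / total_au), and `exceeds_total` (flag raised when the
#'   apparent maximum is above the spiked pool, indicating measurement error).
#' @export
percent_oxidized <- function(series) {
  if (!nrow(series)) stop("empty series")
  total <- attr(series, "total_au")
  i <- which.max(series$au3_uM)
  pct <- 100 * series$au3_uM[i] / total
  list(t_max = series$time_h[i], percent = pct, exceeds_total = pct > 100)
}
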