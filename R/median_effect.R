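# Mass-action median-effect model: fa/fu = (D/Dm)^m, linearised as
# log10(fa/fu) = m*log10(D) - m*log10(Dm).

#' Percent viability from raw MTT absorbances
#'
#' Computes percent cell viability relative to the vehicle control after
#' subtracting the media (no-cell) background:
#' `100 * (treated - media) / (vehicle - media)`. Negative values (over-kill
#' wells reading below the blank) are clipped to 0 and flagged.
#'
#' @param treated Absorbance of compound-treated wells (numeric vector).
#' @param vehicle Absorbance of vehicle-control wells (scalar or vector
#'   recycled against `treated`).
#' @param media Absorbance of the media-only blank (scalar or vector).
#' @return Numeric vector of percent viabilities, with a logical attribute
#'   `"clipped"` marking wells clipped up to 0.
#' @examples
#' viability_from_absorbance(0.60, 1.10, 0.10)  # 50
#' @export
viability_from_absorbance <- function(treated, vehicle, media) {
  stopifnot(is.numeric(treated), is.numeric(vehicle), is.numeric(media))
  if (any(vehicle <= media)) {
    stop("invalid controls: vehicle absorbance must exceed media blank", call. = FALSE)
  }
  v <- 100 * (treated - media) / (vehicle - media)
  clipped <- v < 0
  v[clipped] <- 0
  attr(v, "clipped") <- clipped
  v
}

#' Affected fraction from percent viability
#'
#' The median-effect model works with the affected fraction `fa = 1 - V/100`.
#' For log-linearisation, fa must stay inside the open unit interval, so
#' values outside `[eps, 1 - eps]` are clipped to the bound and flagged.
#'
#' @param viability Percent viability (numeric vector).
#' @param eps Clipping margin for fa (default 0.005).
#' @return Numeric vector of affected fractions in `[eps, 1 - eps]` with a
#'   logical attribute `"clipped"`.
#' @export
fa_from_viability <- function(viability, eps = 0.005) {
  stopifnot(is.numeric(viability), all(is.finite(viability)),
            is.numeric(eps), length(eps) == 1L, eps > 0, eps < 0.5)
  fa <- 1 - viability / 100
  clipped <- fa < eps | fa > 1 - eps
  fa <- pmin(pmax(fa, eps), 1 - eps)
  attr(fa, "clipped") <- clipped
  fa
}

#' Fit the median-effect model to dose-effect points
#'
#' Fits `fa/fu = (D/Dm)^m` by unweighted ordinary least squares on the
#' median-effect plot, `log10(fa/fu)` versus `log10(D)` (base-10 logs
#' throughout). The slope is `m`, the intercept `-m*log10(Dm)`, and `r` is
#' the linear correlation coefficient of the plot, measuring conformity of
#' the data to the mass-action model.
#'
#' Either pass `fa` directly, or `viability` (percent), which is converted
#' with [fa_from_viability()]. Points whose fa falls on a clipping bound are
#' by default retained at the bound (`clip = "retain"`); `clip = "exclude"`
#' drops them before fitting, which is the usual choice for layouts whose
#' extreme doses saturate the effect.
#'
#' @param dose Doses in nM (strictly positive).
#' @param fa Affected fractions in (0, 1); mutually exclusive with
#'   `viability`.
#' @param viability Percent viabilities, converted to fa internally.
#' @param drug_label Label stored with the fit.
#' @param eps Clipping margin passed to [fa_from_viability()].
#' @param clip `"retain"` (keep clipped points at the bound) or `"exclude"`
#'   (drop them).
#' @return An object of class `median_effect_fit`: a list with `Dm` (nM),
#'   `m`, `r`, `n_points`, `drug_label`, `n_clipped` and the points used.
#' @examples
#' d <- c(1, 10, 100)
#' fit <- fit_median_effect(d, fa = 1 / (1 + (10 / d)^1), drug_label = "demo")
#' fit$Dm  # 10
#' @export
fit_median_effect <- function(dose, fa = NULL, viability = NULL,
                              drug_label = "drug", eps = 0.005,
                              clip = c("retain", "exclude")) {
  clip <- match.arg(clip)
  stopifnot(is.numeric(dose), all(is.finite(dose)))
  if (any(dose <= 0)) stop("doses must be strictly positive", call. = FALSE)
  if (is.null(fa) == is.null(viability)) {
    stop("supply exactly one of `fa` or `viability`", call. = FALSE)
  }
  if (!is.null(viability)) {
    fa <- fa_from_viability(viability, eps = eps)
  } else {
    stopifnot(is.numeric(fa), all(is.finite(fa)))
    clipped <- fa < eps | fa > 1 - eps
    fa <- pmin(pmax(fa, eps), 1 - eps)
    attr(fa, "clipped") <- clipped
  }
  if (length(dose) != length(fa)) stop("dose and effect lengths differ", call. = FALSE)
  clipped <- attr(fa, "clipped")
  keep <- if (clip == "exclude") !clipped else rep(TRUE, length(fa))
  d <- dose[keep]; f <- as.numeric(fa)[keep]
  if (length(d) < 2L) {
    stop("insufficient data: need at least 2 usable dose-effect points", call. = FALSE)
  }
  x <- log10(d)
  y <- log10(f / (1 - f))
  if (stats::var(x) == 0) {
    stop("degenerate design: all usable doses identical", call. = FALSE)
  }
  ls <- stats::lm(y ~ x)
  m <- unname(stats::coef(ls)[2L])
  b <- unname(stats::coef(ls)[1L])
  if (!is.finite(m) || m <= 0) {
    stop("median-effect fit failed: non-positive slope (no dose-response gradient)",
         call. = FALSE)
  }
  r <- if (stats::var(y) == 0) 1 else stats::cor(x, y)
  structure(
    list(drug_label = drug_label,
         Dm = 10^(-b / m), m = m, r = r,
         n_points = length(d), n_clipped = sum(clipped),
         points = data.frame(dose_nM = d, fa = f)),
    class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("Median-effect fit: %s\n", x$drug_label))
  cat(sprintf("  Dm (IC50) = %.4g nM   m = %.4g   r = %.4f   n = %d points\n",
              x$Dm, x$m, x$r, x$n_points))
  if (x$n_clipped > 0) cat(sprintf("  (%d point(s) clipped at the fa bounds)\n", x$n_clipped))
  invisible(x)
}

#' Construct a median-effect fit from known parameters
#'
#' Convenience constructor for analytic work (sham combinations, planted
#' truths, worked examples) where `Dm` and `m` are known rather than fitted.
#'
#' @param Dm Median-effect dose (IC50) in nM, > 0.
#' @param m Slope exponent, > 0.
#' @param drug_label Label stored with the fit.
#' @param r Nominal correlation coefficient (default 1).
#' @return A `median_effect_fit` object.
#' @export
median_effect_fit <- function(Dm, m, drug_label = "drug", r = 1) {
  stopifnot(is.numeric(Dm), Dm > 0, is.numeric(m), m > 0, abs(r) <= 1)
  structure(
    list(drug_label = drug_label, Dm = Dm, m = m, r = r,
         n_points = 0L, n_clipped = 0L,
         points = data.frame(dose_nM = numeric(), fa = numeric())),
    class = "median_effect_fit")
}

#' Affected fraction at a dose
#'
#' Evaluates the median-effect curve `fa = 1 / (1 + (Dm/D)^m)`; strictly
#' increasing in dose, with `fa = 0.5` at `D = Dm`.
#'
#' @param fit A `median_effect_fit`.
#' @param dose Dose(s) in nM, strictly positive.
#' @return Affected fraction(s) in (0, 1).
#' @export
effect_at_dose <- function(fit, dose) {
  stopifnot(inherits(fit, "median_effect_fit"), is.numeric(dose))
  if (any(dose <= 0)) stop("dose must be strictly positive", call. = FALSE)
  1 / (1 + (fit$Dm / dose)^fit$m)
}

#' Dose producing a given affected fraction
#'
#' Inverts the median-effect curve: `Dx = Dm * (fa / (1 - fa))^(1/m)`.
#' Exact inverse of [effect_at_dose()]; strictly increasing in fa.
#'
#' @param fit A `median_effect_fit`.
#' @param fa Target affected fraction(s), each in (0, 1).
#' @return Dose(s) in nM.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"), is.numeric(fa))
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie strictly inside (0, 1)", call. = FALSE)
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Percent apoptotic cells
#'
#' `100 * n_apoptotic / n_total`, the standard readout of nuclear-morphology
#' apoptosis counts. A warning is raised when fewer than 200 cells were
#' scored, below the usual counting recommendation.
#'
#' @param n_apoptotic Number of apoptotic cells (0 <= n_apoptotic <= n_total).
#' @param n_total Total number of cells scored (> 0).
#' @return Percent apoptotic cells.
#' @export
apoptotic_fraction <- function(n_apoptotic, n_total) {
  stopifnot(is.numeric(n_apoptotic), is.numeric(n_total))
  if (any(n_total == 0)) stop("n_total must be positive", call. = FALSE)
  if (any(n_apoptotic < 0 | n_apoptotic > n_total)) {
    stop("n_apoptotic must lie in [0, n_total]", call. = FALSE)
  }
  if (any(n_total < 200)) {
    warning("fewer than 200 cells scored; estimate may be unstable", call. = FALSE)
  }
  100 * n_apoptotic / n_total
}

#' Median-effect plot coordinates for a fit
#'
#' Tidy table of the linearised points and fitted line, for external
#' plotting of the median-effect plot.
#'
#' @param fit A `median_effect_fit` with stored points.
#' @return Data frame with `log10_dose`, `log10_fa_fu`, `fitted`.
#' @export
median_effect_plot_data <- function(fit) {
  stopifnot(inherits(fit, "median_effect_fit"))
  p <- fit$points
  x <- log10(p$dose_nM)
  data.frame(log10_dose = x,
             log10_fa_fu = log10(p$fa / (1 - p$fa)),
             fitted = fit$m * (x - log10(fit$Dm)))
}
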