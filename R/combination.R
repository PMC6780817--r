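# Two-drug interaction analysis: Chou-Talalay combination index across
# inhibition levels, dose-reduction index, isobologram and curve-shift
# coordinates, and report tables for constant-ratio and checkerboard designs.

SCHEDULES <- c("simultaneous", "a_then_b", "b_then_a")

#' Describe a constant-ratio combination design
#'
#' Records the pairing of two drugs at a fixed molar ratio together with the
#' administration schedule. For endpoint viability data the schedule is
#' metadata: all regimens are read out at the same total exposure time.
#'
#' @param drug_a,drug_b Drug labels.
#' @param ratio_a,ratio_b Positive integer parts of the molar ratio
#'   (e.g. 1:50 means `ratio_a = 1`, `ratio_b = 50`).
#' @param schedule One of `"simultaneous"`, `"a_then_b"`, `"b_then_a"`.
#' @param exposure_hours_total Total exposure (default 72 h).
#' @param exposure_hours_first First-drug exposure for sequential schedules.
#' @return An object of class `combination_design`.
#' @export
combination_design <- function(drug_a, drug_b, ratio_a = 1L, ratio_b = 1L,
                               schedule = c("simultaneous", "a_then_b", "b_then_a"),
                               exposure_hours_total = 72,
                               exposure_hours_first = NULL) {
  schedule <- match.arg(schedule)
  stopifnot(length(ratio_a) == 1L, length(ratio_b) == 1L,
            ratio_a >= 0, ratio_b >= 0, ratio_a + ratio_b > 0,
            ratio_a == round(ratio_a), ratio_b == round(ratio_b))
  structure(
    list(drug_a = drug_a, drug_b = drug_b,
         ratio_a = as.integer(ratio_a), ratio_b = as.integer(ratio_b),
         schedule = schedule,
         exposure_hours_total = exposure_hours_total,
         exposure_hours_first = exposure_hours_first),
    class = "combination_design")
}

#' @export
print.combination_design <- function(x, ...) {
  cat(sprintf("Combination design: %s:%s = %d:%d (%s, %g h)\n",
              x$drug_a, x$drug_b, x$ratio_a, x$ratio_b, x$schedule,
              x$exposure_hours_total))
  invisible(x)
}

# ratio fractions of the total molar dose
ratio_fractions <- function(design) {
  s <- design$ratio_a + design$ratio_b
  c(a = design$ratio_a / s, b = design$ratio_b / s)
}

as_fit_list <- function(x) {
  if (inherits(x, "median_effect_fit")) list(x) else {
    stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "median_effect_fit")))
    x
  }
}

#' Combination index profile across inhibition levels
#'
#' Computes the two-term (mutually exclusive) Chou-Talalay combination index
#' at each requested inhibition level. The combination curve is fitted on
#' the total molar dose of the constant-ratio mixture; at each fa the total
#' dose achieving fa is split into component doses by the ratio fractions,
#' and `CI = d_a / Dx_a(fa) + d_b / Dx_b(fa)` where `Dx` are the
#' single-agent doses for the same effect. CI < 1 indicates synergism,
#' CI = 1 additivity, CI > 1 antagonism.
#'
#' Each of `fit_a`, `fit_b`, `fit_combo` may be a single fit or a list of
#' per-trial fits; single fits are recycled across trials. CI is computed
#' per trial, then summarised as mean +/- SEM across trials.
#'
#' @param fit_a,fit_b Single-agent `median_effect_fit`s (or per-trial lists).
#' @param fit_combo Fit(s) of the mixture on total molar dose.
#' @param design A [combination_design()].
#' @param fa_levels Inhibition levels (default `c(0.5, 0.75, 0.9, 0.95)`).
#' @param additivity_band Band of CI values labelled additive
#'   (default `c(0.90, 1.10)`).
#' @return An object of class `ci_profile`: per-trial CI matrix, cross-trial
#'   mean and SEM, and a classification per level.
#' @export
combination_index <- function(fit_a, fit_b, fit_combo, design,
                              fa_levels = c(0.5, 0.75, 0.9, 0.95),
                              additivity_band = c(0.90, 1.10)) {
  stopifnot(inherits(design, "combination_design"))
  if (length(fa_levels) == 0L) stop("fa_levels must be non-empty", call. = FALSE)
  if (any(fa_levels <= 0 | fa_levels >= 1)) {
    stop("fa levels must lie strictly inside (0, 1)", call. = FALSE)
  }
  fits_a <- as_fit_list(fit_a)
  fits_b <- as_fit_list(fit_b)
  fits_c <- as_fit_list(fit_combo)
  n_trials <- max(length(fits_a), length(fits_b), length(fits_c))
  recycle <- function(l) if (length(l) == 1L) rep(l, n_trials) else l
  fits_a <- recycle(fits_a); fits_b <- recycle(fits_b); fits_c <- recycle(fits_c)
  if (!all(lengths(list(fits_a, fits_b, fits_c)) == n_trials)) {
    stop("per-trial fit lists must have equal length (or length 1)", call. = FALSE)
  }
  fr <- ratio_fractions(design)
  ci <- matrix(NA_real_, n_trials, length(fa_levels),
               dimnames = list(paste0("trial", seq_len(n_trials)),
                               paste0("fa", fa_levels)))
  for (t in seq_len(n_trials)) {
    d_tot <- dose_for_effect(fits_c[[t]], fa_levels)
    ci[t, ] <- d_tot * fr["a"] / dose_for_effect(fits_a[[t]], fa_levels) +
               d_tot * fr["b"] / dose_for_effect(fits_b[[t]], fa_levels)
  }
  ci_mean <- colMeans(ci)
  ci_sem <- if (n_trials > 1) apply(ci, 2, stats::sd) / sqrt(n_trials) else
    rep(0, length(fa_levels))
  structure(
    list(fa_levels = fa_levels, ci = ci,
         ci_mean = ci_mean, ci_sem = ci_sem,
         classification = classify_ci(ci_mean, additivity_band),
         n_trials = n_trials, design = design,
         additivity_band = additivity_band),
    class = "ci_profile")
}

#' @export
print.ci_profile <- function(x, ...) {
  d <- x$design
  cat(sprintf("CI profile: %s:%s %d:%d (%s), %d trial(s)\n",
              d$drug_a, d$drug_b, d$ratio_a, d$ratio_b, d$schedule, x$n_trials))
  tab <- data.frame(fa = x$fa_levels,
                    ci = sprintf("%.3f ± %.3f", x$ci_mean, x$ci_sem),
                    class = x$classification)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Classify a combination index value
#'
#' CI below the additivity band is synergism, inside it additivity, above it
#' antagonism. The default band (0.90, 1.10) is the conventional
#' nearly-additive window and is configurable.
#'
#' @param ci Positive CI value(s).
#' @param additivity_band Two-element band `(low, high)`.
#' @return Character vector in `{"synergism", "additivity", "antagonism"}`.
#' @examples
#' classify_ci(c(0.524, 1.0, 1.974))
#' @export
classify_ci <- function(ci, additivity_band = c(0.90, 1.10)) {
  stopifnot(is.numeric(ci), length(additivity_band) == 2L,
            additivity_band[1] < additivity_band[2])
  if (any(ci <= 0)) stop("CI must be strictly positive", call. = FALSE)
  ifelse(ci < additivity_band[1], "synergism",
         ifelse(ci > additivity_band[2], "antagonism", "additivity"))
}

#' Dose-reduction index at an inhibition level
#'
#' For each drug, the fold by which its single-agent dose for a given effect
#' exceeds its dose within the combination achieving the same effect:
#' `DRI_x = Dx_x(fa) / d_x(fa)`. The identity
#' `1/DRI_a + 1/DRI_b = CI(fa)` holds exactly.
#'
#' @inheritParams combination_index
#' @param fa Single inhibition level in (0, 1).
#' @return List with `dri_a`, `dri_b` and the matching `ci`.
#' @export
dose_reduction_index <- function(fit_a, fit_b, fit_combo, design, fa) {
  stopifnot(length(fa) == 1L, fa > 0, fa < 1,
            inherits(design, "combination_design"))
  fits_a <- as_fit_list(fit_a); fits_b <- as_fit_list(fit_b)
  fits_c <- as_fit_list(fit_combo)
  if (any(lengths(list(fits_a, fits_b, fits_c)) != 1L)) {
    stop("dose_reduction_index expects one fit per drug; summarise trials upstream",
         call. = FALSE)
  }
  fr <- ratio_fractions(design)
  d_tot <- dose_for_effect(fits_c[[1]], fa)
  d_a <- d_tot * fr["a"]; d_b <- d_tot * fr["b"]
  dri_a <- unname(dose_for_effect(fits_a[[1]], fa) / d_a)
  dri_b <- unname(dose_for_effect(fits_b[[1]], fa) / d_b)
  list(dri_a = dri_a, dri_b = dri_b, ci = 1 / dri_a + 1 / dri_b, fa = fa)
}

#' Isobologram coordinates at a fixed inhibition level
#'
#' Returns the single-agent axis intercepts `(Dx_a(fa), 0)` and
#' `(0, Dx_b(fa))` — the additivity line joins them — and, per combination,
#' the point `(d_a(fa), d_b(fa))` achieved by the mixture. In normalised
#' coordinates (each component dose divided by its intercept) the coordinate
#' sum equals the combination index at the same fa, so points below the
#' additivity line are exactly the synergistic ones.
#'
#' @param fit_a,fit_b Single-agent fits.
#' @param combos A list; each element a list with components `fit_combo`
#'   (mixture fit on total dose) and `design` (a [combination_design()]).
#' @param fa Inhibition level in (0, 1) (the classical display uses 0.95).
#' @return An object of class `isobole`: the fa level, an `intercepts` data
#'   frame and a `points` data frame with raw and normalised coordinates
#'   and the implied CI.
#' @export
isobologram <- function(fit_a, fit_b, combos, fa = 0.95) {
  stopifnot(length(fa) == 1L)
  if (fa <= 0 || fa >= 1) stop("fa must lie strictly inside (0, 1)", call. = FALSE)
  fit_a <- as_fit_list(fit_a)[[1]]; fit_b <- as_fit_list(fit_b)[[1]]
  dx_a <- dose_for_effect(fit_a, fa)
  dx_b <- dose_for_effect(fit_b, fa)
  pts <- do.call(rbind, lapply(combos, function(cb) {
    stopifnot(inherits(cb$design, "combination_design"))
    fr <- ratio_fractions(cb$design)
    d_tot <- dose_for_effect(as_fit_list(cb$fit_combo)[[1]], fa)
    d_a <- unname(d_tot * fr["a"]); d_b <- unname(d_tot * fr["b"])
    data.frame(ratio = sprintf("%d:%d", cb$design$ratio_a, cb$design$ratio_b),
               schedule = cb$design$schedule,
               d_a_nM = d_a, d_b_nM = d_b,
               norm_a = d_a / dx_a, norm_b = d_b / dx_b,
               ci = d_a / dx_a + d_b / dx_b)
  }))
  structure(
    list(fa = fa,
         intercepts = data.frame(drug = c(fit_a$drug_label, fit_b$drug_label),
                                 axis = c("a", "b"),
                                 dose_nM = c(dx_a, dx_b)),
         points = pts),
    class = "isobole")
}

#' @export
print.isobole <- function(x, ...) {
  cat(sprintf("Isobologram at fa = %.2f\n", x$fa))
  print(x$intercepts, row.names = FALSE)
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Curve-shift overlay table for a constant-ratio mixture
#'
#' Re-expresses each mixture observation on each component drug's own
#' concentration axis (total dose split by the ratio fractions) so the
#' combination curve can be overlaid on the single-agent curves. No
#' refitting is performed; single-agent viability predicted from each fit at
#' the component dose is included for reference. A leftward shift of the
#' combination points (lower viability at the same component dose) indicates
#' enhancement.
#'
#' @param fit_a,fit_b Single-agent fits.
#' @param combo_points Data frame with columns `dose_nM` (total molar dose
#'   of the mixture) and `viability_pct` (observed viability).
#' @param design A [combination_design()].
#' @return Long data frame: one row per observation per component, with
#'   `drug`, `component_dose_nM`, `viability_pct` (observed in combination)
#'   and `single_agent_viability_pct` (predicted alone at that dose).
#' @export
curve_shift_table <- function(fit_a, fit_b, combo_points, design) {
  stopifnot(is.data.frame(combo_points),
            all(c("dose_nM", "viability_pct") %in% names(combo_points)),
            inherits(design, "combination_design"))
  fit_a <- as_fit_list(fit_a)[[1]]; fit_b <- as_fit_list(fit_b)[[1]]
  fr <- ratio_fractions(design)
  one <- function(which, fit) {
    d <- combo_points$dose_nM * fr[[which]]
    pred <- ifelse(d > 0, 100 * (1 - effect_at_dose(fit, pmax(d, .Machine$double.xmin))), 100)
    data.frame(drug = fit$drug_label,
               component = which,
               component_dose_nM = d,
               viability_pct = combo_points$viability_pct,
               single_agent_viability_pct = pred)
  }
  out <- rbind(one("a", fit_a), one("b", fit_b))
  # a degenerate ratio leaves one component at dose zero; drop those rows
  out[out$component_dose_nM > 0, , drop = FALSE]
}

# round-half-up at a given unit (base R round() is round-half-even)
round_half_up <- function(x, unit = 1) floor(x / unit + 0.5) * unit

#' Potency ratio and equipotent integer ratio of two drugs
#'
#' The potency ratio is `Dm_b / Dm_a`; the equipotent design ratio is
#' `1 : (ratio rounded to the nearest multiple of ten, half-up)`, falling
#' back to the nearest integer when rounding to tens would give zero.
#'
#' @param fit_a,fit_b Single-agent fits (a = more potent by convention).
#' @param round_to Rounding unit for the equipotent ratio (default 10).
#' @return List with `ratio` (numeric) and `equipotent` (integer pair c(1, k)).
#' @examples
#' potency_ratio(median_effect_fit(6, 2, "RM"), median_effect_fit(356, 1, "DOX"))
#' @export
potency_ratio <- function(fit_a, fit_b, round_to = 10) {
  stopifnot(inherits(fit_a, "median_effect_fit"),
            inherits(fit_b, "median_effect_fit"))
  ratio <- fit_b$Dm / fit_a$Dm
  k <- round_half_up(ratio, round_to)
  if (k < 1) k <- max(1, round_half_up(ratio, 1))
  list(ratio = ratio, equipotent = c(1L, as.integer(k)))
}

#' Classification report across combination designs
#'
#' Builds a heat-map-shaped summary of CI profiles: one row per design, with
#' trial count, CI mean +/- SEM at each inhibition level and the
#' synergism/additivity/antagonism label per cell. Rows are ordered
#' deterministically by schedule (simultaneous, a_then_b, b_then_a) then by
#' the numeric b:a ratio.
#'
#' @param profiles A list of `ci_profile` objects sharing fa levels.
#' @return Data frame, one row per profile.
#' @export
ci_summary_report <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "ci_profile")))
  fa0 <- profiles[[1]]$fa_levels
  if (length(fa0) == 0L) stop("profiles carry no fa levels", call. = FALSE)
  if (!all(vapply(profiles, function(p) identical(p$fa_levels, fa0), TRUE))) {
    stop("all profiles must share the same fa levels", call. = FALSE)
  }
  rows <- lapply(profiles, function(p) {
    d <- p$design
    row <- data.frame(schedule = d$schedule,
                      ratio = sprintf("%d:%d", d$ratio_a, d$ratio_b),
                      n_trials = p$n_trials,
                      stringsAsFactors = FALSE)
    for (i in seq_along(fa0)) {
      pct <- round(100 * fa0[i])
      row[[sprintf("ci_ic%d", pct)]] <- sprintf("%.3f ± %.3f",
                                                p$ci_mean[i], p$ci_sem[i])
      row[[sprintf("ci_mean_ic%d", pct)]] <- unname(p$ci_mean[i])
      row[[sprintf("ci_sem_ic%d", pct)]] <- unname(p$ci_sem[i])
      row[[sprintf("class_ic%d", pct)]] <- unname(p$classification[i])
    }
    row$ratio_value <- d$ratio_b / max(d$ratio_a, 1L)
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$schedule, SCHEDULES), out$ratio_value), , drop = FALSE]
  out$ratio_value <- NULL
  rownames(out) <- NULL
  out
}

#' Checkerboard enhancement summary
#'
#' For a full-factorial dose grid with single-agent margins (rows with a
#' zero dose of the other drug), compares each interior combination cell's
#' viability with both of its single-agent margins and flags cells where the
#' combination is lower than both — candidate enhancement.
#'
#' @param grid Data frame with columns `dose_a_nM`, `dose_b_nM`,
#'   `viability_pct` (replicates allowed; averaged per cell).
#' @return Data frame of interior cells with margin viabilities, differences
#'   and an `enhanced` flag.
#' @export
checkerboard_summary <- function(grid) {
  stopifnot(is.data.frame(grid),
            all(c("dose_a_nM", "dose_b_nM", "viability_pct") %in% names(grid)))
  cells <- stats::aggregate(viability_pct ~ dose_a_nM + dose_b_nM, grid, mean)
  margin_a <- cells[cells$dose_b_nM == 0 & cells$dose_a_nM > 0, ]
  margin_b <- cells[cells$dose_a_nM == 0 & cells$dose_b_nM > 0, ]
  interior <- cells[cells$dose_a_nM > 0 & cells$dose_b_nM > 0, ]
  if (nrow(margin_a) == 0L || nrow(margin_b) == 0L || nrow(interior) == 0L) {
    stop("checkerboard design error: grid must contain single-agent margins ",
         "(zero-dose rows/columns for each drug) and interior cells", call. = FALSE)
  }
  va <- margin_a$viability_pct[match(interior$dose_a_nM, margin_a$dose_a_nM)]
  vb <- margin_b$viability_pct[match(interior$dose_b_nM, margin_b$dose_b_nM)]
  if (anyNA(va) || anyNA(vb)) {
    stop("checkerboard design error: some interior doses lack a matching margin",
         call. = FALSE)
  }
  data.frame(dose_a_nM = interior$dose_a_nM,
             dose_b_nM = interior$dose_b_nM,
             viability_pct = interior$viability_pct,
             margin_a_viability_pct = va,
             margin_b_viability_pct = vb,
             diff_vs_a = interior$viability_pct - va,
             diff_vs_b = interior$viability_pct - vb,
             enhanced = interior$viability_pct < va & interior$viability_pct < vb)
}
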