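# Synthetic MTT plates and impedance traces with planted ground truth, so
# the fitting and combination-index machinery can be validated end-to-end.

#' Planted ground truth for the synthetic-data generator
#'
#' Bundles everything the generator needs: per-drug median-effect parameters,
#' the Loewe interaction level alpha (1 = additive, < 1 synergistic,
#' > 1 antagonistic — by construction the true combination index of the
#' generated surface equals alpha at every achieved effect level), the
#' noise level, the plate layout and the seed.
#'
#' Defaults emulate a steep potent agent (Dm = 6 nM, m = 2) against a
#' shallower, ~60-fold less potent one (Dm = 356 nM, m = 1), probed in
#' quadruplicate half-log dilution series over three independent trials
#' with 3 viability-percent Gaussian well noise.
#'
#' @param drug_a,drug_b Lists with `label`, `Dm` (nM) and `m`.
#' @param alpha Loewe interaction level (> 0).
#' @param sigma_viability SD of Gaussian well noise, viability percent.
#' @param doses_a,doses_b Single-agent dose series (nM).
#' @param replicates Wells per dose (default 4).
#' @param trials Independent trials (default 3).
#' @param schedule_alpha_multipliers Named multipliers applied to alpha per
#'   administration schedule, emulating regimen-dependent interaction;
#'   defaults to no modulation.
#' @param seed Integer seed recorded in the truth and used by default by
#'   every generator.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(drug_a = list(label = "drugA", Dm = 6, m = 2),
                            drug_b = list(label = "drugB", Dm = 356, m = 1),
                            alpha = 1,
                            sigma_viability = 3,
                            doses_a = 10^seq(-1.5, 3, by = 0.5),
                            doses_b = 10^seq(0, 4.5, by = 0.5),
                            replicates = 4L, trials = 3L,
                            schedule_alpha_multipliers =
                              c(simultaneous = 1, a_then_b = 1, b_then_a = 1),
                            seed = 1L) {
  for (d in list(drug_a, drug_b)) {
    stopifnot(is.list(d), !is.null(d$label), d$Dm > 0, d$m > 0)
  }
  stopifnot(alpha > 0, sigma_viability >= 0, all(doses_a > 0), all(doses_b > 0),
            replicates >= 1, trials >= 1,
            all(names(schedule_alpha_multipliers) %in% SCHEDULES))
  structure(
    list(drug_a = drug_a, drug_b = drug_b, alpha = alpha,
         sigma_viability = sigma_viability,
         doses_a = doses_a, doses_b = doses_b,
         replicates = as.integer(replicates), trials = as.integer(trials),
         schedule_alpha_multipliers = schedule_alpha_multipliers,
         seed = as.integer(seed)),
    class = "synthetic_truth")
}

truth_fit <- function(drug) median_effect_fit(drug$Dm, drug$m, drug$label)

effective_alpha <- function(truth, schedule) {
  mult <- truth$schedule_alpha_multipliers
  unname(truth$alpha * (if (schedule %in% names(mult)) mult[[schedule]] else 1))
}

#' Effect of a dose pair under a planted Loewe interaction
#'
#' Solves `d_a / Dx_a(fa) + d_b / Dx_b(fa) = alpha` for the affected
#' fraction fa by bisection (the left side is strictly decreasing in fa).
#' `alpha = 1` is exact Loewe additivity; by construction the true
#' combination index of the resulting surface equals `alpha` at every
#' achieved fa. The interaction is a property of the mixture: when one dose
#' is zero the plain single-agent curve `fa = effect_at_dose(fit, d)` is
#' returned, whatever `alpha`.
#'
#' @param d_a,d_b Component doses in nM (vectors, recycled; `d_a + d_b > 0`).
#' @param fit_a,fit_b Single-agent `median_effect_fit`s.
#' @param alpha Interaction level (> 0).
#' @param tol Bisection tolerance on fa (default 1e-10).
#' @param max_iter Maximum bisection iterations (default 200).
#' @return Affected fraction(s), with a logical attribute `"flagged"` for
#'   doses whose solution lay outside the bracketed fa range and was clipped.
#' @export
loewe_effect <- function(d_a, d_b, fit_a, fit_b, alpha = 1,
                         tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(fit_a, "median_effect_fit"),
            inherits(fit_b, "median_effect_fit"),
            is.numeric(d_a), is.numeric(d_b), all(d_a >= 0), all(d_b >= 0),
            alpha > 0)
  n <- max(length(d_a), length(d_b))
  d_a <- rep_len(d_a, n); d_b <- rep_len(d_b, n)
  if (any(d_a + d_b <= 0)) stop("total dose must be positive", call. = FALSE)
  fa <- numeric(n)
  flagged <- logical(n)
  only_a <- d_b == 0
  only_b <- d_a == 0
  fa[only_a] <- effect_at_dose(fit_a, d_a[only_a])
  fa[only_b] <- effect_at_dose(fit_b, d_b[only_b])
  both <- !(only_a | only_b)
  if (any(both)) {
    g <- function(f) {
      d_a[both] / dose_for_effect(fit_a, f) +
        d_b[both] / dose_for_effect(fit_b, f) - alpha
    }
    lo <- rep(1e-12, sum(both)); hi <- rep(1 - 1e-12, sum(both))
    glo <- g(lo); ghi <- g(hi)
    low_clip <- glo < 0      # even minuscule effect needs more dose than given
    high_clip <- ghi > 0     # dose exceeds what the tolerance can bracket
    solve_idx <- !(low_clip | high_clip)
    f_lo <- lo; f_hi <- hi
    for (i in seq_len(max_iter)) {
      if (!any(solve_idx) || max(f_hi[solve_idx] - f_lo[solve_idx]) <= tol) break
      mid <- (f_lo + f_hi) / 2
      gm <- g(mid)
      up <- solve_idx & (gm > 0)   # g decreasing: root above mid
      dn <- solve_idx & (gm <= 0)
      f_lo[up] <- mid[up]
      f_hi[dn] <- mid[dn]
    }
    res <- (f_lo + f_hi) / 2
    res[low_clip] <- lo[low_clip]
    res[high_clip] <- hi[high_clip]
    fa[both] <- res
    fl <- logical(sum(both)); fl[low_clip | high_clip] <- TRUE
    flagged[both] <- fl
  }
  attr(fa, "flagged") <- flagged
  fa
}

# shared well-noise helper: viability percent with Gaussian noise
viability_wells <- function(fa, truth) {
  100 * (1 - fa) + stats::rnorm(length(fa), 0, truth$sigma_viability)
}

#' Generate a tidy single-agent MTT plate
#'
#' Serial-dilution dose series with `replicates` wells per dose and `trials`
#' independent trials, plus vehicle (dose 0) and media-blank wells.
#' Per-well viability is `100 * (1 - fa)` plus Gaussian noise; media wells
#' carry no viability. Byte-identical output for a fixed `(truth, seed)`.
#'
#' @param truth A [synthetic_truth()].
#' @param drug `"a"` or `"b"`.
#' @param doses Optional dose series override (nM).
#' @param seed Seed (defaults to `truth$seed`).
#' @return Tidy data frame: `drug`, `dose_nM`, `trial`, `replicate`,
#'   `well_type`, `viability_pct`, `seed`.
#' @export
generate_single_drug_plate <- function(truth, drug = c("a", "b"),
                                       doses = NULL, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  drug <- match.arg(drug)
  spec_d <- if (drug == "a") truth$drug_a else truth$drug_b
  if (is.null(doses)) doses <- if (drug == "a") truth$doses_a else truth$doses_b
  fit <- truth_fit(spec_d)
  fa <- effect_at_dose(fit, doses)
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(truth$trials), function(tr) {
      treated <- expand.grid(replicate = seq_len(truth$replicates),
                             dose_nM = doses)
      treated <- data.frame(drug = spec_d$label, dose_nM = treated$dose_nM,
                            trial = tr, replicate = treated$replicate,
                            well_type = "treated",
                            viability_pct = viability_wells(
                              rep(fa, each = truth$replicates), truth))
      vehicle <- data.frame(drug = spec_d$label, dose_nM = 0, trial = tr,
                            replicate = seq_len(truth$replicates),
                            well_type = "vehicle",
                            viability_pct = viability_wells(
                              rep(0, truth$replicates), truth))
      media <- data.frame(drug = spec_d$label, dose_nM = 0, trial = tr,
                          replicate = seq_len(truth$replicates),
                          well_type = "media", viability_pct = NA_real_)
      rbind(treated, vehicle, media)
    }))
    out$seed <- seed
    rownames(out) <- NULL
    out
  })
}

#' Generate a constant-ratio combination plate
#'
#' Total-molar-dose series of the mixture at the design's fixed ratio, with
#' per-well viability derived from [loewe_effect()] at the truth's
#' interaction level (optionally modulated by the design's schedule via
#' `truth$schedule_alpha_multipliers`). Parallel single-agent control series
#' for both drugs are included, matching the usual combination-experiment
#' layout. Degenerate ratios (one part zero) reduce to a single-drug plate
#' on the active component.
#'
#' @param truth A [synthetic_truth()].
#' @param design A [combination_design()].
#' @param total_doses Total-dose series of the mixture (nM); the default
#'   places 8 doses, geometrically spaced over a 500-fold range, such that
#'   the drug-a component spans 0.2-100 nM (or scales the analogous series
#'   by the ratio when drug a is absent).
#' @param include_singles Include the parallel single-agent controls.
#' @param seed Seed (defaults to `truth$seed`).
#' @return Tidy data frame: `drug`, `dose_nM` (total molar dose),
#'   `dose_a_nM`, `dose_b_nM`, `trial`, `replicate`, `well_type`,
#'   `viability_pct`, `seed`.
#' @export
generate_combination_plate <- function(truth, design, total_doses = NULL,
                                       include_singles = TRUE,
                                       seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(design, "combination_design"))
  fr <- ratio_fractions(design)
  fit_a <- truth_fit(truth$drug_a); fit_b <- truth_fit(truth$drug_b)
  if (is.null(total_doses)) {
    base <- 0.2 * 500^((0:7) / 7)     # drug-a component series, nM
    total_doses <- if (fr[["a"]] > 0) base / fr[["a"]] else base * 500
  }
  alpha_eff <- effective_alpha(truth, design$schedule)
  d_a <- total_doses * fr[["a"]]; d_b <- total_doses * fr[["b"]]
  fa <- loewe_effect(d_a, d_b, fit_a, fit_b, alpha_eff)
  combo_label <- paste(truth$drug_a$label, truth$drug_b$label, sep = "+")
  withr::with_seed(seed, {
    combo <- do.call(rbind, lapply(seq_len(truth$trials), function(tr) {
      data.frame(drug = combo_label,
                 dose_nM = rep(total_doses, each = truth$replicates),
                 dose_a_nM = rep(d_a, each = truth$replicates),
                 dose_b_nM = rep(d_b, each = truth$replicates),
                 trial = tr,
                 replicate = seq_len(truth$replicates),
                 well_type = "combo",
                 viability_pct = viability_wells(
                   rep(as.numeric(fa), each = truth$replicates), truth))
    }))
    out <- combo
    if (include_singles) {
      singles <- lapply(c("a", "b"), function(dr) {
        frac <- fr[[dr]]
        if (frac == 0) return(NULL)
        plate <- generate_single_drug_plate(
          truth, dr, seed = sample.int(2^31 - 1, 1))
        plate$dose_a_nM <- if (dr == "a") plate$dose_nM else 0
        plate$dose_b_nM <- if (dr == "b") plate$dose_nM else 0
        plate[, names(out)]
      })
      out <- rbind(out, do.call(rbind, singles))
    }
    rownames(out) <- NULL
    out
  })
}

#' Generate a checkerboard (full-factorial) combination plate
#'
#' Every pair of doses from the two grids, including the zero-dose margins
#' (single-agent rows/columns) and the double-zero vehicle cell, with
#' viability from [loewe_effect()] plus well noise.
#'
#' @param truth A [synthetic_truth()].
#' @param doses_a,doses_b Dose grids in nM, each including 0; defaults span
#'   a 16-fold two-fold-step range around each drug's Dm.
#' @param seed Seed (defaults to `truth$seed`).
#' @return Tidy data frame: `dose_a_nM`, `dose_b_nM`, `trial`, `replicate`,
#'   `viability_pct`, `seed`.
#' @export
generate_checkerboard <- function(truth,
                                  doses_a = c(0, truth$drug_a$Dm * 2^(-2:2)),
                                  doses_b = c(0, truth$drug_b$Dm * 2^(-2:2)),
                                  seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"),
            0 %in% doses_a, 0 %in% doses_b)
  fit_a <- truth_fit(truth$drug_a); fit_b <- truth_fit(truth$drug_b)
  grid <- expand.grid(dose_a_nM = doses_a, dose_b_nM = doses_b)
  fa <- numeric(nrow(grid))
  active <- grid$dose_a_nM + grid$dose_b_nM > 0
  fa[active] <- loewe_effect(grid$dose_a_nM[active], grid$dose_b_nM[active],
                             fit_a, fit_b, truth$alpha)
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(truth$trials), function(tr) {
      data.frame(dose_a_nM = rep(grid$dose_a_nM, each = truth$replicates),
                 dose_b_nM = rep(grid$dose_b_nM, each = truth$replicates),
                 trial = tr,
                 replicate = seq_len(truth$replicates),
                 viability_pct = viability_wells(
                   rep(fa, each = truth$replicates), truth))
    }))
    out$seed <- seed
    rownames(out) <- NULL
    out
  })
}

#' Generate impedance (cell index) traces with known kinetics
#'
#' Vehicle wells follow logistic growth; drug wells follow the same growth
#' multiplied by a dose- and time-dependent survival term. Two kill modes
#' are provided: `"direct_kill"`, an exponential cumulative-exposure kill
#' (rate proportional to dose^exponent x time since treatment, giving a
#' strictly decreasing time-resolved IC50), and `"senescence"`, which adds a
#' transient cell-size/attachment bump that lifts the trace above the
#' vehicle before a delayed kill sets in — the impedance signature of
#' DNA-damaging, senescence-inducing agents.
#'
#' @param truth A [synthetic_truth()] (supplies replicates, seed).
#' @param drug `"a"` or `"b"` (labelling only).
#' @param doses Dose series in nM; 0 rows are vehicle wells.
#' @param mode `"direct_kill"` or `"senescence"`.
#' @param t_end,dt Time grid: 0 to `t_end` hours in steps of `dt`.
#' @param t_treat Treatment time (h) within the grid.
#' @param growth List with logistic parameters `c0`, `K`, `g` (per hour).
#' @param kill_rate Kill-rate constant (per nM^exponent per hour).
#' @param kill_exponent Dose exponent of the kill rate.
#' @param kill_lag_h Delay between treatment and onset of killing; defaults
#'   to 0 for `"direct_kill"` and 48 h for `"senescence"` (arrested cells
#'   persist before dying).
#' @param senescence_amplitude,senescence_tau Bump height (fraction) and
#'   peak time (h post-treatment) for `"senescence"`.
#' @param sigma_ci SD of additive Gaussian noise on the cell index.
#' @param seed Seed (defaults to `truth$seed`).
#' @return Tidy data frame: `time_h`, `well`, `drug`, `dose_nM`,
#'   `replicate`, `cell_index`, `seed`.
#' @export
generate_rtca_traces <- function(truth, drug = c("a", "b"),
                                 doses = c(0, 10^seq(0, 3.5, by = 0.5)),
                                 mode = c("direct_kill", "senescence"),
                                 t_end = 168, dt = 0.5, t_treat = 24,
                                 growth = list(c0 = 0.2, K = 10, g = 0.05),
                                 kill_rate = 5e-4, kill_exponent = 1,
                                 kill_lag_h = NULL,
                                 senescence_amplitude = 0.4,
                                 senescence_tau = 24,
                                 sigma_ci = 0, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"), all(doses >= 0),
            t_treat > 0, t_treat < t_end, dt > 0)
  drug <- match.arg(drug); mode <- match.arg(mode)
  if (is.null(kill_lag_h)) kill_lag_h <- if (mode == "senescence") 48 else 0
  label <- if (drug == "a") truth$drug_a$label else truth$drug_b$label
  times <- seq(0, t_end, by = dt)
  dt_post <- pmax(times - t_treat, 0)
  dt_kill <- pmax(dt_post - kill_lag_h, 0)
  vgrow <- growth$K /
    (1 + (growth$K - growth$c0) / growth$c0 * exp(-growth$g * times))
  trace_for_dose <- function(d) {
    if (d == 0) return(vgrow)
    surv <- exp(-kill_rate * d^kill_exponent * dt_kill)
    bump <- if (mode == "senescence") {
      1 + senescence_amplitude * (dt_post / senescence_tau) *
        exp(1 - dt_post / senescence_tau)
    } else 1
    vgrow * surv * bump
  }
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(seq_along(doses), function(i) {
      base <- trace_for_dose(doses[i])
      do.call(rbind, lapply(seq_len(truth$replicates), function(rep_i) {
        data.frame(time_h = times,
                   well = sprintf("%s_d%02d_r%d", label, i, rep_i),
                   drug = label, dose_nM = doses[i], replicate = rep_i,
                   cell_index = base +
                     if (sigma_ci > 0) stats::rnorm(length(base), 0, sigma_ci) else 0)
      }))
    }))
    out$seed <- seed
    rownames(out) <- NULL
    out
  })
}

#' Write a ground-truth manifest as JSON
#'
#' Records the planted parameters (per-drug Dm and m, alpha, noise, layout,
#' seed) alongside a generated dataset.
#'
#' @param truth A [synthetic_truth()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth manifest written by [write_truth_manifest()]
#'
#' @param path JSON path.
#' @return A `synthetic_truth` object.
#' @export
read_truth_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_truth(drug_a = as.list(x$drug_a), drug_b = as.list(x$drug_b),
                  alpha = x$alpha, sigma_viability = x$sigma_viability,
                  doses_a = x$doses_a, doses_b = x$doses_b,
                  replicates = x$replicates, trials = x$trials,
                  schedule_alpha_multipliers =
                    unlist(x$schedule_alpha_multipliers),
                  seed = x$seed)
}
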