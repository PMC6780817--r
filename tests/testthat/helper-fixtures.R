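# Shared fixtures for the test suite. All data are generated in code.

# 8-dose series centred on a target IC50, spanning fa ~0.1-0.9 for m = 2:
# the identifiable range, where logit-scale noise stays moderate (see the
# methods vignette on dose placement)
identifiable_doses <- function(center) center * 1.4^seq(-3.5, 3.5, by = 1)

# shared-slope pair: the regime in which the constant-ratio Loewe mixture is
# itself a median-effect curve, so the planted interaction level is the true
# CI of the fitted model class at every fa (see the methods vignette).
shared_slope_truth <- function(alpha = 1, sigma = 0, trials = 1, seed = 1,
                               m = 2) {
  synthetic_truth(drug_a = list(label = "A", Dm = 6, m = m),
                  drug_b = list(label = "B", Dm = 356, m = m),
                  alpha = alpha, sigma_viability = sigma,
                  doses_a = identifiable_doses(6),
                  doses_b = identifiable_doses(356),
                  trials = trials, seed = seed)
}

# paper-like unequal-slope pair (steep potent agent vs shallow one)
paper_like_truth <- function(alpha = 1, sigma = 3, trials = 3, seed = 1) {
  synthetic_truth(alpha = alpha, sigma_viability = sigma,
                  trials = trials, seed = seed)
}

design_1_60 <- function(schedule = "simultaneous") {
  combination_design("A", "B", 1L, 60L, schedule)
}

# mixture dose series centred on the planted mixture IC50
combo_dose_series <- function(truth, design) {
  fit_a <- median_effect_fit(truth$drug_a$Dm, truth$drug_a$m)
  fit_b <- median_effect_fit(truth$drug_b$Dm, truth$drug_b$m)
  fr_a <- design$ratio_a / (design$ratio_a + design$ratio_b)
  dmix <- 1 / (fr_a / dose_for_effect(fit_a, 0.5) +
                 (1 - fr_a) / dose_for_effect(fit_b, 0.5))
  mult <- truth$schedule_alpha_multipliers
  alpha_eff <- truth$alpha *
    (if (design$schedule %in% names(mult)) mult[[design$schedule]] else 1)
  identifiable_doses(alpha_eff * dmix)
}

# generate -> fit -> CI pipeline under a planted truth
recovered_ci <- function(truth, design, clip = "exclude",
                         fa_levels = c(0.5, 0.75, 0.9, 0.95)) {
  plate <- generate_combination_plate(truth, design,
                                      total_doses = combo_dose_series(truth, design))
  analyze_combination(plate, design, fa_levels = fa_levels, clip = clip)
}

# post-treatment normalized trace for one well, as time/cell_index frame
well_trace <- function(norm, well_id, t_treat = 24) {
  norm[norm$well == well_id & norm$time_h >= t_treat,
       c("time_h", "cell_index")]
}
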