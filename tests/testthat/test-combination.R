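test_that("sham combination of a drug with itself yields CI = 1 at every level", {
  withr::with_seed(5, {
    for (i in 1:20) {
      fit <- median_effect_fit(10^runif(1, -1, 3), runif(1, 0.3, 4), "X")
      des <- combination_design("X", "X", sample(1:50, 1), sample(1:50, 1))
      prof <- combination_index(fit, fit, fit, des,
                                fa_levels = runif(4, 0.02, 0.98))
      expect_equal(unname(prof$ci_mean), rep(1, 4), tolerance = 1e-6)
    }
  })
})

test_that("CI classification matches the synergism/additivity/antagonism rule", {
  expect_equal(classify_ci(c(0.524, 1.000, 1.974)),
               c("synergism", "additivity", "antagonism"))
  expect_equal(classify_ci(0.95), "additivity")
  expect_equal(classify_ci(0.95, additivity_band = c(0.99, 1.01)), "synergism")
  expect_error(classify_ci(-1), "positive")
})

test_that("noise-free additive data give CI = 1 and planted alpha is recovered", {
  des <- design_1_60()
  prof <- recovered_ci(shared_slope_truth(alpha = 1), des)
  expect_equal(unname(prof$ci_mean), rep(1, 4), tolerance = 0.01)
  expect_equal(unname(prof$classification), rep("additivity", 4))

  prof_syn <- recovered_ci(shared_slope_truth(alpha = 0.5), des)
  expect_true(all(prof_syn$ci_mean > 0.45 & prof_syn$ci_mean < 0.55))
  expect_equal(unname(prof_syn$classification), rep("synergism", 4))
})

test_that("DRI obeys its algebraic identity and the sham halves doses", {
  f <- median_effect_fit(12, 1.3, "X")
  des <- combination_design("X", "X", 1L, 1L)
  dri <- dose_reduction_index(f, f, f, des, 0.7)
  expect_equal(dri$dri_a, 2, tolerance = 1e-9)
  expect_equal(dri$dri_b, 2, tolerance = 1e-9)

  withr::with_seed(8, {
    for (i in 1:50) {
      fa_ <- median_effect_fit(10^runif(1, -1, 3), runif(1, 0.3, 4), "A")
      fb_ <- median_effect_fit(10^runif(1, -1, 3), runif(1, 0.3, 4), "B")
      fc_ <- median_effect_fit(10^runif(1, -1, 3), runif(1, 0.3, 4), "C")
      des <- combination_design("A", "B", sample(1:100, 1), sample(1:100, 1))
      fa_level <- runif(1, 0.05, 0.95)
      dri <- dose_reduction_index(fa_, fb_, fc_, des, fa_level)
      ci <- combination_index(fa_, fb_, fc_, des, fa_levels = fa_level)$ci_mean
      expect_equal(1 / dri$dri_a + 1 / dri$dri_b, unname(ci), tolerance = 1e-9)
    }
  })
})

test_that("planted symmetric synergy doubles both dose reductions", {
  # identical drugs at 1:1 with alpha = 0.5: CI = 0.5 split evenly -> DRI = 4
  truth <- synthetic_truth(drug_a = list(label = "A", Dm = 6, m = 2),
                           drug_b = list(label = "B", Dm = 6, m = 2),
                           alpha = 0.5, sigma_viability = 0, trials = 1)
  des <- combination_design("A", "B", 1L, 1L)
  plate <- generate_combination_plate(truth, des,
                                      total_doses = 6 * 2^seq(-3, 3))
  fr <- fit_dose_response(plate, clip = "exclude")
  dri <- dose_reduction_index(fr$fits$A[[1]], fr$fits$B[[1]],
                              fr$fits[["A+B"]][[1]], des, 0.5)
  expect_equal(dri$dri_a, 4, tolerance = 1e-6)
  expect_equal(dri$dri_b, 4, tolerance = 1e-6)
})

test_that("isobole coordinates carry the CI and the additive point sits on the line", {
  fit_a <- median_effect_fit(6, 2, "A")
  fit_b <- median_effect_fit(356, 1, "B")
  expect_error(isobologram(fit_a, fit_b, list(), fa = 1.2), "inside")

  # a-axis intercept at 95% inhibition for Dm = 6, m = 2
  iso <- isobologram(fit_a, fit_b,
                     list(list(fit_combo = median_effect_fit(180, 1.5, "A+B"),
                               design = design_1_60())), fa = 0.95)
  expect_equal(iso$intercepts$dose_nM[1], 6 * sqrt(19), tolerance = 1e-9)
  expect_equal(iso$points$norm_a + iso$points$norm_b, iso$points$ci,
               tolerance = 1e-12)

  # additive noise-free combo: normalized coordinates sum to 1
  des <- design_1_60()
  plate <- generate_combination_plate(shared_slope_truth(alpha = 1), des)
  fr <- fit_dose_response(plate, clip = "exclude")
  iso1 <- isobologram(fr$fits$A[[1]], fr$fits$B[[1]],
                      list(list(fit_combo = fr$fits[["A+B"]][[1]],
                                design = des)), fa = 0.95)
  expect_equal(iso1$points$norm_a + iso1$points$norm_b, 1, tolerance = 0.01)

  # planted alpha = 0.5: point falls below the additivity line
  plate05 <- generate_combination_plate(shared_slope_truth(alpha = 0.5), des)
  fr05 <- fit_dose_response(plate05, clip = "exclude")
  iso05 <- isobologram(fr05$fits$A[[1]], fr05$fits$B[[1]],
                       list(list(fit_combo = fr05$fits[["A+B"]][[1]],
                                 design = des)), fa = 0.95)
  expect_equal(iso05$points$norm_a + iso05$points$norm_b, 0.5, tolerance = 0.01)
})

test_that("curve-shift table splits total dose by the ratio and shows enhancement", {
  fit_a <- median_effect_fit(6, 2, "A")
  fit_b <- median_effect_fit(356, 1, "B")
  des <- combination_design("A", "B", 1L, 50L)
  pts <- data.frame(dose_nM = 318.75, viability_pct = 40)
  tab <- curve_shift_table(fit_a, fit_b, pts, des)
  expect_equal(tab$component_dose_nM[tab$component == "a"], 6.25)
  expect_equal(tab$component_dose_nM[tab$component == "b"], 312.5)

  # synergistic surface: observed mixture viability lower than each drug alone
  truth <- shared_slope_truth(alpha = 0.5)
  plate <- generate_combination_plate(truth, des, include_singles = FALSE)
  mid <- plate[plate$dose_nM > 30 & plate$dose_nM < 3000 & plate$replicate == 1, ]
  tab2 <- curve_shift_table(fit_a, fit_b,
                            data.frame(dose_nM = mid$dose_nM,
                                       viability_pct = mid$viability_pct), des)
  expect_true(all(tab2$viability_pct < tab2$single_agent_viability_pct))

  # degenerate ratio 1:0 reduces to the single-agent curve
  des10 <- combination_design("A", "B", 1L, 0L)
  d <- 6 * 2^seq(-2, 2)
  pts10 <- data.frame(dose_nM = d,
                      viability_pct = 100 * (1 - effect_at_dose(fit_a, d)))
  tab10 <- curve_shift_table(fit_a, fit_b, pts10, des10)
  expect_equal(unique(tab10$component), "a")
  expect_equal(tab10$viability_pct, tab10$single_agent_viability_pct,
               tolerance = 1e-9)
})

test_that("potency ratio reproduces the ~60-fold worked example and rounding rule", {
  pr <- potency_ratio(median_effect_fit(6, 2, "RM"),
                      median_effect_fit(356, 1, "DOX"))
  expect_equal(pr$ratio, 356 / 6, tolerance = 1e-9)
  expect_equal(pr$equipotent, c(1L, 60L))
  f <- median_effect_fit(10, 1)
  expect_equal(potency_ratio(f, f)$equipotent, c(1L, 1L))
  # round-half-up at the tens boundary
  expect_equal(potency_ratio(median_effect_fit(10, 1),
                             median_effect_fit(449, 1))$equipotent, c(1L, 40L))
  expect_equal(potency_ratio(median_effect_fit(10, 1),
                             median_effect_fit(450, 1))$equipotent, c(1L, 50L))
})

test_that("summary report orders rows, labels cells, and validates inputs", {
  des <- design_1_60()
  prof_add <- recovered_ci(shared_slope_truth(alpha = 1), des)
  rep1 <- ci_summary_report(list(prof_add))
  expect_equal(unname(unlist(rep1[1, grep("^class_", names(rep1))])),
               rep("additivity", 4))

  # schedule-modulated alpha reproduces the regimen ordering
  truth <- shared_slope_truth(alpha = 0.6)
  truth$schedule_alpha_multipliers <-
    c(simultaneous = 1.0, a_then_b = 1.6, b_then_a = 3.0)
  profs <- lapply(c("b_then_a", "a_then_b", "simultaneous"), function(s) {
    recovered_ci(truth, design_1_60(schedule = s))
  })
  rep3 <- ci_summary_report(profs)
  expect_equal(rep3$schedule, c("simultaneous", "a_then_b", "b_then_a"))
  expect_equal(rep3$class_ic50,
               c("synergism", "additivity", "antagonism"))

  expect_error(combination_index(prof_add, prof_add, prof_add, des,
                                 fa_levels = numeric(0)), "non-empty")
  expect_error(ci_summary_report(list()), "length")
})

test_that("checkerboard summary compares cells with margins and flags enhancement", {
  # drug b inert: every interior cell equals its drug-a margin
  doses <- c(0, 1, 10, 100)
  grid <- expand.grid(dose_a_nM = doses, dose_b_nM = doses)
  grid$viability_pct <- 100 / (1 + (grid$dose_a_nM / 10)^1)
  cs <- checkerboard_summary(grid)
  expect_equal(cs$diff_vs_a, rep(0, nrow(cs)), tolerance = 1e-9)
  expect_false(any(cs$enhanced))

  # planted synergy flags interior cells
  cb <- generate_checkerboard(shared_slope_truth(alpha = 0.5, trials = 3))
  cs2 <- checkerboard_summary(cb)
  expect_true(all(cs2$enhanced))

  expect_error(checkerboard_summary(
    data.frame(dose_a_nM = 1, dose_b_nM = 1, viability_pct = 50)),
    "margins")
})

test_that("combination_index validates labels and recycles per-trial fits", {
  fit <- median_effect_fit(6, 2, "A")
  des <- design_1_60()
  plate <- generate_combination_plate(shared_slope_truth(alpha = 1, trials = 2,
                                                         sigma = 2), des)
  prof <- analyze_combination(plate, des)
  expect_equal(prof$n_trials, 2L)
  expect_equal(dim(prof$ci), c(2L, 4L))
  expect_true(all(prof$ci_sem >= 0))
  expect_error(analyze_combination(plate, combination_design("A", "Z", 1, 60)),
               "label mismatch")
  expect_error(combination_index(list(fit, fit), list(fit, fit, fit), fit, des),
               "equal length")
})
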