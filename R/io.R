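# File I/O: tidy CSV dialects for dose-response tables and impedance
# traces, JSON serialization of fits, and report writers.

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

check_numeric <- function(df, cols, path) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "")
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value in column '%s' at data line(s) %s",
                   path, cl, paste(utils::head(bad + 1L, 5), collapse = ", ")),
           call. = FALSE)
    }
    df[[cl]] <- v
  }
  df
}

#' Read a tidy dose-response CSV
#'
#' Expected dialect: comma-separated, header required, '.' decimal, columns
#' `drug`, `dose_nM`, `trial`, `replicate` and either `viability_pct` or the
#' absorbance triple `absorbance_treated`, `absorbance_vehicle`,
#' `absorbance_media` (converted with [viability_from_absorbance()]).
#'
#' @param path CSV path.
#' @return Data frame with a `viability_pct` column.
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) stop(sprintf("%s: file not found", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(sprintf("%s: no data rows", path), call. = FALSE)
  require_columns(df, c("drug", "dose_nM", "trial", "replicate"), path)
  if ("viability_pct" %in% names(df)) {
    df <- check_numeric(df, c("dose_nM", "viability_pct"), path)
  } else {
    abs_cols <- c("absorbance_treated", "absorbance_vehicle", "absorbance_media")
    require_columns(df, abs_cols, path)
    df <- check_numeric(df, c("dose_nM", abs_cols), path)
    df$viability_pct <- as.numeric(viability_from_absorbance(
      df$absorbance_treated, df$absorbance_vehicle, df$absorbance_media))
  }
  df
}

#' Read a tidy cell-index trace CSV
#'
#' Long format: columns `time_h`, `well`, `drug`, `dose_nM`, `cell_index`.
#'
#' @param path CSV path.
#' @return Data frame of traces.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("%s: file not found", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(sprintf("%s: no data rows", path), call. = FALSE)
  require_columns(df, c("time_h", "well", "drug", "dose_nM", "cell_index"), path)
  check_numeric(df, c("time_h", "dose_nM", "cell_index"), path)
}

#' Fit the median-effect model per drug and trial
#'
#' Pools replicate wells within each drug x trial stratum (fa computed per
#' well) and fits one median-effect curve per stratum; per-trial fits are
#' kept separate so that downstream combination indices can be summarised
#' as mean +/- SEM across trials. Vehicle (dose 0) and media wells are
#' excluded from the fits.
#'
#' @param data Tidy dose-response data frame (see [read_dose_response()]).
#' @param eps,clip Passed to [fit_median_effect()].
#' @return List with `fits` (named list: drug -> list of per-trial fits) and
#'   `summary` (data frame: drug, trial, Dm, m, r, n_points).
#' @export
fit_dose_response <- function(data, eps = 0.005, clip = c("retain", "exclude")) {
  clip <- match.arg(clip)
  stopifnot(is.data.frame(data),
            all(c("drug", "dose_nM", "trial", "viability_pct") %in% names(data)))
  if ("well_type" %in% names(data)) {
    data <- data[!data$well_type %in% c("vehicle", "media"), , drop = FALSE]
  }
  data <- data[data$dose_nM > 0 & !is.na(data$viability_pct), , drop = FALSE]
  fits <- list()
  rows <- list()
  for (dr in unique(data$drug)) {
    sub <- data[data$drug == dr, , drop = FALSE]
    per_trial <- lapply(sort(unique(sub$trial)), function(tr) {
      s <- sub[sub$trial == tr, , drop = FALSE]
      fit_median_effect(s$dose_nM, viability = s$viability_pct,
                        drug_label = dr, eps = eps, clip = clip)
    })
    fits[[dr]] <- per_trial
    rows[[dr]] <- do.call(rbind, lapply(seq_along(per_trial), function(i) {
      f <- per_trial[[i]]
      data.frame(drug = dr, trial = sort(unique(sub$trial))[i],
                 Dm_nM = f$Dm, m = f$m, r = f$r, n_points = f$n_points)
    }))
  }
  list(fits = fits, summary = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Serialize median-effect fits to JSON
#'
#' @param fits A `median_effect_fit`, or a (possibly nested) list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  flatten <- function(x) {
    if (inherits(x, "median_effect_fit")) return(list(x))
    do.call(c, lapply(x, flatten))
  }
  recs <- lapply(unname(flatten(fits)), function(f) {
    list(drug_label = f$drug_label, Dm = f$Dm, m = f$m, r = f$r,
         n_points = f$n_points)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tidy fa-CI series of a CI profile (for external plotting)
#'
#' @param profile A `ci_profile`.
#' @return Data frame with `fa`, `ci_mean`, `ci_sem`, `classification`.
#' @export
fa_ci_plot_data <- function(profile) {
  stopifnot(inherits(profile, "ci_profile"))
  data.frame(fa = profile$fa_levels,
             ci_mean = unname(profile$ci_mean),
             ci_sem = unname(profile$ci_sem),
             classification = unname(profile$classification))
}

#' Write a classification report as CSV or JSON
#'
#' @param report Data frame from [ci_summary_report()].
#' @param path Output path; format chosen by extension (.csv or .json).
#' @return `path`, invisibly.
#' @export
write_ci_report <- function(report, path) {
  stopifnot(is.data.frame(report))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}

#' Full combination analysis from a tidy plate table
#'
#' Convenience pipeline: fits the median-effect model per trial for both
#' single agents and the constant-ratio mixture (identified by the label
#' `"<drug_a>+<drug_b>"` on total molar dose), then computes the
#' combination-index profile across trials.
#'
#' @param data Tidy plate data frame containing both single-agent series and
#'   the mixture series (e.g. from [generate_combination_plate()] or
#'   [read_dose_response()]).
#' @param design A [combination_design()] whose drug labels match the data.
#' @param fa_levels,additivity_band Passed to [combination_index()].
#' @param eps,clip Passed to [fit_median_effect()].
#' @return A `ci_profile`.
#' @export
analyze_combination <- function(data, design,
                                fa_levels = c(0.5, 0.75, 0.9, 0.95),
                                additivity_band = c(0.90, 1.10),
                                eps = 0.005, clip = c("retain", "exclude")) {
  clip <- match.arg(clip)
  stopifnot(inherits(design, "combination_design"))
  combo_label <- paste(design$drug_a, design$drug_b, sep = "+")
  labels <- unique(data$drug)
  need <- c(design$drug_a, design$drug_b, combo_label)
  if (!all(need %in% labels)) {
    stop(sprintf("drug label mismatch: data lacks %s",
                 paste(setdiff(need, labels), collapse = ", ")), call. = FALSE)
  }
  fr <- fit_dose_response(data, eps = eps, clip = clip)
  combination_index(fr$fits[[design$drug_a]], fr$fits[[design$drug_b]],
                    fr$fits[[combo_label]], design,
                    fa_levels = fa_levels, additivity_band = additivity_band)
}
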