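# Real-time (impedance) cytotoxicity analysis: cell-index normalization,
# time-resolved IC50 via the four-parameter logistic, and kinetic-shape
# classification.

#' Normalize cell-index traces to the time of compound addition
#'
#' Divides every value of each well's trace by that well's cell index at the
#' grid point nearest to `t_treat`, so the normalized index is 1 at
#' treatment. Idempotent and invariant to per-well scaling.
#'
#' @param traces Long data frame with columns `time_h`, `well`,
#'   `cell_index` (other columns carried through).
#' @param t_treat Treatment time in hours.
#' @return The same data frame with `cell_index` normalized per well.
#' @export
normalize_cell_index <- function(traces, t_treat) {
  stopifnot(is.data.frame(traces),
            all(c("time_h", "well", "cell_index") %in% names(traces)),
            length(t_treat) == 1L, is.finite(t_treat))
  out <- traces
  for (w in unique(out$well)) {
    idx <- out$well == w
    tt <- out$time_h[idx]
    if (is.unsorted(tt, strictly = TRUE)) {
      stop(sprintf("well %s: times must be strictly increasing", w), call. = FALSE)
    }
    ref <- out$cell_index[idx][which.min(abs(tt - t_treat))]
    if (!is.finite(ref) || ref <= 0) {
      stop(sprintf("degenerate well %s: non-positive cell index at treatment time", w),
           call. = FALSE)
    }
    out$cell_index[idx] <- out$cell_index[idx] / ref
  }
  out
}

# snapshot of per-dose mean normalized index at the grid time nearest t
snapshot_at_time <- function(traces, t) {
  tt <- unique(traces$time_h)
  t_near <- tt[which.min(abs(tt - t))]
  snap <- traces[traces$time_h == t_near, , drop = FALSE]
  stats::aggregate(cell_index ~ dose_nM, snap, mean)
}

#' Time-resolved IC50 at a single time point
#'
#' Fits the sigmoidal dose-response (variable slope) model — the
#' four-parameter logistic
#' `y = bottom + (top - bottom) / (1 + (d / ic50)^hill)` — to the
#' normalized cell index versus dose at the grid time nearest `t`.
#' By default the top plateau is anchored to the vehicle (dose 0) level.
#' Time points with no dose-response gradient, a non-converging fit, or an
#' IC50 far outside the tested dose range are flagged undefined rather than
#' fabricated.
#'
#' @param traces Normalized long traces with columns `time_h`, `dose_nM`,
#'   `cell_index`; dose 0 rows are the vehicle.
#' @param t Hours (nearest grid point is used).
#' @param anchor_top Fix the top plateau at the vehicle level (default TRUE).
#' @param min_span Minimum dose-response span, as a fraction of the top
#'   level, below which the fit is flagged `"no_gradient"` (default 0.1).
#' @return List with `ic50` (nM or NA), `status` (`"ok"`, `"no_gradient"`,
#'   `"no_convergence"`, `"out_of_range"`), `time_h` (grid time used) and
#'   `pars` (fitted 4PL parameters when available).
#' @export
ic50_at_time <- function(traces, t, anchor_top = TRUE, min_span = 0.1) {
  stopifnot(is.data.frame(traces),
            all(c("time_h", "dose_nM", "cell_index") %in% names(traces)))
  snap <- snapshot_at_time(traces, t)
  t_used <- unique(traces$time_h)[which.min(abs(unique(traces$time_h) - t))]
  if (!any(snap$dose_nM == 0)) stop("vehicle (dose 0) trace required", call. = FALSE)
  top_level <- snap$cell_index[snap$dose_nM == 0]
  dosed <- snap[snap$dose_nM > 0, , drop = FALSE]
  if (nrow(dosed) < 4L) stop("need at least 4 distinct positive doses", call. = FALSE)
  undefined <- function(status) list(ic50 = NA_real_, status = status,
                                     time_h = t_used, pars = NULL)
  span <- (max(c(dosed$cell_index, top_level)) - min(dosed$cell_index)) / top_level
  if (!is.finite(span) || span < min_span) return(undefined("no_gradient"))
  d <- dosed$dose_nM; y <- dosed$cell_index
  mid <- (top_level + min(y)) / 2
  start_l <- log10(d[which.min(abs(y - mid))])
  # start strictly inside the box: LM stalls when started on a bound
  start_b <- min(max(min(y), 0.01 * top_level), 0.95 * top_level)
  model <- function(p) {
    top <- if (anchor_top) top_level else p[["top"]]
    p[["bottom"]] + (top - p[["bottom"]]) /
      (1 + 10^((log10(d) - p[["lic50"]]) * p[["hill"]]))
  }
  start <- c(bottom = start_b, lic50 = start_l, hill = 1)
  lower <- c(bottom = 0, lic50 = log10(min(d)) - 3, hill = -20)
  upper <- c(bottom = top_level, lic50 = log10(max(d)) + 3, hill = 20)
  if (!anchor_top) {
    start <- c(start, top = top_level)
    lower <- c(lower[1:3], top = 0); lower[["bottom"]] <- 0
    upper <- c(upper[1:3], top = Inf); upper[["bottom"]] <- Inf
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = function(p) y - model(p),
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(undefined("no_convergence"))
  pars <- as.list(fit$par)
  ic50 <- 10^pars$lic50
  # a crossing must lie within a decade of the tested range to be credible
  if (ic50 < min(d) / 10 || ic50 > max(d) * 10 || pars$hill <= 0) {
    return(undefined("out_of_range"))
  }
  list(ic50 = ic50, status = "ok", time_h = t_used, pars = pars)
}

#' IC50 time course over a grid of post-treatment times
#'
#' Evaluates [ic50_at_time()] at each requested time and returns a tidy
#' series; undefined time points keep their status flag and an NA IC50.
#'
#' @inheritParams ic50_at_time
#' @param time_grid Hours at which to estimate the IC50.
#' @return Data frame of class `time_resolved_ic50` with `time_h`,
#'   `ic50_nM`, `status`.
#' @export
ic50_timecourse <- function(traces, time_grid, anchor_top = TRUE,
                            min_span = 0.1) {
  rows <- lapply(time_grid, function(t) {
    r <- ic50_at_time(traces, t, anchor_top = anchor_top, min_span = min_span)
    data.frame(time_h = r$time_h, ic50_nM = r$ic50, status = r$status)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time_h = numeric(), ic50_nM = numeric(), status = character())
  class(out) <- c("time_resolved_ic50", class(out))
  out
}

#' Classify the kinetic shape of a normalized trace
#'
#' Distinguishes the impedance signatures seen after cytotoxic treatment:
#' * `dna_damage_like` — a transient rise above the vehicle trace (the
#'   senescence-associated size/attachment increase typical of DNA-damaging
#'   agents) followed by a decline below the treatment-time level;
#' * `direct_kill` — decline below the treatment-time level without ever
#'   exceeding the vehicle;
#' * `cytostatic` — the trace plateaus near its treatment-time level;
#' * `none` — none of the above (e.g. growth tracking the vehicle).
#'
#' Both traces must be normalized to the treatment time (level 1) and are
#' compared on their common post-treatment time grid.
#'
#' @param trace,vehicle Data frames with `time_h` and `cell_index`
#'   (normalized; one well or a per-dose average).
#' @param rise_threshold Fractional excess over the vehicle that counts as a
#'   rise (default 0.05).
#' @param rise_sustain_h Minimum duration of the rise in hours (default 2).
#' @param decline_threshold Fractional drop below the treatment-time level
#'   that counts as a decline (default 0.20).
#' @param plateau_band Half-width of the band around 1 within which the
#'   trace's endpoint counts as a plateau (default 0.15).
#' @return One of `"dna_damage_like"`, `"direct_kill"`, `"cytostatic"`,
#'   `"none"`.
#' @export
classify_kinetic_shape <- function(trace, vehicle,
                                   rise_threshold = 0.05,
                                   rise_sustain_h = 2,
                                   decline_threshold = 0.20,
                                   plateau_band = 0.15) {
  stopifnot(is.data.frame(trace), is.data.frame(vehicle),
            all(c("time_h", "cell_index") %in% names(trace)),
            all(c("time_h", "cell_index") %in% names(vehicle)))
  common <- intersect(trace$time_h, vehicle$time_h)
  if (length(common) < 3L) {
    stop("trace and vehicle time grids share fewer than 3 points", call. = FALSE)
  }
  common <- sort(common)
  x <- trace$cell_index[match(common, trace$time_h)]
  v <- vehicle$cell_index[match(common, vehicle$time_h)]
  above <- x > (1 + rise_threshold) * v
  rise <- FALSE
  if (any(above)) {
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in which(runs$values)) {
      if (common[ends[i]] - common[starts[i]] >= rise_sustain_h) rise <- TRUE
    }
  }
  peak <- which.max(x)
  decline <- any(x[peak:length(x)] < 1 - decline_threshold)
  if (rise && decline) return("dna_damage_like")
  if (decline && !rise) return("direct_kill")
  tail_mean <- mean(x[max(1L, length(x) - 4L):length(x)])
  if (abs(tail_mean - 1) <= plateau_band) return("cytostatic")
  "none"
}
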