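#' Linear fit of a strain-volume loop
#'
#' Fits the single regression line `strain = k * volume + c` by ordinary
#' least squares over all points of the loop (systolic and diastolic limbs
#' pooled) and reports the slope `k` (%/mL), intercept `c` (%) and the
#' coefficient of determination, interpreted as the degree of
#' systolic-diastolic coupling (R2-S/D coupling): values near 1 mean
#' shortening and relengthening track volume reduction and refilling along
#' one line; low values mean the two limbs diverge — wasted myocardial
#' work. Degenerate loops with zero strain variance (a non-deforming
#' segment) return slope 0 and R2 0; zero volume variance is an error.
#'
#' @param loop an [build_loop()] result, or any data frame with `volume`
#'   and `strain` columns.
#' @param per_limb if `TRUE`, additionally returns separate systolic- and
#'   diastolic-limb fits as a diagnostic (`$systolic`, `$diastolic`).
#'
#' @return A list of class `loop_fit`: `slope`, `intercept`,
#'   `r2_sd_coupling`, `n_points`, `loop_kind`.
#' @examples
#' loop <- build_loop(strain = 0.5 * c(100, 80, 60, 80) - 40,
#'                    volume = c(100, 80, 60, 80), es_index = 3)
#' fit_loop(loop)  # slope 0.5, intercept -40, R2 = 1
#' @export
fit_loop <- function(loop, per_limb = FALSE) {
  x <- loop$volume
  y <- loop$strain
  n <- length(x)
  if (n < 3L) stop("a loop fit needs at least 3 points (got ", n, ")")
  if (var(x) == 0) {
    stop("volume values are all identical; a strain-volume loop needs ",
         "volume variation")
  }
  if (var(y) == 0) {
    fit <- list(slope = 0, intercept = mean(y), r2_sd_coupling = 0,
                n_points = n, loop_kind = attr(loop, "loop_kind"),
                degenerate = "zero strain variance")
  } else {
    m <- lm(y ~ x)
    r2 <- 1 - sum(m$residuals^2) / sum((y - mean(y))^2)
    fit <- list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
                r2_sd_coupling = r2, n_points = n,
                loop_kind = attr(loop, "loop_kind"), degenerate = NULL)
  }
  if (isTRUE(per_limb) && !is.null(loop$limb)) {
    for (limb in c("systolic", "diastolic")) {
      sub <- loop[loop$limb == limb, , drop = FALSE]
      fit[[limb]] <- if (nrow(sub) >= 3L && var(sub$volume) > 0) {
        Recall(sub, per_limb = FALSE)
      }
    }
  }
  class(fit) <- "loop_fit"
  fit
}

#' @export
print.loop_fit <- function(x, ...) {
  cat("<loop_fit>", if (!is.null(x$loop_kind)) x$loop_kind, "\n")
  cat(sprintf("  slope k = %.4g %%/mL, intercept c = %.4g %%\n",
              x$slope, x$intercept))
  cat(sprintf("  R2-S/D coupling = %.4f over %d points\n",
              x$r2_sd_coupling, x$n_points))
  if (!is.null(x$degenerate)) cat("  degenerate:", x$degenerate, "\n")
  invisible(x)
}

#' Peak strain of a trace
#'
#' The peak is the extreme shortening value, i.e. the signed minimum of the
#' strain trace (peaks are negative); ties return the earliest time.
#'
#' @param values strain trace (%).
#' @param times matching time grid (ms); defaults to frame indices.
#' @param window `"full"` searches the whole cycle (default), `"systole"`
#'   restricts the search to frames up to `es_index`.
#' @param es_index required when `window = "systole"`.
#' @return A list with `value` (%), `time` (ms) and `frame`.
#' @export
peak_strain <- function(values, times = seq_along(values) - 1,
                        window = c("full", "systole"), es_index = NULL) {
  window <- match.arg(window)
  if (length(values) == 0L) stop("empty strain trace")
  if (window == "systole") {
    if (is.null(es_index)) stop("`es_index` needed for window = \"systole\"")
    values <- values[seq_len(es_index)]
    times <- times[seq_len(es_index)]
  }
  i <- which.min(values)
  list(value = values[i], time = times[i], frame = i)
}

#' Strain delay index (SDI)
#'
#' Sum over the 16 segments of the difference between peak and
#' end-systolic principal strain, `sum_i (peakPS_i - PS_i(ES))`. Since the
#' peak (most negative) strain is never above the end-systolic strain the
#' sum is `<= 0`; the magnitude measures shortening that does not
#' contribute to end-systolic deformation (wasted work). `abs = TRUE`
#' reports the magnitude instead.
#'
#' @param strain `n_frames x 16` segmental strain matrix or `cycle_record`.
#' @param es_index 1-based end-systolic frame (taken from the record when a
#'   `cycle_record` is given).
#' @param abs report `|SDI|` instead of the signed value.
#' @return SDI in % (signed, `<= 0`, unless `abs = TRUE`).
#' @export
sdi <- function(strain, es_index = NULL, abs = FALSE) {
  if (inherits(strain, "cycle_record")) {
    if (is.null(es_index)) es_index <- strain$es_index
    strain <- strain$strain
  }
  strain <- as_segment_matrix(strain, "strain")
  if (is.null(es_index)) stop("`es_index` is required")
  if (es_index < 1L || es_index > nrow(strain)) stop("es_index out of range")
  peaks <- apply(strain, 2, min)
  value <- sum(peaks - strain[es_index, ])
  if (abs) base::abs(value) else value
}

#' Dyssynchrony as the segmental spread of event times (TpPS-SD%, Tmsv-SD%)
#'
#' Standard deviation across the 16 segments of the time to an event —
#' peak (minimum) strain for TpPS-SD% or minimum segmental volume for
#' Tmsv-SD% — corrected by the R-R interval:
#' `100 * SD(event times) / rr`. The SD uses the sample (n - 1)
#' denominator; ties take the earliest frame.
#'
#' @param traces `n_frames x 16` matrix of the relevant channel (strain for
#'   `event = "peak_strain"`, segmental volume for `event = "min_volume"`).
#' @param times time grid (ms).
#' @param rr R-R interval (ms), `> 0`.
#' @param event which event time to spread.
#' @return Percentage of the R-R interval (`>= 0`).
#' @export
time_sd_pct <- function(traces, times, rr,
                        event = c("peak_strain", "min_volume")) {
  event <- match.arg(event)
  if (rr <= 0) stop("rr must be > 0")
  traces <- as_segment_matrix(traces,
                              if (event == "peak_strain") "strain" else "volume")
  event_times <- times[apply(traces, 2, which.min)]
  100 * sd(event_times) / rr
}

#' Ejection fraction from the global volume trace
#'
#' @param global_volume global volume per frame (mL), or a `cycle_record`.
#' @param ed_index,es_index 1-based end-diastolic / end-systolic frames.
#' @return EF in %, `100 * (EDV - ESV) / EDV`.
#' @export
ejection_fraction <- function(global_volume, ed_index = 1L, es_index = NULL) {
  if (inherits(global_volume, "cycle_record")) {
    rec <- global_volume
    ed_index <- rec$ed_index
    if (is.null(es_index)) es_index <- rec$es_index
    global_volume <- rec$global_volume
  }
  if (is.null(es_index)) stop("`es_index` is required")
  edv <- global_volume[ed_index]
  esv <- global_volume[es_index]
  if (edv <= 0) stop("EDV must be > 0")
  100 * (edv - esv) / edv
}

#' Classify CRT response from the end-systolic volume change
#'
#' A subject is a responder when the LV end-systolic volume is reduced by
#' at least 15% at follow-up relative to baseline (the boundary 15.0% is a
#' responder). When the baseline mid-septal PS-global volume R2-S/D
#' coupling is supplied, the rule-based prediction is also reported:
#' baseline R2 below the cut-off (default 0.55, the published value)
#' predicts response — low septal coupling marks reversible wasted septal
#' work.
#'
#' @param lvesv_baseline,lvesv_followup end-systolic volumes (mL), `> 0`.
#' @param baseline_midseptal_global_r2 optional baseline R2-S/D coupling of
#'   the mid-septal PS-global volume loop.
#' @param r2_cutoff classification constant (default 0.55).
#' @return A list of class `response_assessment`: `lvesv_baseline`,
#'   `lvesv_followup`, `delta_lvesv_pct`, `responder`,
#'   `r2_rule_prediction` (`NA` when no R2 given).
#' @examples
#' classify_response(100, 85)  # delta 15% -> responder
#' @export
classify_response <- function(lvesv_baseline, lvesv_followup,
                              baseline_midseptal_global_r2 = NA_real_,
                              r2_cutoff = 0.55) {
  if (lvesv_baseline <= 0 || lvesv_followup <= 0) {
    stop("end-systolic volumes must be > 0")
  }
  delta <- 100 * (lvesv_baseline - lvesv_followup) / lvesv_baseline
  structure(
    list(lvesv_baseline = lvesv_baseline,
         lvesv_followup = lvesv_followup,
         delta_lvesv_pct = delta,
         responder = delta >= 15,
         r2_rule_prediction = if (is.na(baseline_midseptal_global_r2)) NA
                              else baseline_midseptal_global_r2 < r2_cutoff),
    class = "response_assessment"
  )
}

#' @export
print.response_assessment <- function(x, ...) {
  cat(sprintf("<response_assessment> LVESV %.1f -> %.1f mL (delta %.1f%%): %s\n",
              x$lvesv_baseline, x$lvesv_followup, x$delta_lvesv_pct,
              if (x$responder) "responder" else "non-responder"))
  if (!is.na(x$r2_rule_prediction)) {
    cat("  baseline R2 rule predicts:",
        if (x$r2_rule_prediction) "responder" else "non-responder", "\n")
  }
  invisible(x)
}

#' Per-subject derived metrics
#'
#' Computes the full metric row for one subject-visit: volumes and EF, the
#' slope and R2-S/D coupling of all five loop families, mid-septal and
#' mid-lateral peak PS, global peak PS, SDI, TpPS-SD% and Tmsv-SD%.
#'
#' @param record a `cycle_record`.
#' @param segments wall selection from [select_midwall_segments()].
#' @return One-row data frame.
#' @export
subject_metrics <- function(record, segments = select_midwall_segments()) {
  validate_cycle_record(record)
  loops <- build_loops(record, segments)
  fits <- lapply(loops, fit_loop)
  gs <- global_strain(record$strain)
  row <- data.frame(
    subject_id = record$subject_id,
    visit = record$visit,
    group = attr(record, "group") %||% NA_character_,
    rr_interval = record$rr_interval,
    edv = record$global_volume[record$ed_index],
    esv = record$global_volume[record$es_index],
    ef = ejection_fraction(record),
    stringsAsFactors = FALSE
  )
  for (kind in names(fits)) {
    row[[paste0("slope_", kind)]] <- fits[[kind]]$slope
    row[[paste0("r2_", kind)]] <- fits[[kind]]$r2_sd_coupling
  }
  row$peak_ps_midseptal <-
    peak_strain(composite_strain(record$strain, segments$midseptal))$value
  row$peak_ps_midlateral <-
    peak_strain(composite_strain(record$strain, segments$midlateral))$value
  row$global_peak_ps <- peak_strain(gs)$value
  row$sdi <- sdi(record)
  row$tpps_sd_pct <- time_sd_pct(record$strain, record$times,
                                 record$rr_interval, "peak_strain")
  row$tmsv_sd_pct <- time_sd_pct(record$seg_volume, record$times,
                                 record$rr_interval, "min_volume")
  row
}

#' Metrics table for a set of records
#'
#' @param records list of `cycle_record`s (e.g. from [simulate_cohort()]).
#' @param segments wall selection.
#' @return Data frame with one row per subject-visit.
#' @export
cohort_metrics <- function(records, segments = select_midwall_segments()) {
  do.call(rbind, lapply(records, subject_metrics, segments = segments))
}

#' Attach response labels to a baseline metrics table
#'
#' Pairs baseline and follow-up rows by `subject_id`, computes the
#' end-systolic volume change and the responder label
#' ([classify_response()]), and returns the baseline rows augmented with
#' `lvesv_followup`, `delta_lvesv_pct`, `responder` and
#' `r2_rule_prediction`. Subjects without a follow-up row (e.g. healthy
#' controls) get `NA` labels.
#'
#' @param metrics a [cohort_metrics()] table.
#' @param r2_cutoff classification constant (default 0.55).
#' @return Baseline-row data frame with response columns.
#' @export
add_response <- function(metrics, r2_cutoff = 0.55) {
  base <- metrics[metrics$visit == "baseline", , drop = FALSE]
  fu <- metrics[metrics$visit == "followup", , drop = FALSE]
  if (anyDuplicated(base$subject_id) || anyDuplicated(fu$subject_id)) {
    stop("subjects must have one baseline and at most one follow-up row")
  }
  idx <- match(base$subject_id, fu$subject_id)
  base$lvesv_followup <- fu$esv[idx]
  base$delta_lvesv_pct <- 100 * (base$esv - base$lvesv_followup) / base$esv
  base$responder <- base$delta_lvesv_pct >= 15
  base$r2_rule_prediction <- base$r2_midseptal_global < r2_cutoff
  base$r2_rule_prediction[is.na(base$responder)] <- NA
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a
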