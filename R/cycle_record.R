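#' One subject-visit of frame-by-frame LV traces
#'
#' Container for the traces exported from 3D speckle-tracking analysis of
#' one cardiac cycle: the global volume curve, 16 segmental strain curves
#' and 16 segmental volume curves, all sampled on one uniform time grid,
#' plus the R-R interval and the end-diastolic / end-systolic frame
#' indices. Frame indices are 1-based inside R (frame 1 = R wave = end
#' diastole); on-disk sidecars use 0-based frame indices (see
#' [read_cycle_record()]).
#'
#' @param times time grid (ms), strictly increasing, `>= 8` frames.
#' @param strain `n_frames x 16` matrix of segmental principal strain (%).
#' @param seg_volume `n_frames x 16` matrix of segmental volume (mL).
#' @param global_volume global LV volume (mL) per frame.
#' @param rr_interval R-R interval (ms).
#' @param es_index end-systolic frame (1-based), `1 < es_index <= n_frames`.
#' @param ed_index end-diastolic frame; fixed at 1 (cycle starts at the R
#'   wave).
#' @param subject_id,visit identifiers (`visit` is `"baseline"` or
#'   `"followup"`).
#'
#' @return A list of class `cycle_record`.
#' @export
cycle_record <- function(times, strain, seg_volume, global_volume,
                         rr_interval, es_index, ed_index = 1L,
                         subject_id = "subject", visit = "baseline") {
  rec <- structure(
    list(times = as.numeric(times),
         strain = as_segment_matrix(strain, "strain"),
         seg_volume = as_segment_matrix(seg_volume, "volume"),
         global_volume = as.numeric(global_volume),
         rr_interval = rr_interval,
         ed_index = as.integer(ed_index),
         es_index = as.integer(es_index),
         subject_id = subject_id,
         visit = visit),
    class = "cycle_record"
  )
  validate_cycle_record(rec)
  rec
}

validate_cycle_record <- function(rec) {
  n <- length(rec$times)
  if (n < 8L) stop("a cycle needs at least 8 frames (got ", n, ")")
  if (any(diff(rec$times) <= 0)) stop("time grid must be strictly increasing")
  if (nrow(rec$strain) != n || nrow(rec$seg_volume) != n ||
      length(rec$global_volume) != n) {
    stop("all traces must share the same time grid (", n, " frames)")
  }
  if (anyNA(rec$strain) || anyNA(rec$seg_volume) || anyNA(rec$global_volume)) {
    stop("traces contain missing values")
  }
  if (rec$rr_interval <= 0) stop("rr_interval must be > 0")
  if (rec$ed_index != 1L) stop("ed_index must be 1 (cycle starts at the R wave)")
  if (rec$es_index <= rec$ed_index || rec$es_index > n) {
    stop("es_index must satisfy 1 < es_index <= n_frames")
  }
  invisible(rec)
}

#' @export
print.cycle_record <- function(x, ...) {
  cat("<cycle_record> ", x$subject_id, " [", x$visit, "]\n", sep = "")
  cat("  frames: ", length(x$times), " over R-R ", x$rr_interval, " ms; ",
      "ES frame ", x$es_index, "\n", sep = "")
  cat("  EDV ", format(x$global_volume[x$ed_index], digits = 4), " mL, ",
      "volume at ES ", format(x$global_volume[x$es_index], digits = 4),
      " mL\n", sep = "")
  invisible(x)
}

#' Global principal strain from segmental curves
#'
#' Global PS at each frame is the arithmetic mean of the 16 segmental
#' strain components.
#'
#' @param strain an `n_frames x 16` segmental strain matrix or a
#'   `cycle_record`.
#' @return Numeric vector of global PS (%) per frame.
#' @examples
#' global_strain(matrix(-10, 20, 16))  # constant -10
#' @export
global_strain <- function(strain) {
  if (inherits(strain, "cycle_record")) strain <- strain$strain
  rowMeans(as_segment_matrix(strain, "strain"))
}

#' Locate the end-systolic frame from the global volume curve
#'
#' Surrogate ES detection when no ECG annotation is available: the frame of
#' minimum global volume (first frame on ties).
#'
#' @param global_volume numeric vector of global volume per frame.
#' @return 1-based frame index.
#' @export
detect_es_index <- function(global_volume) {
  which.min(global_volume)
}
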