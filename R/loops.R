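#' Build one strain-volume loop
#'
#' Pairs a strain trace (y axis, %) with a volume trace (x axis, mL) frame
#' by frame to form the per-cycle strain-volume loop, and partitions the
#' points into the systolic and diastolic limbs at the end-systolic frame
#' (the ES frame itself belongs to systole). If the two traces are sampled
#' on different time grids the volume trace is linearly interpolated onto
#' the strain grid first; grids equal within 1e-6 ms are treated as
#' identical.
#'
#' @param strain numeric vector of strain values, or a two-column
#'   `data.frame`/matrix `(time_ms, value)`.
#' @param volume numeric vector of volume values on the same grid, or a
#'   two-column `(time_ms, value)` table on its own grid.
#' @param es_index 1-based end-systolic frame index on the strain grid.
#' @param loop_kind one of `"global_global"`, `"midseptal_global"`,
#'   `"midlateral_global"`, `"midseptal_segmental"`,
#'   `"midlateral_segmental"`.
#'
#' @return A data frame of class `sv_loop` with columns `frame`, `volume`,
#'   `strain`, `limb` and attributes `loop_kind` and `es_index`.
#' @examples
#' loop <- build_loop(strain = c(0, -5, -10, -5), volume = c(100, 80, 60, 80),
#'                    es_index = 3, loop_kind = "global_global")
#' @export
build_loop <- function(strain, volume, es_index,
                       loop_kind = c("global_global", "midseptal_global",
                                     "midlateral_global",
                                     "midseptal_segmental",
                                     "midlateral_segmental")) {
  loop_kind <- match.arg(loop_kind)
  if (is.matrix(strain)) strain <- as.data.frame(strain)
  if (is.matrix(volume)) volume <- as.data.frame(volume)
  strain_t <- NULL
  if (is.data.frame(strain)) {
    strain_t <- as.numeric(strain[[1]])
    strain <- as.numeric(strain[[2]])
  }
  if (is.data.frame(volume)) {
    vol_t <- as.numeric(volume[[1]])
    vol_v <- as.numeric(volume[[2]])
    if (is.null(strain_t)) {
      stop("volume has a time grid but strain does not; supply both as ",
           "(time, value) tables to resample")
    }
    if (length(vol_t) == length(strain_t) &&
        max(abs(vol_t - strain_t)) <= 1e-6) {
      volume <- vol_v
    } else {
      if (min(strain_t) < min(vol_t) - 1e-6 ||
          max(strain_t) > max(vol_t) + 1e-6) {
        stop("volume grid does not cover the strain grid; cannot resample")
      }
      volume <- approx(vol_t, vol_v, xout = strain_t)$y
    }
  }
  n <- length(strain)
  if (length(volume) != n) {
    stop("strain and volume must have the same number of frames (",
         n, " vs ", length(volume), ")")
  }
  es_index <- as.integer(es_index)
  if (es_index < 1L || es_index > n) stop("es_index out of range")
  loop <- data.frame(
    frame = seq_len(n),
    volume = as.numeric(volume),
    strain = as.numeric(strain),
    limb = ifelse(seq_len(n) <= es_index, "systolic", "diastolic"),
    stringsAsFactors = FALSE
  )
  attr(loop, "loop_kind") <- loop_kind
  attr(loop, "es_index") <- es_index
  class(loop) <- c("sv_loop", "data.frame")
  loop
}

#' Build the five strain-volume loop families of one cycle
#'
#' From one [cycle_record()], constructs:
#' \itemize{
#'   \item `global_global` — global PS against global volume,
#'   \item `midseptal_global`, `midlateral_global` — mid-septal /
#'     mid-lateral PS against global volume,
#'   \item `midseptal_segmental`, `midlateral_segmental` — mid-septal /
#'     mid-lateral PS against the corresponding segmental volume.
#' }
#' Multi-segment wall selections are collapsed to a composite channel
#' (mean strain, summed volume).
#'
#' @param record a `cycle_record`.
#' @param segments wall selection from [select_midwall_segments()].
#' @return Named list of five `sv_loop` objects.
#' @examples
#' rec <- simulate_cycle(phenotype_preset("healthy"))
#' loops <- build_loops(rec)
#' @export
build_loops <- function(record, segments = select_midwall_segments()) {
  validate_cycle_record(record)
  sep_s <- composite_strain(record$strain, segments$midseptal)
  lat_s <- composite_strain(record$strain, segments$midlateral)
  sep_v <- composite_volume(record$seg_volume, segments$midseptal)
  lat_v <- composite_volume(record$seg_volume, segments$midlateral)
  es <- record$es_index
  list(
    global_global = build_loop(global_strain(record$strain),
                               record$global_volume, es, "global_global"),
    midseptal_global = build_loop(sep_s, record$global_volume, es,
                                  "midseptal_global"),
    midlateral_global = build_loop(lat_s, record$global_volume, es,
                                   "midlateral_global"),
    midseptal_segmental = build_loop(sep_s, sep_v, es,
                                     "midseptal_segmental"),
    midlateral_segmental = build_loop(lat_s, lat_v, es,
                                      "midlateral_segmental")
  )
}

#' @export
print.sv_loop <- function(x, ...) {
  cat("<sv_loop> ", attr(x, "loop_kind"), ": ", nrow(x), " points (",
      sum(x$limb == "systolic"), " systolic / ",
      sum(x$limb == "diastolic"), " diastolic)\n", sep = "")
  invisible(x)
}

#' Plot a strain-volume loop with its linear fit
#'
#' @param x an `sv_loop`.
#' @param fit optionally a [fit_loop()] result to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sv_loop <- function(x, fit = NULL, ...) {
  sys <- x$limb == "systolic"
  graphics::plot(x$volume, x$strain, type = "n",
                 xlab = "Volume (mL)", ylab = "Strain (%)",
                 main = attr(x, "loop_kind"), ...)
  graphics::lines(x$volume, x$strain, col = "grey60")
  graphics::points(x$volume[sys], x$strain[sys], col = "firebrick", pch = 16)
  graphics::points(x$volume[!sys], x$strain[!sys], col = "steelblue", pch = 1)
  if (!is.null(fit)) {
    graphics::abline(fit$intercept, fit$slope, lty = 2)
  }
  invisible(x)
}
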