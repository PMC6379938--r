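#' The standard 16-segment left ventricular model
#'
#' Segment numbering and anatomy of the ASE 16-segment LV model: segments
#' 1-6 basal, 7-12 mid-ventricular, 13-16 apical, walls ordered anterior,
#' anteroseptal, septal, inferior, posterior, lateral at the basal and mid
#' levels and anterior, septal, inferior, lateral at the apex.
#'
#' @return A data frame with columns `segment` (1-16), `level`
#'   (basal/mid/apical) and `wall`.
#' @examples
#' lv_segment_model()
#' @export
lv_segment_model <- function() {
  data.frame(
    segment = 1:16,
    level = c(rep("basal", 6), rep("mid", 6), rep("apical", 4)),
    wall = c("anterior", "anteroseptal", "septal", "inferior", "posterior",
             "lateral",
             "anterior", "anteroseptal", "septal", "inferior", "posterior",
             "lateral",
             "anterior", "septal", "inferior", "lateral"),
    stringsAsFactors = FALSE
  )
}

#' Mid-ventricular septal and lateral segment selection
#'
#' Returns the segment identifiers used for all "mid-septal" and
#' "mid-lateral" quantities. The default is the single mid septal segment
#' (9) and the single mid lateral segment (12) of the 16-segment model.
#' Multi-segment selections are allowed and are collapsed downstream into a
#' composite channel (mean strain, summed volume), e.g. to include the mid
#' anteroseptal segment in the septal wall.
#'
#' @param midseptal integer vector of septal segment ids (default 9).
#' @param midlateral integer vector of lateral segment ids (default 12).
#'
#' @return A named list with elements `midseptal` and `midlateral`.
#' @examples
#' select_midwall_segments()
#' select_midwall_segments(midseptal = c(8, 9))
#' @export
select_midwall_segments <- function(midseptal = 9L, midlateral = 12L) {
  midseptal <- as.integer(midseptal)
  midlateral <- as.integer(midlateral)
  check_ids <- function(ids, what) {
    if (length(ids) < 1L || anyNA(ids) || any(ids < 1L | ids > 16L)) {
      stop("`", what, "` must contain segment ids in 1..16 ",
           "(standard 16-segment model)")
    }
  }
  check_ids(midseptal, "midseptal")
  check_ids(midlateral, "midlateral")
  if (length(intersect(midseptal, midlateral)) > 0L) {
    stop("midseptal and midlateral selections overlap: segment(s) ",
         paste(intersect(midseptal, midlateral), collapse = ", "))
  }
  list(midseptal = midseptal, midlateral = midlateral)
}

#' Composite strain of a multi-segment selection
#'
#' Per-frame arithmetic mean of the selected segmental strain traces (a
#' single segment passes through unchanged).
#'
#' @param strain n_frames x 16 matrix of segmental strain (%).
#' @param segments integer vector of segment ids.
#' @return Numeric vector of length `nrow(strain)`.
#' @export
composite_strain <- function(strain, segments) {
  strain <- as_segment_matrix(strain, "strain")
  rowMeans(strain[, segments, drop = FALSE])
}

#' Composite volume of a multi-segment selection
#'
#' Per-frame sum of the selected segmental volume traces (segmental volumes
#' are additive shares of the cavity).
#'
#' @param volume n_frames x 16 matrix of segmental volume (mL).
#' @param segments integer vector of segment ids.
#' @return Numeric vector of length `nrow(volume)`.
#' @export
composite_volume <- function(volume, segments) {
  volume <- as_segment_matrix(volume, "volume")
  rowSums(volume[, segments, drop = FALSE])
}

# Validate a frames x 16 segmental matrix; report which segments are missing.
as_segment_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (ncol(m) != 16L) {
    if (!is.null(colnames(m))) {
      want <- sprintf("%s_seg%02d", what, 1:16)
      missing <- setdiff(want, tolower(colnames(m)))
      if (length(missing) > 0L && length(missing) < 16L) {
        stop("segmental ", what, " matrix is missing segments: ",
             paste(missing, collapse = ", "))
      }
    }
    stop("segmental ", what, " matrix must have 16 columns (got ",
         ncol(m), ")")
  }
  storage.mode(m) <- "double"
  m
}
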