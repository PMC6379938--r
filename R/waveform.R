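#' Raised-cosine myocardial activation kernel
#'
#' Smooth (C1) dimensionless activation waveform used by the simulator to
#' shape both segmental shortening and volume ejection across one cardiac
#' cycle. The kernel rises from 0 at `onset` to 1 at `es_time` as a raised
#' cosine, then relaxes back to 0 at `rr` (the next R wave) along a second
#' raised cosine. Outside `[onset, rr)` the kernel is 0, so a shifted copy
#' (`waveform(t - delay, ...)`) models delayed electrical activation.
#'
#' @param t numeric vector of times (ms) at which to evaluate the kernel.
#' @param onset activation onset (ms); activation is 0 for `t < onset`.
#' @param es_time time of peak activation (ms), typically end-systole.
#' @param rr cycle length (ms); activation returns to 0 at `t = rr`.
#'
#' @return Numeric vector of activation values in `[0, 1]`.
#'
#' @examples
#' waveform(150, onset = 0, es_time = 300, rr = 800)  # 0.5, mid-upstroke
#' @export
waveform <- function(t, onset = 0, es_time, rr) {
  stopifnot(is.numeric(t), length(onset) == 1L, length(es_time) == 1L,
            length(rr) == 1L)
  if (es_time <= onset) {
    stop("invalid kernel: `es_time` (", es_time,
         ") must exceed `onset` (", onset, ")")
  }
  if (rr <= es_time) {
    stop("invalid kernel: `rr` (", rr, ") must exceed `es_time` (",
         es_time, ")")
  }
  w <- numeric(length(t))
  rise <- t >= onset & t <= es_time
  fall <- t > es_time & t < rr
  w[rise] <- 0.5 * (1 - cos(pi * (t[rise] - onset) / (es_time - onset)))
  w[fall] <- 0.5 * (1 + cos(pi * (t[fall] - es_time) / (rr - es_time)))
  w
}

# Single-lobe raised-cosine bump on [t0, t1], peak 1 at the midpoint, 0 outside.
# Shapes the rebound-stretch pulse of early-activated segments.
raised_cosine_bump <- function(t, t0, t1) {
  b <- numeric(length(t))
  if (t1 <= t0) return(b)
  inside <- t >= t0 & t <= t1
  b[inside] <- 0.5 * (1 - cos(2 * pi * (t[inside] - t0) / (t1 - t0)))
  b
}
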