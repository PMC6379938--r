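#' Per-segment simulation parameters
#'
#' One row per segment of the 16-segment model. `strain_amplitude` is the
#' peak shortening magnitude (%, non-negative; strain traces are negative on
#' shortening). `activation_delay` shifts the onset of shortening relative
#' to cycle start (R wave), modelling delayed electrical activation.
#' `rebound_fraction` is the fraction of a segment's early shortening that
#' is returned as positive (lengthening) stretch during ejection — the
#' rebound-stretch / wasted-work morphology of early-activated septum being
#' stretched by late-contracting walls. `volume_fraction` is the segment's
#' share of global end-diastolic volume (shares sum to 1) and `volume_delay`
#' phase-shifts the segmental volume waveform.
#'
#' @param segment_id integers 1..16.
#' @param strain_amplitude peak shortening (%), `>= 0`.
#' @param activation_delay onset delay (ms), `>= 0`.
#' @param rebound_fraction fraction in `[0, 1]`.
#' @param volume_fraction positive shares summing to 1.
#' @param volume_delay segmental volume phase shift (ms), `>= 0`.
#'
#' @return A data frame with one row per segment, class `segment_params`.
#' @export
segment_params <- function(segment_id = 1:16,
                           strain_amplitude = 20,
                           activation_delay = 0,
                           rebound_fraction = 0,
                           volume_fraction = 1 / 16,
                           volume_delay = activation_delay) {
  p <- data.frame(
    segment_id = as.integer(segment_id),
    strain_amplitude = as.numeric(strain_amplitude),
    activation_delay = as.numeric(activation_delay),
    rebound_fraction = as.numeric(rebound_fraction),
    volume_fraction = as.numeric(volume_fraction),
    volume_delay = as.numeric(volume_delay)
  )
  validate_segment_params(p)
  class(p) <- c("segment_params", "data.frame")
  p
}

validate_segment_params <- function(p) {
  if (nrow(p) != 16L || !identical(sort(p$segment_id), 1:16)) {
    stop("segment parameters must cover segments 1..16 exactly once")
  }
  if (any(p$strain_amplitude < 0)) stop("strain_amplitude must be >= 0")
  if (any(p$rebound_fraction < 0 | p$rebound_fraction > 1)) {
    stop("rebound_fraction must lie in [0, 1]")
  }
  if (any(p$volume_fraction <= 0)) stop("volume_fraction must be > 0")
  if (abs(sum(p$volume_fraction) - 1) > 1e-9) {
    stop("volume_fraction must sum to 1 (got ",
         format(sum(p$volume_fraction), digits = 12), ")")
  }
  if (any(p$activation_delay < 0) || any(p$volume_delay < 0)) {
    stop("activation_delay and volume_delay must be >= 0")
  }
  invisible(p)
}

#' Simulation configuration for one cardiac cycle
#'
#' @param rr_interval cycle length (ms).
#' @param n_frames frames per cycle (`>= 16`); the grid is uniform with
#'   frame 1 at the R wave (t = 0).
#' @param edv end-diastolic volume (mL).
#' @param esv end-systolic volume (mL), `< edv`.
#' @param es_time_fraction end-systole as a fraction of the R-R interval
#'   (default 0.4, roughly the end of the T wave at rest).
#' @param segments a [segment_params()] table.
#' @param noise_sd_strain additive Gaussian measurement noise SD per strain
#'   channel (%).
#' @param noise_sd_volume additive Gaussian noise SD per segmental volume
#'   channel (mL); the global volume is the sum of the (noisy) segmental
#'   volumes.
#' @param seed optional integer seed applied by [simulate_cycle()].
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(rr_interval = 800,
                       n_frames = 32L,
                       edv = 120,
                       esv = 50,
                       es_time_fraction = 0.4,
                       segments = segment_params(),
                       noise_sd_strain = 0,
                       noise_sd_volume = 0,
                       seed = NULL) {
  cfg <- list(rr_interval = rr_interval, n_frames = as.integer(n_frames),
              edv = edv, esv = esv, es_time_fraction = es_time_fraction,
              segments = segments, noise_sd_strain = noise_sd_strain,
              noise_sd_volume = noise_sd_volume, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$rr_interval > 0, cfg$edv > 0)
  if (cfg$esv >= cfg$edv) stop("esv must be smaller than edv")
  if (cfg$es_time_fraction <= 0 || cfg$es_time_fraction >= 1) {
    stop("es_time_fraction must lie strictly in (0, 1)")
  }
  if (cfg$n_frames < 16L) stop("n_frames must be >= 16")
  if (cfg$noise_sd_strain < 0 || cfg$noise_sd_volume < 0) {
    stop("noise SDs must be >= 0")
  }
  validate_segment_params(cfg$segments)
  es_time <- cfg$es_time_fraction * cfg$rr_interval
  if (any(cfg$segments$activation_delay >= es_time)) {
    stop("activation delays must be smaller than the end-systolic time")
  }
  invisible(cfg)
}

# Wall-wise activation delays of a left bundle branch block-like pattern:
# septum first, lateral wall last, intermediate walls graded (ms).
lbbb_delay_by_wall <- c(anterior = 30, anteroseptal = 0, septal = 0,
                        inferior = 45, posterior = 70, lateral = 100)

wall_values <- function(by_wall) {
  unname(by_wall[lv_segment_model()$wall])
}

#' Phenotype presets for the simulator
#'
#' Parameter templates emulating the group structure of a CRT cohort:
#' \describe{
#'   \item{`healthy`}{synchronous activation (all delays 0, no rebound),
#'     normal volumes (EDV 60 / ESV 22 mL) and large strain amplitudes,
#'     septal above lateral.}
#'   \item{`responder_like`}{dilated LV (EDV 204 / ESV 159 mL), LBBB-like
#'     delay pattern; early septum with substantial rebound stretch (wasted
#'     septal work) and late lateral wall with relatively preserved
#'     amplitude.}
#'   \item{`nonresponder_like`}{dilated LV (EDV 271 / ESV 220 mL), similar
#'     delay pattern but globally depressed amplitudes including the lateral
#'     wall and only minimal septal rebound.}
#'   \item{`post_crt`}{responder after resynchronization: delays largely
#'     removed, rebound abolished, amplitudes recovered, volumes reduced
#'     (EDV 152 / ESV 104 mL).}
#' }
#'
#' @param name one of `"healthy"`, `"responder_like"`,
#'   `"nonresponder_like"`, `"post_crt"`.
#' @param ... overrides passed on to [sim_config()] (e.g. `edv`, `esv`,
#'   `seed`, noise SDs).
#'
#' @return A `sim_config`.
#' @examples
#' cfg <- phenotype_preset("responder_like", noise_sd_strain = 0)
#' @export
phenotype_preset <- function(name = c("healthy", "responder_like",
                                      "nonresponder_like", "post_crt"),
                             ...) {
  name <- match.arg(name)
  base <- switch(
    name,
    healthy = list(
      edv = 60, esv = 22,
      amplitude = c(anterior = 42, anteroseptal = 50, septal = 50,
                    inferior = 44, posterior = 40, lateral = 38),
      delay = c(anterior = 0, anteroseptal = 0, septal = 0,
                inferior = 0, posterior = 0, lateral = 0),
      rebound = 0
    ),
    responder_like = list(
      edv = 204, esv = 159,
      amplitude = c(anterior = 14, anteroseptal = 13, septal = 13,
                    inferior = 15, posterior = 16, lateral = 17),
      delay = lbbb_delay_by_wall,
      rebound = 0.8
    ),
    nonresponder_like = list(
      edv = 271, esv = 220,
      amplitude = c(anterior = 11, anteroseptal = 12, septal = 12,
                    inferior = 11, posterior = 10.5, lateral = 10),
      delay = 1.5 * lbbb_delay_by_wall,
      rebound = 0.25
    ),
    post_crt = list(
      edv = 152, esv = 104,
      amplitude = c(anterior = 19, anteroseptal = 22, septal = 22,
                    inferior = 19, posterior = 20, lateral = 21),
      delay = 0.25 * lbbb_delay_by_wall,
      rebound = 0
    )
  )
  septal <- lv_segment_model()$wall == "septal"
  segs <- segment_params(
    strain_amplitude = wall_values(base$amplitude),
    activation_delay = wall_values(base$delay),
    rebound_fraction = ifelse(septal, base$rebound, 0)
  )
  defaults <- list(edv = base$edv, esv = base$esv, segments = segs,
                   noise_sd_strain = 0.8, noise_sd_volume = 0.3)
  args <- utils::modifyList(defaults, list(...))
  cfg <- do.call(sim_config, args)
  attr(cfg, "preset") <- name
  cfg
}

#' Simulate one cardiac cycle of 16-segment strain and volume traces
#'
#' Generates segmental strain `s_i(t) = -A_i w(t - d_i) + rebound pulse`,
#' segmental volume `V_i(t) = f_i (EDV - (EDV - ESV) w(t - dv_i))` and the
#' global volume as the sum of segmental volumes, on a uniform grid of
#' `n_frames` frames starting at the R wave. `w` is the raised-cosine
#' activation kernel ([waveform()]) peaking at end-systole. The rebound
#' term is a positive raised-cosine pulse starting at the segment's
#' mid-upstroke, peaking at end-systole with amplitude
#' `rebound_fraction * strain_amplitude` and decaying back to zero in early
#' diastole, so rebound stretch both interrupts early shortening (a local
#' strain minimum before ES followed by a positive-going deflection) and
#' reduces net end-systolic shortening — the wasted-septal-work loop
#' morphology.
#' Gaussian noise is added per frame and channel with the configured SDs.
#'
#' @param config a [sim_config()].
#' @param subject_id,visit identifiers stored on the record.
#'
#' @return A [cycle_record()] with the end-diastolic frame at index 1 and
#'   the end-systolic frame nearest `es_time_fraction * rr_interval`.
#' @examples
#' rec <- simulate_cycle(phenotype_preset("healthy", noise_sd_strain = 0,
#'                                        noise_sd_volume = 0))
#' @export
simulate_cycle <- function(config, subject_id = "sim", visit = "baseline") {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  rr <- config$rr_interval
  n <- config$n_frames
  times <- (seq_len(n) - 1) * rr / n
  es_index <- which.min(abs(times - config$es_time_fraction * rr))
  es_time <- times[es_index] # snap ES to the grid
  p <- config$segments[order(config$segments$segment_id), ]

  strain <- matrix(0, n, 16L)
  seg_volume <- matrix(0, n, 16L)
  dv <- config$edv - config$esv
  for (i in 1:16) {
    d <- p$activation_delay[i]
    w_s <- waveform(times - d, onset = 0, es_time = es_time, rr = rr)
    s <- -p$strain_amplitude[i] * w_s
    if (p$rebound_fraction[i] > 0) {
      t0 <- d + 0.5 * es_time
      if (t0 < es_time) {
        amp <- p$rebound_fraction[i] * p$strain_amplitude[i]
        t2 <- min(2 * es_time - t0, rr) # symmetric about ES; stretch decays in early diastole
        s <- s + amp * raised_cosine_bump(times, t0, t2)
      }
    }
    strain[, i] <- s
    w_v <- waveform(times - p$volume_delay[i], onset = 0,
                    es_time = es_time, rr = rr)
    seg_volume[, i] <- p$volume_fraction[i] * (config$edv - dv * w_v)
  }
  if (config$noise_sd_strain > 0) {
    strain <- strain + matrix(rnorm(n * 16L, sd = config$noise_sd_strain),
                              n, 16L)
  }
  if (config$noise_sd_volume > 0) {
    seg_volume <- seg_volume +
      matrix(rnorm(n * 16L, sd = config$noise_sd_volume), n, 16L)
  }
  cycle_record(times = times, strain = strain, seg_volume = seg_volume,
               global_volume = rowSums(seg_volume), rr_interval = rr,
               es_index = es_index, subject_id = subject_id, visit = visit)
}

# Deterministic per-subject substream: a fixed-increment counter hashed into
# a 31-bit seed, so adding subjects never perturbs earlier ones.
substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 16807) %% 2147483647)
}

# Per-subject biological variability: subject-level multiplicative factors
# (overall contractility, overall conduction delay, overall rebound severity)
# on top of independent per-segment jitter.
jitter_config <- function(cfg, amp_sdlog = 0.15, subj_amp_sdlog = 0.4,
                          delay_sd = 10, subj_delay_sdlog = 0.25,
                          subj_rebound_sdlog = 0.5, edv_sdlog = 0.18) {
  p <- cfg$segments
  amp_factor <- rlnorm(1, 0, subj_amp_sdlog)
  delay_factor <- rlnorm(1, 0, subj_delay_sdlog)
  rebound_factor <- rlnorm(1, 0, subj_rebound_sdlog)
  p$strain_amplitude <- p$strain_amplitude * amp_factor * rlnorm(16, 0, amp_sdlog)
  p$activation_delay <- pmax(0, p$activation_delay * delay_factor +
                               rnorm(16, 0, delay_sd) * (p$activation_delay > 0))
  es_time <- cfg$es_time_fraction * cfg$rr_interval
  p$activation_delay <- pmin(p$activation_delay, 0.9 * es_time)
  p$volume_delay <- p$activation_delay
  p$rebound_fraction <- pmin(1, p$rebound_fraction * rebound_factor)
  ef <- (cfg$edv - cfg$esv) / cfg$edv
  edv <- cfg$edv * rlnorm(1, 0, edv_sdlog)
  ef <- min(0.75, max(0.05, ef * rlnorm(1, 0, 0.12)))
  cfg$edv <- edv
  cfg$esv <- edv * (1 - ef)
  class(p) <- c("segment_params", "data.frame")
  cfg$segments <- p
  cfg
}

#' Simulate a cohort of subjects with paired follow-up visits
#'
#' Draws `n_per_group` subjects per phenotype preset with per-subject
#' parameter jitter (multiplicative log-normal on amplitudes and volumes,
#' additive Gaussian on non-zero delays), then generates the paired
#' follow-up visit: `responder_like` subjects follow up as `post_crt` with
#' an end-systolic volume reduction of at least 15% (drawn uniformly in
#' 20-45%), `nonresponder_like` subjects keep their phenotype with an ESV
#' change below the 15% response threshold (uniform in -8% to +10%
#' reduction), and `healthy` subjects get no follow-up. Each subject's
#' parameters come from an independent seed substream, so records are
#' reproducible and earlier subjects are unchanged when more are added.
#'
#' @param n_per_group subjects per preset (`>= 1`).
#' @param presets character vector of preset names (see
#'   [phenotype_preset()]).
#' @param seed integer master seed.
#' @param ... overrides forwarded to [phenotype_preset()] (e.g. noise SDs).
#'
#' @return A list of `cycle_record`s. Each record carries `subject_id`,
#'   `visit` (`"baseline"` or `"followup"`) and a `group` attribute (the
#'   preset name); the true generating parameters are attached as attribute
#'   `"truth"` for recovery tests.
#' @examples
#' recs <- simulate_cohort(2, presets = c("healthy", "responder_like"),
#'                         seed = 1)
#' @export
simulate_cohort <- function(n_per_group,
                            presets = c("healthy", "responder_like",
                                        "nonresponder_like"),
                            seed = 1L, ...) {
  stopifnot(n_per_group >= 1)
  records <- list()
  counter <- 0L
  for (preset in presets) {
    for (k in seq_len(n_per_group)) {
      counter <- counter + 1L
      sid <- sprintf("%s_%03d", preset, k)
      set.seed(substream_seed(seed, counter))
      cfg <- jitter_config(phenotype_preset(preset, ...))
      base <- simulate_cycle(cfg, subject_id = sid, visit = "baseline")
      attr(base, "group") <- preset
      attr(base, "truth") <- cfg
      records[[length(records) + 1L]] <- base

      if (preset %in% c("responder_like", "nonresponder_like")) {
        if (preset == "responder_like") {
          reduction <- runif(1, 0.20, 0.45)
          fu_cfg <- jitter_config(phenotype_preset("post_crt", ...),
                                  edv_sdlog = 0)
        } else {
          reduction <- runif(1, -0.08, 0.10)
          fu_cfg <- jitter_config(phenotype_preset("nonresponder_like", ...),
                                  edv_sdlog = 0)
        }
        esv_fu <- cfg$esv * (1 - reduction)
        # keep the follow-up EF of the jittered phenotype, rescale volumes
        ef_fu <- (fu_cfg$edv - fu_cfg$esv) / fu_cfg$edv
        fu_cfg$esv <- esv_fu
        fu_cfg$edv <- esv_fu / (1 - ef_fu)
        fu <- simulate_cycle(fu_cfg, subject_id = sid, visit = "followup")
        attr(fu, "group") <- preset
        attr(fu, "truth") <- fu_cfg
        records[[length(records) + 1L]] <- fu
      }
    }
  }
  records
}
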