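test_that("fit_loop recovers an exact linear relation and its degenerate cases", {
  v <- c(100, 85, 60, 55, 70, 95)
  loop <- build_loop(0.5 * v - 40, v, es_index = 4)
  f <- fit_loop(loop)
  expect_equal(f$slope, 0.5)
  expect_equal(f$intercept, -40)
  expect_equal(f$r2_sd_coupling, 1)
  # constant strain over varying volume: slope 0, R2 defined as 0
  f0 <- fit_loop(build_loop(rep(-10, 6), v, es_index = 4))
  expect_equal(f0$slope, 0)
  expect_equal(f0$r2_sd_coupling, 0)
  expect_match(f0$degenerate, "strain variance")
  # constant volume is unphysiological
  expect_error(fit_loop(build_loop(0.5 * v, rep(80, 6), es_index = 4)),
               "identical")
  expect_error(fit_loop(data.frame(volume = c(1, 2), strain = c(1, 2))),
               "3 points")
})

test_that("fit_loop matches the normal-equations oracle on random loops", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    v <- rnorm(n, 150, 40)
    s <- -20 + 0.3 * v + rnorm(n, 0, 5)
    f <- fit_loop(data.frame(volume = v, strain = s))
    o <- ols_oracle(v, s)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$r2_sd_coupling, o$r2, tolerance = 1e-10)
  }
})

test_that("R2 is invariant under affine volume rescaling; slope scales", {
  set.seed(11)
  v <- rnorm(20, 100, 20)
  s <- -0.4 * v + rnorm(20, 0, 3)
  f1 <- fit_loop(data.frame(volume = v, strain = s))
  f2 <- fit_loop(data.frame(volume = 2.5 * v + 30, strain = s))
  expect_equal(f2$r2_sd_coupling, f1$r2_sd_coupling, tolerance = 1e-12)
  expect_equal(f2$slope, f1$slope / 2.5, tolerance = 1e-12)
})

test_that("per-limb diagnostic fits are returned on request", {
  rec <- simulate_cycle(phenotype_preset("responder_like", seed = 8))
  loop <- build_loop(rec$strain[, 9], rec$global_volume, rec$es_index)
  f <- fit_loop(loop, per_limb = TRUE)
  expect_false(is.null(f$systolic))
  expect_false(is.null(f$diastolic))
  expect_equal(f$systolic$n_points, rec$es_index)
})

test_that("peak strain is the signed minimum, earliest on ties", {
  t <- seq(0, 775, by = 25)
  tr <- -20 * waveform(t, 0, 300, 800)
  p <- peak_strain(tr, t)
  expect_equal(p$value, -20)
  expect_equal(p$time, 300)
  mono <- seq(0, -15, length.out = 16)
  expect_equal(peak_strain(mono)$value, -15)
  expect_equal(peak_strain(mono)$frame, 16)
  tied <- c(0, -5, -2, -5, 0)
  expect_equal(peak_strain(tied)$frame, 2)
  expect_error(peak_strain(numeric(0)), "empty")
  # systole-restricted search window
  tr2 <- c(0, -5, -3, -8)
  expect_equal(peak_strain(tr2, window = "systole", es_index = 3)$value, -5)
})

test_that("SDI is zero iff every segment bottoms at the ES frame", {
  rec <- simulate_cycle(phenotype_preset("healthy", noise_sd_strain = 0,
                                         noise_sd_volume = 0))
  expect_equal(sdi(rec), 0)
  # a single early-peaking segment contributes its peak-to-ES difference
  strain <- matrix(0, 10, 16)
  es <- 6
  strain[es, ] <- -15 # all peak at ES
  strain[3, 5] <- -20
  strain[es, 5] <- -12
  expect_equal(sdi(strain, es), -20 - (-12))
  expect_equal(sdi(strain, es, abs = TRUE), 8)
  expect_lt(sdi(strain, es), 0)
})

test_that("responder preset wastes more work than healthy (SDI more negative)", {
  h <- simulate_cycle(phenotype_preset("healthy", noise_sd_strain = 0,
                                       noise_sd_volume = 0))
  r <- simulate_cycle(phenotype_preset("responder_like", noise_sd_strain = 0,
                                       noise_sd_volume = 0))
  expect_lt(sdi(r), sdi(h))
  expect_lt(sdi(r), 0)
})

test_that("time-to-event dispersion matches the hand-computed SD", {
  # 8 segments at 400 ms, 8 at 200 ms; sample SD = 103.2796, over RR 800
  times <- seq(0, 775, by = 25)
  traces <- sapply(1:16, function(i) {
    peak_t <- if (i <= 8) 400 else 200
    -10 * waveform(times, 0, peak_t, 800)
  })
  got <- time_sd_pct(traces, times, 800, "peak_strain")
  expect_equal(got, 100 * sd(c(rep(400, 8), rep(200, 8))) / 800,
               tolerance = 1e-12)
  expect_equal(round(got, 2), 12.91)
  # synchronous input: exactly zero
  sync <- sapply(1:16, function(i) -10 * waveform(times, 0, 400, 800))
  expect_equal(time_sd_pct(sync, times, 800, "peak_strain"), 0)
  expect_error(time_sd_pct(sync, times, 0, "peak_strain"), "rr")
})

test_that("ejection fraction follows its definition and guards EDV", {
  expect_equal(ejection_fraction(c(100, 70, 40, 80), 1, 3), 60)
  expect_equal(ejection_fraction(c(200, 170, 180), 1, 2), 15)
  expect_equal(ejection_fraction(c(50, 50), 1, 2), 0)
  expect_error(ejection_fraction(c(0, 10), 1, 2), "EDV")
})

test_that("responder classification has an inclusive 15% boundary", {
  expect_true(classify_response(100, 85)$responder)
  expect_equal(classify_response(100, 85)$delta_lvesv_pct, 15)
  expect_false(classify_response(100, 86)$responder)
  expect_error(classify_response(0, 50), "> 0")
  # published cut-off rule: low baseline septal coupling predicts response
  expect_true(classify_response(100, 85, 0.44)$r2_rule_prediction)
  expect_false(classify_response(100, 85, 0.73)$r2_rule_prediction)
  expect_false(classify_response(100, 85, 0.55)$r2_rule_prediction)
})

test_that("cohort metrics carry one labelled row per subject-visit", {
  recs <- simulate_cohort(2, c("healthy", "responder_like"), seed = 13)
  tab <- cohort_metrics(recs)
  expect_equal(nrow(tab), 6) # 2 healthy + 2 x (baseline + followup)
  expect_setequal(unique(tab$group), c("healthy", "responder_like"))
  resp <- add_response(tab)
  expect_equal(nrow(resp), 4)
  expect_true(all(is.na(resp$responder[resp$group == "healthy"])))
})
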