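test_that("two-sample comparison reproduces the pooled t by hand", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
  cg <- compare_groups(d, "y", "g")
  # pooled variance 1, se = sqrt(2/3), t = -3 / se
  expect_equal(cg$statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(cg$groups$mean, c(2, 5))
  expect_equal(cg$groups$sd, c(1, 1))
  d2 <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2))
  cg2 <- compare_groups(d2, "y", "g")
  expect_equal(cg2$statistic, 0)
  expect_equal(cg2$p_value, 1)
  expect_error(compare_groups(data.frame(g = c("a", "a", "b"), y = 1:3),
                              "y", "g"), "2 observations")
})

test_that("Welch option relaxes the equal-variance assumption", {
  set.seed(2)
  d <- data.frame(g = rep(c("a", "b"), c(10, 10)),
                  y = c(rnorm(10, 0, 1), rnorm(10, 1, 5)))
  pooled <- compare_groups(d, "y", "g", var_equal = TRUE)
  welch <- compare_groups(d, "y", "g", var_equal = FALSE)
  expect_match(welch$method, "Welch")
  expect_false(isTRUE(all.equal(pooled$p_value, welch$p_value)))
})

test_that("paired comparison uses complete pairs and flags zero variance", {
  d <- data.frame(subject_id = rep(1:4, 2),
                  visit = rep(c("baseline", "followup"), each = 4),
                  y = c(5, 6, 7, 8, 4, 5, 6, 7))
  cg <- compare_groups(d, "y", "visit", paired = TRUE)
  expect_match(cg$degenerate, "zero variance") # constant difference of 1
  d$y[5] <- 3
  cg2 <- compare_groups(d, "y", "visit", paired = TRUE)
  expect_null(cg2$degenerate)
  expect_lt(cg2$p_value, 1)
  d_bad <- d[-8, ]
  expect_error(compare_groups(d_bad, "y", "visit", paired = TRUE), "4")
})

test_that("2x2 association test applies the expected-count rule", {
  even <- categorical_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$p_value, 1)
  expect_equal(even$method, "chisq")
  # any expected count below 5 switches to Fisher
  low <- categorical_test(matrix(c(2, 3, 8, 7), 2))
  expect_equal(low$method, "fisher")
  expect_true(all(categorical_test(matrix(c(2, 3, 8, 7), 2))$expected < 10))
  expect_error(categorical_test(matrix(c(0, 0, 3, 7), 2)), "margin")
  expect_error(categorical_test(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("Fisher path matches exact hypergeometric enumeration", {
  # diagonal table [[10,0],[0,10]]: only the two extreme tables are as or
  # more extreme, each with probability 1/choose(20,10)
  f <- categorical_test(matrix(c(10, 0, 0, 10), 2), method = "fisher")
  expect_equal(f$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_lt(f$p_value, 0.001)
})

test_that("logistic screen flags separation and keeps LRT p-values valid", {
  d <- data.frame(responder = rep(c(FALSE, TRUE), each = 10),
                  x = c(rnorm(10, 0), rnorm(10, 10)))
  scr <- logistic_screen(d, "x")
  expect_true(scr$univariate$separation[1])
  expect_true(is.na(scr$univariate$or[1]))
  expect_lt(scr$univariate$p_value[1], 0.001) # LRT still informative
  expect_error(logistic_screen(data.frame(responder = rep(TRUE, 5),
                                          x = rnorm(5)), "x"),
               "both classes")
})

test_that("logistic screen recovers the driving variable of a cohort", {
  set.seed(31)
  recs <- c(simulate_cohort(27, "responder_like", seed = 31),
            simulate_cohort(13, "nonresponder_like", seed = 1031))
  tab <- add_response(cohort_metrics(recs))
  scr <- logistic_screen(tab, c("r2_midseptal_global", "tpps_sd_pct",
                                "tmsv_sd_pct", "sdi"))
  expect_true("r2_midseptal_global" %in% scr$entered)
  mv <- scr$multivariate
  expect_true("r2_midseptal_global" %in% mv$variable)
  p_r2 <- mv$p_value[mv$variable == "r2_midseptal_global"]
  expect_lt(p_r2, 0.05)
  # low coupling predicts response: OR below 1 when estimable
  or_uni <- scr$univariate$or[scr$univariate$variable == "r2_midseptal_global"]
  if (!is.na(or_uni)) expect_lt(or_uni, 1)
})

test_that("ROC finds the separating cut-off and honours direction", {
  scores <- c(0.2, 0.3, 0.4, 0.6, 0.7, 0.8)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- roc_analysis(scores, labels, direction = "low")
  expect_equal(r$auc, 1)
  expect_gt(r$optimal_cutoff, 0.4)
  expect_lt(r$optimal_cutoff, 0.6)
  expect_equal(r$sens_at_cutoff, 100)
  expect_equal(r$spec_at_cutoff, 100)
  # with direction = "high" the same data give AUC 0
  expect_equal(roc_analysis(scores, labels, direction = "high")$auc, 0)
  expect_error(roc_analysis(scores, rep(TRUE, 6)), "both classes")
})

test_that("AUC equals the normalized Mann-Whitney U on random instances", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # ties likely
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    r <- roc_analysis(scores, labels, direction = "high")
    expect_equal(r$auc, auc_mw_oracle(scores, labels), tolerance = 1e-12)
    # reversing the direction flips the AUC
    r2 <- roc_analysis(scores, labels, direction = "low")
    expect_equal(r2$auc, 1 - r$auc, tolerance = 1e-12)
  }
})

test_that("identical markers compare as equal AUCs with p = 1", {
  set.seed(23)
  scores <- rnorm(30)
  labels <- rep(c(TRUE, FALSE), 15)
  ra <- roc_analysis(scores, labels, "high")
  rb <- roc_analysis(scores, labels, "high")
  cmp <- compare_auc(ra, rb)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)
  expect_error(compare_auc(ra, roc_analysis(scores[-1], labels[-1], "high")),
               "same subjects")
})

test_that("DeLong machinery matches a hand-rolled placement-value oracle", {
  set.seed(5)
  scores <- c(0.9, 0.4, 0.7, 0.45, 0.3, 0.65, 0.55, 0.5)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  r <- roc_analysis(scores, labels, "high")
  expect_equal(as.numeric(pROC::var(r$roc)),
               delong_var_oracle(scores, labels), tolerance = 1e-12)
})

test_that("informative marker beats noise in the paired AUC test", {
  set.seed(41)
  wins <- 0
  for (b in 1:20) {
    labels <- rep(c(TRUE, FALSE), each = 100)
    informative <- ifelse(labels, rnorm(200, 1.5), rnorm(200))
    noise <- rnorm(200)
    cmp <- compare_auc(roc_analysis(informative, labels, "high"),
                       roc_analysis(noise, labels, "high"))
    wins <- wins + (cmp$p_value < 0.05)
  }
  expect_gte(wins, 16) # large majority of replicates
})

test_that("Pearson correlation matches the direct formula", {
  x <- c(1, 2, 4, 7, 11)
  y <- c(2.2, 3.9, 8.4, 13.8, 21.7)
  p <- pearson(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(p$r, r_direct, tolerance = 1e-12)
  expect_equal(pearson(x, 2 * x)$r, 1)
  expect_equal(pearson(x, -x + 5)$r, -1)
  expect_error(pearson(x, rep(1, 5)), "variance")
  expect_error(pearson(1:2, 1:2), "3 complete")
})

test_that("Bland-Altman limits follow bias +/- 1.96 sample SD", {
  a <- c(10, 12, 11, 13)
  expect_equal(bland_altman(a, a)$bias, 0)
  expect_equal(bland_altman(a, a)$loa_upper, 0)
  shifted <- bland_altman(a + 3, a)
  expect_equal(shifted$bias, 3)
  expect_equal(shifted$sd_diff, 0)
  d <- bland_altman(c(1, 0, 1, 0), c(0, 1, 0, 1))
  # differences {1,-1,1,-1}: sd = 2/sqrt(3)
  expect_equal(d$bias, 0)
  expect_equal(d$loa_upper, 1.96 * 2 / sqrt(3), tolerance = 1e-12)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})
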