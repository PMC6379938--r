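#' Group comparison of a derived metric
#'
#' Two-group comparison of one metric column: unpaired comparisons use the
#' two-sample t-test (pooled-variance Student's t by default, Welch
#' optionally), paired comparisons the paired t-test. Descriptive
#' mean +/- SD per group is always reported.
#'
#' @param table data frame of subject rows.
#' @param variable metric column name.
#' @param grouping name of a two-level grouping column (unpaired), or of
#'   the within-subject condition column (paired, e.g. `visit`).
#' @param paired paired comparison; requires an `id` column identifying
#'   complete pairs.
#' @param id pairing key column (default `"subject_id"`).
#' @param var_equal pooled-variance t-test (default `TRUE`); `FALSE` gives
#'   Welch.
#' @return A list of class `group_comparison`: `statistic`, `p_value`,
#'   `method`, `groups` (mean, sd, n per level), `degenerate` (paired
#'   comparisons with zero variance of the differences are flagged rather
#'   than tested).
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' compare_groups(d, "y", "g")
#' @export
compare_groups <- function(table, variable, grouping, paired = FALSE,
                           id = "subject_id", var_equal = TRUE) {
  stopifnot(variable %in% names(table), grouping %in% names(table))
  g <- factor(table[[grouping]])
  if (nlevels(g) != 2L) {
    stop("`", grouping, "` must have exactly 2 levels (got ",
         nlevels(g), ")")
  }
  y <- table[[variable]]
  split_y <- split(y, g)
  if (any(vapply(split_y, length, 0L) < 2L)) {
    stop("need at least 2 observations per group")
  }
  desc <- data.frame(
    level = names(split_y),
    n = vapply(split_y, length, 0L),
    mean = vapply(split_y, mean, 0),
    sd = vapply(split_y, sd, 0),
    row.names = NULL
  )
  degenerate <- NULL
  if (paired) {
    if (!id %in% names(table)) stop("paired comparison needs an `", id,
                                    "` column")
    ids <- split(table[[id]], g)
    if (!setequal(ids[[1]], ids[[2]]) ||
        anyDuplicated(ids[[1]]) || anyDuplicated(ids[[2]])) {
      missing <- c(setdiff(ids[[1]], ids[[2]]), setdiff(ids[[2]], ids[[1]]))
      stop("incomplete pairs for subject(s): ",
           paste(unique(missing), collapse = ", "))
    }
    a <- split_y[[1]][order(ids[[1]])]
    b <- split_y[[2]][order(ids[[2]])]
    diffs <- a - b
    if (sd(diffs) == 0) {
      degenerate <- "zero variance of within-pair differences"
      res <- list(statistic = NA_real_, p.value = NA_real_,
                  method = "Paired t-test (degenerate)")
    } else {
      res <- t.test(a, b, paired = TRUE)
    }
  } else {
    res <- t.test(split_y[[1]], split_y[[2]], var.equal = var_equal)
  }
  structure(
    list(statistic = unname(res$statistic), p_value = res$p.value,
         method = res$method, variable = variable, groups = desc,
         degenerate = degenerate),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", x$variable, "--", x$method, "\n")
  for (i in seq_len(nrow(x$groups))) {
    cat(sprintf("  %s: %.3f +/- %.3f (n = %d)\n", x$groups$level[i],
                x$groups$mean[i], x$groups$sd[i], x$groups$n[i]))
  }
  if (is.null(x$degenerate)) {
    cat(sprintf("  t = %.3f, p = %.4g\n", x$statistic, x$p_value))
  } else {
    cat("  degenerate:", x$degenerate, "\n")
  }
  invisible(x)
}

#' Association test for a 2x2 contingency table
#'
#' Pearson chi-square test (without continuity correction) when all
#' expected cell counts are at least 5, Fisher's exact test otherwise;
#' the method actually used is reported. `method` forces one of the two.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @param method `"auto"` (expected-count rule), `"chisq"` or `"fisher"`.
#' @return List with `p_value`, `method`, `expected`.
#' @examples
#' categorical_test(matrix(c(5, 5, 5, 5), 2))
#' @export
categorical_test <- function(counts, method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has an empty margin")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (method == "auto") {
    method <- if (any(expected < 5)) "fisher" else "chisq"
  }
  p <- if (method == "fisher") {
    fisher.test(counts)$p.value
  } else {
    suppressWarnings(chisq.test(counts, correct = FALSE)$p.value)
  }
  list(p_value = p, method = method, expected = expected)
}

#' Univariate-to-multivariate logistic screen for response predictors
#'
#' Mirrors the standard clinical model-building procedure: one univariate
#' logistic regression per candidate variable; candidates with univariate
#' `p < alpha` enter a single multivariate logistic model (entry only, no
#' stepwise elimination). P-values are likelihood-ratio tests (stable near
#' separation, where the Wald statistic collapses); odds ratios are
#' Wald-based with 95% CIs and are reported both per 1 unit and per 1 SD
#' of the predictor (the per-SD OR makes variables on different scales
#' comparable). Complete or quasi-complete separation is flagged per
#' variable and the OR reported as non-estimable.
#'
#' @param table data frame.
#' @param candidates character vector of predictor column names.
#' @param outcome name of a logical/binary outcome column (default
#'   `"responder"`).
#' @param alpha univariate entry threshold (default 0.05).
#' @return A list of class `logistic_screen`: `univariate` (data frame:
#'   variable, or, ci_low, ci_high, p_value, or_per_sd, separation),
#'   `entered`, `multivariate` (same shape, `NULL` when nothing entered).
#' @export
logistic_screen <- function(table, candidates, outcome = "responder",
                            alpha = 0.05) {
  stopifnot(outcome %in% names(table))
  y <- table[[outcome]]
  y <- if (is.logical(y)) y else as.logical(y)
  keep <- !is.na(y)
  table <- table[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2L) {
    stop("outcome must contain both classes")
  }
  quiet_glm <- function(formula, data) {
    sep <- FALSE
    m <- withCallingHandlers(
      glm(formula, data = data, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    m$separation_warning <- sep
    m
  }
  fit_one <- function(vars) {
    d <- table[, vars, drop = FALSE]
    d$.y <- y
    m <- quiet_glm(.y ~ ., d)
    est <- coef(m)[-1]
    se <- sqrt(diag(vcov(m)))[-1]
    # per-variable likelihood-ratio p: robust near separation, where the
    # Wald statistic collapses (Hauck-Donner effect)
    p_lrt <- vapply(vars, function(v) {
      red <- quiet_glm(.y ~ ., d[, c(setdiff(vars, v), ".y"), drop = FALSE])
      stats::pchisq(red$deviance - m$deviance, df = 1, lower.tail = FALSE)
    }, 0)
    # separation inflates the estimate and its SE without bound; the Wald
    # OR and CI are then non-estimable (the LRT p remains valid)
    sep_var <- (m$separation_warning & se > 50) | se > 100 | !m$converged
    data.frame(
      variable = vars,
      or = ifelse(sep_var, NA_real_, exp(est)),
      ci_low = ifelse(sep_var, NA_real_, exp(est - qnorm(0.975) * se)),
      ci_high = ifelse(sep_var, NA_real_, exp(est + qnorm(0.975) * se)),
      p_value = unname(p_lrt),
      or_per_sd = ifelse(sep_var, NA_real_,
                         exp(est * vapply(vars, function(v) sd(table[[v]]), 0))),
      separation = sep_var,
      row.names = NULL
    )
  }
  uni <- do.call(rbind, lapply(candidates, fit_one))
  uni$stage <- "univariate"
  entered <- uni$variable[!is.na(uni$p_value) & uni$p_value < alpha]
  multi <- NULL
  if (length(entered) > 0L) {
    multi <- fit_one(entered)
    multi$stage <- "multivariate"
  }
  structure(list(univariate = uni, entered = entered, multivariate = multi),
            class = "logistic_screen")
}

#' @export
print.logistic_screen <- function(x, ...) {
  cat("<logistic_screen>\n Univariate:\n")
  print(x$univariate[, c("variable", "or", "ci_low", "ci_high", "p_value")],
        digits = 3, row.names = FALSE)
  if (is.null(x$multivariate)) {
    cat(" No variable met the entry criterion.\n")
  } else {
    cat(" Multivariate (entered: ", paste(x$entered, collapse = ", "), "):\n",
        sep = "")
    print(x$multivariate[, c("variable", "or", "ci_low", "ci_high", "p_value")],
          digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' ROC analysis with the sensitivity-plus-specificity optimal cut-off
#'
#' Empirical ROC curve over all observed thresholds (midpoints between
#' consecutive distinct scores), AUC by the trapezoidal rule, and the
#' optimal cut-off maximizing sensitivity + specificity (Youden), with
#' ties broken toward the higher sensitivity. `direction = "low"` declares
#' that low scores predict the positive class (as for R2-S/D coupling,
#' where low septal coupling predicts CRT response).
#'
#' @param scores numeric marker values.
#' @param labels logical (or coercible) class labels, `TRUE` = positive.
#' @param direction `"low"` or `"high"`: which scores indicate positives.
#' @return A list of class `roc_result`: `auc`, `optimal_cutoff`,
#'   `sens_at_cutoff` and `spec_at_cutoff` (percent), `thresholds` table,
#'   and the underlying [pROC::roc] object (`$roc`).
#' @examples
#' roc_analysis(c(0.2, 0.3, 0.4, 0.6, 0.7, 0.8),
#'              c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), direction = "low")
#' @export
roc_analysis <- function(scores, labels, direction = c("low", "high")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to compute a ROC curve")
  }
  # pROC direction: "<" means controls < cases; positives are cases
  proc_dir <- if (direction == "low") ">" else "<"
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = proc_dir,
                 quiet = TRUE)
  co <- pROC::coords(r, "all", ret = c("threshold", "sensitivity",
                                       "specificity"), transpose = FALSE)
  finite <- is.finite(co$threshold)
  j <- co$sensitivity + co$specificity
  best <- which(j == max(j[finite]) & finite)
  if (length(best) > 1L) {
    best <- best[which.max(co$sensitivity[best])]
  }
  structure(
    list(auc = as.numeric(pROC::auc(r)),
         optimal_cutoff = co$threshold[best],
         sens_at_cutoff = 100 * co$sensitivity[best],
         spec_at_cutoff = 100 * co$specificity[best],
         thresholds = co,
         n_positive = sum(labels), n_negative = sum(!labels),
         direction = direction,
         roc = r),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d positive / %d negative)\n",
              x$auc, x$n_positive, x$n_negative))
  cat(sprintf("  optimal cut-off %.4g (%s scores predict positives): ",
              x$optimal_cutoff, x$direction))
  cat(sprintf("sensitivity %.0f%%, specificity %.0f%%\n",
              x$sens_at_cutoff, x$spec_at_cutoff))
  invisible(x)
}

#' Compare two correlated AUCs (DeLong test)
#'
#' Paired comparison of the AUCs of two markers measured on the same
#' subjects, using DeLong's covariance estimator for correlated ROC
#' curves.
#'
#' @param roc_a,roc_b [roc_analysis()] results on the same subjects (same
#'   labels in the same order).
#' @return List with `auc_a`, `auc_b`, `difference`, `p_value`.
#' @export
compare_auc <- function(roc_a, roc_b) {
  la <- roc_a$roc$response
  lb <- roc_b$roc$response
  if (length(la) != length(lb) || !all(la == lb)) {
    stop("the two ROC curves must be computed on the same subjects")
  }
  if (isTRUE(all.equal(roc_a$auc, roc_b$auc)) &&
      identical(roc_a$roc$predictor, roc_b$roc$predictor)) {
    # identical markers: difference is exactly 0 with zero variance
    return(list(auc_a = roc_a$auc, auc_b = roc_b$auc, difference = 0,
                p_value = 1))
  }
  tst <- pROC::roc.test(roc_a$roc, roc_b$roc, method = "delong",
                        paired = TRUE)
  list(auc_a = roc_a$auc, auc_b = roc_b$auc,
       difference = roc_a$auc - roc_b$auc,
       p_value = tst$p.value)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors, `n >= 3`, finite, non-constant.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Bland-Altman agreement between two raters or readings
#'
#' Bias (mean difference `a - b`) and 95% limits of agreement
#' `bias +/- 1.96 * SD(differences)` (sample SD, n - 1 denominator).
#'
#' @param a,b paired measurement vectors of equal length, `n >= 2`.
#' @return A list of class `bland_altman`: `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `means`, `differences`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) {
    stop("paired measurements must have equal length (", length(a),
         " vs ", length(b), ")")
  }
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(bias = bias, sd_diff = s,
         loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
         means = (a + b) / 2, differences = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.4g, 95%% LoA [%.4g, %.4g] (n = %d)\n",
              x$bias, x$loa_lower, x$loa_upper, length(x$differences)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "Mean of methods",
                 ylab = "Difference", ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}
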