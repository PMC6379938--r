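# Independent oracles used across tests. These are deliberately naive,
# direct implementations of the definitions, kept free of any package code
# paths they are used to check.

# Ordinary least squares via the normal equations, plus R2 from its
# definition 1 - SSres/SStot.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r2 = 1 - ss_res / ss_tot)
}

# AUC as the normalized Mann-Whitney U: fraction of (positive, negative)
# pairs where the positive scores higher, ties counting 1/2.
auc_mw_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# DeLong variance of a single AUC from the definition: placement values
# V10 (per positive) and V01 (per negative), var = S10/m + S01/n with
# sample (n-1) variances.
delong_var_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  m <- length(pos)
  n <- length(neg)
  psi <- function(p, q) (p > q) + 0.5 * (p == q)
  v10 <- vapply(pos, function(p) mean(psi(p, neg)), 0)
  v01 <- vapply(neg, function(q) mean(psi(pos, q)), 0)
  var(v10) / m + var(v01) / n
}

# A minimal noise-free synchronous config used by several tests.
flat_config <- function(amplitude = 20, edv = 120, esv = 50, ...) {
  sim_config(edv = edv, esv = esv,
             segments = segment_params(strain_amplitude = amplitude), ...)
}

# Long (wall-stacked) form of the mid-septal vs mid-lateral R2 columns,
# for the paired heterogeneity comparisons.
wall_long <- function(rows) {
  rbind(
    data.frame(subject_id = rows$subject_id, wall = "septal",
               r2 = rows$r2_midseptal_global),
    data.frame(subject_id = rows$subject_id, wall = "lateral",
               r2 = rows$r2_midlateral_global)
  )
}
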