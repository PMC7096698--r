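#' Area under the ROC curve (Mann-Whitney construction)
#'
#' AUC computed from midranks: tied score pairs count 1/2, so the value
#' equals `U / (n1 * n0)` with U the Mann-Whitney statistic. Higher scores
#' are taken to indicate the positive class; use `orientation = -1` to invert
#' a protective score.
#'
#' @param scores numeric vector.
#' @param labels binary vector (1/TRUE = positive class).
#' @param orientation +1 (default) if larger scores mean positive, -1 to flip.
#' @return Scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, orientation = 1) {
  ok <- is.finite(scores) & !is.na(labels)
  scores <- orientation * scores[ok]
  labels <- as.integer(as.logical(labels[ok]))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores)                       # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# placement values: for each positive, the fraction of negatives it beats
# (ties 1/2), and vice versa
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1L]               # positives
  y <- scores[labels == 0L]               # negatives
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi),
       m = m, n = n)
}

#' DeLong comparison of two correlated ROC curves
#'
#' Nonparametric comparison of the AUCs of two scores measured on the same
#' subjects, using placement-value (structural component) estimates of the
#' variance of each AUC and their covariance. The contrast statistic is
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov_ab)` with a two-sided
#' normal p-value; per-curve 95% confidence intervals are
#' `auc +- 1.96 sqrt(var)`.
#'
#' @param scores_a,scores_b paired score vectors on the same subjects.
#' @param labels binary vector (1 = positive class).
#' @param orientation_a,orientation_b +1/-1 score orientations (see
#'   [roc_auc()]).
#' @return A `roc_comparison` object: `auc_a`, `auc_b`, `var_a`, `var_b`,
#'   `cov_ab`, `z`, `p`, `ci_a`, `ci_b`, `m` (positives), `n` (negatives),
#'   `degenerate` flag (TRUE when the variance of the difference is zero and
#'   the p-value is undefined).
#' @export
delong_compare <- function(scores_a, scores_b, labels,
                           orientation_a = 1, orientation_b = 1) {
  ok <- is.finite(scores_a) & is.finite(scores_b) & !is.na(labels)
  a <- orientation_a * scores_a[ok]
  b <- orientation_b * scores_b[ok]
  lab <- as.integer(as.logical(labels[ok]))
  if (sum(lab == 1L) == 0L || sum(lab == 0L) == 0L)
    stop("both classes must be present", call. = FALSE)
  pa <- delong_placements(a, lab)
  pb <- delong_placements(b, lab)
  m <- pa$m; n <- pa$n
  s10 <- stats::cov(cbind(pa$v10, pb$v10))   # across positives
  s01 <- stats::cov(cbind(pa$v01, pb$v01))   # across negatives
  var_a <- s10[1, 1] / m + s01[1, 1] / n
  var_b <- s10[2, 2] / m + s01[2, 2] / n
  cov_ab <- s10[1, 2] / m + s01[1, 2] / n
  var_diff <- var_a + var_b - 2 * cov_ab
  degenerate <- var_diff <= .Machine$double.eps
  z <- if (degenerate) 0 else (pa$auc - pb$auc) / sqrt(var_diff)
  p <- if (degenerate) {
    if (abs(pa$auc - pb$auc) < .Machine$double.eps) 1 else NA_real_
  } else 2 * stats::pnorm(-abs(z))
  structure(
    list(auc_a = pa$auc, auc_b = pb$auc, var_a = var_a, var_b = var_b,
         cov_ab = cov_ab, z = z, p = p,
         ci_a = pa$auc + c(-1, 1) * 1.959964 * sqrt(var_a),
         ci_b = pb$auc + c(-1, 1) * 1.959964 * sqrt(var_b),
         m = m, n = n, degenerate = degenerate),
    class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat("DeLong comparison of correlated ROC curves\n")
  cat(sprintf("  AUC A: %.3f (95%% CI %.3f-%.3f)\n", x$auc_a, x$ci_a[1], x$ci_a[2]))
  cat(sprintf("  AUC B: %.3f (95%% CI %.3f-%.3f)\n", x$auc_b, x$ci_b[1], x$ci_b[2]))
  if (x$degenerate && is.na(x$p))
    cat("  zero variance of the AUC difference: p undefined\n")
  else cat(sprintf("  z = %.3f, p = %.4g\n", x$z, x$p))
  invisible(x)
}

#' Holm-Bonferroni step-down correction
#'
#' Adjusted p-values follow the step-down rule (computed with
#' `stats::p.adjust(method = "holm")`): sort ascending, multiply the i-th by
#' `m - i + 1`, enforce monotonicity, cap at 1. Hypotheses with adjusted
#' p-value below `alpha` are rejected.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (`NA` passed through).
#' @param alpha familywise error level in (0, 1).
#' @return A list with `adjusted` and logical `reject`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  adjusted <- stats::p.adjust(p_values, method = "holm")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted < alpha)
}
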