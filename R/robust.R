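#' Huber robust linear regression via IRLS
#'
#' M-estimation with the Huber weight function, fitted by iteratively
#' reweighted least squares. The residual scale is the median absolute
#' deviation about zero rescaled for consistency at the normal
#' (`median(|r|)/0.6745`), re-estimated at each iteration. Iteration stops
#' when the maximum absolute coefficient change falls below `tol` or after
#' `max_iter` iterations; non-convergence is flagged, not raised. Wald
#' t-statistics use the Huber-corrected covariance and a t reference
#' distribution with `n - p` degrees of freedom.
#'
#' @param outcome numeric response vector (no missing values; callers handle
#'   missingness by listwise deletion).
#' @param predictors numeric matrix or data.frame of predictors (a column of
#'   ones is added internally).
#' @param tuning Huber tuning constant (default 1.345, 95% efficiency at the
#'   normal). Large values recover ordinary least squares.
#' @param max_iter,tol IRLS iteration cap and coefficient-change tolerance.
#' @return A `robust_fit` object: `coefficients`, `standard_errors`,
#'   `t_values`, `p_values`, `scale_estimate`, `n_iterations`, `converged`,
#'   `residuals`, `fitted`, `weights`, `df_residual`, `n`.
#' @export
robust_fit <- function(outcome, predictors, tuning = 1.345,
                       max_iter = 50L, tol = 1e-8) {
  y <- as.numeric(outcome)
  X <- as.matrix(predictors)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- cbind(`(Intercept)` = 1, X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("outcome/predictor lengths differ", call. = FALSE)
  if (anyNA(y) || anyNA(X))
    stop("missing values: apply listwise deletion before fitting",
         call. = FALSE)
  if (n <= p)
    stop("need more observations than coefficients", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  converged <- FALSE
  iter <- 0L
  s <- 0
  repeat {
    iter <- iter + 1L
    r <- y - drop(X %*% beta)
    s <- stats::median(abs(r)) / 0.6744898
    if (s <= .Machine$double.eps * max(1, stats::median(abs(y)))) {
      converged <- TRUE  # exact fit: weights are all 1, nothing to reweight
      break
    }
    w <- pmin(1, tuning * s / abs(r))
    w[!is.finite(w)] <- 1
    fit <- stats::lm.wfit(X, y, w)
    beta_new <- fit$coefficients
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  r <- y - drop(X %*% beta)
  df_res <- n - p
  if (s > 0) {
    u <- r / s
    psi <- pmax(-tuning, pmin(tuning, u))
    psi_p <- as.numeric(abs(u) <= tuning)
    m1 <- mean(psi_p)
    kappa <- 1 + p / n * stats::var(psi_p) / m1^2   # Huber small-sample correction
    v <- kappa^2 * s^2 * sum(psi^2) / df_res / m1^2
  } else v <- 0
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(diag(XtXinv) * v, 0))
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  pval <- 2 * stats::pt(-abs(tval), df_res)
  structure(
    list(coefficients = beta, standard_errors = stats::setNames(se, names(beta)),
         t_values = stats::setNames(tval, names(beta)),
         p_values = stats::setNames(pval, names(beta)),
         scale_estimate = s, n_iterations = iter, converged = converged,
         residuals = r, fitted = drop(X %*% beta),
         weights = if (s > 0) pmin(1, tuning * s / pmax(abs(r), 1e-300)) else
           rep(1, n),
         df_residual = df_res, n = n, tuning = tuning),
    class = "robust_fit")
}

#' @export
coef.robust_fit <- function(object, ...) object$coefficients

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("Huber robust linear regression (n = %d, scale = %.4g, %s in %d iter)\n",
              x$n, x$scale_estimate,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(round(cbind(Estimate = x$coefficients, `Std.Error` = x$standard_errors,
                    t = x$t_values, p = x$p_values), 6))
  invisible(x)
}

#' @export
summary.robust_fit <- function(object, ...) {
  object
}

#' Percentage-bend robust correlation
#'
#' Wilcox's percentage-bend correlation with bend constant `beta`
#' (default 0.2): observations beyond the (1 - beta) quantile of absolute
#' deviation from the median are downweighted through the bend psi function.
#' The p-value uses the t approximation with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param beta bend constant in (0, 0.5).
#' @return A list with `r`, `p`, `n` and the test statistic `t`.
#' @export
robust_correlation <- function(x, y, beta = 0.2) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || length(y) != n)
    stop("need equal-length vectors with at least 4 complete pairs",
         call. = FALSE)
  pb_psi_scores <- function(v) {
    med <- stats::median(v)
    w <- sort(abs(v - med))
    m <- floor((1 - beta) * n + 0.5)
    omega <- w[m]
    if (omega <= 0)
      stop("zero robust spread: percentage-bend correlation undefined",
           call. = FALSE)
    z <- (v - med) / omega
    i1 <- sum(z < -1); i2 <- sum(z > 1)
    sv <- sum(v[abs(z) <= 1])
    phi <- (omega * (i2 - i1) + sv) / (n - i1 - i2)
    a <- (v - phi) / omega
    pmax(-1, pmin(1, a))
  }
  a <- pb_psi_scores(x)
  b <- pb_psi_scores(y)
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  list(r = r, p = p, n = n, t = tstat)
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a two-sided
#' normal p-value.
#'
#' @param r1,r2 correlation coefficients with |r| < 1.
#' @param n1,n2 sample sizes (> 3).
#' @return A list with `z` and `p`.
#' @export
fisher_rz_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| must be < 1 (atanh is infinite at 1)", call. = FALSE)
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both samples", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
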