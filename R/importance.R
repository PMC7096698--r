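# R^2 of the least-squares regression of y on X[, cols] (with intercept)
subset_r2 <- function(y, X, cols) {
  if (length(cols) == 0L) return(0)
  f <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
  1 - sum(f$residuals^2) / sum((y - mean(y))^2)
}

#' General dominance analysis
#'
#' Decomposes the model R^2 over predictors by full subset enumeration: each
#' predictor's incremental R^2 is averaged over all subsets of the remaining
#' predictors within each subset size, and those size-conditional averages
#' are averaged across sizes. The resulting general dominance weights sum to
#' the full-model R^2 exactly and account for predictor intercorrelation.
#'
#' @param outcome numeric response vector.
#' @param predictors numeric matrix/data.frame of p <= 15 predictors.
#' @return An `importance_result` with `dominance_weights`, `r_squared`,
#'   `pct_contribution` (percent of R^2, from the dominance weights) and `n`.
#' @export
dominance_analysis <- function(outcome, predictors) {
  X <- as.matrix(predictors)
  y <- as.numeric(outcome)
  p <- ncol(X)
  if (p > 15)
    stop("dominance enumeration limited to 15 predictors (2^p subsets); ",
         "reduce the predictor set", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  ok <- stats::complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y)
  if (n <= p + 1) stop("need n > p + 1 complete cases", call. = FALSE)
  nsub <- 2^p
  r2 <- numeric(nsub)                 # subset index = bitmask + 1
  for (m in seq_len(nsub) - 1L) {
    cols <- which(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    r2[m + 1L] <- subset_r2(y, X, cols)
  }
  dw <- numeric(p)
  for (i in seq_len(p)) {
    bit_i <- bitwShiftL(1L, i - 1L)
    others <- setdiff(seq_len(p), i)
    by_size <- numeric(p)             # sizes 0..p-1 of the conditioning subset
    cnt <- numeric(p)
    masks <- 0L
    if (length(others) > 0) {
      # enumerate subsets of the others via their bitmasks
      for (m in seq_len(2^(p - 1)) - 1L) {
        mask <- 0L
        mm <- m
        for (k in seq_along(others)) {
          if (bitwAnd(mm, 1L)) mask <- bitwOr(mask, bitwShiftL(1L, others[k] - 1L))
          mm <- bitwShiftR(mm, 1L)
        }
        sz <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
        inc <- r2[bitwOr(mask, bit_i) + 1L] - r2[mask + 1L]
        by_size[sz + 1L] <- by_size[sz + 1L] + inc
        cnt[sz + 1L] <- cnt[sz + 1L] + 1
      }
    } else {
      by_size[1] <- r2[bit_i + 1L]
      cnt[1] <- 1
    }
    dw[i] <- mean((by_size / cnt)[cnt > 0])
  }
  names(dw) <- colnames(X)
  r2_full <- r2[nsub]
  structure(
    list(dominance_weights = dw, r_squared = r2_full,
         pct_contribution = 100 * dw / sum(dw), n = n,
         predictors = colnames(X)),
    class = "importance_result")
}

#' Johnson's relative weights analysis
#'
#' Decomposes the model R^2 via an orthogonal counterpart of the predictor
#' matrix: with `R = P diag(d) P'` the predictor correlation matrix, the
#' loading matrix is its symmetric square root `L = P diag(sqrt(d)) P'`;
#' the relative weight of predictor j is `sum_k L[j,k]^2 * b*_k^2` where
#' `b* = L^{-1} r_xy` are the regression weights of the standardized outcome
#' on the orthogonalized predictors. Relative weights sum to R^2.
#'
#' @inheritParams dominance_analysis
#' @return An `importance_result` with `relative_weights`, `betas`
#'   (standardized coefficients), `r_squared`, `pct_contribution` (percent of
#'   R^2, from the relative weights) and `n`.
#' @export
relative_weights <- function(outcome, predictors) {
  X <- as.matrix(predictors)
  y <- as.numeric(outcome)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- stats::complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 complete cases", call. = FALSE)
  R <- stats::cor(X)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-10)
    stop("singular predictor correlation matrix", call. = FALSE)
  L <- ev$vectors %*% diag(sqrt(ev$values), p) %*% t(ev$vectors)
  rxy <- drop(stats::cor(X, y))
  beta_star <- solve(L, rxy)
  rw <- drop((L^2) %*% beta_star^2)
  names(rw) <- colnames(X)
  betas <- drop(solve(R, rxy))
  names(betas) <- colnames(X)
  r2 <- sum(rw)
  structure(
    list(relative_weights = rw, betas = betas, r_squared = r2,
         pct_contribution = 100 * rw / r2, n = n, predictors = colnames(X)),
    class = "importance_result")
}

#' Combined relative-importance table
#'
#' Runs [relative_weights()] and [dominance_analysis()] on the same data and
#' assembles the per-predictor table reported in the study output: the
#' standardized coefficient with its ordinary-least-squares p-value, the
#' relative weight, the percent contribution to R^2 (from relative weights)
#' and the general dominance weight.
#'
#' @inheritParams dominance_analysis
#' @return An `importance_result` containing the merged fields plus a
#'   `table` data.frame.
#' @export
importance_analysis <- function(outcome, predictors) {
  X <- as.matrix(predictors)
  y <- as.numeric(outcome)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ok <- stats::complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  rw <- relative_weights(y, X)
  dw <- dominance_analysis(y, X)
  # standardized-coefficient p-values from the OLS fit on z-scored data
  Z <- scale(X); yz <- drop(scale(y))
  fit <- stats::summary.lm(stats::lm(yz ~ Z))
  pvals <- fit$coefficients[-1, 4]
  tab <- data.frame(
    predictor = colnames(X),
    beta = unname(rw$betas),
    p = unname(pvals),
    relative_weight = unname(rw$relative_weights),
    pct_contribution = unname(rw$pct_contribution),
    dominance_weight = unname(dw$dominance_weights),
    row.names = NULL)
  structure(
    list(table = tab, betas = rw$betas, relative_weights = rw$relative_weights,
         dominance_weights = dw$dominance_weights,
         pct_contribution = rw$pct_contribution,
         r_squared = rw$r_squared, n = rw$n, predictors = colnames(X)),
    class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("Relative importance (R^2 = %.4f, n = %d)\n", x$r_squared, x$n))
  if (!is.null(x$table)) print(x$table, digits = 4)
  else {
    if (!is.null(x$relative_weights)) {
      cat("relative weights:\n"); print(round(x$relative_weights, 4))
    }
    if (!is.null(x$dominance_weights)) {
      cat("dominance weights:\n"); print(round(x$dominance_weights, 4))
    }
  }
  invisible(x)
}
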