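# In-code fixtures shared across test files.

# bundle whose skeleton carries exactly the supplied MD (and optional FA) values
bundle_from_values <- function(md_vals, fa_vals = NULL) {
  n <- length(md_vals)
  side <- ceiling(n^(1 / 3))
  dm <- c(side, side, max(2, ceiling(n / side^2)))
  md <- array(0, dm)
  fa <- array(0, dm)
  sk <- array(0L, dm)
  md[seq_len(n)] <- md_vals
  fa[seq_len(n)] <- if (is.null(fa_vals)) 0.5 else fa_vals
  sk[seq_len(n)] <- 1L
  suppressWarnings(skeleton_bundle(md, fa, sk))
}

# independent sort-and-interpolate percentile oracle (rank 1 + (n-1)q)
oracle_quantile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  r <- 1 + (n - 1) * q
  lo <- floor(r)
  hi <- ceiling(r)
  x[lo] + (r - lo) * (x[hi] - x[lo])
}
oracle_psmd <- function(x) oracle_quantile(x, 0.95) - oracle_quantile(x, 0.05)

# brute-force general dominance weights by explicit subset enumeration,
# independent of the package implementation (combn + lm)
oracle_dominance <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    summary(stats::lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  dw <- numeric(p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    size_means <- sapply(0:(p - 1), function(k) {
      subs <- if (k == 0) list(integer(0)) else
        utils::combn(others, k, simplify = FALSE)
      mean(sapply(subs, function(s) r2(c(s, i)) - r2(s)))
    })
    dw[i] <- mean(size_means)
  }
  dw
}

# brute-force AUC by pairwise comparison loop
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

small_phantom <- function(...) generate_phantom(phantom_spec(
  grid_shape = c(32, 32, 32), skeleton_fraction = 0.15, ...))
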