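ratings0 <- function(...) {
  args <- utils::modifyList(
    list(fazekas_pvh = 0, fazekas_dwmh = 0, epvs_cso = 0, epvs_bg = 0,
         epvs_midbrain = 0, microbleeds_lobar = 0, microbleeds_deep = 0,
         lacunes_lobar = 0, lacunes_deep = 0), list(...))
  do.call(svd_ratings, args)
}

test_that("rating validation enforces scale ranges and computes totals", {
  r <- ratings0(microbleeds_lobar = 2, microbleeds_deep = 1,
                lacunes_lobar = 1, lacunes_deep = 3)
  expect_equal(r$microbleeds_total, 3)
  expect_equal(r$lacunes_total, 4)
  expect_error(ratings0(fazekas_pvh = 4), "fazekas_pvh")
  expect_error(ratings0(epvs_bg = 5), "epvs_bg")
  expect_error(ratings0(microbleeds_deep = -1), "microbleeds_deep")
  expect_error(ratings0(epvs_cso = 1.5), "epvs_cso")
  # missing modality propagates to totals, not to errors
  rna <- validate_ratings(ratings0())
  rna$microbleeds_lobar <- NA
  rna <- validate_ratings(rna)
  expect_true(is.na(rna$microbleeds_total))
})

test_that("EPVS count-to-grade mapping is the exhaustive monotone step function", {
  expect_equal(epvs_count_to_grade(0), 0L)
  expect_equal(epvs_count_to_grade(11), 2L)
  expect_equal(epvs_count_to_grade(c(1, 10, 20, 21, 40, 41, 60)),
               c(1L, 1L, 2L, 3L, 3L, 4L, 4L))
  # exhaustive check against the binned definition, counts 0..60
  oracle <- function(k) {
    if (k == 0) 0L else if (k <= 10) 1L else if (k <= 20) 2L
    else if (k <= 40) 3L else 4L
  }
  g <- epvs_count_to_grade(0:60)
  expect_equal(g, vapply(0:60, oracle, integer(1)))
  expect_true(all(diff(g) >= 0))
  expect_error(epvs_count_to_grade(-1), "nonnegative")
})

test_that("lacune size filter keeps the inclusive 3-15 mm band", {
  f <- filter_lacunes(c(2.9, 3.0, 15.0, 15.1),
                      c("deep", "deep", "lobar", "lobar"))
  expect_equal(f$total, 2)
  expect_equal(f$deep, 1)
  expect_equal(f$lobar, 1)
  expect_equal(filter_lacunes(numeric(0), character(0))$total, 0)
  fd <- filter_lacunes(c(5, 7), c("deep", "deep"))
  expect_equal(fd$lobar, 0)
  expect_error(filter_lacunes(0, "deep"), "diameter")
})

test_that("burden score counts the four presence criteria and is monotone", {
  expect_equal(svd_burden_score(ratings0()), 0L)
  expect_equal(svd_burden_score(ratings0(
    fazekas_pvh = 3, epvs_bg = 2, lacunes_deep = 1, microbleeds_lobar = 1)), 4L)
  expect_equal(svd_burden_score(ratings0(fazekas_dwmh = 2)), 1L)
  expect_equal(svd_burden_score(ratings0(fazekas_pvh = 2)), 0L)

  # brute-force predicate oracle over a grid of rating combinations
  set.seed(41)
  for (i in 1:50) {
    r <- ratings0(fazekas_pvh = sample(0:3, 1), fazekas_dwmh = sample(0:3, 1),
                  epvs_bg = sample(0:4, 1), microbleeds_deep = sample(0:3, 1),
                  lacunes_lobar = sample(0:3, 1))
    expected <- (r$fazekas_pvh == 3 || r$fazekas_dwmh >= 2) +
      (r$epvs_bg >= 2) + (r$lacunes_total >= 1) + (r$microbleeds_total >= 1)
    expect_equal(svd_burden_score(r), as.integer(expected))
    # monotonicity: raising any marker never lowers the score
    r2 <- r
    r2$epvs_bg <- min(4, r$epvs_bg + 1)
    r2$microbleeds_deep <- r$microbleeds_deep + 1
    expect_gte(svd_burden_score(validate_ratings(r2)), svd_burden_score(r))
  }

  # missing SWI makes the score missing, not zero
  rna <- ratings0()
  rna$microbleeds_lobar <- NA
  expect_true(is.na(svd_burden_score(validate_ratings(rna))))
})

test_that("table ingestion validates row-wise with context", {
  df <- data.frame(fazekas_pvh = c(1, 3), fazekas_dwmh = c(0, 2),
                   epvs_cso = c(0, 1), epvs_bg = c(1, 2),
                   epvs_midbrain = c(0, 1), microbleeds_lobar = c(0, 2),
                   microbleeds_deep = c(0, 0), lacunes_lobar = c(0, 1),
                   lacunes_deep = c(0, 0))
  out <- ratings_from_table(df)
  expect_equal(out$svd_burden, c(0L, 4L))
  df$epvs_bg[2] <- 9
  expect_error(ratings_from_table(df), "row 2")
})
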