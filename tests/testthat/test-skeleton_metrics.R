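test_that("FA masking returns exactly the voxels passing both conditions", {
  # threshold partitions exactly
  md <- c(rep(1e-3, 50), rep(9e-3, 50))
  fa <- c(rep(0.5, 50), rep(0.1, 50))
  b <- bundle_from_values(md, fa)
  vals <- mask_skeleton(b, 0.2)
  expect_length(vals, 50)
  expect_true(all(vals == 1e-3))

  # no exclusion when all FA pass
  b2 <- bundle_from_values(rep(2e-3, 100), rep(0.5, 100))
  expect_length(mask_skeleton(b2, 0.2), 100)

  # random FA field vs brute-force voxel loop
  set.seed(101)
  n <- 500
  md <- runif(n, 5e-4, 1e-3)
  fa <- runif(n, 0, 1)
  b3 <- bundle_from_values(md, fa)
  count_oracle <- 0
  for (i in seq_len(n)) if (fa[i] >= 0.2) count_oracle <- count_oracle + 1
  expect_length(mask_skeleton(b3, 0.2), count_oracle)

  # threshold is inclusive: FA exactly 0.2 is kept
  b4 <- bundle_from_values(c(1, 2), c(0.2, 0.19))
  expect_equal(suppressWarnings(mask_skeleton(b4, 0.2)), 1)

  # empty survivors raise the empty-skeleton error
  b5 <- bundle_from_values(rep(1e-3, 10), rep(0.1, 10))
  expect_error(mask_skeleton(b5, 0.2), "empty skeleton")
})

test_that("PSMD matches hand-computed interpolated order statistics", {
  r <- compute_psmd(bundle_from_values(sample(1:100)))
  expect_equal(r$p95, 95.05)
  expect_equal(r$p5, 5.95)
  expect_equal(r$psmd, 89.1)
  expect_equal(r$n_voxels, 100)

  # constant field: zero width, exact mean, zero sd
  rc <- compute_psmd(bundle_from_values(rep(8e-4, 64)))
  expect_equal(rc$psmd, 0)
  expect_equal(rc$mean_md, 8e-4)
  expect_equal(rc$sd_md, 0)
})

test_that("PSMD converges to analytic normal and uniform quantile spreads", {
  set.seed(7)
  g <- rnorm(1e6, 7e-4, 1e-4)
  r <- psmdkit:::psmd_from_values(g)
  expect_lt(abs(r$psmd - 2 * qnorm(0.95) * 1e-4) / (2 * qnorm(0.95) * 1e-4),
            0.01)
  u <- runif(1e5, 6e-4, 1.2e-3)
  ru <- psmdkit:::psmd_from_values(u)
  expect_lt(abs(ru$psmd - 0.9 * 6e-4) / (0.9 * 6e-4), 0.02)
})

test_that("PSMD is scale-equivariant, translation-invariant and monotone in spread", {
  set.seed(8)
  for (rep in 1:5) {
    x <- rlnorm(200)
    r <- psmdkit:::psmd_from_values(x)
    rs <- psmdkit:::psmd_from_values(3.5 * x)
    expect_equal(rs$psmd, 3.5 * r$psmd)
    expect_equal(rs$p95, 3.5 * r$p95)
    expect_equal(rs$mean_md, 3.5 * r$mean_md)
    expect_equal(rs$sd_md, 3.5 * r$sd_md)
    rt <- psmdkit:::psmd_from_values(x + 2)
    expect_equal(rt$psmd, r$psmd)
    # mean-preserving symmetric dilation about the mean (may push values
    # negative; the retained-value warning is expected there)
    rd <- suppressWarnings(
      psmdkit:::psmd_from_values(mean(x) + 1.7 * (x - mean(x))))
    expect_gte(rd$psmd, r$psmd)
  }
})

test_that("regional PSMD restricts the statistic consistently", {
  ph <- small_phantom(seed = 5)
  reg <- compute_regional_psmd(ph$bundle, ph$atlas, min_voxels = 1)
  expect_setequal(reg$region, names(ph$atlas$legend))

  # union of per-region multisets equals the global multiset (atlas partitions
  # the brain, hence the skeleton)
  global <- sort(mask_skeleton(ph$bundle, 0.2))
  per_region <- sort(unlist(lapply(names(ph$atlas$legend), function(rg) {
    m <- ph$atlas$labels == ph$atlas$legend[[rg]]
    tryCatch(mask_skeleton(ph$bundle, 0.2, extra_mask = m),
             error = function(e) numeric(0))
  })))
  expect_equal(per_region, global)
  expect_equal(sum(reg$n_voxels), length(global))

  # single label covering everything reproduces the global value exactly
  labs <- array(1L, dim = ph$bundle$dim)
  atlas1 <- label_atlas(labs, c(all = 1))
  r1 <- compute_regional_psmd(ph$bundle, atlas1, min_voxels = 1)
  expect_equal(r1$psmd, compute_psmd(ph$bundle)$psmd)

  # identical value multisets give identical psmd (statistic is multiset-only)
  vals <- runif(200, 5e-4, 9e-4)
  expect_equal(psmdkit:::psmd_from_values(vals)$psmd,
               psmdkit:::psmd_from_values(sample(vals))$psmd)

  # undersized regions are reported missing with their observed count
  rmin <- compute_regional_psmd(ph$bundle, ph$atlas, min_voxels = 1e6)
  expect_true(all(is.na(rmin$psmd)))
  expect_true(all(rmin$n_voxels < 1e6))

  # shape mismatch errors
  bad <- label_atlas(array(1L, c(4, 4, 4)), c(all = 1))
  expect_error(compute_regional_psmd(ph$bundle, bad), "grid")
})

test_that("bundle validation enforces grid and value contracts", {
  expect_error(skeleton_bundle(array(0, c(4, 4, 4)), array(0, c(4, 4, 5)),
                               array(1L, c(4, 4, 4))), "grid")
  expect_error(skeleton_bundle(array(0, c(4, 4, 4)), array(2, c(4, 4, 4)),
                               array(1L, c(4, 4, 4))), "FA")
  expect_error(skeleton_bundle(array(0, c(4, 4, 4)), array(0.5, c(4, 4, 4)),
                               array(0L, c(4, 4, 4))), "foreground")
  expect_warning(
    skeleton_bundle(array(c(-1e-4, rep(1e-3, 63)), c(4, 4, 4)),
                    array(0.5, c(4, 4, 4)), array(1L, c(4, 4, 4))),
    "negative")
})
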