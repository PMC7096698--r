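cohort_small <- generate_cohort(cohort_sim_params(n_subjects = 120, seed = 81))
cfg <- study_config()

test_that("association battery fits both covariate models per marker", {
  assoc <- suppressMessages(run_association_battery(cohort_small, cfg))
  expect_setequal(unique(assoc$model), c(1, 2))
  m1 <- assoc[assoc$model == 1, ]
  expect_setequal(m1$marker, names(psmdkit:::association_markers()))
  expect_true(all(m1$p >= 0 & m1$p <= 1))
  expect_true(all(m1$p_holm >= m1$p - 1e-15))
  expect_true(all(assoc$n <= 120))
  # the WMH volume term is strongly associated under the default effects
  expect_true(m1$significant[m1$marker == "wmh_sqrt"])
  # covariate sets recorded per model
  expect_equal(unique(assoc$covariates[assoc$model == 1]), "head_motion")
  expect_match(unique(assoc$covariates[assoc$model == 2]), "diagnosis")
})

test_that("importance battery produces coherent decomposition tables", {
  imp <- run_importance_battery(cohort_small, cfg)
  expect_named(imp, c("regional", "four_markers", "neurodegeneration",
                      "neurodegeneration_adjusted", "cognition"))
  for (tab in imp) {
    for (blk in unique(tab$block)) {
      sl <- tab[tab$block == blk, ]
      expect_lt(abs(sum(sl$pct_contribution) - 100), 1e-6)
      expect_lt(abs(sum(sl$dominance_weight) - sl$r_squared[1]), 1e-9)
      expect_lt(abs(sum(sl$relative_weight) - sl$r_squared[1]), 1e-9)
    }
  }
  expect_setequal(unique(imp$regional$block),
                  c("wmh_fazekas", "wmh_volume", "epvs", "microbleeds",
                    "lacunes"))
})

test_that("regional matrix covers all region pairs with Fisher contrasts", {
  reg <- run_regional_matrix(cohort_small, cfg)
  expect_equal(nrow(reg$matrix), 64)
  expect_equal(nrow(reg$contrasts), 56)
  expect_true(all(abs(reg$matrix$r) <= 1))
  expect_true(all(reg$matrix$p_holm >= reg$matrix$p - 1e-15))
  # one shared latent drives all regions: cells uniformly positive, and the
  # corresponding-region contrasts mostly non-significant (diffuse effect)
  expect_true(all(reg$matrix$r > 0))
  expect_gt(mean(reg$contrasts$p > 0.05), 0.8)
})

test_that("ROC battery orients scores and self-contrast of PSMD is null", {
  roc <- run_roc_battery(cohort_small, cfg)
  expect_true("psmd" %in% roc$score)
  self <- roc[roc$score == "psmd", ]
  expect_equal(self$z_vs_psmd, 0)
  expect_equal(self$p_vs_psmd, 1)
  expect_true(all(roc$auc >= 0 & roc$auc <= 1))
  expect_true(all(roc$ci_lo <= roc$auc & roc$auc <= roc$ci_hi))
  # protective scores are inverted so oriented AUC aligns with impairment
  expect_equal(roc$orientation[roc$score == "gm_volume"], -1)
  expect_error(run_roc_battery(
    transform(cohort_small, acer = 100), cfg), "one impairment class")
})

test_that("extract_subject_metrics composes the imaging modules faithfully", {
  ph <- generate_phantom(phantom_spec(
    grid_shape = c(40, 40, 40), skeleton_fraction = 0.2, seed = 82,
    lesion_blobs = list(list(center = c(20, 20, 28), radius_mm = 6,
                             multiplier = 1.6))))
  ratings <- svd_ratings(2, 1, 1, 2, 0, 1, 0, 0, 0)
  rec <- extract_subject_metrics(
    ph$bundle, ph$flair, ph$brain_mask, ph$ventricle_mask, ph$atlas,
    ratings = ratings,
    covariates = list(subject_id = "P01", age = 71, acer = 80))
  expect_equal(rec$subject_id, "P01")
  expect_equal(rec$psmd, compute_psmd(ph$bundle)$psmd)
  seg <- partition_wmh(segment_wmh(ph$flair, ph$brain_mask, 1.40,
                                   ph$voxel_size),
                       ph$ventricle_mask, ph$atlas)
  expect_equal(rec$wmh_total_mm3, seg$total_volume)
  expect_equal(rec$wmh_pvh_mm3, seg$pvh_volume)
  # points: EPVS-BG grade 2 and one lobar microbleed (Fazekas 2/1 earns none)
  expect_equal(rec$svd_burden, 2L)
  expect_true(all(paste0("psmd_", psmdkit:::lobe_names()) %in% names(rec)))
  expect_false(is.null(attr(rec, "provenance")))

  # identical phantoms give identical records
  rec2 <- extract_subject_metrics(
    ph$bundle, ph$flair, ph$brain_mask, ph$ventricle_mask, ph$atlas,
    ratings = ratings,
    covariates = list(subject_id = "P01", age = 71, acer = 80))
  expect_identical(rec, rec2)

  # missing ratings propagate to a missing burden score
  rec3 <- extract_subject_metrics(
    ph$bundle, ph$flair, ph$brain_mask, ph$ventricle_mask, ph$atlas,
    ratings = NULL, covariates = list(subject_id = "P02"))
  expect_true(is.na(rec3$svd_burden))
})

test_that("run_study writes the full result set and respects the config", {
  dir <- withr::local_tempdir()
  res <- suppressMessages(run_study(
    study_config(sim = cohort_sim_params(n_subjects = 80)),
    out_dir = dir, seed = 83))
  expect_true(all(file.exists(file.path(dir, c(
    "subjects.csv", "associations.csv", "importance_cognition.csv",
    "regional_matrix.csv", "roc_comparison.csv", "run_log.txt",
    "config_resolved.yaml")))))
  expect_equal(nrow(res$cohort), 80)
  # YAML scenario round trip drives the same study
  cfg_path <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(list(sim = list(n_subjects = 80), seed = 83), cfg_path)
  cfg2 <- read_study_config(cfg_path)
  res2 <- suppressMessages(run_study(cfg2))
  expect_equal(res2$cohort$psmd, res$cohort$psmd)
})
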