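#' Study configuration
#'
#' Settings of the full analysis battery. Model 1 adjusts for head motion
#' only; Model 2 for head motion, sex, age and diagnostic group (control
#' reference). Cognitive impairment is defined by ACE-R below `acer_cutoff`
#' (default 83).
#'
#' @param sim a [cohort_sim_params()] describing the simulated cohort.
#' @param acer_cutoff ACE-R impairment cutoff.
#' @param alpha familywise significance level for Holm-Bonferroni.
#' @param min_complete minimum complete cases for a model to be fitted.
#' @param seed integer seed; overrides `sim$seed` when supplied to
#'   [run_study()].
#' @return A `study_config` object.
#' @export
study_config <- function(sim = cohort_sim_params(), acer_cutoff = 83,
                         alpha = 0.05, min_complete = 20, seed = NULL) {
  structure(list(sim = sim, acer_cutoff = acer_cutoff, alpha = alpha,
                 min_complete = min_complete, seed = seed,
                 model1_covariates = "head_motion",
                 model2_covariates = c("head_motion", "sex", "age",
                                       "diagnosis")),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Scenario files carry the [cohort_sim_params()] fields under `sim:` and the
#' [study_config()] fields at the top level.
#'
#' @param path YAML file path.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$group_proportions))
    sim_args$group_proportions <- unlist(sim_args$group_proportions)
  sim <- do.call(cohort_sim_params, sim_args)
  study_config(sim = sim,
               acer_cutoff = y$acer_cutoff %||% 83,
               alpha = y$alpha %||% 0.05,
               min_complete = y$min_complete %||% 20,
               seed = y$seed)
}

# design matrix for a covariate set; diagnosis expands to dummies
covariate_matrix <- function(cohort, covariates) {
  if (length(covariates) == 0L) return(NULL)
  cols <- list()
  for (cv in covariates) {
    if (cv == "diagnosis") {
      d <- stats::model.matrix(~diagnosis, data = cohort)[, -1, drop = FALSE]
      # model.matrix drops rows with NA silently only via na.action; cohort
      # diagnosis is always complete here
      for (j in seq_len(ncol(d))) cols[[colnames(d)[j]]] <- d[, j]
    } else cols[[cv]] <- cohort[[cv]]
  }
  do.call(cbind, cols)
}

# markers of the association battery, in display order (Table-2 analog)
association_markers <- function() {
  c(fazekas_pvh = "WMH Fazekas periventricular",
    fazekas_dwmh = "WMH Fazekas deep",
    fazekas_overall = "WMH Fazekas overall",
    wmh_pvh_sqrt = "WMH volume periventricular",
    wmh_dwmh_sqrt = "WMH volume deep",
    wmh_sqrt = "WMH volume overall",
    epvs_cso = "EPVS centrum semiovale",
    epvs_bg = "EPVS basal ganglia",
    epvs_midbrain = "EPVS midbrain",
    microbleeds_lobar = "Microbleeds lobar",
    microbleeds_deep = "Microbleeds deep",
    microbleeds_total = "Microbleeds total",
    lacunes_lobar = "Lacunes lobar",
    lacunes_deep = "Lacunes deep",
    lacunes_total = "Lacunes total",
    svd_burden = "Total SVD burden score")
}

#' Robust association battery between PSMD and SVD markers
#'
#' For each marker, fits `psmd ~ marker + covariates` by Huber robust
#' regression under the Model-1 ({head motion}) and Model-2 ({head motion,
#' sex, age, diagnosis}) covariate sets, with listwise deletion per model.
#' Holm-Bonferroni correction is applied across the marker battery within
#' each model.
#'
#' @param cohort cohort data.frame (see [generate_cohort()]).
#' @param config a [study_config()].
#' @return A data.frame with one row per marker x model: `marker`, `label`,
#'   `model`, `n`, `t`, `p`, `p_holm`, `significant`, `covariates`.
#' @export
run_association_battery <- function(cohort, config = study_config()) {
  markers <- association_markers()
  rows <- list()
  for (model in c(1, 2)) {
    covs <- if (model == 1) config$model1_covariates else
      config$model2_covariates
    cv_mat <- covariate_matrix(cohort, covs)
    for (mk in names(markers)) {
      x <- cohort[[mk]]
      X <- cbind(stats::setNames(data.frame(x), mk), cv_mat)
      ok <- stats::complete.cases(cohort$psmd, X)
      n_ok <- sum(ok)
      if (n_ok < config$min_complete) {
        message(sprintf("model %d, %s: only %d complete cases, skipped",
                        model, mk, n_ok))
        next
      }
      fit <- robust_fit(cohort$psmd[ok], as.matrix(X[ok, , drop = FALSE]))
      rows[[length(rows) + 1L]] <- data.frame(
        marker = mk, label = markers[[mk]], model = model, n = n_ok,
        estimate = unname(fit$coefficients[mk]),
        t = unname(fit$t_values[mk]), p = unname(fit$p_values[mk]),
        covariates = paste(covs, collapse = "+"))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_holm <- NA_real_
  out$significant <- NA
  for (model in c(1, 2)) {
    sel <- out$model == model
    hb <- holm_bonferroni(out$p[sel], config$alpha)
    out$p_holm[sel] <- hb$adjusted
    out$significant[sel] <- hb$reject
  }
  out
}

#' Relative-importance battery
#'
#' Produces the study's four importance tables:
#' (a) within-marker regional importance for PSMD (Fazekas PVH vs DWMH,
#' volumetric PVH vs DWMH, EPVS CSO/BG/midbrain, lobar vs deep microbleeds,
#' lobar vs deep lacunes); (b) four-marker importance for PSMD (WMH volume,
#' EPVS-BG, microbleed count, lacune count); (c) WMH vs GM vs WM volume for
#' PSMD, without and with diagnosis and ACE-R as additional predictors; and
#' (d) PSMD plus the four markers for ACE-R. Each table carries standardized
#' beta, relative weight, percent contribution to R^2 and general dominance
#' weight.
#'
#' @inheritParams run_association_battery
#' @return A named list of data.frames: `regional`, `four_markers`,
#'   `neurodegeneration`, `neurodegeneration_adjusted`, `cognition`.
#' @export
run_importance_battery <- function(cohort, config = study_config()) {
  imp_table <- function(outcome, pred_cols, block) {
    X <- cohort[, pred_cols, drop = FALSE]
    if ("diagnosis" %in% pred_cols) {
      X <- cbind(X[setdiff(pred_cols, "diagnosis")],
                 covariate_matrix(cohort, "diagnosis"))
    }
    y <- cohort[[outcome]]
    res <- importance_analysis(y, X)
    cbind(block = block, outcome = outcome, res$table,
          r_squared = res$r_squared, n = res$n)
  }
  regional <- rbind(
    imp_table("psmd", c("fazekas_pvh", "fazekas_dwmh"), "wmh_fazekas"),
    imp_table("psmd", c("wmh_pvh_sqrt", "wmh_dwmh_sqrt"), "wmh_volume"),
    imp_table("psmd", c("epvs_cso", "epvs_bg", "epvs_midbrain"), "epvs"),
    imp_table("psmd", c("microbleeds_lobar", "microbleeds_deep"),
              "microbleeds"),
    imp_table("psmd", c("lacunes_lobar", "lacunes_deep"), "lacunes"))
  four <- imp_table("psmd", c("wmh_sqrt", "epvs_bg", "microbleeds_total",
                              "lacunes_total"), "four_markers")
  neuro <- imp_table("psmd", c("wmh_sqrt", "gm_volume", "wm_volume"),
                     "wmh_gm_wm")
  neuro_adj <- imp_table("psmd", c("wmh_sqrt", "gm_volume", "wm_volume",
                                   "diagnosis", "acer"), "wmh_gm_wm_adjusted")
  cogn <- imp_table("acer", c("psmd", "wmh_sqrt", "epvs_bg",
                              "microbleeds_total", "lacunes_total"),
                    "cognition")
  list(regional = regional, four_markers = four, neurodegeneration = neuro,
       neurodegeneration_adjusted = neuro_adj, cognition = cogn)
}

#' Regional PSMD x WMH robust correlation matrix
#'
#' Percentage-bend correlation of every regional PSMD with every regional
#' WMH volume, Holm-Bonferroni corrected across all cells, plus a
#' corresponding-vs-non-corresponding Fisher r-to-z contrast for every
#' off-diagonal pair (the correlation of a region with itself versus with the
#' other region).
#'
#' @inheritParams run_association_battery
#' @return A list with `matrix` (long data.frame: `psmd_region`,
#'   `wmh_region`, `r`, `p`, `p_holm`, `n`) and `contrasts` (data.frame of
#'   Fisher z tests).
#' @export
run_regional_matrix <- function(cohort, config = study_config()) {
  lobes <- lobe_names()
  cells <- expand.grid(psmd_region = lobes, wmh_region = lobes,
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    pc <- paste0("psmd_", cells$psmd_region[i])
    wc <- paste0("wmh_", cells$wmh_region[i], "_sqrt")
    if (!pc %in% names(cohort) || !wc %in% names(cohort)) {
      message(sprintf("missing column for %s x %s, skipped", pc, wc))
      return(NULL)
    }
    ok <- stats::complete.cases(cohort[[pc]], cohort[[wc]])
    rc <- robust_correlation(cohort[[pc]][ok], cohort[[wc]][ok])
    data.frame(psmd_region = cells$psmd_region[i],
               wmh_region = cells$wmh_region[i],
               r = rc$r, p = rc$p, n = rc$n)
  })
  mat <- do.call(rbind, res)
  hb <- holm_bonferroni(mat$p, config$alpha)
  mat$p_holm <- hb$adjusted
  mat$significant <- hb$reject
  key <- paste(mat$psmd_region, mat$wmh_region)
  r_of <- function(pr, wr) mat$r[key == paste(pr, wr)]
  n_of <- function(pr, wr) mat$n[key == paste(pr, wr)]
  contr <- list()
  for (pr in lobes) for (wr in lobes) {
    if (pr == wr) next
    fz <- fisher_rz_compare(r_of(pr, pr), n_of(pr, pr), r_of(pr, wr),
                            n_of(pr, wr))
    contr[[length(contr) + 1L]] <- data.frame(
      psmd_region = pr, wmh_region = wr,
      r_corresponding = r_of(pr, pr), r_noncorresponding = r_of(pr, wr),
      z = fz$z, p = fz$p)
  }
  list(matrix = mat, contrasts = do.call(rbind, contr))
}

# ROC battery score set with orientations: +1 = larger score indicates
# impairment (pathology markers), -1 for protective scores (volumes, FA)
roc_score_set <- function() {
  data.frame(
    score = c("psmd", "wmh_sqrt", "fazekas_overall", "epvs_bg",
              "microbleeds_total", "lacunes_total", "svd_burden",
              "gm_volume", "wm_volume", "mean_md", "sd_md", "mean_fa",
              "sd_fa"),
    orientation = c(1, 1, 1, 1, 1, 1, 1, -1, -1, 1, 1, -1, -1))
}

#' ROC battery: discriminating cognitive impairment
#'
#' Labels subjects impaired iff ACE-R < `config$acer_cutoff`, computes AUC
#' with a DeLong 95% CI for PSMD, each SVD marker and the global brain/DTI
#' measures, and contrasts every score against PSMD with DeLong's test.
#' Score orientations are fixed so that larger oriented scores indicate
#' impairment (volumes and FA inverted) and are recorded per score.
#'
#' @inheritParams run_association_battery
#' @return A data.frame, one row per score: `score`, `orientation`, `n_imp`,
#'   `n_healthy`, `auc`, `ci_lo`, `ci_hi`, `z_vs_psmd`, `p_vs_psmd`.
#' @export
run_roc_battery <- function(cohort, config = study_config()) {
  impaired <- as.integer(cohort$acer < config$acer_cutoff)
  if (length(unique(impaired[!is.na(impaired)])) < 2L)
    stop("only one impairment class present at the ACE-R cutoff",
         call. = FALSE)
  ss <- roc_score_set()
  rows <- lapply(seq_len(nrow(ss)), function(i) {
    sc <- ss$score[i]; orient <- ss$orientation[i]
    ok <- stats::complete.cases(cohort[[sc]], cohort$psmd, impaired)
    dl <- delong_compare(cohort[[sc]][ok], cohort$psmd[ok], impaired[ok],
                         orientation_a = orient, orientation_b = 1)
    data.frame(score = sc, orientation = orient, n_imp = dl$m,
               n_healthy = dl$n, auc = dl$auc_a,
               ci_lo = dl$ci_a[1], ci_hi = dl$ci_a[2],
               z_vs_psmd = dl$z, p_vs_psmd = dl$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full synthetic study
#'
#' Generates a cohort from the configured simulation parameters and runs the
#' complete analysis battery: robust associations between PSMD and each SVD
#' marker (Models 1 and 2), the relative-importance tables, the regional
#' PSMD x WMH correlation matrix with Fisher contrasts, and the ROC battery
#' against cognitive impairment. Output CSVs are byte-identical across runs
#' at a fixed seed; timestamps appear only in `run_log.txt`.
#'
#' @param config a [study_config()].
#' @param out_dir output directory, created if needed; when `NULL` nothing is
#'   written.
#' @param seed optional seed overriding `config$seed` / `config$sim$seed`.
#' @return Invisibly, a list with `cohort`, `associations`, `importance`,
#'   `regional`, `roc` and the resolved `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL, seed = NULL) {
  seed <- seed %||% config$seed %||% config$sim$seed
  config$sim$seed <- as.integer(seed)
  config$seed <- as.integer(seed)
  cohort <- generate_cohort(config$sim)
  cohort$impaired <- as.integer(cohort$acer < config$acer_cutoff)
  assoc <- run_association_battery(cohort, config)
  imp <- run_importance_battery(cohort, config)
  reg <- run_regional_matrix(cohort, config)
  roc <- run_roc_battery(cohort, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name)
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    wr(cohort, "subjects.csv")
    wr(assoc, "associations.csv")
    for (nm in names(imp)) wr(imp[[nm]], paste0("importance_", nm, ".csv"))
    wr(reg$matrix, "regional_matrix.csv")
    wr(reg$contrasts, "regional_contrasts.csv")
    wr(roc, "roc_comparison.csv")
    cfg <- config
    cfg$sim <- unclass(cfg$sim)
    cfg$sim$group_proportions <- as.list(cfg$sim$group_proportions)
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_resolved.yaml"))
    writeLines(c(sprintf("run completed %s", format(Sys.time())),
                 sprintf("seed %d, n_subjects %d", seed,
                         config$sim$n_subjects)),
               file.path(out_dir, "run_log.txt"))
  }
  invisible(list(cohort = cohort, associations = assoc, importance = imp,
                 regional = reg, roc = roc, config = config))
}

#' Extract one subject record from template-space volumes
#'
#' Composes the imaging modules: PSMD (global and regional) from the MD/FA/
#' skeleton bundle, WMH segmentation, periventricular/deep and lobar
#' partition from the FLAIR image, TIV from the brain mask, and the
#' semi-quantitative ratings with the burden score. Every derived field is
#' recomputable from its inputs; the provenance attribute records parameters
#' and input checksums.
#'
#' @param bundle a [skeleton_bundle()].
#' @param flair,brain_mask,ventricle_mask volumes on the bundle grid.
#' @param atlas a [label_atlas()].
#' @param ratings a validated [svd_ratings()] record, or `NULL` if the
#'   rating modalities are missing.
#' @param covariates named list with `subject_id`, `age`, `sex`,
#'   `diagnosis`, `head_motion`, `acer`, `mmse` (missing entries become NA).
#' @param fa_threshold,k,pv_distance_mm component parameters.
#' @return One-row data.frame with a `provenance` attribute.
#' @export
extract_subject_metrics <- function(bundle, flair, brain_mask, ventricle_mask,
                                    atlas, ratings = NULL,
                                    covariates = list(),
                                    fa_threshold = 0.2, k = 1.40,
                                    pv_distance_mm = 10) {
  ctx <- covariates$subject_id %||% "subject"
  step <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s: %s failed: %s", ctx, what, conditionMessage(e)),
           call. = FALSE))
  }
  ps <- step("PSMD", compute_psmd(bundle, fa_threshold))
  reg <- step("regional PSMD", compute_regional_psmd(bundle, atlas,
                                                     fa_threshold))
  seg <- step("WMH segmentation",
              segment_wmh(flair, brain_mask, k, bundle$voxel_size))
  seg <- step("WMH partition",
              partition_wmh(seg, ventricle_mask, atlas, pv_distance_mm))
  tiv <- sum(brain_mask != 0) * prod(bundle$voxel_size)
  nt <- normalize_and_transform(seg$total_volume, tiv)
  rec <- data.frame(
    subject_id = ctx,
    psmd = ps$psmd, mean_md = ps$mean_md, sd_md = ps$sd_md,
    mean_fa = ps$mean_fa, sd_fa = ps$sd_fa,
    wmh_total_mm3 = seg$total_volume, wmh_pvh_mm3 = seg$pvh_volume,
    wmh_dwmh_mm3 = seg$dwmh_volume,
    wmh_norm = nt$normalized, wmh_sqrt = nt$transformed,
    tiv_mm3 = tiv,
    age = covariates$age %||% NA, sex = covariates$sex %||% NA,
    head_motion = covariates$head_motion %||% NA,
    acer = covariates$acer %||% NA, mmse = covariates$mmse %||% NA,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(reg)))
    rec[[paste0("psmd_", reg$region[i])]] <- reg$psmd[i]
  lv <- seg$lobar_volumes
  for (nm in names(lv))
    rec[[paste0("wmh_", nm, "_sqrt")]] <-
      normalize_and_transform(lv[[nm]], tiv)$transformed
  if (!is.null(ratings)) {
    ratings <- validate_ratings(ratings)
    for (f in c("fazekas_pvh", "fazekas_dwmh", "epvs_cso", "epvs_bg",
                "epvs_midbrain", "microbleeds_lobar", "microbleeds_deep",
                "microbleeds_total", "lacunes_lobar", "lacunes_deep",
                "lacunes_total"))
      rec[[f]] <- ratings[[f]]
    rec$svd_burden <- svd_burden_score(ratings)
  } else {
    rec$svd_burden <- NA_integer_
  }
  attr(rec, "provenance") <- list(
    fa_threshold = fa_threshold, k = k, pv_distance_mm = pv_distance_mm,
    grid = bundle$dim, voxel_size = bundle$voxel_size,
    checksums = c(md = sum(bundle$md), fa = sum(bundle$fa),
                  flair = sum(flair)))
  rec
}
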