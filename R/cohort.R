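#' Parameters of the synthetic cohort generator
#'
#' Defines the generative model of a subject table with the dependence
#' structure the downstream analyses assume: a latent per-subject SVD
#' severity drives WMH volume (log-normal), microbleed and lacune counts
#' (negative binomial) and EPVS grades (thresholded latent) with loading
#' `marker_correlation`; PSMD is a linear function of transformed WMH volume,
#' microbleed count and head motion plus Gaussian noise; ACE-R is a linear
#' function of PSMD and GM volume plus noise, truncated to \[0, 100\]; MMSE
#' derives from ACE-R with noise, truncated to \[0, 30\]. Diagnostic groups
#' act as additive shifts on latent severity and on ACE-R; head motion is a
#' positive scalar correlated with latent severity
#' (`motion_severity_cor`, default 0.2), reproducing the confounding that the
#' analyses adjust for.
#'
#' Default magnitudes are anchored to the marginal moments of a 145-subject
#' memory-clinic cohort (PSMD 5.5e-4 (1.0e-4) mm^2/s, sqrt-normalized WMH
#' 0.69 (0.71), GM 39.0 (2.9) % TIV, microbleeds 1.44 (6.3), lacunes
#' 0.86 (2.7), ACE-R 79.4 (15.0)) with diagnostic group proportions
#' 33/20/16/23/26/6/21 over control, MCI, AD, PSP, DLB, depression and FTD.
#'
#' @param n_subjects number of subjects (>= 4).
#' @param effect_wmh_on_psmd PSMD slope per unit sqrt-normalized WMH
#'   (mm^2/s per sqrt(% TIV)).
#' @param effect_mb_on_psmd PSMD slope per microbleed (mm^2/s).
#' @param effect_motion_on_psmd PSMD slope per head-motion unit (mm^2/s).
#' @param effect_psmd_on_acer ACE-R slope per mm^2/s of PSMD.
#' @param effect_gm_on_acer ACE-R slope per % TIV of gray matter.
#' @param noise_sd_psmd,noise_sd_acer residual standard deviations (>= 0).
#' @param marker_correlation latent-severity loading shared across the four
#'   SVD markers, in \[0, 1\].
#' @param group_proportions named proportions per diagnostic label
#'   (sum to 1).
#' @param motion_severity_cor correlation of head motion with latent severity.
#' @param missing_swi_prob,missing_flair_prob per-subject probabilities of a
#'   missing susceptibility-weighted scan (no microbleed data, burden score
#'   missing) and of missing volumetric FLAIR (no WMH volumes).
#' @param psmd_intercept,acer_intercept linear-model intercepts.
#' @param mb_dispersion,lacune_dispersion negative-binomial size parameters.
#' @param seed integer RNG seed.
#' @return A `cohort_sim_params` object.
#' @export
cohort_sim_params <- function(n_subjects = 145,
                              effect_wmh_on_psmd = 1.0e-4,
                              effect_mb_on_psmd = 2e-6,
                              effect_motion_on_psmd = 8e-5,
                              effect_psmd_on_acer = -8e4,
                              effect_gm_on_acer = 1.5,
                              noise_sd_psmd = 5e-5,
                              noise_sd_acer = 7,
                              marker_correlation = 0.6,
                              group_proportions = c(
                                control = 33, mci = 20, ad = 16, psp = 23,
                                dlb = 26, depression = 6, ftd = 21) / 145,
                              motion_severity_cor = 0.2,
                              missing_swi_prob = 3 / 145,
                              missing_flair_prob = 16 / 145,
                              psmd_intercept = 4.7e-4,
                              acer_intercept = 82,
                              mb_dispersion = 0.25,
                              lacune_dispersion = 0.3,
                              seed = 1L) {
  out <- mget(names(formals()))
  if (n_subjects < 4) stop("n_subjects must be >= 4", call. = FALSE)
  stop_if_not_scalar_number(noise_sd_psmd, "noise_sd_psmd", 0, Inf)
  stop_if_not_scalar_number(noise_sd_acer, "noise_sd_acer", 0, Inf)
  stop_if_not_scalar_number(marker_correlation, "marker_correlation", 0, 1)
  if (abs(sum(group_proportions) - 1) > 1e-9)
    stop("group_proportions must sum to 1", call. = FALSE)
  if (is.null(names(group_proportions)))
    stop("group_proportions must be named", call. = FALSE)
  structure(out, class = "cohort_sim_params")
}

# additive group effects: latent SVD severity, ACE-R shift, GM/WM shift
group_effects <- function() {
  data.frame(
    group = c("control", "mci", "ad", "psp", "dlb", "depression", "ftd"),
    sev = c(-0.8, 0.0, 0.2, 0.3, 0.3, -0.3, 0.2),
    acer = c(9, -1, -9, -5, -7, 0, -6),
    gm = c(2, 0, -3, -2, -2, 1, -3))
}

#' Generate a synthetic subject cohort
#'
#' Draws `n_subjects` subject records under the generative model described in
#' [cohort_sim_params()]. Identical parameters (including seed) reproduce an
#' identical table.
#'
#' Column dictionary: `subject_id`; `diagnosis` (factor, control reference);
#' `sex` (0 = male, 1 = female); `age` (years); `head_motion` (a.u., ~1);
#' `tiv_mm3`; `gm_volume`, `wm_volume` (% TIV); `mean_md`, `sd_md`
#' (10^-3 mm^2/s), `mean_fa`, `sd_fa`; WMH volumes `wmh_total_mm3`,
#' `wmh_pvh_mm3`, `wmh_dwmh_mm3` and their normalized (`_norm`, % TIV) and
#' sqrt-transformed (`_sqrt`) versions; Fazekas grades `fazekas_pvh`,
#' `fazekas_dwmh`, `fazekas_overall`; EPVS `epvs_cso`, `epvs_bg`,
#' `epvs_midbrain`; counts `microbleeds_lobar/deep/total`,
#' `lacunes_lobar/deep/total`; `svd_burden` (0-4); `psmd` (mm^2/s) and
#' `psmd_<lobe>` for the 8 octant lobes; `wmh_<lobe>_sqrt`; cognition `acer`
#' (0-100) and `mmse` (0-30).
#'
#' @param params a [cohort_sim_params()].
#' @return A data.frame with one row per subject.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  n <- p$n_subjects
  with_seed(p$seed, {
    ge <- group_effects()
    groups <- names(p$group_proportions)
    unknown <- setdiff(groups, ge$group)
    sev_shift <- stats::setNames(rep(0, length(groups)), groups)
    acer_shift <- sev_shift; gm_shift <- sev_shift
    known <- intersect(groups, ge$group)
    sev_shift[known] <- ge$sev[match(known, ge$group)]
    acer_shift[known] <- ge$acer[match(known, ge$group)]
    gm_shift[known] <- ge$gm[match(known, ge$group)]
    # deterministic group sizes closest to the proportions
    sizes <- floor(p$group_proportions * n)
    rem <- n - sum(sizes)
    if (rem > 0) {
      frac <- p$group_proportions * n - sizes
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      sizes[add] <- sizes[add] + 1
    }
    diagnosis <- factor(sample(rep(groups, times = sizes)), levels = groups)

    mc <- p$marker_correlation
    co <- sqrt(1 - mc^2)
    L <- sev_shift[as.character(diagnosis)] + stats::rnorm(n)   # latent severity

    sex <- stats::rbinom(n, 1, 0.393)              # 1 = female
    age <- stats::rnorm(n, 70.6, 7.8)
    rho <- p$motion_severity_cor
    head_motion <- exp(0.3 * (rho * L + sqrt(max(0, 1 - rho^2)) *
                                stats::rnorm(n)))
    tiv <- stats::rnorm(n, 1.45e6, 1.2e5)
    gm <- 39.9 + gm_shift[as.character(diagnosis)] + stats::rnorm(n, 0, 2.3)
    wm <- 33.0 + 0.5 * gm_shift[as.character(diagnosis)] + stats::rnorm(n, 0, 2.4)

    # WMH: log-normal volume driven by the shared latent
    lw <- mc * L + co * stats::rnorm(n)
    wmh_total <- exp(log(5500) + 1.4 * lw)
    pvh_frac <- stats::plogis(1 + 0.3 * lw + stats::rnorm(n, 0, 0.3))
    wmh_pvh <- pvh_frac * wmh_total
    wmh_dwmh <- wmh_total - wmh_pvh
    nt <- normalize_and_transform(wmh_total, tiv)
    np <- normalize_and_transform(wmh_pvh, tiv)
    nd <- normalize_and_transform(wmh_dwmh, tiv)

    grade_cut <- function(z, cuts)
      as.integer(cut(z, breaks = c(-Inf, cuts, Inf), labels = FALSE)) - 1L
    fazekas_pvh <- grade_cut(lw + stats::rnorm(n, 0, 0.3), c(-1.2, 0.2, 1.3))
    fazekas_dwmh <- grade_cut(lw + stats::rnorm(n, 0, 0.3), c(-1.0, 0.5, 1.6))
    fazekas_overall <- pmax(fazekas_pvh, fazekas_dwmh)

    le <- mc * L + co * stats::rnorm(n)
    epvs_bg <- grade_cut(le, c(-1.8, 0.4, 1.6, 2.8))
    epvs_cso <- grade_cut(mc * L + co * stats::rnorm(n), c(-1.8, 0.4, 1.6, 2.8))
    epvs_midbrain <- as.integer(le + stats::rnorm(n, 0, 0.5) > 1.2)

    lm_ <- mc * L + co * stats::rnorm(n)
    mb_total <- stats::rnbinom(n, size = p$mb_dispersion,
                               mu = exp(log(0.6) + 1.2 * lm_))
    mb_lobar <- stats::rbinom(n, mb_total, 0.6)
    mb_deep <- mb_total - mb_lobar
    ll <- mc * L + co * stats::rnorm(n)
    lac_total <- stats::rnbinom(n, size = p$lacune_dispersion,
                                mu = exp(log(0.5) + 1.0 * ll))
    lac_lobar <- stats::rbinom(n, lac_total, 0.6)
    lac_deep <- lac_total - lac_lobar

    psmd <- p$psmd_intercept +
      p$effect_wmh_on_psmd * nt$transformed +
      p$effect_mb_on_psmd * mb_total +
      p$effect_motion_on_psmd * (head_motion - 1) +
      stats::rnorm(n, 0, p$noise_sd_psmd)

    mean_md <- 0.77 + 0.03 * (0.7 * L + 0.3 * stats::rnorm(n))
    sd_md <- 1000 * psmd / 3.2898 * (1 + stats::rnorm(n, 0, 0.05))
    mean_fa <- 0.49 - 0.02 * L + stats::rnorm(n, 0, 0.02)
    sd_fa <- pmax(0.02, 0.12 + 0.01 * L + stats::rnorm(n, 0, 0.01))

    acer_raw <- p$acer_intercept + acer_shift[as.character(diagnosis)] +
      p$effect_psmd_on_acer * (psmd - 5.5e-4) +
      p$effect_gm_on_acer * (gm - 39) +
      stats::rnorm(n, 0, p$noise_sd_acer)
    acer <- pmin(100, pmax(0, acer_raw))
    mmse <- pmin(30, pmax(0, round(0.3 * acer + stats::rnorm(n, 0, 1.5))))

    lobes <- lobe_names()
    reg_psmd <- sapply(lobes, function(l) psmd + stats::rnorm(n, 0, 2.5e-5))
    colnames(reg_psmd) <- paste0("psmd_", lobes)
    # lobar WMH: total volume split by noisy log-weights (diffuse pattern)
    wshare <- matrix(stats::rnorm(n * 8, 0, 0.4), n, 8)
    wshare <- exp(wshare) / rowSums(exp(wshare))
    reg_wmh <- sapply(seq_along(lobes), function(j)
      sqrt(100 * wmh_total * wshare[, j] / tiv))
    colnames(reg_wmh) <- paste0("wmh_", lobes, "_sqrt")

    df <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      diagnosis = diagnosis, sex = sex, age = age,
      head_motion = head_motion, tiv_mm3 = tiv,
      gm_volume = gm, wm_volume = wm,
      mean_md = mean_md, sd_md = sd_md, mean_fa = mean_fa, sd_fa = sd_fa,
      wmh_total_mm3 = wmh_total, wmh_pvh_mm3 = wmh_pvh,
      wmh_dwmh_mm3 = wmh_dwmh,
      wmh_norm = nt$normalized, wmh_sqrt = nt$transformed,
      wmh_pvh_sqrt = np$transformed, wmh_dwmh_sqrt = nd$transformed,
      fazekas_pvh = fazekas_pvh, fazekas_dwmh = fazekas_dwmh,
      fazekas_overall = fazekas_overall,
      epvs_cso = epvs_cso, epvs_bg = epvs_bg, epvs_midbrain = epvs_midbrain,
      microbleeds_lobar = mb_lobar, microbleeds_deep = mb_deep,
      microbleeds_total = mb_total,
      lacunes_lobar = lac_lobar, lacunes_deep = lac_deep,
      lacunes_total = lac_total,
      psmd = psmd, acer = acer, mmse = mmse,
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(reg_psmd), as.data.frame(reg_wmh))

    # missing modalities: no SWI -> no microbleed data; no volumetric FLAIR
    miss_swi <- stats::runif(n) < p$missing_swi_prob
    miss_flair <- stats::runif(n) < p$missing_flair_prob
    mb_cols <- c("microbleeds_lobar", "microbleeds_deep", "microbleeds_total")
    df[miss_swi, mb_cols] <- NA
    wmh_vol_cols <- c("wmh_total_mm3", "wmh_pvh_mm3", "wmh_dwmh_mm3",
                      "wmh_norm", "wmh_sqrt", "wmh_pvh_sqrt", "wmh_dwmh_sqrt",
                      paste0("wmh_", lobes, "_sqrt"))
    df[miss_flair, wmh_vol_cols] <- NA

    df$svd_burden <- vapply(seq_len(n), function(i) {
      rec <- list(
        fazekas_pvh = df$fazekas_pvh[i], fazekas_dwmh = df$fazekas_dwmh[i],
        epvs_cso = df$epvs_cso[i], epvs_bg = df$epvs_bg[i],
        epvs_midbrain = df$epvs_midbrain[i],
        microbleeds_lobar = df$microbleeds_lobar[i],
        microbleeds_deep = df$microbleeds_deep[i],
        lacunes_lobar = df$lacunes_lobar[i],
        lacunes_deep = df$lacunes_deep[i],
        possible_microbleeds = 0L)
      as.integer(svd_burden_score(validate_ratings(rec)))
    }, integer(1))
    rownames(df) <- NULL
    df
  })
}

#' Named simulation scenarios
#'
#' Predefined parameterizations of [cohort_sim_params()] that express the
#' generative conditions probed by the validation suite:
#'
#' * `"default"` — the reference cohort (moments anchored to the 145-subject
#'   memory-clinic profile).
#' * `"wmh_driver"` — WMH is the dominant PSMD driver: a large WMH slope
#'   (1.5e-4 per sqrt(% TIV)) relative to the PSMD residual SD (5e-5).
#' * `"psmd_driver"` — PSMD is the dominant driver of cognition: a large
#'   ACE-R slope on PSMD (-1.5e5 per mm^2/s) against a modest GM slope (0.8)
#'   and residual SD 6.
#' * `"motion_driver"` — head motion is the sole PSMD driver (marker slopes
#'   zero, motion slope 1.5e-4), for confounder-adjustment checks.
#' * `"null"` — all effect slopes zero, for type-I-error and familywise-error
#'   checks.
#'
#' @param name scenario name.
#' @param ... overrides passed on to [cohort_sim_params()] (e.g. `seed`,
#'   `n_subjects`).
#' @return A `cohort_sim_params` object.
#' @export
cohort_scenario <- function(name = c("default", "wmh_driver", "psmd_driver",
                                     "motion_driver", "null"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    default = list(),
    wmh_driver = list(effect_wmh_on_psmd = 1.5e-4, noise_sd_psmd = 5e-5),
    psmd_driver = list(effect_psmd_on_acer = -1.5e5, effect_gm_on_acer = 0.8,
                       noise_sd_acer = 6),
    motion_driver = list(effect_wmh_on_psmd = 0, effect_mb_on_psmd = 0,
                         effect_motion_on_psmd = 1.5e-4),
    null = list(effect_wmh_on_psmd = 0, effect_mb_on_psmd = 0,
                effect_motion_on_psmd = 0, effect_psmd_on_acer = 0,
                effect_gm_on_acer = 0))
  do.call(cohort_sim_params, utils::modifyList(base, list(...)))
}
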