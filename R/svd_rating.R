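#' Construct a semi-quantitative SVD rating record
#'
#' Encodes the four small vessel disease marker scales for one subject:
#' Fazekas periventricular and deep white matter hyperintensity grades (0-3),
#' enlarged perivascular space (EPVS) grades in the centrum semiovale and
#' basal ganglia (0-4) plus a dichotomous midbrain rating, and microbleed and
#' lacune counts split into deep and lobar locations. `NA` encodes a missing
#' modality (e.g. no susceptibility-weighted scan), not absence: derived
#' totals and the burden score propagate missingness.
#'
#' @param fazekas_pvh,fazekas_dwmh ordinal 0-3.
#' @param epvs_cso,epvs_bg ordinal 0-4.
#' @param epvs_midbrain 0/1 (absent/present).
#' @param microbleeds_lobar,microbleeds_deep nonnegative integer counts
#'   ("definite" microbleeds only).
#' @param lacunes_lobar,lacunes_deep nonnegative integer counts.
#' @param possible_microbleeds excluded "possible microbleed" candidates,
#'   retained for audit only; never analyzed.
#' @return A validated `svd_ratings` object with derived fields
#'   `microbleeds_total` and `lacunes_total`.
#' @export
svd_ratings <- function(fazekas_pvh, fazekas_dwmh, epvs_cso, epvs_bg,
                        epvs_midbrain, microbleeds_lobar, microbleeds_deep,
                        lacunes_lobar, lacunes_deep,
                        possible_microbleeds = 0L) {
  rec <- structure(
    list(fazekas_pvh = fazekas_pvh, fazekas_dwmh = fazekas_dwmh,
         epvs_cso = epvs_cso, epvs_bg = epvs_bg,
         epvs_midbrain = epvs_midbrain,
         microbleeds_lobar = microbleeds_lobar,
         microbleeds_deep = microbleeds_deep,
         lacunes_lobar = lacunes_lobar, lacunes_deep = lacunes_deep,
         possible_microbleeds = possible_microbleeds),
    class = "svd_ratings")
  validate_ratings(rec)
}

rating_ranges <- list(
  fazekas_pvh = c(0, 3), fazekas_dwmh = c(0, 3),
  epvs_cso = c(0, 4), epvs_bg = c(0, 4), epvs_midbrain = c(0, 1),
  microbleeds_lobar = c(0, Inf), microbleeds_deep = c(0, Inf),
  lacunes_lobar = c(0, Inf), lacunes_deep = c(0, Inf),
  possible_microbleeds = c(0, Inf))

#' Validate an SVD rating record
#'
#' Checks every field against its scale range (`NA` allowed, meaning the
#' modality is missing) and fills the derived totals.
#'
#' @param record an `svd_ratings` object or a named list with the same fields.
#' @return The validated `svd_ratings` object.
#' @export
validate_ratings <- function(record) {
  for (f in names(rating_ranges)) {
    v <- record[[f]]
    if (is.null(v)) stop(sprintf("missing rating field '%s'", f), call. = FALSE)
    if (is.na(v)) next
    rng <- rating_ranges[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < rng[1] || v > rng[2] ||
        v != round(v))
      stop(sprintf(
        "invalid value %s for '%s': allowed integer range [%g, %g]",
        format(v), f, rng[1], rng[2]), call. = FALSE)
  }
  record$microbleeds_total <- record$microbleeds_lobar + record$microbleeds_deep
  record$lacunes_total <- record$lacunes_lobar + record$lacunes_deep
  class(record) <- "svd_ratings"
  record
}

#' Map a raw EPVS count to its ordinal grade
#'
#' Grades: 0 (none), 1 (1-10), 2 (11-20), 3 (21-40), 4 (>40).
#'
#' @param count nonnegative integer count(s) of enlarged perivascular spaces.
#' @return Integer grade(s) 0-4.
#' @export
epvs_count_to_grade <- function(count) {
  if (any(count < 0, na.rm = TRUE) || any(count != round(count), na.rm = TRUE))
    stop("EPVS count must be a nonnegative integer", call. = FALSE)
  as.integer(cut(count, breaks = c(-0.5, 0.5, 10.5, 20.5, 40.5, Inf),
                 labels = FALSE)) - 1L
}

#' Filter lacune candidates by the 3-15 mm size rule
#'
#' Candidates below 3 mm diameter are discarded (likely enlarged perivascular
#' spaces); candidates above 15 mm are discarded (likely non-SVD etiologies).
#' Bounds are inclusive.
#'
#' @param diameter_mm positive diameters in mm.
#' @param location character vector, one of `"deep"` or `"lobar"` per candidate.
#' @return A list with integer counts `deep`, `lobar`, `total` and the logical
#'   `retained` vector.
#' @export
filter_lacunes <- function(diameter_mm, location) {
  if (length(diameter_mm) != length(location))
    stop("diameter_mm and location lengths differ", call. = FALSE)
  if (any(diameter_mm <= 0))
    stop("lacune candidate diameters must be > 0", call. = FALSE)
  if (!all(location %in% c("deep", "lobar")))
    stop("location must be 'deep' or 'lobar'", call. = FALSE)
  retained <- diameter_mm >= 3 & diameter_mm <= 15
  list(deep = sum(retained & location == "deep"),
       lobar = sum(retained & location == "lobar"),
       total = sum(retained), retained = retained)
}

#' Total SVD burden score (0-4)
#'
#' One point for each marker class present: WMH (Fazekas PVH grade 3 and/or
#' DWMH grade >= 2), EPVS (basal-ganglia grade >= 2, i.e. more than 10),
#' lacunes (>= 1 anywhere) and microbleeds (>= 1 anywhere). If a required
#' field is missing the score is `NA`.
#'
#' @param ratings a validated [svd_ratings()] record.
#' @return Integer score in 0-4, or `NA` if a component is missing.
#' @export
svd_burden_score <- function(ratings) {
  ratings <- validate_ratings(ratings)
  pts <- c(
    wmh = as.numeric(ratings$fazekas_pvh == 3 | ratings$fazekas_dwmh >= 2),
    epvs = as.numeric(ratings$epvs_bg >= 2),
    lacunes = as.numeric(ratings$lacunes_total >= 1),
    microbleeds = as.numeric(ratings$microbleeds_total >= 1))
  # NA | TRUE is TRUE: a definite point stands even if the partner is missing
  if (!is.na(ratings$fazekas_pvh) && ratings$fazekas_pvh == 3) pts["wmh"] <- 1
  if (!is.na(ratings$fazekas_dwmh) && ratings$fazekas_dwmh >= 2) pts["wmh"] <- 1
  if (anyNA(pts)) return(NA_integer_)
  as.integer(sum(pts))
}

#' Read and validate SVD ratings from a cohort CSV
#'
#' Expects the column dictionary used throughout the package
#' (`fazekas_pvh`, `fazekas_dwmh`, `epvs_cso`, `epvs_bg`, `epvs_midbrain`,
#' `microbleeds_lobar`, `microbleeds_deep`, `lacunes_lobar`, `lacunes_deep`).
#' Validation failures are reported with the row number and field.
#'
#' @param df data.frame (e.g. read from the cohort CSV).
#' @return `df` with derived `microbleeds_total`, `lacunes_total` and
#'   `svd_burden` columns appended/overwritten.
#' @export
ratings_from_table <- function(df) {
  needed <- setdiff(names(rating_ranges), "possible_microbleeds")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("missing rating column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  scores <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    rec <- as.list(df[i, needed])
    rec$possible_microbleeds <- 0L
    rec <- tryCatch(validate_ratings(rec), error = function(e)
      stop(sprintf("row %d: %s", i, conditionMessage(e)), call. = FALSE))
    df$microbleeds_total[i] <- rec$microbleeds_total
    df$lacunes_total[i] <- rec$lacunes_total
    scores[i] <- svd_burden_score(rec)
  }
  df$svd_burden <- scores
  df
}
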