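#' Modal intensity of a masked image
#'
#' Estimates the modal pixel intensity over in-mask voxels with a fixed-bin
#' histogram spanning the in-mask intensity range. Ties between equally
#' populated bins are broken toward the lower bin; the bin center is returned.
#'
#' @param image 3D numeric array (e.g. a FLAIR-like intensity volume, a.u.).
#' @param brain_mask 3D binary array.
#' @param n_bins number of histogram bins (>= 2, default 256).
#' @return Scalar modal intensity (a.u.).
#' @export
estimate_modal_intensity <- function(image, brain_mask, n_bins = 256) {
  if (!identical(dim(image), dim(brain_mask)))
    stop("image and brain_mask grids differ", call. = FALSE)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  vals <- image[brain_mask != 0]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("empty brain mask", call. = FALSE)
  rng <- range(vals)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  # findInterval puts the maximum into bin n_bins + 1; fold it back
  bin <- pmin(findInterval(vals, breaks), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  k <- which.max(counts)          # first max = lower bin on ties
  (breaks[k] + breaks[k + 1]) / 2
}

#' Threshold-based white matter hyperintensity segmentation
#'
#' Segments WMH as in-mask voxels whose intensity strictly exceeds
#' `k` times the modal in-mask intensity (default `k = 1.40`). The strict
#' inequality means a voxel at exactly `k` times the mode is excluded.
#'
#' @inheritParams estimate_modal_intensity
#' @param k threshold multiplier (> 0, default 1.40).
#' @param voxel_size voxel edge lengths in mm (length 3).
#' @return A `lesion_quant` object with `lesion_mask` (integer 0/1 array),
#'   `modal_intensity`, `threshold`, `total_volume` (mm^3) and `voxel_size`.
#'   PVH/DWMH and lobar fields are filled by [partition_wmh()].
#' @export
segment_wmh <- function(image, brain_mask, k = 1.40, voxel_size = c(2, 2, 2),
                        n_bins = 256) {
  stop_if_not_scalar_number(k, "k", 0, Inf, strict_lower = TRUE)
  mode_val <- estimate_modal_intensity(image, brain_mask, n_bins)
  thr <- k * mode_val
  mask <- (brain_mask != 0) & is.finite(image) & (image > thr)
  mask <- as_binary_array(mask)
  vox_mm3 <- prod(voxel_size)
  structure(
    list(lesion_mask = mask, modal_intensity = mode_val, threshold = thr,
         k = k, total_volume = sum(mask) * vox_mm3,
         pvh_volume = NA_real_, dwmh_volume = NA_real_,
         lobar_volumes = NULL, voxel_size = as.numeric(voxel_size)),
    class = "lesion_quant")
}

# minimum Euclidean distance (mm) from each query voxel to a target voxel set;
# chunked brute force over voxel centers — exact, adequate at phantom scales
min_dist_to_mask_mm <- function(query_idx, target_mask, dim, voxel_size,
                                chunk = 512L) {
  tgt_idx <- which(target_mask != 0)
  if (length(tgt_idx) == 0L) return(rep(Inf, length(query_idx)))
  tgt <- voxel_coords_mm(tgt_idx, dim, voxel_size)
  out <- numeric(length(query_idx))
  for (s in seq(1L, length(query_idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(query_idx))
    q <- voxel_coords_mm(query_idx[s:e], dim, voxel_size)
    d2 <- outer(rowSums(q^2), rowSums(tgt^2), `+`) - 2 * tcrossprod(q, tgt)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Partition a WMH mask into periventricular/deep and lobar components
#'
#' Lesion voxels whose center lies within `pv_distance_mm` (Euclidean,
#' default 10 mm) of any ventricle voxel are classified periventricular (PVH);
#' the remainder are deep (DWMH). Lobar volumes are accumulated by the atlas
#' label of each lesion voxel; voxels with label 0 are accumulated under
#' `"unassigned"` and reported in a message.
#'
#' @param result a `lesion_quant` object from [segment_wmh()].
#' @param ventricle_mask 3D binary array on the same grid.
#' @param lobar_atlas a [label_atlas()] on the same grid.
#' @param pv_distance_mm periventricular distance cutoff in mm (inclusive).
#' @return The completed `lesion_quant` object with `pvh_volume`,
#'   `dwmh_volume` and `lobar_volumes`.
#' @export
partition_wmh <- function(result, ventricle_mask, lobar_atlas,
                          pv_distance_mm = 10) {
  stopifnot(inherits(result, "lesion_quant"))
  dm <- dim(result$lesion_mask)
  if (!identical(dim(ventricle_mask), dm))
    stop("ventricle_mask grid does not match the lesion mask", call. = FALSE)
  if (!inherits(lobar_atlas, "label_atlas"))
    stop("lobar_atlas must be a label_atlas", call. = FALSE)
  if (!identical(dim(lobar_atlas$labels), dm))
    stop("lobar_atlas grid does not match the lesion mask", call. = FALSE)
  vox_mm3 <- prod(result$voxel_size)
  les_idx <- which(result$lesion_mask != 0)
  if (length(les_idx) == 0L) {
    result$pvh_volume <- 0
    result$dwmh_volume <- 0
    result$lobar_volumes <- stats::setNames(
      rep(0, length(lobar_atlas$legend)), names(lobar_atlas$legend))
    return(result)
  }
  d <- min_dist_to_mask_mm(les_idx, ventricle_mask, dm, result$voxel_size)
  is_pvh <- d <= pv_distance_mm
  result$pvh_volume <- sum(is_pvh) * vox_mm3
  result$dwmh_volume <- sum(!is_pvh) * vox_mm3
  labs <- lobar_atlas$labels[les_idx]
  lob <- vapply(lobar_atlas$legend, function(l) sum(labs == l) * vox_mm3,
                numeric(1))
  n_unassigned <- sum(labs == 0L)
  if (n_unassigned > 0) {
    message(sprintf("%d lesion voxel(s) outside the lobar atlas (label 0)",
                    n_unassigned))
    lob <- c(lob, unassigned = n_unassigned * vox_mm3)
  }
  result$lobar_volumes <- lob
  result
}

#' Apply a manual edit mask to a WMH segmentation
#'
#' Expert review of automatic segmentations is represented as a voxelwise
#' override: `edit_mask` values 1 force inclusion, 0 force exclusion, and `NA`
#' leaves the automatic decision in place. The number of changed voxels is
#' reported in a message and volumes are recomputed (partition fields are
#' reset and must be recomputed with [partition_wmh()]).
#'
#' @param result a `lesion_quant` object.
#' @param edit_mask 3D array of 0/1/NA on the same grid.
#' @return The edited `lesion_quant` object.
#' @export
apply_edit_mask <- function(result, edit_mask) {
  stopifnot(inherits(result, "lesion_quant"))
  if (!identical(dim(edit_mask), dim(result$lesion_mask)))
    stop("edit_mask grid does not match the lesion mask", call. = FALSE)
  new_mask <- result$lesion_mask
  over <- !is.na(edit_mask)
  new_vals <- as.integer(edit_mask[over] != 0)
  n_changed <- sum(new_mask[over] != new_vals)
  new_mask[over] <- new_vals
  message(sprintf("manual edit changed %d voxel(s)", n_changed))
  result$lesion_mask <- new_mask
  result$total_volume <- sum(new_mask) * prod(result$voxel_size)
  result$pvh_volume <- NA_real_
  result$dwmh_volume <- NA_real_
  result$lobar_volumes <- NULL
  result
}

#' Normalize a volume by TIV and square-root transform
#'
#' Head-size correction expresses a volume as a percentage of total
#' intracranial volume (TIV); because WMH volumes are right-skewed, the
#' normalized value is additionally square-root transformed.
#'
#' @param volume_mm3 volume(s) in mm^3 (>= 0); vectorized.
#' @param tiv_mm3 total intracranial volume in mm^3 (> 0).
#' @return A data.frame with columns `normalized` (% of TIV) and
#'   `transformed` (sqrt of normalized).
#' @examples
#' normalize_and_transform(1e4, 1.45e6)  # ~0.69 % of TIV, sqrt ~0.83
#' @export
normalize_and_transform <- function(volume_mm3, tiv_mm3) {
  if (any(!is.finite(tiv_mm3)) || any(tiv_mm3 <= 0))
    stop("tiv_mm3 must be > 0", call. = FALSE)
  if (any(volume_mm3 < 0, na.rm = TRUE))
    stop("volume_mm3 must be >= 0", call. = FALSE)
  normalized <- 100 * volume_mm3 / tiv_mm3
  data.frame(normalized = normalized, transformed = sqrt(normalized))
}

#' @export
print.lesion_quant <- function(x, ...) {
  cat("WMH threshold segmentation\n")
  cat(sprintf("  modal intensity : %.6g (threshold %.6g = %.2f x mode)\n",
              x$modal_intensity, x$threshold, x$k))
  cat(sprintf("  total volume    : %.1f mm^3 (%d voxels)\n",
              x$total_volume, sum(x$lesion_mask)))
  if (is.finite(x$pvh_volume))
    cat(sprintf("  PVH / DWMH      : %.1f / %.1f mm^3\n",
                x$pvh_volume, x$dwmh_volume))
  invisible(x)
}
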