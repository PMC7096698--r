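#' Specification of a synthetic template-space phantom
#'
#' Describes the geometry and planted quantities of a synthetic brain volume
#' set: an MD/FA/skeleton bundle with a controllable diffusivity peak width,
#' a FLAIR-like image with hyperintense lesion blobs planted above the modal
#' background intensity, a ventricle mask, and an octant lobar atlas.
#'
#' @param grid_shape voxel counts per axis (all >= 16).
#' @param voxel_size_mm physical voxel edge lengths in mm.
#' @param target_psmd planted 95th-5th percentile spread of skeleton MD
#'   (mm^2/s). Skeleton MD is drawn from a Gaussian with
#'   `sd = target_psmd / (2 * qnorm(0.95))`, truncated at zero.
#' @param md_center central skeleton MD value (mm^2/s).
#' @param skeleton_fraction fraction of in-brain voxels on the skeleton
#'   (0 < f < 0.5).
#' @param lesion_blobs list of lesion descriptions, each a list with
#'   `center` (voxel indices, length 3), `radius_mm`, and `multiplier`
#'   (intensity as a multiple of the background mode, > 0).
#' @param background_mode modal FLAIR background intensity (a.u.).
#' @param contaminant_fraction fraction of skeleton voxels carrying FA < 0.2
#'   and CSF-like MD, emulating CSF contamination that FA masking removes.
#' @param seed integer RNG seed; identical spec + seed reproduce identical
#'   volumes.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_size_mm = c(2, 2, 2),
                         target_psmd = 5.51e-4,
                         md_center = 7.7e-4,
                         skeleton_fraction = 0.1,
                         lesion_blobs = list(),
                         background_mode = 100,
                         contaminant_fraction = 0.02,
                         seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 16))
    stop("grid_shape must have 3 axes, all >= 16", call. = FALSE)
  stop_if_not_scalar_number(skeleton_fraction, "skeleton_fraction", 0, 0.5,
                            strict_lower = TRUE)
  if (skeleton_fraction >= 0.5)
    stop("'skeleton_fraction' must be < 0.5", call. = FALSE)
  stop_if_not_scalar_number(target_psmd, "target_psmd", 0, Inf,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(md_center, "md_center", 0, Inf)
  stop_if_not_scalar_number(background_mode, "background_mode", 0, Inf,
                            strict_lower = TRUE)
  stop_if_not_scalar_number(contaminant_fraction, "contaminant_fraction", 0, 1)
  for (i in seq_along(lesion_blobs)) {
    bl <- lesion_blobs[[i]]
    if (is.null(bl$center) || is.null(bl$radius_mm) || is.null(bl$multiplier))
      stop(sprintf("lesion blob %d needs center, radius_mm and multiplier", i),
           call. = FALSE)
    if (bl$multiplier <= 0)
      stop(sprintf("lesion blob %d: intensity multiplier must be > 0", i),
           call. = FALSE)
  }
  structure(
    list(grid_shape = as.integer(grid_shape),
         voxel_size_mm = as.numeric(voxel_size_mm),
         target_psmd = target_psmd, md_center = md_center,
         skeleton_fraction = skeleton_fraction, lesion_blobs = lesion_blobs,
         background_mode = background_mode,
         contaminant_fraction = contaminant_fraction,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

# octant lobar atlas: left/right x frontal/parietal/temporal/occipital
lobe_names <- function() {
  c("left_frontal", "right_frontal", "left_parietal", "right_parietal",
    "left_temporal", "right_temporal", "left_occipital", "right_occipital")
}

#' Generate a synthetic template-space phantom
#'
#' Builds co-registered volumes on a common grid:
#' * a brain mask (inscribed ellipsoid);
#' * a white-matter skeleton as a union of axis-aligned one-voxel-thick
#'   sheets through the brain interior, covering `skeleton_fraction` of the
#'   in-brain voxels;
#' * FA on the skeleton drawn in \[0.2, 0.95\] except a contaminant fraction
#'   below 0.2 (CSF-like, with high MD) that FA masking must remove;
#' * skeleton MD from a Gaussian whose 95th-5th percentile interval equals
#'   `target_psmd`, truncated at zero;
#' * a FLAIR-like image whose in-brain background is unimodal with mode
#'   `background_mode` (clipped to \[0.6, 1.3\] x mode so that only planted
#'   lesions can exceed a 1.40 x mode threshold), with spherical lesion
#'   blobs rasterized by center-of-voxel inclusion at
#'   `multiplier x mode x (1 + U(0.01, 0.08))`;
#' * a central ellipsoidal ventricle mask and an octant lobar atlas
#'   partitioning the brain mask into 8 labels.
#'
#' Identical spec (including seed) reproduces bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `bundle` ([skeleton_bundle()]), `flair`, `brain_mask`,
#'   `ventricle_mask`, `atlas` ([label_atlas()]), `lesion_mask` (the planted
#'   voxel set), `voxel_size`, and the originating `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    dm <- spec$grid_shape
    vx <- spec$voxel_size_mm
    ctr <- (dm + 1) / 2
    semi <- (dm - 2) / 2                       # ellipsoid semi-axes, voxels
    ix <- slice.index(array(0, dm), 1)
    iy <- slice.index(array(0, dm), 2)
    iz <- slice.index(array(0, dm), 3)
    ell <- ((ix - ctr[1]) / semi[1])^2 + ((iy - ctr[2]) / semi[2])^2 +
      ((iz - ctr[3]) / semi[3])^2
    brain <- as_binary_array(ell <= 1)
    n_brain <- sum(brain)

    # ventricles: small central ellipsoid
    vent_ell <- ((ix - ctr[1]) / (semi[1] / 5))^2 +
      ((iy - ctr[2]) / (semi[2] / 3))^2 + ((iz - ctr[3]) / (semi[3] / 5))^2
    ventricles <- as_binary_array(vent_ell <= 1 & brain == 1L)

    # skeleton: axis-aligned one-voxel-thick x-sheets through the interior,
    # filled plane by plane up to the requested fraction (ventricles excluded)
    interior <- brain == 1L & ell <= 0.85 & ventricles == 0L
    n_skel <- max(1L, round(spec$skeleton_fraction * n_brain))
    skel <- array(0L, dm)
    planes <- order(abs(seq_len(dm[1]) - ctr[1]))  # center-out sheet order
    taken <- 0L
    for (px in planes) {
      cand <- which(interior & ix == px)
      if (length(cand) == 0L) next
      take <- min(length(cand), n_skel - taken)
      skel[cand[seq_len(take)]] <- 1L
      taken <- taken + take
      if (taken >= n_skel) break
    }

    # FA: skeleton voxels >= 0.2 except the contaminant fraction; background low
    fa <- array(0, dm)
    fa[brain == 1L] <- stats::runif(n_brain, 0.05, 0.19)
    skel_idx <- which(skel == 1L)
    ns <- length(skel_idx)
    fa_skel <- pmin(0.95, pmax(0.2, stats::rnorm(ns, 0.49, 0.08)))
    n_cont <- round(spec$contaminant_fraction * ns)
    cont <- if (n_cont > 0) sample(ns, n_cont) else integer(0)
    if (n_cont > 0) fa_skel[cont] <- stats::runif(n_cont, 0.05, 0.19)
    fa[skel_idx] <- fa_skel

    # MD: Gaussian on the clean skeleton with the planted peak width
    sigma <- spec$target_psmd / (2 * stats::qnorm(0.95))
    md <- array(0, dm)
    md[brain == 1L] <- pmax(0, stats::rnorm(n_brain, spec$md_center, sigma))
    md_skel <- pmax(0, stats::rnorm(ns, spec$md_center, sigma))
    if (n_cont > 0) md_skel[cont] <- stats::rnorm(n_cont, 3e-3, 2e-4)  # CSF-like
    md[skel_idx] <- md_skel
    md[ventricles == 1L] <- stats::rnorm(sum(ventricles), 3e-3, 2e-4)

    # FLAIR: clipped-Gaussian background (mode preserved), planted lesions above
    flair <- array(0, dm)
    bg <- stats::rnorm(n_brain, spec$background_mode, 0.08 * spec$background_mode)
    bg <- pmin(1.3 * spec$background_mode, pmax(0.6 * spec$background_mode, bg))
    flair[brain == 1L] <- bg
    lesion_mask <- array(0L, dm)
    pos_mm <- cbind((ix - 1) * vx[1], (iy - 1) * vx[2], (iz - 1) * vx[3])
    for (i in seq_along(spec$lesion_blobs)) {
      bl <- spec$lesion_blobs[[i]]
      cen <- as.numeric(bl$center)
      r_vox <- bl$radius_mm / vx
      if (any(cen - r_vox < 1) || any(cen + r_vox > dm))
        stop(sprintf(
          "lesion blob %d (center %s, radius %.1f mm) does not fit in the grid",
          i, paste(cen, collapse = ","), bl$radius_mm), call. = FALSE)
      cen_mm <- (cen - 1) * vx
      d2 <- (pos_mm[, 1] - cen_mm[1])^2 + (pos_mm[, 2] - cen_mm[2])^2 +
        (pos_mm[, 3] - cen_mm[3])^2
      inside <- which(d2 <= bl$radius_mm^2 & brain == 1L)
      lesion_mask[inside] <- 1L
      flair[inside] <- bl$multiplier * spec$background_mode *
        (1 + stats::runif(length(inside), 0.01, 0.08))
    }

    # lobar atlas: octants of the brain mask
    atlas_labels <- array(0L, dm)
    oct <- 1L + (ix > ctr[1]) + 2L * (iy > ctr[2]) + 4L * (iz > ctr[3])
    atlas_labels[brain == 1L] <- oct[brain == 1L]
    legend <- stats::setNames(1:8, lobe_names())

    list(bundle = skeleton_bundle(md, fa, skel, vx),
         flair = flair, brain_mask = brain, ventricle_mask = ventricles,
         atlas = label_atlas(atlas_labels, legend),
         lesion_mask = lesion_mask, voxel_size = vx, spec = spec)
  })
}

#' Write a phantom to NIfTI-1 files
#'
#' Writes `md`, `fa`, `skeleton`, `flair`, `brain_mask`, `ventricle_mask`,
#' `lobes` (atlas) and `lesion_mask` as `.nii.gz` with the voxel size encoded
#' in the affine.
#'
#' @param phantom output of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vols <- list(md = phantom$bundle$md, fa = phantom$bundle$fa,
               skeleton = phantom$bundle$skeleton, flair = phantom$flair,
               brain_mask = phantom$brain_mask,
               ventricle_mask = phantom$ventricle_mask,
               lobes = phantom$atlas$labels,
               lesion_mask = phantom$lesion_mask)
  paths <- vapply(names(vols), function(nm) {
    img <- RNifti::asNifti(vols[[nm]])
    RNifti::pixdim(img) <- phantom$voxel_size
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, f)
    f
  }, character(1))
  invisible(paths)
}

#' Read a skeleton bundle from NIfTI files
#'
#' @param md_file,fa_file,skeleton_file NIfTI paths of co-registered volumes.
#' @return A [skeleton_bundle()].
#' @export
read_skeleton_bundle <- function(md_file, fa_file, skeleton_file) {
  md <- RNifti::readNifti(md_file)
  fa <- RNifti::readNifti(fa_file)
  sk <- RNifti::readNifti(skeleton_file)
  vx <- RNifti::pixdim(md)[1:3]
  skeleton_bundle(array(as.numeric(md), dim(md)),
                  array(as.numeric(fa), dim(fa)),
                  array(as.integer(sk != 0), dim(sk)), vx)
}
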