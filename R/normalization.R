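#' Frame-wise z-normalization of a dynamic PET scan
#'
#' Each frame is independently centred and scaled using the mean and the
#' population standard deviation of the voxels inside the brain mask:
#' `(v - mean_mask) / sd_mask`.  Normalization removes global activity
#' differences between frames and subjects so that voxel time-activity
#' curves can be compared by shape; it must be applied identically when
#' building kinetic classes (training) and when extracting a reference
#' region (testing), with the same brain-mask definition.
#'
#' Out-of-mask voxels are set to `NA` and excluded from every downstream
#' computation; they are never silently zeroed.  The population SD
#' convention (divide by N) is used and recorded in the result.
#'
#' @param pet a [dynamic_image()].
#' @param brain binary [mask_image()]; probability masks must be thresholded
#'   first (see [prepare_tissue_mask()]).  Pass `NULL` for the legacy
#'   whole-field-of-view normalization (every voxel in the statistics).
#' @return A `normalized_dynamic` object: `voxels` (4D, unitless, `NA`
#'   outside the mask), `schedule`, `affine`, `mask_hash`,
#'   `per_frame_mean` and `per_frame_sd`.
#' @export
normalize_frames <- function(pet, brain) {
  stopifnot(inherits(pet, "dynamic_image"))
  whole <- is.null(brain)
  if (!whole) {
    stopifnot(inherits(brain, "mask_image"))
    if (brain$kind != "binary")
      stop("normalization mask must be binary; threshold the probability map first")
    if (!check_alignment(pet, brain))
      stop("brain mask is not aligned with the PET image")
    inmask <- brain$voxels == 1
    if (sum(inmask) < 2L) stop("normalization mask holds fewer than 2 voxels")
  } else {
    inmask <- array(TRUE, dim(pet$voxels)[1:3])
  }
  d <- dim(pet$voxels)
  flat <- matrix(pet$voxels, prod(d[1:3]), d[4L])
  idx <- which(inmask)
  sub <- flat[idx, , drop = FALSE]
  m <- colMeans(sub)
  n <- length(idx)
  s <- sqrt(colMeans(sub^2) - m^2)          # population SD
  bad <- which(!(s > 0))
  if (length(bad))
    stop("degenerate (constant) frame(s) inside the mask: frame ",
         paste(bad, collapse = ", "))
  out <- matrix(NA_real_, prod(d[1:3]), d[4L])
  out[idx, ] <- sweep(sweep(sub, 2L, m), 2L, s, "/")
  structure(list(voxels = array(out, d), schedule = pet$schedule,
                 affine = pet$affine,
                 mask_hash = if (whole) "whole-frame" else mask_hash(brain),
                 per_frame_mean = m, per_frame_sd = s,
                 sd_convention = "population"),
            class = "normalized_dynamic")
}

#' @export
print.normalized_dynamic <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<normalized_dynamic> %dx%dx%d voxels, %d frames, %d in mask\n",
              d[1], d[2], d[3], d[4], sum(!is.na(x$voxels[, , , 1]))))
  invisible(x)
}

#' Export per-frame normalization statistics
#'
#' @param norm a `normalized_dynamic`.
#' @param path output .csv path.
#' @return `path`, invisibly.
#' @export
write_norm_stats <- function(norm, path) {
  utils::write.csv(
    data.frame(frame = seq_len(norm$schedule$n_frames),
               mean = norm$per_frame_mean, sd = norm$per_frame_sd),
    path, row.names = FALSE)
  invisible(path)
}
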