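#' Containers for dynamic PET data and masks
#'
#' `dynamic_image` couples a 4D activity array (x, y, z, frame) with its
#' frame schedule and voxel-to-world geometry.  `mask_image` is a 3D binary
#' or probability volume on the same grid.  Activity units (typically
#' kBq/mL) and the decay-correction status are carried as metadata only;
#' the package never rescales or decay-corrects data.
#'
#' @param voxels 4D numeric array, frames on the 4th dimension.
#' @param schedule a [frame_schedule()] with `n_frames == dim(voxels)[4]`.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @param units free-text activity unit label.
#' @param decay_corrected logical flag recorded as metadata, not verified.
#' @return A `dynamic_image` object.
#' @export
dynamic_image <- function(voxels, schedule, affine = diag(4),
                          units = "kBq/mL", decay_corrected = NA) {
  if (length(dim(voxels)) != 4L)
    stop("dynamic image must be 4D (x, y, z, frame); got ",
         length(dim(voxels)), "D")
  if (dim(voxels)[4L] != schedule$n_frames)
    stop("frame count mismatch: image has ", dim(voxels)[4L],
         " frames but schedule has ", schedule$n_frames)
  if (!all(is.finite(voxels)))
    stop("dynamic image contains non-finite voxel values")
  structure(list(voxels = voxels, schedule = schedule, affine = affine,
                 pixdim = sqrt(colSums(affine[1:3, 1:3]^2)),
                 units = units, decay_corrected = decay_corrected),
            class = "dynamic_image")
}

#' @rdname dynamic_image
#' @param kind `"binary"` or `"probability"`; guessed from the values when
#'   missing.
#' @export
mask_image <- function(voxels, affine = diag(4),
                       kind = c("auto", "binary", "probability")) {
  kind <- match.arg(kind)
  if (length(dim(voxels)) != 3L) stop("mask must be 3D")
  if (anyNA(voxels) || any(voxels < 0) || any(voxels > 1))
    stop("mask values must lie in [0, 1]")
  if (kind == "auto")
    kind <- if (all(voxels %in% c(0, 1))) "binary" else "probability"
  if (kind == "binary" && !all(voxels %in% c(0, 1)))
    stop("binary mask carries values other than {0, 1}")
  structure(list(voxels = voxels, affine = affine,
                 pixdim = sqrt(colSums(affine[1:3, 1:3]^2)), kind = kind),
            class = "mask_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels, %d frames [%s]\n",
              d[1], d[2], d[3], d[4], x$units))
  invisible(x)
}

#' @export
print.mask_image <- function(x, ...) {
  cat(sprintf("<mask_image> %s, %d/%d voxels in mask\n", x$kind,
              sum(x$voxels > 0), length(x$voxels)))
  invisible(x)
}

#' Number of voxels in a binary mask
#' @param mask a `mask_image`.
#' @return integer count of voxels with value 1.
#' @export
mask_count <- function(mask) sum(mask$voxels == 1)

#' A subject: PET scan plus its co-registered masks
#'
#' @param subject_id character id.
#' @param pet a [dynamic_image()].
#' @param masks named list of [mask_image()]s; `brain` is mandatory, the
#'   class builder additionally expects `gm_prob`, `wm_prob` and (depending
#'   on configuration) `high_binding` and/or `blood`.
#' @param genotype `"HAB"`, `"MAB"` or `"unknown"` (TSPO rs6971 binding
#'   class; second-generation tracers need genotype-stratified classes).
#' @return a `subject_record`.
#' @export
subject_record <- function(subject_id, pet, masks,
                           genotype = c("unknown", "HAB", "MAB")) {
  genotype <- match.arg(genotype)
  if (is.null(masks$brain)) stop("subject ", subject_id, ": brain mask missing")
  for (nm in names(masks)) {
    if (!check_alignment(masks[[nm]], pet))
      stop("subject ", subject_id, ": mask '", nm,
           "' is not aligned with the PET grid")
  }
  structure(list(subject_id = subject_id, pet = pet, masks = masks,
                 genotype = genotype), class = "subject_record")
}

#' Read a 4D dynamic PET scan with its timing sidecar
#'
#' @param pet_path 4D NIfTI file.
#' @param timing_path frame timing sidecar (CSV with
#'   `frame_start`,`frame_end` columns, or BIDS-style JSON); see
#'   [read_frame_schedule()].
#' @param unit timing unit of the sidecar, `"s"` or `"min"`.
#' @return a [dynamic_image()].
#' @export
read_dynamic <- function(pet_path, timing_path, unit = "s") {
  nii <- read_nifti(pet_path)
  if (length(dim(nii$data)) != 4L)
    stop("expected a 4D dynamic PET image, got ",
         length(dim(nii$data)), "D: ", pet_path)
  sch <- read_frame_schedule(timing_path, unit = unit)
  if (dim(nii$data)[4L] != sch$n_frames)
    stop("frame count mismatch: image has ", dim(nii$data)[4L],
         " frames, timing file lists ", sch$n_frames)
  dynamic_image(nii$data, sch, affine = nii$affine)
}

#' Read a 3D mask volume
#'
#' @param path NIfTI file.
#' @param kind see [mask_image()].
#' @return a [mask_image()].
#' @export
read_mask <- function(path, kind = "auto") {
  nii <- read_nifti(path)
  d <- nii$data
  if (length(dim(d)) == 4L && dim(d)[4L] == 1L) d <- array(d, dim(d)[1:3])
  mask_image(d, affine = nii$affine, kind = kind)
}

#' Write a dynamic image or mask to NIfTI
#'
#' @param x a `dynamic_image` or `mask_image`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  write_nifti(x$voxels, path, affine = x$affine)
}

#' Do two images share one grid?
#'
#' True iff the array grids have identical shape (first three dimensions)
#' and the affines agree element-wise within `tol` millimetres.  Mask/PET
#' mismatches are always errors upstream; the package never resamples.
#'
#' @param a,b `dynamic_image` or `mask_image` objects.
#' @param tol tolerance on affine entries, mm.
#' @return logical scalar.
#' @export
check_alignment <- function(a, b, tol = 1e-3) {
  da <- dim(a$voxels)[1:3]
  db <- dim(b$voxels)[1:3]
  all(da == db) && all(abs(a$affine - b$affine) <= tol)
}

#' Content hash of a mask (audit token)
#'
#' Used to enforce that the brain mask employed at reference extraction is
#' the same as the one used during class training.
#'
#' @param mask a `mask_image`.
#' @return character md5 digest.
#' @export
mask_hash <- function(mask) {
  digest::digest(list(dim(mask$voxels), round(mask$affine, 6),
                      as.numeric(mask$voxels)), algo = "md5")
}

#' Write / read a time-activity curve CSV
#'
#' One row per frame: `frame_mid_s`, `value`.
#'
#' @param tac numeric vector, one value per frame.
#' @param schedule the matching [frame_schedule()].
#' @param path output .csv path.
#' @return `path` (writer) or a numeric vector with a `frame_mid_s`
#'   attribute (reader).
#' @export
write_tac <- function(tac, schedule, path) {
  stopifnot(length(tac) == schedule$n_frames)
  utils::write.csv(data.frame(frame_mid_s = frame_mid(schedule), value = tac),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac
#' @export
read_tac <- function(path) {
  tab <- utils::read.csv(path)
  structure(as.numeric(tab$value), frame_mid_s = as.numeric(tab$frame_mid_s))
}
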