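#' 3D binary morphology (6-connected)
#'
#' Minimal erosion/dilation with the face-neighbour (6-connected)
#' structuring element, used for partial-volume control on tissue masks.
#' Voxels outside the volume count as background.
#'
#' @param x 3D logical/0-1 array.
#' @param times number of iterations.
#' @return 3D logical array.
#' @keywords internal
erode6 <- function(x, times = 1L) {
  x <- x > 0
  for (i in seq_len(times)) {
    out <- x
    for (ax in 1:3) for (s in c(-1L, 1L)) out <- out & .shift3(x, ax, s, FALSE)
    x <- out
  }
  x
}

#' @rdname erode6
#' @keywords internal
dilate6 <- function(x, times = 1L) {
  x <- x > 0
  for (i in seq_len(times)) {
    out <- x
    for (ax in 1:3) for (s in c(-1L, 1L)) out <- out | .shift3(x, ax, s, FALSE)
    x <- out
  }
  x
}

# shift a 3D array by one voxel along axis `ax`, filling with `fill`
.shift3 <- function(x, ax, s, fill) {
  d <- dim(x)
  out <- array(fill, d)
  src <- dst <- lapply(d, seq_len)
  n <- d[ax]
  if (s > 0) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
  else       { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Binarize a tissue probability map and erode it
#'
#' Only voxels with a high tissue probability (default > 0.9) are kept,
#' limiting partial volume effects; for non-probabilistic segmentations a
#' small erosion serves the same purpose.  Erosion uses the 6-connected
#' structuring element.
#'
#' @param prob_map [mask_image()], probability or binary.
#' @param p_threshold probability cut, strict (`prob > p_threshold`).
#' @param erode erosion iterations (>= 0).
#' @return binary [mask_image()]; the surviving voxel count is attached as
#'   attribute `n_voxels`.
#' @export
prepare_tissue_mask <- function(prob_map, p_threshold = 0.9, erode = 1L) {
  stopifnot(inherits(prob_map, "mask_image"))
  if (!(p_threshold > 0 && p_threshold < 1))
    stop("p_threshold must lie in (0, 1)")
  if (erode < 0) stop("erode must be >= 0")
  bin <- prob_map$voxels > p_threshold
  if (erode > 0) bin <- erode6(bin, as.integer(erode))
  if (!any(bin))
    stop("empty mask after thresholding/erosion; ",
         "lower p_threshold or the erosion count")
  out <- mask_image(array(as.numeric(bin), dim(bin)),
                    affine = prob_map$affine, kind = "binary")
  attr(out, "n_voxels") <- sum(bin)
  out
}

#' Derive a blood mask from early-frame activity
#'
#' Blood (vascular) kinetics are located by summing the early frames of the
#' raw dynamic scan (frames whose midpoint falls within `early_window`
#' seconds, usually the first 2-3 minutes) and keeping the `n_top` voxels
#' with the highest summed signal inside `search_mask` — typically picking
#' up carotids and cerebral sinuses.  Ties at the cutoff are broken by
#' ascending linear voxel index, making the selection deterministic.
#'
#' @param pet raw [dynamic_image()] (not normalized).
#' @param early_window seconds from scan start; frames with
#'   `midpoint <= early_window` are summed.
#' @param n_top number of voxels to keep (paper default ~50).
#' @param search_mask binary [mask_image()] to search within; defaults
#'   should admit the brain margin (e.g. brain mask dilated by 2 voxels).
#' @return binary [mask_image()] with exactly `min(n_top, mask size)`
#'   voxels.
#' @export
build_blood_mask <- function(pet, early_window = 180, n_top = 50L,
                             search_mask) {
  stopifnot(inherits(pet, "dynamic_image"), inherits(search_mask, "mask_image"))
  if (!check_alignment(pet, search_mask))
    stop("search mask is not aligned with the PET image")
  if (n_top < 1L) stop("n_top must be >= 1")
  mid <- frame_mid(pet$schedule)
  early <- which(mid <= early_window)
  if (!length(early))
    stop("early_window (", early_window,
         " s) ends before the first frame midpoint (", mid[1L], " s)")
  d <- dim(pet$voxels)
  flat <- matrix(pet$voxels, prod(d[1:3]), d[4L])
  sums <- rowSums(flat[, early, drop = FALSE])
  idx <- which(search_mask$voxels == 1)
  if (!length(idx)) stop("search mask is empty")
  k <- min(n_top, length(idx))
  # order by descending sum, ties by ascending linear index
  ord <- idx[order(-sums[idx], idx)][seq_len(k)]
  bin <- array(0, d[1:3]); bin[ord] <- 1
  mask_image(bin, affine = pet$affine, kind = "binary")
}

#' Dilated brain mask for the blood-voxel search
#'
#' @param brain binary [mask_image()].
#' @param voxels dilation iterations (default 2, admits sinuses/carotids at
#'   the brain margin).
#' @return binary [mask_image()].
#' @export
blood_search_mask <- function(brain, voxels = 2L) {
  stopifnot(inherits(brain, "mask_image"), brain$kind == "binary")
  dil <- dilate6(brain$voxels, as.integer(voxels))
  mask_image(array(as.numeric(dil), dim(dil)), affine = brain$affine,
             kind = "binary")
}
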