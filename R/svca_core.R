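#' Per-voxel supervised clustering and reference extraction
#'
#' The extraction step of the supervised clustering algorithm: each
#' candidate voxel's normalized TAC is decomposed against the kinetic class
#' matrix `K` by non-negative least squares,
#' `TAC_v = w_1 K_1 + ... + w_n K_n` with all `w_i >= 0`.  The low-binding
#' grey matter (LBGM) ratio `w_LBGM / sum(w_i)` measures how purely the
#' voxel follows reference-like kinetics; voxels whose ratio strictly
#' exceeds a threshold (usually 0.9) form the pseudo-reference region, and
#' their raw (un-normalized) TACs are averaged into the reference curve.
#'
#' @name svca-core
NULL

#' Fit one voxel's TAC against the kinetic classes
#'
#' @param tac_v normalized TAC, length = rows of `K`.
#' @param K kinetic class matrix (n_frames x n_classes).
#' @return list with `w` (non-negative weights, named by class) and
#'   `residual_ss`.
#' @export
nnls_fit_voxel <- function(tac_v, K) {
  K <- as.matrix(K)
  if (ncol(K) < 2L) stop("kinetic class matrix needs >= 2 classes")
  if (length(tac_v) != nrow(K))
    stop("TAC length ", length(tac_v), " != class-matrix rows ", nrow(K))
  fit <- nnls(K, tac_v)
  w <- fit$x
  names(w) <- colnames(K)
  list(w = w, residual_ss = fit$residual_ss)
}

#' LBGM ratio of a weight vector
#'
#' `ratio = w_LBGM / sum(w)`.  When all weights are zero the ratio is
#' defined as 0, so a degenerate voxel can never be selected.
#'
#' @param w non-negative weight vector.
#' @param lbgm_index index of the low-binding grey matter class in `w`.
#' @return scalar in \[0, 1\].
#' @export
compute_ratio <- function(w, lbgm_index = 1L) {
  if (any(w < 0)) stop("weights must be non-negative")
  s <- sum(w)
  if (s == 0) 0 else unname(w[lbgm_index] / s)
}

# fit all candidate voxels; returns weights matrix (n_voxels x n_classes),
# ratio vector and residuals
.fit_candidates <- function(norm, candidate, classes) {
  d <- dim(norm$voxels)
  idx <- which(candidate$voxels == 1)
  if (!length(idx)) stop("candidate mask is empty")
  flat <- matrix(norm$voxels, prod(d[1:3]), d[4L])
  K <- classes$K
  W <- matrix(0, length(idx), ncol(K), dimnames = list(NULL, colnames(K)))
  rss <- numeric(length(idx))
  for (i in seq_along(idx)) {
    tac <- flat[idx[i], ]
    if (anyNA(tac))
      stop("candidate voxel outside the normalization mask ",
           "(candidate must be a subset of the brain mask)")
    fit <- nnls(K, tac)
    W[i, ] <- fit$x
    rss[i] <- fit$residual_ss
  }
  sums <- rowSums(W)
  ratio <- ifelse(sums > 0, W[, classes$lbgm_index] / sums, 0)
  list(idx = idx, W = W, ratio = ratio, rss = rss)
}

.check_extract_inputs <- function(pet, brain, candidate, classes,
                                  genotype, force_mask_mismatch) {
  if (!same_schedule(pet$schedule, classes$schedule))
    stop("frame schedule of the scan does not match the kinetic class set; ",
         "schedules must be identical (no interpolation is performed)")
  if (!check_alignment(pet, brain) || !check_alignment(pet, candidate))
    stop("brain/candidate masks are not aligned with the PET image")
  if (any(candidate$voxels == 1 & brain$voxels != 1))
    stop("candidate mask must be a subset of the brain mask")
  if (!is.na(classes$norm_mask_hash) &&
      classes$norm_mask_hash != "whole-frame" &&
      !startsWith(classes$norm_mask_hash, "policy")) {
    if (mask_hash(brain) != classes$norm_mask_hash) {
      msg <- paste0("brain mask differs from the one used for class ",
                    "training (hash mismatch); using a different mask ",
                    "definition mismatches testing and training data")
      if (force_mask_mismatch) warning(msg, " -- proceeding under --force")
      else stop(msg, " (pass force_mask_mismatch = TRUE to override)")
    }
  }
  if (classes$genotype != "ALL" && genotype != "unknown" &&
      genotype != classes$genotype)
    stop("genotype mismatch: subject is ", genotype,
         " but the class set was trained on ", classes$genotype,
         " binders")
  if (classes$genotype != "ALL" && genotype == "unknown")
    warning("subject genotype unknown; class set is genotype-specific (",
            classes$genotype, ")")
  invisible(TRUE)
}

#' Extract a pseudo-reference region from a dynamic PET scan
#'
#' Normalizes the scan with the brain mask, fits every candidate voxel
#' against the kinetic classes, computes the LBGM ratio map, selects voxels
#' with `ratio > threshold` (strict), and averages the selected voxels'
#' raw (un-normalized) TACs into the reference curve — either an unweighted
#' mean (`"simple"`) or weighted by each voxel's LBGM weight
#' (`"weighted"`).
#'
#' @param pet raw [dynamic_image()].
#' @param brain binary [mask_image()]; must match the training mask
#'   definition (hash-checked).
#' @param candidate binary [mask_image()], subset of `brain`; usually the
#'   subject's low-binding GM mask, or the brain mask itself.
#' @param classes a `kinetic_class_set`.
#' @param threshold LBGM-ratio selection threshold, strict inequality.
#' @param averaging `"simple"` or `"weighted"`.
#' @param genotype subject genotype, checked against the class set.
#' @param min_voxels warn (not fail) when fewer voxels are selected.
#' @param force_mask_mismatch downgrade the mask-hash mismatch error to a
#'   warning.
#' @return a `reference_region_result`: `selected_mask`, `ref_tac` (raw
#'   units), `n_selected`, `threshold`, `averaging`, `ratio_map` (3D array,
#'   `NA` outside candidates), `weights` (matrix over candidate voxels),
#'   `candidate_idx`, `residual_ss`.
#' @export
extract_reference <- function(pet, brain, candidate, classes,
                              threshold = 0.9,
                              averaging = c("simple", "weighted"),
                              genotype = "unknown", min_voxels = 50L,
                              force_mask_mismatch = FALSE) {
  averaging <- match.arg(averaging)
  if (!(threshold >= 0 && threshold <= 1))
    stop("threshold must lie in [0, 1]")
  .check_extract_inputs(pet, brain, candidate, classes, genotype,
                        force_mask_mismatch)
  norm <- normalize_frames(pet, brain)
  fit <- .fit_candidates(norm, candidate, classes)
  sel <- fit$ratio > threshold
  n_selected <- sum(sel)
  if (n_selected == 0L)
    stop("SVCA failed to find a suitable reference region: ",
         "no voxel exceeds the LBGM-ratio threshold ", threshold)
  if (n_selected < min_voxels)
    warning("only ", n_selected, " reference voxels selected ",
            "(floor: ", min_voxels, "); inspect the QC report")
  d <- dim(pet$voxels)
  sel_idx <- fit$idx[sel]
  selv <- array(0, d[1:3]); selv[sel_idx] <- 1
  selected_mask <- mask_image(selv, affine = pet$affine, kind = "binary")
  flat_raw <- matrix(pet$voxels, prod(d[1:3]), d[4L])
  ref_tac <- if (averaging == "simple") {
    colMeans(flat_raw[sel_idx, , drop = FALSE])
  } else {
    wl <- fit$W[sel, classes$lbgm_index]
    if (sum(wl) == 0) stop("weighted averaging impossible: all LBGM weights 0")
    drop(crossprod(flat_raw[sel_idx, , drop = FALSE], wl)) / sum(wl)
  }
  ratio_map <- array(NA_real_, d[1:3])
  ratio_map[fit$idx] <- fit$ratio
  structure(list(selected_mask = selected_mask, ref_tac = ref_tac,
                 n_selected = n_selected, threshold = threshold,
                 averaging = averaging, ratio_map = ratio_map,
                 weights = fit$W, candidate_idx = fit$idx,
                 residual_ss = fit$rss, schedule = pet$schedule,
                 candidate_mask = candidate),
            class = "reference_region_result")
}

#' @export
print.reference_region_result <- function(x, ...) {
  cat(sprintf(
    "<reference_region_result> %d voxels selected (ratio > %.2f, %s average)\n",
    x$n_selected, x$threshold, x$averaging))
  invisible(x)
}

#' Per-class weight maps and the LBGM ratio map
#'
#' Runs the same per-voxel decomposition as [extract_reference()] but
#' returns NIfTI-exportable 3D maps of every class weight and of the ratio,
#' for visual inspection.
#'
#' @inheritParams extract_reference
#' @return list with `weight_maps` (named list of 3D arrays, `NA` outside
#'   candidates) and `ratio_map`.
#' @export
weight_maps <- function(pet, brain, candidate, classes,
                        genotype = "unknown", force_mask_mismatch = FALSE) {
  .check_extract_inputs(pet, brain, candidate, classes, genotype,
                        force_mask_mismatch)
  norm <- normalize_frames(pet, brain)
  fit <- .fit_candidates(norm, candidate, classes)
  d3 <- dim(pet$voxels)[1:3]
  maps <- lapply(seq_along(classes$class_names), function(i) {
    m <- array(NA_real_, d3); m[fit$idx] <- fit$W[, i]; m
  })
  names(maps) <- classes$class_names
  ratio_map <- array(NA_real_, d3)
  ratio_map[fit$idx] <- fit$ratio
  list(weight_maps = maps, ratio_map = ratio_map)
}
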