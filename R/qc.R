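#' Quality control checks for the supervised clustering pipeline
#'
#' Three checks bracket the pipeline: (i) within-class coherence of the
#' training curves, (ii) the extracted reference TAC versus an anatomically
#' defined low-binding region, and (iii) the spatial distribution of the
#' selected voxels.  Every check is pure, never blocks a run, and always
#' returns the numeric evidence behind its verdict.
#'
#' "Early" and "late" frame times are operationalized as the first and last
#' third of frames; both are configurable.
#'
#' @name qc
NULL

.qc_entry <- function(status, ...) c(list(status = status), list(...))

#' QC: coherence of training class curves
#'
#' Per class, the pairwise Pearson correlation over frames between subject
#' curves; a warning is raised in the report when any pair falls below
#' `min_cor`.  Each class also reports the subject whose curve lies
#' farthest (L2 over frames) from the class median curve — the primary
#' outlier candidate.
#'
#' @param per_subject list of [class_tac()]s (>= 2 subjects per class).
#' @param min_cor pairwise-correlation warning threshold.
#' @return a `qc_report` list, one entry per class with `status`
#'   (`"pass"`/`"warn"`), `min_pairwise_cor`, `outlier_subject`,
#'   `outlier_distance`.
#' @export
qc_class_curves <- function(per_subject, min_cor = 0.7) {
  classes <- unique(vapply(per_subject, `[[`, character(1), "class_name"))
  checks <- list()
  for (cls in classes) {
    curves <- Filter(function(tc) tc$class_name == cls, per_subject)
    if (length(curves) < 2L)
      stop("class '", cls, "' needs >= 2 subjects for QC")
    mat <- vapply(curves, `[[`,
                  numeric(length(curves[[1L]]$values)), "values")
    ids <- vapply(curves, `[[`, character(1), "subject_id")
    cm <- stats::cor(mat)
    min_pair <- min(cm[upper.tri(cm)])
    med <- apply(mat, 1L, stats::median)
    dist <- sqrt(colSums((mat - med)^2))
    worst <- which.max(dist)
    checks[[cls]] <- .qc_entry(
      if (min_pair < min_cor) "warn" else "pass",
      min_pairwise_cor = min_pair,
      outlier_subject = ids[worst],
      outlier_distance = unname(dist[worst]))
  }
  structure(list(check = "class_curves", classes = checks),
            class = "qc_report")
}

#' QC: reference TAC versus an anatomical low-binding region
#'
#' A sound pseudo-reference TAC shows a comparable-or-higher peak at early
#' frame times and comparable-or-lower activity at later frame times than
#' an anatomically defined low-binding grey matter TAC (e.g. cerebellar
#' GM).  Passes iff `max(ref[early]) >= (1 - tol) * max(anat[early])` and
#' `mean(ref[late]) <= (1 + tol) * mean(anat[late])`.
#'
#' @param ref_tac,anat_tac raw-unit TACs on the same schedule.
#' @param schedule the shared [frame_schedule()].
#' @param tol comparability tolerance (default 5%).
#' @param early_frac,late_frac fraction of frames treated as early/late.
#' @return a `qc_report` with `status`, `early_ratio`
#'   (`max(ref)/max(anat)` over early frames) and `late_ratio`
#'   (`mean(ref)/mean(anat)` over late frames).
#' @export
qc_reference_vs_anatomical <- function(ref_tac, anat_tac, schedule,
                                       tol = 0.05, early_frac = 1 / 3,
                                       late_frac = 1 / 3) {
  n <- schedule$n_frames
  stopifnot(length(ref_tac) == n, length(anat_tac) == n)
  early <- seq_len(ceiling(n * early_frac))
  late <- seq.int(n - ceiling(n * late_frac) + 1L, n)
  early_ratio <- max(ref_tac[early]) / max(anat_tac[early])
  late_ratio <- mean(ref_tac[late]) / mean(anat_tac[late])
  pass <- early_ratio >= 1 - tol && late_ratio <= 1 + tol
  structure(list(check = "reference_vs_anatomical",
                 status = if (pass) "pass" else "fail",
                 early_ratio = early_ratio, late_ratio = late_ratio,
                 tol = tol), class = "qc_report")
}

#' QC: spatial distribution of the selected reference voxels
#'
#' Selected voxels should be roughly evenly spread across the candidate
#' (healthy grey matter) mask, not clumped.  The candidate mask is split
#' into octants at its centroid; the report warns when any octant holds
#' more than `max_octant_frac` of the selected voxels.
#'
#' @param selected_mask,candidate_mask binary [mask_image()]s,
#'   selected being a subset of candidate.
#' @param max_octant_frac clumping warning threshold.
#' @return a `qc_report` with `n_selected`, `frac_of_candidates`,
#'   `octant_fracs` (length 8) and `status`.
#' @export
qc_selection_distribution <- function(selected_mask, candidate_mask,
                                      max_octant_frac = 0.5) {
  sel <- which(selected_mask$voxels == 1)
  cand <- which(candidate_mask$voxels == 1)
  if (length(setdiff(sel, cand)))
    stop("selected mask is not a subset of the candidate mask")
  if (!length(sel)) stop("no selected voxels; extraction should have failed upstream")
  d <- dim(candidate_mask$voxels)
  co <- arrayInd(cand, d)
  centroid <- colMeans(co)
  cs <- arrayInd(sel, d)
  oct <- 1L + (cs[, 1] > centroid[1]) + 2L * (cs[, 2] > centroid[2]) +
    4L * (cs[, 3] > centroid[3])
  fr <- tabulate(oct, 8L) / length(sel)
  structure(list(check = "selection_distribution",
                 status = if (max(fr) > max_octant_frac) "warn" else "pass",
                 n_selected = length(sel),
                 frac_of_candidates = length(sel) / length(cand),
                 octant_fracs = fr), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$check, "\n", sep = "")
  utils::str(x[-1], give.attr = FALSE)
  invisible(x)
}

#' Logan reference-region DVR (minimal demonstration model)
#'
#' Ordinary least squares on the Logan reference coordinates
#' `y(t) = int_0^t C_T / C_T(t)` versus
#' `x(t) = [int_0^t C_R + C_R(t)/k2_ref] / C_T(t)` (the `k2_ref` term is
#' omitted when `k2_ref` is `NULL`), using frames with midpoint
#' `>= t_star`.  The slope estimates the distribution volume ratio (DVR).
#' Integrals are trapezoids on frame midpoints from time zero.
#'
#' @param target_tac,ref_tac raw-unit TACs on `schedule`.
#' @param schedule the shared [frame_schedule()].
#' @param t_star start of the linear segment, seconds.
#' @param k2_ref reference-region efflux constant, 1/min, or `NULL` to
#'   omit the term.
#' @return a `dvr_result`: `dvr` (slope), `intercept`, `t_star`, `fit_r2`,
#'   `n_points`.
#' @export
logan_ref_dvr <- function(target_tac, ref_tac, schedule, t_star = 0,
                          k2_ref = NULL) {
  n <- schedule$n_frames
  stopifnot(length(target_tac) == n, length(ref_tac) == n)
  mid <- frame_mid(schedule)
  # cumulative trapezoid from t = 0 (activity 0 at injection)
  ctrap <- function(v) {
    tt <- c(0, mid); vv <- c(0, v)
    cumsum(c(0, diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2))[-1L]
  }
  int_t <- ctrap(target_tac)
  int_r <- ctrap(ref_tac)
  use <- which(mid >= t_star)
  if (length(use) < 3L)
    stop("need >= 3 frames with midpoint >= t_star (got ", length(use), ")")
  if (any(target_tac[use] <= 0))
    stop("target TAC must be positive beyond t_star")
  y <- int_t[use] / target_tac[use]
  xr <- int_r[use]
  if (!is.null(k2_ref)) xr <- xr + ref_tac[use] / (k2_ref / 60)  # 1/min -> 1/s
  x <- xr / target_tac[use]
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2L])
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(list(dvr = slope, intercept = unname(fit$coefficients[1L]),
                 t_star = t_star, fit_r2 = r2, n_points = length(use)),
            class = "dvr_result")
}

#' @export
print.dvr_result <- function(x, ...) {
  cat(sprintf("<dvr_result> DVR = %.4f (t* = %.0f s, R^2 = %.4f, %d frames)\n",
              x$dvr, x$t_star, x$fit_r2, x$n_points))
  invisible(x)
}
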