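#' Kinetic classes: canonical normalized time-activity curves per tissue
#'
#' The four-class TSPO PET scheme: low-binding grey matter (`lbgm`, the
#' expected reference kinetics), white matter (`wm`), blood (`blood`) and
#' high-binding grey matter (`hbgm`, e.g. thalamus in healthy volunteers or
#' pathological tissue).  Classes are built once per tracer/scanner from a
#' training cohort and reused for every extraction.
#'
#' @name kinetic-classes
NULL

.class_order <- c("lbgm", "wm", "blood", "hbgm")

#' A single subject's normalized class TAC
#'
#' @param class_name one of `"lbgm"`, `"wm"`, `"blood"`, `"hbgm"`.
#' @param values normalized (unitless) activity per frame.
#' @param schedule the shared [frame_schedule()].
#' @param subject_id provenance.
#' @return a `class_tac` object.
#' @export
class_tac <- function(class_name, values, schedule, subject_id = NA_character_) {
  class_name <- match.arg(class_name, .class_order)
  values <- as.numeric(values)
  if (length(values) != schedule$n_frames)
    stop("class TAC length ", length(values), " != n_frames ",
         schedule$n_frames)
  if (!all(is.finite(values))) stop("class TAC has non-finite values")
  structure(list(class_name = class_name, values = values,
                 schedule = schedule, subject_id = subject_id),
            class = "class_tac")
}

#' Mean normalized TAC over a binary mask
#'
#' Per-frame unweighted mean of the normalized voxel values inside `mask`.
#'
#' @param norm a `normalized_dynamic` (see [normalize_frames()]).
#' @param mask binary, non-empty [mask_image()] aligned with the scan.
#' @param class_name tissue label for the result.
#' @return a [class_tac()].
#' @export
extract_class_tac <- function(norm, mask, class_name) {
  stopifnot(inherits(norm, "normalized_dynamic"), inherits(mask, "mask_image"))
  if (mask$kind != "binary") stop("class mask must be binary")
  d <- dim(norm$voxels)
  if (!all(dim(mask$voxels) == d[1:3]))
    stop("mask grid does not match the normalized image")
  idx <- which(mask$voxels == 1)
  if (!length(idx)) stop("class mask is empty")
  flat <- matrix(norm$voxels, prod(d[1:3]), d[4L])
  vals <- colMeans(flat[idx, , drop = FALSE])
  if (anyNA(vals))
    stop("class mask '", class_name,
         "' reaches outside the normalization mask")
  class_tac(class_name, vals, norm$schedule)
}

#' QC: does a blood TAC look like a blood input function?
#'
#' A plausible blood curve shows a sharp peak at early frame times followed
#' by a fast washout.  The check passes iff the global maximum falls in the
#' first third of frames and the final-frame value is below 50% of the peak
#' (normalized units).  This is a QC flag — it never blocks a pipeline.
#'
#' @param tac a [class_tac()] (any class; typically `blood`).
#' @param schedule optional schedule override.
#' @return list with `pass`, `peak_frame`, `peak_third` (frame count that
#'   bounds "early"), `tail_ratio` (final value / peak).
#' @export
validate_blood_shape <- function(tac, schedule = tac$schedule) {
  v <- tac$values
  n <- length(v)
  if (n < 3L) stop("need at least 3 frames to judge a blood curve")
  third <- ceiling(n / 3)
  pk <- which.max(v)
  # normalized curves can be negative; judge washout relative to peak-to-min
  rng <- v[pk] - min(v)
  tail_ratio <- if (rng > 0) (v[n] - min(v)) / rng else 1
  list(pass = (pk <= third) && (tail_ratio < 0.5) && rng > 0,
       peak_frame = pk, peak_third = third, tail_ratio = tail_ratio)
}

#' Aggregate per-subject class TACs into a kinetic class set
#'
#' Per class and frame, the mean (default) or median across training
#' subjects.  The median is more robust to outlying subjects.  Class order
#' is fixed as lbgm, wm, blood, hbgm with `lbgm` flagged as the reference
#' class.
#'
#' @param per_subject list of [class_tac()] objects (all classes, all
#'   subjects, any order).
#' @param method `"mean"` or `"median"`.
#' @param genotype stratum tag: `"HAB"`, `"MAB"` or `"ALL"`.
#' @param norm_mask_hash audit token from [normalize_frames()].
#' @return a `kinetic_class_set`: `K` (n_frames x n_classes matrix),
#'   `class_names`, `lbgm_index`, `schedule`, `genotype`, `aggregation`,
#'   `norm_mask_hash`, `training_subjects`.
#' @export
aggregate_classes <- function(per_subject, method = c("mean", "median"),
                              genotype = c("ALL", "HAB", "MAB"),
                              norm_mask_hash = NA_character_) {
  method <- match.arg(method)
  genotype <- match.arg(genotype)
  if (!length(per_subject)) stop("no class TACs supplied")
  sch <- per_subject[[1L]]$schedule
  for (tc in per_subject) {
    if (!same_schedule(tc$schedule, sch))
      stop("schedule mismatch across training subjects (subject ",
           tc$subject_id, ")")
  }
  K <- matrix(NA_real_, sch$n_frames, length(.class_order),
              dimnames = list(NULL, .class_order))
  for (cls in .class_order) {
    curves <- Filter(function(tc) tc$class_name == cls, per_subject)
    if (!length(curves))
      stop("class '", cls, "' is represented by no training subject")
    mat <- vapply(curves, `[[`, numeric(sch$n_frames), "values")
    K[, cls] <- if (method == "mean") rowMeans(mat)
                else apply(mat, 1L, stats::median)
  }
  subj <- unique(stats::na.omit(vapply(per_subject, `[[`, character(1),
                                       "subject_id")))
  structure(list(K = K, class_names = .class_order, lbgm_index = 1L,
                 schedule = sch, genotype = genotype, aggregation = method,
                 norm_mask_hash = norm_mask_hash,
                 training_subjects = as.character(subj)),
            class = "kinetic_class_set")
}

#' @export
print.kinetic_class_set <- function(x, ...) {
  cat(sprintf(
    "<kinetic_class_set> %s/%s: %d frames x %d classes (%s), %d subjects\n",
    x$genotype, x$aggregation, nrow(x$K), ncol(x$K),
    paste(x$class_names, collapse = ","), length(x$training_subjects)))
  invisible(x)
}

#' Configuration for kinetic class building
#'
#' @param hbgm_source which mask supplies the high-binding class: the name
#'   of a subject mask, usually `"high_binding"` (pathological GM from
#'   patients) or `"thalamus"` (healthy volunteers).  No default: the choice
#'   must be explicit.
#' @param p_threshold GM/WM probability cut (paper: generally > 0.9).
#' @param erode_binary erosions applied to binary segmentations.
#' @param erode_prob erosions applied after thresholding probability maps.
#' @param early_window_s blood-search early window, seconds.
#' @param n_top_blood hottest-early-voxel count for the blood mask.
#' @param blood_dilate brain-mask dilation for the blood search region.
#' @param aggregation `"mean"` or `"median"`.
#' @param min_subjects warn (not fail) below this cohort size per stratum.
#' @return a validated `class_config` list.
#' @export
class_config <- function(hbgm_source, p_threshold = 0.9, erode_binary = 1L,
                         erode_prob = 0L, early_window_s = 180,
                         n_top_blood = 50L, blood_dilate = 2L,
                         aggregation = c("mean", "median"),
                         min_subjects = 10L) {
  aggregation <- match.arg(aggregation)
  if (missing(hbgm_source) || !is.character(hbgm_source))
    stop("class_config: hbgm_source must name the high-binding mask ",
         "(e.g. \"high_binding\" or \"thalamus\")")
  if (!(p_threshold > 0 && p_threshold < 1))
    stop("p_threshold must lie in (0, 1)")
  if (early_window_s <= 0) stop("early_window_s must be positive")
  if (n_top_blood < 1) stop("n_top_blood must be >= 1")
  structure(list(hbgm_source = hbgm_source, p_threshold = p_threshold,
                 erode_binary = as.integer(erode_binary),
                 erode_prob = as.integer(erode_prob),
                 early_window_s = early_window_s,
                 n_top_blood = as.integer(n_top_blood),
                 blood_dilate = as.integer(blood_dilate),
                 aggregation = aggregation,
                 min_subjects = as.integer(min_subjects)),
            class = "class_config")
}

# mask preparation for one tissue: probability maps are thresholded (+
# optional erosion); binary masks are eroded only
.prep_subject_mask <- function(mask, config) {
  if (mask$kind == "probability")
    prepare_tissue_mask(mask, config$p_threshold, config$erode_prob)
  else if (config$erode_binary > 0)
    prepare_tissue_mask(mask, 0.5, config$erode_binary)
  else mask
}

# one subject's four normalized class TACs
.subject_class_tacs <- function(subj, config) {
  stage <- "normalize"
  res <- tryCatch({
    norm <- normalize_frames(subj$pet, subj$masks$brain)
    stage <- "lbgm mask"
    lbgm <- .prep_subject_mask(subj$masks$gm_prob, config)
    stage <- "wm mask"
    wm <- .prep_subject_mask(subj$masks$wm_prob, config)
    stage <- "blood mask"
    blood <- if (!is.null(subj$masks$blood)) subj$masks$blood
      else build_blood_mask(subj$pet, config$early_window_s,
                            config$n_top_blood,
                            blood_search_mask(subj$masks$brain,
                                              config$blood_dilate))
    stage <- "hbgm mask"
    hb_src <- subj$masks[[config$hbgm_source]]
    if (is.null(hb_src))
      stop("mask '", config$hbgm_source, "' not found")
    hbgm <- .prep_subject_mask(hb_src, config)
    stage <- "TAC extraction"
    tacs <- list(
      extract_class_tac(norm, lbgm, "lbgm"),
      extract_class_tac(norm, wm, "wm"),
      extract_class_tac(norm, blood, "blood"),
      extract_class_tac(norm, hbgm, "hbgm"))
    for (i in seq_along(tacs)) tacs[[i]]$subject_id <- subj$subject_id
    list(tacs = tacs, mask_hash = norm$mask_hash)
  }, error = function(e) {
    stop("subject ", subj$subject_id, " failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  res
}

#' Build kinetic class sets from a training cohort
#'
#' Runs normalization, mask preparation, class-TAC extraction and
#' aggregation for every subject, then emits one [aggregate_classes()]
#' result per requested genotype stratum.  All subjects must share one
#' frame schedule exactly; strata with fewer than `config$min_subjects`
#' subjects trigger a warning (training cohorts of N > 10 are recommended).
#'
#' @param cohort list of [subject_record()]s.
#' @param config a [class_config()].
#' @param strata character vector among `"ALL"`, `"HAB"`, `"MAB"`.
#' @return named list of `kinetic_class_set`s, one per stratum.
#' @export
build_class_sets <- function(cohort, config, strata = "ALL") {
  if (!length(cohort)) stop("empty training cohort")
  stopifnot(inherits(config, "class_config"))
  strata <- match.arg(strata, c("ALL", "HAB", "MAB"), several.ok = TRUE)
  sch <- cohort[[1L]]$pet$schedule
  for (s in cohort) if (!same_schedule(s$pet$schedule, sch))
    stop("subject ", s$subject_id,
         " has a different frame schedule; schedules must match exactly")
  per_subj <- lapply(cohort, .subject_class_tacs, config = config)
  hashes <- vapply(per_subj, `[[`, character(1), "mask_hash")
  set_hash <- if (length(unique(hashes)) == 1L) hashes[1L]
    else digest::digest(list(policy = "per-subject brain masks",
                             n = length(hashes)))
  genos <- vapply(cohort, `[[`, character(1), "genotype")
  out <- list()
  for (st in strata) {
    keep <- if (st == "ALL") seq_along(cohort) else which(genos == st)
    if (!length(keep))
      stop("stratum ", st, " has no training subjects")
    if (length(keep) < config$min_subjects)
      warning("stratum ", st, " has only ", length(keep),
              " subjects; training cohorts of N > 10 are recommended")
    tacs <- unlist(lapply(per_subj[keep], `[[`, "tacs"), recursive = FALSE)
    out[[st]] <- aggregate_classes(tacs, method = config$aggregation,
                                   genotype = st,
                                   norm_mask_hash = set_hash)
  }
  out
}

#' Leave-one-out class building
#'
#' Builds classes from every cohort subject except `held_out`, as required
#' when applying the method to a subject who is part of the training pool.
#'
#' @inheritParams build_class_sets
#' @param held_out subject id to exclude.
#' @param stratum single stratum tag for the result.
#' @return one `kinetic_class_set`.
#' @export
build_class_sets_loo <- function(cohort, config, held_out, stratum = "ALL") {
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  if (!held_out %in% ids)
    stop("held-out subject '", held_out, "' not found in the cohort")
  if (length(cohort) < 2L) stop("leave-one-out needs a cohort of >= 2")
  build_class_sets(cohort[ids != held_out], config, strata = stratum)[[1L]]
}

#' Serialize / deserialize a kinetic class set
#'
#' JSON container with the schedule, stratum, aggregation method, class
#' names, the K matrix (one row per frame), training ids and the
#' normalization-mask hash.  Round-trips bit-exactly.
#'
#' @param x a `kinetic_class_set`.
#' @param path output .json path.
#' @return `path` (writer) / the class set (reader).
#' @export
write_class_set <- function(x, path) {
  stopifnot(inherits(x, "kinetic_class_set"))
  obj <- list(format = "svcaref.kinetic_class_set", version = 1L,
              schedule = list(start = x$schedule$start, end = x$schedule$end),
              genotype = x$genotype, aggregation = x$aggregation,
              class_names = x$class_names, lbgm_index = x$lbgm_index,
              K = apply(unname(x$K), 1L, identity, simplify = FALSE),
              norm_mask_hash = x$norm_mask_hash,
              training_subjects = x$training_subjects)
  # I(17) significant digits: doubles survive the round-trip bit-exactly
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_class_set
#' @export
read_class_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$format) || j$format != "svcaref.kinetic_class_set")
    stop("not a kinetic class set file: ", path)
  K <- if (is.matrix(j$K)) j$K else do.call(rbind, j$K)
  colnames(K) <- j$class_names
  structure(list(K = K, class_names = j$class_names,
                 lbgm_index = as.integer(j$lbgm_index),
                 schedule = frame_schedule(j$schedule$start, j$schedule$end),
                 genotype = j$genotype, aggregation = j$aggregation,
                 norm_mask_hash = j$norm_mask_hash,
                 training_subjects = as.character(j$training_subjects)),
            class = "kinetic_class_set")
}

#' Companion CSV of the class matrix (for humans)
#'
#' @param x a `kinetic_class_set`.
#' @param path output .csv path.
#' @export
write_class_csv <- function(x, path) {
  tab <- data.frame(frame_mid_s = frame_mid(x$schedule))
  for (cls in x$class_names) tab[[cls]] <- x$K[, cls]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
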