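#' Ground-truthed dynamic PET phantoms
#'
#' The simulator produces the data world the algorithm assumes: a labelled
#' 3D volume whose voxels follow class-specific kinetics — a blood curve
#' with a sharp early peak and fast washout (gamma-variate input function),
#' and three tissue classes (low-binding GM, white matter, high-binding GM)
#' modelled as one-tissue-compartment responses to that input, integrated
#' analytically over each frame interval.  Gaussian noise scaled by frame
#' duration stands in for reconstruction noise.  Everything is
#' deterministic for a fixed seed, and the generating truth (labels,
#' per-voxel mixing weights, raw templates) is returned alongside the data.
#'
#' @name synthdata
NULL

#' Tracer kinetic profile for the simulator
#'
#' The blood input is `Cp(t) = A t exp(-t / beta)` with the peak at
#' `t = beta` seconds; tissue classes follow one-tissue-compartment
#' kinetics `dC/dt = K1 Cp - k2 C`.  Defaults give late-frame activity
#' ordering hbgm > lbgm > wm (distribution volumes 5.0, 3.0, ~1.1, with
#' washout rates ordered wm > lbgm > hbgm so the ordering holds to the end
#' of the scan) and a blood peak at 30 s, within the first minute.
#'
#' @param blood_beta gamma-variate time constant, seconds (= peak time).
#' @param blood_peak peak blood activity, kBq/mL.
#' @param K1 named vector of influx constants, mL/cm3/min
#'   (`lbgm`, `wm`, `hbgm`, plus `csf` for the non-class cerebrospinal
#'   fluid compartment the phantom carries; CSF is inside the brain mask
#'   but belongs to no kinetic class, as in real brains — without such
#'   off-class tissue the normalized class curves would be exactly
#'   linearly dependent and per-voxel weights unidentifiable).
#' @param k2 named vector of efflux constants, 1/min.
#' @param hbgm_binding_scale multiplies the hbgm K1; 1.0 emulates
#'   high-affinity binders, ~0.6 medium-affinity binders.
#' @return a `tracer_profile` list.
#' @export
tracer_profile <- function(blood_beta = 30, blood_peak = 80,
                           K1 = c(lbgm = 0.30, wm = 0.15, hbgm = 0.35, csf = 0.05),
                           k2 = c(lbgm = 0.10, wm = 0.14, hbgm = 0.07,
                                  csf = 0.60),
                           hbgm_binding_scale = 1.0) {
  if (blood_beta <= 0 || blood_peak <= 0)
    stop("blood input parameters must be positive")
  # partial named vectors are merged over the defaults
  if (is.null(names(K1)) || is.null(names(k2)))
    stop("K1 and k2 must be named vectors (lbgm, wm, hbgm, csf)")
  defaults <- eval(formals(tracer_profile)$K1)
  K1 <- replace(defaults, names(K1), K1)
  defaults_k2 <- eval(formals(tracer_profile)$k2)
  k2 <- replace(defaults_k2, names(k2), k2)
  if (any(K1 <= 0) || any(k2 <= 0))
    stop("non-physical kinetic parameters: K1 and k2 must be positive")
  if (hbgm_binding_scale <= 0) stop("hbgm_binding_scale must be positive")
  K1[["hbgm"]] <- K1[["hbgm"]] * hbgm_binding_scale
  structure(list(blood_beta = blood_beta, blood_peak = blood_peak,
                 K1 = K1, k2 = k2), class = "tracer_profile")
}

# exact frame averages of the gamma-variate input A t exp(-lam t):
# F(t) = (t/lam + 1/lam^2) exp(-lam t); mean over [t1,t2] = A (F(t1)-F(t2))/dt
.blood_frame_avg <- function(t1, t2, A, lam) {
  F <- function(t) (t / lam + 1 / lam^2) * exp(-lam * t)
  A * (F(t1) - F(t2)) / (t2 - t1)
}

# 1TCM response to the gamma-variate input, frame-averaged analytically:
# C(t) = K1*A/a^2 [exp(-k2 t) - exp(-lam t) - a t exp(-lam t)], a = lam - k2
.tissue_frame_avg <- function(t1, t2, K1s, k2s, A, lam) {
  a <- lam - k2s
  if (abs(a) < 1e-12) stop("degenerate kinetics: k2 equals the input rate")
  E <- function(k) (exp(-k * t1) - exp(-k * t2)) / k
  Tk <- (t1 / lam + 1 / lam^2) * exp(-lam * t1) -
        (t2 / lam + 1 / lam^2) * exp(-lam * t2)
  K1s * A / a^2 * (E(k2s) - E(lam) - a * Tk) / (t2 - t1)
}

#' Raw class template TACs on a frame schedule
#'
#' @param schedule a [frame_schedule()].
#' @param profile a [tracer_profile()].
#' @return matrix `n_frames x 5` with columns `lbgm`, `wm`, `blood`,
#'   `hbgm`, `csf`: frame-averaged activity (kBq/mL) of each pure tissue.
#'   The first four are the kinetic classes; `csf` is the phantom's
#'   off-class compartment.
#' @export
make_class_templates <- function(schedule, profile = tracer_profile()) {
  stopifnot(inherits(profile, "tracer_profile"))
  lam <- 1 / profile$blood_beta
  A <- profile$blood_peak / (profile$blood_beta * exp(-1))
  t1 <- schedule$start; t2 <- schedule$end
  out <- matrix(NA_real_, schedule$n_frames, 5L,
                dimnames = list(NULL, c("lbgm", "wm", "blood", "hbgm",
                                        "csf")))
  out[, "blood"] <- .blood_frame_avg(t1, t2, A, lam)
  for (cls in c("lbgm", "wm", "hbgm", "csf"))
    out[, cls] <- .tissue_frame_avg(t1, t2, profile$K1[[cls]] / 60,
                                    profile$k2[[cls]] / 60, A, lam)
  out
}

#' Specification of a phantom volume
#'
#' The default layout is a 24^3 grid holding a 20^3 "brain" box that
#' contains a central white matter block, a thalamus-like high-binding
#' block, a 64-voxel vascular block and low-binding grey matter everywhere
#' else, scanned on the default 49-min schedule.
#'
#' @param grid_shape 3 integers.
#' @param schedule a [frame_schedule()].
#' @param profile a [tracer_profile()].
#' @param noise_level relative Gaussian noise: the SD of a voxel's value in
#'   frame j is `noise_level * value_j / sqrt(frame_duration_s)`, so longer
#'   frames are quieter, mimicking count statistics (`noise_level` is the
#'   relative SD of a hypothetical 1-s frame).
#' @param mixing `"none"` (pure voxels) or `"dirichlet"`: a partial-volume
#'   model in which tissue voxels within 2 voxels of a region boundary
#'   (the PSF-affected shell) draw convex mixtures of the four kinetic
#'   classes from a Dirichlet centred on their own class, while deeper
#'   voxels remain pure; blood and CSF voxels always stay pure.
#' @param dirichlet_own,dirichlet_other Dirichlet concentrations for the
#'   shell voxels' own class and each other class.  The defaults
#'   (1.2, 0.6) spread the own-class fraction broadly (mean 0.4), as a
#'   heavily PSF-blended interface voxel would be.
#' @param seed RNG seed (integer).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 24L),
                         schedule = default_schedule(),
                         profile = tracer_profile(), noise_level = 0.1,
                         mixing = c("none", "dirichlet"),
                         dirichlet_own = 1.2, dirichlet_other = 0.6,
                         seed = 20260101L) {
  mixing <- match.arg(mixing)
  if (noise_level < 0) stop("noise_level must be >= 0")
  if (any(grid_shape < 12L))
    stop("grid must be at least 12 voxels per axis for the default layout")
  structure(list(grid_shape = as.integer(grid_shape), schedule = schedule,
                 profile = profile, noise_level = noise_level,
                 mixing = mixing, dirichlet_own = dirichlet_own,
                 dirichlet_other = dirichlet_other,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# label volume: 0 background, 1 lbgm, 2 wm, 3 blood, 4 hbgm, 5 csf
.phantom_labels <- function(grid_shape) {
  g <- grid_shape
  lab <- array(0L, g)
  box <- function(lo, hi) {
    lo <- pmax(lo, 1L); hi <- pmin(hi, g)
    list(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  }
  sc <- g / 24                                 # layout scales with the grid
  at <- function(v) as.integer(round(v * sc))
  b <- box(at(c(3, 3, 3)), at(c(22, 22, 22)))
  lab[b$x, b$y, b$z] <- 1L
  wm <- box(at(c(8, 8, 8)), at(c(17, 17, 17)))
  lab[wm$x, wm$y, wm$z] <- 2L
  # CSF: central ventricle block plus sulcal layers on three brain faces
  # (~15% of the brain, within the 10-20% intracranial CSF fraction;
  # off-class tissue that no kinetic class represents)
  vent <- box(at(c(11, 11, 11)), at(c(14, 14, 14)))
  lab[vent$x, vent$y, vent$z] <- 5L
  for (z in c(3, 22)) {
    lay <- box(at(c(3, 3, z)), at(c(22, 22, z)))
    lab[lay$x, lay$y, lay$z] <- 5L
  }
  side <- box(at(c(3, 3, 3)), at(c(3, 22, 22)))
  lab[side$x, side$y, side$z] <- 5L
  bl <- box(at(c(11, 11, 19)), at(c(14, 14, 22)))
  lab[bl$x, bl$y, bl$z] <- 3L
  hb <- box(at(c(18, 18, 9)), at(c(21, 21, 16)))
  lab[hb$x, hb$y, hb$z] <- 4L
  lab
}

# probability map for one label: 1 in the interior, 0.5 on the one-voxel
# partial-volume shell, 0 elsewhere
.prob_from_label <- function(lab, value) {
  bin <- lab == value
  interior <- erode6(bin)
  array(ifelse(interior, 1, ifelse(bin, 0.5, 0)), dim(lab))
}

#' Generate one phantom scan with its ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `pet` (a [dynamic_image()]), `masks` (named list:
#'   `brain` binary, `gm_prob`, `wm_prob` probability maps,
#'   `high_binding` binary thalamus-like mask), and `truth` (list:
#'   `labels`, `templates` raw class template matrix, `weights` matrix of
#'   true mixing weights over brain voxels, `brain_idx` their linear
#'   indices, `blood_mask` binary array of the true vascular voxels).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  g <- spec$grid_shape
  lab <- .phantom_labels(g)
  templates <- make_class_templates(spec$schedule, spec$profile)
  nfr <- spec$schedule$n_frames
  brain_idx <- which(lab > 0L)
  nvox <- length(brain_idx)
  W <- matrix(0, nvox, 5L, dimnames = list(NULL, colnames(templates)))
  cls_of <- c("lbgm", "wm", "blood", "hbgm", "csf")[lab[brain_idx]]
  W[cbind(seq_len(nvox), match(cls_of, colnames(W)))] <- 1
  if (spec$mixing == "dirichlet") {
    # partial-volume model: tissue voxels within 2 voxels of a region
    # boundary (the PSF-affected shell) blend across the four kinetic
    # classes; deeper voxels stay pure, as do vessels and CSF
    for (li in c(1L, 2L, 4L)) {
      bin <- lab == li
      ring <- which(bin & !erode6(bin, 2L))
      vi <- match(ring, brain_idx)
      n_mix <- length(ring)
      if (!n_mix) next
      own <- match(c("lbgm", "wm", "blood", "hbgm", "csf")[li],
                   colnames(W))
      alpha <- matrix(spec$dirichlet_other, n_mix, 4L)
      alpha[, own] <- spec$dirichlet_own
      gam <- matrix(stats::rgamma(n_mix * 4L, shape = alpha), n_mix, 4L)
      W[vi, ] <- 0
      W[vi, 1:4] <- gam / rowSums(gam)
    }
  }
  tacs <- W %*% t(templates)                   # nvox x n_frames
  if (spec$noise_level > 0) {
    # noise tracks the local (frame-wise) activity, scaled by frame
    # duration: SD_j = noise_level * value_j / sqrt(duration_j [s])
    dur <- frame_dur(spec$schedule)
    sd_mat <- spec$noise_level * abs(tacs) *
      matrix(1 / sqrt(dur), nrow(tacs), ncol(tacs), byrow = TRUE)
    tacs <- tacs + stats::rnorm(length(tacs)) * sd_mat
  }
  vol <- array(0, c(g, nfr))
  flat <- matrix(vol, prod(g), nfr)
  flat[brain_idx, ] <- tacs
  pet <- dynamic_image(array(flat, c(g, nfr)), spec$schedule,
                       decay_corrected = TRUE)
  brain <- mask_image(array(as.numeric(lab > 0L), g), kind = "binary")
  masks <- list(
    brain = brain,
    gm_prob = mask_image(.prob_from_label(lab, 1L), kind = "probability"),
    wm_prob = mask_image(.prob_from_label(lab, 2L), kind = "probability"),
    high_binding = mask_image(array(as.numeric(lab == 4L), g),
                              kind = "binary"))
  truth <- list(labels = lab, templates = templates, weights = W,
                brain_idx = brain_idx,
                blood_mask = array(as.numeric(lab == 3L), g))
  list(pet = pet, masks = masks, truth = truth)
}

#' Ground-truth kinetic class set for a phantom world
#'
#' Builds the ideal class matrix for simulation studies that probe the
#' per-voxel decomposition in isolation: the raw class templates passed
#' through the normalization statistics of the noiseless twin of `spec`
#' (same seed and layout, `noise_level = 0`).  Against these classes, a
#' noiseless mixed phantom decomposes exactly to its true mixing weights;
#' what remains to be tested is the degradation under noise.
#'
#' @param spec a [phantom_spec()].
#' @return a `kinetic_class_set` with `training_subjects = "truth"`.
#' @export
oracle_class_set <- function(spec = phantom_spec()) {
  spec0 <- spec
  spec0$noise_level <- 0
  ph <- generate_phantom(spec0)
  norm <- normalize_frames(ph$pet, ph$masks$brain)
  K <- sweep(sweep(ph$truth$templates[, 1:4], 1L, norm$per_frame_mean), 1L,
             norm$per_frame_sd, "/")
  structure(list(K = K, class_names = colnames(K), lbgm_index = 1L,
                 schedule = spec$schedule, genotype = "ALL",
                 aggregation = "mean",
                 norm_mask_hash = mask_hash(ph$masks$brain),
                 training_subjects = "truth"),
            class = "kinetic_class_set")
}

#' Generate a training cohort of phantom subjects
#'
#' Each subject receives multiplicative log-normal jitter on the tissue
#' kinetic parameters (K1, k2) and an independent noise realization;
#' per-subject truth is recorded.  The default 5% jitter represents
#' residual kinetic *shape* variability: frame-wise normalization removes
#' global amplitude differences by design, so the larger amplitude
#' component of real between-subject variability is irrelevant here.  With
#' `genotypes` supplied, medium-affinity binders ("MAB") get their
#' high-binding K1 scaled by `mab_scale`.
#'
#' @param n_subjects cohort size (training sets of N > 10 are
#'   recommended).
#' @param spec base [phantom_spec()]; per-subject seeds are derived from
#'   `spec$seed`.
#' @param jitter_sdlog SD of the log-normal kinetic jitter (0 disables).
#' @param genotypes optional character vector (`"HAB"`/`"MAB"`) of length
#'   `n_subjects`.
#' @param mab_scale hbgm binding scale for MAB subjects.
#' @return list with `subjects` (list of [subject_record()]s) and `truth`
#'   (per-subject truth lists, named by subject id).
#' @export
generate_cohort <- function(n_subjects = 12L, spec = phantom_spec(),
                            jitter_sdlog = 0.05, genotypes = NULL,
                            mab_scale = 0.6) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (!is.null(genotypes) && length(genotypes) != n_subjects)
    stop("genotypes must have one entry per subject")
  subjects <- vector("list", n_subjects)
  truths <- vector("list", n_subjects)
  ids <- sprintf("s%02d", seq_len(n_subjects))
  for (i in seq_len(n_subjects)) {
    seed_i <- (spec$seed + 7919L * i) %% .Machine$integer.max
    set.seed(seed_i)
    p <- spec$profile
    if (jitter_sdlog > 0) {
      # tissue kinetic parameters jitter; the population input function is
      # shared, as in simulation studies with a common template input
      jit <- function(v) v * exp(stats::rnorm(length(v), 0, jitter_sdlog))
      p$K1 <- jit(p$K1); p$k2 <- jit(p$k2)
    }
    geno <- if (is.null(genotypes)) "unknown" else genotypes[i]
    if (identical(geno, "MAB")) p$K1[["hbgm"]] <- p$K1[["hbgm"]] * mab_scale
    spec_i <- spec
    spec_i$profile <- p
    spec_i$seed <- seed_i
    ph <- generate_phantom(spec_i)
    subjects[[i]] <- subject_record(ids[i], ph$pet, ph$masks,
                                    genotype = geno)
    truths[[i]] <- ph$truth
  }
  names(truths) <- ids
  list(subjects = subjects, truth = truths)
}
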