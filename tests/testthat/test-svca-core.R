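test_that("compute_ratio implements the weight-fraction rule exactly", {
  expect_identical(compute_ratio(c(1, 0, 0, 0), 1), 1)
  expect_identical(compute_ratio(c(0, 2, 3, 0), 1), 0)
  expect_identical(compute_ratio(c(0, 0, 0, 0), 1), 0)  # degenerate rule
  expect_identical(compute_ratio(c(1, 1, 1, 1), 1), 0.25)
  expect_error(compute_ratio(c(-1, 1), 1), "non-negative")
  # property: ratio always lands in [0, 1]
  set.seed(31)
  for (i in 1:200) {
    w <- runif(4, 0, 10) * rbinom(4, 1, 0.7)
    r <- compute_ratio(w, sample(4, 1))
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("nnls_fit_voxel recovers a known two-class mixture", {
  co <- cached_cohort(noise_level = 0)
  cfg <- class_config(hbgm_source = "high_binding")
  K <- build_class_sets_loo(co$subjects, cfg, held_out = "s12")$K
  tac <- drop(K %*% c(0.3, 0.7, 0, 0))
  fit <- nnls_fit_voxel(tac, K)
  expect_equal(unname(fit$w), c(0.3, 0.7, 0, 0), tolerance = 1e-8)
  # residual optimality cross-checked against the dense grid oracle
  expect_lte(fit$residual_ss,
             grid_nnls_min(K[, 1:2], tac, step = 1e-3, box = 1) + 1e-8)
  expect_error(nnls_fit_voxel(tac[-1], K), "TAC length")
  expect_error(nnls_fit_voxel(tac, K[, 1, drop = FALSE]), ">= 2 classes")
})

# shared fixtures for the extraction tests
.extract_fixture <- function(noise = 0, mixing = "none", seed = 42L) {
  co <- cached_cohort(noise_level = 0)
  cfg <- class_config(hbgm_source = "high_binding")
  classes <- build_class_sets_loo(co$subjects, cfg, held_out = "s12")
  spec <- fast_spec(noise_level = noise, seed = seed, mixing = mixing)
  ph <- generate_phantom(spec)
  cand <- prepare_tissue_mask(ph$masks$gm_prob, 0.9, 0)
  list(ph = ph, classes = classes, cand = cand)
}

test_that("noiseless extraction selects all pure-lbgm candidates exactly", {
  fx <- .extract_fixture()
  res <- suppressWarnings(
    extract_reference(fx$ph$pet, fx$ph$masks$brain, fx$cand, fx$classes,
                      threshold = 0.9))
  expect_equal(res$n_selected, length(res$candidate_idx))
  expect_equal(res$ref_tac, unname(fx$ph$truth$templates[, "lbgm"]),
               tolerance = 1e-8)
  # ratio map lives in [0,1] on candidates, NA elsewhere
  vals <- res$ratio_map[!is.na(res$ratio_map)]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(sum(!is.na(res$ratio_map)), length(res$candidate_idx))
})

test_that("hbgm-kinetics voxels are rejected at threshold 0.9", {
  fx <- .extract_fixture()
  # candidate mask straddling lbgm and hbgm tissue
  straddle <- fx$cand$voxels
  straddle[fx$ph$truth$labels == 4L] <- 1
  cand2 <- mask_image(straddle, kind = "binary")
  res <- suppressWarnings(
    extract_reference(fx$ph$pet, fx$ph$masks$brain, cand2, fx$classes,
                      threshold = 0.9))
  sel <- which(res$selected_mask$voxels == 1)
  expect_true(all(fx$ph$truth$labels[sel] == 1L))   # only true lbgm survives
  expect_length(setdiff(which(fx$cand$voxels == 1), sel), 0)
})

test_that("threshold 1.0 exhausts the selection and errors", {
  fx <- .extract_fixture(noise = 0.1)
  expect_error(
    extract_reference(fx$ph$pet, fx$ph$masks$brain, fx$cand, fx$classes,
                      threshold = 1.0),
    "failed to find a suitable reference region")
  expect_error(
    extract_reference(fx$ph$pet, fx$ph$masks$brain, fx$cand, fx$classes,
                      threshold = 1.5), "threshold")
})

test_that("raising the threshold never increases the selection", {
  fx <- .extract_fixture(noise = 0.1, mixing = "dirichlet")
  ns <- vapply(c(0.5, 0.7, 0.9, 0.95), function(th)
    suppressWarnings(
      extract_reference(fx$ph$pet, fx$ph$masks$brain, fx$cand, fx$classes,
                        threshold = th))$n_selected, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("selection is scale-invariant; the reference TAC is equivariant", {
  fx <- .extract_fixture(noise = 0.1)
  r1 <- suppressWarnings(
    extract_reference(fx$ph$pet, fx$ph$masks$brain, fx$cand, fx$classes))
  scaled <- dynamic_image(fx$ph$pet$voxels * 3.5, fx$ph$pet$schedule)
  r2 <- suppressWarnings(
    extract_reference(scaled, fx$ph$masks$brain, fx$cand, fx$classes))
  expect_identical(r1$selected_mask$voxels, r2$selected_mask$voxels)
  expect_equal(r2$ref_tac, 3.5 * r1$ref_tac, tolerance = 1e-12)
})

test_that("two identical runs are bit-identical", {
  fx <- .extract_fixture(noise = 0.1)
  r1 <- suppressWarnings(
    extract_reference(fx$ph$pet, fx$ph$masks$brain, fx$cand, fx$classes))
  r2 <- suppressWarnings(
    extract_reference(fx$ph$pet, fx$ph$masks$brain, fx$cand, fx$classes))
  expect_identical(r1$selected_mask$voxels, r2$selected_mask$voxels)
  expect_identical(r1$ref_tac, r2$ref_tac)
})

test_that("weighted averaging weights raw TACs by the lbgm weight", {
  fx <- .extract_fixture(noise = 0.1, mixing = "dirichlet")
  rw <- suppressWarnings(
    extract_reference(fx$ph$pet, fx$ph$masks$brain, fx$cand, fx$classes,
                      threshold = 0.7, averaging = "weighted"))
  sel <- which(rw$selected_mask$voxels == 1)
  keep <- rw$ratio_map[rw$candidate_idx] > 0.7
  wl <- rw$weights[keep, fx$classes$lbgm_index]
  d <- dim(fx$ph$pet$voxels)
  flat <- matrix(fx$ph$pet$voxels, prod(d[1:3]), d[4])
  manual <- drop(crossprod(flat[rw$candidate_idx[keep], , drop = FALSE], wl)) /
    sum(wl)
  expect_equal(rw$ref_tac, manual, tolerance = 1e-12)
})

test_that("guard rails: schedule, mask hash, containment, genotype", {
  fx <- .extract_fixture()
  ph <- fx$ph
  # schedule mismatch
  alt_sched <- frame_schedule(2 * ph$pet$schedule$start,
                              2 * ph$pet$schedule$end)
  classes2 <- fx$classes
  classes2$schedule <- alt_sched
  expect_error(
    extract_reference(ph$pet, ph$masks$brain, fx$cand, classes2),
    "schedule")
  # brain-mask hash mismatch errors, force downgrades to warning
  other_brain <- mask_image(
    array(as.numeric(svcaref:::dilate6(ph$masks$brain$voxels, 1)),
          dim(ph$masks$brain$voxels)), kind = "binary")
  expect_error(
    extract_reference(ph$pet, other_brain, fx$cand, fx$classes),
    "hash mismatch")
  expect_warning(
    extract_reference(ph$pet, other_brain, fx$cand, fx$classes,
                      force_mask_mismatch = TRUE),
    "force")
  # candidate must be inside the brain mask
  out_cand <- fx$cand$voxels
  out_cand[which(ph$masks$brain$voxels == 0)[1]] <- 1
  expect_error(
    extract_reference(ph$pet, ph$masks$brain,
                      mask_image(out_cand, kind = "binary"), fx$classes),
    "subset")
  # genotype routing
  hab_classes <- fx$classes
  hab_classes$genotype <- "HAB"
  expect_error(
    extract_reference(ph$pet, ph$masks$brain, fx$cand, hab_classes,
                      genotype = "MAB"),
    "genotype mismatch")
})

test_that("weight maps agree with per-voxel fits and the ratio bookkeeping", {
  fx <- .extract_fixture(noise = 0.1)
  wm <- weight_maps(fx$ph$pet, fx$ph$masks$brain, fx$cand, fx$classes)
  expect_named(wm$weight_maps, fx$classes$class_names)
  idx <- which(!is.na(wm$ratio_map))
  expect_true(all(wm$ratio_map[idx] >= 0 & wm$ratio_map[idx] <= 1))
  # spot-check three voxels against direct nnls_fit_voxel
  norm <- normalize_frames(fx$ph$pet, fx$ph$masks$brain)
  d <- dim(norm$voxels)
  flat <- matrix(norm$voxels, prod(d[1:3]), d[4])
  set.seed(6)
  for (v in sample(idx, 3)) {
    fit <- nnls_fit_voxel(flat[v, ], fx$classes$K)
    per_map <- vapply(wm$weight_maps, function(m) m[v], numeric(1))
    expect_equal(unname(per_map), unname(fit$w), tolerance = 1e-10)
    expect_equal(sum(per_map), sum(fit$w), tolerance = 1e-10)
  }
})
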