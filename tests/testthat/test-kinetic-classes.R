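test_that("prepare_tissue_mask thresholds then erodes (6-connected)", {
  g <- c(7, 7, 7)
  prob <- array(0, g)
  prob[2:6, 2:6, 2:6] <- 1                # 5^3 cube of certainty
  pm <- mask_image(prob)
  out <- prepare_tissue_mask(pm, p_threshold = 0.9, erode = 1)
  expect_equal(mask_count(out), 27)       # interior 3^3 survives
  expect_equal(which(out$voxels == 1),
               which(array(seq_len(prod(g)), g) > 0 &
                     slice.index(prob, 1) %in% 3:5 &
                     slice.index(prob, 2) %in% 3:5 &
                     slice.index(prob, 3) %in% 3:5))
  # erode 0 is the plain thresholded map
  out0 <- prepare_tissue_mask(pm, 0.9, 0)
  expect_equal(out0$voxels, array(as.numeric(prob > 0.9), g))
  expect_error(prepare_tissue_mask(mask_image(array(0.5, g)), 0.9, 0),
               "empty mask")
  expect_error(prepare_tissue_mask(pm, 1.2, 0), "p_threshold")
})

test_that("build_blood_mask finds the hottest early voxels deterministically", {
  ph <- generate_phantom(fast_spec(noise_level = 0))
  search <- blood_search_mask(ph$masks$brain, 2)
  bm <- build_blood_mask(ph$pet, early_window = 180, n_top = 50,
                         search_mask = search)
  expect_equal(mask_count(bm), 50)
  # every selected voxel lies in the true vascular region (64 voxels whose
  # early activity dwarfs tissue by construction)
  expect_true(all(ph$truth$blood_mask[bm$voxels == 1] == 1))
  # n_top = mask size returns the mask itself
  small <- mask_image(array(as.numeric(ph$truth$blood_mask), dim(bm$voxels)),
                      kind = "binary")
  all_of <- build_blood_mask(ph$pet, 180, mask_count(small), small)
  expect_equal(all_of$voxels, small$voxels)
  expect_error(build_blood_mask(ph$pet, early_window = 1, n_top = 5,
                                search_mask = search), "early_window")
})

test_that("blood-mask ties at the cutoff break by ascending linear index", {
  arr <- array(0, c(3, 3, 1, 2))
  arr[, , 1, 1] <- c(9, 5, 5, 5, 1, 1, 1, 1, 1)  # three tied at rank 2-4
  arr[, , 1, 2] <- 1
  img <- dynamic_image(arr, frame_schedule(c(0, 60), c(60, 120)))
  mask <- mask_image(array(1, c(3, 3, 1)), kind = "binary")
  bm <- build_blood_mask(img, early_window = 60, n_top = 2, search_mask = mask)
  expect_equal(which(bm$voxels == 1), c(1L, 2L))  # 9 then the lowest-index 5
})

test_that("extract_class_tac equals a brute-force per-frame mean", {
  rd <- random_dynamic(shape = c(6, 6, 6), n_frames = 8, seed = 21)
  norm <- normalize_frames(rd$img, rd$mask)
  inm <- which(rd$mask$voxels == 1)
  # one voxel: exactly that voxel's TAC
  one <- array(0, dim(rd$mask$voxels)); one[inm[1]] <- 1
  t1 <- extract_class_tac(norm, mask_image(one, kind = "binary"), "lbgm")
  expect_equal(t1$values, brute_mask_mean(norm$voxels, inm[1]))
  # random 10-voxel mask vs independent mean
  set.seed(9)
  ten <- sample(inm, 10)
  mten <- array(0, dim(rd$mask$voxels)); mten[ten] <- 1
  t10 <- extract_class_tac(norm, mask_image(mten, kind = "binary"), "wm")
  expect_equal(t10$values, brute_mask_mean(norm$voxels, ten))
  # mask reaching outside the normalization mask errors
  outside <- array(0, dim(rd$mask$voxels))
  outside[which(rd$mask$voxels == 0)[1]] <- 1
  expect_error(extract_class_tac(norm, mask_image(outside, kind = "binary"),
                                 "wm"), "outside")
  expect_error(extract_class_tac(norm,
                                 mask_image(array(0, dim(rd$mask$voxels)),
                                            kind = "binary"), "wm"),
               "empty")
})

test_that("validate_blood_shape accepts input-like curves only", {
  s <- default_schedule()
  tm <- make_class_templates(s)
  norm_b <- (tm[, "blood"] - mean(tm[, "blood"])) / sd(tm[, "blood"])
  pass <- validate_blood_shape(class_tac("blood", norm_b, s))
  expect_true(pass$pass)
  expect_lte(pass$peak_frame, ceiling(s$n_frames / 3))
  mono <- validate_blood_shape(class_tac("blood", seq_len(20), s))
  expect_false(mono$pass)
  flat <- validate_blood_shape(class_tac("blood", rep(1, 20), s))
  expect_false(flat$pass)
})

test_that("aggregation reproduces the mean/median oracles", {
  s <- tiny_schedule(6)
  mk <- function(cls, vals, id) class_tac(cls, vals, s, id)
  base <- lapply(c("lbgm", "wm", "blood", "hbgm"),
                 function(cl) mk(cl, rnorm(6), "s01"))
  # one subject: the set equals that subject's curves
  one <- aggregate_classes(base)
  for (cl in c("lbgm", "wm", "blood", "hbgm"))
    expect_equal(one$K[, cl],
                 Filter(function(x) x$class_name == cl, base)[[1]]$values)
  expect_equal(one$lbgm_index, 1L)
  expect_equal(one$class_names, c("lbgm", "wm", "blood", "hbgm"))
  # two subjects c and c + 2 -> mean c + 1
  shift <- lapply(base, function(tc) mk(tc$class_name, tc$values + 2, "s02"))
  two <- aggregate_classes(c(base, shift), method = "mean")
  expect_equal(two$K[, "lbgm"],
               base[[1]]$values + 1)
  # 11 subjects, one gross outlier, median agrees with a sort-based oracle
  set.seed(4)
  curves <- lapply(1:11, function(i)
    mk("lbgm", sin(1:6) + rnorm(6, 0, 0.05), sprintf("s%02d", i)))
  curves[[5]]$values <- curves[[5]]$values + 100
  others <- lapply(c("wm", "blood", "hbgm"), function(cl) mk(cl, rnorm(6), "s01"))
  med <- aggregate_classes(c(curves, others), method = "median")
  mat <- vapply(curves, `[[`, numeric(6), "values")
  sort_med <- apply(mat, 1, function(r) {
    sr <- sort(r); (sr[6] + sr[6]) / 2     # n = 11, middle element
  })
  expect_equal(med$K[, "lbgm"], sort_med, tolerance = 1e-12)
  # missing class errors
  expect_error(aggregate_classes(curves), "class 'wm'")
})

test_that("aggregation with mean is linear over cohorts", {
  s <- tiny_schedule(5)
  set.seed(8)
  mk_cohort <- function(off) {
    unlist(lapply(1:3, function(i)
      lapply(c("lbgm", "wm", "blood", "hbgm"), function(cl)
        class_tac(cl, rnorm(5) + off, s, sprintf("s%02d", i)))),
      recursive = FALSE)
  }
  a <- mk_cohort(0); b <- mk_cohort(1)
  ab <- Map(function(x, y) class_tac(x$class_name, x$values + y$values,
                                     s, x$subject_id), a, b)
  expect_equal(aggregate_classes(ab)$K,
               aggregate_classes(a)$K + aggregate_classes(b)$K)
})

test_that("build_class_sets runs the full training pipeline per stratum", {
  co <- cached_cohort(noise_level = 0)
  cfg <- class_config(hbgm_source = "high_binding")
  sets <- suppressWarnings(build_class_sets(co$subjects, cfg, strata = "ALL"))
  expect_named(sets, "ALL")
  cs <- sets$ALL
  expect_equal(dim(cs$K), c(20L, 4L))
  expect_equal(length(cs$training_subjects), 12L)
  # each aggregated class curve correlates best with the matching class
  # curve of a zero-jitter template subject, extracted the same way
  # (comparison must live in normalized space: the frame-wise transform is
  # not affine in time, so raw templates are not directly comparable)
  ph0 <- generate_phantom(fast_spec(noise_level = 0))
  norm0 <- normalize_frames(ph0$pet, ph0$masks$brain)
  ref_curves <- list(
    lbgm = extract_class_tac(norm0,
      prepare_tissue_mask(ph0$masks$gm_prob, 0.9, 0), "lbgm"),
    wm = extract_class_tac(norm0,
      prepare_tissue_mask(ph0$masks$wm_prob, 0.9, 0), "wm"),
    blood = extract_class_tac(norm0,
      mask_image(ph0$truth$blood_mask, kind = "binary"), "blood"),
    hbgm = extract_class_tac(norm0,
      prepare_tissue_mask(ph0$masks$high_binding, 0.5, 1), "hbgm"))
  for (cl in cs$class_names) {
    cors <- vapply(ref_curves, function(tc) cor(cs$K[, cl], tc$values),
                   numeric(1))
    expect_equal(names(which.max(cors)), cl)
  }
  expect_error(build_class_sets(list(), cfg), "empty")
})

test_that("genotype strata split disjointly and small strata warn", {
  spec <- fast_spec(noise_level = 0, seed = 77L)
  co <- generate_cohort(8, spec, genotypes = rep(c("HAB", "MAB"), each = 4))
  cfg <- class_config(hbgm_source = "high_binding")
  ws <- capture_warnings(
    sets <- build_class_sets(co$subjects, cfg, strata = c("HAB", "MAB")))
  expect_true(any(grepl("N > 10", ws)))
  expect_length(intersect(sets$HAB$training_subjects,
                          sets$MAB$training_subjects), 0)
  expect_equal(sets$HAB$genotype, "HAB")
})

test_that("leave-one-out equals manual exclusion bit-exactly", {
  co <- cached_cohort(noise_level = 0)
  cfg <- class_config(hbgm_source = "high_binding")
  loo <- build_class_sets_loo(co$subjects, cfg, held_out = "s07")
  expect_length(loo$training_subjects, 11)
  expect_false("s07" %in% loo$training_subjects)
  ids <- vapply(co$subjects, `[[`, character(1), "subject_id")
  manual <- suppressWarnings(
    build_class_sets(co$subjects[ids != "s07"], cfg))[[1]]
  expect_identical(loo$K, manual$K)
  expect_error(build_class_sets_loo(co$subjects, cfg, "nope"), "not found")
})

test_that("class-set serialization round-trips bit-exactly", {
  co <- cached_cohort(noise_level = 0)
  cfg <- class_config(hbgm_source = "high_binding")
  cs <- build_class_sets_loo(co$subjects, cfg, held_out = "s12")
  f <- withr::local_tempfile(fileext = ".json")
  write_class_set(cs, f)
  back <- read_class_set(f)
  expect_identical(unname(back$K), unname(cs$K))
  expect_identical(back$training_subjects, cs$training_subjects)
  expect_identical(back$norm_mask_hash, cs$norm_mask_hash)
  expect_true(same_schedule(back$schedule, cs$schedule))
})
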