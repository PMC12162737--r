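test_that("subject scenes are deterministic in (seed, subject_id)", {
  spec <- small_spec(seed = 7)
  a <- generate_subject_truth(spec, 0)
  b <- generate_subject_truth(spec, 0)
  expect_identical(a$grid, b$grid)
  expect_identical(a$r_inner_mm, b$r_inner_mm)
  c <- generate_subject_truth(small_spec(seed = 8), 0)
  expect_false(identical(a$grid, c$grid))
})

test_that("zero jitter gives identical geometry but fresh texture", {
  spec <- small_spec(subject_jitter = 0)
  a <- generate_subject_truth(spec, 0)
  b <- generate_subject_truth(spec, 1)
  expect_identical(a$r_inner_mm, b$r_inner_mm)
  expect_identical(a$r_outer_mm, b$r_outer_mm)
  expect_identical(a$center_mm, b$center_mm)
  expect_identical(a$myo_mean, b$myo_mean)
  expect_false(identical(a$grid, b$grid))  # different texture realization
})

test_that("per-subject jitter stays within the truncated +/- 3 sd bounds", {
  spec <- phantom_spec(seed = 7)
  ji <- spec$subject_jitter[["intensity"]]
  jr <- spec$subject_jitter[["radius"]]
  for (s in 0:11) {
    tr <- generate_subject_truth(spec, s)
    expect_lte(abs(tr$myo_mean / spec$myo_mean_intensity - 1), 3 * ji)
    expect_lte(abs(tr$blood / spec$blood_intensity - 1), 3 * ji)
    expect_lte(abs(tr$r_outer_mm / spec$r_outer_mm - 1), 3 * jr)
  }
})

test_that("invalid phantom specs are rejected with the violated invariant", {
  expect_error(phantom_spec(r_inner_mm = 30, r_outer_mm = 29),
               "r_inner_mm < r_outer_mm")
  expect_error(phantom_spec(myo_mean_intensity = 150, myo_texture_sd = 20),
               "segmentation")
  expect_error(phantom_spec(blood_intensity = 100), "blood_intensity")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
})

test_that("rendering honors the acquisition geometry", {
  truth <- generate_subject_truth(phantom_spec(), 1)
  acq <- default_acquisitions()[[1]]
  img <- render_fov(truth, acq)
  expect_identical(dim(img), c(224L, 157L))
  expect_equal(img$spacing_mm[1], 329 / 224)  # ~1.469 mm/pixel
  expect_equal(img$spacing_mm[2], 256 / 157)
  expect_identical(render_fov(truth, acq)$pixels, img$pixels)  # deterministic
})

test_that("the anatomy sits at the same mm position at every field of view", {
  truth <- generate_subject_truth(phantom_spec(), 2)
  centroids <- sapply(default_acquisitions(), function(acq) {
    img <- render_fov(truth, acq)
    co <- radiomap:::pixel_coords(img)
    blood <- img$pixels > 170
    c(sum(outer(co$x1, rep(1, length(co$x2)))[blood]) / sum(blood),
      sum(outer(rep(1, length(co$x1)), co$x2)[blood]) / sum(blood))
  })
  expect_lt(max(abs(centroids[1, ] - centroids[1, 1])), 1)
  expect_lt(max(abs(centroids[2, ] - centroids[2, 1])), 1)
  sp <- sapply(default_acquisitions(), function(a) a$fov_mm / a$matrix_px)
  expect_false(any(duplicated(t(sp))))
})

test_that("cohort bookkeeping: n_subjects x n_fov images plus manifest", {
  spec <- small_spec()
  acqs <- list(small_acq(90, 48, "A"), small_acq(100, 48, "B"),
               small_acq(110, 48, "C"))
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(spec, acqs, n_subjects = 2, out_dir = dir)
  expect_equal(nrow(cohort), 6)
  expect_true(all(file.exists(cohort$path)))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 6)
  expect_setequal(man$fov_label, c("A", "B", "C"))

  one <- generate_cohort(spec, acqs[1], n_subjects = 1)
  expect_equal(nrow(one), 1)

  again <- generate_cohort(spec, acqs, n_subjects = 2)
  expect_identical(lapply(cohort$image, `[[`, "pixels"),
                   lapply(again$image, `[[`, "pixels"))
})

test_that("scene intensities are threshold-separable by tissue", {
  spec <- phantom_spec()
  for (s in 1:12) {
    tr <- generate_subject_truth(spec, s)
    d <- dim(tr$grid)
    x1 <- tr$grid_origin_mm[1] + (seq_len(d[1]) - 1) * tr$grid_res_mm
    x2 <- tr$grid_origin_mm[2] + (seq_len(d[2]) - 1) * tr$grid_res_mm
    r2 <- outer((x1 - tr$center_mm[1])^2, (x2 - tr$center_mm[2])^2, `+`)
    annulus <- tr$grid[r2 <= tr$r_outer_mm^2 & r2 > tr$r_inner_mm^2]
    blood <- tr$grid[r2 <= tr$r_inner_mm^2]
    expect_gte(mean(annulus >= 0 & annulus <= 170), 0.99)
    expect_gte(mean(blood > 170), 0.99)
  }
})

test_that("changing the field of view changes at least one texture feature", {
  truth <- generate_subject_truth(phantom_spec(), 1)
  acqs <- default_acquisitions()
  vecs <- lapply(acqs[c(1, 3)], function(a) {
    img <- render_fov(truth, a)
    mask <- threshold_segment(img, circle_region(img, truth$center_mm,
                                                 truth$r_outer_mm))
    extract_all(img, mask)$values
  })
  texture <- !startsWith(names(vecs[[1]]), "firstorder")
  rel <- abs(vecs[[2]][texture] - vecs[[1]][texture]) /
    pmax(abs(vecs[[1]][texture]), 1e-12)
  expect_gt(max(rel, na.rm = TRUE), 0.10)
})
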