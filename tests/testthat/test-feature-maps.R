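test_that("tile size in pixels follows round(mm / spacing)", {
  img1 <- img_from(matrix(0, 20, 20), spacing = c(1.5, 1.5))
  expect_equal(build_tile_grid(img1, c(3, 3, 8))$tile_px, c(2L, 2L))
  # protocol spacing 329/224 ~ 1.469 mm -> round(2.042) = 2 px
  img2 <- img_from(matrix(0, 224, 157), spacing = c(329 / 224, 256 / 157))
  expect_equal(build_tile_grid(img2, c(3, 3, 8))$tile_px, c(2L, 2L))
  # spacing so coarse that a tile is under half a pixel -> clamped to 1
  img3 <- img_from(matrix(0, 10, 10), spacing = c(8, 8))
  expect_equal(build_tile_grid(img3, c(3, 3, 8))$tile_px, c(1L, 1L))
  # tile at least the image extent -> a single tile
  img4 <- img_from(matrix(0, 6, 4), spacing = c(1, 1))
  g4 <- build_tile_grid(img4, c(50, 50, 8))
  expect_equal(g4$n_tiles, c(1L, 1L))
})

test_that("tiles partition the pixel grid, trailing tiles kept", {
  img <- img_from(matrix(0, 7, 5), spacing = c(1, 1))
  grid <- build_tile_grid(img, c(2, 2, 8))
  expect_equal(grid$n_tiles, c(4L, 3L))
  tid <- radiomap:::tile_id_matrix(grid)
  expect_equal(length(unique(as.vector(tid))), 12)
  expect_equal(sum(tabulate(tid)), 7 * 5)  # every pixel in exactly one tile
})

test_that("a single whole-image tile reproduces conventional extraction", {
  set.seed(3)
  img <- img_from(matrix(rnorm(16 * 12, 100, 30), 16, 12),
                  spacing = c(1.5, 1.5))
  grid <- build_tile_grid(img, c(100, 100, 8))
  maps <- compute_all_maps(img, grid)
  expect_length(maps, 93)
  conv <- extract_all(img, full_mask(img))
  for (f in names(maps)) {
    ro <- map_roi_mean(maps[[f]], full_mask(img))
    if (is.na(conv$values[[f]])) {
      expect_true(is.na(as.numeric(ro)))
    } else {
      expect_identical(as.numeric(ro), conv$values[[f]], label = f)
    }
  }
})

test_that("maps broadcast per-tile values at the right locations", {
  # two 2x2 tiles: left constant 10, right constant 20
  img <- img_from(matrix(c(10, 10, 10, 10, 20, 20, 20, 20), 2, 4),
                  spacing = c(1, 1))
  grid <- build_tile_grid(img, c(2, 2, 8))
  m <- compute_feature_map(img, grid, "firstorder_Mean")
  expect_equal(m$values[, 1:2], matrix(10, 2, 2))
  expect_equal(m$values[, 3:4], matrix(20, 2, 2))
  v <- compute_feature_map(img, grid, "firstorder_Variance")
  expect_true(all(v$values == 0))
  expect_error(compute_feature_map(img, grid, "glcm_Bogus"), "valid names")
})

test_that("editing one tile only changes that tile's map", {
  set.seed(9)
  img <- img_from(matrix(rnorm(64, 50, 10), 8, 8), spacing = c(1, 1))
  grid <- build_tile_grid(img, c(4, 4, 8))
  m1 <- compute_feature_map(img, grid, "firstorder_Mean")
  px <- img$pixels
  px[1:4, 1:4] <- px[1:4, 1:4] + 5
  img2 <- image_slice(px, img$spacing_mm, img$slice_thickness_mm,
                      img$origin_mm)
  m2 <- compute_feature_map(img2, grid, "firstorder_Mean")
  delta <- m2$values - m1$values
  expect_true(all(delta[1:4, 1:4] != 0))
  expect_true(all(delta[5:8, ] == 0))
  expect_true(all(delta[, 5:8] == 0))
})

test_that("undersized tiles are flagged invalid for texture features", {
  img <- img_from(matrix(seq_len(12) + 0, 3, 4), spacing = c(1, 1))
  grid <- build_tile_grid(img, c(2, 2, 8))  # rows split 2+1: bottom tiles 2px
  gm <- compute_feature_map(img, grid, "glcm_JointEntropy")
  expect_true(all(!gm$valid[3, ]))
  expect_true(all(gm$valid[1:2, ]))
  fm <- compute_feature_map(img, grid, "firstorder_Mean")
  expect_true(all(fm$valid))

  mask <- full_mask(img)
  ro <- map_roi_mean(gm, mask)
  expect_gt(attr(ro, "invalid_fraction"), 0)
  expect_equal(as.numeric(ro), mean(gm$values[1:2, ]))
})

test_that("ROI readout is the unweighted masked mean", {
  img <- img_from(matrix(0, 4, 4), spacing = c(1, 1))
  grid <- build_tile_grid(img, c(100, 100, 8))
  m <- radiomap:::new_parametric_map(matrix(7, 4, 4),
                                     matrix(TRUE, 4, 4),
                                     "firstorder_Mean", img)
  expect_equal(as.numeric(map_roi_mean(m, full_mask(img))), 7)
  half <- matrix(10, 4, 4); half[, 3:4] <- 20
  m2 <- radiomap:::new_parametric_map(half, matrix(TRUE, 4, 4),
                                      "firstorder_Mean", img)
  expect_equal(as.numeric(map_roi_mean(m2, full_mask(img))), 15)
  expect_error(map_roi_mean(m2, radiomap:::new_seg_mask(
    matrix(FALSE, 4, 4), img)), "empty")
})

test_that("maps inherit and persist the source geometry", {
  truth <- generate_subject_truth(small_spec(), 1)
  img <- render_fov(truth, small_acq(100, 48))
  grid <- build_tile_grid(img)
  m <- compute_feature_map(img, grid, "firstorder_Mean")
  expect_equal(m$spacing_mm, img$spacing_mm)
  expect_equal(m$origin_mm, img$origin_mm)
  path <- withr::local_tempfile(fileext = ".nrrd")
  write_nrrd(m, path)
  back <- read_nrrd(path)
  expect_equal(back$spacing_mm, img$spacing_mm)
  expect_equal(back$origin_mm, img$origin_mm)
  expect_equal(back$pixels, m$values)
})

test_that("the pipeline's weighted readout equals pixel-level broadcasting", {
  truth <- generate_subject_truth(small_spec(), 2)
  img <- render_fov(truth, small_acq(100, 48))
  mask <- threshold_segment(img, circle_region(img, truth$center_mm,
                                               truth$r_outer_mm))
  grid <- build_tile_grid(img)
  fv <- radiomap:::map_feature_vector(img, mask, grid)
  maps <- compute_all_maps(img, grid,
                           features = c("firstorder_Mean", "glcm_Contrast",
                                        "glszm_ZonePercentage"))
  for (f in names(maps))
    expect_equal(fv$values[[f]], as.numeric(map_roi_mean(maps[[f]], mask)),
                 tolerance = 1e-12, label = f)
})
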