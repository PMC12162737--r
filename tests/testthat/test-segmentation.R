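test_that("circle_region selects pixel centers by physical distance", {
  img <- img_from(matrix(0, 20, 20), spacing = c(1.5, 1.5))
  expect_true(all(circle_region(img, c(0, 0), 1000)$mask))
  # a tiny radius at an exact pixel center hits exactly that pixel
  co <- radiomap:::pixel_coords(img)
  one <- circle_region(img, c(co$x1[5], co$x2[7]), 0.01)
  expect_equal(sum(one$mask), 1)
  expect_true(one$mask[5, 7])
  # brute-force count of centers within 30 mm
  mask <- circle_region(img, c(0, 0), 30)$mask
  cnt <- 0
  for (i in seq_along(co$x1)) for (j in seq_along(co$x2))
    if (co$x1[i]^2 + co$x2[j]^2 <= 30^2) cnt <- cnt + 1
  expect_equal(sum(mask), cnt)
  expect_error(circle_region(img, c(1e4, 1e4), 5), "intersect")
})

test_that("threshold_segment keeps the in-window largest component", {
  img <- img_from(matrix(100, 10, 10))
  region <- circle_region(img, c(0, 0), 4)
  out <- threshold_segment(img, region, 0, 170)
  expect_identical(out$mask, region$mask)

  # value not present in the image -> empty -> advisory error
  expect_error(threshold_segment(img, region, 50, 50), "threshold")

  # two in-window blobs: only the larger survives
  m <- matrix(500, 10, 10)
  m[2:3, 2:3] <- 100   # 4 px blob
  m[7:9, 7:9] <- 100   # 9 px blob
  img2 <- img_from(m)
  out2 <- threshold_segment(img2, full_mask(img2), 0, 170)
  expect_equal(sum(out2$mask), 9)
  expect_true(all(out2$mask[7:9, 7:9]))
})

test_that("widening the window never removes candidate pixels", {
  set.seed(42)
  img <- img_from(matrix(runif(400, 0, 300), 20, 20))
  region <- full_mask(img)
  for (k in 1:5) {
    lo <- runif(1, 0, 100); hi <- runif(1, 150, 300)
    narrow <- img$pixels >= lo & img$pixels <= hi
    wide <- img$pixels >= (lo - 20) & img$pixels <= (hi + 20)
    expect_true(all(wide[narrow]))
  }
})

test_that("threshold segmentation is idempotent on its own output", {
  truth <- generate_subject_truth(phantom_spec(), 3)
  img <- render_fov(truth, default_acquisitions()[[2]])
  m1 <- threshold_segment(img, circle_region(img, truth$center_mm,
                                             truth$r_outer_mm))
  m2 <- threshold_segment(img, m1)
  expect_identical(m1$mask, m2$mask)
})

test_that("phantom myocardium is recovered with Dice >= 0.90 and no blood", {
  spec <- phantom_spec()
  for (s in c(1, 5)) {
    truth <- generate_subject_truth(spec, s)
    for (acq in default_acquisitions()[c(1, 3)]) {
      img <- render_fov(truth, acq)
      mask <- threshold_segment(img, circle_region(img, truth$center_mm,
                                                   truth$r_outer_mm))
      ann <- annulus_mask(img, truth)
      expect_gte(dice_coefficient(mask, ann), 0.90)
      co <- radiomap:::pixel_coords(img)
      r2 <- outer((co$x1 - truth$center_mm[1])^2,
                  (co$x2 - truth$center_mm[2])^2, `+`)
      blood_core <- r2 <= (truth$r_inner_mm - 2)^2  # clearly inside the pool
      expect_equal(sum(mask$mask & blood_core), 0)
    }
  }
})
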