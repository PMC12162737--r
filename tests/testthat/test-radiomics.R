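test_that("discretization follows the fixed-bin-width formula", {
  img <- img_from(matrix(c(0, 25, 50, 50), 2, 2))
  reg <- discretize(img, full_mask(img), extraction_settings(bin_width = 25))
  expect_equal(reg$ng, 3)
  expect_equal(sort(unique(as.vector(reg$levels))), 1:3)

  img2 <- img_from(matrix(c(0, 24.9, 0, 24.9), 2, 2))
  expect_equal(discretize(img2, full_mask(img2),
                          extraction_settings(bin_width = 25))$ng, 1)

  img3 <- img_from(matrix(7, 3, 3))
  reg3 <- discretize(img3, full_mask(img3))
  expect_equal(reg3$ng, 1)
  expect_true(all(reg3$levels == 1))

  # occupied levels are re-indexed consecutively
  img4 <- img_from(matrix(c(0, 100, 0, 100), 2, 2))
  reg4 <- discretize(img4, full_mask(img4),
                     extraction_settings(bin_width = 25))
  expect_equal(reg4$ng, 2)
  expect_setequal(unique(as.vector(reg4$levels)), 1:2)
})

test_that("first-order statistics match hand arithmetic", {
  img <- img_from(matrix(c(1, 2, 3, 4), 2, 2), spacing = c(2, 3),
                  thickness = 8)
  fo <- first_order(img, full_mask(img), unit_settings())
  expect_equal(fo[["firstorder_Mean"]], 2.5)
  expect_equal(fo[["firstorder_Range"]], 3)
  expect_equal(fo[["firstorder_RootMeanSquared"]], sqrt(7.5))
  expect_equal(fo[["firstorder_Variance"]], 1.25)  # population variance
  expect_equal(fo[["firstorder_Energy"]], 30)
  expect_equal(fo[["firstorder_TotalEnergy"]], 30 * 2 * 3 * 8)
  expect_equal(fo[["firstorder_Median"]], 2.5)
  expect_equal(fo[["firstorder_Entropy"]], 2)  # 4 equiprobable levels
  expect_equal(fo[["firstorder_Uniformity"]], 0.25)

  cst <- img_from(matrix(5, 2, 2))
  fc <- first_order(cst, full_mask(cst))
  expect_equal(fc[["firstorder_Variance"]], 0)
  expect_equal(fc[["firstorder_Range"]], 0)
  expect_equal(fc[["firstorder_Uniformity"]], 1)
  expect_equal(fc[["firstorder_Entropy"]], 0)
  expect_true(is.na(fc[["firstorder_Skewness"]]))
  expect_true(is.na(fc[["firstorder_Kurtosis"]]))
  expect_false(attr(fc, "valid")[["firstorder_Skewness"]])
})

test_that("percentiles are ordered on arbitrary regions", {
  for (seed in 1:20) {
    rr <- random_region(seed)
    fo <- first_order(rr$image, rr$mask, unit_settings())
    expect_lte(fo[["firstorder_10Percentile"]], fo[["firstorder_Median"]])
    expect_lte(fo[["firstorder_Median"]], fo[["firstorder_90Percentile"]])
  }
})

test_that("GLCM features match the hand-enumerated 2x2 example", {
  # [[1,2],[1,2]]: two horizontal pairs, symmetrized -> p(1,2)=p(2,1)=0.5
  img <- img_from(matrix(c(1, 1, 2, 2), 2, 2))
  s <- unit_settings(angles_2d = 0)
  g <- glcm_features(discretize(img, full_mask(img), s), s)
  expect_equal(g[["glcm_JointEntropy"]], 1)
  expect_equal(g[["glcm_Contrast"]], 1)
  expect_equal(g[["glcm_MaximumProbability"]], 0.5)
  expect_equal(g[["glcm_JointEnergy"]], 0.5)
})

test_that("constant regions degenerate as documented", {
  img <- img_from(matrix(4, 5, 5))
  s <- extraction_settings()
  reg <- discretize(img, full_mask(img), s)
  g <- glcm_features(reg, s)
  expect_equal(g[["glcm_Contrast"]], 0)
  expect_equal(g[["glcm_JointEnergy"]], 1)
  expect_true(is.na(g[["glcm_Correlation"]]))
  expect_false(attr(g, "valid")[["glcm_Correlation"]])
  n <- ngtdm_features(reg, s)
  expect_equal(n[["ngtdm_Coarseness"]], 1e6)  # capped large-value limit
  expect_equal(n[["ngtdm_Contrast"]], 0)
})

test_that("GLRLM features match hand-enumerated runs", {
  img <- img_from(matrix(c(1, 1, 2, 2, 2), 1, 5))
  s <- unit_settings(angles_2d = 0)
  r <- glrlm_features(discretize(img, full_mask(img), s), s)
  expect_equal(r[["glrlm_ShortRunEmphasis"]], (1 / 4 + 1 / 9) / 2)
  expect_equal(r[["glrlm_RunPercentage"]], 2 / 5)

  cst <- img_from(matrix(3, 1, 7))
  rc <- glrlm_features(discretize(cst, full_mask(cst), s), s)
  expect_equal(rc[["glrlm_LongRunEmphasis"]], 49)  # one run of length N
})

test_that("GLSZM zones are 8-connected components of equal level", {
  s <- unit_settings()
  # checkerboard: diagonal equal levels connect -> 2 zones of size 2
  cb <- img_from(matrix(c(1, 2, 2, 1), 2, 2))
  z <- glszm_features(discretize(cb, full_mask(cb), s), s)
  expect_equal(z[["glszm_SmallAreaEmphasis"]], 0.25)
  expect_equal(z[["glszm_ZonePercentage"]], 0.5)
  # four distinct levels -> four singleton zones
  q <- img_from(matrix(c(1, 3, 2, 4), 2, 2))
  z4 <- glszm_features(discretize(q, full_mask(q), s), s)
  expect_equal(z4[["glszm_SmallAreaEmphasis"]], 1)
  expect_equal(z4[["glszm_ZonePercentage"]], 1)
  # constant region of N pixels: one zone of size N
  cst <- img_from(matrix(2, 3, 4))
  zc <- glszm_features(discretize(cst, full_mask(cst), s), s)
  expect_equal(zc[["glszm_ZonePercentage"]], 1 / 12)
  expect_equal(zc[["glszm_LargeAreaEmphasis"]], 144)
})

test_that("GLDM dependence counts match the 3x3 hand example", {
  # constant 3x3: center has 8 dependent neighbors, corners 3, edges 5
  img <- img_from(matrix(5, 3, 3))
  s <- extraction_settings()
  d <- gldm_features(discretize(img, full_mask(img), s), s)
  expect_equal(d[["gldm_LargeDependenceEmphasis"]],
               (4 * 4^2 + 4 * 6^2 + 9^2) / 9)
  expect_equal(d[["gldm_DependenceNonUniformity"]],
               (4^2 + 4^2 + 1^2) / 9)
  expect_equal(d[["gldm_GrayLevelNonUniformity"]], 9)
})

test_that("single-pixel masks degenerate as documented", {
  img <- img_from(matrix(c(9, 1, 1, 1), 2, 2))
  mask <- radiomap:::new_seg_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2),
                                  img)
  s <- extraction_settings()
  reg <- discretize(img, mask, s)
  d <- gldm_features(reg, s)
  expect_equal(d[["gldm_SmallDependenceEmphasis"]], 1)  # dependence 0 -> j=1
  n <- ngtdm_features(reg, s)  # no valid neighbors
  expect_true(all(is.na(n)))
  expect_true(all(!attr(n, "valid")))
  fo <- first_order(img, mask, s)
  expect_equal(fo[["firstorder_Variance"]], 0)
  expect_true(is.na(fo[["firstorder_Skewness"]]))
  g <- glcm_features(reg, s)  # no pixel pair at any angle
  expect_true(all(is.na(g)))
})

test_that("extract_all emits the full 93-feature catalog deterministically", {
  rr <- random_region(11)
  fv <- extract_all(rr$image, rr$mask, unit_settings())
  expect_length(fv$values, 93)
  expect_identical(names(fv$values), feature_catalog()$feature)
  counts <- table(sub("_.*", "", names(fv$values)))
  expect_equal(unname(counts[c("firstorder", "glcm", "gldm", "glrlm",
                               "glszm", "ngtdm")]),
               c(18L, 24L, 14L, 16L, 16L, 5L), ignore_attr = TRUE)
  fv2 <- extract_all(rr$image, rr$mask, unit_settings())
  expect_identical(fv$values, fv2$values)
  expect_error(extract_all(rr$image,
                           radiomap:::new_seg_mask(
                             matrix(FALSE, 8, 8), rr$image)),
               "empty")
})

test_that("texture features are shift-invariant; first-order moments shift", {
  rr <- random_region(12)
  s <- unit_settings()
  a <- extract_all(rr$image, rr$mask, s)
  shifted <- image_slice(rr$image$pixels + 1000, rr$image$spacing_mm,
                         rr$image$slice_thickness_mm, rr$image$origin_mm)
  b <- extract_all(shifted, radiomap:::new_seg_mask(rr$mask$mask, shifted), s)
  texture <- !startsWith(names(a$values), "firstorder")
  expect_equal(b$values[texture], a$values[texture], tolerance = 1e-12)
  expect_equal(b$values[["firstorder_Mean"]],
               a$values[["firstorder_Mean"]] + 1000)
  expect_equal(b$values[["firstorder_Variance"]],
               a$values[["firstorder_Variance"]], tolerance = 1e-8)
})

test_that("bounded features stay in their theoretical ranges", {
  for (seed in 1:25) {
    rr <- random_region(seed + 500)
    fv <- extract_all(rr$image, rr$mask, unit_settings())$values
    expect_gt(fv[["firstorder_Uniformity"]], 0)
    expect_lte(fv[["firstorder_Uniformity"]], 1)
    expect_gte(fv[["firstorder_Entropy"]], 0)
    expect_gte(fv[["glcm_Contrast"]], 0)
    expect_gt(fv[["glrlm_RunPercentage"]], 0)
    expect_lte(fv[["glrlm_RunPercentage"]], 1)
    expect_gt(fv[["glszm_ZonePercentage"]], 0)
    expect_lte(fv[["glszm_ZonePercentage"]], 1)
  }
})

test_that("every texture feature matches its brute-force oracle", {
  s <- unit_settings()
  for (seed in 1:100) {
    rr <- random_region(seed)
    reg <- discretize(rr$image, rr$mask, s)
    L <- reg$levels
    got <- c(glcm_features(reg, s), gldm_features(reg, s),
             glrlm_features(reg, s), glszm_features(reg, s),
             ngtdm_features(reg, s))
    want <- c(oracle_glcm(L, reg$ng), oracle_gldm(L, reg$ng, 0),
              oracle_glrlm(L, reg$ng), oracle_glszm(L, reg$ng),
              oracle_ngtdm(L, reg$ng))
    expect_identical(sort(names(got)), sort(names(want)))
    want <- want[names(got)]
    for (f in names(got)) {
      if (is.na(want[[f]])) {
        expect_true(is.na(got[[f]]), label = paste(f, "NA at seed", seed))
      } else {
        expect_equal(got[[f]], want[[f]], tolerance = 1e-8,
                     label = paste(f, "seed", seed))
      }
    }
  }
})
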