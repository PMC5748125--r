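test_that("adaptive thresholding recovers a uniform hot sphere", {
  sph <- sphere_mask_volume(15, inside = 10, outside = 1)
  m <- segment_pet_voi(sph$volume, sph$center)
  analytic <- 4 / 3 * pi * 1.5^3
  expect_lt(abs(tumor_volume(m) - analytic) / analytic, 0.15)
  # source-to-background formula with peak 10, bg 1 at beta = 0.41
  expect_equal(attr(m, "threshold"), 1 + 0.41 * 9, tolerance = 1e-9)
  expect_true(attr(m, "converged"))
})

test_that("segmentation output contains the seed and is one component", {
  les <- clean_pair(offset = c(8, 0, 0), seed = 31)
  w <- which(les$suv$values == max(les$suv$values), arr.ind = TRUE)[1, ]
  seed_pt <- world_coords(les$suv, w)
  m <- segment_pet_voi(les$suv, seed_pt)
  seed_idx <- nearest_voxel(les$suv, seed_pt)
  expect_true(m$mask[seed_idx[1], seed_idx[2], seed_idx[3]])
  expect_true(petmatch:::is_single_component_26(m$mask))
})

test_that("seeding in background raises a segmentation failure", {
  sph <- sphere_mask_volume(12, inside = 10, outside = 1)
  corner <- world_coords(sph$volume, c(1, 1, 1))
  expect_error(segment_pet_voi(sph$volume, corner),
               "segmentation failure")
})

test_that("mask transfer is the identity on a shared grid and idempotent", {
  les <- clean_pair(seed = 7)
  dwi_mask <- segment_dwi(les$dwi)
  adc <- les$adc
  t1 <- transfer_mask(dwi_mask, adc)
  expect_identical(t1$mask, dwi_mask$mask)
  t2 <- transfer_mask(t1, adc)
  expect_identical(t2$mask, t1$mask)
})

test_that("DWI delineation covers the ellipsoid interior", {
  les <- clean_pair(seed = 17)
  dwi_mask <- segment_dwi(les$dwi)
  mask <- transfer_mask(dwi_mask, les$adc)
  # analytic membership on the MRI grid (PET-frame ellipsoid at origin)
  shp <- dim(les$adc$values)
  g <- as.matrix(expand.grid(i = 1:shp[1], j = 1:shp[2], k = 1:shp[3]))
  w <- sweep(sweep(g - 1, 2, les$adc$spacing, "*"), 2,
             les$adc$origin, "+")
  w <- sweep(w, 2, les$truth$translation, "+")
  semi <- les$truth$semi_axes
  inside <- (w[, 1] / semi[1])^2 + (w[, 2] / semi[2])^2 +
            (w[, 3] / semi[3])^2 <= 1
  covered <- sum(mask$mask[g[inside, , drop = FALSE]]) / sum(inside)
  expect_gte(covered, 0.99)
})

test_that("histogram refinement removes a constructed low-value gap", {
  set.seed(1)
  vals <- c(0, 10, 40, rnorm(500, 1300, 100))
  arr <- array(1500, c(16, 16, 4))
  arr[seq_along(vals)] <- pmax(vals, 0)
  vol <- image_volume(arr, c(2.6, 2.6, 5), modality = "ADC")
  mask <- array(FALSE, dim(arr)); mask[seq_along(vals)] <- TRUE
  lm <- lesion_mask(mask, vol)
  r <- refine_adc_roi(vol, lm)
  expect_equal(r$removed, 3)
  refined_min <- min(vol$values[r$mask$mask])
  expect_gte(refined_min, r$cutoff)
  expect_gt(refined_min, 900)   # inside the main cluster
  expect_lt(refined_min, 1300)
})

test_that("refinement leaves gap-free and constant masks untouched", {
  set.seed(2)
  vals <- runif(400, 1000, 1400)  # contiguous histogram, no gap
  arr <- array(1200, c(10, 10, 5)); arr[seq_along(vals)] <- vals
  vol <- image_volume(arr, c(2.6, 2.6, 5), modality = "ADC")
  mask <- array(FALSE, dim(arr)); mask[seq_along(vals)] <- TRUE
  lm <- lesion_mask(mask, vol)
  r <- refine_adc_roi(vol, lm, histogram_refine_config(p_low = 0))
  expect_equal(r$removed, 0)
  expect_identical(r$mask$mask, lm$mask)

  cvol <- image_volume(array(777, c(6, 6, 6)), c(1, 1, 1),
                       modality = "ADC")
  cm <- full_mask(cvol)
  rc <- refine_adc_roi(cvol, cm)
  expect_equal(rc$removed, 0)
})

test_that("refinement is a pure filter that can only raise the minimum", {
  for (s in 1:5) {
    spec <- lesion_spec(rim_outlier_frac = 0.1, noise_adc = 50, seed = s)
    les <- make_lesion_pair(spec)
    mask <- transfer_mask(segment_dwi(les$dwi), les$adc)
    r <- refine_adc_roi(les$adc, mask)
    expect_true(all(mask$mask[r$mask$mask]))  # refined subset of input
    expect_gte(min(les$adc$values[r$mask$mask]),
               min(les$adc$values[mask$mask]))
  }
})

test_that("tumor volume converts voxel counts to cm3", {
  v <- const_volume(shape = c(10, 10, 10), spacing = c(1, 1, 1))
  m <- full_mask(v)
  expect_equal(tumor_volume(m), 1.0)
  v2 <- const_volume(shape = c(10, 1, 1), spacing = c(5, 5, 3.27))
  m2 <- full_mask(v2)
  expect_equal(tumor_volume(m2), 10 * 81.75 / 1000)
})

test_that("segmented ellipsoid volume matches the analytic value", {
  les <- clean_pair(semi_axes = c(20, 15, 10), seed = 9)
  res <- analyze_lesion_pair(les$suv, les$adc, les$dwi,
                             translation_vector(0, 0, 0))
  analytic <- 4 / 3 * pi * 20 * 15 * 10 / 1000
  expect_lt(abs(res$record$v_pet_cm3 - analytic) / analytic, 0.10)
  expect_lt(abs(res$record$v_mri_cm3 - analytic) / analytic, 0.10)
})

test_that("mask volume is stable under grid refinement", {
  sph <- sphere_mask_volume(15, spacing = c(4, 4, 4), inside = 10)
  coarse <- tumor_volume(sph$mask)
  src <- image_volume(array(as.numeric(sph$mask$mask),
                            dim(sph$mask$mask)),
                      sph$mask$spacing, sph$mask$origin, "SUV")
  shp <- dim(src$values) * 4L - 3L
  fine <- resample_volume(src, src$spacing / 4, shp, method = "nearest")
  fine_mask <- lesion_mask(array(fine$values > 0.5, dim(fine$values)),
                           fine)
  expect_lt(abs(tumor_volume(fine_mask) - coarse) / coarse, 0.05)
})

test_that("max diameter matches brute force and known configurations", {
  v <- const_volume(shape = c(8, 8, 8), spacing = c(2, 2, 2))
  single <- array(FALSE, c(8, 8, 8)); single[4, 4, 4] <- TRUE
  expect_equal(max_diameter(lesion_mask(single, v)), 0)

  two <- array(FALSE, c(8, 8, 8)); two[1, 1, 1] <- TRUE
  v30 <- const_volume(shape = c(8, 8, 8), spacing = c(10, 10, 10))
  two[4, 1, 1] <- TRUE
  expect_equal(max_diameter(lesion_mask(two, v30)), 30)

  sph <- sphere_mask_volume(25, spacing = c(3, 3, 3))
  d <- max_diameter(sph$mask)
  expect_lt(abs(d - 50), sqrt(sum(sph$mask$spacing^2)))
  expect_equal(d, oracle_diameter(sph$mask), tolerance = 1e-12)
})
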