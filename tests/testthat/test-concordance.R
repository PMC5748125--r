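test_that("extremum location honours the tie rule", {
  v <- const_volume(shape = c(4, 4, 4), spacing = c(1, 1, 1))
  one <- array(FALSE, c(4, 4, 4)); one[2, 3, 1] <- TRUE
  loc <- locate_extremum(v, lesion_mask(one, v), "max")
  expect_equal(loc$index, c(2L, 3L, 1L))
  expect_equal(loc$tie_count, 1)

  vals <- array(0, c(4, 4, 4))
  vals[3, 1, 1] <- 5; vals[1, 1, 2] <- 5  # linear indices 3 and 17
  vol <- image_volume(vals, c(1, 1, 1), modality = "SUV")
  loc2 <- locate_extremum(vol, full_mask(vol), "max")
  expect_equal(loc2$index, c(3L, 1L, 1L))  # lowest linear index wins
  expect_equal(loc2$tie_count, 2)
  expect_error(locate_extremum(vol, full_mask(vol), "median"))
})

test_that("extrema and sphere statistics equal exhaustive-scan oracles", {
  set.seed(8)
  for (shape in list(c(12, 10, 8), c(24, 24, 24))) {
    vals <- array(sample(1:50, prod(shape), replace = TRUE), shape)
    vol <- image_volume(vals, c(2.1, 1.7, 3.2), c(-5, 2, 0), "SUV")
    mask_arr <- array(runif(prod(shape)) < 0.4, shape)
    mask_arr[1, 1, 1] <- TRUE
    mask <- lesion_mask(mask_arr, vol)
    for (kind in c("max", "min")) {
      got <- locate_extremum(vol, mask, kind)
      want <- oracle_extremum(vals, mask_arr, kind)
      expect_equal(got$index, as.integer(want$index))
      expect_equal(got$value, want$value)
      expect_equal(got$tie_count, want$tie_count)
    }
    for (rep in 1:10) {
      ctr_idx <- which(mask_arr, arr.ind = TRUE)
      ctr_idx <- ctr_idx[sample(nrow(ctr_idx), 1), ]
      center <- world_coords(vol, ctr_idx) + runif(3, -1, 1)
      got <- sphere_stats(vol, mask, center)
      want <- oracle_sphere(vol, mask_arr, center, got$radius_mm)
      expect_equal(got$min, want$min)
      expect_equal(got$max, want$max)
      expect_equal(got$mean, want$mean)
      expect_equal(got$n_voxels, want$n)
    }
  }
})

test_that("inter-extremum distance follows the frame convention", {
  mk <- function(world) {
    structure(list(index = c(1L, 1L, 1L), world = world, value = 1,
                   tie_count = 1L, kind = "max"),
              class = "extremum_locus")
  }
  expect_equal(extrema_distance(mk(c(1, 2, 3)), mk(c(1, 2, 3)),
                                c(0, 0, 0)), 0)
  expect_equal(extrema_distance(mk(c(0, 0, 0)), mk(c(-3, -4, 0)),
                                c(0, 0, 0)), 5)
  # symmetric under swapping frame roles with the inverse translation
  t <- c(4, -1, 2)
  expect_equal(extrema_distance(mk(c(1, 5, -2)), mk(c(0, 1, 1)), t),
               extrema_distance(mk(c(0, 1, 1)), mk(c(1, 5, -2)), -t))
})

test_that("a mismatch-scale offset is measured through the pipeline", {
  les <- clean_pair(offset = c(15, 12.46, 0), translation = c(4, 6, -2),
                    semi_axes = c(24, 18, 14), seed = 19)
  expect_equal(les$truth$offset_mm, 19.5, tolerance = 1e-3)
  res <- analyze_lesion_pair(les$suv, les$adc, les$dwi,
                             translation_vector(4, 6, -2))
  tol <- max(sqrt(sum(les$suv$spacing^2)), sqrt(sum(les$adc$spacing^2)))
  expect_lt(abs(res$record$distance_mm - 19.5), tol)
  expect_equal(res$record$match, "mismatch")
})

test_that("match classification is boundary-inclusive at the threshold", {
  expect_equal(classify_match(5.3, 12), "match")
  expect_equal(classify_match(19.5, 12), "mismatch")
  expect_equal(classify_match(12.0, 12), "match")
  expect_error(classify_match(-1, 12), "finite")
  expect_error(classify_match(5, 0), "> 0")
})

test_that("sphere radius and constant-volume statistics are exact", {
  expect_equal(sphere_radius_mm(1), (3 * 1000 / (4 * pi))^(1 / 3))
  expect_equal(sphere_radius_mm(1), 6.2035, tolerance = 1e-4)
  v <- const_volume(4.2, shape = c(10, 10, 10), spacing = c(2, 2, 2))
  s <- sphere_stats(v, full_mask(v), c(9, 9, 9))
  expect_equal(s$min, 4.2); expect_equal(s$max, 4.2)
  expect_equal(s$mean, 4.2)
  expect_error(sphere_stats(v, full_mask(v), c(100, 0, 0)), "outside")
})

test_that("sphere statistics fall back to the nearest in-mask voxel", {
  v <- const_volume(1, shape = c(20, 4, 4), spacing = c(2, 2, 2))
  m <- array(FALSE, c(20, 4, 4)); m[20, 4, 4] <- TRUE
  mask <- lesion_mask(m, v)
  expect_warning(s <- sphere_stats(v, mask, c(0, 0, 0)), "nearest")
  expect_equal(s$n_voxels, 1)
  expect_true(s$fallback)
})

test_that("record invariants hold across random phantoms", {
  set.seed(30)
  for (s in 1:8) {
    off <- runif(3, -6, 6)
    spec <- lesion_spec(suv_focus = off / 2, adc_focus = -off / 2,
                        translation = rnorm(3, 0, 5),
                        rim_outlier_frac = 0.05,
                        noise_suv = 0.1, noise_adc = 30, noise_dwi = 2,
                        seed = 300 + s)
    les <- make_lesion_pair(spec)
    rec <- analyze_lesion_pair(
      les$suv, les$adc, les$dwi,
      translation_vector(spec$translation[1], spec$translation[2],
                         spec$translation[3]))$record
    expect_lte(rec$adc_min, rec$adc_min_at_suvmax)
    expect_gte(rec$suv_max, rec$suv_max_at_adcmin)
    expect_lte(rec$suv_mean, rec$suv_max)
    expect_lte(rec$adc_min, rec$adc_mean)
    expect_gte(rec$distance_mm, 0)
  }
})

test_that("distance is invariant to a global world-frame shift", {
  les <- clean_pair(offset = c(12, 0, 6), translation = c(3, 1, -2),
                    seed = 44)
  shift <- c(25, -40, 13)
  shifted <- function(v) image_volume(v$values, v$spacing,
                                      v$origin + shift, v$modality)
  tr <- translation_vector(3, 1, -2)
  r1 <- analyze_lesion_pair(les$suv, les$adc, les$dwi, tr)$record
  r2 <- analyze_lesion_pair(shifted(les$suv), shifted(les$adc),
                            shifted(les$dwi), tr)$record
  expect_equal(r2$distance_mm, r1$distance_mm, tolerance = 1e-9)
})

test_that("coincident foci report a match with a near-zero distance", {
  les <- clean_pair(offset = c(0, 0, 0), translation = c(2, 2, 2),
                    seed = 3)
  res <- analyze_lesion_pair(les$suv, les$adc, les$dwi,
                             translation_vector(2, 2, 2))
  diag_tol <- max(sqrt(sum(les$suv$spacing^2)),
                  sqrt(sum(les$adc$spacing^2)))
  expect_lte(res$record$distance_mm, diag_tol)
  expect_equal(res$record$match, "match")
})
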