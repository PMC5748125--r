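test_that("coincident foci land on the same world point across modalities", {
  les <- clean_pair(offset = c(0, 0, 0), translation = c(7, -3, 2))
  suv_idx <- which(les$suv$values == max(les$suv$values),
                   arr.ind = TRUE)[1, ]
  # argmin restricted to the lesion: the low-ADC lung background is not
  # part of the comparison
  shp <- dim(les$adc$values)
  g <- as.matrix(expand.grid(i = 1:shp[1], j = 1:shp[2], k = 1:shp[3]))
  w <- sweep(sweep(g - 1, 2, les$adc$spacing, "*"), 2,
             les$adc$origin, "+")
  w <- sweep(w, 2, les$truth$translation, "+")
  semi <- les$truth$semi_axes
  inside <- (w[, 1] / semi[1])^2 + (w[, 2] / semi[2])^2 +
            (w[, 3] / semi[3])^2 <= 1
  vals_in <- les$adc$values[g[inside, , drop = FALSE]]
  adc_idx <- g[inside, , drop = FALSE][which.min(vals_in), ]
  p_pet <- world_coords(les$suv, suv_idx)
  p_mri <- apply_translation(world_coords(les$adc, adc_idx),
                             les$truth$translation)
  half_diag <- 0.5 * max(sqrt(sum(les$suv$spacing^2)),
                         sqrt(sum(les$adc$spacing^2)))
  expect_lt(sqrt(sum((p_pet - p_mri)^2)), 2 * half_diag)
})

test_that("a 20 mm focus offset is recovered through the pipeline", {
  les <- clean_pair(offset = c(16, 12, 0), translation = c(5, 2, -4),
                    semi_axes = c(24, 18, 14))
  expect_equal(les$truth$offset_mm, 20)
  tr <- translation_vector(5, 2, -4)
  res <- analyze_lesion_pair(les$suv, les$adc, les$dwi, tr)
  tol <- max(sqrt(sum(les$suv$spacing^2)), sqrt(sum(les$adc$spacing^2)))
  expect_lt(abs(res$record$distance_mm - 20), tol)
})

test_that("generation is deterministic under a fixed seed", {
  spec <- lesion_spec(rim_outlier_frac = 0.1, noise_suv = 0.2,
                      noise_adc = 40, noise_dwi = 3, seed = 99)
  a <- make_lesion_pair(spec)
  b <- make_lesion_pair(spec)
  expect_identical(a$suv$values, b$suv$values)
  expect_identical(a$adc$values, b$adc$values)
  expect_identical(a$dwi$values, b$dwi$values)
})

test_that("noise-free SUV peak sits at the voxel nearest the focus", {
  les <- clean_pair(offset = c(10, 6, 0), seed = 3)
  spec_focus <- les$truth$p_s
  idx <- which(les$suv$values == max(les$suv$values), arr.ind = TRUE)
  expect_equal(nrow(idx), 1)
  expect_equal(as.integer(idx[1, ]),
               as.integer(nearest_voxel(les$suv, spec_focus)))
  # peak bounded by plateau + amplitude, attenuated at most by half a
  # voxel diagonal of Gaussian falloff
  half_diag2 <- sum((les$suv$spacing / 2)^2)
  lo <- 5 + 4 * exp(-half_diag2 / (2 * (min(c(20, 15, 12)) / 3)^2))
  expect_lte(max(les$suv$values), 5 + 4)
  expect_gte(max(les$suv$values), lo)
})

test_that("ADC volumes are clipped at zero even with outliers and noise", {
  spec <- lesion_spec(rim_outlier_frac = 0.3, noise_adc = 200, seed = 12)
  les <- make_lesion_pair(spec)
  expect_gte(min(les$adc$values), 0)
})

test_that("lesion specs reject foci outside the ellipsoid", {
  expect_error(lesion_spec(semi_axes = c(10, 10, 10),
                           suv_focus = c(11, 0, 0)), "outside")
  expect_error(lesion_spec(semi_axes = c(10, 10, 10),
                           adc_focus = c(0, 0, -12)), "outside")
  expect_error(lesion_spec(rim_outlier_frac = 1.2), "rim_outlier_frac")
  expect_error(lesion_spec(adc_plateau = 500, adc_depth = 600), ">= 0")
})

test_that("reader-translation noise matches its generating parameters", {
  sc <- cohort_scenario(n = 60, reader_sd = 2.5, n_readers = 2,
                        noise_suv = 0, noise_adc = 0, noise_dwi = 0,
                        rim_outlier_frac = 0, seed = 21)
  co <- make_cohort(sc)
  r1 <- co$readers[co$readers$reader == 1, ]
  r2 <- co$readers[co$readers$reader == 2, ]
  d <- sqrt((r1$dx - r2$dx)^2 + (r1$dy - r2$dy)^2 + (r1$dz - r2$dz)^2)
  # difference of two reader vectors ~ N(0, 2*sd^2 I3); its norm is a
  # scaled chi_3 with mean 2*sqrt(2/pi)*s and sd s*sqrt(3 - 8/pi),
  # s = reader_sd * sqrt(2)
  s <- 2.5 * sqrt(2)
  exp_mean <- s * 2 * sqrt(2 / pi)
  exp_sd <- s * sqrt(3 - 8 / pi)
  expect_lt(abs(mean(d) - exp_mean), 3 * exp_sd / sqrt(60))
  expect_lt(abs(sd(d) - exp_sd), 3 * exp_sd / sqrt(2 * 60))
})

test_that("a cohort of one lesion has a single truth row", {
  sc <- cohort_scenario(n = 1, seed = 5)
  co <- make_cohort(sc)
  expect_length(co$lesions, 1)
  expect_equal(nrow(co$truth), 1)
  expect_equal(nrow(co$readers[co$readers$reader == 1, ]), 1)
})

test_that("strong negative coupling surfaces in measured records", {
  # scaled-down Monte Carlo: full-cohort correlations match the target
  # coupling sign at every seed
  rs <- sapply(1:3, function(s) {
    sc <- cohort_scenario(n = 20, rho = -0.9, offset_range = c(0, 5),
                          n_readers = 1, seed = 100 + s)
    co <- make_cohort(sc)
    recs <- do.call(rbind, lapply(seq_along(co$lesions), function(i) {
      row <- co$readers[co$readers$lesion == i, ]
      analyze_lesion_pair(co$lesions[[i]]$suv, co$lesions[[i]]$adc,
                          co$lesions[[i]]$dwi,
                          translation_vector(row$dx, row$dy, row$dz),
                          lesion_id = i)$record
    }))
    correlate(recs$suv_max, recs$adc_min)$r_p
  })
  expect_true(all(rs < -0.5))
})

test_that("a written cohort round-trips through the files pipeline inputs", {
  sc <- cohort_scenario(n = 2, seed = 8, diameter_mean = 30,
                        diameter_sd = 5)
  co <- make_cohort(sc)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "lesion001_suv.nii.gz")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  suv <- read_nifti(file.path(dir, "lesion001_suv.nii.gz"), "SUV")
  expect_equal(suv$values, co$lesions[[1]]$suv$values, tolerance = 1e-5)
  expect_equal(suv$spacing, co$lesions[[1]]$suv$spacing)
})
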