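#' Specification of one synthetic PET/MRI lesion pair
#'
#' Describes an ellipsoidal lung lesion on near-zero background, with a
#' hypermetabolic SUV focus (Gaussian bump on a lesion plateau) and a
#' low-ADC high-cellularity focus (Gaussian trough in an ADC plateau) at a
#' controllable spatial offset. A stated fraction of lesion-rim ADC voxels
#' is replaced by near-zero outliers, emulating contamination by aerated
#' lung tissue, to exercise histogram refinement.
#'
#' @param semi_axes ellipsoid semi-axes (mm, all > 0), axes (x, y, z).
#' @param center lesion center (mm) in the PET world frame.
#' @param suv_background SUV outside the lesion (lung background).
#' @param suv_plateau base SUV inside the lesion.
#' @param suv_amplitude height of the SUV focus above the plateau.
#' @param suv_focus world position (mm, PET frame) of the SUV focus; must
#'   lie inside the ellipsoid. Default: lesion center.
#' @param suv_width Gaussian sigma (mm) of the SUV focus; default one
#'   third of the smallest semi-axis.
#' @param adc_plateau ADC inside the lesion away from the trough
#'   (1e-6 mm^2/s).
#' @param adc_depth depth of the ADC trough below the plateau; the trough
#'   floor `adc_plateau - adc_depth` must be >= 0.
#' @param adc_focus world position (mm, PET frame) of the ADC trough.
#' @param adc_width Gaussian sigma (mm) of the trough.
#' @param adc_outside ADC outside the lesion.
#' @param rim_outlier_frac fraction in [0, 1] of lesion boundary voxels on
#'   the ADC grid replaced by uniform values in [0, 100) 1e-6 mm^2/s.
#' @param noise_suv,noise_adc,noise_dwi additive Gaussian noise sd per
#'   modality (0 disables).
#' @param dwi_inside,dwi_outside DWI b=800 magnitude inside/outside the
#'   lesion (arbitrary units).
#' @param translation true rigid translation (mm) mapping MRI world
#'   coordinates into the PET frame.
#' @param seed integer seed making the pair reproducible; `NULL` leaves
#'   the RNG state alone.
#' @return a `lesion_spec` list.
#' @export
lesion_spec <- function(semi_axes = c(20, 15, 12),
                        center = c(0, 0, 0),
                        suv_background = 0.4,
                        suv_plateau = 5,
                        suv_amplitude = 4,
                        suv_focus = center,
                        suv_width = min(semi_axes) / 3,
                        adc_plateau = 1300,
                        adc_depth = 800,
                        adc_focus = center,
                        adc_width = min(semi_axes) / 3,
                        adc_outside = 150,
                        rim_outlier_frac = 0.05,
                        noise_suv = 0, noise_adc = 0, noise_dwi = 0,
                        dwi_inside = 100, dwi_outside = 5,
                        translation = c(0, 0, 0),
                        seed = NULL) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("semi_axes must be 3 positive numbers (mm)")
  in_ell <- function(p) sum(((p - center) / semi_axes)^2) <= 1
  if (!in_ell(suv_focus)) stop("SUV focus lies outside the ellipsoid")
  if (!in_ell(adc_focus)) stop("ADC focus lies outside the ellipsoid")
  if (adc_plateau - adc_depth < 0)
    stop("ADC trough floor (plateau - depth) must be >= 0")
  if (rim_outlier_frac < 0 || rim_outlier_frac > 1)
    stop("rim_outlier_frac must be in [0, 1]")
  if (any(c(noise_suv, noise_adc, noise_dwi) < 0))
    stop("noise sd must be >= 0")
  spec <- list(semi_axes = semi_axes, center = as.numeric(center),
               suv_background = suv_background, suv_plateau = suv_plateau,
               suv_amplitude = suv_amplitude,
               suv_focus = as.numeric(suv_focus), suv_width = suv_width,
               adc_plateau = adc_plateau, adc_depth = adc_depth,
               adc_focus = as.numeric(adc_focus), adc_width = adc_width,
               adc_outside = adc_outside,
               rim_outlier_frac = rim_outlier_frac,
               noise_suv = noise_suv, noise_adc = noise_adc,
               noise_dwi = noise_dwi,
               dwi_inside = dwi_inside, dwi_outside = dwi_outside,
               translation = as.numeric(translation), seed = seed)
  class(spec) <- "lesion_spec"
  spec
}

# voxel-center coordinate matrix of a grid (n_voxels x 3), column-major
grid_points <- function(shape, spacing, origin) {
  g <- as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                             k = seq_len(shape[3])))
  sweep(sweep(g - 1, 2, spacing, "*"), 2, origin, "+")
}

#' Generate one paired SUV / ADC / DWI phantom
#'
#' The SUV volume lives on the PET grid in the PET world frame; ADC and
#' DWI live on the MRI grid in an MRI frame displaced from the PET frame
#' by the true translation (`point_PET = point_MRI + translation`). Inside
#' the ellipsoid, SUV = plateau + amplitude * Gaussian(suv_focus) and
#' ADC = plateau - depth * Gaussian(adc_focus), clipped at 0; outside, the
#' respective background levels. Deterministic under a fixed seed.
#'
#' @param spec a [lesion_spec].
#' @param pet_spacing,mri_spacing voxel sizes (mm) of the two grids;
#'   defaults match typical whole-body FDG-PET (5 x 5 x 3.27 mm) and
#'   b=800 echo-planar DWI (2.6 x 2.6 x 5 mm) reconstructions.
#' @param margin_mm padding (mm) around the ellipsoid on all sides.
#' @return list with elements `suv`, `adc`, `dwi` ([image_volume]s) and
#'   `truth` (list: `p_s`, `p_a`, `offset_mm`, `translation`,
#'   `volume_cm3`, `semi_axes`, `center`).
#' @export
make_lesion_pair <- function(spec,
                             pet_spacing = c(5, 5, 3.27),
                             mri_spacing = c(2.6, 2.6, 5),
                             margin_mm = 20) {
  stopifnot(inherits(spec, "lesion_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  half <- spec$semi_axes + margin_mm

  make_grid <- function(spacing, center) {
    shape <- pmax(as.integer(ceiling(2 * half / spacing)) + 1L, 2L)
    origin <- center - (shape - 1) / 2 * spacing
    list(shape = shape, spacing = spacing, origin = origin)
  }
  gauss <- function(pts, focus, width) {
    d2 <- (pts[, 1] - focus[1])^2 + (pts[, 2] - focus[2])^2 +
          (pts[, 3] - focus[3])^2
    exp(-d2 / (2 * width^2))
  }
  inside_ell <- function(pts) {
    ((pts[, 1] - spec$center[1]) / spec$semi_axes[1])^2 +
    ((pts[, 2] - spec$center[2]) / spec$semi_axes[2])^2 +
    ((pts[, 3] - spec$center[3]) / spec$semi_axes[3])^2 <= 1
  }

  # --- SUV on the PET grid (PET frame)
  gp <- make_grid(pet_spacing, spec$center)
  pts <- grid_points(gp$shape, gp$spacing, gp$origin)
  ins <- inside_ell(pts)
  suv <- ifelse(ins,
                spec$suv_plateau +
                  spec$suv_amplitude * gauss(pts, spec$suv_focus,
                                             spec$suv_width),
                spec$suv_background)
  if (spec$noise_suv > 0)
    suv <- suv + stats::rnorm(length(suv), 0, spec$noise_suv)
  suv <- pmax(suv, 0)
  suv_vol <- image_volume(array(suv, gp$shape), gp$spacing, gp$origin,
                          modality = "SUV")

  # --- ADC / DWI on the MRI grid (MRI frame = PET frame - translation)
  gm <- make_grid(mri_spacing, spec$center - spec$translation)
  pts_m <- grid_points(gm$shape, gm$spacing, gm$origin)
  pts_p <- sweep(pts_m, 2, spec$translation, "+")  # map into PET frame
  ins_m <- inside_ell(pts_p)

  adc <- ifelse(ins_m,
                spec$adc_plateau -
                  spec$adc_depth * gauss(pts_p, spec$adc_focus,
                                         spec$adc_width),
                spec$adc_outside)
  if (spec$noise_adc > 0)
    adc <- adc + stats::rnorm(length(adc), 0, spec$noise_adc)
  # rim outliers: near-zero ADC at boundary voxels of the lesion
  if (spec$rim_outlier_frac > 0) {
    ins_arr <- array(ins_m, gm$shape)
    b <- which(boundary_voxels(ins_arr))
    n_out <- round(spec$rim_outlier_frac * length(b))
    if (n_out > 0) {
      pick <- sample(b, n_out)
      adc[pick] <- stats::runif(n_out, 0, 100)
    }
  }
  adc <- pmax(adc, 0)
  adc_vol <- image_volume(array(adc, gm$shape), gm$spacing, gm$origin,
                          modality = "ADC")

  dwi <- ifelse(ins_m, spec$dwi_inside, spec$dwi_outside)
  if (spec$noise_dwi > 0)
    dwi <- dwi + stats::rnorm(length(dwi), 0, spec$noise_dwi)
  dwi_vol <- image_volume(array(dwi, gm$shape), gm$spacing, gm$origin,
                          modality = "DWI_B800")

  truth <- list(
    p_s = spec$suv_focus, p_a = spec$adc_focus,
    offset_mm = sqrt(sum((spec$suv_focus - spec$adc_focus)^2)),
    translation = spec$translation,
    volume_cm3 = 4 / 3 * pi * prod(spec$semi_axes) / 1000,
    semi_axes = spec$semi_axes, center = spec$center)
  list(suv = suv_vol, adc = adc_vol, dwi = dwi_vol, truth = truth)
}

#' Scenario for a synthetic lesion cohort
#'
#' Cohort-level distributions: lesion sizes, inter-focus offsets, the
#' coupling between metabolic activity and cellularity, true inter-scan
#' translations, and per-reader registration noise.
#'
#' @param n number of lesions (>= 1).
#' @param diameter_mean,diameter_sd,diameter_range max-diameter (mm)
#'   distribution: normal, truncated to `diameter_range`. Defaults emulate
#'   a surgical lung-tumor cohort (mean about 51 mm, sd about 31 mm).
#' @param offset_range range (mm) of the true SUV-focus / ADC-trough
#'   offset, drawn uniformly; offsets larger than the lesion supports are
#'   capped so both foci stay inside the ellipsoid.
#' @param size_dependent_offset when `TRUE`, the offset upper bound scales
#'   with lesion diameter (`0.35 * diameter`), emulating mismatch arising
#'   preferentially in large heterogeneous tumors.
#' @param rho target cohort-level correlation between SUVmax and ADCmin in
#'   [-1, 1]; internally the SUV focus amplitude and ADC trough depth are
#'   drawn from a bivariate normal with correlation `-rho` (a deeper
#'   trough lowers ADCmin).
#' @param translation_sd sd (mm) per axis of the true MRI-to-PET
#'   translations.
#' @param reader_sd sd (mm) per axis of each reader's translation error
#'   around the truth.
#' @param n_readers number of emulated readers (>= 1).
#' @param noise_suv,noise_adc,noise_dwi voxel noise sd per modality.
#' @param rim_outlier_frac rim ADC outlier fraction (see [lesion_spec]).
#' @param seed master seed; lesion `i` uses derived seed `seed + i`.
#' @return a `cohort_scenario` list.
#' @export
cohort_scenario <- function(n,
                            diameter_mean = 51, diameter_sd = 31,
                            diameter_range = c(16, 120),
                            offset_range = c(0, 8),
                            size_dependent_offset = FALSE,
                            rho = 0,
                            translation_sd = 5,
                            reader_sd = 2.5,
                            n_readers = 2,
                            noise_suv = 0.1, noise_adc = 30,
                            noise_dwi = 2,
                            rim_outlier_frac = 0.05,
                            seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  if (n_readers < 1) stop("n_readers must be >= 1")
  structure(list(n = as.integer(n), diameter_mean = diameter_mean,
                 diameter_sd = diameter_sd,
                 diameter_range = diameter_range,
                 offset_range = offset_range,
                 size_dependent_offset = size_dependent_offset,
                 rho = rho, translation_sd = translation_sd,
                 reader_sd = reader_sd, n_readers = as.integer(n_readers),
                 noise_suv = noise_suv, noise_adc = noise_adc,
                 noise_dwi = noise_dwi,
                 rim_outlier_frac = rim_outlier_frac,
                 seed = as.integer(seed)),
            class = "cohort_scenario")
}

#' Generate a synthetic lesion cohort with ground truth
#'
#' Draws per-lesion sizes, focus offsets, coupled SUV amplitude / ADC
#' trough depth, a true inter-scan translation, and per-reader perturbed
#' translations; then renders each lesion pair with [make_lesion_pair].
#' All cohort-level draws happen under the master seed, each lesion's
#' voxel rendering under the derived seed `seed + i`.
#'
#' @param scenario a [cohort_scenario].
#' @return list with `lesions` (list of [make_lesion_pair] results),
#'   `truth` (data.frame: lesion, diameter_mm, offset_mm, volume_cm3,
#'   translation dx/dy/dz) and `readers` (data.frame: lesion, reader,
#'   dx, dy, dz).
#' @export
make_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  n <- sc$n

  # truncated-normal diameters
  d <- stats::rnorm(n, sc$diameter_mean, sc$diameter_sd)
  while (any(bad <- d < sc$diameter_range[1] | d > sc$diameter_range[2]))
    d[bad] <- stats::rnorm(sum(bad), sc$diameter_mean, sc$diameter_sd)

  # coupled amplitude / depth: corr(amp, depth) = -rho so that
  # corr(SUVmax, ADCmin) ~ rho
  z1 <- stats::rnorm(n)
  z2 <- -sc$rho * z1 + sqrt(max(0, 1 - sc$rho^2)) * stats::rnorm(n)
  amp <- pmin(pmax(4 + 1.5 * z1, 0.8), 6.3)
  plateau_adc <- stats::rnorm(n, 1300, 60)
  depth <- pmin(pmax(800 + 220 * z2, 250), plateau_adc - 250)

  # offsets and random directions
  off_hi <- if (sc$size_dependent_offset) 0.35 * d else
            rep(sc$offset_range[2], n)
  off_lo <- min(sc$offset_range[1], min(off_hi))
  delta <- stats::runif(n, off_lo, off_hi)
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))

  trans <- matrix(stats::rnorm(3 * n, 0, sc$translation_sd), ncol = 3)
  readers <- do.call(rbind, lapply(seq_len(sc$n_readers), function(r) {
    data.frame(lesion = seq_len(n), reader = r,
               dx = trans[, 1] + stats::rnorm(n, 0, sc$reader_sd),
               dy = trans[, 2] + stats::rnorm(n, 0, sc$reader_sd),
               dz = trans[, 3] + stats::rnorm(n, 0, sc$reader_sd))
  }))

  ratios <- cbind(1, stats::runif(n, 0.75, 0.95),
                  stats::runif(n, 0.6, 0.85))

  lesions <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    semi <- d[i] / 2 * ratios[i, ]
    # cap the offset so both foci stay safely inside the ellipsoid
    dmax <- 2 * 0.8 / sqrt(sum((u[i, ] / semi)^2))
    delta_i <- min(delta[i], dmax)
    p_s <- delta_i / 2 * u[i, ]
    p_a <- -delta_i / 2 * u[i, ]
    spec <- lesion_spec(
      semi_axes = semi, center = c(0, 0, 0),
      suv_amplitude = amp[i],
      suv_focus = p_s, adc_focus = p_a,
      adc_plateau = plateau_adc[i], adc_depth = depth[i],
      rim_outlier_frac = sc$rim_outlier_frac,
      noise_suv = sc$noise_suv, noise_adc = sc$noise_adc,
      noise_dwi = sc$noise_dwi,
      translation = trans[i, ],
      seed = sc$seed + i)
    lesions[[i]] <- make_lesion_pair(spec)
    truth[[i]] <- data.frame(
      lesion = i, diameter_mm = d[i],
      offset_mm = lesions[[i]]$truth$offset_mm,
      volume_cm3 = lesions[[i]]$truth$volume_cm3,
      dx = trans[i, 1], dy = trans[i, 2], dz = trans[i, 3])
  }
  list(lesions = lesions, truth = do.call(rbind, truth),
       readers = readers)
}

#' Write a synthetic cohort to disk
#'
#' NIfTI volumes per lesion plus `truth.csv` and `readers.csv`.
#'
#' @param cohort result of [make_cohort].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$lesions)) {
    les <- cohort$lesions[[i]]
    write_nifti(les$suv, file.path(dir, sprintf("lesion%03d_suv.nii.gz", i)))
    write_nifti(les$adc, file.path(dir, sprintf("lesion%03d_adc.nii.gz", i)))
    write_nifti(les$dwi, file.path(dir, sprintf("lesion%03d_dwi.nii.gz", i)))
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$readers, file.path(dir, "readers.csv"),
                   row.names = FALSE)
  invisible(dir)
}
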