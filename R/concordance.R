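#' Locate the extremum voxel of a masked volume
#'
#' Finds SUVmax (`kind = "max"`) or ADCmin (`kind = "min"`) over the
#' voxels of a lesion mask. Ties are broken toward the lowest linearized
#' voxel index (x fastest), and the number of tying voxels is recorded.
#'
#' @param volume an [image_volume].
#' @param mask a [lesion_mask] on the same grid.
#' @param kind `"max"` or `"min"`.
#' @return object of class `extremum_locus`: list with `index` (voxel
#'   triple), `world` (mm, native frame), `value`, `tie_count`, `kind`.
#' @export
locate_extremum <- function(volume, mask, kind = c("max", "min")) {
  kind <- match.arg(kind)
  stopifnot(inherits(volume, "image_volume"),
            inherits(mask, "lesion_mask"))
  if (!identical(dim(volume$values), dim(mask$mask)))
    stop("volume and mask must share a grid")
  if (!any(mask$mask)) stop("empty mask")
  lin <- which(mask$mask)
  vals <- volume$values[lin]
  ext <- if (kind == "max") max(vals) else min(vals)
  hits <- lin[vals == ext]
  li <- min(hits)  # lowest linear index, x fastest
  shp <- dim(volume$values)
  k <- (li - 1) %/% (shp[1] * shp[2])
  r <- (li - 1) %% (shp[1] * shp[2])
  idx <- c(r %% shp[1] + 1, r %/% shp[1] + 1, k + 1)
  structure(list(index = as.integer(idx),
                 world = world_coords(volume, idx),
                 value = ext, tie_count = length(hits), kind = kind),
            class = "extremum_locus")
}

#' @export
print.extremum_locus <- function(x, ...) {
  cat(sprintf("<extremum_locus %s> value %g at voxel (%s), world (%s) mm%s\n",
              x$kind, x$value, paste(x$index, collapse = ", "),
              paste(format(x$world, digits = 4), collapse = ", "),
              if (x$tie_count > 1)
                sprintf(" [%d-way tie]", x$tie_count) else ""))
  invisible(x)
}

#' World-frame distance between the SUVmax and ADCmin voxels
#'
#' The MRI-frame locus is mapped into the PET frame with the rigid
#' translation before taking the Euclidean distance:
#' `|| pet_world - (mri_world + t) ||`.
#'
#' @param pet_locus [extremum_locus] in the PET frame (SUVmax).
#' @param mri_locus [extremum_locus] in the MRI frame (ADCmin).
#' @param t [translation_vector] mapping MRI world into the PET frame.
#' @return distance in mm.
#' @export
extrema_distance <- function(pet_locus, mri_locus, t) {
  p <- as.numeric(pet_locus$world)
  q <- apply_translation(mri_locus$world, t)
  if (!all(is.finite(c(p, q)))) stop("loci must be finite")
  sqrt(sum((p - q)^2))
}

#' Classify spatial match versus mismatch
#'
#' A lesion is a spatial match when the SUVmax-ADCmin distance does not
#' exceed the registration-accuracy threshold (boundary inclusive).
#'
#' @param distance inter-extremum distance in mm (>= 0).
#' @param threshold_mm match threshold in mm (> 0); 12 mm is the value
#'   derived from sequential PET/MRI registration accuracy.
#' @return `"match"` or `"mismatch"`.
#' @export
classify_match <- function(distance, threshold_mm = 12) {
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("distance must be finite and >= 0")
  if (!is.finite(threshold_mm) || threshold_mm <= 0)
    stop("threshold must be > 0")
  ifelse(distance <= threshold_mm, "match", "mismatch")
}

#' Radius of a sphere of given volume
#'
#' @param volume_cm3 sphere volume in cm^3.
#' @return radius in mm; 6.2035 mm for the default 1 cm^3.
#' @export
sphere_radius_mm <- function(volume_cm3 = 1) {
  (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)
}

#' Statistics in a fixed-volume sphere around a point
#'
#' Computes min/max/mean over voxels whose centers lie within the sphere
#' radius of `center` AND inside the lesion mask, so background or
#' necrotic-rim voxels outside the VOI never enter. If the intersection
#' is empty the single nearest in-mask voxel is used, with a warning.
#'
#' @param volume an [image_volume].
#' @param mask a [lesion_mask] on the same grid.
#' @param center world mm triple (native frame of `volume`); must lie
#'   inside the volume extent.
#' @param sphere_volume_cm3 sphere volume; default 1 cm^3
#'   (radius 6.2035 mm).
#' @return object of class `sphere_stats`: list with `value_at_center`
#'   (nearest-voxel value), `min`, `max`, `mean`, `n_voxels`,
#'   `radius_mm`, `fallback` (TRUE when the nearest-voxel fallback was
#'   used).
#' @export
sphere_stats <- function(volume, mask, center, sphere_volume_cm3 = 1) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(mask, "lesion_mask"))
  if (!identical(dim(volume$values), dim(mask$mask)))
    stop("volume and mask must share a grid")
  center <- as.numeric(center)
  ctr_idx <- nearest_voxel(volume, center)  # errors if outside extent
  r <- sphere_radius_mm(sphere_volume_cm3)
  shp <- dim(volume$values)
  half <- ceiling(r / volume$spacing)
  lo <- pmax(ctr_idx - half, 1)
  hi <- pmin(ctr_idx + half, shp)
  g <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                             k = lo[3]:hi[3]))
  w <- sweep(sweep(g - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
  d2 <- (w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 +
        (w[, 3] - center[3])^2
  inmask <- mask$mask[g]
  sel <- g[d2 <= r^2 & inmask, , drop = FALSE]
  fallback <- FALSE
  if (nrow(sel) == 0) {
    warning("sphere contains no in-mask voxel; using nearest mask voxel")
    fallback <- TRUE
    wm <- which(mask$mask, arr.ind = TRUE)
    wpts <- sweep(sweep(wm - 1, 2, volume$spacing, "*"), 2,
                  volume$origin, "+")
    dd <- (wpts[, 1] - center[1])^2 + (wpts[, 2] - center[2])^2 +
          (wpts[, 3] - center[3])^2
    sel <- wm[which.min(dd), , drop = FALSE]
  }
  vals <- volume$values[sel]
  structure(list(
    value_at_center = volume$values[ctr_idx[1], ctr_idx[2], ctr_idx[3]],
    min = min(vals), max = max(vals), mean = mean(vals),
    n_voxels = length(vals), radius_mm = r, fallback = fallback),
    class = "sphere_stats")
}

#' Full per-lesion concordance record
#'
#' Computes every per-lesion outcome parameter: the PET-side metrics
#' (SUVmax, SUVmean, V_PET, maximum diameter), the ADC-side metrics
#' (ADCmin, ADCmean, V_MRI), the cross-modal sphere statistics
#' (ADC@SUVmax, ADCmin@SUVmax, ADCmean@SUVmax and SUV@ADCmin,
#' SUVmax@ADCmin, SUVmean@ADCmin in a fixed-volume sphere), the
#' world-frame inter-extremum distance and the match classification.
#' Cross-modal positions are converted between frames with the rigid
#' translation; values are read by nearest-voxel lookup.
#'
#' @param suv SUV [image_volume] (PET grid, PET frame).
#' @param adc ADC [image_volume] (MRI grid, MRI frame).
#' @param pet_mask [lesion_mask] on the PET grid.
#' @param adc_mask refined [lesion_mask] on the MRI grid.
#' @param translation [translation_vector], MRI world to PET frame.
#' @param threshold_mm spatial-match threshold (mm), default 12.
#' @param sphere_volume_cm3 sphere volume for neighbourhood statistics.
#' @param lesion_id,reader_id identifiers copied into the record.
#' @return one-row `data.frame` with columns `lesion`, `reader`,
#'   `suv_max`, `suv_mean`, `v_pet_cm3`, `diameter_mm`, `adc_min`,
#'   `adc_mean`, `v_mri_cm3`, `adc_at_suvmax`, `adc_min_at_suvmax`,
#'   `adc_mean_at_suvmax`, `suv_at_adcmin`, `suv_max_at_adcmin`,
#'   `suv_mean_at_adcmin`, `distance_mm`, `match`, `tie_suvmax`,
#'   `tie_adcmin`.
#' @export
lesion_report <- function(suv, adc, pet_mask, adc_mask, translation,
                          threshold_mm = 12, sphere_volume_cm3 = 1,
                          lesion_id = 1L, reader_id = 1L) {
  suv_loc <- locate_extremum(suv, pet_mask, "max")
  adc_loc <- locate_extremum(adc, adc_mask, "min")

  # SUVmax position in the MRI frame; ADCmin position in the PET frame
  suvmax_mri <- apply_translation(suv_loc$world, -as.numeric(translation))
  adcmin_pet <- apply_translation(adc_loc$world, as.numeric(translation))

  adc_sphere <- sphere_stats(adc, adc_mask, suvmax_mri,
                             sphere_volume_cm3)
  suv_sphere <- sphere_stats(suv, pet_mask, adcmin_pet,
                             sphere_volume_cm3)

  d <- extrema_distance(suv_loc, adc_loc, translation)
  data.frame(
    lesion = lesion_id, reader = reader_id,
    suv_max = suv_loc$value,
    suv_mean = mean(suv$values[pet_mask$mask]),
    v_pet_cm3 = tumor_volume(pet_mask),
    diameter_mm = max_diameter(pet_mask),
    adc_min = adc_loc$value,
    adc_mean = mean(adc$values[adc_mask$mask]),
    v_mri_cm3 = tumor_volume(adc_mask),
    adc_at_suvmax = adc_sphere$value_at_center,
    adc_min_at_suvmax = adc_sphere$min,
    adc_mean_at_suvmax = adc_sphere$mean,
    suv_at_adcmin = suv_sphere$value_at_center,
    suv_max_at_adcmin = suv_sphere$max,
    suv_mean_at_adcmin = suv_sphere$mean,
    distance_mm = d,
    match = classify_match(d, threshold_mm),
    tie_suvmax = suv_loc$tie_count,
    tie_adcmin = adc_loc$tie_count)
}
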