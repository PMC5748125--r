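# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's internal code paths.

# exhaustive scan for the extremum of a masked array, with the same
# lowest-linear-index tie rule
oracle_extremum <- function(values, mask, kind) {
  best <- if (kind == "max") -Inf else Inf
  best_lin <- NA_integer_
  ties <- 0L
  for (lin in seq_along(values)) {
    if (!mask[lin]) next
    v <- values[lin]
    better <- if (kind == "max") v > best else v < best
    if (better) {
      best <- v; best_lin <- lin; ties <- 1L
    } else if (v == best) {
      ties <- ties + 1L
    }
  }
  shp <- dim(values)
  k <- (best_lin - 1) %/% (shp[1] * shp[2])
  r <- (best_lin - 1) %% (shp[1] * shp[2])
  list(index = c(r %% shp[1] + 1, r %/% shp[1] + 1, k + 1),
       value = best, tie_count = ties)
}

# exhaustive scan of every voxel for fixed-volume sphere statistics
oracle_sphere <- function(volume, mask_arr, center, radius) {
  shp <- dim(volume$values)
  g <- as.matrix(expand.grid(i = 1:shp[1], j = 1:shp[2], k = 1:shp[3]))
  w <- sweep(sweep(g - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
  d <- sqrt((w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 +
            (w[, 3] - center[3])^2)
  sel <- d <= radius & mask_arr[g]
  vals <- volume$values[g[sel, , drop = FALSE]]
  list(min = min(vals), max = max(vals), mean = mean(vals),
       n = length(vals))
}

# textbook product-moment correlation
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# brute-force pairwise maximum distance over all true voxels
oracle_diameter <- function(mask) {
  w <- which(mask$mask, arr.ind = TRUE)
  pts <- sweep(sweep(w - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
  best <- 0
  for (i in seq_len(nrow(pts))) {
    d2 <- rowSums(sweep(pts, 2, pts[i, ])^2)
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# a constant-valued volume
const_volume <- function(value = 1, shape = c(8, 8, 8),
                         spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         modality = "SUV") {
  image_volume(array(value, shape), spacing, origin, modality)
}

# full-volume mask
full_mask <- function(volume) {
  lesion_mask(array(TRUE, dim(volume$values)), volume)
}

# a digitized sphere mask of given radius (mm) centered in the grid
sphere_mask_volume <- function(radius_mm, spacing = c(2.5, 2.5, 2.5),
                               pad_mm = 10, inside = 10, outside = 1) {
  half <- radius_mm + pad_mm
  shp <- as.integer(ceiling(2 * half / spacing)) + 1L
  ctr <- (shp - 1) / 2 * spacing
  g <- as.matrix(expand.grid(i = 1:shp[1], j = 1:shp[2], k = 1:shp[3]))
  w <- sweep(g - 1, 2, spacing, "*")
  d2 <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 + (w[, 3] - ctr[3])^2
  vol <- image_volume(array(ifelse(d2 <= radius_mm^2, inside, outside),
                            shp), spacing, c(0, 0, 0), "SUV")
  list(volume = vol, center = ctr,
       mask = lesion_mask(array(d2 <= radius_mm^2, shp), vol))
}

# noise-free lesion pair with controllable offset and translation
clean_pair <- function(offset = c(0, 0, 0), translation = c(0, 0, 0),
                       seed = 1, ...) {
  spec <- lesion_spec(suv_focus = offset / 2, adc_focus = -offset / 2,
                      translation = translation,
                      rim_outlier_frac = 0, seed = seed, ...)
  make_lesion_pair(spec)
}
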