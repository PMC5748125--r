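#' Configuration for adaptive-threshold PET VOI segmentation
#'
#' The segmentation iterates a source-to-background threshold: given the
#' current mask, background `bg` is the mean SUV in a shell around the
#' mask, the peak is the mask maximum, and the next threshold is
#' `bg + beta * (peak - bg)`.
#'
#' @param beta threshold fraction in (0, 1); default 0.41.
#' @param shell_mm width (mm) of the background shell around the mask.
#' @param max_iter maximum number of threshold iterations (>= 1).
#' @return an `adaptive_threshold_config` list.
#' @export
adaptive_threshold_config <- function(beta = 0.41, shell_mm = 10,
                                      max_iter = 25) {
  if (beta <= 0 || beta >= 1) stop("beta must be in (0, 1)")
  if (shell_mm <= 0) stop("shell_mm must be > 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(beta = beta, shell_mm = shell_mm,
                 max_iter = as.integer(max_iter)),
            class = "adaptive_threshold_config")
}

#' Segment a PET lesion VOI by iterative adaptive thresholding
#'
#' Starting from the peak in a small neighbourhood of the seed, the mask
#' at each step is the 26-connected component containing the seed of
#' voxels with SUV at or above the current threshold; background is
#' re-estimated from a shell around the mask and the threshold updated to
#' `bg + beta * (peak - bg)` until the mask stabilizes.
#'
#' @param suv an [image_volume] of modality `"SUV"`.
#' @param seed_point world mm triple inside the lesion.
#' @param cfg an [adaptive_threshold_config].
#' @return a [lesion_mask] containing the seed voxel, with attributes
#'   `threshold` (final SUV cutoff), `background`, `peak`, `iterations`
#'   and `converged`.
#' @export
segment_pet_voi <- function(suv, seed_point,
                            cfg = adaptive_threshold_config()) {
  stopifnot(inherits(suv, "image_volume"),
            inherits(cfg, "adaptive_threshold_config"))
  seed_idx <- nearest_voxel(suv, seed_point)
  v <- suv$values
  seed_val <- v[seed_idx[1], seed_idx[2], seed_idx[3]]

  # initial peak: maximum within a 10 mm ball of the seed
  nb <- dilate_mm(array(seq_along(v) ==
                          ((seed_idx[3] - 1) * prod(dim(v)[1:2]) +
                           (seed_idx[2] - 1) * dim(v)[1] + seed_idx[1]),
                        dim = dim(v)),
                  suv$spacing, 10)
  peak <- max(v[nb])
  thr <- cfg$beta * peak
  if (seed_val < thr)
    stop("segmentation failure: seed voxel below initial threshold")

  mask <- NULL
  converged <- FALSE
  bg <- 0
  for (it in seq_len(cfg$max_iter)) {
    cand <- v >= thr
    if (!cand[seed_idx[1], seed_idx[2], seed_idx[3]])
      stop("segmentation failure: seed voxel fell below threshold ",
           "(seed in background?)")
    new_mask <- flood_fill_26(cand, seed_idx)
    shell <- dilate_mm(new_mask, suv$spacing, cfg$shell_mm) & !new_mask
    bg <- if (any(shell)) mean(v[shell]) else 0
    peak <- max(v[new_mask])
    if (seed_val <= bg)
      stop("segmentation failure: seed SUV does not exceed local background")
    thr_new <- bg + cfg$beta * (peak - bg)
    if (!is.null(mask) && identical(new_mask, mask)) {
      converged <- TRUE
      mask <- new_mask
      break
    }
    mask <- new_mask
    thr <- thr_new
  }
  if (!converged)
    warning("adaptive threshold did not converge in ", cfg$max_iter,
            " iterations; returning the last mask")
  out <- lesion_mask(mask, suv)
  attr(out, "threshold") <- thr
  attr(out, "background") <- bg
  attr(out, "peak") <- peak
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  out
}

# Otsu threshold on a numeric vector (256-bin histogram); maximizes
# between-class variance, breaking ties toward the lower threshold
# (larger foreground).
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  nb <- 256L
  br <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-(nb + 1)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  k <- which.max(sigma_b)  # which.max returns the first (lowest) maximum
  br[k + 1L]
}

#' Delineate a lesion on the b=800 DWI volume
#'
#' Automated stand-in for manual 2D ROI stacks: Otsu threshold inside a
#' bounding box around the seed, then the 26-connected component
#' containing the seed.
#'
#' @param dwi an [image_volume] of modality `"DWI_B800"`.
#' @param seed_point world mm triple inside the lesion; default the
#'   global DWI maximum.
#' @param box_mm half-width (mm) of the bounding box used for Otsu.
#' @return a [lesion_mask] on the DWI grid.
#' @export
segment_dwi <- function(dwi, seed_point = NULL, box_mm = 60) {
  stopifnot(inherits(dwi, "image_volume"))
  if (is.null(seed_point)) {
    w <- which(dwi$values == max(dwi$values), arr.ind = TRUE)[1, ]
    seed_point <- world_coords(dwi, w)
  }
  seed_idx <- nearest_voxel(dwi, seed_point)
  shp <- dim(dwi$values)
  half <- pmax(ceiling(box_mm / dwi$spacing), 1)
  lo <- pmax(seed_idx - half, 1)
  hi <- pmin(seed_idx + half, shp)
  box <- dwi$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  thr <- otsu_threshold(as.numeric(box))
  cand <- dwi$values > thr
  if (!cand[seed_idx[1], seed_idx[2], seed_idx[3]])
    stop("DWI segmentation failure: seed voxel below the Otsu threshold")
  lesion_mask(flood_fill_26(cand, seed_idx), dwi)
}

#' Transfer a DWI lesion mask onto an ADC map
#'
#' Identity copy when both share the MRI grid; nearest-neighbour
#' resampling otherwise.
#'
#' @param dwi_mask a [lesion_mask] drawn on the b=800 DWI volume.
#' @param adc the target [image_volume] of modality `"ADC"`.
#' @return a [lesion_mask] aligned to `adc`.
#' @export
transfer_mask <- function(dwi_mask, adc) {
  stopifnot(inherits(dwi_mask, "lesion_mask"),
            inherits(adc, "image_volume"))
  same_grid <- identical(dim(dwi_mask$mask), dim(adc$values)) &&
    max(abs(dwi_mask$spacing - adc$spacing)) < 1e-9 &&
    max(abs(dwi_mask$origin - adc$origin)) < 1e-9
  if (same_grid) return(lesion_mask(dwi_mask$mask, adc))
  src <- image_volume(array(as.numeric(dwi_mask$mask),
                            dim = dim(dwi_mask$mask)),
                      dwi_mask$spacing, dwi_mask$origin,
                      modality = "DWI_B800")
  res <- resample_volume(src, adc$spacing, dim(adc$values),
                         origin = adc$origin, method = "nearest")
  m <- array(res$values > 0.5, dim = dim(res$values))
  if (!any(m)) stop("mask transfer produced an empty mask")
  lesion_mask(m, adc)
}

#' Configuration for histogram-based ADC ROI refinement
#'
#' @param bin_width histogram bin width in 1e-6 mm^2/s (default 50).
#' @param p_low fallback lower percentile in [0, 0.5) applied when the
#'   histogram has no empty-bin gap below its mode (default 0.01).
#' @return a `histogram_refine_config` list.
#' @export
histogram_refine_config <- function(bin_width = 50, p_low = 0.01) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (p_low < 0 || p_low >= 0.5) stop("p_low must be in [0, 0.5)")
  structure(list(bin_width = bin_width, p_low = p_low),
            class = "histogram_refine_config")
}

#' Refine an ADC ROI by removing low-value histogram outliers
#'
#' Bins the masked ADC values (bins anchored at 0), finds the widest run
#' of empty bins strictly below the histogram mode, and removes all
#' voxels strictly below the upper edge of that run; ties between equally
#' wide runs go to the run nearest the mode. Without any empty-bin gap,
#' voxels strictly below the `p_low` sample quantile are removed. The
#' mode bin is never removed.
#'
#' @param adc an [image_volume] of modality `"ADC"`.
#' @param mask a [lesion_mask] on the ADC grid.
#' @param cfg a [histogram_refine_config].
#' @return list with `mask` (refined [lesion_mask]), `removed` (voxel
#'   count) and `cutoff` (ADC value below which voxels were removed).
#' @export
refine_adc_roi <- function(adc, mask, cfg = histogram_refine_config()) {
  stopifnot(inherits(adc, "image_volume"), inherits(mask, "lesion_mask"))
  if (!identical(dim(adc$values), dim(mask$mask)))
    stop("mask and ADC volume must share a grid")
  vals <- adc$values[mask$mask]
  bw <- cfg$bin_width
  nbin <- floor(max(vals) / bw) + 1L
  bin <- pmin(floor(vals / bw) + 1L, nbin)  # bin b covers [(b-1)bw, b*bw)
  counts <- tabulate(bin, nbins = nbin)
  mode_bin <- which.max(counts)

  cutoff <- 0
  if (mode_bin > 1L) {
    below <- counts[seq_len(mode_bin - 1L)]
    r <- rle(below == 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    empty <- which(r$values)
    if (length(empty) > 0) {
      widths <- r$lengths[empty]
      best <- empty[widths == max(widths)]
      best <- best[length(best)]  # tie: run nearest the mode
      cutoff <- ends[best] * bw   # upper edge of the empty run
    }
  }
  if (cutoff == 0 && cfg$p_low > 0) {
    q <- stats::quantile(vals, cfg$p_low, names = FALSE)
    # never cut into the mode bin
    cutoff <- min(q, (mode_bin - 1L) * bw)
  }

  keep <- mask$mask & !(adc$values < cutoff & mask$mask)
  removed <- sum(mask$mask) - sum(keep)
  if (!any(keep)) stop("refinement would empty the mask")
  parent <- image_volume(adc$values, adc$spacing, adc$origin,
                         modality = "ADC")
  list(mask = lesion_mask(keep, parent), removed = removed,
       cutoff = cutoff)
}

#' Lesion volume from a mask
#'
#' True-voxel count times voxel volume, in cm^3.
#'
#' @param mask a [lesion_mask].
#' @return volume in cm^3.
#' @export
tumor_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  n <- sum(mask$mask)
  if (n == 0) stop("empty mask")
  n * prod(mask$spacing) / 1000
}

#' Maximum lesion diameter in 3D
#'
#' Largest pairwise Euclidean distance between centers of mask voxels,
#' computed over boundary voxels (which contain all extremal voxels).
#'
#' @param mask a [lesion_mask].
#' @return diameter in mm (0 for a single voxel).
#' @export
max_diameter <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (!any(mask$mask)) stop("empty mask")
  b <- which(boundary_voxels(mask$mask), arr.ind = TRUE)
  pts <- sweep(sweep(b - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
  n <- nrow(pts)
  if (n == 1) return(0)
  sq <- rowSums(pts^2)
  best <- 0
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    cross <- pts[s:e, , drop = FALSE] %*% t(pts)
    d2 <- outer(sq[s:e], sq, "+") - 2 * cross
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}
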