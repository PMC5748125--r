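#' Axis-aligned 3D image volume
#'
#' Container for a scalar 3D image on a regular, axis-aligned grid, the
#' common currency of the package. Geometry follows the voxel-center
#' convention: the world position (mm) of voxel `(i, j, k)` (1-based) is
#' `origin + (c(i, j, k) - 1) * spacing`, with axes ordered (x, y, z).
#'
#' @param values numeric 3D array. SUV is unitless, ADC is in
#'   1e-6 mm^2/s, DWI b=800 magnitude is in arbitrary units.
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of the center of
#'   voxel (1, 1, 1).
#' @param modality one of `"SUV"`, `"ADC"`, `"DWI_B800"`. ADC volumes must
#'   be non-negative.
#' @return An object of class `image_volume`: a list with elements
#'   `values`, `spacing`, `origin`, `modality`.
#' @examples
#' v <- image_volume(array(1, c(4, 4, 4)), spacing = c(5, 5, 3.27),
#'                   modality = "SUV")
#' world_coords(v, c(1, 1, 1))
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0),
                         modality = c("SUV", "ADC", "DWI_B800")) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) < 1L))
    stop("all three dimensions must be positive")
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  if (modality == "ADC" && any(values < 0))
    stop("ADC volumes must be non-negative")
  structure(list(values = values, spacing = spacing, origin = origin,
                 modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing %s mm, origin %s mm\n",
              x$modality, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' Binary lesion mask aligned to a parent volume
#'
#' A volume of interest (VOI): logical array with the same shape and
#' geometry as the volume it was drawn on.
#'
#' @param mask logical (or 0/1 numeric) 3D array with at least one `TRUE`.
#' @param parent an [image_volume] supplying shape, spacing and origin.
#' @return An object of class `lesion_mask` with elements `mask`,
#'   `spacing`, `origin`.
#' @export
lesion_mask <- function(mask, parent) {
  stopifnot(inherits(parent, "image_volume"))
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("numeric mask must contain only 0/1")
    mask <- array(mask == 1, dim = dim(mask))
  }
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a logical 3D array")
  if (!identical(dim(mask), dim(parent$values)))
    stop("mask shape must match its parent volume")
  if (anyNA(mask)) stop("mask must not contain NA")
  if (!any(mask)) stop("mask must contain at least one TRUE voxel")
  structure(list(mask = mask, spacing = parent$spacing,
                 origin = parent$origin),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d/%s voxels, spacing %s mm\n",
              sum(x$mask), prod(dim(x$mask)),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Rigid 3D translation vector
#'
#' The frame convention throughout the package: a translation maps MRI
#' world coordinates into the PET world frame,
#' `point_PET = point_MRI + t`.
#'
#' @param dx,dy,dz finite displacements in mm.
#' @return numeric length-3 vector `c(dx, dy, dz)`.
#' @export
translation_vector <- function(dx, dy, dz) {
  t <- c(dx, dy, dz)
  if (length(t) != 3L || !all(is.finite(t)))
    stop("translation components must be 3 finite numbers")
  as.numeric(t)
}

# coerce points to an n x 3 numeric matrix
as_points <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) %% 3L != 0L) stop("points must have 3 coordinates")
    p <- matrix(as.numeric(p), ncol = 3L, byrow = TRUE)
  }
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("points must be an n x 3 matrix")
  p
}

#' World coordinates of voxel indices
#'
#' @param volume an [image_volume] or [lesion_mask].
#' @param index integer voxel index triple (1-based), or an n x 3 matrix
#'   of them.
#' @return numeric length-3 vector (or n x 3 matrix) of world mm
#'   coordinates of the voxel center(s).
#' @export
world_coords <- function(volume, index) {
  idx <- as_points(index)
  shp <- if (inherits(volume, "lesion_mask")) dim(volume$mask)
         else dim(volume$values)
  if (any(idx < 1) || any(idx > matrix(shp, nrow(idx), 3, byrow = TRUE)) ||
      any(idx != round(idx)))
    stop("voxel index out of bounds")
  w <- sweep(sweep(idx - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
  if (nrow(w) == 1L) drop(w) else w
}

#' Nearest voxel index to a world point
#'
#' @param volume an [image_volume] or [lesion_mask].
#' @param point world mm triple (or n x 3 matrix).
#' @param strict error when the point lies outside the volume extent
#'   (voxel centers padded by half a voxel); when `FALSE` the index is
#'   clamped to the grid.
#' @return integer voxel index triple (or n x 3 matrix).
#' @export
nearest_voxel <- function(volume, point, strict = TRUE) {
  p <- as_points(point)
  shp <- if (inherits(volume, "lesion_mask")) dim(volume$mask)
         else dim(volume$values)
  cont <- sweep(sweep(p, 2, volume$origin, "-"), 2, volume$spacing, "/") + 1
  if (strict) {
    lo <- 0.5; hi <- matrix(shp + 0.5, nrow(cont), 3, byrow = TRUE)
    if (any(cont < lo) || any(cont > hi))
      stop("point lies outside the volume extent")
  }
  idx <- round(cont)
  idx <- pmax(idx, 1L)
  idx <- pmin(idx, matrix(shp, nrow(idx), 3, byrow = TRUE))
  storage.mode(idx) <- "integer"
  if (nrow(idx) == 1L) drop(idx) else idx
}

#' Apply a rigid translation to world points
#'
#' Componentwise sum; `apply_translation(p, t)` followed by
#' `apply_translation(., -t)` is the identity.
#'
#' @param point world mm triple or n x 3 matrix.
#' @param t [translation_vector] (numeric length-3, mm).
#' @return translated point(s), same shape as the input.
#' @export
apply_translation <- function(point, t) {
  t <- as.numeric(t)
  if (length(t) != 3L || !all(is.finite(t))) stop("invalid translation")
  p <- as_points(point)
  if (!all(is.finite(p))) stop("points must be finite")
  out <- sweep(p, 2, t, "+")
  if (nrow(out) == 1L) drop(out) else out
}

# Vectorized sampling of an image_volume at arbitrary world points.
# method "trilinear" or "nearest"; points outside the source extent get
# `fill` (default 0, emulating air/lung background).
sample_at <- function(volume, points, method = c("trilinear", "nearest"),
                      fill = 0) {
  method <- match.arg(method)
  p <- as_points(points)
  shp <- dim(volume$values)
  # continuous 1-based voxel coordinate
  cont <- sweep(sweep(p, 2, volume$origin, "-"), 2, volume$spacing, "/") + 1
  out <- rep(as.numeric(fill), nrow(p))
  if (method == "nearest") {
    idx <- round(cont)
    ok <- idx[, 1] >= 1 & idx[, 1] <= shp[1] &
          idx[, 2] >= 1 & idx[, 2] <= shp[2] &
          idx[, 3] >= 1 & idx[, 3] <= shp[3]
    if (any(ok)) {
      lin <- (idx[ok, 3] - 1) * shp[1] * shp[2] +
             (idx[ok, 2] - 1) * shp[1] + idx[ok, 1]
      out[ok] <- volume$values[lin]
    }
    return(out)
  }
  # trilinear: valid where the 8-neighbour cell is inside the grid
  ok <- cont[, 1] >= 1 & cont[, 1] <= shp[1] &
        cont[, 2] >= 1 & cont[, 2] <= shp[2] &
        cont[, 3] >= 1 & cont[, 3] <= shp[3]
  if (!any(ok)) return(out)
  c0 <- cont[ok, , drop = FALSE]
  f <- pmin(floor(c0), matrix(shp - 1L, nrow(c0), 3, byrow = TRUE))
  f <- pmax(f, 1)
  d <- c0 - f
  v <- volume$values
  lin <- function(ix, iy, iz) {
    v[(iz - 1) * shp[1] * shp[2] + (iy - 1) * shp[1] + ix]
  }
  x0 <- f[, 1]; y0 <- f[, 2]; z0 <- f[, 3]
  x1 <- pmin(x0 + 1, shp[1]); y1 <- pmin(y0 + 1, shp[2])
  z1 <- pmin(z0 + 1, shp[3])
  wx <- d[, 1]; wy <- d[, 2]; wz <- d[, 3]
  val <-
    lin(x0, y0, z0) * (1 - wx) * (1 - wy) * (1 - wz) +
    lin(x1, y0, z0) * wx       * (1 - wy) * (1 - wz) +
    lin(x0, y1, z0) * (1 - wx) * wy       * (1 - wz) +
    lin(x1, y1, z0) * wx       * wy       * (1 - wz) +
    lin(x0, y0, z1) * (1 - wx) * (1 - wy) * wz +
    lin(x1, y0, z1) * wx       * (1 - wy) * wz +
    lin(x0, y1, z1) * (1 - wx) * wy       * wz +
    lin(x1, y1, z1) * wx       * wy       * wz
  out[ok] <- val
  out
}

#' Resample a volume onto a new axis-aligned grid
#'
#' Trilinear interpolation for intensity volumes, nearest neighbour for
#' label-like data. Target voxel centers falling outside the source extent
#' are filled with 0 (air/lung background).
#'
#' @param volume an [image_volume].
#' @param spacing target per-axis voxel size (mm, > 0).
#' @param shape target integer dimensions.
#' @param origin target origin (mm); defaults to the source origin.
#' @param method `"trilinear"` or `"nearest"`.
#' @return an [image_volume] on the target grid, same modality.
#' @export
resample_volume <- function(volume, spacing, shape, origin = volume$origin,
                            method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(volume, "image_volume"))
  spacing <- as.numeric(spacing); shape <- as.integer(shape)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("target spacing must be 3 positive numbers")
  if (length(shape) != 3L || any(shape < 1L))
    stop("target shape must be 3 positive integers")
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  pts <- sweep(sweep(as.matrix(g) - 1, 2, spacing, "*"), 2,
               as.numeric(origin), "+")
  vals <- sample_at(volume, pts, method = method, fill = 0)
  image_volume(array(vals, dim = shape), spacing = spacing,
               origin = origin, modality = volume$modality)
}

#' Read an axis-aligned volume from a NIfTI file
#'
#' Only diagonal (axis-aligned, positively oriented) affines are supported;
#' spacing is taken from the affine diagonal and the origin from its
#' translation column.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param modality modality tag to attach (`"SUV"`, `"ADC"`, `"DWI_B800"`).
#' @return an [image_volume].
#' @export
read_nifti <- function(path, modality = c("SUV", "ADC", "DWI_B800")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  m <- aff[1:3, 1:3]
  offdiag <- m; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(m)))) || any(diag(m) <= 0))
    stop("unsupported orientation: only diagonal, positively oriented ",
         "affines are handled")
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  image_volume(vals, spacing = diag(m), origin = aff[1:3, 4],
               modality = modality)
}

#' Write a volume or mask to a NIfTI file
#'
#' Geometry is stored as a diagonal affine in both qform and sform; values
#' are written as float32 (masks as uint8).
#'
#' @param x an [image_volume] or [lesion_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "lesion_mask")) {
    vals <- array(as.integer(x$mask), dim = dim(x$mask))
    dtype <- "uint8"
  } else if (inherits(x, "image_volume")) {
    vals <- x$values
    dtype <- "float"
  } else stop("`x` must be an image_volume or lesion_mask")
  img <- RNifti::asNifti(vals,
    reference = list(pixdim = c(1, x$spacing, 1, 1, 1, 1)))
  aff <- diag(c(x$spacing, 1))
  aff[1:3, 4] <- x$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Read a binary mask from a NIfTI file
#'
#' @param path path to a NIfTI mask with values in {0, 1}.
#' @param parent [image_volume] the mask belongs to; its geometry must
#'   match the file's.
#' @return a [lesion_mask].
#' @export
read_nifti_mask <- function(path, parent) {
  v <- read_nifti(path, modality = "DWI_B800")  # tag irrelevant for masks
  if (!identical(dim(v$values), dim(parent$values)) ||
      max(abs(v$spacing - parent$spacing)) > 1e-4 ||
      max(abs(v$origin - parent$origin)) > 1e-3)
    stop("mask geometry does not match its parent volume")
  lesion_mask(array(v$values > 0.5, dim = dim(v$values)), parent)
}
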