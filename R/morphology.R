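# Internal 3D binary morphology on logical arrays.
# Connectivity is 26-neighbour throughout; all routines are vectorized
# frontier/stencil expansions so masks of ~1e5 voxels stay fast in pure R.

# 26-connected neighbour offsets (rows of a 26 x 3 matrix)
neighbour_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# Flood fill: 26-connected component of `candidates` containing seed_idx.
# candidates: logical 3D array; seed_idx: integer triple (1-based).
# Returns a logical array of the same shape.
flood_fill_26 <- function(candidates, seed_idx) {
  shp <- dim(candidates)
  seed_idx <- as.integer(seed_idx)
  if (!candidates[seed_idx[1], seed_idx[2], seed_idx[3]])
    stop("seed voxel is not a candidate")
  off <- neighbour_offsets_26()
  visited <- array(FALSE, dim = shp)
  visited[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  frontier <- matrix(seed_idx, nrow = 1)
  lin <- function(ix) (ix[, 3] - 1) * shp[1] * shp[2] +
                      (ix[, 2] - 1) * shp[1] + ix[, 1]
  while (nrow(frontier) > 0) {
    n <- nrow(frontier)
    nb <- frontier[rep(seq_len(n), each = 26), , drop = FALSE] +
          off[rep(seq_len(26), times = n), , drop = FALSE]
    ok <- nb[, 1] >= 1 & nb[, 1] <= shp[1] &
          nb[, 2] >= 1 & nb[, 2] <= shp[2] &
          nb[, 3] >= 1 & nb[, 3] <= shp[3]
    nb <- nb[ok, , drop = FALSE]
    if (nrow(nb) == 0) break
    li <- lin(nb)
    keep <- candidates[li] & !visited[li]
    li <- unique(li[keep])
    if (length(li) == 0) break
    visited[li] <- TRUE
    k3 <- (li - 1) %/% (shp[1] * shp[2])
    r <- (li - 1) %% (shp[1] * shp[2])
    frontier <- cbind(r %% shp[1] + 1, r %/% shp[1] + 1, k3 + 1)
  }
  visited
}

# TRUE when the mask forms a single 26-connected component.
is_single_component_26 <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) return(FALSE)
  comp <- flood_fill_26(mask, w[1, ])
  sum(comp) == nrow(w)
}

# Stencil offsets (voxel steps) whose world displacement is <= radius_mm
# for the given anisotropic spacing; excludes the zero offset.
stencil_offsets_mm <- function(spacing, radius_mm) {
  k <- floor(radius_mm / spacing)
  g <- as.matrix(expand.grid(dx = -k[1]:k[1], dy = -k[2]:k[2],
                             dz = -k[3]:k[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
        (g[, 3] * spacing[3])^2
  g[d2 <= radius_mm^2 & d2 > 0, , drop = FALSE]
}

# Dilate a logical array by a world-space (mm) ball under anisotropic
# spacing. Returns the dilated logical array.
dilate_mm <- function(mask, spacing, radius_mm) {
  off <- stencil_offsets_mm(spacing, radius_mm)
  if (nrow(off) == 0) return(mask)
  shp <- dim(mask)
  w <- which(mask, arr.ind = TRUE)
  n <- nrow(w)
  nb <- w[rep(seq_len(n), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = n), , drop = FALSE]
  ok <- nb[, 1] >= 1 & nb[, 1] <= shp[1] &
        nb[, 2] >= 1 & nb[, 2] <= shp[2] &
        nb[, 3] >= 1 & nb[, 3] <= shp[3]
  nb <- nb[ok, , drop = FALSE]
  out <- mask
  out[nb] <- TRUE
  out
}

# Boundary voxels: TRUE voxels with at least one FALSE (or out-of-array)
# 6-neighbour. 6-connectivity is enough for diameter candidates: the
# extreme voxels of any mask are 6-boundary voxels.
boundary_voxels <- function(mask) {
  shp <- dim(mask)
  pad <- array(FALSE, dim = shp + 2L)
  pad[2:(shp[1] + 1), 2:(shp[2] + 1), 2:(shp[3] + 1)] <- mask
  interior <-
    pad[1:shp[1], 2:(shp[2] + 1), 2:(shp[3] + 1)] &
    pad[3:(shp[1] + 2), 2:(shp[2] + 1), 2:(shp[3] + 1)] &
    pad[2:(shp[1] + 1), 1:shp[2], 2:(shp[3] + 1)] &
    pad[2:(shp[1] + 1), 3:(shp[2] + 2), 2:(shp[3] + 1)] &
    pad[2:(shp[1] + 1), 2:(shp[2] + 1), 1:shp[3]] &
    pad[2:(shp[1] + 1), 2:(shp[2] + 1), 3:(shp[3] + 2)]
  mask & !interior
}
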