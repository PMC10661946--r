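#' A 3D voxel grid with anisotropic spacing
#'
#' The basic image container of the package: a 3D array (binary mask or
#' intensity values) together with its voxel size in micrometres. The axis
#' order is `(z, y, x)`, matching confocal stacks sampled coarsely in z
#' (sections every 2 um) and finely in xy. World positions in micrometres sit
#' at voxel centres: the 1-based voxel `(i, j, k)` is centred at
#' `((i - 0.5) * dz, (j - 0.5) * dy, (k - 0.5) * dx)`.
#'
#' @param values 3D array; logical (or 0/1 numeric) for masks, numeric within
#'   `[0, bit_max]` for intensity channels.
#' @param voxel_size_um positive numeric triple `(dz, dy, dx)` in micrometres.
#' @param channel_name label for the channel (e.g. `"endothelium"`).
#' @param bit_max maximum representable intensity; 4095 for the 12-bit
#'   effective range of the acquisition this package targets.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, voxel_size_um, channel_name = "",
                       bit_max = 4095) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) < 1L))
    stop("all dimensions must be >= 1")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be a positive numeric triple (dz, dy, dx)")
  if (is.logical(values)) {
    mask <- TRUE
  } else {
    u <- unique(as.vector(values))
    mask <- all(u %in% c(0, 1))
    if (!mask) {
      rng <- range(values)
      if (rng[1] < 0 || rng[2] > bit_max)
        stop(sprintf("intensity values outside declared range [0, %d]", bit_max))
    }
  }
  structure(
    list(values = values, voxel_size_um = voxel_size_um,
         channel_name = channel_name, bit_max = bit_max, is_mask = mask),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid '%s'> %d x %d x %d voxels (z,y,x), %.3g x %.3g x %.3g um, %s\n",
              x$channel_name, d[1], d[2], d[3],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3],
              if (x$is_mask) sprintf("mask (%d fg)", sum(x$values != 0))
              else sprintf("intensity in [%.0f, %.0f]", min(x$values), max(x$values))))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

# Accept a voxel_grid or a bare array; return the array.
vg_values <- function(x) {
  if (inherits(x, "voxel_grid")) x$values else x
}

# Logical mask array from a voxel_grid or array.
vg_mask <- function(x) {
  v <- vg_values(x)
  if (!is.logical(v)) v <- v != 0
  v
}

vg_spacing <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, "voxel_grid")) x$voxel_size_um else default
}

# Voxel volume in um^3.
vg_voxvol <- function(x) prod(vg_spacing(x))

check_same_geometry <- function(a, b, what = "grids") {
  if (!identical(dim(vg_values(a)), dim(vg_values(b))))
    stop(sprintf("%s must share the same shape", what))
  if (inherits(a, "voxel_grid") && inherits(b, "voxel_grid") &&
      !isTRUE(all.equal(a$voxel_size_um, b$voxel_size_um)))
    stop(sprintf("%s must share the same voxel size", what))
  invisible(TRUE)
}

# World coordinates (um) of 1-based voxel indices (n x 3 matrix, (z,y,x)).
voxel_to_um <- function(idx, spacing) {
  sweep(idx - 0.5, 2L, spacing, `*`)
}
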