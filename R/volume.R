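#' Tomographic volume container
#'
#' A `tomo_volume` couples a 3D density grid with its physical voxel size
#' and origin. Coordinates are physical (nanometres) throughout the package;
#' the voxel with array index `(i, j, k)` (1-based in R) is centred at
#' `origin + (c(i, j, k) - 1) * voxel_size`, i.e. 0-based voxel centres sit
#' at integer multiples of the voxel size from the origin. Axis conventions:
#' dimension 1 = x, 2 = y (tilt axis of the simulated acquisition),
#' 3 = z (beam direction).
#'
#' @param grid numeric 3D array of densities.
#' @param voxel_size voxel edge length in nm (> 0).
#' @param origin physical position (nm) of the centre of voxel `(1, 1, 1)`.
#' @param metadata free-form provenance list.
#' @return An object of class `tomo_volume`.
#' @examples
#' v <- tomo_volume(array(0, c(8, 8, 8)), voxel_size = 1)
#' dim(v$grid)
#' @export
tomo_volume <- function(grid, voxel_size, origin = c(0, 0, 0),
                        metadata = list()) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("grid must be a 3D array")
  if (any(dim(grid) < 1L)) stop("grid dimensions must all be >= 1")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number (nm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite length-3 vector (nm)")
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin), metadata = metadata),
            class = "tomo_volume")
}

#' @export
print.tomo_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<tomo_volume> %d x %d x %d voxels @ %.4g nm\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  extent: %.1f x %.1f x %.1f nm, origin (%.1f, %.1f, %.1f) nm\n",
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density range: [%.4g, %.4g]\n",
              min(x$grid), max(x$grid)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

# World (nm) -> continuous 1-based array index coordinates.
world_to_index <- function(vol, pts) {
  pts <- rbind(pts)
  sweep(pts, 2, vol$origin, `-`) / vol$voxel_size + 1
}

# Physical coordinates (nm) of voxel centres along each axis.
vol_axes <- function(vol) {
  d <- dim(vol$grid)
  lapply(1:3, function(i) vol$origin[i] + (seq_len(d[i]) - 1) * vol$voxel_size)
}
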