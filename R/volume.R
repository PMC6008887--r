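#' 3D image volume with physical geometry
#'
#' Container for a 3D scalar field together with its voxel spacing (mm) and the
#' world position of the first voxel center. The world-coordinate convention is
#' voxel-center, 0-based: \code{world(v) = origin + v * spacing} for an integer
#' voxel index \code{v}. All distances are millimetres; intensities are
#' unitless. Volumes are axis-aligned (no direction matrix).
#'
#' @param data 3D numeric array.
#' @param spacing Per-axis voxel size in mm, length 3, strictly positive.
#' @param origin World position (mm) of the center of voxel (0,0,0), length 3.
#' @param frame_id Free-text label of the reference frame.
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         frame_id = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin,
                 frame_id = as.character(frame_id)[1]),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing: %s mm\n", paste(signif(x$spacing, 6), collapse = " x ")))
  cat(sprintf("  origin:  (%s) mm\n", paste(signif(x$origin, 6), collapse = ", ")))
  if (nzchar(x$frame_id)) cat(sprintf("  frame:   %s\n", x$frame_id))
  rng <- range(x$data)
  cat(sprintf("  range:   [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

is_image_volume <- function(x) inherits(x, "image_volume")

as_volume_array <- function(x) {
  if (is_image_volume(x)) x$data else x
}

#' Map voxel indices to world coordinates
#'
#' @param vol An \code{image_volume}.
#' @param voxels n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, voxels) {
  voxels <- rbind(voxels)
  sweep(sweep(voxels, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Map world coordinates to (fractional, 0-based) voxel indices
#'
#' @param vol An \code{image_volume}.
#' @param points n x 3 matrix of world coordinates in mm.
#' @return n x 3 matrix of 0-based voxel indices.
#' @export
world_to_voxel <- function(vol, points) {
  points <- rbind(points)
  sweep(sweep(points, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

# Shared-grid check used by operations that combine two volumes.
check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-9)
    stop("volumes are not on the same grid")
  invisible(TRUE)
}
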