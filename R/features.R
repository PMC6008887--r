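#' Per-voxel feature field for the bone classifier
#'
#' For every voxel the 5-vector (I, E, mu, var, skew): the raw intensity, the
#' sheet-enhanced value, and the mean, population variance and skewness (third
#' standardized moment) of the enhanced values in a cubic window centered on
#' the voxel. Windows use reflect padding; skewness is defined as 0 where the
#' window variance is zero (constant shadow regions would otherwise be
#' undefined).
#'
#' @param raw Raw \code{image_volume}.
#' @param enhanced Sheet-enhanced \code{image_volume} on the same grid.
#' @param window Odd cubic window edge length, default 9.
#' @return Object of class \code{voxel_features}: arrays \code{i_raw, e_val,
#'   mu, var, skew} plus grid attributes.
#' @export
extract_features <- function(raw, enhanced, window = 9L) {
  if (!is_image_volume(raw)) raw <- image_volume(raw)
  if (!is_image_volume(enhanced))
    enhanced <- image_volume(enhanced, spacing = raw$spacing, origin = raw$origin)
  check_same_grid(raw, enhanced)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("`window` must be odd and positive")
  m <- .window_moments(enhanced$data, dim(enhanced$data), window)
  out <- list(i_raw = raw$data, e_val = enhanced$data,
              mu = m$mu, var = m$var, skew = m$skew)
  attr(out, "spacing") <- raw$spacing
  attr(out, "origin") <- raw$origin
  attr(out, "window") <- window
  class(out) <- "voxel_features"
  out
}

#' Flatten a feature field to an n x 5 matrix
#'
#' @param features A \code{voxel_features} object (or an n x 5 matrix, passed
#'   through).
#' @return n x 5 matrix with columns \code{i, e, mu, var, skew}.
#' @export
feature_matrix <- function(features) {
  if (is.matrix(features)) {
    if (ncol(features) != 5L) stop("feature matrix must have 5 columns")
    colnames(features) <- c("i", "e", "mu", "var", "skew")
    return(features)
  }
  if (!inherits(features, "voxel_features"))
    stop("`features` must be a voxel_features object or n x 5 matrix")
  cbind(i = as.vector(features$i_raw), e = as.vector(features$e_val),
        mu = as.vector(features$mu), var = as.vector(features$var),
        skew = as.vector(features$skew))
}
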