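#' Select region-growing seeds from the classified bone mask
#'
#' Takes the 0.01 percent (fraction 1e-4, floor of one) of classified bone
#' voxels with the highest bone score. Ties are broken by ascending linear
#' voxel index so the selection is deterministic.
#'
#' @param mask Binary bone mask (\code{image_volume} or 3D array).
#' @param scores Bone-score volume on the same grid.
#' @param fraction Fraction of bone voxels to keep, default 1e-4.
#' @return List with \code{index} (linear 1-based), \code{ijk} (1-based voxel
#'   indices), \code{scores} and \code{n_bone}.
#' @export
select_seeds <- function(mask, scores, fraction = 1e-4) {
  m <- as_volume_array(mask)
  s <- as_volume_array(scores)
  if (!identical(dim(m), dim(s))) stop("mask and scores are not on the same grid")
  idx <- which(m != 0)
  n <- length(idx)
  if (n == 0L) stop("no bone voxels: cannot select seeds")
  k <- max(1L, as.integer(ceiling(fraction * n)))
  sc <- s[idx]
  ord <- order(-sc, idx)[seq_len(k)]
  sel <- idx[ord]
  list(index = sel, ijk = arrayInd(sel, dim(m)), scores = s[sel], n_bone = n)
}

#' Seeded region growing on the classified mask
#'
#' Returns the union of the 26-connected components of the mask that contain
#' at least one seed; growth never leaves the classified mask.
#'
#' @param mask Binary mask (\code{image_volume} or array).
#' @param seeds A seed set from [select_seeds()] (or vector of linear 1-based
#'   indices into the mask).
#' @return Binary array (or \code{image_volume} if the input was one) of the
#'   grown region.
#' @export
region_grow <- function(mask, seeds) {
  m <- as_volume_array(mask)
  idx <- if (is.list(seeds)) seeds$index else as.integer(seeds)
  grown <- .region_grow(array(as.integer(m != 0), dim(m)), dim(m),
                        as.integer(idx) - 1L)
  grown <- array(as.numeric(grown), dim(m))
  if (is_image_volume(mask))
    image_volume(grown, spacing = mask$spacing, origin = mask$origin,
                 frame_id = mask$frame_id)
  else grown
}

#' Extract a triangle mesh from a binary mask
#'
#' Isosurface of the mask at the given level (default 0.5, the midpoint of a
#' 0/1 mask) with linearly interpolated vertex positions, mapped to world
#' millimetres through the volume's spacing and origin. Ultrasound cortical
#' surfaces are open sheets, so the mesh is not required to be watertight.
#'
#' @param mask Binary \code{image_volume} (or array; unit spacing).
#' @param iso Iso level, default 0.5.
#' @param label Role tag for the mesh.
#' @return A \code{surface_mesh}.
#' @export
extract_mesh <- function(mask, iso = 0.5, label = "US-intraop") {
  if (!is_image_volume(mask)) mask <- image_volume(mask)
  if (all(mask$data <= iso)) stop("empty mask: no isosurface")
  res <- .iso_surface(mask$data, dim(mask$data), iso)
  verts <- voxel_to_world(mask, res$vertices)
  surface_mesh(verts, res$faces, label = label)
}

#' Segment the bone cortical surface in an ultrasound volume
#'
#' Full pipeline: sheet enhancement, feature extraction, Gaussian Bayes
#' classification, probability-ranked seed selection, 26-connected region
#' growing, and isosurface meshing. Deterministic for fixed inputs and model.
#'
#' @param raw Raw ultrasound \code{image_volume}.
#' @param model A \code{bone_qda} fit (or path to a model JSON).
#' @param sigma_mm Sheetness scale; defaults to the model's recorded value.
#' @param window Feature window; defaults to the model's recorded value.
#' @param seed_fraction Seed fraction, default 1e-4.
#' @param keep_volumes Keep the enhanced and score volumes in the result
#'   (large); default FALSE.
#' @return Object of class \code{bone_segmentation}: grown \code{mask}
#'   (\code{image_volume}), \code{mesh} (\code{surface_mesh}), seed set and
#'   voxel counts.
#' @export
segment_bone <- function(raw, model, sigma_mm = NULL, window = NULL,
                         seed_fraction = 1e-4, keep_volumes = FALSE) {
  if (is.character(model)) model <- read_model(model)
  if (!inherits(model, "bone_qda")) stop("`model` must be a bone_qda fit")
  sigma_mm <- sigma_mm %||% model$sigma_mm %||% 0.5
  window <- window %||% model$window %||% 9L

  enhanced <- enhance_volume(raw, sigma_mm = sigma_mm,
                             alpha = model$alpha, gamma = model$gamma)
  feats <- extract_features(raw, enhanced, window = window)
  cls <- classify_volume(feats, model)
  if (sum(cls$mask$data) == 0)
    stop("no bone voxels classified in this volume")
  seeds <- select_seeds(cls$mask, cls$score, fraction = seed_fraction)
  grown <- region_grow(cls$mask, seeds)
  mesh <- extract_mesh(grown, label = "US-intraop")

  out <- list(mask = grown, mesh = mesh, seeds = seeds,
              n_classified = sum(cls$mask$data), n_grown = sum(grown$data),
              sigma_mm = sigma_mm, window = window)
  if (keep_volumes) {
    out$enhanced <- enhanced
    out$score <- cls$score
    out$classified_mask <- cls$mask
  }
  class(out) <- "bone_segmentation"
  out
}

#' @export
print.bone_segmentation <- function(x, ...) {
  cat("<bone_segmentation>\n")
  cat(sprintf("  classified bone voxels: %d; grown: %d (%.1f%%)\n",
              x$n_classified, x$n_grown, 100 * x$n_grown / max(1, x$n_classified)))
  cat(sprintf("  seeds: %d; sheetness sigma: %g mm; window: %d^3\n",
              length(x$seeds$index), x$sigma_mm, x$window))
  cat(sprintf("  mesh: %d vertices, %d faces\n",
              nrow(x$mesh$vertices), nrow(x$mesh$faces)))
  invisible(x)
}
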