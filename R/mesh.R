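#' Triangle surface mesh in world coordinates
#'
#' Vertices are always stored in world millimetres (never voxel units), so
#' meshes derived from ultrasound and from CT live in the same metric space and
#' registration treats them identically. Zero-area triangles are removed at
#' construction.
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param label Role tag, e.g. "US-intraop", "CT-preop", "CT-intraop", "CT-ref".
#' @return An object of class \code{surface_mesh}.
#' @export
surface_mesh <- function(vertices, faces, label = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must be n x 3")
  if (nrow(faces) > 0 && ncol(faces) != 3L) stop("`faces` must be m x 3")
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    a <- vertices[faces[, 1], , drop = FALSE]
    e1 <- vertices[faces[, 2], , drop = FALSE] - a
    e2 <- vertices[faces[, 3], , drop = FALSE] - a
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    area2 <- cx * cx + cy * cy + cz * cz
    keep <- area2 > 1e-24
    faces <- faces[keep, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces,
                 label = as.character(label)[1]),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh>%s %d vertices, %d faces\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$vertices) > 0) {
    bb <- apply(x$vertices, 2, range)
    cat(sprintf("  bbox: [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(x)
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh A \code{surface_mesh}.
#' @param transform A \code{rigid_transform}.
#' @param label Optional new role tag.
#' @return The transformed \code{surface_mesh}.
#' @export
transform_mesh <- function(mesh, transform, label = mesh$label) {
  surface_mesh(rt_apply(transform, mesh$vertices), mesh$faces, label = label)
}
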