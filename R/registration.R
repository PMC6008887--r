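#' Rigid transform (rotation + translation) on world coordinates
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation Length-3 translation in mm.
#' @return Object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!identical(dim(rotation), c(3L, 3L))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0) stop("rotation has det -1 (reflection)")
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("translation must be 3 finite values")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Compose two rigid transforms: \code{rt_compose(a, b)(x) = a(b(x))}
#' @param a,b \code{rigid_transform}s.
#' @return The composed \code{rigid_transform}.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param tr A \code{rigid_transform}.
#' @return The inverse \code{rigid_transform}.
#' @export
rt_invert <- function(tr) {
  rigid_transform(t(tr$R), as.vector(-t(tr$R) %*% tr$t))
}

#' Apply a rigid transform to points
#' @param tr A \code{rigid_transform}.
#' @param pts n x 3 matrix of points (mm).
#' @return n x 3 matrix of transformed points.
#' @export
rt_apply <- function(tr, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(tr$R), 2, tr$t, "+")
}

#' Least-squares rigid alignment of paired points (orthogonal Procrustes)
#'
#' Closed-form rigid transform minimizing \eqn{\sum_i \|T(src_i) - dst_i\|^2}
#' (Kabsch/Umeyama with reflection guard). Requires at least 3 non-collinear
#' pairs.
#'
#' @param src,dst n x 3 matrices of corresponding points.
#' @return A \code{rigid_transform} mapping src onto dst.
#' @export
landmark_align <- function(src, dst) {
  src <- rbind(src); dst <- rbind(dst)
  if (nrow(src) != nrow(dst)) stop("point sets differ in size")
  if (nrow(src) < 3L) stop("need at least 3 point pairs")
  if (any(!is.finite(src)) || any(!is.finite(dst))) stop("non-finite points")
  cs <- colMeans(src); cd <- colMeans(dst)
  sc <- sweep(src, 2, cs); dc <- sweep(dst, 2, cd)
  H <- crossprod(sc, dc)
  sv <- svd(H)
  # degenerate geometry: all points (nearly) on a line
  spread <- svd(sc, nu = 0, nv = 0)$d
  if (spread[2] <= 1e-9 * max(spread[1], 1))
    stop("geometry error: source points are collinear or coincident")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  rigid_transform(R, cd - as.vector(R %*% cs))
}

# run `expr` under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random vertex subsample of a mesh
#'
#' Samples \code{min(n, #vertices)} vertices uniformly without replacement,
#' deterministically for a given seed (the caller's RNG state is untouched).
#'
#' @param mesh A \code{surface_mesh}.
#' @param n Target number of points, default 2000.
#' @param seed RNG seed, default 0.
#' @return m x 3 matrix of sampled vertex positions.
#' @export
subsample_mesh <- function(mesh, n = 2000L, seed = 0L) {
  nv <- nrow(mesh$vertices)
  if (nv == 0L) stop("empty mesh")
  if (nv <= n) return(mesh$vertices)
  keep <- with_seed(seed, sample.int(nv, n))
  mesh$vertices[keep, , drop = FALSE]
}

#' Iterative closest point rigid registration (point-to-point)
#'
#' Classic ICP: nearest-neighbour correspondences (exact, kd-tree), closed-form
#' rigid update by orthogonal Procrustes, iterated until the RMS closest-point
#' distance changes by less than \code{tol} or \code{max_iter} is reached.
#' \code{rms_history[k]} is the RMS nearest-neighbour distance under the
#' transform of iteration k; it is non-increasing after the first entry.
#'
#' @param moving,fixed n x 3 point matrices (mm).
#' @param init Initial \code{rigid_transform} applied to \code{moving}.
#' @param max_iter Iteration cap, default 200.
#' @param tol RMS change threshold in mm, default 1e-6.
#' @return Object of class \code{icp_registration}: \code{transform} (maps
#'   moving to fixed), \code{rms_history}, \code{iterations},
#'   \code{converged}, final \code{rms}.
#' @export
icp <- function(moving, fixed, init = rigid_transform(), max_iter = 200L,
                tol = 1e-6) {
  moving <- rbind(moving); fixed <- rbind(fixed)
  if (nrow(moving) < 3L || nrow(fixed) < 3L) stop("need at least 3 points per set")
  if (any(!is.finite(moving)) || any(!is.finite(fixed))) stop("non-finite points")
  tr <- init
  rms_history <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  repeat {
    mp <- rt_apply(tr, moving)
    nn <- .nn_query(fixed, mp)
    rms <- sqrt(mean(nn$dist^2))
    rms_history <- c(rms_history, rms)
    k <- length(rms_history)
    if (k > 1L && abs(rms_history[k - 1L] - rms) < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) break
    tr <- landmark_align(moving, fixed[nn$index, , drop = FALSE])
    iterations <- iterations + 1L
  }
  structure(list(transform = tr, rms_history = rms_history,
                 iterations = iterations, converged = converged,
                 rms = rms_history[length(rms_history)]),
            class = "icp_registration")
}

#' @export
print.icp_registration <- function(x, ...) {
  cat(sprintf("<icp_registration> %d iterations, %sconverged, final RMS %.4g mm\n",
              x$iterations, if (x$converged) "" else "NOT ", x$rms))
  print(x$transform)
  invisible(x)
}

#' Surface (segmentation) distance between two meshes
#'
#' For every vertex of \code{us_mesh}, the Euclidean distance to the nearest
#' vertex ("node") of \code{ref_mesh}; one-sided by design, so holes in the
#' ultrasound segmentation do not contribute.
#'
#' @param us_mesh Query mesh (e.g. the segmented ultrasound surface).
#' @param ref_mesh Reference mesh (e.g. the CT / ground-truth surface).
#' @return List with \code{distances} (per US vertex, mm) and summary
#'   \code{max}, \code{mean}, \code{sd}, \code{n}.
#' @export
surface_distance <- function(us_mesh, ref_mesh) {
  if (nrow(us_mesh$vertices) == 0L || nrow(ref_mesh$vertices) == 0L)
    stop("empty mesh")
  nn <- .nn_query(ref_mesh$vertices, us_mesh$vertices)
  d <- nn$dist
  list(distances = d, max = max(d), mean = mean(d), sd = stats::sd(d),
       n = length(d))
}

#' Target registration error between two poses of the same mesh
#'
#' Distances between corresponding vertices (i-th to i-th) of two rigid poses
#' of one source mesh. Requires identical vertex count and ordering.
#'
#' @param mesh_a,mesh_b Two \code{surface_mesh}es with corresponding vertices.
#' @return List with \code{distances} and summary \code{min}, \code{max},
#'   \code{mean}, \code{sd}.
#' @export
tre <- function(mesh_a, mesh_b) {
  if (nrow(mesh_a$vertices) != nrow(mesh_b$vertices))
    stop("correspondence error: vertex counts differ")
  d <- sqrt(rowSums((mesh_a$vertices - mesh_b$vertices)^2))
  list(distances = d, min = min(d), max = max(d), mean = mean(d),
       sd = stats::sd(d))
}

#' Register a preoperative CT mesh to an intraoperative ultrasound mesh
#'
#' Two-stage surface registration: coarse initialization from 3-4 manually
#' picked landmark pairs (orthogonal Procrustes), then point-to-point ICP on
#' random 2000-vertex subsets of both meshes. Because the ultrasound surface
#' covers only part of the bone, ICP correspondences are drawn from the
#' (partial) ultrasound subset into the (full) CT subset; the resulting
#' transform is inverted so the returned transform maps CT into the ultrasound
#' frame, and is applied to the full CT mesh.
#'
#' @param ct_mesh Preoperative CT \code{surface_mesh} (moving).
#' @param us_mesh Intraoperative ultrasound \code{surface_mesh} (fixed).
#' @param landmarks Optional list with \code{ct} and \code{us}: k x 3 matrices
#'   (k >= 3) of paired coarse landmarks; NULL starts from the identity.
#' @param n Subsample size per mesh, default 2000.
#' @param seed Subsampling seed, default 0.
#' @param max_iter,tol ICP controls.
#' @return Object of class \code{ct_registration}: \code{mesh} (the registered
#'   CT mesh, role "CT-intraop"), \code{transform} (CT to US frame),
#'   \code{icp} result and \code{init} transform.
#' @export
register_ct_to_us <- function(ct_mesh, us_mesh, landmarks = NULL, n = 2000L,
                              seed = 0L, max_iter = 200L, tol = 1e-6) {
  init <- if (is.null(landmarks)) rigid_transform()
          else landmark_align(landmarks$ct, landmarks$us)
  us_pts <- subsample_mesh(us_mesh, n, seed)
  ct_pts <- subsample_mesh(ct_mesh, n, seed + 1L)
  res <- icp(us_pts, ct_pts, init = rt_invert(init), max_iter = max_iter,
             tol = tol)
  tr <- rt_invert(res$transform)
  structure(list(mesh = transform_mesh(ct_mesh, tr, label = "CT-intraop"),
                 transform = tr, icp = res, init = init),
            class = "ct_registration")
}

#' @export
print.ct_registration <- function(x, ...) {
  cat("<ct_registration> CT-preop -> US frame\n")
  print(x$transform)
  cat(sprintf("  ICP: %d iterations, final RMS %.4g mm\n",
              x$icp$iterations, x$icp$rms))
  invisible(x)
}
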