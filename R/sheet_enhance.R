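#' @useDynLib bonecho, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd quantile cov plogis
#' @importFrom utils head
NULL

#' Sampled Gaussian derivative kernel
#'
#' Returns a centred 1D kernel of half-width \code{radius = ceiling(3*sigma)}
#' sampling the analytic Gaussian (derivative) of scale \code{sigma} (in
#' voxels). Kernels are moment-normalized so that discrete convolution is exact
#' on low-order polynomials: order 0 sums to 1, order 1 reproduces the slope of
#' a linear ramp, order 2 reproduces the curvature of a quadratic.
#'
#' @param sigma Scale in voxels, > 0.
#' @param order Derivative order: 0, 1 or 2.
#' @return Numeric kernel of length \code{2*ceiling(3*sigma) + 1}.
#' @export
gaussian_kernel <- function(sigma, order = 0L) {
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  if (!order %in% 0:2) stop("`order` must be 0, 1 or 2")
  r <- ceiling(3 * sigma)
  t <- seq(-r, r)
  g <- exp(-t^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  k <- switch(as.character(order),
    "0" = g,
    "1" = -t / sigma^2 * g,
    "2" = (t^2 - sigma^2) / sigma^4 * g
  )
  # discrete moment normalization
  if (order == 0L) {
    k <- k / sum(k)
  } else if (order == 1L) {
    k <- k / sum(-t * k) # convolution with x must give 1
  } else {
    k <- k - mean(k) # exact zero response to constants
    k <- k * (2 / sum(t^2 * k)) # convolution with x^2 must give 2
  }
  k
}

#' Hessian field of a volume by Gaussian derivative convolution
#'
#' Computes the six unique entries of the per-voxel Hessian by separable
#' convolution with sampled Gaussian derivative kernels of physical scale
#' \code{sigma_mm}. Per-axis kernel scales are \code{sigma_mm / spacing}
#' voxels, truncated at radius \code{3*sigma}; boundaries use reflect padding.
#' Entries are in mm^-2 (derivatives with respect to world coordinates).
#'
#' @param vol An \code{image_volume} (or plain 3D array, unit spacing).
#' @param sigma_mm Gaussian scale in mm.
#' @return List with arrays \code{dxx, dyy, dzz, dxy, dxz, dyz} and the
#'   attributes of the input grid.
#' @export
hessian_field <- function(vol, sigma_mm) {
  if (!is_image_volume(vol)) vol <- image_volume(vol)
  d <- dim(vol$data)
  sigma_vox <- sigma_mm / vol$spacing
  radius <- ceiling(3 * sigma_vox)
  if (any(d < 2 * radius + 1))
    stop(sprintf("volume too small for kernel: need >= %s voxels per axis",
                 paste(2 * radius + 1, collapse = "x")))
  kern <- lapply(1:3, function(ax) lapply(0:2, function(o)
    gaussian_kernel(sigma_vox[ax], o) / vol$spacing[ax]^o))

  dims <- as.integer(d)
  x <- vol$data
  # share convolution passes: z first, then y, then x
  z_pass <- lapply(0:2, function(o) NULL)
  get_z <- function(o) {
    if (is.null(z_pass[[o + 1]]))
      z_pass[[o + 1]] <<- .conv3_axis(x, dims, kern[[3]][[o + 1]], 2L)
    z_pass[[o + 1]]
  }
  zy_pass <- new.env(parent = emptyenv())
  get_zy <- function(oy, oz) {
    key <- paste0(oy, oz)
    if (is.null(zy_pass[[key]]))
      zy_pass[[key]] <- .conv3_axis(get_z(oz), dims, kern[[2]][[oy + 1]], 1L)
    zy_pass[[key]]
  }
  entry <- function(ox, oy, oz)
    .conv3_axis(get_zy(oy, oz), dims, kern[[1]][[ox + 1]], 0L)

  out <- list(
    dxx = entry(2, 0, 0), dyy = entry(0, 2, 0), dzz = entry(0, 0, 2),
    dxy = entry(1, 1, 0), dxz = entry(1, 0, 1), dyz = entry(0, 1, 1)
  )
  attr(out, "spacing") <- vol$spacing
  attr(out, "origin") <- vol$origin
  attr(out, "sigma_mm") <- sigma_mm
  class(out) <- "hessian_field"
  out
}

#' Per-voxel eigenvalues of a Hessian field
#'
#' Closed-form symmetric 3x3 eigen-decomposition at every voxel. Eigenvalues
#' are sorted by signed value, \code{lam1 >= lam2 >= lam3}.
#'
#' @param h A \code{hessian_field}.
#' @return List of arrays \code{lam1, lam2, lam3} (class \code{eigen_field}).
#' @export
eigen_decompose <- function(h) {
  if (!inherits(h, "hessian_field")) stop("`h` must be a hessian_field")
  e <- .eig3_sym(h$dxx, h$dyy, h$dzz, h$dxy, h$dxz, h$dyz)
  attr(e, "spacing") <- attr(h, "spacing")
  attr(e, "origin") <- attr(h, "origin")
  class(e) <- "eigen_field"
  e
}

#' Sheetness weight function
#'
#' The asymmetry weight used by the sheetness measure. For \code{lam_j < 0}:
#' \itemize{
#'   \item \code{(1 + lam_i/|lam_j|)^gamma} when \code{lam_j <= lam_i <= 0},
#'   \item \code{(1 - alpha*lam_i/|lam_j|)^gamma} when
#'     \code{|lam_j|/alpha > lam_i > 0},
#'   \item 0 otherwise.
#' }
#' It is 1 when \code{lam_i = 0} (both branches agree) and decreases with the
#' deviation of \code{lam_i} from 0.
#'
#' @param lam_i,lam_j Eigenvalues (vectorized); every \code{lam_j} must be < 0.
#' @param alpha Asymmetry weight, default 0.5.
#' @param gamma Sharpness exponent, default 1.
#' @return Weights in [0, 1].
#' @export
omega <- function(lam_i, lam_j, alpha = 0.5, gamma = 1) {
  if (any(lam_j >= 0)) stop("omega requires lam_j < 0")
  n <- max(length(lam_i), length(lam_j))
  lam_i <- rep_len(lam_i, n)
  lam_j <- rep_len(lam_j, n)
  aj <- abs(lam_j)
  w <- numeric(n)
  b1 <- lam_j <= lam_i & lam_i <= 0
  b2 <- !b1 & lam_i > 0 & lam_i < aj / alpha
  w[b1] <- (1 + lam_i[b1] / aj[b1])^gamma
  w[b2] <- (1 - alpha * lam_i[b2] / aj[b2])^gamma
  w
}

#' Sheetness measure from ordered eigenvalues
#'
#' \code{S = |lam3| * omega(lam2; lam3) * omega(lam1; lam3)} where
#' \code{lam3 < 0}, and 0 elsewhere, so the response is a non-negative
#' "bright sheet" score. Maximal for surface-like structures
#' (\code{lam3 << lam2 ~ lam1 ~ 0}); tube- and blob-like structures are
#' suppressed by the omega weights.
#'
#' @param eigs An \code{eigen_field} (or list with lam1, lam2, lam3 arrays).
#' @param alpha,gamma Parameters of [omega()].
#' @return Array of sheetness values, same shape as the input.
#' @export
sheetness <- function(eigs, alpha = 0.5, gamma = 1) {
  l1 <- eigs$lam1; l2 <- eigs$lam2; l3 <- eigs$lam3
  s <- array(0, dim(l3))
  neg <- l3 < 0
  if (any(neg)) {
    s[neg] <- abs(l3[neg]) *
      omega(l2[neg], l3[neg], alpha, gamma) *
      omega(l1[neg], l3[neg], alpha, gamma)
  }
  s
}

#' Sheet enhancement of an ultrasound volume
#'
#' Runs the full enhancement chain: Gaussian-derivative Hessian at scale
#' \code{sigma_mm}, closed-form eigen-decomposition, and the sheetness
#' measure. The default scale (0.5 mm) is on the order of the axial resolution
#' of a 7.5 MHz probe and localizes the centerline of a 2-4 mm wide cortical
#' echo; it is exposed because the optimal scale tracks the echo width.
#'
#' @param vol An \code{image_volume}.
#' @param sigma_mm Filter scale in mm (default 0.5).
#' @param alpha,gamma Sheetness parameters (defaults 0.5 and 1).
#' @return An \code{image_volume} of sheetness values on the input grid.
#' @export
enhance_volume <- function(vol, sigma_mm = 0.5, alpha = 0.5, gamma = 1) {
  if (!is_image_volume(vol)) vol <- image_volume(vol)
  h <- hessian_field(vol, sigma_mm)
  e <- eigen_decompose(h)
  image_volume(sheetness(e, alpha, gamma), spacing = vol$spacing,
               origin = vol$origin, frame_id = vol$frame_id)
}

#' Classify local structure from ordered Hessian eigenvalues
#'
#' Discriminates surface-, tube- and sphere-like local structure from the
#' eigenvalue relations (with \code{s = max(|lam|)} as scale):
#' "approximately zero" means \code{|lam| <= tol*s} and "much smaller" means a
#' gap of at least \code{(1-tol)*s}. Intended as a diagnostic; the pipeline
#' itself uses the continuous sheetness measure.
#'
#' @param lam1,lam2,lam3 Ordered eigenvalues (lam1 >= lam2 >= lam3), scalars.
#' @param tol Relative tolerance in (0, 1), default 0.25.
#' @return One of "surface", "tube", "sphere", "none".
#' @export
classify_structure <- function(lam1, lam2, lam3, tol = 0.25) {
  if (lam1 < lam2 || lam2 < lam3) stop("eigenvalues must be ordered lam1 >= lam2 >= lam3")
  s <- max(abs(c(lam1, lam2, lam3)))
  if (s == 0) return("none")
  near0 <- function(x) abs(x) <= tol * s
  muchless <- function(a, b) (b - a) >= (1 - tol) * s
  if (near0(lam1) && near0(lam2) && muchless(lam3, lam2)) return("surface")
  if (near0(lam1) && muchless(lam2, lam1) && abs(lam2 - lam3) <= tol * s) return("tube")
  if (abs(lam1 - lam2) <= tol * s && abs(lam2 - lam3) <= tol * s &&
      muchless(lam1, 0)) return("sphere")
  "none"
}
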