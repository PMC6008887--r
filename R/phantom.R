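#' Specification of a synthetic bone phantom
#'
#' Describes an in-silico long-bone phantom imaged by a downward (+z) beam:
#' speckle-textured soft tissue above the bone, a bright cortical echo sheet
#' centered on the true bone surface, and an acoustic shadow beneath it. The
#' bone is a cylindrical shaft (along x) with an optional flared, azimuthally
#' asymmetric "plateau" end emulating the epiphysis; the asymmetry breaks the
#' rotational symmetry of the shaft so surface registration is well posed.
#'
#' Speckle is modelled as multiplicative log-normal noise on a correlated
#' Gaussian random field whose correlation lengths play the role of the
#' speckle-cell size of a 7.5 MHz probe; the specular cortical echo carries a
#' reduced share of it. The echo profile across the surface is Gaussian in
#' surface-normal distance with sigma = echo_width/4, so the stated width
#' spans about 95 percent of the echo energy. Specular directivity is modelled
#' as a cos^2 gain in the beam-to-normal angle, so the bright line fades where
#' the surface turns away from the probe, as it does in real bone ultrasound;
#' bone annotations are restricted to the visibly bright arc (gain >= 0.5).
#'
#' @param shape Volume dimensions in voxels, default c(160, 160, 160).
#' @param spacing Isotropic voxel size in mm, default 0.115.
#' @param radius Shaft radius in mm, default 6.
#' @param flare_amp Plateau flare amplitude in mm, default 2.5.
#' @param flare_offset Position of the flare midpoint along the bone axis, mm
#'   from the volume center, default 1.8, so the plateau is inside every
#'   imaged section (scans always include it).
#' @param flare_width Logistic width of the flare in mm, default 2.5.
#' @param flare_asym Azimuthal asymmetry of the flare (0 = surface of
#'   revolution), default 0.45.
#' @param shaft_tri Relative amplitude of the rounded-triangular cross-section
#'   harmonic of the shaft (tibial shafts are roughly triangular; this also
#'   makes roll observable to surface registration), default 0.15.
#' @param shaft_tri_phase Orientation of the triangular cross-section in
#'   radians, default 0.5.
#' @param surface_depth Depth (mm) of the shaft crest below the volume top,
#'   default 6.
#' @param echo_width Full width of the bright cortical echo in mm; must lie in
#'   the physiological 2-4 mm range. Default 3.
#' @param echo_amplitude Peak echo amplitude above the local background,
#'   default 110 (8-bit-like scale).
#' @param tissue_mean Mean soft-tissue intensity, default 55.
#' @param shadow_attenuation Shadow mean as a fraction of tissue mean,
#'   default 0.12.
#' @param speckle_sigma Log-sd of the multiplicative speckle, default 0.35
#'   (0 disables noise).
#' @param speckle_cell Speckle correlation lengths (x, y, z) in mm,
#'   default c(0.45, 0.45, 0.25) (lateral, lateral, axial).
#' @param echo_speckle_factor Fraction of the speckle log-sd carried by the
#'   specular echo, default 0.4.
#' @param specular_exponent Exponent p of the cos^p specular directivity of
#'   the cortical echo, default 2.
#' @param echo_cell Correlation length (mm) of the echo's gain modulation,
#'   default 1.0: the coherent specular reflection varies smoothly along the
#'   surface rather than at speckle-cell scale.
#' @param label_halfwidth Half-thickness (mm) of the "bone" training
#'   annotation around the echo centerline, default 0.15 (the annotator traces
#'   the thin cortical line).
#' @param label_margin Unlabeled margin (mm) between the bone line and the
#'   adjacent tissue/shadow annotations, default 0.1 (annotation imprecision).
#' @param label_gain_min Minimum specular gain at which the annotator still
#'   traces the bone line, default 0.5 (the dimmer fringe is left unlabeled).
#' @param section_offset Shift of the imaged section along the bone axis (mm),
#'   default 0.
#' @param tilt_deg Rotations (about y, about x) of the bone inside the volume,
#'   degrees, default c(0, 0).
#' @param offset Lateral/depth shift (y, z) of the bone axis in mm,
#'   default c(0, 0).
#' @param noise_seed RNG seed for the speckle field, default 0.
#' @return Object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(160L, 160L, 160L), spacing = 0.115,
                         radius = 6, flare_amp = 2.5, flare_offset = 1.8,
                         flare_width = 2.5, flare_asym = 0.45,
                         shaft_tri = 0.15, shaft_tri_phase = 0.5,
                         surface_depth = 6, echo_width = 3,
                         echo_amplitude = 110, tissue_mean = 55,
                         shadow_attenuation = 0.12, speckle_sigma = 0.35,
                         speckle_cell = c(0.45, 0.45, 0.25),
                         echo_speckle_factor = 0.4, echo_cell = 1.0,
                         specular_exponent = 2,
                         label_halfwidth = 0.15,
                         label_margin = 0.1, label_gain_min = 0.5,
                         section_offset = 0, tilt_deg = c(0, 0),
                         offset = c(0, 0), noise_seed = 0L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L)) stop("`shape` must be 3 sizes >= 16")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (echo_width < 2 || echo_width > 4)
    stop("`echo_width` must lie in the 2-4 mm range of cortical echoes")
  spec <- list(shape = shape, spacing = spacing, radius = radius,
               flare_amp = flare_amp, flare_offset = flare_offset,
               flare_width = flare_width, flare_asym = flare_asym,
               shaft_tri = shaft_tri, shaft_tri_phase = shaft_tri_phase,
               surface_depth = surface_depth, echo_width = echo_width,
               echo_amplitude = echo_amplitude, tissue_mean = tissue_mean,
               shadow_attenuation = shadow_attenuation,
               speckle_sigma = speckle_sigma, speckle_cell = speckle_cell,
               echo_speckle_factor = echo_speckle_factor, echo_cell = echo_cell,
               specular_exponent = specular_exponent,
               label_halfwidth = label_halfwidth, label_margin = label_margin,
               label_gain_min = label_gain_min,
               section_offset = section_offset, tilt_deg = tilt_deg,
               offset = offset, noise_seed = as.integer(noise_seed))
  class(spec) <- "phantom_spec"
  spec
}

# placement of the bone inside the volume: bone-frame basis and anchor
phantom_placement <- function(spec) {
  ext <- spec$shape * spec$spacing
  c0 <- c(ext[1] / 2, ext[2] / 2 + spec$offset[1],
          spec$surface_depth + spec$radius + spec$offset[2])
  ay <- spec$tilt_deg[1] * pi / 180
  ax <- spec$tilt_deg[2] * pi / 180
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  R <- Rx %*% Ry
  list(c0 = c0, R = R, ext = ext)
}

# flare profile along the bone axis; s is a bone-frame coordinate (0 at the
# volume center), so the bone geometry is independent of the rendered volume
phantom_flare <- function(spec, s) {
  spec$flare_amp * stats::plogis((s + spec$section_offset - spec$flare_offset) /
                                   spec$flare_width)
}

# radius of the bone surface at axial position s and azimuth (cosine/sine of
# the angle from "top"); the 3-phi harmonic gives the shaft its rounded
# triangular tibial cross-section
phantom_radius <- function(spec, s, cos_top, sin_top) {
  c3 <- 4 * cos_top^3 - 3 * cos_top
  s3 <- sin_top * (3 - 4 * sin_top^2)
  tri <- spec$shaft_tri * (c3 * cos(3 * spec$shaft_tri_phase) +
                             s3 * sin(3 * spec$shaft_tri_phase))
  spec$radius * (1 + tri) + phantom_flare(spec, s) * (1 + spec$flare_asym * cos_top)
}

# correlated unit-variance Gaussian field emulating speckle cells
speckle_field <- function(shape, spacing, cell_mm) {
  g <- array(stats::rnorm(prod(shape)), shape)
  dims <- as.integer(shape)
  for (ax in 1:3) {
    sig <- cell_mm[ax] / spacing[ax]
    if (sig > 0.2)
      g <- .conv3_axis(g, dims, gaussian_kernel(sig, 0L), ax - 1L)
  }
  g / stats::sd(g)
}

#' Generate a synthetic bone-phantom ultrasound volume with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: for each beam column
#' (+z), speckled soft tissue above the bone surface, a Gaussian-profile
#' bright echo sheet centered on the true surface, and an attenuated shadow
#' below it. Deterministic for a fixed \code{noise_seed}.
#'
#' @param spec A \code{phantom_spec}.
#' @return List with \code{volume} (the rendered \code{image_volume}) and
#'   \code{truth}: \code{center_surface_mesh} (the true cortical surface at
#'   the echo centerline), \code{label_volume} (\code{image_volume} with codes
#'   0 unlabeled, 1 bone, 2 tissue, 3 shadow), \code{z_surface} (per-column
#'   surface depth in mm, NA where the beam misses the bone) and
#'   \code{cos_theta} (per-column beam-to-normal cosine).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  pl <- phantom_placement(spec)
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  sp <- spec$spacing
  n <- as.double(nx) * ny * nz
  xw <- (seq_len(nx) - 1) * sp[1]
  yw <- (seq_len(ny) - 1) * sp[2]
  zw <- (seq_len(nz) - 1) * sp[3]

  X <- rep(xw, times = ny * nz) - pl$c0[1]
  Y <- rep(rep(yw, each = nx), times = nz) - pl$c0[2]
  Z <- rep(zw, each = nx * ny) - pl$c0[3]
  R <- pl$R
  xb <- R[1, 1] * X + R[2, 1] * Y + R[3, 1] * Z
  yb <- R[1, 2] * X + R[2, 2] * Y + R[3, 2] * Z
  zb <- R[1, 3] * X + R[2, 3] * Y + R[3, 3] * Z
  rm(X, Y)
  rho <- sqrt(yb * yb + zb * zb)
  cos_top <- ifelse(rho > 0, -zb / rho, 0)
  sin_top <- ifelse(rho > 0, yb / rho, 0)
  f <- rho - phantom_radius(spec, xb, cos_top, sin_top)
  rm(xb, yb, zb, rho, cos_top, sin_top)

  # per-column first surface crossing along +z (columns are x-fastest)
  M <- matrix(f < 0, nrow = nx * ny, ncol = nz)
  hit <- max.col(M, ties.method = "first")
  valid <- M[cbind(seq_len(nx * ny), hit)] & hit > 1L
  fM <- matrix(f, nrow = nx * ny, ncol = nz)
  f0 <- fM[cbind(seq_len(nx * ny), pmax(hit - 1L, 1L))]
  f1 <- fM[cbind(seq_len(nx * ny), hit)]
  rm(M, fM)
  frac <- ifelse(valid, f0 / pmax(f0 - f1, 1e-12), NA_real_)
  zs <- ifelse(valid, zw[pmax(hit - 1L, 1L)] + frac * sp[3], NA_real_)
  zs_xy <- matrix(zs, nx, ny)

  if (mean(valid) < 0.05)
    stop("geometry error: bone surface (almost) entirely outside the volume")

  # beam-to-normal cosine from the surface slope
  gx <- zs_xy * 0; gy <- zs_xy * 0
  gx[2:(nx - 1), ] <- (zs_xy[3:nx, ] - zs_xy[1:(nx - 2), ]) / (2 * sp[1])
  gy[, 2:(ny - 1)] <- (zs_xy[, 3:ny] - zs_xy[, 1:(ny - 2)]) / (2 * sp[2])
  cos_theta <- 1 / sqrt(1 + gx^2 + gy^2)
  cos_theta[!is.finite(cos_theta)] <- NA_real_

  zs_all <- rep(zs, times = nz)
  ct_col <- pmax(ifelse(is.na(cos_theta), 1, cos_theta), 0.3)
  ct_all <- rep(as.vector(ct_col), times = nz)
  dz <- Z - (zs_all - pl$c0[3]) # Z still holds z - c0[3]
  rm(Z)
  dz[is.na(dz)] <- -Inf # beam misses bone: everything counts as "above"

  w <- spec$echo_width
  sig_e <- w / 4
  shadow_mean <- spec$shadow_attenuation * spec$tissue_mean
  # tissue fades into shadow across the echo band; the gentle slope keeps the
  # bright-ridge maximum on the true surface (per-column argmax oracle)
  base <- shadow_mean + (spec$tissue_mean - shadow_mean) *
    stats::plogis(-dz * ct_all / (w / 4))
  # specular directivity: the echo fades as the surface turns away from the beam
  gain_col <- ifelse(is.na(cos_theta), 0, cos_theta^spec$specular_exponent)
  gain <- rep(as.vector(gain_col), times = nz)
  ridge <- spec$echo_amplitude * gain * exp(-f * f / (2 * sig_e^2))
  ridge[!rep(valid, times = nz)] <- 0
  ridge[abs(dz) > 1.5 * w * ct_all^-1] <- 0
  rm(gain)

  if (spec$speckle_sigma > 0) {
    g <- with_seed(spec$noise_seed,
                   speckle_field(spec$shape, sp, spec$speckle_cell))
    ss <- spec$speckle_sigma
    se <- spec$echo_speckle_factor * ss
    intensity <- base * exp(ss * g - ss^2 / 2)
    rm(g)
    if (se > 0) {
      # smooth gain modulation of the coherent specular echo
      g2 <- with_seed(spec$noise_seed + 1L,
                      speckle_field(spec$shape, sp, rep(spec$echo_cell, 3)))
      intensity <- intensity + ridge * exp(se * g2 - se^2 / 2)
      rm(g2)
    } else {
      intensity <- intensity + ridge
    }
  } else {
    intensity <- base + ridge
  }
  rm(base)

  # training annotations: the thin cortical line is "bone"; tissue and shadow
  # regions are painted right up to it (as a human annotator partitions the
  # volume), separated only by a small imprecision margin in normal distance
  labels <- integer(length(f))
  vall <- rep(valid, times = nz)
  u <- dz * ct_all # approximate surface-normal distance (signed, + below)
  edge <- spec$label_halfwidth + spec$label_margin
  bright <- rep(as.vector(gain_col) >= spec$label_gain_min, times = nz)
  labels[vall & bright & abs(f) <= spec$label_halfwidth &
           abs(dz) <= w / ct_all] <- 1L
  labels[u < -edge] <- 2L
  labels[vall & u > edge] <- 3L
  rm(u)
  rm(f, dz, vall, ct_all, zs_all)

  vol <- image_volume(array(intensity, spec$shape), spacing = sp,
                      origin = c(0, 0, 0), frame_id = "US")
  lab_vol <- image_volume(array(as.numeric(labels), spec$shape), spacing = sp,
                          origin = c(0, 0, 0), frame_id = "US")

  mesh <- height_field_mesh(zs_xy, xw, yw, label = "truth-center")
  list(volume = vol,
       truth = list(center_surface_mesh = mesh, label_volume = lab_vol,
                    z_surface = zs_xy, cos_theta = cos_theta,
                    placement = pl))
}

# triangulated height field over valid columns
height_field_mesh <- function(zs_xy, xw, yw, label = "") {
  nx <- length(xw); ny <- length(yw)
  valid <- is.finite(zs_xy)
  vid <- matrix(0L, nx, ny)
  vid[valid] <- seq_len(sum(valid))
  verts <- cbind(rep(xw, times = ny)[valid],
                 rep(yw, each = nx)[valid],
                 zs_xy[valid])
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  a <- vid[cbind(i, j)]; b <- vid[cbind(i + 1, j)]
  cc <- vid[cbind(i, j + 1)]; d <- vid[cbind(i + 1, j + 1)]
  t1 <- cbind(a, b, d)[a > 0 & b > 0 & d > 0, , drop = FALSE]
  t2 <- cbind(a, d, cc)[a > 0 & d > 0 & cc > 0, , drop = FALSE]
  surface_mesh(verts, rbind(t1, t2), label = label)
}

#' Extract a labeled training block
#'
#' Generates a phantom of the given cubic size (default the classical 150^3
#' training volume) and returns the raw block together with exact voxel labels
#' from the ground truth. Errors if any of the three classes is absent.
#'
#' @param spec A \code{phantom_spec}; its geometry is reused, only the shape
#'   is replaced.
#' @param size Cubic block edge in voxels, default 150.
#' @return List with \code{raw} (\code{image_volume}), \code{labels}
#'   (\code{image_volume}, codes 1 bone / 2 tissue / 3 shadow / 0 unlabeled)
#'   and \code{truth}.
#' @export
generate_training_block <- function(spec, size = 150L) {
  spec$shape <- rep(as.integer(size), 3)
  ph <- generate_phantom(spec)
  lab <- ph$truth$label_volume$data
  missing <- setdiff(1:3, unique(as.vector(lab)))
  if (length(missing))
    stop("spec error: training block misses class(es): ",
         paste(c("bone", "tissue", "shadow")[missing], collapse = ", "))
  list(raw = ph$volume, labels = ph$truth$label_volume, truth = ph$truth)
}

#' Train the Gaussian Bayes classifier on a synthetic training block
#'
#' Convenience wrapper reproducing the training protocol: generate a labeled
#' block, enhance it, extract features and fit [bone_qda()]. The one model is
#' meant to be reused across all experiments on phantoms with the same
#' intensity statistics.
#'
#' @param spec A \code{phantom_spec} describing the phantom family.
#' @param size Training block edge in voxels, default 150.
#' @param sigma_mm,window,alpha,gamma Feature settings (defaults 0.5 mm, 9,
#'   0.5, 1).
#' @return A \code{bone_qda} fit.
#' @export
train_phantom_model <- function(spec = phantom_spec(), size = 150L,
                                sigma_mm = 0.5, window = 9L,
                                alpha = 0.5, gamma = 1) {
  blk <- generate_training_block(spec, size)
  enhanced <- enhance_volume(blk$raw, sigma_mm = sigma_mm,
                             alpha = alpha, gamma = gamma)
  feats <- extract_features(blk$raw, enhanced, window = window)
  bone_qda(feats, blk$labels$data, window = window, sigma_mm = sigma_mm,
           alpha = alpha, gamma = gamma)
}

#' Build the full CT bone-surface mesh of the phantom
#'
#' Parametric triangle mesh of the complete bone surface (shaft plus flare),
#' extending beyond the imaged volume along the bone axis, in the exact world
#' frame of the phantom (the role of the tracker-referenced CT mesh).
#'
#' @param spec A \code{phantom_spec}.
#' @param margin Extension beyond the volume along the bone axis in mm,
#'   default 9.
#' @param nu,nv Axial and azimuthal mesh resolution, defaults 200 and 128.
#' @param label Role tag, default "CT-ref".
#' @return A \code{surface_mesh}.
#' @export
make_ct_mesh <- function(spec, margin = 9, nu = 200L, nv = 128L,
                         label = "CT-ref") {
  pl <- phantom_placement(spec)
  half <- pl$ext[1] / 2 + margin
  s <- seq(-half, half, length.out = nu)
  phi <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  sg <- rep(s, times = nv)
  pg <- rep(phi, each = nu)
  r <- phantom_radius(spec, sg, cos(pg), sin(pg))
  # bone-frame coordinates: top is -z
  pb <- cbind(sg, r * sin(pg), -r * cos(pg))
  verts <- sweep(pb %*% t(pl$R), 2, pl$c0, "+")
  iu <- rep(seq_len(nu - 1L), times = nv)
  iv <- rep(seq_len(nv), each = nu - 1L)
  ivn <- ifelse(iv == nv, 1L, iv + 1L)
  a <- (iv - 1L) * nu + iu
  b <- (iv - 1L) * nu + iu + 1L
  cc <- (ivn - 1L) * nu + iu
  d <- (ivn - 1L) * nu + iu + 1L
  faces <- rbind(cbind(a, b, d), cbind(a, d, cc))
  surface_mesh(verts, faces, label = label)
}

#' Random rigid pose
#'
#' Rotation about a uniformly random axis by a uniform angle up to
#' \code{max_rot_deg}, translation in a uniformly random direction with
#' uniform magnitude up to \code{max_trans_mm}. Deterministic per seed.
#'
#' @param seed RNG seed.
#' @param max_rot_deg Maximum rotation angle in degrees, default 30.
#' @param max_trans_mm Maximum translation in mm, default 20.
#' @return A \code{rigid_transform}.
#' @export
random_pose <- function(seed, max_rot_deg = 30, max_trans_mm = 20) {
  with_seed(seed, {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 0, max_rot_deg * pi / 180)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    tr <- stats::runif(1, 0, max_trans_mm) * dir
    # re-orthonormalize against accumulated floating error
    sv <- svd(R)
    rigid_transform(sv$u %*% t(sv$v), tr)
  })
}

#' Generate a complete synthetic registration experiment
#'
#' Builds everything one registration experiment needs: the ultrasound volume
#' of the posed phantom with ground truth, the exact tracker-referenced CT
#' mesh (world frame), the preoperative CT mesh (the same mesh moved to a
#' canonical preoperative frame by the inverse pose), and jittered coarse
#' landmark pairs emulating manual picking.
#'
#' @param spec A \code{phantom_spec} (its \code{noise_seed} is replaced by
#'   \code{seed}).
#' @param pose A \code{rigid_transform} carrying the preoperative frame to the
#'   world (tracker) frame; identity by default.
#' @param seed RNG seed for speckle and landmark jitter.
#' @param landmark_jitter RMS landmark error in mm, default 2.
#' @param n_landmarks Number of landmark pairs, default 4.
#' @return List with \code{volume}, \code{truth}, \code{ct_ref},
#'   \code{ct_preop}, \code{pose} and \code{landmarks} (list of matrices
#'   \code{ct}, \code{us}).
#' @export
generate_registration_experiment <- function(spec, pose = rigid_transform(),
                                             seed = 0L, landmark_jitter = 2,
                                             n_landmarks = 4L) {
  spec$noise_seed <- as.integer(seed)
  ph <- generate_phantom(spec)
  ct_ref <- make_ct_mesh(spec, label = "CT-ref")
  ct_preop <- transform_mesh(ct_ref, rt_invert(pose), label = "CT-preop")

  v <- ph$truth$center_surface_mesh$vertices
  qx <- stats::quantile(v[, 1], c(0.05, 0.95, 0.4, 0.7))
  pick <- function(xq, yq) {
    cand <- which(abs(v[, 1] - xq) <= max(1, diff(range(v[, 1])) / 40))
    cand[which.min(abs(v[cand, 2] - stats::quantile(v[cand, 2], yq)))]
  }
  # spread in both axis position and azimuth so roll is observable
  ids <- c(pick(qx[1], 0.2), pick(qx[2], 0.8), pick(qx[3], 0.85),
           pick(qx[4], 0.15))
  ids <- ids[seq_len(min(n_landmarks, length(ids)))]
  pts <- v[ids, , drop = FALSE]
  jit <- landmark_jitter / sqrt(3)
  lm <- with_seed(seed + 101L, list(
    us = pts + matrix(stats::rnorm(length(pts), sd = jit), ncol = 3),
    ct = rt_apply(rt_invert(pose), pts) +
      matrix(stats::rnorm(length(pts), sd = jit), ncol = 3)
  ))
  list(volume = ph$volume, truth = ph$truth, ct_ref = ct_ref,
       ct_preop = ct_preop, pose = pose,
       landmarks = list(ct = lm$ct, us = lm$us))
}
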