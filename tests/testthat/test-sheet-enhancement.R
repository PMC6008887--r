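test_that("Gaussian-derivative Hessian is exact on low-order polynomials", {
  n <- 41
  idx <- seq_len(n) - 21
  const <- image_volume(array(5, c(n, n, n)))
  h0 <- hessian_field(const, sigma_mm = 2)
  for (e in h0[c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")])
    expect_lt(max(abs(e)), 1e-10)

  quad <- image_volume(array(rep(idx^2, n * n), c(n, n, n)))
  hq <- hessian_field(quad, sigma_mm = 2)
  core <- 15:27
  expect_equal(max(abs(hq$dxx[core, core, core] - 2)), 0, tolerance = 1e-8)
  expect_lt(max(abs(hq$dyy[core, core, core])), 1e-8)
  expect_lt(max(abs(hq$dxy[core, core, core])), 1e-8)

  prod_xy <- outer(idx, idx)
  pv <- image_volume(array(rep(as.vector(prod_xy), n), c(n, n, n)))
  hp <- hessian_field(pv, sigma_mm = 2)
  expect_equal(max(abs(hp$dxy[core, core, core] - 1)), 0, tolerance = 1e-8)
  expect_lt(max(abs(hp$dxx[core, core, core])), 1e-8)

  expect_error(hessian_field(image_volume(array(0, c(5, 5, 5))), sigma_mm = 2),
               "too small")
})

test_that("anisotropic spacing yields world-unit derivatives", {
  n <- 41
  idx <- seq_len(n) - 21
  sp <- c(0.25, 0.5, 1)
  xmm <- idx * sp[1]
  quad <- image_volume(array(rep(xmm^2, n * n), c(n, n, n)), spacing = sp)
  hq <- hessian_field(quad, sigma_mm = 1)
  expect_equal(hq$dxx[21, 21, 21], 2, tolerance = 1e-8)
})

test_that("per-voxel eigenvalues match independent solvers", {
  set.seed(42)
  ms <- replicate(300, { m <- matrix(rnorm(9), 3); (m + t(m)) / 2 },
                  simplify = FALSE)
  h <- structure(list(
    dxx = vapply(ms, function(m) m[1, 1], 0), dyy = vapply(ms, function(m) m[2, 2], 0),
    dzz = vapply(ms, function(m) m[3, 3], 0), dxy = vapply(ms, function(m) m[1, 2], 0),
    dxz = vapply(ms, function(m) m[1, 3], 0), dyz = vapply(ms, function(m) m[2, 3], 0)),
    class = "hessian_field")
  e <- eigen_decompose(h)
  expect_true(all(e$lam1 >= e$lam2 & e$lam2 >= e$lam3))
  for (i in seq_along(ms)) {
    # LAPACK route
    ref <- sort(eigen(ms[[i]], symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    expect_equal(c(e$lam1[i], e$lam2[i], e$lam3[i]), ref, tolerance = 1e-8)
  }
  # characteristic-polynomial route on a subset
  for (i in 1:25) {
    m <- ms[[i]]
    cp <- c(-det(m),
            m[1, 1] * m[2, 2] + m[1, 1] * m[3, 3] + m[2, 2] * m[3, 3] -
              m[1, 2]^2 - m[1, 3]^2 - m[2, 3]^2,
            -sum(diag(m)), 1)
    roots <- sort(Re(polyroot(cp)), decreasing = TRUE)
    expect_equal(c(e$lam1[i], e$lam2[i], e$lam3[i]), roots, tolerance = 1e-6)
  }
  # diagonal special cases
  d <- eigen_decompose(structure(list(dxx = 0, dyy = 0, dzz = -2, dxy = 0,
                                      dxz = 0, dyz = 0), class = "hessian_field"))
  expect_identical(c(d$lam1, d$lam2, d$lam3), c(0, 0, -2))
  d2 <- eigen_decompose(structure(list(dxx = 2, dyy = 2, dzz = 2, dxy = 0,
                                       dxz = 0, dyz = 0), class = "hessian_field"))
  expect_identical(c(d2$lam1, d2$lam2, d2$lam3), c(2, 2, 2))
})

test_that("omega matches hand-evaluated values and its contract", {
  expect_equal(omega(0, -1), 1, tolerance = 1e-12)
  expect_equal(omega(-2, -2), 0, tolerance = 1e-12)
  expect_equal(omega(0.5, -1, alpha = 0.5, gamma = 1), 0.75, tolerance = 1e-12)
  expect_error(omega(0, 1), "lam_j < 0")
  # continuity at lam_i = 0 and monotone decay on both branches
  eps <- 1e-9
  expect_equal(omega(-eps, -1), 1, tolerance = 1e-6)
  expect_equal(omega(eps, -1), 1, tolerance = 1e-6)
  neg <- omega(seq(0, -1, by = -0.05), -1)
  pos <- omega(seq(0, 1.9, by = 0.05), -1)
  expect_true(all(diff(neg) <= 1e-12))
  expect_true(all(diff(pos) <= 1e-12))
  expect_true(all(neg >= 0 & neg <= 1) && all(pos >= 0 & pos <= 1))
  # outside the admissible band the weight vanishes
  expect_equal(omega(2.5, -1), 0)
  expect_equal(omega(-1.5, -1), 0)
})

test_that("sheetness matches hand values and is a non-negative sheet score", {
  as_eigs <- function(l1, l2, l3)
    list(lam1 = array(l1, c(1, 1, 1)), lam2 = array(l2, c(1, 1, 1)),
         lam3 = array(l3, c(1, 1, 1)))
  expect_equal(as.vector(sheetness(as_eigs(0, 0, -2))), 2, tolerance = 1e-12)
  expect_equal(as.vector(sheetness(as_eigs(1, 1, 0.5))), 0)
  expect_equal(as.vector(sheetness(as_eigs(0, -2, -2))), 0, tolerance = 1e-12)
  set.seed(7)
  trip <- apply(matrix(rnorm(3000), ncol = 3), 1, sort, decreasing = TRUE)
  s <- sheetness(list(lam1 = array(trip[1, ], c(1000, 1, 1)),
                      lam2 = array(trip[2, ], c(1000, 1, 1)),
                      lam3 = array(trip[3, ], c(1000, 1, 1))))
  expect_true(all(s >= 0))
  expect_true(all(s[trip[3, ] >= 0] == 0))
})

gaussian_plane_volume <- function(n, normal, sigma_mm, spacing = 1) {
  normal <- normal / sqrt(sum(normal^2))
  idx <- (seq_len(n) - (n + 1) / 2) * spacing
  g <- expand.grid(x = idx, y = idx, z = idx)
  d <- as.matrix(g) %*% normal
  image_volume(array(100 * exp(-d^2 / (2 * sigma_mm^2)), c(n, n, n)),
               spacing = rep(spacing, 3))
}

test_that("sheetness response to a bright plane is near rotation invariant", {
  n <- 41
  va <- gaussian_plane_volume(n, c(0, 0, 1), sigma_mm = 2)
  vb <- gaussian_plane_volume(n, c(1, 0, 1), sigma_mm = 2)
  ea <- enhance_volume(va, sigma_mm = 2)
  eb <- enhance_volume(vb, sigma_mm = 2)
  c0 <- (n + 1) / 2
  ra <- ea$data[c0, c0, c0]
  rb <- eb$data[c0, c0, c0]
  expect_gt(ra, 0)
  expect_lt(abs(ra - rb) / ra, 0.10)
})

test_that("sheetness maximum localizes the center of a Gaussian sheet", {
  n <- 41
  w <- 2 # profile half-width (sigma) in voxels
  v <- gaussian_plane_volume(n, c(0, 0, 1), sigma_mm = w)
  e <- enhance_volume(v, sigma_mm = w)
  c0 <- (n + 1) / 2
  prof <- e$data[c0, c0, ]
  expect_lte(abs(which.max(prof) - c0), 1)
})

test_that("structure classification reproduces the eigenvalue conditions", {
  expect_equal(classify_structure(0, 0, -5), "surface")
  expect_equal(classify_structure(0, -5, -5), "tube")
  expect_equal(classify_structure(-5, -5, -5), "sphere")
  expect_equal(classify_structure(5, 0, -5), "none")
  expect_equal(classify_structure(0, 0, 0), "none")
  expect_error(classify_structure(-1, 0, 1), "ordered")
})
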