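test_that("rigid transforms form a group and validate their invariants", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "reflection")
  set.seed(10)
  R <- random_rotation()
  tr <- rigid_transform(R, c(1, -2, 3))
  inv <- rt_invert(tr)
  comp <- rt_compose(inv, tr)
  expect_lt(max(abs(comp$R - diag(3))), 1e-12)
  expect_lt(max(abs(comp$t)), 1e-12)
  pts <- matrix(rnorm(30), ncol = 3)
  expect_equal(rt_apply(inv, rt_apply(tr, pts)), pts, tolerance = 1e-12)
  ab <- rt_compose(tr, inv)
  expect_lt(max(abs(rt_apply(ab, pts) - pts)), 1e-12)
})

test_that("landmark alignment solves the orthogonal Procrustes problem", {
  set.seed(11)
  src <- matrix(rnorm(12), ncol = 3)
  expect_lt(max(abs(landmark_align(src, src)$R - diag(3))), 1e-9)
  R <- random_rotation(); tv <- c(4, -1, 2)
  dst <- sweep(src %*% t(R), 2, tv, "+")
  fit <- landmark_align(src, dst)
  expect_lt(max(abs(fit$R - R)), 1e-9)
  expect_lt(max(abs(fit$t - tv)), 1e-9)
  col <- cbind(1:3, 2 * (1:3), -1 * (1:3)) # collinear points
  expect_error(landmark_align(col, col + 1), "collinear")
  # optimality: no random rigid transform does better on noisy pairs
  src2 <- matrix(rnorm(30), ncol = 3)
  dst2 <- sweep(src2 %*% t(R), 2, tv, "+") + matrix(rnorm(30, sd = 0.3), ncol = 3)
  best <- landmark_align(src2, dst2)
  res_best <- sum((rt_apply(best, src2) - dst2)^2)
  for (i in 1:1000) {
    cand <- rigid_transform(random_rotation(), rnorm(3, sd = 3))
    expect_gte(sum((rt_apply(cand, src2) - dst2)^2), res_best - 1e-9)
  }
})

test_that("mesh subsampling clamps, is seed-deterministic and contained", {
  v <- matrix(rnorm(1500 * 3), ncol = 3)
  m <- surface_mesh(v, matrix(integer(), 0, 3))
  expect_equal(nrow(subsample_mesh(m, 2000, seed = 0)), 1500)
  s1 <- subsample_mesh(m, 100, seed = 3)
  s2 <- subsample_mesh(m, 100, seed = 3)
  s3 <- subsample_mesh(m, 100, seed = 4)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_true(all(s1 %in% v))
  # the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(subsample_mesh(m, 10, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("ICP recovers exact rigid motion and its RMS never increases", {
  set.seed(12)
  pts <- matrix(runif(600, -10, 10), ncol = 3)
  same <- icp(pts, pts)
  expect_lt(max(abs(same$transform$R - diag(3))), 1e-9)
  expect_lt(max(abs(same$transform$t)), 1e-9)
  expect_lt(same$rms, 1e-12)

  # small known motion, init within 10 deg / 5 mm of truth
  ang <- 8 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  tv <- c(2, -3, 1)
  fixed <- sweep(pts %*% t(R), 2, tv, "+")
  res <- icp(pts, fixed, init = rigid_transform())
  expect_true(res$converged)
  expect_lt(max(abs(res$transform$R - R)), 1e-6)
  expect_lt(max(abs(res$transform$t - tv)), 1e-6)

  for (trial in 1:50) {
    moving <- matrix(runif(150, -5, 5), ncol = 3)
    fixed <- matrix(runif(150, -5, 5), ncol = 3)
    r <- icp(moving, fixed, max_iter = 20)
    expect_true(all(diff(r$rms_history[-1]) <= 1e-9))
  }
})

test_that("surface distance is the nearest-vertex distance, per the oracle", {
  set.seed(13)
  va <- matrix(rnorm(90), ncol = 3)
  ma <- surface_mesh(va, matrix(integer(), 0, 3))
  expect_equal(surface_distance(ma, ma)$mean, 0)

  grid <- as.matrix(expand.grid(x = seq(0, 5, by = 0.25),
                                y = seq(0, 5, by = 0.25), z = 0))
  plane <- surface_mesh(grid, matrix(integer(), 0, 3))
  shifted <- surface_mesh(sweep(grid, 2, c(0, 0, 0.5), "+"),
                          matrix(integer(), 0, 3))
  sd_ <- surface_distance(shifted, plane)
  expect_equal(sd_$mean, 0.5, tolerance = 1e-9) # normal shift: exact here
  expect_equal(sd_$max, 0.5, tolerance = 1e-9)

  vb <- matrix(rnorm(120), ncol = 3)
  mb <- surface_mesh(vb, matrix(integer(), 0, 3))
  got <- surface_distance(ma, mb)
  oracle <- nn_bruteforce(vb, va)
  expect_equal(got$distances, oracle$dist, tolerance = 1e-12)
  expect_equal(got$mean, mean(oracle$dist), tolerance = 1e-12)
  expect_equal(got$max, max(oracle$dist), tolerance = 1e-12)
})

test_that("TRE matches closed forms and is invariant to common motion", {
  set.seed(14)
  v <- matrix(rnorm(300), ncol = 3)
  m <- surface_mesh(v, matrix(integer(), 0, 3))
  expect_equal(tre(m, m)$mean, 0)
  tv <- c(1, 2, -2)
  mt <- surface_mesh(sweep(v, 2, tv, "+"), matrix(integer(), 0, 3))
  t1 <- tre(m, mt)
  expect_equal(t1$mean, sqrt(sum(tv^2)), tolerance = 1e-12)
  expect_equal(t1$sd, 0, tolerance = 1e-12)
  # rotation about the centroid: per-vertex chord 2 r sin(theta/2)
  ctr <- colMeans(v)
  th <- 0.3
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  vr <- sweep(sweep(v, 2, ctr) %*% t(Rz), 2, ctr, "+")
  t2 <- tre(m, surface_mesh(vr, matrix(integer(), 0, 3)))
  vc <- sweep(v, 2, ctr)
  r_xy <- sqrt(vc[, 1]^2 + vc[, 2]^2) # chord in the rotation plane
  expect_equal(t2$distances, 2 * r_xy * sin(th / 2), tolerance = 1e-9)
  expect_error(tre(m, surface_mesh(v[1:50, ], matrix(integer(), 0, 3))),
               "correspondence")
  # common rigid transform leaves TRE unchanged
  tr <- rigid_transform(random_rotation(), c(5, 5, 5))
  t3 <- tre(transform_mesh(m, tr), transform_mesh(mt, tr))
  expect_equal(t3$distances, t1$distances, tolerance = 1e-9)
})

test_that("CT-to-US registration converges to near identity when aligned", {
  set.seed(15)
  spec <- test_phantom_spec()
  ct <- make_ct_mesh(spec, margin = 3, nu = 80, nv = 48)
  us_part <- ct$vertices[ct$vertices[, 3] < spec$surface_depth + 3 &
                           abs(ct$vertices[, 1] - 9.6) < 6, ]
  us <- surface_mesh(us_part, matrix(integer(), 0, 3), label = "US-intraop")
  reg <- register_ct_to_us(ct, us, landmarks = NULL, n = 800, seed = 1)
  expect_lt(max(abs(reg$transform$R - diag(3))), 0.02)
  expect_lt(max(abs(reg$transform$t)), 0.2)
})
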