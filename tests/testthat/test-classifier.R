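sim_class_data <- function(n, means, sds = NULL) {
  # simple diagonal-covariance 5-D Gaussians, one block per class
  sds <- sds %||% lapply(means, function(m) rep(1, 5))
  X <- do.call(rbind, lapply(seq_along(means), function(k)
    sweep(sweep(matrix(rnorm(n[k] * 5), ncol = 5), 2, sds[[k]], "*"),
          2, means[[k]], "+")))
  lab <- rep(c("bone", "tissue", "shadow"), times = n)
  list(X = X, lab = lab)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("priors equal the training sample proportions", {
  set.seed(1)
  d <- sim_class_data(c(100, 300, 100),
                      list(rep(0, 5), rep(5, 5), rep(-5, 5)))
  m <- bone_qda(d$X, d$lab)
  pr <- vapply(m$classes, `[[`, 0, "prior")
  expect_equal(unname(pr), c(0.2, 0.6, 0.2))
  expect_equal(sum(pr), 1)
})

test_that("discriminant matches hand-evaluated values", {
  mu <- c(1, 2, 3, 4, 5)
  m <- make_qda_model(list(mu, mu + 100, mu - 100),
                      list(diag(5), diag(5), diag(5)),
                      c(1, 1, 1)) # P = 1 per class: the ln P term vanishes
  y0 <- qda_discriminant(m, matrix(mu, 1))
  expect_equal(unname(y0[1, "bone"]), 0, tolerance = 1e-12)
  x <- mu; x[1] <- x[1] + 1; x[2] <- x[2] + 1 # ||x - mu||^2 = 2
  y1 <- qda_discriminant(m, matrix(x, 1))
  expect_equal(unname(y1[1, "bone"]), -1, tolerance = 1e-12)
  expect_error(qda_discriminant(m, matrix(c(NA, 1, 1, 1, 1), 1)), "finite")
})

test_that("with identity covariances and equal priors argmax is nearest mean", {
  set.seed(2)
  means <- list(c(0, 0, 0, 0, 0), c(3, 0, 0, 0, 0), c(0, 3, 0, 0, 0))
  m <- make_qda_model(means, list(diag(5), diag(5), diag(5)), rep(1 / 3, 3))
  X <- matrix(rnorm(5000, sd = 3), ncol = 5)
  Y <- qda_discriminant(m, X)
  got <- max.col(Y, ties.method = "first")
  nearest <- apply(X, 1, function(x)
    which.min(vapply(means, function(mu) sum((x - mu)^2), 0)))
  expect_equal(got, nearest)
})

test_that("dropping the evidence term preserves the posterior argmax", {
  set.seed(3)
  n <- c(150, 300, 250)
  d <- sim_class_data(n, list(rep(0, 5), rep(2, 5), rep(-2, 5)),
                      list(rep(1, 5), rep(2, 5), rep(0.5, 5)))
  model <- bone_qda(d$X, d$lab)
  X <- matrix(rnorm(3000, sd = 2.5), ncol = 5)
  Y <- qda_discriminant(model, X)
  # brute-force Bayes posterior with explicit normalization over classes
  dens <- vapply(model$classes, function(ck) {
    apply(X, 1, function(x) {
      q <- x - ck$mean
      exp(-0.5 * as.numeric(q %*% solve(ck$cov, q))) /
        sqrt((2 * pi)^5 * det(ck$cov)) * ck$prior
    })
  }, numeric(nrow(X)))
  post <- dens / rowSums(dens)
  expect_equal(max.col(Y, ties.method = "first"),
               max.col(post, ties.method = "first"))
  # the bone rule with strict inequalities agrees voxel-wise
  mask_y <- Y[, 1] > Y[, 2] & Y[, 1] > Y[, 3]
  mask_p <- post[, 1] > post[, 2] & post[, 1] > post[, 3]
  expect_equal(mask_y, mask_p)
})

test_that("class means are recovered within 3 standard errors at n = 1e4", {
  set.seed(4)
  truth <- list(c(0, 1, 2, 3, 4), c(10, 11, 12, 13, 14), c(-8, -7, -6, -5, -4))
  d <- sim_class_data(c(1e4, 1e4, 1e4), truth)
  m <- bone_qda(d$X, d$lab)
  for (k in 1:3) {
    se <- sqrt(diag(m$classes[[k]]$cov) / 1e4)
    expect_true(all(abs(m$classes[[k]]$mean - truth[[k]]) < 3 * se))
  }
})

test_that("well-separated classes classify almost perfectly", {
  set.seed(5)
  truth <- list(rep(0, 5), rep(10, 5), rep(-10, 5)) # 10 sd apart
  d <- sim_class_data(c(4000, 4000, 4000), truth)
  m <- bone_qda(d$X, d$lab)
  pred <- predict(m, d$X)
  acc <- mean((pred == "bone") == (d$lab == "bone"))
  expect_gt(acc, 0.999)
})

test_that("ties go to background and a larger bone prior never shrinks the mask", {
  mu <- rep(0, 5)
  m_tie <- make_qda_model(list(mu, mu, mu), list(diag(5), diag(5), diag(5)),
                          rep(1 / 3, 3))
  X <- matrix(rnorm(500), ncol = 5)
  expect_true(all(predict(m_tie, X) == "background"))
  set.seed(6)
  means <- list(rep(0, 5), rep(2, 5), rep(-2, 5))
  covs <- list(diag(5), diag(5), diag(5))
  X <- matrix(rnorm(5000, sd = 2), ncol = 5)
  masks <- lapply(c(0.05, 0.2, 0.6), function(p) {
    m <- make_qda_model(means, covs, c(p, (1 - p) / 2, (1 - p) / 2))
    predict(m, X) == "bone"
  })
  expect_true(all(masks[[1]] <= masks[[2]]))
  expect_true(all(masks[[2]] <= masks[[3]]))
})

test_that("degenerate training inputs raise training errors", {
  X <- rbind(matrix(rnorm(500), ncol = 5),
             matrix(rnorm(500, mean = 5), ncol = 5))
  lab <- c(rep("bone", 100), rep("tissue", 100))
  expect_error(bone_qda(X, lab), "shadow")
  # identical vectors only in one class: singular covariance
  X2 <- rbind(matrix(1, 10, 5), matrix(rnorm(500), ncol = 5),
              matrix(rnorm(500, mean = 5), ncol = 5))
  lab2 <- c(rep("bone", 10), rep("tissue", 100), rep("shadow", 100))
  expect_error(bone_qda(X2, lab2), "singular")
})

test_that("model JSON serialization round-trips the discriminants", {
  set.seed(7)
  d <- sim_class_data(c(200, 200, 200),
                      list(rep(0, 5), rep(3, 5), rep(-3, 5)))
  m <- bone_qda(d$X, d$lab, window = 9L, sigma_mm = 0.5)
  p <- tempfile(fileext = ".json")
  write_model(m, p)
  m2 <- read_model(p)
  X <- matrix(rnorm(500), ncol = 5)
  expect_equal(qda_discriminant(m, X), qda_discriminant(m2, X),
               tolerance = 1e-12)
  expect_equal(m2$window, 9L)
  unlink(p)
})
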