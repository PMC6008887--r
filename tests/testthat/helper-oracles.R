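# Independent brute-force oracles and small fixtures used across the suite.

# reflect (symmetric, edge-repeating) index, 1-based
reflect_idx <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  j[j < 0] <- j[j < 0] + 2 * n
  ifelse(j < n, j + 1, 2 * n - j)
}

# direct sliding-window moments with reflect padding (triple loop; the oracle
# for the incremental implementation)
direct_window_moments <- function(a, window) {
  d <- dim(a); h <- window %/% 2
  mu <- va <- sk <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    vals <- a[reflect_idx(i + (-h:h), d[1]),
              reflect_idx(j + (-h:h), d[2]),
              reflect_idx(k + (-h:h), d[3])]
    m <- mean(vals)
    m2 <- mean((vals - m)^2)
    m3 <- mean((vals - m)^3)
    mu[i, j, k] <- m
    va[i, j, k] <- m2
    sk[i, j, k] <- if (m2 <= 1e-12 * (1 + m^2)) 0 else m3 / m2^1.5
  }
  list(mu = mu, var = va, skew = sk)
}

# breadth-first 26-connected flood fill (oracle for region_grow)
flood_fill_oracle <- function(mask, seeds) {
  d <- dim(mask)
  out <- array(FALSE, d)
  queue <- as.list(seeds)
  for (s in seeds) out[arrayInd(s, d)] <- TRUE
  while (length(queue)) {
    idx <- queue[[1]]; queue <- queue[-1]
    ijk <- arrayInd(idx, d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (!dx && !dy && !dz) next
      p <- ijk + c(dx, dy, dz)
      if (any(p < 1) || any(p > d)) next
      lin <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
      if (mask[lin] != 0 && !out[lin]) {
        out[lin] <- TRUE
        queue[[length(queue) + 1]] <- lin
      }
    }
  }
  out
}

# all-pairs nearest-neighbour (oracle for the kd-tree)
nn_bruteforce <- function(ref, query) {
  idx <- integer(nrow(query)); dd <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    d2 <- colSums((t(ref) - query[i, ])^2)
    idx[i] <- which.min(d2) # which.min takes the first (lowest index) on ties
    dd[i] <- sqrt(d2[idx[i]])
  }
  list(index = idx, dist = dd)
}

# hand-built Gaussian Bayes model with given parameters
make_qda_model <- function(means, covs, priors) {
  cls <- c("bone", "tissue", "shadow")
  classes <- lapply(seq_along(cls), function(k) {
    R <- chol(covs[[k]])
    list(name = cls[k], mean = means[[k]], cov = covs[[k]], chol = R,
         logdet = 2 * sum(log(diag(R))), prior = priors[k])
  })
  names(classes) <- cls
  structure(list(classes = classes, counts = rep(NA_integer_, 3),
                 n_train = NA_integer_, window = 9L, sigma_mm = 0.5,
                 alpha = 0.5, gamma = 1),
            class = "bone_qda")
}

# coarse phantom for fast tests: same geometry at 0.3 mm voxels
test_phantom_spec <- function(...) {
  phantom_spec(shape = c(64L, 64L, 64L), spacing = 0.3, ...)
}

# one shared coarse phantom + classifier for the pipeline tests (built once
# per test run)
test_model_cache <- new.env(parent = emptyenv())
get_test_model <- function() {
  if (is.null(test_model_cache$model))
    test_model_cache$model <- train_phantom_model(test_phantom_spec(), size = 64L)
  test_model_cache$model
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
}

mesh_euler_characteristic <- function(mesh) {
  ed <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(1, 3)])
  ed <- unique(t(apply(ed, 1, sort)))
  nrow(mesh$vertices) - nrow(ed) + nrow(mesh$faces)
}
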