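BONE_CLASSES <- c("bone", "tissue", "shadow")

normalize_labels <- function(labels) {
  labels <- as.vector(labels)
  if (is.numeric(labels)) {
    out <- rep(NA_character_, length(labels))
    out[labels == 1] <- "bone"; out[labels == 2] <- "tissue"; out[labels == 3] <- "shadow"
    return(out)
  }
  labels <- as.character(labels)
  labels[!labels %in% BONE_CLASSES] <- NA_character_
  labels
}

#' Gaussian Bayes (quadratic discriminant) voxel classifier
#'
#' Fits one multivariate Gaussian per class (bone, soft tissue, acoustic
#' shadow) to labeled voxel feature vectors: per-class sample mean, sample
#' covariance and prior equal to the class share of the labeled voxels. The
#' discriminant of a feature vector x for class k is
#' \deqn{Y_k(x) = -\frac12 (x-\mu_k)^T \Sigma_k^{-1} (x-\mu_k)
#'   - \frac12 \ln|\Sigma_k| + \ln P(C_k),}
#' the log posterior up to the class-independent evidence term, so the argmax
#' over classes equals the Bayes rule. A voxel is labeled bone only when
#' Y_bone strictly exceeds both other discriminants (ties go to background).
#'
#' Covariances are used via Cholesky factorization; if a class covariance is
#' not positive definite, a ridge \code{eps*I} with
#' \code{eps = 1e-6 * trace(cov)/5} is added once before failing.
#'
#' @param x A \code{voxel_features} object or n x 5 feature matrix.
#' @param labels Per-voxel labels: character ("bone", "tissue", "shadow",
#'   anything else = unlabeled) or integer codes (1, 2, 3; 0/NA = unlabeled),
#'   same length/shape as the feature field.
#' @param min_per_class Minimum labeled voxels per class (default 6).
#' @param window,sigma_mm,alpha,gamma Optional metadata recording the feature
#'   extraction settings the model expects; stored and re-used by
#'   [segment_bone()].
#' @return An object of class \code{bone_qda}.
#' @seealso [predict.bone_qda()], [qda_discriminant()], [classify_volume()]
#' @export
bone_qda <- function(x, labels, min_per_class = 6L,
                     window = NULL, sigma_mm = NULL, alpha = 0.5, gamma = 1) {
  if (inherits(x, "voxel_features") && is.null(window))
    window <- attr(x, "window")
  X <- feature_matrix(x)
  lab <- normalize_labels(labels)
  if (length(lab) != nrow(X)) stop("labels and features disagree in length")
  keep <- !is.na(lab)
  if (!any(keep)) stop("no labeled voxels")
  X <- X[keep, , drop = FALSE]
  lab <- lab[keep]
  if (any(!is.finite(X))) stop("non-finite feature values among labeled voxels")

  counts <- table(factor(lab, levels = BONE_CLASSES))
  if (any(counts < min_per_class))
    stop("training error: classes with too few labeled voxels: ",
         paste(BONE_CLASSES[counts < min_per_class], collapse = ", "))
  total <- sum(counts)

  classes <- lapply(BONE_CLASSES, function(cl) {
    Xk <- X[lab == cl, , drop = FALSE]
    mu <- colMeans(Xk)
    cov <- stats::cov(Xk)
    R <- tryCatch(chol(cov), error = function(e) NULL)
    if (is.null(R)) {
      eps <- 1e-6 * sum(diag(cov)) / 5
      R <- tryCatch(chol(cov + diag(eps, 5)), error = function(e) NULL)
      if (is.null(R))
        stop("numeric error: singular covariance for class '", cl, "'")
      cov <- cov + diag(eps, 5)
    }
    list(name = cl, mean = mu, cov = cov, chol = R,
         logdet = 2 * sum(log(diag(R))),
         prior = as.numeric(counts[cl]) / total)
  })
  names(classes) <- BONE_CLASSES
  structure(list(classes = classes, counts = as.vector(counts),
                 n_train = total, window = window, sigma_mm = sigma_mm,
                 alpha = alpha, gamma = gamma),
            class = "bone_qda")
}

#' Quadratic discriminant scores
#'
#' Evaluates the per-class discriminant \eqn{Y_k} for each feature vector.
#'
#' @param model A \code{bone_qda} fit.
#' @param x Feature matrix (n x 5) or \code{voxel_features}.
#' @return n x 3 matrix of scores with columns bone, tissue, shadow.
#' @export
qda_discriminant <- function(model, x) {
  if (!inherits(model, "bone_qda")) stop("`model` must be a bone_qda fit")
  X <- feature_matrix(x)
  if (any(!is.finite(X))) stop("non-finite feature values")
  out <- matrix(NA_real_, nrow(X), 3, dimnames = list(NULL, BONE_CLASSES))
  for (cl in BONE_CLASSES) {
    ck <- model$classes[[cl]]
    Xc <- sweep(X, 2, ck$mean)
    Z <- Xc %*% backsolve(ck$chol, diag(5))
    out[, cl] <- -0.5 * rowSums(Z * Z) - 0.5 * ck$logdet + log(ck$prior)
  }
  out
}

#' @export
print.bone_qda <- function(x, ...) {
  cat("<bone_qda> Gaussian Bayes voxel classifier (bone / tissue / shadow)\n")
  cat(sprintf("  trained on %d labeled voxels (bone %d, tissue %d, shadow %d)\n",
              x$n_train, x$counts[1], x$counts[2], x$counts[3]))
  cat(sprintf("  priors: %s\n",
              paste(sprintf("%s %.3f", BONE_CLASSES,
                            vapply(x$classes, `[[`, 0, "prior")), collapse = ", ")))
  if (!is.null(x$window))
    cat(sprintf("  feature window: %d^3; sheetness sigma: %s mm\n", x$window,
                if (is.null(x$sigma_mm)) "?" else format(x$sigma_mm)))
  invisible(x)
}

#' @export
summary.bone_qda <- function(object, ...) {
  print(object)
  for (cl in BONE_CLASSES) {
    ck <- object$classes[[cl]]
    cat(sprintf("\nclass %s (prior %.3f):\n", cl, ck$prior))
    cat("  mean: ", paste(signif(ck$mean, 4), collapse = ", "), "\n")
    cat("  cov diag: ", paste(signif(diag(ck$cov), 4), collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
coef.bone_qda <- function(object, ...) {
  t(vapply(object$classes, `[[`, numeric(5), "mean"))
}

#' Predict method for the bone classifier
#'
#' @param object A \code{bone_qda} fit.
#' @param newdata Feature matrix or \code{voxel_features}.
#' @param type "class" for hard labels ("bone"/"background", ties to
#'   background), "scores" for the n x 3 discriminant matrix.
#' @param ... Unused.
#' @return See \code{type}.
#' @export
predict.bone_qda <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  Y <- qda_discriminant(object, newdata)
  if (type == "scores") return(Y)
  ifelse(Y[, "bone"] > Y[, "tissue"] & Y[, "bone"] > Y[, "shadow"],
         "bone", "background")
}

#' Classify a whole volume into a bone mask and bone-score volume
#'
#' Applies the trained discriminants voxel-wise. The mask is 1 exactly where
#' Y_bone strictly exceeds both Y_tissue and Y_shadow; the score volume stores
#' Y_bone for downstream seed ranking.
#'
#' @param features A \code{voxel_features} field.
#' @param model A \code{bone_qda} fit.
#' @return List with \code{mask} (0/1 \code{image_volume}) and \code{score}
#'   (Y_bone \code{image_volume}).
#' @export
classify_volume <- function(features, model) {
  if (!inherits(features, "voxel_features"))
    stop("`features` must be a voxel_features field")
  dims <- dim(features$i_raw)
  Y <- qda_discriminant(model, features)
  mask <- as.numeric(Y[, "bone"] > Y[, "tissue"] & Y[, "bone"] > Y[, "shadow"])
  sp <- attr(features, "spacing"); or <- attr(features, "origin")
  list(mask = image_volume(array(mask, dims), spacing = sp, origin = or),
       score = image_volume(array(Y[, "bone"], dims), spacing = sp, origin = or))
}

#' Save / load a classifier as JSON
#'
#' Stores class means, covariances and priors together with the feature
#' settings (window, sheetness sigma/alpha/gamma) needed to reproduce the
#' feature field.
#'
#' @param model A \code{bone_qda} fit.
#' @param path JSON file path.
#' @return \code{write_model}: invisibly, \code{path}; \code{read_model}: the
#'   restored \code{bone_qda}.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "bone_qda")) stop("`model` must be a bone_qda fit")
  payload <- list(
    format = "bonecho_qda_v1",
    window = model$window, sigma_mm = model$sigma_mm,
    alpha = model$alpha, gamma = model$gamma,
    counts = model$counts, n_train = model$n_train,
    classes = lapply(model$classes, function(ck)
      list(name = ck$name, mean = ck$mean, cov = ck$cov, prior = ck$prior))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "bonecho_qda_v1")) stop("not a bonecho model file")
  classes <- lapply(BONE_CLASSES, function(cl) {
    ck <- p$classes[[cl]]
    cov <- matrix(unlist(ck$cov), 5, 5)
    R <- chol(cov)
    list(name = cl, mean = as.numeric(ck$mean), cov = cov, chol = R,
         logdet = 2 * sum(log(diag(R))), prior = ck$prior)
  })
  names(classes) <- BONE_CLASSES
  structure(list(classes = classes, counts = p$counts, n_train = p$n_train,
                 window = p$window, sigma_mm = p$sigma_mm,
                 alpha = p$alpha, gamma = p$gamma),
            class = "bone_qda")
}
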