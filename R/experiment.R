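#' Run a seeded suite of synthetic segmentation / registration experiments
#'
#' Emulates the twelve-acquisition evaluation protocol on the synthetic
#' phantom: for each experiment a different section and in-volume attitude of
#' the bone is drawn, the ultrasound volume is simulated and segmented with
#' one shared classifier, the segmentation error against the ground-truth
#' centerline surface is measured, and (optionally) the preoperative CT mesh
#' is registered via jittered landmarks + ICP under a random rigid pose and
#' the target registration error against the exactly-posed reference CT mesh
#' is computed. Fully reproducible from \code{(spec, base_seed)}.
#'
#' @param n_experiments Number of experiments, default 12.
#' @param base_seed Base RNG seed; per-experiment seeds are derived from it.
#' @param spec Phantom family, default [phantom_spec()] (160^3 voxels at
#'   0.115 mm).
#' @param model A trained \code{bone_qda}; if NULL one is trained on a 150^3
#'   synthetic block of the same family (training happens once, not per
#'   experiment).
#' @param registration Run the registration stage too? Default TRUE.
#' @param n_subsample ICP subsample size, default 2000.
#' @param landmark_jitter Landmark RMS jitter in mm, default 2.
#' @param max_rot_deg,max_trans_mm Random pose ranges, defaults 30 deg, 20 mm.
#' @param verbose Print one line per experiment.
#' @return Object of class \code{bonecho_suite}: \code{results} data frame
#'   (one row per experiment), \code{overall} summary list, \code{errors}
#'   (messages of failed experiments, if any) and the run parameters.
#' @export
run_experiment_suite <- function(n_experiments = 12L, base_seed = 0L,
                                 spec = phantom_spec(), model = NULL,
                                 registration = TRUE, n_subsample = 2000L,
                                 landmark_jitter = 2, max_rot_deg = 30,
                                 max_trans_mm = 20, verbose = FALSE) {
  if (is.null(model)) model <- train_phantom_model(spec)

  rows <- vector("list", n_experiments)
  errors <- character(0)
  for (i in seq_len(n_experiments)) {
    si <- as.integer(base_seed) + 7919L * i
    row <- tryCatch({
      spec_i <- spec
      pars <- with_seed(si, list(
        section = stats::runif(1, -3, 3),
        tilt = stats::runif(2, -6, 6),
        offset = stats::runif(2, -0.8, 0.8)
      ))
      spec_i$section_offset <- pars$section
      spec_i$tilt_deg <- pars$tilt
      spec_i$offset <- pars$offset
      pose <- random_pose(si + 1L, max_rot_deg, max_trans_mm)
      exper <- generate_registration_experiment(
        spec_i, pose, seed = si + 2L, landmark_jitter = landmark_jitter)
      seg <- segment_bone(exper$volume, model)
      sdist <- surface_distance(seg$mesh, exper$truth$center_surface_mesh)
      row <- data.frame(
        experiment = i, seed = si,
        seg_max = sdist$max, seg_mean = sdist$mean, seg_sd = sdist$sd,
        n_vertices = nrow(seg$mesh$vertices),
        tre_min = NA_real_, tre_max = NA_real_, tre_mean = NA_real_,
        tre_sd = NA_real_, icp_rms = NA_real_, icp_iterations = NA_integer_)
      if (registration) {
        reg <- register_ct_to_us(exper$ct_preop, seg$mesh,
                                 landmarks = exper$landmarks,
                                 n = n_subsample, seed = si + 3L)
        terr <- tre(reg$mesh, exper$ct_ref)
        row$tre_min <- terr$min; row$tre_max <- terr$max
        row$tre_mean <- terr$mean; row$tre_sd <- terr$sd
        row$icp_rms <- reg$icp$rms
        row$icp_iterations <- reg$icp$iterations
      }
      if (verbose)
        cat(sprintf("experiment %2d: seg mean %.3f mm%s\n", i, row$seg_mean,
                    if (registration) sprintf(", TRE mean %.3f mm", row$tre_mean)
                    else ""))
      row
    }, error = function(e) {
      errors <<- c(errors, sprintf("experiment %d: %s", i, conditionMessage(e)))
      if (verbose) cat(sprintf("experiment %2d: FAILED (%s)\n", i,
                               conditionMessage(e)))
      NULL
    })
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)
  overall <- list(
    n = nrow(results),
    seg_mean = mean(results$seg_mean),
    seg_mean_sd = stats::sd(results$seg_mean),
    seg_worst_mean = max(results$seg_mean),
    tre_mean = if (registration) mean(results$tre_mean) else NA_real_,
    tre_mean_sd = if (registration) stats::sd(results$tre_mean) else NA_real_,
    tre_worst_mean = if (registration) max(results$tre_mean) else NA_real_
  )
  structure(list(results = results, overall = overall, errors = errors,
                 params = list(n_experiments = n_experiments,
                               base_seed = base_seed, spec = spec,
                               registration = registration,
                               n_subsample = n_subsample,
                               landmark_jitter = landmark_jitter,
                               max_rot_deg = max_rot_deg,
                               max_trans_mm = max_trans_mm)),
            class = "bonecho_suite")
}

#' @export
print.bonecho_suite <- function(x, ...) {
  cat(sprintf("<bonecho_suite> %d experiments (base seed %d)\n",
              x$params$n_experiments, x$params$base_seed))
  df <- x$results
  cat("\nSegmentation error (US mesh vertex to nearest truth vertex, mm):\n")
  print(data.frame(exp = df$experiment, max = round(df$seg_max, 3),
                   mean = round(df$seg_mean, 3), sd = round(df$seg_sd, 3),
                   vertices = df$n_vertices), row.names = FALSE)
  cat(sprintf("overall mean: %.3f mm (SD of means %.3f mm), worst mean: %.3f mm\n",
              x$overall$seg_mean, x$overall$seg_mean_sd, x$overall$seg_worst_mean))
  if (x$params$registration) {
    cat("\nTarget registration error (corresponding CT vertices, mm):\n")
    print(data.frame(exp = df$experiment, min = round(df$tre_min, 3),
                     max = round(df$tre_max, 3), mean = round(df$tre_mean, 3),
                     sd = round(df$tre_sd, 3)), row.names = FALSE)
    cat(sprintf("overall mean TRE: %.3f mm, worst mean TRE: %.3f mm\n",
                x$overall$tre_mean, x$overall$tre_worst_mean))
  }
  if (length(x$errors))
    cat("\nfailed experiments:\n", paste(" ", x$errors, collapse = "\n"), "\n")
  invisible(x)
}
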