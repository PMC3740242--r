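#' Simulate a head-motion trace
#'
#' Seeded Gaussian random walk: per-volume increments of the 3 translation
#' axes (mm) and 3 rotation axes (deg).
#'
#' @param n_volumes Number of volumes.
#' @param scale_translation,scale_rotation Per-volume step standard
#'   deviations (mm, deg).  0 gives an identically zero trace.
#' @return `n_volumes` x 6 matrix (columns `tx,ty,tz,rx,ry,rz`).
#' @export
simulate_motion <- function(n_volumes, scale_translation = 0.02,
                            scale_rotation = 0.02) {
  steps <- cbind(
    matrix(stats::rnorm(3 * n_volumes, sd = scale_translation), ncol = 3),
    matrix(stats::rnorm(3 * n_volumes, sd = scale_rotation), ncol = 3))
  steps[1L, ] <- 0
  m <- apply(steps, 2, cumsum)
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Simulate a block-design fMRI time series for one run
#'
#' Per-voxel signal in arbitrary units around a carrier level of 100 (so
#' that a response of `r` % signal change adds `r` units at the block
#' plateau): baseline carrier, plus each exemplar's noiseless response
#' pattern modulated by its HRF-convolved block boxcar, plus white Gaussian
#' noise, plus a head-motion artifact whose per-volume amplitude is
#' proportional to the volume-to-volume motion magnitude.  By default the
#' artifact is spatially white at the voxel scale (independent across
#' voxels), concentrating its energy in high spatial-frequency bands;
#' `artifact_spatial = "smooth"` low-passes it over the ROI instead.
#'
#' @param model A [build_model()] result.
#' @param schedule A [schedule_runs()] object.
#' @param responses Named list with elements `A` and `B`: noiseless
#'   per-voxel responses (% signal change) from [voxel_response()].
#' @param sigma_white Temporal noise SD, % signal change per volume.
#' @param motion_scale Per-volume motion random-walk step SD (mm and deg);
#'   0 gives a zero trace and no artifact.
#' @param artifact_gain Artifact amplitude, % signal change per unit of
#'   volume-to-volume motion magnitude.
#' @param artifact_spatial `"white"` or `"smooth"`.
#' @param hrf_args Optional [hrf()] parameter list.
#' @return List: `series` (volumes x voxels), `motion` (volumes x 6),
#'   `schedule`.
#' @export
simulate_timeseries <- function(model, schedule, responses,
                                sigma_white = 1.1, motion_scale = 0.02,
                                artifact_gain = 60,
                                artifact_spatial = c("white", "smooth"),
                                hrf_args = list()) {
  artifact_spatial <- match.arg(artifact_spatial)
  n_vol <- schedule$n_volumes
  n_vox <- nrow(model$rf)
  times <- (seq_len(n_vol) - 1L) * schedule$TR
  blocks <- schedule$blocks

  sig <- matrix(100, n_vol, n_vox)
  for (ex in c("A", "B")) {
    b <- blocks[blocks$exemplar == ex, ]
    reg <- .convolved_regressor(b$onset, b$duration, times, schedule$TR,
                                hrf_args = hrf_args)
    sig <- sig + outer(reg, responses[[ex]])
  }
  sig <- sig + matrix(stats::rnorm(n_vol * n_vox, sd = sigma_white),
                      n_vol, n_vox)

  motion <- if (motion_scale > 0) {
    simulate_motion(n_vol, motion_scale, motion_scale)
  } else {
    matrix(0, n_vol, 6,
           dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
  }
  if (motion_scale > 0 && artifact_gain > 0) {
    d <- abs(diff(motion))
    step <- c(0, (rowMeans(d[, 1:3, drop = FALSE]) +
                    rowMeans(d[, 4:6, drop = FALSE])) / 2)
    art <- matrix(stats::rnorm(n_vol * n_vox), n_vol, n_vox)
    if (artifact_spatial == "smooth") {
      S <- smoothing_matrix(model$voxel_positions, fwhm = 8)
      art <- art %*% t(S)
    }
    sig <- sig + artifact_gain * step * art
  }
  list(series = sig, motion = motion, schedule = schedule)
}

#' Simulate one subject's session and estimate activity patterns
#'
#' Builds (or takes) a subject's cortical model, simulates `n_runs` runs per
#' stimulus family (both exemplars per run), fits the run-wise GLM with
#' motion confounds, and combines runs into a `pattern_set` per family.
#'
#' @param model A [build_model()] result, or `NULL` to build one from
#'   `model_args`.
#' @param families Character vector of stimulus families to simulate.
#' @param n_runs Runs per family.
#' @param schedule A [schedule_runs()] object.
#' @param seed Integer seed (controls model, noise and motion).
#' @param sigma_white,motion_scale,artifact_gain,artifact_spatial See
#'   [simulate_timeseries()].
#' @param model_args List of [build_model()] arguments used when `model` is
#'   `NULL`.
#' @param keep_series Keep the raw time series in the result (memory-heavy).
#' @param subject Subject label.
#' @return A list of class `v1_subject`: `model`, `patterns` (named list of
#'   `pattern_set` per family), `motion` (named list of per-run traces, in
#'   family/run order), `motion_scale`, `schedule`, and optionally `series`.
#' @export
simulate_subject <- function(model = NULL,
                             families = c("grating", "spiral",
                                          "patchswap_grating",
                                          "patchswap_spiral"),
                             n_runs = 2, schedule = schedule_runs(),
                             seed = 1, sigma_white = 1.1,
                             motion_scale = 0.02, artifact_gain = 60,
                             artifact_spatial = "white",
                             model_args = list(), keep_series = FALSE,
                             subject = "sub01") {
  if (is.null(model)) {
    model <- do.call(build_model, c(list(seed = seed), model_args))
  }
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(seed + 1L)

  patterns <- list()
  motion <- list()
  series <- list()
  for (fam in families) {
    resp <- list(
      A = voxel_response(model, stim_spec(fam, "A", model$tiling)),
      B = voxel_response(model, stim_spec(fam, "B", model$tiling)))
    run_sets <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      ts <- simulate_timeseries(model, schedule, resp,
                                sigma_white = sigma_white,
                                motion_scale = motion_scale,
                                artifact_gain = artifact_gain,
                                artifact_spatial = artifact_spatial)
      des <- build_design(schedule, motion = ts$motion)
      run_sets[[r]] <- fit_glm(ts$series, des,
                               coords = model$voxel_positions)
      motion[[paste0(fam, "_run", r)]] <- ts$motion
      if (keep_series) series[[paste0(fam, "_run", r)]] <- ts$series
    }
    ps <- combine_patterns(run_sets)
    ps$family <- fam
    ps$subject <- subject
    patterns[[fam]] <- ps
  }
  out <- list(model = model, patterns = patterns, motion = motion,
              motion_scale = motion_scale, schedule = schedule,
              subject = subject, families = families)
  if (keep_series) out$series <- series
  structure(out, class = "v1_subject")
}

#' @export
print.v1_subject <- function(x, ...) {
  cat(sprintf("v1_subject %s: %d voxels, families: %s\n", x$subject,
              nrow(x$model$rf), paste(x$families, collapse = ", ")))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Default conditions emulate the study design: 18 subjects, ~1126-voxel V1
#' models, 2 runs per stimulus family with 4 subruns each (8 t-patterns per
#' exemplar).  Subjects vary in noise level and head-motion scale
#' (log-normal spread around the cohort defaults); each subject has an
#' independent columnar field but shares the global-map weights.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param families Stimulus families to simulate.
#' @param seed Integer cohort seed; subject seeds are derived from it.
#' @param model_args List of [build_model()] arguments shared by subjects.
#' @param sigma_white Cohort-median temporal noise SD (% signal change).
#' @param motion_scale Cohort-median motion step SD (0 disables motion).
#' @param motion_spread Log-normal SD (log units) of per-subject motion
#'   scales.
#' @param noise_spread Log-normal SD of per-subject noise SDs.
#' @param artifact_gain,artifact_spatial See [simulate_timeseries()].
#' @param n_runs Runs per family.
#' @param schedule A [schedule_runs()] object.
#' @return A list of class `v1_cohort` of `v1_subject` objects.
#' @export
simulate_cohort <- function(n_subjects = 18,
                            families = c("grating", "spiral",
                                         "patchswap_grating",
                                         "patchswap_spiral"),
                            seed = 1, model_args = list(),
                            sigma_white = 1.1, motion_scale = 0.02,
                            motion_spread = 0.5, noise_spread = 0.2,
                            artifact_gain = 60, artifact_spatial = "white",
                            n_runs = 2, schedule = schedule_runs()) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(seed)
  subj_seed <- sample.int(2^30, n_subjects)
  mscale <- motion_scale * exp(stats::rnorm(n_subjects, sd = motion_spread))
  nscale <- sigma_white * exp(stats::rnorm(n_subjects, sd = noise_spread))
  subjects <- lapply(seq_len(n_subjects), function(i) {
    simulate_subject(families = families, n_runs = n_runs,
                     schedule = schedule, seed = subj_seed[i],
                     sigma_white = nscale[i],
                     motion_scale = if (motion_scale > 0) mscale[i] else 0,
                     artifact_gain = artifact_gain,
                     artifact_spatial = artifact_spatial,
                     model_args = model_args,
                     subject = sprintf("sub%02d", i))
  })
  structure(subjects, class = "v1_cohort")
}

#' @export
print.v1_cohort <- function(x, ...) {
  cat(sprintf("v1_cohort: %d subjects (%s)\n", length(x),
              paste(x[[1L]]$families, collapse = ", ")))
  invisible(x)
}
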