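#' Boynton-style hemodynamic response function
#'
#' Delayed gamma kernel `h(t) = ((t - delta)/tau)^(n-1) * exp(-(t - delta)/tau)`
#' for `t >= delta`, 0 before, rescaled so its peak (at
#' `t = delta + tau * (n - 1)`) equals 1.
#'
#' @param t Time in seconds (vectorized; any real).
#' @param n Shape count (default 3).
#' @param tau Time constant in seconds (default 1.25).
#' @param delta Onset delay in seconds (default 2.5).
#' @return Unitless amplitudes.
#' @examples
#' hrf(5)      # 1 at the peak
#' hrf(1)      # 0 before the onset delay
#' @export
hrf <- function(t, n = 3, tau = 1.25, delta = 2.5) {
  if (n <= 0 || tau <= 0 || delta < 0) stop("hrf parameters must be positive")
  s <- pmax(t - delta, 0) / tau
  h <- s^(n - 1) * exp(-s)
  h[t < delta] <- 0
  peak <- (n - 1)^(n - 1) * exp(-(n - 1))
  h / peak
}

# boxcar for a set of (onset, duration) epochs convolved with the HRF and
# sampled at `times`; computed on a fine grid then peak-normalized
.convolved_regressor <- function(onsets, durations, times, TR,
                                 dt = 0.1, hrf_args = list()) {
  t_max <- max(times) + TR
  grid <- seq(0, t_max, by = dt)
  box <- numeric(length(grid))
  for (i in seq_along(onsets)) {
    box[grid >= onsets[i] & grid < onsets[i] + durations[i]] <- 1
  }
  h <- do.call(hrf, c(list(t = seq(0, 32, by = dt)), hrf_args))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(grid)] * dt
  conv <- pmax(conv, 0)       # clip FFT ringing; the true convolution is >= 0
  reg <- stats::approx(grid, conv, xout = times, rule = 2)$y
  if (max(reg) > 0) reg <- reg / max(reg)
  reg
}

#' Build a GLM design matrix for one run
#'
#' One task regressor per (exemplar, subrun) — each exemplar's block boxcars
#' within that subrun convolved with the [hrf()] and peak-normalized — plus
#' the six head-motion confounds and an intercept.  The first
#' `discard_volumes` volumes are dropped before modeling (replicating the
#' usual discarding of T1-saturated volumes, and keeping volume bookkeeping
#' identical to the acquisition convention).
#'
#' @param schedule A [schedule_runs()] object.
#' @param motion Motion trace: matrix/data.frame with 6 columns (3
#'   translations in mm, 3 rotations in deg), one row per volume (either all
#'   `n_volumes` rows or the retained rows only).
#' @param TR Repetition time in seconds (defaults to the schedule's).
#' @param n_volumes Number of acquired volumes (defaults to the schedule's).
#' @param discard_volumes Leading volumes dropped before modeling.
#' @param hrf_args Optional list of [hrf()] parameters.
#' @return A list of class `glm_design`: `X` (retained volumes x columns),
#'   `task_info` (data.frame mapping task columns to exemplar/subrun),
#'   `keep` (retained volume indices), `TR`.
#' @export
build_design <- function(schedule, motion = NULL, TR = schedule$TR,
                         n_volumes = schedule$n_volumes,
                         discard_volumes = 2, hrf_args = list()) {
  if (n_volumes * TR + 1e-9 < schedule$run_duration) {
    stop("invalid design: schedule longer than the acquired volumes")
  }
  keep <- seq.int(discard_volumes + 1L, n_volumes)
  times <- (keep - 1L) * TR
  blocks <- schedule$blocks
  combos <- unique(blocks[, c("exemplar", "subrun")])
  combos <- combos[order(combos$subrun, combos$exemplar), ]
  X_task <- sapply(seq_len(nrow(combos)), function(i) {
    b <- blocks[blocks$exemplar == combos$exemplar[i] &
                  blocks$subrun == combos$subrun[i], ]
    .convolved_regressor(b$onset, b$duration, times, TR, hrf_args = hrf_args)
  })
  colnames(X_task) <- paste0(combos$exemplar, "_s", combos$subrun)

  if (is.null(motion)) {
    motion <- matrix(0, length(keep), 6)
  } else {
    motion <- as.matrix(motion)
    if (nrow(motion) == n_volumes) motion <- motion[keep, , drop = FALSE]
    if (nrow(motion) != length(keep)) {
      stop("invalid design: motion trace length does not match the volumes")
    }
  }
  colnames(motion) <- paste0("motion", 1:6)
  X <- cbind(X_task, motion, intercept = 1)
  structure(list(X = X, task_info = combos, keep = keep, TR = TR),
            class = "glm_design")
}

#' Fit the voxel-wise GLM and extract t-value patterns
#'
#' Ordinary least squares per voxel;
#' `t = beta / (sigma_hat * sqrt((X'X)^-1_jj))` with
#' `sigma_hat^2 = RSS / (rows - rank)`.  Returns one t-map (and one %
#' signal-change map, `100 * beta / beta_intercept`) per task regressor.
#' All-zero confound columns (e.g. a zero motion trace) are dropped before
#' fitting.
#'
#' @param series Numeric matrix, volumes x voxels (all acquired volumes; the
#'   design's `keep` rows are used).
#' @param design A [build_design()] result.
#' @param coords Optional voxels x 3 coordinate matrix (mm), carried through.
#' @return A `pattern_set`: `t` and `psc` (voxels x patterns matrices),
#'   `meta` (data.frame: exemplar, subrun, run), `coords`.
#' @export
fit_glm <- function(series, design, coords = NULL) {
  series <- as.matrix(series)
  Y <- series[design$keep, , drop = FALSE]
  X <- design$X
  task_cols <- seq_len(nrow(design$task_info))
  drop_cols <- which(apply(X, 2, function(c) all(c == 0)))
  drop_cols <- setdiff(drop_cols, task_cols)
  if (length(drop_cols)) X <- X[, -drop_cols, drop = FALSE]
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    stop(sprintf("degenerate design: rank %d < %d columns (offending: %s)",
                 qr_x$rank, ncol(X), paste(dep, collapse = ", ")))
  }
  xtx_inv <- chol2inv(chol(crossprod(X)))
  beta <- xtx_inv %*% crossprod(X, Y)
  rownames(beta) <- colnames(X)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtx_inv_diag <- diag(xtx_inv)
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  tmat <- beta / se
  b0 <- beta[colnames(X) == "intercept", ]
  t_task <- t(tmat[task_cols, , drop = FALSE])
  psc_task <- t(100 * beta[task_cols, , drop = FALSE] /
                  rep(b0, each = length(task_cols)))
  meta <- data.frame(exemplar = design$task_info$exemplar,
                     subrun = design$task_info$subrun,
                     run = 1L)
  pattern_set(t = t_task, psc = psc_task, meta = meta, coords = coords)
}

#' Construct a pattern set
#'
#' Container for voxel activity patterns: one column of `t` (and `psc`) per
#' (exemplar, subrun, run) condition.
#'
#' @param t Voxels x patterns matrix of t-values.
#' @param psc Optional matching matrix of % signal change.
#' @param meta data.frame with one row per pattern: `exemplar`, `subrun`,
#'   `run`.
#' @param coords Optional voxels x 3 matrix of coordinates in mm.
#' @param family Optional stimulus-family label.
#' @param subject Optional subject label.
#' @return An object of class `pattern_set`.
#' @export
pattern_set <- function(t, psc = NULL, meta, coords = NULL,
                        family = NULL, subject = NULL) {
  t <- as.matrix(t)
  stopifnot(nrow(meta) == ncol(t))
  if (!is.null(coords)) stopifnot(nrow(coords) == nrow(t))
  structure(list(t = t, psc = psc, meta = meta, coords = coords,
                 family = family, subject = subject),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: %d voxels x %d patterns (%d run(s), exemplars: %s)\n",
              nrow(x$t), ncol(x$t), length(unique(x$meta$run)),
              paste(sort(unique(x$meta$exemplar)), collapse = "/")))
  invisible(x)
}

#' Combine pattern sets across runs
#'
#' Concatenates the patterns of several runs of the same ROI into a single
#' set, renumbering `run` and assigning a global cross-validation fold id
#' `fold = (run - 1) * subruns_per_run + subrun`.
#'
#' @param ... `pattern_set` objects (or a single list of them).
#' @return A combined `pattern_set` whose `meta` gains a `fold` column.
#' @export
combine_patterns <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "pattern_set")) {
    sets <- sets[[1L]]
  }
  n_sub <- max(vapply(sets, function(s) max(s$meta$subrun), 0))
  t <- do.call(cbind, lapply(sets, `[[`, "t"))
  psc_list <- lapply(sets, `[[`, "psc")
  psc <- if (!any(vapply(psc_list, is.null, TRUE))) do.call(cbind, psc_list)
  meta <- do.call(rbind, lapply(seq_along(sets), function(i) {
    m <- sets[[i]]$meta
    m$run <- i
    m
  }))
  meta$fold <- (meta$run - 1L) * n_sub + meta$subrun
  pattern_set(t, psc, meta, coords = sets[[1L]]$coords,
              family = sets[[1L]]$family, subject = sets[[1L]]$subject)
}
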