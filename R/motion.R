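#' Head-motion index
#'
#' Average head movement per volume: the mean over the 3 translation axes of
#' the absolute volume-to-volume translation changes (mm), and the mean over
#' the 3 rotation axes of the absolute rotation changes (deg), averaged over
#' time and then averaged together.  The index deliberately mixes mm and
#' deg by unweighted averaging (it is unit-inconsistent by construction) and
#' uses frame-wise differences, so it is invariant to any constant offset of
#' the parameters.
#'
#' @param trace Volumes x 6 matrix/data.frame (3 translations in mm, then 3
#'   rotations in deg), or a list of such traces (e.g. one per run), which
#'   are concatenated run-wise (differences are not taken across run
#'   boundaries).
#' @return A list of class `motion_index`: `index`, `translation`,
#'   `rotation`, `n_volumes`.
#' @export
motion_index <- function(trace) {
  traces <- if (is.data.frame(trace) || is.matrix(trace)) list(trace) else trace
  dts <- NULL
  drs <- NULL
  n_vol <- 0L
  for (tr in traces) {
    tr <- as.matrix(tr)
    if (nrow(tr) < 2) stop("undefined index: need >= 2 volumes")
    d <- abs(diff(tr))
    dts <- c(dts, rowMeans(d[, 1:3, drop = FALSE]))
    drs <- c(drs, rowMeans(d[, 4:6, drop = FALSE]))
    n_vol <- n_vol + nrow(tr)
  }
  tmean <- mean(dts)
  rmean <- mean(drs)
  structure(list(index = (tmean + rmean) / 2, translation = tmean,
                 rotation = rmean, n_volumes = n_vol),
            class = "motion_index")
}

#' @export
print.motion_index <- function(x, ...) {
  cat(sprintf("motion index: %.4f (translation %.4f mm, rotation %.4f deg, %d volumes)\n",
              x$index, x$translation, x$rotation, x$n_volumes))
  invisible(x)
}

#' Motion indices for a simulated cohort
#'
#' @param cohort A `v1_cohort`.
#' @return Numeric vector of per-subject indices (all runs combined), named
#'   by subject.
#' @export
cohort_motion_indices <- function(cohort) {
  vapply(cohort, function(s) motion_index(s$motion)$index, numeric(1),
         USE.NAMES = FALSE) |>
    stats::setNames(vapply(cohort, `[[`, "", "subject"))
}

#' Exclude high-motion outlier subjects
#'
#' Drops subjects whose motion index exceeds the group mean plus `k`
#' standard deviations (one-sided, computed once on the full set, no
#' iteration).
#'
#' @param indices Per-subject motion indices.
#' @param k SD multiplier (default 3).
#' @return Logical vector: `TRUE` for retained subjects.
#' @export
exclude_outliers <- function(indices, k = 3) {
  if (length(indices) < 3) stop("need >= 3 subjects")
  if (!is.finite(k)) return(rep(TRUE, length(indices)))
  thr <- mean(indices) + k * stats::sd(indices)
  if (is.na(thr)) return(rep(TRUE, length(indices)))
  indices <= thr
}

#' Correlation between head motion and decoding accuracy
#'
#' Pearson product-moment correlation across subjects between motion
#' indices and decoding accuracies (typically each subject's mean accuracy
#' over the four stimulus families), with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param indices Per-subject motion indices.
#' @param accuracies Paired per-subject accuracies.
#' @return List: `r`, `p.value`, `n`.
#' @export
corr_accuracy <- function(indices, accuracies) {
  if (length(indices) != length(accuracies)) stop("unpaired vectors")
  n <- length(indices)
  if (n < 4) stop("need >= 4 subjects")
  if (stats::sd(indices) == 0 || stats::sd(accuracies) == 0) {
    stop("undefined correlation: zero variance")
  }
  r <- stats::cor(indices, accuracies)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p.value = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' Band-resolved motion-decodability correlation
#'
#' For each spatial-frequency band, correlates per-subject band-pass
#' decoding accuracy (averaged over `families`) with the head-motion index,
#' after excluding high-motion outliers.
#'
#' @param cohort A `v1_cohort` simulated with motion enabled.
#' @param grid Band FWHM grid in mm.
#' @param families Families whose accuracies are averaged per subject.
#' @param k Outlier SD multiplier (see [exclude_outliers()]).
#' @param bandwidth Band width in mm.
#' @return A list of class `motion_band_corr`: `bands` (data.frame `fwhm`,
#'   `r`, `p`), `indices`, `retained` (logical), `overall` (the unfiltered
#'   [corr_accuracy()] result on leave-one-subrun-out accuracies).
#' @export
band_resolved_corr <- function(cohort, grid = 1:40,
                               families = c("grating", "spiral",
                                            "patchswap_grating",
                                            "patchswap_spiral"),
                               k = 3, bandwidth = 1) {
  families <- intersect(families, cohort[[1L]]$families)
  indices <- cohort_motion_indices(cohort)
  retained <- exclude_outliers(indices, k = k)
  keep <- which(retained)

  acc_plain <- rowMeans(sapply(families, function(fam) {
    vapply(cohort, function(s) loso_accuracy(s$patterns[[fam]])$accuracy,
           numeric(1))
  }))
  overall <- corr_accuracy(indices[keep], acc_plain[keep])

  # per-band subject accuracies: subjects x bands, averaged over families
  acc_mat <- 0
  for (fam in families) {
    sw <- sweep_decode(cohort, family = fam, kind = "band", grid = grid,
                       bandwidth = bandwidth)
    m <- matrix(sw$curve$accuracy, nrow = length(grid))  # fwhm x subjects
    acc_mat <- acc_mat + t(m) / length(families)
  }
  bands <- do.call(rbind, lapply(seq_along(grid), function(j) {
    cc <- corr_accuracy(indices[keep], acc_mat[keep, j])
    data.frame(fwhm = grid[j], r = cc$r, p = cc$p.value)
  }))
  structure(list(bands = bands, indices = indices, retained = retained,
                 overall = overall),
            class = "motion_band_corr")
}
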