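#' ROI-masked Gaussian smoothing matrix
#'
#' Row-normalized Gaussian weight matrix over in-ROI voxel positions:
#' `S[v, u] = w_vu / sum_u(w_vu)` with
#' `w_vu = exp(-||p_v - p_u||^2 / (2 sigma^2))` and
#' `sigma = fwhm / sqrt(8 log 2)`.  Voxels outside the ROI get weight zero
#' (they are simply absent from the matrix), so smoothing never mixes in
#' out-of-ROI values.  `fwhm = 0` returns the identity.
#'
#' @param coords Voxels x 3 coordinate matrix in mm.
#' @param fwhm Kernel full width at half maximum in mm (>= 0).
#' @param roi Optional logical mask over rows of `coords`.
#' @return An n x n matrix (n = number of in-ROI voxels).
#' @export
smoothing_matrix <- function(coords, fwhm, roi = NULL) {
  coords <- as.matrix(coords)
  if (!is.null(roi)) coords <- coords[roi, , drop = FALSE]
  n <- nrow(coords)
  if (n == 0L) stop("invalid roi: no voxels")
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(diag(n))
  sigma <- fwhm / sqrt(8 * log(2))
  d2 <- as.matrix(stats::dist(coords))^2
  w <- exp(-d2 / (2 * sigma^2))
  w / rowSums(w)
}

#' ROI-masked Gaussian smoothing (spatial low-pass)
#'
#' Replaces each voxel's value by the Gaussian-weighted average of the
#' surrounding in-ROI voxels; out-of-ROI voxels have weight zero.  This is
#' the low-pass filtered pattern.
#'
#' @param pattern Numeric vector (one value per in-ROI voxel) or voxels x
#'   patterns matrix.
#' @param coords Voxels x 3 coordinates in mm.
#' @param fwhm FWHM in mm; 0 is the identity.
#' @param roi Optional logical mask (applied to both `pattern` rows and
#'   `coords`).
#' @param S Optional precomputed [smoothing_matrix()] (overrides
#'   `coords`/`fwhm`).
#' @return Filtered pattern, same shape as the (masked) input.
#' @export
masked_smooth <- function(pattern, coords = NULL, fwhm = NULL, roi = NULL,
                          S = NULL) {
  if (is.null(S)) S <- smoothing_matrix(coords, fwhm, roi)
  p <- as.matrix(pattern)
  if (!is.null(roi)) p <- p[roi, , drop = FALSE]
  out <- S %*% p
  dimnames(out) <- dimnames(p)
  if (is.vector(pattern) || is.null(dim(pattern))) unname(drop(out)) else out
}

#' Spatial high-pass filtering by smoothing subtraction
#'
#' `highpass = pattern - masked_smooth(pattern, fwhm)`: the n-mm high-pass
#' filtered map is the original unsmoothed map minus the n-mm smoothed map.
#'
#' @inheritParams masked_smooth
#' @return Filtered pattern.
#' @export
highpass_filter <- function(pattern, coords = NULL, fwhm = NULL, roi = NULL,
                            S = NULL) {
  if (is.null(S) && (is.null(fwhm) || fwhm <= 0)) {
    stop("highpass requires fwhm > 0")
  }
  p <- as.matrix(pattern)
  if (!is.null(roi)) p <- p[roi, , drop = FALSE]
  out <- p - masked_smooth(p, coords, fwhm, roi = NULL, S = S)
  if (is.vector(pattern) || is.null(dim(pattern))) unname(drop(out)) else out
}

#' Spatial band-pass filtering (1-mm-bandwidth difference of Gaussians)
#'
#' The band labeled `fwhm` is the `(fwhm - bandwidth)`-mm smoothed pattern
#' minus the `fwhm`-mm smoothed pattern, with FWHM 0 meaning the identity:
#' the 1-mm band is the original minus the 1-mm smoothed pattern, the 5-mm
#' band the 4-mm minus the 5-mm smoothed pattern.
#'
#' @inheritParams masked_smooth
#' @param bandwidth Difference of the two FWHMs, mm (default 1).
#' @return Filtered pattern.
#' @export
bandpass_filter <- function(pattern, coords, fwhm, bandwidth = 1,
                            roi = NULL) {
  if (fwhm < bandwidth) stop("invalid band: fwhm < bandwidth")
  p <- as.matrix(pattern)
  if (!is.null(roi)) {
    p <- p[roi, , drop = FALSE]
    coords <- as.matrix(coords)[roi, , drop = FALSE]
  }
  lo <- masked_smooth(p, coords, fwhm - bandwidth)
  hi <- masked_smooth(p, coords, fwhm)
  out <- lo - hi
  if (is.vector(pattern) || is.null(dim(pattern))) unname(drop(out)) else out
}

# filtered feature matrix for a pattern set at one grid point
.filtered_features <- function(t_mat, coords, kind, fwhm, bandwidth = 1,
                               cache = NULL) {
  Sm <- function(f) {
    if (f <= 0) return(diag(nrow(t_mat)))
    key <- sprintf("%.6g", f)
    if (!is.null(cache)) {
      if (is.null(cache[[key]])) cache[[key]] <- smoothing_matrix(coords, f)
      return(cache[[key]])
    }
    smoothing_matrix(coords, f)
  }
  switch(kind,
         low = Sm(fwhm) %*% t_mat,
         high = t_mat - Sm(fwhm) %*% t_mat,
         band = Sm(fwhm - bandwidth) %*% t_mat - Sm(fwhm) %*% t_mat,
         none = t_mat,
         stop("unknown filter kind"))
}

#' Filter-resolved decoding sweep
#'
#' Applies a spatial filter of one kind at each FWHM of a grid to every
#' subject's t-patterns (train and test patterns filtered identically) and
#' re-runs leave-one-subrun-out SVM decoding, yielding accuracy as a
#' function of spatial scale.
#'
#' @param cohort A `v1_cohort` (list of `v1_subject`), or a list of
#'   `pattern_set` objects (one per subject).
#' @param family Stimulus family to decode (ignored when pattern sets are
#'   passed directly).
#' @param kind `"low"`, `"high"` or `"band"`.
#' @param grid Ascending FWHM grid in mm.
#' @param bandwidth Band width in mm (bands only).
#' @param C SVM cost.
#' @param voxel_subset Optional logical/integer voxel selector applied to
#'   patterns and coordinates before filtering (used by ring-resolved
#'   decoding).
#' @return A list of class `decoding_sweep`: `curve` (data.frame: subject,
#'   fwhm, accuracy), `group` (data.frame: fwhm, mean_accuracy, p — group
#'   signed-rank vs chance), `kind`, `family`.
#' @export
sweep_decode <- function(cohort, family = "grating",
                         kind = c("band", "low", "high"),
                         grid = 1:40, bandwidth = 1, C = 1,
                         voxel_subset = NULL) {
  kind <- match.arg(kind)
  if (is.unsorted(grid)) stop("grid must be ascending")
  sets <- .as_pattern_sets(cohort, family)
  curve <- list()
  for (i in seq_along(sets)) {
    ps <- sets[[i]]
    t_mat <- ps$t
    coords <- ps$coords
    if (!is.null(voxel_subset)) {
      t_mat <- t_mat[voxel_subset, , drop = FALSE]
      coords <- coords[voxel_subset, , drop = FALSE]
    }
    cache <- new.env(parent = emptyenv())
    acc <- vapply(grid, function(f) {
      feats <- .filtered_features(t_mat, coords, kind, f, bandwidth, cache)
      loso_accuracy(ps, C = C, x = feats)$accuracy
    }, numeric(1))
    curve[[i]] <- data.frame(subject = ps$subject %||% paste0("sub", i),
                             fwhm = grid, accuracy = acc)
  }
  curve <- do.call(rbind, curve)
  group <- do.call(rbind, lapply(grid, function(f) {
    a <- curve$accuracy[curve$fwhm == f]
    p <- if (length(a) >= 5) group_signedrank(a)$p.value else NA_real_
    data.frame(fwhm = f, mean_accuracy = mean(a), p = p)
  }))
  structure(list(curve = curve, group = group, kind = kind,
                 family = family),
            class = "decoding_sweep")
}

# normalize cohort-like inputs to a list of pattern sets for one family
.as_pattern_sets <- function(cohort, family) {
  if (inherits(cohort, "pattern_set")) return(list(cohort))
  lapply(cohort, function(s) {
    if (inherits(s, "v1_subject")) {
      ps <- s$patterns[[family]]
      if (is.null(ps)) stop("family not simulated for this subject: ", family)
      ps
    } else {
      s
    }
  })
}
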