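#' Write a simulated subject to disk
#'
#' Serializes one simulated subject in interoperable formats: per-run 4-D
#' NIfTI time series (voxels embedded in a bounding grid at the voxel
#' pitch; requires the `RNifti` package and `keep_series = TRUE` at
#' simulation time), per-run events and motion TSVs (BIDS-style columns),
#' and ground-truth TSV/JSON (receptive-field table with tile assignments,
#' model parameters).
#'
#' @param subject A `v1_subject`.
#' @param dir Output directory (created if missing).
#' @param write_nifti Write the NIfTI series when available.
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir, write_nifti = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sch <- subject$schedule
  ev <- sch$events
  events <- data.frame(onset = ev$onset, duration = ev$duration,
                       trial_type = ev$exemplar, subrun = ev$subrun)
  utils::write.table(events, file.path(dir, "events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (nm in names(subject$motion)) {
    utils::write.table(
      as.data.frame(subject$motion[[nm]]),
      file.path(dir, paste0("motion_", nm, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  rf <- subject$model$rf
  rf_out <- cbind(rf, as.data.frame(subject$model$voxel_positions))
  utils::write.table(rf_out, file.path(dir, "ground_truth_rf.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    m <- subject$model
    params <- list(subject = subject$subject,
                   n_voxels = nrow(rf),
                   magnification_k = m$magnification_k,
                   tuned_amplitude = m$tuned_amplitude,
                   w_radial = m$w_radial, w_vertical = m$w_vertical,
                   coherence_gain = m$coherence_gain,
                   sigma_columnar = m$sigma_columnar,
                   motion_scale = subject$motion_scale)
    jsonlite::write_json(params, file.path(dir, "ground_truth_params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (write_nifti && !is.null(subject$series)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("the 'RNifti' package is required to write NIfTI series")
    }
    vol <- .voxel_grid_index(subject$model$voxel_positions)
    for (nm in names(subject$series)) {
      arr <- array(0, c(vol$dim, nrow(subject$series[[nm]])))
      for (tt in seq_len(nrow(subject$series[[nm]]))) {
        frame <- array(0, vol$dim)
        frame[vol$index] <- subject$series[[nm]][tt, ]
        arr[, , , tt] <- frame
      }
      img <- RNifti::asNifti(arr, reference = NULL)
      RNifti::pixdim(img) <- c(vol$pitch, vol$pitch, vol$pitch,
                               subject$schedule$TR)
      RNifti::writeNifti(img, file.path(dir, paste0("series_", nm, ".nii.gz")))
    }
  }
  invisible(dir)
}

# map arbitrary mm coordinates onto a minimal bounding voxel grid
.voxel_grid_index <- function(pos, pitch = 2) {
  ijk <- sweep(round(pos / pitch), 2, apply(round(pos / pitch), 2, min)) + 1
  dims <- apply(ijk, 2, max)
  list(dim = as.integer(dims),
       index = cbind(ijk[, 1], ijk[, 2], ijk[, 3]),
       pitch = pitch)
}

#' Write a simulated cohort to disk
#'
#' One subdirectory per subject (see [write_subject()]).
#'
#' @param cohort A `v1_cohort`.
#' @param dir Output root directory.
#' @param write_nifti Write NIfTI series when available.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_nifti = TRUE) {
  for (s in cohort) {
    write_subject(s, file.path(dir, s$subject), write_nifti = write_nifti)
  }
  invisible(dir)
}

#' Write per-subject decoding accuracies to TSV
#'
#' @param accuracies Named per-subject accuracy vector (or data.frame).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_accuracies <- function(accuracies, path) {
  df <- if (is.data.frame(accuracies)) accuracies else
    data.frame(subject = names(accuracies) %||% seq_along(accuracies),
               accuracy = as.numeric(accuracies))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
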