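#' Parcellate the V1 ROI into log-polar patches
#'
#' Assigns every voxel to the V1 representation of a stimulus tile, using
#' the model's ground-truth receptive-field centers, at one of five nested
#' scales: 36 (ring x wedge tiles), 12 (radial wedges, rings merged), 4
#' (visual-field quadrants bounded by the vertical/horizontal meridians,
#' 3 wedges each), 2 (left/right hemifields) or 1 (whole ROI).
#'
#' @param rf Ground-truth receptive-field table (`model$rf` from
#'   [build_model()]): needs columns `x`, `y` inside the annulus.
#' @param tiling The stimulus [lp_tiling()].
#' @param scale One of 36, 12, 4, 2, 1.
#' @return A list of class `parcellation`: `scale`, `labels` (per-voxel
#'   integer patch label, 1-based), `info` (data.frame describing each
#'   label), `n_patches`.
#' @export
parcellate <- function(rf, tiling = lp_tiling(), scale = 36) {
  if (!scale %in% c(36, 12, 4, 2, 1)) stop("scale must be 36, 12, 4, 2 or 1")
  tl <- .tile_polar(tiling, sqrt(rf$x^2 + rf$y^2),
                    (atan2(rf$y, rf$x) * 180 / pi) %% 360, snap = 1e-9)
  if (any(tl$outside)) {
    stop("unassigned voxels: RF centers outside the annulus at rows ",
         paste(utils::head(which(tl$outside), 10), collapse = ", "))
  }
  nr <- tiling$n_rings
  nw <- tiling$n_wedges
  wedges_per_quadrant <- nw / 4
  labels <- switch(as.character(scale),
    "36" = tl$wedge * nr + tl$ring + 1L,
    "12" = tl$wedge + 1L,
    "4"  = tl$wedge %/% wedges_per_quadrant + 1L,
    "2"  = ifelse(tl$wedge < nw / 4 | tl$wedge >= 3 * nw / 4, 1L, 2L),
    "1"  = rep(1L, nrow(rf)))
  info <- switch(as.character(scale),
    "36" = {
      g <- expand.grid(ring = seq_len(nr) - 1L, wedge = seq_len(nw) - 1L)
      data.frame(label = g$wedge * nr + g$ring + 1L,
                 ring = g$ring, wedge = g$wedge)[order(g$wedge * nr + g$ring), ]
    },
    "12" = data.frame(label = seq_len(nw), wedge = seq_len(nw) - 1L),
    "4"  = data.frame(label = 1:4,
                      quadrant = c("upper-right", "upper-left",
                                   "lower-left", "lower-right")),
    "2"  = data.frame(label = 1:2, hemifield = c("right", "left")),
    "1"  = data.frame(label = 1L, region = "whole-ROI"))
  structure(list(scale = scale, labels = as.integer(labels), info = info,
                 n_patches = nrow(info), tiling = tiling),
            class = "parcellation")
}

#' Remove patch means from a pattern (keep the fine scale)
#'
#' Subtracts each patch's mean from its voxels, shifting every patch to a
#' mean of 0 and retaining only the within-patch fine-scale pattern
#' component.
#'
#' @param pattern Numeric vector or voxels x patterns matrix.
#' @param parcellation A [parcellate()] result aligned with the voxels.
#' @return Same shape as `pattern`.
#' @export
remove_patch_means <- function(pattern, parcellation) {
  p <- as.matrix(pattern)
  lab <- parcellation$labels
  stopifnot(length(lab) == nrow(p))
  counts <- tabulate(lab, nbins = parcellation$n_patches)
  if (any(counts == 0)) {
    warning("empty patch(es) skipped: ",
            paste(which(counts == 0), collapse = ", "))
  }
  means <- rowsum(p, lab) / counts[sort(unique(lab))]
  out <- p - means[match(lab, sort(unique(lab))), , drop = FALSE]
  dimnames(out) <- dimnames(p)
  if (is.vector(pattern) || is.null(dim(pattern))) unname(drop(out)) else out
}

#' Patch-mean (coarse-scale) pattern
#'
#' Mean value per patch, ordered by patch label: the coarse-scale feature
#' vector used for patch-average decoding.  Empty patches yield `NA`.
#'
#' @inheritParams remove_patch_means
#' @return Vector (or patches x patterns matrix) of patch means.
#' @export
patch_means <- function(pattern, parcellation) {
  p <- as.matrix(pattern)
  lab <- parcellation$labels
  stopifnot(length(lab) == nrow(p))
  n <- parcellation$n_patches
  counts <- tabulate(lab, nbins = n)
  out <- matrix(NA_real_, n, ncol(p))
  present <- sort(unique(lab))
  out[present, ] <- rowsum(p, lab) / counts[present]
  rownames(out) <- parcellation$info$label
  if (is.vector(pattern) || is.null(dim(pattern))) drop(out) else out
}

#' Per-patch response table
#'
#' Average response of each of the 36 V1 patches to each stimulus exemplar,
#' in % signal change relative to fixation baseline (GLM betas scaled by the
#' baseline estimate, averaged across subruns and runs), annotated with each
#' patch's visual-field position and the local stimulus orientation of each
#' exemplar (evaluated at the patch center of the exemplar's orientation
#' field).
#'
#' @param cohort A `v1_cohort`, a single `v1_subject`, or a list of them.
#' @param families Families to tabulate (default: all simulated).
#' @return A data.frame of class `patch_table` with columns `subject`,
#'   `family`, `exemplar`, `patch`, `ring`, `wedge`, `angle`, `ecc`,
#'   `stim_ori`, `response` (36 patches x 2 exemplars per subject/family).
#' @export
build_patch_table <- function(cohort, families = NULL) {
  if (inherits(cohort, "v1_subject")) cohort <- list(cohort)
  rows <- list()
  for (subj in cohort) {
    parc <- parcellate(subj$model$rf, subj$model$tiling, 36)
    centers <- tile_centers(subj$model$tiling)
    centers$label <- centers$wedge * subj$model$tiling$n_rings +
      centers$ring + 1L
    centers <- centers[order(centers$label), ]
    fams <- families %||% subj$families
    for (fam in fams) {
      ps <- subj$patterns[[fam]]
      if (is.null(ps$psc)) stop("incomplete table: no % signal change maps")
      for (ex in c("A", "B")) {
        sel <- ps$meta$exemplar == ex
        if (!any(sel)) stop("incomplete table: missing exemplar ", ex)
        voxel_psc <- rowMeans(ps$psc[, sel, drop = FALSE])
        pm <- patch_means(voxel_psc, parc)
        spec <- stim_spec(fam, ex, subj$model$tiling, grout_width = 0)
        ori <- orientation_at(spec, centers$x, centers$y)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj$subject, family = fam, exemplar = ex,
          patch = centers$label, ring = centers$ring,
          wedge = centers$wedge, angle = centers$angle,
          ecc = centers$ecc, stim_ori = ori, response = as.numeric(pm))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("patch_table", "data.frame")
  out
}

# hypothetically optimal orientation per observation
.theta_opt <- function(table, hypothesis) {
  switch(hypothesis,
         radial = table$angle %% 180,
         vertical = rep(90, nrow(table)),
         stop("hypothesis must be 'radial' or 'vertical'"))
}

.default_hypothesis <- function(family) {
  if (grepl("grating", family[1L])) "radial" else "vertical"
}

#' Cosine-predictor scores of a preference hypothesis
#'
#' `cos(2 * (stim_ori - theta_opt))` per (patch, exemplar) observation:
#' peak (+1) where the local stimulus orientation equals the hypothesized
#' optimum (radial direction, or vertical), trough (-1) at the orthogonal
#' orientation.
#'
#' @param table A [build_patch_table()] result (one family).
#' @param hypothesis `"radial"` or `"vertical"` (default chosen by family:
#'   radial for grating families, vertical for spiral families).
#' @return Numeric vector aligned with `table` rows.
#' @export
cosine_predictor <- function(table, hypothesis = NULL) {
  hypothesis <- hypothesis %||% .default_hypothesis(table$family)
  d <- (table$stim_ori - .theta_opt(table, hypothesis)) * pi / 180
  # round so observations at mathematically equal angles are exact ties
  round(cos(2 * d), 12)
}

#' Cosine tuning-model fit of a global preference map
#'
#' Per subject, least-squares fit of
#' `response = beta0 + beta1 * cos(2 * (stim_ori - theta_opt))` over the 72
#' (patch, exemplar) observations of one stimulus family.  `beta0` is the
#' confound mean (overall response across orientations, % signal change);
#' `beta1` the preference amplitude (positive = preference for the
#' hypothesized optimal orientation, negative = tangential/horizontal
#' preference).  Radial preference is estimable for grating families only
#' and vertical preference for spiral families only; for the complementary
#' pairing the predictor is constant (the design is balanced about that
#' orientation) and the fit stops with an unidentifiable-amplitude error.
#'
#' @param table A [build_patch_table()] result restricted to one family.
#' @param hypothesis `"radial"` or `"vertical"`; default by family.
#' @return A data.frame of class `preference_fit`: `subject`, `beta0`,
#'   `beta1`, plus attributes `hypothesis` and `family`.
#' @export
cosine_fit <- function(table, hypothesis = NULL) {
  stopifnot(length(unique(table$family)) == 1L)
  hypothesis <- hypothesis %||% .default_hypothesis(table$family)
  pred <- cosine_predictor(table, hypothesis)
  if (stats::sd(pred) < 1e-10) {
    stop("unidentifiable amplitude: the ", hypothesis,
         " cosine predictor is constant for family ", table$family[1L],
         " (the design is balanced about this orientation)")
  }
  fits <- lapply(split(seq_len(nrow(table)), table$subject), function(i) {
    cf <- stats::coef(stats::lm(table$response[i] ~ pred[i]))
    data.frame(subject = table$subject[i][1L],
               beta0 = unname(cf[1L]), beta1 = unname(cf[2L]))
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  attr(out, "hypothesis") <- hypothesis
  attr(out, "family") <- table$family[1L]
  class(out) <- c("preference_fit", "data.frame")
  out
}

#' Rank-order test for a global preference map
#'
#' Uses the radial or vertical preference hypothesis to predict the rank
#' order of patch responses across all 36 patches for both exemplars, and
#' measures prediction accuracy per subject by Spearman's r (average ranks
#' for ties).  Group inference: two-sided Wilcoxon signed-rank test of the
#' per-subject correlations against 0 (negative values would indicate
#' tangential/horizontal preference).  By default each patch's responses
#' are centered across its two exemplars before ranking, removing
#' between-patch baseline heterogeneity; `center = FALSE` ranks the raw
#' responses.
#'
#' @param table A [build_patch_table()] result restricted to one family.
#' @param hypothesis `"radial"` or `"vertical"`; default by family.
#' @param center Center responses within each patch across exemplars.
#' @return A list of class `preference_test`: `per_subject` (data.frame
#'   `subject`, `r`), `p.value` (group), `n`, `hypothesis`, `family`.
#' @export
rank_preference_test <- function(table, hypothesis = NULL, center = TRUE) {
  stopifnot(length(unique(table$family)) == 1L)
  hypothesis <- hypothesis %||% .default_hypothesis(table$family)
  pred <- cosine_predictor(table, hypothesis)
  per <- lapply(split(seq_len(nrow(table)), table$subject), function(i) {
    y <- table$response[i]
    if (center) {
      y <- y - stats::ave(y, table$patch[i])
    }
    r <- if (stats::sd(y) == 0) NA_real_ else
      stats::cor(pred[i], y, method = "spearman")
    data.frame(subject = table$subject[i][1L], r = r)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  rs <- per$r[!is.na(per$r)]
  p <- if (length(rs) >= 2) signed_rank_test(rs, "two.sided")$p.value else NA_real_
  structure(list(per_subject = per, p.value = p, n = length(rs),
                 hypothesis = hypothesis, family = table$family[1L]),
            class = "preference_test")
}

#' @export
print.preference_test <- function(x, ...) {
  cat(sprintf("%s preference (%s): median r = %.3f, n = %d, p = %.4g\n",
              x$hypothesis, x$family, stats::median(x$per_subject$r,
                                                    na.rm = TRUE),
              x$n, x$p.value))
  invisible(x)
}

#' Compare preference-map strength between stimulus types
#'
#' Two-sided signed-rank test on per-subject differences of the rank-order
#' prediction accuracies (Spearman r) of two [rank_preference_test()]
#' results, paired by subject.
#'
#' @param test_a,test_b `preference_test` results with matching subjects.
#' @return As [paired_signedrank()].
#' @export
prefmap_compare <- function(test_a, test_b) {
  a <- test_a$per_subject
  b <- test_b$per_subject
  m <- merge(a, b, by = "subject", suffixes = c("_a", "_b"))
  paired_signedrank(m$r_a, m$r_b)
}

#' Preference test after excluding low-contrast patches
#'
#' Control analysis for imprecise patch definitions: per patch, the response
#' contrast between the two exemplars (`exemplar B - exemplar A`) is
#' compared with the contrast predicted by the preference hypothesis; the
#' fraction `q` of patches with the smallest absolute measured contrast is
#' excluded and the remaining actual-versus-predicted contrasts are
#' Spearman-correlated, with a two-sided group signed-rank test per `q`.
#'
#' @param table A [build_patch_table()] result restricted to one family.
#' @param hypothesis `"radial"` or `"vertical"`; default by family.
#' @param q_grid Exclusion fractions within `[0, 0.95]`.
#' @return A list of class `exclusion_sweep`: `per_subject` (data.frame
#'   `subject`, `q`, `r`, `n_retained`), `group` (data.frame `q`, `p`,
#'   `n_defined`); sweeps leaving fewer than 3 patches are flagged
#'   undefined (`r = NA`).
#' @export
contrast_exclusion <- function(table, hypothesis = NULL,
                               q_grid = seq(0, 0.95, by = 0.05)) {
  stopifnot(length(unique(table$family)) == 1L)
  if (any(q_grid < 0 | q_grid > 0.95)) stop("q_grid must lie in [0, 0.95]")
  hypothesis <- hypothesis %||% .default_hypothesis(table$family)
  pred <- cosine_predictor(table, hypothesis)
  rows <- list()
  for (s in unique(table$subject)) {
    i <- which(table$subject == s)
    a <- i[table$exemplar[i] == "A"][order(table$patch[i][table$exemplar[i] == "A"])]
    b <- i[table$exemplar[i] == "B"][order(table$patch[i][table$exemplar[i] == "B"])]
    cmeas <- table$response[b] - table$response[a]
    cpred <- pred[b] - pred[a]
    ord <- order(abs(cmeas))
    n <- length(cmeas)
    for (q in q_grid) {
      keep <- ord[seq.int(floor(q * n) + 1L, n)]
      r <- if (length(keep) < 3 || stats::sd(cmeas[keep]) == 0 ||
               stats::sd(cpred[keep]) == 0) NA_real_ else
        stats::cor(cmeas[keep], cpred[keep], method = "spearman")
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, q = q, r = r, n_retained = length(keep))
    }
  }
  per <- do.call(rbind, rows)
  group <- do.call(rbind, lapply(q_grid, function(q) {
    rs <- per$r[per$q == q & !is.na(per$r)]
    p <- if (length(rs) >= 2) signed_rank_test(rs, "two.sided")$p.value
    else NA_real_
    data.frame(q = q, p = p, n_defined = length(rs))
  }))
  structure(list(per_subject = per, group = group,
                 hypothesis = hypothesis, family = table$family[1L]),
            class = "exclusion_sweep")
}

#' Univariate response summaries
#'
#' Mean % signal change (i) per stimulus family (averaged over exemplars,
#' patches and subjects, with SEM across subjects), (ii) per eccentricity
#' ring and (iii) per polar-angle wedge (both averaged across families),
#' with pairwise two-sided signed-rank tests between rings.
#'
#' @param table A [build_patch_table()] result (any number of families).
#' @return A list of class `univariate_summary`: `by_family`, `by_ring`,
#'   `by_wedge` (data.frames with `mean` and `sem`), `ring_tests`
#'   (data.frame of pairwise p-values), `per_subject_family`.
#' @export
univariate_summary <- function(table) {
  agg <- function(split_var) {
    per_subj <- stats::aggregate(
      list(response = table$response),
      by = list(subject = table$subject, level = table[[split_var]]),
      FUN = mean)
    names(per_subj)[2L] <- split_var
    out <- do.call(rbind, lapply(split(per_subj, per_subj[[split_var]]),
      function(d) data.frame(
        level = d[[split_var]][1L], mean = mean(d$response),
        sem = stats::sd(d$response) / sqrt(nrow(d)))))
    rownames(out) <- NULL
    list(summary = out, per_subject = per_subj)
  }
  fam <- agg("family")
  ring <- agg("ring")
  wedge <- agg("wedge")
  rings <- sort(unique(table$ring))
  ring_tests <- NULL
  if (length(rings) >= 2) {
    pairs <- utils::combn(rings, 2)
    ring_tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- ring$per_subject$response[ring$per_subject$ring == pairs[1, j]]
      b <- ring$per_subject$response[ring$per_subject$ring == pairs[2, j]]
      data.frame(ring_a = pairs[1, j], ring_b = pairs[2, j],
                 p = paired_signedrank(a, b)$p.value)
    }))
  }
  structure(list(by_family = fam$summary, by_ring = ring$summary,
                 by_wedge = wedge$summary, ring_tests = ring_tests,
                 per_subject_family = fam$per_subject),
            class = "univariate_summary")
}

#' Eccentricity-resolved band-pass decoding
#'
#' Restricts each subject's patterns to the voxels of one eccentricity ring
#' of the 36-patch parcellation (central, intermediate or peripheral) and
#' runs the spatial-filter decoding sweep on that subset.
#'
#' @param cohort A `v1_cohort`.
#' @param family Stimulus family to decode.
#' @param ring `"central"`, `"intermediate"` or `"peripheral"` (rings 0-2),
#'   or a 0-based ring index.
#' @param grid FWHM grid in mm.
#' @param kind Filter kind (default `"band"`).
#' @param ... Passed to [sweep_decode()].
#' @return A `decoding_sweep` (see [sweep_decode()]).
#' @export
decode_by_ring <- function(cohort, family = "grating",
                           ring = c("central", "intermediate", "peripheral"),
                           grid = 1:40, kind = "band", ...) {
  ring_idx <- if (is.numeric(ring)) as.integer(ring) else
    match(match.arg(ring), c("central", "intermediate", "peripheral")) - 1L
  if (inherits(cohort, "v1_subject")) cohort <- list(cohort)
  sweeps <- lapply(cohort, function(subj) {
    sel <- subj$model$rf$ring == ring_idx
    if (!any(sel)) stop("invalid roi: no voxels in ring ", ring_idx)
    sweep_decode(list(subj$patterns[[family]]), family = family,
                 kind = kind, grid = grid, voxel_subset = sel, ...)
  })
  curve <- do.call(rbind, lapply(sweeps, `[[`, "curve"))
  group <- do.call(rbind, lapply(grid, function(f) {
    a <- curve$accuracy[curve$fwhm == f]
    p <- if (length(a) >= 5) group_signedrank(a)$p.value else NA_real_
    data.frame(fwhm = f, mean_accuracy = mean(a), p = p)
  }))
  structure(list(curve = curve, group = group, kind = kind,
                 family = family, ring = ring_idx),
            class = "decoding_sweep")
}
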