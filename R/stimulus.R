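#' Stimulus specification
#'
#' Describes one exemplar of one of the four stimulus families presented
#' inside the log-polar annulus:
#'
#' * `grating`: uniform square-wave grating, oriented 45 degrees clockwise
#'   (variant `"A"`) or anticlockwise (variant `"B"`) from vertical, i.e.
#'   orientations 45 and 135 in the package convention (degrees anticlockwise
#'   from the rightward horizontal, range `[0, 180)`).
#' * `spiral`: logarithmic spiral whose edges keep a constant +/-45-degree
#'   angle to the local radial direction; variant `"A"` is the clockwise
#'   sense (orientation `(theta - 45) mod 180` at polar angle `theta`),
#'   variant `"B"` anticlockwise (`(theta + 45) mod 180`).
#' * `patchswap_grating`, `patchswap_spiral`: patchwork stimuli built by
#'   swapping the odd-parity tiles of the log-polar checkerboard between the
#'   two coherent parents, preserving the local 90-degree orientation
#'   disparity while destroying global form.
#'
#' The two variants of every family differ in orientation by exactly 90
#' degrees at every in-annulus, non-grout location.
#'
#' @param family One of `"grating"`, `"spiral"`, `"patchswap_grating"`,
#'   `"patchswap_spiral"`.
#' @param variant `"A"` or `"B"`.
#' @param tiling An [lp_tiling()].
#' @param spatial_freq Grating spatial frequency, cycles per visual degree.
#' @param perimeter_cycles Spiral contrast cycles per full turn around the
#'   annulus.
#' @param grout_width Width in degrees of the mid-gray grout lines that make
#'   the tiling visible in all stimuli (0 disables them).
#' @param phase Square-wave phase in radians, `[0, 2*pi)`.
#' @return An object of class `stim_spec`.
#' @examples
#' sp <- stim_spec("spiral", "A")
#' orientation_at(sp, 3, 0)  # (0 - 45) mod 180 = 135
#' @export
stim_spec <- function(family = c("grating", "spiral",
                                 "patchswap_grating", "patchswap_spiral"),
                      variant = c("A", "B"), tiling = lp_tiling(),
                      spatial_freq = 1.25, perimeter_cycles = 22,
                      grout_width = 0.06, phase = 0) {
  family <- match.arg(family)
  variant <- match.arg(variant)
  structure(list(
    family = family, variant = variant, tiling = tiling,
    spatial_freq = spatial_freq, perimeter_cycles = perimeter_cycles,
    grout_width = grout_width, phase = phase %% (2 * pi),
    coherent = !grepl("^patchswap", family)
  ), class = "stim_spec")
}

#' @export
print.stim_spec <- function(x, ...) {
  cat(sprintf("stimulus: %s %s (phase %.3f rad%s)\n", x$family, x$variant,
              x$phase, if (x$coherent) "" else ", patch-swapped"))
  invisible(x)
}

# orientation field of a *coherent parent* variant ("A"/"B") at polar angle
# ang (degrees); base determines grating vs spiral
.parent_orientation <- function(base, variant, ang) {
  if (base == "grating") {
    rep(if (variant == "A") 45 else 135, length(out <- ang))
  } else {
    s <- if (variant == "A") -1 else 1   # clockwise / anticlockwise sense
    (ang + s * 45) %% 180
  }
}

# square-wave contrast of a coherent parent at (x, y); phase shared
.parent_contrast <- function(base, variant, spec, x, y) {
  if (base == "grating") {
    alpha <- if (variant == "A") 45 else 135
    # coordinate along the axis orthogonal to the orientation
    d <- -x * sin(alpha * pi / 180) + y * cos(alpha * pi / 180)
    arg <- 2 * pi * spec$spatial_freq * d + spec$phase
  } else {
    s <- if (variant == "A") -1 else 1
    r <- sqrt(x^2 + y^2)
    theta <- atan2(y, x)
    # iso-contrast curves of xi are the +/-45-degree logarithmic spirals
    xi <- theta - s * log(pmax(r, .Machine$double.eps))
    arg <- spec$perimeter_cycles * xi + spec$phase
  }
  ifelse(cos(arg) >= 0, 1, -1)
}

.family_base <- function(family) if (grepl("grating", family)) "grating" else "spiral"

# per-point parent variant for a spec: coherent families use their own
# variant everywhere; patch-swapped families follow the checkerboard
.source_variant <- function(spec, x, y) {
  if (spec$coherent) return(rep(spec$variant, length(x)))
  tl <- tile_of(spec$tiling, x, y)
  par <- checker_parity(tl$ring, tl$wedge)
  other <- if (spec$variant == "A") "B" else "A"
  out <- ifelse(par == "keep", spec$variant, other)
  out[tl$outside] <- NA_character_
  out
}

#' Orientation field of a stimulus
#'
#' Local edge orientation, in degrees anticlockwise from the rightward
#' horizontal, range `[0, 180)`.  `NA` outside the annulus and on grout
#' lines, where no oriented contrast is present.
#'
#' @param spec A [stim_spec()].
#' @param x,y Visual-degree coordinates (vectorized).
#' @return Numeric vector of orientations (`NA` where undefined).
#' @export
orientation_at <- function(spec, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  ecc <- sqrt(x^2 + y^2)
  ang <- (atan2(y, x) * 180 / pi) %% 360
  base <- .family_base(spec$family)
  src <- .source_variant(spec, x, y)
  out <- rep(NA_real_, n)
  for (v in c("A", "B")) {
    i <- which(!is.na(src) & src == v)
    if (length(i)) out[i] <- .parent_orientation(base, v, ang[i])
  }
  bad <- ecc < spec$tiling$r_inner | ecc > spec$tiling$r_outer |
    (spec$grout_width > 0 &
       .boundary_distance(spec$tiling, x, y) < spec$grout_width / 2)
  out[bad] <- NA_real_
  out
}

#' Contrast field of a stimulus
#'
#' Hard-edged (rectangular, 100%-contrast) stimulus polarity: +1 on bright
#' bars, -1 on dark bars, 0 on the mid-gray background (outside the annulus
#' or within half a grout width of a tile boundary).
#'
#' @inheritParams orientation_at
#' @return Integer-valued vector in \{-1, 0, +1\}.
#' @export
contrast_at <- function(spec, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  ecc <- sqrt(x^2 + y^2)
  base <- .family_base(spec$family)
  src <- .source_variant(spec, x, y)
  out <- rep(0, n)
  for (v in c("A", "B")) {
    i <- which(!is.na(src) & src == v)
    if (length(i)) out[i] <- .parent_contrast(base, v, spec, x[i], y[i])
  }
  bad <- ecc < spec$tiling$r_inner | ecc > spec$tiling$r_outer |
    (spec$grout_width > 0 &
       .boundary_distance(spec$tiling, x, y) < spec$grout_width / 2)
  out[bad] <- 0
  out
}

#' Render a stimulus to a raster
#'
#' Samples [contrast_at()] on a square pixel grid centered on fixation.  If
#' `phase` is `NULL`, one phase is drawn uniformly from `[0, 2*pi)` using
#' `seed` (shared across all tiles of the render, so patch-swapped exemplars
#' stay in register with their parents).
#'
#' @param spec A [stim_spec()].
#' @param pixels_per_degree Raster resolution; below ~8 px/deg the hard edges
#'   alias (a warning is issued).
#' @param seed Integer seed used when drawing a random phase.
#' @param phase Fixed phase in radians, or `NULL` to randomize.
#' @param margin Mid-gray margin around the annulus, degrees.
#' @return A list of class `stim_raster`: `image` (matrix in \{-1,0,1\},
#'   rows = y from top), `ppd`, `extent_deg`, `phase`, `spec`.
#' @export
render_stimulus <- function(spec, pixels_per_degree = 16, seed = NULL,
                            phase = NULL, margin = 0.46) {
  if (pixels_per_degree < 8) {
    warning("resolution below 8 px/deg: hard edges will alias")
  }
  if (is.null(phase)) {
    if (!is.null(seed)) {
      restore <- .Random.seed_exists()
      on.exit(restore(), add = TRUE)
      set.seed(seed)
    }
    phase <- stats::runif(1, 0, 2 * pi)
  }
  spec$phase <- phase %% (2 * pi)
  half <- spec$tiling$r_outer + margin
  n <- ceiling(2 * half * pixels_per_degree)
  cc <- (seq_len(n) - 0.5) / pixels_per_degree - half
  xs <- matrix(cc, n, n, byrow = TRUE)
  ys <- matrix(rev(cc), n, n)
  img <- matrix(contrast_at(spec, as.vector(xs), as.vector(ys)), n, n)
  structure(list(image = img, ppd = pixels_per_degree,
                 extent_deg = 2 * half, phase = spec$phase, spec = spec),
            class = "stim_raster")
}

# save/restore .Random.seed so render_stimulus(seed=) does not disturb the
# caller's RNG stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Write a rendered stimulus to PNG
#'
#' 8-bit gray-scale encoding: background 128, dark bars 0, bright bars 255.
#' Requires the `png` package.
#'
#' @param raster A `stim_raster` from [render_stimulus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(raster, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write PNG files")
  }
  img <- (raster$image + 1) / 2            # -1,0,1 -> 0, .5, 1
  img[raster$image == 0] <- 128 / 255
  png::writePNG(img, path)
  invisible(path)
}
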