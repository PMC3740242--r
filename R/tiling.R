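#' Exponentially spaced ring radii
#'
#' Boundary radii of `n_rings` concentric rings spanning an annulus, spaced so
#' that consecutive radii have a constant ratio (equal widths on a log-polar,
#' i.e. cortically magnified, representation).
#'
#' @param r_inner Inner annulus radius in visual degrees (> 0).
#' @param r_outer Outer annulus radius in visual degrees (> `r_inner`).
#' @param n_rings Number of rings (>= 1).
#' @return Numeric vector of `n_rings + 1` radii, from `r_inner` to `r_outer`.
#' @examples
#' ring_radii(1.5, 7.04, 3) # c(1.50, 2.51, 4.20, 7.04) to 2 decimals
#' @export
ring_radii <- function(r_inner, r_outer, n_rings) {
  if (!is.numeric(r_inner) || !is.numeric(r_outer) ||
      r_inner <= 0 || r_outer <= r_inner) {
    stop("invalid geometry: need 0 < r_inner < r_outer")
  }
  if (n_rings < 1) stop("invalid geometry: n_rings must be >= 1")
  r_inner * (r_outer / r_inner)^(seq(0, n_rings) / n_rings)
}

#' Log-polar tiling of an annulus
#'
#' Defines the tiling of a stimulus annulus into `n_rings` exponentially
#' spaced rings crossed by `n_wedges` equal polar-angle wedges.  With the
#' default `wedge_origin = 0` the wedge boundaries include the horizontal and
#' (for `n_wedges` a multiple of 4 or with 30-degree wedges) the vertical
#' meridians.
#'
#' @param r_inner,r_outer Annulus radii in visual degrees.
#' @param n_rings Number of eccentricity rings.
#' @param n_wedges Number of polar-angle wedges.
#' @param wedge_origin Polar angle (degrees, anticlockwise from rightward
#'   horizontal) of the first wedge boundary.
#' @return An object of class `lp_tiling`.
#' @examples
#' tl <- lp_tiling()
#' tl$ring_radii
#' @export
lp_tiling <- function(r_inner = 1.5, r_outer = 7.04, n_rings = 3,
                      n_wedges = 12, wedge_origin = 0) {
  radii <- ring_radii(r_inner, r_outer, n_rings)
  structure(list(
    r_inner = r_inner, r_outer = r_outer,
    n_rings = n_rings, n_wedges = n_wedges,
    ring_radii = radii,
    wedge_width = 360 / n_wedges,
    wedge_origin = wedge_origin
  ), class = "lp_tiling")
}

#' @export
print.lp_tiling <- function(x, ...) {
  cat(sprintf("log-polar tiling: %d rings x %d wedges, %.2f-%.2f deg\n",
              x$n_rings, x$n_wedges, x$r_inner, x$r_outer))
  cat("ring radii:", paste(sprintf("%.2f", x$ring_radii), collapse = ", "), "\n")
  invisible(x)
}

#' Tile membership of visual-field points
#'
#' Assigns each point to a (ring, wedge) tile of the log-polar tiling, or to
#' `"outside"` when its eccentricity falls outside the annulus.  Rings use
#' half-open eccentricity intervals `[r_i, r_{i+1})` with the outermost
#' interval closed at `r_outer`; wedges use half-open polar-angle intervals
#' anticlockwise from `wedge_origin`.  Indices are 0-based, matching the
#' checkerboard-parity convention.
#'
#' @param tiling An [lp_tiling()].
#' @param x,y Point coordinates in visual degrees (vectorized).
#' @return A data.frame with columns `ring`, `wedge` (0-based, `NA` outside)
#'   and logical `outside`.
#' @export
tile_of <- function(tiling, x, y) {
  .tile_polar(tiling, sqrt(x^2 + y^2), (atan2(y, x) * 180 / pi) %% 360)
}

# tile assignment from polar coordinates; `snap` clamps eccentricities that
# are within a relative tolerance of the annulus borders (used where the
# coordinates come from a round trip through Cartesian space)
.tile_polar <- function(tiling, ecc, ang, snap = 0) {
  if (snap > 0) {
    lo <- tiling$r_inner
    hi <- tiling$r_outer
    ecc[abs(ecc - lo) < snap * lo] <- lo
    ecc[abs(ecc - hi) < snap * hi] <- hi
  }
  radii <- tiling$ring_radii
  ring <- findInterval(ecc, radii, rightmost.closed = TRUE) - 1L
  outside <- ring < 0L | ring >= tiling$n_rings
  ring[outside] <- NA_integer_
  rel <- (ang - tiling$wedge_origin) %% 360
  # snap angles within 1e-9 deg of a wedge boundary onto it, so points
  # constructed from trigonometric round trips land on the intended side
  near <- round(rel / tiling$wedge_width) * tiling$wedge_width
  rel <- ifelse(abs(rel - near) < 1e-9, near, rel)
  wedge <- as.integer(floor(rel / tiling$wedge_width)) %% tiling$n_wedges
  wedge[outside] <- NA_integer_
  data.frame(ring = ring, wedge = wedge, outside = outside)
}

#' Checkerboard parity of a tile
#'
#' Log-polar checkerboard phase used to build patch-swapped stimuli: tiles
#' with even `ring + wedge` keep their parent exemplar's content, odd tiles
#' swap it.  Adjacent tiles (sharing a ring or wedge edge) always differ.
#'
#' @param ring,wedge 0-based tile indices (vectorized).
#' @return Character vector, `"keep"` or `"swap"`.
#' @export
checker_parity <- function(ring, wedge) {
  ifelse((ring + wedge) %% 2L == 0L, "keep", "swap")
}

#' Tile center points
#'
#' Geometric centers of all tiles: eccentricity at the geometric mean of the
#' ring boundaries (the midpoint on the log-eccentricity axis), polar angle at
#' the wedge midpoint.
#'
#' @param tiling An [lp_tiling()].
#' @return data.frame with `ring`, `wedge`, `ecc`, `angle` (degrees), `x`, `y`.
#' @export
tile_centers <- function(tiling) {
  g <- expand.grid(ring = seq_len(tiling$n_rings) - 1L,
                   wedge = seq_len(tiling$n_wedges) - 1L)
  r0 <- tiling$ring_radii[g$ring + 1L]
  r1 <- tiling$ring_radii[g$ring + 2L]
  ecc <- sqrt(r0 * r1)
  ang <- (tiling$wedge_origin + (g$wedge + 0.5) * tiling$wedge_width) %% 360
  data.frame(ring = g$ring, wedge = g$wedge, ecc = ecc, angle = ang,
             x = ecc * cos(ang * pi / 180), y = ecc * sin(ang * pi / 180))
}

# distance (deg) from points to the nearest tile boundary (ring circle or
# radial wedge line); used for grout-line masking
.boundary_distance <- function(tiling, x, y) {
  ecc <- sqrt(x^2 + y^2)
  ang <- (atan2(y, x) * 180 / pi) %% 360
  d_ring <- apply(abs(outer(ecc, tiling$ring_radii, "-")), 1L, min)
  rel <- (ang - tiling$wedge_origin) %% tiling$wedge_width
  d_ang <- pmin(rel, tiling$wedge_width - rel) * pi / 180
  # perpendicular distance to the radial line through the origin
  d_wedge <- ecc * sin(pmin(d_ang, pi / 2))
  pmin(d_ring, d_wedge)
}
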