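#' Build a synthetic V1 cortical model
#'
#' Lays fMRI voxels on a regular grid over a complex-log model of the V1
#' cortical sheet (`w = k * log(x + i*y)`, with `k` the cortical
#' magnification in mm per log-degree) covering the retinotopic image of the
#' stimulus annulus, and equips every voxel with an orientation tuning
#' vector in double-angle space.  Tuning has two separable components, the
#' two mechanisms whose contributions to orientation decodability the
#' analysis modules are designed to disentangle:
#'
#' * a columnar component: each voxel's idiosyncratic average over a fine
#'   (sub-voxel) orientation-preference field, modeled as smoothed complex
#'   Gaussian noise with correlation length `sigma_columnar` mm on the
#'   cortical sheet;
#' * a global component: radial (`w_radial * exp(2i*theta)`, `theta` the
#'   voxel's receptive-field polar angle) plus vertical
#'   (`w_vertical * exp(2i * 90deg)`) preference maps.  When a stimulus is
#'   not globally coherent (patch-swapped families), the global component is
#'   scaled by `coherence_gain` in [voxel_response()], implementing the
#'   hypothesis that global preference maps depend on coherent global form.
#'
#' The sheet is embedded in 3-D on a cylinder of radius `k` so that voxel
#' coordinates (used by the spatial-filtering module) have a realistic
#' folded-cortex extent rather than a 135-mm flat strip.
#'
#' @param target_voxels Approximate ROI size; the magnification `k` is solved
#'   from it unless `magnification_k` is given.
#' @param tiling Stimulus [lp_tiling()]; the model covers its annulus.
#' @param seed Integer seed; the model is deterministic given it.
#' @param voxel_mm Voxel pitch in mm (isotropic grid on the sheet).
#' @param sigma_columnar Correlation length (mm) of the columnar field.
#' @param columnar_dx Sampling pitch (mm) of the fine columnar field.
#' @param columnar_strength Root-mean-square modulus of the per-voxel
#'   columnar tuning vectors (0 disables the columnar mechanism).
#' @param baseline Untuned response, % signal change, for a fully covered
#'   receptive field (`B` in the response model).
#' @param baseline_slope Optional linear trend of baseline over
#'   log-eccentricity position in the annulus, % signal change
#'   (positive = inner rings respond more strongly).
#' @param tuned_amplitude Orientation-tuned response amplitude `A`, % signal
#'   change per unit tuning modulus.
#' @param w_radial,w_vertical Global-map weights (tuning-modulus units).
#' @param coherence_gain Multiplier in `[0, 1]` applied to the global
#'   component for non-coherent stimuli.
#' @param rf_sigma_intercept,rf_sigma_slope Receptive-field width model,
#'   `sigma = intercept + slope * eccentricity` (degrees).
#' @param magnification_k Cortical magnification, mm per log-degree; `NULL`
#'   to solve from `target_voxels`.
#' @param n_quad Number of receptive-field quadrature points used when
#'   aggregating stimulus fields per voxel.
#' @return An object of class `v1_model`.
#' @examples
#' m <- build_model(target_voxels = 120, seed = 1)
#' nrow(m$rf)
#' @export
build_model <- function(target_voxels = 1126, tiling = lp_tiling(), seed = 1,
                        voxel_mm = 2, sigma_columnar = 0.8,
                        columnar_dx = 0.25, columnar_strength = 0.45,
                        baseline = 2.5, baseline_slope = 0,
                        tuned_amplitude = 0.3,
                        w_radial = 1 / 12, w_vertical = 0.07,
                        coherence_gain = 0.1,
                        rf_sigma_intercept = 0.2, rf_sigma_slope = 0.1,
                        magnification_k = NULL, n_quad = 48) {
  if (target_voxels < 4 || sigma_columnar <= 0 || columnar_dx <= 0 ||
      baseline <= 0 || tuned_amplitude < 0) {
    stop("invalid params")
  }
  rho <- tiling$r_outer / tiling$r_inner
  k <- magnification_k %||%
    sqrt(voxel_mm^2 * target_voxels / (log(rho) * 2 * pi))

  # voxel grid on the sheet: u = k*log(ecc), v = k*theta (theta in radians)
  u0 <- k * log(tiling$r_inner)
  u1 <- k * log(tiling$r_outer)
  us <- seq(u0, u1, by = voxel_mm)
  n_v <- max(4L, floor(2 * pi * k / voxel_mm))
  vs <- -pi * k + (seq_len(n_v) - 1L) * voxel_mm
  g <- expand.grid(u = us, v = vs)
  if (nrow(g) == 0L) stop("invalid params: empty annulus coverage")

  # clamp against roundoff so boundary voxels stay inside the annulus
  ecc <- pmin(pmax(exp(g$u / k), tiling$r_inner), tiling$r_outer)
  ang <- ((g$v / k) * 180 / pi) %% 360
  rf <- data.frame(
    voxel = seq_len(nrow(g)),
    u = g$u, v = g$v,
    x = ecc * cos(ang * pi / 180), y = ecc * sin(ang * pi / 180),
    ecc = ecc, angle = ang,
    sigma = rf_sigma_intercept + rf_sigma_slope * ecc
  )
  tl <- .tile_polar(tiling, ecc, ang, snap = 1e-9)
  rf$ring <- tl$ring
  rf$wedge <- tl$wedge
  # cylinder embedding: circumference 2*pi*k matches the sheet's v extent
  pos <- cbind(x = g$u,
               y = k * cos(g$v / k),
               z = k * sin(g$v / k))

  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(seed)

  t_col <- if (columnar_strength > 0) {
    .columnar_tuning(g$u, g$v, u0, u1, k, sigma_columnar, columnar_dx,
                     voxel_mm, columnar_strength)
  } else {
    complex(real = numeric(nrow(g)), imaginary = numeric(nrow(g)))
  }
  th2 <- 2 * ang * pi / 180
  t_glob <- w_radial * complex(argument = th2) +
    w_vertical * complex(argument = rep(pi, nrow(g)))

  base_v <- baseline + baseline_slope *
    (0.5 - (log(ecc) - log(tiling$r_inner)) / log(rho))

  # fixed equal-weight Gaussian quadrature offsets (golden-angle spiral with
  # Rayleigh-inverse radii), scaled per voxel by rf sigma
  j <- seq_len(n_quad)
  rho_q <- sqrt(-2 * log(1 - (j - 0.5) / n_quad))
  a_q <- 2 * pi * j * (sqrt(5) - 1) / 2
  quad <- cbind(dx = rho_q * cos(a_q), dy = rho_q * sin(a_q))

  structure(list(
    voxel_positions = pos, rf = rf,
    tuning_columnar = t_col, tuning_global = t_glob,
    baseline = base_v, tuned_amplitude = tuned_amplitude,
    w_radial = w_radial, w_vertical = w_vertical,
    coherence_gain = coherence_gain,
    sigma_columnar = sigma_columnar, magnification_k = k,
    tiling = tiling, quadrature = quad, seed = seed
  ), class = "v1_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.v1_model <- function(x, ...) {
  cat(sprintf(
    "v1_model: %d voxels, k = %.1f mm/log-deg, |columnar| rms = %.3f, w_rad = %.3f, w_vert = %.3f\n",
    nrow(x$rf), x$magnification_k,
    sqrt(mean(Mod(x$tuning_columnar)^2)), x$w_radial, x$w_vertical))
  invisible(x)
}

# fine columnar preference field on the sheet (wrapped in v), averaged into
# voxel apertures; returns complex tuning vectors with RMS modulus `strength`
.columnar_tuning <- function(u, v, u0, u1, k, sigma_mm, dx, voxel_mm, strength) {
  pad <- 3 * sigma_mm + voxel_mm
  uf <- seq(u0 - pad, u1 + pad, by = dx)
  n_vf <- max(8L, round(2 * pi * k / dx))
  dv <- 2 * pi * k / n_vf            # exactly periodic v grid
  vf <- -pi * k + (seq_len(n_vf) - 1L) * dv
  nu <- length(uf)

  z <- matrix(complex(real = stats::rnorm(nu * n_vf),
                      imaginary = stats::rnorm(nu * n_vf)), nu, n_vf)
  z <- .blur_complex(z, sigma_mm / dx, sigma_mm / dv)
  z <- z / sqrt(mean(Mod(z)^2))

  half <- voxel_mm / 2
  iu_lo <- findInterval(u - half, uf) + 1L
  iu_hi <- findInterval(u + half, uf)
  t_col <- complex(length.out = length(u))
  for (i in seq_along(u)) {
    dv_rel <- ((vf - v[i] + pi * k) %% (2 * pi * k)) - pi * k
    jv <- which(abs(dv_rel) <= half)
    t_col[i] <- mean(z[iu_lo[i]:iu_hi[i], jv])
  }
  rms <- sqrt(mean(Mod(t_col)^2))
  if (rms > 0) t_col <- t_col * (strength / rms)
  t_col
}

# separable Gaussian blur of a complex matrix; rows (u) open boundary with
# renormalization, columns (v) circular
.blur_complex <- function(z, s_row, s_col) {
  .blur1 <- function(m, s, circular) {
    if (s <= 0) return(m)
    hw <- max(1L, ceiling(3 * s))
    kk <- stats::dnorm(seq(-hw, hw), sd = s)
    kk <- kk / sum(kk)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    if (circular) {
      for (d in seq(-hw, hw)) {
        idx <- ((seq_len(n) - 1L + d) %% n) + 1L
        out <- out + kk[d + hw + 1L] * m[idx, , drop = FALSE]
      }
    } else {
      wsum <- numeric(n)
      for (d in seq(-hw, hw)) {
        idx <- seq_len(n) + d
        ok <- idx >= 1L & idx <= n
        out[ok, ] <- out[ok, ] + kk[d + hw + 1L] * m[idx[ok], , drop = FALSE]
        wsum[ok] <- wsum[ok] + kk[d + hw + 1L]
      }
      out <- out / wsum
    }
    out
  }
  z <- .blur1(z, s_row, circular = FALSE)       # u dimension (rows)
  t(.blur1(t(z), s_col, circular = TRUE))       # v dimension (columns)
}

#' Preferred orientation of each voxel
#'
#' Half the argument of the total tuning vector (columnar plus global),
#' mapped to `[0, 180)` degrees.
#'
#' @param model A [build_model()] result.
#' @param coherent Whether to apply the full global component (`TRUE`) or
#'   scale it by `coherence_gain`.
#' @return Numeric vector of orientations in degrees.
#' @export
preferred_orientation <- function(model, coherent = TRUE) {
  gain <- if (coherent) 1 else model$coherence_gain
  t_v <- model$tuning_columnar + gain * model$tuning_global
  (Arg(t_v) / 2 * 180 / pi) %% 180
}

#' Noiseless voxel responses to a stimulus
#'
#' Response of every model voxel to one stimulus exemplar, in % signal
#' change: `r_v = B_v * m_v + A * Re(Conj(t_v) * s_v)`, where `m_v` is the
#' receptive-field-weighted mean contrast energy of the stimulus (0 over
#' grout lines and background), `s_v` the RF-weighted mean of
#' `exp(2i * orientation)` over in-annulus points, and
#' `t_v = t_columnar + gain * t_global` the voxel tuning vector, with
#' `gain = coherence_gain` for non-coherent (patch-swapped) stimuli and 1
#' otherwise.
#'
#' @param model A [build_model()] result.
#' @param spec A [stim_spec()].
#' @return Numeric vector of % signal change, one value per voxel.
#' @export
voxel_response <- function(model, spec) {
  rf <- model$rf
  n <- nrow(rf)
  q <- model$quadrature
  nq <- nrow(q)
  xs <- rep(rf$x, each = nq) + as.vector(outer(q[, "dx"], rf$sigma))
  ys <- rep(rf$y, each = nq) + as.vector(outer(q[, "dy"], rf$sigma))
  ori <- orientation_at(spec, xs, ys)
  con <- contrast_at(spec, xs, ys)
  e2 <- complex(length.out = length(ori))
  ok <- !is.na(ori)
  e2[ok] <- complex(argument = 2 * ori[ok] * pi / 180)
  s_v <- colMeans(matrix(e2, nq, n))
  m_v <- colMeans(matrix(abs(con), nq, n))
  gain <- if (spec$coherent) 1 else model$coherence_gain
  t_v <- model$tuning_columnar + gain * model$tuning_global
  model$baseline * m_v + model$tuned_amplitude * Re(Conj(t_v) * s_v)
}
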