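# Independent oracles used across test files.

# brute-force O(n^2) masked Gaussian smoothing (double loop)
oracle_smooth <- function(pattern, coords, fwhm) {
  sigma <- fwhm / sqrt(8 * log(2))
  n <- length(pattern)
  out <- numeric(n)
  for (v in seq_len(n)) {
    num <- 0
    den <- 0
    for (u in seq_len(n)) {
      w <- exp(-sum((coords[v, ] - coords[u, ])^2) / (2 * sigma^2))
      num <- num + w * pattern[u]
      den <- den + w
    }
    out[v] <- num / den
  }
  out
}

# brute-force exact signed-rank p-value by enumerating all 2^n sign patterns
oracle_signedrank <- function(d, sides = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(seq_len(2^n) - 1L, function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0
    sum(r[signs])
  }, numeric(1))
  p_ge <- mean(vs >= v_obs)
  p_le <- mean(vs <= v_obs)
  switch(sides,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Spearman correlation from first principles (average ranks)
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# trace one iso-contrast edge of a spiral by bisection on the contrast sign
# at a set of radii, then numerically compare the tangent with the radial
# direction
oracle_spiral_edge_angle <- function(spec, radii) {
  find_edge <- function(r, lo, hi) {
    if (hi < lo) hi <- hi + 2 * pi     # interval wrapping 2*pi
    f <- function(a) contrast_at(spec, r * cos(a), r * sin(a))
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) == f(lo)) lo <- mid else hi <- mid
    }
    ((lo + hi) / 2) %% (2 * pi)
  }
  # at each radius, locate the edge nearest the previous one so the points
  # follow a single spiral arm
  n_scan <- 720
  angs <- numeric(length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]
    aa <- seq(0, 2 * pi, length.out = n_scan + 1)[-(n_scan + 1)]
    cc <- contrast_at(spec, r * cos(aa), r * sin(aa))
    flips <- which(cc != cc[c(2:n_scan, 1)] & cc != 0 &
                     cc[c(2:n_scan, 1)] != 0)
    cand <- vapply(flips, function(j) {
      find_edge(r, aa[j], aa[j %% n_scan + 1L])
    }, numeric(1))
    if (i == 1) {
      angs[i] <- cand[1L]
    } else {
      d <- abs((cand - angs[i - 1] + pi) %% (2 * pi) - pi)
      angs[i] <- cand[which.min(d)]
    }
  }
  # unwrap and differentiate the contour theta(r)
  angs <- cumsum(c(angs[1], ((diff(angs) + pi) %% (2 * pi)) - pi))
  dtheta_dr <- diff(angs) / diff(radii)
  r_mid <- (radii[-1] + radii[-length(radii)]) / 2
  atan(abs(r_mid * dtheta_dr)) * 180 / pi   # angle between tangent and radius
}

# small deterministic pattern set: two class-mean patterns plus noise,
# 2 runs x 4 subruns
make_toy_patterns <- function(n_vox = 12, delta = 1, noise = 0.1,
                              seed = 1, n_folds = 8) {
  set.seed(seed)
  mu_a <- rnorm(n_vox)
  mu_b <- mu_a + delta * rnorm(n_vox)
  t <- sapply(seq_len(2 * n_folds), function(i) {
    mu <- if (i %% 2 == 1) mu_a else mu_b
    mu + noise * rnorm(n_vox)
  })
  meta <- data.frame(
    exemplar = rep(c("A", "B"), n_folds),
    subrun = rep(seq_len(n_folds), each = 2),
    run = rep(1:2, each = n_folds))
  meta$fold <- meta$subrun
  coords <- cbind(2 * seq_len(n_vox), 0, 0)
  pattern_set(t, meta = meta, coords = coords, family = "toy",
              subject = "toy01")
}

# one small simulated subject shared across tests (built once per session)
.test_cache <- new.env(parent = emptyenv())
tiny_subject <- function() {
  if (is.null(.test_cache$subj)) {
    .test_cache$subj <- simulate_subject(
      families = "grating", seed = 101,
      model_args = list(target_voxels = 120))
  }
  .test_cache$subj
}
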