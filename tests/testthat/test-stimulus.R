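sample_annulus <- function(n, tiling = lp_tiling(), seed = 7) {
  set.seed(seed)
  ecc <- sqrt(runif(n, tiling$r_inner^2, tiling$r_outer^2))
  ang <- runif(n, 0, 2 * pi)
  data.frame(x = ecc * cos(ang), y = ecc * sin(ang))
}

test_that("the two exemplars of every family differ by 90 degrees everywhere", {
  pts <- sample_annulus(4000)
  for (fam in c("grating", "spiral", "patchswap_grating", "patchswap_spiral")) {
    oa <- orientation_at(stim_spec(fam, "A"), pts$x, pts$y)
    ob <- orientation_at(stim_spec(fam, "B"), pts$x, pts$y)
    ok <- !is.na(oa)
    expect_gt(sum(ok), 3000)
    expect_equal(is.na(oa), is.na(ob))
    d <- abs(oa[ok] - ob[ok]) %% 180
    expect_true(all(abs(d - 90) < 1e-9), label = paste(fam, "disparity"))
  }
})

test_that("gratings are oblique and mirror-symmetric about the vertical", {
  ng <- function(f, v) stim_spec(f, v, grout_width = 0)
  expect_equal(orientation_at(ng("grating", "A"), 3, 0), 45)
  expect_equal(orientation_at(ng("grating", "B"), 3, 0), 135)
  # with grout lines present, (3, 0) sits on the horizontal boundary line
  expect_true(is.na(orientation_at(stim_spec("grating", "A"), 3, 0)))
  # cardinal balance: reflecting about vertical maps one exemplar's
  # orientation onto the other's
  pts <- sample_annulus(500)
  oa <- orientation_at(stim_spec("grating", "A"), pts$x, pts$y)
  ob <- orientation_at(stim_spec("grating", "B"), -pts$x, pts$y)
  ok <- !is.na(oa) & !is.na(ob)
  expect_true(all(abs((180 - oa[ok]) %% 180 - ob[ok] %% 180) < 1e-9))
})

test_that("spirals deviate from the local radial direction by exactly +/-45", {
  pts <- sample_annulus(2000)
  ang <- (atan2(pts$y, pts$x) * 180 / pi) %% 360
  oa <- orientation_at(stim_spec("spiral", "A"), pts$x, pts$y)
  ob <- orientation_at(stim_spec("spiral", "B"), pts$x, pts$y)
  ok <- !is.na(oa)
  dev_a <- (oa[ok] - ang[ok]) %% 180
  dev_b <- (ob[ok] - ang[ok]) %% 180
  expect_true(all(abs(dev_a - 135) < 1e-9))  # -45 mod 180
  expect_true(all(abs(dev_b - 45) < 1e-9))   # +45
})

test_that("numerically traced spiral edges keep a 45-degree angle to the radius", {
  spec <- stim_spec("spiral", "A", grout_width = 0, phase = 1.1)
  radii <- seq(1.7, 6.8, length.out = 100)
  angles <- oracle_spiral_edge_angle(spec, radii)
  expect_true(all(abs(angles - 45) < 0.1))
})

test_that("orientation is absent exactly where contrast is zero", {
  pts <- sample_annulus(2000)
  pts <- rbind(pts, data.frame(x = c(0.5, 8, 2.511414), y = c(0, 0, 0)))
  for (fam in c("grating", "patchswap_spiral")) {
    spec <- stim_spec(fam, "A", phase = 0.4)
    ori <- orientation_at(spec, pts$x, pts$y)
    con <- contrast_at(spec, pts$x, pts$y)
    expect_equal(is.na(ori), con == 0)
  }
})

test_that("grating contrast oscillates at 1.25 cycles per degree", {
  spec <- stim_spec("grating", "A", phase = 0.7)
  # transect orthogonal to the 45-degree orientation, i.e. along 135 degrees,
  # offset to stay clear of the central hole
  tt <- seq(-6.5, 6.5, by = 1 / 64)
  x <- tt * cos(135 * pi / 180) + 2 * cos(45 * pi / 180)
  y <- tt * sin(135 * pi / 180) + 2 * sin(45 * pi / 180)
  cc <- contrast_at(spec, x, y)
  nz <- which(cc != 0)
  flips <- which(diff(cc[nz]) != 0)
  # frequency from the span between the first and last edge
  pos <- (tt[nz][flips] + tt[nz][flips + 1]) / 2
  f <- (length(flips) - 1) / (2 * (max(pos) - min(pos)))
  expect_equal(f, 1.25, tolerance = 0.01)
})

test_that("spirals have 22 contrast cycles along a circle", {
  spec <- stim_spec("spiral", "A", phase = 2.1)
  aa <- seq(0, 2 * pi, length.out = 10001)[-10001]
  cc <- contrast_at(spec, 3 * cos(aa), 3 * sin(aa))
  cc <- cc[cc != 0]                       # bridge grout crossings
  flips <- sum(cc != c(cc[-1], cc[1]))    # cyclic sign changes
  expect_equal(flips / 2, 22)
})

test_that("patch-swapped exemplars tile-complement their parents", {
  tl <- lp_tiling()
  ctr <- tile_centers(tl)
  phase <- 0.9
  pa <- contrast_at(stim_spec("grating", "A", phase = phase), ctr$x, ctr$y)
  pb <- contrast_at(stim_spec("grating", "B", phase = phase), ctr$x, ctr$y)
  sa <- contrast_at(stim_spec("patchswap_grating", "A", phase = phase),
                    ctr$x, ctr$y)
  sb <- contrast_at(stim_spec("patchswap_grating", "B", phase = phase),
                    ctr$x, ctr$y)
  par <- checker_parity(ctr$ring, ctr$wedge)
  expect_equal(sa[par == "keep"], pa[par == "keep"])
  expect_equal(sa[par == "swap"], pb[par == "swap"])
  expect_equal(sb[par == "keep"], pb[par == "keep"])
  expect_equal(sb[par == "swap"], pa[par == "swap"])
  # the union of one patch-swapped exemplar's tiles covers half of each parent
  expect_equal(sum(par == "keep"), 18)
  expect_equal(sum(par == "swap"), 18)
})

test_that("rendering is deterministic, phase-inverting and annulus-bounded", {
  spec <- stim_spec("spiral", "B")
  r1 <- render_stimulus(spec, pixels_per_degree = 12, seed = 5)
  r2 <- render_stimulus(spec, pixels_per_degree = 12, seed = 5)
  expect_identical(r1$image, r2$image)
  # half-cycle phase shift inverts tile interiors, keeps zeros
  ra <- render_stimulus(spec, pixels_per_degree = 12, phase = 0)
  rb <- render_stimulus(spec, pixels_per_degree = 12, phase = pi)
  expect_identical(ra$image == 0, rb$image == 0)
  expect_identical(ra$image[ra$image != 0], -rb$image[rb$image != 0])
  # bounding circle of nonzero pixels has the stimulus diameter
  nz <- which(ra$image != 0, arr.ind = TRUE)
  half <- ra$extent_deg / 2
  px <- (nz[, 2] - 0.5) / ra$ppd - half
  py <- half - (nz[, 1] - 0.5) / ra$ppd
  expect_equal(2 * max(sqrt(px^2 + py^2)), 14.08, tolerance = 0.02)
  expect_warning(render_stimulus(spec, pixels_per_degree = 4, phase = 0),
                 "alias")
})
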