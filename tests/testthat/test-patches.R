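toy_rf <- function() {
  ctr <- tile_centers(lp_tiling())
  # 3 voxels per tile, jittered inside the tile
  set.seed(12)
  rf <- do.call(rbind, lapply(seq_len(nrow(ctr)), function(i) {
    data.frame(x = ctr$x[i] * exp(runif(3, -0.02, 0.02)),
               y = ctr$y[i] * exp(runif(3, -0.02, 0.02)),
               ring = ctr$ring[i], wedge = ctr$wedge[i])
  }))
  rf
}

test_that("parcellation labels every voxel and the scales nest exactly", {
  rf <- toy_rf()
  p36 <- parcellate(rf, scale = 36)
  expect_equal(length(unique(p36$labels)), 36)
  expect_equal(p36$n_patches, 36)
  # direct parcellation at coarser scales equals merging the 36-scale one
  tl <- lp_tiling()
  for (sc in c(12, 4, 2, 1)) {
    direct <- parcellate(rf, scale = sc)$labels
    info36 <- parcellate(rf, scale = 36)$info
    wedge36 <- info36$wedge[match(p36$labels, info36$label)]
    merged <- switch(as.character(sc),
                     "12" = wedge36 + 1L,
                     "4" = wedge36 %/% 3L + 1L,
                     "2" = ifelse(wedge36 < 3 | wedge36 >= 9, 1L, 2L),
                     "1" = rep(1L, length(wedge36)))
    expect_equal(direct, merged, label = paste("scale", sc))
  }
  # a voxel at 2 deg eccentricity, 15 deg polar angle is in tile (0, 0)
  one <- parcellate(data.frame(x = 2 * cos(pi / 12), y = 2 * sin(pi / 12)),
                    scale = 36)
  expect_equal(one$info$ring[one$info$label == one$labels], 0)
  expect_equal(one$info$wedge[one$info$label == one$labels], 0)
  expect_error(parcellate(data.frame(x = 0.2, y = 0)), "unassigned")
})

test_that("patch-mean removal annihilates coarse structure exactly", {
  rf <- toy_rf()
  parc <- parcellate(rf, scale = 36)
  n <- nrow(rf)
  expect_equal(remove_patch_means(rep(4.2, n), parc), numeric(n))
  set.seed(3)
  x <- rnorm(n)
  fine <- remove_patch_means(x, parc)
  expect_equal(max(abs(patch_means(fine, parc))), 0, tolerance = 1e-12)
  # variance decomposition: total = within-patch + between-patch
  recon <- x - fine
  ssq <- function(v) sum((v - mean(v))^2)
  expect_equal(ssq(x), ssq(fine) + ssq(recon) +
                 2 * sum((fine - mean(fine)) * (recon - mean(recon))),
               tolerance = 1e-10)
  expect_lt(abs(sum((fine - mean(fine)) * (recon - mean(recon)))), 1e-10)
})

test_that("patch means aggregate consistently across scales", {
  rf <- toy_rf()
  n <- nrow(rf)
  set.seed(4)
  x <- rnorm(n)
  p1 <- parcellate(rf, scale = 1)
  expect_equal(patch_means(x, p1), mean(x), ignore_attr = TRUE)
  # hemifield means are size-weighted means of the 36-scale patch means
  p36 <- parcellate(rf, scale = 36)
  p2 <- parcellate(rf, scale = 2)
  m36 <- patch_means(x, p36)
  sizes <- tabulate(p36$labels, 36)
  wedge36 <- p36$info$wedge
  right <- wedge36 < 3 | wedge36 >= 9
  m2 <- patch_means(x, p2)
  expect_equal(unname(m2[1]),
               sum(m36[right] * sizes[right]) / sum(sizes[right]),
               tolerance = 1e-12)
  expect_equal(unname(m2[2]),
               sum(m36[!right] * sizes[!right]) / sum(sizes[!right]),
               tolerance = 1e-12)
})

test_that("the cosine fit interpolates a noiseless tuning table exactly", {
  ctr <- tile_centers(lp_tiling())
  label <- ctr$wedge * 3 + ctr$ring + 1L
  mk <- function(beta0, beta1) {
    do.call(rbind, lapply(c("A", "B"), function(ex) {
      ori <- if (ex == "A") 45 else 135
      delta <- (ori - ctr$angle %% 180) * pi / 180
      data.frame(subject = "s1", family = "grating", exemplar = ex,
                 patch = label, ring = ctr$ring, wedge = ctr$wedge,
                 angle = ctr$angle, ecc = ctr$ecc, stim_ori = ori,
                 response = beta0 + beta1 * cos(2 * delta))
    }))
  }
  fit <- cosine_fit(mk(2.0, 0.025))
  expect_equal(fit$beta0, 2.0, tolerance = 1e-12)
  expect_equal(fit$beta1, 0.025, tolerance = 1e-12)
  fit0 <- cosine_fit(mk(2.0, 0))
  expect_equal(fit0$beta1, 0, tolerance = 1e-12)
})

test_that("balanced designs make the complementary hypothesis unidentifiable", {
  ctr <- tile_centers(lp_tiling())
  tab <- do.call(rbind, lapply(c("A", "B"), function(ex) {
    s <- if (ex == "A") -1 else 1
    data.frame(subject = "s1", family = "spiral", exemplar = ex,
               patch = ctr$wedge * 3 + ctr$ring + 1L, ring = ctr$ring,
               wedge = ctr$wedge, angle = ctr$angle, ecc = ctr$ecc,
               stim_ori = (ctr$angle + s * 45) %% 180, response = 2)
  }))
  # radial predictor for spirals is constant (the design is radially
  # balanced), so radial preference cannot be estimated from spirals
  pred <- cosine_predictor(tab, "radial")
  expect_lt(stats::sd(pred), 1e-12)
  expect_error(cosine_fit(tab, "radial"), "unidentifiable")
  # but the vertical predictor is informative
  expect_gt(stats::sd(cosine_predictor(tab, "vertical")), 0.5)
})

test_that("rank-order preference tests recover perfect orderings and ties", {
  ctr <- tile_centers(lp_tiling())
  mk_subject <- function(subject, slope) {
    tab <- do.call(rbind, lapply(c("A", "B"), function(ex) {
      data.frame(subject = subject, family = "grating", exemplar = ex,
                 patch = ctr$wedge * 3 + ctr$ring + 1L, ring = ctr$ring,
                 wedge = ctr$wedge, angle = ctr$angle, ecc = ctr$ecc,
                 stim_ori = if (ex == "A") 45 else 135, response = 0)
    }))
    tab$response <- 2 + slope * cosine_predictor(tab, "radial")
    tab
  }
  tab <- rbind(mk_subject("s1", 0.1), mk_subject("s2", 0.1))
  res <- rank_preference_test(tab)
  expect_equal(res$per_subject$r, c(1, 1))
  neg <- rank_preference_test(rbind(mk_subject("s1", -0.1),
                                    mk_subject("s2", -0.1)))
  expect_equal(neg$per_subject$r, c(-1, -1))
  # tied instance equals the direct average-rank formula
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4)
  expect_equal(stats::cor(x, y, method = "spearman"), oracle_spearman(x, y))
})

test_that("contrast exclusion reduces to the full test at q = 0 and flags degenerate q", {
  ctr <- tile_centers(lp_tiling())
  set.seed(9)
  tab <- do.call(rbind, lapply(c("A", "B"), function(ex) {
    ori <- if (ex == "A") 45 else 135
    delta <- (ori - ctr$angle %% 180) * pi / 180
    data.frame(subject = "s1", family = "grating", exemplar = ex,
               patch = ctr$wedge * 3 + ctr$ring + 1L, ring = ctr$ring,
               wedge = ctr$wedge, angle = ctr$angle, ecc = ctr$ecc,
               stim_ori = ori,
               response = 2 + 0.02 * cos(2 * delta) + 0.005 * rnorm(36))
  }))
  sweep <- contrast_exclusion(tab, q_grid = c(0, 0.5, 0.95))
  r0 <- sweep$per_subject$r[sweep$per_subject$q == 0]
  # q = 0 equals a direct contrast correlation over all 36 patches
  a <- tab[tab$exemplar == "A", ]
  b <- tab[tab$exemplar == "B", ]
  pred <- cosine_predictor(b) - cosine_predictor(a)
  expect_equal(r0, stats::cor(b$response - a$response, pred,
                              method = "spearman"))
  # q = 0.95 retains 2 patches -> undefined
  expect_true(is.na(sweep$per_subject$r[sweep$per_subject$q == 0.95]))
  expect_error(contrast_exclusion(tab, q_grid = 0.99), "0.95")
})

test_that("exclusion sharpens a half-informative table", {
  ctr <- tile_centers(lp_tiling())
  set.seed(31)
  informative <- ctr$ring < 2   # 24 of 36 patches carry signal
  mk <- function(subject) {
    noise <- 0.02 * rnorm(36)
    do.call(rbind, lapply(c("A", "B"), function(ex) {
      ori <- if (ex == "A") 45 else 135
      delta <- (ori - ctr$angle %% 180) * pi / 180
      sig <- ifelse(informative, 0.05 * cos(2 * delta), 0)
      data.frame(subject = subject, family = "grating", exemplar = ex,
                 patch = ctr$wedge * 3 + ctr$ring + 1L, ring = ctr$ring,
                 wedge = ctr$wedge, angle = ctr$angle, ecc = ctr$ecc,
                 stim_ori = ori,
                 response = 2 + sig + (if (ex == "A") noise else -noise))
    }))
  }
  tab <- do.call(rbind, lapply(paste0("s", 1:6), mk))
  sweep <- contrast_exclusion(tab, q_grid = c(0, 0.3))
  r_by_q <- tapply(sweep$per_subject$r, sweep$per_subject$q, mean)
  expect_gt(r_by_q["0.3"], r_by_q["0"])
})

test_that("univariate summaries recover an injected eccentricity gradient", {
  co <- simulate_cohort(n_subjects = 5, families = "grating", seed = 77,
                        motion_scale = 0,
                        model_args = list(target_voxels = 150,
                                          baseline_slope = 0.6,
                                          columnar_strength = 0.1,
                                          tuned_amplitude = 0.05))
  tab <- build_patch_table(co)
  us <- univariate_summary(tab)
  m <- us$by_ring$mean[order(us$by_ring$level)]
  # the injected log-eccentricity gradient makes the inner ring respond more
  # strongly than the peripheral ring
  expect_gt(m[1], m[3])
  inner_vs_outer <- us$ring_tests[us$ring_tests$ring_a == 0 &
                                    us$ring_tests$ring_b == 2, ]
  expect_lt(inner_vs_outer$p, 0.07)
  expect_equal(nrow(tab[tab$subject == "sub01", ]), 72)
})

test_that("ring-restricted decoding partitions the ROI", {
  subj <- tiny_subject()
  rings <- subj$model$rf$ring
  sets <- lapply(0:2, function(r) which(rings == r))
  expect_equal(sort(unlist(sets)), seq_len(nrow(subj$model$rf)))
  expect_equal(sum(lengths(sets)), nrow(subj$model$rf))
  sw <- decode_by_ring(list(subj), "grating", ring = "central",
                       grid = c(2, 6))
  expect_equal(nrow(sw$curve), 2)
  expect_equal(sw$ring, 0L)
})
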