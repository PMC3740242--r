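test_that("the hemodynamic kernel is a delayed, peak-normalized gamma", {
  expect_equal(hrf(1.0), 0)
  expect_equal(hrf(2.5), 0)
  expect_equal(hrf(5.0), 1)                      # peak at delta + tau*(n-1)
  tt <- seq(0, 30, by = 0.001)
  expect_equal(tt[which.max(hrf(tt))], 5, tolerance = 1e-3)
  expect_lt(max(hrf(tt)), 1 + 1e-12)
  expect_error(hrf(1, tau = -1), "positive")
})

test_that("the design matrix has one column per exemplar-subrun plus confounds", {
  sch <- schedule_runs()
  mo <- matrix(rnorm(252 * 6, sd = 0.01), 252, 6)
  des <- build_design(sch, motion = mo)
  expect_equal(ncol(des$X), 8 + 6 + 1)
  expect_equal(nrow(des$X), 250)                 # two volumes discarded
  expect_equal(nrow(des$task_info), 8)
  task <- des$X[, 1:8]
  expect_true(all(task >= 0))
  # each task column is confined to its subrun's span
  for (j in 1:8) {
    sub <- des$task_info$subrun[j]
    blocks <- sch$blocks[sch$blocks$subrun == sub, ]
    t_vol <- (des$keep - 1) * sch$TR
    outside <- t_vol < min(blocks$onset) - 1 |
      t_vol > max(blocks$onset + blocks$duration) + 32
    expect_true(all(task[outside, j] < 1e-6))
  }
  # peak-normalized columns integrate to about 3 x block duration
  integrals <- colSums(task) * sch$TR
  expect_equal(unname(integrals), rep(3 * 14, 8), tolerance = 0.12)
})

test_that("zero motion gives all-zero confound columns that are dropped in the fit", {
  sch <- schedule_runs()
  des <- build_design(sch, motion = NULL)
  expect_true(all(des$X[, 9:14] == 0))
  y <- matrix(rnorm(252 * 3), 252, 3)
  expect_silent(fit_glm(y, des))
})

test_that("noiseless beta recovery is exact and yields 8 patterns per exemplar", {
  sch <- schedule_runs()
  des <- build_design(sch, motion = NULL)
  n_vox <- 5
  beta_true <- matrix(rnorm(8 * n_vox), 8, n_vox)
  y_kept <- des$X[, 1:8] %*% beta_true + 2 +
    0 * des$X[, 15]
  y <- matrix(0, 252, n_vox)
  y[des$keep, ] <- y_kept
  ps <- fit_glm(y, des)
  expect_equal(ncol(ps$t), 8)
  expect_equal(sum(ps$meta$exemplar == "A"), 4)
  # reconstruct beta estimates from psc: psc = 100 * beta / intercept
  expect_equal(unname(t(ps$psc) * 2 / 100), unname(beta_true),
               tolerance = 1e-7)
  # two runs combined: 8 patterns per exemplar
  comb <- combine_patterns(ps, ps)
  expect_equal(sum(comb$meta$exemplar == "A"), 8)
  expect_equal(sort(unique(comb$meta$fold)), 1:8)
})

test_that("t-patterns are scale-free and equivariant to voxel permutation", {
  sch <- schedule_runs()
  des <- build_design(sch, motion = NULL)
  set.seed(21)
  y <- matrix(rnorm(252 * 6, mean = 100), 252, 6)
  y[des$keep, ] <- y[des$keep, ] + des$X[, 1:8] %*% matrix(rnorm(48), 8, 6)
  t1 <- fit_glm(y, des)$t
  t2 <- fit_glm(3.7 * y, des)$t
  expect_equal(t1, t2, tolerance = 1e-9)
  perm <- c(4, 2, 6, 1, 3, 5)
  t3 <- fit_glm(y[, perm], des)$t
  expect_equal(t3, t1[perm, ], tolerance = 1e-12)
})

test_that("confounds orthogonal to the task do not move task estimates", {
  sch <- schedule_runs()
  des0 <- build_design(sch, motion = NULL)
  X_task <- des0$X[, 1:8]
  set.seed(8)
  raw <- rnorm(250)
  ortho <- unname(stats::residuals(stats::lm(raw ~ X_task)))
  mo <- matrix(0, 252, 6)
  mo[des0$keep, 1] <- ortho
  des1 <- build_design(sch, motion = mo)
  y <- matrix(rnorm(252 * 4, mean = 50), 252, 4)
  b0 <- fit_glm(y, des0)$psc
  b1 <- fit_glm(y, des1)$psc
  expect_equal(b0, b1, tolerance = 1e-8)
})

test_that("design/volume mismatches and rank deficiency are reported", {
  sch <- schedule_runs()
  expect_error(build_design(sch, n_volumes = 100), "invalid design")
  mo <- matrix(rnorm(50), 10, 5)
  expect_error(build_design(sch, motion = mo), "invalid design")
  des <- build_design(sch, motion = NULL)
  des$X <- cbind(des$X, dup = des$X[, 1])
  expect_error(fit_glm(matrix(rnorm(252 * 2), 252, 2), des),
               "degenerate design")
})

test_that("noiseless end-to-end simulation recovers the response contrast signs", {
  m <- build_model(target_voxels = 120, seed = 31)
  resp <- list(A = voxel_response(m, stim_spec("grating", "A", m$tiling)),
               B = voxel_response(m, stim_spec("grating", "B", m$tiling)))
  sch <- schedule_runs()
  ts <- simulate_timeseries(m, sch, resp, sigma_white = 0, motion_scale = 0)
  ps <- fit_glm(ts$series, build_design(sch, ts$motion))
  tA <- rowMeans(ps$t[, ps$meta$exemplar == "A"])
  tB <- rowMeans(ps$t[, ps$meta$exemplar == "B"])
  truth <- resp$A - resp$B
  agree <- sign(tA - tB) == sign(truth)
  expect_gte(mean(agree[abs(truth) > 1e-8]), 0.99)
})
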