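test_that("linearly separable patterns decode perfectly", {
  ps <- make_toy_patterns(delta = 2, noise = 0.01)
  expect_equal(loso_accuracy(ps)$accuracy, 1.0)
})

test_that("identical class patterns hit the deterministic tie-break", {
  set.seed(2)
  base <- rnorm(10)
  t <- matrix(rep(base, 16), nrow = 10)
  meta <- data.frame(exemplar = rep(c("A", "B"), 8),
                     subrun = rep(1:8, each = 2), run = 1L)
  ps <- pattern_set(t, meta = meta)
  # every decision value is 0 -> always class A -> exactly half correct
  expect_equal(loso_accuracy(ps)$accuracy, 0.5)
})

test_that("every pattern is tested exactly once with disjoint folds", {
  ps <- make_toy_patterns()
  res <- loso_accuracy(ps)
  expect_equal(res$folds, 8)
  expect_equal(res$n_test, 16)
  expect_equal(res$per_fold$n, rep(2, 8))
})

test_that("cross-validation structure violations are caught", {
  ps <- make_toy_patterns()
  short <- ps
  keep <- ps$meta$subrun <= 2
  short$t <- ps$t[, keep]
  short$meta <- ps$meta[keep, ]
  expect_error(loso_accuracy(short), "invalid cv structure")
  bad <- ps
  bad_labels <- ps$meta$exemplar
  bad_labels[ps$meta$subrun == 3] <- "A"
  expect_error(loso_accuracy(bad, labels = bad_labels),
               "invalid cv structure")
})

test_that("label permutation takes decoding to chance on average", {
  set.seed(99)
  accs <- replicate(40, {
    ps <- make_toy_patterns(delta = 1.5, noise = 0.3,
                            seed = sample.int(1e6, 1))
    perm <- ps$meta$exemplar
    for (s in unique(ps$meta$subrun)) {
      i <- which(ps$meta$subrun == s)
      if (runif(1) < 0.5) perm[i] <- rev(perm[i])
    }
    loso_accuracy(ps, labels = perm)$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.06)
})

test_that("group signed-rank handles degenerate and extreme accuracy sets", {
  res <- group_signedrank(rep(0.5, 18))
  expect_true(res$degenerate)
  expect_equal(res$p.value, 1)
  res2 <- group_signedrank(seq(0.52, 0.9, length.out = 18), sides = "greater")
  expect_equal(res2$p.value, 2^-18, tolerance = 1e-12)
  accs <- c(0.6, 0.7, 0.55, 0.45, 0.65, 0.8)
  expect_equal(group_signedrank(accs, sides = "two.sided")$p.value,
               oracle_signedrank(accs - 0.5, "two.sided"), tolerance = 1e-12)
  expect_error(group_signedrank(c(0.5, 0.6)), ">= 5 subjects")
})

test_that("paired comparisons are symmetric and exact", {
  a <- c(0.8, 0.75, 0.9, 0.7, 0.85, 0.6)
  b <- a - 0.05
  res <- paired_signedrank(a, b)
  expect_equal(res$p.value, 2 / 2^6, tolerance = 1e-12)  # all-positive, 2-sided
  expect_equal(paired_signedrank(a, b)$p.value,
               paired_signedrank(b, a)$p.value)
  expect_equal(paired_signedrank(a, a)$p.value, 1)
  expect_error(paired_signedrank(a, b[-1]), "invalid pairing")
})

test_that("the Fisher discriminant is invariant to invertible smoothing", {
  ps <- make_toy_patterns(n_vox = 10, delta = 0.8, noise = 1.0, seed = 42)
  S <- smoothing_matrix(ps$coords, fwhm = 6)
  expect_gt(abs(det(S)), 0)
  acc0 <- fisher_loso_accuracy(ps)$accuracy
  acc1 <- fisher_loso_accuracy(ps, x = S %*% ps$t)$accuracy
  expect_equal(acc0, acc1, tolerance = 1e-6)
  # the SVM path is not expected to be invariant; just confirm it runs
  expect_true(is.numeric(loso_accuracy(ps, x = S %*% ps$t)$accuracy))
})

test_that("group signed-rank keeps its nominal type-I error under the null", {
  set.seed(123)
  rejections <- replicate(500, {
    acc <- 0.5 + rnorm(18, sd = 0.05)
    group_signedrank(acc, sides = "two.sided")$p.value <= 0.05
  })
  rate <- mean(rejections)
  ci <- stats::binom.test(sum(rejections), 500, p = 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2],
              label = sprintf("type-I error %.3f, CI [%.3f, %.3f]",
                              rate, ci[1], ci[2]))
})
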