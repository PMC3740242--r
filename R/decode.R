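#' Leave-one-subrun-out linear-SVM decoding
#'
#' Decodes exemplar identity (A vs B) from t-value patterns with a linear
#' support vector machine (cost `C`, no feature scaling, t-values used
#' as-is), leaving one subrun's patterns out per fold.  With the default
#' 2-run x 4-subrun design this gives 8 folds, each training on 14 patterns
#' and testing on 2; accuracy is the fraction of all held-out patterns
#' classified correctly.  A decision value of exactly 0 is deterministically
#' broken in favor of exemplar `"A"`.
#'
#' @param patterns A `pattern_set` whose `meta` has `exemplar` and a fold
#'   column (`fold` if present, else `subrun`).
#' @param C SVM regularization constant.
#' @param labels Optional replacement exemplar labels (e.g. permuted),
#'   same length as the number of patterns.
#' @param x Optional replacement feature matrix (voxels x patterns), e.g.
#'   spatially filtered patterns; defaults to `patterns$t`.
#' @return A list of class `decoding_result`: `accuracy`, `n_correct`,
#'   `n_test`, `folds`, `per_fold` (data.frame), `family`, `subject`.
#' @export
loso_accuracy <- function(patterns, C = 1, labels = NULL, x = NULL) {
  meta <- patterns$meta
  fold <- meta$fold %||% meta$subrun
  y <- labels %||% meta$exemplar
  X <- t(x %||% patterns$t)      # patterns x voxels
  folds <- sort(unique(fold))
  if (length(folds) < 3) stop("invalid cv structure: need >= 3 subruns")
  for (f in folds) {
    if (length(unique(y[fold == f])) < 2) {
      stop("invalid cv structure: both exemplars must appear in every subrun")
    }
  }
  per_fold <- lapply(folds, function(f) {
    tr <- fold != f
    pred <- .linear_svm_predict(X[tr, , drop = FALSE], y[tr],
                                X[!tr, , drop = FALSE], C = C)
    data.frame(fold = f, correct = sum(pred == y[!tr]), n = sum(!tr))
  })
  per_fold <- do.call(rbind, per_fold)
  structure(list(
    accuracy = sum(per_fold$correct) / sum(per_fold$n),
    n_correct = sum(per_fold$correct), n_test = sum(per_fold$n),
    folds = length(folds), per_fold = per_fold,
    family = patterns$family, subject = patterns$subject
  ), class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding: %.1f%% (%d/%d over %d folds)\n",
              100 * x$accuracy, x$n_correct, x$n_test, x$folds))
  invisible(x)
}

# train a two-class linear SVM and predict test labels; ties (decision
# value 0) go to the alphabetically first class ("A")
.linear_svm_predict <- function(X_train, y_train, X_test, C = 1) {
  classes <- sort(unique(y_train))
  stopifnot(length(classes) == 2L)
  fit <- e1071::svm(X_train, factor(y_train, levels = classes),
                    kernel = "linear", cost = C, scale = FALSE,
                    type = "C-classification")
  # decision values: positive for the first factor level seen in training
  pred <- stats::predict(fit, X_test, decision.values = TRUE)
  dec <- drop(attr(pred, "decision.values"))
  pos_class <- strsplit(colnames(attr(pred, "decision.values")), "/")[[1L]][1L]
  neg_class <- setdiff(classes, pos_class)
  out <- ifelse(dec > 0, pos_class, neg_class)
  out[dec == 0] <- classes[1L]
  unname(out)
}

#' Leave-one-subrun-out Fisher linear discriminant decoding
#'
#' Same cross-validation as [loso_accuracy()] but classifying with a Fisher
#' linear discriminant using the pooled sample covariance.  Because this
#' discriminant whitens the data, its accuracy is invariant under any
#' invertible linear transform of the patterns — in particular under
#' invertible Gaussian smoothing — unlike the SVM path.  Requires more
#' training patterns than voxels.
#'
#' @inheritParams loso_accuracy
#' @return A `decoding_result`.
#' @export
fisher_loso_accuracy <- function(patterns, labels = NULL, x = NULL) {
  meta <- patterns$meta
  fold <- meta$fold %||% meta$subrun
  y <- labels %||% meta$exemplar
  X <- t(x %||% patterns$t)
  folds <- sort(unique(fold))
  classes <- sort(unique(y))
  per_fold <- lapply(folds, function(f) {
    tr <- fold != f
    Xa <- X[tr & y == classes[1L], , drop = FALSE]
    Xb <- X[tr & y == classes[2L], , drop = FALSE]
    ma <- colMeans(Xa); mb <- colMeans(Xb)
    S <- (crossprod(sweep(Xa, 2, ma)) + crossprod(sweep(Xb, 2, mb))) /
      (nrow(Xa) + nrow(Xb) - 2)
    w <- solve(S, ma - mb)
    thr <- sum(w * (ma + mb)) / 2
    dec <- X[!tr, , drop = FALSE] %*% w - thr
    pred <- ifelse(dec >= 0, classes[1L], classes[2L])
    data.frame(fold = f, correct = sum(pred == y[!tr]), n = sum(!tr))
  })
  per_fold <- do.call(rbind, per_fold)
  structure(list(
    accuracy = sum(per_fold$correct) / sum(per_fold$n),
    n_correct = sum(per_fold$correct), n_test = sum(per_fold$n),
    folds = length(folds), per_fold = per_fold,
    family = patterns$family, subject = patterns$subject
  ), class = "decoding_result")
}

#' Group inference on decoding accuracies
#'
#' Wilcoxon signed-rank test of the single-subject accuracies against
#' chance: the chance level is subtracted and [signed_rank_test()] applied.
#' One-sided (above chance) by default for decoding-versus-chance;
#' preference-map and paired tests in this package are two-sided.
#'
#' @param accuracies Per-subject accuracy fractions.
#' @param chance Chance level (0.5 for two exemplars).
#' @param sides `"greater"` (default), `"two.sided"` or `"less"`.
#' @return List: `p.value`, `median`, `n`, `statistic`, `method`,
#'   `degenerate`.
#' @export
group_signedrank <- function(accuracies, chance = 0.5,
                             sides = c("greater", "two.sided", "less")) {
  sides <- match.arg(sides)
  if (length(accuracies) < 5) stop("need >= 5 subjects for group inference")
  res <- signed_rank_test(accuracies - chance, sides = sides)
  list(p.value = res$p.value, median = stats::median(accuracies),
       n = length(accuracies), statistic = res$statistic,
       method = res$method, degenerate = res$degenerate)
}

#' Paired comparison of decoding accuracies between conditions
#'
#' Two-sided Wilcoxon signed-rank test on per-subject accuracy differences
#' between two stimulus types (or two analysis conditions).
#'
#' @param acc_a,acc_b Equal-length paired per-subject accuracy vectors.
#' @param sides Sidedness (default two-sided).
#' @return As [group_signedrank()], with `median` the median difference.
#' @export
paired_signedrank <- function(acc_a, acc_b,
                              sides = c("two.sided", "greater", "less")) {
  sides <- match.arg(sides)
  if (length(acc_a) != length(acc_b)) {
    stop("invalid pairing: accuracy vectors differ in length")
  }
  res <- signed_rank_test(acc_a - acc_b, sides = sides)
  list(p.value = res$p.value, median = stats::median(acc_a - acc_b),
       n = length(acc_a), statistic = res$statistic,
       method = res$method, degenerate = res$degenerate)
}

#' Per-subject decoding accuracies for a cohort
#'
#' Runs leave-one-subrun-out SVM decoding of one stimulus family for every
#' subject of a simulated cohort.
#'
#' @param cohort A `v1_cohort` (or list of `pattern_set`s).
#' @param family Stimulus family.
#' @param C SVM cost.
#' @return Named numeric vector of per-subject accuracies.
#' @export
decode_cohort <- function(cohort, family = "grating", C = 1) {
  sets <- .as_pattern_sets(cohort, family)
  acc <- vapply(sets, function(ps) loso_accuracy(ps, C = C)$accuracy,
                numeric(1))
  names(acc) <- vapply(seq_along(sets), function(i)
    sets[[i]]$subject %||% paste0("sub", i), "")
  acc
}
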