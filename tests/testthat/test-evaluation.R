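test_that("quality measures agree with hand-checkable cases", {
  q <- quality_measures(confusion_counts(10, 0, 10, 0))
  expect_equal(unclass(q)[c("acc", "prc", "fdr", "spc", "mcc")],
               list(acc = 1, prc = 1, fdr = 0, spc = 1, mcc = 1))
  q2 <- quality_measures(confusion_counts(5, 5, 5, 5))
  expect_equal(q2$acc, 0.5)
  expect_equal(q2$mcc, 0)
})

test_that("measures equal an independent statistical oracle on random counts", {
  set.seed(101)
  for (i in 1:200) {
    counts <- as.list(rmultinom(1, sample(4:200, 1), prob = runif(4, 0.05, 1))[, 1])
    names(counts) <- c("tp", "fp", "tn", "fn")
    q <- quality_measures(do.call(confusion_counts, counts))
    o <- do.call(oracle_measures, counts)
    for (m in c("acc", "prc", "fdr", "spc", "mcc")) {
      if (is.nan(o[[m]])) {
        expect_true(is.nan(q[[m]]), info = m)
      } else {
        expect_equal(q[[m]], o[[m]], tolerance = 1e-12, info = m)
      }
    }
    # complement identity whenever something was predicted positive
    if (counts$tp + counts$fp > 0) expect_equal(q$prc + q$fdr, 1, tolerance = 1e-12)
  }
})

test_that("zero-denominator conventions are flagged", {
  q <- quality_measures(confusion_counts(0, 0, 5, 5))
  expect_true(is.nan(q$prc))
  expect_true(is.nan(q$fdr))
  expect_equal(attr(q, "undefined"), c("prc", "fdr"))
  # all-negative truth with positive predictions: MCC denominator is 0
  q2 <- quality_measures(confusion_counts(0, 5, 5, 0))
  expect_equal(q2$mcc, 0)
  expect_error(confusion_counts(0, 0, 0, 0), "all-zero")
})

test_that("leave-one-out matches a naive retrain loop and sums to N", {
  geom <- window_geometry(4, 2)
  ds <- separable_windows(12, geom, seed = 14)
  cfg <- classifier_config("decision_tree", geometry = geom)
  cc <- leave_one_out(ds, cfg)
  n <- length(ds$y)
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, n)

  # independent brute-force loop with no shared state
  pred <- integer(n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    fold <- dataset_from_windows(ds$sites$window[keep][ds$y[keep] == 1L],
                                 ds$sites$window[keep][ds$y[keep] == -1L], geom)
    m <- train_classifier(fold, cfg)
    pred[i] <- classify_vectors(m, ds$x[i, , drop = FALSE])
  }
  expect_equal(cc$tp, sum(pred == 1L & ds$y == 1L))
  expect_equal(cc$fp, sum(pred == 1L & ds$y == -1L))
  expect_equal(cc$tn, sum(pred == -1L & ds$y == -1L))
  expect_equal(cc$fn, sum(pred == -1L & ds$y == 1L))

  # a separable set is classified perfectly
  expect_equal(cc$fp + cc$fn, 0)
})

test_that("two-sample leave-one-out exercises degenerate folds", {
  ds <- dataset_from_windows("DEVDGS", "AAKDAS", window_geometry(4, 2))
  expect_warning(cc <- leave_one_out(ds, classifier_config("decision_tree")),
                 "single training class")
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 2)
  expect_error(leave_one_out(ds, classifier_config("decision_tree"),
                             on_degenerate_fold = "error"), "lost a class")
})

test_that("ROC endpoints, perfect and anti-perfect scorers behave", {
  labels <- c(rep(1L, 5), rep(-1L, 5))
  r <- roc_points(10:1, labels)
  expect_equal(auc(r), 1)
  r2 <- roc_points(1:10, labels)
  expect_equal(auc(r2), 0)
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1)
  expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_error(roc_points(1:3, c(1L, 1L, 1L)), "both classes")
})

test_that("trapezoid AUC equals the exhaustive pair-counting estimator", {
  set.seed(55)
  for (i in 1:5) {
    labels <- c(rep(1L, 25), rep(-1L, 25))
    scores <- round(rnorm(50), 1) # rounding forces ties
    r <- roc_points(scores, labels)
    expect_equal(auc(r), oracle_pair_auc(scores, labels), tolerance = 1e-12)
    # cross-check against an established ROC implementation
    expect_equal(auc(r),
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<", levels = c(-1, 1)))),
                 tolerance = 1e-12)
    # invariance under strictly monotone score transforms
    expect_equal(auc(roc_points(exp(scores), labels)), auc(r), tolerance = 1e-12)
    expect_equal(auc(roc_points(3 * scores - 7, labels)), auc(r), tolerance = 1e-12)
  }
})

test_that("the threshold sweep reproduces brute-force rates at each score", {
  set.seed(56)
  labels <- c(rep(1L, 20), rep(-1L, 20))
  scores <- round(rnorm(40), 1)
  r <- roc_points(scores, labels)
  for (i in seq_len(nrow(r))) {
    thr <- r$threshold[i]
    pred <- ifelse(scores >= thr, 1L, -1L)
    expect_equal(r$tpr[i], sum(pred == 1L & labels == 1L) / sum(labels == 1L))
    expect_equal(r$fpr[i], sum(pred == 1L & labels == -1L) / sum(labels == -1L))
  }
})

test_that("bootstrap comparison is exact for a perfect classifier", {
  geom <- window_geometry(6, 4)
  ds <- separable_windows(30, geom, seed = 15)
  clf <- train_classifier(ds, classifier_config("svm"))
  out <- bootstrap_compare(list(svm = clf), ds, n_boot = 300, seed = 2)
  expect_equal(out$mean_tpr, 1)
  expect_equal(out$sd_tpr, 0)
  expect_equal(out$mean_fpr, 0)
})

test_that("a single bootstrap replicate equals direct evaluation on that resample", {
  set.seed(60)
  n <- 40
  labels <- sample(c(-1L, 1L), n, replace = TRUE, prob = c(0.5, 0.5))
  pred <- ifelse(runif(n) < 0.8, labels, -labels)
  ds <- dataset_from_windows(character(0), character(0), window_geometry(4, 2))
  ds$y <- labels
  ds$x <- matrix(0L, n, 120)
  out <- bootstrap_compare(list(p = pred), ds, n_boot = 1, seed = 9)
  # reproduce the replicate weights independently and evaluate directly
  set.seed(9)
  w <- rmultinom(1, n, rep(1 / n, n))[, 1]
  tp <- sum(w * (pred == 1L & labels == 1L))
  fp <- sum(w * (pred == 1L & labels == -1L))
  expect_equal(out$mean_tpr, tp / sum(w * (labels == 1L)))
  expect_equal(out$mean_fpr, fp / sum(w * (labels == -1L)))
})

test_that("bootstrap spread matches the binomial closed form", {
  set.seed(61)
  n_pos <- 100
  n_neg <- 100
  labels <- c(rep(1L, n_pos), rep(-1L, n_neg))
  t_true <- 0.8
  pred <- c(ifelse(seq_len(n_pos) <= t_true * n_pos, 1L, -1L),
            ifelse(seq_len(n_neg) <= 10, 1L, -1L))
  ds <- dataset_from_windows(character(0), character(0), window_geometry(4, 2))
  ds$y <- labels
  ds$x <- matrix(0L, length(labels), 120)
  out <- bootstrap_compare(list(p = pred), ds, n_boot = 3000, seed = 10)
  theory <- sqrt(t_true * (1 - t_true) / n_pos)
  expect_lt(out$sd_tpr, 3 * theory)
  expect_gt(out$sd_tpr, theory / 3)
  expect_equal(out$mean_tpr, t_true, tolerance = 0.05)
})

test_that("evaluate_classifiers tabulates measures and builds the vote row", {
  corp <- small_corpus(25, seed = 33)
  geoms <- list(svm = window_geometry(6, 4), rf = window_geometry(12, 12))
  dss <- suppressWarnings(
    build_aligned_datasets(corp$proteins, corp$positive_sites, geoms, seed = 2)
  )
  tab <- evaluate_classifiers(
    dss,
    list(svm = classifier_config("svm"), rf = classifier_config("random_forest")),
    vote = c("svm", "rf")
  )
  expect_equal(nrow(tab), 3)
  preds <- attr(tab, "predictions")
  # the vote row is the strict-majority combination of the members'
  # held-out predictions
  expect_equal(preds$vote, combine_votes(cbind(preds$svm, preds$rf)))
  vq <- tab[3, ]
  both <- combine_votes(cbind(preds$svm, preds$rf))
  expect_equal(vq$prc, sum(both == 1L & dss$svm$y == 1L) / sum(both == 1L))
})
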