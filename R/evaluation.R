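#' Confusion counts
#'
#' @param tp,fp,tn,fn Nonnegative integer counts; at least one must be
#'   positive.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("all-zero confusion counts")
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

# Counts from predicted/true labels in -1/+1.
.counts_from_labels <- function(predicted, truth) {
  confusion_counts(
    tp = sum(predicted == 1L & truth == 1L),
    fp = sum(predicted == 1L & truth == -1L),
    tn = sum(predicted == -1L & truth == -1L),
    fn = sum(predicted == -1L & truth == 1L)
  )
}

#' Classifier quality measures
#'
#' Accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, false discovery rate
#' `FP/(TP+FP)` (the complement of precision -- not the multiple-testing
#' FDR), specificity `TN/(TN+FP)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When no site is
#' predicted positive (`TP+FP = 0`), precision and FDR are undefined and
#' reported as `NaN` with the `undefined` attribute naming them; a zero MCC
#' denominator yields `MCC = 0` by the standard convention.
#'
#' @param counts A [confusion_counts()].
#' @return A `quality_measures` list with elements `acc`, `prc`, `fdr`,
#'   `spc`, `mcc`.
#' @export
quality_measures <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  n <- tp + fp + tn + fn
  undefined <- character(0)
  acc <- (tp + tn) / n
  if (tp + fp > 0) {
    prc <- tp / (tp + fp)
    fdr <- fp / (tp + fp)
  } else {
    prc <- NaN
    fdr <- NaN
    undefined <- c(undefined, "prc", "fdr")
  }
  spc <- if (tn + fp > 0) tn / (tn + fp) else NaN
  if (tn + fp == 0) undefined <- c(undefined, "spc")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  structure(list(acc = acc, prc = prc, fdr = fdr, spc = spc, mcc = mcc),
            undefined = undefined, class = "quality_measures")
}

#' @export
print.quality_measures <- function(x, digits = 3, ...) {
  cat(sprintf("ACC %.1f%%  PRC %.1f%%  FDR %.1f%%  SPC %.1f%%  MCC %.1f%%\n",
              100 * x$acc, 100 * x$prc, 100 * x$fdr, 100 * x$spc, 100 * x$mcc))
  invisible(x)
}

#' Leave-one-out evaluation
#'
#' The canonical protocol of the cleavage-site study: the classifier is
#' retrained as many times as there are sites, each time holding one site
#' out and classifying it with the model fitted on the remaining N-1.
#' Confusion counts aggregate over all N held-out classifications. The
#' per-site held-out predictions and decision scores are attached as
#' attributes `predictions`, `scores` and `labels` (in dataset order), so
#' that ensembles and ROC analyses can reuse them.
#'
#' @param ds A `labeled_dataset` with at least 2 sites and both classes.
#' @param config A [classifier_config()]; hyperparameters are fixed across
#'   folds, only the model is refitted.
#' @param on_degenerate_fold When a fold's training set loses a class
#'   (possible in tiny datasets): predict the training majority class with
#'   a warning (default) or error.
#' @return A [confusion_counts()] with prediction attributes.
#' @export
leave_one_out <- function(ds, config,
                          on_degenerate_fold = c("majority", "error")) {
  on_degenerate_fold <- match.arg(on_degenerate_fold)
  stopifnot(inherits(ds, "labeled_dataset"))
  n <- length(ds$y)
  if (n < 2L || length(unique(ds$y)) < 2L) {
    stop("leave-one-out needs at least 2 sites and both classes")
  }
  pred <- integer(n)
  scores <- numeric(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    train <- .subset_dataset(ds, setdiff(seq_len(n), i))
    if (length(unique(train$y)) < 2L) {
      if (on_degenerate_fold == "error") stop("fold ", i, " lost a class")
      if (!warned) {
        warning("fold(s) with a single training class: predicting the majority class")
        warned <- TRUE
      }
      maj <- if (sum(train$y == 1L) >= sum(train$y == -1L)) 1L else -1L
      pred[i] <- maj
      scores[i] <- maj
      next
    }
    clf <- train_classifier(train, config)
    s <- decision_score(clf, ds$x[i, , drop = FALSE])
    scores[i] <- s
    pred[i] <- if (s >= clf$threshold) 1L else -1L
  }
  out <- .counts_from_labels(pred, ds$y)
  attr(out, "predictions") <- pred
  attr(out, "scores") <- scores
  attr(out, "labels") <- ds$y
  out
}

#' ROC curve and AUC
#'
#' `roc_points()` sweeps the decision threshold over every distinct score,
#' recording (FPR, TPR) with the conventional endpoints (0,0) and (1,1);
#' the AUC is computed by the trapezoid rule. `roc_curve()` scores a
#' dataset with a trained classifier first. The Vote ensemble is
#' threshold-free (binary votes) and has no curve; evaluate it as a single
#' (FPR, TPR) point instead.
#'
#' @param scores Numeric decision scores.
#' @param labels True labels in -1/+1; both classes required.
#' @return A `roc_curve` object: data frame of
#'   `(threshold, fpr, tpr)` rows plus an `auc` attribute (also `$auc`).
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L) stop("ROC requires both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- labels[ord] == 1L
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(pos)[last_of_tie] / n_pos
  fpr <- cumsum(!pos)[last_of_tie] / n_neg
  df <- data.frame(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  auc <- sum(diff(df$fpr) * (df$tpr[-1] + df$tpr[-nrow(df)]) / 2)
  structure(df, auc = auc, class = c("roc_curve", "data.frame"))
}

#' @rdname roc_points
#' @param clf A trained `site_classifier`.
#' @param ds A `labeled_dataset` containing both classes.
#' @export
roc_curve <- function(clf, ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  roc_points(decision_score(clf, ds$x), ds$y)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve with", nrow(x), "points; AUC =", round(attr(x, "auc"), 4), "\n")
  invisible(x)
}

#' Area under a ROC curve
#' @param x A `roc_curve`.
#' @return The trapezoid-rule AUC.
#' @export
auc <- function(x) {
  stopifnot(inherits(x, "roc_curve"))
  attr(x, "auc")
}

#' Bootstrap comparison of fixed-threshold classifiers
#'
#' Emulates the point-cloud ROC comparison protocol: the evaluation set is
#' resampled with replacement `n_boot` times (forming replicates of the
#' original size); on each replicate every classifier -- operating at its
#' fixed, native threshold -- is evaluated, and the per-replicate false-
#' and true-positive rates are averaged. Replicates in which the resample
#' lost one of the classes are skipped and tallied. Resampling is realised
#' as multinomial replicate weights, which is distributionally identical to
#' drawing indices with replacement and allows the 10 000-replicate default
#' to run in seconds.
#'
#' @param classifiers Named list; each element is either a trained
#'   `site_classifier` (scored on `ds$x` at its threshold) or a
#'   precomputed -1/+1 prediction vector over the sites of `ds` (use this
#'   for the Vote ensemble or held-out predictions).
#' @param ds A `labeled_dataset` (supplies features and true labels).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed; global RNG state restored on exit.
#' @return Data frame with one row per classifier: mean and standard
#'   deviation of FPR and TPR over replicates, plus the skipped-replicate
#'   tally.
#' @export
bootstrap_compare <- function(classifiers, ds, n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"), length(classifiers) >= 1L)
  n <- length(ds$y)
  lab <- as.numeric(ds$y == 1L)
  pred <- vapply(classifiers, function(cl) {
    p <- if (inherits(cl, "site_classifier")) classify_vectors(cl, ds$x) else as.integer(cl)
    stopifnot(length(p) == n, all(p %in% c(-1L, 1L)))
    as.numeric(p == 1L)
  }, numeric(n))
  W <- .with_seed(seed, stats::rmultinom(n_boot, size = n, prob = rep(1 / n, n)))
  pos_tot <- as.numeric(crossprod(W, lab))       # positives per replicate
  neg_tot <- n - pos_tot
  ok <- pos_tot > 0 & neg_tot > 0
  tp <- crossprod(W, pred * lab)                 # n_boot x k
  fp <- crossprod(W, pred * (1 - lab))
  tpr <- tp[ok, , drop = FALSE] / pos_tot[ok]
  fpr <- fp[ok, , drop = FALSE] / neg_tot[ok]
  data.frame(
    classifier = names(classifiers) %||% paste0("clf", seq_along(classifiers)),
    mean_fpr = colMeans(fpr), sd_fpr = apply(fpr, 2, stats::sd),
    mean_tpr = colMeans(tpr), sd_tpr = apply(tpr, 2, stats::sd),
    n_replicates = sum(ok), n_skipped = sum(!ok),
    row.names = NULL
  )
}

#' Table of leave-one-out quality measures for several configurations
#'
#' Convenience wrapper running [leave_one_out()] for each configuration and
#' tabulating [quality_measures()], with an optional strict-majority Vote
#' row combining the members' held-out predictions site by site.
#'
#' @param ds A `labeled_dataset`, or a named list of aligned datasets (one
#'   per config, same names; see [build_aligned_datasets()]) when the
#'   configs use different window geometries.
#' @param configs Named list of [classifier_config()]s.
#' @param vote Optional character vector naming the configs whose held-out
#'   predictions are combined into a Vote row.
#' @return Data frame of ACC/PRC/FDR/SPC/MCC per classifier (proportions in
#'   `[0,1]`), with the per-config LOO predictions attached as attribute
#'   `predictions`.
#' @export
evaluate_classifiers <- function(ds, configs, vote = NULL) {
  stopifnot(length(configs) >= 1L, !is.null(names(configs)))
  if (inherits(ds, "labeled_dataset")) {
    ds <- stats::setNames(rep(list(ds), length(configs)), names(configs))
  }
  stopifnot(all(names(configs) %in% names(ds)))
  key <- function(d) d$sites[, c("protein_id", "p1", "label")]
  labels0 <- ds[[names(configs)[1]]]$y
  for (nm in names(configs)) {
    if (!identical(key(ds[[nm]]), key(ds[[names(configs)[1]]]))) {
      stop("datasets are not site-aligned across configs; use build_aligned_datasets()")
    }
  }
  loo <- lapply(names(configs), function(nm) leave_one_out(ds[[nm]], configs[[nm]]))
  names(loo) <- names(configs)
  preds <- lapply(loo, attr, "predictions")
  rows <- lapply(loo, function(cc) as.data.frame(unclass(quality_measures(cc))))
  out <- do.call(rbind, rows)
  out <- cbind(classifier = names(configs), out)
  if (!is.null(vote)) {
    stopifnot(all(vote %in% names(configs)))
    vp <- combine_votes(do.call(cbind, preds[vote]))
    vq <- quality_measures(.counts_from_labels(vp, labels0))
    out <- rbind(out, cbind(classifier = paste0("vote(", paste(vote, collapse = "+"), ")"),
                            as.data.frame(unclass(vq))))
    preds$vote <- vp
  }
  rownames(out) <- NULL
  attr(out, "predictions") <- preds
  attr(out, "scores") <- lapply(loo, attr, "scores")
  out
}
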