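#' Classifier configuration
#'
#' Defaults reproduce the optimised models of the cleavage-site study:
#'
#' * `svm` -- nu-SVC with an RBF kernel, `gamma = 2^-5.5`, `nu = 0.536`,
#'   solver stopping tolerance `1e-5`, window (6, 4). Fitted by libsvm via
#'   \pkg{e1071}; features are one-hot, so no column scaling is applied.
#' * `random_forest` -- 143 trees, 4 features considered per split,
#'   unlimited depth, window (12, 12). Fitted by \pkg{ranger}.
#' * `decision_tree` -- a CART tree (\pkg{rpart}) with binary splits and a
#'   minimum of 5 objects per leaf, window (4, 2). The original study used
#'   the error-based-pruning J48/C4.5 tree; CART's complexity parameter
#'   `cp` (default 0.01) plays the role of its confidence-factor pruning
#'   strength, and J48-only flags supplied in `params` (e.g.
#'   `confidence_factor`, `subtree_raising`, `use_laplace`) are retained as
#'   metadata but do not alter the fit.
#'
#' @param algorithm `"svm"`, `"random_forest"` or `"decision_tree"`.
#' @param geometry A [window_geometry()]; `NULL` takes the algorithm's
#'   optimised default above.
#' @param params Named list of hyperparameter overrides.
#' @param seed Integer seed for stochastic training (random forest).
#' @return A `classifier_config`.
#' @export
#' @examples
#' classifier_config("svm")
#' classifier_config("random_forest", params = list(num_trees = 50))
classifier_config <- function(algorithm = c("svm", "random_forest", "decision_tree"),
                              geometry = NULL, params = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    svm = list(
      geometry = window_geometry(6, 4),
      params = list(nu = 0.536, gamma = 2^-5.5, tolerance = 1e-5)
    ),
    random_forest = list(
      geometry = window_geometry(12, 12),
      params = list(num_trees = 143L, mtry = 4L)
    ),
    decision_tree = list(
      geometry = window_geometry(4, 2),
      params = list(minbucket = 5L, cp = 0.01)
    )
  )
  p <- utils::modifyList(defaults$params, params)
  structure(
    list(algorithm = algorithm, geometry = geometry %||% defaults$geometry,
         params = p, seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' @export
print.classifier_config <- function(x, ...) {
  known <- intersect(names(x$params), c("nu", "gamma", "tolerance", "num_trees", "mtry", "minbucket", "cp"))
  cat(x$algorithm, "config,", format(x$geometry), "\n  ",
      paste(known, unlist(x$params[known]), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Train a cleavage-site classifier
#'
#' @param ds A `labeled_dataset` (see [build_dataset()]); both classes must
#'   be present and its geometry must equal the config's.
#' @param config A [classifier_config()].
#' @return A `site_classifier`: the fitted model, its window geometry and
#'   its decision threshold (the algorithm's native operating point: 0 for
#'   the SVM's signed margin, 0.5 for the tree methods' positive-class
#'   proportion).
#' @export
train_classifier <- function(ds, config = classifier_config()) {
  stopifnot(inherits(ds, "labeled_dataset"), inherits(config, "classifier_config"))
  if (!identical(unclass(ds$geometry), unclass(config$geometry))) {
    stop("dataset geometry ", format(ds$geometry),
         " does not match config geometry ", format(config$geometry))
  }
  if (length(unique(ds$y)) < 2L) {
    stop("degenerate dataset: both classes are required for training")
  }
  y <- factor(ds$y, levels = c(-1L, 1L))
  p <- config$params
  fit <- switch(config$algorithm,
    svm = {
      m <- e1071::svm(ds$x, y, type = "nu-classification", kernel = "radial",
                      gamma = p$gamma, nu = p$nu, tolerance = p$tolerance,
                      scale = FALSE)
      if (is.null(m$SV) || m$tot.nSV == 0L) stop("SVM training failed: no support vectors")
      m
    },
    random_forest = ranger::ranger(
      x = ds$x, y = y, num.trees = p$num_trees, mtry = p$mtry,
      min.node.size = 1L, num.threads = 1L, seed = config$seed,
      verbose = FALSE
    ),
    decision_tree = {
      df <- data.frame(.y = y, ds$x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     minbucket = p$minbucket, cp = p$cp, xval = 0L
                   ))
    }
  )
  structure(
    list(config = config, fit = fit,
         threshold = if (config$algorithm == "svm") 0 else 0.5,
         n_features = ncol(ds$x), feature_names = colnames(ds$x)),
    class = "site_classifier"
  )
}

#' @export
print.site_classifier <- function(x, ...) {
  cat("Trained", x$config$algorithm, "site classifier,", format(x$config$geometry),
      "\n  threshold:", x$threshold, "\n")
  invisible(x)
}

.check_features <- function(clf, x) {
  if (ncol(x) != clf$n_features) {
    stop("feature-vector geometry mismatch: classifier expects ", clf$n_features,
         " features (", format(clf$config$geometry), "), got ", ncol(x))
  }
  if (is.null(colnames(x))) colnames(x) <- clf$feature_names
  x
}

#' Continuous decision scores for encoded site windows
#'
#' The score is monotone in cut-site confidence: the signed margin for the
#' SVM (oriented so positive class scores high), the fraction of trees
#' voting positive for the random forest, and the positive-class leaf
#' proportion for the decision tree. `classify_vectors()` thresholds the
#' score at the classifier's decision threshold (`score >= threshold` is a
#' predicted cut).
#'
#' @param clf A trained `site_classifier`.
#' @param x One-hot feature matrix with the classifier's geometry.
#' @return Numeric score per row.
#' @export
decision_score <- function(clf, x) {
  stopifnot(inherits(clf, "site_classifier"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- .check_features(clf, x)
  if (nrow(x) == 0L) return(numeric(0))
  switch(clf$config$algorithm,
    svm = {
      pr <- stats::predict(clf$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # libsvm labels the column "a/b": positive values favour class a
      sgn <- if (strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1] == "1") 1 else -1
      as.numeric(dv) * sgn
    },
    random_forest = {
      pr <- stats::predict(clf$fit, data = x, predict.all = TRUE,
                           num.threads = 1L, verbose = FALSE)
      pos <- which(clf$fit$forest$levels == "1")
      rowMeans(pr$predictions == pos)
    },
    decision_tree = {
      df <- as.data.frame(x, check.names = FALSE)
      as.numeric(stats::predict(clf$fit, newdata = df, type = "prob")[, "1"])
    }
  )
}

#' @rdname decision_score
#' @param threshold Optional threshold override; default is the
#'   classifier's stored threshold.
#' @return `classify_vectors()`: integer labels in -1/+1.
#' @export
classify_vectors <- function(clf, x, threshold = clf$threshold) {
  ifelse(decision_score(clf, x) >= threshold, 1L, -1L)
}

#' Classify candidate sites of one protein
#'
#' Extracts and encodes the window around each P1 position with the
#' classifier's own geometry, then thresholds the decision score. Under
#' `policy = "skip"` a site whose window overruns a terminus is not
#' classified and yields `NA` (an abstention).
#'
#' @param clf A `site_classifier` or [vote_classifier()].
#' @param sequence Protein sequence string or single-row
#'   [protein_records()].
#' @param p1 Integer vector of candidate P1 positions.
#' @param policy Terminal-window policy, `"pad"` (default) or `"skip"`.
#' @return Integer labels in -1/+1 (or `NA` for abstentions), one per site.
#' @export
classify_sites <- function(clf, sequence, p1, policy = c("pad", "skip")) {
  UseMethod("classify_sites")
}

#' @export
classify_sites.site_classifier <- function(clf, sequence, p1, policy = c("pad", "skip")) {
  policy <- match.arg(policy)
  if (length(p1) == 0L) return(integer(0))
  w <- extract_window(sequence, p1, clf$config$geometry, policy)
  out <- rep(NA_integer_, length(p1))
  ok <- !is.na(w)
  if (any(ok)) {
    out[ok] <- classify_vectors(clf, encode_windows(w[ok], clf$config$geometry))
  }
  out
}

#' Strict-majority Vote ensemble
#'
#' Combines trained classifiers: a site is predicted as a cut only when
#' strictly more than half of the members predict it positive, so the
#' default two-member SVM + random-forest Vote requires both to agree.
#' Members apply their own window geometries. A member that abstains (its
#' window overruns a terminus under `policy = "skip"`) counts as a negative
#' vote -- the conservative choice for an ensemble whose purpose is high
#' precision.
#'
#' @param ... Trained `site_classifier` members (or a single list of them).
#' @return A `vote_classifier`.
#' @export
vote_classifier <- function(...) {
  members <- list(...)
  if (length(members) == 1L && !inherits(members[[1]], "site_classifier")) {
    members <- members[[1]]
  }
  stopifnot(length(members) >= 1L)
  lapply(members, function(m) stopifnot(inherits(m, "site_classifier")))
  structure(list(members = members), class = "vote_classifier")
}

#' @export
print.vote_classifier <- function(x, ...) {
  cat("Vote ensemble of", length(x$members), "classifier(s):",
      paste(vapply(x$members, function(m) m$config$algorithm, ""), collapse = " + "),
      "\n")
  invisible(x)
}

#' @export
classify_sites.vote_classifier <- function(clf, sequence, p1, policy = c("pad", "skip")) {
  policy <- match.arg(policy)
  if (length(p1) == 0L) return(integer(0))
  votes <- vapply(clf$members, function(m) {
    v <- classify_sites(m, sequence, p1, policy)
    v[is.na(v)] <- -1L # abstention counts as a negative vote
    v
  }, integer(length(p1)))
  if (length(p1) == 1L) votes <- matrix(votes, nrow = 1L)
  combine_votes(votes)
}

#' Combine member votes by strict majority
#'
#' @param votes Integer matrix in -1/+1, one row per site, one column per
#'   member.
#' @return -1/+1 labels: +1 iff strictly more than half the members voted
#'   +1.
#' @export
combine_votes <- function(votes) {
  votes <- as.matrix(votes)
  ifelse(rowSums(votes == 1L) > ncol(votes) / 2, 1L, -1L)
}

#' Leave-one-out grid search over window geometries and hyperparameters
#'
#' Rebuilds the dataset at each window geometry (negative sampling under a
#' fixed seed), runs the full leave-one-out protocol at every grid cell and
#' returns the cell with the best LOO accuracy. Ties are broken in favour
#' of the smaller total window, then by grid order. The default grid is the
#' study's model-selection grid: `n_left` in 4, 6, ..., 16 crossed with
#' `n_right` in 0, 2, ..., 16 (112 LOO runs -- expect it to be slow at full
#' size).
#'
#' @param proteins A [protein_records()] data frame.
#' @param positive_sites Named list of positive P1 positions.
#' @param algorithm Passed to [classifier_config()].
#' @param grid Data frame with columns `n_left`, `n_right` and optionally
#'   algorithm hyperparameters; each row is one cell.
#' @param seed Seed for negative sampling and stochastic training.
#' @param negatives Negative-sampling policy, see [build_dataset()].
#' @return A `grid_search_result`: list with `best` (the winning
#'   [classifier_config()]) and `table` (the grid with a `loo_accuracy`
#'   column).
#' @export
grid_search <- function(proteins, positive_sites, algorithm,
                        grid = default_grid(), seed = 1L,
                        negatives = "balanced") {
  stopifnot(nrow(grid) >= 1L, all(c("n_left", "n_right") %in% names(grid)))
  hyper <- setdiff(names(grid), c("n_left", "n_right"))
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    geom <- window_geometry(grid$n_left[i], grid$n_right[i])
    cfg <- classifier_config(algorithm, geometry = geom,
                             params = as.list(grid[i, hyper, drop = FALSE]),
                             seed = seed)
    ds <- suppressWarnings(
      build_dataset(proteins, positive_sites, geom, negatives = negatives, seed = seed)
    )
    cc <- leave_one_out(ds, cfg)
    acc[i] <- (cc$tp + cc$tn) / sum(unlist(cc[c("tp", "fp", "tn", "fn")]))
  }
  table <- cbind(grid, loo_accuracy = acc)
  best_i <- select_best_cell(table)
  best <- classifier_config(
    algorithm,
    geometry = window_geometry(grid$n_left[best_i], grid$n_right[best_i]),
    params = as.list(grid[best_i, hyper, drop = FALSE]), seed = seed
  )
  structure(list(best = best, best_index = best_i, table = table),
            class = "grid_search_result")
}

#' @rdname grid_search
#' @export
default_grid <- function() {
  expand.grid(n_left = seq(4L, 16L, 2L), n_right = seq(0L, 16L, 2L))
}

#' @rdname grid_search
#' @param table Grid table with a `loo_accuracy` column.
#' @return `select_best_cell()`: the winning row index (argmax accuracy;
#'   ties to the smaller `n_left + n_right`, then to the earlier row).
#' @export
select_best_cell <- function(table) {
  best <- which(table$loo_accuracy == max(table$loo_accuracy))
  if (length(best) > 1L) {
    tot <- table$n_left[best] + table$n_right[best]
    best <- best[tot == min(tot)]
  }
  best[1]
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("Grid search over", nrow(x$table), "cells; best cell", x$best_index,
      "with LOO accuracy", round(x$table$loo_accuracy[x$best_index], 4), "\n")
  print(x$best)
  invisible(x)
}

#' Persist and restore trained classifiers
#'
#' `save_model()` writes a single-file serialized bundle plus a JSON
#' metadata sidecar (`<path>.json`) recording the algorithm, window
#' geometry, hyperparameters, residue encoding table and training-set
#' shape. `load_model()` restores the bundle and validates that the
#' encoding table matches the running package, so a restored classifier
#' gives identical predictions on any input.
#'
#' @param clf A `site_classifier` or `vote_classifier`.
#' @param path Bundle file path.
#' @return `load_model()`: the restored classifier.
#' @export
save_model <- function(clf, path) {
  stopifnot(inherits(clf, c("site_classifier", "vote_classifier")))
  bundle <- list(classifier = clf, residue_order = aa_residues(),
                 package_version = as.character(utils::packageVersion("pripper")))
  saveRDS(bundle, path)
  meta <- if (inherits(clf, "vote_classifier")) {
    list(type = "vote", members = lapply(clf$members, .model_meta))
  } else {
    .model_meta(clf)
  }
  meta$residue_order <- paste(aa_residues(), collapse = "")
  meta$package_version <- bundle$package_version
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.model_meta <- function(clf) {
  list(algorithm = clf$config$algorithm,
       n_left = clf$config$geometry$n_left,
       n_right = clf$config$geometry$n_right,
       hyperparameters = clf$config$params,
       threshold = clf$threshold,
       n_features = clf$n_features)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  bundle <- readRDS(path)
  if (!is.list(bundle) || is.null(bundle$classifier)) {
    stop("not a pripper model bundle: ", path)
  }
  if (!identical(bundle$residue_order, aa_residues())) {
    stop("model was saved under a different residue encoding table; refusing to load")
  }
  bundle$classifier
}
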