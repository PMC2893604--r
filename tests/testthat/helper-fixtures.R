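# Shared fixtures, built in code at test time.

# Random valid protein records.
random_records <- function(n, min_len = 20, max_len = 80, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(aa_residues(), sample(min_len:max_len, 1), replace = TRUE), collapse = "")
  }, character(1))
  protein_records(sprintf("rec%03d", seq_len(n)), seqs)
}

# Assemble a labeled_dataset directly from window strings (bypasses
# build_dataset, for classifier-level tests).
dataset_from_windows <- function(pos_windows, neg_windows, geometry) {
  windows <- c(pos_windows, neg_windows)
  y <- c(rep(1L, length(pos_windows)), rep(-1L, length(neg_windows)))
  structure(
    list(
      x = encode_windows(windows, geometry),
      y = y,
      sites = data.frame(protein_id = sprintf("w%03d", seq_along(windows)),
                         p1 = rep(geometry$n_left, length(windows)),
                         window = windows, label = y),
      geometry = geometry,
      provenance = "in-test windows"
    ),
    class = "labeled_dataset"
  )
}

# Cleanly separable toy windows: positives carry the canonical DEVD motif
# at P4..P1, negatives only share Asp at P1.
separable_windows <- function(n_per_class, geometry, seed = 1) {
  set.seed(seed)
  L <- geometry$n_left + geometry$n_right
  stopifnot(geometry$n_left >= 4)
  pos <- vapply(seq_len(n_per_class), function(i) {
    s <- sample(aa_residues(), L, replace = TRUE)
    s[(geometry$n_left - 3):geometry$n_left] <- c("D", "E", "V", "D")
    paste(s, collapse = "")
  }, character(1))
  neg <- vapply(seq_len(n_per_class), function(i) {
    s <- sample(setdiff(aa_residues(), "E"), L, replace = TRUE)
    s[geometry$n_left] <- "D"
    paste(s, collapse = "")
  }, character(1))
  dataset_from_windows(unique(pos), unique(neg), geometry)
}

# Small synthetic corpus shared across tests.
small_corpus <- function(n_proteins = 40, seed = 7, ...) {
  generate_synthetic_corpus(n_proteins = n_proteins, seed = seed, ...)
}

# Independent quality-measure oracle: rebuild the label vectors and use
# generic statistics (mean agreement, Pearson correlation) instead of the
# closed-form confusion formulas.
oracle_measures <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  list(
    acc = mean(truth == pred),
    prc = if (sum(pred) > 0) mean(truth[pred == 1]) else NaN,
    fdr = if (sum(pred) > 0) mean(1 - truth[pred == 1]) else NaN,
    spc = if (sum(truth == 0) > 0) mean(pred[truth == 0] == 0) else NaN,
    mcc = if (stats::sd(truth) > 0 && stats::sd(pred) > 0) stats::cor(truth, pred) else 0
  )
}

# Brute-force digestion oracle: enumerate every subset of the cut
# positions, cut at each subset simultaneously, collect the resulting
# spans, deduplicate.
oracle_all_combination_spans <- function(L, cuts) {
  cuts <- sort(unique(cuts[cuts < L]))
  subsets <- lapply(seq_len(2^length(cuts)) - 1L, function(mask) {
    cuts[bitwAnd(mask, 2^(seq_along(cuts) - 1L)) > 0L]
  })
  spans <- unique(do.call(rbind, lapply(subsets, function(ss) {
    b <- c(0L, ss, L)
    cbind(b[-length(b)] + 1L, b[-1])
  })))
  spans[order(spans[, 1], spans[, 2]), , drop = FALSE]
}

# Independent 1-nearest-neighbour leave-one-out baseline on the one-hot
# encoding (Hamming distance; ties broken toward the first neighbour).
oracle_1nn_loo_accuracy <- function(x, y) {
  d <- as.matrix(stats::dist(x, method = "manhattan"))
  diag(d) <- Inf
  pred <- y[apply(d, 1, which.min)]
  mean(pred == y)
}

# Exhaustive Mann-Whitney AUC estimator: pair counting with ties at 1/2.
oracle_pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
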