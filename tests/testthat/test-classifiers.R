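test_that("all three algorithms separate a cleanly separable training set", {
  geom <- window_geometry(6, 4)
  ds <- separable_windows(40, geom, seed = 2)
  for (alg in c("svm", "random_forest", "decision_tree")) {
    clf <- train_classifier(ds, classifier_config(alg, geometry = geom))
    expect_equal(mean(classify_vectors(clf, ds$x) == ds$y), 1,
                 info = alg)
  }
})

test_that("training validates geometry and class balance", {
  geom <- window_geometry(6, 4)
  ds <- separable_windows(10, geom, seed = 3)
  expect_error(train_classifier(ds, classifier_config("svm", geometry = window_geometry(4, 2))),
               "geometry")
  ds_pos <- dataset_from_windows(ds$sites$window[ds$y == 1L], character(0), geom)
  expect_error(train_classifier(ds_pos, classifier_config("svm", geometry = geom)),
               "degenerate")
})

test_that("random-forest training is reproducible under a fixed seed", {
  ds <- separable_windows(30, window_geometry(12, 12), seed = 5)
  cfg <- classifier_config("random_forest", seed = 77)
  p1 <- classify_vectors(train_classifier(ds, cfg), ds$x)
  p2 <- classify_vectors(train_classifier(ds, cfg), ds$x)
  expect_identical(p1, p2)
})

test_that("LOO accuracy of each algorithm beats an independent 1-NN baseline", {
  corp <- small_corpus(30, seed = 17)
  geoms <- list(svm = window_geometry(6, 4), rf = window_geometry(12, 12),
                tree = window_geometry(4, 2))
  dss <- suppressWarnings(
    build_aligned_datasets(corp$proteins, corp$positive_sites, geoms, seed = 1)
  )
  cfgs <- list(svm = classifier_config("svm"),
               rf = classifier_config("random_forest"),
               tree = classifier_config("decision_tree"))
  for (nm in names(cfgs)) {
    ds <- dss[[nm]]
    cc <- leave_one_out(ds, cfgs[[nm]])
    acc <- (cc$tp + cc$tn) / length(ds$y)
    base <- oracle_1nn_loo_accuracy(ds$x, ds$y)
    expect_gte(acc, base)
  }
})

test_that("decision scores are monotone with the classification rule", {
  geom <- window_geometry(6, 4)
  ds <- separable_windows(40, geom, seed = 6)
  for (alg in c("svm", "random_forest", "decision_tree")) {
    clf <- train_classifier(ds, classifier_config(alg, geometry = geom))
    s <- decision_score(clf, ds$x)
    expect_identical(classify_vectors(clf, ds$x), ifelse(s >= clf$threshold, 1L, -1L))
    # ROC endpoints: threshold +Inf predicts nothing, -Inf everything
    expect_true(all(classify_vectors(clf, ds$x, threshold = Inf) == -1L))
    expect_true(all(classify_vectors(clf, ds$x, threshold = -Inf) == 1L))
  }
  # the forest score is exactly the fraction of trees voting positive
  rf_ds <- separable_windows(40, window_geometry(12, 12), seed = 6)
  rf <- train_classifier(rf_ds, classifier_config("random_forest"))
  votes <- stats::predict(rf$fit, data = rf_ds$x, predict.all = TRUE,
                          num.threads = 1)$predictions
  pos_code <- which(rf$fit$forest$levels == "1")
  expect_equal(decision_score(rf, rf_ds$x), rowMeans(votes == pos_code))
  expect_error(decision_score(rf, ds$x), "geometry mismatch")
})

test_that("the vote rule is a strict majority over member votes", {
  # exhaustive truth table for 1-3 members against an independent rule
  for (k in 1:3) {
    patterns <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), k)))
    got <- combine_votes(patterns)
    want <- apply(patterns, 1, function(v) if (sum(v == 1L) > k / 2) 1L else -1L)
    expect_equal(got, unname(want))
  }
  # two members: positive only on agreement, a 1-1 split is negative
  expect_equal(combine_votes(cbind(1L, 1L)), 1L)
  expect_equal(combine_votes(cbind(1L, -1L)), -1L)
})

test_that("a single-member vote is equivalent to the member", {
  corp <- small_corpus(10, seed = 23)
  geom <- window_geometry(6, 4)
  ds <- suppressWarnings(build_dataset(corp$proteins, corp$positive_sites, geom))
  clf <- train_classifier(ds, classifier_config("svm"))
  vc <- vote_classifier(clf)
  s <- corp$proteins$sequence[1]
  p1 <- scan_candidates(s)
  expect_identical(classify_sites(vc, s, p1), as.integer(classify_sites(clf, s, p1)))
})

test_that("members abstain near termini under skip and abstentions vote negative", {
  ds_small <- separable_windows(30, window_geometry(6, 4), seed = 8)
  ds_wide <- separable_windows(30, window_geometry(12, 12), seed = 8)
  svm <- train_classifier(ds_small, classifier_config("svm"))
  rf <- train_classifier(ds_wide, classifier_config("random_forest"))
  # strong positive context placed too close to the N terminus for the
  # wide member but within reach of the narrow one
  seq <- paste0("AADEVDG", paste(rep("A", 30), collapse = ""))
  p1 <- 6L
  expect_true(is.na(classify_sites(rf, seq, p1, policy = "skip")))
  narrow <- classify_sites(svm, seq, p1, policy = "skip")
  expect_false(is.na(narrow))
  # with skip, the wide member abstains => counts as a negative vote, so
  # the two-member vote cannot be positive regardless of the narrow vote
  vc <- vote_classifier(svm, rf)
  expect_equal(classify_sites(vc, seq, p1, policy = "skip"), -1L)
})

test_that("predictions are invariant under permutation of the residue table", {
  set.seed(31)
  perm <- sample(20)
  permuted_order <- aa_residues()[perm]
  geom <- window_geometry(6, 4)
  ds <- separable_windows(35, geom, seed = 9)
  x_perm <- encode_windows(ds$sites$window, geom, residue_order = permuted_order)
  ds_perm <- ds
  ds_perm$x <- x_perm

  test_w <- vapply(1:40, function(i) paste(sample(aa_residues(), 10, TRUE), collapse = ""), "")
  t_orig <- encode_windows(test_w, geom)
  t_perm <- encode_windows(test_w, geom, residue_order = permuted_order)

  # exact for the SVM: the RBF kernel depends only on pairwise distances,
  # which block permutation preserves
  svm1 <- train_classifier(ds, classifier_config("svm"))
  svm2 <- train_classifier(ds_perm, classifier_config("svm"))
  expect_equal(decision_score(svm1, t_orig), decision_score(svm2, t_perm),
               tolerance = 1e-8)

  # exact for CART on tie-free data: split selection depends on column
  # improvements, not on column order
  tr1 <- train_classifier(ds, classifier_config("decision_tree", geometry = geom))
  tr2 <- train_classifier(ds_perm, classifier_config("decision_tree", geometry = geom))
  expect_identical(classify_vectors(tr1, t_orig), classify_vectors(tr2, t_perm))

  # the forest samples candidate features by column index, so only
  # distributional invariance holds; demand high agreement on clear signal
  rf_geom <- window_geometry(12, 12)
  ds_rf <- separable_windows(35, rf_geom, seed = 9)
  x_rf_perm <- encode_windows(ds_rf$sites$window, rf_geom, residue_order = permuted_order)
  ds_rf_perm <- ds_rf
  ds_rf_perm$x <- x_rf_perm
  rf1 <- train_classifier(ds_rf, classifier_config("random_forest"))
  rf2 <- train_classifier(ds_rf_perm, classifier_config("random_forest"))
  expect_gte(mean(classify_vectors(rf1, ds_rf$x) == classify_vectors(rf2, x_rf_perm)), 0.95)
})

test_that("a tree trained on Asp-anchored negatives never splits on the P1 slot", {
  # every negative carries D at P1 by construction, so the P1 attribute is
  # uninformative and should not appear in the fitted tree
  corp <- small_corpus(40, seed = 19)
  geom <- window_geometry(4, 2)
  ds <- suppressWarnings(build_dataset(corp$proteins, corp$positive_sites, geom))
  clf <- train_classifier(ds, classifier_config("decision_tree"))
  split_vars <- setdiff(as.character(clf$fit$frame$var), "<leaf>")
  expect_gt(length(split_vars), 0)
  expect_false(any(grepl("^P1_", split_vars)))
})

test_that("grid search recomputes per-cell LOO accuracy and breaks ties", {
  corp <- small_corpus(16, seed = 29)
  grid <- expand.grid(n_left = c(4L, 6L), n_right = c(0L, 2L))
  res <- suppressWarnings(
    grid_search(corp$proteins, corp$positive_sites, "decision_tree", grid, seed = 3)
  )
  expect_equal(nrow(res$table), 4)
  # independent recomputation of every cell
  for (i in seq_len(nrow(grid))) {
    geom <- window_geometry(grid$n_left[i], grid$n_right[i])
    ds <- suppressWarnings(
      build_dataset(corp$proteins, corp$positive_sites, geom, seed = 3)
    )
    cc <- leave_one_out(ds, classifier_config("decision_tree", geometry = geom, seed = 3))
    expect_equal(res$table$loo_accuracy[i], (cc$tp + cc$tn) / length(ds$y))
  }
  expect_equal(res$best_index, select_best_cell(res$table))

  # a one-cell grid selects that cell
  res1 <- suppressWarnings(
    grid_search(corp$proteins, corp$positive_sites, "decision_tree",
                data.frame(n_left = 4L, n_right = 2L), seed = 3)
  )
  expect_equal(res1$best_index, 1L)
  expect_equal(res1$best$geometry$n_left, 4L)

  # tie-breaking: best accuracy, then smaller window, then grid order
  tab <- data.frame(n_left = c(6L, 4L, 4L, 8L), n_right = c(4L, 0L, 0L, 2L),
                    loo_accuracy = c(0.9, 0.9, 0.9, 0.8))
  expect_equal(select_best_cell(tab), 2L)
  tab$loo_accuracy <- c(0.95, 0.9, 0.9, 0.8)
  expect_equal(select_best_cell(tab), 1L)
})

test_that("saved models round-trip with identical scores and guard geometry", {
  geom <- window_geometry(6, 4)
  ds <- separable_windows(30, geom, seed = 10)
  clf <- train_classifier(ds, classifier_config("svm"))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(clf, path)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$algorithm, "svm")
  expect_equal(meta$n_left, 6L)

  back <- load_model(path)
  set.seed(41)
  x <- encode_windows(vapply(1:100, function(i) {
    paste(sample(aa_residues(), 10, TRUE), collapse = "")
  }, character(1)), geom)
  expect_identical(classify_vectors(back, x), classify_vectors(clf, x))
  expect_equal(decision_score(back, x), decision_score(clf, x), tolerance = 1e-12)
  wrong <- encode_windows("DEVDGS", window_geometry(4, 2))
  expect_error(classify_vectors(back, wrong), "geometry mismatch")
  expect_error(load_model(file.path(tempdir(), "nope.rds")), "not found")
})
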