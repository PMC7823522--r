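# One-hot encoding, random-forest substrate models, grid search and the
# metric harness.

test_that("one-hot encoding has one feature per (column, symbol) and row sums L", {
  enc1 <- one_hot_encode("ACD")
  expect_identical(ncol(enc1$matrix), 3L)
  expect_identical(unname(rowSums(enc1$matrix)), 3)

  enc2 <- one_hot_encode(c("ACD", "ACE"))
  expect_identical(ncol(enc2$matrix), 4L)  # columns 1,2 shared; column 3 two symbols
  expect_identical(unname(rowSums(enc2$matrix)), c(3, 3))

  expect_error(one_hot_encode(c("AC", "ACD")), "ragged")

  # gaps are first-class symbols
  encg <- one_hot_encode(c("A-D", "AC-"))
  expect_identical(unname(rowSums(encg$matrix)), c(3, 3))
})

test_that("encoding round-trips and unseen symbols leave a zero block", {
  rows <- c("ACDG", "AC-G", "AWDG")
  enc <- one_hot_encode(rows)
  expect_identical(one_hot_decode(enc), rows)
  proj <- encode_with_map("AZDG", enc$map)  # Z unseen at column 2
  expect_identical(unname(rowSums(proj)), 3)
})

test_that("metric computation matches hand confusion-matrix results", {
  m <- compute_metrics(c("a","a","b","b"), c("a","b","b","b"))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$per_class$f1[m$per_class$class == "a"], 2/3)
  expect_equal(m$per_class$f1[m$per_class$class == "b"], 0.8)
  expect_equal(unname(m$macro["f1"]), (2/3 + 0.8) / 2)
  # micro F1 equals accuracy for single-label multiclass
  expect_equal(unname(m$micro["f1"]), m$accuracy)
  # perfect predictions
  p <- compute_metrics(c("x","y","z"), c("x","y","z"))
  expect_equal(p$accuracy, 1); expect_equal(p$mcc, 1)
  expect_true(all(p$per_class$f1 == 1))
  expect_equal(p$accuracy + p$error_rate, 1)
})

test_that("per-class metrics agree with an independent brute-force tally", {
  set.seed(42)
  y <- sample(letters[1:4], 200, TRUE)
  p <- ifelse(runif(200) < 0.7, y, sample(letters[1:4], 200, TRUE))
  m <- compute_metrics(y, p)
  for (cl in letters[1:4]) {
    oracle <- confusion_tally(y, p, cl)
    row <- m$per_class[m$per_class$class == cl, ]
    expect_equal(row$precision, unname(oracle["precision"]), tolerance = 1e-12)
    expect_equal(row$recall, unname(oracle["recall"]), tolerance = 1e-12)
    expect_equal(row$f1, unname(oracle["f1"]), tolerance = 1e-12)
  }
})

test_that("ROC-AUC agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  y <- sample(c("pos", "neg"), 100, TRUE)
  s <- runif(100) + (y == "pos") * 0.5
  scores <- cbind(pos = s, neg = 1 - s)
  m <- compute_metrics(y, ifelse(s > 0.75, "pos", "neg"), scores)
  ref <- as.numeric(pROC::auc(pROC::roc(y == "pos", s, quiet = TRUE)))
  expect_equal(bgcscaffold:::binary_auc(as.integer(y == "pos"), s), ref,
               tolerance = 1e-12)
  # single-class truth: AUC undefined
  m1 <- compute_metrics(c("a","a"), c("a","a"), cbind(a = c(1, 1)))
  expect_true(is.na(m1$auc_macro))
})

test_that("the default hyperparameter grid enumerates 2160 configurations", {
  grid <- enumerate_param_grid(default_param_grid())
  expect_identical(nrow(grid), 2160L)
  expect_identical(nrow(unique(grid)), 2160L)
  expect_error(enumerate_param_grid(list()), "empty")
})

test_that("a separable substrate set reaches cross-validated micro F1 of 1", {
  fx <- fixture_bundle()
  aln <- align_labeled_set(fx$substrate_train, identity_aligner(),
                           min_per_label = 2L)
  cv <- crossvalidate_substrate_model(aln, default_rf_params("AT"),
                                      k = 10L, seed = 1L)
  expect_equal(unname(cv$metrics$micro[["f1"]]), 1)
  expect_equal(cv$metrics$accuracy, 1)
})

test_that("training is reproducible and row-order independent for a fixed seed", {
  fx <- fixture_bundle()
  aln <- align_labeled_set(fx$substrate_train, identity_aligner(),
                           min_per_label = 2L)
  m1 <- train_substrate_model(aln, default_rf_params("AT"), seed = 5L)
  shuffled <- aln[rev(seq_len(nrow(aln))), ]
  class(shuffled) <- class(aln)
  m2 <- train_substrate_model(shuffled, default_rf_params("AT"), seed = 5L)
  p1 <- predict(m1, aligned_row = aln$aligned[1:5])
  p2 <- predict(m2, aligned_row = aln$aligned[1:5])
  expect_identical(p1$label, p2$label)
  expect_equal(p1[, -1], p2[, -1], tolerance = 1e-12)
  # probabilities sum to one
  expect_equal(unname(rowSums(p1[, -1])), rep(1, 5), tolerance = 1e-9)
})

test_that("resubstitution performance bounds held-out performance", {
  fx <- fixture_bundle()
  aln <- align_labeled_set(fx$substrate_train, identity_aligner(),
                           min_per_label = 2L)
  model <- train_substrate_model(aln, default_rf_params("AT"), seed = 2L)
  resub <- compute_metrics(aln$label,
                           predict(model, aligned_row = aln$aligned)$label)
  cv <- crossvalidate_substrate_model(aln, default_rf_params("AT"),
                                      k = 5L, seed = 2L)
  expect_gte(resub$micro[["f1"]], cv$metrics$micro[["f1"]])
})

test_that("grid search selects by mean micro F1 and handles one-config grids", {
  fx <- fixture_bundle()
  aln <- align_labeled_set(fx$substrate_train, identity_aligner(),
                           min_per_label = 2L)
  single <- list(max_depth = 10, max_features = "sqrt", n_estimators = 50,
                 min_samples_split = 2, bootstrap = FALSE, criterion = "gini",
                 min_samples_leaf = 1)
  gs1 <- grid_search(aln, lapply(single, function(x) x), k = 3L, seed = 1L)
  expect_identical(nrow(gs1$configurations), 1L)
  expect_equal(unlist(gs1$best_params), unlist(single))

  small <- list(max_depth = c(10, NA), max_features = "sqrt",
                n_estimators = 50, min_samples_split = 2, bootstrap = FALSE,
                criterion = "gini", min_samples_leaf = 1)
  gs <- grid_search(aln, small, k = 3L, seed = 1L)
  expect_identical(nrow(gs$configurations), 2L)
  expect_equal(max(gs$results$micro_f1), 1)  # separable by construction
})

test_that("unalignable predict-time input raises an informative error", {
  fx <- fixture_bundle()
  aln <- align_labeled_set(fx$substrate_train, identity_aligner(),
                           min_per_label = 2L)
  model <- train_substrate_model(aln, default_rf_params("AT"), seed = 1L,
                                 aligner = identity_aligner())
  expect_error(predict(model, sequence = "ACDEF"), "aligned")
})
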