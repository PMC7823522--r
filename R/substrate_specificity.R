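# Substrate specificity: random-forest classification of AT-domain (PKS)
# and A-domain (NRPS) substrates from one-hot encoded multiple alignments,
# with the grid-search and metric harness.

#' Aligned, labelled sequence set
#'
#' @param id sequence identifiers.
#' @param aligned equal-length aligned sequences (gap "-").
#' @param label substrate label per row.
#' @return data frame of class `aligned_sequence_set`.
#' @export
aligned_sequence_set <- function(id, aligned, label) {
  if (length(unique(nchar(aligned))) > 1L)
    stop("aligned rows must all have the same length")
  df <- data.frame(id = as.character(id), aligned = toupper(aligned),
                   label = as.character(label), stringsAsFactors = FALSE)
  class(df) <- c("aligned_sequence_set", "data.frame")
  df
}

#' Align a labelled domain set into an [aligned_sequence_set()]
#'
#' @param labeled a [labeled_domain_set()] (substrate labels).
#' @param aligner aligner contract object.
#' @param min_per_label labels with fewer members are dropped (training
#'   needs a minimum number of known specificities per substrate).
#' @return an `aligned_sequence_set`.
#' @export
align_labeled_set <- function(labeled, aligner = mafft_aligner(),
                              min_per_label = 10L) {
  counts <- table(labeled$label)
  keep <- labeled$label %in% names(counts)[counts >= min_per_label]
  labeled <- labeled[keep, , drop = FALSE]
  if (nrow(labeled) == 0L) stop("no label has >= ", min_per_label, " sequences")
  aln <- aligner$align(stats::setNames(labeled$sequence, labeled$id))
  aligned_sequence_set(labeled$id, unname(aln[labeled$id]), labeled$label)
}

#' One-hot encode an alignment
#'
#' Every (column, observed symbol) pair becomes one binary feature; the gap
#' symbol is a first-class category, so each row has exactly L ones. The
#' feature map makes the encoding invertible and lets new sequences be
#' projected into the training feature space (symbols unseen in training
#' leave their column block all zero).
#'
#' @param aln an [aligned_sequence_set()] or character vector of equal-length
#'   rows.
#' @return list of class `encoded_features` with `$matrix` (rows x features,
#'   0/1) and `$map` (data frame: column, symbol, feature).
#' @export
one_hot_encode <- function(aln) {
  rows <- if (inherits(aln, "aligned_sequence_set")) aln$aligned else aln
  if (length(unique(nchar(rows))) > 1L) stop("ragged alignment rows")
  L <- nchar(rows[1L])
  chars <- do.call(rbind, strsplit(rows, ""))
  map <- do.call(rbind, lapply(seq_len(L), function(j) {
    sym <- sort(unique(chars[, j]))
    data.frame(column = j, symbol = sym, stringsAsFactors = FALSE)
  }))
  map$feature <- seq_len(nrow(map))
  mat <- matrix(0L, nrow = length(rows), ncol = nrow(map))
  for (j in seq_len(L)) {
    sub <- map[map$column == j, , drop = FALSE]
    idx <- match(chars[, j], sub$symbol)
    mat[cbind(seq_along(rows), sub$feature[idx])] <- 1L
  }
  colnames(mat) <- paste0("c", map$column, "_", map$symbol)
  structure(list(matrix = mat, map = map, length = L), class = "encoded_features")
}

#' Project rows into an existing feature space
#'
#' @param rows character vector of aligned rows (same column count as the
#'   map's alignment).
#' @param map feature map from [one_hot_encode()].
#' @return binary matrix with the training feature columns.
#' @export
encode_with_map <- function(rows, map) {
  L <- max(map$column)
  if (any(nchar(rows) != L)) stop("rows do not match the feature-map column space")
  chars <- do.call(rbind, strsplit(rows, ""))
  mat <- matrix(0L, nrow = length(rows), ncol = nrow(map))
  key <- paste0(map$column, "_", map$symbol)
  for (j in seq_len(L)) {
    f <- match(paste0(j, "_", chars[, j]), key)
    ok <- !is.na(f)
    mat[cbind(which(ok), f[ok])] <- 1L
  }
  colnames(mat) <- paste0("c", map$column, "_", map$symbol)
  mat
}

#' Decode an encoded matrix back to aligned rows
#'
#' @param enc an `encoded_features` object.
#' @return character vector of aligned rows.
#' @export
one_hot_decode <- function(enc) {
  apply(enc$matrix, 1L, function(r) {
    sym <- enc$map$symbol[r == 1L]
    paste(sym[order(enc$map$column[r == 1L])], collapse = "")
  })
}

#' Default random-forest hyperparameters
#'
#' The shipped defaults are the best grid-search configurations for the
#' A-domain (29-substrate) and AT-domain (4-substrate) classifiers:
#' A-domains: max depth 100, 1000 trees, min samples split 10, no bootstrap,
#' gini, min samples leaf 1; AT-domains: max depth 50, 100 trees, min
#' samples split 1, no bootstrap, gini, min samples leaf 2.
#'
#' @param domain "A" or "AT".
#' @return named list of hyperparameters.
#' @export
default_rf_params <- function(domain = c("A", "AT")) {
  domain <- match.arg(domain)
  if (domain == "A")
    list(max_depth = 100, max_features = "auto", n_estimators = 1000,
         min_samples_split = 10, bootstrap = FALSE, criterion = "gini",
         min_samples_leaf = 1)
  else
    list(max_depth = 50, max_features = "auto", n_estimators = 100,
         min_samples_split = 1, bootstrap = FALSE, criterion = "gini",
         min_samples_leaf = 2)
}

#' Default hyperparameter grid
#'
#' @return list of parameter levels whose full crossing has 2160
#'   configurations (see [enumerate_param_grid()]).
#' @export
default_param_grid <- function() {
  list(max_depth = c(10, 50, 100, NA),
       max_features = c("1", "3", "10", "auto", "sqrt"),
       n_estimators = c(100, 500, 1000),
       min_samples_split = c(2, 5, 10),
       bootstrap = c(TRUE, FALSE),
       criterion = c("gini", "entropy"),
       min_samples_leaf = c(1, 5, 10))
}

#' Enumerate a hyperparameter grid
#'
#' @param grid named list of parameter levels.
#' @return data frame with one row per configuration (full crossing).
#' @export
enumerate_param_grid <- function(grid = default_param_grid()) {
  if (length(grid) == 0L || any(lengths(grid) == 0L)) stop("empty parameter grid")
  expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

# Map the sklearn-style hyperparameters onto ranger arguments.
ranger_args <- function(params, n_features) {
  mtry <- switch(as.character(params$max_features),
                 auto = , sqrt = max(1L, floor(sqrt(n_features))),
                 min(n_features, as.integer(params$max_features)))
  min_node <- max(as.numeric(params$min_samples_split),
                  2 * as.numeric(params$min_samples_leaf))
  list(num.trees = as.integer(params$n_estimators),
       mtry = mtry,
       max.depth = if (is.na(params$max_depth)) 0L else as.integer(params$max_depth),
       min.node.size = as.integer(min_node),
       replace = isTRUE(params$bootstrap),
       sample.fraction = 1,
       splitrule = "gini")  # ranger has no entropy splitrule; gini used
}

#' Train a substrate-specificity random forest
#'
#' @param aln an [aligned_sequence_set()].
#' @param params hyperparameter list (see [default_rf_params()]).
#' @param seed integer seed; fixes the forest and makes training
#'   row-order-independent (rows are sorted internally by id).
#' @param aligner aligner used to project new sequences at predict time.
#' @return object of class `substrate_model`.
#' @export
train_substrate_model <- function(aln, params = default_rf_params("A"),
                                  seed = 1L, aligner = NULL) {
  stopifnot(inherits(aln, "aligned_sequence_set"))
  aln <- aln[order(aln$id), , drop = FALSE]
  enc <- one_hot_encode(aln$aligned)
  y <- factor(aln$label)
  ra <- ranger_args(params, ncol(enc$matrix))
  fit <- do.call(ranger::ranger, c(list(
    x = enc$matrix, y = y, probability = TRUE, seed = as.integer(seed),
    num.threads = 1L), ra))
  structure(list(forest = fit, map = enc$map, labels = levels(y),
                 alignment = stats::setNames(aln$aligned, aln$id),
                 params = params, seed = seed, aligner = aligner),
            class = "substrate_model")
}

#' @export
print.substrate_model <- function(x, ...) {
  cat("substrate model:", length(x$labels), "classes,",
      length(x$alignment), "training rows,", nrow(x$map), "features\n")
  invisible(x)
}

#' Predict substrate specificity
#'
#' @param object a `substrate_model`.
#' @param sequence unaligned amino-acid sequence(s); aligned into the
#'   training column space with the model's aligner (insertions dropped).
#' @param aligned_row alternatively, already-aligned row(s) of the training
#'   column width.
#' @param ... unused.
#' @return data frame with `label` and one probability column per class
#'   (probabilities sum to 1).
#' @export
predict.substrate_model <- function(object, sequence = NULL,
                                    aligned_row = NULL, ...) {
  if (is.null(aligned_row)) {
    if (is.null(sequence)) stop("provide sequence or aligned_row")
    aligner <- object$aligner %||% mafft_aligner()
    names(sequence) <- paste0("q", seq_along(sequence))
    aligned_row <- tryCatch(aligner$add(object$alignment, sequence),
                            error = function(e)
                              stop("sequence could not be aligned into the ",
                                   "training column space: ", conditionMessage(e)))
  }
  mat <- encode_with_map(toupper(aligned_row), object$map)
  prob <- stats::predict(object$forest, data = mat, num.threads = 1L)$predictions
  colnames(prob) <- object$forest$forest$levels %||% colnames(prob)
  lab <- colnames(prob)[max.col(prob, ties.method = "first")]
  out <- data.frame(label = lab, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(prob))
}

# stratified fold assignment (labels with < k members fall back to >= 2)
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  for (lab in sort(unique(labels))) {
    idx <- which(labels == lab)
    kk <- min(k, max(2L, length(idx)))
    perm <- with_seed(seed + hash_ints(utf8ToInt(lab)) %% 10000L,
                      sample(length(idx)))
    folds[idx[perm]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validate a substrate model
#'
#' @param aln an [aligned_sequence_set()].
#' @param params hyperparameters.
#' @param k folds.
#' @param seed seed for folds and forests.
#' @return list with `$metrics` (a `classifier_metrics`), `$fold_micro_f1`
#'   (per-fold micro F1), `$y_true`, `$y_pred`, `$y_scores`.
#' @export
crossvalidate_substrate_model <- function(aln, params = default_rf_params("A"),
                                          k = 10L, seed = 1L) {
  folds <- stratified_folds(aln$label, k, seed)
  y_true <- character(0); y_pred <- character(0)
  scores <- list(); fold_f1 <- numeric(0)
  for (f in sort(unique(folds))) {
    tr <- aln[folds != f, , drop = FALSE]; te <- aln[folds == f, , drop = FALSE]
    if (nrow(te) == 0L || nrow(tr) == 0L) next
    class(tr) <- class(aln)
    model <- train_substrate_model(tr, params, seed = seed + f)
    pred <- predict(model, aligned_row = te$aligned)
    y_true <- c(y_true, te$label); y_pred <- c(y_pred, pred$label)
    scores[[length(scores) + 1L]] <- as.matrix(pred[, -1L, drop = FALSE])
    fold_f1 <- c(fold_f1, compute_metrics(te$label, pred$label)$micro[["f1"]])
  }
  all_classes <- sort(unique(aln$label))
  sc <- do.call(rbind, lapply(scores, function(s) {
    m <- matrix(0, nrow(s), length(all_classes),
                dimnames = list(NULL, all_classes))
    m[, colnames(s)] <- s
    m
  }))
  list(metrics = compute_metrics(y_true, y_pred, sc),
       fold_micro_f1 = fold_f1, y_true = y_true, y_pred = y_pred,
       y_scores = sc)
}

#' Hyperparameter grid search by cross-validated micro F1
#'
#' Every configuration in the grid is evaluated by k-fold cross-validation;
#' the selection criterion is the mean micro F1 over folds (ties keep the
#' earliest configuration in grid order). Deterministic for a fixed seed.
#'
#' @param aln an [aligned_sequence_set()].
#' @param param_grid named list of parameter levels (see
#'   [default_param_grid()]); evaluate small grids only -- the full default
#'   grid enumerates 2160 configurations.
#' @param k folds.
#' @param seed seed.
#' @return list with `$best_params`, `$results` (per-config mean/sd micro
#'   F1) and `$configurations` (the enumerated grid).
#' @export
grid_search <- function(aln, param_grid, k = 10L, seed = 1L) {
  configs <- enumerate_param_grid(param_grid)
  res <- data.frame(config = seq_len(nrow(configs)),
                    micro_f1 = NA_real_, sd = NA_real_)
  for (i in seq_len(nrow(configs))) {
    params <- as.list(configs[i, , drop = FALSE])
    cv <- crossvalidate_substrate_model(aln, params, k = k, seed = seed)
    res$micro_f1[i] <- mean(cv$fold_micro_f1)
    res$sd[i] <- stats::sd(cv$fold_micro_f1)
  }
  best <- which.max(res$micro_f1)
  list(best_params = as.list(configs[best, , drop = FALSE]),
       results = cbind(configs, res[, c("micro_f1", "sd")]),
       configurations = configs)
}

#' Reproduce the reference substrate-classifier benchmark
#'
#' Runs the full reference protocol on user-supplied labelled AT-/A-domain
#' FASTA files (label after "|"): MAFFT alignment, one-hot encoding, the
#' shipped best hyperparameters and 10-fold cross-validation, returning the
#' overall metric table and per-class rows. The training datasets themselves
#' are not distributed with the package; place them at
#' `inst/extdata/benchmark/AT_domains.fasta` and `A_domains.fasta` or pass
#' explicit paths.
#'
#' @param at_fasta,a_fasta paths to the labelled domain FASTA files.
#' @param seed seed.
#' @return list with `$AT` and `$A` cross-validation results.
#' @export
reproduce_substrate_benchmark <- function(at_fasta, a_fasta, seed = 1L) {
  out <- list()
  for (dom in c("AT", "A")) {
    path <- if (dom == "AT") at_fasta else a_fasta
    if (!file.exists(path))
      stop("benchmark dataset not found: ", path)
    labeled <- read_labeled_fasta(path)
    aln <- align_labeled_set(labeled, min_per_label = 10L)
    out[[dom]] <- crossvalidate_substrate_model(
      aln, default_rf_params(dom), k = 10L, seed = seed)
  }
  out
}
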