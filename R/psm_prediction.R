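# Postsynthetic-modification (PSM) prediction: SMARTS substructure counting
# on molecules, correlation of cluster domain counts with PSM counts, and
# per-PSM linear regression with a zero-prediction baseline.

default_psm_names <- function() {
  c("Glyco", "Cl", "Spiroketal", "SS", "NO2", "6-Ring", "5-Ring")
}

#' Load the PSM SMARTS pattern table
#'
#' @param path TSV with columns `name` and `smarts`; defaults to the
#'   packaged seven-pattern table (glycoside, halogen, spiroketal,
#'   disulfide, nitro, 6-ring, 5-ring).
#' @return data frame of class `psm_patterns`.
#' @export
load_psm_patterns <- function(path = default_table_path("psm_patterns.tsv")) {
  tab <- read_tsv(path)
  stopifnot(all(c("name", "smarts") %in% names(tab)))
  if (anyDuplicated(tab$name)) stop("duplicate PSM pattern names")
  class(tab) <- c("psm_patterns", "data.frame")
  tab
}

#' Count PSM substructures in molecules
#'
#' Counts unique (symmetry-deduplicated) substructure matches of every PSM
#' SMARTS pattern, via the OpenBabel SMARTS matcher.
#'
#' @param smiles character vector of molecule SMILES.
#' @param patterns a [load_psm_patterns()] table.
#' @return integer matrix, one row per molecule, one column per pattern.
#' @export
count_psms <- function(smiles, patterns = load_psm_patterns()) {
  stopifnot(length(smiles) > 0L)
  sdf <- tryCatch(suppressWarnings(
    ChemmineR::smiles2sdf(stats::setNames(smiles, paste0("m", seq_along(smiles))))),
    error = function(e) stop("invalid molecule in PSM counting: ",
                             conditionMessage(e)))
  counts <- vapply(seq_len(nrow(patterns)), function(i) {
    as.integer(ChemmineR::smartsSearchOB(sdf, patterns$smarts[i],
                                         uniqueMatches = TRUE))
  }, integer(length(smiles)))
  counts <- matrix(counts, nrow = length(smiles),
                   dimnames = list(NULL, patterns$name))
  counts
}

#' Count PSMs over a multi-fragment scaffold
#'
#' @param scaffold a `scaffold` object.
#' @param patterns PSM pattern table.
#' @return named integer vector (sum over fragments).
#' @export
count_psms_scaffold <- function(scaffold, patterns = load_psm_patterns()) {
  colSums(count_psms(scaffold$fragments, patterns))
}

#' Pearson correlation between two count vectors
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return correlation in `[-1, 1]`, or NA when either side has zero
#'   variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Select feature domains per PSM from a correlation table
#'
#' Positively correlating domains are intersected with a curated allow-list
#' of domains whose annotation plausibly links them to the modification.
#'
#' @param corr_table data frame with columns `psm`, `domain`, `r`.
#' @param curation_list character vector of allowed domain ids (possibly
#'   per-PSM as a named list).
#' @return named list: PSM name -> character vector of feature domains.
#' @export
select_domains <- function(corr_table, curation_list) {
  stopifnot(all(c("psm", "domain", "r") %in% names(corr_table)))
  pos <- corr_table[!is.na(corr_table$r) & corr_table$r > 0, , drop = FALSE]
  out <- lapply(split(pos, pos$psm), function(d) {
    allowed <- if (is.list(curation_list))
      curation_list[[d$psm[1L]]] %||% character(0) else curation_list
    intersect(d$domain, allowed)
  })
  out[order(names(out))]
}

#' R-squared of the constant-zero predictor
#'
#' The baseline score for a hypothetical model that never predicts a PSM:
#' `1 - sum(y^2) / sum((y - mean(y))^2)`. For nonnegative targets with at
#' least one positive value this is always <= 0.
#'
#' @param y observed counts.
#' @return baseline R-squared (NA when the targets have zero variance).
#' @export
baseline_r2 <- function(y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum(y^2) / ss_tot
}

#' Train a per-PSM regression model with cross-validated evaluation
#'
#' Ordinary linear least squares of the PSM count on the selected domain
#' counts, evaluated by pooled out-of-fold R-squared over k folds and
#' compared against the zero-prediction baseline. The model is retained
#' only when it outperforms the baseline.
#'
#' @param features numeric matrix/data frame (clusters x feature domains).
#' @param psm_counts numeric vector of observed PSM counts per cluster.
#' @param psm name of the PSM.
#' @param k folds (default 5).
#' @param seed fold seed.
#' @return object of class `psm_regressor` with `$coefficients`, `$cv_r2`,
#'   `$baseline_r2`, `$retained`.
#' @export
train_psm_regressor <- function(features, psm_counts, psm = "PSM", k = 5L,
                                seed = 1L) {
  features <- as.matrix(features)
  n <- length(psm_counts)
  stopifnot(nrow(features) == n)
  if (n < 2L * k) stop("need at least 2k samples")
  base <- baseline_r2(psm_counts)
  if (all(psm_counts == 0)) {
    return(structure(list(psm = psm, features = colnames(features),
                          coefficients = NULL, cv_r2 = NA_real_,
                          baseline_r2 = NA_real_, retained = FALSE),
                     class = "psm_regressor"))
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- numeric(n)
  df <- data.frame(y = psm_counts, features)
  for (f in seq_len(k)) {
    fit <- stats::lm(y ~ ., data = df[folds != f, , drop = FALSE])
    pred[folds == f] <- stats::predict(fit, newdata = df[folds == f, , drop = FALSE])
  }
  cv_r2 <- 1 - sum((psm_counts - pred)^2) / sum((psm_counts - mean(psm_counts))^2)
  full <- stats::lm(y ~ ., data = df)
  structure(list(psm = psm, features = colnames(features),
                 coefficients = stats::coef(full), cv_r2 = cv_r2,
                 baseline_r2 = base, retained = cv_r2 > base),
            class = "psm_regressor")
}

#' @export
print.psm_regressor <- function(x, ...) {
  cat(sprintf("PSM regressor '%s': cv R2 %.3f, baseline %.3f -> %s\n",
              x$psm, x$cv_r2, x$baseline_r2,
              if (x$retained) "retained" else "rejected"))
  invisible(x)
}

#' Predict PSM counts from cluster domain counts
#'
#' Predictions are rounded to the nearest integer and clipped at zero;
#' feature domains absent from the count table are treated as zero.
#'
#' @param regressors list of retained `psm_regressor`s.
#' @param domain_counts named numeric vector (domain id -> count) for one
#'   cluster.
#' @return named integer vector of predicted PSM counts.
#' @export
predict_psms <- function(regressors, domain_counts) {
  out <- vapply(regressors, function(r) {
    if (!isTRUE(r$retained) || is.null(r$coefficients)) return(0L)
    feats <- vapply(r$features, function(d)
      if (d %in% names(domain_counts)) domain_counts[[d]] else 0, 1)
    val <- r$coefficients[[1L]] +
      sum(r$coefficients[-1L] * feats, na.rm = TRUE)
    max(0L, as.integer(round(val)))
  }, integer(1L))
  names(out) <- vapply(regressors, `[[`, "", "psm")
  out
}

#' Read a Pfam-style domain count table
#'
#' @param path TSV with columns `cluster_id`, `domain_id`, `count`.
#' @return data frame.
#' @export
read_domain_counts <- function(path) {
  tab <- read_tsv(path)
  stopifnot(all(c("cluster_id", "domain_id", "count") %in% names(tab)))
  tab
}
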