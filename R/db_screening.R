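# Compound-library screening: ingestion with canonical deduplication,
# fingerprint similarity search, multi-fragment MCS scoring, Bray-Curtis
# PSM scoring, the weighted mixed score and the ranking benchmark.

#' Ingest a compound library into a screening database
#'
#' Accepts SMILES files (one molecule per line, optional tab-separated id)
#' and/or SDF files. Invalid records are skipped with a logged count,
#' duplicates (by canonical SMILES) collapsed, and circular fingerprints and
#' PSM count vectors precomputed for every record.
#'
#' @param paths character vector of library file paths, or a data frame with
#'   columns `smiles` and optionally `id`/`source`.
#' @param patterns PSM pattern table used for the precomputed PSM vectors.
#' @param radius,nbits fingerprint parameters.
#' @return object of class `screening_db`.
#' @export
ingest_library <- function(paths, patterns = load_psm_patterns(),
                           radius = 3L, nbits = 2048L) {
  if (is.data.frame(paths)) {
    recs <- data.frame(id = paths$id %||% paste0("cpd", seq_len(nrow(paths))),
                       smiles = paths$smiles,
                       source = paths$source %||% "memory",
                       stringsAsFactors = FALSE)
  } else {
    recs <- do.call(rbind, lapply(paths, function(p) {
      if (grepl("\\.sdf$", p, ignore.case = TRUE)) {
        sdf <- ChemmineR::read.SDFset(p)
        smi <- vapply(seq_along(sdf), function(i)
          tryCatch(as.character(ChemmineR::sdf2smiles(sdf[i])),
                   error = function(e) NA_character_), "")
        data.frame(id = ChemmineR::sdfid(sdf), smiles = smi,
                   source = basename(p), stringsAsFactors = FALSE)
      } else {
        lines <- readLines(p)
        lines <- lines[nzchar(trimws(lines))]
        if (length(lines) == 0L)
          return(data.frame(id = character(), smiles = character(),
                            source = character(), stringsAsFactors = FALSE))
        parts <- strsplit(lines, "\t", fixed = TRUE)
        data.frame(
          id = vapply(seq_along(parts), function(i)
            if (length(parts[[i]]) > 1L) parts[[i]][2L] else
              paste0(basename(p), "_", i), ""),
          smiles = vapply(parts, `[[`, "", 1L),
          source = basename(p), stringsAsFactors = FALSE)
      }
    }))
  }
  if (nrow(recs) == 0L) stop("no molecules in library input")
  canon <- vapply(recs$smiles, function(s)
    tryCatch(canonical_smiles(s), error = function(e) NA_character_), "",
    USE.NAMES = FALSE)
  invalid <- sum(is.na(canon))
  if (invalid > 0L)
    message(invalid, " invalid record(s) skipped during ingestion")
  recs <- recs[!is.na(canon), , drop = FALSE]
  canon <- canon[!is.na(canon)]
  if (nrow(recs) == 0L) stop("no valid molecules in library input")
  dup <- duplicated(canon)
  recs <- recs[!dup, , drop = FALSE]; canon <- canon[!dup]
  recs$canonical <- canon
  fps <- lapply(canon, morgan_fingerprint, radius = radius, nbits = nbits)
  psm <- count_psms(canon, patterns)
  rownames(psm) <- recs$id
  structure(list(records = recs, fingerprints = fps, psm = psm,
                 patterns = patterns, radius = radius, nbits = nbits),
            class = "screening_db")
}

#' @export
print.screening_db <- function(x, ...) {
  cat("screening db:", nrow(x$records), "compounds from",
      length(unique(x$records$source)), "source(s)\n")
  invisible(x)
}

#' Fingerprint similarity preselection
#'
#' Ranks the database by Tanimoto similarity of the fingerprint of the union
#' of the query fragments; ties are broken by compound id for a stable
#' order.
#'
#' @param fragments character vector of query fragment SMILES.
#' @param db a `screening_db`.
#' @param n number of compounds to return (all if the db is smaller).
#' @return data frame with `id`, `smiles`, `similarity`, best first.
#' @export
tanimoto_topn <- function(fragments, db, n = 50L) {
  query <- paste(fragments, collapse = ".")
  qfp <- morgan_fingerprint(query, radius = db$radius, nbits = db$nbits)
  sims <- vapply(db$fingerprints, tanimoto, 1, a = qfp)
  ord <- order(-sims, db$records$id)
  take <- utils::head(ord, n)
  data.frame(id = db$records$id[take], smiles = db$records$canonical[take],
             similarity = sims[take], stringsAsFactors = FALSE)
}

#' Bray-Curtis similarity of two PSM count vectors
#'
#' `1 - sum(|u - v|) / sum(u + v)`; identical vectors score 1, disjoint
#' vectors 0. Two all-zero vectors are defined as identical (similarity 1).
#'
#' @param u,v equal-length nonnegative count vectors.
#' @return similarity in `[0, 1]`.
#' @export
bray_curtis_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  tot <- sum(u + v)
  if (tot == 0) return(1)
  1 - sum(abs(u - v)) / tot
}

#' Weighted mixed score
#'
#' `a * similarity + b * mcs + c * psm` with nonnegative weights.
#'
#' @param sim,mcs,psm component scores in `[0, 1]` (vectorized).
#' @param weights numeric vector/list with elements `a`, `b`, `c`.
#' @return numeric mixed score.
#' @export
mixed_score <- function(sim, mcs, psm, weights = default_weights("All")) {
  w <- unlist(weights)[c("a", "b", "c")]
  if (any(is.na(w))) stop("weights must provide a, b and c")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (all(w == 0)) stop("at least one weight must be positive")
  w[["a"]] * sim + w[["b"]] * mcs + w[["c"]] * psm
}

#' Packaged per-cluster-type score weights
#'
#' @param type "PKS", "NRPS", "Mixed" or "All".
#' @return list with `a` (similarity), `b` (MCS), `c` (PSM).
#' @export
default_weights <- function(type = "All") {
  tab <- read_tsv(default_table_path("screening_weights.tsv"))
  row <- tab[match(type, tab$type), ]
  if (nrow(row) != 1L || is.na(row$type)) stop("unknown cluster type: ", type)
  list(a = row$similarity, b = row$mcs, c = row$psm)
}

#' Screen a predicted scaffold against a compound database
#'
#' Fingerprint preselection of `n_preselect` compounds, then MCS and
#' Bray-Curtis PSM scoring of the preselection, combined into the mixed
#' score.
#'
#' @param scaffold a `scaffold` (fragments + predicted PSM vector) or a
#'   character vector of fragment SMILES.
#' @param db a `screening_db`.
#' @param weights mixed-score weights (see [default_weights()]).
#' @param n_preselect size of the similarity preselection for MCS/PSM
#'   scoring.
#' @param max_mcs_per_step forwarded to [extended_mcs_score()].
#' @return data frame of class `ranked_matches`: `id`, `similarity`, `mcs`,
#'   `psm`, `mixed`, `rank` (best first; ties share the best rank).
#' @export
screen_scaffold <- function(scaffold, db, weights = default_weights("All"),
                            n_preselect = 50L, max_mcs_per_step = 20L) {
  frags <- if (inherits(scaffold, "scaffold")) scaffold$fragments else scaffold
  psm_vec <- if (inherits(scaffold, "scaffold")) scaffold$psm_vector else
    colSums(count_psms(frags, db$patterns))
  pre <- tanimoto_topn(frags, db, n = n_preselect)
  idx <- match(pre$id, db$records$id)
  mcs <- vapply(pre$smiles, function(t)
    extended_mcs_score(frags, t, max_mcs_per_step = max_mcs_per_step), 1,
    USE.NAMES = FALSE)
  psm <- vapply(idx, function(i)
    bray_curtis_similarity(psm_vec, db$psm[i, ]), 1)
  mixed <- mixed_score(pre$similarity, mcs, psm, weights)
  out <- data.frame(id = pre$id, similarity = pre$similarity, mcs = mcs,
                    psm = psm, mixed = mixed, stringsAsFactors = FALSE)
  out <- out[order(-out$mixed, out$id), , drop = FALSE]
  out$rank <- tied_rank(out$mixed)
  rownames(out) <- NULL
  class(out) <- c("ranked_matches", "data.frame")
  out
}

# 1-based ranks on a descending-sorted score vector; ties share the best rank
tied_rank <- function(scores_desc) {
  vapply(scores_desc, function(s) sum(scores_desc > s) + 1L,
         integer(1L))
}

#' Ranking benchmark over predictions with known true products
#'
#' For every prediction, the whole database is scored and the 1-based rank
#' of the known true product recorded (ties share the best rank). Clusters
#' whose true product is missing from the database are excluded with a
#' warning.
#'
#' @param predictions list of entries, each with `$fragments` (or a
#'   `scaffold`) and `$true_id` (compound id in `db`).
#' @param db a `screening_db`.
#' @param weights mixed-score weights.
#' @param n_preselect preselection size (use `nrow(db$records)` to score
#'   everything).
#' @return list with `$ranks` (named integer vector), `$top10`, `$top50`
#'   (fractions of true products at rank <= 10 / <= 50).
#' @export
rank_benchmark <- function(predictions, db, weights = default_weights("All"),
                           n_preselect = nrow(db$records)) {
  ranks <- integer(0)
  for (p in predictions) {
    true_id <- p$true_id
    if (!true_id %in% db$records$id) {
      warning("true product ", true_id, " missing from the database; excluded")
      next
    }
    sc <- if (inherits(p, "scaffold")) p else p$scaffold %||% p$fragments
    res <- screen_scaffold(sc, db, weights, n_preselect = n_preselect)
    r <- res$rank[match(true_id, res$id)]
    if (is.na(r)) r <- nrow(db$records)  # fell outside the preselection
    ranks[[true_id]] <- r
  }
  if (length(ranks) == 0L) stop("empty benchmark: no true product found")
  list(ranks = ranks, top10 = mean(ranks <= 10L), top50 = mean(ranks <= 50L))
}

#' Grid search for the mixed-score weights
#'
#' Every weight is varied over `seq(0, 1, by = step)`; the criterion is the
#' fraction of true products ranked in the Top 10 by [rank_benchmark()].
#' The lexicographically smallest best configuration is reported.
#'
#' @param predictions,db,n_preselect as in [rank_benchmark()].
#' @param step weight grid step (default 0.1).
#' @return list with `$best` (weight list), `$top10`, `$results` (per-config
#'   data frame).
#' @export
grid_search_weights <- function(predictions, db, step = 0.1,
                                n_preselect = nrow(db$records)) {
  if (length(predictions) == 0L) stop("empty benchmark")
  vals <- seq(0, 1, by = step)
  grid <- expand.grid(a = vals, b = vals, c = vals)
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  grid <- grid[order(grid$a, grid$b, grid$c), , drop = FALSE]
  # score components once per prediction, reuse across configurations
  comp <- lapply(predictions, function(p) {
    sc <- if (inherits(p, "scaffold")) p else p$scaffold %||% p$fragments
    res <- screen_scaffold(sc, db, weights = list(a = 1, b = 0, c = 0),
                           n_preselect = n_preselect)
    list(res = res, true_id = p$true_id)
  })
  top10 <- vapply(seq_len(nrow(grid)), function(g) {
    w <- as.list(grid[g, ])
    r <- vapply(comp, function(x) {
      mixed <- mixed_score(x$res$similarity, x$res$mcs, x$res$psm, w)
      sum(mixed > mixed[match(x$true_id, x$res$id)]) + 1L
    }, integer(1L))
    mean(r <= 10L)
  }, 1)
  best <- which.max(top10)  # first (lexicographically smallest) maximum
  list(best = as.list(grid[best, ]), top10 = top10[best],
       results = cbind(grid, top10 = top10))
}

#' Write screening results as TSV
#'
#' @param matches a `ranked_matches` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screening_results <- function(matches, path)
  write_tsv(as.data.frame(matches), path)
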