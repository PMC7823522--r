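# Domain detection: profile-HMM construction, threshold calibration and
# protein scanning. Profile building and scanning are delegated to the HMMER3
# command-line tools (hmmbuild / hmmsearch); thresholds are applied to
# per-domain bit scores (HMMER's domT semantics).

CARRIER_DOMAINS <- c("ACP", "PCP", "bACP")

#' Construct a validated protein record table
#'
#' @param id protein identifiers (unique).
#' @param sequence amino-acid sequences (20 standard residues plus X).
#' @param gene_locus gene locus tags.
#' @param genomic_start,genomic_end 0-based half-open genomic coordinates.
#' @param strand "+" or "-".
#' @return data frame of class `protein_records`.
#' @export
protein_records <- function(id, sequence, gene_locus = id,
                            genomic_start = NULL, genomic_end = NULL,
                            strand = "+") {
  n <- length(id)
  if (is.null(genomic_start)) {
    # synthetic coordinates in input order (3 bp per residue + spacing)
    len <- nchar(sequence) * 3L
    genomic_end <- cumsum(len + 100L)
    genomic_start <- genomic_end - len
  }
  df <- data.frame(id = as.character(id), sequence = toupper(sequence),
                   gene_locus = as.character(gene_locus),
                   genomic_start = as.integer(genomic_start),
                   genomic_end = as.integer(genomic_end),
                   strand = rep_len(strand, n), stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("protein ids must be unique")
  if (any(!nzchar(df$sequence))) stop("empty protein sequence")
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), df$sequence)
  if (any(bad)) stop("invalid residues in protein(s): ",
                     paste(df$id[bad], collapse = ", "))
  if (any(df$genomic_start >= df$genomic_end)) stop("genomic start must be < end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  class(df) <- c("protein_records", "data.frame")
  df
}

#' Labelled biosynthetic-domain sequence set
#'
#' @param sequence amino-acid sequences.
#' @param label true domain label per sequence.
#' @param id optional sequence identifiers.
#' @return data frame of class `labeled_domain_set`.
#' @export
labeled_domain_set <- function(sequence, label, id = NULL) {
  if (length(sequence) != length(label)) stop("sequence/label length mismatch")
  id <- id %||% sprintf("seq%d", seq_along(sequence))
  df <- data.frame(id = as.character(id), sequence = toupper(sequence),
                   label = as.character(label), stringsAsFactors = FALSE)
  class(df) <- c("labeled_domain_set", "data.frame")
  df
}

#' Read a labelled domain FASTA (label after a "|" in the header)
#'
#' @param path FASTA path; headers look like `id|LABEL`.
#' @return a [labeled_domain_set()].
#' @export
read_labeled_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("labelled FASTA headers must be 'id|label'")
  labeled_domain_set(unname(seqs),
                     vapply(parts, function(p) p[[length(p)]], ""),
                     vapply(parts, function(p) paste(p[-length(p)], collapse = "|"), ""))
}

# -- profile set --------------------------------------------------------------

new_profile_set <- function(profiles) {
  structure(profiles, class = "domain_profile_set")
}

#' @export
`[.domain_profile_set` <- function(x, i) {
  new_profile_set(unclass(x)[i])
}

#' @export
print.domain_profile_set <- function(x, ...) {
  cat("domain profile set:", length(x), "profiles\n")
  for (p in x) cat(sprintf("  %-8s threshold %.1f\n", p$name, p$threshold))
  invisible(x)
}

#' Build profile-HMMs from labelled domain sequences
#'
#' One profile is built per label: the label's sequences are aligned with the
#' supplied aligner and passed to `hmmbuild`. Thresholds are initialised to 0
#' (uncalibrated); see [calibrate_thresholds()].
#'
#' @param labeled a [labeled_domain_set()]; every label needs at least 2
#'   sequences.
#' @param aligner an aligner contract object, default [mafft_aligner()].
#' @return an object of class `domain_profile_set`: a named list of profiles,
#'   each with `$name`, `$hmm` (HMMER3 text) and `$threshold`.
#' @export
build_profiles <- function(labeled, aligner = mafft_aligner()) {
  stopifnot(inherits(labeled, "labeled_domain_set"))
  if (nrow(labeled) == 0L) return(new_profile_set(list()))
  find_tool("hmmbuild")
  counts <- table(labeled$label)
  if (any(counts < 2L))
    stop("label(s) with fewer than 2 sequences: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  profiles <- lapply(sort(names(counts)), function(lab) {
    rows <- labeled[labeled$label == lab, ]
    seqs <- stats::setNames(rows$sequence, rows$id)
    aln <- aligner$align(seqs)
    alnfile <- tempfile(fileext = ".afa")
    hmmfile <- tempfile(fileext = ".hmm")
    on.exit(unlink(c(alnfile, hmmfile)))
    write_fasta(aln, alnfile)
    status <- system2("hmmbuild", c("--amino", "-n", lab, hmmfile, alnfile),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) stop("hmmbuild failed for label ", lab)
    list(name = lab, hmm = readLines(hmmfile), threshold = 0)
  })
  names(profiles) <- vapply(profiles, `[[`, "", "name")
  new_profile_set(profiles)
}

# Run hmmsearch of one profile against a FASTA, returning per-domain hits.
hmmsearch_profile <- function(profile, fasta, min_score = 0) {
  find_tool("hmmsearch")
  hmmfile <- tempfile(fileext = ".hmm")
  domfile <- tempfile(fileext = ".dom")
  on.exit(unlink(c(hmmfile, domfile)))
  writeLines(profile$hmm, hmmfile)
  status <- system2("hmmsearch",
                    c("--domtblout", domfile, "-T", format(min_score),
                      "--domT", format(min_score), hmmfile, fasta),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("hmmsearch failed for profile ", profile$name)
  lines <- grep("^#", readLines(domfile), invert = TRUE, value = TRUE)
  if (length(lines) == 0L)
    return(data.frame(protein_id = character(), domain = character(),
                      seq_start = integer(), seq_end = integer(),
                      bit_score = numeric(), stringsAsFactors = FALSE))
  f <- strsplit(trimws(lines), "\\s+")
  data.frame(
    protein_id = vapply(f, `[[`, "", 1L),
    domain = profile$name,
    # ali coordinates, converted to 0-based half-open
    seq_start = vapply(f, function(x) as.integer(x[[18]]), 1L) - 1L,
    seq_end = vapply(f, function(x) as.integer(x[[19]]), 1L),
    bit_score = vapply(f, function(x) as.numeric(x[[14]]), 1),
    stringsAsFactors = FALSE)
}

#' Calibrate per-profile detection thresholds
#'
#' The threshold of each profile is set to the minimum per-domain bit score
#' the profile attains on its own true-label sequences, so that rescanning
#' the calibration set yields recall 1 per label. Sequences a profile misses
#' entirely are dropped from the minimum with a warning.
#'
#' @param profiles a `domain_profile_set`.
#' @param labeled the calibration [labeled_domain_set()].
#' @return the profile set with `$threshold` filled in.
#' @export
calibrate_thresholds <- function(profiles, labeled) {
  stopifnot(inherits(profiles, "domain_profile_set"), nrow(labeled) > 0L)
  for (lab in names(profiles)) {
    rows <- labeled[labeled$label == lab, ]
    if (nrow(rows) == 0L) next
    fa <- tempfile(fileext = ".fa")
    write_fasta(stats::setNames(rows$sequence, rows$id), fa)
    hits <- hmmsearch_profile(profiles[[lab]], fa, min_score = 0)
    unlink(fa)
    best <- tapply(hits$bit_score, hits$protein_id, max)
    missed <- setdiff(rows$id, names(best))
    if (length(missed) > 0L)
      warning("profile ", lab, " does not detect its own sequence(s): ",
              paste(missed, collapse = ", "),
              "; threshold taken from remaining hits")
    if (length(best) == 0L) {
      warning("profile ", lab, " detects none of its sequences; threshold left at 0")
      next
    }
    profiles[[lab]]$threshold <- max(0, min(best))
  }
  profiles
}

#' Attach an externally supplied KSQ profile
#'
#' The decarboxylating loading-module KS variant (KSQ) is typically imported
#' rather than trained; by convention it reuses the KS detection threshold.
#'
#' @param profiles a `domain_profile_set` containing a KS profile.
#' @param hmm character vector with the HMMER3 text of the KSQ profile.
#' @param threshold optional explicit threshold; defaults to the KS threshold.
#' @return extended profile set.
#' @export
add_ksq_profile <- function(profiles, hmm, threshold = NULL) {
  thr <- threshold %||% (profiles[["KS"]]$threshold %||%
                           stop("no KS profile to take the KSQ threshold from"))
  profiles[["KSQ"]] <- list(name = "KSQ", hmm = hmm, threshold = thr)
  new_profile_set(profiles)
}

# Resolve overlapping retained hits on one protein: when two hits overlap by
# more than half of the shorter hit, keep the higher bit score (ties break
# alphabetically by domain label).
resolve_overlaps <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(-hits$bit_score, hits$domain)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(hits$seq_end[i], hits$seq_end[j]) -
        max(hits$seq_start[i], hits$seq_start[j])
      shorter <- min(hits$seq_end[i] - hits$seq_start[i],
                     hits$seq_end[j] - hits$seq_start[j])
      if (ov > 0.5 * shorter) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  hits[keep, , drop = FALSE]
}

#' Scan proteins for biosynthetic domains
#'
#' Runs every calibrated profile against the proteins, keeps per-domain hits
#' with bit score at or above the profile threshold, resolves overlapping
#' hits (>50% of the shorter hit: higher score wins) and orders the result by
#' genomic position of the protein, then domain start.
#'
#' @param proteins a [protein_records()] table.
#' @param profiles a calibrated `domain_profile_set`.
#' @return data frame of class `domain_hits` with columns `protein_id`,
#'   `domain`, `seq_start`, `seq_end` (0-based half-open) and `bit_score`.
#' @export
scan_proteins <- function(proteins, profiles) {
  empty <- data.frame(protein_id = character(), domain = character(),
                      seq_start = integer(), seq_end = integer(),
                      bit_score = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("domain_hits", "data.frame")
  if (nrow(proteins) == 0L || length(profiles) == 0L) return(empty)
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  write_fasta(stats::setNames(proteins$sequence, proteins$id), fa)
  hits <- do.call(rbind, lapply(profiles, function(p) {
    h <- hmmsearch_profile(p, fa, min_score = 0)
    h[h$bit_score >= p$threshold, , drop = FALSE]
  }))
  rownames(hits) <- NULL
  if (nrow(hits) == 0L) return(empty)
  hits <- do.call(rbind, lapply(split(hits, hits$protein_id), resolve_overlaps))
  pos <- stats::setNames(proteins$genomic_start, proteins$id)
  hits <- hits[order(pos[hits$protein_id], hits$seq_start), , drop = FALSE]
  rownames(hits) <- NULL
  stopifnot(all(hits$seq_start < hits$seq_end))
  class(hits) <- c("domain_hits", "data.frame")
  hits
}

#' Cross-validate domain profiles
#'
#' Stratified k-fold cross-validation of the profile set: for each fold,
#' profiles are rebuilt from the training split and every held-out sequence
#' is assigned the label of the best-scoring profile (no threshold applied;
#' sequences hit by no profile count as misclassified). Metrics are computed
#' from the pooled confusion matrix.
#'
#' @param labeled a [labeled_domain_set()].
#' @param k number of folds (>= 2); labels with fewer than `k` sequences are
#'   skipped with a warning.
#' @param seed fold-assignment seed.
#' @param aligner aligner contract object.
#' @return list with `$metrics` (a `classifier_metrics` object, see
#'   [compute_metrics()]) and `$confusion` (true x predicted table).
#' @export
crossvalidate_profiles <- function(labeled, k = 5L, seed = 1L,
                                   aligner = mafft_aligner()) {
  if (k < 2L) stop("k must be >= 2")
  counts <- table(labeled$label)
  small <- names(counts)[counts < k]
  if (length(small) > 0L) {
    warning("label(s) with fewer than k sequences skipped: ",
            paste(small, collapse = ", "))
    labeled <- labeled[!labeled$label %in% small, , drop = FALSE]
  }
  if (nrow(labeled) == 0L) stop("no label has >= k sequences")
  # stratified fold assignment, independent of label order
  folds <- integer(nrow(labeled))
  for (lab in sort(unique(labeled$label))) {
    idx <- which(labeled$label == lab)
    perm <- with_seed(seed + hash_ints(utf8ToInt(lab)) %% 10000L,
                      sample(length(idx)))
    folds[idx[perm]] <- rep_len(seq_len(k), length(idx))
  }
  y_true <- character(0); y_pred <- character(0)
  for (f in seq_len(k)) {
    train <- labeled[folds != f, , drop = FALSE]
    test <- labeled[folds == f, , drop = FALSE]
    class(train) <- class(labeled)
    profs <- build_profiles(train, aligner)
    fa <- tempfile(fileext = ".fa")
    write_fasta(stats::setNames(test$sequence, test$id), fa)
    scores <- lapply(profs, function(p) {
      h <- hmmsearch_profile(p, fa, min_score = 0)
      if (nrow(h) == 0L) return(numeric(0))
      tapply(h$bit_score, h$protein_id, max)
    })
    unlink(fa)
    pred <- vapply(test$id, function(id) {
      s <- vapply(scores, function(v) if (id %in% names(v)) v[[id]] else -Inf, 1)
      if (all(!is.finite(s))) "<none>" else names(profs)[which.max(s)]
    }, "")
    y_true <- c(y_true, test$label)
    y_pred <- c(y_pred, unname(pred))
  }
  conf <- table(true = y_true, predicted = y_pred)
  list(metrics = compute_metrics(y_true, y_pred), confusion = conf)
}

#' Read and write profile sets
#'
#' Profiles are stored as one concatenated HMMER3 text file plus a sidecar
#' threshold table (TSV with columns `name` and `domT`).
#'
#' @param profiles a `domain_profile_set`.
#' @param hmm_path path of the HMMER3 file.
#' @param threshold_path path of the sidecar TSV.
#' @return `write_profiles()` returns `hmm_path` invisibly;
#'   `read_profiles()` returns a `domain_profile_set`.
#' @export
write_profiles <- function(profiles, hmm_path, threshold_path) {
  writeLines(unlist(lapply(profiles, `[[`, "hmm")), hmm_path)
  write_tsv(data.frame(name = names(profiles),
                       domT = vapply(profiles, `[[`, 1, "threshold")),
            threshold_path)
  invisible(hmm_path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(hmm_path, threshold_path) {
  lines <- readLines(hmm_path)
  starts <- grep("^HMMER3", lines)
  ends <- grep("^//", lines)
  if (length(starts) != length(ends)) stop("malformed HMMER3 file")
  thr <- read_tsv(threshold_path)
  profiles <- lapply(seq_along(starts), function(i) {
    hmm <- lines[starts[i]:ends[i]]
    name <- sub("^NAME\\s+", "", grep("^NAME", hmm, value = TRUE)[1])
    t <- thr$domT[match(name, thr$name)]
    if (is.na(t)) stop("no threshold for profile ", name)
    list(name = name, hmm = hmm, threshold = t)
  })
  names(profiles) <- vapply(profiles, `[[`, "", "name")
  new_profile_set(profiles)
}

#' Default per-domain detection thresholds
#'
#' The packaged bit-score thresholds (domT) for the 20 core biosynthetic
#' domain profiles, as shipped in `extdata/domain_thresholds.tsv`.
#'
#' @return data frame with columns `name` and `domT`.
#' @export
default_domain_thresholds <- function() {
  read_tsv(default_table_path("domain_thresholds.tsv"))
}

#' Write detected hits as TSV
#'
#' @param hits a `domain_hits` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) write_tsv(as.data.frame(hits), path)
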