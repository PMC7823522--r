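# End-to-end pipeline: input parsing -> domain scan -> cluster windows ->
# modules -> blocks -> block order -> substrate prediction -> scaffold ->
# PSM counts -> database screening.

#' Pipeline configuration
#'
#' Bundles every component the pipeline needs. All stochastic components
#' (fold assignment, forests) receive seeds derived from `seed`.
#'
#' @param profiles calibrated `domain_profile_set`.
#' @param patterns module pattern table ([load_pattern_table()]).
#' @param chemistry substrate chemistry table ([load_chemistry_table()]).
#' @param refdb reference block database (`reference_block_db`), or NULL to
#'   keep genomic block order.
#' @param at_model,a_model `substrate_model`s for AT-/A-domain substrate
#'   prediction (NULL: PKS substrates default to "generic"; NRPS modules
#'   require `a_model`).
#' @param psm_regressors list of `psm_regressor`s (optional).
#' @param db screening database (`screening_db`, optional).
#' @param weights mixed-score weights.
#' @param cluster_window maximum genomic gap (bp) between domain-bearing
#'   genes of one cluster.
#' @param top_n number of screening hits reported.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(profiles, patterns = load_pattern_table(),
                            chemistry = load_chemistry_table(), refdb = NULL,
                            at_model = NULL, a_model = NULL,
                            psm_regressors = NULL, db = NULL,
                            weights = default_weights("All"),
                            cluster_window = 10000L, top_n = 50L, seed = 1L) {
  structure(list(profiles = profiles, patterns = patterns,
                 chemistry = chemistry, refdb = refdb, at_model = at_model,
                 a_model = a_model, psm_regressors = psm_regressors, db = db,
                 weights = weights, cluster_window = cluster_window,
                 top_n = top_n, seed = seed), class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML file references the artifact paths (profiles + thresholds,
#' pattern/chemistry tables, reference blocks, libraries) and scalar
#' options; see the packaged fixture bundle for an example.
#'
#' @param path YAML config path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p)) NULL else
    if (file.exists(p)) p else file.path(base, p)
  need <- function(p, what) {
    if (is.null(p)) stop("config misses required path: ", what)
    if (!file.exists(p)) stop("configured file does not exist: ", p)
    p
  }
  profiles <- read_profiles(need(resolve(y$profiles), "profiles"),
                            need(resolve(y$thresholds), "thresholds"))
  patterns <- if (!is.null(y$patterns))
    load_pattern_table(need(resolve(y$patterns), "patterns")) else load_pattern_table()
  chemistry <- if (!is.null(y$chemistry))
    load_chemistry_table(need(resolve(y$chemistry), "chemistry")) else load_chemistry_table()
  refdb <- if (!is.null(y$reference_blocks))
    read_reference_blocks(need(resolve(y$reference_blocks), "reference_blocks"))
  a_model <- if (!is.null(y$a_model)) readRDS(need(resolve(y$a_model), "a_model"))
  at_model <- if (!is.null(y$at_model)) readRDS(need(resolve(y$at_model), "at_model"))
  db <- if (!is.null(y$library))
    ingest_library(need(resolve(y$library), "library"))
  weights <- if (!is.null(y$weights)) y$weights else default_weights("All")
  pipeline_config(profiles, patterns, chemistry, refdb = refdb,
                  at_model = at_model, a_model = a_model, db = db,
                  weights = weights,
                  cluster_window = y$cluster_window %||% 10000L,
                  top_n = y$top_n %||% 50L, seed = y$seed %||% 1L)
}

# group domain-bearing proteins into cluster windows
cluster_windows <- function(proteins, hits, window) {
  with_hits <- proteins[proteins$id %in% unique(hits$protein_id), , drop = FALSE]
  with_hits <- with_hits[order(with_hits$genomic_start), , drop = FALSE]
  if (nrow(with_hits) == 0L) return(list())
  gap <- c(0L, with_hits$genomic_start[-1L] -
             utils::head(with_hits$genomic_end, -1L))
  grp <- cumsum(gap > window)
  split(with_hits$id, grp)
}

# substrate prediction for one module; returns label or NA
predict_module_substrate <- function(m, proteins, hits, config) {
  dom <- m$substrate_domain
  if (dom == "none") return(NA_character_)
  model <- if (dom == "AT") config$at_model else config$a_model
  if (is.null(model)) {
    if (dom == "AT") return("generic")
    stop("an A-domain substrate model is required for NRPS modules")
  }
  h <- hits[hits$protein_id %in% m$protein_ids & hits$domain == dom, , drop = FALSE]
  if (nrow(h) == 0L) return(if (dom == "AT") "generic" else NA_character_)
  h <- h[1L, ]
  seqres <- substring(proteins$sequence[match(h$protein_id, proteins$id)],
                      h$seq_start + 1L, h$seq_end)
  predict(model, sequence = seqres)$label
}

#' Run the full prediction pipeline on one record
#'
#' @param proteins a [protein_records()] table (one genome/record).
#' @param config a [pipeline_config()].
#' @param record_id identifier used in the results.
#' @return list of `cluster_result` objects (one per detected cluster),
#'   each with the genomic span, cluster type (derived from functional
#'   modules only), modules, blocks, scaffold, predicted PSM vector and
#'   ranked matches (when a screening db is configured).
#' @export
run_record <- function(proteins, config, record_id = "record") {
  hits <- scan_proteins(proteins, config$profiles)
  clusters <- cluster_windows(proteins, hits, config$cluster_window)
  results <- list()
  for (ci in seq_along(clusters)) {
    ids <- clusters[[ci]]
    chits <- hits[hits$protein_id %in% ids, , drop = FALSE]
    cprot <- proteins[proteins$id %in% ids, , drop = FALSE]
    modules <- segment_into_modules(chits, cprot,
                                    max_gene_gap = config$cluster_window)
    modules <- lapply(modules, classify_module, patterns = config$patterns)
    modules <- loading_terminal_flags(modules)
    functional <- Filter(function(m)
      m$functional_class %in% c("normal", "special"), modules)
    if (length(functional) == 0L) next
    types <- unique(vapply(functional, `[[`, "", "type"))
    ctype <- if ("mixed" %in% types || length(types) > 1L) "mixed" else types
    blocks <- build_blocks(modules, max_gap = config$cluster_window)
    # blocks made only of non-functional modules carry no chemistry
    blocks <- Filter(function(b) any(vapply(b$modules, function(m)
      m$functional_class %in% c("normal", "special"), TRUE)), blocks)
    ordered <- if (!is.null(config$refdb) && length(blocks) > 1L)
      order_blocks(blocks, config$refdb) else blocks
    chains <- lapply(ordered, function(b) {
      mods <- Filter(function(m)
        m$functional_class %in% c("normal", "special"), b$modules)
      lapply(mods, function(m) {
        substrate <- predict_module_substrate(m, cprot, chits, config)
        module_to_building_block(m, substrate, config$chemistry)
      })
    })
    scaffold <- assemble_scaffold(chains)
    scaffold$psm_vector <- count_psms_scaffold(scaffold)
    if (!is.null(config$psm_regressors)) {
      pred <- predict_psms(config$psm_regressors,
                           domain_pfam_counts(chits))
      common <- intersect(names(pred), names(scaffold$psm_vector))
      scaffold$psm_vector[common] <- scaffold$psm_vector[common] + pred[common]
    }
    matches <- NULL
    if (!is.null(config$db))
      matches <- utils::head(
        screen_scaffold(scaffold, config$db, config$weights,
                        n_preselect = max(config$top_n, 50L)), config$top_n)
    results[[length(results) + 1L]] <- structure(list(
      cluster_id = paste0(record_id, "_c", ci),
      genomic_span = c(min(cprot$genomic_start), max(cprot$genomic_end)),
      type = ctype, modules = modules, blocks = ordered,
      scaffold = scaffold, matches = matches, hits = chits),
      class = "cluster_result")
  }
  results
}

# biosynthetic domain counts act as the annotation-count feature source when
# no external domain-count table is supplied
domain_pfam_counts <- function(hits) {
  tab <- table(hits$domain)
  stats::setNames(as.numeric(tab), names(tab))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster %s [%d-%d] type %s: %d modules, %d block(s)\n",
              x$cluster_id, x$genomic_span[1], x$genomic_span[2], x$type,
              length(x$modules), length(x$blocks)))
  for (f in x$scaffold$fragments) cat("  scaffold:", f, "\n")
  if (!is.null(x$matches))
    cat("  best match:", x$matches$id[1],
        sprintf("(mixed %.3f)\n", x$matches$mixed[1]))
  invisible(x)
}

#' Run the pipeline on an input file
#'
#' FASTA (protein, or DNA -- genes are then called with prodigal) and
#' GenBank inputs are accepted; multi-record files yield one result set per
#' record.
#'
#' @param input path to FASTA or GenBank input.
#' @param config a [pipeline_config()].
#' @return named list: record id -> list of `cluster_result`s.
#' @export
run_pipeline <- function(input, config) {
  first <- readLines(input, n = 50L)
  records <- if (any(grepl("^LOCUS", first))) {
    read_genbank_proteins(input)
  } else if (any(grepl("^>", first))) {
    seqs <- read_fasta(input)
    is_dna <- all(grepl("^[ACGTNacgtn]+$", seqs))
    if (is_dna) list(genome = call_genes_prodigal(input))
    else list(genome = read_protein_fasta(input))
  } else stop("unparseable input (not FASTA or GenBank): ", input)
  out <- lapply(names(records), function(nm)
    run_record(records[[nm]], config, record_id = nm))
  names(out) <- names(records)
  out
}

#' Summarize pipeline results as a data frame
#'
#' @param results output of [run_pipeline()] or [run_record()].
#' @return data frame with one row per cluster.
#' @export
results_summary <- function(results) {
  if (length(results) > 0L && inherits(results[[1L]], "cluster_result"))
    results <- list(record = results)
  rows <- list()
  for (rec in results) for (cl in rec) {
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = cl$cluster_id, type = cl$type,
      start = cl$genomic_span[1], end = cl$genomic_span[2],
      n_modules = length(cl$modules),
      n_functional = sum(vapply(cl$modules, function(m)
        m$functional_class %in% c("normal", "special"), TRUE)),
      n_blocks = length(cl$blocks),
      scaffold = paste(cl$scaffold$fragments, collapse = "."),
      best_match = if (!is.null(cl$matches)) cl$matches$id[1] else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(cluster_id = character(), type = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
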