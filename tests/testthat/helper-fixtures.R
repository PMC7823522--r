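# Shared fixtures built in code. Expensive components (MAFFT/HMMER-backed
# profile training, the end-to-end pipeline run) are built once per test
# session and memoised.

make_module <- function(domains, start = 0L, end = 300L, strand = "+",
                        classify = TRUE, patterns = NULL) {
  m <- bgcscaffold:::new_module(domains, genomic_start = start,
                                genomic_end = end, strand = strand)
  if (classify) m <- classify_module(m, patterns = patterns %||% load_pattern_table())
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_local <- function(seed, expr) bgcscaffold:::with_seed(seed, expr)

make_hits <- function(domains, protein_id = "p1", start0 = 0L, width = 90L,
                      gap = 10L, score = 100) {
  n <- length(domains)
  if (n == 0L) {
    h <- data.frame(protein_id = character(0), domain = character(0),
                    seq_start = integer(0), seq_end = integer(0),
                    bit_score = numeric(0), stringsAsFactors = FALSE)
    class(h) <- c("domain_hits", "data.frame")
    return(h)
  }
  starts <- start0 + (seq_len(n) - 1L) * (width + gap)
  h <- data.frame(protein_id = protein_id, domain = domains,
                  seq_start = starts, seq_end = starts + width,
                  bit_score = score, stringsAsFactors = FALSE)
  class(h) <- c("domain_hits", "data.frame")
  h
}

local_fixture_env <- new.env(parent = emptyenv())

fixture_bundle <- function(seed = 7L) {
  key <- paste0("fx", seed)
  if (is.null(local_fixture_env[[key]]))
    local_fixture_env[[key]] <- generate_fixtures(
      seed = seed, dir = file.path(tempdir(), paste0("fxdir", seed)))
  local_fixture_env[[key]]
}

fixture_config <- function(seed = 7L) {
  key <- paste0("cfg", seed)
  if (is.null(local_fixture_env[[key]]))
    local_fixture_env[[key]] <- build_fixture_config(fixture_bundle(seed))
  local_fixture_env[[key]]
}

fixture_results <- function(seed = 7L) {
  key <- paste0("res", seed)
  if (is.null(local_fixture_env[[key]]))
    local_fixture_env[[key]] <- run_record(fixture_bundle(seed)$genome,
                                           fixture_config(seed), "fixture")
  local_fixture_env[[key]]
}
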