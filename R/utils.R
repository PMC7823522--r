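#' @keywords internal
"_PACKAGE"

# Amino-acid alphabet accepted in protein records (20 standard + X).
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write simple tab-separated tables
#'
#' Thin wrappers with the conventions used throughout the package:
#' header line, tab separator, no quoting, no factors.
#'
#' @param path file path.
#' @param df data frame to write.
#' @return `read_tsv()` returns a data frame; `write_tsv()` returns `path`
#'   invisibly.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Headers are kept verbatim (without the leading `>`); sequences are
#' concatenated across wrapped lines.
#'
#' @param path FASTA file path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  idx <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  names(seqs) <- headers[as.integer(names(seqs))]
  seqs
}

# Locate an executable or fail with an actionable message.
find_tool <- function(name) {
  p <- Sys.which(name)
  if (!nzchar(p)) stop("external tool '", name, "' not found on PATH", call. = FALSE)
  unname(p)
}

# Stable seeded evaluation that does not disturb the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic small-integer hash (FNV-style in double arithmetic; all
# intermediates stay below 2^53 so the computation is exact).
hash_ints <- function(xs) {
  h <- 216613
  for (x in xs) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
  h
}

#' Path to a packaged default data table
#'
#' @param file file name under the package's `extdata` directory.
#' @return absolute path.
#' @export
default_table_path <- function(file) {
  p <- system.file("extdata", file, package = "bgcscaffold")
  if (!nzchar(p)) stop("packaged table not found: ", file)
  p
}
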