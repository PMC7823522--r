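# Minimal GenBank record support: enough of the LOCUS / FEATURES(CDS with
# /locus_tag and /translation) / ORIGIN subset to round-trip annotated
# genomes. Multi-record files (// separators) are supported; one protein
# table is returned per record.

#' Parse GenBank records into protein tables
#'
#' Reads CDS features with their location, strand, locus tag and
#' /translation qualifier. Coordinates are converted to 0-based half-open.
#'
#' @param path GenBank file (possibly multi-record).
#' @return named list (one element per record) of [protein_records()].
#' @export
read_genbank_proteins <- function(path) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(c(0L, utils::head(grepl("^//", lines), -1L))))
  out <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^//", rec)]
    if (!any(grepl("^LOCUS", rec))) next
    name <- strsplit(trimws(sub("^LOCUS", "", grep("^LOCUS", rec, value = TRUE)[1])),
                     "\\s+")[[1]][1]
    cds_idx <- grep("^ {5}CDS ", rec)
    if (length(cds_idx) == 0L) {
      out[[name]] <- protein_records(character(0), character(0))[0, ]
      next
    }
    feat_idx <- grep("^ {5}\\S", rec)
    origin <- grep("^ORIGIN", rec)[1]
    ends <- vapply(cds_idx, function(i) {
      nxt <- feat_idx[feat_idx > i]
      min(c(nxt, origin, length(rec) + 1L), na.rm = TRUE) - 1L
    }, 1L)
    tabs <- lapply(seq_along(cds_idx), function(k) {
      block <- rec[cds_idx[k]:ends[k]]
      loc <- trimws(sub("^ {5}CDS", "", block[1]))
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      if (length(nums) < 2L) stop("unsupported CDS location in record ", name,
                                  ": ", loc)
      qual <- paste(trimws(block[-1]), collapse = " ")
      get_q <- function(q) {
        m <- regmatches(qual, regexpr(paste0("/", q, '="[^"]*"'), qual))
        if (length(m) == 0L) return(NA_character_)
        sub('"$', "", sub(paste0("/", q, '="'), "", m))
      }
      tag <- get_q("locus_tag")
      transl <- gsub(" ", "", get_q("translation") %||% NA_character_)
      if (is.na(transl)) stop("CDS without /translation in record ", name,
                              " (gene calling from DNA required)")
      data.frame(id = if (is.na(tag)) paste0(name, "_cds", k) else tag,
                 sequence = transl,
                 gene_locus = if (is.na(tag)) paste0(name, "_cds", k) else tag,
                 genomic_start = min(nums) - 1L, genomic_end = max(nums),
                 strand = strand, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, tabs)
    out[[name]] <- protein_records(tab$id, tab$sequence, tab$gene_locus,
                                   tab$genomic_start, tab$genomic_end,
                                   tab$strand)
  }
  if (length(out) == 0L) stop("no GenBank records in ", path)
  out
}

# simple one-codon-per-residue reverse translation (synthetic DNA backbone)
REV_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
               M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT",
               X = "NNN")

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Write a protein table as a synthetic annotated GenBank record
#'
#' The DNA backbone is reverse-translated (one fixed codon per residue) and
#' padded with N spacers so that the CDS coordinates are consistent; the
#' /translation qualifiers carry the exact protein sequences.
#'
#' @param proteins a [protein_records()] table.
#' @param path output path.
#' @param name LOCUS name.
#' @param append append as an additional record (multi-record files).
#' @return `path`, invisibly.
#' @export
write_genbank <- function(proteins, path, name = "synthetic", append = FALSE) {
  total <- max(proteins$genomic_end) + 10L
  dna <- rep("N", total)
  for (i in seq_len(nrow(proteins))) {
    aa <- strsplit(proteins$sequence[i], "")[[1]]
    cod <- paste(REV_CODON[aa], collapse = "")
    if (proteins$strand[i] == "-") cod <- revcomp(cod)
    s <- proteins$genomic_start[i] + 1L
    span <- nchar(cod)
    dna[s:(s + span - 1L)] <- strsplit(cod, "")[[1]]
  }
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   SYN", name, total), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (i in seq_len(nrow(proteins))) {
    p <- proteins[i, ]
    span <- nchar(p$sequence) * 3L
    loc <- sprintf("%d..%d", p$genomic_start + 1L, p$genomic_start + span)
    if (p$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf('                     /locus_tag="%s"', p$id), con)
    tr <- p$sequence
    writeLines(sprintf('                     /translation="%s"', tr), con)
  }
  writeLines("ORIGIN", con)
  seqs <- paste(dna, collapse = "")
  pos <- seq(1L, nchar(seqs), by = 60L)
  for (s in pos) {
    chunk <- substring(seqs, s, min(s + 59L, nchar(seqs)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", s, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Parse protein FASTA with gene coordinates
#'
#' Accepts prodigal-style headers (`>id # start # end # strand # ...`,
#' 1-based inclusive, strand 1/-1) as well as plain headers (which get
#' synthetic coordinates in file order).
#'
#' @param path protein FASTA path.
#' @return a [protein_records()] table.
#' @export
read_protein_fasta <- function(path) {
  seqs <- read_fasta(path)
  hdr <- names(seqs)
  seqs <- gsub("\\*$", "", seqs)  # trailing stop codons from gene callers
  if (all(grepl("#", hdr, fixed = TRUE))) {
    parts <- strsplit(hdr, "\\s*#\\s*")
    protein_records(
      id = vapply(parts, `[[`, "", 1L),
      sequence = unname(seqs),
      genomic_start = vapply(parts, function(p) as.integer(p[[2L]]), 1L) - 1L,
      genomic_end = vapply(parts, function(p) as.integer(p[[3L]]), 1L),
      strand = ifelse(vapply(parts, function(p) p[[4L]], "") == "-1", "-", "+"))
  } else {
    protein_records(id = vapply(strsplit(hdr, "\\s+"), `[[`, "", 1L),
                    sequence = unname(seqs))
  }
}

#' Call genes on DNA input with prodigal
#'
#' Thin subprocess contract around the external gene caller; protein input
#' bypasses it entirely.
#'
#' @param dna_fasta path to a DNA FASTA file.
#' @return a [protein_records()] table.
#' @export
call_genes_prodigal <- function(dna_fasta) {
  if (!nzchar(Sys.which("prodigal")))
    stop("DNA input requires the 'prodigal' gene caller on PATH ",
         "(or provide protein input / GenBank with translations)")
  out <- tempfile(fileext = ".faa")
  status <- system2("prodigal", c("-i", dna_fasta, "-a", out, "-p", "meta"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("prodigal failed (exit ", status, ")")
  on.exit(unlink(out))
  read_protein_fasta(out)
}
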