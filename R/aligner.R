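# Aligner contract -----------------------------------------------------------
#
# Every component that needs a multiple alignment takes an `aligner` argument:
# a list with two functions,
#   $align(seqs)            named character vector -> named character vector
#                           of equal-length aligned rows (gap "-")
#   $add(aligned, seqs)     align new sequences into an existing alignment,
#                           keeping the original column space (insertions made
#                           by the new sequences are discarded)
# The default is MAFFT; a trivial aligner for already equal-length sequences
# is provided for tests and degenerate inputs.

#' MAFFT-backed aligner
#'
#' Returns an aligner object satisfying the package's aligner contract,
#' backed by the MAFFT command-line tool. `$add()` uses `mafft --add
#' --keeplength`, so sequences added after training are projected into the
#' original column space.
#'
#' @param extra_args extra command-line arguments passed to mafft.
#' @return list with `$align` and `$add` functions.
#' @export
mafft_aligner <- function(extra_args = "--auto") {
  find_tool("mafft")
  run <- function(args, infile) {
    out <- tempfile(fileext = ".aln")
    status <- system2("mafft", c(extra_args, "--anysymbol", args, shQuote(infile)),
                      stdout = out, stderr = FALSE)
    if (status != 0L) stop("mafft failed (exit ", status, ")")
    aln <- read_fasta(out)
    unlink(out)
    toupper(aln)
  }
  list(
    align = function(seqs) {
      if (length(seqs) == 1L) return(seqs)
      fa <- tempfile(fileext = ".fa")
      on.exit(unlink(fa))
      write_fasta(seqs, fa)
      run(character(0), fa)
    },
    add = function(aligned, seqs) {
      fa <- tempfile(fileext = ".fa"); base <- tempfile(fileext = ".fa")
      on.exit(unlink(c(fa, base)))
      write_fasta(seqs, fa)
      write_fasta(aligned, base)
      aln <- run(c("--add", shQuote(fa), "--keeplength"), base)
      aln[names(seqs)]
    }
  )
}

#' Pass-through aligner for pre-aligned sequences
#'
#' Requires all sequences to have equal length already; useful in tests and
#' when alignments are supplied externally.
#'
#' @return aligner object (see [mafft_aligner()]).
#' @export
identity_aligner <- function() {
  chk <- function(seqs) {
    if (length(unique(nchar(seqs))) > 1L)
      stop("identity_aligner requires equal-length sequences")
    seqs
  }
  list(align = chk,
       add = function(aligned, seqs) chk(c(aligned, seqs))[names(seqs)])
}
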