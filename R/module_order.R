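# Module order: group modules into strand-contiguous blocks and infer the
# most probable block order by local alignment of domain strings against a
# reference database of single-block clusters.

#' Alignment parameters for domain-string alignment
#'
#' Defaults: matched domains score +1, mismatches -1, gap opening -2, gap
#' extension -1 (a gap of length L costs open + L * extend).
#'
#' @param match,mismatch,gap_open,gap_extend integer scores/costs.
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(match = 1L, mismatch = -1L,
                             gap_open = -2L, gap_extend = -1L) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' Smith-Waterman local alignment score over domain labels
#'
#' Affine-gap local alignment (Gotoh recursion) where each domain label is
#' one symbol. Returns the best local alignment score, never below 0.
#'
#' @param a,b character vectors of domain labels.
#' @param params an [alignment_params()] object.
#' @return integer score >= 0.
#' @export
sw_domain_score <- function(a, b, params = alignment_params()) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) return(0L)
  open1 <- params$gap_open + params$gap_extend  # cost of the first gap symbol
  ext <- params$gap_extend
  H <- matrix(0, n + 1L, m + 1L)   # best score ending at (i, j)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in a (consuming b)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in b (consuming a)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (a[i - 1L] == b[j - 1L]) params$match else params$mismatch
      E[i, j] <- max(H[i, j - 1L] + open1, E[i, j - 1L] + ext)
      F[i, j] <- max(H[i - 1L, j] + open1, F[i - 1L, j] + ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  as.integer(best)
}

new_block <- function(modules) {
  doms <- unlist(lapply(modules, `[[`, "domains"))
  structure(list(
    modules = modules,
    strand = modules[[1L]]$strand,
    genomic_start = min(vapply(modules, `[[`, 1L, "genomic_start")),
    genomic_end = max(vapply(modules, `[[`, 1L, "genomic_end")),
    has_start = isTRUE(modules[[1L]]$loading),
    has_end = modules[[length(modules)]]$terminal != "none",
    domains = doms), class = "module_block")
}

#' @export
print.module_block <- function(x, ...) {
  cat(sprintf("<block %s strand %s%s%s | %d module(s)>\n",
              paste(x$domains, collapse = "-"), x$strand,
              if (x$has_start) " | start" else "",
              if (x$has_end) " | end" else "", length(x$modules)))
  invisible(x)
}

#' Group modules into strand-contiguous blocks
#'
#' Only modules located directly next to each other on the same DNA strand
#' are combined into a block; blocks are split after an internal terminal
#' (TE/TD) module so that a terminal module is always last in its block.
#' Modules must be supplied in assembly-line order (the order produced by
#' [segment_into_modules()]).
#'
#' @param modules list of classified `bgc_module`s.
#' @param max_gap maximum genomic gap (bp) between consecutive modules
#'   regarded as adjacent.
#' @return list of `module_block` objects.
#' @export
build_blocks <- function(modules, max_gap = 10000L) {
  if (length(modules) == 0L) return(list())
  blocks <- list(); cur <- list()
  flush <- function() {
    if (length(cur) > 0L) blocks[[length(blocks) + 1L]] <<- new_block(cur)
    cur <<- list()
  }
  prev <- NULL
  for (m in modules) {
    if (!is.null(prev)) {
      gap <- max(0L, max(m$genomic_start, prev$genomic_start) -
                   min(m$genomic_end, prev$genomic_end))
      if (m$strand != prev$strand || gap > max_gap) flush()
    }
    cur[[length(cur) + 1L]] <- m
    if (m$terminal != "none") flush()
    prev <- m
  }
  flush()
  blocks
}

#' Load a reference block database
#'
#' @param path TSV with columns `id` and `domains` (comma-separated domain
#'   labels of a known single-block cluster).
#' @return list of class `reference_block_db`.
#' @export
read_reference_blocks <- function(path) {
  tab <- read_tsv(path)
  stopifnot(all(c("id", "domains") %in% names(tab)))
  structure(lapply(seq_len(nrow(tab)), function(i)
    list(id = tab$id[i],
         domains = strsplit(tab$domains[i], ",", fixed = TRUE)[[1L]])),
    class = "reference_block_db")
}

#' @rdname read_reference_blocks
#' @param refdb a `reference_block_db`.
#' @export
write_reference_blocks <- function(refdb, path) {
  write_tsv(data.frame(
    id = vapply(refdb, `[[`, "", "id"),
    domains = vapply(refdb, function(e) paste(e$domains, collapse = ","), "")),
    path)
}

#' Build a reference block database from module blocks
#'
#' @param blocks named list of `module_block`s (e.g. from single-block
#'   reference clusters).
#' @return a `reference_block_db`.
#' @export
reference_block_db <- function(blocks) {
  ids <- names(blocks) %||% paste0("ref", seq_along(blocks))
  structure(Map(function(id, b) list(id = id, domains = b$domains),
                ids, blocks, USE.NAMES = FALSE),
            class = "reference_block_db")
}

# score of a hypothetical ordered concatenation i -> j against the reference
pair_score <- function(bi, bj, refdb, params) {
  cat_domains <- c(bi$domains, bj$domains)
  max(vapply(refdb, function(r) sw_domain_score(cat_domains, r$domains, params), 1L))
}

#' Infer the most probable block order
#'
#' Computes an all-vs-all matrix of hypothetical ordered block pairs, scores
#' each admissible concatenation against every reference entry with
#' [sw_domain_score()], and greedily merges the best-scoring admissible pair,
#' recomputing the matrix after each merge. Placement rules: a block
#' containing a loading module can only stand at the beginning of a pair, a
#' terminal block only at the end, and two terminal blocks are never merged.
#' Unmergeable blocks are left disconnected.
#'
#' @param blocks list of `module_block`s.
#' @param refdb a `reference_block_db`; if empty, blocks are returned in
#'   genomic order with a warning.
#' @param params [alignment_params()].
#' @param max_blocks refuse inputs with more blocks than this.
#' @return list of `module_block`s: merged assemblies first ordered by
#'   loading-block presence then genomic position.
#' @export
order_blocks <- function(blocks, refdb, params = alignment_params(),
                         max_blocks = 10L) {
  if (length(blocks) <= 1L) return(blocks)
  if (length(blocks) > max_blocks)
    stop("more than max_blocks (", max_blocks, ") blocks")
  if (length(refdb) == 0L) {
    warning("empty reference database; returning blocks in genomic order")
    return(blocks[order(vapply(blocks, `[[`, 1L, "genomic_start"))])
  }
  repeat {
    n <- length(blocks)
    if (n == 1L) break
    best <- NULL
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      bi <- blocks[[i]]; bj <- blocks[[j]]
      if (bi$has_end || bj$has_start) next  # placement rules
      s <- pair_score(bi, bj, refdb, params)
      if (s <= 0L) next
      cand <- list(i = i, j = j, score = s)
      if (is.null(best) || s > best$score ||
          (s == best$score && genomic_preference(blocks, cand, best)))
        best <- cand
    }
    if (is.null(best)) break
    merged <- new_block(c(blocks[[best$i]]$modules, blocks[[best$j]]$modules))
    # a merged block spans both genomic intervals; keep flags from the ends
    merged$has_start <- blocks[[best$i]]$has_start
    merged$has_end <- blocks[[best$j]]$has_end
    blocks <- c(blocks[-c(best$i, best$j)], list(merged))
  }
  key <- order(!vapply(blocks, `[[`, TRUE, "has_start"),
               vapply(blocks, `[[`, 1L, "genomic_start"))
  blocks[key]
}

# tie-break: prefer the pair preserving genomic order, then lower indices
genomic_preference <- function(blocks, cand, best) {
  gs <- function(p) blocks[[p$i]]$genomic_start <= blocks[[p$j]]$genomic_start
  if (gs(cand) != gs(best)) return(gs(cand))
  if (cand$i != best$i) return(cand$i < best$i)
  cand$j < best$j
}

#' All modules contained in a list of blocks, in assembly order
#'
#' @param blocks list of `module_block`s.
#' @return flat list of `bgc_module`s.
#' @export
blocks_to_modules <- function(blocks) {
  unlist(lapply(blocks, `[[`, "modules"), recursive = FALSE)
}
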