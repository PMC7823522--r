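# Module architecture: parse ordered domain hits into biosynthetic modules,
# classify them (normal / special / non-functional; PKS / NRPS / mixed) and
# derive the chemical modification profile of each module.

PKS_SUBSTRATE_DOMAINS <- c("KS", "KSQ", "AT", "tAT_d")
REDUCTION_DOMAINS <- c("KR", "DH", "DH2", "DHt", "ER")
PKS_CORE_DOMAINS <- c(PKS_SUBSTRATE_DOMAINS, REDUCTION_DOMAINS, "cMT", "oMT", "CAL")
NRPS_CORE_DOMAINS <- c("C", "A", "E", "nMT")
TERMINAL_DOMAINS <- c("TE", "TD")
KNOWN_DOMAINS <- unique(c(PKS_CORE_DOMAINS, NRPS_CORE_DOMAINS,
                          CARRIER_DOMAINS, TERMINAL_DOMAINS))

# Table 2 uses "cAL" for the coenzyme A ligase domain; profiles call it CAL.
normalize_domain <- function(d) ifelse(d == "cAL", "CAL", d)

new_module <- function(domains, protein_ids = character(),
                       genomic_start = NA_integer_, genomic_end = NA_integer_,
                       strand = "+") {
  structure(list(domains = domains, type = NA_character_,
                 functional_class = NA_character_,
                 substrate_domain = "none", reduction = "none",
                 methylation = "none", epimerized = FALSE, trans_at = FALSE,
                 loading = FALSE, terminal = "none",
                 protein_ids = protein_ids, genomic_start = genomic_start,
                 genomic_end = genomic_end, strand = strand),
            class = "bgc_module")
}

#' @export
print.bgc_module <- function(x, ...) {
  cat(sprintf("<module %s | %s %s | red %s | meth %s%s%s%s%s>\n",
              paste(x$domains, collapse = "-"), x$functional_class, x$type,
              x$reduction, x$methylation,
              if (isTRUE(x$epimerized)) " | epi" else "",
              if (isTRUE(x$trans_at)) " | trans-AT" else "",
              if (isTRUE(x$loading)) " | loading" else "",
              if (x$terminal != "none") paste0(" | ", x$terminal) else ""))
  invisible(x)
}

#' Load a module pattern table
#'
#' The pattern table maps exact domain arrangements to their functional
#' class, module type and modification; rows have first-match priority over
#' the generic classification rules. The packaged default covers the 20 most
#' common arrangements.
#'
#' @param path TSV with columns `domain_order`, `functional`, `type`,
#'   `modification`; defaults to the packaged table.
#' @return data frame of class `module_pattern_table`.
#' @export
load_pattern_table <- function(path = default_table_path("module_patterns.tsv")) {
  tab <- read_tsv(path)
  need <- c("domain_order", "functional", "type", "modification")
  if (!all(need %in% names(tab))) stop("pattern table must have columns ",
                                       paste(need, collapse = ", "))
  tab$domain_order <- vapply(strsplit(tab$domain_order, "-", fixed = TRUE),
                             function(d) paste(normalize_domain(d), collapse = "-"), "")
  if (anyDuplicated(tab$domain_order))
    tab <- tab[!duplicated(tab$domain_order), , drop = FALSE]  # first match wins
  class(tab) <- c("module_pattern_table", "data.frame")
  tab
}

#' Derive the reduction state of a PKS(-like) module
#'
#' The beta-keto group installed by chain extension can be processed by the
#' module's reductive domains: none -> ketone, KR -> hydroxyl, DH+KR ->
#' enoyl (double bond), DH+ER+KR -> fully reduced alkyl. Dehydratase or
#' enoylreductase without a ketoreductase cannot act (reduction must start
#' at the ketone), giving the flagged state `ketone_star`. The dehydratase
#' variants DH2 and DHt count as DH.
#'
#' @param m a `bgc_module` or character vector of domain labels.
#' @return one of "ketone", "hydroxyl", "enoyl", "alkyl", "ketone_star".
#' @export
reduction_profile <- function(m) {
  d <- if (inherits(m, "bgc_module")) m$domains else m
  red <- unique(ifelse(d %in% c("DH2", "DHt"), "DH", d))
  red <- red[red %in% c("KR", "DH", "ER")]
  if ("KR" %in% red) {
    if (all(c("DH", "ER") %in% red)) "alkyl"
    else if ("DH" %in% red) "enoyl"
    else "hydroxyl"  # KR alone, or KR+ER (the ER cannot act without DH)
  } else if (length(red) > 0L) "ketone_star" else "ketone"
}

# Methyltransferase placement rules. cMT between / before the reductive
# domains, or between AT and the carrier when no reduction is present, is the
# cis arrangement (alpha methylation). cMT after all reductive domains and
# before the carrier is the trans-AT-associated arrangement: alpha
# methylation plus an inferred trans-acting AT. oMT acts only on a plain
# hydroxyl (reduction set exactly {KR}), giving a beta methoxy group. nMT
# between A and the carrier methylates the peptide-bond nitrogen. A cMT in a
# pure NRPS module has no general rule and assigns no modification.
methylation_rules <- function(domains, type) {
  d <- normalize_domain(domains)
  carrier_pos <- which(d %in% CARRIER_DOMAINS)[1]
  res <- list(methylation = "none", trans_inferred = FALSE)
  nrps_side <- type == "NRPS" || (type == "mixed" && !"AT" %in% d)
  if (nrps_side) {
    if ("nMT" %in% d) {
      p <- which(d == "nMT")[1]
      a <- which(d == "A")[1]
      if (!is.na(a) && p > a && (is.na(carrier_pos) || p < carrier_pos))
        res$methylation <- "N_methyl"
    }
    return(res)
  }
  red_pos <- which(d %in% REDUCTION_DOMAINS)
  if ("cMT" %in% d) {
    p <- which(d == "cMT")[1]
    if (length(red_pos) == 0L) {
      res$methylation <- "alpha"          # between AT/KS and carrier
    } else if (any(red_pos > p)) {
      res$methylation <- "alpha"          # cis: within the reductive domains
    } else if (is.na(carrier_pos) || p < carrier_pos) {
      res$methylation <- "alpha"          # trans arrangement: after reductions
      res$trans_inferred <- !("AT" %in% d)
    }
  } else if ("oMT" %in% d) {
    red <- unique(ifelse(d[red_pos] %in% c("DH2", "DHt"), "DH", d[red_pos]))
    if (identical(red, "KR")) res$methylation <- "O_methyl"
    # oMT without (or with other) reduction domains: no general rule
  }
  res
}

# Generic first-principles classification used when an arrangement is not in
# the pattern table.
classify_generic <- function(d) {
  has <- function(x) any(x %in% d)
  pks <- has(PKS_CORE_DOMAINS)
  nrps <- has(NRPS_CORE_DOMAINS)
  acp <- has(c("ACP", "bACP")); pcp <- "PCP" %in% d
  type <- if ((nrps && pks) || (nrps && acp) || (pks && pcp)) "mixed"
          else if (pks) "PKS" else if (nrps) "NRPS"
          else if (pcp) "NRPS" else "PKS"
  red <- if (type == "PKS" || (type == "mixed" && has("AT"))) reduction_profile(d)
         else "none"
  fc <-
    if (!has(c("A", "AT", "KS", "KSQ", "tAT_d"))) "non_functional"
    else if (has("CAL") && !has(c("A", "AT"))) "non_functional"
    else if (has("tAT_d") || (has(c("KS", "KSQ")) && !has(c("A", "AT")))) "special"
    else if (!has(CARRIER_DOMAINS)) "special"
    else if (red == "ketone_star") "special"
    else "normal"
  list(type = type, functional_class = fc, reduction = red)
}

#' Classify a module
#'
#' Sets functional class (normal / special / non_functional), module type
#' (PKS / NRPS / mixed), substrate domain, reduction state, methylation,
#' epimerization, trans-AT, loading and terminal flags. Arrangements listed
#' in the pattern table take their printed classification (first-match
#' semantics); anything else falls through to the generic rules.
#'
#' @param m a `bgc_module` (see [segment_into_modules()]).
#' @param patterns a [load_pattern_table()] result, or NULL for rules only.
#' @return the classified `bgc_module`.
#' @export
classify_module <- function(m, patterns = load_pattern_table()) {
  stopifnot(inherits(m, "bgc_module"), length(m$domains) > 0L)
  d <- normalize_domain(m$domains)
  unknown <- setdiff(d, KNOWN_DOMAINS)
  if (length(unknown) > 0L)
    stop("unknown domain label(s): ", paste(unknown, collapse = ", "))
  key <- paste(d, collapse = "-")
  row <- if (!is.null(patterns)) patterns[match(key, patterns$domain_order), ] else NULL
  if (!is.null(row) && nrow(row) == 1L && !is.na(row$functional)) {
    m$functional_class <- c(N = "normal", S = "special",
                            NF = "non_functional")[[row$functional]]
    m$type <- c(PKS = "PKS", NRPS = "NRPS", Mixed = "mixed")[[row$type]]
    mod <- row$modification
    m$reduction <- switch(mod, Ketone = "ketone", Hydroxyl = "hydroxyl",
                          Enoyl = "enoyl", Alkyl = "alkyl",
                          `Ketone*` = "ketone_star", "none")
    m$epimerized <- identical(mod, "E")
  } else {
    g <- classify_generic(d)
    m$type <- g$type
    m$functional_class <- g$functional_class
    m$reduction <- g$reduction
    m$epimerized <- "E" %in% d && m$type %in% c("NRPS", "mixed")
  }
  m$substrate_domain <- if ("AT" %in% d) "AT" else if ("A" %in% d) "A" else "none"
  meth <- methylation_rules(d, m$type)
  m$methylation <- meth$methylation
  m$trans_at <- m$type == "PKS" && ("tAT_d" %in% d || meth$trans_inferred)
  if (m$trans_at && m$functional_class == "normal") m$functional_class <- "special"
  pks_side <- m$type == "PKS" || (m$type == "mixed" && "AT" %in% d)
  m$loading <- m$functional_class %in% c("normal", "special") &&
    if (pks_side) ("KSQ" %in% d || !"KS" %in% d) else !"C" %in% d
  m$terminal <- if ("TE" %in% d) "TE" else if ("TD" %in% d) "TD" else "none"
  m
}

#' Segment ordered domain hits into modules
#'
#' Hits are processed gene by gene in assembly-line (translation) order: a
#' module ends after a carrier domain (ACP/PCP/bACP) plus any immediately
#' following E/TE/TD domains; trailing domains without a carrier form a
#' dangling module. Dangling modules at a gene end are merged with the first
#' module of the next adjacent same-strand gene when the merged arrangement
#' classifies as a normal module (clusters commonly split modules across
#' genes). Minus-strand gene runs are traversed in reverse genomic order.
#'
#' @param hits a `domain_hits` table from [scan_proteins()].
#' @param proteins the [protein_records()] the hits refer to.
#' @param max_gene_gap maximum genomic gap (bp) between genes regarded as
#'   adjacent for the cross-gene merge.
#' @return list of `bgc_module` objects (unclassified; see
#'   [classify_module()]) in assembly-line order.
#' @export
segment_into_modules <- function(hits, proteins, max_gene_gap = 10000L) {
  if (nrow(hits) == 0L) return(list())
  prot <- proteins[match(unique(hits$protein_id), proteins$id), , drop = FALSE]
  prot <- prot[order(prot$genomic_start), , drop = FALSE]
  # translation-order gene list: reverse each maximal minus-strand run
  ord <- seq_len(nrow(prot))
  r <- rle(prot$strand)
  stops <- cumsum(r$lengths)
  for (i in seq_along(r$values)) if (r$values[i] == "-") {
    seg <- (stops[i] - r$lengths[i] + 1L):stops[i]
    ord[seg] <- rev(ord[seg])
  }
  prot <- prot[ord, , drop = FALSE]

  per_gene <- lapply(seq_len(nrow(prot)), function(gi) {
    p <- prot[gi, ]
    h <- hits[hits$protein_id == p$id, , drop = FALSE]
    h <- h[order(h$seq_start), , drop = FALSE]
    mods <- list(); cur <- character(0)
    i <- 1L
    while (i <= nrow(h)) {
      lab <- normalize_domain(h$domain[i])
      cur <- c(cur, lab)
      if (lab %in% CARRIER_DOMAINS) {
        j <- i + 1L
        while (j <= nrow(h) &&
               normalize_domain(h$domain[j]) %in% c("E", TERMINAL_DOMAINS)) {
          cur <- c(cur, normalize_domain(h$domain[j])); j <- j + 1L
        }
        mods[[length(mods) + 1L]] <- cur
        cur <- character(0)
        i <- j
      } else i <- i + 1L
    }
    if (length(cur) > 0L) mods[[length(mods) + 1L]] <- cur  # dangling tail
    lapply(mods, function(dd)
      new_module(dd, protein_ids = p$id, genomic_start = p$genomic_start,
                 genomic_end = p$genomic_end, strand = p$strand))
  })

  # cross-gene merge of dangling modules (same strand, adjacent genes)
  modules <- list()
  pending <- NULL
  flush_pending <- function() {
    if (!is.null(pending)) modules[[length(modules) + 1L]] <<- pending
    pending <<- NULL
  }
  for (gi in seq_len(nrow(prot))) {
    gm <- per_gene[[gi]]
    if (length(gm) == 0L) { flush_pending(); next }
    if (!is.null(pending)) {
      p <- prot[gi, ]
      prev_gi <- gi - 1L
      adjacent <- p$strand == pending$strand &&
        min(abs(p$genomic_start - pending$genomic_end),
            abs(pending$genomic_start - p$genomic_end)) <= max_gene_gap
      merged <- c(pending$domains, gm[[1L]]$domains)
      mergeable <- adjacent &&
        classify_generic(merged)$functional_class == "normal" &&
        !(classify_generic(pending$domains)$functional_class == "normal" &&
          classify_generic(gm[[1L]]$domains)$functional_class == "normal")
      if (mergeable) {
        gm[[1L]]$domains <- merged
        gm[[1L]]$protein_ids <- c(pending$protein_ids, gm[[1L]]$protein_ids)
        gm[[1L]]$genomic_start <- min(pending$genomic_start, gm[[1L]]$genomic_start)
        gm[[1L]]$genomic_end <- max(pending$genomic_end, gm[[1L]]$genomic_end)
        pending <- NULL
      } else flush_pending()
    }
    last <- gm[[length(gm)]]
    dangling <- !any(normalize_domain(last$domains) %in% CARRIER_DOMAINS)
    if (dangling && gi < nrow(prot)) {
      pending <- last
      gm <- gm[-length(gm)]
    }
    modules <- c(modules, gm)
  }
  flush_pending()
  modules
}

#' Apply loading/terminal/epimerization flags to a module list
#'
#' PKS loading modules are marked by a KSQ domain or the absence of KS;
#' NRPS loading modules by the absence of a condensation domain. Terminal
#' modules carry a TE (carboxyl release) or TD (reductive release) domain;
#' epimerization is marked by an E domain.
#'
#' @param modules list of classified `bgc_module`s.
#' @return the module list with flags set.
#' @export
loading_terminal_flags <- function(modules) {
  lapply(modules, function(m) {
    d <- normalize_domain(m$domains)
    pks_side <- m$type == "PKS" || (m$type == "mixed" && "AT" %in% d)
    m$loading <- m$functional_class %in% c("normal", "special") &&
      if (pks_side) ("KSQ" %in% d || !"KS" %in% d) else !"C" %in% d
    m$terminal <- if ("TE" %in% d) "TE" else if ("TD" %in% d) "TD" else "none"
    m$epimerized <- "E" %in% d && m$type %in% c("NRPS", "mixed")
    m
  })
}

#' Tabular report of a module list
#'
#' @param modules list of `bgc_module`s.
#' @return data frame, one row per module.
#' @export
module_report <- function(modules) {
  do.call(rbind, lapply(modules, function(m) data.frame(
    domains = paste(m$domains, collapse = "-"), type = m$type,
    functional_class = m$functional_class, substrate_domain = m$substrate_domain,
    reduction = m$reduction, methylation = m$methylation,
    epimerized = m$epimerized, trans_at = m$trans_at, loading = m$loading,
    terminal = m$terminal, strand = m$strand,
    genomic_start = m$genomic_start, genomic_end = m$genomic_end,
    stringsAsFactors = FALSE)))
}
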