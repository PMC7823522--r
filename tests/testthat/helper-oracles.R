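# Independent oracles used by the tests. Each one recomputes a quantity by
# a different route than the package implementation.

# Smith-Waterman oracle: Biostrings local pairwiseAlignment on a single-
# character mapping of the domain alphabet (gap of length L costs
# gapOpening + L * gapExtension, matching the package convention).
sw_oracle <- function(a, b, match = 1, mismatch = -1, open = 2, ext = 1) {
  syms <- sort(unique(c(a, b)))
  stopifnot(length(syms) <= 52)
  chars <- c(LETTERS, letters)[seq_along(syms)]
  tr <- function(x) paste(chars[match(x, syms)], collapse = "")
  sm <- matrix(mismatch, length(syms), length(syms),
               dimnames = list(chars[seq_along(syms)], chars[seq_along(syms)]))
  diag(sm) <- match
  pa <- Biostrings::pairwiseAlignment(tr(a), tr(b), type = "local",
                                      substitutionMatrix = sm,
                                      gapOpening = open, gapExtension = ext)
  max(0, Biostrings::score(pa))
}

# Modular-product maximum-clique oracle for the connected common induced
# subgraph (atoms by element, bonds by order). Returns all maximum
# (atoms + bonds) mappings as lists of query/target atom index pairs.
mcs_clique_oracle <- function(q, t, tmask = rep(TRUE, t$n_atoms)) {
  Bq <- bgcscaffold:::bond_order_matrix(q)
  Bt <- bgcscaffold:::bond_order_matrix(t)
  tatoms <- which(tmask)
  pairs <- expand.grid(qa = seq_len(q$n_atoms), ta = tatoms)
  pairs <- pairs[q$elem[pairs$qa] == t$elem[pairs$ta], , drop = FALSE]
  if (nrow(pairs) == 0L) return(list(best = 0, mappings = list()))
  np <- nrow(pairs)
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    if (pairs$qa[i] == pairs$qa[j] || pairs$ta[i] == pairs$ta[j]) next
    if (Bq[pairs$qa[i], pairs$qa[j]] == Bt[pairs$ta[i], pairs$ta[j]])
      edges <- rbind(edges, c(i, j))
  }
  g <- igraph::make_empty_graph(np, directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  cliques <- igraph::max_cliques(g)
  best <- 0; found <- list()
  for (cl in cliques) {
    v <- as.integer(cl)
    qs <- pairs$qa[v]
    # connectivity of the query-side subgraph
    sub <- Bq[qs, qs, drop = FALSE] > 0
    if (length(qs) > 1L) {
      reach <- logical(length(qs)); reach[1] <- TRUE
      repeat {
        new <- reach | apply(sub[, reach, drop = FALSE] > 0, 1, any)
        if (all(new == reach)) break
        reach <- new
      }
      if (!all(reach)) next
    }
    score <- length(qs) + sum(Bq[qs, qs, drop = FALSE] > 0) / 2
    if (score > best) { best <- score; found <- list() }
    if (score == best) found[[length(found) + 1L]] <-
        cbind(qa = qs, ta = pairs$ta[v])
  }
  list(best = best, mappings = found)
}

# Exhaustive multi-fragment MCS oracle (<= 2 fragments): enumerate every
# maximum mapping of fragment 1, delete it, take the best fragment-2 match.
extended_mcs_oracle <- function(fragments, target, normalization = "mean") {
  frags <- lapply(fragments, bgcscaffold::parse_smiles)
  tmol <- bgcscaffold::parse_smiles(target)
  frags <- frags[order(-vapply(frags, `[[`, 1L, "n_atoms"))]
  q_total <- sum(vapply(frags, function(f) f$n_atoms + f$n_bonds, 1L))
  t_total <- tmol$n_atoms + tmol$n_bonds
  step <- function(i, tmask) {
    if (i > length(frags)) return(0)
    res <- mcs_clique_oracle(frags[[i]], tmol, tmask)
    if (res$best == 0) return(step(i + 1L, tmask))
    best <- 0
    for (mp in res$mappings) {
      tm <- tmask; tm[mp[, "ta"]] <- FALSE
      best <- max(best, res$best + step(i + 1L, tm))
    }
    best
  }
  m <- step(1L, rep(TRUE, tmol$n_atoms))
  if (m == 0) return(0)
  if (normalization == "mean") (m / q_total + m / t_total) / 2 else m / q_total
}

# Naive subgraph-matching oracle for plain (element/bond) patterns,
# counting unique matches by matched atom set.
subgraph_count_oracle <- function(pattern_smiles, mol_smiles) {
  p <- bgcscaffold::parse_smiles(pattern_smiles)
  m <- bgcscaffold::parse_smiles(mol_smiles)
  Bp <- bgcscaffold:::bond_order_matrix(p)
  Bm <- bgcscaffold:::bond_order_matrix(m)
  sets <- character(0)
  assign_next <- function(map) {
    qa <- which(is.na(map))[1]
    if (is.na(qa)) {
      sets <<- union(sets, paste(sort(map), collapse = ","))
      return()
    }
    for (ta in setdiff(seq_len(m$n_atoms), map)) {
      if (p$elem[qa] != m$elem[ta]) next
      ok <- TRUE
      for (qb in which(!is.na(map))) {
        if (Bp[qa, qb] > 0 && Bm[ta, map[qb]] != Bp[qa, qb]) { ok <- FALSE; break }
      }
      if (ok) { map2 <- map; map2[qa] <- ta; assign_next(map2) }
    }
  }
  assign_next(rep(NA_integer_, p$n_atoms))
  length(sets)
}

# Confusion-matrix tally independent of compute_metrics
confusion_tally <- function(y_true, y_pred, cl) {
  tp <- sum(y_true == cl & y_pred == cl)
  fp <- sum(y_true != cl & y_pred == cl)
  fn <- sum(y_true == cl & y_pred != cl)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = prec, recall = rec,
    f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}
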