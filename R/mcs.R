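# Multi-fragment maximum-common-substructure scoring. A connected common
# induced subgraph search (atoms compared by element, bonds by order) is run
# fragment by fragment: for the current fragment, up to `max_mcs_per_step`
# alternative maximum mappings are enumerated; for each, the matched atoms
# are deleted from the target and the next fragment is matched against the
# remainder. The best branch wins. Fragment pieces of the target left over
# after a deletion remain eligible for later fragments.

# Enumerate connected common induced subgraph mappings between query q and
# the masked target t. Returns list(best = atoms+bonds score,
# mappings = list of integer vectors q_atom -> t_atom (NA = unmapped),
# atoms, bonds). Each connected query-side subgraph is enumerated once
# (minimum-index seed, exclusion branching); mappings enumerated per
# subgraph.
mcs_mappings <- function(q, t, tmask = rep(TRUE, t$n_atoms), max_mcs = 20L,
                         budget = 2e5) {
  Bq <- bond_order_matrix(q); Bt <- bond_order_matrix(t)
  adjq <- lapply(seq_len(q$n_atoms), function(a) which(Bq[a, ] > 0L))
  state <- new.env(parent = emptyenv())
  state$best <- 0L; state$found <- list(); state$keys <- character(0)
  state$nodes <- 0

  record <- function(map) {
    atoms <- sum(!is.na(map))
    if (atoms == 0L) return()
    sel <- which(!is.na(map))
    bonds <- sum(Bq[sel, sel, drop = FALSE] > 0L) / 2L
    score <- atoms + bonds
    if (score > state$best) {
      state$best <- score; state$found <- list(); state$keys <- character(0)
    }
    if (score == state$best && length(state$found) < max_mcs) {
      key <- paste(sel, map[sel], sep = ":", collapse = ",")
      if (!key %in% state$keys) {
        state$keys <- c(state$keys, key)
        state$found[[length(state$found) + 1L]] <-
          list(map = map, atoms = atoms, bonds = bonds, score = score)
      }
    }
  }

  compatible <- function(qa, ta, map) {
    if (q$elem[qa] != t$elem[ta]) return(FALSE)
    mapped <- which(!is.na(map))
    all(Bq[qa, mapped] == Bt[ta, map[mapped]])
  }

  extend <- function(map, used_t, excluded) {
    state$nodes <- state$nodes + 1
    if (state$nodes > budget) return()
    mapped <- which(!is.na(map))
    frontier <- setdiff(unique(unlist(adjq[mapped])), c(mapped, excluded))
    if (length(frontier) == 0L) { record(map); return() }
    # loose bound: everything not excluded could still be added
    ub <- length(mapped) + length(setdiff(seq_len(q$n_atoms), c(mapped, excluded)))
    if (ub + q$n_bonds < state$best) return()  # atoms + max possible bonds
    qa <- min(frontier)
    extended <- FALSE
    for (ta in which(tmask & !used_t)) {
      if (!compatible(qa, ta, map)) next
      # connectivity on the target side comes free: induced condition forces
      # the bond to the mapped neighbour to exist in t as well
      map2 <- map; map2[qa] <- ta
      used2 <- used_t; used2[ta] <- TRUE
      extend(map2, used2, excluded)
      extended <- TRUE
    }
    # branch where qa is excluded from this subgraph
    extend(map, used_t, c(excluded, qa))
  }

  for (seed in seq_len(q$n_atoms)) {
    lower <- seq_len(seed - 1L)
    for (ta in which(tmask)) {
      if (q$elem[seed] != t$elem[ta]) next
      map <- rep(NA_integer_, q$n_atoms); map[seed] <- ta
      used_t <- rep(FALSE, t$n_atoms); used_t[ta] <- TRUE
      extend(map, used_t, lower)
    }
  }
  list(best = state$best, mappings = state$found)
}

#' Multi-fragment MCS score of predicted scaffold fragments against a target
#'
#' Fragments are sorted by decreasing heavy-atom count and matched in turn:
#' the connected maximum common substructure (atoms by element, bonds by
#' order) between the current fragment and the remaining target is
#' enumerated (up to `max_mcs_per_step` alternatives); each alternative
#' deletes its matched atoms from the target before the next fragment is
#' matched. The returned score aggregates matched atoms plus bonds over the
#' branch that matches most, normalized by default as the mean of the
#' query-side and target-side fractions.
#'
#' @param fragments character vector of fragment SMILES (at most 10).
#' @param target target molecule SMILES.
#' @param max_mcs_per_step cap on MCS alternatives explored per fragment.
#' @param normalization "mean" (mean of query and target fraction) or
#'   "query" (query fraction only).
#' @return numeric score in `[0, 1]`.
#' @export
extended_mcs_score <- function(fragments, target, max_mcs_per_step = 20L,
                               normalization = c("mean", "query")) {
  normalization <- match.arg(normalization)
  if (length(fragments) == 0L) return(0)
  if (length(fragments) > 10L) stop("at most 10 fragments are supported")
  frags <- lapply(fragments, function(f)
    if (inherits(f, "mol_graph")) f else parse_smiles(f))
  tmol <- if (inherits(target, "mol_graph")) target else parse_smiles(target)
  frags <- frags[order(-vapply(frags, `[[`, 1L, "n_atoms"))]

  q_total <- sum(vapply(frags, function(f) f$n_atoms + f$n_bonds, 1L))
  t_total <- tmol$n_atoms + tmol$n_bonds
  best_matched <- 0

  recurse <- function(i, tmask, acc) {
    if (i > length(frags)) {
      if (acc > best_matched) best_matched <<- acc
      return()
    }
    res <- mcs_mappings(frags[[i]], tmol, tmask, max_mcs = max_mcs_per_step)
    if (res$best == 0L || length(res$mappings) == 0L) {
      recurse(i + 1L, tmask, acc)  # fragment finds no match; skip it
      return()
    }
    for (mp in res$mappings) {
      tmask2 <- tmask
      tmask2[mp$map[!is.na(mp$map)]] <- FALSE
      recurse(i + 1L, tmask2, acc + mp$atoms + mp$bonds)
    }
  }
  recurse(1L, rep(TRUE, tmol$n_atoms), 0)

  if (best_matched == 0) return(0)
  qf <- best_matched / q_total
  tf <- best_matched / t_total
  switch(normalization, mean = (qf + tf) / 2, query = qf)
}
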