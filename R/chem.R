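# Molecule layer: SMILES parsing and canonicalization through
# ChemmineR/ChemmineOB (OpenBabel), a lightweight heavy-atom graph
# representation used by the MCS algorithm, and circular (Morgan-style)
# fingerprints with Tanimoto similarity.

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Hydrogens are implicit; atoms carry element symbols, bonds carry integer
#' orders (aromatic rings are kekulized by OpenBabel).
#'
#' @param smiles a single SMILES string.
#' @return list of class `mol_graph` with `$elem` (character vector),
#'   `$bonds` (matrix with columns i, j, order) and `$n_atoms`, `$n_bonds`.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(length(smiles) == 1L, nzchar(smiles))
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(c(q = smiles))),
                  error = function(e) stop("invalid SMILES: ", smiles))
  mol <- mol_from_sdf(sdf[[1]])
  if (any(mol$elem %in% c("0", ""))) {
    # single-atom molecules lose their symbol in the atom block; recover the
    # elements from the V2000 text
    txt <- strsplit(ChemmineOB::convertFormat("SMI", "SDF", source = smiles),
                    "\n")[[1]]
    counts <- txt[4L]
    na <- as.integer(substr(counts, 1L, 3L))
    atoms <- txt[5L:(4L + na)]
    mol$elem <- trimws(substr(atoms, 32L, 34L))
  }
  mol
}

mol_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_\\d+$", "", rownames(ab))
  if (length(elem) == 0L) stop("molecule has no atoms")
  if (is.null(dim(bb)) && length(bb) >= 3L) bb <- matrix(bb, nrow = 1L)
  # atom-only molecules come back as a padded zero row without a bond column
  bonds <- if (is.null(bb) || length(bb) == 0L || ncol(bb) < 3L || nrow(bb) == 0L) {
    matrix(integer(0), 0L, 3L, dimnames = list(NULL, c("i", "j", "order")))
  } else {
    m <- cbind(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
               order = as.integer(bb[, 3L]))
    rownames(m) <- NULL
    m[m[, "i"] > 0L & m[, "j"] > 0L, , drop = FALSE]
  }
  structure(list(elem = elem, bonds = bonds, n_atoms = length(elem),
                 n_bonds = nrow(bonds)), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph:", x$n_atoms, "atoms,", x$n_bonds, "bonds>\n")
  invisible(x)
}

# adjacency: list of data per atom: neighbor indices and bond orders
mol_adjacency <- function(mol) {
  adj <- vector("list", mol$n_atoms)
  for (k in seq_len(mol$n_bonds)) {
    i <- mol$bonds[k, "i"]; j <- mol$bonds[k, "j"]; o <- mol$bonds[k, "order"]
    adj[[i]] <- rbind(adj[[i]], c(j, o))
    adj[[j]] <- rbind(adj[[j]], c(i, o))
  }
  adj
}

# order of the bond between atoms a and b, or 0L if absent
bond_order_matrix <- function(mol) {
  M <- matrix(0L, mol$n_atoms, mol$n_atoms)
  if (mol$n_bonds > 0L) {
    M[mol$bonds[, 1:2, drop = FALSE]] <- mol$bonds[, "order"]
    M[mol$bonds[, c(2L, 1L), drop = FALSE]] <- mol$bonds[, "order"]
  }
  M
}

#' Canonicalize SMILES
#'
#' @param smiles character vector of SMILES.
#' @return canonical SMILES (OpenBabel canonical form).
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", source = s),
                    error = function(e) "")
    out <- strsplit(out, "[\t\n ]")[[1]][1]
    if (is.na(out) || !nzchar(out)) stop("cannot canonicalize SMILES: ", s)
    out
  }, "", USE.NAMES = FALSE)
}

#' Circular (Morgan-style) fingerprint
#'
#' Iterative neighbourhood hashing on the heavy-atom graph: the initial atom
#' invariant combines element, degree and the summed bond orders; each
#' round up to `radius` re-hashes an atom with its sorted (bond order,
#' neighbour invariant) list. All invariants from radius 0 to `radius` are
#' folded into `nbits` bits.
#'
#' @param mol a `mol_graph` or SMILES string.
#' @param radius neighbourhood radius (default 3).
#' @param nbits fingerprint length.
#' @return sorted integer vector of set bit positions (class `circular_fp`).
#' @export
morgan_fingerprint <- function(mol, radius = 3L, nbits = 2048L) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  adj <- mol_adjacency(mol)
  elem_code <- vapply(mol$elem, function(e) hash_ints(utf8ToInt(e)), 1)
  inv <- vapply(seq_len(mol$n_atoms), function(a) {
    nb <- adj[[a]]
    deg <- if (is.null(nb)) 0L else nrow(nb)
    bsum <- if (is.null(nb)) 0L else sum(nb[, 2L])
    hash_ints(c(elem_code[a], deg, bsum))
  }, 1)
  bits <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(mol$n_atoms), function(a) {
      nb <- adj[[a]]
      if (is.null(nb)) return(hash_ints(c(r, inv[a])))
      pairs <- nb[order(nb[, 2L], inv[nb[, 1L]]), , drop = FALSE]
      hash_ints(c(r, inv[a], as.vector(t(cbind(pairs[, 2L], inv[pairs[, 1L]])))))
    }, 1)
    bits <- c(bits, inv)
  }
  structure(sort(unique(as.integer(bits %% nbits))), class = "circular_fp",
            nbits = nbits)
}

#' Tanimoto similarity of two fingerprints
#'
#' @param a,b fingerprints from [morgan_fingerprint()].
#' @return intersection over union of the set bits, in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Count heavy atoms of a SMILES string
#'
#' @param smiles SMILES string.
#' @return integer atom count.
#' @export
heavy_atom_count <- function(smiles) parse_smiles(smiles)$n_atoms
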