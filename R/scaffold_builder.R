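# Scaffold builder: convert classified modules with predicted substrates
# into molecular building blocks and assemble them into scaffold fragments.
#
# Representation. Following the alpha/beta nomenclature of polyketide
# chemistry, every chain-extension step contributes an alpha carbon (carrying
# the substrate substituent and any C-methylations) and a carbonyl carbon.
# The carbonyl contributed by block i is the beta position of block i+1, so
# "reductive domains act on the previous building block" translates into:
# the reduction profile of module i+1 sets the oxidation state of block i's
# carbonyl. NRP blocks contribute a peptide-bond nitrogen (their beta
# position, methylatable), the alpha carbon with the side chain and the
# amide carbonyl. The terminal block's carbonyl is set by the release
# chemistry: TE -> carboxyl, TD -> hydroxyl (reduced release).

#' Load the substrate chemistry table
#'
#' Maps every substrate label the classifiers can emit to a molecular
#' fragment: PK entries give the alpha substituent of malonyl-type
#' extenders, NRP entries the amino-acid side chain, NRP_TEMPLATE entries a
#' full beta+alpha emission (cyclic or planar residues), ARYL entries an
#' aryl starter acid.
#'
#' @param path TSV with columns `label`, `kind`, `fragment`; defaults to the
#'   packaged table.
#' @return data frame of class `substrate_chemistry`.
#' @export
load_chemistry_table <- function(path = default_table_path("substrate_chemistry.tsv")) {
  tab <- read_tsv(path)
  need <- c("label", "kind", "fragment")
  if (!all(need %in% names(tab))) stop("chemistry table needs columns ",
                                       paste(need, collapse = ", "))
  if (anyDuplicated(tab$label)) stop("duplicate labels in chemistry table")
  bad <- !tab$kind %in% c("PK", "NRP", "NRP_TEMPLATE", "ARYL")
  if (any(bad)) stop("unknown chemistry kind(s): ",
                     paste(unique(tab$kind[bad]), collapse = ", "))
  tab$fragment[is.na(tab$fragment)] <- ""
  class(tab) <- c("substrate_chemistry", "data.frame")
  tab
}

#' Convert a classified module and substrate into a building block
#'
#' @param m a classified `bgc_module` (functional class normal or special).
#' @param substrate substrate label (must exist in the chemistry table);
#'   special modules without a substrate prediction (e.g. trans-AT) use the
#'   "generic" malonyl-like entry.
#' @param chemistry a [load_chemistry_table()] result.
#' @return list of class `building_block`.
#' @export
module_to_building_block <- function(m, substrate = NULL,
                                     chemistry = load_chemistry_table()) {
  stopifnot(inherits(m, "bgc_module"))
  if (!m$functional_class %in% c("normal", "special"))
    stop("building blocks are only generated for normal/special modules")
  pks_side <- m$type == "PKS" || (m$type == "mixed" && "AT" %in% m$domains)
  if (is.null(substrate) || is.na(substrate)) {
    if (pks_side || m$substrate_domain == "none") substrate <- "generic"
    else stop("substrate prediction required for an NRPS module")
  }
  row <- chemistry[match(substrate, chemistry$label), ]
  if (nrow(row) != 1L || is.na(row$kind))
    stop("substrate missing from chemistry table: ", substrate)
  alpha_me <- if (m$methylation == "alpha") 1L else 0L
  total_me <- alpha_me + (substrate == "methylmalonyl")
  beta <- m$reduction
  # NRP extensions leave the carbonyl untouched; DH/ER without KR cannot act
  if (beta %in% c("none", "ketone_star")) beta <- "ketone"
  if (m$methylation == "O_methyl") beta <- "methoxy"
  if (total_me >= 2L && beta %in% c("enoyl", "alkyl")) beta <- "hydroxyl"
  structure(list(
    kind = if (row$kind == "PK") "PK" else "NRP",
    chem_kind = row$kind,
    substrate = substrate,
    fragment = row$fragment,
    alpha_methyls = if (row$kind == "PK") total_me else 0L,
    add_methyl = row$kind == "PK" && alpha_me == 1L,
    # own_reduction: what this module's reductive domains do (applied to the
    # previous block by apply_previous_block_rule)
    own_reduction = beta,
    beta_state = "ketone",
    alpha_stereo = if (row$kind %in% c("NRP", "NRP_TEMPLATE") && nzchar(row$fragment))
      (if (isTRUE(m$epimerized)) "D" else "L") else "unset",
    n_methylated = m$methylation == "N_methyl",
    loading = isTRUE(m$loading),
    terminal_cap = switch(m$terminal, TE = "carboxyl", TD = "hydroxyl", "none")
  ), class = "building_block")
}

#' Shift reduction states onto the previous building block
#'
#' Module i's reduction profile is written to building block i-1 (the
#' reductive domains act on the beta position installed by the previous
#' extension); the last block's carbonyl is set by the terminal release
#' chemistry.
#'
#' @param blocks ordered list of `building_block`s (one merged block chain).
#' @return the blocks with `$beta_state` set.
#' @export
apply_previous_block_rule <- function(blocks) {
  k <- length(blocks)
  if (k == 0L) return(blocks)
  for (i in seq_len(k)) {
    blocks[[i]]$beta_state <-
      if (i < k) blocks[[i + 1L]]$own_reduction else "terminal"
  }
  blocks
}

# SMILES emission -------------------------------------------------------------

flip_stereo <- function(s) {
  s <- gsub("@@", "\001", s, fixed = TRUE)
  s <- gsub("@", "@@", s, fixed = TRUE)
  gsub("\001", "@", s, fixed = TRUE)
}

# emit the beta+alpha part of one building block; returns list(smiles,
# enoyl_pending): when the block's beta state is enoyl the double bond is
# written by the *previous* emission, flagged through `pending_bond`.
emit_block <- function(b, pending_bond) {
  out <- ""
  if (b$chem_kind == "ARYL") {
    out <- b$fragment
  } else if (b$chem_kind == "NRP_TEMPLATE") {
    tmpl <- b$fragment
    if (b$alpha_stereo == "D") tmpl <- flip_stereo(tmpl)
    if (b$n_methylated) tmpl <- sub("^N", "N(C)", tmpl)
    out <- tmpl
  } else if (b$kind == "NRP") {
    n_part <- if (b$n_methylated) "N(C)" else "N"
    alpha <- if (!nzchar(b$fragment)) "C"
    else paste0(if (b$alpha_stereo == "D") "[C@H]" else "[C@@H]",
                "(", b$fragment, ")")
    out <- paste0(n_part, alpha)
  } else {  # PK
    branches <- character(0)
    if (nzchar(b$fragment)) branches <- c(branches, b$fragment)
    if (b$add_methyl) branches <- c(branches, "C")
    alpha <- paste0(if (pending_bond) "C" else "C",
                    paste0(vapply(branches, function(x) paste0("(", x, ")"), ""),
                           collapse = ""))
    out <- alpha
  }
  if (pending_bond && b$chem_kind %in% c("NRP", "NRP_TEMPLATE", "ARYL"))
    stop("enoyl double bond cannot be formed into a nitrogen/aryl block")
  paste0(if (pending_bond) "=" else "", out)
}

# emit the carbonyl carbon of a block in its assigned beta state; returns
# list(smiles, pending) where pending signals an enoyl double bond into the
# next block's alpha carbon.
emit_carbonyl <- function(b) {
  st <- b$beta_state
  if (st == "terminal")
    st <- switch(b$terminal_cap, carboxyl = "carboxyl",
                 hydroxyl = "reduced_release", "aldehyde")
  switch(st,
         ketone = list(s = "C(=O)", pending = FALSE),
         hydroxyl = list(s = "C(O)", pending = FALSE),
         enoyl = list(s = "C", pending = TRUE),
         alkyl = list(s = "C", pending = FALSE),
         methoxy = list(s = "C(OC)", pending = FALSE),
         carboxyl = list(s = "C(=O)O", pending = FALSE),
         reduced_release = list(s = "CO", pending = FALSE),
         aldehyde = list(s = "C=O", pending = FALSE),
         stop("unknown beta state: ", st))
}

#' Assemble ordered building blocks into a scaffold fragment
#'
#' Blocks are condensed head to tail: C-C bonds at the alpha/carbonyl
#' junction for PK extensions, amide bonds for NRP extensions (the bond type
#' follows from the downstream block's beta atom). The emitted SMILES is
#' canonicalized.
#'
#' @param blocks ordered list of `building_block`s (one chain); the
#'   previous-block rule is applied internally.
#' @return canonical SMILES of the chain.
#' @export
assemble_chain <- function(blocks) {
  stopifnot(length(blocks) > 0L)
  blocks <- apply_previous_block_rule(blocks)
  out <- character(0)
  pending <- FALSE
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    out <- c(out, emit_block(b, pending))
    carb <- emit_carbonyl(b)
    out <- c(out, carb$s)
    pending <- carb$pending
  }
  if (pending) stop("terminal block cannot carry a pending enoyl bond")
  smi <- paste(out, collapse = "")
  tryCatch(canonical_smiles(smi),
           error = function(e) stop("assembled fragment is not a valid molecule (",
                                    smi, "): ", conditionMessage(e)))
}

#' Assemble a scaffold from ordered blocks of building blocks
#'
#' @param chains list of building-block chains (one per merged module
#'   block); disconnected blocks yield separate fragments.
#' @return object of class `scaffold`: list with `$fragments` (canonical
#'   SMILES per chain) and `$psm_vector` (filled by PSM prediction,
#'   initially zeros).
#' @export
assemble_scaffold <- function(chains) {
  if (length(chains) == 0L || all(lengths(chains) == 0L))
    stop("at least one building block is required")
  frags <- vapply(chains[lengths(chains) > 0L], assemble_chain, "")
  structure(list(fragments = unname(frags),
                 psm_vector = stats::setNames(integer(7L), default_psm_names())),
            class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  cat("scaffold with", length(x$fragments), "fragment(s):\n")
  for (f in x$fragments) cat(" ", f, "\n")
  if (any(x$psm_vector > 0L))
    cat("predicted PSMs:", paste(names(x$psm_vector)[x$psm_vector > 0L],
                                 x$psm_vector[x$psm_vector > 0L],
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Write scaffold fragments as a SMILES file
#'
#' @param scaffold a `scaffold`.
#' @param path output path (one fragment per line, tab-separated id).
#' @param id base identifier.
#' @return `path`, invisibly.
#' @export
write_scaffold_smiles <- function(scaffold, path, id = "scaffold") {
  writeLines(paste0(scaffold$fragments, "\t", id, "_",
                    seq_along(scaffold$fragments)), path)
  invisible(path)
}

#' Write cluster scaffolds as an SDF with provenance fields
#'
#' @param clusters list of `cluster_result`s (see [run_record()]).
#' @param path output SDF path.
#' @return `path`, invisibly.
#' @export
write_scaffold_sdf <- function(clusters, path) {
  smi <- character(0)
  for (cl in clusters)
    smi[paste0(cl$cluster_id, "_f", seq_along(cl$scaffold$fragments))] <-
      cl$scaffold$fragments
  sdfs <- suppressWarnings(ChemmineR::smiles2sdf(smi))
  types <- vapply(names(smi), function(nm) {
    cl_id <- sub("_f\\d+$", "", nm)
    clusters[[match(cl_id, vapply(clusters, `[[`, "", "cluster_id"))]]$type
  }, "")
  ChemmineR::datablock(sdfs) <- lapply(seq_along(smi), function(i)
    c(cluster = sub("_f\\d+$", "", names(smi)[i]), type = types[[i]],
      smiles = smi[[i]]))
  ChemmineR::write.SDF(sdfs, path)
  invisible(path)
}
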