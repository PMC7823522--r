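# Deterministic fixture generator. Emits, per seed: (a) labelled domain
# sequence sets built from distinct planted motifs, (b) a toy annotated
# genome embedding an NRPS cluster with known module order and substrates,
# (c) a substrate training set separable by construction (class-specific
# code positions), (d) a compound library containing the true scaffold plus
# decoys, and (e) domain-count/PSM tables with a known linear relation.
# Everything is reproducible from the seed alone.

random_protein <- function(n) paste(sample(AA_ALPHABET[1:20], n, TRUE), collapse = "")

mutate_protein <- function(s, rate = 0.08, keep = integer(0)) {
  v <- strsplit(s, "")[[1]]
  i <- setdiff(which(stats::runif(length(v)) < rate), keep)
  if (length(i) > 0L) v[i] <- sample(AA_ALPHABET[1:20], length(i), TRUE)
  paste(v, collapse = "")
}

# planted cluster: loading A(G)-PCP | C-A(A)-PCP | C-A(V)-PCP-TE
FIXTURE_SUBSTRATES <- c("G", "A", "V")

#' Generate the deterministic fixture bundle
#'
#' @param seed integer seed; the same seed yields a byte-identical bundle.
#' @param dir optional directory: when given, the bundle is also written as
#'   plain-text files (labelled FASTA sets, GenBank genome, SMILES library,
#'   TSV tables).
#' @param n_domain_seqs sequences per domain family.
#' @param n_substrate_seqs sequences per substrate class.
#' @param n_psm_clusters rows of the synthetic domain-count/PSM table.
#' @param psm_beta slope of the planted linear PSM relation.
#' @return list with `$domain_train`, `$substrate_train`
#'   ([labeled_domain_set()]s), `$genome` ([protein_records()]),
#'   `$true_substrates`, `$true_smiles`, `$library` (data frame),
#'   `$psm_table`, `$psm_beta` and (with `dir`) `$paths`.
#' @export
generate_fixtures <- function(seed = 1L, dir = NULL, n_domain_seqs = 16L,
                              n_substrate_seqs = 12L, n_psm_clusters = 200L,
                              psm_beta = 2) {
  with_seed(seed, {
    # (a) planted domain motifs
    motifs <- list(C = random_protein(70L), A = random_protein(80L),
                   PCP = random_protein(60L), TE = random_protein(70L))
    # substrate classes: class-specific residues at fixed code positions of
    # the A-domain motif; the rest of the motif is shared
    code_pos <- seq(20L, 45L, by = 5L)
    codes <- lapply(FIXTURE_SUBSTRATES, function(s)
      sample(AA_ALPHABET[1:20], length(code_pos), TRUE))
    names(codes) <- FIXTURE_SUBSTRATES
    apply_code <- function(base, code) {
      v <- strsplit(base, "")[[1]]; v[code_pos] <- code; paste(v, collapse = "")
    }
    a_variant <- function(substrate, rate = 0.06) {
      mutate_protein(apply_code(motifs$A, codes[[substrate]]),
                     rate = rate, keep = code_pos)
    }

    # the training families carry a wider mutation spread (10%) than the
    # planted genome instances (2%), so the calibrated minimum-self-score
    # thresholds retain fresh instances
    train_rate <- 0.10
    dom_rows <- list()
    for (lab in c("C", "PCP", "TE")) {
      dom_rows[[lab]] <- data.frame(
        id = paste0(lab, "_", seq_len(n_domain_seqs)),
        sequence = vapply(seq_len(n_domain_seqs),
                          function(i) mutate_protein(motifs[[lab]], train_rate), ""),
        label = lab, stringsAsFactors = FALSE)
    }
    # the A family mixes all substrate classes so one profile detects all
    dom_rows[["A"]] <- data.frame(
      id = paste0("A_", seq_len(n_domain_seqs)),
      sequence = vapply(seq_len(n_domain_seqs), function(i)
        a_variant(FIXTURE_SUBSTRATES[(i %% length(FIXTURE_SUBSTRATES)) + 1L],
                  train_rate), ""),
      label = "A", stringsAsFactors = FALSE)
    dt <- do.call(rbind, dom_rows)
    domain_train <- labeled_domain_set(dt$sequence, dt$label, dt$id)

    # (c) substrate training set (A-domain variants, separable by code)
    st <- do.call(rbind, lapply(FIXTURE_SUBSTRATES, function(s) data.frame(
      id = paste0("sub_", s, "_", seq_len(n_substrate_seqs)),
      sequence = vapply(seq_len(n_substrate_seqs), function(i) a_variant(s), ""),
      label = s, stringsAsFactors = FALSE)))
    substrate_train <- labeled_domain_set(st$sequence, st$label, st$id)

    # (b) toy genome: three adjacent genes carrying the planted modules,
    # plus one distant background gene without biosynthetic domains
    # genome instances sit closer to the motif than the training spread so
    # that the calibrated (minimum-self-score) thresholds retain them
    linker <- "GSGSGS"
    g_rate <- 0.02
    gmut <- function(s) mutate_protein(s, rate = g_rate)
    gene_seq <- list(
      g1 = paste0(a_variant("G", g_rate), linker, gmut(motifs$PCP)),
      g2 = paste0(gmut(motifs$C), linker, a_variant("A", g_rate), linker,
                  gmut(motifs$PCP)),
      g3 = paste0(gmut(motifs$C), linker, a_variant("V", g_rate), linker,
                  gmut(motifs$PCP), linker, gmut(motifs$TE)),
      bg = random_protein(120L))
    lens <- vapply(gene_seq, nchar, 1L) * 3L
    starts <- c(1000L, 0L, 0L, 0L)
    starts[2] <- starts[1] + lens[1] + 200L
    starts[3] <- starts[2] + lens[2] + 200L
    starts[4] <- starts[3] + lens[3] + 60000L  # outside any cluster window
    genome <- protein_records(names(gene_seq), unlist(gene_seq),
                              genomic_start = starts,
                              genomic_end = starts + lens, strand = "+")

    # (d) true scaffold (by construction) and a decoy library
    chem <- load_chemistry_table()
    block_for <- function(substrate, loading = FALSE, terminal = "none") {
      m <- new_module(if (loading) c("A", "PCP")
                      else c("C", "A", "PCP", if (terminal == "TE") "TE"))
      m <- classify_module(m)
      m$terminal <- terminal
      module_to_building_block(m, substrate, chem)
    }
    true_chain <- list(block_for("G", loading = TRUE),
                       block_for("A"),
                       block_for("V", terminal = "TE"))
    true_smiles <- assemble_chain(true_chain)
    decoy_tripeptides <- list(c("L", "S", "T"), c("F", "G", "K"),
                              c("S", "S", "A"), c("T", "P", "G"),
                              c("V", "A", "G"), c("A", "V", "L"))
    decoys <- vapply(decoy_tripeptides, function(ss)
      assemble_chain(list(block_for(ss[1], loading = TRUE), block_for(ss[2]),
                          block_for(ss[3], terminal = "TE"))), "")
    misc <- c("CC(=O)Oc1ccccc1C(O)=O", "ClCc1ccc(Cl)cc1", "C1CCCO1",
              "CC1CCCC(C)O1", "OCC1OC(O)C(O)C(O)C1O", "O=[N+]([O-])c1ccccc1",
              "CCSSCC", "CCCCCCCC(O)=O", "CC(C)CC(N)C(O)=O",
              "c1ccc2[nH]ccc2c1", "CC(=O)NC1OC(CO)C(O)C(O)C1O",
              "CCOC(=O)CC(C)C", "Oc1ccc(CC(N)C(O)=O)cc1",
              "CC(O)C(N)C(O)=O", "NC(CO)C(O)=O", "CCC(C)(O)CC(O)=O",
              "CC(C)C(N)C(O)=O", "OC(=O)CCC(=O)C(O)=O")
    library_df <- data.frame(
      id = c("true_product", paste0("decoy", seq_along(c(decoys, misc)))),
      smiles = c(true_smiles, decoys, misc),
      source = "fixture", stringsAsFactors = FALSE)

    # (e) domain-count / PSM table with a planted linear relation
    x <- stats::rpois(n_psm_clusters, 2)
    y <- pmax(0L, as.integer(round(psm_beta * x + stats::rnorm(n_psm_clusters, 0, 0.5))))
    psm_table <- data.frame(cluster_id = paste0("bgc", seq_len(n_psm_clusters)),
                            domain_count = x, psm_count = y,
                            stringsAsFactors = FALSE)

    bundle <- list(domain_train = domain_train,
                   substrate_train = substrate_train, genome = genome,
                   true_substrates = FIXTURE_SUBSTRATES,
                   true_smiles = true_smiles, library = library_df,
                   psm_table = psm_table, psm_beta = psm_beta, seed = seed)

    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(
        domain_fasta = file.path(dir, "domain_train.fasta"),
        substrate_fasta = file.path(dir, "substrate_train.fasta"),
        genome_gb = file.path(dir, "genome.gb"),
        library_smi = file.path(dir, "library.smi"),
        psm_tsv = file.path(dir, "psm_table.tsv"))
      write_fasta(stats::setNames(domain_train$sequence,
                                  paste0(domain_train$id, "|", domain_train$label)),
                  paths$domain_fasta)
      write_fasta(stats::setNames(substrate_train$sequence,
                                  paste0(substrate_train$id, "|", substrate_train$label)),
                  paths$substrate_fasta)
      write_genbank(genome, paths$genome_gb, name = "fixture")
      writeLines(paste0(library_df$smiles, "\t", library_df$id), paths$library_smi)
      write_tsv(psm_table, paths$psm_tsv)
      bundle$paths <- paths
    }
    bundle
  })
}

#' Build a ready-to-run pipeline configuration from a fixture bundle
#'
#' Trains profiles (with calibrated thresholds) on the bundle's labelled
#' domains, a substrate model on its training set, ingests its compound
#' library and wires everything into a [pipeline_config()]. This step runs
#' MAFFT and HMMER.
#'
#' @param fx a [generate_fixtures()] bundle.
#' @param seed seed forwarded to the trained components.
#' @return a `pipeline_config`.
#' @export
build_fixture_config <- function(fx, seed = fx$seed) {
  aligner <- mafft_aligner()
  profiles <- build_profiles(fx$domain_train, aligner)
  profiles <- calibrate_thresholds(profiles, fx$domain_train)
  aln <- align_labeled_set(fx$substrate_train, aligner,
                           min_per_label = 2L)
  a_model <- train_substrate_model(aln, default_rf_params("A"), seed = seed,
                                   aligner = aligner)
  db <- ingest_library(fx$library)
  pipeline_config(profiles, a_model = a_model, db = db, seed = seed)
}

#' Generate a block-order recovery fixture
#'
#' Builds `k` module blocks (a loading block first, a terminal block last),
#' records their true concatenated domain string as the single reference
#' entry, and returns the blocks in shuffled order.
#'
#' @param seed seed.
#' @param k number of blocks (2..4 are typical).
#' @return list with `$blocks` (shuffled), `$refdb`, `$true_domains`
#'   (character vector: the domain string of the true order).
#' @export
generate_order_fixture <- function(seed = 1L, k = 3L) {
  stopifnot(k >= 2L)
  with_seed(seed, {
    middle_pool <- list(c("C", "A", "PCP"), c("KS", "AT", "KR", "ACP"),
                        c("KS", "AT", "DH", "KR", "ACP"),
                        c("C", "A", "nMT", "PCP"), c("KS", "AT", "ACP"))
    arrangements <- vector("list", k)
    arrangements[[1L]] <- list(c("A", "PCP"))
    if (k > 2L) for (i in 2L:(k - 1L))
      arrangements[[i]] <- middle_pool[sample(length(middle_pool),
                                              sample(1:2, 1), replace = TRUE)]
    arrangements[[k]] <- list(c("C", "A", "PCP", "TE"))
    pos <- 0L
    blocks <- lapply(seq_len(k), function(i) {
      mods <- lapply(arrangements[[i]], function(d) {
        m <- new_module(d, genomic_start = pos, genomic_end = pos + 300L)
        pos <<- pos + 100000L  # far apart: blocks stay separate genomically
        classify_module(m)
      })
      new_block(loading_terminal_flags(mods))
    })
    true_domains <- unlist(lapply(blocks, `[[`, "domains"))
    refdb <- structure(list(list(id = "true", domains = true_domains)),
                       class = "reference_block_db")
    shuffled <- blocks[sample(k)]
    list(blocks = shuffled, refdb = refdb, true_domains = true_domains)
  })
}
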