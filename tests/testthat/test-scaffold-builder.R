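# Building-block generation and scaffold assembly.

chem_tab <- load_chemistry_table()

block_of <- function(domains, substrate, terminal = "none") {
  m <- make_module(domains)
  if (terminal != "none") m$terminal <- terminal
  module_to_building_block(m, substrate, chem_tab)
}

test_that("the chemistry table covers every classifier substrate label", {
  expect_true(all(c("malonyl", "methylmalonyl", "ethylmalonyl",
                    "methoxymalonyl", "generic") %in% chem_tab$label))
  # the 29 amino/aryl acid classes
  aa29 <- c("A","C","D","E","F","G","H","I","K","L","N","P","Q","R","S","T",
            "V","W","Y","aad","bht","dab","dhb","dhbu","dhpg","horn","hpg",
            "orn","pip")
  expect_true(all(aa29 %in% chem_tab$label))
  # every fragment yields a parseable building block in a minimal chain
  for (lab in aa29) {
    b <- block_of(if (lab == "dhb") c("A","PCP") else c("C","A","PCP"), lab,
                  terminal = "TE")
    expect_silent(smi <- assemble_chain(list(b)))
    expect_true(nzchar(smi), label = lab)
  }
})

test_that("a glycine-alanine dipeptide assembles to the hand-drawn structure", {
  chain <- list(block_of(c("A", "PCP"), "G"),
                block_of(c("C", "A", "PCP", "TE"), "A", terminal = "TE"))
  expect_identical(assemble_chain(chain),
                   canonical_smiles("NCC(=O)N[C@@H](C)C(=O)O"))
})

test_that("a single loading module with TE yields the substrate acid alone", {
  expect_identical(assemble_chain(list(block_of(c("A","PCP"), "G", "TE"))),
                   canonical_smiles("NCC(=O)O"))
  # aryl starter acid
  expect_identical(assemble_chain(list(block_of(c("A","PCP"), "dhb", "TE"))),
                   canonical_smiles("OC(=O)c1cccc(O)c1O"))
})

test_that("methylmalonyl with a cMT gives a doubly methylated alpha carbon", {
  b <- block_of(c("KS","AT","cMT","ACP"), "methylmalonyl")
  expect_identical(b$alpha_methyls, 2L)
  # double methylation excludes enoyl/alkyl reduction states
  b2 <- block_of(c("KS","AT","DH","cMT","KR","ACP"), "methylmalonyl")
  expect_identical(b2$alpha_methyls, 2L)
  expect_identical(b2$own_reduction, "hydroxyl")
})

test_that("an oMT module installs a beta methoxy group", {
  b <- block_of(c("KS","AT","oMT","KR","ACP"), "malonyl")
  expect_identical(b$own_reduction, "methoxy")
  chain <- list(block_of(c("KSQ","AT","ACP"), "malonyl"),
                block_of(c("KS","AT","oMT","KR","ACP","TE"), "malonyl", "TE"))
  smi <- assemble_chain(chain)
  expect_identical(smi, canonical_smiles("CC(OC)CC(=O)O"))
})

test_that("reduction states land on the previous block", {
  chain <- list(block_of(c("KSQ","AT","ACP"), "malonyl"),
                block_of(c("KS","AT","DH","KR","ACP"), "malonyl"),
                block_of(c("KS","AT","DH","ER","KR","ACP","TE"), "malonyl", "TE"))
  shifted <- apply_previous_block_rule(chain)
  expect_identical(vapply(shifted, `[[`, "", "beta_state"),
                   c("enoyl", "alkyl", "terminal"))
  # loading block alone: nothing upstream to shift onto
  single <- apply_previous_block_rule(list(block_of(c("A","PCP"), "G", "TE")))
  expect_identical(single[[1]]$beta_state, "terminal")
  # assembled: CH3-CH=CH-CH2-CH2-COOH
  expect_identical(assemble_chain(chain), canonical_smiles("CC=CCCC(=O)O"))
})

test_that("epimerization flips the alpha stereocenter to the D form", {
  l_form <- assemble_chain(list(block_of(c("A","PCP"), "G"),
                                block_of(c("C","A","PCP","TE"), "V", "TE")))
  m <- make_module(c("C","A","PCP","E"))
  m$terminal <- "TE"
  m$epimerized <- TRUE
  d_block <- module_to_building_block(m, "V", chem_tab)
  d_form <- assemble_chain(list(block_of(c("A","PCP"), "G"), d_block))
  expect_identical(d_block$alpha_stereo, "D")
  expect_false(identical(l_form, d_form))
  expect_identical(d_form, canonical_smiles("NCC(=O)N[C@H](C(C)C)C(=O)O"))
})

test_that("N-methylation adds exactly one carbon", {
  plain <- assemble_chain(list(block_of(c("A","PCP"), "G"),
                               block_of(c("C","A","PCP","TE"), "A", "TE")))
  nme <- assemble_chain(list(block_of(c("A","PCP"), "G"),
                             block_of(c("C","A","nMT","PCP","TE"), "A", "TE")))
  expect_identical(heavy_atom_count(nme), heavy_atom_count(plain) + 1L)
})

test_that("assembly is deterministic, canonical and round-trips", {
  chain <- list(block_of(c("A","PCP"), "S"),
                block_of(c("C","A","PCP"), "L"),
                block_of(c("C","A","PCP","TE"), "W", "TE"))
  s1 <- assemble_chain(chain); s2 <- assemble_chain(chain)
  expect_identical(s1, s2)
  expect_identical(canonical_smiles(s1), s1)
})

test_that("heavy atoms add up across condensations", {
  # amide condensations: no heavy atom is lost relative to the block
  # emissions; assembled atom count equals the sum of per-block emissions
  blocks <- list(block_of(c("A","PCP"), "G"),
                 block_of(c("C","A","PCP"), "A"),
                 block_of(c("C","A","PCP","TE"), "V", "TE"))
  assembled <- assemble_chain(blocks)
  # per-residue heavy atoms: gly N,CA,C,O = 4; ala 5; val (+COOH O) 8
  expect_identical(heavy_atom_count(assembled), 4L + 5L + 8L)
})

test_that("special modules without substrate predictions use the generic block", {
  m <- make_module(c("KS","tAT_d","KR","ACP"))
  b <- module_to_building_block(m, NULL, chem_tab)
  expect_identical(b$substrate, "generic")
  # NRPS modules require a prediction
  expect_error(module_to_building_block(make_module(c("C","A","PCP")), NULL,
                                        chem_tab), "substrate")
  # unknown label errors by name
  expect_error(module_to_building_block(make_module(c("C","A","PCP")),
                                        "nosuch", chem_tab), "nosuch")
  # non-functional modules yield no block
  expect_error(module_to_building_block(make_module(c("C","PCP")), "G",
                                        chem_tab), "normal/special")
})

test_that("scaffolds keep one fragment per disconnected chain", {
  sc <- assemble_scaffold(list(
    list(block_of(c("A","PCP"), "G", "TE")),
    list(block_of(c("KSQ","AT","ACP"), "malonyl"),
         block_of(c("KS","AT","ACP","TE"), "malonyl", "TE"))))
  expect_length(sc$fragments, 2L)
  expect_length(sc$psm_vector, 7L)
  expect_error(assemble_scaffold(list()), "at least one")
})
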