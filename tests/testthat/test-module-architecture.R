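# Module segmentation, classification and modification profiles.

TABLE2 <- list(
  list("C-A-PCP",               "normal",         "NRPS",  epi = FALSE),
  list("KS-AT-DH-KR-ACP",       "normal",         "PKS",   red = "enoyl"),
  list("KS-AT-KR-ACP",          "normal",         "PKS",   red = "hydroxyl"),
  list("C-A-PCP-E",             "normal",         "NRPS",  epi = TRUE),
  list("KS-AT-DH-ER-KR-ACP",    "normal",         "PKS",   red = "alkyl"),
  list("KS-AT-ACP",             "normal",         "PKS",   red = "ketone"),
  list("A-PCP",                 "normal",         "NRPS",  epi = FALSE),
  list("C-A-PCP-TE",            "normal",         "NRPS",  epi = FALSE),
  list("KS-tAT_d-KR-ACP",       "special",        "PKS",   red = "hydroxyl"),
  list("KS-tAT_d-DH-KR-ACP",    "special",        "PKS",   red = "enoyl"),
  list("C-A-nMT-PCP",           "normal",         "NRPS",  epi = FALSE),
  list("KS-tAT_d-ACP",          "special",        "PKS",   red = "alkyl"),
  list("cAL-ACP",               "non_functional", "PKS"),
  list("KS-AT-DH-KR-ACP-TE",    "normal",         "PKS",   red = "enoyl"),
  list("C-A-ACP",               "normal",         "mixed", epi = FALSE),
  list("C-PCP",                 "non_functional", "NRPS"),
  list("KS-ACP",                "special",        "PKS",   red = "ketone"),
  list("KS-tAT_d",              "special",        "PKS",   red = "ketone"),
  list("KS-AT",                 "special",        "PKS",   red = "ketone"),
  list("KS-tAT_d-DH-KR-cMT-ACP","special",        "PKS",   red = "enoyl"))

test_that("the 20 packaged arrangements reproduce their printed classification", {
  pat <- load_pattern_table()
  expect_identical(nrow(pat), 20L)
  for (row in TABLE2) {
    doms <- strsplit(row[[1]], "-", fixed = TRUE)[[1]]
    m <- make_module(doms)
    expect_identical(m$functional_class, row[[2]], label = row[[1]])
    expect_identical(m$type, row[[3]], label = row[[1]])
    if (!is.null(row$red))
      expect_identical(m$reduction, row$red, label = row[[1]])
    if (!is.null(row$epi))
      expect_identical(m$epimerized, row$epi, label = row[[1]])
  }
})

test_that("segmentation cuts after the carrier plus trailing E/TE/TD", {
  prot <- protein_records("p1", strrep("ACDEFGHIKL", 100))
  mods <- segment_into_modules(make_hits(c("C","A","PCP","C","A","PCP","E")), prot)
  expect_length(mods, 2L)
  expect_identical(mods[[1]]$domains, c("C", "A", "PCP"))
  expect_identical(mods[[2]]$domains, c("C", "A", "PCP", "E"))

  mods2 <- segment_into_modules(make_hits(c("KS","AT","DH","KR","ACP","TE")), prot)
  expect_length(mods2, 1L)
  expect_identical(mods2[[1]]$domains, c("KS","AT","DH","KR","ACP","TE"))

  expect_length(segment_into_modules(make_hits(character(0))[0, ], prot), 0L)
})

test_that("segmentation is a partition of the input hits", {
  pool <- c("C","A","PCP","KS","AT","KR","DH","ACP","TE","E","nMT","cMT")
  for (seed in 1:5) {
    doms <- with_seed_local(seed, sample(pool, 15, TRUE))
    prot <- protein_records("p1", strrep("ACDEFGHIKL", 200))
    mods <- segment_into_modules(make_hits(doms), prot)
    expect_identical(unlist(lapply(mods, `[[`, "domains")),
                     bgcscaffold:::normalize_domain(doms))
  }
})

test_that("dangling cross-gene modules merge when the merge is a normal module", {
  prot <- protein_records(c("g1", "g2"),
                          c(strrep("ACDEFGHIKL", 40), strrep("ACDEFGHIKL", 40)),
                          genomic_start = c(0L, 1300L),
                          genomic_end = c(1200L, 2500L))
  hits <- rbind(make_hits(c("KS", "AT"), "g1"),
                make_hits(c("KR", "ACP"), "g2"))
  class(hits) <- c("domain_hits", "data.frame")
  mods <- segment_into_modules(hits, prot)
  expect_length(mods, 1L)
  expect_identical(mods[[1]]$domains, c("KS", "AT", "KR", "ACP"))
  expect_identical(classify_module(mods[[1]])$functional_class, "normal")

  # far-apart genes do not merge
  prot2 <- prot; prot2$genomic_start[2] <- 40000L; prot2$genomic_end[2] <- 41200L
  mods2 <- segment_into_modules(hits, prot2)
  expect_length(mods2, 2L)
})

test_that("reduction profiles follow the domain combinations", {
  expect_identical(reduction_profile(c("KS","AT","ACP")), "ketone")
  expect_identical(reduction_profile(c("KS","AT","KR","ACP")), "hydroxyl")
  expect_identical(reduction_profile(c("KS","AT","DH","KR","ACP")), "enoyl")
  expect_identical(reduction_profile(c("KS","AT","DH","ER","KR","ACP")), "alkyl")
  expect_identical(reduction_profile(c("KS","AT","DH","ACP")), "ketone_star")
  expect_identical(reduction_profile(c("KS","AT","ER","ACP")), "ketone_star")
  # dehydratase variants count as DH
  expect_identical(reduction_profile(c("KS","AT","DH2","KR","ACP")), "enoyl")
  expect_identical(reduction_profile(c("KS","AT","DHt","KR","ACP")), "enoyl")
})

test_that("a module with DH but no KR is special (reduction impossible)", {
  m <- make_module(c("KS", "AT", "DH", "ACP"))
  expect_identical(m$functional_class, "special")
  expect_identical(m$reduction, "ketone_star")
})

test_that("methyltransferase placement rules assign the right modification", {
  m <- make_module(c("KS","AT","DH","cMT","KR","ACP"))
  expect_identical(m$methylation, "alpha")
  expect_false(m$trans_at)

  # cMT after the reductions without a cis AT marks a trans-AT module
  m2 <- make_module(c("KS","DH","KR","cMT","ACP"))
  expect_identical(m2$methylation, "alpha")
  expect_true(m2$trans_at)
  expect_identical(m2$functional_class, "special")

  m3 <- make_module(c("C","A","nMT","PCP"))
  expect_identical(m3$methylation, "N_methyl")

  # cMT between AT and carrier without reduction domains: cis methylation
  m4 <- make_module(c("KS","AT","cMT","ACP"))
  expect_identical(m4$methylation, "alpha")

  # oMT only acts on the plain hydroxyl (KR-only) state
  m5 <- make_module(c("KS","AT","oMT","KR","ACP"))
  expect_identical(m5$methylation, "O_methyl")
  m6 <- make_module(c("KS","AT","oMT","ACP"))
  expect_identical(m6$methylation, "none")

  # an NRPS cMT has no general rule
  m7 <- make_module(c("C","A","cMT","PCP"))
  expect_identical(m7$methylation, "none")
})

test_that("loading and terminal flags follow the presence rules", {
  expect_true(make_module(c("A","PCP"))$loading)
  expect_true(make_module(c("KSQ","AT","ACP"))$loading)
  expect_false(make_module(c("KS","AT","ACP"))$loading)
  m <- make_module(c("C","A","PCP","TE"))
  expect_identical(m$terminal, "TE")
  expect_false(m$loading)
  expect_identical(make_module(c("C","A","PCP"))$terminal, "none")
  expect_identical(make_module(c("KS","AT","ACP","TD"))$terminal, "TD")
})

test_that("classification rejects unknown labels and is order-independent", {
  expect_error(classify_module(bgcscaffold:::new_module(c("KS", "FOO"))), "FOO")
  # classification depends only on the module's own domains
  m1 <- make_module(c("C","A","PCP"), start = 0L)
  m2 <- make_module(c("C","A","PCP"), start = 99999L, strand = "-")
  expect_identical(m1$functional_class, m2$functional_class)
  expect_identical(m1$type, m2$type)
})

test_that("minus-strand gene runs are traversed in translation order", {
  # two minus-strand genes: translation order is reverse genomic order
  prot <- protein_records(c("g1", "g2"),
                          rep(strrep("ACDEFGHIKL", 40), 2),
                          genomic_start = c(0L, 1300L),
                          genomic_end = c(1200L, 2500L), strand = "-")
  hits <- rbind(make_hits(c("A", "PCP"), "g2"),
                make_hits(c("C", "A", "PCP", "TE"), "g1"))
  class(hits) <- c("domain_hits", "data.frame")
  mods <- segment_into_modules(hits, prot)
  expect_identical(lapply(mods, `[[`, "domains"),
                   list(c("A", "PCP"), c("C", "A", "PCP", "TE")))
})
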