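# Profile-HMM construction, threshold calibration and protein scanning.

test_that("profile construction validates its input", {
  expect_error(build_profiles(labeled_domain_set("ACDEF", "KS")),
               "fewer than 2.*KS")
  empty <- labeled_domain_set(character(0), character(0))
  expect_length(build_profiles(empty), 0L)
})

test_that("toy motif families give self-preferring, calibrated profiles", {
  fx <- fixture_bundle()
  cfg <- fixture_config()
  profiles <- cfg$profiles
  expect_setequal(names(profiles), c("A", "C", "PCP", "TE"))
  expect_true(all(vapply(profiles, `[[`, 1, "threshold") > 0))

  # rescanning the calibration set yields recall 1 per label, and every
  # retained hit satisfies its threshold
  prot <- protein_records(fx$domain_train$id, fx$domain_train$sequence)
  hits <- scan_proteins(prot, profiles)
  for (lab in names(profiles)) {
    ids <- fx$domain_train$id[fx$domain_train$label == lab]
    found <- hits$protein_id[hits$domain == lab]
    expect_true(all(ids %in% found), label = paste("recall 1 for", lab))
  }
  thr <- vapply(profiles, `[[`, 1, "threshold")
  expect_true(all(hits$bit_score >= thr[hits$domain] - 1e-9))

  # each profile scores its own family higher than foreign families
  for (lab in names(profiles)) {
    own <- hits[hits$domain == lab, ]
    own_ids <- fx$domain_train$id[fx$domain_train$label == lab]
    expect_true(all(own$protein_id %in% own_ids))
  }
})

test_that("scan output is deterministic and ordered by genomic position", {
  fx <- fixture_bundle()
  cfg <- fixture_config()
  h1 <- scan_proteins(fx$genome, cfg$profiles)
  h2 <- scan_proteins(fx$genome, cfg$profiles)
  expect_identical(h1, h2)
  pos <- stats::setNames(fx$genome$genomic_start, fx$genome$id)
  expect_true(!is.unsorted(pos[h1$protein_id]))
  # within a protein, hits are ordered by domain start
  for (p in unique(h1$protein_id))
    expect_true(!is.unsorted(h1$seq_start[h1$protein_id == p]))
  # no proteins -> no hits, not an error
  expect_identical(nrow(scan_proteins(fx$genome[0, ], cfg$profiles)), 0L)
})

test_that("a protein concatenating two motifs yields two ordered hits", {
  fx <- fixture_bundle()
  cfg <- fixture_config()
  # g1 was planted as A followed by PCP
  hits <- scan_proteins(fx$genome[fx$genome$id == "g1", ], cfg$profiles)
  expect_identical(hits$domain, c("A", "PCP"))
  expect_lt(hits$seq_end[1], hits$seq_start[2] + 1L)
})

test_that("raising a threshold above the observed score discards the hit", {
  fx <- fixture_bundle()
  cfg <- fixture_config()
  g1 <- fx$genome[fx$genome$id == "g1", ]
  hits <- scan_proteins(g1, cfg$profiles)
  a_score <- hits$bit_score[hits$domain == "A"]
  profiles <- cfg$profiles
  profiles[["A"]]$threshold <- a_score + 0.1
  expect_false("A" %in% scan_proteins(g1, profiles)$domain)
  profiles[["A"]]$threshold <- a_score - 0.1
  expect_true("A" %in% scan_proteins(g1, profiles)$domain)
})

test_that("overlapping hits keep the higher score, ties break alphabetically", {
  h <- data.frame(protein_id = "p", domain = c("KS", "AT"),
                  seq_start = c(0L, 10L), seq_end = c(100L, 110L),
                  bit_score = c(50, 40), stringsAsFactors = FALSE)
  kept <- bgcscaffold:::resolve_overlaps(h)
  expect_identical(kept$domain, "KS")
  h$bit_score <- c(40, 40)  # tie: alphabetical
  expect_identical(bgcscaffold:::resolve_overlaps(h)$domain, "AT")
  # overlap below half the shorter hit: both kept
  h2 <- data.frame(protein_id = "p", domain = c("KS", "AT"),
                   seq_start = c(0L, 70L), seq_end = c(100L, 200L),
                   bit_score = c(50, 40), stringsAsFactors = FALSE)
  expect_identical(nrow(bgcscaffold:::resolve_overlaps(h2)), 2L)
})

test_that("single-sequence calibration sets the threshold to the self-score", {
  fx <- fixture_bundle()
  cfg <- fixture_config()
  one <- fx$domain_train[fx$domain_train$label == "TE", ][1L, ]
  class(one) <- class(fx$domain_train)
  cal <- calibrate_thresholds(cfg$profiles["TE"], one)
  # the threshold equals the score the profile assigns to that sequence
  p <- protein_records(one$id, one$sequence)
  prof0 <- cfg$profiles["TE"]; prof0[["TE"]]$threshold <- 0
  class(prof0) <- "domain_profile_set"
  h <- scan_proteins(p, prof0)
  expect_equal(cal[["TE"]]$threshold, max(h$bit_score))
})

test_that("an external KSQ profile defaults to the KS threshold", {
  profs <- structure(list(KS = list(name = "KS", hmm = "x", threshold = 72)),
                     class = "domain_profile_set")
  profs <- add_ksq_profile(profs, hmm = "y")
  expect_equal(profs[["KSQ"]]$threshold, 72)
  expect_equal(add_ksq_profile(profs, hmm = "y", threshold = 10)[["KSQ"]]$threshold, 10)
})

test_that("cross-validation separates distinct families and pools the confusion", {
  fx <- fixture_bundle()
  sub <- fx$domain_train[fx$domain_train$label %in% c("C", "PCP", "TE"), ]
  class(sub) <- class(fx$domain_train)
  cv <- crossvalidate_profiles(sub, k = 4L, seed = 3L)
  expect_true(all(cv$metrics$per_class$f1 == 1))
  expect_error(crossvalidate_profiles(sub, k = 1L), "k must be")

  # per-class metrics equal an independent tally of the pooled confusion
  conf <- cv$confusion
  for (cl in rownames(conf)) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    prec <- tp / max(1, tp + fp); rec <- tp / max(1, tp + fn)
    row <- cv$metrics$per_class[cv$metrics$per_class$class == cl, ]
    expect_equal(row$precision, prec, tolerance = 1e-12)
    expect_equal(row$recall, rec, tolerance = 1e-12)
  }
})

test_that("near-identical families confuse only with each other", {
  # carrier-domain analogue: two families two mutations apart, one distinct
  fx <- fixture_bundle()
  base <- with_seed_local(11L, paste(sample(c("A","C","D","E","F","G","H","I",
    "K","L","M","N","P","Q","R","S","T","V","W","Y"), 60, TRUE), collapse = ""))
  twin <- sub("^(..)", "WW", base)
  mut <- function(s, seed) with_seed_local(seed, {
    v <- strsplit(s, "")[[1]]
    i <- sample(length(v), 3)
    v[i] <- sample(c("A","G","S","T"), 3, TRUE)
    paste(v, collapse = "")
  })
  n <- 8L
  c_seqs <- fx$domain_train$sequence[fx$domain_train$label == "C"][1:n]
  labeled <- labeled_domain_set(
    c(vapply(1:n, function(i) mut(base, i), ""),
      vapply(1:n, function(i) mut(twin, 100 + i), ""),
      c_seqs),
    c(rep("ACP", n), rep("bACP", n), rep("C", n)))
  cv <- crossvalidate_profiles(labeled, k = 4L, seed = 5L)
  conf <- cv$confusion
  # the distinct family stays clean
  expect_equal(unname(conf["C", "C"]), n)
  # misclassifications, if any, stay within the confusable pair
  off <- conf[rownames(conf) != "C", setdiff(colnames(conf), c("C")), drop = FALSE]
  total_errors <- sum(conf) - sum(diag(conf[, rownames(conf)]))
  pair_errors <- sum(off) - sum(diag(off[, rownames(off)]))
  expect_equal(total_errors, pair_errors)
})

test_that("profile sets round-trip through the HMMER3 + sidecar format", {
  cfg <- fixture_config()
  hmm <- tempfile(fileext = ".hmm"); thr <- tempfile(fileext = ".tsv")
  write_profiles(cfg$profiles, hmm, thr)
  back <- read_profiles(hmm, thr)
  expect_setequal(names(back), names(cfg$profiles))
  expect_equal(vapply(back, `[[`, 1, "threshold"),
               vapply(cfg$profiles, `[[`, 1, "threshold")[names(back)])
})

test_that("packaged default thresholds cover the core domains", {
  thr <- default_domain_thresholds()
  expect_equal(thr$domT[thr$name == "ACP"], 13.9)
  expect_equal(thr$domT[thr$name == "AT"], 47.4)
  expect_equal(thr$domT[thr$name == "KS"], 72)
  expect_equal(thr$domT[thr$name == "KSQ"], thr$domT[thr$name == "KS"])
  expect_gte(nrow(thr), 20L)
  expect_true(all(thr$domT >= 0))
})
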