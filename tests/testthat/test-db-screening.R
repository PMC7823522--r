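# Library ingestion, similarity search, scoring and ranking.

tiny_db <- function() {
  ingest_library(data.frame(
    id = c("ethanol", "benzene", "glycylalanine", "thf", "dcl"),
    smiles = c("CCO", "c1ccccc1", "NCC(=O)NC(C)C(=O)O", "C1CCCO1", "ClCCCl")))
}

test_that("ingestion collapses duplicates and skips invalid records", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("OCC\ta", "C(O)C\tb", "xxx((\tc", "c1ccccc1\td"), f)
  expect_message(db <- ingest_library(f), "1 invalid")
  expect_identical(nrow(db$records), 2L)  # a == b canonically
  expect_length(db$fingerprints, 2L)
  expect_identical(ncol(db$psm), 7L)

  empty <- tempfile(fileext = ".smi"); writeLines(character(0), empty)
  expect_error(ingest_library(empty), "no molecules")
})

test_that("similarity search puts an identical molecule first with score 1", {
  db <- tiny_db()
  top <- tanimoto_topn("NCC(=O)NC(C)C(=O)O", db, n = 3L)
  expect_identical(top$id[1], "glycylalanine")
  expect_equal(top$similarity[1], 1)
  # db smaller than N: everything comes back
  expect_identical(nrow(tanimoto_topn("CCO", db, n = 50L)), 5L)
  # a molecule sharing no bits scores 0
  s_row <- tanimoto_topn("S", db, n = 5L)
  expect_true(all(s_row$similarity == 0))
})

test_that("similarity ranking is invariant to database insertion order", {
  a <- ingest_library(data.frame(id = c("x", "y", "z"),
                                 smiles = c("CCO", "CCN", "CCC")))
  b <- ingest_library(data.frame(id = c("z", "x", "y"),
                                 smiles = c("CCC", "CCO", "CCN")))
  ta <- tanimoto_topn("CCO", a); tb <- tanimoto_topn("CCO", b)
  expect_identical(ta$id, tb$id)
  expect_equal(ta$similarity, tb$similarity)
})

test_that("Bray-Curtis similarity meets its contract", {
  expect_equal(bray_curtis_similarity(c(2,1,0), c(2,1,0)), 1)
  expect_equal(bray_curtis_similarity(c(1,0), c(0,1)), 0)
  expect_equal(bray_curtis_similarity(2, 1), 2/3)
  expect_equal(bray_curtis_similarity(c(0,0), c(0,0)), 1)
  for (seed in 1:6) {
    uv <- with_seed_local(seed, list(u = rpois(7, 2), v = rpois(7, 2)))
    s <- bray_curtis_similarity(uv$u, uv$v)
    expect_identical(s, bray_curtis_similarity(uv$v, uv$u))
    expect_gte(s, 0); expect_lte(s, 1)
    if (s == 1 && sum(uv$u + uv$v) > 0) expect_identical(uv$u, uv$v)
  }
})

test_that("the mixed score is a weighted sum, monotone in each component", {
  expect_equal(mixed_score(0.7, 0.2, 0.9, list(a = 1, b = 0, c = 0)), 0.7)
  expect_equal(mixed_score(1, 1, 1, list(a = 0.3, b = 0.4, c = 0.1)), 0.8)
  w <- default_weights("All")
  expect_equal(unlist(w), c(a = 0.3, b = 0.4, c = 0.1))
  expect_equal(mixed_score(0.5, 0.5, 0.5, w), 0.5 * 0.8)
  expect_gte(mixed_score(0.6, 0.5, 0.5, w), mixed_score(0.5, 0.5, 0.5, w))
  expect_error(mixed_score(1, 1, 1, list(a = -0.1, b = 0.5, c = 0)), "nonnegative")
  expect_error(mixed_score(1, 1, 1, list(a = 0, b = 0, c = 0)), "positive")
  # per-type defaults are available
  expect_equal(unlist(default_weights("NRPS")), c(a = 1, b = 0.4, c = 0.5))
})

test_that("screening ranks an exact match first, ties share the best rank", {
  db <- tiny_db()
  res <- screen_scaffold("NCC(=O)NC(C)C(=O)O", db, n_preselect = 5L)
  expect_identical(res$id[1], "glycylalanine")
  expect_identical(res$rank[1], 1L)
  expect_true(all(diff(res$rank) >= 0))
  # constant scores: everything ties at rank 1
  expect_identical(bgcscaffold:::tied_rank(c(1, 1, 1)), rep(1L, 3))
  expect_identical(bgcscaffold:::tied_rank(c(3, 2, 2, 1)), c(1L, 2L, 2L, 4L))
})

test_that("rank benchmark counts top-k fractions and excludes missing products", {
  db <- tiny_db()
  preds <- list(list(fragments = "NCC(=O)NC(C)C(=O)O", true_id = "glycylalanine"),
                list(fragments = "CCO", true_id = "ethanol"))
  bm <- rank_benchmark(preds, db)
  expect_identical(unname(bm$ranks), c(1L, 1L))
  expect_equal(bm$top10, 1)
  expect_warning(bm2 <- rank_benchmark(
    c(preds, list(list(fragments = "CC", true_id = "absent"))), db), "absent")
  expect_length(bm2$ranks, 2L)
  expect_error(suppressWarnings(
    rank_benchmark(list(list(fragments = "C", true_id = "no")), db)),
    "empty benchmark")
  # top-k fractions by direct counting
  ranks <- c(1L, 5L, 60L, 2L)
  expect_equal(mean(ranks <= 10), 0.75)
  expect_equal(mean(ranks <= 50), 0.75)
})

test_that("weight grid search finds the discriminating component", {
  # true product is fingerprint-identical; similarity separates it
  db <- tiny_db()
  preds <- list(list(fragments = "NCC(=O)NC(C)C(=O)O", true_id = "glycylalanine"))
  gs <- grid_search_weights(preds, db, step = 0.5)
  expect_equal(gs$top10, 1)
  expect_identical(nrow(gs$results), 26L)  # 3^3 weight grid minus all-zero
  best_rows <- gs$results[gs$results$top10 == gs$top10, ]
  ord <- order(best_rows$a, best_rows$b, best_rows$c)
  expect_equal(unlist(gs$best), unlist(best_rows[ord[1], c("a","b","c")]))
  expect_error(grid_search_weights(list(), db), "empty")
})

test_that("SDF libraries are ingested like SMILES libraries", {
  smi <- c(one = "CCO", two = "c1ccccc1")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))
  f <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, f)
  db <- ingest_library(f)
  expect_identical(nrow(db$records), 2L)
  expect_setequal(db$records$canonical, canonical_smiles(smi))
})
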