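test_that("hypergeometric tail matches exhaustive enumeration and handles edges", {
  # edges
  expect_equal(hypergeometric_tail(0, 4, 5, 20), 1.0)
  expect_equal(hypergeometric_tail(5, 20, 5, 20), 1.0)  # forced full overlap
  expect_error(hypergeometric_tail(6, 4, 5, 20), "inconsistent")
  expect_error(hypergeometric_tail(2, 4, 25, 20), "inconsistent")
  # exhaustive enumeration over all C(20,4) draws
  expect_equal(hypergeometric_tail(3, 4, 5, 20), enumerate_tail(3, 4, 5, 20))
  expect_equal(hypergeometric_tail(2, 3, 6, 15), enumerate_tail(2, 3, 6, 15))
})

test_that("hypergeometric tail is non-increasing in the overlap", {
  for (cfg in list(c(4, 5, 20), c(6, 10, 30), c(3, 3, 12))) {
    tails <- vapply(0:min(cfg[1], cfg[2]), function(o)
      hypergeometric_tail(o, cfg[1], cfg[2], cfg[3]), 0)
    expect_true(all(diff(tails) <= 1e-12))
  }
})

test_that("enrich_feature handles saturation, zero overlap, and dropped genes", {
  universe <- paste0("G", 1:20)
  q <- gene_set("q", universe[1:4])
  # feature == universe: every draw saturates
  sat <- enrich_feature(q, gene_set("all", universe), universe,
                        n_resamples = 100, seed = 1)
  expect_equal(sat$observed_fraction, 1)
  expect_equal(sat$fold_enrichment, 1)
  expect_equal(sat$p_value, 1)
  # disjoint small feature: not enriched
  dis <- enrich_feature(q, gene_set("none", universe[15:17]), universe,
                        n_resamples = 500, seed = 1)
  expect_equal(dis$overlap_count, 0L)
  expect_lte(dis$fold_enrichment, 1)
  expect_gt(dis$p_value, 0.05)
  # genes outside the universe are dropped with a warning
  expect_warning(
    r <- enrich_feature(gene_set("q", c(universe[1:4], "NOTAGENE")),
                        gene_set("f", universe[1:2]), universe,
                        n_resamples = 100, seed = 1),
    "dropped")
  expect_equal(r$overlap_count, 2L)
  # errors
  expect_error(suppressWarnings(
    enrich_feature(gene_set("q", "NOTAGENE"),
                   gene_set("f", universe[1:2]), universe,
                   n_resamples = 100, seed = 1)),
    "no query genes")
  expect_error(enrich_feature(q, gene_set("f", universe[1:2]), universe,
                              n_resamples = 1, seed = 1), "at least 2")
})

test_that("resampling decision matches the exact hypergeometric tail on the worked case", {
  universe <- paste0("G", 1:20)
  feature <- gene_set("f", universe[1:5])
  query <- gene_set("q", universe[c(1, 2, 3, 10)])   # overlap 3 of 4
  r <- enrich_feature(query, feature, universe, n_resamples = 2000, seed = 1)
  exact <- enumerate_tail(3, 4, 5, 20)
  expect_lt(exact, 0.05)                  # the exact test rejects ...
  expect_lt(r$p_value, 0.05)              # ... and so does the resampling test
  expect_gt(r$fold_enrichment, 1)
})

test_that("profiles are deterministic and consistent between single and bulk paths", {
  u <- small_universe(seed = 11)
  p1 <- build_profile("disease", u$disease_genes, u$collection,
                      n_resamples = 300, seed = 99)
  p2 <- build_profile("disease", u$disease_genes, u$collection,
                      n_resamples = 300, seed = 99)
  expect_identical(p1, p2)

  profs <- build_profiles_bulk(u$chemical_table, u$collection,
                               n_resamples = 300, seed = 5,
                               progress_every = 0)
  chem <- names(profs)[3]
  alone <- build_profile(chem, u$chemical_table$chemicals[[chem]],
                         u$collection, n_resamples = 300,
                         seed = derive_seed(5, chem))
  expect_equal(profs[[chem]], alone)

  # enrich_feature reproduces a build_profile row with the same seed
  row <- alone$features[1, ]
  single <- enrich_feature(gene_set(chem, u$chemical_table$chemicals[[chem]]),
                           gene_set(row$feature,
                                    u$collection$sets[[row$feature]]),
                           u$collection$universe, n_resamples = 300,
                           seed = derive_seed(5, chem))
  expect_equal(single$p_value, row$p_value)
  expect_equal(single$overlap_count, row$overlap_count)
  expect_equal(single$fold_enrichment, row$fold_enrichment)
})

test_that("profile members are significant, enriched, and ordered by the contract", {
  u <- small_universe(seed = 3)
  profs <- build_profiles_bulk(u$chemical_table, u$collection,
                               n_resamples = 300, seed = 2,
                               progress_every = 0)
  expect_length(profs, 40)
  for (p in profs) {
    f <- p$features
    expect_true(all(f$p_value < p$alpha))
    expect_true(all(f$fold_enrichment > 1))
    expect_true(all(diff(f$p_value) >= 0))
    ties <- which(diff(f$p_value) == 0)
    expect_true(all(f$fold_enrichment[ties] >= f$fold_enrichment[ties + 1]))
    expect_true(all(f$overlap_count <=
                      pmin(p$n_query_genes,
                           lengths(u$collection$sets[f$feature]))))
    expect_identical(p$feature_names, f$feature)
  }
})

test_that("a feature spanning the whole universe never enters a profile", {
  universe <- paste0("G", 1:50)
  col <- gene_set_collection(list(all = universe, sub = universe[1:5]))
  p <- build_profile("q", universe[1:5], col, n_resamples = 300, seed = 1)
  expect_false("all" %in% p$feature_names)   # fold = 1 is excluded
  expect_true("sub" %in% p$feature_names)    # perfectly concentrated query
})

test_that("a query with no universe overlap yields a flagged empty profile, not an error", {
  col <- gene_set_collection(list(P = paste0("G", 1:10)))
  expect_warning(p <- build_profile("x", c("ZZZ1", "ZZZ2"), col,
                                    n_resamples = 100, seed = 1),
                 "empty profile")
  expect_equal(nrow(p$features), 0)
  expect_equal(p$status, "no_universe_overlap")
  # and bulk propagates it silently as an empty profile
  tab <- chemical_gene_table(list(ok = paste0("G", 1:3), miss = "ZZZ9"))
  profs <- build_profiles_bulk(tab, col, n_resamples = 100, seed = 1,
                               progress_every = 0)
  expect_length(profs, 2)
  expect_equal(profs$miss$status, "no_universe_overlap")
})

test_that("type-I error on a null collection stays near alpha", {
  # features drawn independently of the query; overlap fractions have
  # enough support that the t-approximation to the resampling null holds
  set.seed(81)
  universe <- sprintf("G%03d", 1:500)
  sets <- lapply(1:400, function(i) sample(universe, sample(100:300, 1)))
  names(sets) <- sprintf("F%03d", 1:400)
  col <- gene_set_collection(sets)
  query <- sample(universe, 40)
  tab <- metaprof:::enrichment_table(sort(intersect(query, col$universe)),
                                     col, n_resamples = 1000, seed = 123)
  alpha <- 0.05
  frac <- mean(tab$p_value < alpha)
  se <- sqrt(alpha * (1 - alpha) / nrow(tab))
  expect_lt(abs(frac - alpha), 3 * se + 1e-12)
})

test_that("BH correction shrinks a profile relative to raw p-values", {
  u <- small_universe(seed = 21)
  raw <- build_profile("disease", u$disease_genes, u$collection,
                       n_resamples = 300, seed = 4, p_adjust = "none")
  bh <- build_profile("disease", u$disease_genes, u$collection,
                      n_resamples = 300, seed = 4, p_adjust = "BH")
  expect_true(all(bh$feature_names %in% raw$feature_names))
  expect_lte(nrow(bh$features), nrow(raw$features))
})

test_that("profile TSV output carries entity, rank and 6-significant-digit values", {
  u <- small_universe(seed = 2)
  p <- build_profile("disease", u$disease_genes, u$collection,
                     n_resamples = 200, seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_profiles(p, path)
  back <- read.delim(path)
  expect_equal(names(back), c("entity", "feature", "overlap_count",
                              "fold_enrichment", "p_value", "rank"))
  expect_equal(nrow(back), nrow(p$features))
  expect_equal(back$rank, p$features$rank)
})
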