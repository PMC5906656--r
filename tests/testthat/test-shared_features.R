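test_that("rank_score maps positions to (0,1] with 1 at the top", {
  expect_equal(rank_score(1, 10), 1.0)
  expect_equal(rank_score(10, 10), 0.1)
  expect_equal(rank_score(3, 10), 0.8)
  expect_equal(rank_score(1, 1), 1.0)
  expect_error(rank_score(0, 10), "position")
  expect_error(rank_score(11, 10), "position")
})

test_that("harmonic combined ranking has identity, symmetry, bounds and monotonicity", {
  expect_equal(combined_ranking(1, 1), 1)
  expect_equal(combined_ranking(0.5, 1), 2 * 0.5 / 1.5)
  set.seed(9)
  r1 <- runif(200, 0.01, 1); r2 <- runif(200, 0.01, 1)
  hm <- combined_ranking(r1, r2)
  expect_equal(hm, combined_ranking(r2, r1))                  # symmetric
  expect_true(all(hm >= pmin(r1, r2) - 1e-12))                # bounded below
  expect_true(all(hm <= pmax(r1, r2) + 1e-12))                # bounded above
  expect_equal(combined_ranking(r1, r1), r1)                  # identity
  # strictly monotone in each argument
  eps <- 1e-3
  expect_true(all(combined_ranking(pmin(r1 + eps, 1 + eps), r2) > hm))
  expect_true(all(combined_ranking(r1, pmin(r2 + eps, 1 + eps)) > hm))
  expect_error(combined_ranking(0, 0.5), "positive")
})

test_that("balanced mid-rank features outrank one-sided top features", {
  # 5th of 5 in both profiles beats 1st of 10 in one and 10th of 10 in the other
  balanced <- combined_ranking(rank_score(5, 5), rank_score(5, 5))
  lopsided <- combined_ranking(rank_score(1, 10), rank_score(10, 10))
  expect_equal(balanced, 0.2)
  expect_equal(lopsided, 2 * 1 * 0.1 / 1.1)
  expect_gt(lopsided, 0.18)
  expect_lt(lopsided, balanced)

  # same behavior end to end: feature ranked 5th/5th of 10 vs 1st/10th of 10
  pd <- mock_profile("d", paste0("p", 1:10))
  pm <- mock_profile("m", paste0("p", c(10:6, 1, 5:2)))  # p1 is 6th here
  sh <- shared_pathways(pd, pm)
  mid <- sh$ranking_combined[sh$feature == "p5"]   # 5th in d, 7th in m
  top <- sh$ranking_combined[sh$feature == "p1"]   # 1st in d, 6th in m
  expect_equal(mid, combined_ranking(rank_score(5, 10), rank_score(7, 10)))
  expect_equal(top, combined_ranking(rank_score(1, 10), rank_score(6, 10)))
})

test_that("shared pathways intersect profiles and report the disease-side fraction", {
  pd <- mock_profile("disease", paste0("p", 1:10))
  pm <- mock_profile("met", paste0("p", c(3, 1, 7, 11, 12)))
  sh <- shared_pathways(pd, pm)
  expect_setequal(sh$feature, c("p1", "p3", "p7"))
  expect_true(all(sh$feature %in% pd$feature_names) &&
                all(sh$feature %in% pm$feature_names))
  expect_equal(attr(sh, "shared_fraction"), 100 * 3 / 10)
  expect_true(all(diff(sh$ranking_combined) <= 1e-12))

  # identical profiles: everything shared, top feature combined score 1
  both <- shared_pathways(pd, pd)
  expect_equal(attr(both, "shared_fraction"), 100)
  expect_equal(both$ranking_combined[both$feature == "p1"], 1.0)

  # empty intersection: empty result, not an error
  none <- shared_pathways(pd, mock_profile("met", c("q1", "q2")))
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "shared_fraction"), 0)

  expect_error(shared_pathways(pd, mock_profile("met", character(0))),
               "non-empty")
})

test_that("human genes map to mouse phenotype sets with homolog handling", {
  ann <- phenotype_annotation_table(list(
    "increased intestinal adenoma incidence" = c("Smad4", "Apc"),
    "colon polyps" = c("Trp53")))
  hm <- homolog_map(list(SMAD4 = "Smad4", TP53 = "Trp53",
                         KRAS = c("Kras", "Kras2")))
  mapped <- map_genes_to_phenotype_sets(gene_set("q", c("SMAD4", "TP53")),
                                        hm, ann)
  expect_true("Smad4" %in%
                mapped$collection$sets[["increased intestinal adenoma incidence"]])
  expect_setequal(mapped$query$genes, c("Smad4", "Trp53"))
  expect_equal(mapped$n_unmapped, 0)

  # gene without a homolog is dropped and counted
  m2 <- map_genes_to_phenotype_sets(gene_set("q", c("SMAD4", "NOVEL1")),
                                    hm, ann)
  expect_equal(m2$n_unmapped, 1)
  # two human genes collapsing onto one mouse gene deduplicate
  hm2 <- homolog_map(list(A1 = "Shared1", A2 = "Shared1"))
  ann2 <- phenotype_annotation_table(list(ph = "Shared1"))
  m3 <- map_genes_to_phenotype_sets(gene_set("q", c("A1", "A2")), hm2, ann2)
  expect_equal(m3$query$genes, "Shared1")

  expect_error(map_genes_to_phenotype_sets(gene_set("q", "NOVEL1"), hm, ann),
               "no query gene")
})

test_that("a phenotype holding all mapped genes is the single shared feature", {
  genes <- sprintf("GENE%02d", 1:40)
  mouse <- paste0("M", tolower(genes))
  hm <- homolog_map(stats::setNames(as.list(mouse), genes))
  dz <- gene_set("disease", genes[1:8])
  met <- gene_set("met", genes[c(1:6, 9, 10)])
  both_pool <- paste0("M", tolower(genes[1:10]))
  ann <- c(list(hit = both_pool),
           lapply(stats::setNames(11:20, paste0("bg", 11:20)),
                  function(i) paste0("M", tolower(genes[c(i, i + 10)]))))
  sh <- shared_phenotypes(dz, met, hm, phenotype_annotation_table(ann),
                          n_resamples = 500, seed = 3)
  expect_equal(sh$feature, "hit")
  expect_equal(sh$ranking_combined, 1.0)

  # metabolite genes identical to disease genes: fraction 100%
  sh2 <- shared_phenotypes(dz, dz, hm, phenotype_annotation_table(ann),
                           n_resamples = 500, seed = 3)
  expect_equal(attr(sh2, "shared_fraction"), 100)
})

test_that("phenotype pipeline with an identity homolog map reproduces shared_pathways", {
  u <- small_universe(seed = 13)
  ident <- homolog_map(stats::setNames(as.list(u$collection$universe),
                                       u$collection$universe))
  ann <- phenotype_annotation_table(u$collection$sets)
  met_genes <- u$chemical_table$chemicals[["CHEM0001"]]
  via_phen <- shared_phenotypes(u$disease_genes,
                                gene_set("CHEM0001", met_genes),
                                ident, ann, n_resamples = 300, seed = 17)
  pd <- build_profile("disease", u$disease_genes, u$collection,
                      n_resamples = 300, seed = derive_seed(17, "disease"))
  pm <- build_profile("CHEM0001", met_genes, u$collection,
                      n_resamples = 300, seed = derive_seed(17, "CHEM0001"))
  via_path <- shared_pathways(pd, pm)
  expect_equal(as.data.frame(via_phen), as.data.frame(via_path),
               ignore_attr = "kind")
  expect_equal(attr(via_phen, "shared_fraction"),
               attr(via_path, "shared_fraction"))
})

test_that("shared-feature TSV carries the summary line and full precision columns", {
  sh <- shared_pathways(mock_profile("d", paste0("p", 1:10)),
                        mock_profile("m", paste0("p", 1:5)))
  path <- tempfile(fileext = ".tsv")
  write_shared_features(sh, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# shared: 5 of 10")
  back <- read.delim(path, comment.char = "#")
  expect_equal(back$feature, sh$feature)
})
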