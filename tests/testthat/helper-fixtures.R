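# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from stored data.

# A molecular profile with a prescribed feature ordering, for testing the
# ranking and shared-feature layers independently of the enrichment engine.
mock_profile <- function(entity, features, alpha = 0.05, n_resamples = 1000) {
  n <- length(features)
  df <- data.frame(
    feature = as.character(features),
    overlap_count = rep(1L, n),
    observed_fraction = rep(0.5, n),
    null_mean_fraction = rep(0.1, n),
    fold_enrichment = rep(5, n),
    p_value = if (n > 0) seq(1e-4, alpha / 2, length.out = n) else numeric(0),
    rank = seq_len(n),
    stringsAsFactors = FALSE)
  metaprof:::new_molecular_profile(entity, df, alpha, n_resamples, 10L)
}

# ranked list over n chemicals with given similarity vector (names = ids)
mock_ranked <- function(sim) {
  profs <- lapply(names(sim), function(id) {
    mock_profile(id, if (sim[[id]] > 0) paste0("f", seq_len(sim[[id]])) else character(0))
  })
  names(profs) <- names(sim)
  disease <- mock_profile("disease", paste0("f", 1:100))
  rank_chemicals(disease, profs, measure = "overlap")
}

# tiny deterministic GMT file; returns its path
write_gmt_lines <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# exhaustive hypergeometric tail by enumerating every k-subset of 1..n
enumerate_tail <- function(overlap, query_size, feature_size, universe_size) {
  universe <- seq_len(universe_size)
  feature <- seq_len(feature_size)         # wlog the first genes
  subsets <- utils::combn(universe, query_size)
  hits <- apply(subsets, 2, function(s) sum(s %in% feature) >= overlap)
  mean(hits)
}

# small synthetic universe for fast pipeline-level tests
small_universe <- function(seed = 7, signal_strength = 0.8) {
  generate_universe(synthetic_config(
    n_genes = 200, n_pathways = 40, pathway_size_range = c(5, 20),
    n_chemicals = 40, chemical_genes_range = c(4, 12),
    n_disease_genes = 12, n_disease_pathways = 5,
    n_positive_chemicals = 8, signal_strength = signal_strength,
    n_phenotypes = 20, seed = seed))
}
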