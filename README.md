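# metaprof

Molecular-profile prioritization of gut microbial metabolites for disease.

Hundreds of thousands of small molecules have recorded chemical–gene
associations, but almost none have direct evidence tying them to a given
disease. `metaprof` ranks chemicals by **molecular convergence**: how
strongly the pathways enriched among a chemical's associated genes
coincide with the pathways enriched among the disease's associated genes.
It was designed for gut-microbial-metabolite screens in colorectal cancer
style studies, but takes any disease gene list, any GMT pathway
collection, and any chemical–gene table.

## Method

For an entity with gene set *Q* over the pathway-collection universe *U*,
each pathway *F* is scored by the observed overlap fraction
*s = |Q ∩ F| / |Q|* against a resampled null: *R* = 1000 random gene sets
of size |*Q*| drawn from *U* without replacement. The p-value comes from
the standardized score *t = (s − mean(null)) / sd(null)* referred to a
t distribution (one-sided, enrichment only), and fold enrichment is
*s / mean(null)*. The **molecular profile** is the list of pathways with
*p* < α (default 0.05) and fold > 1, ordered by significance.

Chemicals are ranked against the disease profile by overlap, Jaccard
(|A∩B|/|A∪B|) or cosine (|A∩B|/√(|A||B|)) similarity of the two profiles'
feature-name sets; rankings are evaluated against known positives by
recall, mean/median percentile (random expectation 50%) and decile
enrichment. Top candidates are characterized by the pathways — and,
through mouse homologs and mutational-phenotype annotations, the
phenotypes — shared with the disease, each shared feature scored by the
harmonic combined ranking

    ranking_combined = 2 * ranking_d * ranking_m / (ranking_d + ranking_m)

of its larger-is-better rank scores in the two profiles, so a feature
ranks highly only when it ranks highly for *both* the disease and the
metabolite.

A synthetic-universe generator (`synthetic_config()` /
`generate_universe()`) produces all six pipeline inputs with planted
disease-associated chemicals, so everything is testable end to end
without external database downloads. See the methods vignette
(`vignettes/metabolite-prioritization.Rmd`) for the model, the design
decisions and their rationale.

## Worked example

```r
library(metaprof)
options(metaprof.quiet = TRUE)

u <- generate_universe(synthetic_config(
  n_genes = 300, n_pathways = 40, pathway_size_range = c(8, 25),
  n_chemicals = 60, chemical_genes_range = c(4, 12),
  n_disease_genes = 10, n_disease_pathways = 5,
  n_positive_chemicals = 10, signal_strength = 0.8,
  n_phenotypes = 20, seed = 7))

disease_profile <- build_profile("disease", u$disease_genes, u$collection,
                                 n_resamples = 500,
                                 seed = derive_seed(7, "disease"))
profiles <- build_profiles_bulk(u$chemical_table, u$collection,
                                n_resamples = 500, seed = 7,
                                progress_every = 0)
ranked <- rank_chemicals(disease_profile, profiles, "jaccard")
evaluate_known(ranked, u$known_positives)
```

```
<evaluation_report> 10 of 10 known chemicals found
  Recall: 1.000
  Mean ranking (top %):   10.42%
  Median ranking (top %): 8.33%
  P-value: 2.04e-08
  Decile counts (top 10% ... bottom 10%): 6 3 1 0 0 0 0 0 0 0
```

All 10 planted positives are recovered (recall 1.000); they rank on
average in the top 10.4% of the 60 chemicals — far better than the 50%
random expectation (the p-value tests exactly that) — and six of the ten
land in the first decile. On a null universe (`signal_strength = 0`) the
same pipeline centers on 50%.

Shared-feature characterization of the top-ranked chemical:

```r
top <- ranked$chemical[1]
shared_pathways(disease_profile, profiles[[top]])
```

```
<shared_features> 6 of 8 disease pathways shared (75.0%)
 feature ranking_d ranking_m ranking_combined
  PW0001     0.750 0.8333333        0.7894737
  PW0003     0.625 1.0000000        0.7692308
  PW0004     1.000 0.5000000        0.6666667
  ...
```

Each pathway present in both profiles is listed with its two rank scores
and their harmonic combination; the header gives the fraction of the
disease profile that the chemical touches.

The same pipeline is scriptable: `inst/cli/metaprof.R` provides
`simulate`, `profile`, `rank`, `evaluate`, `shared-pathways`,
`shared-phenotypes` and `run` subcommands over these functions
(`Rscript inst/cli/metaprof.R run --config run.yaml`).

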