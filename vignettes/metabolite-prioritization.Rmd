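---
title: "Molecular-profile prioritization of gut microbial metabolites: methods and design"
author: "metaprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular-profile prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaprof)
options(metaprof.quiet = TRUE)
```

## The problem

Gut microbial metabolites influence colorectal cancer and other diseases,
but for most of the hundreds of thousands of small molecules with recorded
gene associations there is no direct evidence linking them to any disease.
`metaprof` ranks chemicals by *molecular convergence*: a chemical whose
associated genes hit the same biological pathways as a disease's
associated genes is a candidate mediator, even if no study has ever put
the two in one sentence. The same logic extends to mouse mutational
phenotypes, giving an organism-level readout of what a candidate might do.

The pipeline has four stages:

1. **Profiles.** For the disease gene set and for every chemical's gene
   set, build a *molecular profile*: the list of pathways significantly
   enriched among the entity's genes, ordered by significance.
2. **Ranking.** Score every chemical by the set similarity between its
   profile and the disease profile (overlap, Jaccard, or cosine) and rank
   all chemicals.
3. **Evaluation.** Measure recall, mean/median percentile and decile
   enrichment of a list of known disease-associated metabolites.
4. **Shared features.** For top candidates, intersect their profile with
   the disease profile and rank the shared pathways (and, via mouse
   homologs, shared mutational phenotypes) by a harmonic combined score.

## The enrichment model

For a query gene set $Q$ and a feature (pathway or phenotype) $F$ over a
gene universe $U$ (the union of all feature sets), the observed statistic
is the overlap fraction

$$ s_{obs} = \frac{|Q \cap F|}{|Q|}. $$

Its null distribution is obtained by resampling: draw $R$ gene sets of
size $|Q|$ uniformly without replacement from $U$ and recompute the
fraction for each draw ($R = 1000$ by default). Fold enrichment is
$s_{obs} / \bar{s}_{null}$, and the p-value is one-sided towards
enrichment, from the standardized score

$$ t = \frac{s_{obs} - \bar{s}_{null}}{\mathrm{sd}(s_{null})} $$

referred to a t distribution with $R - 1$ degrees of freedom. The profile
keeps features with $p < \alpha$ (default $\alpha = 0.05$, no
multiple-testing correction by default; Benjamini–Hochberg is available
via `p_adjust = "BH"`) **and** fold enrichment $> 1$, sorted by ascending
p-value, ties by descending fold, then feature name.

### Why the null-sd standardization

Two readings of "score the observed value against a resampled null with a
t-test" are possible: divide by $\mathrm{sd}(s_{null})$, or by
$\mathrm{sd}(s_{null})/\sqrt{R}$ (the textbook one-sample t-test). The
second makes the decision depend on $R$: as $R$ grows, *any* observed
fraction above the null mean becomes significant, which is not a useful
enrichment test and disagrees wildly with the exact reference test below.
We therefore treat the observed fraction as a single draw from the null
distribution and standardize by the null sd. Under this reading the
resampling p-value approximates the tail of the overlap distribution, and
the test suite verifies that its accept/reject decision at $\alpha = 0.05$
matches the exact hypergeometric test in at least 95% of random small
configurations.

### The exact oracle

Under the null, $|Q \cap F|$ is hypergeometric, so
$P(X \ge |Q \cap F|)$ computed by `hypergeometric_tail()`
(`stats::phyper` underneath) is an exact reference. It is used as a
cross-check in tests — never as the implementation, because the
resampling route is the method being provided and extends unchanged to
statistics with no closed form. Limits of the approximation: for very
small features (overlap 0 or 1 almost surely) the resampled null is
extremely discrete and the t tail is only a rough guide; decisions near
the threshold can differ from the exact test. This is the source of the
few-percent disagreement allowed above, and it is also why the type-I
calibration test uses features large enough for the overlap fraction to
have real support.

### Degenerate cases

* Null sample with zero variance: $p = 1$ if the observed fraction does
  not exceed the null mean (e.g. a feature equal to the whole universe),
  $p = 0$ if it does (only possible when the null is stuck below the
  observed value).
* Null mean 0 with positive observed overlap: fold enrichment is
  $+\infty$, which sorts before all finite folds; with observed overlap
  also 0, fold is defined as 1 (neutral, never significant).
* Query genes outside the universe are dropped with a warning; a query
  with no gene in the universe yields an *empty profile* flagged
  `no_universe_overlap` rather than an error, so a bulk run over a sparse
  chemical table never aborts.

### Reproducibility contract

All randomness flows from one integer seed. `derive_seed(seed, key)`
hashes a name (a chemical id, a pipeline stage) into a substream seed, so

* `build_profiles_bulk(..., seed = s)` gives, for chemical `c`, exactly
  `build_profile(..., seed = derive_seed(s, "c"))`;
* the null draws for one entity are made **once** and shared by all
  features (they only depend on the query size and the universe), so the
  profile is independent of feature evaluation order, and
  `enrich_feature()` with the same seed reproduces any single row;
* the synthetic generator uses named substreams (`disease`, `pathways`,
  `chemicals`, `phenotypes`), so adding phenotypes does not perturb the
  chemical draws.

The universe is sorted before indices are drawn, so results do not depend
on input file row order.

## Ranking and evaluation

Similarities are computed on the *sets of significant feature names*.
Chemicals are sorted by descending similarity (ties broken by chemical id
for a deterministic output order); tied similarities receive the mean of
the rank positions they span, and the percentile is $100 \cdot
\mathrm{rank} / N$ (smaller = better). Average ranks keep percentile
statistics unbiased under heavy ties — in particular the many chemicals
with empty profiles that all score 0.

`evaluate_known()` reports recall (knowns present anywhere in the ranked
list — coverage of the chemical–gene table is the only thing that limits
it), mean and median percentile of the found knowns, a one-sample t-test
of those percentiles against the random expectation of 50% (two-sided by
default, one-sided available), and the counts of knowns per decile
$(0,10], (10,20], \dots, (90,100]$ — upper-inclusive so percentile 100
falls in the last decile. With a single found known the t-test is
undefined and reported `NA`; with zero variance the p-value is 1.
Reported recalls and shared fractions are rounded half away from zero
(`round_half_away()`), matching how such fractions are conventionally
printed; stored values keep full precision.

## Shared-feature characterization

A shared feature's position $i$ in a profile of size $N$ becomes the rank
score $(N - i + 1)/N \in (0, 1]$ — 1 for the top feature, $1/N$ for the
bottom one — and the combined score of a feature shared by the disease
profile and a metabolite profile is the harmonic mean

$$ r_{combined} = \frac{2\, r_d\, r_m}{r_d + r_m}. $$

The harmonic mean is dominated by its smaller argument, so a feature
ranks highly if and only if it ranks highly on *both* sides; an
arithmetic mean would let a single-sided top rank carry a feature. The
orientation matters: harmonic combination of scores where *small* is good
would paradoxically reward one-sided excellence, which is why positions
are converted to larger-is-better scores first. What the original
ranking currency was (positions, percentiles, p-values) is not
recoverable from the method's verbal description; position-derived scores
are the choice here because they are invariant to the p-value scale and
keep both arguments on (0, 1]. Only the harmonic combination formula
itself is fixed.

For phenotypes, human genes are first translated to mouse homologs
(one-to-many allowed, results collapsed to a set; genes without homologs
dropped and counted), then profiled against the mutational-phenotype
annotation collection exactly as pathways. Disease genes are used
directly (not disease-pathway genes) to build the disease phenotype
profile, keeping the two sides of the comparison symmetric. With an
identity homolog map and the pathway collection relabelled as phenotypes
the phenotype route reproduces `shared_pathways()` exactly; this
end-to-end consistency is a test.

Shared fractions are reported relative to the *disease* profile (the
question is "how much of the disease's biology does this metabolite
touch"), printed with 1 decimal for pathways and as a whole percent for
phenotypes.

## The synthetic universe

Real inputs (disease-genetics gene lists, MSigDB pathways, a STITCH-scale
chemical–gene table, MGD phenotype annotations) are database releases that
cannot ship with a package. `generate_universe()` builds a complete toy
universe with the statistical structure the method assumes:

* a gene universe (default 1000 genes) with overlapping random pathways
  (default 200, sizes 10–50);
* a disease gene set (default 30 genes) seeded into a designated block of
  disease pathways (default 20) — each disease pathway contains *all*
  disease genes, so they are genuinely, strongly enriched (a config whose
  pathway sizes cannot hold the disease genes is rejected up front);
* a sparse chemical–gene table (default 500 chemicals, 5–30 genes each)
  in which planted positive chemicals (default 30) draw a
  `signal_strength` fraction of their genes from the pooled
  disease-pathway genes (default 0.8; 0 gives an exchangeable null
  universe) and background chemicals draw uniformly;
* a mouse mirror: homologs by the MGI case convention
  (`GENE0001 → Gene0001`), phenotype annotations drawn like pathways over
  mouse symbols with the first tenth seeded with the disease homologs;
* a known-positive list equal to the planted positives, with category
  labels cycling through six metabolite-class names purely as fixture
  vocabulary.

Defaults are the package's standing study conditions, also used by the
test suite: they are large enough for percentile statistics to be stable
(30 knowns among 500 chemicals give a null standard error of about 5
percentile points per universe, about 1.2 after 20 replicates) and small
enough that a full profile-rank-evaluate pass over one universe takes
seconds on one core.

What the generator does **not** emulate: STITCH confidence-score
distributions (scores are supported in the reader but not generated),
real pathway topology (hierarchies, hub genes shared by many pathways),
and the extreme sparsity skew of real chemical–gene data. Passing tests
on this generator therefore show that the statistics and plumbing behave
as specified under the assumed structure — not that the method's
biological conclusions transfer to any particular database release.

## Numerical and interface choices

* Confidence filtering of the chemical–gene table defaults to *keep all*;
  a cutoff is exposed (`score_cutoff`) for STITCH-style scored inputs.
* Human symbols are case-folded to uppercase (HGNC convention); mouse
  symbols are matched case-sensitively (MGI convention).
* Output tables are TSV with a header; floats printed with 6 significant
  digits.
* Depletion (fold < 1) is never reported; the method's unit is
  enrichment-only set overlap, with no gene-level running-sum statistics.
* The full pipeline (`run_pipeline()`, or the `inst/cli/metaprof.R`
  script with subcommands `simulate`, `profile`, `rank`, `evaluate`,
  `shared-pathways`, `shared-phenotypes`, `run`) is a thin orchestration
  of the functions above; a test verifies the staged outputs equal direct
  module calls.

## Known limitations

* The resampling test is approximate for tiny features; use
  `hypergeometric_tail()` when an exact overlap test is all that is
  needed.
* With no multiple-testing correction, a profile over $m$ features
  carries about $\alpha m$ false members; they add noise to the
  similarity ranking but no systematic bias (both the disease and the
  chemical side carry them independently).
* Recall is bounded by chemical–gene coverage: a known metabolite with no
  recorded gene association cannot be ranked at all.
* Percentiles of a handful of knowns are noisy; the decile table is the
  more robust summary of top-enrichment.

## A worked micro-example

```{r example}
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

The problem sizes here and in the test suite (up to 1000 genes, 200
pathways, 500 chemicals, 1000 resamples, 20 replicate universes) are the
package's standing desk-scale study conditions; every number the
documentation quotes is recomputed by the tests or the acceptance script
at run time.
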