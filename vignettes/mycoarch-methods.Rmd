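---
title: "Methods: contamination-aware differential abundance for RNA-seq-derived mycobiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contamination-aware differential abundance for RNA-seq-derived mycobiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycoarch)
```

## The problem

Non-human reads in tumor RNA-seq carry a faint signal of the intratumor
microbial community. After taxonomic assignment (e.g. with a
PathoScope-style classifier) one obtains a taxa-by-samples matrix of read
counts for fungal and archaeal species. Two properties of such data drive
everything in this package:

1. **Contamination.** Reagent and handling contaminants can dominate
   low-biomass profiles. Studies of this kind have no negative-control
   wells, so contaminants must be recognized from internal structure:
   association with sequencing batches (date, plate) and independence from
   the sample's total microbial read yield.
2. **Compositionality.** Read counts are relative; only ratios are
   interpretable. All statistics therefore operate on the centered
   log-ratio (CLR, Aitchison) scale.

The pipeline: CLR transform, three contaminant detectors with union
removal, Kruskal-Wallis differential abundance per cohort pair with
Bonferroni correction and a log-fold-change gate, direction-concordant
Venn partitioning of shared hits, clinical-variable association, and
continuous-phenotype gene-set enrichment linking a microbe's abundance to
host pathway expression.

## CLR transform

For counts $c_{ts}$ with pseudocount $\delta$ (default 1),
$y_{ts} = \log(c_{ts}+\delta) - \tfrac1T\sum_{t'}\log(c_{t's}+\delta)$.
Each sample column sums to zero (checked to $10^{-9}$ in the tests); on
strictly positive data with $\delta = 0$ the transform is exactly
depth-invariant. The pseudocount is a knob because zero handling is a
genuine modelling choice; 1 read is the simplest defensible convention.
Natural logs are used internally; fold changes downstream are reported in
base 2 independently.

The default pipeline order is transform &rarr; detect &rarr; remove.
Re-transforming after removal is implicit: every downstream stage
recomputes CLR on the filtered table, because CLR values depend on the
composition and removing taxa changes the geometric mean.

## Contaminant detectors

Each detector turns a visual heuristic into a deterministic statistic:

* **Total-abundance slope** (`slope_contaminant_scan`). Per taxon, the OLS
  slope of $\log(c_{ts}+1)$ on $\log(\text{total reads}_s)$. A genuine
  taxon whose expected count is proportional to microbial depth sits near
  slope 1; a contaminant added at a roughly fixed amount per library is
  *independent* of depth and sits near slope 0. A taxon is flagged when
  $|\hat\beta| \le 0.1$, boundary inclusive. The regression scale is a
  documented switch (`scale = "raw"` regresses raw counts on raw totals):
  the zero-slope-within-$\pm 0.1$ rule is scale-sensitive, and on the CLR
  scale itself a depth-independent contaminant would sit near slope $-1$
  rather than 0, which is why the log-count scale is the default. Taxa
  observed in fewer than `max(3, ceiling(0.1 * n))` samples are skipped
  (slope `NA`, never flagged): a line through fewer points is noise.
* **Plate disproportion** (`plate_contaminant_scan`). The share of a
  taxon's reads contributed by its two highest-abundance plates; flagged
  when the share is at least 0.9 *and* those plates hold fewer than half
  of all samples. The second clause stops the detector from flagging taxa
  simply because the study itself is concentrated on few plates; with
  fewer than three plates the detector abstains entirely.
* **Date clustering** (`date_contaminant_scan`). The same construction
  with a single top sequencing date.

The 0.9 share threshold operationalizes "one functional abundance
cluster" / "disproportionately abundant": essentially all of the taxon's
signal must sit in the implicated batch. Both thresholds are exposed in
the configuration. Removal takes the union of the three flags, and
`render_diagnostics()` writes the per-taxon date/plate/total plots a
reviewer would inspect, with flagged taxa highlighted.

## Differential abundance

Per taxon, a Kruskal-Wallis rank test (implemented directly on mid-ranks
with tie correction; the two-group case is the rank-sum test) compares
CLR abundance between the cohort pair's groups. P-values are
Bonferroni-adjusted within one cohort comparison — the family is the set
of taxa tested in that comparison, not the global set across comparisons,
matching how each comparison is reported on its own. The significance
call is `p_adj < 0.05` and `|logFC| > 1`, where
`logFC = log2((mean rel. abundance A + 1e-6)/(mean rel. abundance B + 1e-6))`.
No fold-change formula is canonical for compositional data; group mean
relative abundance with a small pseudo-fraction is used because it is
interpretable ("at least two-fold difference in average relative
abundance") and symmetric under group exchange. Applying the 0.05
threshold to the adjusted rather than raw p-value is itself a switch
(`adjust = FALSE`), since reports in this area are often ambiguous about
which was meant.

Seven cohort comparisons ship as defaults (`default_cohorts()`): all
tumors vs normals, each histologic subtype (classical,
follicular-variant, tall-cell) vs normals, each gender's tumors vs
gender-matched normals, and BRAF V600E-positive vs -negative tumors
(tumor-only, no normals).

## Overlap partitioning

`partition_by_direction()` implements strict Venn semantics: a taxon
belongs to region $S$ iff it is significant with one common direction in
every cohort of $S$ and in no cohort outside $S$. Taxa significant in
several cohorts with conflicting directions go to a `discordant`
quarantine instead of being forced into a region; this loses nothing and
makes the conflict explicit. The partition law (regions pairwise
disjoint; regions plus discordant exactly cover the taxa significant
anywhere) is property-tested against a brute-force enumerator.

## Clinical association

For taxa that survived the DA filter, CLR abundance is tested across the
levels of six clinical variables (vital status, perineural invasion,
pathologic stage, T/N/M stage) on tumor samples only, again by
Kruskal-Wallis with a Bonferroni family of all (taxon, variable) pairs
tested. Stage sub-levels (IVA, T1b, ...) collapse to their majors by
default; the test is unordered (no trend test is attempted). Variables
degenerate among tumors are skipped with a warning.

## Gene-set enrichment

To connect a microbe to host pathways, genes are ranked by Pearson
correlation (Spearman available) between their expression and the
microbe's CLR abundance, and each gene set receives the weighted
Kolmogorov-Smirnov enrichment score: walking the ranked list, hits add
$|r|^w / \sum_{hits}|r|^w$ (default $w = 1$), misses subtract
$1/(N - N_{hits})$, and the score is the signed maximum deviation, always
in $[-1, 1]$. Significance comes from phenotype permutation (default
1000, mandatory seed): the sample labels of the phenotype are shuffled,
ranking and scores recomputed, and per set the one-sided same-signed tail
fraction with +1 smoothing gives $p > 0$ always. NES divides the observed
score by the mean magnitude of same-signed null scores; the FDR q-value
follows the standard NES-based construction (proportion of pooled
normalized null scores at least as extreme over the proportion of
observed scores at least as extreme, capped at 1). The reported filter is
$p < 0.05$ and FDR $< 0.25$. Phenotype permutation (not gene
permutation) is used because it preserves gene-gene correlation, matching
the expression/phenotype/gene-set three-file design. The six
oncogenic-signature names used in this line of work are available from
`signature_set_names()`; their member lists are curated MSigDB content
and are not redistributed.

## The synthetic study

`simulate_dataset()` exists so that every stage can be tested against a
known truth without controlled-access data. What it emulates:

* **Counts**: negative-binomial with mean `depth_s * proportion_t`;
  per-sample depth log-normal (median $10^5$ microbial reads, `sdlog` 1 —
  microbial yield from host RNA-seq varies over orders of magnitude);
  dispersion 0.2, typical of sequencing counts; baseline proportions
  log-uniform over $10^{-4.5}$–$10^{-3}$.
* **Design**: 453 tumors / 54 adjacent normals; subtypes 385:102:36;
  genders 140:366 (applied as proportions of tumors); 12 sequencing
  dates, 10 plates; 60% BRAF-positive tumors; clinical levels drawn with
  plausible prevalences.
* **Contaminant archetypes**: depth-independent mean (slope archetype),
  confinement to two plates, confinement to one date — 50/25/25 planted
  by default.
* **Effects**: 15 taxa up and 15 down at logFC 2 in tumors, 5 up in
  BRAF-negative tumors; 5 taxa additionally shifted in stage III/IV
  tumors. Clinical-effect taxa also carry a tumor-vs-normal effect,
  because the clinical stage (like the study design it mirrors) only
  examines taxa already called dysregulated — a clinical effect planted
  on a non-dysregulated taxon would be invisible by construction.
* **Expression**: 1000 genes; a 20-gene planted set sharing a latent
  factor with the designated microbe's CLR abundance at correlation 0.8,
  plus null sets.

Default dimensions are roughly 20x below full scale so `run_pipeline()`
completes in seconds; a full-scale configuration is just a different
`simulation_config()`. The truth manifest records every planted
structure, and `score_against_truth()` computes sensitivity and
false-positive rate per stage by exact set comparison.

What the generator does **not** emulate: taxon-taxon ecological
correlation, sample-specific contamination loads, classifier
misassignment noise, and batch effects in the *expression* matrix.
Passing tests therefore demonstrate that the statistics recover the
structure they assume, not that real tumor mycobiome data satisfy those
assumptions.

## Numerical choices and degenerate inputs

* Kruskal-Wallis with all observations identical returns $H = 0$, $p = 1$
  (the tie-correction denominator vanishes); a single group is an error.
* P-values are clamped away from exact 0 before Bonferroni adjustment
  (chi-square tails can underflow).
* The ES extremum uses the first position attaining the maximum absolute
  running sum; when the positive and negative extrema tie exactly the
  sign is a tie-break, which the tests treat as such.
* Zero-variance genes rank with metric 0 (noted), a zero-variance
  phenotype is an error.
* All file writers emit UTF-8 with LF endings and tabs; dates are
  ISO-8601 only.

## Problem sizes used in the test suite

Unit tests run on 60–160-sample, 70–200-taxon simulations. The deeper
statistical checks use: the canonical detector scenario (500 taxa, 200
samples, 50 contaminants per archetype); 200 all-null replicates and 100
planted-effect replicates (n = 100 vs 50) for the calibration and power
of the DA stage; 500 random table triples for the partition law; 1000
random instances for the enrichment-score oracle; and the full default
synthetic study, twice, for end-to-end determinism. The complete suite
runs in about two minutes on one CPU.

## Known limitations

* The slope detector assumes a dominant depth-proportional background; if
  most of the community were contamination, "slope ≈ 1" taxa would be the
  anomaly.
* Bonferroni across hundreds of taxa is deliberately conservative;
  power claims hold for strong planted effects (|logFC| = 2) at the
  simulated sample sizes.
* The fold-change gate operates on relative abundances and inherits their
  compositional coupling; a very large planted effect in one taxon can
  shift apparent fold changes of others slightly.
* Enrichment p-values are permutation-granular (resolution 1/(n_perm+1));
  FDR q-values below ~1/n_perm are reported as computed but carry no
  extra precision.
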