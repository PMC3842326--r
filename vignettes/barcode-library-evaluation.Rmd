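---
title: "Evaluating a DNA barcode reference library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a DNA barcode reference library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(barcodeval)
```

## The problem

A DNA barcode reference library is useful only to the degree that the
sequence variation it captures separates species. `barcodeval` implements
the evaluation pipeline used for multi-marker plant barcoding studies
(typically the core plastid markers *matK* and *rbcL* plus nuclear
ribosomal ITS2): per-sequence quality control, pairwise-distance
barcode-gap analysis, reference-database species discrimination across
marker combinations, tree-based identification, and the accompanying
statistics. All analysis units are per-species: each species is one
independent binomial trial when rates are summarised.

Two notions of success are deliberately kept distinct:

* **Discrimination** — a species is diagnosable when every query of every
  one of its specimens against the reference database returns only that
  species.
* **Barcode gap** — a species' maximum intraspecific p-distance is
  strictly smaller than its minimum distance to any heterospecific
  specimen.

The two disagree in instructive ways (a species with ample intraspecific
variation can still be diagnosable by one consistent difference; a
gap-positive species can fail discrimination when the reference holds
conspecific-identical sequences outside the analysed sample), and the
package quantifies their concordance with McNemar's test.

## Complete samples

Cross-marker comparisons are only meaningful on specimens for which every
marker was recovered. `select_complete_samples()` restricts a library to
those specimens; the reference database for discrimination is nonetheless
built from *all* sequences (`build_reference()`), because restricting it
to the complete sample overestimates discrimination success. Barcode gaps,
in contrast, are computed within the complete sample only; both scopes are
exposed, and mixing them changes the concordance counts — the per-result
`marker_set` labels make the scope explicit.

## Distances

Every unordered pair of sequences is aligned independently
(`pairwise_align()`, affine-gap Needleman–Wunsch) and scored with the
uncorrected p-distance: unambiguous nucleotide differences divided by all
alignment columns; columns with a gap or an ambiguity code count as
aligned positions but never as differences. Defaults (match $+1$,
mismatch $-1$, gap open $-2$, extension $-0.5$ per base, terminal gaps
free) suit the $\ge 99\%$-identity pairs that drive the analysis;
parameters are configurable through `align_params()`. Ties in the dynamic
program are broken deterministically (aligned column, then gap in the
first sequence, then gap in the second), so alignments are reproducible.

Two numerical notes. First, with free terminal gaps a difference at the
extreme end of a sequence can be absorbed into cost-free overhangs, so two
non-identical strings can sit at p-distance zero; this is the intended
behaviour for sequences trimmed to slightly different lengths, but it is
why exactness claims below are stated for interior variation. Second,
identical sequences are deduplicated before alignment, which makes the
quadratic pair pass cheap on libraries dominated by shared haplotypes.

Multilocus distances pool markers by summing differences and columns
before dividing (`multilocus_distance_matrix()`), which is equivalent to
concatenating the per-marker pairwise alignments — markers are used
simultaneously, not vote-averaged.

## Barcode gap

`species_gap()` applies the strict comparison `min_inter > max_intra`.
Conventions: a singleton species has `max_intra = 0`, so its flag is
decided entirely by its nearest heterospecific (zero distance — shared
genotype — means no gap); an exact tie is no gap. Adding specimens can
only raise a species' maximum intraspecific distance and lower other
species' minimum interspecific distances, so gap counts are non-increasing
under denser sampling — a property the test suite checks by incremental
insertion.

## Discrimination

`build_reference()` deduplicates each marker into distinct sequence
types with their owning species. A query returns every species owning a
reference sequence at minimal p-distance, all ties included; since a
complete-sample query's own record is in the reference, the minimal
distance is zero and the true species is always among the returned set
(a leave-one-out mode is available for comparison). Marker combinations
intersect the per-marker returned sets, which handles unequal marker
coverage and makes combination monotone: adding a marker can never turn a
diagnosable species undiagnosable. Conflated species are reported in
descending order of how many queries returned them, alphabetical on ties.

The identification rule here is minimal-distance set retrieval with tie
inclusion. It reproduces the documented failure modes of
diagnostic-position identification systems — shared multilocus genotypes
and absent variation — and the success criterion is implemented literally
(all queries return only the true species), but it is not a
re-implementation of any particular published scoring engine; treat
cross-study comparisons of absolute rates accordingly.

`least_inclusive_clade()` scores tree-based identification: a species
passes when the smallest clade containing all its samples contains no
others. It needs at least two samples per species (singletons are `NA`)
and uses the supplied tree as rooted as read; `nj_tree()` provides a
neighbor-joining convenience tree when no externally inferred tree is
available.

## Sequence QC

`quality_index()` summarises per-base Phred quality values and per-base
read coverage as

$$B_q = \frac{1}{L}\sum_{i=1}^{L} \mathbf{1}[QV_i \ge q]\,
\frac{\min(c_i, x)}{x},$$

with defaults $q = 30$ (one expected error per thousand bases) and
$x = 2$ (both strands represented). The published index this is modelled
on is specified in an external reference; the definition used here keeps
exactly the quantities that enter it — threshold $q$, expected coverage
$x$, observed contig size $c$ — in a fully documented, testable form, and
is monotone in every quality and coverage value.

`linguistic_complexity()` measures repetitiveness as the product over
pattern sizes $k = 3..6$ of observed over maximal distinct $k$-mers,
$\min(4^k, |w|-k+1)$, in sliding windows (width 100, step 1), aggregated
by arithmetic mean (a `min` mode exists; the mean was chosen because a
single low-complexity window should lower, not dominate, a long
sequence's score). Ambiguity codes count as ordinary distinct symbols, so
a run of `N`s is repetitive but is not an A/C/G/T homopolymer.
`find_homopolymers()` reports maximal single-nucleotide runs of at least
eight bases, the empirical threshold for slippage-induced PCR artifacts.

## The synthetic generator and what passing tests mean

`generate_library()` produces libraries with analytically known truth.
Species genotypes derive from one ancestral sequence per marker by
uniform random substitutions; individuals derive from their species
genotype the same way. Since downstream distances are uncorrected
p-distances, no finer substitution model is warranted. Genotype sharing
between configured species pairs is implemented by copying full marker
sequences (distance exactly zero), and homopolymer runs are written into
the ancestral sequence, so no indels arise unless explicitly configured —
which keeps the expected conflation sets (`expected_discrimination()`,
exhaustive set logic over genotypes) and expected gap flags
(`expected_gap()`, Hamming arithmetic) exact rather than simulated.

Defaults mirror a realistic conifer study: marker lengths 769/607/425 bp
(study-scale medians for *matK*/*rbcL*/nrITS2), 1–3 individuals per
species, ~1% interspecific and ~0.2% intraspecific divergence, and a
quality profile with 93.5% of positions at QV 30 or better with mostly
bidirectional coverage. What the generator does **not** emulate: indel
variation (beyond explicit configuration), rate heterogeneity along
sequences, coalescent genealogies, or chromatogram-level error processes.
Passing the oracle tests therefore demonstrates correctness of the
set/distance logic, not robustness to alignment-hard real data.

The oracle-equivalence tests run the full pipeline against the analytic
truth on 100 seeded libraries at study-scale marker lengths with zero
intraspecific divergence — the regime where equality is a theorem (see
the terminal-gap note above). Property tests (monotone marker synergy at
$10^4$ species-by-set cases, sampling monotonicity) use shorter markers
(150–220 bp) and nonzero intraspecific divergence; these sizes are the
package's chosen test problem sizes and exercise identical code paths.

## Statistics

* `wilson_ci()` — Wilson score interval; used for every reported rate.
* `scheffe_test()` — all pairwise contrasts under Scheffé's simultaneous
  criterion; Gaussian mode pools within-group variance, binomial mode
  takes $(k, n)$ pairs with normal-approximation variances
  $\hat p(1-\hat p)/n$ (the appropriate form for per-species success
  counts; this interpretation of a "binomial Scheffé test" is a
  documented package choice).
* `spearman_test()`, `point_biserial()` — rank and Pearson correlations
  with two-sided t-transform p-values.
* `mcnemar_test()` — exact (doubled binomial tail, capped at one) and
  $\chi^2$ forms. The two differ noticeably at small discordant counts
  (for discordant cells $0$ and $6$: exact $0.03125$, $\chi^2$
  $0.014$), which is why `gap_discrimination_concordance()` reports
  both.

## Worked example

```{r example}
cfg <- synthetic_config(n_species = 6, individuals_per_species = c(1, 3),
                        intraspecific_divergence = 0,
                        shared_genotype_pairs = list(c(1, 2)), seed = 7)
gen <- generate_library(cfg)
lib <- select_complete_samples(gen$library)
ref <- build_reference(gen$library)
disc <- species_discrimination(lib, ref,
                               marker_sets = list("matK", "rbcL", "nrITS2",
                                                  c("matK", "rbcL",
                                                    "nrITS2")))
gap <- gap_frequencies(lib)
report <- make_report(disc, gap)
report$table
disc$summary
```

Species 1 and 2 share a multilocus genotype by construction, fail every
marker set, and are mutually conflated; the other four are diagnosable
with a gap everywhere.

The packaged per-species results table for the Podocarpaceae study that
motivated this pipeline is available via `load_results_fixture()` and can
be pushed through the same aggregation path:

```{r fixture}
s <- summarize_results(load_results_fixture())
s$discrimination
s$gap
s$concordance$table
```

## Known limitations

* The aligner is pairwise-only; imported multiple sequence alignments are
  supported for `simple_indel_coding()` but are not built internally.
* Free terminal gaps can place terminally differing sequences at distance
  zero (see above); disable with
  `align_params(free_end_gaps = FALSE)` when sequences are trimmed to a
  common frame.
* Identification is distance-based retrieval, not diagnostic-position
  scoring; absolute discrimination rates are comparable across methods
  only qualitatively.
* Model-corrected distances (K2P etc.) and automatic species delimitation
  are out of scope.
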