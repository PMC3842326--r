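# barcodeval

Evaluation of multi-marker DNA barcode reference libraries in R.

DNA barcoding identifies specimens by comparing short standardized
sequence regions — for plants typically the core plastid markers *matK*
and *rbcL* plus nuclear ribosomal ITS2 — against a reference library.
Whether that works depends on how sequence variation is distributed
within and among species. `barcodeval` implements the evaluation pipeline
for such libraries, aimed at systematists and barcoding projects who need
per-species answers, not just summary rates:

* **Sequence QC** — per-sequence quality index
  `B_q = (1/L) Σ 1[QV_i ≥ q] · min(c_i, x)/x` (defaults `q = 30`,
  `x = 2`), linguistic complexity over sliding windows (k-mers 3–6,
  window 100), and homopolymer screening (runs ≥ 8 bp).
* **Distances** — affine-gap pairwise global alignment with deterministic
  tie-breaking, uncorrected p-distance (unambiguous differences over all
  aligned columns), per-marker and pooled multilocus distance matrices,
  and simple indel coding of imported alignments.
* **Barcode gap** — per species, maximum intraspecific versus minimum
  interspecific distance, with the strict rule `gap ⇔ min_inter >
  max_intra` (singletons decided by their nearest heterospecific).
* **Discrimination** — deduplicated reference database built from all
  sequences; queries return every species at minimal distance (ties
  included); marker combinations intersect per-marker results, so adding
  a marker never loses diagnosability; species are scored `+` only when
  every query of every specimen returns exactly that species. Tree-based
  identification by the least-inclusive-clade criterion is included.
* **Statistics** — Wilson intervals, Scheffé simultaneous contrasts
  (Gaussian and binomial-proportion modes), Spearman and point-biserial
  correlations, exact and χ² McNemar tests.
* **Synthetic libraries** — a seeded generator with analytically known
  conflation sets and gap flags, so the whole pipeline is testable
  without sequence downloads.

## Worked example

```r
library(barcodeval)

cfg <- synthetic_config(n_species = 6, individuals_per_species = c(1, 3),
                        intraspecific_divergence = 0,
                        shared_genotype_pairs = list(c(1, 2)), seed = 7)
gen  <- generate_library(cfg)
lib  <- select_complete_samples(gen$library)
ref  <- build_reference(gen$library)
disc <- species_discrimination(lib, ref,
          marker_sets = list("matK", "rbcL", "nrITS2",
                             c("matK", "rbcL", "nrITS2")))
gap  <- gap_frequencies(lib)
make_report(disc, gap)$table
#>      species n matK rbcL nrITS2 combined gap  conflated
#> 1 Species_01 3    -    -      -        -   0 Species_02
#> 2 Species_02 2    -    -      -        -   0 Species_01
#> 3 Species_03 2    +    +      +        +   1
#> 4 Species_04 3    +    +      +        +   1
#> 5 Species_05 3    +    +      +        +   1
#> 6 Species_06 1    +    +      +        +   1
```

Species 1 and 2 were forced to share a multilocus genotype: every marker
set fails for them (`-`), they are mutually conflated, and neither has a
barcode gap (`gap = 0`); the remaining species are diagnosable everywhere.
The summary (`disc$summary`) reports 4/6 = 66.7% of species discriminated
per marker set with a 95% Wilson interval of 30.0–90.3%.

Real data enter through `read_library()` (one FASTA per marker plus a TSV
metadata table), `read_msa()` (aligned FASTA) and `read_tree()` (Newick);
results leave through `write_report()` as CSV/JSON.

The package also ships the published per-species diagnostic table of a
Podocarpaceae barcoding study (97 species in its complete sample) as a
fixture; `summarize_results(load_results_fixture())` runs it through the
same aggregation path and yields 56.7% of species discriminated with all
three markers combined (Wilson 95% CI 46.8–66.1%), 50.5% with a
multilocus barcode gap, and discordant concordance cells 0/6 (exact
McNemar p = 0.03125).

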