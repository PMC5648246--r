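# barcodegap

Tools for the complete analysis chain of a DNA-barcoding campaign:
given a reference library of aligned COI barcode sequences with
specimen metadata, the package answers the three questions such
campaigns ask —

1. **Is there a barcode gap?** Pairwise divergences (Kimura
   2-parameter or p-distance, pairwise deletion), per-sequence
   furthest-conspecific vs nearest-neighbour profiles, and per-species
   gap verdicts.
2. **Can the library identify unknowns?** Leave-one-out identification
   simulation under Best Match, Best Close Match and the BOLD-style
   criterion (BM / BCM / BIC), with four threshold-selection rules: the
   95th percentile of intraspecific distances, the fixed 1% convention,
   the cumulative-error minimiser and the density minimum.
3. **Do clusters match taxonomy?** Species delimitation into MOTUs by
   barcode-gap discovery (initial and recursive), a
   statistical-parsimony connection limit and refined single linkage,
   classified per species as MATCH / SPLIT / MERGE / MIXTURE.

Around that core: neighbour-joining gene trees with column-resampling
bootstrap, tree-based distinctiveness assessment of singleton species,
per-species Mantel tests of isolation by distance, a one-configuration
pipeline runner, and a calibrated synthetic-library generator with known
ground truth so every stage is testable without any sequence downloads.

The central quantities, in the field's notation: for a sequence pair
with transition fraction *P* and transversion fraction *Q* over the
comparable sites, `K2P = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)`; a species
shows a *barcode gap* when every member's nearest non-conspecific is
farther than its furthest conspecific; MOTUs are the connected
components of sequence-similarity graphs under each clusterer's
linking rule.

## Worked example

```r
library(barcodegap)

sim  <- generate_dataset(simulation_spec(n_species = 50, seed = 7))
ds   <- qc_filter(sim$dataset)$dataset          # >500 bp, <1% ambiguity
dm   <- distance_matrix(ds, model = "K2P")
maps <- taxon_maps(ds)
dm
#> barcode_dist: 269 sequences, model K2P (pairwise deletion)
#>   range 0.00% - 32.15%, 0 inestimable pair(s)

sm <- divergence_summaries(dm, maps$species, maps$genus_of_species)
sprintf("mean intraspecific: %.2f%% (%d comparisons)",
        100 * sm$intraspecific$mean, sm$intraspecific$n_comparisons)
#> "mean intraspecific: 0.28% (785 comparisons)"
sprintf("mean congeneric: %.2f%% (%d comparisons)",
        100 * sm$congeneric$mean, sm$congeneric$n_comparisons)
#> "mean congeneric: 7.07% (1692 comparisons)"

gap_profile(dm, maps$species)
#> gap_profile: 269 sequences, 50 species ( 8 singletons )
#>   barcode gap present for 42 of 42 species with >= 2 individuals

panel <- run_identification_panel(dm, maps$species)
subset(panel, threshold_name == "q95_intra" & count > 0)
#>    criterion threshold_name   threshold           outcome count        pct
#> 5        BCM      q95_intra 0.006118024           correct   260 99.6168582
#> 8        BCM      q95_intra 0.006118024 no_identification     1  0.3831418
#> 9        BIC      q95_intra 0.006118024           correct   260 99.6168582
#> 12       BIC      q95_intra 0.006118024 no_identification     1  0.3831418

part <- abgd_partition(dm, P = 0.01, X = 1.5)
part
#> motu_partition: ABGD_initial - 50 MOTUs over 269 sequences
classify_species(part, maps$species)
#> concordance_report: 50 species
#>   MATCH      50 (100.00%)
#>   SPLIT       0 ( 0.00%)
#>   MERGE       0 ( 0.00%)
#>   MIXTURE     0 ( 0.00%)
```

Reading the output: the simulated library reproduces the statistical
shape of a real regional barcode library (sub-percent divergence within
species, ~7% among congeners), every multi-sequence species shows a
barcode gap, better than 99% of leave-one-out queries are correctly
named at the empirical 95th-percentile threshold (0.61%), and
barcode-gap discovery at a 1% prior recovers exactly the true 50
species. Real libraries carry deep intraspecific splits and shallow
interspecific merges; inject them with the `split_injections` /
`merge_injections` arguments and the same report surfaces them as
SPLIT / MERGE / MIXTURE species and failed gap verdicts.

On real data, start from `read_fasta_with_metadata()` (aligned FASTA +
TSV metadata; BOLD-style column names can be remapped via `col_map`),
or run everything from one YAML configuration with `run_pipeline()` —
see `inst/extdata/toy_config.yaml` for a minimal example and the
package vignette for the method details.

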