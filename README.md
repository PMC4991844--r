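# gooseDiet

DNA-metabarcoding diet analysis for herbivorous waterbirds, built around a
short plant chloroplast barcode (*trnL* (UAA) with the c/h primers) and a
local reference library of candidate food plants. The package covers the
three layers such a study needs:

1. **Marker evaluation** — Kimura two-parameter (K2P) distances with
   pairwise deletion and saturation flags, per-genus/per-family divergence
   summaries, UPGMA trees with the species monophyly resolution rate (Rf),
   the barcoding-gap test (min inter-specific > max intra-specific
   distance), and a deterministic marker ranking.
2. **Amplicon pipeline** — paired-end merging by ungapped overlap,
   demultiplexing by exact 8-nt tag + primer match (IUPAC-aware), mean-Q30
   and 100-bp filters, dereplication, greedy centroid OTU clustering at 98%
   identity, and Smith–Waterman assignment against the reference library
   with strict thresholds (coverage > 98%, identity > 98%,
   e-value < 1e−50) and a lowest-common-ancestor fallback when several
   taxa tie: one species → species rank, several congeneric species →
   genus, several confamilial genera → family.
3. **Diet summaries** — per-group read percentages (Fs) over assigned
   reads, per-sample occurrence, and a rank-aware comparison with
   microhistology percentages (Fm), where a genus-level record in one
   method matches a congeneric species-level record in the other.

A synthetic-data generator (reference libraries with controlled divergence,
tagged error-bearing read pairs drawn from known diet proportions, full
per-read provenance) makes every stage testable without any external data.
The K2P formula, with transition proportion *P* and transversion proportion
*Q* over comparable sites, is
`d = -1/2·ln(1 − 2P − Q) − 1/4·ln(1 − 2Q)`; local-alignment e-values use
the ungapped Karlin–Altschul statistic `E = K·m·n·exp(−λS)` calibrated for
the +1/−2 scoring scheme (λ = 1.33, K = 0.621).

## Worked example

Simulate a small two-family plant library, generate tagged read pairs from
a 75/25 two-species diet at 0.5% per-base error, and run the pipeline:

```r
library(gooseDiet)

lib <- simulateReference(2, 2, 2, seq_len = 180, species_subs = 6,
                         genus_subs = 12, seed = 42)
lib
#> ReferenceLibrary with 8 sequences, 8 species, 2 families, 8 identical-sequence groups

sheet <- simulateSampleSheet(2, groups = "G1", seed = 42)
species <- refTaxonomy(lib)$species
sim <- simulateReads(lib, sheet, setNames(c(0.75, 0.25), species[c(1, 3)]),
                     n_reads = 1000, error_rate = 0.005, seed = 42)
res <- runPipeline(sim$fwd, sim$rev, sheet, runConfig())
res$accounting
#>   sample pair_end retained uniques otus
#> 1    S01      734      734     417   18
#> 2    S02      721      721     395    6

asn <- assignOtus(res$otus, lib)
dt <- dietTable(asn, res$otus, res$sample_groups, refTaxonomy(lib))
dt[, c("group", "taxon", "rank", "n_reads", "fs")]
#>   group     taxon    rank n_reads       fs
#> 1    G1 G01.1 sp1 species    1077 74.84364
#> 2    G1 G01.2 sp1 species     362 25.15636

recoveryReport(sim$truth, dt, res$sample_groups)$mean_abs_error
#> [1] 0.00156
```

About 27% of the 2,000 pairs are discarded: the demultiplexer requires a
perfect tag + primer match, so any sequencing error in those 58 constrained
bases drops the read — the same order of loss the protocol shows on real
data. The surviving reads recover the programmed 75/25 mixture to 0.16
percentage points; high-error reads fall below the 98% clustering identity,
form singleton OTUs, and either still assign to the right species or stay
unassigned (they are excluded from the Fs denominator, never misassigned).

The packaged `inst/extdata/` fixtures hold the published goose-diet tables
(read counts, Fs, Fm for greater white-fronted goose and bean goose) and
the 70-species Shengjin Lake reference taxonomy; `taxonShares()` and
`compareMethods()` reproduce the printed family shares (73% Poaceae, 26%
*Carex* for the white-fronted goose; >99% *Carex* for the bean goose) and
the two microscopy-only taxa.

A thin command-line wrapper with `markers`, `refdb`, `run`, `assign`,
`diet` and `simulate` subcommands lives at
`inst/scripts/gooseDiet-cli.R`.

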