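---
title: "Diet metabarcoding of herbivorous waterbirds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet metabarcoding of herbivorous waterbirds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gooseDiet)
```

## The problem

Herbivorous geese wintering on lake meadows (greater white-fronted goose,
bean goose) feed on sedges, grasses and a narrow set of other wetland
plants. Classical microhistology — identifying plant epidermis fragments in
feces under a microscope — is laborious and rarely resolves food items below
genus. DNA metabarcoding replaces the microscope with a short chloroplast
barcode (here the *trnL* (UAA) intron amplified with the c/h primers):
pooled fecal amplicons carry an 8-nt sample tag on each primer, are
sequenced, demultiplexed, clustered into operational taxonomic units (OTUs),
and matched against a local reference library of candidate food plants.

`gooseDiet` implements that analysis end to end, plus the two pieces of
infrastructure it rests on: the marker-evaluation toolkit used to choose the
barcode locus in the first place, and a synthetic-data generator that makes
every stage testable against a known ground truth.

## Marker evaluation

Candidate barcodes are compared on three axes.

**Divergence.** Pairwise distances use the Kimura two-parameter model. For
an aligned pair with transition proportion $P$ and transversion proportion
$Q$ over comparable sites,

$$ d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q). $$

Sites where either sequence has a gap or an ambiguous base are deleted *per
pair* (pairwise deletion), not across the whole alignment. When
$1-2P-Q \le 0$ or $1-2Q \le 0$ the estimate is saturated; `k2pDistance()`
flags this rather than substituting an arbitrary large number, and
`upgmaTree()` refuses saturated matrices outright. Per genus or family,
`divergenceSummary()` reports the maximal/minimal/mean inter-specific
distance with a *population* standard deviation (the deterministic choice;
a sample SD over the handful of pairs per genus would be undefined for
single-pair groups), and the maximal intra-specific distance.

**Barcoding gap.** `barcodingGap()` is the strict test
min(inter) > max(intra). With no intra-specific pairs the result is
indeterminate (`NA`), never `FALSE`.

**Tree resolution.** `upgmaTree()` performs average-linkage clustering with
node height equal to half the merge distance, so trees are ultrametric and
cophenetic distances reproduce any ultrametric input exactly.
`resolutionRate()` (Rf) is the percentage of species whose leaves form a
monophyletic clade, computed only over species with at least two sequences —
counting singletons as trivially monophyletic would inflate Rf.

`rankMarkers()` orders candidate loci lexicographically: amplification
success, then the number of taxon groups in which the marker attains the
largest mean inter-specific divergence, then the number of groups with a
barcoding gap, then alphabetically. The ordering is a deterministic total
order and an audit table of all criteria accompanies the ranking.

### Alignment parameters

Barcodes of near-equal length are aligned globally (Needleman–Wunsch,
affine gaps, end gaps penalized) with match +1, mismatch −2, gap open −5,
gap extend −2. These are conventional barcode-scale parameters; nothing
downstream is sensitive to them at the divergences involved (≤ 20%).
Alignment is delegated to `Biostrings::pairwiseAlignment()`; the test suite
checks its scores against an independent dynamic-programming oracle on small
instances.

## The reference library

`buildLibrary()` normalizes sequences (upper case, U→T, residual ambiguity
codes → N), rejects records with more than 5% N, and collapses *exactly
identical* sequences into groups. Identity is deliberately exact: the
published library counts "unique sequences" per family, an exact notion.
Sequences differing only by terminal length (one a prefix of the other,
e.g. from differing trim points) are *not* collapsed but provoke a warning.
`resolutionOf()` gives each group its assignable rank — species if the group
holds one species, genus if several congeneric species share the sequence
(the classic *Potamogeton* case), family if several confamilial genera do
(the three-grasses case). Merging groups can only coarsen the rank, never
refine it; a property test asserts this monotonicity.

## The amplicon pipeline

Stages, in order, with their discard categories (the runner asserts
`reads_in == reads_out + sum(discards)` after every stage):

1. **Merge** (`mergePairs()`): the reverse read is reverse-complemented and
   the best *ungapped* overlap (maximizing matches − mismatches) is taken,
   subject to `mergeMinOverlap` (default 20 nt) and
   `mergeMaxMismatchFrac` (default 0.1). Overlap bases take the
   higher-quality call; posterior quality is the maximum of the two scores
   when the calls agree and their absolute difference when they conflict,
   capped at Q41. Ungapped overlap means an indel sequencing error in the
   overlap causes rejection rather than a misaligned merge — the matching
   error model is substitution-only.
2. **Demultiplex** (`demultiplexReads()`): a read is assigned to a sample
   iff it begins with that sample's 8-nt tag + forward primer and ends with
   the reverse-complemented reverse primer + tag, all matched exactly
   (primer IUPAC codes match their degeneracy sets). Reads containing any
   `N` are discarded first; reads matching zero or multiple samples are
   counted separately. Tags and primers are then trimmed.
3. **Filter** (`qualityFilter()`): keep reads with length ≥ 100 nt (exactly
   100 is kept) and mean Phred ≥ 30. "Quality score less than 30" is read
   as the *mean* per-read score; a per-base minimum of Q30 would discard
   nearly all real reads. Both alternatives remain available
   (`qualMode = "min"` and the usearch-style expected-error mode
   `qualMode = "ee"` with `maxExpectedErrors`).
4. **Dereplicate** (`dereplicate()`): exact-sequence grouping with
   per-sample counts, ordered by abundance then lexicographically.
5. **Cluster** (`clusterOtus()`): greedy centroid clustering at 98%
   identity in dereplication order, so centroids are the most abundant
   variants. Identity is matches over alignment columns including end gaps.
   For equal-length pairs the ungapped substitution identity is used
   directly (merged substitution-error amplicons have equal lengths); pairs
   of unequal length are resolved by global alignment, and a pair whose
   length ratio is already below the threshold is rejected without aligning
   (identity can never exceed min(len)/max(len)). `otuAudit()` re-verifies
   the membership invariant after the fact.

No chimera detection is performed; the runner leaves the stage boundary
where such a filter would slot in.

## Taxonomic assignment

Each OTU representative is aligned locally (Smith–Waterman, both strands)
against every library sequence; exhaustive dynamic programming is entirely
adequate at local-library scale and avoids any seeding heuristics. Hits are
filtered with *strict* thresholds exactly as the protocol states them:
query coverage > 98%, identity > 98%, e-value < 1e−50. The e-value is the
ungapped Karlin–Altschul statistic $E = K m n e^{-\lambda S}$; $\lambda$
solves $\tfrac14 e^{\lambda \cdot \mathrm{match}} + \tfrac34
e^{\lambda \cdot \mathrm{mismatch}} = 1$ under uniform base frequencies and
$K$ comes from the standard series over the score random walk
(`calibrateEvalueParams()`; for +1/−2 this gives λ = 1.33, K = 0.621,
matching the published constants for that scheme). With a local reference
library any near-full-length match sits far below 1e−50, so identity and
coverage dominate in practice. Coverage is *query* coverage; subject
coverage is also reported for audit.

Hits tied at the maximum score after filtering form the tie-set. If the
tie-set holds one species, the OTU is assigned at species rank; otherwise
it is assigned at the lowest rank (genus, then family) containing every
tied species — the lowest-common-ancestor rule. Near-ties below the maximum
score are *not* merged into the tie-set; the genus/family calls in the
motivating data come from exactly identical reference sequences, which tie
exactly.

## Diet tables and method comparison

`dietTable()` sums reads per assigned taxon over each bird group's samples;
`fs` is the percentage of the group's *assigned* reads. Unassigned OTUs are
excluded from the denominator and reported separately — the published
tables sum to ~100% under precisely this convention and never report an
unassigned fraction. When a genus-level assignment coexists with
species-level assignments of the same genus, the coarser row is labelled
"*Genus* spp. (except ...)" so that coarse and fine rows partition the
reads. `presenceTable()` reports per-sample incidence.

`compareMethods()` matches metabarcoding detections against microhistology
detections rank-awarely: exact labels first, then a genus-level record in
one method matches a congeneric species-level record in the other, and
family-level records match any finer record of the family. Matching is
one-to-one and processed in label-sorted order, which makes it symmetric
under swapping the two methods (a property test asserts the swap identity).
Records whose names are absent from the reference taxonomy are matched by
string only and flagged.

## The synthetic-data generator

`simulateReference()` draws a root barcode uniformly and evolves it down a
balanced family/genus/species tree with a fixed number of substitutions per
branch at a 2:1 transition:transversion ratio (K2P-like). Defaults (200 nt,
4 substitutions per species branch, 8 per genus branch, 16 per family
branch) give within-genus identities around 96% and cross-genus identities
well below the 98% OTU threshold — the regime of the real *trnL* library,
where most species are separable but congeners are close. Optional planted
identical-sequence groups reproduce the two resolution-limiting cases
(five congeneric species sharing one sequence; three confamilial genera
sharing one). `simulateSampleSheet()` generates 8-nt tags with pairwise
Hamming distance ≥ 3, so one sequencing error cannot move a read between
samples under the perfect-match rule, and uses the *trnL* c/h primer pair
by default.

`simulateReads()` draws per-sample taxon counts multinomially from the
programmed proportions, builds tag+primer+barcode+primer′+tag′ molecules,
and emits overlapping 150-nt read pairs with i.i.d. substitution errors
(no indels — the merge model is ungapped; rejected merges are exercised via
the error knobs instead). Qualities are constant Q35, or a two-state
degraded model with mean Q25 to exercise the Q30 filter. The truth object
records per-read provenance, so tests can verify, read by read, that e.g.
exactly the N-carrying reads die at demultiplexing.

What the generator does *not* emulate: PCR amplification bias (the real
study's main suspected distortion), chimeras, indel sequencing errors by
default, and quality-dependent error rates. Passing the recovery tests
therefore shows the *computational* pipeline is unbiased and conservative —
it does not show that real read proportions equal diet proportions, which
is a property of PCR, not of this code.

## Validation scale and expectations

The acceptance checks run at desk scale, sized to finish in minutes on one
CPU while keeping the statistics meaningful:

- K2P: 200 random pairs (≤ 50 nt) against an independent K80
  implementation, agreement to 1e−12.
- UPGMA: 50 random ultrametric matrices (n ≤ 8) reconstructed exactly from
  cophenetic distances; every output ultrametric.
- Pipeline: 3 samples × 2000 read pairs at 0.5% per-base error —
  conservation identities at every stage and monotonicity of the quality
  filter.
- Recovery: 20 seeds of the same design with two taxa at 75/25%. With the
  perfect-match demultiplexing rule, ~25% of error-bearing reads are
  discarded (comparable to the real study's retention rates), leaving
  roughly 4,500 assigned reads per seed; the binomial sampling floor is
  then ~0.6 pp and the measured mean |Fs error| sits around 0.4–0.7 pp,
  under the 1-pp acceptance bound. With the error rate at zero, recovery is
  exact: Fs equals the realized multinomial draw to machine precision.

## Known limitations

- Marker evaluation aligns pairs, not a multiple alignment; distances can
  differ slightly from MSA-based ones for indel-rich loci.
- The e-value calibration is ungapped; gapped statistics would require
  simulation, and at local-library scale the threshold is inert either way.
- Whether the coverage threshold of the original protocol was query- or
  subject-relative is not recoverable; query coverage is enforced and
  subject coverage reported.
- The residual "(except ...)" labelling lists all co-present finer taxa of
  the coarser row's group, which is self-consistent but not identical to
  the published table's own (internally inconsistent) except-lists.
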