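---
title: "Metagenome capture: detecting preserved lake microbiome DNA in sediments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metagenome capture: detecting preserved lake microbiome DNA in sediments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedcapture)
```

## The problem and the method

Lake sediments archive DNA deposited from overlying water columns, but that
historical signal is buried under the DNA of microorganisms indigenous to the
sediments themselves. `sedcapture` implements *metagenome capture*: the
unassembled reads of a sediment metagenome are recruited against the assembly
of an overlying compartment — always in the downward direction of DNA
preservation (surface water SW → top sediment TS → bottom sediment BS) — and
the distribution of alignment identities is used to delineate closely related
sequences (putative historical DNA plus shared populations) from the
distantly related background. Three directional designs are admitted:
SW_A → TS_R, SW_A → BS_R and TS_A → BS_R; any upward pairing is rejected as a
design error.

The pipeline is, in order:

1. **Permissive recruitment.** Every focal read receives at most one best
   alignment against the reference assembly at a permissive ~70% identity
   floor, so the full shape of the identity distribution is observed.
2. **Threshold delineation.** The histogram of best-hit identities is
   smoothed with a Gaussian kernel; when it is bimodal, the capture threshold
   is placed at the density minimum between the two dominant modes. The
   fallback, used when fewer than two modes are found, is the conventional
   90% cut separating closely (≥ 90%) from distantly (< 90%) related
   populations.
3. **Conserved-scaffold filtering.** Ribosomal and transfer RNA genes are
   shared at high similarity across distantly related taxa, so hits on
   scaffolds carrying an rRNA or tRNA feature are removed; keeping them would
   overestimate DNA preservation.
4. **Accounting.** The captured read count is normalized by the total
   unassembled read count of the recruitment effort and reported as a
   one-decimal percentage (round half-up). Both pre- and post-filter counts
   are retained.
5. **Profiling and ordination.** Free and captured metagenomes are profiled
   as coverage-weighted taxonomic compositions, then compared by
   chord-transformed PCA and by Ward clustering of Bray-Curtis
   dissimilarities.

## Alignment model and identity semantics

Published read mappers rarely define their identity arithmetic precisely, so
the package fixes its own, fully recomputable contract:

\[
\mathrm{identity} = 100 \times \frac{\mathrm{matches}}
{\mathrm{matches} + \mathrm{mismatches} + \mathrm{gap\ columns}}
\]

with every gap column (a read base against a gap, or a gap against a
reference base) counted once, and N never counting as a match. Every emitted
hit stores the three counts, so the identity can be re-derived exactly from
the output.

Recruitment is seed-and-extend: exact k-mer seeds (default k = 13) define
candidate reference windows, and a full affine-gap local alignment (match +1,
mismatch −1, gap open −2, gap extend −1) is computed inside each window. A
hit is reported when it reaches `min_identity` and covers at least
`min_aligned_fraction` (default 0.9) of the read; this glocal behaviour —
whole read aligned up to soft ends — approximates standard recruiters without
reproducing any specific tool. Tie-breaking is fully deterministic: score,
then identity, then matches, then scaffold id, reference position and strand,
so recruitment of identical inputs is byte-identical.

The package carries its own referee: `oracle_align()` is an independently
written, exhaustive full-matrix dynamic program with no seeding or windowing,
restricted to small inputs. Both implementations share the scoring scheme and
the traceback preference order (diagonal over reference-gap over read-gap,
gap open over extend), so wherever the seeded path examines the optimal
window its counts agree exactly with the oracle's. The test suite exercises
this agreement on hundreds of randomized instances; the comparison is run
with k = 8, short enough that seeding is effectively exhaustive at the
divergences sampled (0–15%), which isolates the alignment semantics from seed
sensitivity. At the default k = 13, reads beyond roughly 15% divergence can
lack a clean seed and go unmapped; that regime lies far below every capture
threshold, so it does not affect the method's results, but it is the reason
the equivalence tests pin the seed length.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_identity` | 70 (survey), 90 (capture) | permissive floor and stringent capture threshold, percent identity |
| `min_aligned_fraction` | 0.9 | fraction of the read that must lie inside the alignment |
| `k` | 13 | exact seed length, bases |
| `band_width` | 16 | window margin around seed diagonals, bases |
| smoothing bandwidth | 1.0 | Gaussian kernel SD for the identity histogram, identity points |
| peak prominence | 5% of max | minimum prominence for a histogram mode to count |
| profile window | 1 kb | window for reference-genome recruitment profiles |
| spacer | 200 N | spacer between concatenated reference genomes |

The 90% fallback threshold and the ~70% permissive floor are the
conventional values for delineating close from distant populations in
fragment recruitment. The derived threshold is preferred when the histogram
is genuinely bimodal; on the simulated systems below it lands within about a
point of 90.

## What the simulator emulates

`simulate_lake()` generates a lake system with complete ground truth. Its
defaults are the package's study conditions, set to values a freshwater
metagenomicist would call realistic at desk scale:

* **Communities.** 8 water-column genomes and 8 shared sediment genomes of
  40 kb (split into 5 kb scaffolds, the typical size order of metagenome
  scaffolds), 4 distant background lineages, 6 bottom-only deep genomes;
  log-normal abundances (σ = 1), the conventional community abundance model.
* **Divergence tiers.** Historical reads derive from relatives of the water
  genomes at 3% substitution divergence — comfortably recoverable at ≥ 90%
  identity; background lineages sit at 25% divergence, which recruits
  permissively around ~75% identity and forms the distant mode of the
  bimodal histogram. Reads carry 0.2% substitution errors (a modern
  short-read error rate).
* **Historical fraction.** 0.5% of bottom-sediment reads are historical by
  default, matching the sub-percent regime reported for real lake systems;
  top sediments get 1%. Historical fragments follow a log-normal length
  model (median 120 bases) truncating the 150-base reads, a mild degradation
  signature.
* **Conserved decoys.** A 1.5 kb rRNA-like sequence is planted at 99%
  identity into two genomes of each class (water, shared sediment, distant),
  flagged as rRNA in the annotations. These create exactly the
  false-positive channel the conserved-scaffold filter exists to close.
* **Read counts.** 20k/20k/50k reads for SW/TS/BS; the recovery experiments
  use 50k bottom-sediment reads.

Assemblies are the source genomes themselves: assembly is out of scope, and
capture operates on any scaffold set. The simulator does not model
deamination damage patterns, chimeras, platform-specific error profiles,
strain mixtures within a population, or incomplete assembly of the reference
compartment — passing tests therefore demonstrate correctness of the capture
computation under its stated assumptions, not robustness to every property
of real sediment data. The closed-form companion
`truth_capture_fraction()` integrates the binomial tail of per-read mismatch
counts at each tier's compound divergence-plus-error rate, giving an
aligner-independent expectation that the end-to-end pipeline is required to
match within binomial sampling error.

## Numerical choices and degenerate inputs

* Internal coordinates are 1-based inclusive throughout, matching GFF3 on
  disk and the Bioconductor convention; no off-by-one conversion layer
  exists to get wrong.
* Report percentages round half-up to one decimal (`5.45 → 5.5`); full
  precision is kept internally. This matches how capture tables are printed.
* N bases never count as matches and score as mismatches, which guarantees
  masked (all-N) intervals cannot recruit reads and concatenation spacers
  cannot host chimeric alignments.
* Paired-end mates are treated as independent reads; read counts count each
  mate once. Nothing in the pipeline uses pairing.
* An empty recruitment yields a flagged empty histogram; deriving a
  threshold from it is an error, and the pipeline then falls back to 90.
* Zero-weight and unclassified genes are excluded from profile denominators
  (configurable); profiles always renormalize to 100%.
* Bray-Curtis between two all-zero samples is defined as 0 with a warning.
* PCA signs are fixed by making the largest-magnitude loading of each
  component positive; Ward clustering defaults to the squared-dissimilarity
  (Ward.D2) variant, and applying it to non-Euclidean Bray-Curtis
  dissimilarities follows common ecological practice, uncorrected — a known
  caveat, not an error.

## Design choices where the field leaves room

* **Gene weight in profiles** is scaffold depth × gene length; pure depth
  weighting is available by flag. Length weighting prevents short genes from
  being over-represented when a scaffold's depth is shared by all its genes.
* **Filtering order**: the identity threshold is applied first, then
  conserved-scaffold removal; the percentage denominator is always the total
  input read count and is unaffected by either filter. Both the pre- and
  post-filter counts are reported, since published accounting tables can be
  read either way.
* **Display promotion**: at the phylum display level, proteobacterial
  classes replace "Proteobacteria" and viral lineages pool into a single
  "Viruses" taxon, mirroring how such heat maps are conventionally drawn.
* **Duplicated samples in ordination** co-locate exactly; note that adding a
  duplicate re-weights the covariance, so the axes themselves are not
  invariant under duplication — the tests assert co-location, which is the
  property that holds.
* The reference-genome module reports quantitative per-genome mapped
  fractions at ≥ 90% identity rather than a binary captured/not-captured
  call, leaving interpretation to the user.

## Problem sizes used by the tests

The validation suite runs entirely on simulated systems: oracle-equivalence
on 200 randomized read/assembly instances (≤ 5 kb references), threshold
derivation on 100 replicate two-Gaussian mixtures (modes 97 and 80, SD 2,
2 000 draws per mode — a realistic permissive-pass count at desk scale), and
parameter recovery on four lakes with 50 000 bottom-sediment reads each at
historical fractions 0, 0.2%, 1% and 5%. The recovery experiments disable
conserved decoys so the closed-form truth (which models tiers, not decoy
leakage) is the exact expectation; decoy leakage and its suppression are
exercised separately with the historical fraction at zero, where conserved
decoys are the *only* cross-compartment similarity and scaffold filtering
must remove at least 90% of captured reads.

## Known limitations

* The aligner is a faithful, deterministic recruiter, but it is not a
  reimplementation of any published mapper; absolute mapped fractions on
  real data will differ from tool to tool even at the same nominal
  threshold.
* Relative coverage uses a documented stand-in for annotation-pipeline
  aggregation (depth × gene length over classified genes); multi-copy genes
  are counted as annotated.
* Capture against a snapshot reference assembly bounds what can be
  recovered: lineages absent from the reference cannot be captured, and the
  simulator's recovery results quantify the method under its own
  assumptions rather than promising recovery rates in real sediments.
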