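---
title: "Recruitment profiling and the DNA-fragmentation intactness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recruitment profiling and the DNA-fragmentation intactness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragrec)
```

## Overview

`fragrec` implements two connected pieces of methodology for
metagenomes of low-diversity communities (its design case is a cheese
ecosystem of starter and non-starter lactic acid bacteria):

1. **Recruitment-plotting profiling**: species are identified and
   quantified by aligning quality-controlled shotgun reads to a custom
   database of reference genomes and applying explicit decision rules to
   the alignment table.
2. **The intactness model**: an analytic account of why amplicon-based
   abundances diverge from shotgun abundances when DNA fragment size
   differs between species.

The package also ships a ground-truthed synthetic-community generator so
both pieces can be exercised and falsified at desk scale. This vignette
records the models, the parameters that matter, and the design choices
made where the methodology left them open.

## The recruitment pipeline and its decision rules

A read-vs-genome alignment table (blast6 or PAF; or the built-in
`toy_align()`) is reduced to per-genome *recruitment profiles* in five
steps, all thresholds living in `filter_config()`:

* **Host removal.** A read is discarded when its alignment to the host
  genome has identity *and* query coverage strictly greater than 60%.
  Query coverage uses the read length the artifact sees (the merged-read
  length); values exactly at 60 are kept, following the strict
  "higher than" wording of the source procedure.
* **Quality filter.** Short reads: identity ≥ 60% and alignment overlap
  ≥ 50 bp. Long reads: identity ≥ 70% and read length ≥ 500 bp. Removal
  is specified as "lower/shorter than", so values exactly at a threshold
  are kept. The filter is idempotent and order-preserving.
* **Best hit.** Per read, only the maximal-bitscore hit survives. Exact
  bitscore ties are broken uniformly at random — but reproducibly: tied
  candidates are put in a canonical order (subject id, coordinates) and
  one is drawn from an RNG seeded by `(tie_seed, read id)`. Results are
  therefore independent of row order and bit-identical across reruns,
  while still being "random" across reads; changing `tie_seed` changes
  only tied reads.
* **Retention.** A species is kept iff (a) its genomes pooled recruit
  *strictly more than* `min_reads_retain = 300` reads and (b) the breadth
  of coverage of its best-recruiting genome — the fraction of
  `spread_bins = 100` equal genome bins holding at least one read
  midpoint — reaches `spread_min_breadth = 0.5`. Breadth is the
  quantitative surrogate for the visual "reads spread over the whole
  genome" check of recruitment plots; both knobs are configurable.
  Pooling counts across same-species genomes avoids penalizing species
  whose reads are split among near-identical subspecies genomes, while
  per-genome breadth keeps the spread criterion meaningful.
* **Profiles.** Per genome: read count, base count (sum of *full* read
  lengths, not aligned spans), and the per-bin counts that feed breadth,
  gap detection (`detect_coverage_gaps()`, refused below 300 reads where
  empty bins reflect depth, with `gap_concordance()` as the cross-sample
  Jaccard), and plot export.

Read accounting is conserved and asserted by `run_pipeline()`: input =
recruited + host-removed + filter-removed + unaligned + unknown-subject.

## Abundance modes and the read-length sweep

Short-read abundances are recruited-read counts normalized over retained
species. Long-read abundances are *base-weighted*: each read contributes
its full length in bp, which removes the dependence of read counts on the
(species-specific!) read-length distribution. `length_sweep()` recomputes
base-weighted abundances at increasing minimum read lengths — default
grid 500 bp, then 1,000–10,000 by 1,000 (the methodology names the 1–10
kbp range but no grid; the even 1 kbp grid is this package's choice) —
and `closest_threshold()` returns the threshold whose table is nearest a
reference (typically amplicon-derived) table. Distance is L1 on the union
of species, missing species counted as zero; L1 was chosen because the
source criterion is only "closest similarity", and the full
distance-vs-threshold profile is returned so users can apply another
metric. Ties go to the smallest threshold.

`method_comparison_stats()` is a per-species paired *t*-test plus an
optional Spearman correlation against a per-sample covariate, flagged at
raw p < 0.05 with **no multiplicity correction** — deliberately mirroring
the source analysis rather than silently improving it.

## The intactness model

Idealize a genome's DNA as cut into consecutive pieces of exactly `S`
bp. A target of length `L` amplifies only if wholly contained in one
piece. Of the `S` possible phases of the cutting grid relative to the
target, exactly `S − L + 1` leave it intact (circularity ignored), giving

$$I(S, L) = \frac{S - L + 1}{S} \; (S \ge L), \qquad I = 0 \; (S < L).$$

`intact_fraction()` is this closed form; `infer_effective_fragment_size()`
is its exact inverse `S = (L − 1)/(1 − I)` (undefined at `I = 0`, where
only the bound `S < L` is implied, and at `I = 1`, where `S` is
infinite); `amplicon_bias_ratio()` is `I(S, 1500)/I(S, 300)`, the
predicted under-representation of a species in full-length 16S
sequencing relative to V4 sequencing. `predict_amplicon_abundance()`
weights true abundances by `I(S_i, L)` and, optionally, by 16S copy
number — optional and off by default because copy number is discussed as
a bias direction, not a fitted correction.

`S` is a hypothetical, uniform fragment size. For empirical read sets
there is no canonical estimator of `S` from a non-uniform length
distribution, so the package takes no stance: evaluate the model at the
median and/or mean recruited read length and label which you used.

## The synthetic generator: what it emulates, and what it does not

`simulation_config()` states the simulated world; the defaults are the
package's standing test conditions and are not tuned per test:

| parameter | default | why |
|---|---|---|
| species | 5 × 200 kb genomes, abundance 0.2 each | low-diversity community at desk scale |
| fragmentation | lognormal, median 1 kb for one species, 8 kb for the rest, `sdlog` 0.4 | one heavily fragmented taxon vs intact majority; lognormal is positive, right-skewed, two interpretable parameters |
| subspecies | species 1 has 2 genomes at 1% divergence | near-identical subspecies genomes that co-recruit |
| interspecies divergence | 0.15 | species distinguishable but cross-alignable above the 60% filter |
| target locus | 1,500 bp at position 1,001 | full-length 16S-like gene, fixed position |
| depth | 300 genome copies; 50,000 short / 20,000 long reads | minutes on one CPU |
| error rates | 0.001 short, 0.02 long | post-QC Illumina- and nanopore-like substitution rates |

**Cutting model.** Each genome copy is cut sequentially with i.i.d.
lognormal lengths; the *first* fragment is truncated by a uniform random
phase and the last at the genome end, so fragments exactly partition the
genome (base conservation is exact and tested). The random phase is the
load-bearing numerical choice: it makes the cutting grid uncorrelated
with gene coordinates, and with `sdlog = 0` it reproduces `I =
(S − L + 1)/S` *exactly* — a fixed-phase exact-`S` cut would be
deterministic for a fixed target and could not match the closed form.
With no cutting at all (fragment scale ≫ genome), every target is intact
and predicted abundances equal truth.

**Reads.** Long reads are the fragments themselves (optionally
subsampled), so their length distribution *is* the fragment-length
distribution. Short reads emulate a merged-pair library: an insert of
500–1,500 bp is placed uniformly on a fragment chosen with probability
proportional to its length, and the first ≤ 500 bp on a random strand
become the read. Length-proportional sampling is what makes short-read
counts unbiased by fragmentation — the mechanism under study predicts
exactly this asymmetry between the two platforms.

**Not emulated:** indels and platform error profiles (homopolymer
artifacts, quality scores), PCR efficiency, primer mismatch and
chimeras, plasmids/phages, GC bias. Divergence is substitution-only so
the ungapped `toy_align()` is a valid oracle on these genomes — a green
end-to-end test establishes that the decision rules and accounting are
correct, *not* that the pipeline tolerates real indel-rich nanopore
data or real inter-strain structural variation.

**Amplicon counts.** `simulate_amplicon_counts()` marks a copy's target
amplifiable iff no cut falls strictly inside it, simulating cut
positions only up to the target end (a renewal process — distributionally
identical to cutting the whole genome, and what keeps 100,000-copy runs
in seconds). The independent brute-force route — `cut_genome_copies()`
to explicit fragments, then `count_intact_targets()` — is kept separate
precisely so the closed form, the fast simulator and the enumeration
oracle can disagree if one of them is wrong; the acceptance suite checks
all three against each other within 3 binomial σ.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive on query and subject (blastn
  convention); reverse-strand hits store `subject_start > subject_end`.
  PAF identity is matches / block length; PAF rows get the same monotone
  score used by `toy_align()` (`2·matches − 3·mismatches`, floored at 0)
  because PAF carries no bitscore and best-hit logic only needs a
  deterministic monotone score.
* Abundance tables must sum to 1 within 1e-9 (asserted at construction);
  the inverse-model round-trip is exact to 1e-9 relative tolerance.
* A species whose reads all fall below a sweep threshold stays in the
  table at fraction 0; the sweep errors only when a threshold empties
  *everything*.
* `read_length_distribution()` returns a point mass when all lengths are
  equal (a kernel bandwidth of 0 is not an error worth surfacing) and
  refuses fewer than 30 reads.
* Jaccard gap concordance of two empty gap sets is defined as 1 (two
  gap-free profiles agree).
* `gap_concordance`, `count_intact_targets` and `closest_threshold`
  validate their structural preconditions (same genome/binning,
  exact partition, overlapping species sets) rather than guessing.

## Known limitations

* The effective fragment size `S` of real DNA is not uniform; the model
  is an explanatory device, and the package deliberately reports it
  evaluated at user-chosen summaries rather than fitting it.
* `toy_align()` is ungapped and unchained; it is a test oracle and a
  desk-scale stand-in, not a replacement for blastn or minimap2 on real
  data (production alignment tables enter through `read_alignment_table()`).
* Breadth-of-coverage is a surrogate for expert inspection of
  recruitment plots; a decoy genome with uniformly scattered spurious
  hits above both filters would pass it.
* The paired *t*-test inherits the source analysis' lack of multiple
  testing correction and its compositional caveats (no CLR or
  differential-abundance modelling is attempted).
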