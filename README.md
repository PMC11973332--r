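# fragrec

Fragment **rec**ruitment profiling and DNA **frag**mentation bias modelling
for metagenomes.

## The problem

Shotgun metagenomics of low-diversity food fermentations (e.g. cheese)
and full-length 16S rRNA gene amplicon sequencing of the same samples can
disagree sharply about species relative abundances, even when both
recover the same community. One overlooked mechanism is *species-specific
DNA fragmentation*: when the DNA of a species (a dying starter
lactococcus, say) is degraded into short fragments, shotgun sequencing of
500–1,500 bp inserts still samples it faithfully, but a ~1,500 bp
amplicon target must be *intact* on a single fragment to amplify at all.
Long-read shotgun data make the mechanism visible directly: raising the
minimum read length progressively removes the fragmented species.

`fragrec` provides, in one R package:

* **Recruitment-plotting taxonomic profiling** — best-hit filtering of
  read-vs-genome alignments (blast6 or PAF) against a custom multi-genome
  database: identity ≥ 60% and overlap ≥ 50 bp for short reads,
  identity ≥ 70% and length ≥ 500 bp for long reads, host-read removal at
  identity and query coverage > 60%, highest-bitscore best hit with
  seeded random tie-breaking, species retention requiring **more than
  300** recruited reads and well-spread coverage (breadth over 100 genome
  bins), coverage-gap fingerprints, and read-count ratios between
  same-species (subspecies) genomes.
* **Abundance estimation** — read-count relative abundances for short
  reads; base-weighted abundances (summed read bp) for long reads; a
  minimum-read-length sweep (0.5–10 kbp) with the threshold closest (L1)
  to a reference/amplicon table; minority pooling; paired per-species
  method comparisons (paired *t*, Spearman ρ).
* **The intactness model** — the fraction of intact length-`L` targets
  under an idealized uniform fragment size `S`:

  `I = (S − L + 1)/S` if `S ≥ L`, and `I = 0` if `S < L`,

  with its closed-form inverse `S = (L − 1)/(1 − I)`, the full-length
  (1,500 bp) versus V4 (300 bp) bias ratio `I(S, 1500)/I(S, 300)`, and
  copy-number-aware predicted amplicon abundances.
* **A seeded synthetic-community generator** — random genomes with
  subspecies variants, species-specific lognormal fragment-length
  distributions, shotgun short/long reads with full per-read provenance,
  and amplicon counts governed by target intactness — so every pipeline
  stage is testable against ground truth without downloads. A built-in
  ungapped seed-and-extend aligner (`toy_align`, Rcpp) stands in for
  blastn/minimap2 at desk scale.

## Worked example

Simulate the default 5-species community (200 kb genomes, equal
abundance 0.2, one heavily fragmented species with a 1 kb median fragment
size and two subspecies genomes at 1% divergence), align the 50,000
short reads with the built-in aligner, and run the full pipeline:

```r
library(fragrec)
cfg  <- simulation_config(seed = 7)
made <- make_reference(cfg)
sim  <- fragment_and_read(made$ref, made$truth)
res  <- run_pipeline(pipeline_config(ref = made$ref,
                                     reads = sim$short_reads,
                                     platform = "short",
                                     filter = filter_config(tie_seed = 7),
                                     sample_id = "demo", verbose = FALSE))
res$retention
#>     species reads breadth  best_genome retained reason
#> 1 starter_A 10045       1 starter_A_g2     TRUE     ok
#> 2 starter_B  9995       1 starter_B_g1     TRUE     ok
#> 3   nslab_C 10076       1   nslab_C_g1     TRUE     ok
#> 4   nslab_D  9985       1   nslab_D_g1     TRUE     ok
#> 5 adjunct_E  9898       1 adjunct_E_g1     TRUE     ok
res$abundance
#> Abundance table: sample demo, mode read_count
#>   sample_id   species       mode min_read_length fraction percent
#> 1      demo starter_A read_count               0 0.200904 20.0904
#> 2      demo starter_B read_count               0 0.199904 19.9904
#> 3      demo   nslab_C read_count               0 0.201524 20.1524
#> 4      demo   nslab_D read_count               0 0.199704 19.9704
#> 5      demo adjunct_E read_count               0 0.197964 19.7964
```

All five species are retained (each > 300 reads, breadth 1.0) and the
read-count abundances recover the simulated truth of 0.20 each to within
multinomial noise — short-read shotgun profiling is *unbiased* by
fragmentation, because fragments contribute reads in proportion to their
bases. Every input read is accounted for (`res$counts`): 49,999 of
50,000 recruited, 1 removed by the quality filter, none unaligned.

The intactness model says what the amplicon survey of the same community
would see:

```r
S <- c(1000, 5000, 20000)
data.frame(S, I_full = intact_fraction(S, 1500),
           I_v4 = intact_fraction(S, 300),
           bias = amplicon_bias_ratio(S))
#>       S  I_full    I_v4      bias
#> 1  1000 0.00000 0.70100 0.0000000
#> 2  5000 0.70020 0.94020 0.7447352
#> 3 20000 0.92505 0.98505 0.9390894
```

A species whose DNA is in 1 kb pieces is *invisible* to full-length 16S
sequencing (`I = 0`) yet still amplifies at the V4 locus (`I = 0.70`) —
the full-length-versus-V4 bias the model was built to explain. The
long-read counterpart (`length_sweep()` + `closest_threshold()`)
reproduces the same mechanism from read lengths; see the methods
vignette (`vignettes/fragmentation-recruitment.Rmd`).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/fragrec.R", package = "fragrec"))')
Rscript $CLI simulate --out bundle --seed 7
Rscript $CLI align --ref bundle/genomes.fasta --meta bundle/genomes.tsv \
                   --reads bundle/short_reads.fastq --out bundle/aln.tsv
Rscript $CLI recruit --ref bundle/genomes.fasta --meta bundle/genomes.tsv \
                     --alignments bundle/aln.tsv --out results/
Rscript $CLI model --S 1000,5000,20000 --L 1500
```

Exit codes: 0 ok, 2 configuration error, 3 data error.

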