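# phanner

Analysis of phage-display panning experiments read out by paired-end deep
sequencing of degenerate antibody HCDR3 libraries.

## The problem

In phage-display panning, a library of antibody fragments whose heavy-chain
CDR3 (HCDR3) has been randomized is selected over successive rounds against
an antigen. Deep sequencing of the unselected pool (round 0) and a selected
round (round 3) of barcoded amplicons turns the experiment into a counting
problem: which HCDR3 peptides were enriched or depleted, and how did the
positional diversity of the repertoire change under selection?

phanner implements the complete analysis for libraries built on a degenerate
codon scheme of the form (NNS)₆ KBG HTK GMT — six fully variable codons
followed by three partially restricted ones — displayed with amber (TAG)
suppression, so TAG-containing members are translated with glutamine at the
suppressed position:

* paired FASTQ input with quality filtering (mean and per-base Phred
  thresholds),
* barcode demultiplexing of pooled libraries by exact (or bounded-mismatch)
  prefix match,
* extraction of the 27-nt HCDR3 by **perfect match of the flanking anchor
  sequences**, with the R2 mate consulted only when R1 fails
  ("rescued-by-R2" accounting included),
* amber-suppressed translation (TAG → Q; TAA/TGA invalidate),
* unique nucleotide and peptide counting per pool,
* per-peptide fold change FC = (c₃/N₃)/(c₀/N₀) between rounds, with
  novel/lost side-lists and stratification into mildly (FC ≥ 4 or ≤ 0.25),
  moderately (≥ 7 or ≤ 0.143) and highly (≥ 10 or ≤ 0.1)
  selected/counter-selected bands,
* positional diversity statistics in bits: Shannon entropy
  S = −Σ pᵢ log₂ pᵢ, Weblogo-style information content IC = S_max − S_obs,
  and per-position Kullback–Leibler divergence D(P‖Q) = Σ P log₂(P/Q)
  between the round-3 and round-0 profiles.

A synthetic-data generator emulates the whole experiment — degenerate
library construction, dominant clones carried by many synonymous encodings,
multiplicative per-peptide selection across rounds, barcoded 77-bp amplicon
emission with substitution errors — so the entire pipeline runs and is
tested end-to-end with exact ground truth and no external data.

Everything is tidyverse-native: functions take and return tibbles, results
have `tidy()`/`glance()` methods, and each result type has an `autoplot()`.

## Worked example

Simulate a four-pool experiment (two V-gene contexts × rounds 0 and 3,
10,000 read pairs per pool, 0.1% substitution errors) and run the full
pipeline:

```r
library(phanner)

cfg <- run_config(
  simulate = list(n_variants = 500, depth = 10000, error_rate = 0.001),
  out_dir = "phanner_out", seed = 1
)
report <- run_pipeline(cfg)
report
```

```
<phanner_report>  seed 1  hash 34e6182342bb6a3bbd1287c6923bb3b8
Read pairs: 40000

Classification:
         pool n_pairs n_valid n_rescued_r2 pct_pairs
 unclassified      21       0            0    0.0525
      vh10_r0    9997    9956          698   24.9925
      vh10_r3    9994    9937          677   24.9850
       vh4_r0    9995    9944          650   24.9875
       vh4_r3    9993    9944          718   24.9825

Unique sequences:
 pool_id n_reads_valid n_unique_nt n_unique_pep n_rescued_r2 n_unique_r2_only
 vh10_r0          9956         271          233          698               12
 vh10_r3          9937          85           61          677                1
  vh4_r0          9944         280          242          650               12
  vh4_r3          9944          87           57          718                1

Enrichment [vh4]:
 n_peptides median_fc n_selected n_counter_selected n_novel n_lost
        242         0          1                208      22    207

Enrichment [vh10]:
 n_peptides median_fc n_selected n_counter_selected n_novel n_lost
        233         0          1                204      31    203
Summed KL [vh4_nt]: 0.9101 bits
Summed KL [vh4_peptide]: 1.2230 bits
Summed KL [vh10_nt]: 1.1979 bits
Summed KL [vh10_peptide]: 1.3734 bits
```

Reading this: 39,979 of 40,000 pairs (99.95%) demultiplexed to their pools
— the 21 unclassified pairs carry a sequencing error inside the 6-nt
barcode. About 7% of valid reads were rescued from R2 after an error broke
the R1 anchor match or quality. Selection collapses diversity (280 → 87
unique nucleotide sequences in the vh4 context) and most background
peptides are counter-selected relative to the dominant clones, so the
median fold change is far below 1 while a dominant peptide is the one
strongly selected sequence. The per-residue KL divergence summarises how
strongly each HCDR3 position's residue usage shifted between rounds.

Plots:

```r
autoplot(report$enrichment$vh4$table)        # ordered fold-change series (log scale)
autoplot(report$diversity$kl$vh4_peptide)    # per-residue KL, round 3 vs round 0
autoplot(information_content(theoretical_pfm()))  # analytic library profile
```

All stage outputs (classification, counts, enrichment, entropy and KL
tables, plus the simulated FASTQ and ground truth) are written as TSV under
`out_dir`, each headed by a comment recording the seed and configuration
hash; reruns at a fixed seed are byte-identical.

A thin command-line wrapper is included at `inst/scripts/phanner.R`:

```sh
Rscript inst/scripts/phanner.R --simulate --depth 10000 --out-dir phanner_out --seed 1
Rscript inst/scripts/phanner.R --r1 R1.fastq.gz --r2 R2.fastq.gz --out-dir out
```

## Package layout

* `R/` — scheme/IUPAC model, simulator, FASTQ IO, classification and
  extraction, counting, enrichment, diversity statistics, pipeline
  orchestration
* `tests/testthat/` — unit, property and end-to-end suites (all fixtures
  generated in code)
* `vignettes/hcdr3-panning-methods.Rmd` — the models, parameter choices and
  limitations in detail
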