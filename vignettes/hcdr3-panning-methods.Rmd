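---
title: "Models and methods behind phanner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phanner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phanner)
```

phanner analyses multi-round phage-display panning experiments read out by
paired-end deep sequencing of a degenerate HCDR3 library. This vignette
explains the models and conventions the package commits to, the parameters
that matter, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## The experimental design being modelled

A 9-residue HCDR3 is randomized inside an antibody scFv displayed on phage.
The library is built from degenerate codons: positions 1–6 use NNS (N = any
base, S = G/C), which reaches all 20 amino acids while excluding the ochre
(TAA) and opal (TGA) stops; positions 7–9 use KBG, HTK and GMT, restricting
the C-terminal residues to the sets {A,G,V,S,W,L}, {M,I,L,F} and {D,A}. The
amber stop TAG *can* occur under NNS, but the display host carries a
glutamine suppressor tRNA, so TAG is translated as Q rather than terminating
the protein.

Selection proceeds in panning rounds against an immobilized antigen; the
unselected library ("round 0") and a later round (by default round 3) are
PCR-amplified with pool-identifying barcode primers into a 77-bp amplicon
(6-nt barcode + fixed upstream flank + 27-nt HCDR3 + fixed downstream
flank) and sequenced paired-end, R1 reading the amplicon strand and R2 its
reverse complement.

## Pipeline model

The analysis is three stages — filtering, classification, analysis — over a
tidy table of read pairs.

**Quality filtering.** A read passes when its mean Phred score is at least
`min_mean_phred` (default 20) *and* every base is at least `min_base_phred`
(default 10); boundaries are inclusive and an N base counts as Phred 0. The
defaults are conventional Illumina choices; the published analyses this
models never state a threshold, so both thresholds and the region they apply
to (`whole-read`, the default, or `hcdr3-only`) are configurable. All exact
guarantees the package tests are threshold-independent (they disable
sequencing errors).

**Demultiplexing.** Barcodes are the amplicon's leading bases, so comparison
is prefix-anchored. A read is assigned to the unique pool within
`max_mismatch` (default 0); ties at the minimum distance and reads outside
the budget are counted as unclassified, never guessed. The constructor
enforces pairwise Hamming distance > 2·`max_mismatch`, which makes
assignment unambiguous by construction.

**Extraction.** The 27-nt HCDR3 is located by *perfect* literal match of the
two flank anchors: extraction succeeds only if both anchors occur exactly
once, in order, exactly 27 nt apart. Failures are attributed (`no_anchor`,
`bad_length`, `low_quality`). R2 is consulted only when R1 was discarded,
after reverse-complementing it into amplicon orientation; rescued reads are
flagged so the "uniques seen only in R2" accounting is exact. A configurable
edit-distance relaxation of the anchors is deliberately absent: the
fixed-length exact match is the method's defining filter.

**Translation.** Standard genetic code with TAG read as Q (amber
suppression); TAA or TGA invalidates the sequence, since no ochre/opal
suppressor is present. A valid HCDR3 is: length 27, bases A/C/G/T only, no
unsuppressed stop. Conformity to the degenerate codon scheme is *not*
required — real libraries deviate from their theoretical profile, and
enforcing the scheme would silently discard genuine biology.

**Counting.** Exact multiset counting of unique nucleotide sequences per
pool; peptide counts fold synonymous encodings (including amber-encoded Q,
which is indistinguishable from CAA/CAG glutamine at the peptide level — the
nucleotide table preserves the distinction).

## Enrichment

For each peptide, fold change is the round-3 : round-0 abundance ratio.
Because real pool depths can differ several-fold, the default is
frequency-normalised: FC = (c3/N3)/(c0/N0); the raw count ratio is available
as `normalize = FALSE`. With the default pseudocount of 0, peptides absent
from round 0 go to a separate *novel* list rather than receiving an
arbitrary ratio, and peptides depleted to zero get FC = 0 (*lost* list);
`pseudocount = 0.5` folds both back with finite ratios. A minimum round-0
count filter (default 1) guards against ratio blow-up on singletons.

Stratification uses the three-band convention: mildly (FC ≥ 4 or ≤ 0.25),
moderately (≥ 7 or ≤ 0.143) and highly (≥ 10 or ≤ 0.1) selected /
counter-selected. Two readings of the bands are supported because the
convention is genuinely ambiguous: `exclusive` (default) assigns each
peptide its single band ([4,7), [7,10), [10,∞) and mirrored); `cumulative`
assigns a peptide to every band whose threshold it passes. Reports name the
mode used. The ordered fold-change series breaks ties lexicographically by
peptide so output is deterministic.

## Diversity statistics

All logarithms are base 2. Per-position Shannon entropy is
S = −Σ p log₂ p with 0·log 0 ≡ 0; information content is IC = S_max − S_obs
with S_max = log₂ 4 = 2 bits for DNA and log₂ 20 ≈ 4.32 bits for protein
(uniform 1/20 = 0.05 per residue). No Weblogo small-sample correction is
applied by default (an option exists), so IC estimates from few sequences
are biased upward — compare strata of similar size.

Kullback–Leibler divergence D(P‖Q) = Σ P log₂(P/Q) is computed per position
between the round-3 profile (P) and the round-0 profile (Q), after adding a
pseudocount (default 0.5 per symbol, on the count scale) to both and
renormalising. With the 10⁴–10⁵ unique sequences of a typical pool the
smoothing bias is negligible while removing zeros; with `pseudocount = 0` a
zero in Q where P has mass is an error, not an Inf.

Profiles default to *unique-sequence* weighting — every distinct sequence
counts once, so the statistics measure repertoire diversity rather than
clone abundance; count weighting is a flag. Whether the original analyses
weighted by counts is not documented, which is why both are exposed; unique
weighting is the default because the entropy computations this models are
explicitly described as unweighted. Positions are reported 1-based
(nucleotide 1–27, residue 1–9).

The theoretical profile of the codon scheme itself
(`theoretical_pfm()` + `information_content()`) gives the analytic
reference: IC = 0 at N positions, 1 bit at S/K/M positions, log₂(4/3) ≈
0.415 bits at B/H positions, 2 bits at fixed positions.

## The synthetic-data generator

The generator exists so every downstream stage has an exact oracle; its
defaults are the study conditions the package is tested under.

* **Initial pools** (`make_initial_pool()`): `n_variants` distinct random
  scheme-conforming variants share the background mass uniformly, plus the
  two dominant peptides YLLSPLLLA and VQQVNNALA at a combined
  `dominant_mass = 0.967` — the dominance level observed in the motivating
  libraries — each represented by up to 20 distinct synonymous encodings,
  because real dominant clones are carried by many codon variants rather
  than one expanded clone. The default `n_variants = 2000` is a desk-scale
  stand-in for the 10⁴–10⁵ unique sequences of a real pool, chosen so the
  full test suite runs in minutes; nothing in the pipeline depends on it.
* **Selection** (`apply_selection()`): per-round multiplicative fitness on
  peptides, f ← f·w/Σf·w, optionally followed by a multinomial bottleneck
  that emulates the finite phage population carried between rounds. Without
  a bottleneck, r rounds equal the closed form f·wʳ/Σf·wʳ, which is the
  oracle the tests use. Default `rounds = 3`, matching the panning design
  modelled (a supplementary description of four rounds elsewhere in the
  source material is treated as the typo).
* **Emission** (`emit_reads()`): amplicon = barcode + upstream flank +
  variant + downstream flank (77 bp with the default constants); R1 and the
  reverse-complement R2 receive independent i.i.d. substitution errors at
  `error_rate` (default 0.001, a typical HiSeq substitution rate). Qualities
  are two-level — Q37 for correct bases, Q2 for injected errors — so any
  extraction failure is attributable to a known error. Reads are emitted at
  amplicon length rather than padded to 150 bp: the overrun into vector
  sequence carries no information the pipeline uses. Read IDs embed the
  ground-truth variant for auditing.
* **Fixture constants.** Barcodes ACGTAC/CATACG/GTCAGT/TGACTA (pairwise
  Hamming ≥ 5); upstream flank `GCAGCTTCTCCGTACGTGAA` (contains the BsiWI
  site CGTACG and the Val-Arg-Glu codons GTA CGT GAA); downstream flank
  `TATTGGGGTCAAGGAACCTCTAGA` (Tyr codon TAT, one codon choice for the WGQGT
  framework-4 consensus, XbaI site). The flanks were chosen once, and
  verified by enumeration, so that no window of any scheme-conforming insert
  — nor any junction — can reproduce an anchor; noiseless extraction is
  therefore exact, which is what makes the closed-loop tests meaningful.

**What the generator does not emulate:** PCR amplification bias and
chimeras, indels (substitutions are the platform's dominant error mode, and
the pipeline's fixed-length exact match means indels only lower yield),
quality-score/error-rate coupling beyond the two-level scheme, and the
assembly biases that make real libraries deviate from the theoretical codon
profile. Passing closed-loop tests therefore demonstrates that the pipeline
computes its statistics correctly, not that those statistics are robust to
artefacts absent from the simulation.

## RNG and reproducibility

Every stochastic operation takes a `seed` argument evaluated in a local RNG
scope (`withr::with_seed`), so a fixed configuration reproduces every output
byte for byte, and library code never perturbs the caller's RNG state. R's
base generator is a single global stream, so per-read substreams (under
which a depth change would leave earlier reads' draws untouched) are not
provided; determinism holds at fixed parameters, which is the property the
tests rely on. Every pipeline output file embeds the seed and a hash of the
configuration.

## Degenerate inputs and tie-breaking

Empty pools, empty FASTQ records, zero-length sequences, and mismatched
R1/R2 files raise explicit errors naming the offending record where
possible. Barcode ties are unclassified, never arbitrated. Fold-change
boundary values join the band their threshold names (FC = 4 is mild).
Ordered series break ties lexicographically. Wrong-length input to the
translator is treated as a caller bug (an error), distinct from biological
invalidity (`NA`).

## A small worked run

```{r, eval = FALSE}
cfg <- run_config(
  simulate = list(n_variants = 500, depth = 10000, error_rate = 0.001),
  out_dir = "phanner_out", seed = 1
)
report <- run_pipeline(cfg)
report

fc <- report$enrichment$vh4$table
autoplot(fc)                                  # ordered fold-change series
autoplot(report$diversity$kl$vh4_peptide)      # per-residue KL, round 3 vs 0
autoplot(information_content(theoretical_pfm())) # analytic library profile
```

The problem sizes used throughout the test suite — pools of 200–2,000
variants at depths of 10³–10⁵ read pairs — were chosen as the package's
desk-scale study conditions; the statistics' estimators do not change with
scale, only their sampling variance does.

## Known limitations

* Anchored exact-match extraction cannot recover HCDR3s whose flanks carry
  any sequencing error in both mates; yield, not correctness, degrades with
  error rate.
* No clustering or denoising of near-identical sequences: a sequencing error
  inside the HCDR3 window that survives quality filtering creates a spurious
  rare variant, as it does in the modelled analysis.
* Enrichment has no significance test; fold-change strata are descriptive.
* The protein alphabet folds amber-encoded glutamine into Q, so TAG-specific
  effects are only visible in the nucleotide tables.
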