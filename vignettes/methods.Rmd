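---
title: "Models and methods behind resistomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind resistomir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistomir)
```

resistomir reconstructs, as one tested pipeline, the sequence of analyses
used to discover plant microRNAs that regulate NB-LRR disease-resistance
genes: duplex-based target prediction, perfect-match genome locus mapping
with hairpin free-energy validation, degradome cleavage confirmation,
21-nt phased siRNA detection, TPM expression-response calling, lightweight
NB/LRR/CC domain annotation, and single-gain (Dollo-style) birth/death
reconstruction of miRNA families on dated species trees. Every stage is
exercisable on a seeded synthetic study with a ground-truth manifest, so
the recovery behaviour of each method can be measured without any
external download. This vignette explains the models, their parameters,
the numerical choices, and what the synthetic benchmark does and does not
demonstrate.

## Duplex penalty scoring

Plant miRNAs select their targets by near-perfect antisense
complementarity. We score a candidate duplex with the canonical
plant-target penalty scheme: a mismatch costs 1.0, a G:U wobble 0.5, a
single-nucleotide bulge on either strand 1.0, and every penalty is
doubled when it falls at miRNA positions 2–13 counted from the 5' end
(the region whose pairing is required for slicing). The score of a site
is the minimum over admissible pairings, computed by a banded dynamic
program (`score_duplex()`); with the default `max_bulges = 1` the band
keeps site length within one nucleotide of miRNA length. Sites scoring
strictly below 4 are reported by `scan_transcriptome()`; the inclusive
convention (≤ 4) used by some tools is available via `inclusive = TRUE`.

Two conventions are worth stating because the literature leaves them
implicit. First, a target-side bulge between miRNA positions *i* and
*i + 1* is attributed to position *i + 1* when deciding whether the
core doubling applies. Second, among equal-score pairings the reported
alignment prefers fewer bulges, then more Watson–Crick pairs — a pure
determinism device with no effect on the score. The unit tests check
the dynamic program against an exhaustive enumeration of every pairing
with up to two bulges.

The predicted cleavage coordinate is the transcript position paired with
miRNA position 10 (slicing occurs between positions 10 and 11). With
bulges in play the coordinate is read off the pairing string, never
computed arithmetically; for a bulge-free 21-nt site spanning
`[s, e]` it reduces to `e - 9`.

Overlapping windows around a real site all score below the cutoff (a
shifted window sees the site plus one bulge), so the scanner collapses
mutually overlapping hits to the locally best window. Without this the
output would report each planted site two or three times.

## Genome loci and hairpin validation

Mature miRNAs are mapped to genomes by exact full-length matching on both
strands, treating T and U as equivalent (`find_perfect_loci()`, backed by
Biostrings). Candidate precursors are then excised around each locus over
a grid of flank lengths ({40, 80, 120, 160, 200, 240} nt on each side,
total capped at 400 nt — a range consistent with observed plant precursor
lengths of roughly 130–310 nt) and folded.

`fold_hairpin()` computes a minimum-free-energy structure under a
nearest-neighbor model deliberately restricted to stem-loops: one
terminal loop (minimum 3 nt), nested pairs connected by stacks, bulges
and internal loops, no multibranch loops. Only hairpin precursors matter
here, and excluding multiloops keeps the dynamic program quadratic with a
standard cap of 30 unpaired bases per interior loop. Pair energies are
Watson–Crick and G:U stacking free energies (kcal/mol at 37 °C) from the
Turner nearest-neighbor compilation, bundled as a plain-text table, with
loop-length penalties extrapolated beyond the tabulated sizes by the
Jacobson–Stockmayer `1.75·RT·ln(n/n₀)` term. Helix-end (terminal AU) and
loop-asymmetry corrections are omitted; the model is therefore a
simplification, self-consistent and validated against an exhaustive
enumeration of all stem-loop structures on sequences up to 30 nt.

A candidate passes when (i) dG < −30 kcal/mol, (ii) the mature lies
entirely within one arm of the hairpin (it may not straddle the terminal
loop), and (iii) at least 60% of mature positions are paired. The dG
threshold is the published filter; the one-arm and paired-fraction
criteria are biological sanity checks that can be disabled
(`require_one_arm = FALSE`, `min_paired = 0`) for strict parity with a
dG-only filter.

A note on the dG filter's discriminative power: folding stability scales
with length. A minimal 86-nt construct with a 40-bp stem always passes
−30 while its dinucleotide shuffles almost never do; but *any* random
~130-nt RNA sequence folds near −30 under realistic energy models, so on
longer windows the dG filter alone is weakly specific and the structural
criteria carry more weight.

## Degradome validation

Degradome (PARE) reads mark uncapped 5' ends of mRNA fragments. A
transcript profile (`build_profile()`) assigns each read's count to the
1-based coordinate of its 5' end at every exact occurrence. A predicted
cleavage site is then ranked T-plot style (`classify_category()`):

* category 4 — a single read at the position;
* category 0 — more than one read, equal to the transcript maximum,
  with a unique maximum;
* category 1 — equal to a tied maximum;
* category 2 — above the average depth but not maximal;
* category 3 — at or below the average depth.

"Average depth" is the arithmetic mean over occupied positions, the
usual T-plot convention; a mean over all transcript positions is
available via `mean_all = TRUE`. The p-value is rank-based: the
probability, under a uniform draw from occupied positions, of drawing a
position at least as abundant as the queried one. This null is declared,
simple and swappable; it reproduces the intended behaviour (a dominant
peak at ~27 occupied positions scores p ≈ 1/27 < 0.05) without claiming
parity with any specific published implementation. A site is validated
when any library yields p ≤ 0.05 (union rule), and per-miRNA,
per-library tallies are reported in the "n(category)" notation used in
degradome studies. Signal is required at the exact predicted coordinate
by default; a `tolerance` flag admits ±k nt.

## Phased siRNA detection

Cleavage by 21/22-nt miRNAs can route a transcript into RDR6/DCL4
processing, yielding phased 21-nt siRNAs downstream of the cut. We score
a window/register pair with the log-scale statistic

score = (k − 2) · ln(1 + 10·P / (1 + U)),

where P is the abundance of 21-nt reads on the register, U the abundance
of all other 18–26-nt reads in the window, and k the number of distinct
occupied phase positions; k < 3 or P = 0 scores 0. A 189-nt window (nine
21-nt cycles) slides along the transcript; antisense reads join a
register through the two-nucleotide 3' overhang (5' position + 2 ≡
register mod 21). Overlapping windows above the threshold (score > 15)
merge into maximal clusters, each reporting its best window. Window
size, phase, and the 21-nt-only phased rule are all configurable; the
formula and defaults follow the community-standard phasing statistic,
and the detector is checked against a brute-force all-windows,
all-registers scan. `phase_register_of_cleavage()` reports the offset
between a cluster's register and a predicted cleavage coordinate; 0
means the cluster is in frame with the cut.

## Expression

miRNA abundance is exact-match read counting (no isomiRs), normalized to
TPM (reads per million of the library total; the denominator choice —
total rather than genome-matched reads — is stated here because the
convention varies). Stress responses use
`log2fc = log2((stress + 1)/(mock + 1))` with a 1-TPM pseudocount and
strict thresholds: up above +1, down below −1. Target-gene upregulation
under infection pools replicates (sum of stress TPMs over sum of mock
TPMs plus pseudocount) and requires fold change > 2 together with
stress-mean TPM > 5. A 1.5× convention exists in parts of the
literature; Methods-style 2× is the default and both are exposed
(`min_fc`).

## Domain annotation

The domain scanner is a deliberately lightweight stand-in for
profile-HMM and coiled-coil predictors, sufficient to label NB-LRR-like
proteins in a controlled study: P-loop `[AG]-x(4)-G-K-[ST]`, kinase-2
`[LIVMF](3)-[DE]-D`, GLPL, LRR `L-x-x-L-x-L`, and a coiled-coil score
per 28-residue window (best over the 7 heptad frames of the fraction of
a/d positions occupied by L/I/V/M/F/A, threshold 0.6). Class N requires
a P-loop plus kinase-2 or GLPL; NL additionally ≥ 3 LRR motifs; CNL
additionally ≥ 1 coiled-coil window. On real proteomes these detectors
would be noisy — the heptad score in particular fires on hydrophobic
stretches of random sequence at an appreciable rate — which is exactly
why the synthetic generator composes its spacer regions from an alphabet
that cannot complete any motif (see below).

Target-site conservation is profiled by stacking the bulge-free sites of
one miRNA by miRNA position and computing per-column information content
(2 + Σ f·log₂ f bits); equal-length windows immediately up- and
downstream serve as the flank comparison. Conserved sites inside
divergent flanks produce a site-minus-flank IC gap well above 0.5 bits.

## Evolution

Presence/absence across genomes is the perfect-match locus count matrix.
Family birth/death assumes a single gain with unlimited losses (Dollo
parsimony), matching the way miRNA family histories are narrated — one
birth, lineage-specific deletions. The origin is the MRCA of present
leaves; losses are the maximal all-absent subtrees under the origin.
Among single-gain placements the MRCA provably minimizes the loss count
(any higher gain adds at least one all-absent sibling subtree), and the
tests confirm exact agreement with brute-force enumeration over all gain
nodes on random 6–8-leaf trees. Node ages, when annotated on the tree
(`[&age=lo-hi]` in mya), are carried as intervals and reported with the
origin. Multiple independent gains (homoplasy) are not modeled.

Target protein trees use Poisson-corrected distances with pairwise
deletion — p is the differing fraction over columns where neither
sequence has a gap, d = −ln(1 − p) — and neighbor joining (`ape::nj`
behind a deterministic wrapper that orders taxa lexicographically and
clamps negative branch lengths to zero, moving the deficit to the
adjacent branch). Overlap statistics between miRNA target sets are plain
set intersections for every subset of miRNAs.

## The synthetic study generator

`simulate_study()` emits a complete toy study from one seed:

* **Genomes** per species with mature miRNAs embedded in constructed
  hairpins at recorded loci. The 5' arm is the mature plus a 19-nt
  extension; the 3' arm is the near-complement with three substitutions
  opposite the mature — as in real miR/miR* duplexes — so the mature
  itself is the only perfect-match locus the hairpin contributes.
  Presence patterns are planted as one origin clade per miRNA with
  sporadic leaf losses (probability 0.2), copy numbers 1–3.
* **Transcripts** (600 nt, CDS 101–520) carrying one planted site per
  (miRNA, target) whose duplex score is drawn from
  {0, 0.5, …, 3} and realized exactly by inverting the scoring rule
  (core mismatch +2, non-core mismatch +1, core wobble +1, non-core
  wobble +0.5, never touching miRNA positions 9–11 so the cleavage
  region stays paired). With `max_bulges = 1` and a site of miRNA
  length, no bulged alignment can undercut the planted score, so the
  planted value is provably the optimum.
* **Degradome libraries** with a Poisson(20) signal read at each
  predicted cleavage coordinate over Poisson(2) counts at 30 uniform
  noise positions per transcript — the regime in which a genuine
  cleavage peak is the unique maximum with p ≈ 1/27.
* **Small RNA libraries** (three mock, three stress replicates)
  containing each mature at a base abundance of 100 reads scaled by a
  planted log2 fold change from {−2, 0, +2} in the stress arm; phased
  21-nt reads downstream of every cleavage site over eight cycles with
  geometric decay 0.8 and antisense partners at the +2 overhang;
  ~10% off-register abundance (phased fraction 0.9); and uniform random
  background reads.
* **Proteins** (360 aa, all equal length so they double as an aligned
  set for the NJ stage) with planted domain blocks per label; ~90% of
  targets carry an NB-LRR class, mirroring the observed fraction.
* A dated six-species grass tree, an expression contrast table, and a
  JSON manifest recording everything planted.

These defaults are the study conditions under which all recovery rates
are measured. What passing means — and does not mean: the generator
plants exact-match reads with no sequencing error, no isomiRs, no
multi-locus transcript families, and noise that is exchangeable by
construction, so recovery near 100% demonstrates correctness of the
inference chain, not robustness to the messiness of real libraries.
Conversely the null simulations (shuffled genomes, uniform read
placement, matched-abundance nulls) bound the false-positive behaviour
of each statistic under its own model assumptions only.

Problem sizes were chosen so the full default study (six genomes of
20 kb, five miRNAs, twenty targets, eight libraries) runs end-to-end in
about a minute, and the complete recovery/oracle suite in a few minutes,
keeping the benchmark cheap enough to run on every change.

## Numerical and degenerate-input choices

* All coordinates everywhere are 1-based inclusive on the forward
  strand; a cross-module fixture test locks this in.
* Scores are compared with a 1e-12 slack inside the DPs; tie-breaks are
  deterministic (duplex: fewer bulges, more WC pairs; folding: first
  minimal candidate in fixed scan order; NJ: lexicographic taxon
  order).
* Degenerate inputs fail loudly and early: empty FASTA, duplicate ids,
  non-integer counts, zero-read libraries, unbalanced Newick, inverted
  age intervals, all-absent presence rows, p-distances ≥ 1.
* Sites containing N are skipped with a warning (exact matching and
  pairing are undefined on ambiguity codes); miRNAs containing N are
  rejected for locus mapping.
* `fold_hairpin()` returns the open chain at dG = 0 rather than a
  positive-energy structure, so dG ≤ 0 always holds.
* Reproducibility: every stochastic component draws from R's RNG under
  a caller-supplied seed; `simulate_study()` output is byte-identical
  for identical configs, and `run_pipeline()` is a pure function of
  inputs plus config.

## Known limitations

Beyond the simplifications already flagged — hairpin-only energy model
without end/asymmetry corrections, motif-scan domain calls, rank-based
cleavage p-value, exact-match-only read placement — the pipeline does
not model translational repression, isomiR variation, 24-nt phasing,
genome-level (spliced) target scanning, or gene-tree/species-tree
reconciliation. The Dollo reconstruction reports presence/absence
history only; it does not estimate divergence times, which enter solely
as user-supplied node-age annotations.
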