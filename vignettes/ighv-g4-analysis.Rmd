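---
title: "Strand-resolved G4 potential analysis of IGHV genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-resolved G4 potential analysis of IGHV genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighvg4)
```

# Scope and scientific background

Somatic hypermutation (SHM) of immunoglobulin variable (V) regions is
initiated by AID, a cytidine deaminase with strong sequence preferences:
WRC trinucleotides (W = A/T, R = A/G; the targeted C is the third base)
are hotspots, SYC trinucleotides (S = C/G, Y = C/T) are coldspots, and
the palindromic AGCT motif overlays two AGC hotspots, one per strand.
G-quadruplexes (G4s) are four-stranded structures formed by G-rich DNA;
they bind AID in switch regions, and their formation is intrinsically
strand-asymmetric: a G-rich top strand forms a G4 where the complementary
C-rich bottom strand cannot.

This package implements the analysis layer needed to study G4 formation
potential in germline IGHV alleles and its relationship to SHM: strand-
resolved G4 scoring, sequence attribution, in-silico saturation
mutagenesis with AID-context classification, percent-mismatch (G4-seq
style) track analysis, repertoire mutability statistics, and synthetic
generators that emulate each external data source. Everything operates in
top-strand coordinates: "bottom strand" always means the reverse
complement of the sequence as written, and bottom-strand features are
reported at the top-strand position of the complementary base.

# Sequence handling conventions

**IMGT gapping.** Germline alleles may carry IMGT `.` gap characters that
align framework (FW) and complementarity-determining region (CDR)
boundaries across genes. `ighv_allele()` keeps both the gapped and the
ungapped sequence and converts between the two coordinate systems
(`gapped_to_ungapped()`, `ungapped_to_gapped()`). Region maps are
expressed in gapped coordinates, 1-based inclusive, matching how IMGT
positions are quoted; interval I/O (BED, bedGraph) is 0-based half-open,
matching those standards.

**One-hot encoding.** Learned G4 scorers consume a fixed-width one-hot
input. `encode_one_hot()` uses width 297 nt by default (1188 slots), base
order A, C, G, T within each 4-slot group, zero-padding at the 3' end for
shorter sequences, and truncation to the 5'-most `width` nt for longer
ones. Keeping the 5' end under truncation is the natural complement of
3'-end padding and keeps the two length-adjustment rules consistent; an
external scorer whose convention differs can declare its own width and
base order through its adapter. Scoring paths reject `N` bases (pattern
and learned scorers are defined over A/C/G/T); track and interval paths
accept them.

**Scorer contract.** A `g4_scorer()` is any pure function from a DNA
string to a potential in [0, 1]. The external learned model is deliberately
*not* bundled: it is reached through the same contract via a user-supplied
adapter, and nothing in this package's tests depends on it. Whether such a
model receives gapped or ungapped input is an adapter setting; the
package's own analyses score ungapped sequences.

# The reference G4 scorer

The built-in scorer is a deterministic surrogate built on the canonical
quadruplex consensus G₃₊N₁₋₇G₃₊N₁₋₇G₃₊N₁₋₇G₃₊. `find_canonical_g4_motifs()`
finds maximal G-runs of length ≥ `min_run` (default 3), then selects
non-overlapping run chains left to right, taking at each step the
lexicographically earliest chain of four runs whose inter-run gaps are
1–`max_loop` nt (default 7). Loops may themselves contain shorter G-runs,
and a chain may skip a run when the resulting loop still fits the bound.
Leftmost-greedy selection with maximal runs makes the scanner fully
deterministic; overlap counting is ill-defined for nested G-runs, so
overlapping alternative decompositions are intentionally not enumerated.

The score is

$$\mathrm{score}(s) = 1 - 2^{-q}, \qquad
  q = \sum_{\text{matches } m} \big(\min_{\text{runs } r \in m}
  \mathrm{len}(r) - 2\big),$$

so a sequence without a canonical motif scores exactly 0, one minimal
motif (four G₃ runs) scores 0.5, and longer runs or additional motifs push
the score toward 1. The constants (the 2^(−q) form and the −2 offset) are
package choices made so that unit tests are bit-exact and deterministic;
the reference scorer does **not** reproduce the numeric values of any
learned G4 model, only the qualitative structure (zero without a motif,
monotone in motif strength, strand-asymmetric). Two monotonicity
properties follow from the formula and are asserted in the test suite:
repairing a disrupted G-run inside an otherwise complete motif never
lowers the score, and destroying a required run never raises it.

# Integrated gradients

For differentiable scorers, `integrated_gradients()` attributes a
prediction to input positions by integrating the gradient along the
straight-line path from an all-zeros baseline to the one-hot input,
approximated with a right-endpoint Riemann sum at `n_steps` points
(default 128):

$$\mathrm{attr}_i = x_i \cdot \frac{1}{n}\sum_{k=1}^{n}
  \frac{\partial f}{\partial x_i}\Big(\frac{k}{n} x\Big).$$

The completeness axiom — attributions summing to `f(x) − f(0)` — holds
exactly for linear scorers at any `n_steps` and up to a gap shrinking like
`1/n_steps` otherwise; the realised gap is always returned with the
attributions so downstream users can judge the approximation.
`attribution_to_logo_table()` reshapes attributions into the tidy
position-by-base table used for logo rendering; padding positions carry
exactly zero attribution because their input is zero.

# In-silico saturation mutagenesis

Two complementary experiments cover every position of an allele:
`enumerate_h_to_g()` substitutes G at every non-G site (one mutant per
site), and `enumerate_g_to_h()` mutates every G to each of A/C/T and
averages the three mutant scores into one record per site. Both strands
are always rescored — a top-strand substitution changes both strands'
contexts, so no antisymmetry is assumed — and ΔG4 is the mutated score
minus the germline score, per strand.

C sites are classified by `classify_c_site()` from the two bases 5' of
the C on the strand where the C lives; for a bottom-strand C (a
top-strand G) the context is read off the reverse complement. Sites with
fewer than two 5' bases are neutral by convention, since WRC/SYC are
undefined there. A top-strand C>X substitution has `strand_mutated =
"top"`, a top-strand G (bottom-strand C) `"bottom"`; A/T sites have no
AID-relevant strand and are excluded from C-site analyses.

`strand_effect_summary()` arranges classified C-site deltas into the
site-class × strand-mutated × strand-affected grid. Each mutant
contributes its delta on the mutated strand to the *same*-strand cell and
its delta on the other strand to the *opposite* cell — both, not just the
larger one, since the biological question concerns both outcomes. Pairwise
two-sided Mann–Whitney U tests compare site classes within each cell
group; p-values are reported raw (a Benjamini–Hochberg adjustment can be
applied by the user via `p.adjust`, but raw values are the default
reporting convention here). When every value in a comparison is tied the
normal-approximation p-value is undefined and reported as `NA` rather
than coerced to a number. The "no effect" threshold epsilon defaults to
0.01 on the score scale — small relative to the 0.5 jump the reference
scorer takes when a whole motif appears or disappears, but non-zero so
floating-point noise never counts as an effect.

# Percent-mismatch tracks and motif densities

G4-seq-style assays report the percentage of read mismatches caused by
polymerase stalling; high values mark positions where a G4 formed.
Tracks are strand-resolved (one bedGraph per strand, as the assay
distributes them) and validated to be sorted and non-overlapping.
`call_observed_g4()` thresholds intervals at 25% mismatch — the
established calling threshold for this assay — and merges qualifying
intervals at zero gap tolerance with no minimum length, reporting the
peak value per merged region. `region_mismatch_stats()` returns the
maximum and the width-weighted mean over covered positions only:
uncovered positions are excluded rather than imputed as zero, because the
assay reports mismatch only where reads align and zero-imputation would
deflate means in low-coverage regions. A region with no coverage yields
missing statistics, never zeros.

Motif densities count possibly-overlapping occurrences per nt (AGCTAGCT
contains two AGCTs), and `fold_difference()` compares densities between
subregions. `scan_aid_motifs()` reports every WRC and SYC occurrence on
both strands at the top-strand coordinate of the targeted base, which
makes the palindromic AGCT emit its two overlapping AGC hotspots
automatically. `correlate_potential_vs_activity()` relates per-gene
predicted potential to per-gene maximum mismatch by Spearman correlation
per strand (at least three genes required; constant inputs yield an
undefined correlation, flagged rather than zeroed) plus a two-sided
Mann–Whitney comparison of the strands.

# Repertoire mutability

`repertoire_alignment()` holds substitution-only reads pre-aligned to a
germline; `N` marks uncovered positions, and indel-containing reads are
rejected because all analyses are positional against the germline. The
per-site unit is the mutation frequency (mutated reads over covering
reads), and per-motif mutability averages the targeted-base frequency
over motif occurrences — matching the "average mutation frequency of the
motif" convention rather than per-read counts. A privacy-reduced tabular
input (`position`, `mutated`, `coverage`) is accepted in place of reads.

`topbottom_difference_vs_potential()` computes, per gene and hotspot
motif, the top-minus-bottom difference in mean mutability and its Pearson
correlation with the gene's per-strand potential. Per-gene potential is
taken as supplied by the caller; when a gene has several alleles the
mean-allele score is the recommended summary. `ccc_split_comparison()`
implements the coldspot analysis: top-strand CCC sites are split by the
predicted bottom-strand ΔG4 of their mutation (negative change below
−epsilon versus no difference within ±epsilon; sites with positive delta
are excluded), and the two groups' observed mutation frequencies are
compared by a two-sided Mann–Whitney U test.

# The synthetic study

The generators define the study conditions under which the pipeline is
exercised and tested; their defaults are fixed, not tuned per analysis.

**Germlines** (`germline_sim_config()`): 40 alleles — the number of
functional IGHV genes locatable in the reference genome, and the size of
the track-correlation analyses — of 300 nt (a typical V-gene length) at
GC fraction 0.55 (IGHV-like). Background sequence is sampled with G- and
C-homopolymer runs capped below the cassette's minimum run length, so
canonical G4 motifs exist exactly where planted; each allele is validated
after assembly (the canonical scanner must recover precisely the planted
cassettes per strand, and planted motif counts must equal total
occurrence counts) and resampled until valid. Half the alleles carry one
canonical cassette (runs of 3, loops of 2) — giving the between-gene
variation the correlation analyses need — and every allele receives three
planted AGCT motifs, matching the ~1e-2 per nt AGCT density of real V
regions. Cassettes are wrapped in 1-nt A/T buffers so flanking background
cannot extend their runs and shift the ground-truth footprint. A scaled
IMGT-style FW/CDR layout annotates each allele.

**Repertoires** (`shm_sim_config()`): each read mutates each site
independently with probability `base_rate × class multiplier × coupling`,
substituting uniformly among the three alternatives. The per-site base
rate defaults to 1e-3 per nt, the canonical SHM rate per bp per cell
division; hotspots default to 5× and coldspots to 0.3×, within the range
of measured WRC/SYC biases. The G4 coupling factor multiplies — once per
site, regardless of how many cassettes share a strand — the rate of
hotspot sites on the strand carrying a planted cassette and of CCC
coldspot sites on the opposite strand overlapping a cassette footprint,
emulating the hypothesis that a G4 on one strand exposes the other to
AID. Rates exceeding 1 after multiplication are capped, with a message.
The coldspot-coupling demonstrations in the tests and the acceptance
script run at an accumulated rate of 5e-3 per site (several germinal-
center divisions' worth of the per-division rate): at 1e-3 the coldspot-
attenuated CCC frequencies are so low that per-site counts at 2000 reads
are nearly all zero or one, and no split comparison — however
implemented — is informative at that depth. The germline for those
demonstrations plants four bottom-strand cassettes (16 cassette-opposed
CCC sites) and ten distal CCC motifs, sizes chosen a priori for adequate
power of the rank test.

**Tracks** (`track_sim_config()`): 15-nt intervals with truncated-normal
background (mean 5%, SD 2) and cassette-footprint peaks (mean 60%, SD 5)
on the cassette's strand — comfortably across the 25% calling threshold,
emulating how the real assay separates structured from unstructured
positions. The true assay's noise model is unknown; clipping a normal to
[0, 100] is a pragmatic stand-in. One V region definition per allele is
emitted, with the allele id doubling as the chromosome name.

What the generators deliberately do **not** emulate: read-level
sequencing error, coverage variation (simulated reads cover every
position), clonal lineage structure among reads, VDJ rearrangement,
polymerase-stalling biophysics, and non-canonical G4 conformations
(bulged, two-tetrad, long-loop). Tests passing on synthetic data
therefore demonstrate that the *computations* are correct and that
planted signals of realistic size are recovered — not that the reference
scorer ranks real alleles as a learned model would, nor that real
repertoires satisfy the simulators' independence assumptions.

# Numerical and degenerate-input choices

- Leftmost-greedy, maximal-run motif selection (determinism; see above).
- Standard deviation of a single observation is reported as 0 with `n`
  recorded, so summary tables never contain missing cells.
- Rank-test p-values use the normal approximation (`exact = FALSE`);
  fully tied comparisons yield `NA`, and empty cells skip their tests
  with `n = 0` recorded.
- Constant vectors make correlations undefined (`NA` plus a note), never
  silently 0; fewer than three genes refuses a correlation outright.
- Zero-coverage sites and uncovered regions propagate as missing values.
- All simulators require an explicit seed and restore the caller's RNG
  state, so results are reproducible and generators do not perturb
  surrounding code.

# Known limitations

The reference scorer is intentionally coarse: it sees only canonical
motifs, so its scores saturate in steps of 2^(−q) and it assigns zero to
genuinely G4-prone non-canonical sequences; analyses needing calibrated
potentials should plug in a learned scorer through the adapter. The
in-silico experiments cover single substitutions only — multi-site
combinations grow combinatorially and are out of scope. Switch-region
boundary definition is manual (user-supplied BED); no automatic S-region
detection is attempted. Repertoire inputs must be pre-aligned and
substitution-only; alignment and indel resolution are upstream concerns.
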