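---
title: "Distance-based word and element clustering: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based word and element clustering: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wordclust)
```

## The problem

Many functional genomic entities — CpG dinucleotides, methylatable CAG/CTG
contexts, transcription-factor binding sites, olfactory-receptor genes —
occur in spatial clusters rather than uniformly along chromosomes.
`wordclust` detects such clusters from the distances between consecutive
copies and attaches a statistical significance to each, instead of relying on
sliding windows, densities or arbitrary distance cut-offs. It handles two
kinds of input: DNA words (*k*-mers, possibly IUPAC-degenerate, scanned out
of FASTA sequences) and arbitrary genomic elements (pre-localized BED
intervals).

## The procedure

1. **Occurrence detection** (k-mer mode only). Sequences are split into
   N-free contigs — any ambiguity code breaks the sequence, so no ambiguous
   base can ever lie between two clustered copies. Each contig is scanned
   left to right; when the current window equals a target word an occurrence
   is emitted and the scan resumes at the word's end, so copies never
   overlap.
2. **Distances.** The distance between consecutive copies is the start of
   the downstream copy minus the end of the upstream copy in 1-based
   inclusive arithmetic: abutting copies are at distance 1. Distances are
   never taken across contig or sequence boundaries. Overlapping input
   elements (possible in real gene annotations) are clamped to distance 1 —
   they always co-cluster.
3. **Threshold resolution.** A maximum distance `d_max` is derived from the
   distance distribution under one of four models (below).
4. **Clusters and significance.** Maximal runs of occurrences whose
   consecutive distances are all ≤ `d_max` (ties at `d_max` included) become
   clusters; each receives a negative-binomial p-value, and clusters above
   the `alpha` cut-off are discarded.

## The significance model

Inside a cluster with `n` target copies, everything that is not a target is
a *failure*. For a word of length *k* in a cluster of length `L_c`,

  n_f = L_c − n·k,

the number of no-target bases. For elements, failures are counted in
mean-element-length units, n_f = ⌈L_no / L_mean⌉, where `L_no` is the number
of cluster bases covered by no element. The success probability `p` is the
chance of hitting a target at a random slot:

* k-mer mode: p = N / ((L_s − k + 1) − N·(k − 1)), with `N` the
  non-overlapping occurrence count and `L_s` the summed contig length. The
  denominator is the number of k-mer slots after removing the N·(k−1)
  positions swallowed by non-overlapping copies, and the slot count
  (L_s − k + 1) is accumulated per contig as max(0, contig length − k + 1),
  because detection is confined to contigs; counting slots across ambiguous
  bases would bias `p` downward.
* element mode: p = N·L_mean / L_s, the expected covered fraction. Here
  `L_s` is the full declared sequence length — elements are annotated on
  complete assemblies, gaps included — which is why element mode takes a
  sequence-length table rather than the FASTA itself.

A cluster's p-value is the cumulative negative binomial
P(X ≤ n_f) with r = n − 1 successes: the first copy of any cluster is
trivially present, so only the remaining n − 1 arrivals are tested. For
n = 2 this reduces to the geometric tail 1 − (1 − p)^(n_f + 1). The CDF is
evaluated with `stats::pnbinom`, which works on log scale internally;
the unit tests verify it against exhaustive pmf summation to 1e-10. Clusters
need n ≥ 2 — with n = 1 the test has r = 0 and is degenerate, so singletons
are never reported.

If the formula ever yields p ≥ 1 or a non-positive slot count (conceivable
only on tiny or word-saturated inputs), the run aborts with a diagnostic
rather than producing invalid probabilities: the negative binomial requires
0 < p < 1.

No multiple-testing correction is applied; the raw p-value threshold is the
method's convention. `glance()` reports the number of clusters tested so a
Bonferroni factor can be applied externally.

## Distance models

If copies fell independently with probability `p` per slot, the inter-copy
distance would be memoryless, i.e. geometric: P(d) = p(1 − p)^(d−1), d ≥ 1.
Observed distributions of clustered words instead show an excess of short
distances. The point where the observed curve falls back under the expected
one — the *reversal point* — separates intra-cluster from inter-cluster
distances and is a natural, parameter-free threshold.

* `percentile`: `d_max` is a nearest-rank percentile of the observed
  distances, per sequence; the default percentile of 50 (the median)
  is the classic approximation to the reversal point. Nearest-rank is used
  because distances are discrete and heavily tied; no interpolation.
* `chrom_intersection` (default): the observed/expected crossing, per
  sequence, with that sequence's `p`.
* `genome_intersection`: per-sequence distance distributions are merged
  (counts summed), `N` and the slot totals are pooled, and a single `d_max`
  and a single genome-wide `p` apply everywhere. Appropriate when the
  clustering process is not chromosome-specific; note that with a pooled
  `p`, GC-rich sequences receive smaller p-values than under per-sequence
  probabilities.
* `fixed`: a user-chosen `d_max`, with per-sequence probabilities.

**Crossing detection.** Histograms are noisy, so the crossing is detected by
a simple scan over d = 1, 2, …: the first distance where the normalized
observed frequency drops below the expected curve, after at least one
distance with nonzero observed count at or above it, is returned. The scan
runs one bin past the largest observed distance, so a distribution that
stays above the expected curve throughout its support crosses immediately
after it (all observed mass at d = 1 with p = 0.5 gives a crossing at
d = 2). No smoothing is applied — it would add a parameter the method does
not need. If no crossing is found at all (conceivable only for degenerate
floating-point corner cases, since the observed frequencies sum to 1 and the
expected curve to less than 1 over any finite support), the median is
returned with a warning, as its standard approximation.

**Element mode units.** For elements, a bp distance d is first converted to
failure units ⌈d / L_mean⌉ and the geometric law is taken over failure
counts; the resolved crossing is converted back to bp as
⌊u·L_mean⌋. The percentile and fixed models work directly in bp.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `model` | `chrom_intersection` | how `d_max` is resolved (see above) |
| `percentile` | 50 | percentile model only; 50 = median |
| `max_distance` | — | fixed model only; bp |
| `alpha` | 1e-5 | cluster p-value cut-off |
| `words` / `pattern` | — | literal words, or one IUPAC pattern (`CWG` → CAG, CTG) |

Only the literal words given are searched; there is no implicit
reverse-complementation. A palindromic analysis (e.g. the methylatable CWG
context) is expressed by listing both strands' words, which the IUPAC
expansion does naturally. All words must share one length *k*: the failure
count L_c − n·k and the slot arithmetic are only defined for a single *k*,
so mixed-length sets are rejected rather than given an ad-hoc meaning.

## Coordinates

All tibbles use 0-based half-open coordinates, matching BED on disk;
the 1-based inclusive distance convention (abutting copies ↔ distance 1) is
produced at the distance formula, d = start_downstream − end_upstream + 1.
Cluster reports are BED-compatible TSV with `#`-prefixed summary lines and
re-read losslessly with `read_bed()`.

## Co-localization regions

From refFlat gene models, `derive_regions()` builds strand-aware region
sets: the 1-bp TSS, a 201-bp TSS ± 100 window, the promoter window from
1500 bp upstream to 500 bp downstream of the TSS (2001 bp including the TSS
base, reflected through the TSS on the − strand), 5'/3' UTRs (exonic bases
outside the CDS, in transcription orientation), exons and introns. The TSS
is counted as a 1-bp position; the windowed variant is reported separately
rather than folded into it. `count_region_overlaps()` counts each cluster
once per label when it intersects any interval of that label by ≥ 1 bp
(half-open: a cluster ending where a region starts does not overlap).
Custom tracks can be counted by attaching a `label` to any BED-derived
tibble.

## The simulator and what it does (not) show

`simulate_word_sequence()` emulates the one feature the detector relies on:
a two-regime distance distribution. It plants windows of copies with small
uniform gaps (defaults: eight windows of ten copies, gaps of 1–5 bp, i.e.
distances 2–6) in an otherwise uniform-random sequence carrying a sparse
Bernoulli background (default 0.5 words/kb, kept 100 bp clear of windows so
the planted truth stays unambiguous), over a 50-kb sequence. Filler bases
that accidentally spell a target word are mutated away, so the truth tables
list exactly the realized occurrences. `simulate_elements()` lays out
fixed-length elements in blocks with prescribed gaps plus isolated
background elements.

What the simulator does **not** emulate: isochore structure, repeats,
CpG-specific composition, overlapping genes, chromosome-scale length — so
passing recovery tests demonstrates correctness of the algorithm on
two-regime data, not calibration of the threshold models on real genomes.
The test suite exercises 50-kb sequences over 20 seeds for recovery and
strings ≤ 200 bp against brute-force references; these sizes make every
property checkable exhaustively while keeping the suite quick.

## Numerical and degenerate-input choices

* p-values are computed by `stats::pnbinom` and printed with two
  significant digits in reports; full precision is kept in the tibbles.
* Ties at `d_max` are inside clusters ("equal or below").
* Sequences with fewer than two occurrences have no distances: their
  threshold is `NA` and they simply contribute no clusters.
* IUPAC codes other than N in genome sequences break contigs exactly like N:
  only A/C/G/T content is guaranteed inside a contig, and a degenerate base
  cannot be asserted to match a literal word.
* Soft-masked (lowercase) input is uppercased and scanned: clustered words
  frequently overlap repeats, and silently skipping masked copies would
  bias `N` and the distances.

## Limitations

* The null model is order-0 (single success probability per scope); no
  Markov or GC-stratified nulls.
* No FDR machinery, by design (see above).
* Words of unequal length cannot be mixed in one analysis.
* Genome-scale results depend on assembly and annotation choices; the
  package ships no genomes and makes no claims about any particular one.
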