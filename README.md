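# wordclust

Statistically grounded detection of spatial clusters of DNA words
(*k*-mers) or of arbitrary genomic elements, from the distances between
consecutive copies.

Many genomic entities cluster along chromosomes: CpG dinucleotides form CpG
islands, methylatable CAG/CTG contexts aggregate, olfactory-receptor genes
sit in dense blocks. Most detectors find these with sliding windows or
hand-picked distance cut-offs. `wordclust` instead (1) measures the
distances between consecutive copies (abutting copies are at distance 1),
(2) derives a maximum-distance threshold *d*<sub>max</sub> from the data —
by default the crossing point between the observed distance distribution
and the geometric distribution expected under random placement — and
(3) scores every maximal run of copies with consecutive distances ≤
*d*<sub>max</sub> using the cumulative negative binomial

P(X ≤ n<sub>f</sub>),  pmf C(n<sub>f</sub> + r − 1, r − 1) p<sup>r</sup> (1 − p)<sup>n<sub>f</sub></sup>,  r = n − 1,

where *n* is the number of copies in the cluster, n<sub>f</sub> counts the
failures inside it (for a word of length *k*: n<sub>f</sub> = L<sub>c</sub> −
n·k no-target bases; for elements: ⌈L<sub>no</sub>/L<sub>mean</sub>⌉
mean-length units), and *p* is the success probability —
N/((L<sub>s</sub> − k + 1) − N(k − 1)) for words,
N·L<sub>mean</sub>/L<sub>s</sub> for elements. Clusters with p-value ≤ 1e-5
(configurable) are reported. Word scanning is non-overlapping and strictly
confined to N-free contigs, so no ambiguous base ever lies between two
clustered copies.

It is aimed at anyone who needs defensible cluster calls: CpG-island style
analyses, clustering of methylation contexts or binding motifs, and
cluster detection for gene families or any BED-defined element set,
including co-localization counts against gene annotation (TSS, promoter
window, UTRs, exons, introns).

## Worked example

Simulate a 50-kb sequence with eight planted windows of ten `ATGC` copies
(gaps 1–5 bp) over a sparse background, then detect the clusters with the
genome-wide intersection model:

```r
library(wordclust)

sim <- simulate_word_sequence(seed = 42)
res <- word_cluster(sim$seqs, words = "ATGC", model = "genome_intersection")
res
#> Word/element cluster analysis (kmer mode, genome_intersection distance model)
#>   target words: ATGC (k = 4)
#>   sequences: 1; clusters tested: 8; significant at alpha = 1e-05: 8
#>   resolved d_max (bp): sim1=7

tidy(res)
#> # A tibble: 8 × 10
#>   seq_id start   end     n   L_c   n_f       p  p_value    gc cpg_oe
#>   <chr>  <int> <int> <int> <int> <int>   <dbl>    <dbl> <dbl>  <dbl>
#> 1 sim1    5476  5535    10    59    19 0.00209 5.14e-18 0.508  0.801
#> 2 sim1   11041 11110    10    69    29 0.00209 1.19e-16 0.493  0.739
#> 3 sim1   16606 16673    10    67    27 0.00209 6.90e-17 0.507  0.718
#> # …
```

The resolved `d_max = 7` bp is the observed/expected crossing: planted
copies sit 2–6 bp apart, background copies kilobases apart, and the
threshold falls between the two regimes with no tuning. Each row is one
detected cluster: `n` copies spanning `L_c` bp with `n_f = L_c − 4n`
no-target bases; `p` is the genome-wide per-slot success probability
(~0.002 here), and the negative-binomial p-values (~1e-16) say that packing
ten copies into ~60 bp is inconceivable under random placement. `gc` and
`cpg_oe` are the per-cluster GC fraction and CpG observed/expected ratio,
the standard island composition statistics. `glance(res)` summarises per
sequence (cluster count, mean length ± SD, coverage, threshold);
`autoplot(res)` maps the clusters and `plot_distance_distribution(res)`
shows the two curves and the crossing. All eight planted windows are
recovered exactly.

Element mode works the same way from a BED file plus a sequence-length
table:

```r
res <- element_cluster("or_genes.bed", "chrom.sizes", model = "chrom_intersection")
```

A thin command-line wrapper is included:

```sh
Rscript inst/cli/wordclust.R kmer --fasta genome.fa --pattern CWG \
    --distance-model chrom-intersection --alpha 1e-5 --out clusters.tsv
Rscript inst/cli/wordclust.R elements --bed or_genes.bed --seq-lengths chrom.sizes
Rscript inst/cli/wordclust.R simulate --out-prefix sim --seed 1
```

See `vignettes/wordclust-methods.Rmd` for the model, the four distance
models, the element-mode unit conversions and all numerical choices.

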