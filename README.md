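# draftqc

Quantitative toolkit for draft plant-genome projects. When a genome is
assembled from short reads, a handful of sequence-level statistics
carry most of the quality story and much of the evolutionary signal:

* **Genome size from the k-mer spectrum.** Canonical k-mer multiplicity
  histograms of the raw reads show an error spike, a valley, and a
  coverage peak at multiplicity m_peak; the genome size is estimated as
  `sum_{m >= m_min} m * c_m / m_peak`.
* **Chargaff second-parity QC.** Within one strand, a k-mer `w` and its
  reverse complement `w̄` should be near-equally frequent. The symmetry
  ratio `S(w) = f(w) / (f(w) + f(w̄))` concentrates around 0.5 in a
  clean assembly; its dispersion at k = 4 is a cheap assembly check and
  a basis for comparing assemblies.
* **LTR-retrotransposon insertion dating.** The two LTRs of an element
  are identical at insertion and diverge afterwards. From a global
  alignment of the 5′/3′ pair, the Kimura two-parameter distance
  `K = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]` (P transitions, Q
  transversions, gap/ambiguous columns excluded) converts to an age
  `T = K / (2r)` with substitution rate `r = 1.3e-8`/site/year by
  default.
* **Gene structure and composition.** Intron derivation from GFF3 exon
  models, per-gene structure summaries (lengths, counts, exonic and
  intronic GC), first exon/intron in transcript orientation, and GC
  density curves with mode detection.
* **Expression.** log2 FPKM transforms, GC-binned expression
  histograms, EF1A (elongation factor 1-alpha) normalization,
  cross-species log2 differential indices over an ortholog map,
  top/bottom gene selection, and unique-locus collapsing of top
  unannotated transcripts.

Every stage is validated against **synthetic data with planted ground
truth**: seedable generators produce mixture-GC genomes, LTR elements
whose copies evolve under the exact K2P transition matrix (expected
divergence `2rT` by construction), gene models drawn from published
structure statistics, uniform-coverage reads, and log-normal FPKM
tables with a tunable structure–expression coupling.

## Worked example

```r
library(draftqc)

# a 200 kb genome with bimodal GC, 30x error-free 150 bp reads
g     <- generate_genome(genome_spec(200000,
           data.frame(gc_mean = c(0.30, 0.45), weight = c(0.5, 0.5)),
           seed = 7))
reads <- simulate_reads(g, read_sim_spec(depth = 30, read_length = 150,
                                         seed = 8))
estimate_genome_size(count_kmer_spectrum(reads, k = 17))
#> Genome size estimate: 198,518 bp (k = 17, error valley m = 2, coverage peak m = 27)

# strand-symmetry QC of the genome itself
sm <- symmetry_summary(symmetry_table(strand_kmer_counts(g$genome, k = 4)))
sm$mean_S; sm$sd_S
#> 0.4987; 0.0135

# plant 300 LTR elements (age modes 1/6/11 My), then date them back
pl   <- plant_ltr_elements(g, ltr_plant_spec(300, seed = 9))
ages <- ltr_insertion_ages(pl$pairs)       # align, K2P, T = K/(2r)
age_distribution(ages$T_years)
#> Insertion ages: n = 300, modal bin [1.00, 1.50) My, oldest 11.56 My
mean(ages$K)                               # vs planted mean 2rT = 0.0844
#> 0.0809
```

The size estimate lands within 1% of the planted 200 kb; the symmetry
ratios sit tightly around 0.5 as expected for an un-rearranged genome;
and the recovered age histogram peaks in the bin containing the planted
1 My mode with the older planted shoulders visible, the mean estimated
divergence matching the planted expectation within Monte-Carlo error.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/draftqc` (subcommands `simulate`, `assembly-stats`,
`kmer-size`, `chargaff`, `gc-profile`, `ltr-age`).

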