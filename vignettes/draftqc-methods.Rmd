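---
title: "Methods: genome QC, LTR insertion dating and expression profiling with draftqc"
author: "draftqc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome QC, LTR insertion dating and expression profiling with draftqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(draftqc)
```

# Scope

`draftqc` implements the quantitative core of a draft plant-genome
analysis: estimating genome size from the k-mer spectrum of shotgun
reads, checking assembly quality with Chargaff second-parity (strand
symmetry) statistics, dating LTR-retrotransposon insertions from the
divergence of their two long terminal repeats, profiling GC composition
and gene structure, and comparing expression across organs and species
after housekeeping-gene normalization. Because the original read data
such pipelines are built on are rarely at hand (and are far too large
for routine validation), the package ships seedable synthetic-data
generators with planted ground truth; every analysis stage is tested by
recovering what the generator planted.

# Models and procedures

## k-mer spectrum genome sizing

Reads are decomposed into all length-k windows containing only
`A/C/G/T`; each window is counted once under its canonical form (the
lexicographic minimum of the k-mer and its reverse complement), merging
the two strands. The multiplicity histogram $c_m$ (number of distinct
canonical k-mers seen $m$ times) then typically shows an error spike at
$m = 1$, a valley, and a coverage peak near the mean k-mer coverage
$\lambda = d\,(L - k + 1)/L$ for depth $d$ and read length $L$.

The estimator scans $m$ upward for the first multiplicity at which
$c_m$ stops decreasing (the error valley $m_{\min}$; $m_{\min} = 1$
when the histogram rises immediately, i.e. there is no error peak),
takes the most populous multiplicity at or beyond the valley as the
coverage peak $m_{\mathrm{peak}}$, and reports

$$\hat G \;=\; \frac{\sum_{m \ge m_{\min}} m\,c_m}{m_{\mathrm{peak}}}.$$

This divides the number of usable k-mer instances by the raw peak
multiplicity; no distribution is fitted. The choice is deliberate — it
is the simplest defensible reading of the classical "k-mer frequency
plot" method — and its one weakness is quantization: $m_{\mathrm{peak}}$
is an integer, so when $\lambda$ falls almost exactly on an integer the
peak can land on either neighbor and the estimate moves in steps of
roughly $1/\lambda$. Validation scenarios therefore use read lengths
that place $\lambda$ mid-interval (e.g. depth 30 with 150 bp reads
gives $\lambda = 26.8$, where any peak in 26–28 keeps the error below
5%). Defaults: $k = 17$ (odd k avoids self-complementary k-mers; even
k is rejected). Plateau ties in the valley scan break toward smaller
$m$; ties at the peak break toward smaller $m$ as well.

Heterozygosity- and repeat-aware mixture modeling of the spectrum is
out of scope; the estimator assumes a mostly single-copy genome, which
is what the generator produces.

## Chargaff second-parity QC

Chargaff's second parity rule says that within a single strand, a word
$w$ and its reverse complement $\bar w$ occur at nearly equal
frequency. For every complement pair (keyed by the lexicographically
smaller member) the package computes the symmetry ratio
$S(w) = f(w) / (f(w) + f(\bar w))$ from single-strand counts
(no canonicalization here — the rule is a single-strand statement,
counting the opposite of the spectrum module). A well-assembled genome
gives $S$ tightly concentrated around 0.5; assembly artifacts such as
strand-specific duplications loosen it.

Palindromic k-mers ($w = \bar w$, possible only at even k) have
$S = 0.5$ by construction; they are flagged in the table and excluded
from dispersion summaries so they cannot artificially tighten the
distribution. Pairs never observed are excluded and counted. Summaries
report mean, sample SD, median, and the fraction of pairs within
$\varepsilon$ of 0.5 (default $\varepsilon = 0.01$); comparisons between
two assemblies report both SDs and declare the smaller-SD set tighter.
The default $k = 4$ follows standard practice for this QC; the metric
pair (SD, fraction-within-$\varepsilon$) is the package's declared
quantification of "tighter", since no standard one exists. A sequence
concatenated with its own reverse complement has every pair at exactly
$S = 0.5$; that exactness is what the acceptance script verifies.

## LTR insertion dating

The two LTRs of a retrotransposon are identical when the element
inserts and diverge afterwards on two independent branches. The package
aligns each 5′/3′ pair end-to-end (Needleman–Wunsch with affine gaps,
delegated to `Biostrings::pairwiseAlignment`; match +5, mismatch −4,
gap open 10, gap extend 0.5 — the common nucleotide convention; LTR
pairs are near-identical, so the scoring choice is second-order).
Over the valid columns (both bases unambiguous; gap/ambiguous columns
removed, i.e. pairwise deletion) it computes the Kimura two-parameter
distance from the transition proportion $P$ and transversion proportion
$Q$:

$$K = -\tfrac12 \ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big],$$

and converts to an insertion age $T = K / (2r)$ with the substitution
rate $r = 1.3\times10^{-8}$ per site per year by default (a rate widely
used for plant LTR dating; it is exposed as a parameter). Pairs outside
the K2P domain ($1 - 2P - Q \le 0$ or $1 - 2Q \le 0$) are saturated:
they are excluded and counted rather than clamped, because clamping
fabricates ages. Age histograms use half-open 0.5 My bins from zero and
report the modal bin and the oldest insertion.

## Gene structure and composition

Gene models are exon interval sets (1-based inclusive coordinates, the
native R/Bioconductor convention, used internally everywhere; GFF3 I/O
is therefore conversion-free). Introns are the gaps between consecutive
exons. Structure summaries report per-gene means and sample SDs
(n − 1) of gene length, exon/intron lengths, exon/intron counts, and
exonic/intronic GC; GC is computed over the concatenated exonic (resp.
intronic) sequence of each gene and then averaged across genes, not
pooled over base pairs — the two differ under length variation, and the
per-gene average is the declared convention. "First" exon/intron
follows transcript orientation: for minus-strand genes the genomically
last element is first.

Per-record GC excludes `N` from numerator and denominator. Density
curves use a Gaussian kernel with Silverman's rule bandwidth by
default; modes are strict local maxima with at least 5% of the maximum
density (a prominence threshold that suppresses noise wiggles).

## Expression

FPKM tables are matrices (genes × organs or species). log2 transforms
either drop zero cells (counted) or add a pseudocount; the drop policy
is the default because a pseudocount choice silently shifts histograms.
GC-binned expression uses half-open lower-inclusive GC bins of width
0.20 and log2 FPKM bins of width 0.5, both exposed. Cross-species
comparison first divides every column by its EF1A (elongation factor
1-alpha) cell — making the result invariant to per-column rescaling,
which is the point of housekeeping normalization — and then takes
log2 ratios of the normalized abundances between species over an
ortholog map, in one organ (leaf by default). The EF1A self-index is 0
exactly and swapping species negates every index; both identities are
tested. Ranking functions break FPKM ties by gene id so outputs are
deterministic. In the top/bottom structure contrast, the pooled mean
intron length of a set whose genes carry no introns is reported as 0
(no intron sequence), keeping the contrast well-defined.

# The synthetic cohort

The generators define the validation conditions; their defaults are
fixed once and all tests run against them.

* **Genome**: i.i.d. bases within 1 kb segments whose GC level is drawn
  from a finite mixture — default a single 0.35 component; two-component
  (0.30/0.45) settings reproduce the bimodal GC landscape typical of
  plant genomes.
* **LTR elements**: ancestral LTR at uniform composition; the two
  copies evolve independently under the exact K2P transition matrix at
  branch length $rT$ (not a small-distance Bernoulli approximation), so
  the expected pairwise distance is exactly $2rT$ at any age and planted
  ages up to ~15 My stay unbiased. Transition/transversion rate ratio
  $\kappa = 2$ by default. Ages come from a log-normal mixture
  parameterized by its modes — 1, 6, 11 My with weights 0.7/0.2/0.1 —
  because empirical insertion-age histograms are right-skewed with a
  dominant young peak and trailing older shoulders; a symmetric
  (Gaussian) component centered on a bin edge would split its mass
  between two histogram bins and not actually produce a peak there.
  Elements are inserted at uniform sorted positions; insertion
  lengthens the sequence, so elements never overlap or nest (nesting is
  unnecessary for validating the dating math). LTR length default 2 kb.
* **Genes**: exon counts are a shifted negative binomial matched to
  mean 3.5 / SD 2.96; exon and intron lengths are log-normals matched
  by moments to 208.28/210.62 and 388.62/393.41 bp (log-normals keep
  lengths positive; only mean and SD are specified, so the family is
  the package's choice); exonic/intronic GC 42.74%/30.04% enforced by
  sampling bases at the target composition (not rejection, for speed).
* **Reads**: count `round(G·depth/L)`, uniform starts, uniform strand,
  i.i.d. substitution errors; no indels, no quality realism, no pairs.
* **Expression**: log2 FPKM Gaussian (mean 5, SD 2, matching densities
  that peak near 5 log2 units); a Gaussian-copula coefficient couples
  expression rank to total intron length across all organs (0.8 gives
  Spearman ≈ 0.78), letting tests plant and recover the
  "highly expressed genes carry longer introns" pattern. An EF1A row
  with positive FPKM is always present.

All randomness flows from the single seed in each spec; identical specs
give byte-identical artifacts, and the caller's RNG state is restored.
What the generators do **not** emulate: real repeat landscapes (nested
and solo LTRs, target-site duplications), indel evolution,
heterozygosity, coverage biases, isoform structure, and count noise in
FPKM. Passing recovery tests therefore demonstrates the estimators'
correctness under their stated models, not robustness to every artifact
of real data.

# Problem sizes used in validation

Recovery tests run at deliberately modest scales chosen so each
statistical check is well-powered: 300 planted LTR elements with 2 kb
LTRs for age recovery (per-element K2P noise at 1 My and 2 kb is ~11%
relative, so the <15% mean-error bound is a real test of bias), a
200 kb genome at 30× for spectrum sizing, 5,000 genes for structure
round-trips, and 20 independent expression tables for the coupling
detection count. Unit tests use hand-checkable miniatures; alignment is
verified against exhaustive enumeration on sequences of length ≤ 6, and
the K2P closed form against an independent algebraic re-derivation and
`ape::dist.dna`.

# Degenerate inputs and numerical choices

Even k is rejected in spectrum counting (self-complementary k-mers
would be double-counted relative to the rest). Spectra with no rise
after the valley raise a "no coverage peak" error rather than returning
a size. All-`N` records are flagged, not fatal, in composition;
all-identical GC collapses the density bandwidth to a small floor
rather than erroring. Saturated K2P pairs are excluded and counted.
Expression readers reject duplicate ids, missing cells and negative
FPKM outright; zero-FPKM handling is always an explicit policy.

# Known limitations

The spectrum estimator quantizes at the peak multiplicity (above); the
Chargaff comparison reports dispersion without a significance test; the
aligner is pairwise-only (no multiple alignment) and reports a single
optimal alignment under a fixed deterministic tie-break
(diagonal over gaps); and no annotation, mapping or assembly machinery
is included — gene models, ortholog maps and annotation flags are
inputs, produced upstream or planted by the generators.
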