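---
title: "Joint deletion calling from insert-size profiles: models and methods"
author: "joindel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint deletion calling from insert-size profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(joindel)
```

## The problem and the signal

Medium-size deletions (roughly 500 bp to 10 kb) leave a characteristic
footprint in paired-end short-read data: a read pair whose fragment spans
the deleted sequence aligns to the reference with an apparently inflated
insert size, shifted upward by the deletion length. `joindel` detects and
genotypes such deletions **jointly** across a cohort: all samples are
examined in one coordinated pass, so that a rare deletion carried by a
single genome can borrow statistical strength from the cohort-wide model of
allele frequency, and no post-hoc merging of per-sample call sets is
needed.

The pipeline has two stages:

1. **Profiling** (`profileBam()`, `buildProfile()`): each coordinate-sorted
   alignment file is reduced to a compact, indexed insert-size profile -- one
   record per confidently aligned read pair (position, clip-extended insert
   size, read group) plus the sample's null insert-size distribution.
2. **Joint calling** (`callDeletions()`): the genome is scanned in windows
   of 30 bp (default). In each window, deletion length and cohort allele
   frequency are estimated iteratively from all samples, a weighted
   likelihood-ratio test decides whether a deletion overlaps the window,
   and consecutive significant windows are merged into nonredundant calls
   written as VCF.

## The window model

Let $I^S$ be the insert sizes of the pairs of sample $S$ overlapping a
window and $\Delta^S = \{i - \mu_S\}$ their deviations from the sample's
null mean. The per-read-group null histogram is transformed
(`transformHistogram()`) into the relative likelihood $H^S(\delta)$ of
observing a pair with deviation $\delta$ in a window of width $w$: each
insert size $i$ is weighted by the $i + w - 1$ window placements such a
fragment can overlap, renormalised, and floored at $10^{-10}$ so that
likelihood products never vanish.

Genotype likelihoods for 0, 1 or 2 deletion alleles of length $l$ are
products over the window's deviations,

$$L(G_0 \mid \Delta^S) = \prod_\delta H^S(\delta - \epsilon_S), \qquad
  L(G_2 \mid \Delta^S) = \prod_\delta H^S(\delta - l),$$
$$L(G_1 \mid \Delta^S) = \prod_\delta
  \tfrac{1}{2}\left[H^S(\delta - \epsilon_S) + H^S(\delta - l)\right],$$

where $\epsilon_S$ is a sample-specific reference shift (default 0; an
optional per-window re-centering on the capped median of non-supporting
deviations can absorb local biases such as GC effects). Sample- and
genotype-specific weights combine these likelihoods with Hardy-Weinberg
genotype frequencies at the current allele frequency $f$:

$$a_g^S = \frac{L(G_g \mid \Delta^S)\, L(f, G_g)}
               {\sum_j L(G_j \mid \Delta^S)\, L(f, G_j)},
  \qquad L(f, \cdot) = \left((1-f)^2,\; 2f(1-f),\; f^2\right).$$

The test statistic compares the reference model against the deletion
model,

$$\Lambda = \frac{(1-\pi) \prod_S L(G_0 \mid \Delta^S)}
                 {\pi \prod_S \sum_g a_g^S\, L(G_g \mid \Delta^S)},$$

with deletion prior $\pi = 10^{-4}$; the null hypothesis is rejected when
$-2\log\Lambda$ reaches the $\chi^2_1$ quantile at $P = 0.01$ (one-tailed,
6.6349). Noncarriers contribute $a_0^S \approx 1$ and cancel between
numerator and denominator, which is what lets a single carrier drive the
test in a large cohort.

## Iterative estimation

Each window runs a small fixed-point loop (`iterateWindow()`):

* **Length initialisation**: third quartiles of the per-sample deviations
  are clustered greedily (descending; cluster gap
  $\max(\text{pooled sd}, 40\,\text{bp})$); each cluster median is one
  starting length, so two different deletion lengths overlapping one
  window are estimated separately. Clusters below the minimum detectable
  length are dropped.
* **Frequency initialisation**: the fraction of deviations above
  $3\sigma$, clamped to $[1/2n, 1 - 1/2n]$.
* **Updates**: weights $\to$ frequency
  ($f = \frac{1}{2|\mathcal S|}\sum_S (a_1^S + 2a_2^S)$) $\to$ per-pair
  shift probabilities
  ($P = a_1 H(\delta-l)/(H(\delta-\epsilon)+H(\delta-l)) + a_2$) $\to$
  length ($l = \sum \delta P / \sum P$), until $|\Delta l| \le 2$ bp and
  $|\Delta f| \le 10^{-3}$, at most 15 iterations. Additional termination:
  the length falling below the minimum detectable length aborts the
  initialisation (no call), and a revisited state (oscillation) stops the
  loop with the current state.

Numerical choices worth stating explicitly:

* All products run in natural-log domain; the histogram floor guarantees
  finiteness. The log pipeline is tested against a linear-domain
  brute-force oracle to $10^{-6}$ relative.
* The **minimum detectable length** is derived from the data as half the
  95th percentile of $|\delta|$ under the null (about one standard
  deviation for near-normal inserts), configurable via `minLen`.
* **Uninformative pairs** whose deviation lies outside the support of both
  the null and the $l$-shifted model (both lookups at the floor) are
  excluded from the length update: such pairs typically belong to a
  different deletion length tested by another initialisation, and Eq.-12
  probabilities would otherwise drag the update toward their deviations.
* **Start estimation** tracks the rightmost forward-read evidence among
  pairs supporting the deletion (posterior $P \ge 0.5$ *and* a deviation
  favouring the shifted model -- a homozygous carrier has $P \approx 1$
  for all its pairs, including non-deviated ones downstream of the
  deletion end). Because profile records store the forward start rather
  than per-read alignment ends (a junction-crossing read is clipped at the
  junction in real alignments, so adding a nominal read length would
  overshoot by up to one read length), the caller anchors the start at the
  rightmost supporting forward start + 1, which at 30x coverage sits
  within a few bp of the junction.
* **Window self-consistency**: the test asks whether a deletion of length
  $l$ overlaps the window, so converged states whose estimated interval
  $[\hat s, \hat s + \hat l)$ does not contain the window are discarded.
  Flanking windows are reachable by the *apparent* spans of
  deletion-spanning fragments but would contaminate the merged per-sample
  likelihoods with mixtures of deviated and normal pairs (turning
  homozygous calls into spurious heterozygotes).

## Merging and output

Significant (window, length) pairs are sorted by predicted start, length
and likelihood ratio, then combined left-to-right when starts differ by at
most $\max(\hat l/2,\, 3w)$ and lengths by at most 25% relative
(`mergeCandidates()`). The pass is repeated to a fixed point so that no
two emitted calls still satisfy the merge criteria (group medians move
when windows combine; the first pass is the plain single sweep). A call
reports the median start and length, the mean natural-log genotype
likelihoods over its windows (PHRED-scaled afterwards -- scaling first and
averaging PHRED values would not commute), a genotype from the smallest
PL (ties are reported missing), the PL gap as genotype quality, and the
cohort allele frequency recomputed from the emitted genotypes. Samples
with fewer than 3 pairs or more than 4x the cohort median pair count at
the locus are not genotyped. VCF 4.2 output uses symbolic `<DEL>` alleles
with `END`, negative `SVLEN`, `SVTYPE` and `AF`.

## The profile format

The on-disk `.jdp` format is defined by this package: magic bytes and a
version, little-endian fixed-width integers, per-contig blocks of zig-zag
delta-encoded forward starts stored columnar with insert sizes and read
groups, and a trailing index with one entry per 2^16 bp bucket (record
offset plus decoding anchor) that lets `profileSeek()` jump to a genomic
position without decoding the file. Round trips are lossless and a 30x
profile is about 1-2% of the size of the equivalent uncompressed SAM
rendering. Pair-confidence criteria (primary FR pairs, both mates mapped
to one contig, MAPQ >= 30, no duplicates/QC failures) are exposed in
`jdConfig()`. The null distribution is sampled from user-configurable
regions (default: the middle 60% of each contig); its support is capped at
median + 50 robust standard deviations (MAD-based) so that spanning pairs
of genuine deletions inside the sampling regions cannot inflate the null
-- with clean data this coincides with the mean + 50 sd rule, under
contamination it does not collapse.

## The simulator and what it does (not) cover

`simulateDeletionSet()` draws deletions with lengths uniform on
[100, 10000] bp, allele frequencies uniform on (0, 1), and positions
uniform subject to a 1000 bp minimum gap (uniform spacing of the free
sequence -- an exact sampler of the valid configurations; with exclusion
regions, sequential placement with bounded retries).
`simulateGenotypes()` samples haplotypes by allele frequency and pairs
them into diploids; with 2000 deletions the expected per-individual load
is $n/3 \approx 667$ heterozygous and homozygous deletions each.
`simulateReadPairs()` is a *fragment-level* generator: fragments are
placed uniformly per haplotype with normal inserts (default 450 +/- 15 bp,
truncated at twice the 150 bp read length); mapping haplotype to reference
coordinates inflates spanning inserts by the deletion length and never
generates fragments inside homozygously deleted sequence. The read-pair
caller consumes only positions and insert sizes, so sequence-level
simulation would add nothing the method can see; an optional SAM renderer
(`writeSam()`) exercises the BAM ingestion path.

The simulator deliberately omits sequencing-error models, GC bias,
mappability artifacts and repeat-mediated ambiguous alignments. Passing
end-to-end tests therefore demonstrate correctness of the statistical
machinery under the model's own assumptions, not robustness to every
real-data failure mode; on real cohorts the Hardy-Weinberg, size and
region filters in `filterCalls()`/`hweFilter()` carry that burden.

## Evaluation toolkit

`matchCallsets()` scores calls against truth at 50% reciprocal overlap
with greedy one-to-one assignment (descending overlap, deterministic
tie-break). `hweExactTest()` is an exact conditional test (two-sided,
no mid-P correction) -- exact rather than asymptotic because SV-scale
cohorts routinely produce genotype counts far too small for the chi-square
approximation. Trio statistics classify all 27 genotype combinations by
allele transmission (parent-symmetric), ignore trios with missing
genotypes or all-reference genotypes, and report the Mendelian error rate,
the transmission rate (overall, or restricted to deletions unique to a
single trio with a 0/1 x 0/0 parent pair, where the expectation is 50%),
and de novo candidates (carrier child, 0/0 parents, all GQ >= 50).
`genotypeMatrix()` exports allele counts for external PCA/LD tooling.

## Problem sizes used by the test suite

The shipped tests run, among smaller fixtures: parameter recovery on 100
windows of 100 samples each (median length error <= 2 insert-sd, median
frequency error <= 0.05), and an end-to-end cohort of 20 samples on a
5 Mb contig with 100 deletions of 500-10000 bp at 30x coverage, which
achieves recall and precision >= 0.9 at 50% reciprocal overlap against the
carried truth set. Deletions that no sampled haplotype carries produce no
read pairs by construction and are excluded from the recall denominator.
Trio statistics are checked on genotype-level Mendelian simulations (zero
errors, transmission within the 95% binomial band of 50%).

## Known limitations

* Only deletions are modelled; insertions, inversions and translocations
  are out of scope, as are CRAM input and X-aware genotyping.
* Start positions are insert-size estimates (no split-read refinement);
  expect single-digit bp bias at 30x and more at low coverage.
* Deletions shorter than the minimum detectable length (about one insert
  standard deviation) are invisible to the likelihood-ratio test.
* Two overlapping deletions of similar length at one locus are merged
  into a single call; distinct lengths are kept apart by the relative
  length criterion.

```{r session}
sessionInfo()
```
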