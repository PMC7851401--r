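# joindel

Joint detection and genotyping of medium-size deletions (about 500 bp to
10 kb) across many short-read genomes, from the insert-size signal of
paired-end alignments.

Most structural-variant pipelines call each genome separately and merge
the per-sample call sets afterwards, a step that is error-prone when the
same deletion is reported with shifted coordinates in different samples
and that silently loses variants too weakly supported in any single
genome. `joindel` takes the opposite route: every coordinate-sorted
BAM/SAM is first reduced to a compact, indexed **read-pair profile**
(positions and clip-extended insert sizes of confidently aligned pairs
plus the sample's null insert-size distribution), and the profiles of all
samples are then scanned **together** in 30 bp windows. The package is
aimed at cohort-scale germline analyses -- population panels, trio studies,
de novo screens -- and ships its own cohort simulator and evaluation suite
so the whole method is testable without external sequencing data.

## The model in brief

A read pair whose fragment spans a deletion of length *l* shows an insert
size inflated by *l*. For a window, with per-sample deviations
Δ^S = {i − μ_S} and the window-transformed null likelihood H^S(δ),
genotype likelihoods are products over pairs:

    L(G0 | Δ^S) = Π H^S(δ − ε_S)                       (no deletion allele)
    L(G1 | Δ^S) = Π [H^S(δ − ε_S) + H^S(δ − l)] / 2    (heterozygous)
    L(G2 | Δ^S) = Π H^S(δ − l)                         (homozygous)

Sample weights a_g^S ∝ L(G_g | Δ^S) · L(f, G_g) couple the data to
Hardy-Weinberg genotype frequencies at the cohort allele frequency *f*,
down-weighting noncarriers and boosting carriers of rare alleles. The
likelihood-ratio test

    Λ = (1 − π) Π_S L(G0 | Δ^S)  /  ( π Π_S Σ_g a_g^S L(G_g | Δ^S) )

with prior π = 1e-4 rejects "no deletion" when −2 log Λ ≥ 6.6349
(χ², 1 df, P = 0.01 one-tailed). Deletion length and allele frequency are
estimated per window by a small fixed-point iteration (at most 15 rounds);
consecutive significant windows merge into one call with PHRED-scaled
genotype likelihoods, genotype quality and cohort AF in a multi-sample
VCF. The methods vignette (`vignettes/joint-deletion-calling.Rmd`) derives
every formula and documents all numerical choices.

## Worked example

Simulate a small cohort (five deletions, six diploid genomes, 30x
fragment coverage), profile it, call jointly, and score against the truth:

```r
library(joindel)

dels  <- simulateDeletionSet(5, 4e5, lenRange = c(600, 3000), seed = 11)
coh   <- simulateGenotypes(dels, 6, seed = 12)
profs <- simulateCohortProfiles(coh, coverage = 30, seed = 13)

profs[[1]]
#> ReadPairProfile 'sample001': 39698 read pairs on 1 contig(s), 1 read group(s), read length 150 bp
#> InsertSizeHistogram | read group 1 | n = 23938 | mean = 450.07 bp | sd = 15.06 bp | support [392, 510]

cs <- callDeletions(profs)
calls(cs)
#> GRanges object with 5 ranges and 4 metadata columns:
#>       seqnames        ranges strand |     svlen        af      stat  nWindows
#>   [1]     chrS   33812-35077      * |     -1266  0.416667   4284.12        41
#>   [2]     chrS   50433-51034      * |      -602  0.583333   5228.39        19
#>   [3]     chrS 117222-119047      * |     -1826  0.916667   8833.00        60
#>   [4]     chrS 350974-351606      * |      -633  0.916667   7775.45        20
#>   [5]     chrS 381594-382349      * |      -756  0.750000   7201.89        24

genotypes(cs)[1:3, 1:4]
#>      sample001 sample002 sample003 sample004
#> [1,] "0/1"     "0/0"     "1/1"     "0/0"
#> [2,] "1/1"     "1/1"     "0/0"     "0/1"
#> [3,] "1/1"     "1/1"     "1/1"     "1/1"

unlist(matchCallsets(cs, trueDeletions(coh))[c("recall", "precision", "f1")])
#>    recall precision        f1
#>         1         1         1
```

Each call row is one merged deletion: `svlen` the (negative) estimated
length, `af` the cohort allele frequency recomputed from the emitted
genotypes, `stat` the largest −2 log Λ among its windows, `nWindows` how
many consecutive windows supported it. All five simulated deletions are
recovered at their simulated positions and lengths with the correct
genotypes; `writeDeletionVcf(cs, "calls.vcf")` emits the VCF.

The same pipeline is available from the shell:

```sh
joindel simulate --out-dir sim --n-deletions 100 --n-samples 10 --seed 1
joindel call --out calls.vcf sim/*.jdp
joindel evaluate --vcf calls.vcf --truth sim/truth.vcf
```

Trio quality control: `buildTrioTable()` + `hweFilter()` +
`mendelianErrorRate()` / `transmissionRate()` / `deNovoCandidates()`
implement Hardy-Weinberg filtering, Mendelian-consistency rates,
transmission rates for deletions unique to one trio, and de novo
screening at a genotype-quality threshold.

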