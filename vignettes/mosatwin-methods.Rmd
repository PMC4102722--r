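---
title: "Detecting somatic mosaicism in monozygotic twin pairs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic mosaicism in monozygotic twin pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosatwin)
```

## The problem

Monozygotic (MZ) twins are genetically identical at conception; any genetic
difference between them must have arisen postzygotically, as a somatic
mosaic. Twin pairs discordant for a disease are therefore a powerful design
for finding somatic contributions to disease risk: a variant present in the
affected twin's tissue but absent from the healthy co-twin is a direct
candidate. The catch is that the expected number of true differences is
tiny while sequencing produces thousands of apparent ones, so the analysis
problem is almost entirely one of *discordance screening and false-positive
arbitration* between matched samples.

`mosatwin` implements that analysis as a reusable pipeline: three
complementary single-site discordance detectors, candidate-site selection
for a four-sample (affected/healthy × blood/biopsy) design, automated
arbitration of indel-misalignment artifacts, a windowed depth-ratio CNV
caller with a twin-differential filtering cascade, and a carriership-based
susceptibility score. Because real twin genomes of this kind are not
redistributable, the package ships a synthetic data generator with planted
ground truth; every statistical claim the test suite makes is made against
that truth.

## Genotype likelihoods

All SNV statistics start from per-site read pileups: for each read, the
observed base, phred base quality, phred mapping quality, read start point
and strand. For a diploid genotype $g = \{a_1, a_2\}$ and a read with base
$b$ and error probability $e = 10^{-BQ/10}$,

$$P(b \mid g) = \tfrac12 P(b \mid a_1) + \tfrac12 P(b \mid a_2),
\qquad P(b \mid a) = \begin{cases} 1 - e & b = a \\ e/3 & b \ne a.\end{cases}$$

Log-likelihoods are summed over reads and phred-scaled so the best of the
10 genotypes scores exactly 0. Reads with mapping quality below 10 are
discarded first (the same filter the screening tools apply); sites with no
usable reads become an explicit no-call, distinct from homozygous
reference, and sites below 8 usable reads are flagged low-confidence. The
prior over the 10 genotypes is flat: the screening statistic names a
Bayesian comparison but no prior, and a flat prior keeps results
reproducible without hidden constants (a heterozygosity-weighted prior
would shift scores by a site-independent offset at these depths). Depth is
capped at 500 reads per site; beyond that the posterior is saturated and
the extra reads only cost time.

## The three discordance detectors

**Genotype-difference (somatic) score.** With per-sample posteriors
$P(g \mid A)$ and $P(g \mid B)$ (flat prior, independent across samples
given the data),

$$P(\text{same}) = \sum_{g} P(g \mid A)\, P(g \mid B), \qquad
\text{score} = \min(255,\ \mathrm{round}(-10 \log_{10} P(\text{same}))).$$

The score is phred-scaled: 100 corresponds to a difference probability of
$1 - 10^{-10}$, which is the default screening threshold; the cap at 255 is
applied after rounding. A subtlety worth knowing: for a homozygous
reference sample at depth $d$, $P(\text{same})$ is dominated by the
residual probability $\approx 0.5^d$ that the sample is truly heterozygous,
so a 30× hom-ref vs. 15/15 het comparison scores about 90 — *below* the
screening threshold. Depth, not allele balance alone, drives the score.

**Fisher allele-count test.** Two-sided Fisher's exact test on the 2×2
ref/alt × sample table, with the classical two-sided rule (sum of table
probabilities no larger than the observed table's). The screen keeps
p < 0.01 *and* requires zero occurrences of the variant allele in the
reference sample, mirroring the heuristic screen it models. We use the
standard `stats::fisher.test` implementation; the test suite verifies it
against an exhaustive hypergeometric enumeration for every table with
margins up to 12.

**Quality-filtered Fisher test.** The same test after dropping
observations below base quality 20 or mapping quality 20 and zeroing any
allele whose supporting reads span fewer than 3 unique start points — a
defense against stacked duplicates and local misalignment. The defaults
are conservative and configurable; the screen it models names the filter
kinds but not their values. Both the p-value and the post-filter table are
returned for audit.

No multiple-testing correction is applied at the screening stage — the
design is a deliberately sensitive raw p < 0.01 screen followed by
arbitration — but the run report states the number of tests performed so
users can post-correct.

## Candidate selection and arbitration

In the four-sample design, query positions are reduced before testing:
a variant called in all four samples, in both biopsies, or in both blood
samples cannot be a twin- or tissue-specific somatic event, and variants
with population allele frequency above 20% are overwhelmingly inherited.
Three ordered comparisons are then run: affected biopsy vs. affected
blood, affected blood vs. healthy blood, affected biopsy vs. healthy
biopsy.

Arbitration automates what is otherwise manual alignment review, and only
ever moves candidates toward exclusion:

1. **Realignment check** — the detector statistic is recomputed on
   indel-realigned pileups; if it no longer passes, the call is an
   `artifact`. The packaged fixture reproduces the canonical failure mode:
   both samples carry a 19 bp insertion (`CGCAGCAGGGGCAGCAGGG`)
   heterozygously, but only one sample's library was aligned through it,
   so the misplaced read tails create two spurious SNVs with a convincing
   between-sample allele-count difference. The artifact is encoded
   directly in pileup space — no aligner runs inside the package — because
   its signature (mismatch bases from shifted reads, clean after
   realignment) is fully characterized at the pileup level.
2. **Coverage check** — candidates whose reference sample has fewer than
   8 usable reads are `low-coverage`, the dominant source of false
   "discordances" in practice.
3. **Cross-sample veto** — a variant also visible (≥ 5% of reads by
   default) in a held-out sample of the *other* twin cannot be a somatic
   difference and is marked `artifact`. The held-out samples passed to the
   veto are the healthy twin's, never the affected twin's other tissue:
   a genuinely twin-discordant clonal event is present in both affected
   tissues and must not veto itself.

Survivors are `confirmed-candidate`. Cross-method overlap of the top-k
calls per detector (Venn counts over the seven regions) quantifies how
little the three detectors agree on noise — on event-free synthetic runs
the triple intersection is empty, while planted clonal events are
recovered by all three.

## CNV calling and the differential cascade

Depth is summed per 100 bp window; each sample is scaled to unit median
(library size), and each test window is divided by the mean of 58 scaled
background-panel samples. The panel aggregate is the mean (a median
variant is available behind a flag). A window is a loss below ratio 0.62
and a gain above 1.38 (the one-copy expectations being 0.5 and 1.5);
same-direction runs merge across gaps while support stays ≥ 80%, and a
region survives only with ≥ 20 windows, ≥ 80% support and a mean ratio
beyond its threshold. "Window" here is the unit of region support
throughout (the bait/window distinction of capture designs is not
modeled).

The twin-differential cascade then requires: (1) reciprocal overlap ≥ 90%
between the affected twin's two samples — merged as the *intersection* of
the pair, the conservative choice of candidate bounds; (2) no overlap
(≥ 1 bp, any direction by default) with any healthy-twin region;
(3) for losses, mean mappability uniqueness ≥ 0.5 over the candidate,
since low-mappability regions lose coverage spuriously (uniqueness tracks
are typically derived from 35 bp windows; the threshold is configurable).
A loss-of-heterozygosity check supports or refutes deletion candidates:
a true one-copy loss collapses the carrier's heterozygous fraction; with
fewer than 5 informative sites the verdict is "insufficient" rather than
a guess.

## The risk model

Susceptibility is summarized as a carriership score
$S = \sum_j c_j \ln \mathrm{OR}_j$ over risk loci $j$, with $c_j \in
\{0,1,2\}$ risk-allele copies. Natural log is the default (base 10 behind
a flag); per-carrier counting ($c_j \in \{0,1\}$) is available because the
phrase "each occurring risk allele" admits both readings — the default is
per-copy, the standard additive model. Missing genotypes skip the locus,
with the number used always reported. The score is only interpretable
against a control distribution: controls are scored identically and the
subject's midrank percentile is reported. Distributions carry an identity
key of the locus subset used, so a 133-locus score can never be silently
compared against a 44-locus control distribution. Under Hardy–Weinberg
equilibrium the control mean has the closed form $\sum_j 2 f_j \ln
\mathrm{OR}_j$, which the tests verify by simulation.

## What the generator emulates — and what it does not

Defaults encode the study conditions the pipeline is designed for:

| parameter | default | rationale |
|---|---|---|
| germline diversity | 0.1% of sites | typical human heterozygosity |
| Ti/Tv | 2.1 genome-wide, 2.8 in CDS | standard variant-QC expectations |
| het:hom ratio | 2:1 | typical resequencing value |
| mean depth | 40× | within the 36–72× range of such studies |
| base quality | constant Q30 | error rate 10⁻³ |
| low-MQ reads | 2% at MQ 5 | exercises the MQ < 10 filter |
| somatic VAF | 0.5 (clonal) | mosaic VAFs configurable downward |
| CNV copy ratios | 0.5 / 1.5 | one-copy loss / gain |
| background panel | 58 samples | depth-normalization panel size |
| control cohort | 1,920 subjects | risk-percentile reference |

Every stage draws from its own pseudo-random substream keyed by (master
seed, stage label), so adding a stage never perturbs another stage's
draws, and a fixed seed reproduces byte-identical outputs.

Pileups are simulated at *informative sites only* — germline and somatic
truth positions plus a configurable number of homozygous-reference sites —
not at every base. Every downstream statistic is site-wise, so
whole-genome pileups would add runtime without adding information. The
generator also does not model: read-level alignment (FASTQ/SAM),
platform-specific error profiles (colorspace chemistry, cycle effects),
GC or capture bias in depth, linked errors from shared read ends, or
tumor-like subclonal phylogenies. Passing recovery tests therefore shows
the *inference machinery* is correct under the stated noise model; it
does not certify performance on real libraries, where alignment artifacts
are richer than the one the fixture encodes. The true VAF distribution of
plausible twin discordances is unknown (pooled biopsies dilute mosaics),
so VAF is an exposed parameter, not a fixed constant; the per-VAF power
table in `evaluate_against_truth()` makes the dilution cost measurable.

## Numerical choices and degenerate inputs

Likelihoods are accumulated in natural-log space with log-sum-exp
normalization, so 1,000-read pileups cannot underflow; the linear-space
oracle in the tests agrees to 10⁻¹⁰ on small pileups. Undefined results
are explicit markers, never silent zeros: a no-call site yields no score
(not 0), an all-zero Fisher table yields NA, a variant set without
transversions has no Ti/Tv, an empty concordance denominator is NA.
Top-k ranking breaks ties by (contig, position) for determinism. Readers
of the on-disk formats reject malformed input with the offending line
number rather than repairing it; multi-allelic VCF records are an explicit
unsupported-record error (the comparisons are biallelic throughout), and
BED half-open semantics are preserved exactly.

## Problem sizes used in the tests

The recovery experiments run ten seeds of a 1 Mb twin pair at 40× with 20
planted clonal SNVs (plus ten event-free seeds), ten seeds of 3 kb
(30-window) planted discordant losses over a 200 kb CNV target, and a
100,000-draw substitution-spectrum check of the Ti/Tv targets; these sizes
give stable statistics (binomial standard error below half a percent on
sensitivity) while keeping a full suite run in a few minutes. Oracle
equivalence for the Fisher detector is exhaustive for tables with margins
≤ 12, and the score detector is checked read-for-read against brute-force
posterior enumeration on moderate pileups.

## Known limitations

* The score detector saturates at 255 and is reported as an integer;
  differences beyond $P(\text{same}) < 10^{-25.5}$ are indistinguishable.
* The CNV caller is a single depth-ratio method; the cascade accepts
  externally called region lists (BED), so a second caller can be swapped
  in, but none is bundled.
* InDels are not genotyped; they appear only as the artifact mechanism.
* The risk score is a relative ranking, not a calibrated absolute risk.
* Reported percentiles depend on the simulated control cohort's
  Hardy–Weinberg assumption; real cohorts with population structure will
  have wider score distributions.
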