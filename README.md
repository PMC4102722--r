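# mosatwin

Detection of somatic mosaicism between monozygotic (MZ) twins — or any
pair of matched samples from nominally identical genomes — from per-site
read pileups and windowed sequencing depth.

MZ twins discordant for a disease are a natural experiment for somatic
contributions to disease risk: any genetic difference between co-twins
must have arisen postzygotically. The statistical problem is that true
differences are vanishingly rare while sequencing noise produces
thousands of apparent ones. `mosatwin` implements the screening and
arbitration machinery for that setting:

* **Three discordance detectors** per site and sample pair:
  * a phred-scaled genotype-difference score
    `score = min(255, round(-10 log10 Σ_g P(g|A) P(g|B)))`
    from diploid genotype likelihoods (flat prior, MQ ≥ 10 reads), with a
    screening threshold of 100 (difference probability 1 − 10⁻¹⁰);
  * a two-sided Fisher's exact test on ref/alt allele counts, screened at
    p < 0.01 with zero variant reads required in the reference sample;
  * a quality-filtered Fisher test (BQ ≥ 20, MQ ≥ 20, ≥ 3 unique read
    start points per allele).
* **Candidate selection** for the four-sample design (affected/healthy ×
  blood/biopsy): drop variants called in all four samples, in both
  biopsies, in both bloods, or above 20% population frequency.
* **Arbitration** replacing manual alignment review: recompute statistics
  on indel-realigned pileups (artifact), flag reference-sample depth < 8
  (low-coverage), and veto variants visible in the healthy twin's
  held-out sample.
* **CNV cascade**: 100 bp windowed depth ratios against a background
  panel (default 58 controls); window calls at ratio < 0.62 (loss) /
  > 1.38 (gain); regions need ≥ 20 windows and ≥ 80% support; candidates
  need ≥ 90% reciprocal overlap between the affected twin's samples, no
  overlap with the healthy twin, mappability uniqueness ≥ 0.5 for losses,
  plus a loss-of-heterozygosity support check.
* **Risk score**: carriership model `S = Σ_j c_j ln(OR_j)` over risk loci,
  reported as a midrank percentile in a control cohort (default 1,920
  subjects under Hardy–Weinberg equilibrium).
* **Synthetic twin-pair generator** with planted ground truth (germline
  diversity 0.1%, Ti/Tv 2.1 genome-wide / 2.8 exonic, 40× Poisson depth,
  Q30 phred errors, configurable-VAF somatic plants, a 19 bp
  insertion-misalignment artifact fixture, CNV depth matrices, HWE
  control cohorts) — every claim in the test suite is scored against this
  truth.

See `vignettes/mosatwin-methods.Rmd` for the models, assumptions and
design choices.

## Worked example

```r
library(mosatwin)

cfg <- pipeline_config(seed = 1, outdir = "twin_run",
                       genome_length = 1e5, n_somatic = 5)
rep <- run_pipeline(cfg)

rep$simulate$n_germline        # 97    shared germline SNVs simulated
rep$genotype$concordance       # 0.983 twin concordance (5/302 sites
                               #       discordant: exactly the planted events)
rep$somatic$n_query_sites      # 205   sites after four-sample selection
rep$somatic$truth_eval
#> $sensitivity        1        all 5 planted events confirmed
#> $false_discoveries  0        nothing spurious survived arbitration
rep$cnv$per_stage              # 1 1 1 1 1  planted 3 kb loss survives
                               #            every cascade stage
rep$risk$twin_percentile       # 95.7  planted excess risk alleles rank
                               #       above the control cohort
```

Single-site statistics work standalone. A site with 10/20 variant reads
in one sample and none in 40 reads of the other:

```r
test <- pileup_frame(rep("chr3", 20), rep(55862522L, 20), rep("C", 20),
                     c(rep("T", 10), rep("C", 10)), bq = rep(30, 20),
                     mq = rep(60, 20), start = 55862470L + seq_len(20),
                     strand = rep("+", 20))
refs <- pileup_frame(rep("chr3", 40), rep(55862522L, 40), rep("C", 40),
                     rep("C", 40), bq = rep(30, 40), mq = rep(60, 40),
                     start = 55862470L + seq_len(40), strand = rep("+", 40))
somatic_score(test, refs)               # 120  (passes the >100 screen)
fisher_allele_test(c(10, 10), c(40, 0)) # 2.45e-06  (passes p < 0.01)
```

Whether such a call survives depends on arbitration: the bundled fixture
(`generate_indel_artifact_fixture()`) shows two equally convincing calls
dissolving once reads are realigned through a 19 bp insertion carried by
both samples.

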