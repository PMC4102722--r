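## Independent oracles and small fixture builders shared across tests.
## Oracles are deliberately naive (linear space, exhaustive enumeration)
## and never call the code paths they check.

## Uniform single-site pileup: n reads of one base at one quality.
flat_pileup <- function(base, n, bq = 30, mq = 60, ref = "A", pos = 1L,
                        contig = "c1", starts = seq_len(max(n, 1L))) {
  if (n == 0L) return(pileup_frame())
  pileup_frame(contig = rep(contig, n), pos = rep(pos, n), ref = rep(ref, n),
               base = rep(base, n), bq = rep(bq, n), mq = rep(mq, n),
               start = rep_len(starts, n), strand = rep("+", n))
}

## Mixed-base single-site pileup from a named count vector, e.g. c(A=30, G=10).
mixed_pileup <- function(counts, bq = 30, mq = 60, ref = "A", pos = 1L,
                         contig = "c1") {
  bases <- rep(names(counts), counts)
  n <- length(bases)
  pileup_frame(contig = rep(contig, n), pos = rep(pos, n), ref = rep(ref, n),
               base = bases, bq = rep_len(bq, n), mq = rep_len(mq, n),
               start = seq_len(n), strand = rep("+", n))
}

## Linear-space genotype likelihoods: direct product over reads of
## 0.5 P(b|a1) + 0.5 P(b|a2), no logs. Only safe for small pileups.
oracle_genotype_lik <- function(bases, bq) {
  gts <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")
  e <- 10^(-bq / 10)
  pba <- function(b, a) ifelse(b == a, 1 - e, e / 3)
  out <- vapply(gts, function(g) {
    a1 <- substr(g, 1, 1)
    a2 <- substr(g, 2, 2)
    prod(0.5 * pba(bases, a1) + 0.5 * pba(bases, a2))
  }, numeric(1))
  out
}

## Exhaustive hypergeometric two-sided Fisher p for the 2x2 table
## rows = (ref, alt), cols = (A, B): enumerate every table with the
## observed margins and sum the probabilities of those no more probable
## than the observed table (same 1 + 1e-7 tie tolerance as the classical
## implementation).
oracle_fisher_p <- function(counts_a, counts_b) {
  a <- counts_a[1]; b <- counts_a[2]   # sample A: ref, alt
  c_ <- counts_b[1]; d <- counts_b[2]  # sample B: ref, alt
  N <- a + b + c_ + d
  r1 <- a + c_   # total ref
  c1 <- a + b    # total sample A
  k <- max(0, r1 + c1 - N):min(r1, c1)  # possible values of cell (ref, A)
  probs <- stats::dhyper(k, r1, N - r1, c1)
  obs <- stats::dhyper(a, r1, N - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## Brute-force P(two samples share a genotype): flat-prior posteriors from
## linear-space likelihoods, then the dot product over the 10 genotypes.
oracle_p_same <- function(bases_a, bq_a, bases_b, bq_b) {
  la <- oracle_genotype_lik(bases_a, bq_a)
  lb <- oracle_genotype_lik(bases_b, bq_b)
  sum((la / sum(la)) * (lb / sum(lb)))
}

## Four-sample SNV recovery run used by recovery/acceptance tests:
## simulate a twin pair, plant n_events clonal somatic SNVs in the
## affected twin, run selection + all three detectors + arbitration, and
## score against truth.
snv_recovery_run <- function(seed, n_events, vaf = 0.5, genome_length = 1e6) {
  cfg <- pipeline_config(seed = seed, outdir = tempfile("rec_"),
                         design = "four_sample",
                         genome_length = genome_length,
                         n_somatic = n_events, somatic_vaf = vaf,
                         cnv_loss_kb = 0)
  rep <- run_pipeline(cfg)
  unlink(cfg$outdir, recursive = TRUE)
  rep
}

## CNV recovery run: planted twin-discordant loss (or none), full cascade.
cnv_recovery_run <- function(seed, loss_windows = 30) {
  cfg <- sim_config(seed = seed)
  samples <- c("affected_blood", "affected_biopsy",
               "healthy_blood", "healthy_biopsy")
  ev <- if (loss_windows > 0) {
    data.frame(contig = "sim1", start = 50000L,
               end = 50000L + loss_windows * cfg$window_size,
               direction = "loss",
               samples = "affected_blood,affected_biopsy",
               stringsAsFactors = FALSE)
  } else NULL
  sim <- simulate_cnv_depth(cfg, ev, samples)
  norm <- normalize_depth(sim$depth)
  regs <- lapply(samples, function(s)
    call_cnv_regions(norm$windows, norm$ratios[, s], sample = s))
  names(regs) <- samples
  mapp <- data.frame(contig = "sim1", start = 0L,
                     end = max(sim$depth$windows$end), score = 1)
  differential_cnv_filter(regs$affected_blood, regs$affected_biopsy,
                          regs$healthy_blood, regs$healthy_biopsy, mapp)
}
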