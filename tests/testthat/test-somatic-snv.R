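test_that("somatic score has the documented semantics at the extremes", {
  ## identical deep hom-ref pileups: P(same) -> 1, score -> 0
  a <- flat_pileup("A", 40, bq = 30)
  expect_identical(somatic_score(a, a), 0L)

  ## hom-ref vs. balanced het at depth 30: P(same) is dominated by the
  ## residual chance that sample A is truly het, P(AG|A) = 0.50033^30,
  ## so the score matches the brute-force posterior at 90
  b <- mixed_pileup(c(A = 15, G = 15), bq = 30)
  s <- somatic_score(flat_pileup("A", 30, bq = 30), b)
  p_same <- oracle_p_same(rep("A", 30), rep(30, 30),
                          rep(c("A", "G"), each = 15), rep(30, 30))
  expect_identical(s, as.integer(round(-10 * log10(p_same))))

  ## tripling the depth makes the evidence overwhelming and caps the score
  deep <- somatic_score(flat_pileup("A", 200, bq = 30),
                        mixed_pileup(c(A = 100, G = 100), bq = 30))
  expect_identical(deep, 255L)

  ## either side no-call: no-score marker, never 0
  expect_true(is.na(somatic_score(flat_pileup("A", 10, mq = 5), a)))
})

test_that("somatic score matches the brute-force posterior on moderate pileups", {
  set.seed(77)
  for (case in 1:25) {
    na <- sample(5:15, 1)
    nb <- sample(5:15, 1)
    ba <- sample(c("A", "G"), na, replace = TRUE, prob = c(0.8, 0.2))
    bb <- sample(c("A", "G"), nb, replace = TRUE, prob = c(0.5, 0.5))
    qa <- sample(15:35, na, replace = TRUE)
    qb <- sample(15:35, nb, replace = TRUE)
    pa <- pileup_frame(rep("c1", na), rep(1L, na), rep("A", na), ba, qa,
                       rep(60, na), seq_len(na), rep("+", na))
    pb <- pileup_frame(rep("c1", nb), rep(1L, nb), rep("A", nb), bb, qb,
                       rep(60, nb), seq_len(nb), rep("+", nb))
    expected <- min(255, max(0, round(-10 * log10(
      oracle_p_same(ba, qa, bb, qb)))))
    expect_identical(somatic_score(pa, pb), as.integer(expected))
  }
})

test_that("somatic score is bounded and non-decreasing in VAF separation", {
  base_a <- flat_pileup("A", 40, bq = 30)
  scores <- vapply(seq(0, 20, by = 2), function(k) {
    somatic_score(base_a, mixed_pileup(c(A = 40 - k, G = k), bq = 30))
  }, integer(1))
  expect_true(all(scores >= 0 & scores <= 255))
  expect_true(all(diff(scores) >= 0))
})

test_that("Fisher allele test equals exhaustive enumeration for margins <= 12", {
  for (na in 1:12) {
    for (nb in 1:12) {
      for (a_alt in 0:na) {
        b_alt <- c(0L, nb %/% 2L, nb)   # spot-check three alt counts per margin
        for (b_ in unique(b_alt)) {
          ca <- c(na - a_alt, a_alt)
          cb <- c(nb - b_, b_)
          expect_equal(fisher_allele_test(ca, cb), oracle_fisher_p(ca, cb),
                       tolerance = 1e-12)
        }
      }
    }
  }
  ## frozen values computed with the enumeration oracle
  expect_equal(fisher_allele_test(c(10, 0), c(10, 0)), 1.0)
  expect_equal(fisher_allele_test(c(10, 0), c(5, 5)), 0.03250774, tolerance = 1e-7)
  expect_lt(fisher_allele_test(c(0, 10), c(10, 0)), 0.001)
  ## undefined on an empty sample
  expect_true(is.na(fisher_allele_test(c(0, 0), c(5, 5))))
})

test_that("Fisher test is invariant under sample swap and joint label swap", {
  set.seed(5)
  for (case in 1:40) {
    ca <- c(sample(0:12, 1), sample(0:12, 1))
    cb <- c(sample(0:12, 1), sample(0:12, 1))
    if (sum(ca) == 0 || sum(cb) == 0) next
    p <- fisher_allele_test(ca, cb)
    expect_equal(fisher_allele_test(cb, ca), p, tolerance = 1e-12)
    expect_equal(fisher_allele_test(rev(ca), rev(cb)), p, tolerance = 1e-12)
  }
})

test_that("filtered Fisher zeroes stacked alleles and reduces to the raw test", {
  ## alt supported by 5 reads sharing one start point: zeroed -> p = 1
  alt_stack <- pileup_frame(rep("c1", 25), rep(1L, 25), rep("A", 25),
                            c(rep("G", 5), rep("A", 20)), rep(30, 25),
                            rep(60, 25),
                            c(rep(7L, 5), seq_len(20)), rep("+", 25))
  clean <- flat_pileup("A", 25, bq = 30)
  r <- filtered_fisher_test(alt_stack, clean, ref = "A", alt = "G")
  expect_identical(unname(r$counts["alt", "A"]), 0L)
  expect_equal(r$p, 1.0)

  ## nothing filtered: equals the raw Fisher p
  spread <- mixed_pileup(c(A = 20, G = 5), bq = 30)
  r2 <- filtered_fisher_test(spread, clean, ref = "A", alt = "G")
  expect_equal(r2$p, fisher_allele_test(c(20, 5), c(25, 0)), tolerance = 1e-12)

  ## low-BQ alt reads removed before testing
  lowq <- pileup_frame(rep("c1", 25), rep(1L, 25), rep("A", 25),
                       c(rep("G", 5), rep("A", 20)),
                       c(rep(15, 5), rep(30, 20)), rep(60, 25),
                       seq_len(25), rep("+", 25))
  r3 <- filtered_fisher_test(lowq, clean, ref = "A", alt = "G", min_bq = 20)
  expect_identical(unname(r3$counts["alt", "A"]), 0L)
})

test_that("Fisher screen controls type I error on identical-genotype sites", {
  ## 10^4 null sites at 40x, Q30: both samples hom-ref with error reads
  set.seed(13)
  n <- 1e4
  alt_a <- rbinom(n, 40, 1e-3)
  alt_b <- rbinom(n, 40, 1e-3)
  tabs <- unique(data.frame(a = alt_a, b = alt_b))
  tabs$p <- mapply(function(a, b) fisher_allele_test(c(40 - a, a), c(40 - b, b)),
                   tabs$a, tabs$b)
  p <- tabs$p[match(paste(alt_a, alt_b), paste(tabs$a, tabs$b))]
  expect_lte(mean(p < 0.01), 0.01)
})

test_that("query-position selection implements the four-sample clauses", {
  roles <- c(affected_blood = "ab", affected_biopsy = "ap",
             healthy_blood = "hb", healthy_biopsy = "hp")
  cs <- data.frame(contig = "c1", pos = 1:6, ref = "A", alt = "G",
                   popfreq = c(NA, 0.01, 0.5, NA, NA, 0.19),
                   ab = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
                   ap = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
                   hb = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                   hp = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  kept <- select_query_positions(cs, roles)
  ## pos 1: all four -> out; pos 3: popfreq 0.5 -> out; pos 4: both
  ## biopsies -> out; the rest stay
  expect_identical(kept$pos, c(2L, 5L, 6L))
  expect_error(select_query_positions(cs, roles[-1]), class = "mosa_config_error")
})

test_that("detector thresholds and ordering behave as documented", {
  fx <- generate_indel_artifact_fixture(seed = 3)
  plan <- data.frame(test = "affected_biopsy", reference = "affected_blood")
  calls <- detect_discordances(fx$naive, fx$sites, plan)

  ## all three detectors fire at both artifact sites
  passing <- calls[calls$passes_threshold, ]
  expect_setequal(unique(passing$detector),
                  c("score", "fisher", "filtered_fisher"))
  expect_setequal(unique(passing$pos), fx$truth$artifacts$pos)

  ## site order does not change the (sorted) result
  shuffled <- fx$sites[rev(seq_len(nrow(fx$sites))), ]
  calls2 <- detect_discordances(fx$naive, shuffled, plan)
  rownames(calls) <- rownames(calls2) <- NULL
  expect_identical(calls2, calls)

  ## p_max = 0 empties the Fisher pass lists
  strict <- detector_thresholds(p_max = 0)
  calls0 <- detect_discordances(fx$naive, fx$sites, plan, strict)
  expect_false(any(calls0$passes_threshold &
                     calls0$detector %in% c("fisher", "filtered_fisher")))

  expect_error(detect_discordances(fx$naive, fx$sites,
                 data.frame(test = "nope", reference = "affected_blood")),
               class = "mosa_config_error")
})

test_that("method overlap counts Venn regions with conserved totals", {
  fx <- generate_indel_artifact_fixture(seed = 4)
  plan <- data.frame(test = "affected_biopsy", reference = "affected_blood")
  calls <- detect_discordances(fx$naive, fx$sites, plan)
  v <- method_overlap(calls, k = 2)
  regions <- v[setdiff(names(v), "union")]
  expect_identical(sum(regions), v[["union"]])
  ## both artifact sites rank top-2 for every detector
  expect_identical(v[["all_three"]], 2L)
})

test_that("arbitration classifies artifacts, low coverage and survivors", {
  fx <- generate_indel_artifact_fixture(seed = 5)
  plan <- data.frame(test = "affected_biopsy", reference = "affected_blood")
  calls <- detect_discordances(fx$naive, fx$sites, plan)
  arb <- arbitrate_with_realignment(calls, realigned = fx$realigned,
                                    sites = fx$sites)
  passing <- arb[arb$passes_threshold, ]
  expect_true(all(passing$arbitration == "artifact"))
  expect_true(all(arb$arbitration[!arb$passes_threshold] == "unreviewed"))

  ## a true discordance survives realignment (realigned = naive here)
  som_a <- mixed_pileup(c(A = 20, G = 20), bq = 30, pos = 205L,
                        contig = "artifact1")
  som_a$ref <- fx$sites$ref[fx$sites$pos == 205]
  som_a$base[som_a$base == "A"] <- som_a$ref[1]
  som_a$base[som_a$base == "G"] <- fx$sites$alt[fx$sites$pos == 205]
  clean_b <- flat_pileup(fx$sites$ref[fx$sites$pos == 205], 40, bq = 30,
                         pos = 205L, contig = "artifact1",
                         ref = fx$sites$ref[fx$sites$pos == 205])
  pile <- list(tumor = som_a, normal = clean_b)
  sites205 <- fx$sites[fx$sites$pos == 205, ]
  true_calls <- detect_discordances(pile, sites205,
                                    data.frame(test = "tumor",
                                               reference = "normal"))
  arb2 <- arbitrate_with_realignment(true_calls, realigned = pile,
                                     sites = sites205)
  expect_true(all(arb2$arbitration[arb2$passes_threshold] ==
                    "confirmed-candidate"))

  ## low reference-sample depth
  thin_b <- flat_pileup(sites205$ref, 3, bq = 30, pos = 205L,
                        contig = "artifact1", ref = sites205$ref)
  pile3 <- list(tumor = som_a, normal = thin_b)
  calls3 <- detect_discordances(pile3, sites205,
                                data.frame(test = "tumor",
                                           reference = "normal"))
  arb3 <- arbitrate_with_realignment(calls3, realigned = pile3,
                                     sites = sites205)
  expect_true(all(arb3$arbitration[arb3$passes_threshold] == "low-coverage"))

  ## cross-sample veto: alt allele visible in a held-out sample
  veto <- mixed_pileup(c(A = 30, G = 10), bq = 30, pos = 205L,
                       contig = "artifact1")
  veto$ref <- sites205$ref
  veto$base[veto$base == "A"] <- sites205$ref
  veto$base[veto$base == "G"] <- sites205$alt
  arb4 <- arbitrate_with_realignment(true_calls, realigned = pile,
                                     heldout = list(other_twin = veto),
                                     sites = sites205)
  expect_true(all(arb4$arbitration[arb4$passes_threshold] == "artifact"))

  ## audit error when a candidate site is missing from the realignment
  expect_error(arbitrate_with_realignment(true_calls,
                 realigned = list(tumor = pileup_frame(),
                                  normal = pileup_frame())),
               class = "mosa_audit_error")
})

test_that("truth evaluation scores sensitivity and false discoveries", {
  truth <- mosatwin:::new_truth(somatic = data.frame(
    contig = "c1", pos = c(100L, 200L), ref = "A", alt = "G",
    samples = "tumor", vaf = c(0.5, 0.1), stringsAsFactors = FALSE))
  calls <- data.frame(contig = "c1", pos = c(100L, 300L), ref = "A",
                      alt = "G", test = "tumor", reference = "normal",
                      detector = "score", statistic = 200,
                      passes_threshold = TRUE,
                      arbitration = "confirmed-candidate",
                      stringsAsFactors = FALSE)
  ev <- evaluate_against_truth(calls, truth)
  expect_equal(ev$sensitivity, 0.5)
  expect_identical(ev$false_discoveries, 1L)
  expect_equal(ev$per_vaf$detected[ev$per_vaf$vaf == 0.5], 1)
  expect_equal(ev$per_vaf$detected[ev$per_vaf$vaf == 0.1], 0)

  ev0 <- evaluate_against_truth(calls[0, ], mosatwin:::new_truth())
  expect_true(is.na(ev0$sensitivity))
  expect_identical(ev0$false_discoveries, 0L)
})
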