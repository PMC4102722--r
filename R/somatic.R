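#' Default detector thresholds
#'
#' The three discordance detectors are screened at: somatic score > 100
#' (phred; a difference probability of 1 - 10^-10), Fisher p < 0.01 with no
#' occurrence of the variant allele in the reference sample, and the
#' quality-filtered Fisher test at p < 0.01 with base quality >= 20,
#' mapping quality >= 20 and >= 3 unique read start points per allele.
#'
#' @param score_min minimum somatic score (exclusive)
#' @param p_max maximum Fisher p-value (exclusive)
#' @param require_zero_alt_in_reference apply the zero-alt clause to the
#'   plain Fisher detector
#' @param min_mq mapping-quality read filter for score and plain Fisher
#' @param ff_min_bq,ff_min_mq,ff_min_unique_starts filtered-Fisher filters
#' @return list of class `mosa_thresholds`
#' @export
detector_thresholds <- function(score_min = 100, p_max = 0.01,
                                require_zero_alt_in_reference = TRUE,
                                min_mq = 10, ff_min_bq = 20, ff_min_mq = 20,
                                ff_min_unique_starts = 3) {
  stopifnot(score_min >= 0, score_min <= 255, p_max >= 0, p_max <= 1)
  structure(list(score_min = score_min, p_max = p_max,
                 require_zero_alt_in_reference = require_zero_alt_in_reference,
                 min_mq = min_mq, ff_min_bq = ff_min_bq, ff_min_mq = ff_min_mq,
                 ff_min_unique_starts = ff_min_unique_starts),
            class = "mosa_thresholds")
}

#' Phred-scaled genotype-difference (somatic) score
#'
#' The probability that two samples share the same genotype is
#' P(same) = sum over the 10 diploid genotypes g of P(g|A) P(g|B), with
#' per-sample posteriors from the genotype-likelihood model under a flat
#' prior. The score is -10 log10 P(same), rounded to an integer and capped
#' at 255; a score above 100 corresponds to a difference probability above
#' 1 - 10^-10. Reads with mapping quality below `min_mq` are discarded; if
#' either side then has no usable reads the result is a no-score marker
#' (NA), never 0.
#'
#' @param pileup_a,pileup_b single-site observations for the two samples
#' @param min_mq mapping-quality read filter (default 10)
#' @return integer score in [0, 255], or NA
#' @export
somatic_score <- function(pileup_a, pileup_b, min_mq = 10) {
  ga <- genotype_likelihoods(pileup_a, min_mq = min_mq)
  gb <- genotype_likelihoods(pileup_b, min_mq = min_mq)
  somatic_score_from_loglik(ga$loglik, gb$loglik,
                            no_call = ga$no_call || gb$no_call)
}

## Score from precomputed natural-log likelihood vectors (flat prior).
somatic_score_from_loglik <- function(ll_a, ll_b, no_call = FALSE) {
  if (no_call || anyNA(ll_a) || anyNA(ll_b)) return(NA_integer_)
  lp_a <- ll_a - logsumexp(ll_a)   # log posterior, flat prior
  lp_b <- ll_b - logsumexp(ll_b)
  log_p_same <- logsumexp(lp_a + lp_b)
  score <- round(-10 / log(10) * log_p_same / 1)
  as.integer(min(255, max(0, score)))
}

#' Fisher's exact test on ref/alt allele counts of two samples
#'
#' Two-sided exact test on the 2x2 table (ref, alt) x (sample A, sample B)
#' with the classical two-sided rule: the p-value sums the probabilities of
#' all tables, under fixed margins, no more probable than the observed one.
#'
#' @param counts_a,counts_b integer vectors `c(ref, alt)` for each sample
#' @return the p-value; NA (undefined-result marker) on an all-zero table
#' @export
fisher_allele_test <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 2L, length(counts_b) == 2L,
            all(counts_a >= 0), all(counts_b >= 0))
  if (sum(counts_a) == 0L || sum(counts_b) == 0L) return(NA_real_)
  tab <- matrix(c(counts_a, counts_b), nrow = 2,
                dimnames = list(allele = c("ref", "alt"),
                                sample = c("A", "B")))
  stats::fisher.test(tab)$p.value
}

## Allele counts (ref, alt) at one site after a mapping-quality filter.
allele_counts <- function(pileup, ref, alt, min_mq = 10) {
  use <- pileup$mq >= min_mq
  b <- pileup$base[use]
  c(ref = sum(b == ref), alt = if (is.na(alt)) 0L else sum(b == alt))
}

#' Quality-filtered Fisher test
#'
#' Observations failing the base- or mapping-quality filters are dropped;
#' an allele's count is then zeroed if its supporting reads span fewer than
#' `min_unique_starts` distinct start points (a defense against stacked
#' duplicate or misaligned reads). Fisher's exact test runs on the
#' surviving counts; both the p-value and the post-filter table are
#' returned for audit.
#'
#' @param pileup_a,pileup_b single-site observations for the two samples
#' @param ref,alt the two alleles tested
#' @param min_bq,min_mq,min_unique_starts filter settings
#' @return list: `p` (NA if both samples are empty after filtering),
#'   `counts` (2x2 matrix allele x sample)
#' @export
filtered_fisher_test <- function(pileup_a, pileup_b, ref, alt,
                                 min_bq = 20, min_mq = 20,
                                 min_unique_starts = 3) {
  count1 <- function(p) {
    keep <- p$bq >= min_bq & p$mq >= min_mq
    p <- p[keep, , drop = FALSE]
    cnt <- c(ref = 0L, alt = 0L)
    for (al in c("ref", "alt")) {
      a <- if (al == "ref") ref else alt
      if (is.na(a)) next
      sup <- p[p$base == a, , drop = FALSE]
      if (nrow(sup) > 0L && length(unique(sup$start)) < min_unique_starts) {
        cnt[al] <- 0L
      } else {
        cnt[al] <- nrow(sup)
      }
    }
    cnt
  }
  ca <- count1(pileup_a)
  cb <- count1(pileup_b)
  counts <- cbind(A = ca, B = cb)
  if (sum(ca) == 0L && sum(cb) == 0L) {
    return(list(p = NA_real_, counts = counts))
  }
  p <- if (sum(ca) == 0L || sum(cb) == 0L) NA_real_ else
    fisher_allele_test(ca, cb)
  list(p = p, counts = counts)
}

#' Select query positions for the four-sample twin design
#'
#' Reduces a four-sample call set to the sites worth interrogating for
#' somatic discordance: keep a variant site unless it is called in all
#' four samples, in both biopsies, or in both blood samples, or its
#' population allele frequency exceeds `max_popfreq` (missing frequencies
#' pass).
#'
#' @param callset data.frame with `contig`, `pos`, `popfreq` and one
#'   logical carrier column per sample label
#' @param roles named character vector mapping the four design roles
#'   (`affected_blood`, `affected_biopsy`, `healthy_blood`,
#'   `healthy_biopsy`) to sample labels / carrier columns
#' @param max_popfreq population-frequency ceiling (default 0.20)
#' @return the retained subset of `callset`
#' @export
select_query_positions <- function(callset, roles, max_popfreq = 0.20) {
  need <- c("affected_blood", "affected_biopsy", "healthy_blood",
            "healthy_biopsy")
  if (!all(need %in% names(roles))) {
    abort_mosa(sprintf("roles must name all of: %s", paste(need, collapse = ", ")),
               "mosa_config_error")
  }
  if (!all(roles[need] %in% names(callset))) {
    abort_mosa("callset lacks carrier columns for the named samples",
               "mosa_config_error")
  }
  carr <- as.matrix(callset[, roles[need], drop = FALSE])
  all_four <- rowSums(carr) == 4L
  both_biopsy <- carr[, roles[["affected_biopsy"]]] &
    carr[, roles[["healthy_biopsy"]]]
  both_blood <- carr[, roles[["affected_blood"]]] &
    carr[, roles[["healthy_blood"]]]
  freq_ok <- is.na(callset$popfreq) | callset$popfreq <= max_popfreq
  callset[!all_four & !both_biopsy & !both_blood & freq_ok, , drop = FALSE]
}

#' Run the three discordance detectors over a comparison plan
#'
#' For every site and ordered sample pair (test vs. reference), computes
#' the somatic score, the plain Fisher allele-count test and the
#' quality-filtered Fisher test, and flags which calls pass their detector
#' thresholds — for plain Fisher including the clause that the variant
#' allele must not occur in the reference sample. Output rows are sorted
#' by detector and statistic strength (ties broken by contig, position).
#'
#' @param pileups named list of `mosa_pileup` tables, one per sample
#' @param sites data.frame with `contig`, `pos`, `ref` and optionally
#'   `alt`; when `alt` is NA it is inferred as the most frequent non-
#'   reference base across the pair
#' @param plan data.frame with columns `test`, `reference` naming sample
#'   pairs
#' @param thresholds a [detector_thresholds()]
#' @return data.frame of discordance calls: site, pair, `detector`
#'   (`"score"`, `"fisher"`, `"filtered_fisher"`), `statistic`,
#'   `passes_threshold`, `arbitration` (all `"unreviewed"`)
#' @export
detect_discordances <- function(pileups, sites, plan,
                                thresholds = detector_thresholds()) {
  stopifnot(inherits(thresholds, "mosa_thresholds"))
  if (!all(c(plan$test, plan$reference) %in% names(pileups))) {
    abort_mosa("comparison plan names a sample absent from the pileups",
               "mosa_config_error")
  }
  if (is.null(sites$alt)) sites$alt <- NA_character_
  bysite <- lapply(pileups, split_sites)
  rows <- list()
  for (k in seq_len(nrow(plan))) {
    s_test <- plan$test[k]
    s_ref <- plan$reference[k]
    for (i in seq_len(nrow(sites))) {
      key <- paste0(sites$contig[i], ":", sites$pos[i])
      pa <- bysite[[s_test]][[key]]
      pb <- bysite[[s_ref]][[key]]
      if (is.null(pa)) pa <- pileup_frame()
      if (is.null(pb)) pb <- pileup_frame()
      ref <- sites$ref[i]
      alt <- sites$alt[i]
      if (is.na(alt)) alt <- infer_alt(pa, pb, ref, thresholds$min_mq)
      score <- somatic_score(pa, pb, min_mq = thresholds$min_mq)
      ca <- allele_counts(pa, ref, alt, thresholds$min_mq)
      cb <- allele_counts(pb, ref, alt, thresholds$min_mq)
      p_fisher <- if (sum(ca) == 0L || sum(cb) == 0L) NA_real_ else
        fisher_allele_test(ca, cb)
      ff <- filtered_fisher_test(pa, pb, ref, alt,
                                 min_bq = thresholds$ff_min_bq,
                                 min_mq = thresholds$ff_min_mq,
                                 min_unique_starts = thresholds$ff_min_unique_starts)
      pass_score <- !is.na(score) && score > thresholds$score_min
      pass_fisher <- !is.na(p_fisher) && p_fisher < thresholds$p_max &&
        (!thresholds$require_zero_alt_in_reference || cb[["alt"]] == 0L)
      pass_ff <- !is.na(ff$p) && ff$p < thresholds$p_max
      rows[[length(rows) + 1L]] <- data.frame(
        contig = sites$contig[i], pos = sites$pos[i], ref = ref,
        alt = if (is.na(alt)) NA_character_ else alt,
        test = s_test, reference = s_ref,
        detector = c("score", "fisher", "filtered_fisher"),
        statistic = c(score, p_fisher, ff$p),
        passes_threshold = c(pass_score, pass_fisher, pass_ff),
        arbitration = "unreviewed", stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  if (is.null(calls)) {
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), test = character(),
                      reference = character(), detector = character(),
                      statistic = numeric(), passes_threshold = logical(),
                      arbitration = character(), stringsAsFactors = FALSE))
  }
  calls[order(calls$detector, call_strength(calls), calls$contig, calls$pos,
              method = "radix", decreasing = c(FALSE, TRUE, FALSE, FALSE)), ,
        drop = FALSE]
}

## Statistic strength on a common "larger is stronger" scale: the score
## itself for the score detector, -log10 p for the Fisher detectors.
call_strength <- function(calls) {
  ifelse(calls$detector == "score", calls$statistic,
         -log10(pmax(calls$statistic, 1e-300)))
}

## Most frequent non-reference base across a sample pair (MQ-filtered);
## NA when every usable read matches the reference.
infer_alt <- function(pa, pb, ref, min_mq = 10) {
  b <- c(pa$base[pa$mq >= min_mq], pb$base[pb$mq >= min_mq])
  b <- b[b %in% BASES & b != ref]
  if (length(b) == 0L) return(NA_character_)
  names(sort(table(b), decreasing = TRUE))[1]
}

#' Cross-method overlap of top-ranked calls
#'
#' Takes the top `k` calls of each detector (by statistic strength, ties
#' broken by contig and position) and counts the seven regions of the
#' three-set Venn diagram; call identity is (contig, pos, test, reference).
#'
#' @param calls output of [detect_discordances()]
#' @param k top-k per detector (default 100)
#' @return named integer vector over the seven Venn regions plus `union`
#' @export
method_overlap <- function(calls, k = 100) {
  stopifnot(k >= 1)
  top <- lapply(split(calls, calls$detector), function(d) {
    d <- d[!is.na(d$statistic), , drop = FALSE]
    d <- d[order(call_strength(d), d$contig, d$pos,
                 method = "radix", decreasing = c(TRUE, FALSE, FALSE)), ,
           drop = FALSE]
    head(paste(d$contig, d$pos, d$test, d$reference), k)
  })
  s <- top[["score"]] %||% character()
  f <- top[["fisher"]] %||% character()
  q <- top[["filtered_fisher"]] %||% character()
  all3 <- intersect(intersect(s, f), q)
  c(score_only = length(setdiff(s, union(f, q))),
    fisher_only = length(setdiff(f, union(s, q))),
    filtered_only = length(setdiff(q, union(s, f))),
    score_fisher = length(setdiff(intersect(s, f), q)),
    score_filtered = length(setdiff(intersect(s, q), f)),
    fisher_filtered = length(setdiff(intersect(f, q), s)),
    all_three = length(all3),
    union = length(union(union(s, f), q)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Arbitrate candidate calls with realigned pileups
#'
#' Automates the post-screen review of threshold-passing candidates:
#' a candidate becomes `"artifact"` if its detector statistic falls below
#' threshold when recomputed on indel-realigned pileups, `"low-coverage"`
#' if the reference sample has fewer than `min_depth` usable reads, and
#' `"artifact"` again if the variant allele is also seen (at or above
#' `veto_fraction` of reads) in a held-out sample of the same twin pair —
#' a variant present in the other twin's tissue cannot be somatic.
#' Surviving candidates are `"confirmed-candidate"`. Verdicts only move
#' candidates toward exclusion; `passes_threshold` is never recomputed
#' upward, and non-passing calls stay `"unreviewed"`.
#'
#' @param candidates output of [detect_discordances()]
#' @param realigned named list of realigned `mosa_pileup` tables covering
#'   every candidate site (missing sites raise an audit error)
#' @param heldout optional named list of held-out-sample pileup tables for
#'   the cross-sample veto
#' @param thresholds a [detector_thresholds()]
#' @param min_depth reference-sample depth floor (default 8)
#' @param veto_fraction held-out alt-read fraction triggering the veto
#' @param sites data.frame carrying `alt` per site (as from
#'   [simulate_pileups()]); used for the veto allele
#' @return `candidates` with the `arbitration` column filled in
#' @export
arbitrate_with_realignment <- function(candidates, realigned, heldout = NULL,
                                       thresholds = detector_thresholds(),
                                       min_depth = 8, veto_fraction = 0.05,
                                       sites = NULL) {
  if (nrow(candidates) == 0L) return(candidates)
  re_bysite <- lapply(realigned, split_sites)
  ho_bysite <- if (is.null(heldout)) NULL else lapply(heldout, split_sites)
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    if (!cand$passes_threshold) next
    key <- paste0(cand$contig, ":", cand$pos)
    ra <- re_bysite[[cand$test]][[key]]
    rb <- re_bysite[[cand$reference]][[key]]
    if (is.null(ra) || is.null(rb)) {
      abort_mosa(sprintf("candidate site %s missing from realigned pileups", key),
                 "mosa_audit_error")
    }
    verdict <- "confirmed-candidate"
    if (!passes_on(ra, rb, cand, thresholds)) {
      verdict <- "artifact"
    } else if (sum(rb$mq >= thresholds$min_mq) < min_depth) {
      verdict <- "low-coverage"
    } else if (!is.null(ho_bysite) && !is.na(cand$alt)) {
      for (ho in ho_bysite) {
        h <- ho[[key]]
        if (is.null(h) || nrow(h) == 0L) next
        if (mean(h$base == cand$alt) >= veto_fraction) {
          verdict <- "artifact"
          break
        }
      }
    }
    candidates$arbitration[i] <- verdict
  }
  candidates
}

## Does this candidate's detector still pass its threshold on (pa, pb)?
passes_on <- function(pa, pb, cand, thresholds) {
  if (cand$detector == "score") {
    s <- somatic_score(pa, pb, min_mq = thresholds$min_mq)
    return(!is.na(s) && s > thresholds$score_min)
  }
  if (cand$detector == "fisher") {
    ca <- allele_counts(pa, cand$ref, cand$alt, thresholds$min_mq)
    cb <- allele_counts(pb, cand$ref, cand$alt, thresholds$min_mq)
    if (sum(ca) == 0L || sum(cb) == 0L) return(FALSE)
    p <- fisher_allele_test(ca, cb)
    return(!is.na(p) && p < thresholds$p_max &&
             (!thresholds$require_zero_alt_in_reference || cb[["alt"]] == 0L))
  }
  ff <- filtered_fisher_test(pa, pb, cand$ref, cand$alt,
                             min_bq = thresholds$ff_min_bq,
                             min_mq = thresholds$ff_min_mq,
                             min_unique_starts = thresholds$ff_min_unique_starts)
  !is.na(ff$p) && ff$p < thresholds$p_max
}

#' Score arbitrated calls against the planted truth
#'
#' Sensitivity is the fraction of planted somatic events recovered as
#' confirmed candidates (site-level, any detector); confirmed candidates
#' at artifact or unplanted sites count as false discoveries. A per-VAF
#' power table quantifies the dilution effect of sub-clonal events.
#'
#' @param calls arbitrated calls ([arbitrate_with_realignment()])
#' @param truth a `mosa_truth`
#' @return list: `sensitivity` (NA when nothing was planted),
#'   `n_planted`, `n_detected`, `false_discoveries`, `per_vaf`
#'   (data.frame vaf / planted / detected)
#' @export
evaluate_against_truth <- function(calls, truth) {
  confirmed <- calls[calls$arbitration == "confirmed-candidate", , drop = FALSE]
  ckey <- unique(paste(confirmed$contig, confirmed$pos))
  tkey <- paste(truth$somatic$contig, truth$somatic$pos)
  detected <- tkey %in% ckey
  n_planted <- length(tkey)
  fd <- sum(!(ckey %in% tkey))
  per_vaf <- if (n_planted) {
    agg <- stats::aggregate(detected, by = list(vaf = truth$somatic$vaf),
                            FUN = function(x) c(sum(x), length(x)))
    data.frame(vaf = agg$vaf, detected = agg$x[, 1], planted = agg$x[, 2])
  } else {
    data.frame(vaf = numeric(), detected = integer(), planted = integer())
  }
  list(sensitivity = if (n_planted) mean(detected) else NA_real_,
       n_planted = n_planted, n_detected = sum(detected),
       false_discoveries = fd, per_vaf = per_vaf)
}
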