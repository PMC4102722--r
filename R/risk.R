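#' Carriership risk score: summed log odds ratios
#'
#' For each risk-model locus with an available genotype, the number of
#' risk-allele copies c (0, 1 or 2; or 0/1 under `counting = "carrier"`)
#' is multiplied by the log odds ratio and summed:
#' score = sum over loci of c_j log(OR_j). Loci missing from the genotype
#' input are skipped and counted in `n_loci_skipped`; natural log is the
#' default base.
#'
#' @param genotypes either a named integer vector of risk-allele copies
#'   (names = locus ids) or a data.frame with `locus_id`, `allele1`,
#'   `allele2` (alleles must be the locus's risk or other allele)
#' @param model a `mosa_risk_model`
#' @param log_base base of the logarithm (default `exp(1)`)
#' @param counting `"copies"` (default) or `"carrier"`
#' @param subject subject id recorded on the result
#' @return list of class `mosa_risk_score`: `subject`, `score`,
#'   `n_loci_used`, `n_loci_skipped`, `loci_key` (identity of the locus
#'   subset actually used)
#' @export
risk_sum <- function(genotypes, model, log_base = exp(1),
                     counting = c("copies", "carrier"), subject = "subject") {
  counting <- match.arg(counting)
  stopifnot(inherits(model, "mosa_risk_model"))
  copies <- genotype_copies(genotypes, model)
  used <- !is.na(copies)
  c_j <- copies[used]
  if (counting == "carrier") c_j <- pmin(c_j, 1L)
  lor <- log(model$or_value[used], base = log_base)
  structure(list(subject = subject,
                 score = sum(c_j * lor),
                 n_loci_used = sum(used),
                 n_loci_skipped = sum(!used),
                 loci_key = locus_set_key(model$locus_id[used])),
            class = "mosa_risk_score")
}

## Risk-allele copy count per model locus (NA where missing).
genotype_copies <- function(genotypes, model) {
  if (is.data.frame(genotypes)) {
    idx <- match(model$locus_id, genotypes$locus_id)
    copies <- rep(NA_integer_, nrow(model))
    hit <- which(!is.na(idx))
    for (i in hit) {
      g <- genotypes[idx[i], ]
      alleles <- c(g$allele1, g$allele2)
      ok <- alleles %in% c(model$risk_allele[i], model$other_allele[i])
      if (!all(ok)) {
        abort_mosa(sprintf("locus %s: genotype allele not in {risk, other}",
                           model$locus_id[i]), "mosa_data_error")
      }
      copies[i] <- sum(alleles == model$risk_allele[i])
    }
    copies
  } else {
    idx <- match(model$locus_id, names(genotypes))
    copies <- as.integer(genotypes[idx])
    if (any(!is.na(copies) & (copies < 0L | copies > 2L))) {
      abort_mosa("risk-allele copies must be 0, 1 or 2", "mosa_data_error")
    }
    copies
  }
}

#' Score a control cohort
#'
#' Applies [risk_sum()] to every row of a control genotype matrix and
#' returns the empirical score distribution together with the identity key
#' of the locus subset used, so that percentiles are never compared across
#' different subsets.
#'
#' @param cohort integer matrix (subjects x loci) of risk-allele copies,
#'   with locus ids as column names
#' @param model a `mosa_risk_model`
#' @inheritParams risk_sum
#' @return list of class `mosa_risk_distribution`: `scores`, `n`,
#'   `loci_key`, `mean`, `sd`, `counting`, `log_base`
#' @export
cohort_distribution <- function(cohort, model, log_base = exp(1),
                                counting = c("copies", "carrier")) {
  counting <- match.arg(counting)
  stopifnot(inherits(model, "mosa_risk_model"))
  ids <- colnames(cohort)
  if (is.null(ids) || !all(ids %in% model$locus_id)) {
    abort_mosa("cohort loci do not match the risk model", "mosa_validation_error")
  }
  m <- model[match(ids, model$locus_id), , drop = FALSE]
  if (any(cohort < 0L | cohort > 2L)) {
    abort_mosa("risk-allele copies must be 0, 1 or 2", "mosa_data_error")
  }
  x <- if (counting == "carrier") pmin(cohort, 1L) else cohort
  lor <- log(m$or_value, base = log_base)
  scores <- as.numeric(x %*% lor)
  structure(list(scores = scores, n = length(scores),
                 loci_key = locus_set_key(ids),
                 mean = mean(scores), sd = stats::sd(scores),
                 counting = counting, log_base = log_base),
            class = "mosa_risk_distribution")
}

#' Percentile of a subject's risk score in a control distribution
#'
#' Midrank convention: percentile = 100 (n_below + ties/2) / n. The
#' subject's score and the distribution must have been computed on the
#' same locus subset (guarded by the identity key). Histogram bins and the
#' subject's vertical-line position are returned for plotting.
#'
#' @param score a `mosa_risk_score`
#' @param distribution a `mosa_risk_distribution`
#' @param bins histogram bin count (default 30)
#' @return list: `percentile`, `score`, `n_controls`, `histogram`
#'   (data.frame `mid`, `count`), `vline` (the subject's score)
#' @export
risk_percentile <- function(score, distribution, bins = 30) {
  stopifnot(inherits(score, "mosa_risk_score"),
            inherits(distribution, "mosa_risk_distribution"))
  if (distribution$n == 0L) {
    abort_mosa("empty control distribution", "mosa_validation_error")
  }
  if (!identical(score$loci_key, distribution$loci_key)) {
    abort_mosa("risk score and control distribution use different locus subsets",
               "mosa_comparability_error")
  }
  s <- distribution$scores
  pct <- 100 * (sum(s < score$score) + 0.5 * sum(s == score$score)) /
    distribution$n
  h <- graphics::hist(s, breaks = bins, plot = FALSE)
  list(percentile = pct, score = score$score, n_controls = distribution$n,
       histogram = data.frame(mid = h$mids, count = h$counts),
       vline = score$score)
}
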