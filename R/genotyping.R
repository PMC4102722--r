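#' Diploid genotype likelihoods for one site
#'
#' For genotype g = \{a1, a2\}, each read contributes
#' 0.5 P(b|a1) + 0.5 P(b|a2) with P(b|a) = 1 - e if b = a, else e/3, where
#' e = 10^(-BQ/10). Per-read log-likelihoods are summed over reads and
#' phred-scaled relative to the best genotype, so the best genotype scores
#' exactly 0. Reads with mapping quality below `min_mq` are discarded
#' first; `N` bases are ignored. Sites with zero usable reads yield a
#' no-call (distinct from homozygous reference); sites with fewer than
#' `min_depth` usable reads are flagged low-confidence.
#'
#' @param pileup observations of a single site (a `mosa_pileup` subset)
#' @param min_mq minimum mapping quality (default 10)
#' @param min_depth low-confidence flag threshold (default 8)
#' @param max_depth depth cap per site; beyond it the posterior is
#'   saturated (default 500)
#' @return list of class `mosa_gt_call`: `genotype` (e.g. `"AG"`, or NA on
#'   no-call), `phred` (named 10-vector, minimum 0), `loglik` (natural-log
#'   likelihoods), `depth`, `quality` (phred gap to the second-best
#'   genotype), `no_call`, `low_confidence`
#' @export
genotype_likelihoods <- function(pileup, min_mq = 10, min_depth = 8,
                                 max_depth = 500) {
  use <- pileup$mq >= min_mq & pileup$base %in% BASES
  obs <- pileup[use, , drop = FALSE]
  if (nrow(obs) > max_depth) obs <- obs[seq_len(max_depth), , drop = FALSE]
  if (nrow(obs) == 0L) {
    return(structure(list(genotype = NA_character_,
                          phred = stats::setNames(rep(NA_real_, 10), GENOTYPES),
                          loglik = stats::setNames(rep(NA_real_, 10), GENOTYPES),
                          depth = 0L, quality = NA_real_,
                          no_call = TRUE, low_confidence = TRUE),
                     class = "mosa_gt_call"))
  }
  ll <- genotype_loglik_matrix(obs$base, obs$bq)
  phred <- -10 / log(10) * (ll - max(ll))
  best <- which.min(phred)
  structure(list(genotype = GENOTYPES[best],
                 phred = stats::setNames(phred, GENOTYPES),
                 loglik = stats::setNames(ll, GENOTYPES),
                 depth = nrow(obs),
                 quality = unname(sort(phred)[2]),
                 no_call = FALSE,
                 low_confidence = nrow(obs) < min_depth),
            class = "mosa_gt_call")
}

## Natural-log likelihood of each of the 10 genotypes given observed bases
## and phred base qualities; the shared kernel of genotyping and scoring.
genotype_loglik_matrix <- function(bases, bq) {
  e <- 10^(-bq / 10)
  ## P[a, i] = P(observed base i | true allele a)
  P <- matrix(0, 4, length(bases), dimnames = list(BASES, NULL))
  for (a in BASES) P[a, ] <- ifelse(bases == a, 1 - e, e / 3)
  i1 <- match(GT_ALLELE1, BASES)
  i2 <- match(GT_ALLELE2, BASES)
  lik <- 0.5 * P[i1, , drop = FALSE] + 0.5 * P[i2, , drop = FALSE]
  rowSums(log(lik))
}

#' Call genotypes at every site of a pileup table
#'
#' @param pileup a `mosa_pileup` table (one sample, many sites)
#' @inheritParams genotype_likelihoods
#' @return list with `calls` (data.frame: contig, pos, ref, genotype,
#'   depth, quality, no_call, low_confidence) and `loglik` (sites x 10
#'   matrix of natural-log genotype likelihoods)
#' @export
call_genotypes <- function(pileup, min_mq = 10, min_depth = 8,
                           max_depth = 500) {
  sites <- split_sites(pileup)
  n <- length(sites)
  calls <- vector("list", n)
  ll <- matrix(NA_real_, n, 10, dimnames = list(NULL, GENOTYPES))
  for (i in seq_len(n)) {
    s <- sites[[i]]
    g <- genotype_likelihoods(s, min_mq = min_mq, min_depth = min_depth,
                              max_depth = max_depth)
    calls[[i]] <- data.frame(contig = s$contig[1], pos = s$pos[1],
                             ref = s$ref[1], genotype = g$genotype,
                             depth = g$depth, quality = g$quality,
                             no_call = g$no_call,
                             low_confidence = g$low_confidence,
                             stringsAsFactors = FALSE)
    ll[i, ] <- g$loglik
  }
  df <- do.call(rbind, calls)
  if (is.null(df)) {
    df <- data.frame(contig = character(), pos = integer(), ref = character(),
                     genotype = character(), depth = integer(),
                     quality = numeric(), no_call = logical(),
                     low_confidence = logical(), stringsAsFactors = FALSE)
  }
  o <- order(df$contig, df$pos)
  list(calls = df[o, , drop = FALSE], loglik = ll[o, , drop = FALSE])
}

#' Pairwise genotype concordance
#'
#' Fraction of evaluated sites at which two call sets agree on the
#' unordered genotype. Sites where either call set has a no-call are
#' excluded from the denominator and reported separately. `sites` selects
#' the evaluation set: the union (default) or intersection of the two call
#' sets' sites.
#'
#' @param calls_a,calls_b data.frames as `call_genotypes()$calls`
#' @param sites `"union"` or `"intersection"`
#' @return list: `concordance` (NA when no site is evaluable), `n_sites`,
#'   `n_compared`, `n_discordant`, `n_nocall`
#' @export
pairwise_concordance <- function(calls_a, calls_b,
                                 sites = c("union", "intersection")) {
  sites <- match.arg(sites)
  ka <- paste(calls_a$contig, calls_a$pos)
  kb <- paste(calls_b$contig, calls_b$pos)
  keys <- if (sites == "union") union(ka, kb) else intersect(ka, kb)
  ia <- match(keys, ka)
  ib <- match(keys, kb)
  ga <- ifelse(is.na(ia), NA, calls_a$genotype[ia])
  gb <- ifelse(is.na(ib), NA, calls_b$genotype[ib])
  nocall <- is.na(ga) | is.na(gb)
  n_cmp <- sum(!nocall)
  conc <- if (n_cmp == 0L) NA_real_ else mean(ga[!nocall] == gb[!nocall])
  list(concordance = conc, n_sites = length(keys), n_compared = n_cmp,
       n_discordant = if (n_cmp) sum(ga[!nocall] != gb[!nocall]) else 0L,
       n_nocall = sum(nocall))
}

#' Transition/transversion ratio of a variant set
#'
#' Transitions are A<->G and C<->T; everything else is a transversion.
#'
#' @param variants data.frame with `ref` and `alt` single-base columns
#' @return the ratio (NA with a warning-free marker when there are no
#'   transversions)
#' @export
titv_ratio <- function(variants) {
  if (nrow(variants) == 0L) return(NA_real_)
  ti <- (variants$ref == "A" & variants$alt == "G") |
    (variants$ref == "G" & variants$alt == "A") |
    (variants$ref == "C" & variants$alt == "T") |
    (variants$ref == "T" & variants$alt == "C")
  n_tv <- sum(!ti)
  if (n_tv == 0L) return(NA_real_)
  sum(ti) / n_tv
}

#' Classify the coding effect of an SNV
#'
#' Reconstructs the affected codon from the reference sequence and the
#' gene-model frame, substitutes the alternate allele and translates both
#' codons: synonymous if the amino acid is unchanged, nonsense if a stop is
#' gained, otherwise missense; non-coding outside CDS. Minus-strand CDS are
#' handled by reverse-complementing the codon.
#'
#' @param contig,pos,ref,alt the SNV (1-based position)
#' @param gene_model data.frame as in `mosa_reference$gene_model`
#' @param ref_seqs named character vector of contig sequences
#' @return one of `"synonymous"`, `"missense"`, `"nonsense"`, `"non-coding"`
#' @export
classify_coding_effect <- function(contig, pos, ref, alt, gene_model, ref_seqs) {
  gm <- gene_model[gene_model$contig == contig &
                     gene_model$start < pos & gene_model$end >= pos, ,
                   drop = FALSE]
  if (nrow(gm) == 0L) return("non-coding")
  cds <- gm[1, ]
  seq <- ref_seqs[[contig]]
  p0 <- pos - 1L  # 0-based
  if (cds$strand == "+") {
    cstart <- cds$start + cds$frame
    off <- p0 - cstart
    if (off < 0) return("non-coding")
    codon_start0 <- cstart + 3L * (off %/% 3L)
    if (codon_start0 + 3L > cds$end) {
      abort_mosa("codon extends past CDS bounds", "mosa_annotation_error")
    }
    codon <- substring(seq, codon_start0 + 1L, codon_start0 + 3L)
    idx <- off %% 3L + 1L
    mut <- codon
    substr(mut, idx, idx) <- alt
    if (substr(codon, idx, idx) != ref) {
      abort_mosa("reference allele does not match the reference sequence",
                 "mosa_annotation_error")
    }
  } else {
    cend <- cds$end - cds$frame
    off <- cend - 1L - p0
    if (off < 0) return("non-coding")
    codon_start0 <- cend - 3L * (off %/% 3L + 1L)
    if (codon_start0 < cds$start) {
      abort_mosa("codon extends past CDS bounds", "mosa_annotation_error")
    }
    fwd <- substring(seq, codon_start0 + 1L, codon_start0 + 3L)
    idx_fwd <- 3L - off %% 3L
    if (substr(fwd, idx_fwd, idx_fwd) != ref) {
      abort_mosa("reference allele does not match the reference sequence",
                 "mosa_annotation_error")
    }
    mut_fwd <- fwd
    substr(mut_fwd, idx_fwd, idx_fwd) <- alt
    codon <- revcomp(fwd)
    mut <- revcomp(mut_fwd)
  }
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(mut)
  if (aa_alt == aa_ref) return("synonymous")
  if (aa_alt == "*") return("nonsense")
  "missense"
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Summarize a variant call set
#'
#' Emits the quality-control summary used to sanity-check a sequenced
#' sample: totals per coding-effect class, the Ti/Tv ratio and the NS/S
#' ratio (missense + nonsense over synonymous).
#'
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt`
#' @param gene_model gene model data.frame
#' @param ref_seqs named character vector of contig sequences
#' @return data.frame with one row per statistic (`statistic`, `value`)
#' @export
variant_summary <- function(variants, gene_model, ref_seqs) {
  n <- nrow(variants)
  if (n == 0L) {
    eff <- character(0)
  } else {
    eff <- vapply(seq_len(n), function(i) {
      classify_coding_effect(variants$contig[i], variants$pos[i],
                             variants$ref[i], variants$alt[i],
                             gene_model, ref_seqs)
    }, character(1))
  }
  counts <- table(factor(eff, levels = c("synonymous", "missense", "nonsense",
                                         "non-coding")))
  ns <- counts[["missense"]] + counts[["nonsense"]]
  s <- counts[["synonymous"]]
  data.frame(
    statistic = c("total_snvs", "synonymous", "missense", "nonsense",
                  "non_coding", "titv", "ns_s_ratio"),
    value = c(n, counts[["synonymous"]], counts[["missense"]],
              counts[["nonsense"]], counts[["non-coding"]],
              if (n) titv_ratio(variants) else NA_real_,
              if (s > 0) ns / s else NA_real_),
    stringsAsFactors = FALSE)
}
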