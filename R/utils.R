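#' @keywords internal
"_PACKAGE"

## Diploid genotype space: the 10 unordered pairs over {A,C,G,T}, in the
## fixed column order used by every likelihood matrix in the package.
GENOTYPES <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")
GT_ALLELE1 <- substr(GENOTYPES, 1, 1)
GT_ALLELE2 <- substr(GENOTYPES, 2, 2)
BASES <- c("A", "C", "G", "T")

#' Derive a reproducible substream seed from a master seed and a stage label
#'
#' Each simulation stage draws from its own pseudo-random substream keyed by
#' a stage label, so that adding or reordering stages never perturbs the
#' draws of another stage. The substream seed is a deterministic hash of
#' (master seed, label) into [1, 2^31 - 2].
#'
#' @param seed master integer seed
#' @param label character stage label, e.g. `"germline"`
#' @return an integer seed
#' @export
stage_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, prime
  h <- seed %% m
  for (k in utf8ToInt(label)) {
    h <- (h * 69621 + k) %% m   # Lehmer multiplier keeps products < 2^53
  }
  as.integer(h %% (m - 2L) + 1L)
}

## Evaluate `code` under the substream seed, restoring the caller's RNG state.
with_stage_seed <- function(seed, label, code) {
  withr::with_seed(stage_seed(seed, label), code)
}

## log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Order-insensitive integer key for a set of locus ids (Horner hash over
## the sorted, concatenated ids). Guards percentile comparisons across
## different locus subsets; not cryptographic.
locus_set_key <- function(ids) {
  s <- paste(sort(as.character(ids)), collapse = "|")
  m <- 2147483647
  h <- 17
  for (k in utf8ToInt(s)) {
    h <- (h * 69621 + k) %% m
  }
  sprintf("%08x", h)
}

## Stop with a classed condition so callers/tests can distinguish error kinds.
abort_mosa <- function(msg, class) {
  stop(structure(class = c(class, "mosatwin_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_single_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
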