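#' Read a risk-model table
#'
#' The risk model lists susceptibility loci with their risk allele and
#' published odds ratio (OR); the carriership score sums log-ORs over the
#' risk alleles a subject carries. TSV columns: `locus_id`, `contig`, `pos`,
#' `risk_allele`, `other_allele`, `or_value`, `risk_freq`.
#'
#' @param path TSV file path
#' @return a `data.frame` of class `mosa_risk_model`
#' @export
read_risk_model <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("locus_id", "contig", "pos", "risk_allele", "other_allele",
            "or_value", "risk_freq")
  if (!all(need %in% names(df))) {
    abort_mosa(sprintf("risk model missing columns: %s",
                       paste(setdiff(need, names(df)), collapse = ", ")),
               "mosa_validation_error")
  }
  risk_model(df)
}

#' @rdname read_risk_model
#' @param loci data.frame with the columns listed above
#' @export
risk_model <- function(loci) {
  if (anyDuplicated(loci$locus_id)) {
    abort_mosa("duplicate locus_id in risk model", "mosa_validation_error")
  }
  if (any(!is.finite(loci$or_value)) || any(loci$or_value <= 0)) {
    abort_mosa("risk model odds ratios must be finite and > 0",
               "mosa_validation_error")
  }
  if (any(loci$risk_freq <= 0 | loci$risk_freq >= 1)) {
    abort_mosa("risk-allele frequencies must lie in (0,1)",
               "mosa_validation_error")
  }
  if (any(loci$risk_allele == loci$other_allele)) {
    abort_mosa("risk and other allele must differ", "mosa_validation_error")
  }
  class(loci) <- c("mosa_risk_model", "data.frame")
  loci
}

#' @rdname read_risk_model
#' @param model a `mosa_risk_model`
#' @export
write_risk_model <- function(model, path) {
  utils::write.table(as.data.frame(model), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
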