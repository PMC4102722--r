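## Minimal VCF v4.2 subset: biallelic SNVs, GT and DP honored, AF read from
## INFO when present. Multi-allelic records are an explicit error (the
## twin-pair comparisons are biallelic throughout), never silently split.

#' Read / write a minimal biallelic VCF subset
#'
#' `read_vcf_subset()` parses CHROM/POS/REF/ALT plus per-sample GT and DP and
#' the INFO `AF` key (stored as `popfreq`); unknown INFO keys are ignored.
#' Multi-allelic rows and rows whose FORMAT lacks GT raise errors.
#'
#' @param path file path
#' @return a `data.frame` with columns `contig`, `pos`, `id`, `ref`, `alt`,
#'   `popfreq` (NA when absent) and, per sample `S`, `gt.S` (genotype string
#'   such as `"0/1"`) and `dp.S` (integer depth, NA when absent). Sample
#'   names are kept in `attr(, "samples")`.
#' @export
read_vcf_subset <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) {
    abort_mosa(sprintf("%s: missing #CHROM header line", path), "mosa_parse_error")
  }
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) {
    abort_mosa(sprintf("%s: VCF must carry FORMAT plus >=1 sample", path),
               "mosa_parse_error")
  }
  samples <- cols[10:length(cols)]
  body <- lines[-seq_len(hdr)]
  recs <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols)) {
      abort_mosa(sprintf("%s: malformed record at data line %d", path, i),
                 "mosa_parse_error")
    }
    if (grepl(",", f[5], fixed = TRUE)) {
      abort_mosa(sprintf("%s: multi-allelic record at data line %d (unsupported)",
                         path, i), "mosa_unsupported_record")
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) {
      abort_mosa(sprintf("%s: FORMAT without GT at data line %d", path, i),
                 "mosa_parse_error")
    }
    dp_i <- match("DP", fmt)
    af <- NA_real_
    info <- strsplit(f[8], ";", fixed = TRUE)[[1]]
    hit <- grep("^AF=", info, value = TRUE)
    if (length(hit)) af <- as.numeric(sub("^AF=", "", hit[1]))
    sm <- strsplit(f[10:length(f)], ":", fixed = TRUE)
    gts <- vapply(sm, function(x) x[gt_i], character(1))
    dps <- if (is.na(dp_i)) rep(NA_integer_, length(sm)) else
      vapply(sm, function(x) suppressWarnings(as.integer(x[dp_i])), integer(1))
    list(contig = f[1], pos = as.integer(f[2]), id = f[3], ref = f[4],
         alt = f[5], popfreq = af, gts = gts, dps = dps)
  })
  df <- data.frame(
    contig = vapply(recs, `[[`, character(1), "contig"),
    pos = vapply(recs, `[[`, integer(1), "pos"),
    id = vapply(recs, `[[`, character(1), "id"),
    ref = vapply(recs, `[[`, character(1), "ref"),
    alt = vapply(recs, `[[`, character(1), "alt"),
    popfreq = vapply(recs, `[[`, numeric(1), "popfreq"),
    stringsAsFactors = FALSE)
  for (j in seq_along(samples)) {
    df[[paste0("gt.", samples[j])]] <- vapply(recs, function(r) r$gts[j], character(1))
    df[[paste0("dp.", samples[j])]] <- vapply(recs, function(r) r$dps[j], integer(1))
  }
  attr(df, "samples") <- samples
  df
}

#' @rdname read_vcf_subset
#' @param variants a data.frame as returned by `read_vcf_subset()` (the
#'   `attr(, "samples")` attribute names the sample columns)
#' @export
write_vcf_subset <- function(variants, path) {
  samples <- attr(variants, "samples")
  if (is.null(samples)) {
    samples <- sub("^gt\\.", "", grep("^gt\\.", names(variants), value = TRUE))
  }
  if (any(grepl(",", variants$alt, fixed = TRUE))) {
    abort_mosa("multi-allelic ALT not supported by the VCF writer",
               "mosa_unsupported_record")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  if (nrow(variants)) {
    o <- order(variants$contig, variants$pos)
    v <- variants[o, , drop = FALSE]
    info <- ifelse(is.na(v$popfreq), ".", sprintf("AF=%g", v$popfreq))
    id <- if ("id" %in% names(v)) v$id else "."
    rows <- paste(v$contig, v$pos, id, v$ref, v$alt, ".", "PASS", info, "GT:DP",
                  sep = "\t")
    for (s in samples) {
      dp <- v[[paste0("dp.", s)]]
      dp <- ifelse(is.na(dp), ".", as.character(dp))
      rows <- paste(rows, paste(v[[paste0("gt.", s)]], dp, sep = ":"), sep = "\t")
    }
    writeLines(rows, con)
  }
  invisible(path)
}
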