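## Pileup TSV dialect ("#mosatwin-pileup-v1"): one row per read observation,
## columns contig, pos (1-based), ref, base, bq, mq, start, strand; rows
## grouped by (contig, pos), positions non-decreasing within a contig.

PILEUP_HEADER <- "#mosatwin-pileup-v1"
PILEUP_COLS <- c("contig", "pos", "ref", "base", "bq", "mq", "start", "strand")

#' Construct a validated pileup table
#'
#' A pileup table holds per-site read observations for one sample: for every
#' read covering a site, the observed base, its phred base quality, the
#' read's phred mapping quality, the read's start coordinate (used to count
#' unique start points) and strand. It is the substrate of all site-wise
#' discordance statistics.
#'
#' @param contig,pos,ref,base,bq,mq,start,strand vectors of equal length;
#'   `pos` is 1-based, `ref` in A/C/G/T, `base` in A/C/G/T/N, qualities are
#'   phred-scaled and non-negative, `strand` is `"+"` or `"-"`.
#' @return a `data.frame` of class `mosa_pileup`
#' @export
pileup_frame <- function(contig = character(), pos = integer(),
                         ref = character(), base = character(),
                         bq = numeric(), mq = numeric(),
                         start = integer(), strand = character()) {
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = as.character(ref), base = as.character(base),
                   bq = as.numeric(bq), mq = as.numeric(mq),
                   start = as.integer(start), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_pileup(df)
  class(df) <- c("mosa_pileup", "data.frame")
  df
}

validate_pileup <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$pos < 1L)) abort_mosa("pileup positions must be >= 1", "mosa_parse_error")
  if (any(df$bq < 0) || any(df$mq < 0)) {
    abort_mosa("pileup qualities must be >= 0", "mosa_parse_error")
  }
  if (!all(df$ref %in% BASES)) {
    abort_mosa("pileup ref bases must be one of A,C,G,T", "mosa_parse_error")
  }
  if (!all(df$base %in% c(BASES, "N"))) {
    abort_mosa("pileup observed bases must be one of A,C,G,T,N", "mosa_parse_error")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    abort_mosa("pileup strand must be '+' or '-'", "mosa_parse_error")
  }
  invisible(df)
}

#' Read / write the pileup TSV dialect
#'
#' `write_pileup()` then `read_pileup()` is an identity on validated pileup
#' tables. Readers reject malformed rows (naming the offending line) and
#' positions that are not sorted within a contig; they never repair input.
#'
#' @param path file path
#' @param pileup a `mosa_pileup` table (see [pileup_frame()])
#' @return `read_pileup()` returns a `mosa_pileup` table; an empty file body
#'   yields an empty table.
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != PILEUP_HEADER) {
    abort_mosa(sprintf("%s: missing '%s' header", path, PILEUP_HEADER),
               "mosa_parse_error")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) && identical(body[1], paste(PILEUP_COLS, collapse = "\t"))) {
    body <- body[-1]
  }
  if (length(body) == 0L) return(pileup_frame())
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(PILEUP_COLS))
  if (length(bad)) {
    abort_mosa(sprintf("%s: malformed pileup row at line %d", path, bad[1] + 2L),
               "mosa_parse_error")
  }
  m <- matrix(unlist(parts), ncol = length(PILEUP_COLS), byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  bq <- suppressWarnings(as.numeric(m[, 5]))
  mq <- suppressWarnings(as.numeric(m[, 6]))
  st <- suppressWarnings(as.integer(m[, 7]))
  bad <- which(is.na(pos) | is.na(bq) | is.na(mq) | is.na(st) |
                 bq < 0 | mq < 0 | pos < 1)
  if (length(bad)) {
    abort_mosa(sprintf("%s: invalid numeric field at line %d", path, bad[1] + 2L),
               "mosa_parse_error")
  }
  df <- data.frame(contig = m[, 1], pos = pos, ref = m[, 3], base = m[, 4],
                   bq = bq, mq = mq, start = st, strand = m[, 8],
                   stringsAsFactors = FALSE)
  validate_pileup(df)
  ## positions must be non-decreasing within each contig block
  for (ct in unique(df$contig)) {
    p <- df$pos[df$contig == ct]
    if (is.unsorted(p)) {
      abort_mosa(sprintf("%s: positions not sorted on contig %s", path, ct),
                 "mosa_order_error")
    }
  }
  class(df) <- c("mosa_pileup", "data.frame")
  df
}

#' @rdname read_pileup
#' @export
write_pileup <- function(pileup, path) {
  validate_pileup(pileup)
  o <- order(pileup$contig, pileup$pos)
  pileup <- pileup[o, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(PILEUP_HEADER, paste(PILEUP_COLS, collapse = "\t")), con)
  if (nrow(pileup)) {
    utils::write.table(pileup[, PILEUP_COLS], con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

## Split a pileup table into per-site observation frames, keyed "contig:pos".
split_sites <- function(pileup) {
  if (nrow(pileup) == 0L) return(list())
  split(pileup, paste0(pileup$contig, ":", pileup$pos))
}

## Observations of one site from a pileup table.
site_obs <- function(pileup, contig, pos) {
  pileup[pileup$contig == contig & pileup$pos == pos, , drop = FALSE]
}
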