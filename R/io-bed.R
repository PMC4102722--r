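## BED3+ with optional name/score/strand. Half-open, 0-based coordinates are
## preserved exactly; readers validate rather than repair.

#' Read / write BED intervals
#'
#' Intervals use BED semantics: `start` is 0-based inclusive, `end`
#' exclusive, so `chr1 0 100` covers the first 100 bases. Rows with
#' `start >= end` are rejected.
#'
#' @param path file path
#' @param intervals data.frame with columns `contig`, `start`, `end` and
#'   optionally `name`, `score`, `strand`
#' @return `read_bed()` returns a data.frame with columns `contig`, `start`,
#'   `end` and any of `name`, `score`, `strand` present in the file.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    abort_mosa(sprintf("%s: BED row with <3 fields at line %d", path,
                       which(nf < 3L)[1]), "mosa_parse_error")
  }
  ncol_use <- min(nf)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad)) {
    abort_mosa(sprintf("%s: invalid BED interval at line %d (need 0 <= start < end)",
                       path, bad[1]), "mosa_validation_error")
  }
  df <- data.frame(contig = vapply(parts, `[[`, character(1), 1L),
                   start = start, end = end, stringsAsFactors = FALSE)
  if (ncol_use >= 4L) df$name <- vapply(parts, `[[`, character(1), 4L)
  if (ncol_use >= 5L) {
    df$score <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 5L)))
  }
  if (ncol_use >= 6L) df$strand <- vapply(parts, `[[`, character(1), 6L)
  df
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) && any(intervals$start >= intervals$end)) {
    abort_mosa("BED intervals require start < end", "mosa_validation_error")
  }
  cols <- intersect(c("contig", "start", "end", "name", "score", "strand"),
                    names(intervals))
  ## BED columns are positional: stop at the first absent optional column
  keep <- c("contig", "start", "end")
  for (opt in c("name", "score", "strand")) {
    if (opt %in% cols) keep <- c(keep, opt) else break
  }
  out <- intervals[order(intervals$contig, intervals$start), keep, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Intersection length of [s1,e1) and [s2,e2); 0 when disjoint.
overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))
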