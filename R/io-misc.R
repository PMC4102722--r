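#' Write / read reference sequences as FASTA
#'
#' Thin wrappers over Biostrings; sequences are stored as plain character
#' vectors (named by contig) inside the package's reference bundle.
#'
#' @param contigs named character vector of sequences
#' @param path file path
#' @export
write_fasta <- function(contigs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write / read a windowed depth matrix as TSV
#'
#' Rows are genomic windows (contig, 0-based half-open interval), columns
#' after the first three are per-sample read counts.
#'
#' @param depth a `mosa_depth_matrix` (see [simulate_cnv_depth()])
#' @param path file path
#' @export
write_depth_matrix <- function(depth, path) {
  df <- cbind(depth$windows, as.data.frame(depth$counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#mosatwin-depth-v1 window_size=%d", depth$window_size), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_matrix
#' @export
read_depth_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#mosatwin-depth-v1")) {
    abort_mosa(sprintf("%s: not a mosatwin depth matrix", path), "mosa_parse_error")
  }
  ws <- as.integer(sub(".*window_size=", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          stringsAsFactors = FALSE)
  windows <- df[, c("contig", "start", "end")]
  counts <- as.matrix(df[, setdiff(names(df), c("contig", "start", "end")),
                         drop = FALSE])
  structure(list(windows = windows, counts = counts, window_size = ws),
            class = "mosa_depth_matrix")
}

#' Write a truth set to TSV files
#'
#' Serializes the planted ground truth (germline variants, somatic events,
#' CNV events, artifact sites) as versioned TSVs next to `prefix`.
#'
#' @param truth a `mosa_truth` list
#' @param prefix path prefix; files `<prefix>.<block>.tsv` are written
#' @export
write_truth <- function(truth, prefix) {
  blocks <- c("germline", "somatic", "cnv", "artifacts")
  for (b in blocks) {
    df <- truth[[b]]
    p <- paste0(prefix, ".", b, ".tsv")
    con <- file(p, "w")
    writeLines(sprintf("#mosatwin-truth-%s-v1", b), con)
    if (!is.null(df) && nrow(df)) {
      df <- flatten_sample_col(df)
      utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    close(con)
  }
  invisible(prefix)
}

flatten_sample_col <- function(df) {
  if ("samples" %in% names(df) && is.list(df$samples)) {
    df$samples <- vapply(df$samples, paste, character(1), collapse = ",")
  }
  df
}
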