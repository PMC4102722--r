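#' Normalize a windowed depth matrix against a background panel
#'
#' Each sample column is first scaled to unit median (removing library-size
#' effects); each test sample's per-window ratio is then its scaled depth
#' over the mean scaled depth of the background panel at that window.
#' Windows with zero background mean are masked (NA). The panel mean is
#' the default aggregation; a median variant is available.
#'
#' @param depth a `mosa_depth_matrix`
#' @param background column names of the background panel (defaults to
#'   `depth$background`)
#' @param aggregate `"mean"` (default) or `"median"` background summary
#' @return list: `windows`, `ratios` (windows x test samples),
#'   `masked` (logical per window)
#' @export
normalize_depth <- function(depth, background = NULL,
                            aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(depth, "mosa_depth_matrix"))
  if (is.null(background)) background <- depth$background
  if (length(background) < 2L) {
    abort_mosa("need >= 2 background samples", "mosa_input_error")
  }
  counts <- depth$counts
  if (!all(background %in% colnames(counts))) {
    abort_mosa("background sample absent from depth matrix", "mosa_input_error")
  }
  med <- apply(counts, 2, stats::median)
  if (all(med[background] == 0)) {
    abort_mosa("all-zero background panel", "mosa_input_error")
  }
  med[med == 0] <- 1   # degenerate column guard; its ratios will be masked
  scaled <- sweep(counts, 2, med, "/")
  bgm <- if (aggregate == "mean") {
    rowMeans(scaled[, background, drop = FALSE])
  } else {
    apply(scaled[, background, drop = FALSE], 1, stats::median)
  }
  masked <- bgm == 0
  if (mean(!masked) < 0.95) {
    abort_mosa("more than 5% of windows have zero background coverage",
               "mosa_input_error")
  }
  test <- setdiff(colnames(counts), background)
  ratios <- sweep(scaled[, test, drop = FALSE], 1, bgm, "/")
  ratios[masked, ] <- NA_real_
  list(windows = depth$windows, ratios = ratios, masked = masked)
}

#' Call CNV regions from per-window depth ratios
#'
#' A window is called a loss when its ratio is below `loss_ratio` and a
#' gain when above `gain_ratio`. Maximal same-direction runs of called
#' windows are merged across gaps as long as the merged run's support
#' (fraction of called windows) stays at or above `min_support`. A region
#' is kept iff it spans at least `min_windows` windows, its support is at
#' least `min_support`, and its mean ratio is beyond the direction's
#' threshold.
#'
#' @param windows data.frame `contig`, `start`, `end` (one row per window)
#' @param ratios numeric vector of per-window depth ratios (NA = masked)
#' @param sample sample label recorded on the output regions
#' @param min_windows,min_support,loss_ratio,gain_ratio region filters
#'   (defaults 20 windows, 80% support, <0.62 loss / >1.38 gain)
#' @return data.frame of regions: `contig`, `start`, `end`, `direction`,
#'   `n_windows`, `support_fraction`, `mean_ratio`, `sample`
#' @export
call_cnv_regions <- function(windows, ratios, sample = "sample",
                             min_windows = 20, min_support = 0.80,
                             loss_ratio = 0.62, gain_ratio = 1.38) {
  stopifnot(nrow(windows) == length(ratios))
  dir <- rep(NA_character_, length(ratios))
  dir[!is.na(ratios) & ratios < loss_ratio] <- "loss"
  dir[!is.na(ratios) & ratios > gain_ratio] <- "gain"
  empty <- data.frame(contig = character(), start = integer(), end = integer(),
                      direction = character(), n_windows = integer(),
                      support_fraction = numeric(), mean_ratio = numeric(),
                      sample = character(), stringsAsFactors = FALSE)
  called <- which(!is.na(dir))
  if (length(called) == 0L) return(empty)
  ## maximal runs of consecutively-called same-direction windows
  brk <- c(TRUE, diff(called) != 1L |
             dir[called[-1]] != dir[called[-length(called)]] |
             windows$contig[called[-1]] != windows$contig[called[-length(called)]])
  run_id <- cumsum(brk)
  runs <- lapply(split(called, run_id), function(ix) {
    data.frame(first = ix[1], last = ix[length(ix)], n_called = length(ix),
               direction = dir[ix[1]], contig = windows$contig[ix[1]],
               stringsAsFactors = FALSE)
  })
  runs <- do.call(rbind, runs)
  ## greedy left-to-right merge across gaps while support stays >= min_support
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      m <- merged[nrow(merged), ]
      r <- runs[i, ]
      span <- r$last - m$first + 1L
      supp <- (m$n_called + r$n_called) / span
      if (r$direction == m$direction && r$contig == m$contig &&
          supp >= min_support) {
        merged$last[nrow(merged)] <- r$last
        merged$n_called[nrow(merged)] <- m$n_called + r$n_called
      } else {
        merged <- rbind(merged, r)
      }
    }
  }
  regions <- lapply(seq_len(nrow(merged)), function(i) {
    m <- merged[i, ]
    ix <- m$first:m$last
    data.frame(contig = m$contig,
               start = windows$start[m$first], end = windows$end[m$last],
               direction = m$direction, n_windows = length(ix),
               support_fraction = m$n_called / length(ix),
               mean_ratio = mean(ratios[ix], na.rm = TRUE),
               sample = sample, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, regions)
  keep <- out$n_windows >= min_windows &
    out$support_fraction >= min_support &
    ifelse(out$direction == "loss", out$mean_ratio < loss_ratio,
           out$mean_ratio > gain_ratio)
  out[keep, , drop = FALSE]
}

#' Reciprocal overlap of two intervals
#'
#' Passes iff the intersection covers at least `frac` of the length of
#' each interval (half-open coordinates). Symmetric in its arguments.
#'
#' @param a,b lists/rows with `contig`, `start`, `end`
#' @param frac required reciprocal fraction in (0, 1] (default 0.9)
#' @return list: `pass`, `frac_a`, `frac_b`, `overlap`
#' @export
reciprocal_overlap <- function(a, b, frac = 0.9) {
  stopifnot(frac > 0, frac <= 1)
  if (a$contig != b$contig) {
    return(list(pass = FALSE, frac_a = 0, frac_b = 0, overlap = 0L))
  }
  ov <- overlap_len(a$start, a$end, b$start, b$end)
  fa <- ov / (a$end - a$start)
  fb <- ov / (b$end - b$start)
  list(pass = fa >= frac && fb >= frac, frac_a = fa, frac_b = fb, overlap = ov)
}

#' Twin-differential CNV filtering cascade
#'
#' Stage 1: pair same-direction regions from the affected twin's two
#' samples that reciprocally overlap by at least `frac`, and merge each
#' pair as its intersection. Stage 2: drop candidates overlapping (by
#' >= 1 bp) any region called in either healthy-twin sample. Stage 3: drop
#' loss candidates whose length-weighted mean mappability uniqueness is
#' below `min_uniqueness` (regions of low mappability often lose coverage
#' spuriously). The audit records counts surviving each stage.
#'
#' @param affected_a,affected_b region data.frames (see
#'   [call_cnv_regions()]) for the affected twin's two samples
#' @param healthy_a,healthy_b region data.frames for the healthy twin
#' @param mappability data.frame `contig`, `start`, `end`, `score`
#'   (uniqueness in [0, 1]); required for loss candidates
#' @param frac reciprocal-overlap fraction (default 0.9)
#' @param min_uniqueness mappability floor for losses (default 0.5)
#' @param direction_sensitive_exclusion restrict stage 2 to healthy
#'   regions of the same direction (default FALSE: any overlap excludes)
#' @return list: `candidates` (regions with columns as in
#'   [call_cnv_regions()]), `audit` (data.frame stage / n)
#' @export
differential_cnv_filter <- function(affected_a, affected_b,
                                    healthy_a, healthy_b,
                                    mappability, frac = 0.9,
                                    min_uniqueness = 0.5,
                                    direction_sensitive_exclusion = FALSE) {
  ## stage 1: reciprocal overlap between the affected twin's samples
  cands <- list()
  for (i in seq_len(nrow(affected_a))) {
    for (j in seq_len(nrow(affected_b))) {
      a <- affected_a[i, ]
      b <- affected_b[j, ]
      if (a$direction != b$direction) next
      ro <- reciprocal_overlap(a, b, frac)
      if (!ro$pass) next
      cands[[length(cands) + 1L]] <- data.frame(
        contig = a$contig, start = max(a$start, b$start),
        end = min(a$end, b$end), direction = a$direction,
        n_windows = min(a$n_windows, b$n_windows),
        support_fraction = min(a$support_fraction, b$support_fraction),
        mean_ratio = mean(c(a$mean_ratio, b$mean_ratio)),
        sample = "affected_pair", stringsAsFactors = FALSE)
    }
  }
  stage1 <- if (length(cands)) do.call(rbind, cands) else
    affected_a[0, , drop = FALSE]
  ## stage 2: exclude anything overlapping a healthy-twin region
  healthy <- rbind(healthy_a, healthy_b)
  keep2 <- vapply(seq_len(nrow(stage1)), function(i) {
    x <- stage1[i, ]
    h <- healthy[healthy$contig == x$contig, , drop = FALSE]
    if (direction_sensitive_exclusion) {
      h <- h[h$direction == x$direction, , drop = FALSE]
    }
    if (nrow(h) == 0L) return(TRUE)
    all(overlap_len(x$start, x$end, h$start, h$end) == 0L)
  }, logical(1))
  stage2 <- stage1[keep2, , drop = FALSE]
  ## stage 3: mappability filter on losses
  keep3 <- vapply(seq_len(nrow(stage2)), function(i) {
    x <- stage2[i, ]
    if (x$direction != "loss") return(TRUE)
    mean_uniqueness(x, mappability) >= min_uniqueness
  }, logical(1))
  stage3 <- stage2[keep3, , drop = FALSE]
  list(candidates = stage3,
       audit = data.frame(
         stage = c("input_affected_a", "input_affected_b",
                   "stage1_reciprocal", "stage2_healthy_excluded",
                   "stage3_mappability"),
         n = c(nrow(affected_a), nrow(affected_b), nrow(stage1),
               nrow(stage2), nrow(stage3)),
         stringsAsFactors = FALSE))
}

## Length-weighted mean uniqueness score over a candidate interval;
## bases not covered by the track score 0.
mean_uniqueness <- function(region, mappability) {
  if (is.null(mappability) ||
      !any(mappability$contig == region$contig)) {
    abort_mosa(sprintf("no mappability track for contig %s", region$contig),
               "mosa_audit_error")
  }
  m <- mappability[mappability$contig == region$contig, , drop = FALSE]
  ov <- overlap_len(region$start, region$end, m$start, m$end)
  len <- region$end - region$start
  sum(ov * m$score) / len
}

#' Loss-of-heterozygosity support for a deletion candidate
#'
#' A true one-copy deletion removes heterozygosity in the carrier: within
#' the region, the carrier's fraction of heterozygous genotype calls
#' should collapse relative to the non-carrier twin. The verdict is
#' `"insufficient"` with fewer than `min_snvs` informative sites,
#' `"supported"` when the carrier's het fraction is below half the other
#' sample's, otherwise `"unsupported"`.
#'
#' @param region list/row with `contig`, `start`, `end` (BED coordinates)
#' @param calls_carrier,calls_other genotype-call data.frames
#'   (`call_genotypes()$calls`) for the putative carrier and the other twin
#' @param min_snvs minimum informative sites (default 5)
#' @return list: `verdict`, `het_carrier`, `het_other`, `n_informative`
#' @export
loh_support <- function(region, calls_carrier, calls_other, min_snvs = 5) {
  pick <- function(calls) {
    calls[calls$contig == region$contig & !calls$no_call &
            calls$pos > region$start & calls$pos <= region$end, , drop = FALSE]
  }
  a <- pick(calls_carrier)
  b <- pick(calls_other)
  key <- intersect(paste(a$contig, a$pos), paste(b$contig, b$pos))
  n <- length(key)
  if (n < min_snvs) {
    return(list(verdict = "insufficient", het_carrier = NA_real_,
                het_other = NA_real_, n_informative = n))
  }
  is_het <- function(g) substr(g, 1, 1) != substr(g, 2, 2)
  ha <- mean(is_het(a$genotype[match(key, paste(a$contig, a$pos))]))
  hb <- mean(is_het(b$genotype[match(key, paste(b$contig, b$pos))]))
  verdict <- if (ha < hb / 2) "supported" else "unsupported"
  list(verdict = verdict, het_carrier = ha, het_other = hb, n_informative = n)
}
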