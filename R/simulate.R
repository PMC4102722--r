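#' Simulation configuration for synthetic twin-pair data
#'
#' Bundles every tunable of the synthetic data generator. Defaults encode
#' the study conditions the analysis is designed for: ~0.1% germline
#' nucleotide diversity shared by both co-twins, a transition/transversion
#' ratio of 2.1 genome-wide and 2.8 inside coding sequence, 40x mean
#' coverage with constant Q30 base qualities, a small fraction of poorly
#' mapped reads, a background panel of 58 control samples for CNV depth
#' normalization and a 1,920-member genotyped control cohort.
#'
#' @param genome_length contig length in bp (>= 10 kb)
#' @param diversity germline variants per bp (0.001 = 0.1%)
#' @param titv_genome,titv_exome transition/transversion ratios used outside
#'   and inside coding sequence
#' @param cds_fraction fraction of the genome covered by coding sequence
#' @param mean_depth mean read depth per sample (reads per site)
#' @param base_quality constant phred base quality assigned to reads
#' @param mq_high,mq_low,p_low_mq mapping-quality model: reads get `mq_high`
#'   except a fraction `p_low_mq` that gets `mq_low`
#' @param read_length bp; controls the spread of read start points
#' @param het_fraction fraction of germline variants that are heterozygous
#'   (2:1 het:hom, i.e. 2/3)
#' @param n_homref_sites homozygous-reference sites added to pileup
#'   simulations so detectors see null sites too
#' @param window_size CNV window size in bp
#' @param cnv_target_length length of the CNV target region in bp
#' @param n_background CNV background-panel size
#' @param n_controls risk-cohort size
#' @param seed master seed; every stage derives its own substream via
#'   [stage_seed()]
#' @return a list of class `mosa_sim_config`
#' @export
sim_config <- function(genome_length = 1e6, diversity = 0.001,
                       titv_genome = 2.1, titv_exome = 2.8,
                       cds_fraction = 0.02, mean_depth = 40,
                       base_quality = 30, mq_high = 60, mq_low = 5,
                       p_low_mq = 0.02, read_length = 100,
                       het_fraction = 2 / 3, n_homref_sites = 200,
                       window_size = 100, cnv_target_length = 2e5,
                       n_background = 58, n_controls = 1920, seed = 1) {
  stopifnot(diversity >= 0, titv_genome > 0, titv_exome > 0,
            cds_fraction >= 0, cds_fraction < 1, mean_depth > 0,
            base_quality > 0, het_fraction >= 0, het_fraction <= 1,
            n_background >= 2)
  window_size <- as.integer(window_size)
  structure(as.list(environment()), class = "mosa_sim_config")
}

#' Generate a synthetic reference bundle
#'
#' Builds a uniform-composition contig plus a gene model of non-overlapping
#' CDS intervals (lengths multiples of 3, random strand, frame 0) covering
#' approximately `cds_fraction` of the genome. The 6.6% masked fraction of
#' the real female reference is carried as metadata.
#'
#' @param config a [sim_config()]
#' @return list of class `mosa_reference` with `contigs` (named character),
#'   `gene_model` (contig/start/end/strand/frame, BED coordinates) and
#'   `masked_fraction`
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "mosa_sim_config"))
  L <- as.integer(config$genome_length)
  if (L < 1e4) abort_mosa("genome_length must be >= 10 kb", "mosa_sizing_error")
  seq <- with_stage_seed(config$seed, "reference",
                         paste(sample(BASES, L, replace = TRUE), collapse = ""))
  gene_model <- with_stage_seed(config$seed, "gene_model",
                                place_cds(L, config$cds_fraction))
  structure(list(contigs = c(sim1 = seq),
                 gene_model = gene_model,
                 masked_fraction = 0.066,
                 genome_length = L),
            class = "mosa_reference")
}

## Tile the genome with one CDS per equal-width slot; CDS lengths are
## uniform multiples of 3 in [300, 1500] bp so the total lands near
## cds_fraction * L with sub-0.5% spread.
place_cds <- function(L, cds_fraction) {
  empty <- data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      stringsAsFactors = FALSE)
  if (cds_fraction <= 0) return(empty)
  target <- cds_fraction * L
  mean_len <- 900
  n <- max(1L, round(target / mean_len))
  slot <- floor(L / n)
  max_len <- min(1500L, 3L * floor((slot - 2L) / 3L))
  if (max_len < 300L) {
    abort_mosa("genome too small to place the requested CDS fraction",
               "mosa_sizing_error")
  }
  lens <- 3L * sample(100:(max_len %/% 3L), n, replace = TRUE)
  offs <- vapply(slot - lens - 1L, function(room) sample.int(room, 1L), integer(1))
  start <- (seq_len(n) - 1L) * slot + offs   # 0-based
  data.frame(contig = "sim1", start = start, end = start + lens,
             strand = sample(c("+", "-"), n, replace = TRUE),
             frame = 0L, stringsAsFactors = FALSE)
}

## TRUE for 1-based positions falling inside any gene-model interval.
in_cds <- function(pos, gene_model) {
  if (nrow(gene_model) == 0L) return(rep(FALSE, length(pos)))
  out <- logical(length(pos))
  p0 <- pos - 1L
  for (i in seq_len(nrow(gene_model))) {
    out <- out | (p0 >= gene_model$start[i] & p0 < gene_model$end[i])
  }
  out
}

#' Draw alternate alleles under a transition/transversion spectrum
#'
#' For each reference base, a transition partner (A<->G, C<->T) is chosen
#' with probability `titv / (titv + 1)`, otherwise one of the two
#' transversion partners uniformly. This is the substitution spectrum used
#' for all simulated germline variants.
#'
#' @param ref character vector of reference bases
#' @param titv target transition/transversion ratio
#' @return character vector of alternate bases
#' @export
draw_substitutions <- function(ref, titv) {
  stopifnot(all(ref %in% BASES), titv > 0)
  ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))
  n <- length(ref)
  is_ti <- stats::runif(n) < titv / (titv + 1)
  alt <- character(n)
  alt[is_ti] <- ti_partner[ref[is_ti]]
  if (any(!is_ti)) {
    pick <- 1L + (stats::runif(sum(!is_ti)) < 0.5)
    alt[!is_ti] <- mapply(function(r, k) tv_partners[[r]][k],
                          ref[!is_ti], pick, USE.NAMES = FALSE)
  }
  alt
}

#' Generate shared germline variants for a twin pair
#'
#' The variant count is Binomial(genome length, diversity); positions are
#' uniform without replacement. Alternate alleles follow the exonic
#' spectrum inside CDS and the genome-wide spectrum elsewhere. Both twins
#' receive identical germline genotypes (heterozygous with probability
#' `het_fraction`).
#'
#' @param ref a `mosa_reference`
#' @param config a [sim_config()]
#' @return a truth set (class `mosa_truth`): list with data.frames
#'   `germline` (contig, pos, ref, alt, gt, in_cds), `somatic`, `cnv`,
#'   `artifacts`
#' @export
generate_germline_variants <- function(ref, config) {
  stopifnot(inherits(ref, "mosa_reference"))
  L <- ref$genome_length
  if (config$diversity > 0 && config$diversity * L < 100) {
    abort_mosa("diversity * genome_length must be >= 100 (or diversity 0)",
               "mosa_sizing_error")
  }
  germ <- with_stage_seed(config$seed, "germline", {
    n <- stats::rbinom(1L, L, config$diversity)
    if (n == 0L) {
      data.frame(contig = character(), pos = integer(), ref = character(),
                 alt = character(), gt = character(), in_cds = logical(),
                 stringsAsFactors = FALSE)
    } else {
      pos <- sort(sample.int(L, n))
      rb <- substring(ref$contigs[[1]], pos, pos)
      cds <- in_cds(pos, ref$gene_model)
      alt <- character(n)
      if (any(cds)) alt[cds] <- draw_substitutions(rb[cds], config$titv_exome)
      if (any(!cds)) alt[!cds] <- draw_substitutions(rb[!cds], config$titv_genome)
      gt <- ifelse(stats::runif(n) < config$het_fraction, "0/1", "1/1")
      data.frame(contig = names(ref$contigs)[1], pos = pos, ref = rb, alt = alt,
                 gt = gt, in_cds = cds, stringsAsFactors = FALSE)
    }
  })
  new_truth(germline = germ)
}

new_truth <- function(germline = NULL, somatic = NULL, cnv = NULL,
                      artifacts = NULL) {
  empty_germ <- data.frame(contig = character(), pos = integer(),
                           ref = character(), alt = character(),
                           gt = character(), in_cds = logical(),
                           stringsAsFactors = FALSE)
  empty_som <- data.frame(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          samples = character(), vaf = numeric(),
                          stringsAsFactors = FALSE)
  empty_cnv <- data.frame(contig = character(), start = integer(),
                          end = integer(), direction = character(),
                          copy_ratio = numeric(), samples = character(),
                          stringsAsFactors = FALSE)
  empty_art <- data.frame(contig = character(), pos = integer(),
                          cause = character(), stringsAsFactors = FALSE)
  structure(list(germline = if (is.null(germline)) empty_germ else germline,
                 somatic = if (is.null(somatic)) empty_som else somatic,
                 cnv = if (is.null(cnv)) empty_cnv else cnv,
                 artifacts = if (is.null(artifacts)) empty_art else artifacts),
            class = "mosa_truth")
}

#' Plant somatic events into a truth set
#'
#' Somatic events are tissue-/twin-specific variants present in a strict
#' subset of the samples at a given variant allele fraction (VAF): 0.5 for
#' a clonal heterozygous mosaic, lower when the event is diluted (e.g.
#' pooled biopsies). Events colliding with germline sites are rejected.
#'
#' @param truth a `mosa_truth`
#' @param events data.frame with columns `contig`, `pos`, `samples`
#'   (comma-separated sample labels), `vaf`, and optionally `alt`
#' @param ref a `mosa_reference` (supplies reference bases and, when `alt`
#'   is absent, the transition partner as alternate allele)
#' @param all_samples optional character vector of every sample label in the
#'   design; when given, events must affect a strict subset of it
#' @return the updated `mosa_truth`
#' @export
plant_somatic_events <- function(truth, events, ref, all_samples = NULL) {
  stopifnot(inherits(truth, "mosa_truth"), inherits(ref, "mosa_reference"))
  if (nrow(events) == 0L) return(truth)
  if (any(events$vaf <= 0 | events$vaf > 1)) {
    abort_mosa("somatic event VAF must lie in (0, 1]", "mosa_validation_error")
  }
  key <- paste(events$contig, events$pos)
  gkey <- paste(truth$germline$contig, truth$germline$pos)
  hit <- key %in% gkey
  if (any(hit)) {
    abort_mosa(sprintf("somatic event at %s collides with a germline site",
                       key[which(hit)[1]]), "mosa_collision_error")
  }
  if (anyDuplicated(key)) {
    abort_mosa("duplicate somatic event positions", "mosa_validation_error")
  }
  rb <- substring(ref$contigs[[1]], events$pos, events$pos)
  if (is.null(events$alt)) {
    events$alt <- c(A = "G", G = "A", C = "T", T = "C")[rb]
  }
  if (any(events$alt == rb)) {
    abort_mosa("somatic alt allele equals the reference base",
               "mosa_validation_error")
  }
  if (!is.null(all_samples)) {
    for (s in strsplit(events$samples, ",", fixed = TRUE)) {
      if (!all(s %in% all_samples) || length(s) >= length(all_samples)) {
        abort_mosa("somatic events must affect a strict subset of samples",
                   "mosa_validation_error")
      }
    }
  }
  som <- data.frame(contig = events$contig, pos = as.integer(events$pos),
                    ref = rb, alt = events$alt, samples = events$samples,
                    vaf = events$vaf, stringsAsFactors = FALSE)
  truth$somatic <- rbind(truth$somatic, som)
  truth
}

#' Simulate per-sample pileups at informative sites
#'
#' Sites covered are the germline and somatic truth positions plus
#' `n_homref_sites` randomly chosen homozygous-reference positions (so
#' detectors are exercised on null sites). Per site and sample, depth is
#' Poisson(mean_depth); each read draws its base from the sample's local
#' genotype or VAF and is flipped to a uniformly chosen wrong base with
#' probability `10^(-Q/10)`; mapping qualities and start points follow the
#' configured model.
#'
#' @param ref a `mosa_reference`
#' @param truth a `mosa_truth`
#' @param config a [sim_config()]
#' @param samples character vector of sample labels
#' @param sites optional data.frame (contig, pos) overriding site selection
#' @return list with `pileups` (named list of `mosa_pileup`) and `sites`
#'   (contig, pos, ref, alt — alt NA at hom-ref sites)
#' @export
simulate_pileups <- function(ref, truth, config, samples, sites = NULL) {
  stopifnot(inherits(ref, "mosa_reference"), inherits(truth, "mosa_truth"))
  contig <- names(ref$contigs)[1]
  if (is.null(sites)) {
    used <- c(truth$germline$pos, truth$somatic$pos)
    extra <- with_stage_seed(config$seed, "homref_sites", {
      pool <- setdiff(seq_len(ref$genome_length), used)
      sort(sample(pool, min(config$n_homref_sites, length(pool))))
    })
    pos <- sort(unique(c(used, extra)))
    sites <- data.frame(contig = contig, pos = pos, stringsAsFactors = FALSE)
  }
  sites$ref <- substring(ref$contigs[[1]], sites$pos, sites$pos)
  gi <- match(paste(sites$contig, sites$pos),
              paste(truth$germline$contig, truth$germline$pos))
  si <- match(paste(sites$contig, sites$pos),
              paste(truth$somatic$contig, truth$somatic$pos))
  sites$alt <- ifelse(!is.na(gi), truth$germline$alt[gi],
                      ifelse(!is.na(si), truth$somatic$alt[si], NA_character_))
  som_samples <- strsplit(truth$somatic$samples, ",", fixed = TRUE)
  pileups <- lapply(samples, function(sm) {
    with_stage_seed(config$seed, paste0("pileup:", sm), {
      ## expected alt-allele fraction per site for this sample
      f <- numeric(nrow(sites))
      f[!is.na(gi)] <- ifelse(truth$germline$gt[gi[!is.na(gi)]] == "0/1", 0.5, 1)
      sidx <- which(!is.na(si))
      if (length(sidx)) {
        affected <- vapply(som_samples[si[sidx]], function(s) sm %in% s, logical(1))
        f[sidx][affected] <- truth$somatic$vaf[si[sidx]][affected]
      }
      depth <- stats::rpois(nrow(sites), config$mean_depth)
      idx <- rep.int(seq_len(nrow(sites)), depth)
      n <- length(idx)
      if (n == 0L) return(pileup_frame())
      alt_read <- stats::runif(n) < f[idx]
      base <- ifelse(alt_read, sites$alt[idx], sites$ref[idx])
      e <- 10^(-config$base_quality / 10)
      flip <- stats::runif(n) < e
      if (any(flip)) {
        wrong <- vapply(base[flip], function(b) sample(setdiff(BASES, b), 1L),
                        character(1))
        base[flip] <- wrong
      }
      mq <- ifelse(stats::runif(n) < config$p_low_mq, config$mq_low, config$mq_high)
      start <- sites$pos[idx] - sample.int(config$read_length, n, replace = TRUE) + 1L
      pileup_frame(contig = sites$contig[idx], pos = sites$pos[idx],
                   ref = sites$ref[idx], base = base,
                   bq = config$base_quality, mq = mq, start = pmax(1L, start),
                   strand = sample(c("+", "-"), n, replace = TRUE))
    })
  })
  names(pileups) <- samples
  list(pileups = pileups, sites = sites)
}

#' Build the indel-misalignment artifact fixture
#'
#' Models the classic false-positive mode where reads carrying an insertion
#' allele are aligned against the insertion-free reference: the misplaced
#' read tails produce spurious mismatch bases at positions near the
#' insertion point in one sample, while the matched sample's library was
#' aligned cleanly — so a somatic-variant screen sees a convincing
#' between-sample discordance. Both samples carry the 19 bp insertion
#' `CGCAGCAGGGGCAGCAGGG` heterozygously; the "naive" pileups encode the
#' misalignment at two spurious SNV positions, the "realigned" pileups are
#' artifact-free, and the truth set lists the spurious positions as
#' artifact sites (not somatic events).
#'
#' @param seed integer seed
#' @param depth per-sample read depth at fixture sites
#' @return list with `naive` and `realigned` (each a named list of two
#'   `mosa_pileup` tables, samples `affected_biopsy` / `affected_blood`),
#'   `truth` (a `mosa_truth` with two artifact sites), `sites`, and
#'   `insertion` (list with `seq`, `pos`)
#' @export
generate_indel_artifact_fixture <- function(seed = 1, depth = 50) {
  ins <- "CGCAGCAGGGGCAGCAGGG"     # 19 bp insertion allele
  contig <- "artifact1"
  ins_pos <- 200L                  # insertion after this reference position
  art_pos <- c(205L, 212L)         # spurious SNV1/SNV2 positions
  ctl_pos <- c(150L, 260L)         # clean control sites
  ref_seq <- with_stage_seed(seed, "artifact_ref",
                             paste(sample(BASES, 400, replace = TRUE),
                                   collapse = ""))
  all_pos <- sort(c(art_pos, ctl_pos))
  refb <- substring(ref_seq, all_pos, all_pos)
  names(refb) <- all_pos
  ## spurious base observed at each artifact position = insertion sequence
  ## base that lands there under the naive (shifted) alignment
  spur <- vapply(art_pos, function(p) {
    substring(ins, p - ins_pos, p - ins_pos)
  }, character(1))
  spur <- ifelse(spur == refb[as.character(art_pos)],
                 c(A = "G", G = "A", C = "T", T = "C")[refb[as.character(art_pos)]],
                 spur)
  make_pileup <- function(label, spur_frac) {
    with_stage_seed(seed, paste0("artifact_pileup:", label), {
      rows <- lapply(all_pos, function(p) {
        d <- depth
        rb <- unname(refb[as.character(p)])
        n_spur <- if (p %in% art_pos) round(d * spur_frac) else 0L
        b <- c(rep(unname(spur[match(p, art_pos)]), n_spur), rep(rb, d - n_spur))
        data.frame(contig = contig, pos = p, ref = rb,
                   base = b, bq = 30, mq = ifelse(b == rb, 60, 55),
                   start = pmax(1L, p - sample.int(100L, d, replace = TRUE) + 1L),
                   strand = sample(c("+", "-"), d, replace = TRUE),
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      rownames(df) <- NULL
      class(df) <- c("mosa_pileup", "data.frame")
      df
    })
  }
  naive <- list(affected_biopsy = make_pileup("naive_biopsy", 0.5),
                affected_blood = make_pileup("naive_blood", 0))
  realigned <- list(affected_biopsy = make_pileup("realigned_biopsy", 0),
                    affected_blood = make_pileup("realigned_blood", 0))
  truth <- new_truth(artifacts = data.frame(
    contig = contig, pos = art_pos, cause = "indel_misalignment",
    stringsAsFactors = FALSE))
  sites <- data.frame(contig = contig, pos = all_pos,
                      ref = unname(refb),
                      alt = ifelse(all_pos %in% art_pos,
                                   spur[match(all_pos, art_pos)], NA_character_),
                      stringsAsFactors = FALSE)
  list(naive = naive, realigned = realigned, truth = truth, sites = sites,
       insertion = list(seq = ins, pos = ins_pos, genotype = "0/1"))
}

#' Simulate a windowed CNV depth matrix with planted events
#'
#' Windows of `window_size` bp tile a target region. Per window and sample,
#' the read count is Poisson(mean depth per window x copy ratio); the copy
#' ratio is 1 outside events and the event's ratio (0.5 for a one-copy
#' loss, 1.5 for a one-copy gain by default) inside, for affected samples
#' only. The background panel never carries planted events.
#'
#' @param config a [sim_config()]
#' @param cnv_events data.frame with `contig`, `start`, `end` (BED
#'   coordinates), `direction` ("loss"/"gain"), `samples` (comma-separated),
#'   optionally `copy_ratio`
#' @param samples test-sample labels (the twin samples)
#' @return list with `depth` (class `mosa_depth_matrix`: `windows`,
#'   `counts`, `window_size`, `background` = background column names) and
#'   `truth` (a `mosa_truth` carrying the CNV events)
#' @export
simulate_cnv_depth <- function(config, cnv_events = NULL, samples) {
  stopifnot(inherits(config, "mosa_sim_config"), config$n_background >= 2)
  ws <- config$window_size
  n_win <- floor(config$cnv_target_length / ws)
  windows <- data.frame(contig = "sim1",
                        start = (seq_len(n_win) - 1L) * ws,
                        end = seq_len(n_win) * ws, stringsAsFactors = FALSE)
  if (is.null(cnv_events)) {
    cnv_events <- data.frame(contig = character(), start = integer(),
                             end = integer(), direction = character(),
                             copy_ratio = numeric(), samples = character(),
                             stringsAsFactors = FALSE)
  }
  if (nrow(cnv_events)) {
    if (is.null(cnv_events$copy_ratio)) {
      cnv_events$copy_ratio <- ifelse(cnv_events$direction == "loss", 0.5, 1.5)
    }
    o <- order(cnv_events$start)
    ev <- cnv_events[o, , drop = FALSE]
    if (nrow(ev) > 1L && any(ev$start[-1] < ev$end[-nrow(ev)])) {
      abort_mosa("planted CNV events must not overlap", "mosa_validation_error")
    }
  }
  bg <- sprintf("bg%02d", seq_len(config$n_background))
  all_samples <- c(samples, bg)
  ## window depth = summed per-base coverage over the window, so the
  ## expected count at copy ratio 1 is mean_depth * window_size
  lambda0 <- config$mean_depth * ws
  counts <- with_stage_seed(config$seed, "cnv_depth", {
    m <- matrix(0L, n_win, length(all_samples),
                dimnames = list(NULL, all_samples))
    for (j in seq_along(all_samples)) {
      ratio <- rep(1, n_win)
      if (nrow(cnv_events)) {
        for (i in seq_len(nrow(cnv_events))) {
          aff <- strsplit(cnv_events$samples[i], ",", fixed = TRUE)[[1]]
          if (all_samples[j] %in% aff) {
            inside <- windows$start >= cnv_events$start[i] &
              windows$end <= cnv_events$end[i]
            ratio[inside] <- cnv_events$copy_ratio[i]
          }
        }
      }
      m[, j] <- stats::rpois(n_win, lambda0 * ratio)
    }
    m
  })
  depth <- structure(list(windows = windows, counts = counts,
                          window_size = ws, background = bg),
                     class = "mosa_depth_matrix")
  list(depth = depth, truth = new_truth(cnv = cnv_events))
}

#' Simulate a control cohort genotyped at risk loci
#'
#' Risk-allele copy counts are drawn per locus under Hardy-Weinberg
#' equilibrium (Binomial(2, risk-allele frequency)), independently across
#' loci.
#'
#' @param model a `mosa_risk_model`
#' @param n cohort size (1,920 by default)
#' @param seed integer seed
#' @return integer matrix (subjects x loci) of risk-allele copies, with
#'   locus ids as column names
#' @export
simulate_control_cohort <- function(model, n = 1920, seed = 1) {
  stopifnot(inherits(model, "mosa_risk_model"))
  f <- model$risk_freq
  if (any(f <= 0 | f >= 1)) {
    abort_mosa("risk-allele frequencies must lie strictly in (0,1)",
               "mosa_input_error")
  }
  with_stage_seed(seed, "control_cohort", {
    m <- vapply(f, function(p) stats::rbinom(n, 2L, p), integer(n))
    m <- matrix(as.integer(m), nrow = n)
    colnames(m) <- model$locus_id
    m
  })
}
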