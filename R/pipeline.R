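#' Pipeline configuration
#'
#' Encodes the twin study design and every stage parameter. The
#' four-sample design (affected/healthy x blood/biopsy) enables
#' query-position selection and the cross-sample arbitration veto; the
#' two-sample design (blood only) runs a single affected-vs-healthy
#' comparison.
#'
#' @param seed master seed
#' @param outdir output directory (created if needed)
#' @param design `"four_sample"` or `"two_sample"`
#' @param genome_length simulated genome length (bp)
#' @param n_somatic somatic events planted in the affected twin's samples
#' @param somatic_vaf variant allele fraction of planted events
#' @param cnv_loss_kb length (kb) of the planted twin-discordant loss; 0
#'   disables the CNV stage's planted event
#' @param n_risk_loci risk-model size
#' @param twin_risk_boost planted excess: fraction of loci forced to two
#'   risk-allele copies in the twins (0 = draw like a control)
#' @param sim overrides passed to [sim_config()] as a named list
#' @return list of class `mosa_pipeline_config`
#' @export
pipeline_config <- function(seed = 1, outdir = tempfile("mosatwin_run_"),
                            design = c("four_sample", "two_sample"),
                            genome_length = 1e6, n_somatic = 10,
                            somatic_vaf = 0.5, cnv_loss_kb = 3,
                            n_risk_loci = 133, twin_risk_boost = 0.3,
                            sim = list()) {
  design <- match.arg(design)
  samples <- if (design == "four_sample") {
    c(affected_blood = "affected_blood", affected_biopsy = "affected_biopsy",
      healthy_blood = "healthy_blood", healthy_biopsy = "healthy_biopsy")
  } else {
    c(affected_blood = "affected_blood", healthy_blood = "healthy_blood")
  }
  if (anyDuplicated(samples)) {
    abort_mosa("sample labels must be unique", "mosa_config_error")
  }
  sim <- sim[setdiff(names(sim), c("genome_length", "seed"))]
  cfg <- list(seed = seed, outdir = outdir, design = design,
              samples = samples, genome_length = genome_length,
              n_somatic = n_somatic, somatic_vaf = somatic_vaf,
              cnv_loss_kb = cnv_loss_kb, n_risk_loci = n_risk_loci,
              twin_risk_boost = twin_risk_boost,
              sim = do.call(sim_config, c(list(genome_length = genome_length,
                                               seed = seed), sim)))
  class(cfg) <- "mosa_pipeline_config"
  cfg
}

#' Simulate a plausible risk model
#'
#' Locus odds ratios are drawn uniformly in [1.05, 1.5] (the typical
#' effect-size range of common susceptibility alleles) and risk-allele
#' frequencies uniformly in [0.1, 0.9].
#'
#' @param n_loci number of loci (default 133)
#' @param seed integer seed
#' @return a `mosa_risk_model`
#' @export
simulate_risk_model <- function(n_loci = 133, seed = 1) {
  with_stage_seed(seed, "risk_model", {
    alleles <- t(vapply(seq_len(n_loci),
                        function(i) sample(BASES, 2L), character(2)))
    risk_model(data.frame(
      locus_id = sprintf("rs%05d", seq_len(n_loci)),
      contig = "sim1",
      pos = sort(sample.int(1e6, n_loci)),
      risk_allele = alleles[, 1], other_allele = alleles[, 2],
      or_value = round(stats::runif(n_loci, 1.05, 1.5), 3),
      risk_freq = round(stats::runif(n_loci, 0.1, 0.9), 3),
      stringsAsFactors = FALSE))
  })
}

#' Run the full twin-discordance pipeline on synthetic data
#'
#' Executes simulate -> genotype -> somatic -> cnv -> risk and writes all
#' artifacts (FASTA reference, truth TSVs, per-sample pileups, VCF calls,
#' candidate tables, CNV audit, risk distribution) plus a machine-readable
#' JSON report into `config$outdir`. Reruns with the same configuration
#' produce identical reports.
#'
#' @param config a [pipeline_config()]
#' @return the run report (invisibly written to `report.json`): parameter
#'   echo, per-stage counts, truth-evaluation block, output-file digests
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mosa_pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  samples <- unname(config$samples)
  affected <- grep("^affected", samples, value = TRUE)

  ## --- simulate ---
  ref <- generate_reference(config$sim)
  truth <- generate_germline_variants(ref, config$sim)
  if (config$n_somatic > 0) {
    events <- with_stage_seed(config$seed, "plant_somatic", {
      pool <- setdiff(seq_len(ref$genome_length), truth$germline$pos)
      data.frame(contig = names(ref$contigs)[1],
                 pos = sort(sample(pool, config$n_somatic)),
                 samples = paste(affected, collapse = ","),
                 vaf = config$somatic_vaf, stringsAsFactors = FALSE)
    })
    truth <- plant_somatic_events(truth, events, ref, all_samples = samples)
  }
  sim <- simulate_pileups(ref, truth, config$sim, samples)
  write_fasta(ref$contigs, file.path(config$outdir, "reference.fa"))
  write_truth(truth, file.path(config$outdir, "truth"))
  for (s in samples) {
    write_pileup(sim$pileups[[s]], file.path(config$outdir,
                                             paste0(s, ".pileup.tsv")))
  }

  ## --- genotype ---
  gt <- lapply(sim$pileups, call_genotypes)
  var_sites <- !is.na(sim$sites$alt)
  callset <- data.frame(contig = sim$sites$contig, pos = sim$sites$pos,
                        ref = sim$sites$ref, alt = sim$sites$alt,
                        popfreq = NA_real_, stringsAsFactors = FALSE)
  for (s in samples) {
    calls <- gt[[s]]$calls
    i <- match(paste(callset$contig, callset$pos),
               paste(calls$contig, calls$pos))
    g <- calls$genotype[i]
    callset[[s]] <- !is.na(g) & !is.na(callset$alt) &
      (substr(g, 1, 1) == callset$alt | substr(g, 2, 2) == callset$alt)
  }
  conc <- pairwise_concordance(gt[[samples[1]]]$calls,
                               gt[[samples[length(samples)]]]$calls)
  germ_titv <- titv_ratio(truth$germline)
  vcf <- callset[var_sites, c("contig", "pos", "ref", "alt", "popfreq")]
  vcf$id <- "."
  for (s in samples) {
    vcf[[paste0("gt.", s)]] <- ifelse(callset[[s]][var_sites], "0/1", "0/0")
    vcf[[paste0("dp.", s)]] <- NA_integer_
  }
  attr(vcf, "samples") <- samples
  write_vcf_subset(vcf, file.path(config$outdir, "calls.vcf"))

  ## --- somatic ---
  if (config$design == "four_sample") {
    roles <- c(affected_blood = "affected_blood",
               affected_biopsy = "affected_biopsy",
               healthy_blood = "healthy_blood",
               healthy_biopsy = "healthy_biopsy")
    query <- select_query_positions(callset, roles)
    plan <- data.frame(
      test = c("affected_biopsy", "affected_blood", "affected_biopsy"),
      reference = c("affected_blood", "healthy_blood", "healthy_biopsy"),
      stringsAsFactors = FALSE)
  } else {
    query <- callset
    plan <- data.frame(test = "affected_blood", reference = "healthy_blood",
                       stringsAsFactors = FALSE)
  }
  qsites <- sim$sites[match(paste(query$contig, query$pos),
                            paste(sim$sites$contig, sim$sites$pos)), ,
                      drop = FALSE]
  calls <- detect_discordances(sim$pileups, qsites, plan)
  heldout <- if (config$design == "four_sample") {
    sim$pileups[c("healthy_blood", "healthy_biopsy")]
  } else NULL
  ## no misalignment is simulated here, so the pileups are their own
  ## realigned counterparts; the fixture path exercises true realignment
  arb <- arbitrate_with_realignment(calls, realigned = sim$pileups,
                                    heldout = heldout, sites = qsites)
  venn <- method_overlap(arb, k = 100)
  eval_truth <- evaluate_against_truth(arb, truth)
  utils::write.table(arb, file.path(config$outdir, "somatic_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(venn), file.path(config$outdir, "venn.json"),
                       auto_unbox = TRUE)

  ## --- cnv ---
  cnv_block <- NULL
  if (config$cnv_loss_kb > 0) {
    loss_len <- as.integer(config$cnv_loss_kb * 1000)
    ev <- data.frame(contig = "sim1", start = 50000L,
                     end = 50000L + loss_len, direction = "loss",
                     samples = paste(affected, collapse = ","),
                     stringsAsFactors = FALSE)
    cnv_sim <- simulate_cnv_depth(config$sim, ev, samples)
    norm <- normalize_depth(cnv_sim$depth)
    regions <- lapply(samples, function(s) {
      call_cnv_regions(norm$windows, norm$ratios[, s], sample = s)
    })
    names(regions) <- samples
    mapp <- data.frame(contig = "sim1", start = 0L,
                       end = max(cnv_sim$depth$windows$end), score = 1,
                       stringsAsFactors = FALSE)
    if (config$design == "four_sample") {
      casc <- differential_cnv_filter(regions$affected_blood,
                                      regions$affected_biopsy,
                                      regions$healthy_blood,
                                      regions$healthy_biopsy, mapp)
    } else {
      casc <- differential_cnv_filter(regions$affected_blood,
                                      regions$affected_blood,
                                      regions$healthy_blood,
                                      regions$healthy_blood, mapp)
    }
    write_depth_matrix(cnv_sim$depth, file.path(config$outdir, "cnv_depth.tsv"))
    if (nrow(casc$candidates)) {
      write_bed(casc$candidates[, c("contig", "start", "end", "direction")],
                file.path(config$outdir, "cnv_candidates.bed"))
    }
    utils::write.table(casc$audit, file.path(config$outdir, "cnv_audit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cnv_block <- list(planted = nrow(cnv_sim$truth$cnv),
                      per_stage = stats::setNames(as.list(casc$audit$n),
                                                  casc$audit$stage),
                      candidates = nrow(casc$candidates))
  }

  ## --- risk ---
  model <- simulate_risk_model(config$n_risk_loci, config$seed)
  cohort <- simulate_control_cohort(model, n = config$sim$n_controls,
                                    seed = config$seed)
  dist <- cohort_distribution(cohort, model)
  twin_copies <- with_stage_seed(config$seed, "twin_risk", {
    g <- stats::rbinom(nrow(model), 2L, model$risk_freq)
    if (config$twin_risk_boost > 0) {
      boost <- stats::runif(nrow(model)) < config$twin_risk_boost
      g[boost] <- 2L
    }
    stats::setNames(as.integer(g), model$locus_id)
  })
  twin_score <- risk_sum(twin_copies, model, subject = "affected_twin")
  pct <- risk_percentile(twin_score, dist)
  write_risk_model(model, file.path(config$outdir, "risk_model.tsv"))
  jsonlite::write_json(list(scores = dist$scores, loci_key = dist$loci_key),
                       file.path(config$outdir, "risk_distribution.json"),
                       digits = 10)

  ## --- report ---
  n_conf <- sum(arb$arbitration == "confirmed-candidate")
  report <- list(
    parameters = list(seed = config$seed, design = config$design,
                      genome_length = config$genome_length,
                      n_somatic = config$n_somatic,
                      somatic_vaf = config$somatic_vaf,
                      mean_depth = config$sim$mean_depth,
                      thresholds = unclass(detector_thresholds())),
    simulate = list(n_germline = nrow(truth$germline),
                    n_somatic_planted = nrow(truth$somatic),
                    titv_germline = germ_titv),
    genotype = list(concordance = conc$concordance,
                    n_compared = conc$n_compared),
    somatic = list(n_query_sites = nrow(qsites),
                   n_tests = nrow(calls),
                   n_pass_threshold = sum(calls$passes_threshold),
                   n_confirmed = n_conf,
                   venn = as.list(venn),
                   truth_eval = list(
                     sensitivity = eval_truth$sensitivity,
                     n_planted = eval_truth$n_planted,
                     n_detected = eval_truth$n_detected,
                     false_discoveries = eval_truth$false_discoveries)),
    cnv = cnv_block,
    risk = list(twin_score = twin_score$score,
                twin_percentile = pct$percentile,
                control_mean = dist$mean, n_controls = dist$n,
                n_loci = config$n_risk_loci))
  files <- list.files(config$outdir, full.names = TRUE)
  files <- setdiff(files, file.path(config$outdir, "report.json"))
  report$digests <- as.list(tools::md5sum(files))
  names(report$digests) <- basename(names(report$digests))
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}

#' Generate the bundled demo datasets
#'
#' Writes a four-sample twin-pair design (blood + biopsy for both twins),
#' a two-sample blood-only design, and the indel-misalignment artifact
#' fixture under `dir`, each with its planted truth.
#'
#' @param seed master seed
#' @param dir output directory
#' @return named list of output directories / fixture paths
#' @export
make_demo_dataset <- function(seed = 1, dir = tempfile("mosatwin_demo_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  four <- file.path(dir, "four_sample")
  two <- file.path(dir, "two_sample")
  run_pipeline(pipeline_config(seed = seed, outdir = four,
                               design = "four_sample", genome_length = 1e5))
  run_pipeline(pipeline_config(seed = seed + 1, outdir = two,
                               design = "two_sample",
                               genome_length = 1e5, cnv_loss_kb = 0))
  fx <- generate_indel_artifact_fixture(seed)
  fxdir <- file.path(dir, "artifact_fixture")
  dir.create(fxdir, showWarnings = FALSE)
  for (s in names(fx$naive)) {
    write_pileup(fx$naive[[s]], file.path(fxdir, paste0(s, ".naive.pileup.tsv")))
    write_pileup(fx$realigned[[s]],
                 file.path(fxdir, paste0(s, ".realigned.pileup.tsv")))
  }
  write_truth(fx$truth, file.path(fxdir, "truth"))
  list(four_sample = four, two_sample = two, artifact_fixture = fxdir)
}
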