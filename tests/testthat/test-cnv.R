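test_that("depth normalization is invariant to library size and flags masked windows", {
  n <- 200
  windows <- data.frame(contig = "sim1", start = (0:(n - 1)) * 100L,
                        end = (1:n) * 100L)
  base <- matrix(4000L, n, 5,
                 dimnames = list(NULL, c("test", paste0("bg", 1:4))))
  depth <- structure(list(windows = windows, counts = base,
                          window_size = 100L, background = paste0("bg", 1:4)),
                     class = "mosa_depth_matrix")
  norm <- normalize_depth(depth)
  expect_true(all(abs(norm$ratios[, "test"] - 1) < 1e-12))

  ## doubling the test library changes nothing after median scaling
  doubled <- depth
  doubled$counts[, "test"] <- base[, "test"] * 2L
  norm2 <- normalize_depth(doubled)
  expect_true(all(abs(norm2$ratios[, "test"] - 1) < 1e-12))

  ## zero-background windows are masked, not repaired
  zeroed <- depth
  zeroed$counts[5, paste0("bg", 1:4)] <- 0L
  norm3 <- normalize_depth(zeroed)
  expect_true(is.na(norm3$ratios[5, "test"]))
  expect_true(norm3$masked[5])

  all_zero <- depth
  all_zero$counts[, paste0("bg", 1:4)] <- 0L
  expect_error(normalize_depth(all_zero), class = "mosa_input_error")
})

test_that("region calling applies the window, support and ratio filters", {
  n <- 100
  windows <- data.frame(contig = "sim1", start = (0:(n - 1)) * 100L,
                        end = (1:n) * 100L)
  ratios <- rep(1, n)
  ratios[30:54] <- 0.5        # 25 consecutive loss windows
  r <- call_cnv_regions(windows, ratios, sample = "s")
  expect_identical(nrow(r), 1L)
  expect_identical(r$direction, "loss")
  expect_identical(r$n_windows, 25L)
  expect_equal(r$support_fraction, 1.0)
  expect_equal(r$mean_ratio, 0.5)
  expect_identical(r$start, windows$start[30])
  expect_identical(r$end, windows$end[54])

  ## 15-window run: below the 20-window minimum
  ratios2 <- rep(1, n)
  ratios2[10:24] <- 0.5
  expect_identical(nrow(call_cnv_regions(windows, ratios2, "s")), 0L)

  ## all normal: empty output
  expect_identical(nrow(call_cnv_regions(windows, rep(1, n), "s")), 0L)

  ## gains symmetric with losses
  ratios3 <- rep(1, n)
  ratios3[40:69] <- 1.5
  g <- call_cnv_regions(windows, ratios3, "s")
  expect_identical(g$direction, "gain")
  expect_identical(g$n_windows, 30L)
})

test_that("reciprocal overlap is symmetric with exact boundary behavior", {
  iv <- function(s, e) list(contig = "c1", start = s, end = e)
  same <- reciprocal_overlap(iv(0, 100), iv(0, 100), 0.9)
  expect_true(same$pass)
  expect_equal(c(same$frac_a, same$frac_b), c(1, 1))

  edge <- reciprocal_overlap(iv(0, 100), iv(10, 110), 0.9)
  expect_true(edge$pass)
  expect_equal(c(edge$frac_a, edge$frac_b), c(0.9, 0.9))

  fail <- reciprocal_overlap(iv(0, 100), iv(50, 250), 0.9)
  expect_false(fail$pass)
  expect_equal(c(fail$frac_a, fail$frac_b), c(0.5, 0.25))

  ## symmetry on random interval pairs
  set.seed(3)
  for (case in 1:30) {
    a <- iv(sample(0:500, 1), 0)
    a$end <- a$start + sample(50:400, 1)
    b <- iv(sample(0:500, 1), 0)
    b$end <- b$start + sample(50:400, 1)
    f <- runif(1, 0.1, 1)
    ab <- reciprocal_overlap(a, b, f)
    ba <- reciprocal_overlap(b, a, f)
    expect_identical(ab$pass, ba$pass)
    expect_equal(ab$frac_a, ba$frac_b)
  }
})

test_that("differential cascade filters shared, unmappable and healthy-overlap regions", {
  reg <- function(s, e, dir = "loss", sample = "x", ratio = 0.5)
    data.frame(contig = "c1", start = s, end = e, direction = dir,
               n_windows = (e - s) %/% 100L, support_fraction = 1,
               mean_ratio = ratio, sample = sample, stringsAsFactors = FALSE)
  mapp <- data.frame(contig = "c1", start = 0L, end = 100000L, score = 1)
  none <- reg(0, 100)[0, ]

  ## twin-discordant loss in a mappable region survives every stage
  out <- differential_cnv_filter(reg(1000, 4000), reg(1100, 4100),
                                 none, none, mapp)
  expect_identical(nrow(out$candidates), 1L)
  expect_equal(out$candidates$start, 1100)  # intersection bounds
  expect_equal(out$candidates$end, 4000)
  expect_true(all(diff(out$audit$n[-(1:2)]) <= 0))

  ## shared with the healthy twin: removed at stage 2
  out2 <- differential_cnv_filter(reg(1000, 4000), reg(1000, 4000),
                                  reg(1500, 2000), none, mapp)
  expect_identical(nrow(out2$candidates), 0L)
  expect_identical(out2$audit$n[out2$audit$stage == "stage1_reciprocal"], 1L)

  ## loss inside a zero-uniqueness region: removed at stage 3
  dark <- data.frame(contig = "c1", start = 0L, end = 100000L, score = 0)
  out3 <- differential_cnv_filter(reg(1000, 4000), reg(1000, 4000),
                                  none, none, dark)
  expect_identical(nrow(out3$candidates), 0L)

  ## missing mappability contig is an audit error
  wrong <- data.frame(contig = "c9", start = 0L, end = 1000L, score = 1)
  expect_error(differential_cnv_filter(reg(1000, 4000), reg(1000, 4000),
                                       none, none, wrong),
               class = "mosa_audit_error")
})

test_that("cascade is monotone in its thresholds", {
  casc <- cnv_recovery_run(seed = 21, loss_windows = 30)
  base_n <- nrow(casc$candidates)
  expect_identical(base_n, 1L)
  ## tightening the reciprocal fraction can only shrink the candidate list
  cfg <- sim_config(seed = 21)
  samples <- c("affected_blood", "affected_biopsy",
               "healthy_blood", "healthy_biopsy")
  ev <- data.frame(contig = "sim1", start = 50000L, end = 53000L,
                   direction = "loss",
                   samples = "affected_blood,affected_biopsy")
  sim <- simulate_cnv_depth(cfg, ev, samples)
  norm <- normalize_depth(sim$depth)
  regs <- lapply(samples, function(s)
    call_cnv_regions(norm$windows, norm$ratios[, s], sample = s))
  names(regs) <- samples
  mapp <- data.frame(contig = "sim1", start = 0L,
                     end = max(sim$depth$windows$end), score = 1)
  prev <- Inf
  for (f in c(0.5, 0.7, 0.9, 0.99)) {
    n <- nrow(differential_cnv_filter(regs$affected_blood,
                                      regs$affected_biopsy,
                                      regs$healthy_blood,
                                      regs$healthy_biopsy,
                                      mapp, frac = f)$candidates)
    expect_lte(n, prev)
    prev <- n
  }
  ## and in the caller's region filters
  prev <- Inf
  for (mw in c(10, 20, 40)) {
    n <- nrow(call_cnv_regions(norm$windows, norm$ratios[, "affected_blood"],
                               min_windows = mw))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("LOH support distinguishes supported, insufficient and unsupported", {
  region <- list(contig = "c1", start = 1000L, end = 3000L)
  mk_calls <- function(n_het, n_hom, from = 1001L) {
    pos <- seq(from, length.out = n_het + n_hom, by = 10L)
    n <- length(pos)
    data.frame(contig = rep("c1", n), pos = pos, ref = rep("A", n),
               genotype = c(rep("AG", n_het), rep("AA", n_hom)),
               depth = rep(30L, n), quality = rep(60, n),
               no_call = rep(FALSE, n), low_confidence = rep(FALSE, n),
               stringsAsFactors = FALSE)
  }
  ## carrier lost all heterozygosity: supported
  r <- loh_support(list(contig = "c1", start = 1000L, end = 3000L),
                   mk_calls(0, 20), mk_calls(20, 0))
  expect_identical(r$verdict, "supported")
  expect_equal(r$het_carrier, 0)
  expect_equal(r$het_other, 1)

  ## no informative sites
  empty <- mk_calls(0, 0)
  expect_identical(loh_support(region, empty, empty)$verdict, "insufficient")

  ## equal het fractions: unsupported
  r3 <- loh_support(region, mk_calls(10, 10), mk_calls(10, 10))
  expect_identical(r3$verdict, "unsupported")
})

test_that("depth matrix TSV round-trips", {
  cfg <- sim_config(seed = 30, cnv_target_length = 5e3)
  sim <- simulate_cnv_depth(cfg, NULL, samples = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_matrix(sim$depth, path)
  back <- read_depth_matrix(path)
  expect_identical(back$counts, sim$depth$counts)
  expect_equal(back$windows, sim$depth$windows)
  expect_identical(back$window_size, sim$depth$window_size)
})
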