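test_that("read simulation is reproducible by seed and sensitive to it", {
  ref <- canonicalRef()
  g <- canonicalGuide(ref)
  cfg <- readSimConfig(n_reads = 300, editing_rate_mutant = 0.2,
                       substitution_error_rate = 0.002, seed = 41)
  s1 <- simulateReads(ref, g, cfg)
  s2 <- simulateReads(ref, g, cfg)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateReads(ref, g, readSimConfig(n_reads = 300,
    editing_rate_mutant = 0.2, substitution_error_rate = 0.002, seed = 42))
  expect_false(identical(as.character(s1$reads), as.character(s3$reads)))
})

test_that("noise-free unedited reads are exact substrings of their allele", {
  ref <- canonicalRef()
  g <- canonicalGuide(ref)
  sim <- simulateReads(ref, g, readSimConfig(n_reads = 200, seed = 43))
  mut <- mutantChar(ref)
  wt <- wtSequence(ref, as = "character")
  src <- ifelse(sim$truth$allele == "mutant", mut, wt)
  hit <- mapply(grepl, as.character(sim$reads), src, fixed = TRUE)
  expect_true(all(hit))
  expect_identical(sum(sim$truth$edited), 0L)
})

test_that("edited read counts follow the configured binomial rates", {
  ref <- canonicalRef()
  g <- canonicalGuide(ref)
  sim <- simulateReads(ref, g, readSimConfig(
    n_reads = 20000, editing_rate_mutant = 0.05, seed = 44))
  tr <- sim$truth
  n_mut <- sum(tr$allele == "mutant")
  k <- sum(tr$edited & tr$allele == "mutant")
  # central 99.9% binomial interval, computed independently
  bounds <- qbinom(c(5e-4, 1 - 5e-4), n_mut, 0.05)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
  # allele fraction behaves likewise
  ab <- qbinom(c(5e-4, 1 - 5e-4), 20000, 0.5)
  expect_gte(n_mut, ab[1])
  expect_lte(n_mut, ab[2])
})

test_that("simulated indels sit at the cut site with configured lengths", {
  ref <- canonicalRef()
  g <- canonicalGuide(ref)
  sim <- simulateReads(ref, g, readSimConfig(
    n_reads = 300, allele_fraction_mutant = 1, editing_rate_mutant = 1,
    indel_length_weights = c("-2" = 1, "1" = 1), seed = 45))
  tr <- sim$truth
  expect_true(all(tr$edited))
  expect_true(all(tr$indel_len %in% c(-2L, 1L)))
  expect_true(all(tr$indel_left == guideCutSite(g)))
  lens <- nchar(as.character(sim$reads))
  expect_identical(sort(unique(lens - 101L)), sort(unique(tr$indel_len)))
})

test_that("FASTQ writing round-trips reads", {
  ref <- canonicalRef()
  g <- canonicalGuide(ref)
  sim <- simulateReads(ref, g, readSimConfig(n_reads = 25, seed = 46))
  fq <- tempfile(fileext = ".fastq")
  writeReadsFastq(sim, fq)
  back <- readFastqReads(fq)
  expect_identical(unname(as.character(back)), unname(as.character(sim$reads)))
  expect_identical(length(readLines(fq)), 100L)
})

test_that("editing with all-zero indel weights is refused", {
  expect_error(readSimConfig(editing_rate_mutant = 0.1,
                             indel_length_weights = c("-3" = 0)),
               "zero")
})

test_that("T7E1 densitometry simulation inverts the frequency formula", {
  expect_identical(simulateT7e1(0)$cleaved_density, 0)
  expect_identical(simulateT7e1(100)$uncut_density, 0)
  expect_equal(simulateT7e1(50)$cleaved_density, 0.75)
  expect_error(simulateT7e1(101), "\\[0, 100\\]")
  expect_error(simulateT7e1(-2), "\\[0, 100\\]")
})

test_that("noiseless cohorts shift exactly linearly in efficacy", {
  cfg <- cohortSimConfig(n_mice = 10, noise_sd_db = 0, db_per_percent = 10,
                         seed = 47)
  sim <- simulateCohort(cfg)
  rec <- cohortImprovement(sim$records)
  expect_equal(rec$mean_shift_db, 10 * sim$truth$efficacy, tolerance = 1e-12)
  expect_true(all(rec$efficacy_percent >= 0))
})

test_that("a zero-variance efficacy cohort is flagged as degenerate", {
  sim <- simulateCohort(cohortSimConfig(n_mice = 5, efficacy_sd = 0,
                                        noise_sd_db = 0, seed = 48))
  expect_true(sim$degenerate)
  expect_identical(length(unique(sim$records$efficacy_percent)), 1L)
  expect_error(correlateEfficacyImprovement(
    sim$records$efficacy_percent,
    cohortImprovement(sim$records)$mean_shift_db), "variance")
})

test_that("flux traces are linear-plus-noise and stacks mirror the table", {
  cfg0 <- fluxSimConfig(n_rois = 2, f0_sd = 0, noise_sd = 0,
                        slope_by_group = c(ctrl = 0), seed = 49)
  s0 <- simulateFlux(cfg0)
  expect_true(all(s0$traces$F == s0$traces$F[1]))

  cfg <- fluxSimConfig(n_rois = 3, noise_sd = 0,
                       slope_by_group = c(WT = 0.5, inh = 0), seed = 50)
  st <- simulateFlux(cfg, as_stack = TRUE)
  tr <- extractTraces(st$stack, st$masks, st$frame_interval_s)
  expect_equal(tr$F, st$traces$F, tolerance = 1e-12)
  expect_identical(tr$roi, st$traces$roi)
})
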