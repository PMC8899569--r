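test_that("unedited samples give zero efficacy, not NA", {
  ref <- canonicalRef()
  g <- canonicalGuide(ref)
  sim <- simulateReads(ref, g, readSimConfig(n_reads = 400, seed = 21))
  q <- quantifySample(sim, ref, g)
  expect_identical(efficacyPercent(q), 0)
  expect_gt(classCounts(q)[["mutant_unedited"]], 0)
  expect_identical(sum(classCounts(q)), q@total)
})

test_that("in-frame-only editing yields zero efficacy with excluded reads", {
  ref <- canonicalRef()
  g <- canonicalGuide(ref)
  w3 <- c("-3" = 1)
  sim <- simulateReads(ref, g, readSimConfig(
    n_reads = 500, editing_rate_mutant = 0.4, indel_length_weights = w3,
    seed = 22))
  q <- quantifySample(sim, ref, g)
  expect_identical(efficacyPercent(q), 0)
  expect_gt(classCounts(q)[["mutant_excluded"]], 0)
  expect_identical(classCounts(q)[["mutant_edited"]], 0L)
})

test_that("estimated efficacy tracks the truth table at moderate depth", {
  ref <- canonicalRef()
  g <- canonicalGuide(ref)
  sim <- simulateReads(ref, g, readSimConfig(
    n_reads = 5000, editing_rate_mutant = 0.05,
    substitution_error_rate = 0.001, seed = 23))
  q <- quantifySample(sim, ref, g, return_read_classes = TRUE)
  tr <- sim$truth
  mut <- tr$allele == "mutant"
  oof <- mut & tr$edited & abs(tr$indel_len) <= 8 & tr$indel_len %% 3 != 0
  truth_eff <- 100 * sum(oof) / sum(mut)
  p <- truth_eff / 100
  se <- 100 * sqrt(p * (1 - p) / sum(mut))
  expect_lt(abs(efficacyPercent(q$result) - truth_eff), 3 * se + 1e-9)
})

test_that("error-free samples are classified in perfect agreement with truth", {
  ref <- canonicalRef()
  g <- canonicalGuide(ref)
  sim <- simulateReads(ref, g, readSimConfig(
    n_reads = 2000, editing_rate_mutant = 0.2, editing_rate_wt = 0.05,
    seed = 24))
  q <- quantifySample(sim, ref, g, return_read_classes = TRUE)
  tr <- sim$truth
  expected <- ifelse(tr$allele == "wt", "wt",
    ifelse(!tr$edited, "mutant_unedited",
      ifelse(abs(tr$indel_len) <= 8 & tr$indel_len %% 3 != 0,
             "mutant_edited", "mutant_excluded")))
  expect_identical(q$read_classes$class, expected)
})

test_that("substitution errors alone never create edited calls", {
  ref <- canonicalRef()
  g <- canonicalGuide(ref)
  edited_at <- vapply(c(0, 0.005, 0.02), function(e) {
    sim <- simulateReads(ref, g, readSimConfig(
      n_reads = 2000, substitution_error_rate = e, seed = 25))
    classCounts(quantifySample(sim, ref, g))[["mutant_edited"]]
  }, integer(1))
  expect_identical(edited_at, c(0L, 0L, 0L))
})

test_that("a marker-free read pool flags efficacy as undefined", {
  ref <- canonicalRef()
  g <- canonicalGuide(ref)
  sim <- simulateReads(ref, g, readSimConfig(
    n_reads = 50, allele_fraction_mutant = 0, seed = 26))
  q <- quantifySample(sim, ref, g)
  expect_true(is.na(efficacyPercent(q)))
  expect_match(q@flags, "undefined", all = FALSE)
})

test_that("the efficacy denominator is configurable", {
  ref <- canonicalRef()
  g <- canonicalGuide(ref)
  sim <- simulateReads(ref, g, readSimConfig(
    n_reads = 2000, editing_rate_mutant = 0.3, seed = 27))
  qm <- quantifySample(sim, ref, g, quantConfig(denominator = "mutant"))
  qa <- quantifySample(sim, ref, g, quantConfig(denominator = "classified"))
  cc <- classCounts(qm)
  mut <- sum(cc[c("mutant_edited", "mutant_unedited", "mutant_excluded")])
  expect_equal(efficacyPercent(qm), 100 * cc[["mutant_edited"]] / mut)
  expect_equal(efficacyPercent(qa),
               100 * cc[["mutant_edited"]] / (sum(cc) - cc[["discarded"]]))
  expect_lt(efficacyPercent(qa), efficacyPercent(qm))
})

test_that("background correction subtracts control efficacy and floors at 0", {
  ref <- canonicalRef()
  g <- canonicalGuide(ref)
  mk <- function(rate, seed) {
    quantifySample(simulateReads(ref, g, readSimConfig(
      n_reads = 1500, editing_rate_mutant = rate, seed = seed)), ref, g)
  }
  inj <- mk(0.05, 31)
  ctl0 <- mk(0, 32)
  bc <- backgroundCorrect(inj, ctl0)
  expect_identical(bc$corrected_efficacy, efficacyPercent(inj))

  ctl <- mk(0.01, 33)
  bc2 <- backgroundCorrect(inj, ctl)
  expect_equal(bc2$corrected_efficacy,
               efficacyPercent(inj) - efficacyPercent(ctl))
  expect_false(bc2$floored)

  expect_warning(bc3 <- backgroundCorrect(ctl, inj), "floored")
  expect_identical(bc3$corrected_efficacy, 0)
  expect_true(bc3$floored)

  # mismatched configuration is refused
  other <- quantifySample(simulateReads(ref, g, readSimConfig(
    n_reads = 200, seed = 34)), ref, g, quantConfig(window_halfwidth = 8))
  expect_error(backgroundCorrect(inj, other), "different")
})
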