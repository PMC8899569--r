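freqNamed <- function(v) stats::setNames(v, c("6", "12", "18", "24", "30"))

test_that("mean ABR improvement averages contralateral minus injected", {
  expect_identical(abrImprovement(freqNamed(rep(80, 5)), freqNamed(rep(80, 5))), 0)
  expect_identical(abrImprovement(freqNamed(rep(75, 5)), freqNamed(rep(90, 5))), 15)
  inj <- freqNamed(c(70, 75, 80, 80, 85))
  con <- inj + c(20, 15, 10, 10, 5)
  expect_identical(abrImprovement(inj, con), 12)
  expect_error(abrImprovement(inj[-2], con), "12")
})

test_that("improvement categories use half-open boundaries with 5 dB mild", {
  got <- categorizeImprovement(c(16, 12, 3, 4.999, 5, 9.999, 10, 14.999, 15, -4))
  expect_identical(as.character(got),
                   c("marked", "moderate", "minimal", "minimal", "mild",
                     "mild", "moderate", "moderate", "marked", "minimal"))
  expect_identical(levels(got), c("marked", "moderate", "mild", "minimal"))
})

test_that("correlation matches the closed-form Pearson formula", {
  expect_equal(correlateEfficacyImprovement(1:5, 2 * (1:5) + 3)$r, 1)
  expect_equal(correlateEfficacyImprovement(1:5, -2 * (1:5))$r, -1)
  set.seed(61)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  got <- correlateEfficacyImprovement(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r_manual * sqrt((30 - 2) / (1 - r_manual^2))
  p_manual <- 2 * stats::pt(-abs(tstat), df = 28)
  expect_equal(got$r, r_manual, tolerance = 1e-12)
  expect_equal(got$p_value, p_manual, tolerance = 1e-12)
  expect_identical(got$n, 30L)
  expect_error(correlateEfficacyImprovement(1:2, 1:2), "at least 3")
  expect_error(correlateEfficacyImprovement(rep(1, 5), 1:5), "variance")
})

test_that("per-category summaries keep the fixed marked-to-minimal order", {
  empty <- efficacyByCategory(numeric(0), factor(character(0)))
  expect_identical(as.character(empty$category),
                   c("marked", "moderate", "mild", "minimal"))
  expect_identical(empty$n, rep(0L, 4))

  one <- efficacyByCategory(c(1, 2), categorizeImprovement(c(20, 30)))
  expect_identical(one$n, c(2L, 0L, 0L, 0L))
  expect_equal(one$mean_efficacy[1], 1.5)

  # strong dose-response cohorts order group means marked >= ... >= minimal
  cfg <- cohortSimConfig(n_mice = 60, efficacy_mean = 1, efficacy_sd = 0.6,
                         db_per_percent = 12, noise_sd_db = 0.5, seed = 62)
  sim <- simulateCohort(cfg)
  rec <- cohortImprovement(sim$records)
  byc <- efficacyByCategory(rec$efficacy_percent,
                            categorizeImprovement(rec$mean_shift_db))
  means <- byc$mean_efficacy[byc$n > 0]
  expect_true(all(diff(means) <= 0))
})

test_that("cohort simulation recovers a tuned population correlation", {
  # small replicate check; the full 500-replicate version is in acceptance
  cfg <- cohortSimConfig(n_mice = 20, seed = NULL)  # defaults tune r = 0.5
  set.seed(63)
  r <- replicate(60, {
    sim <- simulateCohort(cfg)
    rec <- cohortImprovement(sim$records)
    correlateEfficacyImprovement(rec$efficacy_percent, rec$mean_shift_db)$r
  })
  expect_lt(abs(mean(r) - 0.5), 0.1)
})

test_that("phenotypeSummary assembles shifts, categories and correlation", {
  sim <- simulateCohort(cohortSimConfig(n_mice = 15, seed = 64))
  out <- phenotypeSummary(sim$records)
  expect_true(all(c("mean_shift_db", "category") %in% names(out$records)))
  expect_true(abs(out$correlation$r) <= 1)
  expect_identical(nrow(out$by_category), 4L)
})
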