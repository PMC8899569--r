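#' @importFrom stats cor.test sd aov lm coef
NULL

.CATEGORY_LEVELS <- c("marked", "moderate", "mild", "minimal")

#' Mean ABR threshold improvement for one animal
#'
#' The hearing improvement of an injected ear is the mean, over the stimulus
#' frequencies, of `contralateral - injected` threshold (dB SPL); positive
#' values mean better hearing in the injected ear.
#'
#' @param injected,contralateral numeric thresholds named by frequency (kHz).
#' @param frequencies frequencies to average (default 6, 12, 18, 24, 30 kHz).
#' @return mean shift in dB.
#' @examples
#' abrImprovement(
#'   injected = c("6" = 75, "12" = 75, "18" = 75, "24" = 75, "30" = 75),
#'   contralateral = c("6" = 90, "12" = 90, "18" = 90, "24" = 90, "30" = 90))
#' @export
abrImprovement <- function(injected, contralateral,
                           frequencies = c(6, 12, 18, 24, 30)) {
  want <- as.character(frequencies)
  miss <- c(setdiff(want, names(injected)), setdiff(want, names(contralateral)))
  if (length(miss)) {
    stop("missing frequencies (kHz): ", paste(unique(miss), collapse = ", "))
  }
  mean(contralateral[want] - injected[want])
}

#' Per-mouse mean ABR shift for a cohort table
#'
#' Applies [abrImprovement()] to each row of a wide cohort table (columns
#' `injected_<kHz>` and `contra_<kHz>`, as produced by [simulateCohort()]).
#'
#' @param records wide cohort data.frame.
#' @param frequencies frequencies to average, kHz.
#' @return `records` with a `mean_shift_db` column appended.
#' @export
cohortImprovement <- function(records, frequencies = c(6, 12, 18, 24, 30)) {
  icol <- paste0("injected_", frequencies)
  ccol <- paste0("contra_", frequencies)
  miss <- setdiff(c(icol, ccol), names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  records$mean_shift_db <- rowMeans(records[ccol]) - rowMeans(records[icol])
  records
}

#' Categorize hearing improvement
#'
#' Mean shifts are binned as marked (>= 15 dB), moderate (10-14 dB), mild
#' (5-9 dB) and minimal (< 5 dB), implemented as half-open intervals
#' `[15, Inf)`, `[10, 15)`, `[5, 10)`, `(-Inf, 5)`; a shift of exactly 5 dB
#' is mild, and negative shifts are minimal. Non-integer shifts use the same
#' intervals without rounding.
#'
#' @param mean_shift_db numeric mean shift(s), dB; vectorized.
#' @return factor with levels marked, moderate, mild, minimal.
#' @examples
#' categorizeImprovement(c(16, 12, 5, 3))
#' @export
categorizeImprovement <- function(mean_shift_db) {
  if (any(!is.finite(mean_shift_db))) stop("mean shift must be finite")
  f <- cut(mean_shift_db, breaks = c(-Inf, 5, 10, 15, Inf), right = FALSE,
           labels = c("minimal", "mild", "moderate", "marked"))
  factor(as.character(f), levels = .CATEGORY_LEVELS)
}

#' Correlate editing efficacy with hearing improvement
#'
#' Standard Pearson correlation with a two-sided t-approximation p-value
#' (via [stats::cor.test()]).
#'
#' @param efficacy_percent per-mouse editing efficacy, percent.
#' @param mean_shift_db per-mouse mean ABR shift, dB.
#' @return list with `r`, `n`, `p_value`.
#' @examples
#' correlateEfficacyImprovement(1:5, c(2, 4, 6, 8, 10))$r  # 1
#' @export
correlateEfficacyImprovement <- function(efficacy_percent, mean_shift_db) {
  stopifnot(length(efficacy_percent) == length(mean_shift_db))
  keep <- is.finite(efficacy_percent) & is.finite(mean_shift_db)
  x <- efficacy_percent[keep]
  y <- mean_shift_db[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete (efficacy, shift) pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in efficacy or shift; correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), n = n, p_value = ct$p.value)
}

#' Editing efficacy summarized by improvement category
#'
#' @param efficacy_percent per-mouse efficacy, percent.
#' @param category factor from [categorizeImprovement()] (or coercible).
#' @return data.frame in fixed order marked, moderate, mild, minimal with
#'   columns `category`, `n`, `mean_efficacy`, `sd_efficacy`; empty groups
#'   have `n = 0` and `NA` summaries.
#' @export
efficacyByCategory <- function(efficacy_percent, category) {
  category <- factor(as.character(category), levels = .CATEGORY_LEVELS)
  stopifnot(length(efficacy_percent) == length(category))
  out <- lapply(.CATEGORY_LEVELS, function(k) {
    e <- efficacy_percent[!is.na(category) & category == k]
    data.frame(category = k, n = length(e),
               mean_efficacy = if (length(e)) mean(e) else NA_real_,
               sd_efficacy = if (length(e) > 1L) sd(e) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$category <- factor(out$category, levels = .CATEGORY_LEVELS)
  out
}

#' Full phenotype summary for a cohort table
#'
#' Convenience wrapper: computes per-mouse mean shifts, categories, the
#' efficacy-improvement Pearson correlation and the per-category efficacy
#' summary. Group-comparison tests (ANOVA across categories) are reported as
#' convenience output via [stats::aov()].
#'
#' @param records wide cohort data.frame with an `efficacy_percent` column.
#' @param frequencies frequencies to average, kHz.
#' @return list with `records` (shift + category columns appended),
#'   `correlation`, `by_category`, and `anova_p` (or `NA` when not testable).
#' @export
phenotypeSummary <- function(records, frequencies = c(6, 12, 18, 24, 30)) {
  records <- cohortImprovement(records, frequencies)
  records$category <- categorizeImprovement(records$mean_shift_db)
  corr <- correlateEfficacyImprovement(records$efficacy_percent,
                                       records$mean_shift_db)
  byc <- efficacyByCategory(records$efficacy_percent, records$category)
  anova_p <- NA_real_
  used <- droplevels(records$category)
  if (nlevels(used) >= 2L) {
    fit <- aov(efficacy_percent ~ category, data = records)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  }
  list(records = records, correlation = corr, by_category = byc,
       anova_p = anova_p)
}
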