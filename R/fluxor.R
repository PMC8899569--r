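#' @importFrom stats pairwise.t.test
NULL

#' Extract ROI traces from an image time series
#'
#' Per region of interest (ROI) and frame, the trace value is the mean pixel
#' intensity inside the ROI mask; timestamps come from the frame interval,
#' with t = 0 at the first frame (the thallium stimulus).
#'
#' @param stack numeric array `rows x cols x frames` (single channel).
#' @param roi_masks named list of logical matrices matching the frame
#'   dimensions; masks must be nonempty and within frame bounds.
#' @param frame_interval_s seconds between frames.
#' @param groups optional named character vector mapping ROI name to group
#'   label (defaults to `"all"`).
#' @return long data.frame: roi, group, t, F.
#' @examples
#' sim <- simulateFlux(fluxSimConfig(n_rois = 1, seed = 1), as_stack = TRUE)
#' tr <- extractTraces(sim$stack, sim$masks, sim$frame_interval_s)
#' all.equal(tr$F, sim$traces$F)
#' @export
extractTraces <- function(stack, roi_masks, frame_interval_s, groups = NULL) {
  stopifnot(length(dim(stack)) == 3L, frame_interval_s > 0)
  if (is.null(names(roi_masks))) {
    names(roi_masks) <- sprintf("roi%02d", seq_along(roi_masks))
  }
  nf <- dim(stack)[3L]
  tt <- (seq_len(nf) - 1L) * frame_interval_s
  out <- lapply(names(roi_masks), function(nm) {
    m <- roi_masks[[nm]]
    if (!is.logical(m) || !all(dim(m) == dim(stack)[1:2])) {
      stop("ROI mask '", nm, "' does not match the frame dimensions")
    }
    if (!any(m)) stop("ROI mask '", nm, "' is empty")
    f <- vapply(seq_len(nf), function(k) mean(stack[, , k][m]), numeric(1))
    g <- if (is.null(groups)) "all" else unname(groups[[nm]])
    data.frame(roi = nm, group = g, t = tt, F = f, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize one thallium-flux trace
#'
#' Computes the baseline `F0` (fluorescence at t = 0, nearest sample, or the
#' mean of all pre-stimulus samples with `f0_mode = "prestim_mean"`), the
#' normalized change `delta_f_ratio = (F(t_end) - F0) / F0` over the
#' recording, and the influx slope from an ordinary least-squares fit of F
#' against t on `[0, t_end]`, with its standard error.
#'
#' @param t timestamps, seconds (strictly increasing; t = 0 present or
#'   bracketed).
#' @param F fluorescence values, arbitrary units.
#' @param t_end end of the analysis window, seconds (default 120).
#' @param f0_mode `"at_zero"` (default) or `"prestim_mean"`.
#' @return list: `f0`, `delta_f_ratio`, `slope`, `slope_se`, `flag`
#'   (character; e.g. non-positive F0 makes the ratio undefined).
#' @examples
#' t <- seq(0, 120, by = 2)
#' summarizeTrace(t, 100 + 0.5 * t)$delta_f_ratio  # 0.6
#' @export
summarizeTrace <- function(t, F, t_end = 120,
                           f0_mode = c("at_zero", "prestim_mean")) {
  f0_mode <- match.arg(f0_mode)
  stopifnot(length(t) == length(F), length(t) >= 2L, all(is.finite(t)),
            all(is.finite(F)), all(diff(t) > 0))
  if (min(t) > 0 || max(t) < t_end) {
    stop("trace must cover [0, t_end]")
  }
  f0 <- if (f0_mode == "at_zero") F[which.min(abs(t))] else mean(F[t <= 0])
  f_end <- F[which.min(abs(t - t_end))]
  flag <- character(0)
  ratio <- if (f0 > 0) (f_end - f0) / f0 else {
    flag <- c(flag, "non-positive F0; delta_f_ratio undefined")
    NA_real_
  }
  win <- t >= 0 & t <= t_end
  tw <- t[win]; fw <- F[win]
  fit <- lm(fw ~ tw)
  slope <- unname(coef(fit)[2L])
  # standard error computed directly (avoids summary.lm noise on exact fits)
  n <- length(tw)
  sxx <- sum((tw - mean(tw))^2)
  sigma2 <- sum(fit$residuals^2) / (n - 2L)
  list(f0 = f0, delta_f_ratio = ratio, slope = slope,
       slope_se = sqrt(sigma2 / sxx), flag = flag)
}

#' Summarize every trace in a trace table
#'
#' @param traces long data.frame (roi, group, t, F), as from
#'   [simulateFlux()] or [extractTraces()].
#' @param t_end,f0_mode passed to [summarizeTrace()].
#' @return data.frame: roi, group, f0, delta_f_ratio, slope, slope_se.
#' @export
summarizeTraces <- function(traces, t_end = 120,
                            f0_mode = c("at_zero", "prestim_mean")) {
  f0_mode <- match.arg(f0_mode)
  rois <- unique(traces$roi)
  out <- lapply(rois, function(r) {
    d <- traces[traces$roi == r, , drop = FALSE]
    s <- summarizeTrace(d$t, d$F, t_end = t_end, f0_mode = f0_mode)
    data.frame(roi = r, group = d$group[1L], f0 = s$f0,
               delta_f_ratio = s$delta_f_ratio, slope = s$slope,
               slope_se = s$slope_se, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare thallium-influx summaries between groups
#'
#' Per-group mean and sd of the normalized fluorescence change and influx
#' slope, in deterministic (alphabetical, or factor-level) group order, plus
#' convenience significance tests: one-way ANOVA across groups and pairwise
#' Welch t-tests (Bonferroni-adjusted) on both quantities. Empty groups are
#' dropped with a warning.
#'
#' @param summaries data.frame from [summarizeTraces()].
#' @return list: `by_group` (n, mean/sd of ratio and slope),
#'   `anova_p_ratio`, `anova_p_slope`, `pairwise_p_ratio`,
#'   `pairwise_p_slope` (matrices or `NULL` when fewer than 2 groups).
#' @export
compareGroups <- function(summaries) {
  g <- summaries$group
  lev <- if (is.factor(g)) levels(g) else sort(unique(g))
  present <- lev[lev %in% g]
  if (length(present) < length(lev)) {
    warning("dropping empty group(s): ",
            paste(setdiff(lev, present), collapse = ", "))
  }
  if (length(present) < 2L) stop("need at least 2 nonempty groups")
  by_group <- do.call(rbind, lapply(present, function(k) {
    d <- summaries[g == k, , drop = FALSE]
    data.frame(group = k, n = nrow(d),
               mean_ratio = mean(d$delta_f_ratio),
               sd_ratio = sd(d$delta_f_ratio),
               mean_slope = mean(d$slope), sd_slope = sd(d$slope),
               stringsAsFactors = FALSE)
  }))
  gf <- factor(g, levels = present)
  p1 <- summary(aov(summaries$delta_f_ratio ~ gf))[[1]][["Pr(>F)"]][1]
  p2 <- summary(aov(summaries$slope ~ gf))[[1]][["Pr(>F)"]][1]
  pw1 <- pairwise.t.test(summaries$delta_f_ratio, gf, pool.sd = FALSE,
                         p.adjust.method = "bonferroni")$p.value
  pw2 <- pairwise.t.test(summaries$slope, gf, pool.sd = FALSE,
                         p.adjust.method = "bonferroni")$p.value
  list(by_group = by_group, anova_p_ratio = p1, anova_p_slope = p2,
       pairwise_p_ratio = pw1, pairwise_p_slope = pw2)
}
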