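#' @importFrom stats rnorm rbinom runif
NULL

# run expr with a temporary RNG state seeded by `seed` (NULL = use current
# stream); restores the caller's .Random.seed afterwards
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Default Cas9 indel length weights
#'
#' A simple NHEJ-like spectrum over signed lengths -8..-1 and +1..+8:
#' +1 insertions dominate, deletion weight declines with length, longer
#' insertions are rare. Any nonnegative, not-all-zero named weight vector
#' (names = signed lengths, zero excluded) can be supplied instead; lengths
#' beyond 8 bp are permitted to exercise the classifier's exclusion rule.
#'
#' @return named numeric vector of weights.
#' @export
defaultIndelWeights <- function() {
  w <- c(8:1, 12, rep(0.5, 7))
  names(w) <- c(as.character(-1:-8), as.character(1:8))
  w[order(as.integer(names(w)))]
}

#' Fraction of simulated indels that count as out-of-frame edits
#'
#' Given indel length weights, the probability that a drawn lesion has
#' `min_len <= |L| <= max_len` and `L` not a multiple of 3 — i.e. would be
#' counted as an edited mutant allele by the classifier. Useful to convert
#' between the lesion rate of the simulator and the expected measured
#' editing efficacy: `efficacy = lesion_rate * outOfFrameFraction(weights)`.
#'
#' @param weights named signed-length weights (see [defaultIndelWeights()]).
#' @param min_len,max_len classifier length bounds.
#' @return proportion in `[0, 1]`.
#' @export
outOfFrameFraction <- function(weights = defaultIndelWeights(),
                               min_len = 1L, max_len = 8L) {
  lens <- as.integer(names(weights))
  ok <- abs(lens) >= min_len & abs(lens) <= max_len & lens %% 3L != 0L
  sum(weights[ok]) / sum(weights)
}

#' Configuration for the amplicon read simulator
#'
#' @param n_reads number of reads to draw.
#' @param read_length read length in nt; reads longer than the (edited)
#'   template are truncated to the full template.
#' @param allele_fraction_mutant proportion of reads drawn from the mutant
#'   allele (0.5 for a heterozygote).
#' @param editing_rate_mutant,editing_rate_wt per-allele probability that a
#'   read carries a Cas9-induced indel at the guide cut site.
#' @param indel_length_weights named nonnegative weights over signed indel
#'   lengths; see [defaultIndelWeights()].
#' @param substitution_error_rate per-base substitution sequencing-error
#'   probability, applied after editing.
#' @param quality_char single FASTQ quality character used for every base
#'   (default "F", Q37).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return validated config list of class `ReadSimConfig`.
#' @export
readSimConfig <- function(n_reads = 10000L, read_length = 150L,
                          allele_fraction_mutant = 0.5,
                          editing_rate_mutant = 0, editing_rate_wt = 0,
                          indel_length_weights = defaultIndelWeights(),
                          substitution_error_rate = 0,
                          quality_char = "F", seed = NULL) {
  stopifnot(n_reads >= 1L, read_length >= 1L)
  probs <- c(allele_fraction_mutant, editing_rate_mutant, editing_rate_wt,
             substitution_error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  w <- indel_length_weights
  lens <- suppressWarnings(as.integer(names(w)))
  if (length(w) == 0L || any(is.na(lens)) || any(lens == 0L)) {
    stop("indel_length_weights must be named by nonzero signed integer lengths")
  }
  if (any(w < 0)) stop("indel weights must be nonnegative")
  if ((editing_rate_mutant > 0 || editing_rate_wt > 0) && sum(w) == 0) {
    stop("editing requested but all indel length weights are zero")
  }
  stopifnot(nchar(quality_char) == 1L)
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 allele_fraction_mutant = allele_fraction_mutant,
                 editing_rate_mutant = editing_rate_mutant,
                 editing_rate_wt = editing_rate_wt,
                 indel_length_weights = w,
                 substitution_error_rate = substitution_error_rate,
                 quality_char = quality_char, seed = seed),
            class = "ReadSimConfig")
}

.applyIndel <- function(seqchar, cut, len) {
  # left breakpoint of the lesion is the cut site (base `cut` is the last
  # unchanged base); deletions remove cut+1 .. cut+|len|, insertions add
  # `len` random bases after `cut`
  n <- nchar(seqchar)
  if (len < 0) {
    if (cut - len > n) stop("deletion of ", -len, " nt does not fit after cut offset ", cut)
    paste0(substr(seqchar, 1L, cut), substr(seqchar, cut - len + 1L, n))
  } else {
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    paste0(substr(seqchar, 1L, cut), ins, substr(seqchar, cut + 1L, n))
  }
}

.substituteErrors <- function(seqchar, n_err) {
  ch <- strsplit(seqchar, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(ch), n_err)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate amplicon sequencing reads with ground truth
#'
#' Draws single-end reads from a heterozygous two-allele amplicon. Each read
#' comes from the mutant or wild-type allele; with the per-allele editing
#' rate it carries exactly one indel whose left breakpoint is the guide cut
#' site, with signed length drawn from the configured weights (insertions use
#' random bases from the seeded stream). Substitution sequencing errors are
#' applied uniformly after editing. Reads always cover the marker base and the
#' cut-site window; with the default read length (longer than the amplicon)
#' each read is the full edited template.
#'
#' @param ref an [AmpliconReference-class].
#' @param guide one-row guide data.frame (see [enumerateGuides()]).
#' @param cfg a [readSimConfig()].
#' @return list of class `ampliconReadSim` with elements `reads`
#'   (named [Biostrings::DNAStringSet]), `qualities` (character vector),
#'   `truth` (data.frame: read_id, allele, edited, indel_len, indel_left,
#'   read_start) and `config`.
#' @examples
#' ref <- kcnq4W276SAmplicon()
#' g <- enumerateGuides(ref, require_variant_overlap = TRUE)[1, ]
#' sim <- simulateReads(ref, g, readSimConfig(n_reads = 50, seed = 1))
#' table(sim$truth$allele)
#' @export
simulateReads <- function(ref, guide, cfg = readSimConfig()) {
  stopifnot(inherits(cfg, "ReadSimConfig"))
  validObject(ref)
  cut <- guideCutSite(guide)
  mutseq <- as.character(refSequence(ref))
  L <- nchar(mutseq)
  if (cut < 1L || cut >= L) stop("guide cut site outside the amplicon")
  wtseq <- if (nrow(alleleSites(ref))) wtSequence(ref, as = "character") else mutseq
  lens <- as.integer(names(cfg$indel_length_weights))
  maxdel <- max(c(0L, -lens[lens < 0]))
  if (cut + maxdel > L) {
    stop("largest deletion (", maxdel, " nt) does not fit 3' of the cut site")
  }
  site_off <- alleleSites(ref)$offset
  req_lo <- max(1L, min(c(site_off, cut)) - 1L)

  .withSeed(cfg$seed, {
    n <- cfg$n_reads
    allele <- ifelse(runif(n) < cfg$allele_fraction_mutant, "mutant", "wt")
    rate <- ifelse(allele == "mutant", cfg$editing_rate_mutant, cfg$editing_rate_wt)
    edited <- runif(n) < rate
    wpos <- sum(cfg$indel_length_weights) > 0
    reads <- character(n)
    starts <- integer(n)
    indel_len <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      tmpl <- if (allele[i] == "mutant") mutseq else wtseq
      if (edited[i]) {
        l <- lens[sample.int(length(lens), 1L, prob = cfg$indel_length_weights)]
        indel_len[i] <- l
        tmpl <- .applyIndel(tmpl, cut, l)
      }
      tl <- nchar(tmpl)
      if (cfg$read_length >= tl) {
        st <- 1L
        rd <- tmpl
      } else {
        req_hi <- min(tl, cut + 12L)
        lo <- max(1L, req_hi - cfg$read_length + 1L)
        hi <- min(req_lo, tl - cfg$read_length + 1L)
        if (lo > hi) {
          stop("read_length = ", cfg$read_length, " cannot cover the marker ",
               "and cut-site window on this amplicon")
        }
        st <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        rd <- substr(tmpl, st, st + cfg$read_length - 1L)
      }
      starts[i] <- st
      reads[i] <- rd
    }
    if (cfg$substitution_error_rate > 0) {
      nerr <- rbinom(n, nchar(reads), cfg$substitution_error_rate)
      for (i in which(nerr > 0L)) reads[i] <- .substituteErrors(reads[i], nerr[i])
    }
    ids <- sprintf("read%06d", seq_len(n))
    dss <- DNAStringSet(reads)
    names(dss) <- ids
    truth <- data.frame(read_id = ids, allele = allele, edited = edited,
                        indel_len = indel_len,
                        indel_left = ifelse(edited, cut, NA_integer_),
                        read_start = starts, stringsAsFactors = FALSE)
    structure(list(reads = dss,
                   qualities = strrep(cfg$quality_char, nchar(reads)),
                   truth = truth, config = cfg, cut_offset = cut),
              class = "ampliconReadSim")
  })
}

#' Write simulated reads as 4-line FASTQ
#'
#' @param sim result of [simulateReads()].
#' @param path output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(sim, path) {
  q <- Biostrings::BStringSet(sim$qualities)
  Biostrings::writeXStringSet(sim$reads, path, format = "fastq",
                              compress = grepl("\\.gz$", path), qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] (qualities are not used
#' by the quantification pipeline by default).
#'
#' @param path FASTQ path (optionally gzipped).
#' @return a named [Biostrings::DNAStringSet].
#' @export
readFastqReads <- function(path) {
  readDNAStringSet(path, format = "fastq")
}

#' Closed-form threshold noise for a target efficacy-improvement correlation
#'
#' In the linear-plus-noise cohort model the per-mouse mean ABR shift is
#' `b * e + mean over k frequencies of (noise_contra - noise_injected)`, so
#' the population Pearson correlation between efficacy `e` and mean shift is
#' `r = b*sd(e) / sqrt(b^2 sd(e)^2 + 2 sigma^2 / k)`. This inverts that for
#' the per-frequency threshold noise sigma.
#'
#' @param r target population correlation in (0, 1).
#' @param db_per_percent slope b, dB of improvement per percent efficacy.
#' @param efficacy_sd sd of the efficacy distribution, percent.
#' @param n_frequencies number of averaged frequencies k.
#' @return per-frequency threshold noise sd, dB.
#' @examples
#' cohortNoiseForCorrelation(0.5, 10, 0.25)
#' @export
cohortNoiseForCorrelation <- function(r, db_per_percent, efficacy_sd,
                                      n_frequencies = 5L) {
  stopifnot(r > 0, r < 1, db_per_percent != 0, efficacy_sd > 0)
  abs(db_per_percent) * efficacy_sd * sqrt(n_frequencies / 2) * sqrt(1 / r^2 - 1)
}

# sd of a Normal(mean, sd) left-truncated at zero (closed form)
.truncatedSdAtZero <- function(mean, sd) {
  if (sd == 0) return(0)
  a <- (0 - mean) / sd
  lambda <- stats::dnorm(a) / (1 - stats::pnorm(a))
  sd * sqrt(1 + a * lambda - lambda^2)
}

#' Configuration for the mouse cohort simulator
#'
#' Emulates a gene-edited cohort in which per-mouse editing efficacy drives a
#' linear improvement of injected-ear ABR thresholds over the contralateral
#' ear, plus Gaussian measurement noise per ear and frequency. Thresholds are
#' clamped to the instrument range (95 dB SPL encodes "no response").
#'
#' @param n_mice cohort size (>= 3, for correlation estimates).
#' @param efficacy_mean,efficacy_sd editing-efficacy distribution, percent
#'   (Gaussian truncated at 0).
#' @param db_per_percent dB of threshold improvement per percent efficacy.
#' @param noise_sd_db per-frequency threshold noise sd; `NULL` derives it
#'   from [cohortNoiseForCorrelation()] for a population r of 0.5.
#' @param frequencies stimulus frequencies, kHz.
#' @param baseline_thresholds untreated thresholds per frequency, dB SPL.
#' @param range instrument range, dB SPL.
#' @param seed integer seed or `NULL`.
#' @return config list of class `CohortSimConfig`.
#' @export
cohortSimConfig <- function(n_mice = 20L, efficacy_mean = 0.5,
                            efficacy_sd = 0.25, db_per_percent = 10,
                            noise_sd_db = NULL,
                            frequencies = c(6, 12, 18, 24, 30),
                            baseline_thresholds = c(60, 65, 70, 75, 80),
                            range = c(10, 95), seed = NULL) {
  stopifnot(n_mice >= 3L, efficacy_sd >= 0, length(frequencies) >= 1L,
            length(baseline_thresholds) == length(frequencies),
            length(range) == 2L, range[1] < range[2])
  if (is.null(noise_sd_db)) {
    noise_sd_db <- if (efficacy_sd > 0 && db_per_percent != 0) {
      # the generative efficacy distribution is truncated at 0, so the tuning
      # uses its actual (truncated) sd, not the nominal Gaussian sd
      cohortNoiseForCorrelation(0.5, db_per_percent,
                                .truncatedSdAtZero(efficacy_mean, efficacy_sd),
                                length(frequencies))
    } else 0
  }
  stopifnot(noise_sd_db >= 0)
  structure(list(n_mice = as.integer(n_mice), efficacy_mean = efficacy_mean,
                 efficacy_sd = efficacy_sd, db_per_percent = db_per_percent,
                 noise_sd_db = noise_sd_db, frequencies = frequencies,
                 baseline_thresholds = baseline_thresholds, range = range,
                 seed = seed),
            class = "CohortSimConfig")
}

#' Simulate a gene-edited mouse cohort with ground truth
#'
#' Per mouse, efficacy is drawn from the configured truncated-Gaussian;
#' the injected-ear threshold at each frequency is
#' `baseline - db_per_percent * efficacy + N(0, noise_sd)` and the
#' contralateral ear is `baseline + independent noise`, both clamped to the
#' instrument range.
#'
#' @param cfg a [cohortSimConfig()].
#' @return list with `records` (wide data.frame: mouse, efficacy_percent, one
#'   `injected_<kHz>` and `contra_<kHz>` column per frequency) and `truth`
#'   (mouse, efficacy, mean_shift_true).
#' @examples
#' sim <- simulateCohort(cohortSimConfig(n_mice = 5, seed = 7))
#' sim$records
#' @export
simulateCohort <- function(cfg = cohortSimConfig()) {
  stopifnot(inherits(cfg, "CohortSimConfig"))
  .withSeed(cfg$seed, {
    n <- cfg$n_mice
    eff <- rnorm(n, cfg$efficacy_mean, cfg$efficacy_sd)
    while (any(bad <- eff < 0)) {  # truncation at 0 by rejection
      eff[bad] <- rnorm(sum(bad), cfg$efficacy_mean, cfg$efficacy_sd)
    }
    k <- length(cfg$frequencies)
    inj <- con <- matrix(NA_real_, n, k)
    for (j in seq_len(k)) {
      inj[, j] <- cfg$baseline_thresholds[j] - cfg$db_per_percent * eff +
        rnorm(n, 0, cfg$noise_sd_db)
      con[, j] <- cfg$baseline_thresholds[j] + rnorm(n, 0, cfg$noise_sd_db)
    }
    inj <- pmin(pmax(inj, cfg$range[1]), cfg$range[2])
    con <- pmin(pmax(con, cfg$range[1]), cfg$range[2])
    colnames(inj) <- paste0("injected_", cfg$frequencies)
    colnames(con) <- paste0("contra_", cfg$frequencies)
    ids <- sprintf("m%03d", seq_len(n))
    records <- data.frame(mouse = ids, efficacy_percent = eff, inj, con,
                          stringsAsFactors = FALSE)
    truth <- data.frame(mouse = ids, efficacy = eff,
                        mean_shift_true = cfg$db_per_percent * eff,
                        stringsAsFactors = FALSE)
    list(records = records, truth = truth,
         degenerate = cfg$efficacy_sd == 0)
  })
}

#' Simulate T7E1 gel densitometry for a known variant frequency
#'
#' Inverts the heteroduplex-cleavage relationship: at variant frequency p (%)
#' the expected cleaved fraction is `1 - (1 - p/100)^2` (the probability that
#' a reannealed duplex is a mismatched heteroduplex). Densities are scaled to
#' sum to 1, then perturbed with Gaussian noise and clipped at zero.
#'
#' @param true_frequency_percent variant frequency in `[0, 100]`.
#' @param density_noise_sd Gaussian noise sd on each band density.
#' @param seed integer seed or `NULL`.
#' @return list with `cleaved_density`, `uncut_density` and
#'   `fraction_cleaved_true`.
#' @examples
#' simulateT7e1(50)  # noiseless cleaved fraction 0.75
#' @export
simulateT7e1 <- function(true_frequency_percent, density_noise_sd = 0,
                         seed = NULL) {
  p <- true_frequency_percent
  if (!is.finite(p) || p < 0 || p > 100) {
    stop("true_frequency_percent must lie in [0, 100]")
  }
  fc <- 1 - (1 - p / 100)^2
  .withSeed(seed, {
    cleaved <- max(0, fc + rnorm(1, 0, density_noise_sd))
    uncut <- max(0, (1 - fc) + rnorm(1, 0, density_noise_sd))
    list(cleaved_density = cleaved, uncut_density = uncut,
         fraction_cleaved_true = fc)
  })
}

#' Configuration for the thallium-flux trace simulator
#'
#' Emulates FluxOR recordings: per region of interest (ROI), fluorescence
#' follows `F(t) = F0 + slope * t + N(0, noise_sd)` over a fixed-interval
#' 0-120 s recording after the thallium stimulus. Group slopes encode channel
#' activity (an inhibitor control has slope 0).
#'
#' @param n_rois ROIs per group.
#' @param f0_mean,f0_sd baseline fluorescence distribution (arbitrary units).
#' @param slope_by_group named numeric vector of influx slopes, units/s.
#' @param noise_sd per-sample Gaussian noise, units.
#' @param frame_interval_s,duration_s sampling interval and recording length,
#'   seconds.
#' @param seed integer seed or `NULL`.
#' @return config list of class `FluxSimConfig`.
#' @export
fluxSimConfig <- function(n_rois = 8L, f0_mean = 100, f0_sd = 5,
                          slope_by_group = c(WT = 0.5, AAV_injected = 0.3,
                                             non_injected = 0.05,
                                             inhibitor = 0),
                          noise_sd = 0, frame_interval_s = 2,
                          duration_s = 120, seed = NULL) {
  stopifnot(n_rois >= 1L, f0_mean > 0, f0_sd >= 0, noise_sd >= 0,
            frame_interval_s > 0, duration_s >= frame_interval_s,
            length(slope_by_group) >= 1L, !is.null(names(slope_by_group)))
  structure(list(n_rois = as.integer(n_rois), f0_mean = f0_mean,
                 f0_sd = f0_sd, slope_by_group = slope_by_group,
                 noise_sd = noise_sd, frame_interval_s = frame_interval_s,
                 duration_s = duration_s, seed = seed),
            class = "FluxSimConfig")
}

#' Simulate thallium-flux fluorescence traces with ground truth
#'
#' @param cfg a [fluxSimConfig()].
#' @param as_stack also build a single-channel image time series in which each
#'   ROI is a disjoint rectangle whose pixels all carry the trace value, so
#'   ROI pixel means reproduce the trace table exactly; returns the stack and
#'   logical ROI masks alongside the table.
#' @return list with `traces` (long data.frame: roi, group, t, F), `truth`
#'   (roi, group, f0, slope) and, when `as_stack`, `stack` (array
#'   rows x cols x frames), `masks` (named list of logical matrices) and
#'   `frame_interval_s`.
#' @examples
#' sim <- simulateFlux(fluxSimConfig(n_rois = 2, seed = 3))
#' head(sim$traces)
#' @export
simulateFlux <- function(cfg = fluxSimConfig(), as_stack = FALSE) {
  stopifnot(inherits(cfg, "FluxSimConfig"))
  .withSeed(cfg$seed, {
    tt <- seq(0, cfg$duration_s, by = cfg$frame_interval_s)
    groups <- names(cfg$slope_by_group)
    rows <- list()
    truth <- list()
    for (g in groups) {
      for (i in seq_len(cfg$n_rois)) {
        f0 <- rnorm(1, cfg$f0_mean, cfg$f0_sd)
        while (f0 <= 0) f0 <- rnorm(1, cfg$f0_mean, cfg$f0_sd)
        s <- cfg$slope_by_group[[g]]
        f <- f0 + s * tt + rnorm(length(tt), 0, cfg$noise_sd)
        roi <- sprintf("%s_roi%02d", g, i)
        rows[[roi]] <- data.frame(roi = roi, group = g, t = tt, F = f,
                                  stringsAsFactors = FALSE)
        truth[[roi]] <- data.frame(roi = roi, group = g, f0 = f0, slope = s,
                                   stringsAsFactors = FALSE)
      }
    }
    traces <- do.call(rbind, rows)
    rownames(traces) <- NULL
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    out <- list(traces = traces, truth = truth)
    if (as_stack) {
      nroi <- nrow(truth)
      side <- 4L                       # 4x4-pixel ROIs with a 2-px gutter
      percol <- ceiling(sqrt(nroi))
      dim_px <- percol * (side + 2L) + 2L
      stack <- array(0, dim = c(dim_px, dim_px, length(tt)))
      masks <- vector("list", nroi)
      names(masks) <- truth$roi
      for (k in seq_len(nroi)) {
        gr <- (k - 1L) %/% percol
        gc <- (k - 1L) %% percol
        r0 <- gr * (side + 2L) + 3L
        c0 <- gc * (side + 2L) + 3L
        m <- matrix(FALSE, dim_px, dim_px)
        m[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- TRUE
        masks[[k]] <- m
        f <- traces$F[traces$roi == truth$roi[k]]
        for (fr in seq_along(tt)) {
          stack[r0:(r0 + side - 1L), c0:(c0 + side - 1L), fr] <- f[fr]
        }
      }
      out$stack <- stack
      out$masks <- masks
      out$frame_interval_s <- cfg$frame_interval_s
    }
    out
  })
}
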