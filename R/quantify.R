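#' Quantification configuration
#'
#' Parameters of the allele-specific classification rule: the window around
#' the Cas9 cut site in which indels are attributed to nuclease activity, and
#' the out-of-frame length rule (net indel length between
#' `min_out_of_frame_len` and `max_indel_len` bp, not a multiple of 3) that
#' defines an edited mutant read while ruling out sequencing artefacts and
#' in-frame variants.
#'
#' @param window_halfwidth nt either side of the cut site (>= 1).
#' @param min_out_of_frame_len,max_indel_len bounds on `|net indel length|`
#'   for a read to count as edited.
#' @param alignment an [alignmentParams()].
#' @param denominator efficacy denominator: `"mutant"` (all mutant-marker
#'   reads: edited + unedited + excluded, the default) or `"classified"`
#'   (all non-discarded reads).
#' @return list of class `QuantConfig`.
#' @export
quantConfig <- function(window_halfwidth = 5L, min_out_of_frame_len = 1L,
                        max_indel_len = 8L, alignment = alignmentParams(),
                        denominator = c("mutant", "classified")) {
  denominator <- match.arg(denominator)
  stopifnot(window_halfwidth >= 1L, min_out_of_frame_len >= 1L,
            max_indel_len >= min_out_of_frame_len,
            inherits(alignment, "AlignmentParams"))
  structure(list(window_halfwidth = as.integer(window_halfwidth),
                 min_out_of_frame_len = as.integer(min_out_of_frame_len),
                 max_indel_len = as.integer(max_indel_len),
                 alignment = alignment, denominator = denominator),
            class = "QuantConfig")
}

.READ_CLASSES <- c("mutant_edited", "mutant_unedited", "mutant_excluded",
                   "wt", "discarded")

#' Call the allele marker from an aligned read
#'
#' Reads the base aligned to the silent-marker column. The mutant allele is
#' identified exclusively by this phased marker base; only marker-positive
#' reads can contribute to editing efficacy.
#'
#' @param ar an [alignRead()] result.
#' @param ref the [AmpliconReference-class] (must have a marker site).
#' @return one of `"mutant"`, `"wt"`, `"other"` (mismatching base or marker
#'   inside a deletion), or `"uncovered"` (alignment does not span the
#'   marker; such reads are discarded downstream).
#' @export
callMarker <- function(ar, ref) {
  m <- markerSite(ref)
  if (is.null(m)) stop("reference has no marker site annotation")
  .markerFromGapped(ar$pattern, ar$subject, ar$sstart, ar$send,
                    m$offset, m$mut_base, m$wt_base)
}

.markerFromGapped <- function(pattern, subject, sstart, send,
                              offset, mut_base, wt_base) {
  if (sstart > offset || send < offset) return("uncovered")
  pc <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  sc <- strsplit(subject, "", fixed = TRUE)[[1L]]
  refpos <- cumsum(sc != "-") + sstart - 1L
  col <- which(sc != "-" & refpos == offset)[1L]
  base <- pc[col]
  if (base == mut_base) "mutant"
  else if (base == wt_base) "wt"
  else "other"   # includes "-": marker deleted in the read
}

#' Collect indels in the cut-site window
#'
#' Returns insertion/deletion operations whose reference interval intersects
#' `[cut - w, cut + w]`; substitutions are ignored (they never count as
#' edits). An insertion's interval is taken as its two flanking reference
#' bases.
#'
#' @param ar an [alignRead()] result.
#' @param cut_offset between-base cut position (base 5' of the cut).
#' @param cfg a [quantConfig()] (supplies the window half-width).
#' @return data.frame subset of `ar$ops` with a `signed_length` column
#'   (insertions positive, deletions negative).
#' @export
callIndels <- function(ar, cut_offset, cfg = quantConfig()) {
  w <- cfg$window_halfwidth
  ops <- ar$ops
  keep <- (ops$op %in% c("insertion", "deletion")) &
    ops$ref_start <= cut_offset + w & ops$ref_end >= cut_offset - w
  out <- ops[keep, , drop = FALSE]
  out$signed_length <- ifelse(out$op == "insertion", out$length, -out$length)
  rownames(out) <- NULL
  out
}

#' Classify a read under the allele-specific editing rule
#'
#' A read is an edited mutant allele when it carries the silent marker base
#' and an out-of-frame indel pattern of `min_out_of_frame_len` to
#' `max_indel_len` bp (default 1-8) at the cut site; in-frame or over-long
#' indels on marker-positive reads are excluded (not edited), marker-negative
#' reads are wild type, and reads whose marker base is unreadable are
#' discarded. Multiple window indels are summed into one net signed length
#' before the frame test, so indels netting to an in-frame change are
#' excluded.
#'
#' @param marker_call output of [callMarker()].
#' @param indels_in_window output of [callIndels()], or a numeric vector of
#'   signed indel lengths.
#' @param cfg a [quantConfig()].
#' @return one of `"mutant_edited"`, `"mutant_unedited"`,
#'   `"mutant_excluded"`, `"wt"`, `"discarded"`.
#' @examples
#' classifyRead("mutant", -2)   # edited
#' classifyRead("mutant", -3)   # excluded (in-frame)
#' classifyRead("wt", -2)       # wt: never counted as edited
#' @export
classifyRead <- function(marker_call, indels_in_window = numeric(0),
                         cfg = quantConfig()) {
  if (is.data.frame(indels_in_window)) {
    indels_in_window <- indels_in_window$signed_length
  }
  if (marker_call %in% c("uncovered", "other")) return("discarded")
  if (marker_call == "wt") return("wt")
  if (marker_call != "mutant") stop("unknown marker call: ", marker_call)
  if (length(indels_in_window) == 0L) return("mutant_unedited")
  L <- sum(indels_in_window)
  if (abs(L) >= cfg$min_out_of_frame_len && abs(L) <= cfg$max_indel_len &&
      L %% 3L != 0L) "mutant_edited" else "mutant_excluded"
}

#' SampleQuantResult: per-sample allele-specific editing quantification
#'
#' Holds the per-class read counts and the editing efficacy
#' `100 * mutant_edited / (mutant_edited + mutant_unedited +
#' mutant_excluded)` (denominator configurable). When no marker-positive read
#' is present the efficacy is `NA` and flagged, never silently 0.
#'
#' @slot counts named integer per read class.
#' @slot total total reads.
#' @slot markerPositive reads carrying the mutant marker base.
#' @slot efficacy efficacy percent (`NA` when undefined).
#' @slot cutOffset,window cut site and window half-width used.
#' @slot indelSpectrum named integer: net signed indel length counts among
#'   marker-positive reads with window indels.
#' @slot refId,denominator,flags provenance and warnings.
#' @slot config echo of the [quantConfig()] used.
#' @exportClass SampleQuantResult
setClass("SampleQuantResult", slots = c(
  counts = "integer", total = "integer", markerPositive = "integer",
  efficacy = "numeric", cutOffset = "integer", window = "integer",
  indelSpectrum = "integer", refId = "character", denominator = "character",
  flags = "character", config = "list"))

setValidity("SampleQuantResult", function(object) {
  msgs <- character(0)
  if (!identical(sort(names(object@counts)), sort(.READ_CLASSES))) {
    msgs <- c(msgs, "counts must cover exactly the five read classes")
  }
  if (sum(object@counts) != object@total) {
    msgs <- c(msgs, "class counts must sum to the total")
  }
  e <- object@efficacy
  if (!is.na(e) && (e < 0 || e > 100)) {
    msgs <- c(msgs, "efficacy must lie in [0, 100] or be NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SampleQuantResult-class named per-class read counts.
#' @param x a `SampleQuantResult`.
#' @export
classCounts <- function(x) x@counts

#' @describeIn SampleQuantResult-class editing efficacy percent (`NA` when no
#'   marker-positive reads).
#' @export
efficacyPercent <- function(x) x@efficacy

#' @describeIn SampleQuantResult-class net indel length spectrum among
#'   marker-positive reads.
#' @export
indelSpectrum <- function(x) x@indelSpectrum

setMethod("show", "SampleQuantResult", function(object) {
  cat("SampleQuantResult (", object@refId, "): ", object@total, " reads\n",
      sep = "")
  print(object@counts)
  cat(sprintf("efficacy: %s%% (denominator: %s reads; cut %d, window +/-%d)\n",
              ifelse(is.na(object@efficacy), "NA",
                     format(object@efficacy, digits = 4)),
              object@denominator, object@cutOffset, object@window))
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = "; "), "\n")
})

#' Quantify allele-specific editing in one amplicon sample
#'
#' Aligns every read glocally to the mutant amplicon, calls the marker base
#' and cut-site-window indels, classifies each read
#' (see [classifyRead()]), and reports per-class counts plus editing efficacy
#' on the mutant-marker denominator. Duplicate read sequences are aligned
#' once and their counts multiplied, which makes deep amplicon samples cheap.
#'
#' @param reads a named [Biostrings::DNAStringSet], a FASTQ path, or a
#'   [simulateReads()] result.
#' @param ref an [AmpliconReference-class] with a marker site.
#' @param guide one-row guide data.frame (for the cut site), or a single
#'   integer cut offset.
#' @param cfg a [quantConfig()].
#' @param return_read_classes also return the per-read class table (for
#'   audits and truth comparisons).
#' @return a [SampleQuantResult-class]; with `return_read_classes = TRUE`, a
#'   list `(result, read_classes)`.
#' @examples
#' ref <- kcnq4W276SAmplicon()
#' g <- enumerateGuides(ref, require_variant_overlap = TRUE)[1, ]
#' sim <- simulateReads(ref, g, readSimConfig(n_reads = 200,
#'   editing_rate_mutant = 0.3, seed = 2))
#' quantifySample(sim, ref, g)
#' @export
quantifySample <- function(reads, ref, guide, cfg = quantConfig(),
                           return_read_classes = FALSE) {
  stopifnot(inherits(cfg, "QuantConfig"))
  validObject(ref)
  if (inherits(reads, "ampliconReadSim")) reads <- reads$reads
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- readFastqReads(reads)
  }
  seqs <- as.character(reads)
  if (length(seqs) == 0L) stop("empty read set")
  ids <- if (!is.null(names(seqs))) names(seqs) else
    sprintf("read%06d", seq_along(seqs))
  m <- markerSite(ref)
  if (is.null(m)) stop("reference has no marker site annotation")
  cut <- if (is.numeric(guide)) as.integer(guide) else guideCutSite(guide)
  refchar <- as.character(refSequence(ref))
  params <- cfg$alignment
  w <- cfg$window_halfwidth

  uniq <- unique(seqs)
  idx <- match(seqs, uniq)
  uclass <- character(length(uniq))
  unet <- rep(NA_integer_, length(uniq))
  chunk <- 5000L
  for (off in seq(1L, length(uniq), by = chunk)) {
    sel <- off:min(off + chunk - 1L, length(uniq))
    b <- .alignBatch(uniq[sel], refchar, params)
    for (j in seq_along(sel)) {
      pc <- strsplit(b$pattern[j], "", fixed = TRUE)[[1L]]
      sc <- strsplit(b$subject[j], "", fixed = TRUE)[[1L]]
      ident <- sum(pc == sc & pc != "-") / length(pc)
      if (ident < params$min_identity) {
        uclass[sel[j]] <- "discarded"
        next
      }
      send <- b$sstart[j] + sum(sc != "-") - 1L
      mk <- .markerFromGapped(b$pattern[j], b$subject[j], b$sstart[j], send,
                              m$offset, m$mut_base, m$wt_base)
      ops <- .opsFromGapped(b$pattern[j], b$subject[j], b$sstart[j])
      keep <- (ops$op %in% c("insertion", "deletion")) &
        ops$ref_start <= cut + w & ops$ref_end >= cut - w
      sl <- ifelse(ops$op[keep] == "insertion", 1L, -1L) * ops$length[keep]
      uclass[sel[j]] <- classifyRead(mk, sl, cfg)
      if (mk == "mutant" && length(sl)) unet[sel[j]] <- sum(sl)
    }
  }

  cls <- uclass[idx]
  counts <- vapply(.READ_CLASSES, function(k) sum(cls == k), integer(1))
  marker_pos <- sum(counts[c("mutant_edited", "mutant_unedited",
                             "mutant_excluded")])
  denom <- if (cfg$denominator == "mutant") marker_pos else
    sum(counts) - counts[["discarded"]]
  flags <- character(0)
  if (denom == 0L) {
    eff <- NA_real_
    flags <- c(flags, "no reads in the efficacy denominator; efficacy undefined")
  } else {
    eff <- 100 * counts[["mutant_edited"]] / denom
  }
  net <- unet[idx]
  spec <- table(net[!is.na(net)])
  spectrum <- stats::setNames(as.integer(spec), names(spec))

  res <- new("SampleQuantResult", counts = counts,
             total = length(seqs), markerPositive = as.integer(marker_pos),
             efficacy = eff, cutOffset = cut, window = w,
             indelSpectrum = spectrum, refId = ampliconId(ref),
             denominator = cfg$denominator, flags = flags,
             config = unclass(cfg)[c("window_halfwidth", "min_out_of_frame_len",
                                     "max_indel_len", "denominator")])
  if (!return_read_classes) return(res)
  list(result = res,
       read_classes = data.frame(read_id = ids, class = cls,
                                 stringsAsFactors = FALSE))
}

#' Background-correct an injected sample against a control
#'
#' Subtracts the apparent efficacy of a matched control sample (contralateral
#' non-injected ear, or an uninjected animal) from the injected sample,
#' flooring at zero; this removes inter-individual variation and residual
#' sequencing/analysis noise. Both raw values are retained.
#'
#' @param injected,control [SampleQuantResult-class] objects produced with
#'   the same reference, cut site, window and denominator.
#' @return list of class `backgroundCorrection`: `corrected_efficacy`,
#'   `injected_efficacy`, `control_efficacy`, `floored`.
#' @export
backgroundCorrect <- function(injected, control) {
  same <- identical(injected@refId, control@refId) &&
    identical(injected@cutOffset, control@cutOffset) &&
    identical(injected@window, control@window) &&
    identical(injected@denominator, control@denominator)
  if (!same) {
    stop("injected and control were quantified under different ",
         "reference/guide/config; background correction is not meaningful")
  }
  ie <- injected@efficacy
  ce <- control@efficacy
  if (is.na(ie) || is.na(ce)) {
    return(structure(list(corrected_efficacy = NA_real_,
                          injected_efficacy = ie, control_efficacy = ce,
                          floored = NA), class = "backgroundCorrection"))
  }
  floored <- ce > ie
  if (floored) {
    warning("control efficacy exceeds injected efficacy; corrected value floored at 0")
  }
  structure(list(corrected_efficacy = max(0, ie - ce),
                 injected_efficacy = ie, control_efficacy = ce,
                 floored = floored), class = "backgroundCorrection")
}
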