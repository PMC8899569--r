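#' Enumerate SpCas9 guide candidates on an amplicon
#'
#' Scans the chosen allele sequence for every NGG protospacer-adjacent motif
#' whose 20-nt protospacer window lies on the amplicon, on the top strand, the
#' bottom strand, or both. SpCas9 cleaves bluntly 3 bp 5' of the PAM, i.e.
#' between protospacer positions 17 and 18; cut sites are reported as
#' between-base positions, as the top-strand offset of the base 5' of the cut.
#'
#' Allele-discriminating guide selection for a dominant-negative variant needs
#' candidates whose protospacer covers the pathogenic base, so that the guide
#' mismatches the wild-type allele; set `require_variant_overlap = TRUE` to
#' keep only those.
#'
#' @param ref an [AmpliconReference-class].
#' @param allele `"mutant"` (stored sequence) or `"wt"` (derived; errors when
#'   no sites are annotated).
#' @param require_variant_overlap keep only candidates whose protospacer
#'   covers the pathogenic site offset.
#' @param strands `"both"`, `"top"` or `"bottom"`.
#' @return data.frame sorted by protospacer start (then strand), with columns
#'   `protospacer` (20 nt, guide-strand sense), `pam` (3 nt NGG), `strand`
#'   (`"+"`/`"-"`), `start`, `end` (protospacer span, top-strand coordinates),
#'   `cut_offset` (top-strand base 5' of the blunt cut),
#'   `variant_pos` (pathogenic base position 1-20 within the protospacer, 5'
#'   to 3', or `NA`), and `pam_distance` (nt from the pathogenic base to the
#'   PAM-proximal protospacer end, or `NA`).
#' @examples
#' ref <- kcnq4W276SAmplicon()
#' g <- enumerateGuides(ref, allele = "wt", strands = "top")
#' g[g$protospacer == "CCTCCTATGCCGACTCGCTC", ]
#' @export
enumerateGuides <- function(ref, allele = c("mutant", "wt"),
                            require_variant_overlap = FALSE,
                            strands = c("both", "top", "bottom")) {
  allele <- match.arg(allele)
  strands <- match.arg(strands)
  validObject(ref)
  s <- alleleSequence(ref, allele)
  L <- nchar(s)
  pat <- pathogenicSite(ref)
  variant_off <- if (is.null(pat)) NA_integer_ else pat$offset

  scan_one <- function(seqchar, strand) {
    if (nchar(seqchar) < 23L) return(NULL)
    # lookahead regex: every NGG start, including overlapping occurrences
    hits <- gregexpr("(?=[ACGT]GG)", seqchar, perl = TRUE)[[1L]]
    hits <- hits[hits >= 21L]
    if (length(hits) == 0L || hits[1L] == -1L) return(NULL)
    proto <- substring(seqchar, hits - 20L, hits - 1L)
    pam <- substring(seqchar, hits, hits + 2L)
    if (strand == "+") {
      start <- hits - 20L
      end <- hits - 1L
      cut <- start + 16L
    } else {
      # positions on the reverse complement map back as i -> L - i + 1
      start <- L - hits + 2L
      end <- L - hits + 21L
      cut <- end - 17L
    }
    data.frame(protospacer = proto, pam = pam, strand = strand,
               start = as.integer(start), end = as.integer(end),
               cut_offset = as.integer(cut), stringsAsFactors = FALSE)
  }

  out <- list()
  if (strands %in% c("both", "top")) out <- c(out, list(scan_one(s, "+")))
  if (strands %in% c("both", "bottom")) {
    rc <- as.character(Biostrings::reverseComplement(DNAString(s)))
    out <- c(out, list(scan_one(rc, "-")))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  g <- if (length(out)) do.call(rbind, out) else
    data.frame(protospacer = character(0), pam = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               cut_offset = integer(0), stringsAsFactors = FALSE)

  if (nrow(g)) {
    covered <- !is.na(variant_off) & g$start <= variant_off & g$end >= variant_off
    g$variant_pos <- ifelse(covered,
      ifelse(g$strand == "+", variant_off - g$start + 1L, g$end - variant_off + 1L),
      NA_integer_)
    g$pam_distance <- ifelse(covered, 21L - g$variant_pos, NA_integer_)
  } else {
    g$variant_pos <- integer(0)
    g$pam_distance <- integer(0)
  }

  if (require_variant_overlap) {
    if (is.na(variant_off)) stop("require_variant_overlap needs a pathogenic site annotation")
    g <- g[!is.na(g$variant_pos), , drop = FALSE]
  }
  g <- g[order(g$start, g$strand), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Cut site of a guide candidate
#'
#' Recomputes the blunt SpCas9 cut position (3 bp 5' of the PAM, between
#' protospacer positions 17 and 18) from the guide's span and strand,
#' reported as the top-strand offset of the base 5' of the cut.
#'
#' @param guide a one-row data.frame as returned by [enumerateGuides()] (or
#'   any list with `start`, `end`, `strand`).
#' @return integer between-base offset.
#' @export
guideCutSite <- function(guide) {
  if (is.data.frame(guide)) {
    stopifnot(nrow(guide) == 1L)
    guide <- as.list(guide)
  }
  stopifnot(guide$end - guide$start == 19L, guide$strand %in% c("+", "-"))
  cut <- if (guide$strand == "+") guide$start + 16L else guide$end - 17L
  as.integer(cut)
}

#' Allele-discrimination report for a guide
#'
#' Re-reads the protospacer from the derived wild-type sequence and reports
#' whether the guide covers the pathogenic base. A guide whose protospacer
#' covers the variant mismatches the wild-type allele at exactly that
#' position, the property exploited to spare the functional allele.
#'
#' @param guide one-row guide data.frame (from [enumerateGuides()] on the
#'   mutant allele).
#' @param ref the [AmpliconReference-class]; must have a pathogenic site.
#' @return list with `overlaps_pathogenic`, `pam_distance` (or `NA`) and
#'   `wt_protospacer` (guide-strand sense).
#' @export
alleleDiscrimination <- function(guide, ref) {
  if (is.data.frame(guide)) {
    stopifnot(nrow(guide) == 1L)
    guide <- as.list(guide)
  }
  pat <- pathogenicSite(ref)
  if (is.null(pat)) stop("reference has no pathogenic site annotation")
  wt <- wtSequence(ref, as = "character")
  sub <- substring(wt, guide$start, guide$end)
  if (guide$strand == "-") {
    sub <- as.character(Biostrings::reverseComplement(DNAString(sub)))
  }
  overlaps <- guide$start <= pat$offset && guide$end >= pat$offset
  pd <- if (overlaps) {
    vp <- if (guide$strand == "+") pat$offset - guide$start + 1L else guide$end - pat$offset + 1L
    21L - vp
  } else NA_integer_
  list(overlaps_pathogenic = overlaps, pam_distance = pd, wt_protospacer = sub)
}
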