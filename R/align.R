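#' @importFrom Biostrings pairwiseAlignment nucleotideSubstitutionMatrix
NULL

#' Alignment scoring parameters
#'
#' Affine-gap scoring for glocal (global in the read, local in the reference)
#' alignment of amplicon reads to the mutant reference. A gap of length L
#' costs `gap_open + L * gap_extend`. Defaults follow the EDNAFULL-style
#' scheme common in amplicon aligners.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch penalty (>= 0; applied as a negative score).
#' @param gap_open,gap_extend affine gap penalties, `gap_open >= gap_extend >= 0`.
#' @param min_identity minimum fraction of matching alignment columns for a
#'   read to be retained; reads below it are discarded.
#' @return list of class `AlignmentParams`.
#' @export
alignmentParams <- function(match = 5, mismatch = 4, gap_open = 10,
                            gap_extend = 0.5, min_identity = 0.75) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= gap_extend,
            gap_extend >= 0, min_identity >= 0, min_identity <= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity),
            class = "AlignmentParams")
}

.submat <- function(params) {
  nucleotideSubstitutionMatrix(match = params$match,
                               mismatch = -params$mismatch, baseOnly = TRUE)
}

# Align a character vector of reads against one reference string.
# Returns list(score, pattern, subject, sstart) of equal length.
.alignBatch <- function(reads, refchar, params) {
  aln <- pairwiseAlignment(DNAStringSet(reads), DNAString(refchar),
                           substitutionMatrix = .submat(params),
                           gapOpening = params$gap_open,
                           gapExtension = params$gap_extend,
                           type = "global-local")
  list(score = Biostrings::score(aln),
       pattern = as.character(Biostrings::pattern(aln)),
       subject = as.character(Biostrings::subject(aln)),
       sstart = Biostrings::start(Biostrings::subject(aln)))
}

# Column-walk a gapped read/reference pair into an operation table.
# `sstart` is the 1-based reference offset of the first aligned ref base.
.opsFromGapped <- function(pattern, subject, sstart) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  sc <- strsplit(subject, "", fixed = TRUE)[[1L]]
  stopifnot(length(pc) == length(sc))
  refpos <- cumsum(sc != "-") + sstart - 1L  # for gap cols: last ref base seen
  opcode <- ifelse(sc == "-", "insertion",
                   ifelse(pc == "-", "deletion",
                          ifelse(pc == sc, "match", "mismatch")))
  r <- rle(opcode)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(r$values)
  ref_start <- ref_end <- integer(n)
  inserted <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (r$values[k] == "insertion") {
      l <- refpos[i0]                       # base 5' of the insertion point
      ref_start[k] <- l
      ref_end[k] <- l + 1L
      inserted[k] <- paste(pc[i0:i1], collapse = "")
    } else {
      # non-insertion runs start on a reference base, so refpos is exact
      ref_start[k] <- refpos[i0]
      ref_end[k] <- refpos[i1]
    }
  }
  data.frame(op = r$values, ref_start = ref_start, ref_end = ref_end,
             length = r$lengths, inserted = inserted, stringsAsFactors = FALSE)
}

#' Align one read glocally to the mutant amplicon
#'
#' Optimal affine-gap alignment, global in the read and local in the
#' reference (the whole read must align within the amplicon). Identity is the
#' fraction of matching columns over all alignment columns (gaps included).
#' Reads are always aligned to the mutant reference; allele identity is later
#' decided solely from the marker column, never from alignment-score
#' competition between alleles.
#'
#' @param read character read sequence (or length-1 `DNAStringSet`).
#' @param ref an [AmpliconReference-class].
#' @param params an [alignmentParams()].
#' @param read_id identifier carried into the result.
#' @return list of class `AlignedRead`: `read_id`, `score`, `identity`,
#'   `discard` (identity below threshold), `sstart`, `send`, `ops`
#'   (operation table: op, ref_start, ref_end, length, inserted), and the
#'   gapped `pattern`/`subject` strings.
#' @examples
#' ref <- kcnq4W276SAmplicon()
#' rd <- substr(as.character(refSequence(ref)), 10, 90)
#' alignRead(rd, ref)$identity  # 1
#' @export
alignRead <- function(read, ref, params = alignmentParams(), read_id = "read") {
  if (!is.character(read)) read <- as.character(read)
  stopifnot(length(read) == 1L, nchar(read) > 0L)
  b <- .alignBatch(read, as.character(refSequence(ref)), params)
  .alignedReadFromBatch(b, 1L, params, read_id)
}

.alignedReadFromBatch <- function(b, i, params, read_id) {
  p <- b$pattern[i]; s <- b$subject[i]; sstart <- b$sstart[i]
  pc <- strsplit(p, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  ident <- sum(pc == sc & pc != "-") / length(pc)
  structure(list(read_id = read_id, score = b$score[i], identity = ident,
                 discard = ident < params$min_identity,
                 sstart = sstart, send = sstart + sum(sc != "-") - 1L,
                 ops = .opsFromGapped(p, s, sstart),
                 pattern = p, subject = s),
            class = "AlignedRead")
}
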