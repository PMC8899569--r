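#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
NULL

#' AmpliconReference: a two-allele amplicon with annotated variant sites
#'
#' Stores the MUTANT-allele amplicon sequence together with the annotated
#' allele sites (a silent marker base that phases reads to the mutant allele,
#' and the pathogenic base targeted for disruption). The wild-type sequence is
#' never stored; it is always derived by substituting the wild-type base at
#' each site (see [wtSequence()]), so the two alleles cannot diverge.
#'
#' Coordinates are 1-based, inclusive, on the top strand of the amplicon.
#'
#' @slot id single character identifier.
#' @slot sequence a [Biostrings::DNAString] holding the mutant-allele amplicon
#'   (A/C/G/T only; ambiguity codes are rejected).
#' @slot sites data.frame with columns `offset` (integer), `wt_base`,
#'   `mut_base` (single bases, `wt_base != mut_base`), and `role`
#'   (`"marker"` or `"pathogenic"`). The sequence must carry `mut_base`
#'   at every `offset`.
#'
#' @seealso [AmpliconReference()], [wtSequence()], [kcnq4W276SAmplicon()]
#' @name AmpliconReference-class
#' @aliases AmpliconReference-class
#' @exportClass AmpliconReference
setClass("AmpliconReference",
  slots = c(id = "character", sequence = "DNAString", sites = "data.frame")
)

.validSiteFrame <- function(sites, seqlen, seqchar) {
  msgs <- character(0)
  needed <- c("offset", "wt_base", "mut_base", "role")
  if (!all(needed %in% names(sites))) {
    return(sprintf("sites must have columns %s", paste(needed, collapse = ", ")))
  }
  if (nrow(sites) == 0L) return(character(0))
  bases <- c("A", "C", "G", "T")
  if (!all(sites$wt_base %in% bases) || !all(sites$mut_base %in% bases)) {
    msgs <- c(msgs, "site bases must be one of A, C, G, T")
  }
  if (any(sites$wt_base == sites$mut_base)) {
    msgs <- c(msgs, "wt_base and mut_base must differ at every site")
  }
  if (!all(sites$role %in% c("marker", "pathogenic"))) {
    msgs <- c(msgs, "site role must be 'marker' or 'pathogenic'")
  }
  off <- sites$offset
  if (any(off < 1L | off > seqlen)) {
    msgs <- c(msgs, "site offset outside sequence bounds")
  } else {
    have <- substring(seqchar, off, off)
    bad <- which(have != sites$mut_base)
    if (length(bad)) {
      msgs <- c(msgs, sprintf(
        "sequence does not carry mut_base at offset %s (found %s, annotated %s)",
        paste(off[bad], collapse = ","), paste(have[bad], collapse = ","),
        paste(sites$mut_base[bad], collapse = ",")))
    }
  }
  if (anyDuplicated(off)) msgs <- c(msgs, "duplicated site offsets")
  msgs
}

setValidity("AmpliconReference", function(object) {
  msgs <- character(0)
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id)) {
    msgs <- c(msgs, "id must be a single non-empty string")
  }
  seqchar <- as.character(object@sequence)
  if (grepl("[^ACGT]", seqchar)) {
    msgs <- c(msgs, "sequence must contain only A, C, G, T (no ambiguity codes)")
  }
  msgs <- c(msgs, .validSiteFrame(object@sites, nchar(seqchar), seqchar))
  if (length(msgs)) msgs else TRUE
})

#' Construct an allele-site annotation
#'
#' One row of the site table consumed by [AmpliconReference()].
#'
#' @param offset 1-based position on the amplicon top strand.
#' @param wt_base,mut_base single wild-type / mutant nucleotides (must differ).
#' @param role `"marker"` (silent phasing base) or `"pathogenic"`.
#' @return one-row data.frame.
#' @examples
#' alleleSite(41, "C", "A", "marker")
#' @export
alleleSite <- function(offset, wt_base, mut_base, role = c("marker", "pathogenic")) {
  role <- match.arg(role)
  data.frame(offset = as.integer(offset), wt_base = toupper(wt_base),
             mut_base = toupper(mut_base), role = role,
             stringsAsFactors = FALSE)
}

.emptySites <- function() {
  data.frame(offset = integer(0), wt_base = character(0),
             mut_base = character(0), role = character(0),
             stringsAsFactors = FALSE)
}

#' Construct an AmpliconReference
#'
#' @param id amplicon identifier.
#' @param sequence mutant-allele amplicon sequence (character or
#'   [Biostrings::DNAString]).
#' @param sites data.frame of allele sites, typically `rbind()` of
#'   [alleleSite()] rows. May have zero rows for a monoallelic amplicon.
#' @return an [AmpliconReference-class] object.
#' @examples
#' ref <- AmpliconReference("toy", "ACGTACGTAA",
#'   alleleSite(3, "C", "G", "marker"))
#' @export
AmpliconReference <- function(id, sequence, sites = .emptySites()) {
  if (is.character(sequence)) sequence <- DNAString(toupper(sequence))
  new("AmpliconReference", id = id, sequence = sequence,
      sites = as.data.frame(sites, stringsAsFactors = FALSE))
}

#' @describeIn AmpliconReference-class amplicon identifier.
#' @param x an `AmpliconReference`.
#' @export
ampliconId <- function(x) x@id

#' @describeIn AmpliconReference-class mutant-allele sequence as a
#'   [Biostrings::DNAString].
#' @export
refSequence <- function(x) x@sequence

#' @describeIn AmpliconReference-class site annotation table.
#' @export
alleleSites <- function(x) x@sites

.siteByRole <- function(x, role) {
  s <- x@sites[x@sites$role == role, , drop = FALSE]
  if (nrow(s) == 0L) return(NULL)
  s[1L, , drop = FALSE]
}

#' @describeIn AmpliconReference-class the marker site row (or `NULL`).
#' @export
markerSite <- function(x) .siteByRole(x, "marker")

#' @describeIn AmpliconReference-class the pathogenic site row (or `NULL`).
#' @export
pathogenicSite <- function(x) .siteByRole(x, "pathogenic")

#' Derive the wild-type allele sequence
#'
#' Substitutes the wild-type base at every annotated site and changes nothing
#' else; the returned sequence has the same length as the mutant amplicon.
#'
#' @param ref an [AmpliconReference-class].
#' @param as character: `"DNAString"` (default) or `"character"`.
#' @return the wild-type sequence.
#' @examples
#' ref <- kcnq4W276SAmplicon()
#' wtSequence(ref, as = "character")
#' @export
wtSequence <- function(ref, as = c("DNAString", "character")) {
  as <- match.arg(as)
  validObject(ref)
  s <- as.character(ref@sequence)
  if (nrow(ref@sites)) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    ch[ref@sites$offset] <- ref@sites$wt_base
    s <- paste(ch, collapse = "")
  }
  if (as == "character") s else DNAString(s)
}

#' Allele sequence by name
#'
#' @param ref an [AmpliconReference-class].
#' @param allele `"mutant"` (the stored sequence) or `"wt"` (derived).
#' @return character sequence.
#' @export
alleleSequence <- function(ref, allele = c("mutant", "wt")) {
  allele <- match.arg(allele)
  if (allele == "mutant") return(as.character(ref@sequence))
  if (nrow(ref@sites) == 0L) {
    stop("allele = 'wt' requested but no allele sites are annotated; ",
         "no wild-type sequence is derivable")
  }
  wtSequence(ref, as = "character")
}

setMethod("show", "AmpliconReference", function(object) {
  cat("AmpliconReference '", object@id, "': ",
      length(object@sequence), " nt (mutant allele stored)\n", sep = "")
  if (nrow(object@sites)) {
    for (i in seq_len(nrow(object@sites))) {
      s <- object@sites[i, ]
      cat(sprintf("  %-10s offset %d  %s>%s\n", s$role, s$offset,
                  s$wt_base, s$mut_base))
    }
  } else cat("  (no allele sites annotated)\n")
})

#' The Kcnq4 W276S knock-in amplicon fixture
#'
#' The 101-nt single-stranded donor used to create the Kcnq4 p.W276S
#' (c.830G>C) knock-in allele, carrying the phased silent marker c.810C>A
#' 20 nt upstream of the pathogenic base. On this amplicon the marker sits at
#' offset 41 (C>A) and the pathogenic base at offset 61 (G>C); the wild-type
#' derived sequence restores the TGG tryptophan codon at positions 60-62.
#'
#' @return an [AmpliconReference-class].
#' @examples
#' ref <- kcnq4W276SAmplicon()
#' pathogenicSite(ref)$offset - markerSite(ref)$offset  # 20
#' @export
kcnq4W276SAmplicon <- function() {
  donor <- paste0(
    "TCTACCTGGCTGAGAAGGATGCCAACTCTGACTTCTCCTC",
    "ATATGCCGACTCGCTCTGGTCGGGGACGGTGCGTGAGCAT",
    "CTGTGCAGGGCTGCCCTTACC")
  AmpliconReference(
    id = "Kcnq4-W276S-donor",
    sequence = donor,
    sites = rbind(alleleSite(41L, "C", "A", "marker"),
                  alleleSite(61L, "G", "C", "pathogenic")))
}

#' Read an amplicon reference from FASTA plus a YAML site sidecar
#'
#' The FASTA record holds the mutant-allele amplicon; the sidecar lists the
#' allele sites, e.g.
#' \preformatted{
#' sites:
#'   - {offset: 41, wt_base: C, mut_base: A, role: marker}
#'   - {offset: 61, wt_base: G, mut_base: C, role: pathogenic}
#' }
#'
#' @param fasta path to a single-record FASTA file.
#' @param sites_yaml path to the YAML sidecar (optional; omit for an amplicon
#'   without annotated sites).
#' @return an [AmpliconReference-class].
#' @examples
#' fa <- system.file("extdata", "kcnq4_w276s_donor.fa", package = "alleleEditR")
#' yml <- system.file("extdata", "kcnq4_w276s_sites.yaml", package = "alleleEditR")
#' if (requireNamespace("yaml", quietly = TRUE)) readAmpliconReference(fa, yml)
#' @export
readAmpliconReference <- function(fasta, sites_yaml = NULL) {
  seqs <- readDNAStringSet(fasta)
  if (length(seqs) != 1L) stop("expected exactly one FASTA record, found ", length(seqs))
  sites <- .emptySites()
  if (!is.null(sites_yaml)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a site sidecar requires the 'yaml' package")
    }
    y <- yaml::read_yaml(sites_yaml)
    rows <- lapply(y$sites, function(s) {
      alleleSite(s$offset, s$wt_base, s$mut_base, s$role)
    })
    if (length(rows)) sites <- do.call(rbind, rows)
  }
  AmpliconReference(id = names(seqs)[1L], sequence = as.character(seqs[[1L]]),
                    sites = sites)
}
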