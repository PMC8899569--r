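test_that("wild-type derivation substitutes annotated sites and nothing else", {
  # no sites: identity
  plain <- AmpliconReference("plain", "ACGTACGTACGTACGTACGTACGT")
  expect_identical(wtSequence(plain, as = "character"),
                   "ACGTACGTACGTACGTACGTACGT")

  ref <- canonicalRef()
  mut <- mutantChar(ref)
  wt <- wtSequence(ref, as = "character")
  expect_identical(nchar(wt), nchar(mut))
  diffs <- which(strsplit(wt, "")[[1]] != strsplit(mut, "")[[1]])
  expect_identical(diffs, alleleSites(ref)$offset)
})

test_that("the canonical knock-in amplicon carries the documented anatomy", {
  ref <- canonicalRef()
  mut <- mutantChar(ref)
  wt <- wtSequence(ref, as = "character")

  # marker and pathogenic sites 20 nt apart, located by their local contexts
  expect_identical(pathogenicSite(ref)$offset - markerSite(ref)$offset, 20L)
  expect_identical(as.integer(regexpr("TCATATG", mut)) + 2L,
                   markerSite(ref)$offset)
  expect_identical(as.integer(regexpr("TGGTCG", mut)) + 4L,
                   pathogenicSite(ref)$offset)

  # WT sequence exposes the knock-in protospacer followed by its PAM,
  # and restores the TGG tryptophan codon over the mutant TCG
  expect_true(grepl("CCTCCTATGCCGACTCGCTCTGG", wt, fixed = TRUE))
  p_off <- pathogenicSite(ref)$offset
  expect_identical(substr(mut, p_off - 1, p_off + 1), "TCG")
  expect_identical(substr(wt, p_off - 1, p_off + 1), "TGG")
})

test_that("re-applying the mutant bases to the WT sequence is the identity", {
  ref <- canonicalRef()
  ch <- strsplit(wtSequence(ref, as = "character"), "")[[1]]
  ch[alleleSites(ref)$offset] <- alleleSites(ref)$mut_base
  expect_identical(paste(ch, collapse = ""), mutantChar(ref))
})

test_that("invalid references are rejected with informative errors", {
  # annotated mut_base disagrees with the sequence
  expect_error(AmpliconReference("x", "ACGTACGT", alleleSite(2, "A", "G")),
               "mut_base")
  # offset out of bounds
  expect_error(AmpliconReference("x", "ACGT", alleleSite(9, "C", "A")),
               "bounds")
  # identical wt and mut base
  expect_error(AmpliconReference("x", "ACGT", alleleSite(1, "A", "A")),
               "differ")
  # ambiguity codes rejected
  expect_error(AmpliconReference("x", "ACGTN"), "only A, C, G, T")
  # wt allele underivable without sites
  expect_error(alleleSequence(AmpliconReference("x", "ACGTACGTACGT"), "wt"),
               "derivable")
})

test_that("FASTA + YAML sidecar round-trips the canonical reference", {
  skip_if_not_installed("yaml")
  ref <- canonicalRef()

  # freshly written files
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">Kcnq4-W276S-donor", mutantChar(ref)), fa)
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("sites:",
               "  - {offset: 41, wt_base: C, mut_base: A, role: marker}",
               "  - {offset: 61, wt_base: G, mut_base: C, role: pathogenic}"),
             yml)
  got <- readAmpliconReference(fa, yml)
  expect_identical(as.character(refSequence(got)), mutantChar(ref))
  expect_identical(alleleSites(got), alleleSites(ref))

  # the fixtures shipped with the package parse to the same object
  shipped <- readAmpliconReference(
    system.file("extdata", "kcnq4_w276s_donor.fa", package = "alleleEditR"),
    system.file("extdata", "kcnq4_w276s_sites.yaml", package = "alleleEditR"))
  expect_identical(as.character(refSequence(shipped)), mutantChar(ref))
  expect_identical(alleleSites(shipped), alleleSites(ref))
})
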