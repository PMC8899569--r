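# shared fixtures, built in code
canonicalRef <- function() kcnq4W276SAmplicon()

# the variant-overlapping guide candidate used throughout the simulations
canonicalGuide <- function(ref = canonicalRef()) {
  enumerateGuides(ref, allele = "mutant", require_variant_overlap = TRUE,
                  strands = "both")[1L, ]
}

mutantChar <- function(ref = canonicalRef()) as.character(refSequence(ref))
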