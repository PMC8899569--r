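---
title: "Quantifying allele-specific CRISPR editing and its phenotypic correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allele-specific CRISPR editing and its phenotypic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleleEditR)
```

## The analysis problem

Dominant-negative disease alleles — such as *Kcnq4* c.830G>C (p.W276S), a
common cause of DFNA2 progressive hearing loss — can be treated by
selectively disrupting the mutant allele with SpCas9 while sparing the
wild-type copy. Measuring how well that worked from amplicon deep sequencing
of a heterozygous tissue raises a phasing problem: once Cas9 has cut at the
pathogenic base, indels at the cut site destroy the very nucleotide that
distinguishes the two alleles, so a read with an indel cannot be assigned to
an allele by the pathogenic position itself.

The design analyzed here solves this with a **phased silent marker**: the
knock-in allele carries a synonymous base change 20 nt upstream of the
pathogenic variant (c.810C>A). Every read is assigned to an allele by the
marker column alone, and editing is then scored only on marker-positive
(mutant) reads. alleleEditR implements this pipeline end to end, together
with the surrounding analyses of such a study: guide enumeration around the
variant, T7E1 densitometry conversion, ABR threshold-shift statistics, and
thallium-flux (FluxOR) trace quantification. Every step has a seeded
synthetic-data generator with a ground-truth table, so the whole pipeline is
testable against known answers.

## The reference model

`AmpliconReference` stores the **mutant-allele** amplicon (the therapeutic
target) plus its annotated sites; the wild-type sequence is always derived by
substituting the wild-type base at each site (`wtSequence()`), never stored,
so the two alleles cannot drift apart. Coordinates are 1-based, inclusive,
top strand. Ambiguity codes are rejected: amplicon references are fully
resolved sequences, and a permissive N would silently weaken the marker
logic.

The canonical fixture `kcnq4W276SAmplicon()` is the 101-nt single-stranded
donor used to build the knock-in allele: marker C>A at offset 41, pathogenic
G>C at offset 61 (the mutant TCG serine codon at 60–62; the derived wild type
restores TGG tryptophan).

## Guide enumeration

`enumerateGuides()` reports every 20-nt protospacer with an NGG PAM whose
window lies on the amplicon, on either strand, with the blunt SpCas9 cut
placed 3 bp 5′ of the PAM (between protospacer positions 17 and 18). Cut
sites are between-base positions reported as the offset of the base 5′ of the
cut; this convention round-trips exactly to alignment columns. Both strands
are scanned and variant overlap is a filter flag rather than a hard-coded
"downstream" rule, because allele-discriminating guides can place the variant
anywhere in the protospacer; `alleleDiscrimination()` re-reads each
protospacer from the derived wild-type allele so the single mismatch that
protects the functional allele is explicit.

## Read classification

Reads are aligned **glocally** (global in the read, local in the reference)
to the mutant amplicon with affine-gap scoring (defaults: match 5, mismatch
−4, gap open 10, gap extend 0.5 — the EDNAFULL-style scheme common in
amplicon tools). Alignment is only ever to the mutant reference: allele
identity comes exclusively from the marker column, never from score
competition between the two allele references, which would bias reads with
cut-site damage at the pathogenic base. Reads whose alignment identity falls
below 0.75 are discarded.

Each retained read is then classified:

* marker column carries the mutant base → mutant; wild-type base → `wt`;
  any other base, or the marker inside a deletion, or an alignment that does
  not span the marker → `discarded` (a deliberate no-call, since allele
  origin cannot be established);
* indels whose reference interval intersects the cut-site window
  (default half-width 5 nt; an insertion's interval is its two flanking
  bases) are summed into one net signed length *L*;
* a mutant read with 1 ≤ |L| ≤ 8 and *L* not a multiple of 3 is
  `mutant_edited`; with no window indel, `mutant_unedited`; otherwise
  (in-frame net change, |L| > 8, or indels netting to zero)
  `mutant_excluded`.

The out-of-frame 1–8 bp rule is the heart of the method: it rules out both
substitution sequencing errors (which are never indels) and in-frame variants
that would not disrupt the protein. Treating multiple window indels as one
net length reads "any out-of-frame indel pattern" as net frame disruption;
the alternative (any single out-of-frame indel) differs only on the rare
multi-indel reads, which the one-lesion simulator never produces, so the
choice is exercised directly in unit tests instead.

**Efficacy** is `100 × mutant_edited / (mutant_edited + mutant_unedited +
mutant_excluded)`. The mutant-marker denominator is the reading consistent
with statements like "0.6% of mutant alleles were disrupted"; an alternative
denominator over all classified reads is exposed as
`quantConfig(denominator = "classified")`. When no read enters the
denominator the efficacy is `NA` with a flag — never silently zero.
`backgroundCorrect()` subtracts a matched control sample's apparent efficacy
(contralateral ear or uninjected animal), floored at zero, and refuses
samples quantified under different reference/guide/window settings.

### Numerical choices

* Gap-placement ties in repeats are resolved by the aligner's deterministic
  convention (not forced leftmost); equivalent placements can shift an indel
  by a few bases, which the ±5 nt window absorbs. Scores are
  placement-invariant and are verified against a brute-force affine-gap
  dynamic program in the test suite.
* The cut-site window half-width (5 nt) balances capturing
  placement-shifted lesions against excluding unrelated distal indels; it is
  configurable and echoed in every result.
* Identity is matches over all alignment columns, gaps included, so long
  deletions still count against identity; 0.75 rejects junk reads while
  keeping 8-bp-deletion reads (identity ≈ 0.92 on a 101-nt amplicon).
* No base-quality filtering is applied at the marker column by default; the
  pipeline treats qualities as opaque.

## The synthetic-data generators

`simulateReads()` draws single-end reads from the heterozygous pair (mutant
fraction 0.5 by default), gives each read at most **one** Cas9 lesion whose
left breakpoint is the guide cut site — compound edits would make the truth
table ambiguous — with signed length from a configurable NHEJ-like spectrum
(`defaultIndelWeights()`: +1 insertions dominant, deletion weight declining
with length, longer insertions rare), then applies uniform substitution
sequencing errors. Quality strings are constant Q37; the classification rule
performs no quality filtering, so modeling quality variation would add
nothing testable. Read length defaults to 150 nt, longer than the 101-nt
amplicon, so each read spans the whole template; shorter reads are placed to
always cover the marker and cut-site window.

What the generator deliberately does **not** emulate: PCR bias and chimeras,
paired-end merging artefacts, sequencer indel errors (an optional stress for
the window logic, not part of the defaults), microhomology-dependent indel
spectra, and cell-type contamination of dissected tissue. Passing tests
therefore show the *classifier and estimator* are correct under the stated
error model, not that every real-library artefact is handled.

Because the default spectrum contains in-frame lengths, the measured
efficacy of a simulated sample is the lesion rate times
`outOfFrameFraction()` (≈ 0.81 for the defaults). When a sample with a given
*measured* efficacy is wanted — e.g. the 0.6% in-vivo and 1.5% explant levels
recomputed by `scripts/acceptance.R` — the lesion rate is scaled by that
fraction.

`simulateCohort()` implements a linear-plus-noise phenotype model: per-mouse
efficacy from a Gaussian truncated at 0 (rejection sampling; default mean
0.5%, sd 0.25%, the sub-percent regime where hearing rescue was observed),
injected-ear threshold = baseline − `db_per_percent` × efficacy + noise,
contralateral = baseline + independent noise, clamped to the 10–95 dB SPL
instrument range. The population correlation between efficacy and mean shift
has the closed form `r = bσe / sqrt(b²σe² + 2σ²/k)` over k frequencies; the
default noise sd inverts this for r = 0.5 using the **truncated**
distribution's sd (the nominal Gaussian sd would mistune r by ≈ 0.04).
Baselines (60–80 dB SPL across 6–30 kHz) keep range-clamping rare so the
linear model stays honest.

`simulateT7e1()` inverts the heteroduplex formula (below);
`simulateFlux()` produces linear-plus-noise fluorescence traces per ROI and,
on request, an image stack whose ROI rectangles carry the trace values
exactly, so `extractTraces()` can be validated to machine precision.

## T7E1 conversion

With variant frequency p, random reannealing of denatured amplicons yields
mismatched (cleavable) duplexes with probability `1 − (1 − p/100)²`, so
`t7e1VariantFrequency()` converts a cleaved fraction f as
`100 × (1 − √(1 − f))`. Inputs within 1e−12 of [0, 1] are clipped as float
noise; anything further out is an error, never a silent clip — silent
clipping would mask densitometry mistakes upstream.

## Phenotype statistics

`abrImprovement()` averages contralateral-minus-injected thresholds over
6/12/18/24/30 kHz; `categorizeImprovement()` bins the mean shift as marked
(≥ 15 dB), moderate (10–14), mild (5–9), minimal (< 5). The published
category edges overlap at exactly 5 dB ("5–9" vs "≤ 5"); the package
resolves this as half-open intervals with 5 → mild, taking the explicit 5–9
range as inclusive of its endpoints. This is a convention choice, applied
unrounded to non-integer shifts, and is stated here rather than hidden.
`correlateEfficacyImprovement()` is a standard Pearson r with two-sided
t-approximation p; zero-variance input is an error (undefined), not a zero.
Group comparisons (ANOVA across categories, pairwise tests in the flux
module) are convenience output delegated to base R's standard routines.

## Thallium-flux quantification

For each ROI trace, `summarizeTrace()` takes F₀ as the sample at t = 0 (the
instant of Tl⁺ addition; a pre-stimulus average is available for noisy
recordings), the normalized change `ΔF₁₂₀₋₀/F₀ = (F(120) − F₀)/F₀` from the
raw nearest samples, and the influx slope from ordinary least squares of F
against t on [0, 120] s with its standard error. The ratio is invariant
under rescaling of F, the slope is not — both facts are property-tested.
`extractTraces()` reduces a single-channel stack to per-ROI pixel-mean
traces; ROI masks are supplied externally (no automatic outer-hair-cell
segmentation is attempted).

## Problem sizes used in validation

The shipped tests and `scripts/acceptance.R` validate at the sizes the
method is meant for: 100,000 reads per sample at lesion rates from 0.3% to
30% with substitution error 0.001; 500 simulated 20-mouse cohorts for
correlation recovery; 1000 noisy traces (noise sd 5% of F₀) for slope
coverage; 200 random alignment instances up to 200 nt against the
brute-force dynamic program; and exhaustive enumeration of the
classification rule table. These sizes were chosen so each estimate's
sampling error is small relative to the tolerance being checked.

## Known limitations

* Single-marker phasing: reads whose marker base is destroyed (deleted or
  miscalled) are discarded, so efficacy is estimated on the reads that
  remain; at substitution error e this silently drops ≈ e of reads and
  misassigns ≈ e/3 (the error that happens to produce the other allele's
  base). At e = 0.001 both effects are far below the binomial noise of a
  100k-read sample.
* One amplicon at a time; no UMI handling, paired-end merging, or off-target
  site discovery (off-target amplicons can be quantified by reusing the same
  pipeline with their own references).
* The cohort and flux models are linear by construction; they validate the
  estimators, not the biology of saturation or dye kinetics.
* On-target efficiency prediction and genome-wide off-target search are out
  of scope (external predictors cover these).
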