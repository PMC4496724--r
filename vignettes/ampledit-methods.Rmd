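---
title: "ampledit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ampledit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampledit)
```

## The assay being modelled

An embryo injected at the zygote stage with a designer nuclease (ZFN or
TALEN pair) and, optionally, a single-stranded oligonucleotide (ODN)
repair template develops into a mosaic of cell lineages. PCR of a ~550 bp
amplicon around the nuclease cut site, sequenced as MiSeq 2×250 bp paired
ends, samples the allele pool of the whole embryo. The analysis question
is compositional: what fraction of reads carry the template-specified
edit, a random NHEJ indel, a point mutation, or one of the two wild-type
alleles A and B (which differ at three SNPs inside the target window)?
The per-embryo answer drives a transfer decision: an embryo whose
intended-edit fraction exceeds ~96% is, within sequencing resolution,
non-mosaic and biallelically edited.

## Pipeline model and assumptions

**Trimming.** Each read is cut to its longest contiguous run of bases
with per-base error probability $10^{-Q/10}$ strictly below 0.01
(i.e. Phred > 20). Ties between equally long runs go to the leftmost run
— the choice is arbitrary but must be deterministic. Trimming happens
before joining.

**Joining.** Read 2 is reverse-complemented and candidate overlaps are
scanned from the longest possible down to 14 bases; the first overlap
with 100% identity wins. There is deliberately no mismatch tolerance:
with a 100 bp generated overlap and realistic error rates this rejects
roughly 15–25% of pairs, which is accepted because rejection is
error-agnostic across alleles and therefore does not bias composition
estimates. In the overlap the shared base keeps the higher of the two
qualities. Joined reads shorter than 250 bp are removed (the boundary
length is kept).

**Mapping.** Joined reads are aligned to the reference amplicon with a
single-pass semi-global affine-gap alignment (read global, reference
overhangs free), replacing the interactive iterative mapper used in the
original workflow. Default scores: match +2, mismatch −3, gap open −12,
gap extend −1 (a gap of length $L$ costs $12 + L$). These were chosen so
that a contiguous 5–24 bp indel scores better as one affine gap event
than as scattered gaps or mismatch runs, which is what makes indel
alleles recoverable as single events. Both orientations are tried; reads
whose matching-base fraction falls below 0.7 are `UNMAPPED`. The 71 bp
key window is then read off the alignment in reference coordinates, gap
characters removed; reads that do not span both window boundaries are
`PARTIAL_SPAN` rejections.

**Enumeration.** Every distinct window sequence is counted. The report
always contains the two wild-type windows (even at zero) plus every
other sequence whose fraction strictly exceeds 1% — "over 1%", so a
sequence at exactly 1.0% is excluded. The denominator is
joined-and-mapped reads; whether the original workflow used all pairs or
mapped pairs is not documented, and this choice is recorded in the
output.

**Classification.** Precedence: exact match to an intended-edit template
window, then exact match to a wild-type window, then global alignment to
both wild-type backgrounds. The background call prefers surviving
polymorphic-site bases over alignment score; when the sites are deleted
and the scores tie, the background is `ambiguous` — never silently A or
B. A single pure indel is `INDEL`; substitutions only are `POINT`
(transversion = purine↔pyrimidine, transition otherwise); anything mixed
is `COMPLEX`. Labels reconstruct the reporting convention
(`24 bp DEL-A`, `A-T TV-A`, `T-A TV, 9 bp DEL-B`). An allele carrying a
template indel plus extra substitutions is flagged
(`template_plus_sub`); by default it does **not** count toward the
intended percentage — how such reads were tallied originally is
unstated — and `include_template_plus_sub = TRUE` switches that.

**Mosaicism call.** `NON_MOSAIC_BIALLELIC` iff the intended-edit
percentage exceeds the threshold (default 96, mirroring the "greater
than 96%" transfer-candidate cohort); `UNEDITED` iff all edited classes
together stay below 1%; otherwise `MOSAIC_EDITED`. A consequence of
tying the biallelic call to *template* edits: an embryo that is 100% a
single NHEJ indel is reported `MOSAIC_EDITED`, not biallelic. This
matches the stated contract but differs from how one historical
indel-only embryo was described; treat the call as "biallelic for the
intended edit".

## Statistics

Integer percentages round half away from zero, validated cell-by-cell
against the bundled development/mutation table (`group_rate_cells()`).
The two-sided Fisher test sums hypergeometric probabilities of all
tables no more probable than the observed one (with a $10^{-7}$ relative
tolerance against floating-point ties); degenerate margins return 1 with
a warning. The binomial logit-link model
$(\text{edited}, \text{not edited}) \sim \text{nucleic acid} \times
\text{enzyme}$ is fitted by IRLS written out explicitly (converging on
deviance change $< 10^{-8}$, with the per-iteration deviance trace
exposed and monotonicity tested); reference levels are DNA and TALEN,
the best-performing combination, so the interaction coefficient reads as
the extra log-odds beyond the main effects. Records at the 8 h injection
time point are excluded before fitting because one enzyme has no data
there, which would otherwise confound the enzyme main effect. P-values
are Wald z-tests; `lr_test()` provides the likelihood-ratio alternative.
No overdispersion correction is offered: within-embryo reads are treated
as i.i.d. draws, which is optimistic for real embryos (lineage
structure) and exact for the simulator.

## The synthetic-data generator: what it does and does not emulate

The real amplicon sequence is not available, and downstream logic is
sequence-agnostic, so loci are random sequences with the assay geometry:
550 bp amplicon, centred 71 bp key window, three A/B polymorphic sites.
Two generator choices are load-bearing:

* A fixed cut-site cassette (`T·GGCGCC·TGA`) is embedded at the window
  centre and flanks are rejection-sampled so that wild type carries
  exactly one SfoI site and no XbaI site, the 9 bp deletion template
  removes the SfoI site, and the 5 bp insertion template (`CTAGA` after
  the anchor T) creates exactly one XbaI site — on both backgrounds.
  This makes the restriction-digest diagnostics provable properties of
  every generated locus rather than accidents of a seed.
* Polymorphic sites are placed inside the window but outside a ±15 bp
  protected zone around the cassette, mirroring the real locus where the
  SNPs sit in the nuclease binding arms flanking the cut. Cut-site
  deletions up to ~24 bp therefore leave the background-diagnostic bases
  intact.

Reads are drawn per pair from the embryo's allele mixture. The
sequencing fragment is 400 bp centred on the allele's key window
(2×250 bp reads with a generated 100 bp overlap), matching the gel-sized
fragments the assay sequenced. Qualities are Phred+33 around a
configurable mean (default Q30 ≈ 0.1% error per base, jitter SD 2, with
an optional linear 3′ tail decline), and substitution errors are drawn
at exactly $10^{-Q/10}$ per base so the emitted qualities are truthful.
Sequencing indel errors are off by default to keep ground truth
unambiguous (`indel_error_rate` enables them); `error_free = TRUE`
expresses the noiseless limit exactly. Default depth is 20,000 pairs —
typical per-sample depths for this assay run from about 11,000 to
405,000 pairs, and a value near the low end of that range keeps tests
honest and fast. Every random draw
flows through an explicit seed; no global RNG state leaks.

What a green synthetic test does **not** establish: PCR amplification
bias and chimeras, lineage-structured (non-binomial) allele sampling
within an embryo, adapter read-through, quality-miscalibration, and
PhiX contamination are all outside the generator. Results on real data
additionally depend on the mapper replacement: the original interactive
mapper with iterative re-mapping may place complex indels differently
than the single-pass affine alignment used here.

## Numerical and convention choices

* Coordinates are 1-based inclusive everywhere (the R convention);
  reports are 1-based as required. Insertions anchor after the preceding
  reference base.
* Gap cost is `open + L·extend`, matching the alignment engine; the
  plain-R dynamic-programming oracle in the test suite uses the same
  convention and was verified against the engine before being frozen.
* Restriction cuts are reported at the motif start; only fragment
  presence/absence is diagnostic, so cut chemistry offsets are not
  modelled. Fragment lengths always partition the sequence length.
* Enumeration ties (equal counts) break lexicographically by sequence;
  trimming ties break leftmost; equal-score background ties are
  `ambiguous`.
* The Fisher test treats a degenerate margin as p = 1 with a warning
  rather than an error, so batch comparisons over sparse tables keep
  running.

## Known limitations

* Joining requires perfect overlap identity; at high error rates or
  short overlaps the joined-read yield drops, shrinking the effective
  depth (the stage log accounts for every discarded pair).
* Background assignment for alleles that delete all three polymorphic
  sites is `ambiguous` by construction; such alleles exist in real data.
* The `template_plus_sub` flag requires the indel to match a template's
  kind, length and position within ±2 bp; repeat-induced gap placement
  shifts beyond that fall back to plain `COMPLEX`.
* The GLM assumes binomial reads within embryo; overdispersed real
  embryos will have anti-conservative Wald p-values.
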