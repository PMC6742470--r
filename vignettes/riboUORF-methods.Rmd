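---
title: "riboUORF: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboUORF: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `riboUORF` computes, why the defaults are what
they are, and where the genuinely open design choices were decided. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The biological question and the statistic

Upstream open reading frames (uORFs) sit in the transcript leader sequence
(TLS, the 5'UTR) and, when translated, usually repress initiation at the
downstream main ORF. Under stress, reduced global initiation can paradoxically
de-repress specific uORF-controlled mRNAs. Ribosome profiling measures
where ribosomes sit; comparing how ribosome occupancy partitions between a
main ORF and its uORFs across two conditions therefore reads out changes in
uORF activity without any absolute-abundance normalization: transcript
abundance appears in both the CDS and the uORF counts of the same
transcript and cancels in their ratio. For the same reason no translational
efficiencies (and no companion RNA-seq) are required.

Per uORF *u* on transcript *t* and condition *c* the package computes

$$R_c(u) = \frac{\overline{K^{\mathrm{CDS}}_{t\cdot}} + p}
                {\overline{K^{\mathrm{uORF}}_{u\cdot}} + p},
\qquad
\mathrm{log2FC}(u) = \log_2 \frac{R_{tx}(u)}{R_{ctrl}(u)},$$

where the bars are means of size-factor-normalized counts over the
replicates of *c* and *p* is a pseudocount (default 1). Records are ranked
by $|\mathrm{log2FC}|$; the top and bottom 5% of eligible records are
flagged `strongest_change` and `least_change`. The output is a ranking,
deliberately without p-values: with typical ribo-seq replicate numbers a
quantile cut on the ratio-of-ratios is transparent and reproducible, and
flagged candidates are starting points for validation, not significance
claims.

### Sign convention

`log2FC > 0` means the main ORF gains occupancy relative to its uORF under
treatment — relieved repression. `log2FC < 0` means the uORF tightens its
grip. Both tails are biologically interesting, which is why ranking is
two-sided on the absolute value.

## Annotation reduction

One transcript per gene is kept: among protein-coding transcripts with
Gencode confidence `level` 1 (validated) or 2 (manually annotated), the one
with the greatest **mature length** (sum of exon lengths). Two open points
were decided as follows:

* *Longest by what measure?* Mature length, not CDS length. The leader is
  where uORFs live, so a measure that ignores the leader could pick a
  transcript with a truncated TLS and silently lose uORFs.
* *Ties and missing levels.* Equal mature lengths are broken by the
  lexicographically smallest transcript id (determinism across runs);
  transcripts without a `level` attribute are treated as level 3 and thus
  excluded by default — fail-closed on unknown provenance.

Transcripts whose CDS length is not a multiple of 3 exist in real Gencode
releases (selenoproteins, frameshifts, edge-case models); they are kept
with a warning by default and dropped in strict mode
(`readGtf(enforceCdsFrame = TRUE)`).

Internally all transcript-space coordinates are 0-based half-open (as in
BED); genomic ranges use the 1-based closed Bioconductor convention, and
conversions happen only at file boundaries (GTF in/out is 1-based closed,
the uORF CSV and BED12 are 0-based half-open).

## uORF discovery

A uORF is every span that begins with a configured start codon (default
canonical ATG only; near-cognate starts can be enabled) and runs to the
first in-frame stop codon, wholly inside the leader. Span lengths include
the stop codon and must lie in [9, 400] nt: 9 nt is the smallest ORF with
one codon besides start and stop, and 400 nt is the conventional upper
bound below main-ORF scale. Consequences of "first in-frame stop" and
"every start":

* each start position yields at most one uORF;
* nested or stop-sharing uORFs with distinct starts are all reported
  (multi-uORF leaders such as PPP1R15A's are the motivating case), with ids
  `<transcript>.u1, .u2, ...` ordinal by transcript start;
* peptide length is `length_nt/3 − 1` amino acids — initiator methionine
  counted, stop codon not. The published PPP1R15A spans reproduce their
  published peptide lengths (81 nt → 26 aa, 69 nt → 22 aa), which is what
  fixes the "stop codon included" convention.

Codons containing `N` never match a start or a stop: on ambiguous sequence
the scanner stays conservative. uORFs overlapping the main CDS are excluded
by default (`requireContained`); an off switch exists for exploratory use
because the convention in published uORF catalogues varies.

Discovery is replaced in *comprehensive mode* by reading a pre-built uORF
annotation CSV, in which case no read-evidence filter is applied — uORFs
with zero counts are retained on purpose and only excluded from the
quantile ranking. In discovery mode a minimal evidence filter (summed raw
counts ≥ 1 by default) stands in for initiation-site calling: this package
deliberately does not model translation-initiation-site statistics, so its
experiment-specific annotations are coverage-based, not TIS-based.

## P-site counting

Reads are reduced to a single inferred P-site: the base 12 nt into the read
from its 5' end in transcript direction, walking through aligned blocks and
skipping junction gaps. The choices here:

* *Point assignment rather than overlap counting.* A 30-nt RPF spanning the
  uORF/CDS boundary would otherwise count to both features; a P-site
  assigns it to exactly one of any set of disjoint features.
* *Fixed 12-nt offset, length window 25–35 nt.* The standard convention
  for RPFs around 28–32 nt; both are configurable
  (`rpfCountParam()`), but no metagene auto-calibration is attempted —
  input BAMs are assumed to be processed ribo-seq data.
* Secondary and supplementary alignments are ignored by default
  (multimapper double-counting), reads are not deduplicated (no UMI logic;
  pre-processing is out of scope), and `forward` strandedness is the
  default (read strand equals transcript strand).

Boundary behaviour is exact and tested: a P-site on the first base of a
feature counts, on the past-the-end base it does not.

## Normalization and eligibility

Size factors are the median-of-ratios estimator computed on the **CDS
table only** and applied to both tables. CDS features are long and their
counts stable; uORF features are short, sparse, and exactly the features
whose between-condition behaviour is under test, so including them in the
size-factor estimate would let the signal distort the normalization.
Features with a zero in any library are excluded from the median, as usual.

The pseudocount (default 1.0) keeps ratios finite for zero-count uORFs,
which comprehensive mode deliberately retains. Such raw-zero uORFs are
additionally excluded from the quantile ranking: a ratio made of two
pseudocounts carries no evidence, and with the published set sizes
(1933 annotated, 55 without reads) the eligible count 1878 at the 5% cut
gives a selection of 94, while 939 eligible gives 47 — the cut size is
`round(q × N_eligible)` with round-half-up, which is what reproduces both
published selection sizes simultaneously.

One numerical subtlety: the median-of-ratios reference (geometric mean)
distributes a per-library scaling `c` across all factors as
`c^{1/m}`, so *normalized values* are only scale-invariant up to a common
factor. That common factor cancels exactly in the CDS/uORF ratio when the
pseudocount is zero; with a nonzero pseudocount the invariance is
approximate to order `p / mean count`. The exact-invariance property is
therefore tested at `pseudocount = 0`.

## The synthetic world

`syntheticSpec()` describes the reference simulation; `makeWorld()` and
`simulateRpfs()` realize it deterministically from its seed. Defaults, with
reasoning:

| parameter | default | why |
|---|---|---|
| `nGenes` | 200 | large enough for a stable 5% quantile, small enough to re-simulate in seconds |
| `repsPerCondition` | 4 + 4 | replicate structure of a typical two-condition ribo-seq study |
| `tlsLen` | 150–300 nt | common human leader lengths, room for 1–2 uORFs |
| planted uORF lengths | 9–75 nt (multiples of 3) | mean ≈ 40 nt, matching short human uORFs |
| `uorfAllocation` | 0.15 | strongly translated uORFs; baseline main-ORF-to-uORF ratios ≈ 5–6, the regime of the classic stress-responsive leaders |
| `baseReadsPerFeature` | 500 | per-transcript library depth giving tens of uORF reads per library |
| `nbDispersion` | 0.1 | typical biological replicate dispersion for count data |
| `nPlantedEffects`, `effectLog2` | 10 genes, ±2 | clearly separated from null variation yet within the biologically observed range |
| `readLen` | 28–32 nt | the canonical RPF length window |

Design notes: leader backgrounds are generated and then *scrubbed* of every
ATG that is not a planted start, and planted uORF interiors use pyrimidine-
only codons (no A/G), so no start or stop codon can arise in any frame or
across any junction — discovered uORFs equal planted uORFs exactly, making
the discovery acceptance check exact rather than statistical. Reads are
placed so the P-site lands uniformly inside the intended feature; they are
gapless within exons and acquire `N`-gaps only by crossing exon junctions.
Planted effects multiply the CDS:uORF allocation odds by `2^effect` in
treatment libraries, so the expected log2 ratio shift equals the planted
effect (attenuated slightly by the pseudocount).

What the simulation does **not** emulate — and hence what passing tests do
not show about real data: sequencing errors and soft-clipping, multimapping
ambiguity, non-uniform footprint distributions along ORFs (initiation
peaks, pausing), leader-initiated ORFs overlapping the CDS, transcript-
level quantification uncertainty, and uORFs created or destroyed by leader
isoform switching. Results on real data will be noisier than the planted-
effect recovery suggests; the simulation validates the machinery, not the
biology.

## Degenerate inputs and numeric conventions

* A transcript without a leader (`cdsStartT == 0`) has no uORFs; its empty
  TLS is valid.
* No feature with positive counts in every library is a fatal error for
  size factors (the error message suggests checking library quality).
* Quantile flags: ties in `|log2FC|` break by `uorf_id`; the `least_change`
  set is drawn from records not already flagged strongest, so flags are
  mutually exclusive even in tiny sets.
* A uORF missing from the count table counts as zero (logged); a uORF
  whose transcript has no CDS feature is skipped (logged).
* Written normalized tables are rounded to 6 decimals; identity of
  re-read values is guaranteed to that precision.

## Problem sizes used by the shipped checks

The test suite exercises the scanner against an exhaustive brute-force
oracle on 1,000 random leaders of length 0–600 nt, coordinate mapping
against a per-base walk oracle on random multi-exon models, and the full
pipeline on worlds of 4–20 genes; the acceptance script and one acceptance
test regenerate the full 200-gene reference world. These sizes keep a
complete run in the low minutes on a single CPU while covering every code
path, including minus-strand and junction-spanning features.

## Known limitations

* Initiation-site statistics are out of scope: experiment-specific
  discovery is coverage-based and will include uORFs translated only
  elongation-like, and miss uORFs with initiation evidence but sparse body
  coverage.
* Only canonical `{TAA, TAG, TGA}` stops and (by default) ATG starts;
  no stop-codon readthrough, no overlapping-ORF (oORF) classes, no
  selenocysteine models.
* One transcript per gene means uORFs private to discarded isoforms are
  invisible.
* GFF3 input is not supported; the Gencode GTF dialect is expected.
* The ranking has no error control; downstream use should treat the
  flag sets as candidate lists.
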