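---
title: "Methods: Sanger sequence-based typing in SangerHLA"
author: "SangerHLA Developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Sanger sequence-based typing in SangerHLA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SangerHLA)
```

# The problem

The HLA genes are the most polymorphic loci in the human genome; clinical
typing must decide which *pair* of database alleles a patient carries.
Sanger sequencing of a diploid template superimposes both alleles in one
electropherogram, so the observable is a string of possibly degenerate
bases: a position where the alleles differ shows two peaks and is reported
as a 2-fold IUPAC code. Typing is then an inverse problem — find the
allele pairs whose positionwise union ("signature") explains the
degenerate read — and is intrinsically ambiguous, because distinct pairs
can share a signature (the cis/trans phase of two heterozygous sites is
invisible to a single trace). Group-specific sequencing primers (GSSPs),
which amplify and sequence one allele group alone, provide the extra
evidence that resolves such ties.

This vignette records the model, parameter and design choices behind each
stage of the package; the README shows the surface API.

# Heterozygote calling from peak geometry

For base $i$ at trace-point position $p_i$ the search window is
$[\,p_i - (p_i - p_{i-1})/2,\; p_i + (p_{i+1} - p_i)/2\,]$ — half the
distance to each neighbouring peak. The first and last bases lack one
neighbour; the missing half-window falls back to half the *mean*
inter-peak spacing of the read, which is the least-surprising stand-in for
a typical peak pitch (≈12 trace points on 3730-class instruments).

A secondary peak calls the position heterozygous when all three hold:

* its apex is a **local maximum** of another channel inside the window.
  Local maxima are points strictly above the left neighbour and at least
  the right neighbour, so a flat-topped (clipped) peak counts once, at its
  first point;
* the apex lies within `distanceUnits` trace points of the primary apex
  (default 4). We read "distance" as apex-to-apex distance in trace
  points, since every other quantity in the window formulas is a
  trace-point position. An alternative reading — distance from the window
  boundary — exists; the parameter makes the choice adjustable;
* its height strictly exceeds `ratioThreshold` (default 0.3) times the
  primary apex height. "Maximum signal" is read per base (the primary
  apex at that position), not as the global trace maximum: classification
  is per-position, and a global reference would make calls depend on
  unrelated parts of the trace.

The primary channel is the one with the greatest signal at the called peak
position; ties (exactly balanced dyes) resolve in channel order
A < C < G < T, and a secondary-channel tie resolves by greater height then
the same channel order, so calls are deterministic. Only 2-fold degenerate
codes are ever *emitted* (a diploid has at most two alleles per site);
3/4-fold codes are accepted on input. Positions whose four channels are
all zero are called `N`. Quality values do not gate heterozygote calls by
default (`minQuality = 0`); whether production SBT tools gate on quality
is not documented, so the knob exists but is off.

# Degenerate alignment

Each degenerate base is an unordered diploid pair: a plain base $X$ is
$(X,X)$, a 2-fold code its two bases. A column comparing sample and
reference scores the size of the maximum one-to-one matching between the
two pairs — 2, 1 or 0 — and internal indels score −1. Columns scoring 0
are *recorded* as mismatched sites but not negatively scored: the
candidate ranking uses mismatch counts, so the score separates "how well
aligned" from "how many unexplained sites". For codes decoding to more
than two bases (possible in references, never emitted by the caller) the
maximum-matching rule is generalised: score 1 if the decoded sets
intersect, else 0. This degenerate-vs-degenerate rule is this package's
generalisation of the one-sided scheme; the 15×15 table is fully exercised
against an exhaustive-pairing oracle in the tests.

Alignment is semi-global with free end gaps **on both sequences**: reads
begin and end outside exon boundaries, and may cover only part of an exon.
Gaps are linear (open = extend = −1) because the scheme defines a single
indel score. Traceback ties prefer column over deletion over insertion —
fewest gaps, deterministic output. The optimum over the last row/column of
the dynamic-programming matrix prefers the bottom-right-most cell. The DP
runs in C++ (Rcpp); the R-level oracle in the test suite recomputes the
optimum by memoised recursion over all monotone alignments.

Two reference-only symbols get special treatment: `.` (a column that is a
gap in the alignment) costs nothing to skip and is never a mismatch; `*`
(unknown sequence) aligns neutrally, like `N`, and is never a mismatch —
unknown stretches must not exclude alleles.

# Reference model and pair enumeration

Alleles live in shared multiple-alignment coordinates (0-based half-open
internally; 1-based text formats are converted at the parse boundary).
Both the IMGT-style alignment text (first allele spelled out, `-`
identity, `.` gap, `*` unknown, `|` exon boundary) and a simple TSV
dialect (`allele_name`, `exon`, `sequence`) are supported; the parsed,
expanded form serialises to a TSV plus JSON manifest — a transparent flat
file store rather than an embedded database, chosen for testability. Exon
numbers for alignment segments default to 1..n and can be supplied
explicitly, since header coordinate lines in alignment files are not
machine-stable.

The per-locus consensus is the positionwise IUPAC union of all observed
bases. Because references are pre-aligned, each read is aligned **once**
to this consensus and projected into alignment coordinates; all
allele-pair comparisons are then positionwise, avoiding a quadratic number
of DP alignments. This is the central engineering decision the
enumeration stage rests on.

Strand merging takes the single covering strand's call, the shared call
when both agree, and the higher-quality call (ties to forward) with a
conflict flag when they disagree. A read whose alignment score falls below
`minScoreFrac` (default 0.5) of its maximum attainable score is rejected
as a wrong-locus/orientation input rather than silently merged.

A candidate pair's mismatch count is the number of covered columns where
the sample code and the pair signature differ *as sets*: a heterozygous
call that the pair does not predict (or vice versa) is a mismatch, because
heterozygous evidence must be explained. Uncovered columns and columns
where the signature is `*` or all-gap are skipped and reported as
coverage. Candidates are ranked by mismatch count, then total column
score, then name order; the ranking keys beyond mismatch count are not
prescribed anywhere, so score-then-name was chosen for determinism. The
display window `maxMismatch` (default 5) mirrors the short ranked list a
lab user reviews. Before pairing, alleles whose *one-sided*
incompatibility (covered columns whose base falls outside the sample code)
exceeds `maxMismatch` are pruned — every such column is necessarily a
mismatch for any pair containing the allele, so pruning is lossless.
Multi-exon samples sum mismatches over all covered exons. A result is
unambiguous when exactly one two-field-distinct pair attains the minimum
mismatch count.

# GSSP resolution

No public schema exists for commercial GSSP kits, so definitions are
alignment-anchored records: identifier, locus, exon, half-open column
region, and a degenerate *selector* the amplified allele must match over
that region. Amplifiability is modelled as selector match rather than
primer thermodynamics — GSSPs act as allele-group selectors, and a
sequence-level model keeps the filter deterministic and desk-testable.
A read is matched to a definition by aligning it to each candidate locus
consensus and taking the selector-consistent definition with the largest
region overlap (ties by identifier); inconsistent reads raise an error
listing the three nearest misses. A candidate pair survives filtering iff
one of its alleles both matches the selector and equals the read over the
covered region columns; bases outside the region are ignored, degenerate
read positions are ignored (with a non-specific-amplification warning
above `maxHetFrac`, default 0.2), and ranking order is preserved. The
automatic filter is the headless equivalent of the manual combine-and-
filter step a GUI user performs; callers who prefer to inspect evidence
can apply definitions one at a time.

# The simulator: what it does and does not show

`makeReference()` draws a founder sequence uniformly and substitutes each
column of every other allele independently (default rate 0.02 — the
same order as exon-level divergence between alleles of one HLA locus;
30 alleles × two 270-column exons is the default locus size, a realistic
exon-2/3 workload while staying desk-scale). `simulateSample()` renders
each truth base as a Gaussian peak (σ = 2.5 points, spacing 12, amplitude
1000) with linear superposition, balanced heterozygous peaks
(`hetBalance = 1`), optional multiplicative per-peak amplitude noise
(default 5%) and optional ±2-point position jitter to exercise the
distance criterion. `makeAmbiguousCase()` plants the classic cis/trans
pattern — haplotypes A–C, A–T, G–C, G–T at two columns — so two pairs
share one signature, plus a GSSP selecting exactly one true allele.

What passing on simulated data shows: the geometric heterozygote rule, the
coordinate bookkeeping, the enumeration/ranking logic and the GSSP filter
are correct under the stated peak model. What it does not show: robustness
to dye blobs, mobility shifts, baseline drift, quality decay toward read
ends, primer artefacts, or indel-carrying alleles — none of which the
renderer models. Results on real instrument data therefore depend on
upstream trace quality in ways these tests cannot certify.

# Numerical and degenerate-input choices

* Trace-point and alignment coordinates are 0-based internally; ABIF
  stores analyzed traces (`DATA` 9–12), and edited base-call tags (index
  2) are preferred over originals (index 1) when both exist, matching
  what a user last saw in a trace editor (configurable).
* Missing quality tags are an error in strict mode; permissive mode fills
  0 with a warning.
* Empty base lists are valid everywhere (empty calls, header-only
  reports), not errors; an empty candidate list is a "no typing" result.
* All randomness flows through explicit seeds; identical inputs and
  parameters produce byte-identical JSON reports, and a saved session
  reproduces its results on reload without re-reading chromatograms.
* Problem sizes in the test suite (30-allele locus, 270-column exons, 200
  simulated samples, 500 aligner-oracle pairs, 20 ambiguity cases) were
  chosen as the smallest scales at which every code path — pruning,
  multi-exon coverage, tie-breaking — is exercised.

# Known limitations

* Indel heterozygosity (frame-shifted superposition after a heterozygous
  indel) is not modelled; alleles differing by indels from the consensus
  align, but a mixed trace of them would not be deconvolved.
* Re-basecalling from raw signal is out of scope: peak positions come
  from the instrument's `PLOC` tag.
* Four-field resolution, G/P group collapsing and population-frequency
  priors are out of scope; reporting is two-field.
* SCF/ZTR trace formats are not read; only ABIF.
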