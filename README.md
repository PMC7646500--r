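# SangerHLA

A headless, scriptable engine for Sanger sequence-based typing (SBT) of
highly polymorphic loci — first and foremost the human leukocyte antigen
(HLA) class I and II genes, whose accurate typing underpins solid-organ and
bone-marrow transplantation matching. It is aimed at typing-lab
bioinformaticians who want the analysis backend of an SBT workstation
(base calling, allele assignment, ambiguity resolution) as reproducible R
functions and a command-line tool rather than a GUI.

## What it does

A diploid sample sequenced by capillary Sanger produces an electropherogram
in which the two alleles are superimposed: positions where they differ show
two peaks. The engine works in four stages.

**1. Heterozygote base calling.** For base *i* with peak position
*p<sub>i</sub>*, the search window is

```
R_low  = p_i − (p_i − p_{i−1}) / 2
R_high = p_i + (p_{i+1} − p_i) / 2
```

A position is called heterozygous when a second channel has a local maximum
inside `[R_low, R_high]`, within 4 trace points of the primary apex, whose
height exceeds 0.3 × the primary apex height; the call is then the 2-fold
IUPAC-IUB code of the two bases (e.g. A/G → `R`). Both constants are
parameters (`hetCallParams()`).

**2. Degenerate semi-global alignment.** A degenerate base stands for an
unordered allele pair (A ≡ (A,A), R ≡ (A,G)). A column comparing sample
base *s* with reference base *r* scores

```
Score(s, r) = 2  (both alleles match)
              1  (one allele matches)
              0  (mismatch)
             −1  (indel)
```

so A vs A = 2, R vs A = 1, G vs A = 0 (`scoreBases()`). Alignment is
semi-global — end gaps are free, because reads extend beyond and may cover
only part of an exon (`semiglobalAlign()`, dynamic programming in C++).

**3. Allele-pair enumeration.** Forward and reverse calls are merged into a
sample consensus in reference alignment coordinates (`mergeReads()`). For
every unordered pair of reference alleles, its *signature* — the
positionwise IUPAC union of the two alleles — is compared to the sample;
candidates are ranked by the number of mismatched sites (`enumeratePairs()`,
`rankReport()`), reported at two-field resolution (`A*01:01`).

**4. GSSP ambiguity resolution.** Distinct pairs can share a signature
(classic cis/trans ambiguity). Group-specific sequencing primer (GSSP)
reads sequence one allele alone; batch-imported GSSP definitions
(`importGssps()`) are automatically matched to reads (`identifyGssp()`) and
used to filter the ambiguity set (`filterWithGssp()`).

A simulator (`makeReference()`, `simulateSample()`, `makeAmbiguousCase()`)
renders Gaussian-peak diploid chromatograms with known truth, so the whole
pipeline is testable without instrument data. ABIF (`.ab1`/`.fsa`) traces
are read and written natively (`readABIF()`, `writeABIF()`).

## Worked example

```r
library(SangerHLA)

p   <- simParams(nAlleles = 10, exonLength = 100, seed = 7, amplitudeNoise = 0)
ref <- makeReference(p)                              # 10-allele locus "SYN"
sim <- simulateSample(ref, "SYN*02:01", "SYN*05:01", p, seed = 3)

fwd <- callBases(sim$forward)                        # degenerate IUPAC calls
rev <- callBases(reverseOrient(sim$reverse), source = "reverse")
cons <- mergeReads(fwd, rev, consensusSeq(ref, "SYN"),
                   sampleID = "demo", locus = "SYN")
res <- rankReport(enumeratePairs(cons, ref), sampleID = "demo", locus = "SYN")
res
```

```
TypingResult 'demo' SYN: typed
  SYN*02:01 + SYN*05:01  mismatches=0 score=400
  SYN*01:01 + SYN*02:01  mismatches=1 score=399
  SYN*01:01 + SYN*05:01  mismatches=2 score=398
  SYN*01:01 + SYN*01:01  mismatches=3 score=397
  SYN*02:01 + SYN*02:01  mismatches=3 score=397
  assignment: SYN*02:01 / SYN*05:01
```

The simulated pair is recovered with zero mismatched sites: its combined
signature explains every one of the 200 aligned columns (score 400 = 200
columns × 2), while the runner-up pair leaves one site unexplained. The
`mismatches` column is exactly what a lab user ranks candidates by; an
`AMBIGUOUS` flag on the assignment would signal that a GSSP read is needed.

The same pipeline is scriptable from a shell via `exec/sangerhla`
(`type`, `simulate`, `db-build`, `gssp-import`, `report` subcommands).

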