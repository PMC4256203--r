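---
title: "Comparative sialotranscriptome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative sialotranscriptome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sialoseq)
```

## The analysis this package implements

Triatomine bugs such as *Triatoma infestans*, the Chagas-disease vector,
inject saliva rich in anti-hemostatic proteins while blood feeding. Studies
of the salivary-gland transcriptome (the *sialotranscriptome*) typically
sequence a handful of pooled libraries — here a 2-stage (nymph/adult) by
5-population design of ten libraries — map reads onto assembled coding
sequences (CDS), and ask three questions:

1. **Which transcripts differ between stages or populations?** Counts per
   CDS are pooled within each side of a contrast and compared with a
   normalized fold-change ratio plus a per-CDS chi-squared test.
2. **How does expression distribute over functional classes?** CDS are
   classified (Secreted, Housekeeping, Transposable element, Viral,
   Unknown) from annotation text, and per-class summaries of counts and
   RPKM are built.
3. **Which gene classes are under diversifying selection?** SNPs called
   against the CDS are classified synonymous (S) or non-synonymous (NS)
   and scaled to rates per 100 codons; a class NS/S well above 1 (as for
   secreted salivary proteins) is the signature of interest.

A companion module summarizes rDNA spacer (ITS-1/ITS-2) alignments into
haplotypes and per-column variability statistics, the marker set used to
select genetically distinct strains.

Because the original raw data are hundreds of millions of reads, the
package ships a synthetic-data generator that emulates the study design
with known ground truth; all end-to-end validation runs on it.

## Read QC and counting

Reads are end-trimmed while terminal base qualities are below 10 and
rejected when the trimmed mean quality is below 20 or fewer than 25 bases
remain (`trim_and_filter()`). Counting (`count_library()`) uses an exact
25-mer seed index over both strands of every CDS followed by a banded
extension that allows at most one gap. This is a contract-level
re-implementation of word-size-25 `blastn` mapping, not a bitwise clone:
at the 96% identity floor over ~300-base reads, a true alignment contains
an exact 25-mer with overwhelming probability, so seed-and-extend finds
the same top-scoring CDS set. Scoring is +1 match, −2 mismatch, −3 gap
opening, −1 per extended gap base (configurable); identity is matches over
aligned read length. The gap search extends to 10 bases by default
(`max_gap_len`), ample for the one-gap budget.

Ties are the subtle part. Up to five CDS tied at the maximum score each
receive a full count (`tie_mode = "each"`), so the per-library total R is
the sum of per-CDS counts and can exceed the number of distinct mapped
reads — matching the per-CDS accrual framing of the original analysis. A
`"fractional"` mode (1/k per tied CDS) is available. Reads tied across
*more* than five CDS are discarded and tallied rather than truncated to an
arbitrary five, which would make counts depend on candidate order.

## Differential expression

For groups 1 and 2 with per-CDS reads `r1`, `r2` and totals `R1`, `R2`,
the fold statistic is the normalized ratio `r1*R2 / [R1*(r2+1)]` (and its
mirror); the +1 pseudocount caps the ratio when the comparison group is
empty. Significance comes from a Pearson chi-squared (1 df, no continuity
correction) on the 2x2 table `[[r1, R1-r1], [r2, R2-r2]]`. A CDS is called
overexpressed when the ratio is at least 10 *and* the test is significant.

Two choices were genuinely open and are exposed as parameters:

* **Multiple testing.** No threshold or correction is specified for the
  original per-CDS tests. With ~10^4 CDS per contrast an uncorrected
  α = 0.05 is anti-conservative, so the default is Bonferroni over the CDS
  tested per contrast (`mtc = "bonferroni"`), with `mtc = "none"` to
  reproduce uncorrected behaviour.
* **RPKM.** Defined here as `reads * 1e9 / (length_nt * total_mapped)`
  with `total_mapped` the library's R; multi-library ("overall") RPKM
  pools counts and totals before applying the formula (`pooled_rpkm()`)
  rather than averaging per-library RPKM — pooling is the natural reading
  of an "all libraries combined" value and is what `rpkm_matrix()` feeds
  the heat-map filter.

Heat-map preparation (`row_average_normalize()`) drops rows with overall
RPKM below 20, then divides each row by its own mean so every surviving
row averages 1. Where the original figure legend mentions Z-scores while
the methods text says row-average, row-average is primary here and
`method = "zscore"` is the option.

One consequence of the pseudocount worth knowing: in the permissive limit
(fold 1, α 1) a CDS with balanced low counts, e.g. `r1 = r2 = 5`, has both
ratios equal to 5/6 and is *not* called; the "calls everything expressed"
intuition only holds for one-sided CDS. The tests document this.

## Polymorphism statistics

SNP calls are accepted when depth ≥ 20 and quality ≥ 13 (both inclusive).
Each accepted SNP is classified against the reference codon in frame 0
from CDS base 1 under the standard genetic code (hand-coded in
`CODON_TABLE` and verified against an independent translation oracle over
all 576 single-base codon changes); stop↔sense changes are
non-synonymous. Multiple SNPs in one codon are classified independently
against the reference codon — the per-SNP convention of the original
custom program — not haplotype-aware. Codons containing `N` are excluded
from both counts and denominators; CDS whose length is not a multiple of
3 are rejected outright rather than silently re-framed.

Rates are `100 * count / n_codons` per CDS. Class summaries average
per-CDS rates with equal weight (length-weighting is the other defensible
choice; equal weighting matches the reported per-class mean ± SE
structure) and report NS/S as the **ratio of class means**, not the mean
of per-CDS ratios — the latter is undefined for CDS with S = 0 and does
not reproduce the published class ratios. Only CDS with at least one
accepted SNP enter class tables, mirroring the "polymorphic CDS" universe
of the original tables; the per-library comparison
(`per_library_polymorphism()`) restricts every library to the *shared*
union of polymorphic CDS so its bars are comparable.

## Haplotype and alignment-column summaries

`collapse_haplotypes()` groups identical aligned sequences, labelling
ITS-2 haplotypes by numbers and ITS-1 by capital letters in order of first
appearance (`composite_haplotypes()` joins them into CH labels). Column
classification is mutually exclusive: a variable column containing a gap
is *gapped*; gap-free variable columns are *substitutions*, split into
parsimony-informative (≥ 2 bases each in ≥ 2 sequences) and singleton
sites. This reproduces the published accounting where 13 variable ITS-2
positions = 3 substitutions + 10 gapped. Ambiguity codes are treated as
missing and ignored for distinct-state counting. Note that the published
ITS-2 gapped percentage (2.05%) does not recompute from its own counts
(10/481 = 2.08%), likely a typo; the package reports recomputed values.

## The synthetic-data generator

`sim_config()` fixes the study conditions; its defaults are the package's
standing choices, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| design | 2 stages × 5 regions = 10 libraries | the study design |
| class proportions | 0.20 / 0.65 / 0.05 / 0.004 / 0.096 | published assembly composition |
| protein length | log-normal, mean 398 aa, sdlog 0.45, ≥ 104 codons | published mean protein size; floor keeps every CDS longer than a read |
| reads per library | 50,000 | ~1000× scale-down of the real ~40M, enough for ≥ 10× effects to be unambiguous |
| read length | 300 nt | the sequencing chemistry's read length |
| baseline expression | log-normal, sdlog 1.0 | wide dynamic range typical of salivary libraries |
| per-library noise | log-normal, sdlog 0.25 | modest library-to-library variability (no biological replicates) |
| overexpressed fraction | 3% | ~326 of 11,188 CDS were called ≥ 10× in some contrast |
| planted folds | log-uniform 10–1000 | reported effects range from ~10× to > 1000× |
| error rate | 0.002/base | post-QC substitution error scale |
| bad reads | 5% below mean Q20; 30% with Q2–9 3' tails | gives the QC filter real work |
| SNP rates | per-class S/NS per 100 codons from the published class table | secreted-like classes NS-rich, housekeeping S-rich |
| low-confidence SNPs | 10% below the 20/13 thresholds | exercises the filter |

Read qualities use a two-component model (good cores Q35–40, low tails
Q2–9, whole bad reads Q12–19) with one quality value per read segment — a
deliberate simplification sufficient for contract testing, not an
error-profile model. The generator does **not** emulate assembly
artifacts, isoforms, chimeras, realistic Illumina error spectra, or
coverage biases; passing recovery tests therefore demonstrates the
correctness of the counting/testing/rate machinery under the stated
model, not robustness to real-data pathologies upstream of it.

Planted SNPs are chosen from each codon's single-base substitutions whose
effect is verified against the genetic code at generation time, so
generator truth and classifier output must agree exactly. The optional
`paralog_families` knob duplicates CDS at ~97% identity with the
divergence concentrated in one window, so reads from conserved stretches
genuinely exercise the tied-match rule.

## Recovery metrics and problem sizes

`run_synthetic_pipeline()` executes simulate → QC → map → count →
contrast → call → SNP-rate on one configuration. Recovery is scored
against planted truth: a planted effect is detected when its CDS is
called in its own contrast with the right direction. A call counts as a
false positive only when *no* planted effect implies it — a strong region
effect legitimately reappears as `over_in_2` in the other regions'
contrasts, because the pooled "others" side carries it; treating those as
errors would penalize correct inference.

The standing validation configuration is 2,000 CDS and 50,000 reads per
library (10 libraries), under which planted ≥ 10× effects are recovered
with sensitivity ≥ 0.9 at FDR ≤ 0.1 and class NS/S ratios within 15% of
their configured values; `scripts/acceptance.R` recomputes these from
scratch at a caller-supplied seed. The misses concentrate, as they
should, in planted folds near the 10× threshold on weakly expressed CDS,
where the pseudocount keeps the estimated ratio just under 10.

## Numerical and degenerate-input conventions

* All on-disk coordinates are 1-based inclusive (VCF convention);
  conversions live in the I/O layer only.
* Degenerate 2x2 tables (a zero expected cell) return chi2 = 0, p = 1.
* `ns_over_s()` is `NA` when the mean S rate is 0; SE columns are `NA`
  for single-CDS groups.
* All-zero expression rows cannot be row-normalized and are dropped.
* Mapping candidate order is fixed (lexicographic CDS ids) so counts are
  reproducible run to run; everything random flows from a single integer
  seed.

## Known limitations

* The mapper targets the ≥ 96% identity regime; it is not a general
  aligner and does not emit alignments, only counted assignments.
* The keyword vocabulary (~70 entries) is a documented approximation of
  the original ~300-word list, which was never published; classification
  fidelity on real annotations depends on extending it.
* NS/S here is a raw count ratio, not a codon-model dN/dS; it has no
  correction for the different numbers of synonymous and non-synonymous
  sites per codon and should be read comparatively across classes.
* Chi-squared on pooled counts ignores biological replication (the
  original design has none); with per-library variability the test is
  anti-conservative, which is why calls also require a 10× ratio.
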