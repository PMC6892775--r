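---
title: "Methods: mutation profiling of radiation-mutagenized re-sequenced cohorts"
author: "radmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation profiling of radiation-mutagenized re-sequenced cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmut)
```

# The experimental design this package models

A mutagenized cohort consists of several independent mutant lines derived
from irradiated seed, each selfed for a few generations (M4–M6 is typical)
and re-sequenced as a single plant, together with the non-mutagenized
parental line ("wild type"). Because each line descends from an independent
M1 plant, a genuine induced mutation is expected in exactly one line;
variants present in several lines, or in the wild type, reflect pre-existing
divergence between the cohort's parent and the reference assembly
("background"), not mutagenesis. That expectation is what the whole filter
is built on.

# The reliable-mutation filter

For every (chromosome, position, ref, alt) site, each sample's variant
allele frequency is computed from AD read counts,
VAF = alt / (ref + alt). A site is retained as a line-private mutation iff

- exactly one mutant line has VAF in `[focal_min_vaf, focal_max_vaf]`
  (default [0.25, 1.00]), and
- every other sample — wild type included, samples without a call counting
  as 0% — has VAF ≤ `other_max_vaf` (default 0.10).

All boundaries are inclusive on the retaining side: a call at exactly 25%
is kept, another sample at exactly 10% does not disqualify a site. A
retained call with VAF ≥ `hom_min_vaf` = 0.75 (inclusive) is homozygous.
Sites with zero informative depth are defined to have VAF 0 with a warning:
for the focal line this can only reject, and for other samples absence of
evidence satisfies the 0% requirement. We deliberately do not require
wild-type coverage at every site; requiring it would discard real mutations
in regions where the deep wild-type run happens to have a gap, while the
exclusivity across the remaining lines already protects against most
background leakage.

Choosing the VAF denominator as ref + alt depths (AD) rather than total
depth (DP) matters at sites with non-informative reads: AD-based VAF is the
quantity the filter thresholds describe, and it makes the 25%/75%/10%
boundaries exact binomial statements about the sampled alleles.

# Classification

Variants are first normalized: shared padding bases are trimmed (keeping
the conventional anchor base for pure indels) and indels are left-aligned
against the reference, so that equivalent representations of the same edit
compare equal. Within each line, maximal runs of single-base substitutions
at strictly consecutive positions are merged into one multi-nucleotide
variant (MNV); a one-base gap breaks the run. Merging is per line — two
lines substituting adjacent bases remain two independent SBSs. The merged
record is homozygous only if every member is.

Size rules then classify each record: substitutions of span 1 are SBS, span
≥ 2 are MNV; length changes of 1–10 bp are InDels and more than 50 bp are
SVs. The definitions leave 11–50 bp open; we surface that gap as an explicit
`unclassified` class rather than silently folding it into either neighbor,
so per-line totals remain comparable with the four-class convention while
nothing is hidden.

# Spectra and context

The substitution spectrum is directional on the reference strand (12
classes, G>A and C>T kept separate) because the analyses it feeds report
those classes separately. Ti/Tv is (A>G + G>A + C>T + T>C) over the
remaining eight classes and is reported as undefined — never computed by a
division — when there are no transversions.

For dinucleotide context, a G>A site is "at a purine dinucleotide" when the
reference base immediately 5′ **or** 3′ of the mutated G is A or G; C>T
sites are tested against pyrimidine neighbors. The direction is not
specified by the convention this follows, so `side = "5prime"`/`"3prime"`
expose the restricted variants, with `either` the default. The analysis is
strictly on the reference strand: a G>A with only a 3′ pyrimidine neighbor
is *not* rescued by being a C>T with a 5′ purine on the other strand. A
mismatch between the recorded ref allele and the genome base is a hard
error, since it means the coordinates and the FASTA disagree.

Reported percentages are rounded half-up to two decimals
(`round_half_up()`), matching the usual table print style; base R's
round-half-to-even would differ in the last digit on exact ties.

# Window landscape and HF/LF regions

Windows tile each chromosome from position 1 (1-based inclusive; only BED
output is 0-based half-open), with the last window short. The default
window is 1 Mb, with 100 kb for fine-grained profiles. A window is
high-frequency (HF) when its per-bp mutation frequency is at least
`hf_multiplier` (default 4) times its chromosome's mean frequency **and**
it contains at least 2 mutations; low-frequency (LF) windows contain none.
The multiplier is our operationalization — the motivating examples show
ratios near 5–6× — and both it and the minimum count are exposed rather
than fixed silently. Adjacent qualifying windows merge into regions, and
HF versus LF frequencies are compared with a Welch two-sample t-test.

InDel–SBS proximity asks, for each InDel in a treatment's pooled mutation
list, whether any SBS lies within `distance` bp on the same chromosome.
"Adjacent" is not a quantified notion in the literature this mirrors, so
the default 10 kb radius comes with a sensitivity table over 1/5/10/50 kb.
Treatment-level analyses pool all lines of a treatment, since per-line
counts are too sparse for windowed statistics.

# Effect annotation

Each mutation position is assigned one feature with fixed precedence
exon > splice_region > UTR5 > UTR3 > intron > upstream > downstream >
intergenic ("exon" meaning exonic *and* inside the CDS interval). General
annotators emit every overlapping annotation; a single-category call per
mutation is what downstream percentage tables need, hence the explicit
precedence. Upstream/downstream windows are 5 kb from the transcript
bounds, strand-aware — the common annotator default, configurable. Splice
region is the first 2 intronic bases at each exon boundary.

Coding substitutions are evaluated by joint replacement of all affected
codons on the coding strand (an MNV spanning a codon boundary changes both
codons at once, not base-by-base): identical amino acids → silent, a new
stop where the reference had none → nonsense, loss of the reference stop →
stop_lost, otherwise missense. CDS indels are frameshift when the length
change is not a multiple of 3; a frameshift counts as functionally
affecting its gene only when the shifted translation terminates before the
original stop, which matches the premature-termination reading of
"functionally affected" (nonsense and stop_lost always count). Translation
uses the standard genetic code via a codon lookup table built from
Biostrings' `GENETIC_CODE`.

# The selfing-inheritance model and M1 estimation

A new mutation arises heterozygous in the M1 plant. Each selfing
generation sends a heterozygous mutation to homozygous with probability
1/4, keeps it heterozygous with probability 1/2, and loses it with
probability 1/4; homozygous and lost are absorbing. Hence at generation g,

p_het = (1/2)^(g−1),  p_hom = p_lost = (1 − p_het)/2,

and the lost and homozygous classes are exactly equinumerous in
expectation at every generation. That symmetry is what justifies the M1
back-estimator **2 × homozygous + heterozygous**: each observed homozygous
mutation stands in for itself plus one expected lost sibling. The
estimator is exact integer arithmetic and, under forward simulation of the
chain, unbiased (the suite verifies the mean over 1,000 simulated cohorts
of 200 mutations at g = 4–6 against the closed form, and the closed form
against a transition-matrix power for g = 1..20).

One tension worth stating: the chain's asymptotic fixation probability is
1/2, not 1/4; "only a quarter of mutations are permanently preserved" is
true only of the single-generation step (the M2 homozygote fraction). We
implement the chain and the stated estimator and leave the folklore figure
as what it is. Chimerism in M1 plants (sectored soma, so a mutation enters
the germ line at below 50%) is out of scope; for a chimeric M1 the
estimator is biased low. Per-base rates divide the cohort mean M1 count by
a genome length the caller supplies — the sum of the genome model's
chromosome lengths by default, or an assembly length passed explicitly.

# BSA mapping

Segregation is tested with the uncorrected Pearson χ² against an a:b ratio
(3:1 default, 1 df). The continuity-corrected statistic was deliberately
not used: the uncorrected form is the convention in segregation tables of
this size and is what reproduces published worked values. A marker is
pool-associated when the two bulk consensus calls differ and the recessive
pool is fixed for the mutant parent's allele. Pool genotypes are abstract
consensus calls (band scoring), not read counts; in the forward simulator
a pool reads as fixed when the other allele falls below a 10% detection
share of the pooled DNA. Candidate causal mutations are the nonsense,
stop-lost and frameshift mutations within ±2 Mb of the associated marker
(radius configurable), nearest first.

# The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions the pipeline targets: 6 lines, Poisson(100) mutations per line,
type mix 175:36:72:0 (SBS:MNV:InDel:SV), Ti/Tv 2.22, 83.1% deletions among
InDels, sequencing at selfing generation 4, mean depth 30, 50 shared
background variants. SV weight is zero by default — none were observed in
the motivating cohorts — but the class is generable so the classifier
branch stays testable. Each SBS is a transition with probability
titv/(1 + titv); MNVs substitute every base of a 2–5 bp run; deletions
carry the VCF anchor-base representation and are left-aligned at
generation time so recovery can be judged by exact identity. Zygosity
comes from the same selfing chain used by the estimator, and lost
mutations stay in the truth table (fate `"lost"`) while never reaching the
VCF. Read support is Poisson total depth with binomial alt counts at p = 1
(hom), 0.5 (het), 0 (absent).

What it does *not* emulate: mapping error and strand bias (so VAFs sit
cleanly around the 0.5/1.0 modes the filter boundaries were designed
around), sequencing error, FASTQ-level artifacts, chimeric M1 plants, and
any realistic spatial process behind clustered mutation regions — hotspots
are a simple multiplicative rate on declared windows, an assumption made
for testing, not a claim about mutational mechanism. Passing recovery
tests therefore demonstrates the correctness of the bookkeeping (filter
logic, merging, classification, zygosity, annotation), not robustness to
noisy real-world calls.

Mutations are placed with a minimum spacing of 15 bp within and across
lines (110 bp when SVs are enabled). This prevents two same-line SBS draws
from fusing into an accidental MNV, keeps indel spans clear of neighboring
sites, and keeps every site private by construction, which is what makes
per-line truth counts exactly recoverable.

# Numerical choices and degenerate inputs

- Zero-depth VAF is 0 with a warning; Ti/Tv with no transversions, and
  spacing on a zero-mutation chromosome, are reported as undefined (`NA`)
  rather than dividing.
- Identical groups in a t-test (zero pooled variance) return p = 1 and
  t = 0 instead of erroring, so degenerate null cases are well-defined.
- Gene models with CDS length not divisible by 3 produce a warning and an
  `NA` effect.
- Percentages are rounded half-up to two decimals at the reporting layer
  only; internal values are never rounded.
- Test problem sizes: cohorts of 3–6 lines on 0.35–3 Mb toy genomes,
  1,000-site filter oracles, 1,000-replicate estimator simulations,
  10,000-position window and feature oracles, and 100-seed hotspot and BSA
  detection runs. These sizes were chosen so each property is measured
  with comfortable statistical margin while the whole suite runs in about
  a minute.

# Known limitations

- The annotator is a reduced single-transcript model: no regulatory
  features, no HGVS, no multi-transcript genes, and a mutation gets one
  feature, not all overlapping ones.
- Complex replacements (delins of unequal span beyond trim-then-classify)
  and breakpoint-level SV typing (inversions, translocations) are out of
  scope.
- The filter has no mapping-quality or strand-bias terms; it assumes the
  caller's AD values are trustworthy.
- The inheritance model ignores selection, segregation distortion and
  outcrossing; generations enter only through the (generation-free)
  estimator's validation.
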