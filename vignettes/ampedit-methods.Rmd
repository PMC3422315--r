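---
title: "Quantifying focused A-to-I RNA editing from barcoded amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying focused A-to-I RNA editing from barcoded amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampedit)
```

## The measurement problem

Adenosine-to-inosine (A-to-I) RNA editing, catalysed by ADAR enzymes,
rewrites single adenosines in mRNA; inosine base-pairs like guanosine, so
an edited position appears as an A-to-G substitution in cDNA sequencing.
For a focused panel of candidate sites, targeted amplicon deep sequencing
gives a direct, quantitative readout: amplify short (roughly 100-250 bp)
fragments spanning each site by RT-PCR, pool many samples per lane with a
6-nt inline barcode at the start of each 76-nt read, and sequence to a
depth of tens of thousands of reads per site.

The editing level at a site is estimated as

$$\hat f = \frac{n_G}{n_A + n_G}$$

where $n_A$ and $n_G$ count reads carrying A or G at the site among reads
assigned to the amplicon and covering the position. C and T calls are
sequencing errors on this substrate and are excluded from the denominator.
At depth $N$, $\hat f$ is a binomial proportion with standard error
$\sqrt{f(1-f)/N}$ — at $N = 5\times10^4$ even a 0.1% editing signal is
measured with a standard error near 0.014%, which is what makes the assay
quantitative across the full 0-100% range. `editing_frequency()` also
emits a Wilson score interval per site; this interval is a convenience
extension, not part of the core estimate.

## Pipeline stages and the parameters that matter

**Demultiplexing** (`demultiplex()`) matches the 6-nt barcode prefix
exactly and trims it. Barcodes are designed with balanced composition
(3 A/T + 3 G/C); the composition rule is a primer-design guideline, so a
violation warns rather than errors. Exact matching is deliberate: the
barcodes differ by design, and a mismatched prefix is routed to the
unassigned pool rather than guessed.

**Filtering** removes reads containing any N call (`filter_ns()`) and, at
assignment time, reads whose best match is shorter than 30 nt. The 30-nt
boundary is inclusive: a 30-nt exact match is retained, a 29-nt match is
not.

**Assignment** (`assign_reads()`) scores every gapless placement of the
read on every amplicon. Declared editing sites are masked from mismatch
counting, so a read's editing status can never change (or bias) its
assignment — a property the test suite checks by toggling A and G at the
declared sites. The identity threshold over the unmasked overlap defaults
to 0.90: amplicon reads are exact reference fragments apart from rare
substitution errors, so genuine reads sit near identity 1 and the
threshold only has to reject chance matches. Alignment is gapless because
indel errors are rare on this platform and such reads simply fail the
identity threshold. Exact score ties between two distinct amplicons are
rejected as ambiguous rather than broken arbitrarily. The inner loop is
implemented in C++ (`src/align.cpp`) since it dominates run time at assay
depth.

**Background error** (`estimate_error_rate()`). The A-to-G error rate of
the whole assay (PCR plus sequencing) is measured where editing cannot be:
reference-A positions within ±10 nt of each declared site that are not
themselves declared sites. The window default quantifies "near the site"
while staying inside the amplicon; it is configurable. The pooled rate —
total G misreads over total A-or-G calls at control positions — is the
detection floor: on this assay class it sits near 0.08%, and that value is
the default tier boundary below.

**Site tiers** (`categorize_sites()`): Category I, mean editing above 1%
(confidently edited); Category II, between background and 1%; Category
III, at or below the 0.08% background, i.e. indistinguishable from error.
Boundary inclusivity is fixed — a mean exactly at background is III, and
exactly 1% is II — reconciling "greater than 1%" for I with "equal to or
less than background" for III; both thresholds are arguments.

**SNP screening** (`flag_snp()`). A germline polymorphism mimics editing
with a tell-tale pattern: carriers near 50% (heterozygous) or 100%
(homozygous/hemizygous) while other samples sit near 0%. The heuristic
flags a site when that cross-sample inconsistency appears, or when a
matched genomic-DNA sample shows more than 5% G. The ±10-percentage-point
tolerance and the 5% genomic threshold are this package's
quantification of a qualitative argument; both are exposed as arguments.

**Isoform phasing** (`phase_reads()`, `infer_codon_grouping()`,
`collapse_to_isoforms()`). When several sites sit within one amplicon —
the serotonin 2C receptor's five sites A, B, E, C, D span just 13 nt —
each read reports their joint state. Only reads covering all k sites with
an A or G at every site are phased; there is no partial-haplotype
imputation, which is harmless here because the site span is far shorter
than the 70-nt insert, and it keeps every haplotype count an observed
count. The reading frame is inferred by exhaustive search over the three
frames for the unique frame under which every declared amino-acid change
is produced by its single-site A-to-G substitution; zero or multiple
consistent frames raise an error rather than a guess. Collapsing
translates the affected codons with inosine read as guanosine: for the
receptor, codon outcomes {I,V,M} x {N,D,S,G} x {I,V} give 24 distinct
protein isoforms from 32 joint states.

```{r isoforms}
ht <- example_targets()$HTR2C_syn
infer_codon_grouping(ht)
nrow(enumerate_isoforms(ht))
```

**Group statistics** (`compare_groups()` and friends). The unit of
analysis is always the per-sample frequency — each subject contributes one
number per site regardless of read depth, so depth never masquerades as
sample size. The default test is the pooled-variance Student t-test
(Welch by flag), two-tailed, with one Benjamini-Hochberg family per
analysis run (e.g. 29 sites, or 24 isoforms) and significance called on
adjusted q-values at alpha = 0.05. Tissue-pH subgrouping uses a strict
cutoff at pH 6.1 (below = low pH; the boundary value is normal), since
prolonged agonal states acidify brain tissue and depress editing; the
low-pH subgroup is compared to matched normal-pH samples with a paired
t-test. Region screening flags sites whose means differ by more than
two-fold, orientation-free.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates reads of the form 6-nt barcode + amplicon
prefix, with per-read editing states drawn independently per site or from
a joint haplotype distribution, independent per-base substitution errors
(A-to-G at $8\times10^{-4}$ by default, matching the assay's observed
background; other substitutions at the same default rate), and
contaminant classes for the filters to remove: reads with an N call and
spurious 20-29 nt fragments, 1% each by default (the published aggregate
mapped-read fractions do not decompose the loss, so these are plausible
round figures chosen once). Default coverage is $5\times10^4$ reads per
sample per amplicon, the depth scale of the assay. A truth table records
every read's sample, amplicon, haplotype and injected errors, and a fixed
seed reproduces the dataset byte for byte.

Deliberate simplifications, which bound what green tests prove about real
data: errors are independent per base with no quality-score structure and
no position-dependent rate; barcode bases are error-free (real barcode
errors would send about 1% of reads to the unassigned pool, which the
pipeline handles but the truth-recovery test does not exercise); there are
no PCR duplicates, chimeras, indels, or allele-specific amplification
bias; and reads all start at amplicon position zero as amplicon sequencing
dictates. `simulate_null_cohort()` skips the read level entirely and
draws per-sample frequencies binomially at depth, which is the correct
marginal model for group-statistics studies but carries no read-level
artefacts.

The bundled amplicons (`example_targets()`) are synthetic: real amplicon
sequences are not redistributed, so the fixtures reproduce only the
editing-region codon structure, site spacings and amino-acid changes of
the serotonin 2C receptor case (plus a synonymous-site and a single-site
amplicon), embedded in arbitrary flanks constructed so that exactly one
reading frame is consistent and control-A positions exist near the sites.

## Numerical and degenerate-case choices

- Sites with zero A+G coverage in a sample are reported missing (NA) and
  excluded from that site's mean and n — never imputed as zero.
- SEM is sd/sqrt(n); with one contributing sample it is NA.
- A paired test on zero-variance, nonzero-mean differences reports the
  smallest representable positive p with a `degenerate` flag; identical
  inputs give t = 0, p = 1.
- Background is never subtracted from reported frequencies; it is
  reported alongside and used only for tiering.
- Fold-change ratios with a zero mean are undefined; such pairs are
  flagged only when the nonzero mean exceeds the background floor.
- Assignment ties within one amplicon keep the smallest offset; ties
  across amplicons reject the read as ambiguous.

## Problem sizes used in the test suite

The suite validates estimator recovery at the assay's native depth
($5\times10^4$ reads per site, across editing fractions 0.1%-90%) and the
background estimator at the same depth, both within four binomial
standard deviations of truth. Cohort-level properties use 200 replicates
of the five-group 15/15/15/15/12 null design at 29 sites. End-to-end
read-level checks (truth recovery, count conservation, phasing) run at a
few hundred to a few thousand reads per sample-amplicon pair, which keeps
the full suite under a minute while leaving the deep-coverage checks at
full depth.

## Known limitations

- Single-end, gapless, amplicon-panel scope: this is not a genome-wide
  editing caller and has no indel handling.
- The identity threshold and tie policy stand in for an unpublished
  legacy mapping criterion; they are explicit and configurable, but not a
  reimplementation of any specific historical script.
- The SNP heuristic is a screen, not a genotyper; matched genomic DNA
  remains the decisive evidence.
- Editing fractions at sites outside the first 70 nt of an amplicon are
  invisible with the default read length; the manifest loader does not
  warn about such sites (the simulator simply never covers them).
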