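# ampedit

Quantification of adenosine-to-inosine (A-to-I) RNA editing at focused
sites from barcoded amplicon deep-sequencing reads.

A-to-I editing, catalysed by ADAR enzymes, deaminates adenosines in mRNA;
inosine is read as guanosine by sequencers, so an edited site shows an
A→G substitution in cDNA. For a panel of candidate sites, targeted
amplicon sequencing — short RT-PCR fragments, pooled per lane with a 6-nt
inline barcode at the start of each 76-nt read, sequenced to ~5×10⁴ reads
per site — turns editing quantification into counting. `ampedit`
implements the complete analysis for such experiments, for researchers
measuring editing panels across tissues, conditions or disease cohorts:

- **Demultiplexing and filtering**: exact barcode-prefix routing, removal
  of N-containing reads and of reads whose best match is shorter than
  30 nt.
- **Assignment**: gapless sliding alignment of each read against every
  amplicon (C++ inner loop), with declared editing sites masked from
  mismatch counting so a read's editing status cannot bias its mapping.
- **Quantification**: per-site pileups and the editing level
  f = n_G / (n_A + n_G), with Wilson intervals; background A-to-G error
  estimated from unedited reference-A positions within ±10 nt of each
  site (typically ≈0.08%, the detection floor).
- **Interpretation**: site tiers (Category I > 1%, II between background
  and 1%, III at/below background), and SNP flagging from the
  carrier-like cross-sample pattern (≈50%/100% in some samples, ≈0% in
  others) or matched genomic DNA.
- **Isoform phasing**: joint haplotypes over multiple sites of one
  amplicon and codon-level collapse to protein isoforms — the serotonin
  2C receptor's five sites (A, B, E, C, D) give 24 isoforms from 32
  joint states.
- **Group statistics**: per-sample-frequency t-tests with one
  Benjamini–Hochberg family per run, tissue-pH subgrouping (cutoff 6.1)
  with paired tests, and two-fold region screening.
- **Simulation**: a read simulator with truth tables (editing states,
  injected errors, contaminants) so the whole pipeline is testable
  without any external data.

## Worked example

The package ships synthetic example amplicons (`example_targets()`):
real amplicon sequences are not redistributed, but the serotonin 2C
receptor fixture reproduces the editing region's codon structure, site
spacings and amino-acid changes exactly.

```r
library(ampedit)
tg <- example_targets()
mf <- example_manifest()

spec <- simulation_spec(tg, mf, fractions = 0.3, coverage = 2000, seed = 42)
sim  <- simulate_dataset(spec)
out  <- run_demux(sim$reads, mf, tg)
out$tally
#>   sample_id n_demux n_dropped_n assigned rejected
#> 1 s1           6000          67     5878       55
#> 2 s2           6000          65     5875       60
#> 3 s3           6000          60     5887       53
#> 4 s4           6000          52     5881       67
```

Every lane's accounting is conserved: assigned + rejected + N-dropped +
unassigned = total reads. Quantify and tier the sites:

```r
fr  <- editing_frequency(pileup_sites(out$assignments, tg))
estimate_error_rate(out$assignments, tg)
#> <error_estimate> A-to-G background 0.0786% (80 G / 101814 A+G calls,
#>                  13 control positions, +/-10 nt)

agg <- aggregate_sites(fr)
agg$category <- categorize_sites(agg$mean_f)
agg
#>   gene  site_label mean_f   sem_f     n category
#> 1 AZIN1 S/G         0.303 0.00773     4 I
#> 2 GRIA2 Q/Q         0.287 0.0116      4 I
#> ...
```

All sites were simulated at a true fraction of 0.30, and the recovered
means sit within sampling error of 0.30; the background estimate
(0.0786%) recovers the simulated 8×10⁻⁴ A→G error rate. Phase the
five-site receptor amplicon and collapse to protein isoforms:

```r
ht  <- tg$HTR2C_syn
hap <- phase_reads(out$assignments[out$assignments$sample_id == "s1", ], ht)
collapse_to_isoforms(hap, infer_codon_grouping(ht), ht)
#>   isoform count frequency haplotypes
#> 1 INI       316    0.162  AAAAA
#> 2 VNI       195    0.0997 GAAAA,GGAAA
#> 3 ISI       164    0.0838 AAAGA
#> ...
nrow(enumerate_isoforms(ht))
#> [1] 24
```

`INI` is the unedited receptor; each row's haplotypes show which joint
editing states translate to the same protein. Group comparisons run on a
sites × samples frequency matrix with `compare_groups()`, which returns
per-site means, SEMs, t, p, BH-adjusted q and a significance call.

A thin command-line wrapper over these functions is installed at
`system.file("cli", "ampedit.R", package = "ampedit")` with subcommands
`simulate`, `demux`, `quantify`, `isoforms` and `compare`.

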