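# One-off generator for the synthetic fixture files under inst/extdata/.
# Run from the repo root. Deterministic; the outputs are frozen text.
set.seed(20120817)

GC <- local({
  b <- c("T", "C", "A", "G")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  cods <- apply(expand.grid(b, b, b)[, 3:1], 1, paste0, collapse = "")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  names(aa) <- cods
  aa
})
rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                         collapse = "")

check_frames <- function(seq, offs, aa_changes) {
  # returns the set of frames consistent with every (unedited, edited) pair
  ok <- c()
  for (fr in 0:2) {
    good <- TRUE
    for (i in seq_along(offs)) {
      off <- offs[i]
      cs <- off - ((off - fr) %% 3)
      if (cs < 0 || cs + 2 >= nchar(seq)) { good <- FALSE; break }
      codon <- substr(seq, cs + 1, cs + 3)
      pos <- off - cs + 1
      ed <- codon; substr(ed, pos, pos) <- "G"
      pair <- strsplit(aa_changes[i], "/")[[1]]
      if (pair[1] == pair[2]) {
        if (GC[codon] != GC[ed]) { good <- FALSE; break }
      } else if (GC[codon] != pair[1] || GC[ed] != pair[2]) {
        good <- FALSE; break
      }
    }
    if (good) ok <- c(ok, fr)
  }
  ok
}

make_amplicon <- function(total_len, core, core_at, offs, aa_changes) {
  repeat {
    left <- rnd(core_at)
    right <- rnd(total_len - core_at - nchar(core))
    seq <- paste0(left, core, right)
    offs_abs <- core_at + offs
    if (any(substring(seq, offs_abs + 1, offs_abs + 1) != "A")) next
    fr <- check_frames(seq, offs_abs, aa_changes)
    if (length(fr) != 1) next
    # need >= 3 control A positions within +/-10 nt of the sites
    bases <- strsplit(seq, "")[[1]]
    near <- rep(FALSE, total_len)
    for (s in offs_abs) near[max(1, s - 9):min(total_len, s + 11)] <- TRUE
    ctrl <- sum(bases == "A" & near) - length(offs_abs)
    if (ctrl < 3) next
    return(list(seq = seq, offs = offs_abs, frame = fr))
  }
}

# serotonin 2C receptor editing region: codons I-R-N-P-I, sites A,B,E,C,D
htr2c <- make_amplicon(150, "ATACGTAATCCTATT", 30, c(0, 2, 6, 7, 12),
                       c("I/V", "I/M", "N/D", "N/S", "I/V"))
# glutamate receptor-like: synonymous Q/Q (CAA->CAG) + recoding Q/R (CAA->CGA)
gria2 <- make_amplicon(140, "CAATGGCAA", 54, c(2, 7), c("Q/Q", "Q/R"))
# single recoding S/G site (AGC->GGC)
azin1 <- make_amplicon(120, "AGC", 45, c(0), c("S/G"))

stopifnot(htr2c$frame == 30 %% 3)

fa <- c(">HTR2C_syn", htr2c$seq, ">GRIA2_syn", gria2$seq,
        ">AZIN1_syn", azin1$seq)
writeLines(fa, "inst/extdata/synthetic_amplicons.fasta")

sites <- data.frame(
  amplicon_id = c(rep("HTR2C_syn", 5), rep("GRIA2_syn", 2), "AZIN1_syn"),
  gene = c(rep("HTR2C", 5), rep("GRIA2", 2), "AZIN1"),
  site_label = c("A", "B", "E", "C", "D", "Q/Q", "Q/R", "S/G"),
  genomic_position = c(113988938, 113988940, 113988944, 113988945, 113988950,
                       1000000 + gria2$offs, 1000000 + azin1$offs),
  offset = c(htr2c$offs, gria2$offs, azin1$offs),
  aa_change = c("I/V", "I/M", "N/D", "N/S", "I/V", "Q/Q", "Q/R", "S/G"))
write.table(sites, "inst/extdata/synthetic_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

man <- data.frame(
  sample_id = c("s1", "s2", "s3", "s4"),
  barcode = c("CAGCTA", "TGACTG", "ACGTGA", "GTCAGT"),
  group = c("control", "control", "MDD", "MDD"),
  region = c("cortex", "cerebellum", "cortex", "cerebellum"),
  ph = c(6.61, 6.45, 6.02, 6.70),
  age = c(48, 37, 52, 61),
  pmi = c(20.5, 50, 18, 24))
write.table(man, "inst/extdata/synthetic_barcodes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("frames:", htr2c$frame, gria2$frame, azin1$frame, "\n")
cat("done\n")
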