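# Shared fixtures and independent oracles, built in code at test time.

# Brute-force Benjamini-Hochberg step-up, independent of stats::p.adjust:
# on sorted p-values, q(i) = min over j >= i of m * p(j) / j, clipped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    qs[i] <- min(1, best)
  }
  q <- numeric(m)
  q[o] <- qs
  q
}

# A minimal single-site amplicon built in code: site at offset 30, exactly
# five other reference-A positions inside the +/-10 nt control window
# (offsets 25, 27, 33, 35, 38) and none elsewhere in the window.
toy_target <- function() {
  bases <- rep("C", 60)
  bases[seq(2, 60, by = 7)] <- "T"
  bases[seq(3, 60, by = 11)] <- "G"
  bases[c(26, 28, 34, 36, 39)] <- "A"   # 1-based: offsets 25,27,33,35,38
  bases[31] <- "A"                      # the editing site, offset 30
  bases[1:10] <- "A"                    # far from the window
  seq <- paste(bases, collapse = "")
  amplicon_target("TOY1", "TOY", seq,
                  data.frame(site_label = "X", genomic_position = 500030L,
                             offset = 30L, aa_change = "synonymous"))
}

# Assignment rows built directly (bypassing alignment) for counting tests.
toy_assignments <- function(seqs, amplicon_id = "TOY1", offset = 0L,
                            sample_id = "s1") {
  tibble::tibble(read_id = sprintf("r%05d", seq_along(seqs)), seq = seqs,
                 sample_id = sample_id, amplicon_id = amplicon_id,
                 aligned_offset = offset, matched_length = nchar(seqs),
                 identity = 1, status = "assigned")
}

with_base <- function(seq, offset, base) {
  substr(seq, offset + 1L, offset + 1L) <- base
  seq
}

example_tg <- example_targets()
example_mf <- example_manifest()
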