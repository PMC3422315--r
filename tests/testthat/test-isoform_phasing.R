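test_that("single-site phasing reproduces the marginal editing frequency", {
  toy <- toy_target()
  amp <- toy$sequence
  seqs <- c(rep(with_base(amp, 30, "G"), 60), rep(amp, 40))
  asn <- toy_assignments(seqs)
  hap <- phase_reads(asn, toy)
  expect_identical(attr(hap, "n_phased"), 100L)
  expect_identical(hap$count[hap$state == "G"], 60L)
  expect_identical(hap$count[hap$state == "A"], 40L)
  f <- editing_frequency(pileup_site(asn, toy, "X"))$f
  expect_equal(hap$frequency[hap$state == "G"], f)

  # a read with a C at the site is excluded from phasing
  asn2 <- toy_assignments(c(seqs, with_base(amp, 30, "C")))
  hap2 <- phase_reads(asn2, toy)
  expect_identical(attr(hap2, "n_phased"), 100L)
  expect_identical(attr(hap2, "n_excluded"), 1L)
})

test_that("sites farther apart than any read are not co-observable", {
  seqb <- strrep("CGT", 40)
  substr(seqb, 1, 1) <- "A"
  substr(seqb, 101, 101) <- "A"
  wide <- amplicon_target(
    "WIDE", "W", seqb,
    data.frame(site_label = c("p", "q"), genomic_position = c(1L, 101L),
               offset = c(0L, 100L), aa_change = "synonymous"))
  asn <- toy_assignments(substr(seqb, 1, 70), amplicon_id = "WIDE")
  expect_error(phase_reads(asn, wide), "not co-observable")
})

test_that("codon frame inference recovers the serotonin-receptor codon grouping", {
  cm <- infer_codon_grouping(example_tg$HTR2C_syn)
  expect_identical(cm$codon_index, c(1L, 1L, 3L, 3L, 5L))
  expect_identical(cm$codon_pos, c(1L, 3L, 1L, 2L, 1L))
  # supplying the inferred frame explicitly validates cleanly
  cm2 <- infer_codon_grouping(example_tg$HTR2C_syn,
                              frame_offset = attr(cm, "frame_offset"))
  expect_equal(as.data.frame(cm2), as.data.frame(cm))
})

test_that("synonymous sites map without amino-acid change; inconsistent declarations error", {
  cm <- infer_codon_grouping(example_tg$GRIA2_syn, site_labels = "Q/Q")
  expect_identical(cm$codon_pos, 3L)

  bad <- example_tg$HTR2C_syn
  bad$sites$aa_change[1] <- "I/M"   # site A truly gives I/V
  expect_error(infer_codon_grouping(bad), "site 'A'|no reading frame")
})

test_that("all 32 joint states of the five-site receptor collapse to 24 protein isoforms", {
  iso <- enumerate_isoforms(example_tg$HTR2C_syn)
  expect_identical(nrow(iso), 24L)
  expect_identical(attr(iso, "wild_type"), "INI")
  # residue alphabet per codon: {I,V,M} x {N,D,S,G} x {I,V}
  expect_setequal(unique(substr(iso$isoform, 1, 1)), c("I", "V", "M"))
  expect_setequal(unique(substr(iso$isoform, 2, 2)), c("N", "D", "S", "G"))
  expect_setequal(unique(substr(iso$isoform, 3, 3)), c("I", "V"))
  expect_equal(sum(iso$frequency), 1)

  # a single synonymous site yields one isoform from two haplotypes
  iso_qq <- enumerate_isoforms(example_tg$GRIA2_syn, site_labels = "Q/Q")
  expect_identical(nrow(iso_qq), 1L)
  expect_identical(iso_qq$haplotypes, "A,G")
})

test_that("phasing recovers simulated linked haplotypes and marginals match pileups", {
  tg <- example_tg["HTR2C_syn"]
  mf <- example_mf[1, ]
  probs <- c(AAAAA = 0.4, GGGGG = 0.3, GAAAA = 0.2, AAGGA = 0.1)
  hap_spec <- tibble::tibble(sample_id = "s1", amplicon_id = "HTR2C_syn",
                             state = names(probs), prob = unname(probs))
  spec <- simulation_spec(tg, mf, haplotypes = hap_spec, coverage = 4000,
                          error_ag = 0, error_other = 0, n_rate = 0,
                          short_rate = 0, seed = 5)
  sim <- simulate_dataset(spec)
  out <- run_demux(sim$reads, mf, tg)
  hap <- phase_reads(out$assignments, tg$HTR2C_syn)
  expect_setequal(hap$state, names(probs))
  # multinomial sampling error: 4 SD per state frequency
  for (st in names(probs)) {
    p <- probs[[st]]
    tol <- 4 * sqrt(p * (1 - p) / attr(hap, "n_phased"))
    expect_lt(abs(hap$frequency[hap$state == st] - p), tol)
  }
  # marginalizing the haplotype table reproduces each site's pileup frequency
  pl <- editing_frequency(pileup_sites(out$assignments, tg))
  for (j in seq_along(attr(hap, "sites"))) {
    marg <- sum(hap$count[substr(hap$state, j, j) == "G"]) / attr(hap, "n_phased")
    f <- pl$f[pl$site_label == attr(hap, "sites")[j]]
    expect_equal(marg, f)
  }
  # collapse never increases the number of categories
  cm <- infer_codon_grouping(tg$HTR2C_syn)
  iso <- collapse_to_isoforms(hap, cm, tg$HTR2C_syn)
  expect_lte(nrow(iso), nrow(hap))
  expect_equal(sum(iso$frequency), 1)
})
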