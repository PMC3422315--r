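test_that("site pileups count exactly the covering reads", {
  toy <- toy_target()
  amp <- toy$sequence
  seqs <- c(rep(amp, 50), rep(with_base(amp, 30, "G"), 50))
  pl <- pileup_site(toy_assignments(seqs), toy, "X")
  expect_identical(pl$nA, 50L)
  expect_identical(pl$nG, 50L)
  expect_identical(pl$coverage_ag, 100L)

  # a read whose alignment ends one base before the site contributes nothing
  short <- substr(amp, 1, 30)            # covers offsets 0..29, site at 30
  pl2 <- pileup_site(toy_assignments(c(amp, short)), toy, "X")
  expect_identical(pl2$nA, 1L)
  expect_identical(pl2$coverage_ag, 1L)

  expect_error(pileup_site(toy_assignments(amp), toy, "nope"), "site_label")
})

test_that("editing frequency is G over A-plus-G, with C/T calls excluded", {
  f_of <- function(nA, nG, nC = 0L, nT = 0L) {
    editing_frequency(tibble::tibble(nA = nA, nC = nC, nG = nG, nT = nT))$f
  }
  expect_equal(f_of(100L, 0L), 0)
  expect_equal(f_of(50L, 50L), 0.5)
  expect_equal(f_of(83L, 17L, nC = 5L), 0.17)

  zero <- editing_frequency(tibble::tibble(nA = 0L, nC = 3L, nG = 0L, nT = 0L))
  expect_true(is.na(zero$f))
  expect_true(zero$no_coverage)

  # Wilson interval brackets the point estimate and stays in [0, 1]
  w <- editing_frequency(tibble::tibble(nA = 95L, nC = 0L, nG = 5L, nT = 0L))
  expect_true(w$wilson_lo > 0 && w$wilson_lo < w$f)
  expect_true(w$wilson_hi < 1 && w$wilson_hi > w$f)
})

test_that("background error rate pools A-to-G misreads over flanking control positions", {
  toy <- toy_target()
  amp <- toy$sequence
  # 250 perfect reads over 5 control positions = 1250 A calls; flip one to G
  seqs <- rep(amp, 250)
  seqs[1] <- with_base(seqs[1], 25, "G")
  est <- estimate_error_rate(toy_assignments(seqs), list(toy), window = 10)
  expect_identical(est$n_control_positions, 5L)
  expect_identical(est$total_A + est$total_G, 1250L)
  expect_equal(est$rate, 0.0008)

  clean <- estimate_error_rate(toy_assignments(rep(amp, 10)), list(toy))
  expect_equal(clean$rate, 0)

  # the declared site itself is never a control position: editing at the
  # site does not perturb the estimate
  edited <- rep(with_base(amp, 30, "G"), 10)
  est2 <- estimate_error_rate(toy_assignments(edited), list(toy))
  expect_equal(est2$rate, 0)

  # no reference-A positions in the window -> asks for a wider window
  bare <- amplicon_target(
    "BARE", "B", paste0(strrep("C", 25), "A", strrep("C", 34)),
    data.frame(site_label = "X", genomic_position = 1L, offset = 25L,
               aa_change = "synonymous"))
  expect_error(estimate_error_rate(toy_assignments(bare$sequence,
                                                   amplicon_id = "BARE"),
                                   list(bare)),
               "widen the window")
})

test_that("simulated background error is recovered within binomial sampling error", {
  e <- 8e-4
  spec <- simulation_spec(example_tg["HTR2C_syn"], example_mf[1, ],
                          fractions = 0, coverage = 5000, error_ag = e,
                          error_other = 0, n_rate = 0, short_rate = 0,
                          seed = 101)
  sim <- simulate_dataset(spec)
  out <- run_demux(sim$reads, example_mf[1, ], example_tg["HTR2C_syn"])
  est <- estimate_error_rate(out$assignments, example_tg["HTR2C_syn"])
  n_calls <- est$total_A + est$total_G
  tol <- 4 * sqrt(e * (1 - e) / n_calls)
  expect_lt(abs(est$rate - e), tol)
})

test_that("sites are tiered against the background with fixed boundary behaviour", {
  expect_identical(categorize_sites(0.0696), "I")
  expect_identical(categorize_sites(0.005), "II")
  expect_identical(categorize_sites(0.0005), "III")
  # boundaries: at background -> III, at 1% -> II
  expect_identical(categorize_sites(c(0.0008, 0.01)), c("III", "II"))
  expect_error(categorize_sites(1.5))
})

test_that("SNP flagging fires on carrier patterns and genomic DNA, not on consistent editing", {
  het <- flag_snp(c(0.1321, 0.0511, 0.50, 0.50))
  expect_true(het$flag)
  expect_match(het$reason, "inconsisten")

  cons <- flag_snp(c(0.09, 0.10, 0.11, 0.10))
  expect_false(cons$flag)

  gdna <- flag_snp(0.50, gdna_f = 0.50)
  expect_true(gdna$flag)
  expect_match(gdna$reason, "genomic DNA")

  single <- flag_snp(0.4)
  expect_false(single$flag)
  expect_match(single$reason, "insufficient")
})

test_that("per-site aggregation uses the unweighted mean and SD/sqrt(n) SEM", {
  freqs <- tibble::tibble(
    gene = "G", site_label = rep(c("x", "y", "z"), c(3, 2, 1)),
    sample_id = c("a", "b", "c", "a", "b", "a"),
    f = c(0.2, 0.2, 0.2, 0.1, 0.3, 0.5))
  agg <- aggregate_sites(freqs)
  x <- agg[agg$site_label == "x", ]
  expect_equal(x$mean_f, 0.2)
  expect_equal(x$sem_f, 0)
  y <- agg[agg$site_label == "y", ]
  expect_equal(y$mean_f, 0.2)
  expect_equal(y$sem_f, 0.1)
  z <- agg[agg$site_label == "z", ]
  expect_equal(z$mean_f, 0.5)
  expect_true(is.na(z$sem_f))
  expect_identical(z$n, 1L)

  # missing samples are excluded from n, not imputed
  freqs$f[2] <- NA
  agg2 <- aggregate_sites(freqs)
  expect_identical(agg2[agg2$site_label == "x", ]$n, 2L)
})
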