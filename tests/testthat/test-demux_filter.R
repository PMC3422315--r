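test_that("demultiplexing routes reads by exact barcode prefix and trims it", {
  mf <- validate_barcode_manifest(
    data.frame(sample_id = c("sampA", "sampB"),
               barcode = c("CAGCTA", "TGACTG")))
  insert <- substr(example_tg$AZIN1_syn$sequence, 1, 70)
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:10),
    seq = c(rep(paste0("CAGCTA", insert), 5),
            rep(paste0("TGACTG", insert), 5)),
    qual = strrep("I", 76))
  dm <- demultiplex(reads, mf)
  expect_identical(dm$tally$n, c(5L, 5L, 0L))
  expect_true(all(dm$assigned$seq == insert))
  expect_identical(sum(dm$tally$n), nrow(reads))

  reads$seq[1] <- paste0("TTTTTT", insert)
  dm2 <- demultiplex(reads, mf)
  expect_identical(dm2$tally$n[dm2$tally$sample_id == "unassigned"], 1L)
  expect_identical(dm2$unassigned$read_id, "r01")

  expect_error(demultiplex(reads, data.frame(sample_id = character(),
                                             barcode = character())),
               "empty")
})

test_that("the N filter drops exactly the reads containing N calls", {
  reads <- tibble::tibble(read_id = c("a", "b", "c"),
                          seq = c("ACGTNACGT", "ACGTACGT",
                                  strrep("N", 8)),
                          qual = strrep("I", c(9, 8, 8)))
  fl <- filter_ns(reads)
  expect_identical(fl$reads$read_id, "b")
  expect_identical(fl$n_dropped, 2L)
  # idempotent
  fl2 <- filter_ns(fl$reads)
  expect_identical(fl2$n_dropped, 0L)
  expect_identical(fl2$reads, fl$reads)
})

test_that("assignment finds exact placements and enforces the 30 bp boundary", {
  tg <- example_tg
  amp <- tg$AZIN1_syn$sequence
  mk <- function(s) tibble::tibble(read_id = "r1", seq = s,
                                   qual = strrep("I", nchar(s)))
  r70 <- assign_reads(mk(substr(amp, 1, 70)), tg)
  expect_identical(r70$status, "assigned")
  expect_identical(r70$amplicon_id, "AZIN1_syn")
  expect_identical(r70$aligned_offset, 0L)
  expect_identical(r70$matched_length, 70L)
  expect_equal(r70$identity, 1)

  r29 <- assign_reads(mk(substr(amp, 11, 39)), tg)   # 29 nt exact match
  expect_identical(r29$status, "short")
  expect_true(is.na(r29$amplicon_id))
  expect_identical(r29$matched_length, 29L)

  r30 <- assign_reads(mk(substr(amp, 11, 40)), tg)   # 30 nt boundary read
  expect_identical(r30$status, "assigned")
  expect_identical(r30$matched_length, 30L)

  expect_error(assign_reads(mk("ACGT"), list()), "empty target")
})

test_that("masking the editing sites makes assignment independent of editing status", {
  tg <- example_tg
  set.seed(11)
  # reads at random offsets from each amplicon, sites toggled A <-> G
  for (t in tg) {
    for (rep in 1:20) {
      start <- sample.int(t$length - 40L, 1L)
      len <- sample(40:70, 1L)
      stop_ <- min(t$length, start + len - 1L)
      base_read <- substr(t$sequence, start, stop_)
      edited <- base_read
      for (off in t$sites$offset) {
        pos <- off - (start - 1L) + 1L
        if (pos >= 1 && pos <= nchar(edited)) {
          substr(edited, pos, pos) <- "G"
        }
      }
      reads <- tibble::tibble(read_id = c("plain", "edited"),
                              seq = c(base_read, edited),
                              qual = strrep("I", nchar(base_read)))
      asn <- assign_reads(reads, tg)
      expect_identical(asn$amplicon_id[1], t$amplicon_id)
      expect_identical(asn$amplicon_id[2], t$amplicon_id)
      expect_identical(asn$identity[1], asn$identity[2])
    }
  }
})

test_that("every retained simulated read is assigned to its generating amplicon", {
  spec <- simulation_spec(example_tg, example_mf, fractions = 0.3,
                          coverage = 500, seed = 42)
  sim <- simulate_dataset(spec)
  out <- run_demux(sim$reads, example_mf, example_tg)
  merged <- merge(out$assignments, sim$truth, by = "read_id")
  kept <- merged[merged$status == "assigned", ]
  expect_gt(nrow(kept), 0)
  expect_true(all(kept$amplicon_id.x == kept$amplicon_id.y))
  expect_true(all(kept$sample_id.x == kept$sample_id.y))
})

test_that("read accounting is conserved through demultiplexing, filtering and assignment", {
  spec <- simulation_spec(example_tg, example_mf, fractions = 0.1,
                          coverage = 400, n_rate = 0.05, short_rate = 0.05,
                          seed = 9)
  sim <- simulate_dataset(spec)
  out <- run_demux(sim$reads, example_mf, example_tg)
  total <- sum(out$tally$assigned) + sum(out$tally$rejected) +
    sum(out$tally$n_dropped_n) + attr(out$tally, "unassigned")
  expect_identical(total, nrow(sim$reads))
  # per-sample partition as well
  expect_identical(out$tally$n_demux,
                   out$tally$assigned + out$tally$rejected +
                     out$tally$n_dropped_n)
})
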