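# Demultiplexing by inline barcode, read filtering, and gapless assignment
# of reads to amplicon references.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path, plain or gzipped.
#' @return Tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(read_id = names(x),
         seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a read table to FASTQ
#'
#' @param reads Tibble with `read_id`, `seq`, `qual`.
#' @param path Output path (`.gz` suffix compresses).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Demultiplex pooled reads by exact barcode prefix
#'
#' Routes each read to the sample whose barcode exactly matches the read's
#' prefix and trims the barcode from routed reads. Barcode matching is
#' exact: the barcodes are designed to be mutually distinguishable, so reads
#' with a mismatched or unknown prefix go to the unassigned pool.
#'
#' @param reads Read tibble (see [read_fastq()]).
#' @param manifest A `barcode_manifest` (see [read_barcode_manifest()]).
#' @return List with `assigned` (reads plus a `sample_id` column, barcode
#'   trimmed from `seq`/`qual`), `unassigned` (untouched reads), and `tally`
#'   (per-sample read counts plus an `"unassigned"` row; counts sum to the
#'   input count).
#' @export
demultiplex <- function(reads, manifest) {
  manifest <- validate_barcode_manifest(manifest)
  bl <- nchar(manifest$barcode[1])
  prefix <- substr(reads$seq, 1L, bl)
  idx <- match(prefix, manifest$barcode)
  too_short <- nchar(reads$seq) <= bl
  idx[too_short] <- NA_integer_

  hit <- !is.na(idx)
  assigned <- reads[hit, , drop = FALSE]
  assigned$sample_id <- manifest$sample_id[idx[hit]]
  assigned$seq <- substr(assigned$seq, bl + 1L, nchar(assigned$seq))
  assigned$qual <- substr(assigned$qual, bl + 1L, nchar(assigned$qual))
  unassigned <- reads[!hit, , drop = FALSE]

  counts <- table(factor(assigned$sample_id, levels = manifest$sample_id))
  tally <- tibble(
    sample_id = c(manifest$sample_id, "unassigned"),
    n = c(as.integer(counts), sum(!hit)))
  stopifnot(sum(tally$n) == nrow(reads))
  list(assigned = as_tibble(assigned), unassigned = as_tibble(unassigned),
       tally = tally)
}

#' Remove reads containing N base calls
#'
#' Base-caller ambiguities ("N") make the editing-site base call unusable,
#' so any read containing at least one N is dropped before assignment.
#'
#' @param reads Read tibble.
#' @return List with `reads` (retained, unchanged) and `n_dropped`.
#' @export
filter_ns <- function(reads) {
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  list(reads = reads[!has_n, , drop = FALSE], n_dropped = sum(has_n))
}

.status_labels <- c("assigned", "short", "low_identity", "ambiguous")

#' Assign barcode-trimmed reads to amplicon references
#'
#' Each read is compared against every amplicon by gapless sliding
#' alignment. Declared editing-site positions are masked from mismatch
#' counting, which makes the assignment invariant to each read's editing
#' status. The best placement per amplicon maximizes matched length, then
#' identity over the unmasked overlap; the best amplicon wins on the same
#' key. Reads whose best passing match is shorter than `min_match` bases
#' are rejected as short (the >= 30 bp retention rule), reads with no
#' placement at or above `min_identity` are rejected as low-identity, and
#' exact ties between two distinct amplicons are rejected as ambiguous.
#'
#' @param reads Read tibble (barcode-trimmed, N-free).
#' @param targets Named list of [amplicon_target()] objects.
#' @param min_match Minimum matched length in nt (default 30).
#' @param min_identity Minimum identity over the unmasked overlap
#'   (default 0.90).
#' @param search_revcomp Also try each read's reverse complement and keep
#'   the better orientation (default `FALSE`; amplicon reads are sequenced
#'   in a fixed orientation).
#' @return Tibble with `read_id`, `seq`, `amplicon_id` (NA when rejected),
#'   `aligned_offset` (0-based start of the read on the amplicon),
#'   `matched_length`, `identity`, `status` (one of `"assigned"`,
#'   `"short"`, `"low_identity"`, `"ambiguous"`), and `sample_id` if
#'   present in `reads`.
#' @export
assign_reads <- function(reads, targets, min_match = 30L,
                         min_identity = 0.90, search_revcomp = FALSE) {
  if (length(targets) == 0L) stop("empty target list")
  amp_ids <- vapply(targets, `[[`, "", "amplicon_id")
  amp_seqs <- vapply(targets, `[[`, "", "sequence")
  masks <- lapply(targets, function(t) as.integer(t$sites$offset))

  useqs <- unique(reads$seq)
  res <- assign_reads_cpp(useqs, unname(amp_seqs), unname(masks),
                          as.integer(min_match), min_identity)
  if (isTRUE(search_revcomp)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(useqs)))
    res_rc <- assign_reads_cpp(rc, unname(amp_seqs), unname(masks),
                               as.integer(min_match), min_identity)
    better <- res_rc$matched_length > res$matched_length |
      (res_rc$matched_length == res$matched_length &
         res_rc$identity > res$identity)
    res[better, ] <- res_rc[better, ]
  }

  i <- match(reads$seq, useqs)
  out <- reads
  out$amplicon_id <- ifelse(is.na(res$target[i]), NA_character_,
                            amp_ids[res$target[i]])
  out$aligned_offset <- res$offset[i]
  out$matched_length <- res$matched_length[i]
  out$identity <- res$identity[i]
  out$status <- .status_labels[res$status[i] + 1L]
  as_tibble(out)
}

#' Run demultiplexing, filtering and assignment end-to-end
#'
#' Convenience wrapper chaining [demultiplex()], [filter_ns()] and
#' [assign_reads()], with a per-sample accounting table whose categories
#' (assigned, rejected at assignment, N-dropped) always sum, together with
#' the unassigned pool, to the input read count.
#'
#' @inheritParams assign_reads
#' @param manifest A `barcode_manifest`.
#' @return List with `assignments` (see [assign_reads()]; demultiplexed,
#'   N-free reads), `unassigned`, and `tally` (per-sample `n_demux`,
#'   `n_dropped_n`, `assigned`, `rejected`, plus attribute `total`).
#' @export
run_demux <- function(reads, manifest, targets, min_match = 30L,
                      min_identity = 0.90, search_revcomp = FALSE) {
  dm <- demultiplex(reads, manifest)
  kept <- filter_ns(dm$assigned)
  asn <- assign_reads(kept$reads, targets, min_match = min_match,
                      min_identity = min_identity,
                      search_revcomp = search_revcomp)
  samples <- unique(c(dm$tally$sample_id[dm$tally$sample_id != "unassigned"]))
  per_sample <- function(ids, x) as.integer(table(factor(x, levels = ids)))
  dropped_by <- dm$assigned[grepl("N", dm$assigned$seq, fixed = TRUE), ]
  tally <- tibble(
    sample_id = samples,
    n_demux = per_sample(samples, dm$assigned$sample_id),
    n_dropped_n = per_sample(samples, dropped_by$sample_id),
    assigned = per_sample(samples,
                          asn$sample_id[asn$status == "assigned"]),
    rejected = per_sample(samples,
                          asn$sample_id[asn$status != "assigned"]))
  attr(tally, "total") <- nrow(reads)
  attr(tally, "unassigned") <- nrow(dm$unassigned)
  stopifnot(sum(tally$assigned) + sum(tally$rejected) + sum(tally$n_dropped_n) +
              nrow(dm$unassigned) == nrow(reads))
  list(assignments = asn, unassigned = dm$unassigned, tally = tally)
}
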