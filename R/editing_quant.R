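# Per-site pileups, editing frequencies, background error estimation,
# site categorization, SNP flagging and cross-sample aggregation.

.base_at <- function(seq, aligned_offset, site_offset) {
  # base call of each read at an amplicon offset; NA when not covered
  pos <- site_offset - aligned_offset + 1L
  ok <- pos >= 1L & pos <= nchar(seq)
  out <- rep(NA_character_, length(seq))
  out[ok] <- substr(seq[ok], pos[ok], pos[ok])
  out
}

.count_bases <- function(calls) {
  tab <- table(factor(calls, levels = c("A", "C", "G", "T")))
  as.integer(tab)
}

#' Pile up base calls at one editing site
#'
#' Counts, among the reads assigned to the site's amplicon that cover the
#' site, how many carry each base at the site position. Reads whose gapless
#' alignment does not span the site contribute nothing.
#'
#' @param assignments Assignment tibble (see [assign_reads()]) restricted or
#'   not to one sample; only rows with `status == "assigned"` and matching
#'   `amplicon_id` are used.
#' @param target The [amplicon_target()] carrying the site.
#' @param site_label Label of the site within `target$sites`.
#' @return One-row tibble with `nA`, `nC`, `nG`, `nT` and
#'   `coverage_ag = nA + nG`.
#' @export
pileup_site <- function(assignments, target, site_label) {
  srow <- target$sites[target$sites$site_label == site_label, , drop = FALSE]
  if (nrow(srow) != 1L) stop("unknown site_label: ", site_label)
  off <- srow$offset
  if (off < 0L || off >= target$length) stop("site offset outside amplicon")
  a <- assignments[assignments$status == "assigned" &
                     !is.na(assignments$amplicon_id) &
                     assignments$amplicon_id == target$amplicon_id, ,
                   drop = FALSE]
  calls <- .base_at(a$seq, a$aligned_offset, off)
  cnt <- .count_bases(calls)
  tibble(gene = target$gene, site_label = site_label,
         genomic_position = srow$genomic_position,
         nA = cnt[1], nC = cnt[2], nG = cnt[3], nT = cnt[4],
         coverage_ag = cnt[1] + cnt[3])
}

#' Pile up all declared sites, per sample
#'
#' @param assignments Assignment tibble with a `sample_id` column.
#' @param targets Named list of [amplicon_target()] objects.
#' @return Tibble with one row per sample x site: `sample_id`, `gene`,
#'   `site_label`, `genomic_position`, base counts and `coverage_ag`.
#' @export
pileup_sites <- function(assignments, targets) {
  a <- assignments[assignments$status == "assigned" &
                     !is.na(assignments$amplicon_id), , drop = FALSE]
  if (!"sample_id" %in% names(a)) a$sample_id <- "sample1"
  out <- list()
  for (t in targets) {
    rows <- a[a$amplicon_id == t$amplicon_id, , drop = FALSE]
    for (j in seq_len(nrow(t$sites))) {
      off <- t$sites$offset[j]
      calls <- .base_at(rows$seq, rows$aligned_offset, off)
      keep <- !is.na(calls)
      for (sid in unique(rows$sample_id)) {
        sel <- keep & rows$sample_id == sid
        cnt <- .count_bases(calls[sel])
        out[[length(out) + 1L]] <- tibble(
          sample_id = sid, gene = t$gene,
          site_label = t$sites$site_label[j],
          genomic_position = t$sites$genomic_position[j],
          nA = cnt[1], nC = cnt[2], nG = cnt[3], nT = cnt[4],
          coverage_ag = cnt[1] + cnt[3])
      }
    }
  }
  if (!length(out)) {
    return(tibble(sample_id = character(), gene = character(),
                  site_label = character(), genomic_position = integer(),
                  nA = integer(), nC = integer(), nG = integer(),
                  nT = integer(), coverage_ag = integer()))
  }
  do.call(rbind, out)
}

#' Editing frequency from a site pileup
#'
#' The editing level is the number of reads carrying G at the site divided
#' by the number of reads carrying A or G there; C and T calls (sequencing
#' errors) are excluded from the denominator. Sites with no A or G coverage
#' in a sample are flagged as missing (`f = NA`), never imputed as zero.
#' A Wilson score interval on the G proportion is emitted as a convenience
#' (an extension beyond the plain point estimate).
#'
#' @param pileup Pileup tibble (one or more rows) with `nA` and `nG`.
#' @param conf Confidence level for the Wilson interval (default 0.95).
#' @return The input with columns `f` (fraction in \[0,1\] or NA),
#'   `no_coverage` (logical), `wilson_lo`, `wilson_hi`.
#' @export
editing_frequency <- function(pileup, conf = 0.95) {
  n <- pileup$nA + pileup$nG
  f <- ifelse(n > 0, pileup$nG / n, NA_real_)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  centre <- (f + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(f * (1 - f) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  out <- pileup
  out$f <- f
  out$no_coverage <- n == 0L
  out$wilson_lo <- pmax(0, centre - half)
  out$wilson_hi <- pmin(1, centre + half)
  out
}

#' Estimate the background A-to-G error rate from flanking control positions
#'
#' Apparent A-to-G substitutions at reference-A positions that are not
#' declared editing sites measure the combined PCR and sequencing error of
#' the assay, which bounds the smallest detectable editing signal. Control
#' positions are reference-A offsets within `window` nt of any declared
#' site (the declared sites themselves are excluded); the pooled rate is
#' total G misreads over total A-or-G calls at those positions.
#'
#' @param assignments Assignment tibble (see [assign_reads()]).
#' @param targets Named list of [amplicon_target()] objects.
#' @param window Control window half-width in nt around each declared site
#'   (default 10).
#' @return Object of class `error_estimate`: list with `rate`,
#'   `n_control_positions`, `total_A`, `total_G`, `window`, and
#'   `per_position` (tibble with `amplicon_id`, `offset`, `nA`, `nG`,
#'   `rate`).
#' @export
estimate_error_rate <- function(assignments, targets, window = 10L) {
  per <- list()
  for (t in targets) {
    site_off <- t$sites$offset
    bases <- strsplit(t$sequence, "")[[1]]
    is_a <- bases == "A"
    near <- rep(FALSE, t$length)
    for (s in site_off) {
      lo <- max(0L, s - window); hi <- min(t$length - 1L, s + window)
      near[(lo:hi) + 1L] <- TRUE
    }
    ctrl <- which(is_a & near) - 1L
    ctrl <- setdiff(ctrl, site_off)
    if (!length(ctrl)) next
    rows <- assignments[assignments$status == "assigned" &
                          !is.na(assignments$amplicon_id) &
                          assignments$amplicon_id == t$amplicon_id, ,
                        drop = FALSE]
    for (off in ctrl) {
      calls <- .base_at(rows$seq, rows$aligned_offset, off)
      cnt <- .count_bases(calls)
      per[[length(per) + 1L]] <- tibble(
        amplicon_id = t$amplicon_id, offset = off,
        nA = cnt[1], nG = cnt[3],
        rate = ifelse(cnt[1] + cnt[3] > 0, cnt[3] / (cnt[1] + cnt[3]),
                      NA_real_))
    }
  }
  if (!length(per)) {
    stop("no control reference-A positions within +/-", window,
         " nt of the declared sites; widen the window")
  }
  per <- do.call(rbind, per)
  tot_a <- sum(per$nA); tot_g <- sum(per$nG)
  structure(
    list(rate = if (tot_a + tot_g > 0) tot_g / (tot_a + tot_g) else NA_real_,
         n_control_positions = nrow(per), total_A = tot_a, total_G = tot_g,
         window = window, per_position = per),
    class = "error_estimate")
}

#' @export
print.error_estimate <- function(x, ...) {
  cat(sprintf(
    "<error_estimate> A-to-G background %.4f%% (%d G / %d A+G calls, %d control positions, +/-%d nt)\n",
    100 * x$rate, x$total_G, x$total_A + x$total_G,
    x$n_control_positions, x$window))
  invisible(x)
}

#' Categorize sites by mean editing frequency against the background
#'
#' Sites are tiered by their mean editing level across samples:
#' Category I above the confirmation threshold (mean f > 1%), Category II
#' between the background error rate and 1% (0.08% < f <= 1%), and
#' Category III at or below background (f <= 0.08%), i.e. indistinguishable
#' from sequencing error. Boundary behaviour is fixed: f equal to the
#' background is III and f equal to 1% is II.
#'
#' @param mean_f Numeric vector of mean editing fractions in \[0,1\].
#' @param background Background error rate (fraction; default 0.0008).
#' @param category1 Category I threshold (fraction; default 0.01).
#' @return Character vector over `"I"`, `"II"`, `"III"`.
#' @export
categorize_sites <- function(mean_f, background = 0.0008, category1 = 0.01) {
  stopifnot(all(mean_f >= 0 & mean_f <= 1, na.rm = TRUE))
  ifelse(mean_f > category1, "I",
         ifelse(mean_f > background, "II", "III"))
}

#' Flag a site as a probable single-nucleotide polymorphism
#'
#' Germline SNPs masquerade as editing: a heterozygous carrier shows an
#' A-to-G fraction near 50% (or near 100% when homozygous / hemizygous)
#' while non-carriers sit near 0%, producing the highly inconsistent
#' cross-sample pattern that true editing does not. The flag fires when
#' (a) a matched genomic-DNA frequency exceeds `gdna_threshold`, or
#' (b) some sample lies within `near_tol` of 50% or 100% while another lies
#' within `near_tol` of 0%.
#'
#' @param per_sample_f Numeric vector of per-sample editing fractions.
#' @param gdna_f Optional matched genomic-DNA A-to-G fraction.
#' @param near_tol Tolerance around the genotype fractions (default 0.10).
#' @param gdna_threshold Genomic-DNA fraction above which the site is called
#'   a genotype, not editing (default 0.05).
#' @return List with `flag` (logical) and `reason` (character).
#' @export
flag_snp <- function(per_sample_f, gdna_f = NULL, near_tol = 0.10,
                     gdna_threshold = 0.05) {
  f <- per_sample_f[!is.na(per_sample_f)]
  if (!is.null(gdna_f) && !is.na(gdna_f) && gdna_f > gdna_threshold) {
    return(list(flag = TRUE, reason = sprintf(
      "genomic DNA A-to-G fraction %.3f exceeds genotype threshold %.3f",
      gdna_f, gdna_threshold)))
  }
  if (length(f) < 2L && is.null(gdna_f)) {
    return(list(flag = FALSE,
                reason = "insufficient evidence: single sample and no genomic DNA"))
  }
  carrier <- abs(f - 0.5) <= near_tol | f >= 1 - near_tol
  nearzero <- f <= near_tol
  if (any(carrier) && any(nearzero)) {
    return(list(flag = TRUE, reason = sprintf(
      "cross-sample inconsistency: fraction(s) near 50%%/100%% (%s) with other sample(s) near 0%% (%s)",
      paste(sprintf("%.3f", f[carrier]), collapse = ", "),
      paste(sprintf("%.3f", f[nearzero]), collapse = ", "))))
  }
  list(flag = FALSE, reason = "consistent across samples")
}

#' Aggregate per-sample editing frequencies per site
#'
#' Unweighted mean over samples with informative coverage; the standard
#' error of the mean is the sample standard deviation divided by the square
#' root of the number of contributing samples. Samples with no A-or-G
#' coverage at a site are excluded from that site's mean and n rather than
#' imputed. With a single contributing sample the SEM is undefined (NA).
#'
#' @param freqs Long tibble with columns `gene`, `site_label`, `sample_id`,
#'   `f` (fractions; NA = missing), e.g. the output of
#'   [editing_frequency()].
#' @return Tibble with one row per site: `gene`, `site_label`, `mean_f`,
#'   `sem_f`, `n`.
#' @export
aggregate_sites <- function(freqs) {
  key <- paste(freqs$gene, freqs$site_label, sep = "\r")
  out <- lapply(split(seq_len(nrow(freqs)), key), function(i) {
    f <- freqs$f[i]
    f <- f[!is.na(f)]
    tibble(gene = freqs$gene[i[1]], site_label = freqs$site_label[i[1]],
           mean_f = if (length(f)) mean(f) else NA_real_,
           sem_f = if (length(f) > 1L) sd(f) / sqrt(length(f)) else NA_real_,
           n = length(f))
  })
  res <- do.call(rbind, out[order(names(out))])
  rownames(res) <- NULL
  res
}
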