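# Read-level and cohort-level simulators with truth tables. The simulator
# defines the study conditions every other module is validated against:
# 76-nt reads carrying a 6-nt inline barcode, per-site coverage near
# 5 x 10^4 reads, a per-base A-to-G error near 8 x 10^-4, and small
# admixtures of N-containing and short spurious reads.

#' Build a simulation specification
#'
#' @param targets Named list of [amplicon_target()] objects.
#' @param manifest A `barcode_manifest` (samples and barcodes).
#' @param fractions Per-site true editing fractions: either a single number
#'   applied everywhere, or a tibble with columns `sample_id`,
#'   `amplicon_id`, `site_label`, `fraction`. Sites without an entry are
#'   unedited (fraction 0).
#' @param haplotypes Optional joint haplotype distribution for multi-site
#'   amplicons: tibble with `sample_id`, `amplicon_id`, `state` (string
#'   over A/G, one character per declared site in table order) and `prob`.
#'   Overrides `fractions` for the sample/amplicon pairs it covers.
#' @param coverage Reads per sample per amplicon (default 5e4, the
#'   per-site depth scale of the assay).
#' @param error_ag Per-base A-to-G substitution error rate (default 8e-4).
#' @param error_other Per-base rate of all other substitutions combined
#'   (default 8e-4), split evenly over the alternative bases.
#' @param n_rate Fraction of reads carrying an N base call (default 0.01).
#' @param short_rate Fraction of reads replaced by a spurious short
#'   (20-29 nt) amplicon fragment (default 0.01).
#' @param read_length Total read length including the barcode (default 76).
#' @param seed Integer RNG seed; identical seeds give byte-identical
#'   output.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(targets, manifest, fractions = 0,
                            haplotypes = NULL, coverage = 5e4,
                            error_ag = 8e-4, error_other = 8e-4,
                            n_rate = 0.01, short_rate = 0.01,
                            read_length = 76L, seed = 1L) {
  rates <- c(error_ag, error_other, n_rate, short_rate)
  stopifnot(all(rates >= 0 & rates <= 1), coverage >= 0)
  if (is.numeric(fractions) && length(fractions) == 1L) {
    stopifnot(fractions >= 0, fractions <= 1)
  }
  structure(
    list(targets = targets, manifest = validate_barcode_manifest(manifest),
         fractions = fractions, haplotypes = haplotypes,
         coverage = as.integer(coverage), error_ag = error_ag,
         error_other = error_other, n_rate = n_rate,
         short_rate = short_rate, read_length = as.integer(read_length),
         seed = as.integer(seed)),
    class = "simulation_spec")
}

.site_fraction <- function(spec, sample_id, amplicon_id, site_label) {
  fr <- spec$fractions
  if (is.numeric(fr) && length(fr) == 1L) return(fr)
  row <- fr[fr$sample_id == sample_id & fr$amplicon_id == amplicon_id &
              fr$site_label == site_label, , drop = FALSE]
  if (nrow(row) == 0L) 0 else row$fraction[1]
}

# multiply-mutate a character vector of reads at (read, pos) -> base events;
# events on the same read are applied in successive rounds so none is lost
.apply_substitutions <- function(seqs, read_idx, pos, base) {
  if (!length(read_idx)) return(seqs)
  round_no <- stats::ave(seq_along(read_idx), read_idx, FUN = seq_along)
  for (r in sort(unique(round_no))) {
    sel <- round_no == r
    tmp <- seqs[read_idx[sel]]
    substr(tmp, pos[sel], pos[sel]) <- base[sel]
    seqs[read_idx[sel]] <- tmp
  }
  seqs
}

.simulate_sample_amplicon <- function(spec, sample_id, barcode, target) {
  insert_len <- min(spec$read_length - nchar(barcode), target$length)
  insert <- substr(target$sequence, 1L, insert_len)
  sites <- target$sites[target$sites$offset < insert_len, , drop = FALSE]
  k <- nrow(sites)
  n <- spec$coverage
  if (n == 0L) return(NULL)

  # joint editing-state distribution over the covered sites
  hap <- spec$haplotypes
  hap <- if (is.null(hap)) NULL else
    hap[hap$sample_id == sample_id & hap$amplicon_id == target$amplicon_id, ,
        drop = FALSE]
  if (!is.null(hap) && nrow(hap) > 0L) {
    if (any(nchar(hap$state) != k)) {
      stop("haplotype distribution over wrong number of sites for ",
           target$amplicon_id, " (expected ", k, ")")
    }
    states <- hap$state
    probs <- hap$prob / sum(hap$prob)
  } else if (k > 0L) {
    p_site <- vapply(sites$site_label, function(sl)
      .site_fraction(spec, sample_id, target$amplicon_id, sl), 0)
    grid <- expand.grid(rep(list(c("A", "G")), k), stringsAsFactors = FALSE)
    states <- apply(as.matrix(grid), 1L, paste, collapse = "")
    probs <- apply(as.matrix(grid), 1L, function(st)
      prod(ifelse(st == "G", p_site, 1 - p_site)))
  } else {
    states <- ""
    probs <- 1
  }
  counts <- as.integer(stats::rmultinom(1L, n, probs))

  seqs <- character(n)
  truth_state <- character(n)
  at <- 0L
  for (i in seq_along(states)) {
    if (counts[i] == 0L) next
    tmpl <- insert
    if (k > 0L) {
      st <- strsplit(states[i], "")[[1]]
      for (j in seq_len(k)) {
        substr(tmpl, sites$offset[j] + 1L, sites$offset[j] + 1L) <- st[j]
      }
    }
    idx <- (at + 1L):(at + counts[i])
    seqs[idx] <- tmpl
    truth_state[idx] <- states[i]
    at <- at + counts[i]
  }

  # per-base substitution errors: position-wise binomial event counts,
  # events assigned to distinct reads per position
  tmpl_bases <- matrix("", nrow = n, ncol = 0)  # unused; per-read lookup below
  ev_read <- integer(0); ev_pos <- integer(0); ev_base <- character(0)
  for (b in seq_len(insert_len)) {
    ref <- substr(seqs, b, b)          # per-read base (site-dependent)
    is_a <- ref == "A"
    p_tot <- ifelse(is_a, spec$error_ag + spec$error_other, spec$error_other)
    # two strata: A-positions and non-A positions share rates; draw jointly
    u <- runif(n)
    hit <- u < p_tot
    if (!any(hit)) next
    for (i in which(hit)) {
      if (is_a[i]) {
        # split between the A->G channel and the other-substitution channel
        if (runif(1) < spec$error_ag / (spec$error_ag + spec$error_other)) {
          nb <- "G"
        } else {
          nb <- sample(c("C", "T"), 1L)
        }
      } else {
        nb <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1L)
      }
      ev_read <- c(ev_read, i); ev_pos <- c(ev_pos, b)
      ev_base <- c(ev_base, nb)
    }
  }
  seqs <- .apply_substitutions(seqs, ev_read, ev_pos, ev_base)
  n_errors <- tabulate(ev_read, nbins = n)

  # spurious short fragments and N contamination
  is_short <- runif(n) < spec$short_rate
  for (i in which(is_short)) {
    flen <- sample(20:29, 1L)
    fstart <- sample.int(max(1L, target$length - flen + 1L), 1L)
    seqs[i] <- substr(target$sequence, fstart, fstart + flen - 1L)
  }
  has_n <- runif(n) < spec$n_rate & !is_short
  for (i in which(has_n)) {
    pos <- sample.int(nchar(seqs[i]), 1L)
    substr(seqs[i], pos, pos) <- "N"
  }

  tibble(sample_id = sample_id, amplicon_id = target$amplicon_id,
         seq = paste0(barcode, seqs), state = truth_state,
         n_errors = n_errors, has_n = has_n, is_short = is_short)
}

#' Simulate a barcoded amplicon sequencing dataset with a truth table
#'
#' Generates reads of the form barcode + amplicon prefix, with per-read
#' editing states drawn from the per-site fractions (or joint haplotype
#' distribution), independent per-base substitution errors, and the
#' configured admixtures of N-containing and short spurious reads. The
#' truth table records, for every emitted read, its sample, amplicon,
#' editing-state vector, injected error count and contamination flags.
#'
#' @param spec A [simulation_spec()].
#' @param fastq_path Optional path; when given the reads are also written
#'   as FASTQ (constant Q40 qualities).
#' @return List with `reads` (tibble `read_id`, `seq`, `qual`) and `truth`
#'   (tibble `read_id`, `sample_id`, `amplicon_id`, `state`, `n_errors`,
#'   `has_n`, `is_short`, `clean`).
#' @export
simulate_dataset <- function(spec, fastq_path = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  parts <- list()
  for (s in seq_len(nrow(spec$manifest))) {
    for (t in spec$targets) {
      parts[[length(parts) + 1L]] <- .simulate_sample_amplicon(
        spec, spec$manifest$sample_id[s], spec$manifest$barcode[s], t)
    }
  }
  all <- do.call(rbind, parts)
  ord <- sample.int(nrow(all))
  all <- all[ord, , drop = FALSE]
  ids <- sprintf("read%08d", seq_len(nrow(all)))
  reads <- tibble(read_id = ids, seq = all$seq,
                  qual = strrep("I", nchar(all$seq)))
  truth <- tibble(read_id = ids, sample_id = all$sample_id,
                  amplicon_id = all$amplicon_id, state = all$state,
                  n_errors = all$n_errors, has_n = all$has_n,
                  is_short = all$is_short,
                  clean = !all$has_n & !all$is_short)
  if (!is.null(fastq_path)) write_fastq(reads, fastq_path)
  list(reads = reads, truth = truth)
}

#' Simulate a multi-group cohort of per-sample editing frequencies
#'
#' Draws per-sample observed editing frequencies directly at the site
#' level (binomial sampling at the assay's coverage, plus the background
#' A-to-G error), for null or effect-injected studies of the group
#' statistics. Under the default arguments all groups share identical true
#' fractions (a global null). Group sizes default to a five-group design
#' of 15/15/15/15/12 samples.
#'
#' @param site_means Named numeric vector of true editing fractions, one
#'   per site.
#' @param group_sizes Named integer vector of samples per group.
#' @param coverage Reads per site per sample (default 5e4).
#' @param error_ag Background A-to-G error rate (default 8e-4).
#' @param effects Optional named list: group label -> multiplier applied to
#'   the true fractions of that group (scalar or one value per site).
#' @param ph_mean,ph_sd Normal parameters for simulated tissue pH
#'   (defaults 6.5 and 0.3, giving a small low-pH tail).
#' @param low_ph_depression Fractional depression of the true editing
#'   fractions in samples with pH below `ph_cutoff` (default 0 = none).
#' @param ph_cutoff pH cutoff for the depression (default 6.1).
#' @param seed Optional integer seed.
#' @return List with `freq` (matrix, sites x samples) and `metadata`
#'   (tibble `sample_id`, `group`, `ph`).
#' @export
simulate_null_cohort <- function(site_means,
                                 group_sizes = c(control = 15, MDD = 15,
                                                 MDD_suicide = 15, SCZ = 15,
                                                 SCZ_suicide = 12),
                                 coverage = 5e4, error_ag = 8e-4,
                                 effects = NULL, ph_mean = 6.5, ph_sd = 0.3,
                                 low_ph_depression = 0, ph_cutoff = 6.1,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(site_means >= 0 & site_means <= 1))
  groups <- rep(names(group_sizes), group_sizes)
  n <- length(groups)
  ids <- sprintf("s%03d", seq_len(n))
  ph <- rnorm(n, ph_mean, ph_sd)
  freq <- matrix(NA_real_, nrow = length(site_means), ncol = n,
                 dimnames = list(names(site_means), ids))
  for (j in seq_len(n)) {
    mult <- 1
    if (!is.null(effects) && groups[j] %in% names(effects)) {
      mult <- effects[[groups[j]]]
    }
    p <- pmin(1, pmax(0, site_means * mult))
    if (ph[j] < ph_cutoff) p <- p * (1 - low_ph_depression)
    p_obs <- p + (1 - p) * error_ag
    freq[, j] <- rbinom(length(p), coverage, p_obs) / coverage
  }
  list(freq = freq,
       metadata = tibble(sample_id = ids, group = groups, ph = ph))
}
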