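# Joint haplotype phasing of multi-site amplicons and codon-level collapse
# to protein isoforms.

#' Phase reads into joint editing haplotypes
#'
#' Each read assigned to the amplicon that covers all `k` requested sites
#' with an A or G base at every site contributes one haplotype observation:
#' the length-`k` string of its bases at the sites, in site order (e.g.
#' `"GAAGG"`; A = unedited, G = edited). Reads not spanning all sites, or
#' carrying a C/T sequencing error at any site, are excluded from phasing
#' (they still count in single-site pileups of the sites they do cover).
#'
#' @param assignments Assignment tibble (see [assign_reads()]).
#' @param target The multi-site [amplicon_target()].
#' @param site_labels Sites to phase, in output order (default: all of the
#'   target's sites in table order).
#' @return Tibble with `state`, `count`, `frequency`, carrying attributes
#'   `sites` (labels in order), `n_phased` and `n_excluded`.
#' @export
phase_reads <- function(assignments, target, site_labels = NULL) {
  if (is.null(site_labels)) site_labels <- target$sites$site_label
  idx <- match(site_labels, target$sites$site_label)
  if (anyNA(idx)) stop("unknown site_label(s): ",
                       paste(site_labels[is.na(idx)], collapse = ", "))
  offs <- target$sites$offset[idx]
  k <- length(offs)
  stopifnot(k >= 1L)

  rows <- assignments[assignments$status == "assigned" &
                        !is.na(assignments$amplicon_id) &
                        assignments$amplicon_id == target$amplicon_id, ,
                      drop = FALSE]
  span <- max(offs) - min(offs) + 1L
  if (nrow(rows) > 0L && span > max(nchar(rows$seq))) {
    stop("sites not co-observable: span ", span,
         " nt exceeds the longest read")
  }
  calls <- vapply(offs, function(o) .base_at(rows$seq, rows$aligned_offset, o),
                  character(nrow(rows)))
  calls <- matrix(calls, nrow = nrow(rows), ncol = k)
  covered <- rowSums(is.na(calls)) == 0L
  ag_only <- covered & rowSums(matrix(calls %in% c("A", "G"),
                                      nrow = nrow(rows))) == k
  states <- apply(calls[ag_only, , drop = FALSE], 1L, paste, collapse = "")
  tab <- table(states)
  n_phased <- sum(tab)
  out <- tibble(state = names(tab), count = as.integer(tab),
                frequency = if (n_phased > 0) as.integer(tab) / n_phased
                            else numeric(length(tab)))
  out <- out[order(-out$count, out$state), ]
  attr(out, "sites") <- site_labels
  attr(out, "n_phased") <- as.integer(n_phased)
  attr(out, "n_excluded") <- as.integer(nrow(rows) - n_phased)
  out
}

.translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

.parse_aa_change <- function(x) {
  # "I/V" -> c("I","V"); "Q/Q" and "synonymous" -> synonymous
  if (identical(tolower(x), "synonymous")) return(NULL)
  parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("cannot parse aa_change: ", x)
  if (parts[1] == parts[2]) return(NULL)
  parts
}

#' Infer the codon frame and group editing sites by codon
#'
#' The reading frame of the amplicon is inferred by exhaustive search over
#' the three possible frames: a frame is consistent when, for every declared
#' site, the codon containing it lies fully inside the amplicon, translates
#' (standard genetic code) to the declared unedited residue, and the
#' single-site A-to-G substitution yields the declared edited residue
#' (or the same residue for synonymous sites). Exactly one consistent frame
#' must exist; zero or several is an error, never a silent guess.
#'
#' @param target The [amplicon_target()].
#' @param site_labels Sites to map (default: all).
#' @param frame_offset Optional known frame (0, 1 or 2: amplicon offset of
#'   the first full codon). When supplied it is validated rather than
#'   searched.
#' @return Tibble with `site_label`, `offset`, `codon_start` (0-based
#'   amplicon offset), `codon_index` (1-based, relative to the first
#'   affected codon), `codon_pos` (1-3 within the codon), carrying
#'   attribute `frame_offset`.
#' @export
infer_codon_grouping <- function(target, site_labels = NULL,
                                 frame_offset = NULL) {
  if (is.null(site_labels)) site_labels <- target$sites$site_label
  sites <- target$sites[match(site_labels, target$sites$site_label), ,
                        drop = FALSE]
  if (anyNA(sites$offset)) stop("unknown site_label(s)")

  check_frame <- function(fr) {
    msgs <- character(0)
    for (i in seq_len(nrow(sites))) {
      off <- sites$offset[i]
      cstart <- off - ((off - fr) %% 3L)
      if (cstart < 0L || cstart + 2L >= target$length) {
        msgs <- c(msgs, sprintf("site '%s': codon not fully inside amplicon",
                                sites$site_label[i]))
        next
      }
      codon <- substr(target$sequence, cstart + 1L, cstart + 3L)
      pos <- off - cstart + 1L
      edited <- codon
      substr(edited, pos, pos) <- "G"
      aa_un <- .translate_codon(codon)
      aa_ed <- .translate_codon(edited)
      decl <- .parse_aa_change(sites$aa_change[i])
      if (is.null(decl)) {
        if (aa_un != aa_ed) {
          msgs <- c(msgs, sprintf(
            "site '%s': declared synonymous but %s -> %s changes %s to %s",
            sites$site_label[i], codon, edited, aa_un, aa_ed))
        }
      } else if (aa_un != decl[1] || aa_ed != decl[2]) {
        msgs <- c(msgs, sprintf(
          "site '%s': declared %s/%s but codon %s -> %s gives %s/%s",
          sites$site_label[i], decl[1], decl[2], codon, edited, aa_un, aa_ed))
      }
    }
    msgs
  }

  if (!is.null(frame_offset)) {
    msgs <- check_frame(frame_offset %% 3L)
    if (length(msgs)) stop(paste(msgs, collapse = "\n"))
    frame <- frame_offset %% 3L
  } else {
    results <- lapply(0:2, check_frame)
    ok <- which(lengths(results) == 0L)
    if (length(ok) == 0L) {
      stop("no reading frame is consistent with the declared amino-acid changes:\n",
           paste(sprintf("frame %d: %s", 0:2,
                         vapply(results, function(m) m[1], "")),
                 collapse = "\n"))
    }
    if (length(ok) > 1L) {
      stop("reading frame ambiguous: frames ",
           paste(ok - 1L, collapse = " and "),
           " are both consistent with the declared amino-acid changes")
    }
    frame <- ok - 1L
  }

  cstart <- sites$offset - ((sites$offset - frame) %% 3L)
  first <- min(cstart)
  out <- tibble(site_label = sites$site_label, offset = sites$offset,
                codon_start = cstart,
                codon_index = (cstart - first) %/% 3L + 1L,
                codon_pos = sites$offset - cstart + 1L)
  attr(out, "frame_offset") <- as.integer(frame)
  out
}

#' Collapse editing haplotypes to protein isoforms
#'
#' Each haplotype state vector is translated codon-by-codon over the codons
#' that contain at least one editing site (edited sites read as G, inosine
#' being decoded as guanosine); haplotypes yielding the same residue string
#' are merged. Because several codon changes are synonymous or convergent,
#' the number of isoforms is at most the number of haplotypes (for the
#' serotonin 2C receptor's five sites, 32 haplotypes collapse to 24
#' isoforms).
#'
#' @param haplotypes Haplotype tibble from [phase_reads()] (or any tibble
#'   with `state` and `count` plus a `sites` attribute or matching site
#'   order).
#' @param codon_map Codon map from [infer_codon_grouping()] for the same
#'   sites, in the same order.
#' @param target The [amplicon_target()].
#' @return Tibble with `isoform` (residue string over the affected codons,
#'   in codon order), `count`, `frequency`, `haplotypes` (contributing
#'   state vectors, comma-separated); attribute `wild_type` gives the
#'   all-unedited residue string.
#' @export
collapse_to_isoforms <- function(haplotypes, codon_map, target) {
  k <- nchar(haplotypes$state[1])
  if (nrow(codon_map) != k) stop("codon map does not cover all sites")
  codon_starts <- sort(unique(codon_map$codon_start))

  translate_state <- function(state) {
    bases <- strsplit(target$sequence, "")[[1]]
    st <- strsplit(state, "")[[1]]
    bases[codon_map$offset + 1L] <- st
    aa <- vapply(codon_starts, function(cs) {
      .translate_codon(paste(bases[(cs + 1L):(cs + 3L)], collapse = ""))
    }, "")
    paste(aa, collapse = "")
  }

  iso <- vapply(haplotypes$state, translate_state, "")
  tot <- sum(haplotypes$count)
  groups <- split(seq_len(nrow(haplotypes)), iso)
  out <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    tibble(isoform = g, count = sum(haplotypes$count[i]),
           frequency = if (tot > 0) sum(haplotypes$count[i]) / tot else 0,
           haplotypes = paste(sort(haplotypes$state[i]), collapse = ","))
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$count, out$isoform), ]
  attr(out, "wild_type") <- translate_state(paste(rep("A", k), collapse = ""))
  attr(out, "sites") <- attr(haplotypes, "sites")
  out
}

#' Enumerate all possible isoforms of a multi-site amplicon
#'
#' Enumerates all 2^k edited/unedited state vectors of the requested sites
#' with equal weight and collapses them through the inferred codon map,
#' giving the full combinatorial isoform repertoire independent of any
#' observed haplotype distribution.
#'
#' @inheritParams infer_codon_grouping
#' @return The [collapse_to_isoforms()] table over all 2^k states.
#' @export
enumerate_isoforms <- function(target, site_labels = NULL) {
  if (is.null(site_labels)) site_labels <- target$sites$site_label
  k <- length(site_labels)
  cmap <- infer_codon_grouping(target, site_labels)
  grid <- expand.grid(rep(list(c("A", "G")), k), stringsAsFactors = FALSE)
  states <- apply(as.matrix(grid), 1L, paste, collapse = "")
  hap <- tibble(state = states, count = 1L,
                frequency = 1 / length(states))
  attr(hap, "sites") <- site_labels
  collapse_to_isoforms(hap, cmap, target)
}
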