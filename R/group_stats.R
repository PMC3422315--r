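# Group-comparison statistics: per-site t-tests with Benjamini-Hochberg
# correction, pH subgrouping with paired tests, and fold-change screening.
# The unit of analysis is always the per-sample editing frequency, never
# the read.

#' Two-group t-test on per-sample editing frequencies
#'
#' @param x,y Numeric vectors of per-sample frequencies, one value per
#'   sample (each group needs at least 2 values).
#' @param variant `"pooled"` (Student, equal variances; default) or
#'   `"welch"`.
#' @return List with `t`, `df`, `p` (two-tailed) and `degenerate` (TRUE
#'   when both groups have zero variance).
#' @export
two_group_ttest <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2L,
                p = .Machine$double.xmin, degenerate = TRUE))
  }
  tt <- t.test(x, y, var.equal = (variant == "pooled"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value), degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a family of p-values to control the false discovery rate:
#' `q(i) = min over j >= i of m * p(j) / j` on the sorted p-values, mapped
#' back to the input order and clipped at 1. Delegates to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvals Numeric vector of p-values in \[0,1\] (may be empty).
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Paired t-test on matched per-sample editing frequencies
#'
#' Tests whether matched differences (e.g. low-pH sample minus its matched
#' normal-pH control, or one value per site across a panel of sites) are
#' centred at zero. When the differences have zero variance but a nonzero
#' mean the t statistic is unbounded; the p-value is then reported at the
#' smallest representable positive double with `degenerate = TRUE`.
#'
#' @param x,y Matched numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  d <- x[ok] - y[ok]
  if (length(d) < 2L) stop("need >= 2 matched pairs")
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = length(d) - 1L, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L,
                p = .Machine$double.xmin, degenerate = TRUE))
  }
  tt <- t.test(d, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value), degenerate = FALSE)
}

#' Split samples into low- and normal-pH subgroups
#'
#' Post-mortem brain pH proxies the agonal state; prolonged agonal states
#' push pH below ~6.1 and depress RNA editing. Samples with pH strictly
#' below the cutoff form the low-pH subgroup; pH at or above the cutoff is
#' normal. Samples with missing pH are excluded with a warning.
#'
#' @param metadata Data frame with `sample_id` and `ph`.
#' @param cutoff pH cutoff (default 6.1).
#' @return List with `low` and `normal` (rows of `metadata`).
#' @export
subgroup_by_ph <- function(metadata, cutoff = 6.1) {
  if (!all(c("sample_id", "ph") %in% names(metadata))) {
    stop("metadata needs columns 'sample_id' and 'ph'")
  }
  miss <- is.na(metadata$ph)
  if (any(miss)) {
    warning("excluding sample(s) with missing pH: ",
            paste(metadata$sample_id[miss], collapse = ", "))
    metadata <- metadata[!miss, , drop = FALSE]
  }
  list(low = metadata[metadata$ph < cutoff, , drop = FALSE],
       normal = metadata[metadata$ph >= cutoff, , drop = FALSE])
}

#' Screen site means for a fold difference between two conditions
#'
#' Flags sites whose mean editing differs by more than `threshold`-fold
#' between two conditions (e.g. two brain regions). The ratio is
#' orientation-free: max(a, b) / min(a, b). When one mean is zero the ratio
#' is undefined; the site is then flagged only when the nonzero mean
#' exceeds `floor` (default: the background error rate).
#'
#' @param mean_a,mean_b Numeric vectors of per-site means (same length).
#' @param threshold Fold-change threshold (default 2).
#' @param floor Floor for calling a zero-vs-nonzero pair (default 0.0008).
#' @return Tibble with `ratio`, `flagged`, `note`.
#' @export
fold_change_screen <- function(mean_a, mean_b, threshold = 2.0,
                               floor = 0.0008) {
  stopifnot(length(mean_a) == length(mean_b))
  hi <- pmax(mean_a, mean_b); lo <- pmin(mean_a, mean_b)
  ratio <- ifelse(lo > 0, hi / lo, NA_real_)
  flagged <- ifelse(lo > 0, ratio > threshold, hi > floor)
  note <- ifelse(lo > 0, "",
                 ifelse(hi > floor, "undefined ratio: one mean is zero",
                        "undefined ratio: both means at/below floor"))
  tibble(ratio = ratio, flagged = flagged, note = note)
}

#' Per-site two-group comparison with FDR control
#'
#' Runs one t-test per site between two sample groups and adjusts the
#' whole family of p-values with Benjamini-Hochberg in a single run (one
#' family per analysis, e.g. 29 sites or 24 isoforms).
#'
#' @param freq Numeric matrix, sites (rows, named) x samples (columns named
#'   by sample id). Values are per-sample editing fractions; NA = missing.
#' @param metadata Data frame with `sample_id` and `group`.
#' @param groups Length-2 character vector: the two group labels to
#'   compare (first vs second).
#' @param variant t-test variant, see [two_group_ttest()].
#' @param alpha Significance level applied to the adjusted q-values
#'   (default 0.05).
#' @return Tibble with one row per site: `site`, `mean_a`, `sem_a`, `n_a`,
#'   `mean_b`, `sem_b`, `n_b`, `t`, `df`, `p`, `q`, `significant`.
#' @export
compare_groups <- function(freq, metadata, groups,
                           variant = c("pooled", "welch"), alpha = 0.05) {
  variant <- match.arg(variant)
  stopifnot(length(groups) == 2L)
  ids_a <- metadata$sample_id[metadata$group == groups[1]]
  ids_b <- metadata$sample_id[metadata$group == groups[2]]
  a <- freq[, colnames(freq) %in% ids_a, drop = FALSE]
  b <- freq[, colnames(freq) %in% ids_b, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) stop("each group needs >= 2 samples")

  sem <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_
  rows <- lapply(seq_len(nrow(freq)), function(i) {
    xa <- a[i, ][!is.na(a[i, ])]
    xb <- b[i, ][!is.na(b[i, ])]
    tt <- two_group_ttest(xa, xb, variant)
    tibble(site = rownames(freq)[i],
           mean_a = mean(xa), sem_a = sem(xa), n_a = length(xa),
           mean_b = mean(xb), sem_b = sem(xb), n_b = length(xb),
           t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= alpha
  out
}
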