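# Loading and validation of amplicon references, editing-site tables,
# barcode manifests and sample metadata.

#' Construct an amplicon target
#'
#' An amplicon target couples one PCR amplicon reference sequence (stored in
#' mRNA-sense orientation, so edited adenosines always read A-to-G) with the
#' editing sites it carries. Site offsets are 0-based positions within the
#' amplicon; genomic positions are 1-based reference-assembly coordinates and
#' are carried through to reports unchanged.
#'
#' @param amplicon_id Unique amplicon identifier (FASTA id).
#' @param gene Gene symbol.
#' @param sequence DNA string over A/C/G/T, mRNA-sense.
#' @param sites Data frame with columns `site_label`, `genomic_position`,
#'   `offset` (0-based within the amplicon) and `aa_change` (`"I/V"` style,
#'   `"Q/Q"` or `"synonymous"` for silent sites).
#' @return An object of class `amplicon_target`.
#' @export
amplicon_target <- function(amplicon_id, gene, sequence, sites) {
  sequence <- toupper(as.character(sequence))
  sites <- as_tibble(sites)
  errs <- character(0)
  len <- nchar(sequence)
  if (len < 50L || len > 500L) {
    errs <- c(errs, sprintf("amplicon '%s': length %d outside [50, 500]",
                            amplicon_id, len))
  }
  if (grepl("[^ACGT]", sequence)) {
    errs <- c(errs, sprintf("amplicon '%s': sequence contains non-ACGT characters",
                            amplicon_id))
  }
  needed <- c("site_label", "genomic_position", "offset", "aa_change")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols)) {
    stop("site table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(sites$offset)) {
    errs <- c(errs, sprintf("amplicon '%s': duplicated site offsets", amplicon_id))
  }
  for (i in seq_len(nrow(sites))) {
    off <- sites$offset[i]
    if (off < 0L || off >= len) {
      errs <- c(errs, sprintf(
        "amplicon '%s' site '%s': offset %d outside [0, %d)",
        amplicon_id, sites$site_label[i], off, len))
    } else if (substr(sequence, off + 1L, off + 1L) != "A") {
      errs <- c(errs, sprintf(
        "amplicon '%s' gene %s site '%s': reference base is not A at offset %d",
        amplicon_id, gene, sites$site_label[i], off))
    }
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  structure(
    list(amplicon_id = amplicon_id, gene = gene, sequence = sequence,
         length = len, sites = sites),
    class = "amplicon_target")
}

#' @export
print.amplicon_target <- function(x, ...) {
  cat(sprintf("<amplicon_target> %s (%s), %d nt, %d editing site(s): %s\n",
              x$amplicon_id, x$gene, x$length, nrow(x$sites),
              paste(x$sites$site_label, collapse = ", ")))
  invisible(x)
}

#' Read amplicon references and their editing sites
#'
#' Reads a FASTA of amplicon reference sequences plus a tab-separated
#' editing-site table and returns one validated [amplicon_target()] per
#' amplicon that carries at least one declared site. The site table must
#' have columns `amplicon_id`, `gene`, `site_label`, `genomic_position`,
#' `offset` (0-based within the amplicon) and `aa_change`. Validation errors
#' are aggregated and reported together with their site-table row numbers.
#'
#' @param fasta_path Path to the amplicon FASTA (ids must match the site
#'   table's `amplicon_id` values).
#' @param site_table_path Path to the tab-separated site table.
#' @return Named list of `amplicon_target` objects (possibly empty).
#' @export
read_targets <- function(fasta_path, site_table_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  tab <- read.delim(site_table_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(tab) == 0L) return(list())
  needed <- c("amplicon_id", "gene", "site_label", "genomic_position",
              "offset", "aa_change")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("site table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  errs <- character(0)
  unknown <- !(tab$amplicon_id %in% names(seqs))
  if (any(unknown)) {
    errs <- c(errs, sprintf("row %d: unknown amplicon_id '%s'",
                            which(unknown), tab$amplicon_id[unknown]))
  }
  key <- paste(tab$gene, tab$site_label, sep = ":")
  dup <- duplicated(key)
  if (any(dup)) {
    errs <- c(errs, sprintf("row %d: duplicate (gene, site_label) '%s'",
                            which(dup), key[dup]))
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))

  out <- list()
  for (aid in unique(tab$amplicon_id)) {
    rows <- tab[tab$amplicon_id == aid, , drop = FALSE]
    gene <- rows$gene[1]
    tgt <- tryCatch(
      amplicon_target(aid, gene, as.character(seqs[[aid]]),
                      rows[, c("site_label", "genomic_position", "offset",
                               "aa_change")]),
      error = function(e) e)
    if (inherits(tgt, "error")) {
      errs <- c(errs, sprintf("rows %s: %s",
                              paste(which(tab$amplicon_id == aid), collapse = ","),
                              conditionMessage(tgt)))
    } else {
      out[[aid]] <- tgt
    }
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  out
}

#' Write amplicon references and their editing sites
#'
#' Inverse of [read_targets()]: writes the FASTA and the tab-separated site
#' table so that re-reading yields an identical target set.
#'
#' @param targets Named list of [amplicon_target()] objects.
#' @param fasta_path,site_table_path Output paths.
#' @return Invisibly, `targets`.
#' @export
write_targets <- function(targets, fasta_path, site_table_path) {
  seqs <- Biostrings::DNAStringSet(vapply(targets, `[[`, "", "sequence"))
  names(seqs) <- vapply(targets, `[[`, "", "amplicon_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  tabs <- lapply(targets, function(t) {
    cbind(data.frame(amplicon_id = t$amplicon_id, gene = t$gene,
                     stringsAsFactors = FALSE),
          as.data.frame(t$sites))
  })
  tab <- do.call(rbind, tabs)
  write.table(tab, site_table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(targets)
}

#' Read a barcode manifest with sample metadata
#'
#' The manifest is a tab-separated file with columns `sample_id` and
#' `barcode` (6-nt inline barcodes read as the prefix of each sequencing
#' read) and optional metadata columns (`group`, `region`, `ph`, `age`,
#' `pmi`). Barcodes must be unique and of equal length; barcodes that do not
#' follow the balanced-composition design guideline (3 A/T plus 3 G/C bases)
#' raise a warning but are accepted, since the guideline constrains primer
#' design, not read processing.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble of class `barcode_manifest`.
#' @export
read_barcode_manifest <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
  validate_barcode_manifest(as_tibble(tab))
}

#' Validate an in-memory barcode manifest
#'
#' @param manifest Data frame with at least `sample_id` and `barcode`.
#' @return The manifest as a tibble of class `barcode_manifest`.
#' @export
validate_barcode_manifest <- function(manifest) {
  manifest <- as_tibble(manifest)
  if (!all(c("sample_id", "barcode") %in% names(manifest))) {
    stop("barcode manifest needs columns 'sample_id' and 'barcode'")
  }
  if (nrow(manifest) == 0L) stop("barcode manifest is empty")
  manifest$barcode <- toupper(manifest$barcode)
  bad_len <- nchar(manifest$barcode) != 6L
  if (any(bad_len)) {
    stop(sprintf("barcode length != 6 for sample(s): %s",
                 paste(manifest$sample_id[bad_len], collapse = ", ")))
  }
  if (anyDuplicated(manifest$barcode)) {
    dups <- manifest$barcode[duplicated(manifest$barcode)]
    stop("duplicate barcode(s), demultiplexing would be ambiguous: ",
         paste(unique(dups), collapse = ", "))
  }
  if (anyDuplicated(manifest$sample_id)) {
    stop("duplicate sample_id(s) in manifest")
  }
  n_at <- nchar(gsub("[^AT]", "", manifest$barcode))
  off_design <- n_at != 3L
  if (any(off_design)) {
    warning(sprintf(
      "barcode(s) not composed of 3 A/T + 3 G/C bases: %s",
      paste(manifest$barcode[off_design], collapse = ", ")))
  }
  if ("ph" %in% names(manifest)) {
    bad_ph <- !is.na(manifest$ph) & manifest$ph <= 0
    if (any(bad_ph)) {
      stop("non-positive pH for sample(s): ",
           paste(manifest$sample_id[bad_ph], collapse = ", "))
    }
  }
  class(manifest) <- c("barcode_manifest", class(manifest))
  manifest
}

#' Write a barcode manifest
#'
#' @param manifest A validated manifest (see [read_barcode_manifest()]).
#' @param path Output TSV path.
#' @return Invisibly, `manifest`.
#' @export
write_barcode_manifest <- function(manifest, path) {
  write.table(as.data.frame(manifest), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}

#' Bundled synthetic example targets and manifest
#'
#' Loads the synthetic amplicon reference set shipped with the package:
#' an HTR2C-like amplicon whose five closely spaced sites (A, B, E, C, D)
#' reproduce the serotonin 2C receptor editing-region codon structure, a
#' GRIA2-like amplicon with a recoding Q/R site plus a synonymous Q/Q site,
#' and an AZIN1-like amplicon with a single S/G site. Sequences are
#' synthetic stand-ins (real amplicon sequences are not redistributed);
#' only the site spacings, amino-acid changes and genomic coordinates of
#' the editing region are faithful.
#'
#' @return For `example_targets()`, a named list of [amplicon_target()]
#'   objects; for `example_manifest()`, a `barcode_manifest` tibble.
#' @export
example_targets <- function() {
  read_targets(
    system.file("extdata", "synthetic_amplicons.fasta", package = "ampedit"),
    system.file("extdata", "synthetic_sites.tsv", package = "ampedit"))
}

#' @rdname example_targets
#' @export
example_manifest <- function() {
  read_barcode_manifest(
    system.file("extdata", "synthetic_barcodes.tsv", package = "ampedit"))
}

#' Reported human-brain editing sites bundled as fixture tables
#'
#' Per-site summaries for coding-region A-to-I editing sites measured in
#' normal human brain by targeted amplicon deep sequencing: the 36 sites
#' with mean editing above 1% ("Category I", with mean and SEM percent
#' editing, hg18 genomic coordinates and mean read depth) and the 4 sites
#' with mean editing between the 0.08% background and 1% ("Category II").
#'
#' @param category `"I"` or `"II"`.
#' @return A tibble; Category I rows carry `gene`, `site_label`,
#'   `genomic_position`, `mean_percent`, `sem_percent`, `reads_mean`,
#'   `is_new`; Category II rows carry `gene` only.
#' @export
brain_editing_sites <- function(category = c("I", "II")) {
  category <- match.arg(category)
  file <- if (category == "I") "brain_category1_sites.tsv" else
    "brain_category2_sites.tsv"
  as_tibble(read.delim(system.file("extdata", file, package = "ampedit"),
                       sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                       comment.char = "#"))
}
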