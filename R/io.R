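#' Read a promoter training set from FASTA plus a TSS table
#'
#' The TSS table is a TSV with header columns `id`, `tss_index` (0-based),
#' `species`, `snrna_class`. FASTA ids and table ids must correspond 1:1.
#'
#' @param fasta_path Path to a FASTA file of promoter sequences.
#' @param tss_table_path Path to the TSV TSS table.
#' @param resolve_iupac Passed to [promoter_record()].
#' @return List of [promoter_record()] objects in FASTA file order.
#' @export
read_promoter_set <- function(fasta_path, tss_table_path, resolve_iupac = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  tab <- read.delim(tss_table_path, stringsAsFactors = FALSE)
  need <- c("id", "tss_index", "species", "snrna_class")
  if (!all(need %in% names(tab))) {
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(ids, tab$id)
  if (length(missing)) {
    stop("no TSS table entry for FASTA record(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(tab$id, ids)
  if (length(extra)) {
    stop("TSS table entries without a FASTA record: ",
         paste(extra, collapse = ", "))
  }
  if (anyDuplicated(ids)) stop("duplicated FASTA ids")
  rownames(tab) <- tab$id
  lapply(seq_along(ids), function(i) {
    row <- tab[ids[i], ]
    promoter_record(ids[i], as.character(seqs[[i]]), row$tss_index,
                    species = row$species, snrna_class = row$snrna_class,
                    resolve_iupac = resolve_iupac)
  })
}

#' Write a promoter set as FASTA plus a TSS table
#'
#' Inverse of [read_promoter_set()]; round-trips byte-identically for
#' normalized input.
#'
#' @param records List of [promoter_record()] objects.
#' @param fasta_path,tss_table_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_promoter_set <- function(records, fasta_path, tss_table_path) {
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  tab <- data.frame(
    id = names(seqs),
    tss_index = vapply(records, `[[`, 0L, "tss_index"),
    species = vapply(records, `[[`, "", "species"),
    snrna_class = vapply(records, `[[`, "", "snrna_class"),
    stringsAsFactors = FALSE
  )
  write.table(tab, tss_table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, tss_table_path))
}

#' Extract the TSS-anchored window of a promoter record
#'
#' Cuts `[tss - upstream, tss + downstream)` (0-based half-open). The returned
#' record has `tss_index == upstream` when the window is fully covered.
#'
#' @param record A [promoter_record()].
#' @param window A [window_spec()].
#' @param allow_truncation If `TRUE`, a window extending past either end of
#'   the sequence is truncated instead of raising an error.
#' @return A [promoter_record()] covering the window.
#' @export
extract_promoter_window <- function(record, window = window_spec(),
                                    allow_truncation = FALSE) {
  stopifnot(inherits(record, "promoter_record"), inherits(window, "window_spec"))
  len <- nchar(record$sequence)
  from <- record$tss_index - window$upstream      # 0-based inclusive
  to <- record$tss_index + window$downstream      # 0-based exclusive
  if (from < 0L || to > len) {
    if (!allow_truncation) {
      short_up <- max(0L, -from)
      short_dn <- max(0L, to - len)
      stop(sprintf(
        "window (%d,%d) exceeds sequence '%s' by %d bp upstream / %d bp downstream",
        window$upstream, window$downstream, record$id, short_up, short_dn))
    }
    from <- max(from, 0L); to <- min(to, len)
  }
  out <- record
  out$sequence <- substr(record$sequence, from + 1L, to)
  out$tss_index <- record$tss_index - from
  out
}

#' Write paired reads as a pair of FASTQ files (Phred+33)
#'
#' @param pairs List of [read_pair()] objects.
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  write_one <- function(path, which_read, which_qual, suffix) {
    con <- file(path, "w")
    on.exit(close(con))
    for (p in pairs) {
      writeLines(c(paste0("@", p$id, suffix), p[[which_read]], "+",
                   p[[which_qual]]), con)
    }
  }
  write_one(r1_path, "read1", "quality1", "/1")
  write_one(r2_path, "read2", "quality2", "/2")
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into read pairs
#'
#' @param r1_path,r2_path FASTQ paths (records in matching order).
#' @return List of [read_pair()] objects.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  ## suppressed: Biostrings warns about dropping FASTQ metadata columns
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1_path))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2_path))
  if (length(r1) != length(r2)) stop("mate files differ in record count")
  ids <- sub("/[12]$", "", sub("\\s.*$", "", names(r1)))
  q1 <- unname(as.character(Biostrings::quality(r1)))
  q2 <- unname(as.character(Biostrings::quality(r2)))
  s1 <- unname(as.character(r1)); s2 <- unname(as.character(r2))
  lapply(seq_along(r1), function(i) {
    read_pair(ids[i], s1[i], s2[i], q1[i], q2[i])
  })
}
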