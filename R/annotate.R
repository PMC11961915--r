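#' Promoter element definition
#'
#' @param name One of `"TATA"`, `"USE"`, `"MSP"`.
#' @param consensus IUPAC consensus string.
#' @param max_mismatches Mismatches tolerated in a match.
#' @param expected_offset Expected TSS-relative start position (negative =
#'   upstream).
#' @param offset_tolerance Half-width of the search interval around
#'   `expected_offset`.
#' @return An object of class `element_def`.
#' @export
element_def <- function(name, consensus, max_mismatches = 0L,
                        expected_offset, offset_tolerance) {
  stopifnot(nchar(consensus) > 0L, max_mismatches < nchar(consensus))
  structure(list(name = name, consensus = toupper(consensus),
                 max_mismatches = as.integer(max_mismatches),
                 expected_offset = as.integer(expected_offset),
                 offset_tolerance = as.integer(offset_tolerance)),
            class = "element_def")
}

#' Default Pol III promoter element definitions
#'
#' The canonical monocot U6/U3 grammar: a TATA box (`TATAWA`, exact) near
#' -30, the upstream sequence element (USE, `TCCCACATCG`, up to 2
#' mismatches) upstream of the TATA, and one or more monocot-specific
#' promoter elements (MSP, `RGCCCR`, exact) 5' of the USE.
#'
#' @return Named list of [element_def()]s.
#' @export
default_element_defs <- function() {
  list(
    TATA = element_def("TATA", "TATAWA", 0L, expected_offset = -30L,
                       offset_tolerance = 10L),
    USE = element_def("USE", "TCCCACATCG", 2L, expected_offset = -62L,
                      offset_tolerance = 40L),
    MSP = element_def("MSP", "RGCCCR", 0L, expected_offset = -125L,
                      offset_tolerance = 100L)
  )
}

#' Spacing rule between promoter elements
#'
#' Inter-element spacing is a major determinant of Pol III recognition, so
#' validity requires the USE-to-TATA and TATA-to-TSS gaps to fall inside
#' allowed intervals. Defaults bracket the canonical layout; in normal use
#' they are replaced by [learn_spacing()].
#'
#' @param use_tata_gap Allowed interval (bp) between USE end and TATA start.
#' @param tata_tss_gap Allowed interval (bp) between TATA start and the TSS.
#' @param source `"default"` or `"learned_from_training"`.
#' @return An object of class `spacing_rule`.
#' @export
spacing_rule <- function(use_tata_gap = c(15L, 35L), tata_tss_gap = c(20L, 35L),
                         source = "default") {
  stopifnot(length(use_tata_gap) == 2L, use_tata_gap[1L] <= use_tata_gap[2L],
            length(tata_tss_gap) == 2L, tata_tss_gap[1L] <= tata_tss_gap[2L])
  structure(list(use_tata_gap = as.integer(use_tata_gap),
                 tata_tss_gap = as.integer(tata_tss_gap), source = source),
            class = "spacing_rule")
}

#' @rdname spacing_rule
#' @export
default_spacing_rule <- function() spacing_rule()

## mismatches of an exact word against an IUPAC consensus
count_mismatches <- function(word, consensus) {
  w <- strsplit(word, "")[[1L]]
  cs <- IUPAC_SETS[strsplit(consensus, "")[[1L]]]
  sum(!mapply(function(base, set) base %in% set, w, cs))
}

#' Annotate TATA/USE/MSP elements and validate the promoter grammar
#'
#' Scans the region upstream of the TSS for each element with
#' mismatch-tolerant consensus matching, keeps candidates within each
#' element's offset tolerance, and picks the candidate closest to its
#' expected offset (all MSP candidates are reported; MSP number and position
#' vary between promoters). The verdict is valid iff all three elements are
#' found, at least one MSP lies entirely 5' of the USE, element order
#' MSP < USE < TATA < TSS holds, and both spacing gaps fall inside the rule.
#'
#' @param record A [promoter_record()] with its TSS set.
#' @param defs Element definitions ([default_element_defs()]).
#' @param spacing A [spacing_rule()], or `NULL` to skip the spacing check
#'   (element presence and ordering only).
#' @return A list with `annotations` (data frame: `element`, `start`, `end`
#'   TSS-relative half-open, `matched_seq`, `mismatches`, `primary`),
#'   `valid`, `missing`, and `spacing_ok`.
#' @export
annotate_elements <- function(record, defs = default_element_defs(),
                              spacing = default_spacing_rule()) {
  stopifnot(inherits(record, "promoter_record"))
  tss <- record$tss_index
  if (is.null(tss) || is.na(tss)) stop("record has no TSS index")
  upstream <- substr(record$sequence, 1L, tss)

  rows <- list()
  primary <- list()
  for (def in defs) {
    wlm <- nchar(def$consensus)
    if (nchar(upstream) < wlm) next
    hits <- match_consensus(upstream, def$consensus, def$max_mismatches)
    offsets <- hits - tss                           # TSS-relative starts
    keep <- abs(offsets - def$expected_offset) <= def$offset_tolerance &
      (offsets + wlm) <= 0L
    hits <- hits[keep]; offsets <- offsets[keep]
    if (!length(hits)) next
    ord <- order(abs(offsets - def$expected_offset), offsets)
    sel <- if (def$name == "MSP") ord else ord[1L]
    for (k in seq_along(sel)) {
      i <- sel[k]
      matched <- substr(upstream, hits[i] + 1L, hits[i] + wlm)
      rows[[length(rows) + 1L]] <- data.frame(
        element = def$name, start = offsets[i], end = offsets[i] + wlm,
        matched_seq = matched,
        mismatches = count_mismatches(matched, def$consensus),
        primary = (k == 1L), stringsAsFactors = FALSE)
    }
    primary[[def$name]] <- c(start = offsets[sel[1L]],
                             end = offsets[sel[1L]] + wlm)
  }
  annotations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element = character(), start = integer(), end = integer(),
               matched_seq = character(), mismatches = integer(),
               primary = logical(), stringsAsFactors = FALSE)

  missing <- setdiff(vapply(defs, `[[`, "", "name"), names(primary))
  valid <- length(missing) == 0L
  spacing_ok <- NA
  if (valid) {
    tata <- primary$TATA; use <- primary$USE
    msp_rows <- annotations[annotations$element == "MSP", , drop = FALSE]
    ## at least one MSP entirely 5' of the USE, and USE before TATA before TSS
    msp_5prime <- msp_rows$end <= use[["start"]]
    order_ok <- any(msp_5prime) && use[["end"]] <= tata[["start"]] &&
      tata[["end"]] <= 0L
    if (order_ok && any(msp_5prime)) {
      ## primary MSP: the reported-primary one if 5' of USE, else the closest
      ## 5'-of-USE candidate
      if (!msp_5prime[which(msp_rows$primary)]) {
        annotations$primary[annotations$element == "MSP"] <- FALSE
        first5 <- rownames(msp_rows)[which(msp_5prime)[1L]]
        annotations[first5, "primary"] <- TRUE
      }
    }
    if (is.null(spacing)) {
      spacing_ok <- NA
      valid <- order_ok
    } else {
      gap_ut <- tata[["start"]] - use[["end"]]
      gap_tt <- -tata[["start"]]
      spacing_ok <- gap_ut >= spacing$use_tata_gap[1L] &&
        gap_ut <= spacing$use_tata_gap[2L] &&
        gap_tt >= spacing$tata_tss_gap[1L] &&
        gap_tt <= spacing$tata_tss_gap[2L]
      valid <- order_ok && spacing_ok
    }
  }
  list(annotations = annotations, valid = valid, missing = missing,
       spacing_ok = spacing_ok)
}

#' Learn the spacing rule from annotated training promoters
#'
#' Annotates each training record (element presence and ordering only),
#' collects the observed USE-to-TATA and TATA-to-TSS gaps, and returns their
#' min-max intervals widened by `slack` on each side. Records that fail
#' annotation are excluded and counted in the attached report.
#'
#' @param training List of [promoter_record()]s.
#' @param defs Element definitions.
#' @param slack Widening in bp applied to both interval ends (default 2).
#' @return A [spacing_rule()] with `source = "learned_from_training"` and an
#'   attribute `report` (`n_total`, `n_used`, `n_failed`, `failed_ids`).
#' @export
learn_spacing <- function(training, defs = default_element_defs(), slack = 2L) {
  gaps_ut <- integer(0); gaps_tt <- integer(0); failed <- character(0)
  for (rec in training) {
    ann <- annotate_elements(rec, defs = defs, spacing = NULL)
    if (!ann$valid) { failed <- c(failed, rec$id); next }
    a <- ann$annotations[ann$annotations$primary, ]
    tata <- a[a$element == "TATA", ]; use <- a[a$element == "USE", ]
    gaps_ut <- c(gaps_ut, tata$start - use$end)
    gaps_tt <- c(gaps_tt, -tata$start)
  }
  if (length(gaps_ut) < 5L) {
    stop(sprintf("only %d of %d training records are annotatable (need >= 5)",
                 length(gaps_ut), length(training)))
  }
  rule <- spacing_rule(c(min(gaps_ut) - slack, max(gaps_ut) + slack),
                       c(min(gaps_tt) - slack, max(gaps_tt) + slack),
                       source = "learned_from_training")
  attr(rule, "report") <- list(n_total = length(training),
                               n_used = length(gaps_ut),
                               n_failed = length(failed), failed_ids = failed)
  rule
}

#' Write element annotations as a BED-like TSV
#'
#' Positions are reported both TSS-relative (negative = upstream) and as
#' absolute 0-based half-open coordinates on the stored sequence.
#'
#' @param records List of [promoter_record()]s.
#' @param path Output TSV path.
#' @param defs,spacing Passed to [annotate_elements()].
#' @return Invisibly, a list with the annotation data frame (`elements`) and
#'   the per-promoter validity report (`validity`), as written.
#' @export
write_annotation_report <- function(records, path,
                                    defs = default_element_defs(),
                                    spacing = default_spacing_rule()) {
  ann_rows <- list(); val_rows <- list()
  for (rec in records) {
    ann <- annotate_elements(rec, defs = defs, spacing = spacing)
    a <- ann$annotations
    if (nrow(a)) {
      a <- cbind(promoter_id = rec$id, a,
                 abs_start = a$start + rec$tss_index,
                 abs_end = a$end + rec$tss_index)
      ann_rows[[length(ann_rows) + 1L]] <- a
    }
    val_rows[[length(val_rows) + 1L]] <- data.frame(
      promoter_id = rec$id, valid = ann$valid,
      missing = paste(ann$missing, collapse = ","),
      spacing_ok = ann$spacing_ok, stringsAsFactors = FALSE)
  }
  elements <- if (length(ann_rows)) do.call(rbind, ann_rows) else NULL
  validity <- do.call(rbind, val_rows)
  if (!is.null(elements)) {
    write.table(elements, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(validity, sub("(\\.tsv)?$", ".validity.tsv", path, perl = TRUE)[1],
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(elements = elements, validity = validity))
}
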