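#' Fixed parts of an LbCas12a crRNA cassette
#'
#' The default direct repeat is the standard LbCas12a repeat with an initial
#' G prepended for proper expression from U6 promoters (so the stored repeat
#' string already carries the G). The terminator is a poly-T run.
#'
#' @param repeat_seq Direct repeat (default `"GAATTTCTACTAAGTGTAGAT"`, 21 nt).
#' @param terminator_length Number of T's in the terminator (default 7).
#' @return An object of class `cassette_parts`.
#' @export
cassette_parts <- function(repeat_seq = "GAATTTCTACTAAGTGTAGAT",
                           terminator_length = 7L) {
  repeat_seq <- normalize_dna(repeat_seq)
  if (substr(repeat_seq, 1L, 1L) != "G") {
    stop("repeat must start with G (added for proper U6-driven expression)")
  }
  terminator_length <- as.integer(terminator_length)
  stopifnot(terminator_length >= 1L)
  structure(list(repeat_seq = repeat_seq,
                 terminator = strrep("T", terminator_length)),
            class = "cassette_parts")
}

#' Assemble a crRNA expression cassette
#'
#' Two grammars: `simplex` is promoter + repeat + spacer + terminator (one
#' spacer, length 17-30 by default); `flanked_array` flanks every spacer
#' with repeats on both sides: promoter + repeat + (spacer + repeat) x m +
#' terminator, all spacers exactly 23 bp. A T-run of 4 or more inside a
#' spacer triggers a premature Pol III termination warning.
#'
#' @param promoter_id Identifier of the driving promoter.
#' @param promoter_seq Promoter DNA sequence.
#' @param spacers Character vector of spacer sequences (ACGT).
#' @param mode `"simplex"` or `"flanked_array"`.
#' @param parts A [cassette_parts()].
#' @param simplex_spacer_range Allowed simplex spacer length interval.
#' @return An object of class `crrna_cassette` with the assembled sequence
#'   and a 0-based half-open feature table.
#' @export
build_cassette <- function(promoter_id, promoter_seq, spacers,
                           mode = c("simplex", "flanked_array"),
                           parts = cassette_parts(),
                           simplex_spacer_range = c(17L, 30L)) {
  mode <- match.arg(mode)
  promoter_seq <- normalize_dna(promoter_seq, id = promoter_id)
  spacers <- vapply(spacers, normalize_dna, "", USE.NAMES = FALSE)
  if (mode == "simplex") {
    if (length(spacers) != 1L) stop("simplex cassette requires exactly 1 spacer")
    len <- nchar(spacers)
    if (len < simplex_spacer_range[1L] || len > simplex_spacer_range[2L]) {
      stop(sprintf("simplex spacer length %d outside [%d, %d]",
                   len, simplex_spacer_range[1L], simplex_spacer_range[2L]))
    }
  } else {
    if (length(spacers) < 1L) stop("flanked_array requires >= 1 spacer")
    bad <- nchar(spacers) != 23L
    if (any(bad)) {
      stop("flanked_array spacers must all be 23 bp; offending: ",
           paste(which(bad), collapse = ", "))
    }
  }
  for (i in seq_along(spacers)) {
    if (grepl("TTTT", spacers[i], fixed = TRUE)) {
      warning(sprintf(
        "spacer %d contains a T-run >= 4 (premature Pol III termination risk)", i))
    }
  }

  feats <- list(c(type = "promoter", seq = promoter_seq, label = promoter_id))
  if (mode == "simplex") {
    feats <- c(feats, list(
      c(type = "repeat", seq = parts$repeat_seq, label = "LbCas12a_repeat"),
      c(type = "spacer", seq = spacers, label = names(spacers)[1L] %||% "spacer_1"),
      c(type = "terminator", seq = parts$terminator, label = "polyT")))
  } else {
    feats <- c(feats, list(
      c(type = "repeat", seq = parts$repeat_seq, label = "LbCas12a_repeat")))
    for (i in seq_along(spacers)) {
      feats <- c(feats, list(
        c(type = "spacer", seq = spacers[i],
          label = names(spacers)[i] %||% sprintf("spacer_%d", i)),
        c(type = "repeat", seq = parts$repeat_seq, label = "LbCas12a_repeat")))
    }
    feats <- c(feats, list(
      c(type = "terminator", seq = parts$terminator, label = "polyT")))
  }
  seqs <- vapply(feats, `[[`, "", "seq")
  ends <- cumsum(nchar(seqs))
  features <- data.frame(
    type = vapply(feats, `[[`, "", "type"),
    label = vapply(feats, `[[`, "", "label"),
    start = ends - nchar(seqs), end = ends,   # 0-based half-open
    stringsAsFactors = FALSE)
  structure(list(
    promoter_id = promoter_id, promoter_seq = promoter_seq,
    spacers = spacers, mode = mode, parts = parts,
    assembled_seq = paste(seqs, collapse = ""), features = features
  ), class = "crrna_cassette")
}

#' @export
print.crrna_cassette <- function(x, ...) {
  cat(sprintf("<crrna_cassette> %s, %s, %d spacer(s), %d bp\n",
              x$promoter_id, x$mode, length(x$spacers),
              nchar(x$assembled_seq)))
  invisible(x)
}

#' Stack crRNA cassettes into a construct layout
#'
#' Concatenates cassettes in order, reverse-complementing any in reverse
#' orientation (head-to-head or head-to-tail stackings are both expressible),
#' emits the `{n}PX{m}` shorthand when all cassettes carry the same number of
#' spacers, and flags repeated promoter sequences, which can increase clonal
#' instability and silencing risk.
#'
#' @param cassettes List of [build_cassette()] results.
#' @param orientations Character vector, `"forward"`/`"reverse"` per cassette.
#' @param allow_repeated_promoters If `FALSE` (default) duplicated promoter
#'   ids are an error; duplicated promoter sequences always raise a flag.
#' @return An object of class `construct_layout` with the assembled sequence,
#'   a strand-aware feature table (construct coordinates, 0-based half-open),
#'   the shorthand, and any flags.
#' @export
stack_construct <- function(cassettes, orientations = NULL,
                            allow_repeated_promoters = FALSE) {
  stopifnot(length(cassettes) >= 1L)
  if (is.null(orientations)) orientations <- rep("forward", length(cassettes))
  stopifnot(length(orientations) == length(cassettes),
            all(orientations %in% c("forward", "reverse")))
  ids <- vapply(cassettes, `[[`, "", "promoter_id")
  if (!allow_repeated_promoters && anyDuplicated(ids)) {
    stop("duplicated promoter ids: ", paste(unique(ids[duplicated(ids)]),
                                            collapse = ", "))
  }
  flags <- character(0)
  pseqs <- vapply(cassettes, `[[`, "", "promoter_seq")
  if (anyDuplicated(pseqs)) {
    flags <- c(flags, "repeated_promoter_sequence")
  }
  n_spacers <- vapply(cassettes, function(cc) length(cc$spacers), 0L)
  shorthand <- if (length(unique(n_spacers)) == 1L) {
    sprintf("%dPX%d", length(cassettes), n_spacers[1L])
  } else NA_character_

  offset <- 0L
  seq_parts <- character(length(cassettes))
  feat_rows <- list()
  for (i in seq_along(cassettes)) {
    cc <- cassettes[[i]]
    Lc <- nchar(cc$assembled_seq)
    f <- cc$features
    if (orientations[i] == "forward") {
      seq_parts[i] <- cc$assembled_seq
      feat_rows[[i]] <- data.frame(
        cassette = i, type = f$type, label = f$label,
        start = offset + f$start, end = offset + f$end, strand = "+",
        stringsAsFactors = FALSE)
    } else {
      seq_parts[i] <- revcomp(cc$assembled_seq)
      feat_rows[[i]] <- data.frame(
        cassette = i, type = f$type, label = f$label,
        start = offset + Lc - f$end, end = offset + Lc - f$start, strand = "-",
        stringsAsFactors = FALSE)
    }
    offset <- offset + Lc
  }
  features <- do.call(rbind, feat_rows)
  features <- features[order(features$start), ]
  rownames(features) <- NULL
  structure(list(
    cassettes = cassettes, orientations = orientations,
    shorthand = shorthand, sequence = paste(seq_parts, collapse = ""),
    features = features, flags = flags
  ), class = "construct_layout")
}

#' @export
print.construct_layout <- function(x, ...) {
  cat(sprintf("<construct_layout> %s, %d cassette(s), %d bp%s\n",
              ifelse(is.na(x$shorthand), "(mixed)", x$shorthand),
              length(x$cassettes), nchar(x$sequence),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Write a construct as annotated FASTA (sequence + GFF3 features)
#'
#' Emits the assembled sequence as FASTA and the promoter/repeat/spacer/
#' terminator features as GFF3 with correct strands, so the construct
#' round-trips through standard parsers.
#'
#' @param layout A [stack_construct()] result.
#' @param fasta_path,gff_path Output paths.
#' @param construct_id Sequence name used in both files.
#' @return Invisibly, the `GRanges` written to the GFF3.
#' @export
emit_construct_annotation <- function(layout, fasta_path, gff_path,
                                      construct_id = "construct") {
  seqs <- Biostrings::DNAStringSet(setNames(layout$sequence, construct_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  f <- layout$features
  gr <- GenomicRanges::GRanges(
    seqnames = construct_id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- f$type
  S4Vectors::mcols(gr)$Name <- f$label
  S4Vectors::mcols(gr)$source <- "pol3kit"
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(gr)
}
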