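#' @useDynLib pol3kit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom stats pbinom rbeta runif setNames aggregate kruskal.test
#'   wilcox.test cor.test pbeta sd
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Normalize a DNA sequence to the ACGT alphabet
#'
#' Uppercases soft-masked (lowercase) bases with a warning and either rejects
#' IUPAC ambiguity codes (default) or resolves each to the overall most
#' frequent unambiguous base it can stand for (ties broken in ACGT order).
#'
#' @param seq Character scalar, DNA sequence.
#' @param resolve_iupac Logical; if `TRUE` ambiguity codes are resolved to the
#'   most frequent base of the sequence among the code's expansion.
#' @param id Optional identifier used in error messages.
#' @return Normalized sequence over `{A,C,G,T}`.
#' @export
normalize_dna <- function(seq, resolve_iupac = FALSE, id = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  label <- if (is.null(id)) "" else sprintf(" in '%s'", id)
  if (grepl("[a-z]", seq)) {
    warning(sprintf("lowercase (soft-masked) bases uppercased%s", label))
    seq <- toupper(seq)
  }
  if (nchar(seq) == 0L) stop("empty sequence", label)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- !chars %in% names(IUPAC_SETS)
  if (any(bad)) {
    stop(sprintf("invalid DNA character(s)%s: %s", label,
                 paste(unique(chars[bad]), collapse = ", ")))
  }
  ambig <- !chars %in% DNA_BASES
  if (any(ambig)) {
    if (!resolve_iupac) {
      stop(sprintf("IUPAC ambiguity code(s)%s: %s (set resolve_iupac = TRUE to resolve)",
                   label, paste(unique(chars[ambig]), collapse = ", ")))
    }
    counts <- table(factor(chars[!ambig], levels = DNA_BASES))
    for (i in which(ambig)) {
      allowed <- IUPAC_SETS[[chars[i]]]
      chars[i] <- allowed[which.max(counts[allowed])]
    }
    seq <- paste(chars, collapse = "")
  }
  seq
}

#' Construct a TSS-anchored promoter record
#'
#' The atom of training and design: a promoter sequence stored in transcribed
#' orientation together with the 0-based index of the first transcribed base
#' (the TSS). All user-facing coordinates elsewhere are reported relative to
#' the TSS with negative values upstream.
#'
#' @param id Record identifier.
#' @param sequence DNA sequence (normalized through [normalize_dna()]).
#' @param tss_index 0-based index of the first transcribed base;
#'   `0 <= tss_index <= nchar(sequence)`.
#' @param species Species label.
#' @param snrna_class One of `"U6"`, `"U3"`, `"unknown"`.
#' @param resolve_iupac Passed to [normalize_dna()].
#' @return An object of class `promoter_record`.
#' @export
promoter_record <- function(id, sequence, tss_index, species = "unknown",
                            snrna_class = c("unknown", "U6", "U3"),
                            resolve_iupac = FALSE) {
  snrna_class <- match.arg(snrna_class)
  sequence <- normalize_dna(sequence, resolve_iupac = resolve_iupac, id = id)
  tss_index <- as.integer(tss_index)
  if (is.na(tss_index) || tss_index < 0L || tss_index > nchar(sequence)) {
    stop(sprintf("tss_index %s out of range [0, %d] for record '%s'",
                 tss_index, nchar(sequence), id))
  }
  structure(
    list(id = as.character(id), species = as.character(species),
         snrna_class = snrna_class, sequence = sequence,
         tss_index = tss_index, strand = "+"),
    class = "promoter_record"
  )
}

#' @export
print.promoter_record <- function(x, ...) {
  cat(sprintf("<promoter_record> %s [%s, %s] %d bp, TSS at %d (-%d/+%d)\n",
              x$id, x$species, x$snrna_class, nchar(x$sequence),
              x$tss_index, x$tss_index, nchar(x$sequence) - x$tss_index))
  invisible(x)
}

#' TSS-relative extraction window
#'
#' @param upstream Bases upstream of the TSS to keep (default 500).
#' @param downstream Bases at and downstream of the TSS to keep (default 50).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(upstream = 500L, downstream = 50L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  stopifnot(upstream > 0L, downstream >= 0L)
  structure(list(upstream = upstream, downstream = downstream),
            class = "window_spec")
}

window_length <- function(window) window$upstream + window$downstream

#' Paired sequencing read
#'
#' @param id Fragment identifier.
#' @param read1,read2 DNA strings (read 2 as sequenced, i.e. reverse strand).
#' @param quality1,quality2 Phred+33 quality strings; default constant `"I"`.
#' @return An object of class `read_pair`.
#' @export
read_pair <- function(id, read1, read2,
                      quality1 = strrep("I", nchar(read1)),
                      quality2 = strrep("I", nchar(read2))) {
  stopifnot(nchar(read1) == nchar(quality1), nchar(read2) == nchar(quality2))
  structure(list(id = as.character(id), read1 = read1, read2 = read2,
                 quality1 = quality1, quality2 = quality2),
            class = "read_pair")
}

## integer base codes A=0 C=1 G=2 T=3; kmer code is big-endian base-4
dna_to_int <- function(seq) {
  m <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES) - 1L
  if (anyNA(m)) stop("non-ACGT character in sequence")
  m
}

int_to_dna <- function(codes) paste(DNA_BASES[codes + 1L], collapse = "")

#' K-mer codes of every window start in a sequence
#'
#' @param seq DNA string over ACGT.
#' @param wl Word length.
#' @return Integer vector of length `nchar(seq) - wl + 1`, each in
#'   `[0, 4^wl)`, big-endian base-4 encoding (A=0, C=1, G=2, T=3).
#' @keywords internal
kmer_codes <- function(seq, wl = 6L) {
  b <- dna_to_int(seq)
  n <- length(b) - wl + 1L
  if (n < 1L) return(integer(0))
  code <- numeric(n)
  for (j in seq_len(wl)) code <- code + b[j:(j + n - 1L)] * 4^(wl - j)
  as.integer(code)
}

kmer_code_to_word <- function(code, wl = 6L) {
  vapply(code, function(k) {
    digits <- integer(wl)
    for (j in wl:1) { digits[j] <- k %% 4L; k <- k %/% 4L }
    int_to_dna(digits)
  }, character(1))
}

#' Reverse complement of a DNA string
#' @param seq DNA string (IUPAC allowed).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## dinucleotide counts as a named 16-vector (AA, AC, ..., TT)
dinuc_counts <- function(seq) {
  b <- dna_to_int(seq)
  n <- length(b)
  if (n < 2L) stop("sequence must have length >= 2")
  codes <- b[-n] * 4L + b[-1L] + 1L
  counts <- tabulate(codes, nbins = 16L)
  names(counts) <- as.vector(t(outer(DNA_BASES, DNA_BASES, paste0)))
  counts
}

#' Shannon entropy (nats) of a sequence's dinucleotide composition
#' @param seq DNA string over ACGT, length >= 2.
#' @return Entropy in nats, in `[0, log(16)]`.
#' @export
dinucleotide_entropy <- function(seq) {
  p <- dinuc_counts(seq)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

## positional bin of each 0-based window position under equal-width binning
position_bins <- function(win_len, n_bins) {
  pos <- seq_len(win_len) - 1L
  pmin(as.integer(floor(pos * n_bins / win_len)), n_bins - 1L)
}

## round half up to `digits` decimals (report convention; base round() is
## round-half-even)
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}
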