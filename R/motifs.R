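#' Configuration for position-binned motif overrepresentation discovery
#'
#' @param word_length Exact word length scanned (default 6, matching the
#'   scoring model's 6-mers).
#' @param n_bins Number of equal-width positional bins over the training
#'   window (default 5).
#' @param merge_hamming Maximum Hamming distance from a seed word for greedy
#'   merging into a degenerate consensus (default 1).
#' @param p_threshold Upper bound on the binomial enrichment p-value for a
#'   motif to be reported (default 1e-3).
#' @param pseudocount Smoothing pseudocount for rates (default 0.5).
#' @return An object of class `discovery_config`.
#' @export
discovery_config <- function(word_length = 6L, n_bins = 5L, merge_hamming = 1L,
                             p_threshold = 1e-3, pseudocount = 0.5) {
  word_length <- as.integer(word_length); n_bins <- as.integer(n_bins)
  stopifnot(word_length >= 4L, n_bins >= 1L,
            p_threshold > 0, p_threshold < 1, pseudocount > 0)
  structure(list(word_length = word_length, n_bins = n_bins,
                 merge_hamming = as.integer(merge_hamming),
                 p_threshold = p_threshold, pseudocount = pseudocount),
            class = "discovery_config")
}

## bin index of every k-mer start position (0-based) in a window of length L
kmer_bin_map <- function(win_len, wl, n_bins) {
  starts <- 0:(win_len - wl)
  pmin(as.integer(floor(starts * n_bins / win_len)), n_bins - 1L)
}

## word x bin count matrix over a set of equal-length sequences
count_words_binned <- function(seqs, wl, n_bins) {
  L <- nchar(seqs[[1L]])
  bins <- kmer_bin_map(L, wl, n_bins)
  n_words <- 4L^wl
  counts <- matrix(0, nrow = n_words, ncol = n_bins)
  for (s in seqs) {
    codes <- kmer_codes(s, wl)
    for (b in seq_len(n_bins)) {
      idx <- codes[bins == (b - 1L)] + 1L
      counts[, b] <- counts[, b] + tabulate(idx, nbins = n_words)
    }
  }
  counts
}

hamming_words <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

## IUPAC letter for a set of bases
iupac_letter <- function(bases) {
  rev_map <- setNames(names(IUPAC_SETS),
                      vapply(IUPAC_SETS, function(x)
                        paste(sort(x), collapse = ""), ""))
  key <- paste(sort(unique(bases)), collapse = "")
  out <- rev_map[[key]]
  if (is.null(out)) stop("invalid base set: ", key)
  out
}

## column-wise IUPAC consensus of equal-length words
iupac_consensus <- function(words) {
  mat <- do.call(rbind, strsplit(words, ""))
  paste(apply(mat, 2L, iupac_letter), collapse = "")
}

#' Expand an IUPAC consensus to all matching exact words
#'
#' @param consensus IUPAC degenerate string.
#' @return Character vector of all ACGT words matching the consensus.
#' @export
expand_iupac <- function(consensus) {
  chars <- strsplit(consensus, "")[[1L]]
  bad <- !chars %in% names(IUPAC_SETS)
  if (any(bad)) stop("invalid IUPAC character(s): ",
                     paste(unique(chars[bad]), collapse = ", "))
  sets <- IUPAC_SETS[chars]
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

#' Find all matches of an IUPAC consensus in a sequence
#'
#' Overlapping matches are allowed; only the given strand is scanned
#' (Pol III promoter elements are orientation-specific).
#'
#' @param seq DNA string over ACGT.
#' @param consensus IUPAC degenerate string.
#' @param max_mismatch Maximum number of mismatching positions (default 0).
#' @return Integer vector of 0-based match start positions.
#' @export
match_consensus <- function(seq, consensus, max_mismatch = 0L) {
  chars <- strsplit(toupper(consensus), "")[[1L]]
  bad <- !chars %in% names(IUPAC_SETS)
  if (any(bad)) stop("invalid IUPAC character(s): ",
                     paste(unique(chars[bad]), collapse = ", "))
  if (nchar(seq) < nchar(consensus)) return(integer(0))
  hits <- Biostrings::matchPattern(toupper(consensus),
                                   Biostrings::DNAString(seq),
                                   max.mismatch = max_mismatch,
                                   fixed = FALSE)
  as.integer(BiocGenerics::start(hits)) - 1L
}

#' Discover position-binned overrepresented motifs
#'
#' Partitions the training window into `n_bins` equal-width positional bins,
#' counts every word of `word_length` per bin in foreground and background,
#' scores one-sided binomial upper-tail enrichment at the background
#' per-position word rate, then greedily merges enriched words within
#' `merge_hamming` of each seed (most enriched first) into IUPAC consensi,
#' recomputing counts for the merged consensus. Background sequences of the
#' same length as the training window are binned with the same scheme;
#' otherwise background counts are pooled (a single, positionally uniform
#' rate). Deterministic given inputs; ties in `enrichment_p` break
#' lexicographically by consensus.
#'
#' @param training List of [promoter_record()]s sharing one window (equal
#'   lengths and `tss_index`).
#' @param background Character vector of background DNA sequences. If `NULL`,
#'   seeded dinucleotide-preserving shuffles of the training sequences are
#'   used (see `bg_seed`).
#' @param config A [discovery_config()].
#' @param bg_seed Seed for the default shuffle background.
#' @return A list of motif models (class `motif_model`), sorted ascending by
#'   `enrichment_p`, containing only motifs with
#'   `enrichment_p <= p_threshold`.
#' @export
discover_motifs <- function(training, background = NULL,
                            config = discovery_config(), bg_seed = 1L) {
  stopifnot(length(training) >= 1L)
  fg_seqs <- vapply(training, `[[`, "", "sequence")
  tss <- vapply(training, `[[`, 0L, "tss_index")
  lens <- nchar(fg_seqs)
  if (length(unique(lens)) != 1L || length(unique(tss)) != 1L) {
    stop("training records must share a common window (equal length and tss_index)")
  }
  if (is.null(background)) {
    background <- vapply(seq_along(fg_seqs), function(i)
      shuffle_preserving_dinucleotides(fg_seqs[i], seed = bg_seed + i), "")
  }
  wl <- config$word_length
  if (any(nchar(background) < wl)) stop("background sequence shorter than word_length")
  L <- lens[1L]
  if (L < wl) stop("training window shorter than word_length")
  n_bins <- config$n_bins
  n_words <- 4L^wl
  pc <- config$pseudocount

  fg_counts <- count_words_binned(fg_seqs, wl, n_bins)
  fg_npos <- length(training) * tabulate(kmer_bin_map(L, wl, n_bins) + 1L,
                                         nbins = n_bins)

  if (all(nchar(background) == L)) {
    bg_counts <- count_words_binned(background, wl, n_bins)
    bg_npos <- length(background) * tabulate(kmer_bin_map(L, wl, n_bins) + 1L,
                                             nbins = n_bins)
  } else {
    pooled <- numeric(n_words)
    total_pos <- 0L
    for (s in background) {
      codes <- kmer_codes(s, wl)
      pooled <- pooled + tabulate(codes + 1L, nbins = n_words)
      total_pos <- total_pos + length(codes)
    }
    bg_counts <- matrix(rep(pooled, n_bins), ncol = n_bins)
    bg_npos <- rep(total_pos, n_bins)
  }

  ## smoothed per-position rates; a consensus rate is the sum of its member
  ## words' rates, so smoothing is additive under IUPAC expansion
  rate <- function(count, npos, m = 1L) (count + pc * m) / (npos + pc * n_words)

  bin_bounds <- cbind(floor((0:(n_bins - 1L)) * L / n_bins),
                      floor((1:n_bins) * L / n_bins)) - tss[1L]

  motifs <- list()
  all_words <- kmer_code_to_word(0:(n_words - 1L), wl)
  for (b in seq_len(n_bins)) {
    p_word <- pbinom(fg_counts[, b] - 1L, fg_npos[b],
                     rate(bg_counts[, b], bg_npos[b]), lower.tail = FALSE)
    cand <- which(p_word <= config$p_threshold & fg_counts[, b] > 0L)
    if (!length(cand)) next
    pool <- all_words[cand[order(p_word[cand], all_words[cand])]]
    while (length(pool)) {
      seed <- pool[1L]
      dists <- vapply(pool, hamming_words, 0L, a = seed)
      members <- pool[dists <= config$merge_hamming]
      consensus <- iupac_consensus(members)
      expanded <- expand_iupac(consensus)
      idx <- match(expanded, all_words)
      fg_c <- sum(fg_counts[idx, b]); bg_c <- sum(bg_counts[idx, b])
      m <- length(expanded)
      bg_rate <- rate(bg_c, bg_npos[b], m)
      motifs[[length(motifs) + 1L]] <- structure(list(
        consensus = consensus,
        member_words = members,
        bin_index = b - 1L,
        bin_bounds = bin_bounds[b, ],
        fg_count = fg_c, bg_count = bg_c,
        enrichment_p = pbinom(fg_c - 1L, fg_npos[b], bg_rate,
                              lower.tail = FALSE),
        log_odds = log(rate(fg_c, fg_npos[b], m) / bg_rate)
      ), class = "motif_model")
      pool <- setdiff(pool, members)
    }
  }
  motifs <- Filter(function(m) m$enrichment_p <= config$p_threshold, motifs)
  ord <- order(vapply(motifs, `[[`, 0, "enrichment_p"),
               vapply(motifs, `[[`, "", "consensus"))
  motifs[ord]
}

#' Tabulate discovered motifs
#'
#' @param motifs List of motif models from [discover_motifs()].
#' @return A data frame with one row per motif (consensus, bin, TSS-relative
#'   bin bounds, counts, enrichment p, log-odds).
#' @export
motif_table <- function(motifs) {
  data.frame(
    consensus = vapply(motifs, `[[`, "", "consensus"),
    bin_index = vapply(motifs, `[[`, 0L, "bin_index"),
    bin_start = vapply(motifs, function(m) m$bin_bounds[1L], 0),
    bin_end = vapply(motifs, function(m) m$bin_bounds[2L], 0),
    fg_count = vapply(motifs, `[[`, 0, "fg_count"),
    bg_count = vapply(motifs, `[[`, 0, "bg_count"),
    enrichment_p = vapply(motifs, `[[`, 0, "enrichment_p"),
    log_odds = vapply(motifs, `[[`, 0, "log_odds"),
    stringsAsFactors = FALSE
  )
}
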