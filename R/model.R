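#' Train the composite promoter-likeness scoring model
#'
#' Builds position-binned 6-mer tables from TSS-anchored training windows:
#' a smoothed relative-frequency table (per sequence, per bin, normalized
#' over the `4^word_length` word universe, then averaged over sequences so
#' duplicated sequences do not change the model) and an enrichment table
#' (natural-log ratio of training to background smoothed frequency). The
#' third scoring term, dinucleotide entropy, has no trained parameters.
#' There is deliberately no train/test split: the model is a descriptive
#' position-specific word profile, closer to Naive Bayes than to a
#' cross-validated classifier.
#'
#' @param training List of [promoter_record()]s on a common window.
#' @param background Character vector of background sequences; `NULL` uses
#'   seeded dinucleotide-preserving shuffles of the training set.
#' @param config A [discovery_config()] supplying `word_length`, `n_bins`
#'   and `pseudocount` (one shared positional bin scheme keeps the motif
#'   discovery and the scoring model coherent).
#' @param weights Numeric length-3 vector `(w_freq, w_enr, w_ent)`,
#'   non-negative; the terms are per-position means, so the weights are
#'   length-scale-free.
#' @param window The [window_spec()] the training records were extracted
#'   with; defaults to upstream = common `tss_index`.
#' @param bg_seed Seed for the default shuffle background.
#' @return An object of class `promoter_score_model`.
#' @export
train_model <- function(training, background = NULL,
                        config = discovery_config(),
                        weights = c(1, 1, 1), window = NULL, bg_seed = 1L) {
  if (length(training) == 0L) stop("empty training set")
  stopifnot(length(weights) == 3L, all(weights >= 0))
  fg_seqs <- vapply(training, `[[`, "", "sequence")
  tss <- vapply(training, `[[`, 0L, "tss_index")
  lens <- nchar(fg_seqs)
  if (length(unique(lens)) != 1L || length(unique(tss)) != 1L) {
    stop("training records must share a common window (equal length and tss_index)")
  }
  L <- lens[1L]
  if (is.null(window)) window <- window_spec(max(tss[1L], 1L), L - tss[1L])
  if (is.null(background)) {
    background <- vapply(seq_along(fg_seqs), function(i)
      shuffle_preserving_dinucleotides(fg_seqs[i], seed = bg_seed + i), "")
  }
  wl <- config$word_length
  n_bins <- config$n_bins
  pc <- config$pseudocount

  freq_fg <- mean_binned_freq(fg_seqs, wl, n_bins, pc, L)
  freq_bg <- mean_binned_freq(background, wl, n_bins, pc, L)

  classes <- unique(vapply(training, `[[`, "", "snrna_class"))
  training_class <- if (setequal(classes, "U6")) "U6_only" else "U6_and_U3"

  structure(list(
    word_length = wl, n_bins = n_bins, window = window,
    freq_table = freq_fg,
    enr_table = log(freq_fg / freq_bg),
    weights = setNames(as.numeric(weights), c("w_freq", "w_enr", "w_ent")),
    pseudocount = pc,
    training_class = training_class,
    training_ids = sort(vapply(training, `[[`, "", "id"))
  ), class = "promoter_score_model")
}

## per-sequence smoothed word distribution per bin, averaged over sequences;
## sequences of a length other than the window are pooled (uniform over bins)
mean_binned_freq <- function(seqs, wl, n_bins, pc, win_len) {
  n_words <- 4L^wl
  acc <- matrix(0, nrow = n_words, ncol = n_bins)
  bins <- kmer_bin_map(win_len, wl, n_bins)
  npos_bin <- tabulate(bins + 1L, nbins = n_bins)
  for (s in seqs) {
    if (nchar(s) < wl) stop("sequence shorter than word_length")
    codes <- kmer_codes(s, wl)
    if (nchar(s) == win_len) {
      for (b in seq_len(n_bins)) {
        cnt <- tabulate(codes[bins == (b - 1L)] + 1L, nbins = n_words)
        acc[, b] <- acc[, b] + (cnt + pc) / (npos_bin[b] + pc * n_words)
      }
    } else {
      cnt <- tabulate(codes + 1L, nbins = n_words)
      p <- (cnt + pc) / (length(codes) + pc * n_words)
      acc <- acc + p
    }
  }
  acc / length(seqs)
}

#' @export
print.promoter_score_model <- function(x, ...) {
  cat(sprintf(
    "<promoter_score_model> %d-mers, %d bins, window -%d/+%d, %s, %d training seqs\n",
    x$word_length, x$n_bins, x$window$upstream, x$window$downstream,
    x$training_class, length(x$training_ids)))
  invisible(x)
}

## map sequence positions into the model window; sequences shorter than the
## window are anchored at the 3' end so a trimmed promoter ends at the TSS
model_offset <- function(seq_len, model) {
  win_len <- window_length(model$window)
  if (seq_len == win_len) return(0L)
  if (seq_len > win_len) {
    stop(sprintf("sequence length %d exceeds model window %d", seq_len, win_len))
  }
  if (seq_len > model$window$upstream) {
    stop(sprintf(
      "partial-window scoring anchors the 3' end at the TSS; length %d exceeds the %d-bp upstream arm",
      seq_len, model$window$upstream))
  }
  model$window$upstream - seq_len
}

#' Score a sequence under a promoter-likeness model
#'
#' The total score is `w_freq * freq_term + w_enr * enr_term +
#' w_ent * ent_term`, where `freq_term` is the mean over word positions of
#' the log smoothed frequency of the 6-mer at that position's bin,
#' `enr_term` is the mean per-position log-odds, and `ent_term` is the
#' Shannon entropy (nats) of the global dinucleotide composition
#' (maximum `log(16)`). Sequences shorter than the model window are scored
#' in partial-window mode, TSS-anchored from the 3' end.
#'
#' @param seq DNA string over ACGT.
#' @param model A [train_model()] result.
#' @return A list of class `score_breakdown` with `freq_term`, `enr_term`,
#'   `ent_term` and `total`.
#' @export
score_sequence <- function(seq, model) {
  b <- dna_to_int(seq)   # validates alphabet
  wl <- model$word_length
  if (length(b) < wl) stop("sequence shorter than model word_length")
  offset <- model_offset(length(b), model)
  codes <- kmer_codes(seq, wl)
  win_len <- window_length(model$window)
  bins <- kmer_bin_map(win_len, wl, model$n_bins)[offset + seq_along(codes)]
  idx <- cbind(codes + 1L, bins + 1L)
  freq_term <- mean(log(model$freq_table[idx]))
  enr_term <- mean(model$enr_table[idx])
  ent_term <- dinucleotide_entropy(seq)
  w <- model$weights
  structure(list(
    freq_term = freq_term, enr_term = enr_term, ent_term = ent_term,
    total = w[["w_freq"]] * freq_term + w[["w_enr"]] * enr_term +
      w[["w_ent"]] * ent_term
  ), class = "score_breakdown")
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random shuffle that conserves the exact dinucleotide count multiset
#' (hence also mononucleotide counts, first and last base), via a random
#' Eulerian path in the dinucleotide transition multigraph
#' (arborescence-conditioned last-edge sampling).
#'
#' @param seq DNA string over ACGT, length >= 2.
#' @param seed Optional integer; when given the result is deterministic and
#'   the caller's RNG state is left untouched.
#' @return Shuffled DNA string with identical dinucleotide counts.
#' @export
shuffle_preserving_dinucleotides <- function(seq, seed = NULL) {
  b <- dna_to_int(seq)
  n <- length(b)
  if (n < 2L) stop("sequence must have length >= 2")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  s <- b[1L]; t <- b[n]
  out_edges <- lapply(0:3, function(v) b[which(b[-n] == v) + 1L])
  has_out <- vapply(out_edges, length, 0L) > 0L

  repeat {
    last_edge <- rep(NA_integer_, 4L)
    for (v in 0:3) {
      if (v != t && has_out[v + 1L]) {
        ed <- out_edges[[v + 1L]]
        last_edge[v + 1L] <- ed[sample.int(length(ed), 1L)]
      }
    }
    ok <- TRUE
    for (v in 0:3) {
      if (v == t || !has_out[v + 1L]) next
      cur <- v; steps <- 0L
      while (cur != t && steps < 5L) {
        cur <- last_edge[cur + 1L]
        if (is.na(cur) || !has_out[cur + 1L] && cur != t) { cur <- -1L; break }
        steps <- steps + 1L
      }
      if (cur != t) { ok <- FALSE; break }
    }
    if (ok) break
  }

  ordered <- vector("list", 4L)
  for (v in 0:3) {
    ed <- out_edges[[v + 1L]]
    if (!length(ed)) { ordered[[v + 1L]] <- integer(0); next }
    if (v == t || is.na(last_edge[v + 1L])) {
      ordered[[v + 1L]] <- ed[sample.int(length(ed))]
    } else {
      le <- last_edge[v + 1L]
      rest <- ed[-match(le, ed)]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      ordered[[v + 1L]] <- c(rest, le)
    }
  }

  path <- integer(n)
  path[1L] <- s
  ptr <- rep(1L, 4L)
  cur <- s
  for (i in 2:n) {
    nxt <- ordered[[cur + 1L]][ptr[cur + 1L]]
    ptr[cur + 1L] <- ptr[cur + 1L] + 1L
    path[i] <- nxt
    cur <- nxt
  }
  int_to_dna(path)
}

#' Serialize a scoring model to JSON
#'
#' The document carries the full frequency and enrichment tables, weights,
#' window, bin scheme and a provenance hash of the sorted training ids.
#'
#' @param model A `promoter_score_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_score_model <- function(model, path) {
  doc <- list(
    format = "pol3kit_score_model", version = 1L,
    word_length = model$word_length, n_bins = model$n_bins,
    window = list(upstream = model$window$upstream,
                  downstream = model$window$downstream),
    freq_table = model$freq_table, enr_table = model$enr_table,
    weights = as.list(model$weights), pseudocount = model$pseudocount,
    training_class = model$training_class,
    training_ids = model$training_ids,
    provenance_hash = fingerprint_string(paste(model$training_ids, collapse = ","))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scoring model from JSON
#' @param path Path written by [write_score_model()].
#' @return A `promoter_score_model`.
#' @export
read_score_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "pol3kit_score_model")) {
    stop("not a pol3kit score model: ", path)
  }
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  structure(list(
    word_length = as.integer(doc$word_length),
    n_bins = as.integer(doc$n_bins),
    window = window_spec(doc$window$upstream, doc$window$downstream),
    freq_table = as_mat(doc$freq_table),
    enr_table = as_mat(doc$enr_table),
    weights = setNames(as.numeric(doc$weights[c("w_freq", "w_enr", "w_ent")]),
                       c("w_freq", "w_enr", "w_ent")),
    pseudocount = doc$pseudocount,
    training_class = doc$training_class,
    training_ids = doc$training_ids
  ), class = "promoter_score_model")
}

## stable 64-bit-ish FNV-1a string fingerprint, hex encoded
fingerprint_string <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  for (byte in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), byte)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
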