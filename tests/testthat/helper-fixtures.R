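## Shared fixtures, built in code and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

## the default synthetic training set (42 U6 + 24 U3, -500/+50 windows)
default_training <- function() {
  if (is.null(.fixtures$ts)) {
    .fixtures$ts <- generate_training_set(training_set_spec(seed = 20240101))
  }
  .fixtures$ts
}

default_spacing <- function() {
  if (is.null(.fixtures$spacing)) {
    .fixtures$spacing <- learn_spacing(default_training()$records)
  }
  .fixtures$spacing
}

default_model <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- train_model(default_training()$records, bg_seed = 404L)
  }
  .fixtures$model
}

## i.i.d. uniform ACGT sequences
random_seqs <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
}

## a tiny enumerable design instance: length-10 window, 2 bins
tiny_design_model <- function() {
  if (is.null(.fixtures$tiny_model)) {
    seqs <- random_seqs(10, 10, seed = 99)
    training <- lapply(seqs[1:5], function(s)
      promoter_record(paste0("t_", s), s, 10))
    .fixtures$tiny_model <- train_model(
      training, background = seqs[6:10],
      config = discovery_config(word_length = 6, n_bins = 2),
      window = window_spec(10, 0))
  }
  .fixtures$tiny_model
}

## independent exhaustive-search oracle: score every length-L sequence by
## direct vectorized arithmetic on integer encodings (never calls
## score_sequence or the annealer)
brute_force_optimum <- function(model, L) {
  wl <- model$word_length
  nk <- L - wl + 1L
  win_len <- model$window$upstream + model$window$downstream
  binmap <- pmin(floor((0:(nk - 1L)) * model$n_bins / win_len), model$n_bins - 1L)
  x <- 0:(4^L - 1)
  lf <- log(model$freq_table)
  en <- model$enr_table
  w <- model$weights
  tf <- numeric(length(x)); te <- numeric(length(x))
  for (p in 0:(nk - 1L)) {
    code <- (x %/% 4^(L - wl - p)) %% 4^wl
    idx <- cbind(code + 1L, binmap[p + 1L] + 1L)
    tf <- tf + lf[idx]
    te <- te + en[idx]
  }
  dmat <- matrix(0L, nrow = length(x), ncol = 16L)
  for (p in 0:(L - 2L)) {
    d <- (x %/% 4^(L - 2L - p)) %% 16
    for (j in 0:15) dmat[, j + 1L] <- dmat[, j + 1L] + (d == j)
  }
  pm <- dmat / (L - 1L)
  ent <- -rowSums(ifelse(pm > 0, pm * log(pm), 0))
  tot <- w[["w_freq"]] * tf / nk + w[["w_enr"]] * te / nk + w[["w_ent"]] * ent
  list(optimum = max(tot), argmax = x[which.max(tot)])
}

## naive position-by-position word count in one bin (counting oracle)
naive_bin_count <- function(seqs, word, bin, n_bins) {
  L <- nchar(seqs[[1L]])
  wl <- nchar(word)
  total <- 0L
  for (s in seqs) {
    for (p in 0:(L - wl)) {
      b <- min(floor(p * n_bins / L), n_bins - 1L)
      if (b == bin && substr(s, p + 1L, p + wl) == word) total <- total + 1L
    }
  }
  total
}

## plant a literal motif into background sequences at a fixed 0-based offset
plant_motif <- function(seqs, motif, at) {
  vapply(seqs, function(s) {
    paste0(substr(s, 1L, at), motif, substr(s, at + nchar(motif) + 1L, nchar(s)))
  }, "", USE.NAMES = FALSE)
}

## midpoint of the maximal plateau of a deletion profile (uniform-length
## deletions centered on one point give a flat top, so plain which.max is
## ill-defined)
profile_peak <- function(prof) {
  mx <- prof$positions[prof$per_position_deletion_pct >=
                         max(prof$per_position_deletion_pct) - 1e-9]
  mean(range(mx))
}
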