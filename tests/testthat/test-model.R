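test_that("frequency tables are per-sequence normalized and duplication-invariant", {
  s <- random_seqs(1, 120, seed = 3)
  one <- train_model(list(promoter_record("a", s, 120)),
                     background = random_seqs(1, 120, seed = 4),
                     window = window_spec(120, 0))
  two <- train_model(list(promoter_record("a", s, 120),
                          promoter_record("b", s, 120)),
                     background = random_seqs(1, 120, seed = 4),
                     window = window_spec(120, 0))
  expect_equal(one$freq_table, two$freq_table)
  ## per-bin normalization over the 4^6 word universe
  expect_true(all(abs(colSums(one$freq_table) - 1) < 1e-9))
})

test_that("training == background zeroes the enrichment table", {
  seqs <- random_seqs(3, 150, seed = 9)
  training <- lapply(seq_along(seqs), function(i)
    promoter_record(sprintf("t%d", i), seqs[i], 150))
  m <- train_model(training, background = seqs, window = window_spec(150, 0))
  expect_true(all(abs(m$enr_table) < 1e-12))
})

test_that("the TATA neighborhood dominates its bin after training on the synthetic set", {
  m <- default_model()
  ## -30 maps into the last of 5 bins over the 550-bp window
  tata_bin <- kmer_bin_map(550, 6, 5)[500 - 30 + 1]
  top10 <- order(m$freq_table[, tata_bin + 1], decreasing = TRUE)[1:10]
  words <- kmer_code_to_word(top10 - 1L, 6)
  tata_words <- expand_iupac("TATAWA")
  expect_true(any(words %in% tata_words))
})

test_that("score terms behave at their boundaries and reproduce exactly", {
  m <- default_model()
  s_poly <- strrep("A", 550)
  b <- score_sequence(s_poly, m)
  expect_equal(b$ent_term, 0)
  expect_equal(b$total,
               m$weights[["w_freq"]] * b$freq_term +
                 m$weights[["w_enr"]] * b$enr_term)

  s_rand <- random_seqs(1, 550, seed = 77)
  b_rand <- score_sequence(s_rand, m)
  expect_gt(b_rand$ent_term, 2.5)
  expect_lte(b_rand$ent_term, log(16))

  ## bit-reproducible scoring
  expect_identical(score_sequence(s_rand, m)$total,
                   score_sequence(s_rand, m)$total)
  expect_error(score_sequence("ACGTN", m), "non-ACGT|shorter")
})

test_that("a model trained on one sequence scores it above random sequences", {
  x <- random_seqs(1, 200, seed = 41)
  m <- train_model(list(promoter_record("x", x, 200)),
                   background = random_seqs(5, 200, seed = 42),
                   window = window_spec(200, 0))
  tx <- score_sequence(x, m)$total
  ys <- random_seqs(200, 200, seed = 43)
  ty <- vapply(ys, function(y) score_sequence(y, m)$total, 0, USE.NAMES = FALSE)
  expect_true(all(tx >= ty))
})

test_that("scoring is invariant to training-sequence order", {
  ts <- default_training()
  m1 <- train_model(ts$records[1:10], background = random_seqs(5, 550, seed = 8))
  m2 <- train_model(rev(ts$records[1:10]), background = random_seqs(5, 550, seed = 8))
  s <- random_seqs(1, 550, seed = 88)
  expect_equal(score_sequence(s, m1)$total, score_sequence(s, m2)$total)
})

test_that("partial-window scoring anchors the 3' end at the TSS", {
  m <- default_model()
  full <- random_seqs(1, 550, seed = 50)
  prom_500 <- substr(full, 1, 500)        # the upstream arm
  b <- score_sequence(prom_500, m)
  expect_true(is.finite(b$total))
  expect_error(score_sequence(random_seqs(1, 600, seed = 51), m), "exceeds")
  expect_error(score_sequence(random_seqs(1, 540, seed = 52), m),
               "upstream arm")
})

test_that("dinucleotide shuffles conserve the dinucleotide multiset exactly", {
  expect_identical(shuffle_preserving_dinucleotides("AAAA", seed = 1), "AAAA")
  sh <- shuffle_preserving_dinucleotides("ACGT", seed = 5)
  expect_identical(dinuc_counts(sh), dinuc_counts("ACGT"))

  s <- random_seqs(1, 550, seed = 60)
  for (seed in c(1, 2, 3)) {
    sh <- shuffle_preserving_dinucleotides(s, seed = seed)
    expect_identical(dinuc_counts(sh), dinuc_counts(s))
  }
  ## deterministic given seed, and the caller's RNG state is untouched
  set.seed(123); before <- .Random.seed
  a <- shuffle_preserving_dinucleotides(s, seed = 9)
  expect_identical(.Random.seed, before)
  b <- shuffle_preserving_dinucleotides(s, seed = 9)
  expect_identical(a, b)
})

test_that("training promoters outscore their dinucleotide shuffles on average", {
  ts <- default_training()
  m <- default_model()
  recs <- ts$records[seq(1, 66, by = 4)]
  real <- vapply(recs, function(r) score_sequence(r$sequence, m)$total, 0)
  shuf <- vapply(seq_along(recs), function(i)
    score_sequence(shuffle_preserving_dinucleotides(recs[[i]]$sequence,
                                                    seed = 700 + i), m)$total, 0)
  expect_gt(mean(real), mean(shuf))
})

test_that("models serialize to JSON and back without changing scores", {
  m <- default_model()
  path <- tempfile(fileext = ".json")
  write_score_model(m, path)
  m2 <- read_score_model(path)
  s <- random_seqs(1, 550, seed = 91)
  expect_equal(score_sequence(s, m2)$total, score_sequence(s, m)$total,
               tolerance = 1e-12)
  expect_identical(m2$training_class, m$training_class)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something_else"), bad, auto_unbox = TRUE)
  expect_error(read_score_model(bad), "not a pol3kit")
})
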