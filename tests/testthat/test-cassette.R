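test_that("simplex and flanked-array assembly lengths are exact", {
  prom <- random_seqs(1, 300, seed = 1)
  spacer23 <- random_seqs(1, 23, seed = 2)
  cas <- build_cassette("P1", prom, spacer23, mode = "simplex")
  expect_identical(nchar(cas$assembled_seq), 300L + 21L + 23L + 7L)  # 351
  expect_identical(cas$assembled_seq,
                   paste0(prom, "GAATTTCTACTAAGTGTAGAT", spacer23, "TTTTTTT"))

  spacers6 <- vapply(1:6, function(i) random_seqs(1, 23, seed = 10 + i), "")
  arr <- build_cassette("P2", prom, spacers6, mode = "flanked_array")
  expect_identical(nchar(arr$assembled_seq), 300L + 7L * 21L + 6L * 23L + 7L)  # 592
  ## every spacer is flanked by repeats on both sides
  expect_identical(sum(arr$features$type == "repeat"), 7L)
  expect_identical(sum(arr$features$type == "spacer"), 6L)
})

test_that("assembled length formulas hold for any spacer count", {
  prom <- random_seqs(1, 280, seed = 3)
  for (m in 1:5) {
    spacers <- vapply(seq_len(m), function(i) random_seqs(1, 23, seed = 20 + i), "")
    arr <- build_cassette(sprintf("P%d", m), prom, spacers, mode = "flanked_array")
    expect_identical(nchar(arr$assembled_seq),
                     280L + (m + 1L) * 21L + m * 23L + 7L)
  }
  for (len in c(17L, 23L, 30L)) {
    cas <- build_cassette("S", prom, strrep("A", len), mode = "simplex")
    expect_identical(nchar(cas$assembled_seq), 280L + 21L + len + 7L)
  }
})

test_that("cassette validation enforces spacer rules and warns on T-runs", {
  prom <- random_seqs(1, 100, seed = 4)
  expect_error(build_cassette("P", prom, c("A", "C"), mode = "simplex"),
               "exactly 1 spacer")
  expect_error(build_cassette("P", prom, strrep("A", 12), mode = "simplex"),
               "outside")
  expect_error(build_cassette("P", prom, strrep("A", 20), mode = "flanked_array"),
               "23 bp")
  expect_warning(
    build_cassette("P", prom, "ACGTTTTTACGACGACGACGACG", mode = "flanked_array"),
    "T-run")
})

test_that("stacking emits shorthand and instability flags", {
  proms <- lapply(1:4, function(i) random_seqs(1, 200, seed = 30 + i))
  cassettes <- lapply(1:4, function(i)
    build_cassette(sprintf("GSP%d", i), proms[[i]],
                   random_seqs(1, 23, seed = 40 + i), mode = "simplex"))
  layout <- stack_construct(cassettes)
  expect_identical(layout$shorthand, "4PX1")
  expect_length(layout$flags, 0L)
  expect_identical(nchar(layout$sequence),
                   sum(vapply(cassettes, function(cc) nchar(cc$assembled_seq), 0L)))

  one8 <- build_cassette("GSP9", proms[[1]],
                         vapply(1:8, function(i) random_seqs(1, 23, seed = 50 + i), ""),
                         mode = "flanked_array")
  expect_identical(stack_construct(list(one8))$shorthand, "1PX8")

  ## same promoter sequence under two ids -> instability flag
  twins <- list(build_cassette("A", proms[[1]], strrep("ACG", 7), mode = "simplex"),
                build_cassette("B", proms[[1]], random_seqs(1, 21, seed = 60),
                               mode = "simplex"))
  expect_true("repeated_promoter_sequence" %in% stack_construct(twins)$flags)

  ## duplicated ids are an error unless explicitly allowed
  dup <- list(cassettes[[1]], cassettes[[1]])
  expect_error(stack_construct(dup), "duplicated promoter ids")
  expect_silent(stack_construct(dup, allow_repeated_promoters = TRUE))
})

test_that("reverse orientation is an involution and maps features to the minus strand", {
  prom <- random_seqs(1, 150, seed = 70)
  cas <- build_cassette("R1", prom, random_seqs(1, 23, seed = 71),
                        mode = "simplex")
  expect_identical(revcomp(revcomp(cas$assembled_seq)), cas$assembled_seq)

  layout <- stack_construct(list(cas), orientations = "reverse")
  expect_identical(layout$sequence, revcomp(cas$assembled_seq))
  expect_true(all(layout$features$strand == "-"))
  ## the reversed promoter occupies the construct's 3' end
  prom_feat <- layout$features[layout$features$type == "promoter", ]
  Lc <- nchar(cas$assembled_seq)
  expect_identical(prom_feat$start, Lc - 150L)
  expect_identical(prom_feat$end, Lc)
})

test_that("construct annotation round-trips through FASTA + GFF3 parsers", {
  proms <- lapply(1:2, function(i) random_seqs(1, 120, seed = 80 + i))
  cassettes <- list(
    build_cassette("F1", proms[[1]],
                   vapply(1:6, function(i) random_seqs(1, 23, seed = 90 + i), ""),
                   mode = "flanked_array"),
    build_cassette("F2", proms[[2]], random_seqs(1, 23, seed = 99),
                   mode = "simplex"))
  layout <- stack_construct(cassettes, orientations = c("forward", "reverse"))
  fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
  emit_construct_annotation(layout, fa, gff)

  seq_back <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(seq_back[[1]]), layout$sequence)

  gr <- rtracklayer::import(gff)
  expect_identical(length(gr), nrow(layout$features))
  expect_identical(sum(S4Vectors::mcols(gr)$type == "repeat"), 7L + 1L)
  expect_identical(sum(S4Vectors::mcols(gr)$type == "spacer"), 6L + 1L)
  ## coordinates and strands survive the round trip (GFF is 1-based closed)
  ord <- order(BiocGenerics::start(gr))
  f <- layout$features[order(layout$features$start), ]
  expect_identical(BiocGenerics::start(gr)[ord], f$start + 1L)
  expect_identical(BiocGenerics::end(gr)[ord], f$end)
  expect_identical(as.character(BiocGenerics::strand(gr))[ord], f$strand)
})
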