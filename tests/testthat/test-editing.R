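## small deterministic fixture: 120-bp amplicon, 27-bp window in the middle
small_site <- function() {
  ref <- random_seqs(1, 120, seed = 900)
  target_site("unit_site", ref, 50, 77, nick_positions = c(72, 77))
}

test_that("the Indel% formula is exact on a constructed read set", {
  site <- small_site()
  ref <- site$amplicon_ref
  del9 <- paste0(substr(ref, 1, 60), substr(ref, 70, 120))  # 9-bp deletion in window
  reads <- c(ref, ref, ref, del9)
  cs <- call_reads(reads, site)
  expect_identical(cs$n_total_reads, 4L)
  expect_identical(cs$n_indel_reads, 1L)
  expect_equal(cs$indel_pct, 25.0)
  ## integer identity
  expect_equal(cs$indel_pct * cs$n_total_reads, 100 * cs$n_indel_reads)

  all_ref <- call_reads(rep(ref, 5), site)
  expect_equal(all_ref$indel_pct, 0.0)
})

test_that("indels outside the window do not count and Ns never count", {
  site <- small_site()
  ref <- site$amplicon_ref
  ## 5-bp deletion upstream of the window (positions 10-15)
  del_out <- paste0(substr(ref, 1, 10), substr(ref, 16, 120))
  ## substitutions and Ns are not indels
  n_read <- paste0(substr(ref, 1, 59), "NN", substr(ref, 62, 120))
  cs <- call_reads(c(del_out, n_read, ref), site)
  expect_identical(cs$n_indel_reads, 0L)
  expect_identical(cs$n_total_reads, 3L)
})

test_that("unalignable reads are dropped and counted, not called", {
  site <- small_site()
  junk <- random_seqs(1, 100, seed = 901)
  cs <- call_reads(c(site$amplicon_ref, junk), site)
  expect_identical(cs$n_total_reads, 1L)
  expect_identical(length(cs$dropped), 1L)
})

test_that("reverse-orientation mates are called through their complement", {
  site <- small_site()
  ref <- site$amplicon_ref
  del9 <- paste0(substr(ref, 1, 60), substr(ref, 70, 120))
  cs <- call_reads(c(revcomp(del9), revcomp(ref)), site)
  expect_identical(cs$n_total_reads, 2L)
  expect_identical(cs$n_indel_reads, 1L)
})

test_that("deletion profiles hit the trivial boundary cases", {
  site <- small_site()
  ref <- site$amplicon_ref
  unedited <- call_reads(rep(ref, 4), site)
  prof0 <- deletion_profile(list(unedited), site)
  expect_identical(length(prof0$per_position_deletion_pct), 40L)
  expect_true(all(prof0$per_position_deletion_pct == 0))

  ## every read deleted at reference positions 60-68 (0-based)
  del9 <- paste0(substr(ref, 1, 60), substr(ref, 70, 120))
  edited <- call_reads(rep(del9, 4), site)
  prof1 <- deletion_profile(list(edited), site)
  in_del <- prof1$positions >= 60 & prof1$positions < 69
  expect_true(all(prof1$per_position_deletion_pct[in_del] == 100))
  expect_true(all(prof1$per_position_deletion_pct[!in_del] == 0))

  ## mixture linearity: half edited reads -> half the profile
  half <- call_reads(c(rep(del9, 2), rep(ref, 2)), site)
  prof_half <- deletion_profile(list(half), site)
  expect_equal(prof_half$per_position_deletion_pct,
               prof1$per_position_deletion_pct / 2)

  expect_error(deletion_profile(list(call_reads(character(0), site)), site),
               "0 reads")
})

test_that("advanceable classification is strictly over the threshold", {
  expect_false(classify_advanceable(10.0))
  expect_true(classify_advanceable(10.01))
  expect_identical(classify_advanceable(c(0, 10, 10.5, 99)),
                   c(FALSE, FALSE, TRUE, TRUE))
  expect_error(classify_advanceable(NA_real_), "missing")
  ## monotone in indel_pct
  x <- sort(runif(50, 0, 100))
  expect_false(is.unsorted(classify_advanceable(x)))
})

test_that("population summaries reproduce printed advanceable rates from counts", {
  ## reconstruct populations from (n plants, k advanceable) count pairs
  pop_from_counts <- function(construct, n, k) {
    data.frame(plant_id = sprintf("%s_%03d", construct, 1:n),
               construct_id = construct, copy_number = "1",
               indel_pct = c(rep(60, k), rep(1, n - k)))
  }
  plants <- rbind(pop_from_counts("Chr08:Chr01", 33, 25),
                  pop_from_counts("GSP2273", 28, 28),
                  pop_from_counts("pM200_4PX1", 48, 5))
  s <- summarize_population(plants)
  s <- s[match(c("Chr08:Chr01", "GSP2273", "pM200_4PX1"), s$construct_id), ]
  expect_equal(s$advanceable_rate_pct, c(75.8, 100.0, 10.4))
  expect_identical(s$n_advanceable, c(25L, 28L, 5L))
  expect_identical(s$n_plants, c(33L, 28L, 48L))
})

test_that("the copy-number filter keeps only single/double-copy plants", {
  plants <- data.frame(
    plant_id = sprintf("p%d", 1:6), construct_id = "X",
    copy_number = c("1", "2", "multi", "1", "multi", "2"),
    indel_pct = c(50, 50, 50, 5, 5, 5))
  s <- summarize_population(plants)
  expect_identical(s$n_plants, 4L)
  expect_identical(s$n_advanceable, 2L)
  s_all <- summarize_population(plants, copy_filter = NULL)
  expect_identical(s_all$n_plants, 6L)
  expect_error(summarize_population(plants, copy_filter = "3"), "no plants")
})

test_that("active-promoter classification uses an inclusive per-site threshold", {
  stats <- data.frame(
    promoter_id = c("ctrl", "ctrl", "p1", "p1", "p2", "p2"),
    site_id = rep(c("genic", "intergenic"), 3),
    mean = c(10, 20, 8.0, 19, 11, 17.9),
    sd = c(2, 1, NA, NA, NA, NA))
  res <- classify_active_promoters(stats, "ctrl")
  ## thresholds: genic 8, intergenic 19; p1 is at both bounds (inclusive)
  expect_true("p1" %in% res$active_ids)
  ## p2 fails the intergenic site -> conjunction rule rejects it
  expect_false("p2" %in% res$active_ids)
  expect_identical(res$n_total, 2L)
  expect_error(classify_active_promoters(stats, "absent"), "not found")
})

test_that("luciferase QC and expression normalization honor their boundaries", {
  expect_true(luciferase_qc(1000, 10))          # exactly 100-fold
  expect_false(luciferase_qc(999, 10))          # 99.9-fold
  expect_false(luciferase_qc(10, 10))           # equal luminescence
  expect_error(luciferase_qc(100, 0), "positive")

  expect_equal(normalize_expression(8, c(4, 16)), 1.0)
  expect_equal(normalize_expression(5, 5), 1.0)
  ## scale invariance
  expect_equal(normalize_expression(3 * 7, 3 * c(2, 8)),
               normalize_expression(7, c(2, 8)))
  expect_error(normalize_expression(-1, c(2, 8)), "positive")
})

test_that("rate comparisons wrap the standard nonparametric tests", {
  vals <- c(1, 2, 3, 4, 1, 2, 3, 4)
  grp <- rep(c("a", "b"), each = 4)
  res <- compare_rates(vals, grp)
  expect_equal(res$pairwise$p, 1)

  expect_equal(correlate_rates(1:8, (1:8)^2)$rho, 1)

  expect_error(compare_rates(c(1, 2, 3), c("a", "a", "b")), ">= 2")
})

test_that("the pairwise test detects a two-standard-deviation shift", {
  set.seed(424)
  reject <- vapply(1:300, function(i) {
    x <- rnorm(20); y <- rnorm(20, mean = 2)
    res <- compare_rates(c(x, y), rep(c("a", "b"), each = 20))
    res$pairwise$p < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.9)
})
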