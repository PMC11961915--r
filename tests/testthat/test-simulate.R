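test_that("the default training set has the documented size and grammar", {
  ts <- default_training()
  expect_length(ts$records, 66L)
  classes <- vapply(ts$records, `[[`, "", "snrna_class")
  expect_identical(sum(classes == "U6"), 42L)
  expect_identical(sum(classes == "U3"), 24L)
  expect_true(all(vapply(ts$records, function(r) nchar(r$sequence), 0L) == 550L))
  expect_true(all(vapply(ts$records, `[[`, 0L, "tss_index") == 500L))
  ## planted truth respects MSP < USE < TATA < TSS per record
  by_id <- split(ts$truth, ts$truth$id)
  for (tr in by_id) {
    expect_lt(tr$end[tr$element == "MSP"], tr$start[tr$element == "USE"] + 1)
    expect_lt(tr$end[tr$element == "USE"], tr$start[tr$element == "TATA"] + 1)
    expect_lte(tr$end[tr$element == "TATA"], 0)
  }
})

test_that("a single-record set carries the USE exactly once at its planted offset", {
  one <- generate_training_set(training_set_spec(n_u6 = 1, n_u3 = 0, seed = 5))
  rec <- one$records[[1]]
  hits <- match_consensus(rec$sequence, "TCCCACATCG")
  expect_length(hits, 1L)
  planted <- one$truth[one$truth$element == "USE", ]
  expect_identical(hits - rec$tss_index, planted$start)
})

test_that("generation is bit-reproducible given the seed", {
  a <- generate_training_set(training_set_spec(n_u6 = 3, n_u3 = 2, seed = 77))
  b <- generate_training_set(training_set_spec(n_u6 = 3, n_u3 = 2, seed = 77))
  fa1 <- tempfile(); fa2 <- tempfile()
  write_promoter_set(a$records, fa1, tempfile())
  write_promoter_set(b$records, fa2, tempfile())
  expect_identical(readLines(fa1), readLines(fa2))
  c <- generate_training_set(training_set_spec(n_u6 = 3, n_u3 = 2, seed = 78))
  expect_false(identical(vapply(a$records, `[[`, "", "sequence"),
                         vapply(c$records, `[[`, "", "sequence")))
})

test_that("infeasible element layouts are rejected up front", {
  expect_error(training_set_spec(msp_offset_range = c(-70, -50)),
               "collide")
  expect_error(training_set_spec(msp_offset_range = c(-600, -300)),
               "outside the upstream window")
})

test_that("read simulation closes the loop with the caller at the extremes", {
  site <- synthetic_target_site(seed = 5)
  ## rate 0: everything matches the reference
  sim0 <- generate_edited_reads(edit_sim_spec(site, 0, 50, seed = 1))
  expect_true(all(!sim0$truth$edited))
  cs0 <- call_reads(sim0$pairs, site)
  expect_equal(cs0$indel_pct, 0.0)

  ## rate 1 with a fixed 9-bp deletion at the nick: everything is called
  sim1 <- generate_edited_reads(edit_sim_spec(site, 1, 50,
                                              del_len_range = c(9, 9), seed = 2))
  cs1 <- call_reads(sim1$pairs, site)
  expect_equal(cs1$indel_pct, 100.0)
})

test_that("the deterministic edited count equals the rounded expectation", {
  site <- synthetic_target_site(seed = 5)
  sim <- generate_edited_reads(edit_sim_spec(site, 0.3, 300, seed = 3))
  expect_identical(sum(sim$truth$edited), 90L)
  cs <- call_reads(sim$pairs, site)
  expect_identical(cs$n_indel_reads, 90L)
  expect_identical(cs$n_total_reads, 300L)

  ## the binomial flag restores sampling around the expectation
  simb <- generate_edited_reads(edit_sim_spec(site, 0.3, 300, binomial = TRUE,
                                              seed = 4))
  expect_true(abs(sum(simb$truth$edited) - 90L) < 50L)
})

test_that("deletions longer than the nick context are rejected", {
  site <- synthetic_target_site(seed = 5, amplicon_length = 60)
  expect_error(edit_sim_spec(site, 0.5, 10, del_len_range = c(50, 60)),
               "context")
})

test_that("population simulation matches its Beta-derived truth", {
  ## concentrated near 100%: every plant is advanceable
  high <- generate_population(data.frame(construct_id = "high", n_plants = 28,
                                         shape1 = 50, shape2 = 1), seed = 6)
  s_high <- summarize_population(high$plants, copy_filter = NULL)
  expect_equal(s_high$advanceable_rate_pct, 100.0)

  ## concentrated at 5%: no plant is advanceable
  low <- generate_population(data.frame(construct_id = "low", n_plants = 40,
                                        shape1 = 250, shape2 = 4750), seed = 7)
  s_low <- summarize_population(low$plants, copy_filter = NULL)
  expect_equal(s_low$advanceable_rate_pct, 0.0)
  expect_lt(low$truth$true_advanceable_fraction, 1e-12)

  expect_error(generate_population(
    data.frame(construct_id = "bad", n_plants = 5, shape1 = -1, shape2 = 2)),
    "positive")
})

test_that("the advanceable estimate converges to the planted fraction", {
  ## choose Beta parameters whose exact advanceable fraction is 0.758
  target <- 0.758
  shape1 <- 2
  shape2 <- uniroot(function(b) pbeta(0.1, shape1, b, lower.tail = FALSE) - target,
                    c(1, 100))$root
  expect_equal(pbeta(0.1, shape1, shape2, lower.tail = FALSE), target,
               tolerance = 1e-6)
  pop <- generate_population(data.frame(construct_id = "lln", n_plants = 10000,
                                        shape1 = shape1, shape2 = shape2),
                             seed = 8)
  s <- summarize_population(pop$plants, copy_filter = NULL)
  expect_lt(abs(s$advanceable_rate_pct_full - 75.8), 1.5)
})
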