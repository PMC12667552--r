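# Extraction, alignment, classification and yield statistics.

test_that("payload extraction follows the anchor/polyA pattern", {
  lay <- read_layout()
  clean <- paste0(lay$anchor5, NINEMER, strrep("A", 20))
  empty <- paste0(lay$anchor5, strrep("A", 20))
  no_tail <- paste0(lay$anchor5, NINEMER, "CCCCC")
  ex <- extract_payloads(c(clean, empty, no_tail), lay)
  expect_identical(ex$payload, c(NINEMER, "", NA_character_))
  expect_identical(ex$extracted, c(TRUE, TRUE, FALSE))
  expect_identical(ex$strand[1:2], c("forward", "forward"))
})

test_that("reverse-complement reads are recovered on the second pass", {
  lay <- read_layout()
  fwd <- paste0(lay$anchor5, NINEMER, strrep("A", 20))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  ex <- extract_payloads(c(fwd, rc), lay)
  expect_identical(ex$payload, c(NINEMER, NINEMER))
  expect_identical(ex$strand, c("forward", "reverse"))
})

test_that("extraction is non-greedy and leftmost", {
  lay <- read_layout()
  # payload then a tail longer than 10: the capture must stop at the first
  # ten-A run, leaving nothing of the tail in the payload
  read <- paste0(lay$anchor5, "GC", strrep("A", 30))
  expect_identical(extract_payloads(read, lay)$payload, "GC")
})

test_that("global alignment matches the unit-cost edit distance oracle", {
  expect_identical(align_to_target(NINEMER, NINEMER)$score, 0L)
  expect_identical(align_to_target("GCTGCT", NINEMER)$score, 3L)
  aln <- align_to_target("CAC", "CCC")
  expect_identical(aln$score, 1L)
  expect_identical(aln$ops$op, c("M", "S", "M"))
  # empty payload: r deletions
  expect_identical(align_to_target("", "CCC")$score, 3L)

  # exhaustive cross-check on a 2-letter alphabet, lengths <= 5 here
  # (the full <=8 sweep runs with the acceptance checks)
  qs <- all_strings(5)
  ts <- all_strings(5)[-1]  # non-empty targets
  got <- eosqc:::nw_cost_matrix_cpp(qs, ts)
  oracle <- adist(qs, ts)
  expect_true(all(got == oracle))
})

test_that("traceback tie-breaking is deterministic and leftmost for deletions", {
  aln <- align_to_target("CC", "CCC")
  expect_identical(aln$ops$op, c("D", "M", "M"))
  expect_identical(aln$ops$target_pos[1], 1L)
  # substitution preferred over a deletion+insertion pair
  aln2 <- align_to_target("CAC", "CCC")
  expect_identical(sum(aln2$ops$op %in% c("D", "I")), 0L)
})

test_that("error classification conserves target positions", {
  cls <- classify_errors(align_to_target(NINEMER, NINEMER))
  expect_identical(cls$n_correct, 9L)
  expect_identical(cls$n_del + cls$n_ins + cls$n_sub, 0L)

  cls <- classify_errors(align_to_target("GCTGCT", NINEMER))
  expect_identical(cls$n_del, 3L)

  # extra A in the read: one insertion, five correct
  cls <- classify_errors(align_to_target("GCATCT", "GCTCT"))
  expect_identical(cls$n_ins, 1L)
  expect_identical(cls$n_correct, 5L)

  # conservation on a random population
  set.seed(7)
  run <- simulate_run(NINEMER, 300, seed = 8,
                      model = error_model(p_del = 0.1, p_ins = 0.05, p_sub = 0.05))
  cl <- classify_reads(run$payload, NINEMER)
  expect_true(all(cl$n_correct + cl$n_del + cl$n_sub == 9L))
})

test_that("compute_metrics implements the printed yield formulas", {
  # all payloads correct
  m <- compute_metrics(rep(NINEMER, 10), NINEMER)
  expect_identical(m$full_length_yield, 1)
  expect_identical(m$stepwise_yield, 1)
  expect_true(all(m$error_rate == 0))

  # mixed population: rates from counts
  m <- compute_metrics(c(rep(NINEMER, 3), "GCTGCT"), NINEMER)
  expect_equal(m$full_length_yield, 0.75)
  expect_equal(m$N_del, 3L)
  expect_equal(m$error_rate[["del"]], 100 * 3 / (4 * 9))
  expect_equal(m$correct_proportion, (4 * 9 - 3) / (4 * 9))
  expect_equal(m$stepwise_yield^m$r, m$full_length_yield, tolerance = 1e-12)

  expect_error(compute_metrics(character(0), NINEMER), "no extracted")
})

test_that("stepwise yield algebra holds over random populations", {
  set.seed(31)
  for (i in 1:5) {
    run <- simulate_run(NINEMER, 500, seed = 100 + i,
                        model = error_model(p_del = runif(1, 0, 0.2)))
    m <- compute_metrics(classify_reads(run$payload, NINEMER), NINEMER)
    expect_equal(m$stepwise_yield^m$r, m$full_length_yield, tolerance = 1e-12)
    expect_identical(m$N_right + m$N_del + m$N_sub, m$n_reads * m$r)
  }
})

test_that("deletion-only simulations recover p_del through the full pipeline", {
  p <- 0.0305
  n <- 20000
  run <- simulate_run(NINEMER, n, seed = 4242, model = error_model(p_del = p))
  ex <- extract_payloads(run)
  expect_true(all(ex$extracted))
  m <- compute_metrics(classify_reads(ex, NINEMER), NINEMER)
  se <- sqrt(p * (1 - p) / (n * 9))
  expect_lt(abs(m$error_rate[["del"]] / 100 - p), 3 * se)
  expect_identical(m$N_sub, 0L)
  expect_identical(m$N_ins, 0L)
})

test_that("per-position profile reflects the channel and the screen", {
  # error-free reads: target base frequency 1 at every position
  p <- per_position_profile(rep(NINEMER, 20), NINEMER)
  tchars <- strsplit(NINEMER, "")[[1]]
  for (k in 1:9) expect_identical(unname(p$freq[k, tchars[k]]), 1)
  expect_true(all(abs(rowSums(p$freq) - 1) < 1e-12))

  # del-only channel: deleted fraction ~ p_del at every position
  pd <- 0.0305
  run <- simulate_run(NINEMER, 20000, seed = 77, model = error_model(p_del = pd))
  prof <- per_position_profile(run$payload, NINEMER)
  se <- sqrt(pd * (1 - pd) / min(prof$n_tallied))
  expect_true(all(abs(prof$freq[, "del"] - pd) < 3 * se + 1e-9))

  # conditional screen: a read failing early does not vote later
  prof2 <- per_position_profile(c("GCTGCTGCT", "ACTGCTGCT"), NINEMER)
  expect_identical(prof2$n_tallied, c(2L, rep(1L, 8)))
})
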