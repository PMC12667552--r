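# Synthesis-by-cycle simulator: noiseless/degenerate channels, determinism,
# binomial expectations, ground-truth event logs, read I/O.

test_that("degenerate channels behave as expected", {
  lay <- read_layout()
  run <- simulate_run(NINEMER, n_reads = 5, seed = 1, model = error_model(p_del = 0))
  expect_true(all(run$payload == NINEMER))
  expect_true(all(run$sequence == paste0(lay$anchor5, NINEMER, strrep("A", 20))))

  run <- simulate_run(NINEMER, n_reads = 5, seed = 1, model = error_model(p_del = 1))
  expect_true(all(run$payload == ""))
  expect_true(all(run$sequence == paste0(lay$anchor5, strrep("A", 20))))

  rd <- simulate_read(NINEMER, error_model(p_del = 0))
  expect_identical(rd$payload, NINEMER)
  expect_identical(rd$sequence, paste0(lay$anchor5, NINEMER, strrep("A", 20)))
  expect_identical(replay_events(rd$events, NINEMER), NINEMER)
})

test_that("identical seeds give bit-identical runs, different seeds differ", {
  mod <- error_model(p_del = 0.1, p_ins = 0.02, p_sub = 0.03)
  a <- simulate_run(NINEMER, 200, seed = 11, model = mod)
  b <- simulate_run(NINEMER, 200, seed = 11, model = mod)
  c <- simulate_run(NINEMER, 200, seed = 12, model = mod)
  expect_identical(a, b)
  expect_false(identical(a$payload, c$payload))
})

test_that("payload length matches binomial thinning at p_del = 0.0305", {
  n <- 20000
  p <- 0.0305
  run <- simulate_run(NINEMER, n, seed = 2025, model = error_model(p_del = p))
  expected <- 9 * (1 - p)
  se <- sqrt(9 * p * (1 - p) / n)  # SE of the mean payload length
  expect_lt(abs(mean(nchar(run$payload)) - expected), 3 * se)
})

test_that("fraction of reads with a deletion matches 1 - (1-p)^r", {
  n <- 20000
  run <- simulate_run("TTTTTT", n, seed = 99, model = error_model(p_del = 0.1))
  frac <- mean(nchar(run$payload) < 6)
  expected <- 1 - 0.9^6
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("event logs replay to the simulated payload", {
  mod <- error_model(p_del = 0.1, p_ins = 0.05, p_sub = 0.08)
  run <- simulate_run(NINEMER, 500, seed = 5, model = mod)
  replayed <- vapply(run$events, replay_events, character(1),
                     target = NINEMER, USE.NAMES = FALSE)
  expect_identical(replayed, run$payload)
})

test_that("invalid model and layout parameters are rejected", {
  expect_error(error_model(p_del = 0.7, p_sub = 0.5), "exceed 1")
  expect_error(error_model(p_del = -0.1), "probability")
  expect_error(read_layout(tail_length = 5), "at least 10")
  expect_error(read_layout(anchor5 = ""), "non-empty")
  expect_error(simulate_run(NINEMER, 0, seed = 1), ">= 1")
  expect_error(simulate_run(NINEMER, 10), "seed")
})

test_that("reads round-trip through FASTA and FASTQ with event headers", {
  run <- simulate_run(NINEMER, 10, seed = 3, model = error_model(p_del = 0.2))
  fa <- withr::local_tempfile(fileext = ".fa")
  fq <- withr::local_tempfile(fileext = ".fq")
  write_reads(run, fa, "fasta")
  write_reads(run, fq, "fastq")
  expect_identical(length(readLines(fq)), 4L * nrow(run))
  for (path in c(fa, fq)) {
    back <- read_reads(path)
    expect_identical(back$sequence, run$sequence)
    expect_identical(back$read_id, run$read_id)
    expect_identical(back$events, run$events)
  }
})

test_that("the bundled target table carries the seven study sequences", {
  tab <- challenge_sequences()
  expect_identical(nrow(tab), 7L)
  expect_true(all(grepl("^[ACGT]+$", tab$sequence)))
  expect_identical(tab$sequence[tab$name == "storage_60nt"], storage_fragment())
  expect_identical(nchar(tab$sequence[tab$name == "ninemer"]), 9L)
})
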