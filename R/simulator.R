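# Synthesis-by-cycle read simulator.
#
# One synthesis cycle is modelled as two draws: the controlled incorporation
# either fails (deletion, probability p_del), incorporates a wrong base
# (substitution, unconditional probability p_sub) or incorporates the target
# base; independently, an extra uncontrolled incorporation may follow
# (insertion, probability p_ins). Deletion and substitution are therefore
# mutually exclusive outcomes of one cycle, which keeps per-cycle
# expectations analytic and makes the error-rate estimator
# N_err / (reads x cycles) a direct estimate of the per-cycle probability.

#' Per-cycle synthesis error model
#'
#' @param p_del Per-cycle probability that no base is incorporated
#'   (deletion). Default 0.0305, the deletion rate observed for the 9-mer
#'   benchmark on the tetrahedral-DNA-nanostructure scaffold.
#' @param p_ins Per-cycle probability of one extra uncontrolled
#'   incorporation after the cycle (insertion).
#' @param p_sub Per-cycle probability of incorporating a wrong base
#'   (substitution). `p_del + p_sub` must not exceed 1.
#' @param sub_base_dist Distribution over the three wrong bases, as a
#'   probability vector named by base or `NULL` for uniform.
#' @param ins_base_dist Distribution over the four bases for inserted
#'   nucleotides; `NULL` for uniform.
#' @param seq_error_rate Optional per-base post-synthesis sequencing
#'   substitution rate applied uniformly over the whole read.
#' @return An object of class `"error_model"`.
#' @examples
#' error_model(p_del = 0.0305)
#' @export
error_model <- function(p_del = 0.0305, p_ins = 0, p_sub = 0,
                        sub_base_dist = NULL, ins_base_dist = NULL,
                        seq_error_rate = 0) {
  p_del <- assert_prob(p_del, "p_del")
  p_ins <- assert_prob(p_ins, "p_ins")
  p_sub <- assert_prob(p_sub, "p_sub")
  seq_error_rate <- assert_prob(seq_error_rate, "seq_error_rate")
  if (p_del + p_sub > 1) {
    stop("p_del + p_sub must not exceed 1 (they are exclusive outcomes of ",
         "one cycle)", call. = FALSE)
  }
  norm_dist <- function(d, k, what) {
    if (is.null(d)) return(NULL)
    if (!is.numeric(d) || length(d) != k || any(d < 0) || sum(d) <= 0) {
      stop(what, " must be ", k, " non-negative weights", call. = FALSE)
    }
    d / sum(d)
  }
  structure(list(p_del = p_del, p_ins = p_ins, p_sub = p_sub,
                 sub_base_dist = norm_dist(sub_base_dist, 3L, "sub_base_dist"),
                 ins_base_dist = norm_dist(ins_base_dist, 4L, "ins_base_dist"),
                 seq_error_rate = seq_error_rate),
            class = "error_model")
}

#' Read layout: initiator context and polyA tail
#'
#' Simulated reads have the form `anchor5 + payload + tail`. The default
#' anchor is the constant initiator context used by the payload-extraction
#' pattern; the default tail is a fixed run of 20 adenines (the extraction
#' pattern requires at least ten consecutive A, so the minimum tail length
#' is 10).
#'
#' @param anchor5 Constant 5' context preceding the payload.
#' @param tail_base Tail base, default `"A"`.
#' @param tail_length Fixed tail length, or the minimum length when
#'   `tail_law = "geometric"`.
#' @param tail_law `"fixed"` or `"geometric"` (minimum `tail_length`, mean
#'   `tail_length + 1/tail_geom_p - 1`).
#' @param tail_geom_p Success probability of the geometric excess length.
#' @return An object of class `"read_layout"`.
#' @export
read_layout <- function(anchor5 = "AGTGCTACTAGGACGACTCGAATT",
                        tail_base = "A", tail_length = 20L,
                        tail_law = c("fixed", "geometric"),
                        tail_geom_p = 0.25) {
  assert_dna(anchor5, "anchor5")
  if (nchar(anchor5) == 0L) stop("anchor5 must be non-empty", call. = FALSE)
  if (!tail_base %in% DNA_BASES) stop("tail_base must be one of A,C,G,T", call. = FALSE)
  tail_law <- match.arg(tail_law)
  tail_length <- as.integer(tail_length)
  if (is.na(tail_length) || tail_length < 10L) {
    stop("tail_length must be at least 10 (the extraction pattern needs ten ",
         "consecutive tail bases)", call. = FALSE)
  }
  structure(list(anchor5 = anchor5, tail_base = tail_base,
                 tail_length = tail_length, tail_law = tail_law,
                 tail_geom_p = tail_geom_p),
            class = "read_layout")
}

# Vectorised core: simulate payloads + event logs for n reads of one target.
# Returns list(payload, events). Event log: one comma-separated token per
# cycle - "M", "D" or "Sx" (x the wrong base), with "+y" appended when an
# insertion of base y follows the cycle.
#' @noRd
simulate_payloads <- function(target, n, model) {
  tchars <- seq_chars(target)
  r <- length(tchars)
  u <- matrix(runif(n * r), n, r)
  del <- u < model$p_del
  sub <- !del & u < model$p_del + model$p_sub

  emit <- matrix(rep(tchars, each = n), n, r)
  ev <- matrix("M", n, r)
  ev[del] <- "D"
  emit[del] <- ""

  nsub <- sum(sub)
  if (nsub > 0) {
    # wrong base: draw index 1..3 over the three non-target bases
    wdist <- model$sub_base_dist %||% rep(1 / 3, 3)
    widx <- sample.int(3L, nsub, replace = TRUE, prob = wdist)
    wrong <- vapply(seq_len(nsub), function(k) {
      setdiff(DNA_BASES, emit[sub][k])[widx[k]]
    }, character(1))
    emit[sub] <- wrong
    ev[sub] <- paste0("S", wrong)
  }

  ins <- matrix(runif(n * r) < model$p_ins, n, r)
  insmat <- matrix("", n, r)
  nins <- sum(ins)
  if (nins > 0) {
    idist <- model$ins_base_dist %||% rep(0.25, 4)
    ibase <- DNA_BASES[sample.int(4L, nins, replace = TRUE, prob = idist)]
    insmat[ins] <- ibase
    ev[ins] <- paste0(ev[ins], "+", ibase)
  }

  # interleave emission and insertion columns, then paste row-wise
  cols <- vector("list", 2L * r)
  cols[seq(1L, 2L * r, by = 2L)] <- lapply(seq_len(r), function(j) emit[, j])
  cols[seq(2L, 2L * r, by = 2L)] <- lapply(seq_len(r), function(j) insmat[, j])
  payload <- do.call(paste0, cols)
  events <- do.call(paste, c(lapply(seq_len(r), function(j) ev[, j]),
                             list(sep = ",")))
  list(payload = payload, events = events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a single synthesis read
#'
#' Draws one read from the per-cycle error channel using the current RNG
#' stream (call [set.seed()] or use [simulate_run()] for reproducibility).
#'
#' @param target Target payload sequence (A/C/G/T).
#' @param model An [error_model()].
#' @param layout A [read_layout()].
#' @return A list with `sequence` (full read), `payload` (synthesized
#'   segment), and `events` (per-cycle ground-truth log; see
#'   [replay_events()]).
#' @export
simulate_read <- function(target, model = error_model(), layout = read_layout()) {
  assert_dna(target, "target")
  if (nchar(target) == 0L) stop("target must be non-empty", call. = FALSE)
  sim <- simulate_payloads(target, 1L, model)
  tail_len <- layout$tail_length
  if (layout$tail_law == "geometric") {
    tail_len <- layout$tail_length + stats::rgeom(1L, layout$tail_geom_p)
  }
  sequence <- paste0(layout$anchor5, sim$payload,
                     strrep(layout$tail_base, tail_len))
  if (model$seq_error_rate > 0) {
    sequence <- apply_sequencing_errors(sequence, model$seq_error_rate)
  }
  list(sequence = sequence, payload = sim$payload, events = sim$events)
}

#' @noRd
apply_sequencing_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- seq_chars(s)
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                        character(1))
    }
    paste0(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a full synthesis run
#'
#' Generates `n_reads` reads of one target under a fixed seed; identical
#' arguments give bit-identical output.
#'
#' @inheritParams simulate_read
#' @param n_reads Number of reads (>= 1).
#' @param seed Integer seed controlling all randomness of the run.
#' @return A data.frame with columns `read_id`, `sequence`, `payload`
#'   (ground-truth synthesized segment) and `events` (per-cycle log).
#' @examples
#' run <- simulate_run("GCTGCTGCT", n_reads = 5, seed = 1,
#'                     model = error_model(p_del = 0.1))
#' run$payload
#' @export
simulate_run <- function(target, n_reads, seed, model = error_model(),
                         layout = read_layout()) {
  assert_dna(target, "target")
  if (nchar(target) == 0L) stop("target must be non-empty", call. = FALSE)
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1L) stop("n_reads must be >= 1", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  sim <- simulate_payloads(target, n_reads, model)
  tail_len <- rep(layout$tail_length, n_reads)
  if (layout$tail_law == "geometric") {
    tail_len <- layout$tail_length + stats::rgeom(n_reads, layout$tail_geom_p)
  }
  sequence <- paste0(layout$anchor5, sim$payload,
                     strrep(layout$tail_base, tail_len))
  if (model$seq_error_rate > 0) {
    sequence <- apply_sequencing_errors(sequence, model$seq_error_rate)
  }
  data.frame(read_id = sprintf("read_%06d", seq_len(n_reads)),
             sequence = sequence, payload = sim$payload, events = sim$events,
             stringsAsFactors = FALSE)
}

#' Replay a per-cycle event log
#'
#' Rebuilds the synthesized payload recorded in a read's ground-truth event
#' log, for scoring classifier output against the simulator's truth.
#' Tokens are comma-separated, one per cycle: `M` (correct base), `D`
#' (deletion), `Sx` (substitution by base `x`); a suffix `+y` denotes an
#' inserted base `y` following the cycle. Post-synthesis sequencing errors
#' are not part of the log.
#'
#' @param events Event string as produced by [simulate_run()].
#' @param target The target sequence the log refers to.
#' @return The payload string implied by the log.
#' @export
replay_events <- function(events, target) {
  tchars <- seq_chars(target)
  toks <- strsplit(events, ",", fixed = TRUE)[[1L]]
  if (length(toks) != length(tchars)) {
    stop("event log has ", length(toks), " cycles but target has ",
         length(tchars), call. = FALSE)
  }
  out <- character(0)
  for (k in seq_along(toks)) {
    parts <- strsplit(toks[k], "+", fixed = TRUE)[[1L]]
    main <- parts[1L]
    emitted <- switch(substr(main, 1L, 1L),
                      M = tchars[k],
                      D = "",
                      S = substr(main, 2L, 2L),
                      stop("bad event token: ", toks[k], call. = FALSE))
    out <- c(out, emitted, if (length(parts) > 1L) parts[2L])
  }
  paste0(out, collapse = "")
}

#' Write / read simulated reads as FASTA or FASTQ
#'
#' Headers carry the read id and the ground-truth event log
#' (`read_id events=...`), so classifier accuracy can be scored exactly.
#' FASTQ output uses a constant quality character.
#'
#' @param reads Data.frame from [simulate_run()] (columns `read_id`,
#'   `sequence`, optionally `events`).
#' @param path Output file path.
#' @param format `"fasta"` or `"fastq"`.
#' @param qual_char Single quality character for FASTQ output.
#' @return `write_reads()` the path, invisibly. `read_reads()` a data.frame
#'   with `read_id`, `sequence` and (when present in headers) `events`.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq"),
                        qual_char = "I") {
  format <- match.arg(format)
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  ids <- reads$read_id
  if (!is.null(reads$events)) ids <- paste0(ids, " events=", reads$events)
  set <- Biostrings::DNAStringSet(setNames(reads$sequence, ids))
  if (format == "fasta") {
    Biostrings::writeXStringSet(set, path)
  } else {
    quals <- Biostrings::BStringSet(strrep(qual_char, nchar(reads$sequence)))
    Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals)
  }
  invisible(path)
}

#' @rdname write_reads
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  set <- Biostrings::readDNAStringSet(path, format = format)
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  events <- ifelse(grepl("events=", hdr, fixed = TRUE),
                   sub("^.*events=(\\S+).*$", "\\1", hdr), NA_character_)
  out <- data.frame(read_id = id, sequence = as.character(set),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(!is.na(events))) out$events <- events
  out
}

#' Bundled target sequences
#'
#' The seven target oligonucleotides used throughout the package: the 9-mer
#' benchmark, a hairpin-forming 16-mer (annotated with its reported folding
#' free energy), two homopolymers, low- and high-GC probes, and the 60-nt
#' information-storage fragment.
#'
#' @return A data.frame with columns `name`, `sequence`, `annotation`.
#' @examples
#' challenge_sequences()
#' @export
challenge_sequences <- function() {
  data.frame(
    name = c("ninemer", "hairpin", "homopolymer_C3", "homopolymer_T6",
             "low_gc", "high_gc", "storage_60nt"),
    sequence = c("GCTGCTGCT", "CGAGCTAGTCAGCTCG", "CCC", "TTTTTT",
                 "ATATGATATC", "CGCGTCGCGA", storage_fragment()),
    annotation = c("9-cycle benchmark",
                   "hairpin, deltaG = -7.10",
                   "C homopolymer", "T homopolymer",
                   "GC content 20%", "GC content 80%",
                   "60-nt information-storage fragment"),
    stringsAsFactors = FALSE)
}
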