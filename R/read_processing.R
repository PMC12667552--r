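# Payload extraction, alignment-based error classification and yield
# statistics.
#
# Extraction follows the pattern  anchor5 (.*?) AAAAAAAAAA : the shortest
# segment between the first exact occurrence of the initiator context and
# the next run of ten tail bases (leftmost, non-greedy). Classification
# aligns each extracted payload globally to the target under unit edit
# costs and counts deletions, insertions and substitutions per target
# position.

#' Extract synthesized payloads from reads
#'
#' For each read, the shortest segment between the first occurrence of
#' `layout$anchor5` and the next run of ten tail bases is extracted
#' (leftmost, non-greedy; anchors are matched exactly). If the forward
#' strand does not match, the reverse complement is searched. Reads where
#' neither strand matches are reported with `extracted = FALSE`. A
#' zero-length payload is a valid observation (a fully failed synthesis).
#'
#' @param reads Character vector of read sequences, or a data.frame with a
#'   `sequence` column (and optionally `read_id`).
#' @param layout A [read_layout()].
#' @return A data.frame with columns `read_id`, `payload`, `strand`
#'   (`"forward"`/`"reverse"`/`NA`) and `extracted` (logical).
#' @examples
#' lay <- read_layout()
#' extract_payloads(paste0(lay$anchor5, "GCTGCTGCT", strrep("A", 20)), lay)
#' @export
extract_payloads <- function(reads, layout = read_layout()) {
  if (is.data.frame(reads)) {
    ids <- reads$read_id %||% sprintf("read_%06d", seq_len(nrow(reads)))
    seqs <- reads$sequence
  } else {
    seqs <- as.character(reads)
    ids <- sprintf("read_%06d", seq_along(seqs))
  }
  pattern <- paste0(layout$anchor5, "(.*?)", strrep(layout$tail_base, 10L))
  m <- regexpr(pattern, seqs, perl = TRUE)
  start <- attr(m, "capture.start")[, 1L]
  len <- attr(m, "capture.length")[, 1L]
  fwd <- ifelse(m == -1L, NA_character_, substr(seqs, start, start + len - 1L))

  payload <- fwd
  strand <- ifelse(is.na(fwd), NA_character_, "forward")
  miss <- is.na(fwd)
  if (any(miss)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[miss])))
    m2 <- regexpr(pattern, rc, perl = TRUE)
    start2 <- attr(m2, "capture.start")[, 1L]
    len2 <- attr(m2, "capture.length")[, 1L]
    rev_payload <- ifelse(m2 == -1L, NA_character_,
                          substr(rc, start2, start2 + len2 - 1L))
    payload[miss] <- rev_payload
    strand[miss] <- ifelse(is.na(rev_payload), NA_character_, "reverse")
  }
  data.frame(read_id = ids, payload = payload, strand = strand,
             extracted = !is.na(payload), stringsAsFactors = FALSE)
}

#' Globally align a payload to the target
#'
#' Optimal global alignment under unit edit costs (match 0, substitution 1,
#' gap 1). Among co-optimal alignments the traceback is deterministic:
#' diagonal moves are preferred over gaps, and target-consuming gaps
#' (deletions) over read-consuming gaps (insertions), which places
#' co-optimal homopolymer deletions leftmost on the target. An empty
#' payload yields `nchar(target)` deletions.
#'
#' @param payload Extracted payload (may be `""`).
#' @param target Non-empty target sequence.
#' @return A list of class `"alignment_result"`: `score` (edit distance) and
#'   `ops`, a data.frame with columns `op` (`M`/`S`/`D`/`I`), `target_pos`
#'   and `read_pos` (`I` rows carry the target position they follow;
#'   `D` rows have `read_pos = NA`).
#' @examples
#' align_to_target("GCTGCT", "GCTGCTGCT")$score  # 3 deletions
#' @export
align_to_target <- function(payload, target) {
  assert_dna(payload, "payload")
  assert_dna(target, "target")
  if (nchar(target) == 0L) stop("target must be non-empty", call. = FALSE)
  res <- nw_align_cpp(payload, target)
  structure(list(score = res$score,
                 ops = data.frame(op = res$op, target_pos = res$target_pos,
                                  read_pos = res$read_pos,
                                  stringsAsFactors = FALSE)),
            class = "alignment_result")
}

#' Classify the errors of one aligned payload
#'
#' Assigns one outcome per target position (`correct`, `deletion` or
#' `substitution`) and tallies insertions against the target position they
#' follow (0 = before the first position). For every alignment,
#' `n_correct + n_del + n_sub == nchar(target)`.
#'
#' @param aln An `"alignment_result"` from [align_to_target()].
#' @return A list with `n_correct`, `n_del`, `n_ins`, `n_sub`, `outcome`
#'   (character vector over target positions) and `ins_after` (integer
#'   vector indexed 0..r of insertion counts).
#' @export
classify_errors <- function(aln) {
  stopifnot(inherits(aln, "alignment_result"))
  ops <- aln$ops
  body_ops <- ops[ops$op != "I", , drop = FALSE]
  r <- nrow(body_ops)
  outcome <- character(r)
  outcome[body_ops$op == "M"] <- "correct"
  outcome[body_ops$op == "S"] <- "substitution"
  outcome[body_ops$op == "D"] <- "deletion"
  outcome <- outcome[order(body_ops$target_pos)]
  ins_after <- integer(r + 1L)
  ins <- ops$target_pos[ops$op == "I"]
  if (length(ins)) {
    tab <- table(factor(ins, levels = 0:r))
    ins_after <- as.integer(tab)
  }
  list(n_correct = sum(outcome == "correct"),
       n_del = sum(outcome == "deletion"),
       n_ins = length(ins),
       n_sub = sum(outcome == "substitution"),
       outcome = outcome,
       ins_after = setNames(ins_after, 0:r))
}

# Align and classify a payload vector in one C++ pass over unique payloads.
#' @noRd
classify_core <- function(payloads, target) {
  uniq <- unique(payloads)
  res <- classify_batch_cpp(uniq, target)
  idx <- match(payloads, uniq)
  list(uniq = uniq, idx = idx, res = res)
}

#' Align and classify a set of extracted payloads
#'
#' Vectorised [align_to_target()] + [classify_errors()] over a read
#' population (identical payloads are aligned once). Payloads longer than
#' `max_payload_factor` times the target are retained and classified —
#' insertions then dominate — unless a finite cap is set, in which case
#' longer payloads are dropped with a count reported in the attribute
#' `n_capped`.
#'
#' @param payloads Character vector of payloads (or the data.frame from
#'   [extract_payloads()]; only rows with `extracted == TRUE` are used).
#' @param target Non-empty target sequence.
#' @param max_payload_factor Length cap as a multiple of the target length
#'   (default `Inf`, no cap).
#' @return A data.frame with one row per read: `payload`, `score`,
#'   `n_correct`, `n_del`, `n_ins`, `n_sub`, `full_length` (payload equals
#'   target).
#' @export
classify_reads <- function(payloads, target, max_payload_factor = Inf) {
  assert_dna(target, "target")
  if (is.data.frame(payloads)) payloads <- payloads$payload[payloads$extracted]
  payloads <- as.character(payloads)
  n_capped <- 0L
  if (is.finite(max_payload_factor)) {
    cap <- max_payload_factor * nchar(target)
    keep <- nchar(payloads) <= cap
    n_capped <- sum(!keep)
    payloads <- payloads[keep]
  }
  if (length(payloads) == 0L) {
    stop("no extracted payloads to classify", call. = FALSE)
  }
  cc <- classify_core(payloads, target)
  out <- data.frame(payload = payloads,
                    score = cc$res$score[cc$idx],
                    n_correct = cc$res$n_match[cc$idx],
                    n_del = cc$res$n_del[cc$idx],
                    n_ins = cc$res$n_ins[cc$idx],
                    n_sub = cc$res$n_sub[cc$idx],
                    full_length = payloads == target,
                    stringsAsFactors = FALSE)
  attr(out, "n_capped") <- n_capped
  out
}

#' Synthesis quality metrics for one target
#'
#' From classified reads, computes the per-class error rates
#' `N_class / (S_all x r)`, the proportion of correct bases
#' `N_right / (S_all x r)`, the full-length yield `S_right / S_all`
#' (payload exactly equal to the target) and the average stepwise yield
#' `full_length_yield^(1/r)`, where `S_all` is the number of extracted
#' sequences and `r` the number of synthesis rounds (the target length).
#'
#' @param classified Data.frame from [classify_reads()], or a character
#'   vector of payloads (classified internally).
#' @param target Target sequence; sets `r = nchar(target)` unless `r` is
#'   given.
#' @param r Number of synthesis rounds (defaults to the target length).
#' @return An object of class `"synthesis_metrics"`: counts (`n_reads`,
#'   `n_full_length`, `N_right`, `N_del`, `N_ins`, `N_sub`, `r`) and
#'   derived rates (`error_rate` named vector in percent,
#'   `correct_proportion`, `full_length_yield`, `stepwise_yield`, all
#'   fractions in [0, 1] except `error_rate`).
#' @examples
#' m <- compute_metrics(c("GCTGCTGCT", "GCTGCT"), "GCTGCTGCT")
#' m$full_length_yield
#' @export
compute_metrics <- function(classified, target, r = nchar(target)) {
  assert_dna(target, "target")
  if (!is.data.frame(classified)) {
    classified <- classify_reads(classified, target)
  }
  n <- nrow(classified)
  if (n == 0L) stop("no extracted reads: yield denominators are undefined",
                    call. = FALSE)
  N_all <- n * r
  N_del <- sum(classified$n_del)
  N_ins <- sum(classified$n_ins)
  N_sub <- sum(classified$n_sub)
  N_right <- sum(classified$n_correct)
  s_right <- sum(classified$full_length)
  y_total <- s_right / n
  structure(list(
    n_reads = n, n_full_length = s_right, r = r,
    N_right = N_right, N_del = N_del, N_ins = N_ins, N_sub = N_sub,
    error_rate = c(del = 100 * N_del / N_all,
                   ins = 100 * N_ins / N_all,
                   sub = 100 * N_sub / N_all),
    correct_proportion = N_right / N_all,
    full_length_yield = y_total,
    stepwise_yield = y_total^(1 / r)),
    class = "synthesis_metrics")
}

#' @export
print.synthesis_metrics <- function(x, ...) {
  cat("Synthesis metrics over", x$n_reads, "extracted reads,",
      x$r, "rounds\n")
  cat(sprintf("  full-length yield: %.2f%%  (S_right = %d)\n",
              100 * x$full_length_yield, x$n_full_length))
  cat(sprintf("  stepwise yield:    %.2f%%\n", 100 * x$stepwise_yield))
  cat(sprintf("  error rates:  del %.3f%%  ins %.3f%%  sub %.3f%%\n",
              x$error_rate[["del"]], x$error_rate[["ins"]],
              x$error_rate[["sub"]]))
  cat(sprintf("  correct bases: %.2f%%\n", 100 * x$correct_proportion))
  invisible(x)
}

#' Per-position outcome profile
#'
#' For each target position, the frequency of the outcomes A/C/G/T/deleted
#' among the reads tallied there (the observed base is the target base for
#' a match and the substituted base otherwise). With
#' `screen = "conditional"` (the default, mirroring position-by-position
#' consensus readout), a read contributes at position k only while its
#' alignment is all-match over positions 1..k-1; a prefix-correct short
#' read therefore contributes up to and including its first trailing
#' deletion and is excluded beyond it. With `screen = "none"` every read
#' contributes at every position. Insertions are not part of the position
#' outcomes. Rows sum to 1.
#'
#' @param payloads Character vector of payloads (or [extract_payloads()]
#'   output).
#' @param target Target sequence.
#' @param screen `"conditional"` or `"none"`.
#' @return A list with `freq` (r x 5 matrix, columns A,C,G,T,del; rows sum
#'   to 1), `counts` (same shape, raw tallies) and `n_tallied` (reads per
#'   position).
#' @export
per_position_profile <- function(payloads, target,
                                 screen = c("conditional", "none")) {
  screen <- match.arg(screen)
  assert_dna(target, "target")
  if (is.data.frame(payloads)) payloads <- payloads$payload[payloads$extracted]
  payloads <- as.character(payloads)
  if (length(payloads) == 0L) stop("no payloads", call. = FALSE)
  r <- nchar(target)
  cc <- classify_core(payloads, target)
  obs <- cc$res$observed[cc$idx, , drop = FALSE]       # base or "-"
  ok <- cc$res$outcome[cc$idx, , drop = FALSE] == 0L   # match indicator

  counts <- matrix(0L, r, 5L, dimnames = list(NULL, c(DNA_BASES, "del")))
  n_tallied <- integer(r)
  alive <- rep(TRUE, length(payloads))
  for (k in seq_len(r)) {
    idx <- if (screen == "conditional") alive else rep(TRUE, length(payloads))
    col <- obs[idx, k]
    col[col == "-"] <- "del"
    tab <- table(factor(col, levels = colnames(counts)))
    counts[k, ] <- as.integer(tab)
    n_tallied[k] <- sum(idx)
    if (screen == "conditional") alive <- alive & ok[, k]
  }
  freq <- counts / pmax(rowSums(counts), 1L)
  list(freq = freq, counts = counts, n_tallied = n_tallied)
}

#' Summarise a run's extraction and metrics into flat key-value text
#'
#' @param metrics A `"synthesis_metrics"` object.
#' @param path Output path for a two-column TSV (`key`, `value`).
#' @return The path, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "synthesis_metrics"))
  kv <- c(n_reads = metrics$n_reads,
          n_full_length = metrics$n_full_length,
          r = metrics$r,
          N_right = metrics$N_right, N_del = metrics$N_del,
          N_ins = metrics$N_ins, N_sub = metrics$N_sub,
          del_rate_pct = metrics$error_rate[["del"]],
          ins_rate_pct = metrics$error_rate[["ins"]],
          sub_rate_pct = metrics$error_rate[["sub"]],
          correct_proportion = metrics$correct_proportion,
          full_length_yield = metrics$full_length_yield,
          stepwise_yield = metrics$stepwise_yield)
  utils::write.table(data.frame(key = names(kv), value = unname(kv)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
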