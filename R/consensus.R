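# Majority-vote consensus recovery.
#
# Two procedures: the modal full payload string ("global" vote over whole
# reads), and a position-by-position conditional vote in which position k
# is called from the reads that agreed with the consensus at all earlier
# positions. Ties are broken lexicographically (A < C < G < T) and flagged
# rather than randomised, so runs are reproducible.

#' Global majority vote over whole payloads
#'
#' Returns the most frequent payload string. A tie between distinct modal
#' strings is broken lexicographically and flagged.
#'
#' @param payloads Non-empty character vector of payloads (or the
#'   data.frame from [extract_payloads()]).
#' @return A list of class `"consensus_result"`: `consensus`,
#'   `payload_freq` (data.frame of distinct payloads and counts, most
#'   frequent first), `tie` (logical), `method = "global"`.
#' @examples
#' global_majority(c("ACG", "ACG", "AGG"))$consensus
#' @export
global_majority <- function(payloads) {
  if (is.data.frame(payloads)) payloads <- payloads$payload[payloads$extracted]
  payloads <- as.character(payloads)
  if (length(payloads) == 0L) stop("empty payload collection", call. = FALSE)
  tab <- table(payloads)
  tab <- tab[order(-as.integer(tab), names(tab))]  # count desc, then lexicographic
  tie <- length(tab) > 1L && tab[2L] == tab[1L]
  structure(list(consensus = names(tab)[1L],
                 payload_freq = data.frame(payload = names(tab),
                                           count = as.integer(tab),
                                           stringsAsFactors = FALSE,
                                           row.names = NULL),
                 tie = tie, tie_positions = integer(0),
                 method = "global"),
            class = "consensus_result")
}

#' Position-by-position conditional majority vote
#'
#' Iterates over positions k = 1..`length`: among the reads that survived
#' through position k-1 and are at least k bases long, the base at
#' position k is tallied and the most frequent becomes the consensus call;
#' the survivors at k are the tallied reads whose base matches that call.
#' Reads shorter than k drop out of the tally at k (and, being shorter
#' still, of all later positions) but their earlier votes stand. By
#' default the screen is referenced to the evolving consensus itself, so
#' the procedure needs no knowledge of the target; passing a `reference`
#' sequence screens against a known target instead (error-profiling use).
#'
#' @param payloads Non-empty character vector of payloads (or
#'   [extract_payloads()] output).
#' @param length Number of positions to call (>= 1).
#' @param reference Optional known sequence to screen against instead of
#'   the evolving consensus.
#' @return A list of class `"consensus_result"`: `consensus` (string of
#'   `length` bases), `per_position_counts` (`length` x 4 matrix of base
#'   tallies), `surviving_reads` (non-increasing integer vector: survivors
#'   after each call), `tie_positions`, `tie`, `method = "conditional"`.
#' @examples
#' conditional_consensus(c("ACG", "ACG", "AGG"), 3)$surviving_reads  # 3 2 2
#' @export
conditional_consensus <- function(payloads, length, reference = NULL) {
  if (is.data.frame(payloads)) payloads <- payloads$payload[payloads$extracted]
  payloads <- as.character(payloads)
  if (base::length(payloads) == 0L) stop("empty payload collection", call. = FALSE)
  len <- as.integer(length)
  if (is.na(len) || len < 1L) stop("length must be >= 1", call. = FALSE)
  if (!is.null(reference)) {
    assert_dna(reference, "reference")
    if (nchar(reference) < len) {
      stop("reference is shorter than the requested consensus length",
           call. = FALSE)
    }
  }

  nc <- nchar(payloads)
  counts <- matrix(0L, len, 4L, dimnames = list(NULL, DNA_BASES))
  consensus <- character(len)
  survivors <- integer(len)
  ties <- integer(0)
  alive <- rep(TRUE, base::length(payloads))

  for (k in seq_len(len)) {
    idx <- alive & nc >= k
    if (!any(idx)) {
      stop("survivor set is empty at position ", k,
           " (consensus called through position ", k - 1L, ")", call. = FALSE)
    }
    ch <- substr(payloads[idx], k, k)
    tab <- table(factor(ch, levels = DNA_BASES))
    counts[k, ] <- as.integer(tab)
    top <- max(tab)
    call_k <- DNA_BASES[which(tab == top)]
    if (base::length(call_k) > 1L) ties <- c(ties, k)
    consensus[k] <- call_k[1L]  # lexicographic tie-break (A < C < G < T)
    screen_k <- if (is.null(reference)) consensus[k] else substr(reference, k, k)
    alive <- alive & nc >= k & substr(payloads, k, k) == screen_k
    survivors[k] <- sum(alive)
  }
  structure(list(consensus = paste0(consensus, collapse = ""),
                 per_position_counts = counts,
                 surviving_reads = survivors,
                 tie_positions = ties, tie = base::length(ties) > 0L,
                 method = "conditional"),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Majority-vote consensus (", x$method, ")\n", sep = "")
  cat("  consensus: ", x$consensus, "\n", sep = "")
  if (x$method == "conditional") {
    cat("  survivors: ", x$surviving_reads[1L], " -> ",
        x$surviving_reads[base::length(x$surviving_reads)], "\n", sep = "")
  }
  if (x$tie) cat("  ties at positions:", paste(x$tie_positions, collapse = ","), "\n")
  invisible(x)
}

#' Decode the stored byte message from a consensus
#'
#' Delegates to [decode_message()]; the consensus length must be a
#' multiple of 4 so that whole bytes can be framed.
#'
#' @param consensus A `"consensus_result"` or a plain DNA string.
#' @param map A [base_map()].
#' @return A raw vector of decoded bytes.
#' @export
decode_information <- function(consensus, map = base_map()) {
  seq <- if (inherits(consensus, "consensus_result")) consensus$consensus else consensus
  decode_message(seq, map)
}

#' Write a per-position count matrix as TSV (heatmap-ready)
#'
#' @param consensus A `"consensus_result"` from [conditional_consensus()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_position_counts <- function(consensus, path) {
  stopifnot(inherits(consensus, "consensus_result"))
  m <- consensus$per_position_counts
  df <- data.frame(position = seq_len(nrow(m)), m,
                   survivors = consensus$surviving_reads)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
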