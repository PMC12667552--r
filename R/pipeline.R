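# End-to-end orchestration: simulate -> extract -> classify -> consensus ->
# decode, as one reproducible, seeded run. Each stage is also callable on
# its own; the pipeline simply composes them and (optionally) writes the
# per-stage artifacts plus a flat summary for provenance.

#' Run the full synthesis-and-readout pipeline
#'
#' Simulates a sequencing run for `target` (or reads one from
#' `reads_file`), extracts payloads, classifies errors and computes yield
#' metrics, calls a consensus, and — when the consensus length is a
#' multiple of 4 — decodes the stored byte message.
#'
#' @param target Target payload sequence. Required when simulating;
#'   optional (used for metrics) when `reads_file` is given.
#' @param n_reads Number of reads to simulate.
#' @param seed Integer seed (mandatory when simulating).
#' @param model An [error_model()].
#' @param layout A [read_layout()].
#' @param map A [base_map()] for the decode stage.
#' @param reads_file Optional FASTA/FASTQ of existing reads; disables the
#'   simulation stage.
#' @param consensus_method `"conditional"` (default) or `"global"`.
#' @param consensus_length Positions to call in conditional mode; defaults
#'   to `nchar(target)`.
#' @param decode Whether to run the decode stage (default: only when the
#'   consensus length is a multiple of 4).
#' @param out_dir Optional directory; when given, writes `reads.fq`,
#'   `payloads.tsv`, `metrics.tsv`, `consensus.fa`, `position_counts.tsv`,
#'   `message.bin` and `config.txt` (the resolved configuration).
#' @return A list of class `"eos_pipeline_report"` with elements `config`,
#'   `n_reads`, `n_extracted`, `metrics` ([compute_metrics()] result),
#'   `consensus` (a `"consensus_result"`), `message` (raw vector or NULL)
#'   and `timings` (seconds per stage).
#' @examples
#' rep <- run_pipeline("GCTGCTGCT", n_reads = 200, seed = 1,
#'                     model = error_model(p_del = 0))
#' rep$metrics$full_length_yield  # 1
#' @export
run_pipeline <- function(target = NULL, n_reads = 10000L, seed = NULL,
                         model = error_model(), layout = read_layout(),
                         map = base_map(), reads_file = NULL,
                         consensus_method = c("conditional", "global"),
                         consensus_length = NULL, decode = NULL,
                         out_dir = NULL) {
  consensus_method <- match.arg(consensus_method)
  simulate <- is.null(reads_file)
  if (simulate) {
    if (is.null(target)) {
      stop("stage 'simulate': a target sequence is required", call. = FALSE)
    }
    if (is.null(seed)) {
      stop("stage 'simulate': a seed is mandatory for reproducible runs",
           call. = FALSE)
    }
  } else if (!file.exists(reads_file)) {
    stop("stage 'input': reads_file does not exist: ", reads_file,
         call. = FALSE)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- tic() - t0
    res
  }

  reads <- stage("simulate/input", {
    if (simulate) {
      simulate_run(target, n_reads, seed, model, layout)
    } else {
      read_reads(reads_file)
    }
  })
  extracted <- stage("extract", extract_payloads(reads, layout))

  metrics <- NULL
  if (!is.null(target)) {
    metrics <- stage("analyze", {
      compute_metrics(classify_reads(extracted, target), target)
    })
  }

  cons <- stage("consensus", {
    if (consensus_method == "global") {
      global_majority(extracted)
    } else {
      clen <- consensus_length %||% nchar(target)
      if (is.null(clen) || clen < 1L) {
        stop("consensus_length is required when no target is given")
      }
      conditional_consensus(extracted, clen)
    }
  })

  do_decode <- decode %||% (nchar(cons$consensus) %% 4L == 0L)
  message_bytes <- if (do_decode) {
    stage("decode", decode_information(cons, map))
  } else NULL

  config <- list(simulate = simulate, target = target, n_reads = n_reads,
                 seed = seed, reads_file = reads_file,
                 p_del = model$p_del, p_ins = model$p_ins, p_sub = model$p_sub,
                 seq_error_rate = model$seq_error_rate,
                 anchor5 = layout$anchor5, tail_length = layout$tail_length,
                 tail_law = layout$tail_law,
                 base_map = paste0(unname(unclass(map)), collapse = ""),
                 consensus_method = consensus_method)

  if (!is.null(out_dir)) {
    if (simulate) write_reads(reads, file.path(out_dir, "reads.fq"), "fastq")
    utils::write.table(extracted, file.path(out_dir, "payloads.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(metrics)) write_metrics(metrics, file.path(out_dir, "metrics.tsv"))
    write_payload_file(cons$consensus, file.path(out_dir, "consensus.fa"),
                       name = "consensus")
    if (cons$method == "conditional") {
      write_position_counts(cons, file.path(out_dir, "position_counts.tsv"))
    }
    if (!is.null(message_bytes)) {
      writeBin(message_bytes, file.path(out_dir, "message.bin"))
    }
    writeLines(paste0(names(config), "\t",
                      vapply(config, function(v) paste0(format(v), collapse = ","),
                             character(1))),
               file.path(out_dir, "config.txt"))
  }

  structure(list(config = config, n_reads = nrow(reads),
                 n_extracted = sum(extracted$extracted),
                 metrics = metrics, consensus = cons,
                 message = message_bytes, timings = unlist(timings)),
            class = "eos_pipeline_report")
}

#' @export
print.eos_pipeline_report <- function(x, ...) {
  cat("EOS pipeline report\n")
  cat("  reads:", x$n_reads, " extracted:", x$n_extracted, "\n")
  if (!is.null(x$metrics)) {
    cat(sprintf("  full-length yield: %.2f%%, stepwise: %.2f%%\n",
                100 * x$metrics$full_length_yield,
                100 * x$metrics$stepwise_yield))
  }
  cat("  consensus (", x$consensus$method, "): ",
      substr(x$consensus$consensus, 1L, 60L), "\n", sep = "")
  if (!is.null(x$message)) {
    cat("  decoded bytes:", length(x$message), "\n")
  }
  invisible(x)
}
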