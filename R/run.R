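# End-to-end orchestration: parameters, the detect pipeline over FASTQ
# files or in-memory read sets, the simulate entry point, and result
# writers. Paired-end mates are treated as independent read streams.

#' Detection run parameters
#'
#' @param k k-mer length (default 12, the working value for FLT3 exons
#'   14-15; must be >= 4).
#' @param delta Number of consecutive consistent trace positions required
#'   on each side of a break (default 2; equivalent to calling with
#'   (k+delta)-mers).
#' @param min_kmer_fraction Bloom-filter screening threshold: minimum
#'   fraction of a read's k-mers found in the reference set (default 0.30).
#' @param bloom_fp_rate Target Bloom-filter false-positive rate.
#' @param reporting_threshold Minimum VAF for the summary view (default
#'   0.01, the conventional clinical cut-off).
#' @param keep_deletions Keep deletion groups in the summary view?
#' @return A `run_params` object.
#' @export
run_params <- function(k = 12L, delta = 2L, min_kmer_fraction = 0.3,
                       bloom_fp_rate = 0.01, reporting_threshold = 0.01,
                       keep_deletions = FALSE) {
  k <- as.integer(k); delta <- as.integer(delta)
  if (is.na(k) || k < 4L) stop("'k' must be at least 4")
  if (is.na(delta) || delta < 0L) stop("'delta' must be >= 0")
  for (nm in c("min_kmer_fraction", "bloom_fp_rate",
               "reporting_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop("'", nm, "' must be a single value in [0, 1]")
  }
  structure(list(k = k, delta = delta,
                 min_kmer_fraction = min_kmer_fraction,
                 bloom_fp_rate = bloom_fp_rate,
                 reporting_threshold = reporting_threshold,
                 keep_deletions = isTRUE(keep_deletions)),
            class = "run_params")
}

read_fastq_seqs <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(set))
  data.frame(read_id = ids, seq = as.character(set),
             stringsAsFactors = FALSE)
}

#' Detect and quantify duplications in a read set
#'
#' Runs the full pipeline: index the reference, screen every read against
#' the Bloom filter (in both orientations), trace the kept reads,
#' disambiguate, correct substitutions, find/merge/validate breaks, call
#' events, accumulate coverage and report pooled groups with corrected
#' counts, VAF and AR.
#'
#' @param reference The reference sequence: a path to a single-record
#'   FASTA file, or the raw nucleotide string itself.
#' @param reads The reads: a character vector of FASTQ paths (plain or
#'   gzip; several files — e.g. the two mates of a paired-end run — are
#'   processed as one stream), or a data frame with columns `read_id` and
#'   `seq` such as the `reads` element of [generate_reads()].
#' @param params A [run_params()].
#' @param out_prefix If non-NULL, results are written to
#'   `<prefix>.json` and `<prefix>.tsv` (see [write_results()]).
#' @return An `itd_result`: list with `summary` and `full` group tables,
#'   `events` (per-read calls), `coverage` (`total` and `wildtype`
#'   vectors over k-mer start positions), and `stats` (read accounting).
#' @export
run_detect <- function(reference, reads, params = run_params(),
                       out_prefix = NULL) {
  stopifnot(inherits(params, "run_params"))
  if (length(reference) == 1L && file.exists(reference) &&
      !grepl("^[ACGTacgt]+$", reference)) {
    reference <- read_reference_fasta(reference)
  }
  index <- kmer_index(reference, k = params$k,
                      bloom_fp_rate = params$bloom_fp_rate)

  if (is.character(reads)) {
    missing <- reads[!file.exists(reads)]
    if (length(missing))
      stop("read file not found: ", paste(missing, collapse = ", "))
    reads <- do.call(rbind, lapply(reads, read_fastq_seqs))
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))

  n_pos <- index$n_kmers
  cov <- new_coverage_profile(n_pos)
  events_list <- list()
  n_total <- nrow(reads)
  n_kept <- 0L
  len_sum <- 0

  for (i in seq_len(n_total)) {
    s <- toupper(reads$seq[i])
    vals <- seq_to_vals(s)
    sc <- screen_vals(vals, index, params$min_kmer_fraction)
    if (!sc$keep) next
    if (sc$orientation == "reverse-complement") s <- revcomp(s)
    n_kept <- n_kept + 1L
    len_sum <- len_sum + nchar(s)
    pr <- process_read(s, index, params, read_id = reads$read_id[i])
    ev <- pr$events
    gk <- NULL
    if (nrow(ev)) {
      events_list[[length(events_list) + 1L]] <- ev
      gk <- event_group_key(ev)[which.max(ev$size)]
    }
    cov <- add_trace_coverage(cov, pr$trace, gk)
  }

  events <- if (length(events_list)) do.call(rbind, events_list)
            else empty_events()
  mean_len <- if (n_kept > 0L) len_sum / n_kept else NA_real_
  groups <- quantify_events(events, cov, params, mean_len)
  rep <- report_events(groups, params$reporting_threshold,
                       params$keep_deletions)
  result <- structure(list(
    summary = rep$summary,
    full = rep$full,
    events = events,
    coverage = list(total = cov$total,
                    wildtype = pmax(wildtype_coverage(cov), 0)),
    stats = list(n_reads = n_total, n_kept = n_kept,
                 n_discarded = n_total - n_kept,
                 mean_read_length = mean_len,
                 mean_coverage = mean(cov$total)),
    params = params
  ), class = "itd_result")
  if (!is.null(out_prefix)) write_results(result, out_prefix)
  result
}

#' @export
print.itd_result <- function(x, ...) {
  cat("ITD detection result\n")
  cat("  reads: ", x$stats$n_reads, " total, ", x$stats$n_kept,
      " kept (mean length ",
      if (is.na(x$stats$mean_read_length)) "NA"
      else round(x$stats$mean_read_length, 1), " nt)\n", sep = "")
  cat("  mean coverage over k-mer starts: ",
      round(x$stats$mean_coverage, 1), "\n", sep = "")
  if (nrow(x$summary)) {
    cat("  events at VAF >= ", x$params$reporting_threshold, ":\n", sep = "")
    print(x$summary[, c("kind", "size", "ref_start", "ref_end", "q",
                        "q_prime", "vaf", "ar")], digits = 4)
  } else {
    cat("  no events at VAF >= ", x$params$reporting_threshold, "\n",
        sep = "")
  }
  invisible(x)
}

#' Write detection results to JSON and TSV
#'
#' The JSON file holds everything (full group table, per-read events, run
#' statistics, parameters), with 0-based half-open coordinates. The TSV is
#' the thresholded summary; with `coords = "1based"` its `ref_start`/
#' `ref_end` columns become 1-based inclusive for human consumption.
#'
#' @param result An `itd_result` from [run_detect()].
#' @param out_prefix Output path prefix.
#' @param coords `"0based"` (default) or `"1based"` for the TSV.
#' @return The two paths, invisibly.
#' @export
write_results <- function(result, out_prefix, coords = c("0based", "1based")) {
  coords <- match.arg(coords)
  json_path <- paste0(out_prefix, ".json")
  tsv_path <- paste0(out_prefix, ".tsv")
  payload <- list(
    groups = result$full,
    events = result$events,
    stats = result$stats,
    params = unclass(result$params),
    coordinates = "0-based, half-open"
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  tab <- result$summary
  if (coords == "1based" && nrow(tab)) {
    tab$ref_start <- tab$ref_start + 1L   # 1-based inclusive start
  }
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}

#' Simulate a read set and write it to disk
#'
#' Wraps [generate_reference()] and [generate_reads()]: writes
#' `<prefix>.fastq` (reads), `<prefix>_truth.tsv` (per-read truth table)
#' and `<prefix>_config.json` (an echo of the configuration, plus the
#' reference sequence used).
#'
#' @param config A [sim_config()].
#' @param out_prefix Output path prefix.
#' @param reference Optional reference string; generated from the config
#'   seed when omitted.
#' @param gzip Compress the FASTQ?
#' @return The simulation object from [generate_reads()], invisibly, with
#'   a `paths` element added.
#' @export
run_simulate <- function(config, out_prefix, reference = NULL,
                         gzip = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(reference))
    reference <- generate_reference(config$reference_length, config$seed)
  sim <- generate_reads(config, reference)
  fq <- paste0(out_prefix, if (gzip) ".fastq.gz" else ".fastq")
  write_fastq(sim$reads, fq)
  truth_path <- paste0(out_prefix, "_truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg_path <- paste0(out_prefix, "_config.json")
  jsonlite::write_json(c(unclass(config), list(reference = reference)),
                       cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  sim$paths <- c(fastq = fq, truth = truth_path, config = cfg_path)
  invisible(sim)
}
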