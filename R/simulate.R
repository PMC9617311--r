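# Deterministic simulator of duplication-bearing read sets. One mutant
# haplotype per duplication spec is built by tandem-duplicating a reference
# interval; reads are drawn with uniform start positions from the mutant
# and wild-type haplotypes in proportions matching the target VAFs, with
# i.i.d. substitution errors and an optional reverse-complemented fraction.
# Start positions are uniform so that the read-edge detectability model the
# quantification correction assumes is actually exercised. Quality strings
# are constant, as the detector ignores qualities.

#' Simulation configuration
#'
#' @param reference_length Reference length in nucleotides (>= 50).
#' @param duplications List of duplication specs, each a list with 0-based
#'   `start`, `length` (nt) and `vaf` (target variant allele frequency in
#'   (0, 1]; the VAFs may sum to at most 1, the remainder being wild type).
#'   May be empty for a pure wild-type read set.
#' @param read_length Read length R (default 120 nt, matching common
#'   2 x 121 bp capture protocols after trimming).
#' @param n_reads Number of reads to draw.
#' @param error_rate Per-base substitution error probability.
#' @param revcomp_fraction Fraction of reads emitted as reverse
#'   complements (default 0.5: both strands are sequenced).
#' @param seed Integer seed; the whole read set is reproducible from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(reference_length = 300L, duplications = list(),
                       read_length = 120L, n_reads = 5000L,
                       error_rate = 0, revcomp_fraction = 0.5,
                       seed = 1L) {
  stopifnot(reference_length >= 50L, read_length >= 1L, n_reads >= 0L,
            error_rate >= 0, error_rate < 1,
            revcomp_fraction >= 0, revcomp_fraction <= 1)
  if (length(duplications)) {
    for (d in duplications) {
      if (!all(c("start", "length", "vaf") %in% names(d)))
        stop("each duplication spec needs 'start', 'length' and 'vaf'")
      if (d$vaf <= 0 || d$vaf > 1)
        stop("duplication vaf must be in (0, 1], got ", d$vaf)
      if (d$start < 0 || d$length < 1 ||
          d$start + d$length > reference_length)
        stop("duplication interval [", d$start, ", ", d$start + d$length,
             ") outside reference of length ", reference_length)
    }
    if (sum(vapply(duplications, `[[`, numeric(1), "vaf")) > 1)
      stop("duplication VAFs sum to more than 1")
  }
  structure(list(reference_length = as.integer(reference_length),
                 duplications = duplications,
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads),
                 error_rate = error_rate,
                 revcomp_fraction = revcomp_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random reference sequence
#'
#' Uniform i.i.d. ACGT string, reproducible from the seed.
#'
#' @param length Sequence length (>= 50).
#' @param seed Integer seed.
#' @return A nucleotide string.
#' @export
generate_reference <- function(length, seed = 1L) {
  stopifnot(length >= 50L)
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
        collapse = "")
}

# tandem-duplicate reference[start, start+len) (0-based, half-open)
apply_duplication <- function(reference, start, len) {
  paste0(substr(reference, 1L, start + len),
         substr(reference, start + 1L, nchar(reference)))
}

#' Simulate a read set carrying tandem duplications
#'
#' @param config A [sim_config()].
#' @param reference The reference string (e.g. from
#'   [generate_reference()]); every haplotype must be at least one read
#'   long.
#' @return A list with `reads` (data frame: `read_id`, `seq`, `qual`),
#'   `truth` (data frame: per read the source haplotype, 0-based start on
#'   that haplotype, strand, error count, and whether the read covers its
#'   haplotype's junction), `haplotypes` (named character vector) and
#'   `junctions` (data frame: per duplication its haplotype name, size,
#'   0-based `ref_start`/`ref_end` of the duplicated interval and the
#'   junction offset on the mutant haplotype).
#' @export
generate_reads <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  reference <- toupper(reference)
  if (nchar(reference) != config$reference_length)
    stop("reference length does not match the configuration")
  set.seed(config$seed)
  R <- config$read_length

  haps <- c(wildtype = reference)
  probs <- 1
  junctions <- data.frame(haplotype = character(0), size = integer(0),
                          ref_start = integer(0), ref_end = integer(0),
                          junction = integer(0), vaf = numeric(0),
                          stringsAsFactors = FALSE)
  for (i in seq_along(config$duplications)) {
    d <- config$duplications[[i]]
    nm <- paste0("dup", i)
    haps[[nm]] <- apply_duplication(reference, d$start, d$length)
    probs <- c(probs, d$vaf)
    probs[1L] <- probs[1L] - d$vaf
    junctions <- rbind(junctions, data.frame(
      haplotype = nm, size = as.integer(d$length),
      ref_start = as.integer(d$start),
      ref_end = as.integer(d$start + d$length),
      junction = as.integer(d$start + d$length), vaf = d$vaf,
      stringsAsFactors = FALSE))
  }
  if (any(nchar(haps) < R))
    stop("read length ", R, " exceeds a haplotype length")

  n <- config$n_reads
  hap_idx <- sample.int(length(haps), n, replace = TRUE, prob = probs)
  starts <- integer(n)
  seqs <- character(n)
  n_err <- integer(n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    hap <- haps[[hap_idx[i]]]
    s <- sample.int(nchar(hap) - R + 1L, 1L) - 1L
    starts[i] <- s
    read <- substr(hap, s + 1L, s + R)
    if (config$error_rate > 0) {
      hit <- which(stats::runif(R) < config$error_rate)
      if (length(hit)) {
        ch <- strsplit(read, "", fixed = TRUE)[[1L]]
        for (p in hit)
          ch[p] <- sample(setdiff(bases, ch[p]), 1L)
        read <- paste(ch, collapse = "")
      }
      n_err[i] <- length(hit)
    }
    seqs[i] <- read
  }
  rc <- stats::runif(n) < config$revcomp_fraction
  seqs[rc] <- vapply(seqs[rc], revcomp, character(1), USE.NAMES = FALSE)

  hap_names <- names(haps)[hap_idx]
  junc <- junctions$junction[match(hap_names, junctions$haplotype)]
  covers <- !is.na(junc) & starts <= junc - 1L & starts + R >= junc + 1L
  ids <- sprintf("read_%06d", seq_len(n))
  list(
    reads = data.frame(read_id = ids, seq = seqs,
                       qual = strrep("I", R), stringsAsFactors = FALSE),
    truth = data.frame(read_id = ids, haplotype = hap_names,
                       start = starts,
                       strand = ifelse(rc, "-", "+"),
                       n_errors = n_err,
                       covers_junction = covers,
                       stringsAsFactors = FALSE),
    haplotypes = haps,
    junctions = junctions,
    config = config
  )
}

#' Write simulated reads to a FASTQ file
#'
#' @param reads The `reads` data frame from [generate_reads()].
#' @param path Output path; a `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$read_id
  qs <- Biostrings::QualityScaledDNAStringSet(
    seqs, Biostrings::PhredQuality(reads$qual))
  Biostrings::writeQualityScaledXStringSet(
    qs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}
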