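#' Index the k-mers of a reference sequence with their positions
#'
#' Builds the two structures the detector works from: an exact hash table
#' mapping every k-mer of the reference to the ordered list of its 0-based
#' start positions (repeated k-mers keep all their positions, so no
#' information is lost), and a Bloom filter over the same k-mer set used to
#' screen off-target reads cheaply.
#'
#' All coordinates in the package are 0-based with half-open intervals.
#'
#' @param reference A single nucleotide string over ACGT (case-insensitive).
#'   The reference is curated input: any other character is an error, as is
#'   a reference shorter than `k`.
#' @param k k-mer length (default 12; must be between 2 and 26 — very
#'   small values are only useful for didactic examples, and the run-level
#'   parameters enforce k >= 4).
#' @param bloom_fp_rate Target false-positive rate of the Bloom filter.
#' @return An object of class `kmer_index`.
#' @examples
#' idx <- kmer_index("CAGCAGT", k = 4)
#' query_positions(idx, "CAGC")
#' @export
kmer_index <- function(reference, k = 12L, bloom_fp_rate = 0.01) {
  stopifnot(is.character(reference), length(reference) == 1L)
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > 26L)
    stop("'k' must be an integer between 2 and 26")
  if (bloom_fp_rate <= 0 || bloom_fp_rate >= 1)
    stop("'bloom_fp_rate' must be in (0, 1)")
  reference <- toupper(reference)
  len <- nchar(reference)
  if (len < k)
    stop("reference (", len, " nt) is shorter than k = ", k)
  vals <- seq_to_vals(reference)
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop("reference contains a non-ACGT character ('",
         substr(reference, bad, bad), "') at position ", bad - 1L,
         " (0-based)")
  }
  codes <- vals_to_codes(vals, k)
  keys <- code_key(codes)
  pos_map <- split(0:(len - k), keys)
  env <- list2env(pos_map, hash = TRUE, size = max(29L, length(pos_map)))
  structure(list(
    reference = reference,
    k = k,
    length = len,
    n_kmers = len - k + 1L,
    positions = env,
    bloom = bloom_new(codes, bloom_fp_rate),
    bloom_fp_rate = bloom_fp_rate
  ), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("k-mer position index\n")
  cat("  reference: ", x$length, " nt, k = ", x$k, "\n", sep = "")
  cat("  k-mers:    ", x$n_kmers, " (", length(ls(x$positions)),
      " distinct)\n", sep = "")
  cat("  Bloom:     ", x$bloom$m, " bits, ", x$bloom$h,
      " hash functions, target fp ", x$bloom_fp_rate, "\n", sep = "")
  invisible(x)
}

#' Exact reference positions of a k-mer
#'
#' Looks the k-mer up in the hash table (never the Bloom filter — traces
#' require exact answers) and returns every 0-based start position at which
#' it occurs in the reference, in ascending order.
#'
#' @param index A [kmer_index()].
#' @param kmer A single string of length `k`.
#' @return Integer vector of 0-based positions; empty if the k-mer does not
#'   occur (including k-mers with non-ACGT characters).
#' @export
query_positions <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  if (!is.character(kmer) || length(kmer) != 1L || nchar(kmer) != index$k)
    stop("'kmer' must be a single string of length k = ", index$k)
  code <- vals_to_code1(seq_to_vals(toupper(kmer)))
  if (is.na(code)) return(integer(0))
  get0(code_key(code), envir = index$positions, ifnotfound = integer(0))
}

# internal fast path: position list for a precomputed code
positions_of_code <- function(index, code) {
  if (is.na(code)) return(integer(0))
  get0(code_key(code), envir = index$positions, ifnotfound = integer(0))
}

#' Bloom-filter membership of k-mers
#'
#' Probabilistic membership against the reference k-mer set: always `TRUE`
#' for an indexed k-mer (Bloom filters yield no false negatives), `TRUE`
#' for a non-indexed k-mer only with probability around the configured
#' false-positive rate.
#'
#' @param index A [kmer_index()].
#' @param kmers Character vector of k-mers (each of length `k`).
#' @return Logical vector, one element per k-mer.
#' @export
bloom_contains <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"), is.character(kmers))
  if (length(kmers) && any(nchar(kmers) != index$k))
    stop("all queries must have length k = ", index$k)
  codes <- vapply(kmers,
                  function(s) vals_to_code1(seq_to_vals(toupper(s))),
                  numeric(1), USE.NAMES = FALSE)
  bloom_query(index$bloom, codes)
}

#' Read the reference sequence from a FASTA file
#'
#' The detector targets one short region (for FLT3-ITD work, the genomic
#' sequence of FLT3 exons 14-15), so the FASTA must hold exactly one
#' record.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @return The uppercased reference sequence as a single string.
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(set) != 1L)
    stop("reference FASTA must contain exactly one record, found ",
         length(set))
  toupper(as.character(set[[1L]]))
}
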