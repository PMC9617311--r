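# 2-bit nucleotide encoding shared by the index, the Bloom filter and the
# trace machinery. A k-mer is packed into a single double (exact up to
# k = 26, since 4^26 == 2^52 < 2^53); any window touching a non-ACGT byte
# encodes as NA.

.base_vals <- local({
  v <- rep(NA_real_, 256)
  v[utf8ToInt("A") + 1L] <- 0
  v[utf8ToInt("C") + 1L] <- 1
  v[utf8ToInt("G") + 1L] <- 2
  v[utf8ToInt("T") + 1L] <- 3
  v[utf8ToInt("a") + 1L] <- 0
  v[utf8ToInt("c") + 1L] <- 1
  v[utf8ToInt("g") + 1L] <- 2
  v[utf8ToInt("t") + 1L] <- 3
  v
})

# one value in 0..3 per base, NA for anything outside ACGT (case-insensitive)
seq_to_vals <- function(seq) {
  .base_vals[utf8ToInt(seq) + 1L]
}

# codes of all k-mer windows, in read order; NA where the window holds an NA
vals_to_codes <- function(vals, k) {
  n <- length(vals)
  if (n < k) return(numeric(0))
  if (k == 1L) return(vals)
  drop(stats::embed(vals, k) %*% 4^(0:(k - 1L)))
}

# code of one k-mer already split into values; NA-safe
vals_to_code1 <- function(vals) {
  if (anyNA(vals)) return(NA_real_)
  sum(vals * 4^((length(vals) - 1L):0))
}

# doubles such as 4^25 print in scientific notation under as.character();
# keys must round-trip exactly, hence the explicit format
code_key <- function(codes) {
  sprintf("%.0f", codes)
}

#' Reverse complement of a nucleotide string
#'
#' Bases outside ACGT (e.g. `N`) are kept as-is and only reversed.
#'
#' @param seq A single nucleotide string.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(seq) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCATGCA", seq))))
}

# complement-and-reverse on the 0..3 value scale; NA (non-ACGT) propagates
rc_vals <- function(vals) {
  rev(3 - vals)
}
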