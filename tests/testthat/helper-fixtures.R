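# Shared fixtures and independent oracles. The didactic fixture uses k = 3
# on a 10 nt reference with the AGAT segment tandem-duplicated in the read;
# its trace is 3 4 5 - - 4 5 6 7 with break (3, 4) and duplication length 4.

fig_ref <- "GGTCAGATCA"
fig_read <- "CAGATAGATCA"

# brute-force substring scan: all 0-based occurrences of kmer in ref
naive_positions <- function(ref, kmer) {
  k <- nchar(kmer)
  n <- nchar(ref) - k + 1L
  if (n < 1L) return(integer(0))
  hits <- vapply(seq_len(n), function(i) substr(ref, i, i + k - 1L) == kmer,
                 logical(1))
  which(hits) - 1L
}

# independent trace oracle: naive scan per read k-mer
naive_trace <- function(ref, read, k) {
  n <- nchar(read) - k + 1L
  lapply(seq_len(n), function(i)
    naive_positions(ref, substr(read, i, i + k - 1L)))
}

# run-length oracle for maximal absent runs, written as a plain scan
scan_breaks <- function(absent) {
  j1 <- integer(0); j2 <- integer(0)
  inside <- FALSE
  for (i in seq_along(absent)) {
    if (absent[i] && !inside) { j1 <- c(j1, i - 1L); inside <- TRUE }
    if (!absent[i] && inside) { j2 <- c(j2, i - 2L); inside <- FALSE }
  }
  if (inside) j2 <- c(j2, length(absent) - 1L)
  data.frame(j1 = j1, j2 = j2)
}

# tandem-duplicate ref[start, start+len), 0-based half-open
tandem_dup <- function(ref, start, len) {
  paste0(substr(ref, 1L, start + len), substr(ref, start + 1L, nchar(ref)))
}

# smallest start >= from whose duplication junction is "clean": no k-mer
# spanning the junction occurs in the reference (no junction overlap)
pick_clean_dup_start <- function(ref, len, k, from = 50L) {
  for (s in from:(nchar(ref) - len - 1L)) {
    mut <- tandem_dup(ref, s, len)
    junction <- s + len
    clean <- TRUE
    for (j in (junction - k + 1L):(junction - 1L)) {
      kmer <- substr(mut, j + 1L, j + k)
      if (length(naive_positions(ref, kmer))) { clean <- FALSE; break }
    }
    if (clean) return(s)
  }
  stop("no clean duplication start found")
}

# 0-based window of a haplotype
hap_read <- function(hap, start, len) substr(hap, start + 1L, start + len)

substitute_base <- function(seq, pos0, base) {
  substr(seq, pos0 + 1L, pos0 + 1L) <- base
  seq
}

other_base <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
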