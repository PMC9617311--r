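# Minimal Bloom filter over packed k-mer codes. Sized from the number of
# distinct k-mers and a target false-positive rate; membership uses double
# hashing g_i(x) = h1(x) + i * h2(x) (mod m). Guarantees no false negatives.
# The reference is a few hundred nucleotides, so the filter is kilobytes at
# most even with generous sizing.

.bloom_prime <- 2147483647  # 2^31 - 1, Mersenne prime

bloom_new <- function(codes, fp_rate = 0.01) {
  codes <- unique(codes[!is.na(codes)])
  n <- max(1L, length(codes))
  m <- max(64L, as.integer(ceiling(-n * log(fp_rate) / log(2)^2)))
  h <- max(1L, as.integer(round(m / n * log(2))))
  bf <- list(bits = logical(m), m = m, h = h, n_inserted = length(codes),
             fp_rate = fp_rate)
  if (length(codes)) {
    idx <- .bloom_indices(codes, m, h)
    bf$bits[unique(idx)] <- TRUE
  }
  bf
}

# all h probe positions (1-based) for a vector of codes
.bloom_indices <- function(codes, m, h) {
  c0 <- codes %% .bloom_prime
  g1 <- (69069 * c0 + 12345) %% .bloom_prime
  g2 <- ((40503 * c0 + 69621) %% .bloom_prime) %% (m - 1) + 1
  unlist(lapply(0:(h - 1L), function(i) ((g1 + i * g2) %% m) + 1L),
         use.names = FALSE)
}

# vectorised membership; NA codes (windows with non-ACGT bases) are misses
bloom_query <- function(bf, codes) {
  ok <- !is.na(codes)
  out <- logical(length(codes))
  if (!any(ok)) return(out)
  c0 <- codes[ok] %% .bloom_prime
  g1 <- (69069 * c0 + 12345) %% .bloom_prime
  g2 <- ((40503 * c0 + 69621) %% .bloom_prime) %% (bf$m - 1) + 1
  hit <- rep(TRUE, length(c0))
  for (i in 0:(bf$h - 1L)) {
    hit <- hit & bf$bits[((g1 + i * g2) %% bf$m) + 1L]
    if (!any(hit)) break
  }
  out[ok] <- hit
  out
}
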