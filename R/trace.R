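# The trace is the algorithm's central object: for a read R and reference T,
# entry i of the trace lists the reference positions at which the k-mer
# R[i .. i+k-1] occurs. A raw trace holds one integer vector per entry
# (possibly empty); after disambiguation each entry is a single position or
# NA. A break is a maximal run of NA entries; every read/reference
# difference shows up as a break, and duplications additionally make the
# positions "go back" across it.

new_trace <- function(entries, k, read_seq = NA_character_,
                      read_id = NA_character_, state = "raw",
                      orientation = "forward") {
  structure(list(read_id = read_id, read_seq = read_seq, k = k,
                 entries = entries, state = state,
                 orientation = orientation),
            class = "kmer_trace")
}

#' @export
print.kmer_trace <- function(x, ...) {
  cat("k-mer trace (", x$state, ") for read ", x$read_id,
      ", k = ", x$k, "\n", sep = "")
  if (x$state == "raw") {
    shown <- vapply(x$entries, function(e)
      if (length(e)) paste(e, collapse = "/") else "-", character(1))
  } else {
    shown <- ifelse(is.na(x$entries), "-", as.character(x$entries))
  }
  cat(" ", paste(shown, collapse = " "), "\n")
  invisible(x)
}

#' Construct a disambiguated trace from known positions
#'
#' Convenience constructor used to study the break/size calculus directly:
#' `positions` is the full entry list of an already-disambiguated trace,
#' with `NA` marking k-mers absent from the reference.
#'
#' @param positions Integer vector (NA = absent entry), one per k-mer start.
#' @param k k-mer length the entries refer to.
#' @param read_id Optional identifier.
#' @return A disambiguated trace usable with [find_breaks()],
#'   [is_duplication_break()], [validate_break()] and [call_event()].
#' @examples
#' tr <- trace_from_positions(c(3, 4, 5, NA, NA, 4, 5, 6, 7), k = 3)
#' find_breaks(tr)
#' @export
trace_from_positions <- function(positions, k, read_id = "manual") {
  new_trace(as.integer(positions), as.integer(k), read_id = read_id,
            state = "disambiguated")
}

#' Screen a read against the reference k-mer set
#'
#' Computes, for the read as given and for its reverse complement, the
#' fraction of its k-mers found in the Bloom filter, and keeps the read in
#' the better orientation when that fraction reaches `min_fraction`
#' (default 30%). k-mers containing non-ACGT characters count as absent.
#' Screening never aborts a run: reads shorter than k are simply dropped.
#'
#' @param read_seq A single nucleotide string.
#' @param index A [kmer_index()].
#' @param min_fraction Minimum k-mer fraction to keep the read.
#' @return A list with elements `keep` (logical), `orientation`
#'   (`"forward"` or `"reverse-complement"`, ties go to forward) and
#'   `fraction` (the winning fraction).
#' @export
screen_read <- function(read_seq, index, min_fraction = 0.3) {
  vals <- seq_to_vals(toupper(read_seq))
  screen_vals(vals, index, min_fraction)
}

# internal: screening on precomputed base values
screen_vals <- function(vals, index, min_fraction) {
  k <- index$k
  if (length(vals) < k)
    return(list(keep = FALSE, orientation = "forward", fraction = 0))
  f_fwd <- mean(bloom_query(index$bloom, vals_to_codes(vals, k)))
  f_rev <- mean(bloom_query(index$bloom, vals_to_codes(rc_vals(vals), k)))
  if (f_fwd >= f_rev) {
    list(keep = f_fwd >= min_fraction, orientation = "forward",
         fraction = f_fwd)
  } else {
    list(keep = f_rev >= min_fraction, orientation = "reverse-complement",
         fraction = f_rev)
  }
}

#' Compute the raw k-mer position trace of a read
#'
#' Looks every k-mer of the read up in the exact hash table (the Bloom
#' filter plays no part here) and records all its reference positions.
#'
#' @param read_seq A single nucleotide string, already in the orientation
#'   chosen by [screen_read()].
#' @param index A [kmer_index()].
#' @param read_id Optional identifier carried through to called events.
#' @return A raw-state trace with `nchar(read_seq) - k + 1` entries.
#' @export
compute_trace <- function(read_seq, index, read_id = NA_character_) {
  read_seq <- toupper(read_seq)
  vals <- seq_to_vals(read_seq)
  k <- index$k
  if (length(vals) < k)
    stop("read (", length(vals), " nt) is shorter than k = ", k)
  keys <- code_key(vals_to_codes(vals, k))
  entries <- unname(mget(keys, envir = index$positions,
                         ifnotfound = list(integer(0))))
  new_trace(entries, k, read_seq = read_seq, read_id = read_id)
}

#' Resolve multi-position trace entries to a single position
#'
#' Short k-mers can occur at several reference positions; at most one is
#' the true origin. Entries are resolved left to right. Rule 1: when the
#' previous entry is resolved and its value + 1 is among the candidates,
#' that candidate is kept (so runs of consecutive positions chain through
#' repeats). Rule 2: otherwise the candidate minimising the summed absolute
#' distance to the neighbouring positions is kept, where the neighbours are
#' the nearest present entries on each side and a break may only be crossed
#' when the entry sits immediately next to it. Remaining ties, and entries
#' with no usable neighbour, resolve to the smallest position so output is
#' deterministic.
#'
#' @param trace A raw-state trace from [compute_trace()].
#' @return The trace in disambiguated state: one integer (or NA) per entry.
#' @export
disambiguate <- function(trace) {
  stopifnot(inherits(trace, "kmer_trace"))
  if (trace$state != "raw") stop("trace is already disambiguated")
  entries <- trace$entries
  n <- length(entries)
  lens <- lengths(entries)
  present <- lens > 0L
  res <- rep(NA_integer_, n)
  single <- lens == 1L
  res[single] <- unlist(entries[single], use.names = FALSE)

  neighbour_values <- function(j) {
    if (!is.na(res[j])) res[j] else entries[[j]]
  }
  # nearest present entry on one side; crossing at most the one adjacent break
  find_neighbour <- function(i, step) {
    j <- i + step
    if (j < 1L || j > n) return(NA_integer_)
    if (present[j]) return(j)
    # i sits immediately next to a break: allowed to cross it, once
    while (j >= 1L && j <= n && !present[j]) j <- j + step
    if (j >= 1L && j <= n && present[j]) j else NA_integer_
  }

  for (i in which(lens > 1L)) {
    cands <- entries[[i]]
    if (i > 1L && !is.na(res[i - 1L]) && (res[i - 1L] + 1L) %in% cands) {
      res[i] <- res[i - 1L] + 1L
      next
    }
    nb <- c(find_neighbour(i, -1L), find_neighbour(i, 1L))
    nb <- nb[!is.na(nb)]
    if (!length(nb)) {
      res[i] <- min(cands)
      next
    }
    score <- vapply(cands, function(cand) {
      sum(vapply(nb, function(j) min(abs(cand - neighbour_values(j))),
                 numeric(1)))
    }, numeric(1))
    res[i] <- min(cands[score == min(score)])
  }
  trace$entries <- res
  trace$state <- "disambiguated"
  trace
}

#' Find the breaks of a trace
#'
#' A break is a maximal run of absent entries, identified by the indices of
#' its first and last absent entry (0-based, inclusive). Runs touching the
#' trace ends are included.
#'
#' @param trace A disambiguated trace.
#' @return A data frame with columns `j1` and `j2`, one row per break,
#'   sorted by `j1`.
#' @export
find_breaks <- function(trace) {
  stopifnot(inherits(trace, "kmer_trace"))
  if (trace$state != "disambiguated")
    stop("find_breaks() needs a disambiguated trace")
  absent <- is.na(trace$entries)
  if (!any(absent))
    return(data.frame(j1 = integer(0), j2 = integer(0)))
  r <- rle(absent)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(j1 = starts[r$values] - 1L, j2 = ends[r$values] - 1L)
}

#' Correct substitution-induced breaks in a trace
#'
#' A single substitution (mutation or sequencing error) at read position
#' j1 + k - 1 makes the k k-mers containing it absent, opening a break at
#' j1. For each break with a resolved left flank, the k-mer starting at j1
#' is re-tested with the three alternative bases at its last position; if
#' one of them occurs in the reference immediately after the left-flank
#' position, the read base is tentatively rewritten and the correction
#' walks on to the next k-mers of the break by plain lookup, requiring
#' consecutive positions. The edit is committed only when it explains the
#' whole break this way — exactly what one isolated substitution does, its
#' break spanning at most k entries that all contain the mis-called base.
#' When the walk stalls the correction "did not work" and everything is
#' reverted, leaving the break untouched. This all-or-nothing rule is what
#' keeps tandem duplications alive: a junction k-mer also differs from the
#' reference continuation at its last base only, so a greedy per-k-mer
#' edit chain would rewrite a duplication junction base by base and erase
#' the event. Breaks must be re-derived from the returned trace with
#' [find_breaks()].
#'
#' @param trace A disambiguated trace.
#' @param index The [kmer_index()] the trace was computed against.
#' @return The trace with corrected entries and (possibly) corrected
#'   `read_seq`.
#' @export
correct_substitutions <- function(trace, index) {
  stopifnot(inherits(trace, "kmer_trace"), inherits(index, "kmer_index"))
  if (trace$state != "disambiguated")
    stop("correct_substitutions() needs a disambiguated trace")
  if (is.na(trace$read_seq))
    stop("trace carries no read sequence; cannot correct")
  k <- index$k
  last_pos <- index$length - k  # largest valid k-mer start in the reference
  res <- trace$entries
  vals <- seq_to_vals(trace$read_seq)
  pw <- 4^((k - 1L):0)
  brks <- find_breaks(trace)
  for (b in seq_len(nrow(brks))) {
    j1 <- brks$j1[b]; j2 <- brks$j2[b]
    if (j1 == 0L) next                    # no left flank to anchor on
    if (j2 - j1 + 1L > k) next            # more than one substitution's worth
    prev <- res[j1]                       # entry j1-1 (0-based), R index j1
    if (is.na(prev)) next
    p <- prev + 1L
    if (p + (j2 - j1) > last_pos) next
    win <- vals[(j1 + 1L):(j1 + k)]
    alt <- if (is.na(win[k])) 0:3 else setdiff(0:3, win[k])
    for (base in alt) {
      w2 <- win
      w2[k] <- base
      if (anyNA(w2)) break
      if (!p %in% positions_of_code(index, sum(w2 * pw))) next
      # tentative edit: it must explain the whole break by consecutive
      # plain lookups, otherwise it is reverted
      tmp <- vals
      tmp[j1 + k] <- base
      ok <- TRUE
      for (j in seq_len(j2 - j1) + j1) {
        w <- tmp[(j + 1L):(j + k)]
        if (anyNA(w) ||
            !(p + j - j1) %in% positions_of_code(index, sum(w * pw))) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        vals <- tmp
        res[(j1 + 1L):(j2 + 1L)] <- p + 0L:(j2 - j1)
        break
      }
    }
  }
  ok <- !is.na(vals)
  chars <- strsplit(trace$read_seq, "", fixed = TRUE)[[1L]]
  chars[ok] <- c("A", "C", "G", "T")[vals[ok] + 1L]
  trace$read_seq <- paste(chars, collapse = "")
  trace$entries <- res
  trace
}
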