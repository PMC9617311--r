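# Turning validated breaks into events. For a break (j1, j2) with resolved
# flanks, the duplication/indel size is
#     d = t[j1-1] - t[j2+1] + (j2 - j1 + 2)
# where t[] are the flanking trace positions. When nothing is inserted at
# the junction and no junction k-mer happens to match the reference,
# j2 - j1 + 2 == k and the formula reduces to t[j1-1] - t[j2+1] + k; each
# inserted junction base lengthens the break by one, each junction overlap
# shortens it by one, and the general formula absorbs both. Substitutions
# within k nt of the junction lengthen the break and shift a flank by equal
# amounts, so the computed size is unchanged.

flank_values <- function(trace, j1, j2) {
  res <- trace$entries
  n <- length(res)
  lf <- if (j1 >= 1L) res[j1] else NA_integer_          # t[j1-1]
  rf <- if (j2 + 2L <= n) res[j2 + 2L] else NA_integer_ # t[j2+1]
  c(lf, rf)
}

event_size0 <- function(trace, j1, j2) {
  fl <- flank_values(trace, j1, j2)
  if (anyNA(fl)) return(NA_integer_)
  fl[1L] - fl[2L] + (j2 - j1 + 2L)
}

#' Does a break carry the duplication signature?
#'
#' A duplication makes the trace positions go back across the break:
#' with g = j2 - j1 + 1 the break size, the test is
#' t\[j1-1\] + g - 1 > t\[j2+1\].
#'
#' @param trace A disambiguated trace.
#' @param brk One-row data frame (or list) with `j1`, `j2`.
#' @return `TRUE`, `FALSE`, or `NA` when a flank is missing (break at a
#'   trace edge — uncallable, never an error).
#' @export
is_duplication_break <- function(trace, brk) {
  j1 <- brk$j1[1L]; j2 <- brk$j2[1L]
  fl <- flank_values(trace, j1, j2)
  if (anyNA(fl)) return(NA)
  g <- j2 - j1 + 1L
  fl[1L] + g - 1L > fl[2L]
}

#' Validate a break with delta consecutive flanking positions
#'
#' An event is only reported when `delta` trace entries on each side of the
#' break exist, are present, and continue the flank arithmetically:
#' t\[j1-1-i\] + i = t\[j1-1\] and t\[j2+1+i\] - i = t\[j2+1\] for
#' 1 <= i <= delta. This is equivalent to calling with (k+delta)-mers and
#' suppresses spurious matches of short k-mers. With `delta = 0` the check
#' reduces to the flanks being present.
#'
#' @param trace A disambiguated trace.
#' @param brk One-row data frame (or list) with `j1`, `j2`.
#' @param delta Number of consecutive consistent positions required
#'   (default 2).
#' @return `TRUE` or `FALSE` (also `FALSE` when fewer than `delta` entries
#'   are available on either side: the event is undetectable at this read
#'   edge, which the quantification correction accounts for).
#' @export
validate_break <- function(trace, brk, delta = 2L) {
  stopifnot(delta >= 0L)
  res <- trace$entries
  n <- length(res)
  j1 <- brk$j1[1L]; j2 <- brk$j2[1L]
  fl <- flank_values(trace, j1, j2)
  if (anyNA(fl)) return(FALSE)
  if (delta == 0L) return(TRUE)
  li <- j1 - 1L - seq_len(delta)          # 0-based entry indices, left side
  ri <- j2 + 1L + seq_len(delta)
  if (any(li < 0L) || any(ri > n - 1L)) return(FALSE)
  lv <- res[li + 1L]; rv <- res[ri + 1L]
  !anyNA(lv) && !anyNA(rv) &&
    all(lv + seq_len(delta) == fl[1L]) &&
    all(rv - seq_len(delta) == fl[2L])
}

#' Merge nearby breaks belonging to one event
#'
#' A junction base that happens to match the reference can split one
#' logical break into two, separated by one or a few stray present entries.
#' Two breaks (j1, j2) and (j1', j2') separated by fewer than delta present
#' entries (j1' <= j2 + delta) are merged into (j1, j2') whenever both
#' separate calls would be longer
#' in magnitude than the call from the merged break, applied left to right
#' until a fixpoint. Breaks whose separate or merged size cannot be
#' computed (missing flank) are left as they are.
#'
#' @param breaks Data frame of breaks from [find_breaks()], sorted by `j1`.
#' @param trace The disambiguated trace the breaks belong to.
#' @param delta Merge window (same `delta` as [validate_break()]).
#' @return A data frame of (possibly merged) breaks.
#' @export
merge_breaks <- function(breaks, trace, delta = 2L) {
  i <- 1L
  while (i < nrow(breaks)) {
    j1a <- breaks$j1[i];     j2a <- breaks$j2[i]
    j1b <- breaks$j1[i + 1L]; j2b <- breaks$j2[i + 1L]
    if (j1b <= j2a + delta) {
      s1 <- event_size0(trace, j1a, j2a)
      s2 <- event_size0(trace, j1b, j2b)
      sm <- event_size0(trace, j1a, j2b)
      if (!anyNA(c(s1, s2, sm)) &&
          abs(s1) > abs(sm) && abs(s2) > abs(sm)) {
        breaks$j2[i] <- j2b
        breaks <- breaks[-(i + 1L), , drop = FALSE]
        next                              # retry from the merged break
      }
    }
    i <- i + 1L
  }
  rownames(breaks) <- NULL
  breaks
}

#' Call the event behind a validated break
#'
#' Computes the size d = t\[j1-1\] - t\[j2+1\] + j2 - j1 + 2 and classifies
#' the break: a duplication when the positions go back (see
#' [is_duplication_break()]), otherwise an insertion for d > 0 or a
#' deletion for d < 0; d == 0 yields no event (a pure substitution
#' remnant). For a duplication the duplicated reference interval is
#' \[t\[j2+1\], t\[j1-1\] + k) — its sequence is
#' `substr(reference, ref_start + 1, ref_end)`.
#'
#' @param trace A disambiguated trace.
#' @param brk One-row data frame (or list) with `j1`, `j2`; the break is
#'   assumed validated ([validate_break()]).
#' @param k k-mer length (defaults to the trace's).
#' @return A one-row data frame (`read_id`, `kind`, `size`, `ref_start`,
#'   `ref_end`, `left_flank_pos`, `right_flank_pos`, `j1`, `j2`, `b`) or
#'   `NULL` when no event is called. `size` is the positive magnitude in
#'   nucleotides; `kind` distinguishes deletions.
#' @export
call_event <- function(trace, brk, k = trace$k) {
  j1 <- brk$j1[1L]; j2 <- brk$j2[1L]
  fl <- flank_values(trace, j1, j2)
  if (anyNA(fl)) return(NULL)
  d <- fl[1L] - fl[2L] + (j2 - j1 + 2L)
  if (d == 0L) return(NULL)
  dup <- isTRUE(is_duplication_break(trace, brk))
  if (d > 0L) {
    kind <- if (dup) "duplication" else "insertion"
    size <- d
    ref_start <- if (dup) fl[2L] else fl[1L] + k
    ref_end <- if (dup) fl[1L] + k else fl[1L] + k
  } else {
    kind <- "deletion"
    size <- -d
    ref_start <- fl[1L] + k               # first deleted base
    ref_end <- fl[2L]
  }
  data.frame(read_id = trace$read_id, kind = kind, size = size,
             ref_start = ref_start, ref_end = ref_end,
             left_flank_pos = fl[1L], right_flank_pos = fl[2L],
             j1 = j1, j2 = j2, b = j2 - j1 + 1L,
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(read_id = character(0), kind = character(0), size = integer(0),
             ref_start = integer(0), ref_end = integer(0),
             left_flank_pos = integer(0), right_flank_pos = integer(0),
             j1 = integer(0), j2 = integer(0), b = integer(0),
             stringsAsFactors = FALSE)
}

# full per-read pipeline on a kept, correctly oriented read; returns both
# the final trace (needed for coverage) and the called events
process_read <- function(read_seq, index, params = run_params(),
                         read_id = NA_character_) {
  tr <- compute_trace(read_seq, index, read_id = read_id)
  tr <- disambiguate(tr)
  tr <- correct_substitutions(tr, index)
  brks <- find_breaks(tr)
  brks <- merge_breaks(brks, tr, delta = params$delta)
  events <- empty_events()
  for (b in seq_len(nrow(brks))) {
    brk <- brks[b, ]
    if (!validate_break(tr, brk, delta = params$delta)) next
    ev <- call_event(tr, brk)
    if (!is.null(ev)) events <- rbind(events, ev)
  }
  list(trace = tr, events = events)
}

#' Call all events in one read
#'
#' Runs the complete per-read pipeline — trace, disambiguation,
#' substitution correction, break finding, merging, delta-validation,
#' calling — and returns every event the read supports. Reads may carry
#' several duplications; all validated ones are emitted.
#'
#' @param read_seq A kept read, in the orientation chosen by
#'   [screen_read()].
#' @param index A [kmer_index()].
#' @param params A [run_params()] object.
#' @param read_id Optional identifier.
#' @return A data frame of events (zero rows for a wild-type read).
#' @export
call_events_in_read <- function(read_seq, index, params = run_params(),
                                read_id = NA_character_) {
  process_read(read_seq, index, params, read_id)$events
}
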