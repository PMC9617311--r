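# Abundance estimation. Coverage follows the traces: when entry i of a
# read's trace resolves to reference position j, the coverage at j gains
# one (k-mer-start convention; VAF/AR are ratios, so the convention cancels
# as long as it is applied on both sides). Reads supporting an event
# contribute their coverage to that event's group; wild-type coverage is
# the total minus all group contributions. An event whose junction sits in
# the first or last t-1 nucleotides of a read cannot be detected, so raw
# supporting counts are corrected by the factor 1 + 2(t-1)/R under a
# uniform junction-position model.

event_group_key <- function(events) {
  paste(events$kind, events$size, events$ref_start, events$ref_end,
        sep = ":")
}

new_coverage_profile <- function(n_pos) {
  structure(list(total = numeric(n_pos), groups = list()),
            class = "coverage_profile")
}

add_trace_coverage <- function(profile, trace, group_key = NULL) {
  res <- trace$entries
  cov <- tabulate(res[!is.na(res)] + 1L, nbins = length(profile$total))
  profile$total <- profile$total + cov
  if (!is.null(group_key)) {
    if (is.null(profile$groups[[group_key]]))
      profile$groups[[group_key]] <- numeric(length(profile$total))
    profile$groups[[group_key]] <- profile$groups[[group_key]] + cov
  }
  profile
}

wildtype_coverage <- function(profile) {
  wt <- profile$total
  for (g in profile$groups) wt <- wt - g
  wt
}

#' Accumulate reference coverage from disambiguated traces
#'
#' Each present trace entry increments the coverage at the reference
#' position it resolved to. When `events` is supplied (the per-read event
#' table), the coverage of each event-supporting read is additionally
#' recorded under its event group — a read with several events is
#' attributed to its largest one — so that wild-type coverage can be
#' obtained by subtraction.
#'
#' @param traces A list of disambiguated traces (kept reads only).
#' @param index The [kmer_index()] the traces were computed against.
#' @param events Optional combined event data frame with `read_id` keys
#'   matching the traces.
#' @return A `coverage_profile`: total coverage per k-mer start position
#'   plus one coverage vector per event group.
#' @export
accumulate_coverage <- function(traces, index, events = NULL) {
  profile <- new_coverage_profile(index$n_kmers)
  key_by_read <- character(0)
  if (!is.null(events) && nrow(events)) {
    keys <- event_group_key(events)
    for (id in unique(events$read_id)) {
      rows <- which(events$read_id == id)
      key_by_read[[id]] <- keys[rows[which.max(events$size[rows])]]
    }
  }
  for (tr in traces) {
    gk <- if (!is.na(tr$read_id) && tr$read_id %in% names(key_by_read))
      key_by_read[[tr$read_id]] else NULL
    profile <- add_trace_coverage(profile, tr, gk)
  }
  profile
}

#' Minimum read span needed to detect an event
#'
#' A break of size b flanked by delta consistent positions on each side
#' needs t = 2 * delta + b + k - 1 nucleotides of the read, so events whose
#' junction falls in the first or last t - 1 nucleotides go undetected.
#'
#' @param b Break size (>= 1).
#' @param delta Validation parameter of [validate_break()].
#' @param k k-mer length.
#' @return t, in nucleotides.
#' @examples
#' min_detectable_span(b = 11, delta = 2, k = 12)  # 26, the defaults
#' @export
min_detectable_span <- function(b, delta, k) {
  stopifnot(b >= 1)
  2L * as.integer(delta) + as.integer(b) + as.integer(k) - 1L
}

#' Correct a supporting-read count for read-edge undetectability
#'
#' Under a uniform junction-position model a fraction 2(t-1)/R of the
#' event-bearing reads cannot be detected, so the corrected count is
#' q' = q * (1 + 2(t-1)/R). With mixed read lengths R is the mean length
#' of kept reads. For events whose detectable span approaches the read
#' length (2(t-1) >= R) the uniform model breaks down; the factor is then
#' capped at 3 with a warning.
#'
#' @param q Raw supporting-read count.
#' @param t Minimum detectable span from [min_detectable_span()].
#' @param read_length R, the (mean) length of kept reads.
#' @return The corrected, real-valued count q'.
#' @export
corrected_count <- function(q, t, read_length) {
  stopifnot(read_length > 0)
  factor <- 1 + 2 * (t - 1) / read_length
  if (2 * (t - 1) >= read_length) {
    warning("event detectable span (t = ", t, ") is large relative to the ",
            "read length (", read_length, "); correction capped at 3x")
    factor <- min(factor, 3)
  }
  q * factor
}

# most frequent value; ties go to the smallest
mode_int <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)][1L])
}

#' Pool events into groups and compute corrected counts, VAF and AR
#'
#' Events sharing the same kind, length and reference interval are pooled.
#' Per group: q is the number of supporting reads, b the modal break size
#' among them, t the minimum detectable span, q' the edge-corrected count,
#' and, with w the wild-type coverage at the group's `ref_start` anchor,
#' VAF = q' / (q' + w) and AR = q' / w (so AR = VAF / (1 - VAF)). A group
#' at a position with zero wild-type coverage reports VAF 1 and infinite
#' AR.
#'
#' @param events Combined event data frame across reads.
#' @param coverage A `coverage_profile` from [accumulate_coverage()] (built
#'   with the same `events`).
#' @param params A [run_params()].
#' @param mean_read_length Mean length of kept reads (R in the correction).
#' @return A data frame, one row per group, sorted by decreasing VAF:
#'   `kind`, `size`, `ref_start`, `ref_end`, `q`, `b`, `t`, `q_prime`,
#'   `wildtype_coverage`, `vaf`, `ar`.
#' @export
quantify_events <- function(events, coverage, params = run_params(),
                            mean_read_length) {
  empty <- data.frame(kind = character(0), size = integer(0),
                      ref_start = integer(0), ref_end = integer(0),
                      q = integer(0), b = integer(0), t = integer(0),
                      q_prime = numeric(0), wildtype_coverage = numeric(0),
                      vaf = numeric(0), ar = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(events) || !nrow(events)) return(empty)
  wt <- wildtype_coverage(coverage)
  keys <- event_group_key(events)
  out <- lapply(unique(keys), function(key) {
    rows <- events[keys == key, , drop = FALSE]
    q <- length(unique(rows$read_id))
    b <- mode_int(rows$b)
    t <- min_detectable_span(b, params$delta, params$k)
    qp <- corrected_count(q, t, mean_read_length)
    anchor <- rows$ref_start[1L] + 1L     # 0-based -> R index
    anchor <- min(max(anchor, 1L), length(wt))
    w <- max(wt[anchor], 0)
    data.frame(kind = rows$kind[1L], size = rows$size[1L],
               ref_start = rows$ref_start[1L], ref_end = rows$ref_end[1L],
               q = q, b = b, t = t, q_prime = qp,
               wildtype_coverage = w,
               vaf = if (qp == 0) 0 else qp / (qp + w),
               ar = if (w > 0) qp / w else Inf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$vaf, out$ref_start, out$size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute VAF and AR for one pooled group
#'
#' @param q_prime Corrected supporting count.
#' @param wildtype_cov Wild-type coverage at the group's anchor position.
#' @return A list with `vaf` and `ar`.
#' @export
compute_group_metrics <- function(q_prime, wildtype_cov) {
  if (wildtype_cov <= 0)
    return(list(vaf = if (q_prime > 0) 1 else 0,
                ar = if (q_prime > 0) Inf else 0))
  list(vaf = q_prime / (q_prime + wildtype_cov), ar = q_prime / wildtype_cov)
}

#' Split pooled groups into a thresholded summary and a full table
#'
#' The summary keeps groups at or above the reporting threshold (default
#' VAF 0.01, the conventional clinical cut-off) and drops deletions unless
#' asked otherwise — short single-nucleotide deletions are common artefacts
#' worth filtering, while the full table keeps every call auditable.
#'
#' @param groups Data frame from [quantify_events()].
#' @param reporting_threshold Minimum VAF for the summary view.
#' @param keep_deletions Keep deletion groups in the summary?
#' @return A list with `summary` and `full` data frames, both sorted by
#'   decreasing VAF.
#' @export
report_events <- function(groups, reporting_threshold = 0.01,
                          keep_deletions = FALSE) {
  keep <- groups$vaf >= reporting_threshold
  if (!keep_deletions) keep <- keep & groups$kind != "deletion"
  summary <- groups[keep, , drop = FALSE]
  rownames(summary) <- NULL
  list(summary = summary, full = groups)
}
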