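ref300 <- generate_reference(300, seed = 42)
idx300 <- kmer_index(ref300, k = 12)
p_def <- run_params()

test_that("coverage counts one increment per resolved trace entry", {
  tr <- disambiguate(compute_trace(ref300, idx300))
  cov1 <- accumulate_coverage(list(tr), idx300)
  expect_equal(cov1$total, rep(1, idx300$n_kmers))
  covn <- accumulate_coverage(rep(list(tr), 7), idx300)
  expect_equal(covn$total, rep(7, idx300$n_kmers))
})

test_that("uniform-start wild-type coverage is flat over the interior", {
  cfg <- sim_config(reference_length = 300, read_length = 120,
                    n_reads = 2000, error_rate = 0,
                    revcomp_fraction = 0, seed = 19)
  sim <- generate_reads(cfg, ref300)
  traces <- lapply(seq_len(nrow(sim$reads)), function(i)
    disambiguate(compute_trace(sim$reads$seq[i], idx300)))
  cov <- accumulate_coverage(traces, idx300)
  # k-mer start j is reachable from R - k + 1 read starts inside the
  # interior [R - k, L - R]
  interior <- (120 - 12 + 1):(300 - 120 + 1)
  expected <- 2000 * (120 - 12 + 1) / (300 - 120 + 1)
  expect_true(all(abs(cov$total[interior] - expected) <=
                    5 * sqrt(expected)))
})

test_that("the minimum detectable span follows t = 2*delta + b + k - 1", {
  expect_identical(min_detectable_span(b = 2, delta = 0, k = 3), 4L)
  # defaults: clean duplication break b = k - 1 = 11
  expect_identical(min_detectable_span(b = 11, delta = 2, k = 12), 26L)
  for (b in 1:20)
    expect_identical(min_detectable_span(b + 1, 2, 12) -
                       min_detectable_span(b, 2, 12), 1L)
})

test_that("edge correction scales counts by 1 + 2(t-1)/R", {
  expect_equal(corrected_count(100, t = 26, read_length = 121),
               100 * (1 + 50 / 121))
  expect_equal(corrected_count(57, t = 1, read_length = 120), 57)
  expect_equal(corrected_count(0, t = 26, read_length = 120), 0)
  # q'/q grows with t, shrinks with R
  expect_gt(corrected_count(10, 30, 120), corrected_count(10, 26, 120))
  expect_lt(corrected_count(10, 26, 150), corrected_count(10, 26, 120))
  # degenerate events comparable to the read length warn; the factor is
  # bounded above by 3
  expect_warning(qp <- corrected_count(10, t = 80, read_length = 120),
                 "capped")
  expect_equal(qp, 10 * (1 + 2 * 79 / 120))
  expect_warning(qp3 <- corrected_count(10, t = 200, read_length = 120),
                 "capped")
  expect_equal(qp3, 30)
})

test_that("group metrics satisfy the VAF/AR identities", {
  m <- compute_group_metrics(q_prime = 250, wildtype_cov = 250)
  expect_equal(m$vaf, 0.5)
  expect_equal(m$ar, 1)
  m0 <- compute_group_metrics(q_prime = 10, wildtype_cov = 0)
  expect_equal(m0$vaf, 1)
  expect_identical(m0$ar, Inf)
})

test_that("coverage is conserved and AR = VAF/(1-VAF) in a full run", {
  cfg <- sim_config(
    reference_length = 300,
    duplications = list(list(start = 100, length = 30, vaf = 0.3)),
    read_length = 120, n_reads = 1200, error_rate = 0,
    revcomp_fraction = 0, seed = 23)
  sim <- generate_reads(cfg, ref300)
  res <- run_detect(ref300, sim$reads, p_def)
  g <- res$summary[res$summary$kind == "duplication", ]
  expect_identical(nrow(g), 1L)
  expect_equal(g$ar, g$vaf / (1 - g$vaf))
  expect_gte(g$q_prime, g$q)
  # wildtype + event-group coverage adds back to the total everywhere
  traces <- list(); events <- list()
  for (i in seq_len(nrow(sim$reads))) {
    pr <- itdtrace:::process_read(toupper(sim$reads$seq[i]), idx300, p_def,
                                  sim$reads$read_id[i])
    traces[[i]] <- pr$trace
    if (nrow(pr$events)) events[[length(events) + 1L]] <- pr$events
  }
  events <- do.call(rbind, events)
  cov <- accumulate_coverage(traces, idx300, events)
  total_back <- itdtrace:::wildtype_coverage(cov)
  for (grp in cov$groups) total_back <- total_back + grp
  expect_equal(total_back, cov$total)
  expect_true(all(itdtrace:::wildtype_coverage(cov) >= 0))
})

test_that("reported VAF recovers the simulated mixing proportion", {
  cases <- list(list(vaf = 0.05, len = 30L), list(vaf = 0.2, len = 30L),
                list(vaf = 0.5, len = 30L), list(vaf = 0.2, len = 9L),
                list(vaf = 0.2, len = 60L))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    cfg <- sim_config(
      reference_length = 300,
      duplications = list(list(start = 100, length = cs$len,
                               vaf = cs$vaf)),
      read_length = 120, n_reads = 5000, error_rate = 0, seed = 100 + i)
    res <- run_detect(ref300, generate_reads(cfg, ref300)$reads, p_def)
    g <- res$full[res$full$kind == "duplication" &
                    res$full$size == cs$len, ]
    expect_identical(nrow(g), 1L)
    expect_lt(abs(g$vaf - cs$vaf) / cs$vaf, 0.2)
  }
  # at the 1% clinical limit, average three replicates to tame sampling noise
  vafs <- vapply(1:3, function(r) {
    cfg <- sim_config(
      reference_length = 300,
      duplications = list(list(start = 100, length = 30L, vaf = 0.01)),
      read_length = 120, n_reads = 5000, error_rate = 0, seed = 200 + r)
    res <- run_detect(ref300, generate_reads(cfg, ref300)$reads, p_def)
    g <- res$full[res$full$kind == "duplication" & res$full$size == 30L, ]
    g$vaf[1]
  }, numeric(1))
  expect_lt(abs(mean(vafs) - 0.01) / 0.01, 0.2)
})

test_that("reporting separates the thresholded summary from the full table", {
  groups <- data.frame(
    kind = c("duplication", "duplication", "deletion"),
    size = c(21L, 21L, 1L),
    ref_start = c(50L, 120L, 80L), ref_end = c(71L, 141L, 81L),
    q = c(40L, 3L, 30L), b = 11L, t = 26L,
    q_prime = c(56.7, 4.2, 42.5),
    wildtype_coverage = c(2000, 2000, 2000),
    vaf = c(0.028, 0.002, 0.021), ar = c(0.028, 0.0021, 0.021),
    stringsAsFactors = FALSE)
  rep <- report_events(groups, reporting_threshold = 0.01)
  # sub-threshold and deletion groups drop from the summary, stay in full
  expect_identical(nrow(rep$summary), 1L)
  expect_identical(rep$summary$ref_start, 50L)
  expect_identical(nrow(rep$full), 3L)
  rep2 <- report_events(groups, 0.01, keep_deletions = TRUE)
  expect_identical(nrow(rep2$summary), 2L)

  # same length at different positions pools separately
  ev <- rbind(
    data.frame(read_id = c("r1", "r2"), kind = "duplication", size = 21L,
               ref_start = 50L, ref_end = 71L, left_flank_pos = 59L,
               right_flank_pos = 50L, j1 = 20L, j2 = 30L, b = 11L),
    data.frame(read_id = "r3", kind = "duplication", size = 21L,
               ref_start = 120L, ref_end = 141L, left_flank_pos = 129L,
               right_flank_pos = 120L, j1 = 20L, j2 = 30L, b = 11L))
  cov <- itdtrace:::new_coverage_profile(idx300$n_kmers)
  cov$total <- rep(100, idx300$n_kmers)
  q <- quantify_events(ev, cov, p_def, mean_read_length = 120)
  expect_identical(nrow(q), 2L)
  expect_setequal(q$ref_start, c(50L, 120L))
  expect_setequal(q$q, c(2L, 1L))

  # no events at all: a valid empty result
  q0 <- quantify_events(itdtrace:::empty_events(), cov, p_def, 120)
  expect_identical(nrow(q0), 0L)
})
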