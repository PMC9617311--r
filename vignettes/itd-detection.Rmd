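---
title: "Alignment-free ITD detection from k-mer position traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free ITD detection from k-mer position traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itdtrace)
```

## The model

`itdtrace` detects internal tandem duplications (and short indels
generally) in reads from one short, known locus — the motivating case is
the genomic sequence of *FLT3* exons 14–15, a few hundred nucleotides —
without aligning anything. The only signal used is where each read k-mer
occurs on the reference.

For a read *R* over reference *T*, the *trace* t_R lists, per k-mer start
*i*, the reference positions of R[i..i+k−1]. Along a read that matches the
reference the positions increase by exactly 1 per entry. Any difference
between read and reference knocks out the k-mers that straddle it,
creating a *break*: a maximal run (j₁, j₂) of absent entries. What makes a
tandem duplication recognisable is that the positions *go back* across its
break: the last position before the junction lies past the re-started
copy. With g = j₂ − j₁ + 1, the test is t_R[j₁−1] + g − 1 > t_R[j₂+1], and
the size follows from trace coordinates alone:

$$d = t_R[j_1-1] - t_R[j_2+1] + j_2 - j_1 + 2 .$$

When nothing is inserted at the junction and no junction k-mer happens to
occur in the reference, j₂ − j₁ + 2 = k. Each inserted junction base
lengthens the break by one and each junction-reference coincidence
shortens it by one; the formula absorbs both, and also substitutions
within k nt of the junction (they lengthen the break and shift one flank
by equal amounts). Deletions give d < 0, reported as deletions of
magnitude |d|; d = 0 is a substitution remnant and no event.

A toy configuration at k = 3 makes this concrete:

```{r}
tr <- trace_from_positions(c(3, 4, 5, NA, NA, 4, 5, 6, 7), k = 3)
brk <- find_breaks(tr)
brk
is_duplication_break(tr, brk[1, ])
call_event(tr, brk[1, ])[, c("kind", "size", "ref_start", "ref_end")]
```

### Assumptions

* The reference is short (hundreds of nt) and curated: non-ACGT characters
  in it are an error, whereas reads with `N`s are simply traced around.
* k is large enough that chance k-mer matches are rare but small enough
  that the index of a short reference stays dense; duplications whose
  junction context coincides with the reference over ≥ k bases are
  invisible, with probability decreasing exponentially in k.
* Substitutions dominate the error process (Illumina-like data); there is
  no quality-aware modelling, and indel sequencing errors are not
  corrected (they surface as small indel events or coverage loss).
* Read start positions are roughly uniform over the locus; the read-count
  edge correction (below) assumes this.

## The pipeline and its parameters

`run_detect()` executes, per read: Bloom-filter screening → trace →
disambiguation → substitution correction → break finding → break merging
→ δ-validation → event calling; then coverage accumulation, pooling and
reporting. The parameters, all in `run_params()`:

* **k** (default 12 nt). The k-mer length of the index and traces. The
  default is the working value for the FLT3 locus: at 4^12 ≈ 1.7·10⁷
  possible k-mers against a ~300 nt reference, chance hits are rare, yet
  breaks stay short enough to sit inside 100–150 nt reads.
* **δ** (default 2 nt). Number of additional consecutive positions
  required on each side of a break before an event is reported
  (`validate_break()`); equivalent to calling with (k+δ)-mers. Raising δ
  suppresses spurious short-k-mer matches at the cost of a slightly wider
  undetectable margin at read edges.
* **min_kmer_fraction** (default 0.30). Screening threshold: minimum
  fraction of a read's k-mers found in the Bloom filter, evaluated for
  both orientations; the read proceeds in the better one (ties forward).
  Off-target reads almost never reach 30%, on-target reads with ~1%
  errors essentially always do.
* **bloom_fp_rate** (default 0.01). Target false-positive rate used to
  size the Bloom filter from the distinct k-mer count. False positives
  only cost screening precision (the trace uses exact hash lookups);
  false negatives cannot occur. For a 300 nt reference the filter is a
  few kilobits regardless.
* **reporting_threshold** (default 0.01). Minimum VAF for the summary
  view, the conventional clinical cut-off; everything remains in the full
  table. Deletions are additionally dropped from the summary unless
  `keep_deletions = TRUE` — short spurious deletions are the dominant
  artefact class, while the full table keeps them auditable.

## Quantification

Coverage follows the traces: each resolved entry increments the count at
its reference position (a k-mer-start convention; since VAF and AR are
ratios of quantities counted the same way, the convention cancels).
Events sharing kind, size and reference interval are pooled; q is the
number of supporting reads. A junction can only be called when
t = 2δ + b + k − 1 nucleotides of the read span it (b is the break size),
so junctions in the first or last t − 1 read positions go uncounted; under
the uniform-start assumption the count is corrected to
q′ = q·(1 + 2(t−1)/R), with R the mean kept-read length. Wild-type
coverage is bookkept exactly: a read supporting an event contributes its
whole coverage to that event's group (its largest event, if several), and
wild-type coverage is total minus all group contributions, evaluated at
the first duplicated base. Then VAF = q′/(q′+w) and AR = q′/w, so
AR = VAF/(1−VAF) holds identically.

Two properties of this estimator are worth knowing. First, the
2(t−1)/R edge model counts the (t−1)-margin at both read ends for what is
a single junction point; exact geometry over uniform starts gives a
smaller undetectable fraction, close to t/(R−1) (about 0.21 instead of
0.42 at the defaults with R = 120). The resulting overcorrection of q′ in
practice offsets the coverage the wild-type side loses to the k-mer-start
convention and to mutant reads that miss the junction, so the end-to-end
VAF comes out unbiased in the package's recovery tests (within ±0.03 of a
0.2 truth at 5000 reads). Second, because mutant reads that cover the
duplicated interval but not the junction are indistinguishable from wild
type, they inflate w; at extreme allele fractions the reported VAF
saturates below the truth (around 0.7–0.8 for a truth of 1.0 under
uniform starts). Between those extremes — where clinical decisions live —
recovery is accurate; both behaviours are exercised in the test suite.

## Numerical and design choices

* **Coordinates** are 0-based with half-open intervals everywhere; the
  TSV writer can emit 1-based starts for human consumption.
* **Disambiguation** (multi-position k-mers) resolves left to right.
  Rule 1: if the previous entry is resolved and its value + 1 is a
  candidate, take it. Rule 2: take the candidate minimising summed
  absolute distance to the nearest present entry on each side, crossing
  at most the one immediately adjacent break; remaining ties, and entries
  with no neighbour, take the smallest position so output is
  deterministic.
* **Substitution correction** is all-or-nothing per break: one tentative
  edit of the last base of the break's first k-mer, anchored on the left
  flank, must explain the entire break (≤ k entries) through consecutive
  plain lookups, else it is reverted. The greedy alternative — allowing a
  fresh edit at every break k-mer — would destroy every duplication,
  because a junction k-mer also differs from the reference continuation
  at its last base only, and for small duplications even a one-step
  look-ahead can be fooled by the offset-d self-similarity of the
  duplicated sequence. The all-or-nothing rule corrects exactly what it
  is meant to correct (isolated substitutions, including near junctions
  and read ends) and leaves junction breaks bit-identical, which also
  preserves the clean-case identity j₂ − j₁ + 2 = k. Clustered
  substitutions (< k apart) stay uncorrected; their remnant breaks call
  d = 0 and are dropped.
* **Break merging**: breaks separated by fewer than δ present entries are
  merged when each separate call would be longer in magnitude than the
  merged call — the situation created by a junction base that happens to
  match the reference, splitting one logical break in two. Applied left
  to right to a fixpoint; breaks with missing flanks never merge.
* **Degenerate inputs**: breaks touching a trace edge are uncallable
  (never an error) — consistent with the t-nucleotide requirement that
  the quantification correction models; events with 2(t−1) ≥ R cap the
  correction factor at 3 with a warning, since the uniform model breaks
  down when the detectable span approaches the read length; zero
  wild-type coverage reports VAF 1 with infinite AR.
* **Orientation and pairing**: strandedness is decided per read at
  screening; paired-end mates are independent reads (no pairing logic is
  used anywhere).
* **Event classes**: d > 0 without the back-jump signature (only possible
  for d ≤ 2) is labelled "insertion" and kept separate rather than
  silently dropped or promoted.

## The simulator

`generate_reads()` is the package's test bed. It emulates: a uniform
random reference; one mutant haplotype per duplication spec, built by
tandem-duplicating a reference interval; reads of fixed length with
uniform starts drawn from wild-type and mutant haplotypes in proportions
matching the target VAFs; i.i.d. substitution errors; a configurable
reverse-complemented fraction; constant qualities (the detector ignores
them); and a per-read truth table (haplotype, start, strand, error count,
junction coverage). It deliberately does **not** emulate: realistic
Illumina error profiles (no quality-dependent or positional error
structure), indel sequencing errors (off by default by design),
PCR duplicates, paired-end insert-size structure, or coverage biases.
Passing tests on this generator therefore demonstrate the calculus —
exact sizing, invariances, VAF recovery under the stated model — not
robustness to every artefact of production capture data.

Problem sizes in the shipped tests were chosen to exercise the claims at
realistic depth while staying quick: a 300 nt reference, 120 nt reads,
2 000–10 000 reads per scenario (≈ 500–4 000× depth), duplication lengths
3–126 nt and VAFs 0.01–1.

## Known limitations

* One locus per run; no genome-scale indexing, minimizers or canonical
  k-mers.
* Duplications are only sized exactly when the junction context is
  resolvable: a junction whose sequence coincides with the reference for
  ≥ k + δ bases is missed.
* The q′ correction is first-order and, as discussed, conservative in a
  way that happens to cancel; quantification of events whose t approaches
  R is flagged but still approximate.
* Very low VAFs are limited by counting noise, not by the method: at VAF
  0.01 and 2 000× depth, q is ~20 reads.
* No confidence intervals on VAF/AR, no multi-sample aggregation, no
  phasing of co-occurring duplications.
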