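# itdtrace

Alignment-free detection, sizing and quantification of internal tandem
duplications (ITDs) from short sequencing reads, using only the positions
of read k-mers on a short reference sequence.

## The problem

Internal tandem duplications of the *FLT3* gene (*FLT3*-ITD, an in-frame
duplication of 3 to several hundred nucleotides inside exons 14–15) occur
in 20–30% of acute myeloid leukemia cases and drive both risk
stratification and therapy choice, together with their allelic ratio.
General-purpose aligners do not call tandem duplications directly, and
specialised alignment-based callers are resource-hungry. `itdtrace` is for
anyone who needs to screen capture or RNA-seq read sets against one short
locus and get exact ITD lengths, positions and allele fractions without
any alignment step.

## The method

Let *T* be the reference and *R* a read. Every k-mer of *T* (default
k = 12) is indexed with all its 0-based start positions in a hash table,
and the k-mer set is also stored in a Bloom filter. A read is kept when at
least 30% of its k-mers (in the better of the two orientations) hit the
Bloom filter. For a kept read the **trace** t_R is computed: entry *i*
holds the reference positions of the read k-mer starting at *i*, resolved
to at most one position by a consecutive-position rule and a
nearest-neighbour distance rule. A **break** (j₁, j₂) is a maximal run of
absent entries; breaks of isolated substitutions are corrected away, and a
break whose flanking positions "go back" —

    t_R[j₁−1] + g − 1 > t_R[j₂+1],   g = j₂ − j₁ + 1

— is a tandem duplication whose exact length is

    d = t_R[j₁−1] − t_R[j₂+1] + j₂ − j₁ + 2.

The call is accepted only if δ (default 2) further trace positions on each
side continue the flanks arithmetically, which is equivalent to calling
with (k+δ)-mers. Identical events are pooled; the supporting count q is
corrected for junctions falling too close to read ends,
q′ = q·(1 + 2(t−1)/R) with t = 2δ + b + k − 1, and reported as
VAF = q′/(q′ + w) and AR = q′/w, with w the wild-type coverage at the
duplication start.

## Worked example

Simulate a 21 nt duplication at VAF 0.25 on a random 300 nt reference and
detect it:

```r
library(itdtrace)

ref <- generate_reference(300, seed = 42)
cfg <- sim_config(reference_length = 300,
                  duplications = list(list(start = 100, length = 21, vaf = 0.25)),
                  read_length = 120, n_reads = 4000, error_rate = 0.005, seed = 1)
sim <- generate_reads(cfg, ref)
res <- run_detect(ref, sim$reads, run_params())
print(res)
#> ITD detection result
#>   reads: 4000 total, 4000 kept (mean length 120 nt)
#>   mean coverage over k-mer starts: 1475.1
#>   events at VAF >= 0.01:
#>          kind size ref_start ref_end   q q_prime    vaf     ar
#> 1 duplication   21       100     121 400   566.7 0.2419 0.3191
```

The single summary row says: one duplication group of exactly 21 nt, whose
duplicated reference interval is \[100, 121) (0-based, half-open), was
supported by 400 reads, 566.7 after read-edge correction, for an estimated
variant allele frequency of 0.24 (truth: 0.25) and allelic ratio 0.32.
Reads, reference and results can equally come from / go to files:

```sh
Rscript inst/cli/itdtrace.R detect --ref ref.fa --reads r1.fastq.gz \
        --reads r2.fastq.gz -k 12 --delta 2 --threshold 0.01 --out results
```

writes `results.json` (all groups, per-read events, run statistics) and
`results.tsv` (the thresholded summary).

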