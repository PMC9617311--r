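Package: itdtrace
Title: Alignment-Free Detection and Quantification of Internal Tandem
    Duplications from k-mer Position Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, sizes and quantifies internal tandem duplications
    (and more generally short insertions and deletions) in high-throughput
    sequencing reads relative to a short reference sequence, without any
    read alignment. Reads are screened with a Bloom filter over the
    reference k-mers, each kept read is converted into a trace of k-mer
    positions on the reference, and runs of positions that suddenly "go
    back" across a break in the trace are called as tandem duplications
    whose exact length follows from the trace coordinates alone. Supporting
    read counts are corrected for duplications falling too close to read
    ends, and reported as variant allele frequencies and allelic ratios.
    Designed for targeted loci such as FLT3 exons 14-15 in acute myeloid
    leukemia, where internal tandem duplications of 3 to several hundred
    nucleotides are a key prognostic marker. Includes a deterministic
    simulator of duplication-bearing read sets for validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
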