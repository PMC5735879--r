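Package: seedoverlap
Title: Two-Level Seed Chaining for Long-Read Overlap Detection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: All-vs-all overlap detection for noisy long sequencing reads
    (PacBio-style, 10-15% error, indel-dominant). Reads are stored two bits
    per base; a k-mer occurrence index over both strands of the reference set
    drives per-pair seed matching, consistent-run clustering with a relative
    indel-drift tolerance, a binomial mu-minus-3-sigma significance filter on
    seed counts, and a second-pass extension with shorter k'-mers that pushes
    the overlap boundaries outward. Only alignment boundaries are reported, in
    a 12-column M4-style tabular dialect. The package also ships a
    Smith-Waterman based evaluation suite (sensitivity, specificity,
    precision, F1 under presence/length/bounds correctness modes) and an
    indel-dominant read simulator that produces exact ground-truth placements,
    so the whole system can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
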