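Package: metharray
Title: Methylation Array Profiling, DMR Detection and Intensity-Based CNV Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for 450k-style DNA methylation microarrays:
    probe filtering and quantile normalization, beta/M-value computation with
    probe-type bias correction, genomic-class methylation profiling,
    region-chaining differentially methylated region (DMR) detection with
    Mann-Whitney testing and Benjamini-Hochberg correction, copy-number
    inference from total probe fluorescence against a copy-stable control
    cohort, and window-of-linearity qPCR quantification. Ships a synthetic
    array-cohort generator with planted ground truth (DMRs, CNV segments,
    global tumor hypomethylation) so every stage is testable end to end
    without array downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
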