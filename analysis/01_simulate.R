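#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort and record its ground truth.

source("analysis/00_config.R")

st <- study_cohort()
write_manifest(st$manifest, file.path(RESULTS_DIR, "manifest.tsv"))
write_truth(st$truth, file.path(RESULTS_DIR, "truth.json"))

cat("cohort:", length(st$data$probes), "probes x",
    length(st$data$samples), "samples\n")
print(table(st$data$group))
cat("planted DMRs:", nrow(PLANTED_DMRS),
    "| planted CNV segments:", nrow(PLANTED_CNVS),
    "| negative controls:", sum(st$manifest$is_negative_control), "\n")
cat("wrote", file.path(RESULTS_DIR, "manifest.tsv"), "and truth.json\n")
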