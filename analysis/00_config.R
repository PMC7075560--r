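# Shared study configuration for the analysis workflow.
#
# One synthetic 450k-like cohort carries every planted feature the stages
# interrogate: uncultured (d0_PTC) and long-term cultured (LT_PTC) sorted
# spermatogonia-like normal profiles, globally hypomethylated seminoma-like
# (SE) tumors sparing promoters/CGIs, 12 planted DMRs separating the two
# PTC groups, an i(12p)-style 12p gain in all SE samples plus a focal loss
# in SE_1, and a 10-sample copy-stable female control cohort.
#
# The generators are fully deterministic given the seed, so each numbered
# script re-derives the cohort instead of passing bulky intermediates.

library(metharray)

STUDY_SEED <- 1234L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

dmr_starts <- seq(40000, by = 90000, length.out = 12)
PLANTED_DMRS <- data.frame(
  chrom = "3", start = dmr_starts, end = dmr_starts + 800L,
  n_probes = 6L, delta_m = 3, group = "LT_PTC")

PLANTED_CNVS <- data.frame(
  target = c("SE", "SE_1"),
  chrom = c("12", "13"),
  start = 1L,
  end = c(450000L, 500000L),   # 12p-arm-style gain; focal 13q loss
  copy = c(3L, 1L),
  mosaic_fraction = 1)

study_config <- function() {
  sim_config(seed = STUDY_SEED, n_probes = 8000,
             n_samples_per_group = c(d0_PTC = 4, LT_PTC = 4, SE = 4,
                                     control = 10),
             planted_dmrs = PLANTED_DMRS,
             planted_cnvs = PLANTED_CNVS)
}

study_cohort <- function() {
  cfg <- study_config()
  man <- simulate_manifest(cfg)
  sim <- simulate_cohort(cfg, man)
  list(cfg = cfg, manifest = man, data = sim$data, truth = sim$truth)
}
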