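test_that("probe totals sum channels, floor at 1, and are channel-symmetric", {
  meth <- matrix(c(300, 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  unmeth <- matrix(c(200, 0), 2, 1, dimnames = dimnames(meth))
  raw <- intensity_set(meth, unmeth, NULL, c(s1 = "x"))
  expect_equal(probe_totals(raw), pmax(meth + unmeth, 1))
  expect_equal(probe_totals(raw)["b", 1], 1)
  swapped <- intensity_set(unmeth, meth, NULL, c(s1 = "x"))
  expect_equal(probe_totals(raw), probe_totals(swapped))
})

test_that("bins hold equal probe counts with the remainder merged", {
  man <- toy_manifest(chrom = "1", pos = seq_len(100L) * 1000L,
                      probe_id = sprintf("cg%04d", 1:100))
  b <- build_bins(man, probes_per_bin = 25L)
  expect_equal(b$n_probes, rep(25L, 4))
  man2 <- toy_manifest(chrom = "1", pos = seq_len(103L) * 1000L,
                       probe_id = sprintf("cg%04d", 1:103))
  b2 <- build_bins(man2, probes_per_bin = 25L)
  expect_equal(b2$n_probes, c(25L, 25L, 25L, 28L))
  # bins are ordered, non-overlapping, and confined to one chromosome
  sc <- small_cohort()
  bins <- build_bins(sc$man, probes_per_bin = 50L)
  expect_true(all(vapply(seq_len(nrow(bins)), function(i) {
    probes <- bins$probe_ids[[i]]
    length(unique(sc$man$chrom[match(probes, sc$man$probe_id)])) == 1L
  }, logical(1))))
  for (ch in unique(bins$chrom)) {
    sub <- bins[bins$chrom == ch, ]
    expect_true(all(diff(sub$start) > 0))
    expect_true(all(sub$end[-nrow(sub)] < sub$start[-1]))
  }
  n_cpg <- sum(!sc$man$is_negative_control)
  expect_equal(nrow(bins), sum(tapply(!sc$man$is_negative_control,
                                      sc$man$chrom, sum) %/% 50L))
  expect_gt(nrow(bins), n_cpg / 50L - 24L)
})

test_that("log2 ratios map to the published five-state sequence", {
  ratios <- c(-1.0, -0.96, -0.5, -0.24, 0.0, 0.12, 0.5, 0.72, 1.0)
  expected <- c("hom_del", "hom_del", "hemi_del", "hemi_del", "neutral",
                "dup", "dup", "high_gain", "high_gain")
  expect_equal(classify_cnv_state(ratios), expected)
  # total function: a fine grid maps to exactly one state each
  grid <- seq(-2, 2, by = 0.01)
  expect_false(any(is.na(classify_cnv_state(grid))))
  expect_error(cnv_thresholds(homozygous_del_max = 0), NULL)
})

test_that("control baseline is order-invariant and flags degenerate spread", {
  probes <- sprintf("cg%03d", 1:60)
  man <- toy_manifest(chrom = "1", pos = seq_along(probes) * 1000L,
                      probe_id = probes)
  bins <- build_bins(man, probes_per_bin = 30L)
  base_int <- matrix(rep(rlnorm(60, log(2000), 0.5), 4), 60, 4,
                     dimnames = list(probes, sprintf("c%d", 1:4)))
  grp <- setNames(rep("control", 4), colnames(base_int))
  ctrl <- intensity_set(base_int, base_int, NULL, grp)
  bl <- control_baseline(ctrl, bins)
  expect_true(all(bl$baseline_mad == 0))
  expect_true(all(bl$degenerate))
  perm <- base_int[, c(3, 1, 4, 2)]
  bl2 <- control_baseline(intensity_set(perm, perm, NULL, grp), bins)
  expect_equal(bl$baseline_median, bl2$baseline_median)
  expect_error(control_baseline(
    intensity_set(base_int[, 1:2], base_int[, 1:2], NULL, grp[1:2]), bins),
    ">= 3 control")
})

test_that("a held-out copy-2 sample centers on ratio 0", {
  sc <- small_cohort()
  bins <- build_bins(sc$man, probes_per_bin = 50L)
  ds <- sc$sim$data
  ctrl <- ds$samples[ds$group == "control"]
  sub <- function(ss) intensity_set(ds$meth[, ss, drop = FALSE],
                                    ds$unmeth[, ss, drop = FALSE],
                                    NULL, ds$group[ss])
  bl <- control_baseline(sub(ctrl), bins)
  pr <- sample_profile(ds, "d0_PTC_1", bl, bins, sex = "female")
  expect_lt(abs(mean(pr$log2_ratio)), 0.05)
  expect_equal(sum(pr$gain_loss != 0), 0L)
})

test_that("planted gains and losses are recovered; 10% mosaics are not", {
  pc <- data.frame(
    target = c("SE_1", "SE_1", "SE_2"),
    chrom = c("5", "8", "12"),
    start = 1L,
    end = c(905000L, 725000L, 1000000L),  # roughly arm-scale at 1/100
    copy = c(3L, 1L, 3L),
    mosaic_fraction = c(1, 1, 0.1))
  cfg <- sim_config(seed = 202, n_probes = 12000, planted_cnvs = pc,
                    n_samples_per_group = c(SE = 2, control = 10))
  man <- simulate_manifest(cfg)
  sim <- simulate_cohort(cfg, man)
  ds <- sim$data
  bins <- build_bins(man, probes_per_bin = 50L)
  ctrl <- ds$samples[ds$group == "control"]
  sub_ctrl <- intensity_set(ds$meth[, ctrl], ds$unmeth[, ctrl], NULL,
                            ds$group[ctrl])
  bl <- control_baseline(sub_ctrl, bins)
  pr1 <- sample_profile(ds, "SE_1", bl, bins, sex = "female")
  in_seg <- function(pr, i) pr$chrom == pc$chrom[i] & pr$start >= pc$start[i] &
    pr$end <= pc$end[i]
  gain <- in_seg(pr1, 1)
  expect_gt(sum(gain), 5L)
  # copy 3 at 100%: expected ratio log2(3/2) ~ 0.585 -> duplication
  expect_gte(mean(pr1$state[gain] == "dup" & pr1$gain_loss[gain] == 1L), 0.95)
  loss <- in_seg(pr1, 2)
  # copy 1 at 100%: expected ratio -1, below the -0.96 cutoff; the published
  # cutoffs call this hom_del and that coarseness is preserved
  expect_gte(mean(pr1$gain_loss[loss] == -1L), 0.95)
  expect_gte(mean(pr1$state[loss] == "hom_del"), 0.5)
  # off-segment bins stay almost entirely quiet
  expect_lte(mean(pr1$gain_loss[!(gain | loss)] != 0), 0.02)
  # 10% mosaic single-copy gain: expected ratio log2(1.05) ~ 0.07 < 0.12
  pr2 <- sample_profile(ds, "SE_2", bl, bins, sex = "female")
  mosaic <- in_seg(pr2, 3)
  expect_gt(sum(mosaic), 5L)
  expect_equal(sum(pr2$gain_loss[mosaic] == 1L), 0L)
})

test_that("male chrX is baseline-shifted; unknown sex suppresses X calls", {
  # a male sample carries one X against the two-X female baseline
  pc <- data.frame(target = "SE_1", chrom = "X", start = 1L, end = 1560000L,
                   copy = 1L, mosaic_fraction = 1)
  cfg <- sim_config(seed = 303, n_probes = 8000, planted_cnvs = pc,
                    n_samples_per_group = c(SE = 1, control = 6))
  man <- simulate_manifest(cfg)
  sim <- simulate_cohort(cfg, man)
  ds <- sim$data
  bins <- build_bins(man, probes_per_bin = 50L)
  ctrl <- ds$samples[ds$group == "control"]
  bl <- control_baseline(intensity_set(ds$meth[, ctrl], ds$unmeth[, ctrl],
                                       NULL, ds$group[ctrl]), bins)
  pr_m <- sample_profile(ds, "SE_1", bl, bins, sex = "male")
  on_x <- pr_m$chrom == "X"
  expect_gt(sum(on_x), 3L)
  expect_true(all(pr_m$gain_loss[on_x] == 0L))
  # without the shift the same sample's X would read as lost
  pr_f <- sample_profile(ds, "SE_1", bl, bins, sex = "female")
  expect_true(all(pr_f$gain_loss[on_x] == -1L))
  expect_warning(pr_u <- sample_profile(ds, "SE_1", bl, bins, sex = "unknown"),
                 "chrX")
  expect_true(all(pr_u$gain_loss[on_x] == 0L))
})

test_that("cohort summaries aggregate ratios and break ties to zero", {
  sc <- small_cohort()
  bins <- build_bins(sc$man, probes_per_bin = 50L)
  ds <- sc$sim$data
  ctrl <- ds$samples[ds$group == "control"]
  bl <- control_baseline(intensity_set(ds$meth[, ctrl], ds$unmeth[, ctrl],
                                       NULL, ds$group[ctrl]), bins)
  pr <- sample_profile(ds, "SE_1", bl, bins, sex = "female")
  single <- cohort_summary(list(pr), "SE")
  expect_equal(single$mean_log2_ratio, pr$log2_ratio)
  expect_equal(single$gain_loss, pr$gain_loss)
  # opposite calls in a bin: majority is 0
  pr_up <- pr; pr_up$gain_loss[1] <- 1L
  pr_dn <- pr; pr_dn$gain_loss[1] <- -1L
  agg <- cohort_summary(list(pr_up, pr_dn), "SE")
  expect_equal(agg$gain_loss[1], 0L)
  # mismatched bin tables are an integrity error
  pr_bad <- pr[-1, ]
  expect_error(cohort_summary(list(pr, pr_bad)), "bin definitions")
  # SEG export of a profile round-trips
  path <- withr::local_tempfile(fileext = ".seg")
  write_cnv_seg(pr, path)
  back <- read_seg(path)
  expect_equal(back$log2_ratio, pr$log2_ratio)
  expect_equal(back$state, pr$state)
})
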