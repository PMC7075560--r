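test_that("candidate chaining matches hand-derived regions", {
  man <- toy_manifest(chrom = "1", pos = c(100L, 250L, 400L, 560L, 900L))
  reg <- find_candidate_regions(man, dmr_params())
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 100L)
  expect_equal(reg$end, 560L)
  expect_equal(reg$n_probes, 4L)
  # gap of exactly 200 continues a chain; 201 breaks it
  man200 <- toy_manifest(chrom = "1", pos = c(100L, 300L, 500L, 700L))
  expect_equal(nrow(find_candidate_regions(man200, dmr_params())), 1L)
  man201 <- toy_manifest(chrom = "1", pos = c(100L, 301L, 502L, 703L))
  expect_equal(nrow(find_candidate_regions(man201, dmr_params())), 0L)
  # chains never span chromosomes
  man2 <- toy_manifest(chrom = c("1", "1", "2", "2"),
                       pos = c(100L, 200L, 300L, 400L))
  expect_equal(nrow(find_candidate_regions(man2, dmr_params(min_probes = 2))), 2L)
  # invariant to input probe order
  shuf <- man[c(4, 1, 5, 3, 2), ]
  expect_equal(find_candidate_regions(shuf, dmr_params())[, 1:4], reg[, 1:4])
})

test_that("Mann-Whitney on pooled M-values matches exact enumeration", {
  # 4 vs 4 fully separated: U = 16, exact two-sided p = 2/70
  mset <- two_group_mset(c(5, 6, 7, 8), c(1, 2, 3, 4))
  res <- test_region(mset, "cg0000001", "A", "B")
  expect_equal(res$u_statistic, 16)
  expect_equal(res$p_raw, 2 / choose(8, 4))
  expect_equal(res$delta_median_m, 4)
  # identical groups: no effect, p at the null
  same <- two_group_mset(c(1, 2, 3), c(1, 2, 3))
  res2 <- test_region(same, "cg0000001", "A", "B")
  expect_equal(res2$delta_median_m, 0)
  expect_gt(res2$p_raw, 0.95)
  # all values tied at one constant: p = 1, no division by zero
  const <- two_group_mset(c(2, 2, 2), c(2, 2, 2))
  res3 <- test_region(const, "cg0000001", "A", "B")
  expect_equal(res3$p_raw, 1)
  expect_equal(res3$u_statistic, 4.5)
  # property: exact path equals brute-force enumeration, combined n <= 10
  set.seed(99)
  for (i in 1:60) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- rnorm(na); b <- rnorm(nb, sample(c(0, 2), 1))
    got <- test_region(two_group_mset(a, b), "cg0000001", "A", "B")
    expect_equal(got$p_raw, brute_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(17)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- adjust_bh(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15 & adj <= 1))
  }
})

test_that("effect-size gates and modes control DMR status", {
  # two groups separated by exactly delta M on every probe in one region
  probes <- sprintf("cg%07d", 1:4)
  samples <- sprintf("s%d", 1:8)
  group <- setNames(rep(c("A", "B"), each = 4), samples)
  base <- matrix(rnorm(32, 0, 0.01), 4, 8, dimnames = list(probes, samples))
  delta <- 1.39
  m <- base + outer(rep(0, 4), ifelse(group == "A", delta, 0), "+")
  beta <- inv <- 2^m / (1 + 2^m)
  mset <- methylation_set(beta, m, group)
  man <- toy_manifest(chrom = "1", pos = c(100L, 200L, 300L, 400L),
                      probe_id = probes)
  res <- call_dmrs(mset, man, "A", "B", dmr_params(mode = "methods"))
  expect_equal(nrow(res), 1L)
  expect_lt(res$p_adj, 0.05)
  expect_equal(res$delta_median_m, 1.39, tolerance = 0.02)
  expect_false(res$is_dmr)  # |delta M| below the 1.4 threshold
  # push the shift past the threshold: called
  m2 <- base + outer(rep(0, 4), ifelse(group == "A", 1.6, 0), "+")
  b2 <- 2^m2 / (1 + 2^m2)
  res2 <- call_dmrs(methylation_set(b2, m2, group), man, "A", "B",
                    dmr_params(mode = "methods"))
  expect_true(res2$is_dmr)
  # results mode gates on beta difference (0.25) and alpha 0.01
  pr <- dmr_params(mode = "results")
  expect_equal(pr$alpha, 0.01)
  res3 <- call_dmrs(methylation_set(b2, m2, group), man, "A", "B", pr)
  expect_equal(res3$is_dmr, abs(res3$delta_median_beta) >= 0.25 &
                 res3$p_adj <= 0.01)
  # sparse manifest: no candidates, empty result, not an error
  sparse <- toy_manifest(chrom = "1", pos = c(100L, 5000L))
  expect_equal(nrow(call_dmrs(mset, sparse, "A", "B")), 0L)
})

test_that("planted DMRs are recovered and no extra regions invented", {
  pd <- data.frame(chrom = "1", start = seq(20000, by = 60000, length.out = 8),
                   end = seq(20000, by = 60000, length.out = 8) + 800,
                   n_probes = 6L, delta_m = 3, group = "LT_PTC")
  cfg <- sim_config(seed = 101, n_probes = 4000, planted_dmrs = pd,
                    n_samples_per_group = c(d0_PTC = 4, LT_PTC = 4,
                                            control = 3))
  man <- simulate_manifest(cfg)
  sim <- simulate_cohort(cfg, man)
  pp <- preprocess_pipeline(sim$data, man)
  res <- call_dmrs(pp$meth, man, "LT_PTC", "d0_PTC")
  called <- res[res$is_dmr, ]
  overlaps <- function(i, tab)
    any(tab$chrom == pd$chrom[i] & tab$start <= pd$end[i] &
          tab$end >= pd$start[i])
  hits <- vapply(seq_len(nrow(pd)), overlaps, logical(1), tab = called)
  expect_gte(sum(hits), 7L)
  false_calls <- vapply(seq_len(nrow(called)), function(j)
    !any(pd$chrom == called$chrom[j] & pd$start <= called$end[j] &
           pd$end >= called$start[j]), logical(1))
  expect_equal(sum(false_calls), 0L)
  # planted effect is recovered on the M scale
  expect_equal(median(called$delta_median_m), 3, tolerance = 0.5)
})

test_that("no planted signal yields a controlled false-call proportion", {
  cfg <- sim_config(seed = 55, n_probes = 3000,
                    n_samples_per_group = c(d0_PTC = 4, LT_PTC = 4,
                                            control = 3))
  man <- simulate_manifest(cfg)
  sim <- simulate_cohort(cfg, man)
  pp <- preprocess_pipeline(sim$data, man)
  res <- call_dmrs(pp$meth, man, "LT_PTC", "d0_PTC")
  testable <- !is.na(res$p_adj)
  expect_gt(sum(testable), 100L)
  expect_lte(mean(res$p_adj[testable] <= 0.05), 0.07)
  expect_equal(sum(res$is_dmr), 0L)
})
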