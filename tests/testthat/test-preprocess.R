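make_raw <- function(meth, unmeth, detect_p = NULL, groups = NULL) {
  if (is.null(groups))
    groups <- setNames(rep("d0_PTC", ncol(meth)), colnames(meth))
  intensity_set(meth, unmeth, detect_p, groups)
}

test_that("detection p-values follow the negative-control ecdf", {
  # 99 negative controls with totals 1..99 and three query probes
  n_neg <- 99L
  man <- rbind(toy_manifest(chrom = "1", pos = 1000L + 1:3,
                            probe_id = sprintf("cg%03d", 1:3)),
               toy_manifest(chrom = "1", pos = 1:n_neg,
                            probe_id = sprintf("neg%03d", 1:n_neg),
                            is_cpg_target = FALSE, negative = TRUE))
  totals <- c(200, 0.5, 50, 1:n_neg)  # query: above all, below all, median
  meth <- matrix(totals / 2, ncol = 1,
                 dimnames = list(c(sprintf("cg%03d", 1:3),
                                   sprintf("neg%03d", 1:n_neg)), "s1"))
  raw <- make_raw(meth, meth)
  dp <- detection_pvalues(raw, man)
  expect_equal(dp["cg001", "s1"], 0)
  expect_equal(dp["cg002", "s1"], 1)
  expect_equal(dp["cg003", "s1"], 0.5, tolerance = 2 / n_neg)
  expect_true(all(dp >= 0 & dp <= 1))
  # too few negative controls: directed error
  expect_error(detection_pvalues(raw, man[1:10, ]), "negative-control")
})

test_that("a probe detected in 6 of 7 samples fails the 95% rule", {
  probes <- c("cgA", "cgB")
  samples <- sprintf("s%d", 1:7)
  meth <- matrix(100, 2, 7, dimnames = list(probes, samples))
  dp <- matrix(0.001, 2, 7, dimnames = list(probes, samples))
  dp["cgA", "s7"] <- 0.5  # 6/7 ~ 0.857 < 0.95
  man <- toy_manifest(chrom = "1", pos = c(100L, 300L), probe_id = probes)
  raw <- make_raw(meth, meth, dp)
  res <- filter_probes(raw, man)
  expect_equal(res$data$probes, "cgB")
  expect_equal(res$report$removed[["detection"]], 1L)
})

test_that("filters apply in sequence and match planted counts", {
  sc <- small_cohort()
  res <- filter_probes(sc$sim$data, sc$man)
  rep <- res$report
  n_cpg <- sum(!sc$man$is_negative_control)
  expect_equal(rep$n_input, nrow(sc$man))
  expect_equal(rep$removed[["non_cpg"]], sc$cfg$n_negative_controls)
  expect_equal(rep$removed[["detection"]],
               length(sc$sim$truth$failed_probes))
  expect_equal(rep$removed[["snp_within_10bp"]],
               round(sc$cfg$snp_probe_fraction * n_cpg))
  expect_equal(rep$removed[["multi_target"]],
               round(sc$cfg$multi_target_fraction * n_cpg))
  expect_equal(rep$n_input - sum(rep$removed), rep$n_retained)
  # planted failure/flag sets are disjoint by construction, so sequential
  # counts equal the planted totals exactly
  expect_equal(rep$n_retained, n_cpg - sum(rep$removed[-1]))
  # idempotence: filtering the filtered set removes nothing
  res2 <- filter_probes(res$data, sc$man)
  expect_equal(res2$report$n_retained, rep$n_retained)
  expect_equal(sum(res2$report$removed), 0L)
})

test_that("quantile normalization maps samples onto the mean quantile function", {
  set.seed(31)
  probes <- sprintf("cg%03d", 1:50)
  a <- sort(rlnorm(50, 5, 1))
  b <- rev(a) / 3
  # same pooled ranks, doubled scale: both samples map onto the common mean
  meth <- cbind(s1 = a, s2 = 2 * a)
  unmeth <- cbind(s1 = b, s2 = 2 * b)
  rownames(meth) <- rownames(unmeth) <- probes
  raw <- make_raw(meth, unmeth, groups = c(s1 = "d0_PTC", s2 = "d0_PTC"))
  norm <- quantile_normalize(raw)
  pooled <- function(ds, s) sort(c(ds$meth[, s], ds$unmeth[, s]))
  expect_equal(pooled(norm, "s1"), pooled(norm, "s2"))
  expect_equal(pooled(norm, "s1"), sort(c(a, b) * 1.5), ignore_attr = TRUE)
  # identical distributions are a fixed point
  raw2 <- make_raw(cbind(s1 = a, s2 = a), cbind(s1 = b, s2 = b),
                   groups = c(s1 = "x", s2 = "x"))
  expect_equal(quantile_normalize(raw2)$meth, cbind(s1 = a, s2 = a),
               ignore_attr = TRUE)
  # random matrices: per-sample pooled sorted vectors identical afterwards
  m <- matrix(rlnorm(200, 6, 1), 50, 4,
              dimnames = list(probes, sprintf("s%d", 1:4)))
  u <- matrix(rlnorm(200, 6, 1), 50, 4, dimnames = dimnames(m))
  raw3 <- make_raw(m, u, groups = setNames(rep("x", 4), colnames(m)))
  n3 <- quantile_normalize(raw3)
  srt <- sapply(colnames(m), function(s) pooled(n3, s))
  expect_true(all(abs(srt - srt[, 1]) < 1e-9))
  # ranks within each sample preserved
  expect_equal(apply(rbind(n3$meth, n3$unmeth), 2, rank),
               apply(rbind(m, u), 2, rank))
  # single sample: identity with a warning
  raw1 <- make_raw(m[, 1, drop = FALSE], u[, 1, drop = FALSE],
                   groups = c(s1 = "x"))
  expect_warning(out1 <- quantile_normalize(raw1), "single sample")
  expect_equal(out1$meth, m[, 1, drop = FALSE])
})

test_that("beta and M follow the channel formulas with clamping", {
  meth <- matrix(c(100, 800, 1000, 0), 4, 1,
                 dimnames = list(sprintf("cg%d", 1:4), "s1"))
  unmeth <- matrix(c(100, 200, 0, 0), 4, 1,
                   dimnames = dimnames(meth))
  ds <- make_raw(meth, unmeth, groups = c(s1 = "x"))
  mm <- compute_beta_m(ds)
  expect_equal(mm$beta[1:3, 1], c(0.5, 0.8, 1), ignore_attr = TRUE)
  expect_equal(mm$m[1:2, 1], c(0, 2), ignore_attr = TRUE)
  # beta 1 clamps to 0.999 for the logit: M = log2(999)
  expect_equal(mm$m[3, 1], log2(999), ignore_attr = TRUE)
  # both channels zero: missing, propagated
  expect_true(is.na(mm$beta[4, 1]) && is.na(mm$m[4, 1]))
  expect_true(all(abs(mm$m) <= log2(999) + 1e-12, na.rm = TRUE))
  # beta and M increase together (monotone bijection)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(beta_to_m(b)) > 0))
})

test_that("type-bias correction is a monotone quantile map onto type I", {
  set.seed(7)
  n1 <- 200; n2 <- 300
  man <- toy_manifest(chrom = "1", pos = seq_len(n1 + n2) * 1000L,
                      probe_id = sprintf("cg%04d", seq_len(n1 + n2)),
                      design_type = rep(c("I", "II"), c(n1, n2)))
  b1 <- runif(n1, 0, 1)          # type I spans the full range
  b2 <- runif(n2, 0.1, 0.8)      # type II compressed
  beta <- matrix(c(b1, b2), ncol = 1,
                 dimnames = list(man$probe_id, "s1"))
  mset <- methylation_set(beta, beta_to_m(beta), c(s1 = "x"))
  corr <- correct_type_bias(mset, man)
  ii <- man$design_type == "II"
  expect_equal(corr$beta[!ii, 1], b1, ignore_attr = TRUE)  # type I untouched
  expect_lt(min(corr$beta[ii, 1]), min(b2))  # range expands toward type I
  expect_gt(max(corr$beta[ii, 1]), max(b2))
  expect_true(all(corr$beta >= 0 & corr$beta <= 1))
  # order within type II preserved
  expect_equal(order(corr$beta[ii, 1]), order(b2))
  expect_equal(corr$meta$type_bias, "quantile-map-II-onto-I")
  # already-matching distributions: near-identity
  beta_eq <- matrix(c(b1, sort(b1)[round(seq(1, n1, length.out = n2))]),
                    ncol = 1, dimnames = list(man$probe_id, "s1"))
  mset_eq <- methylation_set(beta_eq, beta_to_m(beta_eq), c(s1 = "x"))
  corr_eq <- correct_type_bias(mset_eq, man)
  expect_equal(corr_eq$beta[ii, 1], beta_eq[ii, 1], tolerance = 0.02,
               ignore_attr = TRUE)
  # too few probes of one type: skipped with a warning
  expect_warning(correct_type_bias(mset, man[c(1:10, (n1 + 1):(n1 + n2)), ]),
                 "skipped")
})

test_that("the pipeline records its fixed stage order", {
  sc <- small_cohort()
  pp <- preprocess_pipeline(sc$sim$data, sc$man)
  expect_equal(pp$meth$meta$pipeline,
               c("filter", "quantile_normalize", "beta", "type_bias", "m"))
  expect_true(all(pp$meth$beta >= 0 & pp$meth$beta <= 1, na.rm = TRUE))
  expect_true(all(is.finite(pp$meth$m[!is.na(pp$meth$m)])))
})
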