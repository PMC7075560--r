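#' Probe-filtering parameters
#'
#' @param detect_p_max Detection p-value a probe must reach to count as
#'   detected in a sample (default 0.01).
#' @param detect_sample_frac Fraction of samples in which a probe must be
#'   detected to survive (default 0.95).
#' @param drop_non_cpg Drop probes not targeting a CpG (includes negative
#'   controls and rs probes).
#' @param drop_snp_probes Drop probes with a SNP at or within 10 bp of the
#'   target CpG (minor allele frequency >= 0.05).
#' @param drop_multi_target Drop probes mapping to multiple genomic targets.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(detect_p_max = 0.01, detect_sample_frac = 0.95,
                          drop_non_cpg = TRUE, drop_snp_probes = TRUE,
                          drop_multi_target = TRUE) {
  stopifnot(detect_p_max > 0, detect_p_max < 1,
            detect_sample_frac > 0, detect_sample_frac <= 1)
  structure(list(detect_p_max = detect_p_max,
                 detect_sample_frac = detect_sample_frac,
                 drop_non_cpg = drop_non_cpg,
                 drop_snp_probes = drop_snp_probes,
                 drop_multi_target = drop_multi_target),
            class = "filter_params")
}

#' Detection p-values from negative-control probes
#'
#' The array chemistry gives no direct background model here, so detection is
#' scored against the negative-control probes: for probe n in sample s,
#' `p = 1 - ecdf_neg(meth_ns + unmeth_ns)` where `ecdf_neg` is the empirical
#' CDF of negative-control total intensities in that sample. A probe brighter
#' than every control gets p = 0; dimmer than every control, p = 1.
#'
#' @param raw An [intensity_set()].
#' @param manifest Manifest with >= 20 negative-control probes.
#' @return Matrix of detection p-values (probes x samples).
#' @export
detection_pvalues <- function(raw, manifest) {
  neg <- manifest$probe_id[manifest$is_negative_control]
  neg <- intersect(neg, raw$probes)
  if (length(neg) < 20L)
    stop("need >= 20 negative-control probes to estimate detection p-values; ",
         "supply a detect_p matrix from the scanner instead")
  total <- raw$meth + raw$unmeth
  dp <- matrix(NA_real_, length(raw$probes), length(raw$samples),
               dimnames = list(raw$probes, raw$samples))
  for (s in raw$samples) {
    bg <- total[neg, s]
    bg <- bg[!is.na(bg)]
    dp[, s] <- 1 - ecdf(bg)(total[, s])
  }
  dp
}

#' Filter probes
#'
#' Applies the standard probe filters in a fixed sequential order so the
#' per-criterion removal counts are well defined: (1) non-CpG probes
#' (negative controls, rs probes), (2) probes without detectable signal
#' (detected at `p <= detect_p_max` in fewer than `detect_sample_frac` of
#' samples; missing cells are excluded from the denominator, never imputed),
#' (3) multi-target probes, (4) SNP-adjacent probes.
#'
#' @param raw An [intensity_set()]. If it carries no `detect_p` matrix it is
#'   computed from negative controls via [detection_pvalues()].
#' @param manifest Manifest covering all probes in `raw`.
#' @param params A [filter_params()].
#' @return `list(data = filtered intensity_set, report = filter report)`.
#'   The report records `n_input`, ordered per-criterion removals, and
#'   `n_retained` (`n_input - sum(removed) = n_retained`).
#' @export
filter_probes <- function(raw, manifest, params = filter_params()) {
  man <- manifest[match(raw$probes, manifest$probe_id), , drop = FALSE]
  dp <- raw$detect_p
  if (is.null(dp)) dp <- detection_pvalues(raw, manifest)
  keep <- rep(TRUE, length(raw$probes))
  removed <- integer(0)

  if (params$drop_non_cpg) {
    drop <- keep & !man$is_cpg_target
    removed["non_cpg"] <- sum(drop)
    keep <- keep & !drop
  }
  detected <- dp <= params$detect_p_max
  n_obs <- rowSums(!is.na(detected))
  frac <- ifelse(n_obs > 0, rowSums(detected, na.rm = TRUE) / n_obs, 0)
  drop <- keep & frac < params$detect_sample_frac
  removed["detection"] <- sum(drop)
  keep <- keep & !drop
  if (params$drop_multi_target) {
    drop <- keep & man$multi_target
    removed["multi_target"] <- sum(drop)
    keep <- keep & !drop
  }
  if (params$drop_snp_probes) {
    drop <- keep & man$snp_within_10bp_maf05
    removed["snp_within_10bp"] <- sum(drop)
    keep <- keep & !drop
  }
  if (!any(keep))
    stop("all probes removed by filtering; check detection p-values and flags")

  out <- intensity_set(raw$meth[keep, , drop = FALSE],
                       raw$unmeth[keep, , drop = FALSE],
                       dp[keep, , drop = FALSE], raw$group)
  report <- list(n_input = length(keep), removed = removed,
                 n_retained = sum(keep))
  list(data = out, report = report)
}

#' Quantile-normalize channel intensities across samples
#'
#' Per sample, the methylated and unmethylated channels are pooled into one
#' intensity distribution and every sample's pooled distribution is mapped
#' onto the across-sample mean quantile function; ranks within a sample are
#' preserved and ties share the mean of their target quantiles. Pooling the
#' channels is deliberate: each probe contributes one high and one low
#' channel whichever way it is methylated, so the pooled distribution is
#' comparable across samples even when global methylation differs — whereas
#' normalizing the channels separately would squeeze a globally
#' hypomethylated sample's channel distributions onto the others' and leak
#' the global shift into every beta value.
#'
#' @param raw An [intensity_set()].
#' @return A quantile-normalized [intensity_set()].
#' @export
quantile_normalize <- function(raw) {
  if (length(raw$samples) < 2L) {
    warning("single sample: quantile normalization is the identity")
    return(raw)
  }
  stacked <- rbind(raw$meth, raw$unmeth)
  norm <- limma::normalizeQuantiles(stacked, ties = TRUE)
  n <- nrow(raw$meth)
  meth <- norm[seq_len(n), , drop = FALSE]
  unmeth <- norm[n + seq_len(n), , drop = FALSE]
  dimnames(meth) <- dimnames(unmeth) <- dimnames(raw$meth)
  intensity_set(meth, unmeth, raw$detect_p, raw$group)
}

#' Compute beta and M values
#'
#' `beta = meth / (meth + unmeth)`; `M = log2(beta / (1 - beta))` with beta
#' clamped to `[eps, 1 - eps]` before the logit so M stays finite
#' (|M| <= log2((1-eps)/eps), ~9.97 at the default eps = 1e-3). Cells where
#' both channels are zero (or missing) give a missing beta.
#'
#' @param ds An [intensity_set()].
#' @param eps Clamp width for the logit (default 1e-3, documented in `meta`).
#' @return A [methylation_set()].
#' @export
compute_beta_m <- function(ds, eps = 1e-3) {
  total <- ds$meth + ds$unmeth
  beta <- ifelse(!is.na(total) & total > 0, ds$meth / total, NA_real_)
  m <- beta_to_m(beta, eps)
  methylation_set(beta, m, ds$group,
                  meta = list(m_clamp_eps = eps))
}

#' Logit-transform beta to M with clamping
#' @param beta Beta values in \[0,1\] (vector or matrix).
#' @param eps Clamp width.
#' @return M values, same shape.
#' @export
beta_to_m <- function(beta, eps = 1e-3) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Correct type I / type II probe bias
#'
#' The two 450k probe chemistries yield systematically different beta
#' distributions. Per sample, type II beta values are monotonically mapped
#' onto that sample's type I beta distribution, stratified by methylation
#' state (type I values are untouched): values below 1/3 are quantile-mapped
#' onto the type I sub-distribution below 1/3, values above 2/3 onto the
#' type I sub-distribution above 2/3, and the sparse intermediate stratum is
#' carried by an affine bridge between the images of the two stratum
#' boundaries. Stratifying is essential on bimodal methylation data: a
#' single whole-distribution quantile (or rank) map is violently unstable
#' for intermediate betas, because tiny differences in the two types' mode
#' proportions throw mid-gap values across the methylation gap. Conditioning
#' on the stratum removes that dependence on mode proportions, the same
#' observation that motivates beta-mixture corrections. The map is
#' deterministic, weakly order-preserving within type II, and output stays
#' in \[0,1\]; the mode name is recorded in `meta$type_bias` so results are
#' never conflated with full mixture-model corrections. M-values are
#' recomputed from the corrected betas.
#'
#' @param meth A [methylation_set()].
#' @param manifest Manifest providing `design_type` per probe.
#' @param min_probes_per_type Samples with fewer probes of either type are
#'   left uncorrected, with a warning (default 50).
#' @return A corrected [methylation_set()].
#' @export
correct_type_bias <- function(meth, manifest, min_probes_per_type = 50L) {
  man <- manifest[match(meth$probes, manifest$probe_id), , drop = FALSE]
  ii <- man$design_type == "II"
  beta <- meth$beta
  # percentile-anchored monotone quantile map of one stratum onto another
  map_stratum <- function(x, from, to) {
    if (length(x) == 0) return(x)
    if (length(unique(from)) < 2L || length(unique(to)) < 2L) return(x)
    qs <- seq(0, 1, by = 0.02)
    stats::approx(quantile(from, qs, names = FALSE),
                  quantile(to, qs, names = FALSE),
                  xout = x, ties = mean, rule = 2)$y
  }
  lo_cut <- 1 / 3; hi_cut <- 2 / 3
  for (s in meth$samples) {
    b1 <- beta[!ii, s]; b2 <- beta[ii, s]
    ok1 <- !is.na(b1); ok2 <- !is.na(b2)
    if (sum(ok1) < min_probes_per_type || sum(ok2) < min_probes_per_type) {
      warning(sprintf("sample %s: < %d probes of one design type; ",
                      s, min_probes_per_type), "type-bias correction skipped")
      next
    }
    t1 <- b1[ok1]
    lo2 <- ok2 & b2 < lo_cut
    hi2 <- ok2 & b2 > hi_cut
    mid2 <- ok2 & !lo2 & !hi2
    t1_lo <- t1[t1 < lo_cut]; t1_hi <- t1[t1 > hi_cut]
    b2[lo2] <- map_stratum(b2[lo2], b2[lo2], t1_lo)
    b2[hi2] <- map_stratum(b2[hi2], b2[hi2], t1_hi)
    # affine bridge over the sparse mid stratum, continuous at the cuts
    l_img <- if (length(t1_lo) >= 2) max(t1_lo) else lo_cut
    h_img <- if (length(t1_hi) >= 2) min(t1_hi) else hi_cut
    b2[mid2] <- l_img + (b2[mid2] - lo_cut) / (hi_cut - lo_cut) *
      (h_img - l_img)
    beta[ii, s] <- pmin(1, pmax(0, b2))
  }
  eps <- if (!is.null(meth$meta$m_clamp_eps)) meth$meta$m_clamp_eps else 1e-3
  methylation_set(beta, beta_to_m(beta, eps), meth$group,
                  meta = c(meth$meta[setdiff(names(meth$meta), "type_bias")],
                           list(type_bias = "quantile-map-II-onto-I")))
}

#' Run the full preprocessing pipeline
#'
#' Fixed, logged order: filter -> quantile normalize -> beta -> type-bias
#' correct -> M.
#'
#' @param raw An [intensity_set()].
#' @param manifest Probe manifest.
#' @param params A [filter_params()].
#' @param type_bias `"quantile-map"` (default) or `"none"`.
#' @param eps Beta clamp for the logit.
#' @return `list(meth = methylation_set, filter_report = report)`.
#' @export
preprocess_pipeline <- function(raw, manifest, params = filter_params(),
                                type_bias = c("quantile-map", "none"),
                                eps = 1e-3) {
  type_bias <- match.arg(type_bias)
  flt <- filter_probes(raw, manifest, params)
  norm <- quantile_normalize(flt$data)
  meth <- compute_beta_m(norm, eps)
  if (type_bias == "quantile-map")
    meth <- correct_type_bias(meth, manifest)
  meth$meta$pipeline <- c("filter", "quantile_normalize", "beta",
                          if (type_bias == "quantile-map") "type_bias", "m")
  list(meth = meth, filter_report = flt$report)
}
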