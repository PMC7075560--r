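#' DMR-calling parameters
#'
#' Two published parameterizations are kept as explicit modes rather than
#' reconciled: `methods` mode calls a region a DMR at BH-adjusted p <= 0.05
#' with a median M-value difference >= 1.4; `results` mode uses BH p <= 0.01
#' with a minimum median methylation (beta) difference of 0.25.
#'
#' @param min_probes Minimum CpG probes per candidate region (default 4).
#' @param max_gap_bp Maximum gap between consecutive probes in a chain
#'   (default 200, inclusive).
#' @param min_median_m_diff Effect-size threshold on |median M difference|
#'   in methods mode (default 1.4).
#' @param min_median_beta_diff Effect-size threshold on |median beta
#'   difference| in results mode (default 0.25, i.e. 25%).
#' @param alpha BH-adjusted significance threshold (0.05 methods,
#'   0.01 results).
#' @param mode `"methods"` or `"results"`.
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(min_probes = 4L, max_gap_bp = 200L,
                       min_median_m_diff = 1.4, min_median_beta_diff = 0.25,
                       alpha = NULL, mode = c("methods", "results")) {
  mode <- match.arg(mode)
  if (is.null(alpha)) alpha <- if (mode == "methods") 0.05 else 0.01
  stopifnot(min_probes >= 2L, max_gap_bp > 0,
            min_median_m_diff > 0, min_median_beta_diff > 0,
            alpha > 0, alpha < 1)
  structure(list(min_probes = as.integer(min_probes),
                 max_gap_bp = as.integer(max_gap_bp),
                 min_median_m_diff = min_median_m_diff,
                 min_median_beta_diff = min_median_beta_diff,
                 alpha = alpha, mode = mode),
            class = "dmr_params")
}

#' Find CpG-dense candidate regions by greedy chaining
#'
#' Per chromosome, a probe extends the current chain iff its position is
#' within `max_gap_bp` (inclusive) of the previous probe; chains with at
#' least `min_probes` members become candidate regions. Chains never span
#' chromosomes. Negative-control probes are ignored. The result is invariant
#' to input probe order (probes are sorted internally by chrom, pos,
#' probe_id).
#'
#' @param manifest Filtered probe manifest (rows define the testable probes).
#' @param params A [dmr_params()].
#' @return `data.frame(chrom, start, end, n_probes)` with a list-column
#'   `probe_ids`; `start`/`end` span the first to last member probe
#'   (1-based inclusive).
#' @export
find_candidate_regions <- function(manifest, params = dmr_params()) {
  man <- manifest[!manifest$is_negative_control, , drop = FALSE]
  ord <- order(match(man$chrom, c(ALLOWED_CHROMS, "Y")), man$pos, man$probe_id)
  if (!identical(ord, seq_len(nrow(man)))) {
    man <- man[ord, , drop = FALSE]
  }
  regions <- list()
  for (ch in unique(man$chrom)) {
    sub <- man[man$chrom == ch, , drop = FALSE]
    gap <- diff(sub$pos)
    # new chain starts where the gap to the previous probe exceeds max_gap_bp
    chain_id <- cumsum(c(1L, as.integer(gap > params$max_gap_bp)))
    for (id in unique(chain_id)) {
      idx <- which(chain_id == id)
      if (length(idx) < params$min_probes) next
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = sub$pos[idx[1L]], end = sub$pos[idx[length(idx)]],
        n_probes = length(idx),
        probe_ids = I(list(sub$probe_id[idx])), stringsAsFactors = FALSE)
    }
  }
  if (length(regions) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      probe_ids = I(list())))
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney test of one region between two groups
#'
#' The two test populations are the pooled per-probe-per-sample M-values of
#' the region's probes in each group (n_probes x n_samples values per side).
#' The p-value is the exact two-sided Mann-Whitney probability when the
#' combined sample size is <= 30 and tie-free, otherwise the normal
#' approximation with tie and continuity correction. The U statistic and the
#' sign of the median differences are oriented as group_a minus group_b
#' (U = number of (a, b) pairs with a > b, counting ties as 1/2).
#'
#' @param meth A [methylation_set()].
#' @param probe_ids Probe ids of the region's members.
#' @param group_a,group_b Group labels.
#' @return `list(u_statistic, p_raw, median_m_a, median_m_b, delta_median_m,
#'   median_beta_a, median_beta_b, delta_median_beta, n_a, n_b, testable)`.
#'   A side with no non-missing values marks the region untestable
#'   (`p_raw = NA`); such regions are excluded from the BH family.
#' @export
test_region <- function(meth, probe_ids, group_a, group_b) {
  rows <- match(probe_ids, meth$probes)
  rows <- rows[!is.na(rows)]
  sa <- meth$samples[meth$group == group_a]
  sb <- meth$samples[meth$group == group_b]
  if (length(sa) == 0 || length(sb) == 0)
    stop("both groups must have samples")
  ma <- as.vector(meth$m[rows, sa, drop = FALSE])
  mb <- as.vector(meth$m[rows, sb, drop = FALSE])
  ba <- as.vector(meth$beta[rows, sa, drop = FALSE])
  bb <- as.vector(meth$beta[rows, sb, drop = FALSE])
  ma <- ma[!is.na(ma)]; mb <- mb[!is.na(mb)]
  res <- list(u_statistic = NA_real_, p_raw = NA_real_,
              median_m_a = median(ma), median_m_b = median(mb),
              delta_median_m = median(ma) - median(mb),
              median_beta_a = median(ba, na.rm = TRUE),
              median_beta_b = median(bb, na.rm = TRUE),
              n_a = length(ma), n_b = length(mb), testable = FALSE)
  res$delta_median_beta <- res$median_beta_a - res$median_beta_b
  if (length(ma) == 0 || length(mb) == 0) return(res)
  res$testable <- TRUE
  ties <- anyDuplicated(c(ma, mb)) > 0L
  if (length(ma) == sum(ma == ma[1]) && length(mb) == sum(mb == ma[1])) {
    # every value identical: no evidence either way, degenerate variance
    res$u_statistic <- length(ma) * length(mb) / 2
    res$p_raw <- 1
    return(res)
  }
  exact <- (length(ma) + length(mb) <= 30L) && !ties
  wt <- suppressWarnings(
    wilcox.test(ma, mb, exact = exact, correct = TRUE, conf.int = FALSE))
  res$u_statistic <- unname(wt$statistic)
  res$p_raw <- min(1, wt$p.value)
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment: with p sorted ascending,
#' `p_adj(i) = min over j >= i of m * p(j) / j`, capped at 1; input order is
#' restored on return.
#'
#' @param p Vector of p-values in \[0,1\].
#' @return Adjusted p-values, same order.
#' @export
adjust_bh <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Call differentially methylated regions between two groups
#'
#' Pipeline: chain candidate regions on the filtered manifest, Mann-Whitney
#' test each region's pooled M-values, BH-adjust over all testable regions,
#' then flag DMRs by the mode-specific thresholds (`methods`: adjusted
#' p <= alpha and |median M difference| >= 1.4; `results`: adjusted
#' p <= alpha and |median beta difference| >= 0.25). Records are sorted by
#' adjusted p then decreasing |effect|.
#'
#' @param meth A [methylation_set()] (post-preprocessing).
#' @param manifest Manifest covering the dataset's probes.
#' @param group_a,group_b Group labels to compare (effect sign is a - b).
#' @param params A [dmr_params()].
#' @return `data.frame` of region records: coordinates, member probes,
#'   group medians on both scales, `u_statistic`, `p_raw`, `p_adj`,
#'   `is_dmr`. Untestable regions carry `NA` p-values and `is_dmr = FALSE`.
#' @export
call_dmrs <- function(meth, manifest, group_a, group_b,
                      params = dmr_params()) {
  man <- manifest[manifest$probe_id %in% meth$probes, , drop = FALSE]
  regions <- find_candidate_regions(man, params)
  if (nrow(regions) == 0) {
    regions$group_a <- character(0); regions$group_b <- character(0)
    regions$median_m_a <- regions$median_m_b <- regions$delta_median_m <-
      regions$median_beta_a <- regions$median_beta_b <-
      regions$delta_median_beta <- regions$u_statistic <-
      regions$p_raw <- regions$p_adj <- numeric(0)
    regions$is_dmr <- logical(0)
    return(regions)
  }
  tests <- lapply(regions$probe_ids, test_region, meth = meth,
                  group_a = group_a, group_b = group_b)
  pick <- function(f) vapply(tests, `[[`, numeric(1), f)
  regions$group_a <- group_a
  regions$group_b <- group_b
  regions$median_m_a <- pick("median_m_a")
  regions$median_m_b <- pick("median_m_b")
  regions$delta_median_m <- pick("delta_median_m")
  regions$median_beta_a <- pick("median_beta_a")
  regions$median_beta_b <- pick("median_beta_b")
  regions$delta_median_beta <- pick("delta_median_beta")
  regions$u_statistic <- pick("u_statistic")
  regions$p_raw <- pick("p_raw")
  testable <- vapply(tests, `[[`, logical(1), "testable")
  regions$p_adj <- NA_real_
  regions$p_adj[testable] <- adjust_bh(regions$p_raw[testable])
  effect_ok <- if (params$mode == "methods")
    abs(regions$delta_median_m) >= params$min_median_m_diff
  else
    abs(regions$delta_median_beta) >= params$min_median_beta_diff
  regions$is_dmr <- testable & !is.na(regions$p_adj) &
    regions$p_adj <= params$alpha & effect_ok
  effect <- if (params$mode == "methods") regions$delta_median_m
            else regions$delta_median_beta
  ord <- order(regions$p_adj, -abs(effect), na.last = TRUE)
  out <- regions[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- params
  attr(out, "effect_scale") <- if (params$mode == "methods") "M" else "beta"
  out
}
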