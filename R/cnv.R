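#' Five-state copy-number thresholds
#'
#' Published log2-ratio cutoffs: homozygous deletions <= -0.96,
#' hemizygous/mosaic deletions <= -0.24, neutral between -0.24 and 0.12
#' (both exclusive), duplications >= +0.12, high-copy gains >= +0.72.
#'
#' @param homozygous_del_max,hemizygous_del_max,duplication_min,high_gain_min
#'   State cutoffs on the log2-ratio scale.
#' @return A list of class `cnv_thresholds`.
#' @export
cnv_thresholds <- function(homozygous_del_max = -0.96,
                           hemizygous_del_max = -0.24,
                           duplication_min = 0.12,
                           high_gain_min = 0.72) {
  stopifnot(homozygous_del_max < hemizygous_del_max,
            hemizygous_del_max < duplication_min,
            duplication_min < high_gain_min)
  structure(list(homozygous_del_max = homozygous_del_max,
                 hemizygous_del_max = hemizygous_del_max,
                 neutral_low = hemizygous_del_max,
                 neutral_high = duplication_min,
                 duplication_min = duplication_min,
                 high_gain_min = high_gain_min),
            class = "cnv_thresholds")
}

CNV_STATES <- c("hom_del", "hemi_del", "neutral", "dup", "high_gain")

#' Classify log2 ratios into the five copy-number states
#'
#' Total on finite input: every ratio maps to exactly one state, with the
#' published inclusive/exclusive boundaries (-0.96 and -0.24 belong to the
#' deletion states; 0.12 and 0.72 to the gain states).
#'
#' @param log2_ratio Numeric vector.
#' @param thresholds A [cnv_thresholds()].
#' @return Character vector of states.
#' @export
classify_cnv_state <- function(log2_ratio, thresholds = cnv_thresholds()) {
  th <- thresholds
  ifelse(is.na(log2_ratio), NA_character_,
  ifelse(log2_ratio <= th$homozygous_del_max, "hom_del",
  ifelse(log2_ratio <= th$hemizygous_del_max, "hemi_del",
  ifelse(log2_ratio >= th$high_gain_min, "high_gain",
  ifelse(log2_ratio >= th$duplication_min, "dup", "neutral")))))
}

#' Total probe fluorescence per sample
#'
#' Copy number scales total fluorescence, so the CNV track works on the
#' per-probe total of the unmethylated and methylated signals, floored at
#' `floor` a.u. so homozygous deletions stay finite on the log2 scale.
#'
#' @param raw An [intensity_set()] (pre-beta, raw or normalized).
#' @param floor Minimum total (default 1 a.u.).
#' @return Matrix of totals (probes x samples).
#' @export
probe_totals <- function(raw, floor = 1) {
  pmax(raw$meth + raw$unmeth, floor)
}

#' Divide probes into chromosomal bins
#'
#' Equal-probe-count bins per chromosome (consecutive runs of
#' `probes_per_bin` manifest-ordered probes; a remainder shorter than a full
#' bin is merged into the last bin, so every bin has >= `probes_per_bin`
#' probes on chromosomes with at least one full bin). Bin span runs from the
#' first to the last member probe. Autosomes plus X only; negative controls
#' are excluded. A chromosome with fewer than `min_probes_per_bin` probes
#' yields a single undersized bin flagged `undersized`.
#'
#' @param manifest Probe manifest.
#' @param probes_per_bin Target probes per bin (default 50).
#' @param min_probes_per_bin Flagging threshold for undersized bins
#'   (default 10).
#' @return `data.frame(bin_id, chrom, start, end, n_probes, undersized)`
#'   with list-column `probe_ids`; bins are non-overlapping and ordered
#'   within each chromosome.
#' @export
build_bins <- function(manifest, probes_per_bin = 50L,
                       min_probes_per_bin = 10L) {
  man <- manifest[!manifest$is_negative_control &
                    manifest$chrom %in% ALLOWED_CHROMS, , drop = FALSE]
  man <- sort_manifest(man)
  bins <- list()
  for (ch in unique(man$chrom)) {
    sub <- man[man$chrom == ch, , drop = FALSE]
    n <- nrow(sub)
    n_full <- n %/% probes_per_bin
    if (n_full == 0L) {
      starts <- 1L; ends <- n
    } else {
      starts <- seq(1L, by = probes_per_bin, length.out = n_full)
      ends <- c(starts[-1L] - 1L, n)  # remainder merged into the last bin
    }
    for (k in seq_along(starts)) {
      idx <- starts[k]:ends[k]
      bins[[length(bins) + 1L]] <- data.frame(
        chrom = ch, start = sub$pos[idx[1L]], end = sub$pos[idx[length(idx)]],
        n_probes = length(idx), undersized = length(idx) < min_probes_per_bin,
        probe_ids = I(list(sub$probe_id[idx])), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, bins)
  out <- cbind(bin_id = sprintf("bin_%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# per-sample library scaling: subtract each sample's median log2 total
scaled_log2_totals <- function(totals) {
  lt <- log2(totals)
  sweep(lt, 2L, apply(lt, 2L, median, na.rm = TRUE))
}

bin_medians <- function(scaled_lt, bins) {
  m <- vapply(seq_len(nrow(bins)), function(i) {
    rows <- match(bins$probe_ids[[i]], rownames(scaled_lt))
    apply(scaled_lt[rows, , drop = FALSE], 2L, median, na.rm = TRUE)
  }, numeric(ncol(scaled_lt)))
  if (is.null(dim(m))) m <- rbind(m)
  t(m)
}

#' Copy-stable control baseline
#'
#' Defines the stable-copy reference from a cohort of copy-stable (female)
#' control samples. Per sample, log2 totals are median-centred (library-size
#' scaling); then every probe is centred on its median across the control
#' cohort. Probe centring matters because per-probe affinity spans orders of
#' magnitude on these arrays and, unlike a mean, the bin median does not
#' cancel it between a sample and the controls — without it the affinity
#' spread leaks into every bin ratio. On the centred values, the baseline is
#' the per-bin median and MAD of the per-control-sample bin medians. Bins
#' where all controls agree exactly (MAD 0) are flagged so the `mad_floor`
#' applies.
#'
#' @param controls An [intensity_set()] of >= 3 control samples.
#' @param bins Bin table from [build_bins()].
#' @param floor Intensity floor passed to [probe_totals()].
#' @return `data.frame(bin_id, baseline_median, baseline_mad, degenerate)`
#'   carrying the per-probe control reference as attribute `"probe_ref"`.
#' @export
control_baseline <- function(controls, bins, floor = 1) {
  if (length(controls$samples) < 3L)
    stop("need >= 3 control samples: baseline dispersion is undefined")
  slt <- scaled_log2_totals(probe_totals(controls, floor))
  probe_ref <- apply(slt, 1L, median, na.rm = TRUE)
  slt <- sweep(slt, 1L, probe_ref)
  bm <- bin_medians(slt, bins)   # bins x control samples
  out <- data.frame(bin_id = bins$bin_id,
                    baseline_median = apply(bm, 1L, median, na.rm = TRUE),
                    baseline_mad = apply(bm, 1L, mad, na.rm = TRUE),
                    degenerate = apply(bm, 1L, mad, na.rm = TRUE) == 0)
  attr(out, "probe_ref") <- probe_ref
  out
}

#' Copy-number profile of one sample
#'
#' The sample's log2 totals are median-centred exactly as the controls were
#' and each probe is centred on the control cohort's per-probe reference;
#' per bin, `log2_ratio` = median over bin probes minus the baseline median.
#' A bin is `significant` when |log2_ratio| exceeds
#' `k * max(baseline MAD, mad_floor)` (robust z against the control
#' dispersion). For male samples, chrX ratios are shifted by +1 before
#' thresholding, since the female baseline carries two X copies. State
#' follows [classify_cnv_state()]; `gain_loss` is +1 for a significant gain
#' state, -1 for a significant deletion state, else 0.
#'
#' @param raw An [intensity_set()] containing the sample.
#' @param sample Sample label.
#' @param baseline From [control_baseline()].
#' @param bins From [build_bins()] (same table the baseline used).
#' @param thresholds A [cnv_thresholds()].
#' @param sex `"female"`, `"male"`, or `"unknown"` (chrX calls suppressed
#'   with a warning).
#' @param k Robust-z multiplier (default 3).
#' @param mad_floor Minimum dispersion on the log2 scale (default 0.05).
#' @param floor Intensity floor.
#' @return `data.frame` of class `cnv_profile`: bin coordinates,
#'   `log2_ratio`, `significant`, `state`, `gain_loss`.
#' @export
sample_profile <- function(raw, sample, baseline, bins,
                           thresholds = cnv_thresholds(),
                           sex = c("female", "male", "unknown"),
                           k = 3, mad_floor = 0.05, floor = 1) {
  sex <- match.arg(sex)
  if (!sample %in% raw$samples) stop("sample not in dataset: ", sample)
  if (!identical(baseline$bin_id, bins$bin_id))
    stop("integrity error: baseline and bin table do not match")
  slt <- scaled_log2_totals(probe_totals(raw, floor))[, sample, drop = FALSE]
  probe_ref <- attr(baseline, "probe_ref")
  if (is.null(probe_ref) || !identical(names(probe_ref), rownames(slt)))
    stop("integrity error: baseline probe reference does not match the sample")
  slt <- sweep(slt, 1L, probe_ref)
  bm <- bin_medians(slt, bins)[, 1L]
  ratio <- bm - baseline$baseline_median
  on_x <- bins$chrom == "X"
  if (sex == "male") ratio[on_x] <- ratio[on_x] + 1
  sig <- abs(ratio) > k * pmax(baseline$baseline_mad, mad_floor)
  if (sex == "unknown" && any(on_x)) {
    warning("sex unspecified: chrX calls suppressed")
    sig[on_x] <- FALSE
  }
  state <- classify_cnv_state(ratio, thresholds)
  gain_loss <- ifelse(sig & state %in% c("dup", "high_gain"), 1L,
                      ifelse(sig & state %in% c("hom_del", "hemi_del"), -1L, 0L))
  out <- data.frame(sample = sample, bin_id = bins$bin_id, chrom = bins$chrom,
                    start = bins$start, end = bins$end,
                    n_probes = bins$n_probes, log2_ratio = ratio,
                    significant = sig, state = state, gain_loss = gain_loss,
                    stringsAsFactors = FALSE)
  class(out) <- c("cnv_profile", class(out))
  out
}

#' Aggregate copy-number calls over a sample group
#'
#' Per bin: mean of member log2 ratios and the majority `gain_loss` call
#' (ties, including 0-vs-nonzero splits with no majority, resolve to 0).
#'
#' @param profiles List of [sample_profile()] outputs sharing one bin table.
#' @param group Label recorded in the output.
#' @return `data.frame(group, bin_id, chrom, start, end, n_samples,
#'   mean_log2_ratio, gain_loss)`.
#' @export
cohort_summary <- function(profiles, group = "group") {
  if (length(profiles) < 1L) stop("need >= 1 profile")
  ids <- lapply(profiles, `[[`, "bin_id")
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]])))
    stop("integrity error: profiles use different bin definitions")
  ratios <- sapply(profiles, `[[`, "log2_ratio")
  calls <- sapply(profiles, `[[`, "gain_loss")
  if (is.null(dim(ratios))) { ratios <- cbind(ratios); calls <- cbind(calls) }
  majority <- apply(calls, 1L, function(v) {
    tb <- table(factor(v, levels = c(-1L, 0L, 1L)))
    top <- names(tb)[tb == max(tb)]
    if (length(top) > 1L) 0L else as.integer(top)
  })
  b <- profiles[[1]]
  data.frame(group = group, bin_id = b$bin_id, chrom = b$chrom,
             start = b$start, end = b$end, n_samples = length(profiles),
             mean_log2_ratio = rowMeans(ratios), gain_loss = majority,
             stringsAsFactors = FALSE)
}

#' Export a CNV profile as SEG rows
#' @param profile A [sample_profile()] result.
#' @param path Output path.
#' @export
write_cnv_seg <- function(profile, path) {
  seg <- data.frame(sample = profile$sample, chrom = profile$chrom,
                    start = profile$start, end = profile$end,
                    n_bins = profile$n_probes,
                    log2_ratio = profile$log2_ratio, state = profile$state,
                    stringsAsFactors = FALSE)
  write_seg(seg, path)
}
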