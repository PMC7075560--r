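#' Fit amplification efficiency from the window of linearity
#'
#' Window-of-linearity efficiency estimation: among candidate windows of
#' `window_len` contiguous cycles inside the exponential phase (fluorescence
#' above the noise floor and below half the plateau), pick the window
#' maximizing the r-squared of `log2(fluorescence) ~ cycle`; the per-cycle
#' amplification efficiency is `2^slope`. The noise floor is
#' `mean + 3 * sd` of the first five cycles; on short fixtures whose
#' exponential phase starts immediately this floor can exceed every eligible
#' cycle, in which case all positive cycles below half-plateau are used
#' instead.
#'
#' @param curve One reaction's `data.frame(cycle, fluorescence)` (rows
#'   ordered by cycle; >= 10 cycles).
#' @param window_len Candidate window lengths in cycles (default 4:6).
#' @param min_r2 Below this window r-squared the fit is flagged low-quality
#'   (default 0.99); the efficiency is still reported.
#' @return `list(efficiency, window = c(first, last cycle), r2,
#'   low_quality)`. Efficiencies outside (1, 2.1\] are flagged. A curve with
#'   no usable rising phase returns `efficiency = NA` with `low_quality =
#'   TRUE`.
#' @export
fit_efficiency <- function(curve, window_len = 4:6, min_r2 = 0.99) {
  f <- curve$fluorescence
  cyc <- curve$cycle
  if (length(f) < 10L) stop("need >= 10 cycles")
  noise_floor <- mean(f[1:5]) + 3 * sd(f[1:5])
  half_plateau <- max(f) / 2
  eligible <- which(f > noise_floor & f <= half_plateau & f > 0)
  if (length(eligible) < min(window_len))
    eligible <- which(f > 0 & f <= half_plateau)
  bad <- list(efficiency = NA_real_, window = c(NA_integer_, NA_integer_),
              r2 = NA_real_, low_quality = TRUE)
  if (length(eligible) < 2L) return(bad)
  best <- NULL
  for (len in window_len) {
    if (length(eligible) < len) next
    for (s in seq_len(length(eligible) - len + 1L)) {
      idx <- eligible[s:(s + len - 1L)]
      if (idx[len] - idx[1L] != len - 1L) next  # must be contiguous cycles
      fit <- lm(log2(f[idx]) ~ cyc[idx])
      # a noiseless geometric curve fits exactly; that is expected, not a
      # numerical problem, so the perfect-fit warning is silenced
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (is.null(best) || isTRUE(r2 > best$r2))
        best <- list(slope = coef(fit)[[2]], r2 = r2,
                     window = c(cyc[idx[1L]], cyc[idx[len]]))
    }
  }
  if (is.null(best)) {  # no contiguous window: fall back to any 2+ cycles
    idx <- eligible
    fit <- lm(log2(f[idx]) ~ cyc[idx])
    best <- list(slope = coef(fit)[[2]],
                 r2 = if (length(idx) > 2)
                   suppressWarnings(summary(fit)$r.squared) else 1,
                 window = c(cyc[idx[1L]], cyc[length(idx)]))
  }
  eff <- 2^best$slope
  list(efficiency = eff, window = best$window, r2 = best$r2,
       low_quality = !isTRUE(best$r2 >= min_r2) || eff <= 1 || eff > 2.1)
}

#' Estimate starting quantity N0
#'
#' Inverts the exponential model at a fluorescence threshold: the
#' quantification cycle Cq is the fractional cycle where fluorescence
#' crosses `f_threshold` (log-linear interpolation between the bracketing
#' cycles), and `n0 = f_threshold / efficiency^Cq`. Within the exponential
#' window the estimate is invariant to the threshold choice.
#'
#' @param curve One reaction's `data.frame(cycle, fluorescence)`.
#' @param efficiency Fold-per-cycle efficiency from [fit_efficiency()].
#' @param f_threshold Fluorescence threshold; defaults to the geometric mean
#'   of the fitted-window endpoints' fluorescence when a `window` is given.
#' @param window Optional `c(first, last)` cycles of the fitted window, used
#'   only for the default threshold.
#' @return `list(n0, cq, undetected)`; a curve never reaching the threshold
#'   returns `n0 = 0` with `undetected = TRUE`.
#' @export
estimate_n0 <- function(curve, efficiency, f_threshold = NULL, window = NULL) {
  f <- curve$fluorescence
  cyc <- curve$cycle
  if (is.null(f_threshold)) {
    if (is.null(window) || any(is.na(window)))
      stop("supply f_threshold or a fitted window")
    ends <- f[match(window, cyc)]
    f_threshold <- sqrt(prod(ends))
  }
  if (max(f) < f_threshold)
    return(list(n0 = 0, cq = NA_real_, undetected = TRUE))
  i <- which(f >= f_threshold)[1L]
  if (i == 1L) {
    cq <- cyc[1L]
  } else {
    lf0 <- log2(max(f[i - 1L], .Machine$double.eps))
    lf1 <- log2(f[i])
    cq <- cyc[i - 1L] + (cyc[i] - cyc[i - 1L]) * (log2(f_threshold) - lf0) /
      (lf1 - lf0)
  }
  list(n0 = f_threshold / efficiency^cq, cq = cq, undetected = FALSE)
}

#' Quantify a set of amplification curves
#'
#' Per reaction: fit the efficiency window, estimate N0 at the default
#' threshold, and return one row per reaction plus per-(target, sample)
#' replicate means.
#'
#' @param curves Long `data.frame(reaction_id, target, sample, replicate,
#'   cycle, fluorescence)` as produced by [simulate_qpcr_curves()].
#' @param window_len Passed to [fit_efficiency()].
#' @return `data.frame(reaction_id, target, sample, replicate, efficiency,
#'   window_first, window_last, r2, low_quality, cq, n0, undetected)`.
#' @export
quantify_curves <- function(curves, window_len = 4:6) {
  out <- lapply(split(curves, curves$reaction_id), function(rx) {
    rx <- rx[order(rx$cycle), , drop = FALSE]
    ef <- fit_efficiency(rx, window_len = window_len)
    n0 <- if (is.na(ef$efficiency))
      list(n0 = NA_real_, cq = NA_real_, undetected = TRUE)
    else estimate_n0(rx, ef$efficiency, window = ef$window)
    data.frame(reaction_id = rx$reaction_id[1L], target = rx$target[1L],
               sample = rx$sample[1L], replicate = rx$replicate[1L],
               efficiency = ef$efficiency, window_first = ef$window[1L],
               window_last = ef$window[2L], r2 = ef$r2,
               low_quality = ef$low_quality, cq = n0$cq, n0 = n0$n0,
               undetected = n0$undetected, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalize target expression to two reference genes
#'
#' Replicate N0 values are averaged per reaction set first (mean over
#' triplicates), then the target mean is divided by the geometric mean of
#' the two reference-gene means. The arithmetic-mean combination of
#' references is available as an option.
#'
#' @param n0_target Numeric vector of target-gene replicate N0 values.
#' @param n0_refs List of two numeric vectors, one per reference gene.
#' @param ref_combine `"geometric"` (default) or `"arithmetic"`.
#' @return `list(normalized, flagged)`; `flagged` is `TRUE` (and
#'   `normalized` `NA`) when any reference is undetected (mean N0 <= 0).
#' @export
normalize_expression <- function(n0_target, n0_refs,
                                 ref_combine = c("geometric", "arithmetic")) {
  ref_combine <- match.arg(ref_combine)
  if (length(n0_refs) != 2L) stop("exactly two reference genes expected")
  t_mean <- mean(n0_target, na.rm = TRUE)
  r_means <- vapply(n0_refs, mean, numeric(1), na.rm = TRUE)
  if (any(!is.finite(r_means)) || any(r_means <= 0))
    return(list(normalized = NA_real_, flagged = TRUE))
  denom <- if (ref_combine == "geometric") sqrt(prod(r_means))
           else mean(r_means)
  list(normalized = t_mean / denom, flagged = FALSE)
}
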