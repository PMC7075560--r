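BETA_BIN_BREAKS <- seq(0, 1, by = 0.1)

beta_histogram <- function(beta) {
  beta <- beta[!is.na(beta)]
  # bins [0,0.1), ..., [0.9,1.0]; the last bin is closed at 1.0
  idx <- pmin(findInterval(beta, BETA_BIN_BREAKS), 10L)
  counts <- tabulate(idx, nbins = 10L)
  data.frame(bin_low = BETA_BIN_BREAKS[1:10], bin_high = BETA_BIN_BREAKS[2:11],
             count = counts)
}

#' Global beta-value distribution for one sample group
#'
#' Pools the beta values of all samples in the group and bins them into ten
#' width-0.1 bins covering \[0,1\] as \[0,0.1), ..., \[0.9,1.0\]. Normal
#' cells show a bimodal profile (most mass in the two extreme bins);
#' globally hypomethylated tumors shift mass out of the top bin.
#'
#' @param meth A [methylation_set()].
#' @param group Group label present in the dataset.
#' @return `data.frame(class, group, bin_low, bin_high, count)` with
#'   attributes `n_values` (histogram total) and `median_beta`.
#' @export
global_distribution <- function(meth, group) {
  sel <- meth$samples[meth$group == group]
  if (length(sel) == 0) stop("no samples in group '", group, "'")
  pooled <- as.vector(meth$beta[, sel, drop = FALSE])
  h <- beta_histogram(pooled)
  out <- cbind(data.frame(class = "global", group = group), h)
  attr(out, "n_values") <- sum(h$count)
  attr(out, "median_beta") <- median(pooled, na.rm = TRUE)
  out
}

#' Per-genomic-class beta distributions
#'
#' One histogram per (class, group). A probe contributes to every class it
#' belongs to, so summed class counts exceed the probe count whenever
#' memberships overlap. The default class vocabulary is the nine coarse
#' classes (TSS, 5'UTR, gene body, 3'UTR, LINE, SINE, LTR, CGI, enhancer);
#' manifests using the finer TSS1500/TSS200 labels are folded into `TSS`
#' when `collapse_tss` is set.
#'
#' @param meth A [methylation_set()].
#' @param manifest Probe manifest.
#' @param classes Class labels to profile (default: all present).
#' @param groups Groups to profile (default: all).
#' @param collapse_tss Fold TSS1500/TSS200 into TSS (default TRUE).
#' @return Tidy `data.frame(class, group, bin_low, bin_high, count)` plus a
#'   `"summary"` attribute `data.frame(class, group, n_probes, median_beta)`.
#' @export
class_distributions <- function(meth, manifest, classes = NULL,
                                groups = NULL, collapse_tss = TRUE) {
  man <- manifest[match(meth$probes, manifest$probe_id), , drop = FALSE]
  memb <- class_membership(man, collapse_tss = collapse_tss)
  if (is.null(classes)) classes <- colnames(memb)
  unknown <- setdiff(classes, colnames(memb))
  if (length(unknown) > 0)
    stop("unknown class name(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(colnames(memb), collapse = ", "))
  if (is.null(groups)) groups <- unique(unname(meth$group))

  rows <- list(); summ <- list()
  for (cls in classes) {
    probes_in <- memb[, cls]
    for (g in groups) {
      sel <- meth$samples[meth$group == g]
      pooled <- as.vector(meth$beta[probes_in, sel, drop = FALSE])
      h <- beta_histogram(pooled)
      rows[[paste(cls, g)]] <- cbind(data.frame(class = cls, group = g), h)
      summ[[paste(cls, g)]] <- data.frame(
        class = cls, group = g, n_probes = sum(probes_in),
        median_beta = if (sum(probes_in) > 0) median(pooled, na.rm = TRUE)
                      else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- {
    s <- do.call(rbind, summ); rownames(s) <- NULL; s
  }
  out
}
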