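#' @keywords internal
"_PACKAGE"

#' @importFrom stats ecdf mad median prcomp quantile rbeta rbinom rlnorm rnorm
#'   runif sd setNames wilcox.test p.adjust phyper hclust dist cutree
#'   cophenetic lm coef var aggregate ks.test
#' @importFrom utils read.delim write.table head
NULL

ALLOWED_CHROMS <- c(as.character(1:22), "X")
CLASS_VOCAB <- c("TSS", "5UTR", "gene_body", "3UTR",
                 "LINE", "SINE", "LTR", "CGI", "enhancer")

MANIFEST_COLS <- c("probe_id", "chrom", "pos", "design_type", "is_cpg_target",
                   "classes", "gene_symbol", "snp_within_10bp_maf05",
                   "multi_target", "is_negative_control")

#' Read a probe manifest
#'
#' Loads the tab-separated probe annotation table (one row per probe) used by
#' every pipeline stage. Coordinates are 1-based genome positions; the
#' `classes` column holds a semicolon-separated set of genomic-class labels
#' (empty for intergenic or control probes).
#'
#' @param path Path to a tab-separated manifest with a header row naming all
#'   required columns (order irrelevant): `probe_id`, `chrom`, `pos`,
#'   `design_type` (`I`/`II`), `is_cpg_target`, `classes`, `gene_symbol`,
#'   `snp_within_10bp_maf05`, `multi_target`, `is_negative_control`.
#' @param allow_chrY Chromosome Y probes are rejected by default (the CNV
#'   scheme covers autosomes plus X only); set `TRUE` to accept them.
#' @return A `data.frame` of probe annotations, sorted by (chrom, pos,
#'   probe_id).
#' @export
read_manifest <- function(path, allow_chrY = FALSE) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(MANIFEST_COLS, names(tab))
  if (length(missing) > 0)
    stop("manifest format error: missing required column(s): ",
         paste(missing, collapse = ", "))
  tab <- tab[, MANIFEST_COLS]
  tab$pos <- as.integer(tab$pos)
  for (fl in c("is_cpg_target", "snp_within_10bp_maf05", "multi_target",
               "is_negative_control"))
    tab[[fl]] <- as.logical(tab[[fl]])
  tab$chrom <- sub("^chr", "", tab$chrom)
  validate_manifest(tab, allow_chrY = allow_chrY)
  sort_manifest(tab)
}

validate_manifest <- function(man, allow_chrY = FALSE) {
  allowed <- if (allow_chrY) c(ALLOWED_CHROMS, "Y") else ALLOWED_CHROMS
  bad <- setdiff(unique(man$chrom), allowed)
  if (length(bad) > 0)
    stop("manifest integrity error: unknown chromosome(s): ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(man$probe_id))
    stop("manifest integrity error: duplicate probe_id(s): ",
         paste(unique(man$probe_id[duplicated(man$probe_id)]), collapse = ", "))
  if (any(is.na(man$pos)) || any(man$pos < 1L))
    stop("manifest integrity error: positions must be integers >= 1")
  if (!all(man$design_type %in% c("I", "II")))
    stop("manifest format error: design_type must be 'I' or 'II'")
  negs <- man$is_negative_control
  if (any(negs & (man$is_cpg_target | nzchar(man$classes))))
    stop("manifest integrity error: negative-control probes must not be CpG ",
         "targets and must carry no genomic classes")
  invisible(man)
}

sort_manifest <- function(man) {
  ord <- order(match(man$chrom, c(ALLOWED_CHROMS, "Y")), man$pos, man$probe_id)
  man <- man[ord, , drop = FALSE]
  rownames(man) <- NULL
  man
}

#' Write a probe manifest
#' @param man Manifest `data.frame` as returned by [read_manifest()].
#' @param path Output path (tab-separated, with header).
#' @export
write_manifest <- function(man, path) {
  write.table(man[, MANIFEST_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Split the `classes` column into a probe-by-class logical matrix
#' @param man Manifest `data.frame`.
#' @param collapse_tss If the manifest uses the finer TSS1500/TSS200 labels,
#'   fold them into a single `TSS` class.
#' @return Logical matrix, rows = probes (manifest order), columns = class
#'   labels present in the manifest.
#' @export
class_membership <- function(man, collapse_tss = TRUE) {
  lst <- strsplit(man$classes, ";", fixed = TRUE)
  if (collapse_tss)
    lst <- lapply(lst, function(x) unique(sub("^TSS1500$|^TSS200$", "TSS", x)))
  labs <- sort(unique(unlist(lst)))
  mat <- matrix(FALSE, nrow(man), length(labs),
                dimnames = list(man$probe_id, labs))
  for (j in seq_along(labs))
    mat[, j] <- vapply(lst, function(x) labs[j] %in% x, logical(1))
  mat
}

#' Construct an intensity dataset
#'
#' The container for raw two-channel array intensities: probe x sample
#' matrices of methylated / unmethylated fluorescence and per-cell detection
#' p-values, plus a sample-to-group map.
#'
#' @param meth,unmeth Numeric matrices (probes x samples) of non-negative
#'   channel intensities, with rownames = probe ids and colnames = samples.
#' @param detect_p Matrix of detection p-values in \[0,1\], same shape, or
#'   `NULL` if to be computed from negative-control probes.
#' @param group Named character vector mapping each sample to its group label.
#' @return An object of class `intensity_set`.
#' @export
intensity_set <- function(meth, unmeth, detect_p = NULL, group) {
  stopifnot(is.matrix(meth), is.matrix(unmeth))
  if (!identical(dim(meth), dim(unmeth)))
    stop("meth and unmeth matrices must share the same probe x sample shape")
  if (!is.null(detect_p) && !identical(dim(detect_p), dim(meth)))
    stop("detect_p matrix must share the meth/unmeth shape")
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stop("intensity format error: intensities must be >= 0")
  if (any(is.infinite(meth)) || any(is.infinite(unmeth)))
    stop("intensity format error: intensities must be finite")
  samples <- colnames(meth)
  if (is.null(samples)) stop("intensity matrices need sample colnames")
  if (is.null(rownames(meth)))
    rownames(meth) <- rownames(unmeth) <- sprintf("p%06d", seq_len(nrow(meth)))
  if (!all(samples %in% names(group)))
    stop("every sample needs a group label; missing: ",
         paste(setdiff(samples, names(group)), collapse = ", "))
  structure(list(probes = rownames(meth), samples = samples,
                 group = group[samples], meth = meth, unmeth = unmeth,
                 detect_p = detect_p),
            class = "intensity_set")
}

#' @export
print.intensity_set <- function(x, ...) {
  cat(sprintf("intensity_set: %d probes x %d samples\n",
              length(x$probes), length(x$samples)))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$group)),
                               table(x$group)), collapse = " "), "\n")
  invisible(x)
}

#' Read an intensity table
#'
#' Reads a long-format tab-separated table with columns `probe_id`, `sample`,
#' `meth`, `unmeth`, `detect_p` and aligns the resulting matrices to manifest
#' probe order. Missing (`NA`) intensity cells are kept as missing and counted
#' in the load report attached as attribute `"load_report"`; they are never
#' imputed.
#'
#' @param path Path to the table.
#' @param manifest Manifest `data.frame`; every probe in the table must be
#'   present in it.
#' @param group Named character vector sample -> group label.
#' @return An [intensity_set()] with probes in manifest order and samples in
#'   file order.
#' @export
read_intensities <- function(path, manifest, group) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "sample", "meth", "unmeth", "detect_p")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0)
    stop("intensity format error: missing column(s): ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(unique(tab$probe_id), manifest$probe_id)
  if (length(unknown) > 0)
    stop("intensity integrity error: probe(s) absent from manifest: ",
         paste(head(unknown, 5), collapse = ", "))
  if (any(tab$meth < 0, na.rm = TRUE) || any(tab$unmeth < 0, na.rm = TRUE))
    stop("intensity format error: negative intensity")
  samples <- unique(tab$sample)
  probes <- manifest$probe_id
  shape <- list(probes, samples)
  mk <- function(col) {
    m <- matrix(NA_real_, length(probes), length(samples), dimnames = shape)
    m[cbind(match(tab$probe_id, probes), match(tab$sample, samples))] <- tab[[col]]
    m
  }
  meth <- mk("meth"); unmeth <- mk("unmeth"); dp <- mk("detect_p")
  ds <- intensity_set(meth, unmeth, dp, group)
  n_missing <- sum(is.na(meth)) + sum(is.na(unmeth))
  attr(ds, "load_report") <- list(n_cells = 2L * length(meth),
                                  n_missing = n_missing)
  ds
}

#' Write an intensity table (long format)
#' @param ds An [intensity_set()].
#' @param path Output path.
#' @export
write_intensities <- function(ds, path) {
  long <- data.frame(
    probe_id = rep(ds$probes, times = length(ds$samples)),
    sample = rep(ds$samples, each = length(ds$probes)),
    meth = as.vector(ds$meth), unmeth = as.vector(ds$unmeth),
    detect_p = if (is.null(ds$detect_p)) NA_real_ else as.vector(ds$detect_p))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a methylation dataset
#'
#' Probe x sample beta and M matrices after filtering and normalization.
#' M = log2(beta/(1-beta)); beta of 0 or 1 is clamped by the documented
#' epsilon before the logit (see [compute_beta_m()]).
#'
#' @param beta Matrix of beta values in \[0,1\] (probes x samples, dimnames set).
#' @param m Matrix of M-values, same shape.
#' @param group Named character vector sample -> group.
#' @param meta List of processing metadata (modes, parameters).
#' @return An object of class `methylation_set`.
#' @export
methylation_set <- function(beta, m, group, meta = list()) {
  stopifnot(is.matrix(beta), is.matrix(m), identical(dim(beta), dim(m)))
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0,1]")
  samples <- colnames(beta)
  structure(list(probes = rownames(beta), samples = samples,
                 group = group[samples], beta = beta, m = m, meta = meta),
            class = "methylation_set")
}

#' @export
print.methylation_set <- function(x, ...) {
  cat(sprintf("methylation_set: %d probes x %d samples\n",
              length(x$probes), length(x$samples)))
  if (length(x$meta)) cat("meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Write genomic regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open, so a region chr1:100-560 becomes the line `1 99 560`.
#'
#' @param regions `data.frame` with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`.
#' @param path Output path.
#' @export
write_region_bed <- function(regions, path) {
  if (nrow(regions) > 0 && any(regions$end < regions$start))
    stop("region integrity error: end < start")
  bed <- data.frame(chrom = regions$chrom,
                    start = if (nrow(regions)) regions$start - 1L else integer(0),
                    end = regions$end,
                    name = if ("name" %in% names(regions)) regions$name
                           else sprintf("region_%d", seq_len(nrow(regions))))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions back to 1-based inclusive coordinates
#' @param path BED path (chrom, start, end\[, name\]).
#' @return `data.frame` with `chrom`, `start`, `end`, `name`.
#' @export
read_region_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0)))
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 4) names(bed)[4] <- "name" else bed$name <- NA_character_
  if (any(bed$end <= bed$start))
    stop("BED integrity error: end <= start")
  data.frame(chrom = as.character(bed$chrom), start = bed$start + 1L,
             end = bed$end, name = bed$name, stringsAsFactors = FALSE)
}

#' Write copy-number segments as SEG
#'
#' SEG rows are 1-based inclusive with columns `sample`, `chrom`, `start`,
#' `end`, `n_bins`, `log2_ratio`, `state`. Round-trips losslessly through
#' [read_seg()].
#'
#' @param seg `data.frame` with those columns (one row per bin or segment).
#' @param path Output path.
#' @export
write_seg <- function(seg, path) {
  cols <- c("sample", "chrom", "start", "end", "n_bins", "log2_ratio", "state")
  missing <- setdiff(cols, names(seg))
  if (length(missing) > 0)
    stop("SEG format error: missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(seg) > 0 && any(seg$end < seg$start))
    stop("SEG integrity error: end < start")
  write.table(seg[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file written by [write_seg()]
#' @param path SEG path.
#' @return `data.frame` with the SEG columns.
#' @export
read_seg <- function(path) {
  seg <- read.delim(path, stringsAsFactors = FALSE)
  seg$chrom <- as.character(seg$chrom)
  seg
}
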