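#' Default synthetic genome: 23 chromosomes at 1/100 scale
#'
#' Chromosome lengths (bp) of the human autosomes plus X divided by 100, so a
#' ~20,000-probe cohort covers the genome densely enough for binning and
#' region chaining while the full pipeline runs in seconds.
#' @return Named integer vector of chromosome lengths.
#' @export
default_chrom_lengths <- function() {
  full <- c(`1` = 248956422, `2` = 242193529, `3` = 198295559,
            `4` = 190214555, `5` = 181538259, `6` = 170805979,
            `7` = 159345973, `8` = 145138636, `9` = 138394717,
            `10` = 133797422, `11` = 135086622, `12` = 133275309,
            `13` = 114364328, `14` = 107043718, `15` = 101991189,
            `16` = 90338345, `17` = 83257441, `18` = 80373285,
            `19` = 58617616, `20` = 64444167, `21` = 46709983,
            `22` = 50818468, X = 156040895)
  setNames(as.integer(round(full / 100)), names(full))
}

#' Build a simulation configuration
#'
#' Bundles every knob of the synthetic 450k-like cohort: a bimodal beta model
#' for normal cells (modes near 0.05 and 0.95), global tumor hypomethylation
#' that spares promoter/CGI probes, planted DMRs of stated effect size,
#' planted CNV segments that scale total probe intensity by copy number, and
#' a copy-stable female control cohort.
#'
#' @param seed Integer seed; every generator call is deterministic given it.
#' @param n_probes Number of CpG-target probes (negative controls are extra).
#' @param n_samples_per_group Named counts per group; must include `control`
#'   (the copy-stable cohort, copy number 2 everywhere).
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param beta_modes Beta-distribution shape pairs for the unmethylated
#'   (mean 0.05) and methylated (mean 0.95) modes; the defaults are sharp
#'   enough that, as on real arrays, the bulk of probes read below 10% or
#'   above 90% methylation.
#' @param meth_mode_prob Named pair of per-probe probabilities of the
#'   methylated mode, `cgi` for CpG-island probes and `noncgi` for the rest
#'   (defaults 0.2 / 0.8: islands mostly unmethylated, bulk genome mostly
#'   methylated). A scalar applies one probability everywhere.
#' @param tumor_groups Groups receiving the global hypomethylation re-draw.
#' @param tumor_hypometh_fraction Fraction of methylated-mode probes re-drawn
#'   from the unmethylated mode in tumor samples.
#' @param hypometh_exclude_classes Classes spared from the re-draw; promoter
#'   and CpG-island probes stay bimodal by default, matching the observation
#'   that tumor hypomethylation is concentrated outside promoters/CGIs.
#' @param intensity Lognormal intensity model: per-probe affinity
#'   (`meanlog`, `sdlog_probe`), per-cell measurement noise (`sdlog_noise`),
#'   background level for negative-control/failed probes
#'   (`background_meanlog`, `background_sdlog`), and the zero-intensity
#'   `floor` (a.u.) applied before any log2.
#' @param noise_sd Gaussian measurement noise on the beta scale.
#' @param cluster_fraction Fraction of probes placed in CGI-like clusters
#'   (4-8 probes, 30-120 bp apart) so CpG-dense candidate regions exist.
#' @param cluster_size,cluster_gap Ranges for cluster probe count and spacing.
#' @param planted_dmrs `data.frame(chrom, start, end, n_probes, delta_m,
#'   group)`: regions where `group`'s M-values sit `delta_m` above the
#'   baseline shared by all other groups.
#' @param dmr_baseline_beta Beta value of planted-DMR probes in non-target
#'   groups (default 0.2, i.e. M = -2).
#' @param planted_cnvs `data.frame(target, chrom, start, end, copy,
#'   mosaic_fraction)`: `target` is a group name or sample label; `copy` in
#'   0..4; `mosaic_fraction` is the cell fraction carrying the CNV.
#' @param failed_probe_fraction,snp_probe_fraction,multi_target_fraction
#'   Fractions of probes planted as detection failures, SNP-flagged, and
#'   multi-target (disjoint sets, never inside planted DMRs).
#' @param n_negative_controls Count of negative-control probes.
#' @param design_type_I_prob Probability a probe is design type I.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_probes = 20000L,
                       n_samples_per_group = c(d0_PTC = 4L, LT_PTC = 4L,
                                               SE = 4L, control = 10L),
                       chrom_lengths = default_chrom_lengths(),
                       beta_modes = list(unmeth = c(5, 95),
                                         meth = c(95, 5)),
                       meth_mode_prob = c(cgi = 0.2, noncgi = 0.8),
                       tumor_groups = "SE",
                       tumor_hypometh_fraction = 0.5,
                       hypometh_exclude_classes = c("CGI", "TSS"),
                       intensity = list(meanlog = log(2000), sdlog_probe = 0.5,
                                        sdlog_noise = 0.1,
                                        background_meanlog = log(100),
                                        background_sdlog = 0.5, floor = 1),
                       noise_sd = 0.02,
                       cluster_fraction = 0.5,
                       cluster_size = c(4L, 8L),
                       cluster_gap = c(30L, 120L),
                       planted_dmrs = NULL,
                       dmr_baseline_beta = 0.2,
                       planted_cnvs = NULL,
                       failed_probe_fraction = 0.005,
                       snp_probe_fraction = 0.02,
                       multi_target_fraction = 0.01,
                       n_negative_controls = 100L,
                       design_type_I_prob = 0.28) {
  cfg <- as.list(environment())
  if (!"control" %in% names(cfg$n_samples_per_group))
    stop("config error: n_samples_per_group must include a 'control' group")
  if (!is.null(cfg$planted_dmrs)) {
    pd <- cfg$planted_dmrs
    if (any(pd$n_probes < 4L))
      stop("config error: planted DMRs need n_probes >= 4")
    bad <- pd$end > cfg$chrom_lengths[as.character(pd$chrom)] | pd$start < 1
    if (any(bad | is.na(bad)))
      stop("config error: planted DMR outside chromosome bounds")
    if (sum(pd$n_probes) > cfg$n_probes)
      stop("config error: planted DMR probes exceed n_probes")
    if (!all(pd$group %in% names(cfg$n_samples_per_group)))
      stop("config error: planted DMR group not in n_samples_per_group")
  }
  if (!is.null(cfg$planted_cnvs)) {
    pc <- cfg$planted_cnvs
    if (is.null(pc$mosaic_fraction)) pc$mosaic_fraction <- 1
    if (!all(pc$copy %in% 0:4))
      stop("config error: planted CNV copy number must be in 0..4")
    known <- c(names(cfg$n_samples_per_group),
               sample_labels(cfg$n_samples_per_group))
    if (!all(pc$target %in% known))
      stop("config error: planted CNV target not a known group or sample")
    if (any(pc$target == "control" & pc$copy != 2L))
      stop("config error: control cohort must stay copy-stable (copy 2)")
    bad <- pc$end > cfg$chrom_lengths[as.character(pc$chrom)] | pc$start < 1
    if (any(bad | is.na(bad)))
      stop("config error: planted CNV outside chromosome bounds")
    cfg$planted_cnvs <- pc
  }
  structure(cfg, class = "sim_config")
}

sample_labels <- function(n_per_group) {
  unlist(lapply(names(n_per_group), function(g)
    sprintf("%s_%d", g, seq_len(n_per_group[[g]]))), use.names = FALSE)
}

logit2 <- function(b) log2(b / (1 - b))
inv_logit2 <- function(m) 2^m / (1 + 2^m)

in_region <- function(chrom, pos, rchrom, rstart, rend) {
  chrom == as.character(rchrom) & pos >= rstart & pos <= rend
}

#' Generate a synthetic probe manifest
#'
#' Places `n_probes` CpG-target probes on the scaled genome: planted-DMR
#' probes first (spacing <= 200 bp within each region), then CGI-like
#' clusters and uniform singletons, avoiding planted regions. Class labels,
#' design types and SNP/multi-target flags are assigned per the configured
#' proportions; negative-control probes are appended with no classes.
#'
#' @param config A [sim_config()].
#' @return Manifest `data.frame` sorted by (chrom, pos), passing
#'   [read_manifest()] validation.
#' @export
simulate_manifest <- function(config) {
  set.seed(config$seed)
  cl <- config$chrom_lengths
  chroms <- names(cl)

  pchrom <- character(0); ppos <- integer(0); pdmr <- integer(0)
  pd <- config$planted_dmrs
  if (!is.null(pd)) {
    for (i in seq_len(nrow(pd))) {
      n <- pd$n_probes[i]
      spacing <- max(1L, min(150L, (pd$end[i] - pd$start[i]) %/% max(1L, n - 1L)))
      pos <- pd$start[i] + spacing * (0:(n - 1L))
      pchrom <- c(pchrom, rep(as.character(pd$chrom[i]), n))
      ppos <- c(ppos, pos)
      pdmr <- c(pdmr, rep(i, n))
    }
  }
  avoid <- function(chrom, pos) {
    if (is.null(pd)) return(rep(FALSE, length(pos)))
    hit <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(pd)))
      hit <- hit | in_region(chrom, pos, pd$chrom[i],
                             pd$start[i] - 250L, pd$end[i] + 250L)
    hit
  }

  n_rest <- config$n_probes - length(ppos)
  n_clustered <- round(n_rest * config$cluster_fraction)
  bchrom <- character(0); bpos <- integer(0); bclust <- logical(0)
  # CGI-like clusters
  while (sum(bclust) < n_clustered) {
    size <- sample(config$cluster_size[1]:config$cluster_size[2], 1L)
    ch <- sample(chroms, 1L, prob = cl)
    anchor <- sample.int(cl[[ch]] - 2000L, 1L)
    gaps <- sample(config$cluster_gap[1]:config$cluster_gap[2], size - 1L,
                   replace = TRUE)
    pos <- anchor + c(0L, cumsum(gaps))
    if (any(avoid(rep(ch, size), pos))) next
    bchrom <- c(bchrom, rep(ch, size)); bpos <- c(bpos, pos)
    bclust <- c(bclust, rep(TRUE, size))
  }
  # uniform singletons
  n_single <- n_rest - sum(bclust)
  while (n_single > 0) {
    ch <- sample(chroms, n_single, replace = TRUE, prob = cl)
    pos <- vapply(ch, function(c) sample.int(cl[[c]], 1L), integer(1))
    keep <- !avoid(ch, pos)
    bchrom <- c(bchrom, ch[keep]); bpos <- c(bpos, pos[keep])
    bclust <- c(bclust, rep(FALSE, sum(keep)))
    n_single <- n_single - sum(keep)
  }

  chrom <- c(pchrom, bchrom)
  pos <- c(ppos, bpos)
  clustered <- c(rep(TRUE, length(ppos)), bclust)
  dmr_idx <- c(pdmr, rep(NA_integer_, length(bpos)))
  # de-duplicate coincident placements deterministically
  key <- paste(chrom, pos)
  while (anyDuplicated(key)) {
    d <- duplicated(key)
    pos[d] <- pos[d] + 1L
    key <- paste(chrom, pos)
  }

  n <- length(pos)
  probe_id <- sprintf("cg%07d", seq_len(n))
  design_type <- ifelse(runif(n) < config$design_type_I_prob, "I", "II")

  cls <- vector("list", n)
  p_cls <- function(p_clust, p_bg) ifelse(clustered, p_clust, p_bg)
  draw <- function(p) runif(n) < p
  memb <- cbind(TSS = draw(p_cls(0.40, 0.08)),
                `5UTR` = draw(0.05),
                gene_body = draw(0.30),
                `3UTR` = draw(0.04),
                LINE = draw(p_cls(0.02, 0.15)),
                SINE = draw(p_cls(0.02, 0.15)),
                LTR = draw(p_cls(0.01, 0.05)),
                CGI = draw(p_cls(0.80, 0.05)),
                enhancer = draw(0.06))
  classes <- apply(memb, 1L, function(r) paste(colnames(memb)[r], collapse = ";"))

  snp <- multi <- rep(FALSE, n)
  eligible <- which(is.na(dmr_idx))
  n_snp <- round(config$snp_probe_fraction * n)
  n_multi <- round(config$multi_target_fraction * n)
  picked <- sample(eligible, n_snp + n_multi)
  snp[picked[seq_len(n_snp)]] <- TRUE
  multi[picked[n_snp + seq_len(n_multi)]] <- TRUE

  man <- data.frame(probe_id = probe_id, chrom = chrom, pos = as.integer(pos),
                    design_type = design_type, is_cpg_target = TRUE,
                    classes = classes,
                    gene_symbol = ifelse(memb[, "gene_body"] | memb[, "TSS"],
                                         sprintf("GENE%05d", 1L + pos %% 5000L),
                                         ""),
                    snp_within_10bp_maf05 = snp, multi_target = multi,
                    is_negative_control = FALSE, stringsAsFactors = FALSE)
  if (config$n_negative_controls > 0) {
    nn <- config$n_negative_controls
    neg <- data.frame(probe_id = sprintf("neg%05d", seq_len(nn)),
                      chrom = "1", pos = seq_len(nn),
                      design_type = "II", is_cpg_target = FALSE, classes = "",
                      gene_symbol = "", snp_within_10bp_maf05 = FALSE,
                      multi_target = FALSE, is_negative_control = TRUE,
                      stringsAsFactors = FALSE)
    man <- rbind(man, neg)
  }
  validate_manifest(man)
  sort_manifest(man)
}

#' Generate a synthetic intensity cohort with planted ground truth
#'
#' Per probe and sample, a true beta is drawn from the group model (tumor
#' groups apply the hypomethylation re-draw outside the spared classes;
#' planted DMRs override beta in their regions for the target group), a total
#' intensity is drawn from the lognormal affinity model scaled by
#' copy_number/2, channels are set to `meth = beta * T`,
#' `unmeth = (1 - beta) * T`, then beta-scale noise is applied and channels
#' recomposed at fixed total — so copy number (total) and methylation
#' (channel split) stay orthogonal by construction. Detection p-values are
#' near zero for passing probes and ~Uniform(0,1) for planted failed probes
#' and negative controls.
#'
#' @param config A [sim_config()].
#' @param manifest Manifest generated from the same config.
#' @return `list(data = intensity_set, truth = ground truth list)`. The truth
#'   carries the planted DMR regions (with member probe ids), CNV segments,
#'   per-group true beta matrix, per-sample copy-state matrix, and the
#'   planted failed/hypomethylated probe sets.
#' @export
simulate_cohort <- function(config, manifest) {
  set.seed(config$seed + 1L)
  groups_n <- config$n_samples_per_group
  samples <- sample_labels(groups_n)
  group <- setNames(rep(names(groups_n), times = unlist(groups_n)), samples)
  n <- nrow(manifest)
  is_neg <- manifest$is_negative_control
  memb <- class_membership(manifest)

  pd <- config$planted_dmrs
  dmr_probe_ids <- list()
  planted <- rep(FALSE, n)
  if (!is.null(pd)) {
    for (i in seq_len(nrow(pd))) {
      hit <- in_region(manifest$chrom, manifest$pos, pd$chrom[i],
                       pd$start[i], pd$end[i]) & !is_neg
      dmr_probe_ids[[i]] <- manifest$probe_id[hit]
      planted <- planted | hit
    }
  }

  # true beta per probe per group; methylated-mode probability may differ
  # between CGI and non-CGI probes (islands are mostly unmethylated)
  pm <- config$meth_mode_prob
  if (length(pm) == 1L) pm <- c(cgi = unname(pm), noncgi = unname(pm))
  in_cgi <- if ("CGI" %in% colnames(memb)) memb[, "CGI"] else rep(FALSE, n)
  mode_meth <- runif(n) < ifelse(in_cgi, pm[["cgi"]], pm[["noncgi"]])
  bm <- config$beta_modes
  beta_base <- ifelse(mode_meth,
                      rbeta(n, bm$meth[1], bm$meth[2]),
                      rbeta(n, bm$unmeth[1], bm$unmeth[2]))
  spared <- rep(FALSE, n)
  for (cls in intersect(config$hypometh_exclude_classes, colnames(memb)))
    spared <- spared | memb[, cls]
  true_beta <- matrix(rep(beta_base, length(groups_n)), ncol = length(groups_n),
                      dimnames = list(manifest$probe_id, names(groups_n)))
  hypometh_probes <- list()
  for (g in intersect(config$tumor_groups, names(groups_n))) {
    eligible <- mode_meth & !spared & !planted & !is_neg
    redraw <- eligible & runif(n) < config$tumor_hypometh_fraction
    true_beta[redraw, g] <- rbeta(sum(redraw), bm$unmeth[1], bm$unmeth[2])
    hypometh_probes[[g]] <- manifest$probe_id[redraw]
  }
  if (!is.null(pd)) {
    b0 <- config$dmr_baseline_beta
    for (i in seq_len(nrow(pd))) {
      hit <- manifest$probe_id %in% dmr_probe_ids[[i]]
      true_beta[hit, ] <- b0
      true_beta[hit, pd$group[i]] <- inv_logit2(logit2(b0) + pd$delta_m[i])
    }
  }

  # per-sample copy scale (mosaic-aware): scale = (2(1-f) + copy*f) / 2
  copy_scale <- matrix(1, n, length(samples),
                       dimnames = list(manifest$probe_id, samples))
  copy_state <- matrix(2L, n, length(samples),
                       dimnames = list(manifest$probe_id, samples))
  pc <- config$planted_cnvs
  if (!is.null(pc)) {
    for (i in seq_len(nrow(pc))) {
      hit <- in_region(manifest$chrom, manifest$pos, pc$chrom[i],
                       pc$start[i], pc$end[i]) & !is_neg
      targ <- if (pc$target[i] %in% names(groups_n))
        samples[group[samples] == pc$target[i]] else pc$target[i]
      f <- pc$mosaic_fraction[i]
      copy_scale[hit, targ] <- (2 * (1 - f) + pc$copy[i] * f) / 2
      copy_state[hit, targ] <- pc$copy[i]
    }
  }

  # planted detection failures: disjoint from DMR/SNP/multi-target probes
  pool <- which(!planted & !is_neg & !manifest$snp_within_10bp_maf05 &
                  !manifest$multi_target)
  n_fail <- round(config$failed_probe_fraction * sum(!is_neg))
  failed <- rep(FALSE, n)
  failed[sample(pool, n_fail)] <- TRUE

  ints <- config$intensity
  affinity <- ifelse(is_neg | failed,
                     rlnorm(n, ints$background_meanlog, ints$background_sdlog),
                     rlnorm(n, ints$meanlog, ints$sdlog_probe))
  noise_ps <- matrix(rlnorm(n * length(samples), 0, ints$sdlog_noise),
                     n, length(samples))
  total <- affinity * noise_ps * copy_scale

  beta_true_ps <- true_beta[, group[samples], drop = FALSE]
  beta_true_ps[is_neg, ] <- runif(sum(is_neg) * length(samples))
  beta_obs <- beta_true_ps
  if (config$noise_sd > 0)
    beta_obs <- pmin(1, pmax(0, beta_obs +
      matrix(rnorm(n * length(samples), 0, config$noise_sd), n)))
  meth <- beta_obs * total
  unmeth <- (1 - beta_obs) * total
  dimnames(meth) <- dimnames(unmeth) <- list(manifest$probe_id, samples)

  detect_p <- matrix(runif(n * length(samples)) * 0.005, n, length(samples),
                     dimnames = list(manifest$probe_id, samples))
  noisy <- is_neg | failed
  detect_p[noisy, ] <- runif(sum(noisy) * length(samples))

  truth <- list(
    dmr_regions = if (is.null(pd)) NULL else
      cbind(pd, data.frame(probe_ids = I(dmr_probe_ids))),
    cnv_segments = pc,
    true_beta = true_beta,
    copy_state = copy_state,
    failed_probes = manifest$probe_id[failed],
    hypometh_probes = hypometh_probes)
  list(data = intensity_set(meth, unmeth, detect_p, group), truth = truth)
}

#' Serialize planted ground truth (regions and segments) to JSON
#' @param truth Truth list from [simulate_cohort()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  out <- list(
    dmr_regions = if (is.null(truth$dmr_regions)) list() else
      lapply(seq_len(nrow(truth$dmr_regions)), function(i)
        list(chrom = as.character(truth$dmr_regions$chrom[i]),
             start = truth$dmr_regions$start[i],
             end = truth$dmr_regions$end[i],
             delta_m = truth$dmr_regions$delta_m[i],
             group = truth$dmr_regions$group[i],
             probe_ids = truth$dmr_regions$probe_ids[[i]])),
    cnv_segments = if (is.null(truth$cnv_segments)) list() else
      truth$cnv_segments,
    failed_probes = truth$failed_probes)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate synthetic qPCR amplification curves
#'
#' Ideal geometric growth capped at a plateau:
#' `fluorescence(c) = min(plateau, n0 * efficiency^c) + noise`, floored at 0.
#' Supports replicate reactions (qPCR is typically run in triplicate).
#'
#' @param efficiency Fold amplification per cycle, in (1, 2\].
#' @param n0 Starting quantity (arbitrary fluorescence units).
#' @param n_cycles Number of cycles (>= 10).
#' @param plateau Saturation fluorescence (`Inf` for none).
#' @param noise_sd Gaussian noise sd: fluorescence units when `noise_type`
#'   is `"additive"`, a fraction of the ideal signal when `"proportional"`
#'   (instrument noise largely scales with signal, so 1% proportional noise
#'   is `noise_sd = 0.01`).
#' @param noise_type `"additive"` or `"proportional"`.
#' @param n_replicates Number of replicate curves.
#' @param seed Optional integer seed for the noise draws.
#' @param target,sample Labels carried into the output.
#' @return `data.frame(reaction_id, target, sample, replicate, cycle,
#'   fluorescence)`.
#' @export
simulate_qpcr_curves <- function(efficiency, n0, n_cycles = 40L,
                                 plateau = Inf, noise_sd = 0,
                                 noise_type = c("additive", "proportional"),
                                 n_replicates = 1L, seed = NULL,
                                 target = "target", sample = "S1") {
  noise_type <- match.arg(noise_type)
  if (efficiency <= 1) stop("efficiency must exceed 1 (fold per cycle)")
  if (n_cycles < 10L) stop("need at least 10 cycles")
  if (!is.null(seed)) set.seed(seed)
  cyc <- seq_len(n_cycles)
  ideal <- pmin(plateau, n0 * efficiency^cyc)
  out <- lapply(seq_len(n_replicates), function(r) {
    f <- ideal
    if (noise_sd > 0) {
      sdv <- if (noise_type == "additive") rep(noise_sd, n_cycles)
             else noise_sd * ideal
      f <- pmax(0, f + rnorm(n_cycles, 0, sdv))
    }
    data.frame(reaction_id = sprintf("%s_%s_rep%d", target, sample, r),
               target = target, sample = sample, replicate = r,
               cycle = cyc, fluorescence = f, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
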