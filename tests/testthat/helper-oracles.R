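# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
brute_mw_p <- function(a, b) {
  vals <- c(a, b)
  u_stat <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_stat(a, b)
  idxs <- utils::combn(length(vals), length(a))
  us <- apply(idxs, 2L, function(i) u_stat(vals[i], vals[-i]))
  p_le <- mean(us <= obs + 1e-9)
  p_ge <- mean(us >= obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg step-up, written directly from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(n * p[o] / seq_len(n))))
  pmin(1, adj)[order(o)]
}

# Mean silhouette width from a distance matrix and integer labels.
silhouette_mean <- function(d, labels) {
  d <- as.matrix(d)
  s <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# Hand-built manifest rows for unit fixtures.
toy_manifest <- function(chrom, pos, probe_id = sprintf("cg%07d", seq_along(pos)),
                         design_type = "II", classes = "",
                         is_cpg_target = TRUE, snp = FALSE, multi = FALSE,
                         negative = FALSE) {
  data.frame(probe_id = probe_id, chrom = as.character(chrom),
             pos = as.integer(pos), design_type = design_type,
             is_cpg_target = is_cpg_target, classes = classes,
             gene_symbol = "", snp_within_10bp_maf05 = snp,
             multi_target = multi, is_negative_control = negative,
             stringsAsFactors = FALSE)
}

# methylation_set holding one probe so pooled group values are per-sample.
two_group_mset <- function(vals_a, vals_b) {
  samples <- c(sprintf("A%d", seq_along(vals_a)),
               sprintf("B%d", seq_along(vals_b)))
  m <- matrix(c(vals_a, vals_b), nrow = 1,
              dimnames = list("cg0000001", samples))
  beta <- 2^m / (1 + 2^m)
  group <- setNames(rep(c("A", "B"), c(length(vals_a), length(vals_b))),
                    samples)
  methylation_set(beta, m, group)
}

# Small simulated cohort shared by several tests (built once per test run).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_probes = 6000,
                        n_samples_per_group = c(d0_PTC = 4, LT_PTC = 4,
                                                SE = 4, control = 10))
      man <- simulate_manifest(cfg)
      sim <- simulate_cohort(cfg, man)
      cache <<- list(cfg = cfg, man = man, sim = sim)
    }
    cache
  }
})
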