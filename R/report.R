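#' Unsupervised hierarchical clustering of samples
#'
#' Deterministic agglomerative clustering on the most variable probes:
#' probes are ranked by beta variance across samples, the top
#' `top_k_variable_probes` kept, and samples clustered on the chosen
#' distance/linkage. No random state is involved, so the tree is
#' reproducible and invariant to sample input order.
#'
#' @param meth A [methylation_set()].
#' @param top_k_variable_probes Number of top-variance probes (default 5000;
#'   all probes are used, with a warning, when fewer are available).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param distance Distance metric for [stats::dist()] (default
#'   `"euclidean"`), computed on beta values.
#' @param k Number of groups for the reported tree cut (default 2).
#' @return `list(tree = hclust, sample_order, cophenetic, labels_k)`.
#' @export
hierarchical_cluster <- function(meth, top_k_variable_probes = 5000L,
                                 linkage = "average", distance = "euclidean",
                                 k = 2L) {
  if (length(meth$samples) < 3L) stop("need >= 3 samples to cluster")
  v <- apply(meth$beta, 1L, var, na.rm = TRUE)
  v[is.na(v)] <- -Inf
  if (length(v) < top_k_variable_probes) {
    warning("fewer probes than requested: using all ", length(v))
    top <- seq_along(v)
  } else {
    top <- order(v, decreasing = TRUE)[seq_len(top_k_variable_probes)]
  }
  sub <- meth$beta[top, order(colnames(meth$beta)), drop = FALSE]
  d <- dist(t(sub), method = distance)
  tree <- hclust(d, method = linkage)
  list(tree = tree, sample_order = tree$labels[tree$order],
       cophenetic = cophenetic(tree), labels_k = cutree(tree, k = k))
}

#' Principal component analysis of sample methylation profiles
#'
#' Centred PCA of the sample-by-probe M-value matrix (beta available as an
#' option); returns per-sample component scores and explained-variance
#' fractions.
#'
#' @param meth A [methylation_set()].
#' @param n_components Number of components to return (default 3).
#' @param scale_values `"m"` (default) or `"beta"`.
#' @return `list(scores = samples x components matrix, explained_variance)`.
#' @export
pca_scores <- function(meth, n_components = 3L,
                       scale_values = c("m", "beta")) {
  scale_values <- match.arg(scale_values)
  if (length(meth$samples) < 3L) stop("need >= 3 samples")
  x <- t(if (scale_values == "m") meth$m else meth$beta)
  keep <- colSums(is.na(x)) == 0L
  x <- x[, keep, drop = FALSE]
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(nc), drop = FALSE],
       explained_variance = ev[seq_len(nc)])
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail test of hit-gene overlap per gene set, with
#' BH adjustment across sets. This is generic over-representation plumbing,
#' not a replica of any annotation web service.
#'
#' @param hit_genes Character vector of hits (must be a subset of
#'   `background_genes`).
#' @param background_genes Character vector, the tested universe.
#' @param gene_sets Named list of character vectors.
#' @return `data.frame(set, n_set, n_overlap, p, q)` sorted by p.
#' @export
enrichment <- function(hit_genes, background_genes, gene_sets) {
  background_genes <- unique(background_genes)
  if (length(background_genes) == 0) stop("empty background")
  hit_genes <- unique(hit_genes)
  if (!all(hit_genes %in% background_genes))
    stop("hit genes must be a subset of the background")
  n_bg <- length(background_genes)
  n_hit <- length(hit_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background_genes)
    ov <- length(intersect(hit_genes, set))
    # P(X >= ov) for X ~ Hypergeom(n_set in bg, draws = n_hit)
    p <- if (length(set) == 0 || n_hit == 0) 1
         else phyper(ov - 1L, length(set), n_bg - length(set), n_hit,
                     lower.tail = FALSE)
    data.frame(set = nm, n_set = length(set), n_overlap = ov, p = min(1, p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- adjust_bh(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
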