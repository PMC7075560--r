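#!/usr/bin/env Rscript
# Stage 7: sample-level summaries (hierarchical clustering, PCA), a generic
# gene-set enrichment of DMR genes, and the run-manifest provenance record.

source("analysis/00_config.R")

st <- study_cohort()
pp <- preprocess_pipeline(st$data, st$manifest)
bio <- pp$meth$samples[pp$meth$group != "control"]
meth <- methylation_set(pp$meth$beta[, bio], pp$meth$m[, bio], pp$meth$group)

cl <- hierarchical_cluster(meth, top_k_variable_probes = 3000L, k = 2L)
cat("clustering (k = 2):\n")
print(split(names(cl$labels_k), cl$labels_k))

pc <- pca_scores(meth, n_components = 3)
cat("explained variance:", round(pc$explained_variance, 3), "\n")
write.table(data.frame(sample = rownames(pc$scores),
                       group = unname(meth$group[rownames(pc$scores)]),
                       pc$scores),
            file.path(RESULTS_DIR, "pca_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# enrichment of genes hit by the culture-associated (planted) DMRs against a
# toy gene-set collection
res_lt <- call_dmrs(pp$meth, st$manifest, "LT_PTC", "d0_PTC")
hit_probes <- unlist(res_lt$probe_ids[res_lt$is_dmr])
gene_of <- st$manifest$gene_symbol[match(hit_probes, st$manifest$probe_id)]
hits <- unique(gene_of[nzchar(gene_of)])
background <- unique(st$manifest$gene_symbol[nzchar(st$manifest$gene_symbol)])
set.seed(STUDY_SEED)
gene_sets <- list(random_set_a = sample(background, 150),
                  random_set_b = sample(background, 150),
                  dmr_biased_set = unique(c(sample(hits, min(50, length(hits))),
                                            sample(background, 100))))
enr <- enrichment(hits, background, gene_sets)
print(enr)
write.table(enr, file.path(RESULTS_DIR, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

run_manifest <- list(
  seed = STUDY_SEED,
  n_probes = st$cfg$n_probes,
  groups = as.list(st$cfg$n_samples_per_group),
  preprocessing = pp$meth$meta,
  dmr_params = unclass(dmr_params()),
  cnv = list(probes_per_bin = 50L, k = 3, mad_floor = 0.05),
  cluster = list(top_k_variable_probes = 3000L, linkage = "average",
                 distance = "euclidean"),
  pca = list(scale = "m", n_components = 3L))
jsonlite::write_json(run_manifest, file.path(RESULTS_DIR, "run_manifest.json"),
                     auto_unbox = TRUE)
cat("wrote pca_scores.tsv, enrichment.tsv, run_manifest.json\n")
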