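#!/usr/bin/env Rscript
# Stage 3: system-level structure. Connectivity of the correlation
# network and its relation to the state score, the Euclidean-distance
# profile, per-probe state correlations, and the dorsal/ventral
# concordance of treatment-induced fold changes.

suppressMessages(library(exprstate))

study_dir <- "results/study"
out_dir <- "results/structure"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

zprep <- function(m) zscore_rows(suppressWarnings(drop_constant_rows(m)))

regions <- c("dorsal", "ventral")
expr <- lapply(regions, function(r)
  load_expression(file.path(study_dir, paste0("expression_", r, ".tsv")),
                  file.path(study_dir, "sample_info.tsv"),
                  present_path = file.path(study_dir, "present_calls.tsv"))$expression)
names(expr) <- regions
info <- read.delim(file.path(study_dir, "sample_info.tsv"))
ann <- read.delim(file.path(study_dir, "present_calls.tsv"))
present_fraction <- rowMeans(ann[, -1])

z <- lapply(expr, zprep)
scores <- lapply(z, compute_pca1)

# connectivity on a seeded 2000-gene subsample of the dorsal matrix
conn <- gene_connectivity(z$dorsal, scores$dorsal, max_genes = 2000,
                          seed = seed)
curve <- connectivity_state_curve(conn)
cat(sprintf("connectivity vs |r with PCA1|: spearman r = %.3f (p = %.3g)\n",
            curve$spearman_r, curve$spearman_p))
print(curve$bins)
write.table(conn, file.path(out_dir, "connectivity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# distance from the lowest-state transcriptome
for (r in regions) {
  prof <- euclidean_profile(z[[r]], scores[[r]])
  cat(sprintf("%s: distance vs PCA1 linearity r = %.3f (reference %s)\n",
              r, prof$linearity_r, prof$reference_sample))
}

# per-probe state correlations among present probes
pres_ids <- ann$probe_id[present_fraction > 0.5]
sig <- sapply(regions, function(r) {
  tab <- pca1_gene_correlations(z[[r]], scores[[r]])
  tab$significant[match(pres_ids, tab$probe_id)]
})
cat(sprintf("present probes significantly tracking PCA1: %.1f%% in >=1 region, %.1f%% in both\n",
            100 * mean(rowSums(sig) > 0, na.rm = TRUE),
            100 * mean(rowSums(sig) == 2, na.rm = TRUE)))

# treatment fold changes and their cross-region concordance
fc <- lapply(regions, function(r) {
  ri <- info[match(colnames(expr[[r]]), info$sample_id), ]
  log_fold_change(expr[[r]], ri$sample_id[ri$treatment == "CORT_FLX"],
                  ri$sample_id[ri$treatment == "CORT"])
})
names(fc) <- regions
conc <- regional_concordance(fc$dorsal, fc$ventral)
print(conc)
for (r in regions)
  write.table(fc[[r]], file.path(out_dir, paste0("fold_change_", r, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
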