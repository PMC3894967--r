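#!/usr/bin/env Rscript
# Stage 2: score the global gene expression system state (PCA1) and show
# that the score is insensitive to which probes are used to compute it.
#
# Reads the study written by 01_simulate.R, z-scores each region's matrix,
# computes PCA1 pooled and per region, orients the pooled score so treated
# samples score higher, and runs two subsampling protocols: five ordered
# non-overlapping 2000-probe groups, and as many shuffled 2%-of-probe
# groups as fit.

suppressMessages(library(exprstate))

study_dir <- "results/study"
out_dir <- "results/state"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

zprep <- function(m) zscore_rows(suppressWarnings(drop_constant_rows(m)))

regions <- c("dorsal", "ventral")
expr <- lapply(regions, function(r)
  load_expression(file.path(study_dir, paste0("expression_", r, ".tsv")),
                  file.path(study_dir, "sample_info.tsv"))$expression)
names(expr) <- regions
info <- read.delim(file.path(study_dir, "sample_info.tsv"))

# pooled score, oriented by treatment
pooled_z <- zprep(cbind(expr$dorsal, expr$ventral))
pooled <- compute_pca1(pooled_z)
treat <- info$treatment[match(colnames(pooled_z), info$sample_id)]
pooled <- orient_scores(pooled, anchor = as.numeric(treat == "CORT_FLX"))
cat(sprintf("pooled PC1 explains %.1f%% of variance\n",
            100 * pooled$variance_explained[1]))

scores <- lapply(regions, function(r) {
  s <- compute_pca1(zprep(expr[[r]]))
  orient_scores(s, anchor = pooled$pca1[match(s$sample_ids,
                                              pooled$sample_ids)])
})
names(scores) <- regions
for (r in regions)
  cat(sprintf("%s PC1 variance share: %.1f%%\n", r,
              100 * scores[[r]]$variance_explained[1]))

# pooled-vs-regional and cross-region agreement
for (r in regions)
  cat(sprintf("pooled vs %s scores: r = %.3f\n", r,
              cor(pooled$pca1[scores[[r]]$sample_ids], scores[[r]]$pca1)))
cat(sprintf("dorsal vs ventral scores (same animals): r = %.3f\n",
            cor(scores$dorsal$pca1, scores$ventral$pca1)))

# subsampling robustness
for (r in regions) {
  five <- subsample_state_concordance(
    expr[[r]], partition_probes(rownames(expr[[r]]), 2000, 5, "ordered"),
    reference = scores[[r]])
  g2 <- floor(0.02 * nrow(expr[[r]]))
  pct2 <- subsample_state_concordance(
    expr[[r]], partition_probes(rownames(expr[[r]]), g2, "max", "shuffled",
                                seed = seed + 100L),
    reference = scores[[r]])
  cat(sprintf("%s: five-group min r = %.4f; %d groups of %d probes min r = %.4f\n",
              r, five$min_r, length(pct2$scores), g2, pct2$min_r))
  write.table(five$pairwise_r,
              file.path(out_dir, paste0("five_group_r_", r, ".tsv")),
              sep = "\t", quote = FALSE)
}

tab <- do.call(rbind, lapply(regions, function(r)
  data.frame(region = r, sample_id = scores[[r]]$sample_ids,
             pca1 = unname(scores[[r]]$pca1))))
tab$pca1_pooled <- pooled$pca1[match(tab$sample_id, pooled$sample_ids)]
write.table(tab, file.path(out_dir, "state_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", file.path(out_dir, "state_scores.tsv"), "\n")
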