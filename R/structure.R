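# System-level diagnostics: correlation-network connectivity, the
# connectivity-versus-state relationship, Euclidean distance from the
# lowest-state transcriptome, per-probe PCA1 correlations, and cross-region
# fold-change concordance.

#' Correlation-network connectivity per gene
#'
#' Builds an adjacency from pairwise cross-correlations of expression
#' profiles: two genes are connected when their correlation is significant
#' at `alpha` (two-sided test via the exact t-transform). Connectivity is
#' the number of connections divided by the total number of genes analyzed,
#' a proxy for a gene's position in the regulatory hierarchy.
#'
#' @param z z-scored probes/genes-by-samples matrix (>= 4 samples).
#' @param scores `state_scores` for the same samples (used for the per-gene
#'   correlation with PCA1).
#' @param alpha adjacency significance threshold (default 0.001).
#' @param max_genes optional cap; a seeded uniform subsample of rows is
#'   analyzed when the matrix is larger (pairwise work is quadratic).
#' @param seed seed for the subsample.
#' @param method `"pearson"` (default) or `"spearman"` profile correlations;
#'   the t-transform p-value is used for both.
#' @return data.frame: `gene_id`, `n_connections`, `connectivity`
#'   (`n_connections` / genes analyzed), `r_with_pca1`, `p_with_pca1`;
#'   attributes `alpha`, `max_genes`, `seed`, `n_samples`.
#' @export
gene_connectivity <- function(z, scores, alpha = 0.001, max_genes = NULL,
                              seed = 1L, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_matrix(z)
  stopifnot(inherits(scores, "state_scores"))
  n <- ncol(z)
  if (n < 4) stop("connectivity needs >= 4 samples")
  if (!identical(colnames(z), scores$sample_ids))
    stop("scores do not match the matrix samples")
  if (!is.null(max_genes)) {
    if (max_genes < 2) stop("max_genes must be >= 2")
    if (max_genes < nrow(z)) {
      keep <- withr::with_seed(seed, sort(sample.int(nrow(z), max_genes)))
      z <- z[keep, , drop = FALSE]
    }
  }
  G <- nrow(z)

  R <- stats::cor(t(z), method = method)
  P <- cor_pvalue(R, n)
  diag(P) <- 1                          # self-correlation is not a connection
  n_connections <- as.integer(rowSums(P < alpha))
  r1 <- drop(stats::cor(t(z), scores$pca1, method = method))

  out <- data.frame(gene_id = rownames(z),
                    n_connections = n_connections,
                    connectivity = n_connections / G,
                    r_with_pca1 = r1,
                    p_with_pca1 = cor_pvalue(r1, n),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "max_genes") <- max_genes
  attr(out, "seed") <- seed
  attr(out, "n_samples") <- n
  out
}

#' Connectivity versus state-correlation curve
#'
#' Bins genes into equal-count quantile bins of connectivity and summarizes
#' how closely each bin's genes follow PCA1 (mean absolute correlation with
#' the state score, regardless of direction). In a hierarchical expression
#' system more connected genes track the global state more closely, which
#' appears as a positive Spearman correlation across genes.
#'
#' @param table output of [gene_connectivity()].
#' @param n_bins number of quantile bins (>= 2).
#' @return list with `bins` (data.frame: bin, n, mean_connectivity,
#'   mean_abs_r), `spearman_r`, `spearman_p`.
#' @export
connectivity_state_curve <- function(table, n_bins = 10) {
  stopifnot(nrow(table) > 0, n_bins >= 2)
  conn <- table$connectivity
  absr <- abs(table$r_with_pca1)
  if (length(unique(conn)) == 1) {
    warning("all connectivities identical; returning a single bin")
    bin <- rep(1L, length(conn))
    n_bins <- 1L
  } else {
    # equal-count bins via ranks (connectivity is heavy-tailed, so
    # equal-width bins would leave most bins empty)
    bin <- ceiling(rank(conn, ties.method = "first") * n_bins / length(conn))
  }
  bins <- data.frame(
    bin = sort(unique(bin)),
    n = as.vector(table(bin)),
    mean_connectivity = as.vector(tapply(conn, bin, mean)),
    mean_abs_r = as.vector(tapply(absr, bin, mean))
  )
  if (length(unique(conn)) == 1 || length(unique(absr)) == 1) {
    sr <- NA_real_; sp <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::cor.test(conn, absr, method = "spearman", exact = FALSE))
    sr <- unname(ct$estimate); sp <- ct$p.value
  }
  list(bins = bins, spearman_r = sr, spearman_p = sp)
}

#' Euclidean distance from the lowest-state transcriptome
#'
#' Distances of every sample's (z-scored) transcriptome from the sample with
#' the lowest PCA1, and the linearity of that distance with PCA1. A global
#' state score should order transcriptomes along a path, so distance from
#' the extreme sample grows linearly with the score.
#'
#' @param z z-scored probes-by-samples matrix.
#' @param scores `state_scores` aligned to the matrix samples.
#' @return list of class `distance_profile`: `sample_ids`, `distance`
#'   (named vector), `reference_sample`, `linearity_r`.
#' @export
euclidean_profile <- function(z, scores) {
  check_matrix(z)
  stopifnot(inherits(scores, "state_scores"))
  if (!identical(colnames(z), scores$sample_ids))
    stop("scores do not match the matrix samples")
  lo <- which(scores$pca1 == min(scores$pca1))
  if (length(lo) > 1) {
    message("tie for minimum PCA1; using lexicographically smallest sample ID")
    lo <- lo[order(scores$sample_ids[lo])][1]
  }
  ref <- scores$sample_ids[lo]
  D <- as.matrix(stats::dist(t(z)))     # pairwise sample distances
  distance <- D[, ref]
  structure(list(sample_ids = scores$sample_ids,
                 distance = distance,
                 reference_sample = ref,
                 linearity_r = stats::cor(distance, scores$pca1)),
            class = "distance_profile")
}

#' Correlation of every probe's profile with PCA1
#'
#' @param z z-scored probes-by-samples matrix (>= 4 samples).
#' @param scores `state_scores` aligned to the matrix samples.
#' @param alpha per-probe significance level, uncorrected (default 0.05).
#' @return data.frame: `probe_id`, `r`, `p_value`, `significant`,
#'   `direction` (sign of r).
#' @export
pca1_gene_correlations <- function(z, scores, alpha = 0.05) {
  check_matrix(z)
  stopifnot(inherits(scores, "state_scores"))
  n <- ncol(z)
  if (n < 4) stop("needs >= 4 samples")
  if (!identical(colnames(z), scores$sample_ids))
    stop("scores do not match the matrix samples")
  s <- scores$pca1
  s0 <- (s - mean(s)) / stats::sd(s)
  # rows of z are standardized, so r is the scaled inner product
  r <- drop(z %*% s0) / (n - 1)
  r <- pmin(pmax(r, -1), 1)
  p <- cor_pvalue(r, n)
  data.frame(probe_id = rownames(z), r = r, p_value = p,
             significant = p < alpha, direction = sign(r),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-region concordance of fold-change responses
#'
#' Compares two fold-change tables computed over the same probes in two
#' regions: the Pearson correlation of log2 fold changes, the percentage of
#' probes significant in at least one / both regions, and among those the
#' percentage whose response direction agrees across regions. Probes with a
#' fold change of exactly zero in either region are undirected and are
#' excluded from the direction-agreement percentages (count reported).
#'
#' @param fc_dorsal,fc_ventral data.frames from [log_fold_change()] over the
#'   identical probe set.
#' @param alpha per-probe significance level (default 0.05).
#' @return list of class `concordance_report` with `pearson_r_fc`,
#'   `pct_sig_any`, `pct_sig_both`, `pct_same_dir_any`, `pct_same_dir_both`,
#'   `n_probes`, `n_zero_fc_excluded`.
#' @export
regional_concordance <- function(fc_dorsal, fc_ventral, alpha = 0.05) {
  sd_ <- setdiff(fc_dorsal$probe_id, fc_ventral$probe_id)
  sv <- setdiff(fc_ventral$probe_id, fc_dorsal$probe_id)
  if (length(sd_) || length(sv))
    stop("fold-change tables cover different probes: ",
         paste(utils::head(c(sd_, sv), 10), collapse = ", "))
  v <- fc_ventral[match(fc_dorsal$probe_id, fc_ventral$probe_id), ]
  d <- fc_dorsal

  sig_d <- d$p_value < alpha
  sig_v <- v$p_value < alpha
  any_sig <- sig_d | sig_v
  both_sig <- sig_d & sig_v
  zero <- d$log2_fc == 0 | v$log2_fc == 0
  if (any(zero))
    message("regional_concordance: excluding ", sum(zero),
            " zero-fold-change probe(s) from direction agreement")
  same_dir <- sign(d$log2_fc) == sign(v$log2_fc)

  pct <- function(x) 100 * mean(x)
  agree <- function(sel) {
    sel <- sel & !zero
    if (!any(sel)) return(NA_real_)
    pct(same_dir[sel])
  }
  structure(list(
    pearson_r_fc = stats::cor(d$log2_fc, v$log2_fc),
    pct_sig_any = pct(any_sig),
    pct_sig_both = pct(both_sig),
    pct_same_dir_any = agree(any_sig),
    pct_same_dir_both = agree(both_sig),
    n_probes = nrow(d),
    n_zero_fc_excluded = sum(zero)
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Cross-region fold-change concordance over", x$n_probes, "probes\n")
  cat(sprintf("  Pearson r (log2 FC): %.3f\n", x$pearson_r_fc))
  cat(sprintf("  significant in >=1 region: %.1f%%; in both: %.1f%%\n",
              x$pct_sig_any, x$pct_sig_both))
  cat(sprintf("  same direction | >=1 sig: %.1f%%; | both sig: %.1f%%\n",
              x$pct_same_dir_any, x$pct_same_dir_both))
  invisible(x)
}
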