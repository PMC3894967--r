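# PCA1 state scoring and the probe-subsampling concordance protocol.
#
# PCA is done with samples as observations and probes as variables on
# z-scored data, so the first principal component score (PCA1) is one number
# per array summarizing where that transcriptome sits along the dominant
# covarying gene expression program. Because probes number tens of
# thousands and samples a few dozen, scores are obtained from the
# eigendecomposition of the samples-by-samples cross-product matrix, which
# shares its nonzero spectrum with the probe-space covariance matrix.

#' Compute the first principal component state score (PCA1)
#'
#' @param z z-scored probes-by-samples matrix (rows mean 0, sd 1).
#' @param n_components number of leading variance-explained fractions to
#'   report.
#' @return object of class `state_scores`: list with `sample_ids`, `pca1`
#'   (named vector, unit sample standard deviation), `variance_explained`
#'   (fractions for components 1..`n_components`), `orientation` (sign-rule
#'   record), and `loadings` (probe-space direction, for sign handling).
#' @details The score vector's sign is mathematically arbitrary; it is fixed
#'   by the largest-absolute-loading-positive rule and recorded, and can be
#'   re-oriented against any anchor with [orient_scores()].
#' @export
compute_pca1 <- function(z, n_components = 4) {
  check_matrix(z, "z-scored matrix")
  n <- ncol(z)
  if (n < 2) stop("PCA needs >= 2 samples")
  if (nrow(z) < 2) stop("PCA needs >= 2 probes")
  if (max(abs(rowMeans(z))) > 1e-6)
    stop("matrix rows are not standardized (row means exceed 1e-6); ",
         "apply zscore_rows() first")

  S <- crossprod(z)                      # samples x samples
  ee <- eigen(S, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  variance_explained <- ev / sum(ev)
  u1 <- ee$vectors[, 1]
  loadings <- drop(z %*% u1)             # per-probe weight on component 1

  i <- which.max(abs(loadings))
  flipped <- loadings[i] < 0
  if (flipped) {
    u1 <- -u1
    loadings <- -loadings
  }
  pca1 <- u1 / stats::sd(u1)
  names(pca1) <- colnames(z)
  names(loadings) <- rownames(z)

  structure(list(
    sample_ids = colnames(z),
    pca1 = pca1,
    variance_explained = variance_explained[seq_len(min(n_components, length(ev)))],
    orientation = list(rule = "largest_loading",
                       anchor = rownames(z)[i], flipped = flipped),
    loadings = loadings,
    n_probes = nrow(z)
  ), class = "state_scores")
}

#' @export
print.state_scores <- function(x, ...) {
  cat("PCA1 state scores:", length(x$pca1), "samples,",
      x$n_probes, "probes\n")
  cat("  variance explained (PC1..):",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "), "\n")
  cat("  orientation:", x$orientation$rule,
      if (isTRUE(x$orientation$flipped)) "(flipped)" else "", "\n")
  print(round(x$pca1, 3))
  invisible(x)
}

#' Fix the sign of a PCA1 score vector against an anchor
#'
#' PCA defines scores only up to sign. Given a numeric anchor (one value per
#' sample), the scores are flipped so that their Pearson correlation with
#' the anchor is non-negative; with the `"largest_loading"` token the stored
#' largest-absolute-loading-positive rule is (re)applied. A correlation of
#' exactly zero leaves the sign unchanged with a warning.
#'
#' @param scores `state_scores` object.
#' @param anchor numeric vector (length = number of samples, non-constant)
#'   or the string `"largest_loading"`.
#' @return re-oriented `state_scores` with an updated orientation record.
#' @export
orient_scores <- function(scores, anchor = "largest_loading") {
  stopifnot(inherits(scores, "state_scores"))
  if (is.character(anchor) && length(anchor) == 1 &&
      anchor == "largest_loading") {
    i <- which.max(abs(scores$loadings))
    flip <- scores$loadings[i] < 0
    rec <- list(rule = "largest_loading",
                anchor = names(scores$loadings)[i], flipped = flip)
  } else {
    anchor <- as.numeric(anchor)
    if (length(anchor) != length(scores$pca1))
      stop("anchor length must equal the number of samples")
    if (stats::sd(anchor) == 0) stop("anchor is constant")
    r <- stats::cor(scores$pca1, anchor)
    if (abs(r) < 1e-12) {
      warning("anchor is exactly orthogonal to PCA1; sign left unchanged")
      flip <- FALSE
    } else {
      flip <- r < 0
    }
    rec <- list(rule = "anchor_correlation", anchor = "numeric anchor",
                flipped = flip)
  }
  if (flip) {
    scores$pca1 <- -scores$pca1
    scores$loadings <- -scores$loadings
  }
  scores$orientation <- rec
  scores
}

#' Partition probes into non-overlapping equal-size groups
#'
#' Emulates the subset-validation protocol: groups taken either as
#' consecutive blocks in probe-ID order (the published convention, e.g.
#' group 1 = probes 1-2000, group 2 = probes 2001-4000) or after a seeded
#' shuffle. Leftover probes that cannot fill a complete group are discarded.
#'
#' @param probe_ids ordered probe identifiers.
#' @param group_size probes per group (>= 2).
#' @param n_groups integer, or `"max"` for as many full groups as fit.
#' @param mode `"ordered"` or `"shuffled"`.
#' @param seed integer seed for shuffled mode (required there for
#'   reproducibility).
#' @return object of class `probe_partition`: list with `groups` (list of
#'   probe-ID vectors), `mode`, `seed`, `group_size`.
#' @export
partition_probes <- function(probe_ids, group_size, n_groups = "max",
                             mode = c("ordered", "shuffled"), seed = NULL) {
  mode <- match.arg(mode)
  if (anyDuplicated(probe_ids)) stop("probe_ids contains duplicates")
  if (group_size < 2) stop("group_size must be >= 2")
  max_groups <- length(probe_ids) %/% group_size
  if (identical(n_groups, "max")) n_groups <- max_groups
  if (n_groups < 1 || n_groups > max_groups)
    stop("insufficient probes for ", n_groups, " group(s) of ", group_size,
         "; at most ", max_groups, " feasible")
  ids <- if (mode == "shuffled") {
    if (is.null(seed)) stop("shuffled mode requires a seed")
    withr::with_seed(seed, sample(probe_ids))
  } else probe_ids
  groups <- lapply(seq_len(n_groups), function(g)
    ids[((g - 1) * group_size + 1):(g * group_size)])
  structure(list(groups = groups, mode = mode, seed = seed,
                 group_size = group_size), class = "probe_partition")
}

#' Concordance of PCA1 across independent probe groups
#'
#' Computes PCA1 separately within each probe group of a partition, aligns
#' every group's sign to a reference score vector (by default PCA1 on all
#' probes of the matrix), and reports the full pairwise Pearson correlation
#' matrix of the aligned group scores. Near-identical group scores (high
#' minimum pairwise r) demonstrate that the state score measures a systemic
#' property distributed across the transcriptome rather than a property of
#' particular probes.
#'
#' @param matrix probes-by-samples matrix. With `zscore_within = TRUE`
#'   (default) each group's submatrix is z-scored on its own (constant rows
#'   dropped); otherwise the matrix must already be z-scored globally.
#' @param partition `probe_partition` covering a subset of the matrix rows.
#' @param reference optional `state_scores` to sign-align against; default
#'   is PCA1 computed on all rows of `matrix`.
#' @param zscore_within z-score within each group (default) or use the
#'   matrix as given.
#' @return object of class `subsample_report`: list with `scores` (per-group
#'   `state_scores`), `pairwise_r` (symmetric matrix), `min_r`, `median_r`
#'   (off-diagonal summaries), `reference`.
#' @export
subsample_state_concordance <- function(matrix, partition, reference = NULL,
                                        zscore_within = TRUE) {
  check_matrix(matrix)
  stopifnot(inherits(partition, "probe_partition"))
  miss <- setdiff(unlist(partition$groups), rownames(matrix))
  if (length(miss))
    stop("partition refers to probe(s) not in the matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))

  prep <- function(m) {
    if (zscore_within) zscore_rows(suppressWarnings(drop_constant_rows(m)))
    else m
  }
  if (is.null(reference))
    reference <- compute_pca1(prep(matrix))

  scores <- lapply(seq_along(partition$groups), function(g) {
    sub <- prep(matrix[partition$groups[[g]], , drop = FALSE])
    if (nrow(sub) < 2)
      stop("group ", g, " has fewer than 2 usable probes")
    orient_scores(compute_pca1(sub), anchor = reference$pca1)
  })
  names(scores) <- paste0("group", seq_along(scores))

  mat <- vapply(scores, function(s) s$pca1, numeric(length(reference$pca1)))
  pairwise_r <- stats::cor(mat)
  off <- pairwise_r[upper.tri(pairwise_r)]
  structure(list(scores = scores, pairwise_r = pairwise_r,
                 min_r = min(off), median_r = stats::median(off),
                 reference = reference),
            class = "subsample_report")
}

#' @export
print.subsample_report <- function(x, ...) {
  cat("PCA1 subsampling concordance:", length(x$scores), "groups of",
      x$scores[[1]]$n_probes, "probes\n")
  cat(sprintf("  min pairwise r = %.4f, median = %.4f\n", x$min_r, x$median_r))
  invisible(x)
}
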