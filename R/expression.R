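# Expression-matrix data model, TSV I/O and preprocessing.
#
# The expression container is a plain numeric matrix, probes in rows
# (rownames = probe IDs) and samples in columns (colnames = sample IDs), on
# the log2 scale, as produced upstream by RMA/MAS5-style summarization.
# Probe annotation is a data.frame with columns probe_id, gene_symbol and
# present_fraction; sample metadata is a data.frame with one row per array.

#' Load an expression study from tab-delimited files
#'
#' Reads a probes-by-samples log2 expression matrix, per-sample metadata,
#' and (optionally) present calls and probe-to-gene annotation. The
#' expression file must be tab-delimited with a `probe_id` first column and
#' one column per sample; the metadata file must cover every sample in the
#' matrix (it may contain additional samples, e.g. the other brain region of
#' a two-region study). Present-call cells may be coded `P`/`A` or `1`/`0`.
#'
#' @param path expression matrix TSV.
#' @param metadata_path sample metadata TSV with columns `sample_id`,
#'   `animal_id`, `region`, `treatment`, `fst_immobility_s`, `nsf_latency_s`.
#' @param present_path optional present-call TSV (same layout as the
#'   expression matrix; its sample columns may be a superset of the matrix's,
#'   in which case `present_fraction` is computed across all of them, as when
#'   present calls from both regions of a study are pooled).
#' @param annotation_path optional TSV with columns `probe_id`,
#'   `gene_symbol` (empty/NA symbol allowed).
#' @return list with elements `expression` (numeric matrix), `info`
#'   (data.frame, rows ordered as the matrix columns), `annotation`
#'   (data.frame: `probe_id`, `gene_symbol`, `present_fraction`) and
#'   `present` (logical matrix of per-sample calls, or NULL).
#' @export
load_expression <- function(path, metadata_path, present_path = NULL,
                            annotation_path = NULL) {
  for (f in c(path, metadata_path, present_path, annotation_path))
    if (!file.exists(f)) stop("file not found: ", f)

  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  probe_ids <- dt[[1]]
  if (anyDuplicated(probe_ids))
    stop("duplicate probe ID(s) in ", path, ": ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  vals <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(dt[, -1, with = FALSE], is.numeric, logical(1)))
    col <- names(dt)[-1][bad[1]]
    cell <- suppressWarnings(as.numeric(dt[[col]]))
    row <- which(is.na(cell) & !is.na(dt[[col]]))[1]
    stop("non-numeric value in column '", col, "', row '",
         probe_ids[row], "'")
  }
  rownames(vals) <- probe_ids
  check_matrix(vals)

  info <- as.data.frame(data.table::fread(metadata_path, sep = "\t"))
  need <- c("sample_id", "animal_id", "region", "treatment",
            "fst_immobility_s", "nsf_latency_s")
  miss <- setdiff(need, names(info))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(colnames(vals), info$sample_id)
  if (length(absent))
    stop("sample(s) in expression matrix but not metadata: ",
         paste(absent, collapse = ", "))
  info <- info[match(colnames(vals), info$sample_id), , drop = FALSE]
  rownames(info) <- NULL
  if (any(info$nsf_latency_s > 480))
    stop("nsf_latency_s exceeds the 480 s test ceiling")
  if (anyDuplicated(info[, c("animal_id", "region")]))
    stop("duplicated (animal_id, region) pairs in metadata")

  present <- NULL
  present_fraction <- rep(NA_real_, length(probe_ids))
  if (!is.null(present_path)) {
    pd <- data.table::fread(present_path, sep = "\t", header = TRUE,
                            colClasses = list(character = 1))
    if (!identical(pd[[1]], probe_ids))
      stop("present-call probe IDs do not match the expression matrix")
    pm <- as.matrix(pd[, -1, with = FALSE])
    present <- matrix(pm %in% c("P", "1", "TRUE", "true"),
                      nrow = nrow(pm), dimnames = list(probe_ids, colnames(pm)))
    bad <- !(pm %in% c("P", "A", "1", "0", "TRUE", "FALSE", "true", "false"))
    if (any(bad)) stop("present-call cells must be P/A or 1/0")
    present_fraction <- rowMeans(present)
  }

  if (!is.null(annotation_path)) {
    ann <- as.data.frame(data.table::fread(annotation_path, sep = "\t",
                                           colClasses = "character"))
    if (!all(c("probe_id", "gene_symbol") %in% names(ann)))
      stop("annotation must have probe_id and gene_symbol columns")
    ann <- ann[match(probe_ids, ann$probe_id), ]
    if (anyNA(ann$probe_id))
      stop("annotation is missing probe(s): ",
           paste(utils::head(probe_ids[is.na(ann$probe_id)], 5), collapse = ", "))
    gene_symbol <- ann$gene_symbol
    gene_symbol[gene_symbol == ""] <- NA_character_
  } else {
    gene_symbol <- rep(NA_character_, length(probe_ids))
  }

  annotation <- data.frame(probe_id = probe_ids, gene_symbol = gene_symbol,
                           present_fraction = present_fraction,
                           stringsAsFactors = FALSE)
  list(expression = vals, info = info, annotation = annotation,
       present = present)
}

#' Filter probes by present-call fraction
#'
#' Retains probes detected ("present") in strictly more than `min_fraction`
#' of samples, the background filter used before gene-level annotation work
#' (present in greater than 50% of samples by default).
#'
#' @param matrix probes-by-samples numeric matrix.
#' @param annotation data.frame with `probe_id` and `present_fraction`.
#' @param min_fraction retention threshold; strict inequality.
#' @return the filtered matrix, probe order preserved.
#' @export
present_filter <- function(matrix, annotation, min_fraction = 0.5) {
  check_matrix(matrix)
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  idx <- match(rownames(matrix), annotation$probe_id)
  if (anyNA(idx))
    stop("probe(s) without annotation: ",
         paste(utils::head(rownames(matrix)[is.na(idx)], 5), collapse = ", "))
  frac <- annotation$present_fraction[idx]
  if (anyNA(frac))
    stop("present_fraction missing for annotated probe(s)")
  matrix[frac > min_fraction, , drop = FALSE]
}

#' Summarize probe-level values to one row per gene
#'
#' Two conventions: `weighted_present` averages a gene's probes with weights
#' equal to each probe's present-call fraction (the convention used to build
#' single per-gene values for annotation lists); `simple_mean` averages
#' per-probe mean-centered log2 rows (each row minus its mean, i.e. the
#' two-probe averaging convention used for BDNF-style gene summaries).
#'
#' @param matrix probes-by-samples numeric matrix (log2 scale).
#' @param annotation data.frame with `probe_id`, `gene_symbol`,
#'   `present_fraction`.
#' @param mode `"weighted_present"` or `"simple_mean"`.
#' @return genes-by-samples matrix; probes without a gene symbol are dropped
#'   (count reported via `message()`).
#' @export
summarize_probes_to_genes <- function(matrix, annotation,
                                      mode = c("weighted_present", "simple_mean")) {
  mode <- match.arg(mode)
  check_matrix(matrix)
  idx <- match(rownames(matrix), annotation$probe_id)
  if (anyNA(idx))
    stop("probe(s) without annotation: ",
         paste(utils::head(rownames(matrix)[is.na(idx)], 5), collapse = ", "))
  gene <- annotation$gene_symbol[idx]
  drop <- is.na(gene) | gene == ""
  if (any(drop))
    message("summarize_probes_to_genes: dropping ", sum(drop),
            " probe(s) without a gene symbol")
  m <- matrix[!drop, , drop = FALSE]
  gene <- gene[!drop]
  if (!nrow(m)) stop("no annotated probes to summarize")

  if (mode == "weighted_present") {
    w <- annotation$present_fraction[idx][!drop]
    if (anyNA(w)) stop("present_fraction required for weighted_present mode")
    wsum <- rowsum(w, gene)
    zero <- rownames(wsum)[wsum[, 1] == 0]
    if (length(zero))
      stop("gene(s) with all-zero present-call weights: ",
           paste(zero, collapse = ", "))
    num <- rowsum(m * w, gene)
    out <- num / wsum[, 1]
  } else {
    centered <- m - rowMeans(m)
    out <- rowsum(centered, gene)
    counts <- table(gene)
    out <- out / as.vector(counts[rownames(out)])
  }
  out <- as.matrix(out)
  check_matrix(out, "gene-level matrix")
  out
}

#' Drop rows with zero variance
#'
#' Flat probes carry no information for covariance analysis and make
#' z-scoring undefined; this removes them with a warning naming the count.
#'
#' @param matrix probes-by-samples numeric matrix.
#' @return matrix without constant rows.
#' @export
drop_constant_rows <- function(matrix) {
  check_matrix(matrix)
  sds <- row_sd(matrix)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant row(s) before z-scoring")
    matrix <- matrix[sds > 0, , drop = FALSE]
  }
  matrix
}

row_sd <- function(m) {
  n <- ncol(m)
  sqrt(rowSums((m - rowMeans(m))^2) / (n - 1))
}

#' Z-score each probe across samples
#'
#' Centers and scales every row to mean 0 and sample standard deviation 1
#' (n - 1 denominator). Constant rows are an error; callers that expect
#' them should apply [drop_constant_rows()] first.
#'
#' @param matrix probes-by-samples numeric matrix.
#' @return z-scored matrix of the same shape.
#' @export
zscore_rows <- function(matrix) {
  check_matrix(matrix)
  if (ncol(matrix) < 2) stop("z-scoring needs >= 2 samples")
  sds <- row_sd(matrix)
  if (any(sds == 0))
    stop("constant row(s): ",
         paste(utils::head(rownames(matrix)[sds == 0], 5), collapse = ", "),
         if (sum(sds == 0) > 5) " ..." else "")
  (matrix - rowMeans(matrix)) / sds
}

#' Per-probe log2 fold changes between two sample groups
#'
#' The matrix is assumed to be on the log2 scale already, so the fold change
#' is the difference of group means. P-values come from a two-sided Welch
#' two-sample t-test on the log2 values of each probe; with a group of size
#' one the fold change is still returned and the p-value is NA.
#'
#' @param matrix probes-by-samples numeric matrix (log2 scale).
#' @param samples_treated,samples_control disjoint, non-empty sample ID sets.
#' @param var_equal use the pooled-variance (Student) test instead of Welch.
#' @return data.frame: `probe_id`, `log2_fc`, `t`, `p_value`, `direction`
#'   (sign of `log2_fc`).
#' @export
log_fold_change <- function(matrix, samples_treated, samples_control,
                            var_equal = FALSE) {
  check_matrix(matrix)
  if (!length(samples_treated) || !length(samples_control))
    stop("both sample groups must be non-empty")
  if (length(intersect(samples_treated, samples_control)))
    stop("treated and control groups overlap: ",
         paste(intersect(samples_treated, samples_control), collapse = ", "))
  miss <- setdiff(c(samples_treated, samples_control), colnames(matrix))
  if (length(miss))
    stop("sample(s) not in matrix: ", paste(miss, collapse = ", "))

  x <- matrix[, samples_treated, drop = FALSE]
  y <- matrix[, samples_control, drop = FALSE]
  lfc <- rowMeans(x) - rowMeans(y)
  if (var_equal && ncol(x) >= 2 && ncol(y) >= 2) {
    n1 <- ncol(x); n2 <- ncol(y)
    sp2 <- (rowSums((x - rowMeans(x))^2) + rowSums((y - rowMeans(y))^2)) /
      (n1 + n2 - 2)
    tstat <- lfc / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
    zero <- sp2 == 0
    tstat[zero] <- ifelse(lfc[zero] == 0, 0, sign(lfc[zero]) * Inf)
    p[zero] <- ifelse(lfc[zero] == 0, 1, .Machine$double.xmin)
    wt <- list(t = tstat, p = pmax(p, .Machine$double.xmin))
  } else {
    wt <- row_welch(x, y)
    if (ncol(x) < 2 || ncol(y) < 2)
      message("log_fold_change: a group has a single sample; ",
              "p-values unavailable")
  }
  data.frame(probe_id = rownames(matrix), log2_fc = lfc, t = wt$t,
             p_value = wt$p, direction = sign(lfc),
             row.names = NULL, stringsAsFactors = FALSE)
}
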