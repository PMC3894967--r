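# End-to-end orchestration: load or generate a two-region study, score the
# global state, validate it by probe subsampling, run the system
# diagnostics, and relate state to behavior. Every stage's numbers are
# regenerable from the configuration and seeds.

#' Build a pipeline run configuration
#'
#' @param input `"synthetic"` or `"files"`.
#' @param params [generator_params()] for synthetic input.
#' @param paths named list for file input: per-region expression TSVs under
#'   `expression` (named list region -> path), plus `metadata`, `present`,
#'   `annotation` (the layout written by [write_study()]).
#' @param group_size,n_groups,partition_mode subsampling protocol (defaults:
#'   five ordered non-overlapping groups of 2000 probes).
#' @param alpha_fc,alpha_adjacency,alpha_normality significance levels for
#'   fold changes (0.05), network adjacency (0.001) and the normality gate
#'   (0.05).
#' @param max_genes connectivity gene cap (seeded subsample; pairwise work
#'   is quadratic). `NULL` analyzes every probe.
#' @param exclude_ambiguous apply the ambiguous-responder exclusion in the
#'   behavior stage.
#' @param seed root seed; stage seeds are derived from it.
#' @param output_dir optional directory; when set, [run_pipeline()] writes
#'   a JSON report plus per-table TSVs there.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = c("synthetic", "files"),
                       params = generator_params(), paths = NULL,
                       group_size = 2000L, n_groups = 5L,
                       partition_mode = "ordered",
                       alpha_fc = 0.05, alpha_adjacency = 0.001,
                       alpha_normality = 0.05,
                       max_genes = 5000L, exclude_ambiguous = TRUE,
                       seed = 1L, output_dir = NULL) {
  input <- match.arg(input)
  for (a in c(alpha_fc, alpha_adjacency, alpha_normality))
    if (!(a > 0 && a < 1)) stop("alpha levels must lie in (0, 1)")
  if (input == "files" && is.null(paths))
    stop("file input requires 'paths'")
  structure(list(input = input, params = params, paths = paths,
                 group_size = as.integer(group_size),
                 n_groups = n_groups, partition_mode = partition_mode,
                 alpha_fc = alpha_fc, alpha_adjacency = alpha_adjacency,
                 alpha_normality = alpha_normality,
                 max_genes = max_genes,
                 exclude_ambiguous = exclude_ambiguous,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `params` block is
#' forwarded to [generator_params()].
#'
#' @param path YAML file.
#' @return `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$params)) y$params <- do.call(generator_params, y$params)
  do.call(run_config, y)
}

stage_seeds <- function(root) {
  # small fixed offsets keep every derived seed well under 2^31
  list(generate = root, partition = root + 1000L, connectivity = root + 2000L)
}

#' Run the full state-scoring analysis pipeline
#'
#' Stages, in order: load/generate the study; drop constant probes and
#' z-score per region; PCA1 on all samples pooled (oriented so treated
#' samples score higher) and per region (oriented to the pooled reference);
#' probe-subsampling concordance per region; connectivity and the
#' connectivity-state curve; Euclidean distance profile; per-region log2
#' fold changes (treated vs control) and cross-region concordance; the
#' state-behavior association table.
#'
#' @param config a [run_config()].
#' @return list of class `run_report` with per-stage results and a
#'   provenance block (config, seeds, package version). Written as
#'   `report.json` + per-table TSVs when `config$output_dir` is set.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- stage_seeds(config$seed)
  stage <- function(name) message("[", name, "] ", appendLF = FALSE)

  stage("input")
  if (config$input == "synthetic") {
    study <- generate_study(config$params)
    message("generated synthetic study, seed ", config$params$seed)
    expr <- study$expression
    info <- study$info
    annotation <- study$annotation
  } else {
    expr <- list()
    loaded <- NULL
    for (r in names(config$paths$expression)) {
      loaded <- load_expression(config$paths$expression[[r]],
                                config$paths$metadata,
                                present_path = config$paths$present,
                                annotation_path = config$paths$annotation)
      expr[[r]] <- loaded$expression
    }
    info <- as.data.frame(data.table::fread(config$paths$metadata, sep = "\t"))
    annotation <- loaded$annotation
    message("loaded ", length(expr), " region matrices")
  }
  regions <- names(expr)

  stage("zscore")
  z <- lapply(expr, function(m) zscore_rows(suppressWarnings(drop_constant_rows(m))))
  message(paste(vapply(z, nrow, 1L), collapse = "/"), " probes retained")

  stage("state")
  shared <- Reduce(intersect, lapply(z, rownames))
  pooled_raw <- do.call(cbind, lapply(expr, function(m) m[shared, , drop = FALSE]))
  pooled_z <- zscore_rows(suppressWarnings(drop_constant_rows(pooled_raw)))
  pooled <- compute_pca1(pooled_z)
  pooled_info <- info[match(colnames(pooled_z), info$sample_id), ]
  if (!anyNA(pooled_info$treatment) &&
      length(unique(pooled_info$treatment)) == 2) {
    pooled <- orient_scores(pooled,
                            anchor = as.numeric(pooled_info$treatment == "CORT_FLX"))
  }
  scores <- lapply(regions, function(r) {
    s <- compute_pca1(z[[r]])
    orient_scores(s, anchor = pooled$pca1[match(s$sample_ids,
                                                pooled$sample_ids)])
  })
  names(scores) <- regions
  message("PC1 variance share: ",
          paste(sprintf("%s %.1f%%", regions,
                        100 * vapply(scores, function(s)
                          s$variance_explained[1], 1)), collapse = ", "))

  stage("subsampling")
  concordance_by_region <- lapply(regions, function(r) {
    part <- partition_probes(rownames(expr[[r]]), config$group_size,
                             n_groups = config$n_groups,
                             mode = config$partition_mode,
                             seed = seeds$partition)
    subsample_state_concordance(expr[[r]], part, reference = scores[[r]])
  })
  names(concordance_by_region) <- regions
  message("min pairwise r: ",
          paste(sprintf("%s %.3f", regions,
                        vapply(concordance_by_region, function(x) x$min_r, 1)),
                collapse = ", "))

  stage("connectivity")
  connectivity <- gene_connectivity(z[[1]], scores[[1]],
                                    alpha = config$alpha_adjacency,
                                    max_genes = config$max_genes,
                                    seed = seeds$connectivity)
  curve <- connectivity_state_curve(connectivity)
  message(nrow(connectivity), " genes, spearman(connectivity, |r|) = ",
          sprintf("%.3f", curve$spearman_r))

  stage("distance")
  distance <- lapply(regions, function(r) euclidean_profile(z[[r]], scores[[r]]))
  names(distance) <- regions
  message("linearity r: ",
          paste(sprintf("%s %.3f", regions,
                        vapply(distance, function(d) d$linearity_r, 1)),
                collapse = ", "))

  stage("fold_change")
  fc <- lapply(regions, function(r) {
    ri <- info[match(colnames(expr[[r]]), info$sample_id), ]
    log_fold_change(expr[[r]],
                    ri$sample_id[ri$treatment == "CORT_FLX"],
                    ri$sample_id[ri$treatment == "CORT"])
  })
  names(fc) <- regions
  concordance <- if (length(regions) == 2) {
    regional_concordance(fc[[1]], fc[[2]], alpha = config$alpha_fc)
  } else NULL
  if (!is.null(concordance))
    message(sprintf("FC r = %.3f, sig any/both = %.1f%%/%.1f%%",
                    concordance$pearson_r_fc, concordance$pct_sig_any,
                    concordance$pct_sig_both))

  stage("behavior")
  behavior <- behavior_state_report(scores, info,
                                    exclude_ambiguous = config$exclude_ambiguous,
                                    normality_alpha = config$alpha_normality)
  message(nrow(behavior), " associations")

  report <- structure(list(
    state = list(pooled = pooled, by_region = scores),
    subsampling = concordance_by_region,
    connectivity = connectivity,
    connectivity_curve = curve,
    distance = distance,
    fold_change = fc,
    regional_concordance = concordance,
    behavior = behavior,
    provenance = list(config = unclass(config),
                      stage_seeds = seeds,
                      package_version = as.character(utils::packageVersion("exprstate")))
  ), class = "run_report")

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Serialize a run report to JSON and TSV tables
#'
#' @param report `run_report` from [run_pipeline()].
#' @param directory output directory (created if missing).
#' @return invisibly, the path of the JSON report.
#' @export
write_report <- function(report, directory) {
  stopifnot(inherits(report, "run_report"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(directory, f)

  scores_tab <- do.call(rbind, c(
    list(data.frame(set = "pooled",
                    sample_id = report$state$pooled$sample_ids,
                    pca1 = unname(report$state$pooled$pca1))),
    lapply(names(report$state$by_region), function(r)
      data.frame(set = r, sample_id = report$state$by_region[[r]]$sample_ids,
                 pca1 = unname(report$state$by_region[[r]]$pca1)))))
  data.table::fwrite(scores_tab, fp("state_scores.tsv"), sep = "\t")
  data.table::fwrite(report$connectivity, fp("connectivity.tsv"), sep = "\t")
  data.table::fwrite(report$behavior, fp("behavior.tsv"), sep = "\t")
  for (r in names(report$fold_change))
    data.table::fwrite(report$fold_change[[r]],
                       fp(paste0("fold_change_", r, ".tsv")), sep = "\t")

  js <- list(
    variance_explained = lapply(report$state$by_region, function(s)
      s$variance_explained),
    orientation = lapply(report$state$by_region, function(s) s$orientation),
    subsampling = lapply(report$subsampling, function(x)
      list(pairwise_r = x$pairwise_r, min_r = x$min_r,
           median_r = x$median_r)),
    connectivity_curve = report$connectivity_curve,
    distance = lapply(report$distance, function(d)
      list(reference_sample = d$reference_sample,
           linearity_r = d$linearity_r, distance = as.list(d$distance))),
    regional_concordance = unclass(report$regional_concordance),
    provenance = report$provenance
  )
  path <- fp("report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Optional reader for GEO series-matrix files
#'
#' Extracts the expression block delimited by `!series_matrix_table_begin`
#' and `!series_matrix_table_end` from a (decompressed) GEO series matrix,
#' returning a probes-by-samples numeric matrix. Provided so the pipeline
#' can be pointed at repository-style files; sample metadata must still be
#' supplied separately.
#'
#' @param path series-matrix text file.
#' @return numeric matrix (probe IDs in rows, sample accessions in columns).
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1)
    stop("no series-matrix table block found in ", path)
  block <- lines[(beg + 1):(end - 1)]
  dt <- data.table::fread(text = block, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- gsub('"', "", dt[[1]])
  colnames(m) <- gsub('"', "", colnames(m))
  check_matrix(m, "series matrix")
  m
}
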