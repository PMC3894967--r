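# State-behavior association: normality-gated correlation, group
# comparisons, and the ambiguous-responder exclusion rule.

#' Correlation with an automatic Pearson/Spearman choice
#'
#' Applies a Shapiro-Wilk normality test to each variable; Pearson is used
#' when both look normal (p > `normality_alpha`), Spearman (average ranks
#' for ties, t-approximate p-value) otherwise. This mirrors the common
#' small-cohort convention of rank-based correlation for non-normal
#' behavioral measures.
#'
#' @param x,y numeric vectors of equal length >= 4, no missing values.
#' @param normality_alpha Shapiro-Wilk gate level (default 0.05).
#' @param x_name,y_name labels carried into the result.
#' @return data.frame row: `x_name`, `y_name`, `method`, `r`, `p_value`,
#'   `n`, `normality_p_x`, `normality_p_y`.
#' @export
auto_correlate <- function(x, y, normality_alpha = 0.05,
                           x_name = deparse1(substitute(x)),
                           y_name = deparse1(substitute(y))) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need >= 4 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  shx <- stats::shapiro.test(x)$p.value
  shy <- stats::shapiro.test(y)$p.value
  method <- if (shx > normality_alpha && shy > normality_alpha)
    "pearson" else "spearman"
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  data.frame(x_name = x_name, y_name = y_name, method = method,
             r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
             normality_p_x = shx, normality_p_y = shy,
             stringsAsFactors = FALSE)
}

#' Two-group comparison of a behavioral measure
#'
#' Two-sided two-sample t-test; Welch (unequal variances) by default, with
#' the pooled-variance Student test available for literal replication of
#' classical analyses.
#'
#' @param values_treated,values_control numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance test instead of Welch.
#' @return list with `t`, `p_value`, `mean_treated`, `mean_control`, `df`.
#' @export
group_compare <- function(values_treated, values_control, var_equal = FALSE) {
  if (length(values_treated) < 2 || length(values_control) < 2)
    stop("each group needs >= 2 values")
  tt <- stats::t.test(values_treated, values_control, var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_treated = mean(values_treated),
       mean_control = mean(values_control),
       df = unname(tt$parameter))
}

#' Flag treated animals with an ambiguous behavioral response
#'
#' An animal counts as a responder on a test when its value falls below a
#' per-test cutoff (lower immobility / lower latency = antidepressant
#' response); by default the cutoff is the control arm's median for that
#' test. Animals responding on exactly one of the two tests are flagged
#' ambiguous - the exclusion applied before relating state to behavior, so
#' that general (two-test) responders and non-responders anchor the
#' association.
#'
#' @param info treated-arm sample metadata (data.frame with `animal_id`,
#'   `fst_immobility_s`, `nsf_latency_s`; duplicate animal rows, e.g. one
#'   per region, are collapsed).
#' @param controls control-arm metadata, same columns (non-empty).
#' @param rule optional list with `fst_cutoff`, `nsf_cutoff` overriding the
#'   control-median rule.
#' @return data.frame: `animal_id`, `fst_responder`, `nsf_responder`,
#'   `ambiguous`; attribute `thresholds`.
#' @export
flag_ambiguous_responders <- function(info, controls, rule = NULL) {
  if (!nrow(controls)) stop("control arm is empty")
  if (!nrow(info)) stop("treated arm is empty")
  a <- unique(info[, c("animal_id", "fst_immobility_s", "nsf_latency_s")])
  ctl <- unique(controls[, c("animal_id", "fst_immobility_s", "nsf_latency_s")])
  thr <- list(
    fst_cutoff = rule$fst_cutoff %||% stats::median(ctl$fst_immobility_s),
    nsf_cutoff = rule$nsf_cutoff %||% stats::median(ctl$nsf_latency_s)
  )
  fst_r <- a$fst_immobility_s < thr$fst_cutoff
  nsf_r <- a$nsf_latency_s < thr$nsf_cutoff
  out <- data.frame(animal_id = a$animal_id,
                    fst_responder = fst_r, nsf_responder = nsf_r,
                    ambiguous = xor(fst_r, nsf_r),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thr
  out
}

#' State-behavior association table per region
#'
#' Relates each region's PCA1 scores to the two behavioral measures
#' (forced-swim immobility, novelty-suppressed-feeding latency) with
#' [auto_correlate()], optionally excluding treated animals whose
#' behavioral response was ambiguous (responder on exactly one test).
#'
#' @param scores_by_region named list (region -> `state_scores`).
#' @param info sample metadata covering every scored sample.
#' @param exclude_ambiguous apply the ambiguous-responder exclusion
#'   (default TRUE).
#' @param normality_alpha gate level passed to [auto_correlate()].
#' @return data.frame with one row per region x behavior: `region`,
#'   `behavior`, `method`, `r`, `p_value`, `n`, normality p-values;
#'   attribute `excluded_animals`.
#' @export
behavior_state_report <- function(scores_by_region, info,
                                  exclude_ambiguous = TRUE,
                                  normality_alpha = 0.05) {
  stopifnot(is.list(scores_by_region), length(scores_by_region) >= 1)
  excluded <- character(0)
  if (exclude_ambiguous) {
    flags <- flag_ambiguous_responders(
      info[info$treatment == "CORT_FLX", , drop = FALSE],
      info[info$treatment == "CORT", , drop = FALSE])
    excluded <- flags$animal_id[flags$ambiguous]
    if (length(excluded))
      message("behavior_state_report: excluding ", length(excluded),
              " ambiguous responder(s): ", paste(excluded, collapse = ", "))
  }
  n_ceiling <- sum(unique(info[, c("animal_id", "nsf_latency_s")])$nsf_latency_s >= 480)
  if (n_ceiling)
    message("behavior_state_report: ", n_ceiling,
            " animal(s) at the 480 s NSF ceiling (kept, ties by rank)")

  rows <- list()
  for (region in names(scores_by_region)) {
    sc <- scores_by_region[[region]]
    idx <- match(sc$sample_ids, info$sample_id)
    if (anyNA(idx))
      stop("scored sample(s) missing from metadata: ",
           paste(sc$sample_ids[is.na(idx)], collapse = ", "))
    meta <- info[idx, ]
    keep <- !(meta$animal_id %in% excluded)
    if (sum(keep) < 4)
      stop("fewer than 4 usable animals after exclusion in region ", region)
    for (behavior in c("fst_immobility_s", "nsf_latency_s")) {
      res <- auto_correlate(sc$pca1[keep], meta[[behavior]][keep],
                            normality_alpha = normality_alpha,
                            x_name = paste0("pca1_", region),
                            y_name = behavior)
      rows[[length(rows) + 1]] <- cbind(region = region, behavior = behavior,
                                        res[, -(1:2)])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded_animals") <- excluded
  out
}
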