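# Internal helpers shared across modules.

#' Two-sided p-value for a Pearson (or rank) correlation
#'
#' Exact t-transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees
#' of freedom, vectorized over `r`. Matches `stats::cor.test` for Pearson
#' correlations and the t-approximation used for Spearman with ties.
#'
#' @param r correlation value(s) in \[-1, 1\].
#' @param n number of paired observations (must be >= 3).
#' @return vector (or matrix, following `r`) of two-sided p-values.
#' @keywords internal
#' @noRd
cor_pvalue <- function(r, n) {
  if (n < 3) stop("correlation p-value needs n >= 3")
  r2 <- pmin(r * r, 1)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  # keep p in (0, 1]: a perfect correlation yields the smallest representable p
  pmax(p, .Machine$double.xmin)
}

#' Vectorized two-sided Welch t-test over rows
#'
#' @param x,y matrices with the same rows; columns are the two groups'
#'   samples. Each group needs >= 2 columns for a p-value.
#' @return list with `t`, `df`, `p` vectors (NA where undefined).
#' @keywords internal
#' @noRd
row_welch <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  if (n1 < 2 || n2 < 2) {
    return(list(t = rep(NA_real_, nrow(x)), df = NA_real_,
                p = rep(NA_real_, nrow(x))))
  }
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  # both groups constant: diff 0 -> t = 0, p = 1; diff != 0 -> p -> 0
  zero <- se2 == 0
  if (any(zero)) {
    d <- m1 - m2
    tstat[zero] <- ifelse(d[zero] == 0, 0, sign(d[zero]) * Inf)
    p[zero] <- ifelse(d[zero] == 0, 1, .Machine$double.xmin)
    df[zero] <- n1 + n2 - 2
  }
  list(t = tstat, df = df, p = pmax(p, .Machine$double.xmin))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check an expression matrix: numeric, finite, uniquely named
#' @keywords internal
#' @noRd
check_matrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must have probe row names and sample column names")
  if (anyDuplicated(rownames(m)))
    stop(what, ": duplicated probe IDs: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop(what, ": duplicated sample IDs: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!all(is.finite(m)))
    stop(what, " contains non-finite values")
  invisible(m)
}
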