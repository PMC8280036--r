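#' Constraint-score percentile ranks
#'
#' Converts pLI and RVIS scores to percentile ranks over the supplied gene
#' universe, with average ranks for ties: percentile = 100 * rank / n over
#' the genes with a non-missing score. pLI is ranked descending (pLI near
#' 1, i.e. strong loss-of-function intolerance, gives a low percentile);
#' RVIS ascending (strongly negative RVIS gives a low percentile). A low
#' percentile therefore always means a more intolerant gene.
#'
#' @param records data frame with columns `gene`, `pli`, `rvis`
#'   (either may be `NA` per gene, but each metric needs at least one
#'   non-missing value).
#' @return `records` with added columns `pli_percentile`,
#'   `rvis_percentile` (missing where the score is missing).
#' @export
percentile_ranks <- function(records) {
  pct <- function(x, metric) {
    ok <- !is.na(x)
    if (!any(ok)) stop(sprintf("all %s scores missing", metric), call. = FALSE)
    out <- rep(NA_real_, length(x))
    out[ok] <- 100 * rank(x[ok], ties.method = "average") / sum(ok)
    out
  }
  records$pli_percentile <- pct(-records$pli, "pLI")
  records$rvis_percentile <- pct(records$rvis, "RVIS")
  records
}

#' Mann-Whitney / Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two samples. For small problems
#' (`length(a) + length(b) <= 12` by default) the p-value is exact,
#' enumerating all assignments of the pooled observations to the two
#' groups (ties handled through the value-based U statistic, counting tied
#' pairs as 1/2). Larger problems use the normal approximation with tie
#' correction and a 0.5 continuity correction.
#'
#' @param a,b numeric vectors, each non-empty.
#' @param exact logical; default enumerates exactly when
#'   `length(a) + length(b) <= 12`.
#' @return list with elements `U` (the Mann-Whitney U of sample `a`),
#'   `p` (two-sided), and `method`.
#' @export
rank_sum_test <- function(a, b, exact = NULL) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  m <- length(a); n <- length(b)
  stopifnot(m >= 1L, n >= 1L)
  u_stat <- function(x, y) {
    sum(vapply(x, function(v) sum(v > y) + 0.5 * sum(v == y), numeric(1)))
  }
  U <- u_stat(a, b)
  mid <- m * n / 2
  if (is.null(exact)) exact <- (m + n) <= 12L
  if (exact) {
    pool <- c(a, b)
    sets <- combn(m + n, m)
    dev <- abs(apply(sets, 2L, function(ix) u_stat(pool[ix], pool[-ix])) - mid)
    p <- mean(dev >= abs(U - mid) - 1e-9)
    return(list(U = U, p = p, method = "exact enumeration"))
  }
  N <- m + n
  ties <- table(c(a, b))
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal approximation"))
  z <- (abs(U - mid) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-max(z, 0)))
  list(U = U, p = p, method = "normal approximation")
}

#' Count genes in the intolerant top fraction
#'
#' Counts genes whose constraint percentiles all fall at or below a cutoff
#' (default: top 50%, i.e. the more intolerant half). Genes missing one
#' metric are judged on the available one; genes missing both are not
#' counted.
#'
#' @param records data frame with `pli_percentile` and/or
#'   `rvis_percentile` columns (see [percentile_ranks()]).
#' @param cutoff_percentile inclusive upper bound (default 50).
#' @return integer count.
#' @export
top_fraction_count <- function(records, cutoff_percentile = 50) {
  pct <- cbind(if ("pli_percentile" %in% names(records)) records$pli_percentile,
               if ("rvis_percentile" %in% names(records)) records$rvis_percentile)
  if (is.null(pct)) stop("no percentile columns present", call. = FALSE)
  sum(apply(pct, 1L, function(row) {
    any(!is.na(row)) && all(row[!is.na(row)] <= cutoff_percentile)
  }))
}
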