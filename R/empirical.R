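# Empirical percentiles with distribution-free order-statistic upper
# confidence limits.

#' Order-statistic index for a distribution-free upper confidence limit
#'
#' For a sample of size `n`, the k-th smallest observation is an upper
#' confidence limit for the population quantile at level `p` when `k` is the
#' smallest integer such that the binomial cumulative distribution
#' `P(X <= k)` with `X ~ Binomial(n, p)` reaches the confidence level.
#' Because `P(X <= n) = 1`, a valid index always exists and `k <= n`.
#'
#' @param n Sample size (>= 1).
#' @param p Quantile level in (0, 1); default the 95th percentile.
#' @param conf Confidence level in (0, 1); default 95%.
#' @return Integer index `k` in `1..n`.
#' @export
#' @examples
#' order_stat_index(100)
order_stat_index <- function(n, p = 0.95, conf = 0.95) {
  stopifnot(length(n) == 1L, n >= 1, n == round(n),
            p > 0, p < 1, conf > 0, conf < 1)
  k <- stats::qbinom(conf, size = n, prob = p)
  max(1L, min(as.integer(k), as.integer(n)))
}

#' Empirical percentile and its distribution-free upper confidence limit
#'
#' Computes the sample percentile at level `p` and the order-statistic upper
#' confidence limit at level `conf` for one set of absorption fractions.
#' The percentile uses a configurable quantile convention (default type 7,
#' linear interpolation between order statistics); the confidence limit is
#' always the exact k-th smallest observation, never interpolated.
#'
#' @param values Numeric vector of absorption fractions in (0, 1).
#' @param p Percentile level (default 0.95).
#' @param conf Confidence level for the upper limit (default 0.95).
#' @param quantile_type Quantile algorithm passed to [stats::quantile()].
#' @return List with `n`, `k`, `p95` and `ucl95` (both in percent of applied
#'   dose), and the raw fractions `p95_fraction`, `ucl95_fraction`.
#' @export
empirical_default <- function(values, p = 0.95, conf = 0.95,
                              quantile_type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    stop("empirical_default requires at least one value", call. = FALSE)
  }
  n <- length(values)
  k <- order_stat_index(n, p, conf)
  sorted <- sort(values)
  p95 <- unname(stats::quantile(values, probs = p, type = quantile_type))
  ucl <- sorted[k]
  list(
    n = n, k = k,
    p95 = 100 * p95, ucl95 = 100 * ucl,
    p95_fraction = p95, ucl95_fraction = ucl
  )
}

#' Empirical default-value table per category cell
#'
#' Applies [empirical_default()] to each of the eight formulation-category
#' by concentration-status cells of a prepared dataset.
#'
#' @param prepared A `da_prepared` table from [prepare_dataset()].
#' @param p,conf,quantile_type Passed to [empirical_default()].
#' @return Data frame with one row per non-empty cell: the cell key, the
#'   replicate count `n`, the order-statistic index `k`, and `p95`/`ucl95`
#'   in percent (full precision; round for presentation).
#' @export
empirical_table <- function(prepared, p = 0.95, conf = 0.95,
                            quantile_type = 7) {
  cells <- category_cells()
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- prepared$formulation_category == cells$formulation_category[i] &
      prepared$status == cells$status[i]
    if (!any(sel)) next
    res <- empirical_default(prepared$fraction_absorbed[sel],
                             p = p, conf = conf,
                             quantile_type = quantile_type)
    rows[[length(rows) + 1L]] <- data.frame(
      formulation_category = cells$formulation_category[i],
      status = cells$status[i],
      n = res$n, k = res$k, p95 = res$p95, ucl95 = res$ucl95,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
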