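#' Treatment-effectiveness arithmetic
#'
#' Helpers for summarising stone-treatment outcomes: a patient counts as
#' an effective response when the stone disappeared or shrank. The
#' effectiveness rate is reported as a percentage rounded half-up to two
#' decimals, and two groups are compared with a standard two-proportion
#' test on the effective / not-effective 2x2 table.
#'
#' @name clinical
NULL

#' Stone-outcome table
#'
#' @param disappeared,reduced,unchanged Non-negative integer counts of
#'   patients whose stones disappeared, shrank, or did not change.
#' @return A list of class `outcome_table` with a `total` field.
#' @export
#' @examples
#' outcome_table(22, 12, 4)
outcome_table <- function(disappeared, reduced, unchanged) {
  counts <- c(disappeared = disappeared, reduced = reduced,
              unchanged = unchanged)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0)
    stop("at least one patient is required", call. = FALSE)
  structure(as.list(counts), total = sum(counts), class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  cat(sprintf(
    "Stone outcomes: %d disappeared, %d reduced, %d unchanged (n = %d); effective rate %.2f%%\n",
    x$disappeared, x$reduced, x$unchanged, attr(x, "total"),
    effective_rate(x)))
  invisible(x)
}

#' Total effective rate of treatment
#'
#' `100 * (disappeared + reduced) / total`, rounded half-up to two
#' decimals.
#'
#' @param t An [outcome_table()].
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' effective_rate(outcome_table(22, 12, 4))  # 89.47
effective_rate <- function(t) {
  stopifnot(inherits(t, "outcome_table"))
  round_half_up(100 * (t$disappeared + t$reduced) / attr(t, "total"), 2)
}

#' Compare effectiveness rates of two groups
#'
#' Builds the 2x2 effective / not-effective table and runs a chi-square
#' test with continuity correction, falling back to Fisher's exact test
#' when any expected cell count is below 5. Symmetric in its arguments.
#'
#' @param a,b [outcome_table()] objects.
#' @param alpha Significance level (default 0.05).
#' @return List with `method`, `statistic` (NA for Fisher), `p_value`,
#'   `significant`, and the two rates.
#' @export
#' @examples
#' compare_rates(outcome_table(25, 20, 7), outcome_table(22, 12, 4))
compare_rates <- function(a, b, alpha = 0.05) {
  stopifnot(inherits(a, "outcome_table"), inherits(b, "outcome_table"))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  eff <- c(a$disappeared + a$reduced, b$disappeared + b$reduced)
  tot <- c(attr(a, "total"), attr(b, "total"))
  tab <- rbind(effective = eff, not_effective = tot - eff)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    res <- list(method = "fisher", statistic = NA_real_, p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    res <- list(method = "chisq", statistic = unname(ct$statistic),
                p_value = ct$p.value)
  }
  res$significant <- res$p_value < alpha
  res$rates <- c(effective_rate(a), effective_rate(b))
  res
}
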