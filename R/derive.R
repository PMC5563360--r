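#' Published risk summary
#'
#' A point estimate with a 95 per cent interval, as printed in a paper or
#' report, from which implicit event counts can be derived when the
#' underlying individual-level transition data are unavailable.
#'
#' @param kind `"absolute"` for an absolute per-interval risk or
#'   `"relative"` for a relative risk against a baseline group.
#' @param point Point estimate.
#' @param ci_low,ci_high 95 per cent confidence limits, `ci_low <= point
#'   <= ci_high`.
#' @param baseline_risk Baseline absolute risk; required when `kind =
#'   "relative"` so that the implied absolute risk `point * baseline_risk`
#'   can be formed.
#' @param time_unit Label for the risk interval (e.g. `"1 year"`).
#' @return An object of class `risk_summary`.
#' @export
risk_summary <- function(kind = c("absolute", "relative"), point,
                         ci_low, ci_high, baseline_risk = NULL,
                         time_unit = "1 year") {
  kind <- match.arg(kind)
  if (!(ci_low <= point && point <= ci_high)) {
    stop("need ci_low <= point <= ci_high")
  }
  if (kind == "relative" && is.null(baseline_risk)) {
    stop("relative-risk summaries need a baseline_risk")
  }
  if (kind == "absolute" && (point < 0 || point > 1)) {
    stop("absolute risk must lie in [0, 1]")
  }
  structure(list(kind = kind, point = point, ci_low = ci_low,
                 ci_high = ci_high, baseline_risk = baseline_risk,
                 time_unit = time_unit),
            class = "risk_summary")
}

#' Derive implicit event counts from a published risk summary
#'
#' Reconstructs the integer numerator and denominator that a published
#' risk estimate and its 95 per cent confidence interval imply, so that a
#' binomial likelihood can be formed for structure comparison when the
#' raw data are not available.  The standard error on the log-risk scale
#' is taken as the CI width divided by `2 * 1.96`, and the denominator is
#' solved from the delta-method binomial variance
#' \eqn{var(\log \hat p) \approx (1-p) / (n p)}.  For relative-risk
#' summaries the implied absolute risk is `point * baseline_risk` (the
#' baseline is treated as fixed).
#'
#' @param summary A [risk_summary()].
#' @param denominator_hint Optional known denominator; when supplied it is
#'   used directly and only the numerator is derived.
#' @return A list with integer `events` and `denominator`, the implied
#'   `risk`, and `ci_check`: the 95 per cent interval recomputed from the
#'   returned counts together with its maximum absolute discrepancy from
#'   the input interval (on the absolute-risk scale).
#' @examples
#' s <- risk_summary("absolute", 0.022, 0.016, 0.029)
#' derive_counts(s)
#' @export
derive_counts <- function(summary, denominator_hint = NULL) {
  stopifnot(inherits(summary, "risk_summary"))
  scale <- if (summary$kind == "relative") summary$baseline_risk else 1
  risk <- summary$point * scale
  lo <- summary$ci_low * scale
  hi <- summary$ci_high * scale
  if (risk <= 0 || risk >= 1) stop("implied absolute risk must be in (0, 1)")
  se_log <- (log(hi) - log(lo)) / (2 * stats::qnorm(0.975))
  if (!is.finite(se_log) || se_log <= 0) {
    stop("confidence interval implies zero or negative variance")
  }
  if (is.null(denominator_hint)) {
    n <- round((1 - risk) / (risk * se_log^2))
  } else {
    n <- round(denominator_hint)
  }
  if (n < 1) stop("derived denominator is below 1")
  x <- max(1L, round(risk * n))
  p_hat <- x / n
  half <- stats::qnorm(0.975) * sqrt((1 - p_hat) / x)
  ci <- p_hat * exp(c(-half, half))
  list(events = as.integer(x), denominator = as.integer(n), risk = p_hat,
       ci_check = list(ci_low = ci[1], ci_high = ci[2],
                       max_discrepancy = max(abs(ci - c(lo, hi)))))
}
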