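#' Individual-level cost or utility samples by state
#'
#' @param group Character vector of state labels, one per observation.
#' @param value Numeric vector of observed costs (currency per cycle,
#'   positive) or utilities (dimensionless).
#' @return An object of class `outcome_samples`: a data frame with
#'   columns `group` and `value`.
#' @export
outcome_samples <- function(group, value) {
  if (length(group) != length(value)) {
    stop("'group' and 'value' must have equal length")
  }
  df <- data.frame(group = as.character(group), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  class(df) <- c("outcome_samples", "data.frame")
  df
}

#' Read outcome samples from a CSV with header `group,value`
#' @param path Path to the CSV file.
#' @return An [outcome_samples()] object.
#' @export
read_outcome_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "value") %in% names(df))) {
    stop("outcome CSV must have header 'group,value'")
  }
  outcome_samples(df$group, df$value)
}

#' Compare common versus state-specific mean costs by gamma likelihood
#'
#' Fits gamma generalised linear models with a log link to individual
#' cost samples: one model with a single mean shared by all states and
#' one with a separate mean per state, both with a common shape.  The two
#' fits are compared by AIC; a negative difference (common minus
#' separate) supports equal costs and hence merging the states.
#'
#' @param samples An [outcome_samples()] with at least two groups, each
#'   holding at least two strictly positive values.
#' @return A `comparison_table` with rows `separate` (reference) and
#'   `common`; `delta_aic` is AIC(common) - AIC(separate).
#' @export
fit_cost_models <- function(samples) {
  stopifnot(inherits(samples, "outcome_samples"))
  if (any(samples$value <= 0)) stop("costs must be strictly positive")
  check_groups(samples)
  sep <- gamma_group_fit(samples$value, factor(samples$group))
  com <- gamma_group_fit(samples$value, factor(rep("all", nrow(samples))))
  outcome_comparison(sep, com)
}

# ML fit of gamma with group-specific means (log link) and shared shape.
# With a saturated group factor the mean MLEs are the group means for any
# shape, so the glm point fit plus the profiled ML shape is the joint MLE.
gamma_group_fit <- function(value, group) {
  fit <- if (nlevels(group) > 1L) {
    stats::glm(value ~ 0 + group, family = stats::Gamma(link = "log"))
  } else {
    stats::glm(value ~ 1, family = stats::Gamma(link = "log"))
  }
  shape <- MASS::gamma.shape(fit)$alpha
  mu <- stats::fitted(fit)
  ll <- sum(stats::dgamma(value, shape = shape, rate = shape / mu,
                          log = TRUE))
  list(loglik = ll, k = nlevels(group) + 1L,
       means = tapply(value, group, mean), shape = shape)
}

#' Compare common versus state-specific mean utilities by truncated
#' normal likelihood
#'
#' Utilities are modelled as normal with an upper truncation (by default
#' at 1, full health); the common-mean and separate-means models share a
#' single scale parameter and are compared by AIC as in
#' [fit_cost_models()].
#'
#' @param samples An [outcome_samples()]; all values must lie at or below
#'   `upper_bound`.
#' @param upper_bound Upper truncation point; `Inf` gives the untruncated
#'   normal model.
#' @return A `comparison_table` with rows `separate` and `common`.
#' @export
fit_utility_models <- function(samples, upper_bound = 1) {
  stopifnot(inherits(samples, "outcome_samples"))
  if (any(samples$value > upper_bound)) {
    stop("utility values exceed the upper truncation bound")
  }
  check_groups(samples)
  if (stats::sd(samples$value) == 0) {
    stop("utility samples have zero variance")
  }
  sep <- truncnorm_group_fit(samples$value, factor(samples$group),
                             upper_bound)
  com <- truncnorm_group_fit(samples$value,
                             factor(rep("all", nrow(samples))), upper_bound)
  outcome_comparison(sep, com)
}

truncnorm_loglik <- function(value, mu, sigma, b) {
  if (sigma <= 0) return(-Inf)
  ll <- sum(stats::dnorm(value, mu, sigma, log = TRUE))
  if (is.finite(b)) {
    ll <- ll - sum(stats::pnorm((b - mu) / sigma, log.p = TRUE))
  }
  ll
}

truncnorm_group_fit <- function(value, group, b) {
  g <- as.integer(group)
  ng <- nlevels(group)
  mu0 <- tapply(value, group, mean)
  s0 <- stats::sd(value)
  if (s0 == 0) s0 <- 1e-3
  obj <- function(par) {
    mu <- par[seq_len(ng)]
    sigma <- exp(par[ng + 1L])
    -truncnorm_loglik(value, mu[g], sigma, b)
  }
  opt <- stats::optim(c(mu0, log(s0)), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12))
  mu <- opt$par[seq_len(ng)]
  names(mu) <- levels(group)
  list(loglik = -opt$value, k = ng + 1L, means = mu,
       sd = exp(opt$par[ng + 1L]))
}

check_groups <- function(samples) {
  tab <- table(samples$group)
  if (length(tab) < 2L && length(unique(samples$group)) < 2L) {
    stop("need at least two groups to compare")
  }
  if (any(tab < 2L)) stop("every group needs at least two observations")
}

outcome_comparison <- function(sep, com) {
  rows <- data.frame(
    constraint = c("separate", "common"),
    loglik = c(sep$loglik, com$loglik),
    k = c(sep$k, com$k),
    aic = c(aic(sep$loglik, sep$k), aic(com$loglik, com$k)),
    stringsAsFactors = FALSE)
  rows$delta_aic <- rows$aic - rows$aic[1]
  rows$verdict <- c("reference",
                    if (rows$delta_aic[2] > 0) "split" else "merge")
  class(rows) <- c("comparison_table", "data.frame")
  attr(rows, "fits") <- list(separate = sep, common = com)
  rows
}

#' Prevalence-weighted cost (or utility) for a merged state
#'
#' @param values Named numeric vector of per-state values for the states
#'   being merged.
#' @param prevalence Non-negative weights, same length/order (or same
#'   names) as `values`; not all zero.  Weights are normalised internally,
#'   so any rescaling gives the same answer.
#' @return The weighted mean value for the merged state.
#' @examples
#' merge_costs(c(High = 150, Low = 110), c(High = 0.5, Low = 0.5))  # 130
#' @export
merge_costs <- function(values, prevalence) {
  if (length(values) != length(prevalence)) {
    stop("'values' and 'prevalence' must have equal length")
  }
  if (!is.null(names(values)) && !is.null(names(prevalence))) {
    prevalence <- prevalence[names(values)]
  }
  if (any(prevalence < 0) || any(is.na(prevalence))) {
    stop("prevalence weights must be non-negative")
  }
  tot <- sum(prevalence)
  if (tot == 0) stop("prevalence weights must not all be zero")
  if (all(values == values[1])) return(values[[1]])  # exact when equal
  sum(values * prevalence) / tot
}
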