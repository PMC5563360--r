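#' Define a decision strategy
#'
#' A strategy pairs a transition model with an initial distribution
#' (e.g. the post-diagnosis severity mix a test strategy produces) and an
#' optional per-state cost add-on (e.g. drug costs under treatment).
#'
#' @param label Strategy name.
#' @param model A [transition_model()].
#' @param init Initial distribution over the model's states.
#' @param cost_add Per-state additional cost per cycle, added to the
#'   (possibly sampled) state costs; defaults to zero.
#' @return An object of class `strategy`.
#' @export
strategy <- function(label, model, init, cost_add = NULL) {
  stopifnot(inherits(model, "transition_model"))
  init <- state_vector(init, model$space, "init")
  cost_add <- state_vector(cost_add, model$space, "cost_add")
  structure(list(label = label, model = model, init = init,
                 cost_add = cost_add),
            class = "strategy")
}

#' Specify a probabilistic sensitivity analysis
#'
#' Priors are keyed by state (or origin-state) label on a *sampling
#' space*: by default the strategies' own state space, or the merged
#' space when `merge` is supplied, in which case the sampled merged-level
#' parameters are expanded to the split space with the merge constraints
#' imposed (shared Dirichlet row, shared cost and utility per group).
#' Parameters not given a prior keep their template values (point
#' masses).
#'
#' @param trans_alpha Named list: origin state -> named vector of
#'   Dirichlet parameters over its destinations.  The conjugate default
#'   in practice is observed transition counts plus 1.
#' @param cost_prior Named list: state -> `c(meanlog, sdlog)` of a
#'   log-normal cost distribution.
#' @param utility_prior Named list: state -> `c(mean, sd, upper)` of an
#'   upper-truncated normal utility distribution (`upper` defaults to 1).
#' @param n_draws Number of PSA draws (>= 1).
#' @param seed Integer seed; draws are reproducible bit-for-bit.
#' @param wtp Willingness to pay per QALY (currency).
#' @param n_cycles Cohort horizon in cycles.
#' @param discount_annual,half_cycle Passed to [expected_outcomes()].
#' @param merge Optional [merge_spec()]: sample at the merged level and
#'   expand, so a constrained split-model PSA matches the merged-model
#'   PSA draw for draw under the same seed.
#' @return An object of class `psa_spec`.
#' @export
psa_spec <- function(trans_alpha = list(), cost_prior = list(),
                     utility_prior = list(), n_draws = 1000, seed = 1,
                     wtp = 20000, n_cycles = 10, discount_annual = 0,
                     half_cycle = FALSE, merge = NULL) {
  if (n_draws < 1) stop("'n_draws' must be at least 1")
  if (wtp < 0) stop("'wtp' must be non-negative")
  for (a in trans_alpha) {
    if (any(unlist(a) <= 0)) stop("Dirichlet parameters must be positive")
  }
  structure(list(trans_alpha = trans_alpha, cost_prior = cost_prior,
                 utility_prior = utility_prior, n_draws = n_draws,
                 seed = seed, wtp = wtp, n_cycles = n_cycles,
                 discount_annual = discount_annual,
                 half_cycle = half_cycle, merge = merge),
            class = "psa_spec")
}

# one Dirichlet row via normalised gammas (fixed RNG consumption order)
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# upper-truncated normal by inverse CDF (one uniform per value)
rtruncnorm1 <- function(n, mean, sd, upper = 1) {
  u <- stats::runif(n)
  if (sd == 0) return(rep(pmin(mean, upper), n))
  stats::qnorm(u * stats::pnorm((upper - mean) / sd)) * sd + mean
}

# draw one parameter set on the sampling space; block order is fixed
# (transition rows, then costs, then utilities, each in spec order)
draw_params <- function(spec) {
  p_rows <- lapply(spec$trans_alpha, rdirichlet1)
  for (o in names(p_rows)) names(p_rows[[o]]) <- names(spec$trans_alpha[[o]])
  costs <- vapply(spec$cost_prior, function(pr) {
    stats::rlnorm(1, meanlog = pr[1], sdlog = pr[2])
  }, 1)
  utils_ <- vapply(spec$utility_prior, function(pr) {
    up <- if (length(pr) >= 3) pr[3] else 1
    rtruncnorm1(1, pr[1], pr[2], up)
  }, 1)
  list(p_rows = p_rows, costs = costs, utilities = utils_)
}

# apply sampled parameters (keyed on the sampling space) to a strategy's
# model, expanding merged-level values to the split space when needed
apply_params <- function(strat, params, spec) {
  model <- strat$model
  states <- model$space$states
  group_of <- stats::setNames(states, states)
  if (!is.null(spec$merge)) {
    for (i in seq_along(spec$merge$groups)) {
      group_of[spec$merge$groups[[i]]] <- spec$merge$labels[i]
    }
  }
  P <- model$P
  for (o in names(params$p_rows)) {
    row <- params$p_rows[[o]]
    members <- states[group_of[states] == o]
    if (length(members) == 0L) {
      stop("prior references unknown sampling state '", o, "'")
    }
    for (s in members) {
      new_row <- stats::setNames(numeric(length(states)), states)
      for (d in names(row)) {
        dest_members <- states[group_of[states] == d]
        if (length(dest_members) == 1L) {
          new_row[dest_members] <- row[d]
        } else {
          # within-group allocation keeps the template's conditional split
          tmpl <- P[s, dest_members]
          w <- if (sum(tmpl) > 0) tmpl / sum(tmpl)
               else rep(1 / length(dest_members), length(dest_members))
          new_row[dest_members] <- row[d] * w
        }
      }
      P[s, ] <- new_row
    }
  }
  cost <- model$cost
  for (o in names(params$costs)) {
    cost[states[group_of[states] == o]] <- params$costs[o]
  }
  utility <- model$utility
  for (o in names(params$utilities)) {
    utility[states[group_of[states] == o]] <- params$utilities[o]
  }
  transition_model(model$space, P, cost + strat$cost_add, utility,
                   model$cycle_length)
}

strategy_outcomes <- function(strat, params, spec) {
  m <- apply_params(strat, params, spec)
  tr <- cohort_trace(m, strat$init, spec$n_cycles)
  expected_outcomes(tr, m, spec$discount_annual, spec$half_cycle)
}

flatten_params <- function(params) {
  out <- c()
  for (o in names(params$p_rows)) {
    r <- params$p_rows[[o]]
    out <- c(out, stats::setNames(as.numeric(r),
                                  paste0("p[", o, "->", names(r), "]")))
  }
  named_block <- function(v, prefix) {
    if (length(v) == 0L) return(NULL)
    stats::setNames(as.numeric(v), paste0(prefix, "[", names(v), "]"))
  }
  c(out, named_block(params$costs, "cost"),
    named_block(params$utilities, "utility"))
}

block_of_column <- function(cols) {
  sub("^(p\\[[^-]+)->.*\\]$", "\\1]", cols)
}

#' Run a probabilistic sensitivity analysis
#'
#' For each draw, samples transition rows (Dirichlet), state costs
#' (log-normal) and utilities (truncated normal) from the priors in
#' `spec`, runs the cohort engine for every strategy, and records costs,
#' QALYs and net monetary benefit `NB = wtp * QALY - cost`.  Parameter
#' draws are shared across strategies within a draw, and the whole run is
#' reproducible under the spec's seed.
#'
#' @param strategies List of [strategy()] objects sharing one state
#'   space.
#' @param spec A [psa_spec()].
#' @return An object of class `psa_results`: list with matrices `nb`,
#'   `cost`, `qaly` (draw x strategy), `params` (draw x flattened
#'   parameter data frame), `wtp`, and `spec`.
#' @export
sample_psa <- function(strategies, spec) {
  stopifnot(inherits(spec, "psa_spec"))
  if (inherits(strategies, "strategy")) strategies <- list(strategies)
  labels <- vapply(strategies, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("strategy labels must be unique")
  spaces <- lapply(strategies, function(s) s$model$space$states)
  if (!all(vapply(spaces, identical, TRUE, y = spaces[[1]]))) {
    stop("strategies must share one state space")
  }
  set.seed(spec$seed)
  n <- spec$n_draws
  nb <- cost <- qaly <- matrix(NA_real_, n, length(strategies),
                               dimnames = list(NULL, labels))
  plist <- vector("list", n)
  for (i in seq_len(n)) {
    params <- draw_params(spec)
    plist[[i]] <- flatten_params(params)
    for (j in seq_along(strategies)) {
      out <- strategy_outcomes(strategies[[j]], params, spec)
      cost[i, j] <- out["cost"]
      qaly[i, j] <- out["qaly"]
    }
  }
  nb <- spec$wtp * qaly - cost
  params_df <- as.data.frame(do.call(rbind, plist))
  structure(list(nb = nb, cost = cost, qaly = qaly, params = params_df,
                 wtp = spec$wtp, spec = spec, strategies = labels),
            class = "psa_results")
}

#' @export
print.psa_results <- function(x, ...) {
  cat("PSA with", nrow(x$nb), "draws,", ncol(x$nb), "strategies (wtp =",
      x$wtp, ")\n")
  cat("Mean NB by strategy:\n")
  print(round(colMeans(x$nb), 2))
  invisible(x)
}

#' Incremental net benefit versus a reference strategy
#'
#' @param results A [sample_psa()] result.
#' @param reference Label of the reference strategy.
#' @return Data frame with one row per strategy: mean INB and central
#'   95 per cent interval across draws.
#' @export
inb <- function(results, reference) {
  stopifnot(inherits(results, "psa_results"))
  if (!(reference %in% results$strategies)) {
    stop("unknown reference strategy '", reference, "'")
  }
  d <- results$nb - results$nb[, reference]
  data.frame(strategy = colnames(d),
             inb = colMeans(d),
             lower = apply(d, 2, stats::quantile, 0.025),
             upper = apply(d, 2, stats::quantile, 0.975),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Probability each strategy is cost effective
#'
#' The fraction of PSA draws in which each strategy attains the highest
#' net benefit; exact ties are split equally among the tied strategies.
#'
#' @param results A [sample_psa()] result.
#' @return Named numeric vector of probabilities summing to 1.
#' @export
prob_ce <- function(results) {
  stopifnot(inherits(results, "psa_results"))
  if (ncol(results$nb) < 2L) stop("need at least two strategies")
  wins <- stats::setNames(numeric(ncol(results$nb)),
                          colnames(results$nb))
  for (i in seq_len(nrow(results$nb))) {
    r <- results$nb[i, ]
    best <- which(r == max(r))
    wins[best] <- wins[best] + 1 / length(best)
  }
  wins / nrow(results$nb)
}

#' Cost-effectiveness acceptability curve
#'
#' Recomputes the probability of cost effectiveness over a grid of
#' willingness-to-pay values from the stored per-draw costs and QALYs.
#'
#' @param results A [sample_psa()] result.
#' @param wtp_grid Numeric vector of willingness-to-pay values.
#' @return Data frame with columns `wtp`, `strategy`, `p_ce`.
#' @export
ceac <- function(results, wtp_grid) {
  stopifnot(inherits(results, "psa_results"))
  out <- do.call(rbind, lapply(wtp_grid, function(w) {
    nb <- w * results$qaly - results$cost
    tmp <- results
    tmp$nb <- nb
    p <- prob_ce(tmp)
    data.frame(wtp = w, strategy = names(p), p_ce = as.numeric(p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Expected value of perfect information
#'
#' Per-decision EVPI is the expected net benefit of deciding with
#' perfect knowledge of the parameters minus the expected net benefit of
#' the best decision under current uncertainty:
#' `mean(max_s NB) - max_s(mean NB)`.  It is non-negative and invariant
#' to adding a constant to all net benefits.
#'
#' @param results A [sample_psa()] result.
#' @param population Optional scaling list with `size` (persons affected
#'   per year), `horizon_years`, and `discount` (annual rate), giving the
#'   population EVPI `evpi * size * sum((1 + discount)^-(0:(H-1)))`.
#' @return List with `per_decision` and (when scaling is supplied)
#'   `population`.
#' @export
evpi <- function(results, population = NULL) {
  stopifnot(inherits(results, "psa_results"))
  per <- mean(apply(results$nb, 1, max)) - max(colMeans(results$nb))
  out <- list(per_decision = per)
  if (!is.null(population)) {
    disc <- if (is.null(population$discount)) 0 else population$discount
    h <- population$horizon_years
    out$population <- per * population$size *
      sum((1 + disc)^-(0:(h - 1)))
  }
  out
}

#' Expected value of partial perfect information
#'
#' Estimates the value of learning a subset of parameter blocks exactly.
#' The default regression estimator fits, per strategy, a smooth of net
#' benefit on the chosen parameters (a generalised additive model) and
#' evaluates `mean(max_s fitted) - max_s(mean fitted)`.  A two-level
#' nested Monte Carlo estimator is available for validation via
#' [evppi_two_level()].
#'
#' @param results A [sample_psa()] result.
#' @param subset Character vector of parameter blocks, e.g.
#'   `"p[Well]"` (a whole transition row), `"cost[High]"`,
#'   `"utility[High]"`; individual flattened columns such as
#'   `"p[Well->Dead]"` are also accepted.
#' @return The EVPPI estimate (same currency units as net benefit);
#'   within estimator error it lies in `[0, EVPI]`.
#' @export
evppi <- function(results, subset) {
  stopifnot(inherits(results, "psa_results"))
  if (length(subset) == 0L) stop("parameter subset must be non-empty")
  cols <- colnames(results$params)
  blocks <- block_of_column(cols)
  pick <- cols %in% subset | blocks %in% subset
  if (!any(pick)) {
    stop("no sampled parameters match the requested subset")
  }
  X <- results$params[, pick, drop = FALSE]
  # drop degenerate (constant) and redundant simplex-complement columns
  keep <- vapply(X, function(v) stats::sd(v) > 1e-12, TRUE)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0L) return(0)
  names(X) <- paste0("x", seq_len(ncol(X)))
  fitted <- sapply(seq_len(ncol(results$nb)), function(j) {
    dat <- cbind(nb = results$nb[, j], X)
    if (stats::sd(dat$nb) < 1e-12) return(rep(dat$nb[1], nrow(dat)))
    kk <- max(3, min(10, floor(nrow(dat) / (5 * ncol(X)))))
    form <- stats::as.formula(paste(
      "nb ~", paste0("s(", names(X), ", k = ", kk, ")", collapse = " + ")))
    stats::fitted(mgcv::gam(form, data = dat))
  })
  max(0, mean(apply(fitted, 1, max)) - max(colMeans(fitted)))
}

#' Two-level Monte Carlo EVPPI
#'
#' Nested estimator: for each outer draw of the chosen parameter blocks,
#' the remaining parameters are sampled `n_inner` times and net benefits
#' averaged; EVPPI is the mean over outer draws of the best inner-mean
#' net benefit, minus the best overall strategy's mean.
#'
#' @param strategies,spec As in [sample_psa()].
#' @param subset Character vector of parameter blocks (`"p[origin]"`,
#'   `"cost[state]"`, `"utility[state]"`).
#' @param n_outer,n_inner Outer and inner sample sizes.
#' @param seed Integer seed.
#' @return The EVPPI estimate.
#' @export
evppi_two_level <- function(strategies, spec, subset, n_outer = 100,
                            n_inner = 100, seed = 1) {
  stopifnot(inherits(spec, "psa_spec"))
  if (inherits(strategies, "strategy")) strategies <- list(strategies)
  known <- c(paste0("p[", names(spec$trans_alpha), "]"),
             paste0("cost[", names(spec$cost_prior), "]"),
             paste0("utility[", names(spec$utility_prior), "]"))
  bad <- setdiff(subset, known)
  if (length(bad)) stop("unknown parameter blocks: ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  ns <- length(strategies)
  inner_means <- matrix(NA_real_, n_outer, ns)
  all_nb <- matrix(NA_real_, n_outer * n_inner, ns)
  row <- 0L
  for (o in seq_len(n_outer)) {
    outer <- draw_params(spec)
    acc <- matrix(NA_real_, n_inner, ns)
    for (i in seq_len(n_inner)) {
      inner <- draw_params(spec)
      # perfect information on the subset: overwrite with the outer draw
      for (nm in names(spec$trans_alpha)) {
        if (paste0("p[", nm, "]") %in% subset) {
          inner$p_rows[[nm]] <- outer$p_rows[[nm]]
        }
      }
      for (nm in names(spec$cost_prior)) {
        if (paste0("cost[", nm, "]") %in% subset) {
          inner$costs[nm] <- outer$costs[nm]
        }
      }
      for (nm in names(spec$utility_prior)) {
        if (paste0("utility[", nm, "]") %in% subset) {
          inner$utilities[nm] <- outer$utilities[nm]
        }
      }
      for (j in seq_len(ns)) {
        out <- strategy_outcomes(strategies[[j]], inner, spec)
        acc[i, j] <- spec$wtp * out["qaly"] - out["cost"]
      }
      row <- row + 1L
      all_nb[row, ] <- acc[i, ]
    }
    inner_means[o, ] <- colMeans(acc)
  }
  max(0, mean(apply(inner_means, 1, max)) - max(colMeans(all_nb)))
}
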