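#' Discrete-time Markov transition model
#'
#' Bundles a state space with a row-stochastic per-cycle transition
#' matrix and per-state costs and utilities.
#'
#' @param space A [state_space()]; its ordering fixes the matrix layout.
#' @param P Square transition matrix, rows and columns in the order of
#'   `space$states`; every row must sum to 1 (tolerance `1e-8`) and
#'   absorbing states must have a unit diagonal entry.
#' @param cost Per-state cost per cycle (currency); named or in state
#'   order.  Defaults to zero.
#' @param utility Per-state utility (dimensionless, accrued per year
#'   occupied).  Defaults to zero.
#' @param cycle_length Cycle length in years (e.g. `12 / 52` for a
#'   12-week cycle).
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(space, P, cost = NULL, utility = NULL,
                             cycle_length = 1) {
  stopifnot(inherits(space, "state_space"))
  ns <- length(space$states)
  P <- as.matrix(P)
  if (!all(dim(P) == ns)) stop("'P' must be ", ns, " x ", ns)
  dimnames(P) <- list(space$states, space$states)
  if (any(P < -1e-12) || any(P > 1 + 1e-12)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  if (any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("every row of 'P' must sum to 1")
  }
  for (a in space$absorbing) {
    if (abs(P[a, a] - 1) > 1e-8) {
      stop("absorbing state '", a, "' must have P[", a, ",", a, "] = 1")
    }
  }
  cost <- state_vector(cost, space, "cost")
  utility <- state_vector(utility, space, "utility")
  if (cycle_length <= 0) stop("'cycle_length' must be positive")
  structure(list(space = space, P = P, cost = cost, utility = utility,
                 cycle_length = cycle_length),
            class = "transition_model")
}

state_vector <- function(x, space, what) {
  ns <- length(space$states)
  if (is.null(x)) x <- numeric(ns)
  if (!is.null(names(x))) {
    miss <- setdiff(space$states, names(x))
    if (length(miss)) stop(what, " missing for states: ",
                           paste(miss, collapse = ", "))
    x <- x[space$states]
  } else if (length(x) != ns) {
    stop("'", what, "' must have one value per state")
  }
  stats::setNames(as.numeric(x), space$states)
}

#' @export
print.transition_model <- function(x, digits = 4, ...) {
  cat("Transition model,", length(x$space$states), "states, cycle length",
      x$cycle_length, "years\n")
  print(round(x$P, digits))
  print(data.frame(cost = x$cost, utility = x$utility))
  invisible(x)
}

#' Propagate a cohort through a transition model
#'
#' Standard cohort recursion: the occupancy row vector at cycle `t + 1`
#' is the occupancy at `t` post-multiplied by the transition matrix.
#'
#' @param model A [transition_model()].
#' @param init Initial distribution over states (named or in state
#'   order); must sum to 1.
#' @param n_cycles Number of cycles (non-negative integer).
#' @return An object of class `cohort_trace`: matrix of dimension
#'   `(n_cycles + 1) x n_states`, row `t + 1` holding the occupancy after
#'   `t` cycles.
#' @export
cohort_trace <- function(model, init, n_cycles) {
  stopifnot(inherits(model, "transition_model"))
  init <- state_vector(init, model$space, "init")
  if (abs(sum(init) - 1) > 1e-8) stop("'init' must sum to 1")
  if (any(init < 0)) stop("'init' must be non-negative")
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 0) stop("'n_cycles' must be non-negative")
  occ <- matrix(0, n_cycles + 1L, length(init),
                dimnames = list(0:n_cycles, model$space$states))
  occ[1L, ] <- init
  for (t in seq_len(n_cycles)) {
    occ[t + 1L, ] <- occ[t, , drop = FALSE] %*% model$P
  }
  structure(occ, class = c("cohort_trace", "matrix"))
}

#' Expected discounted costs and QALYs of a cohort trace
#'
#' @param trace A [cohort_trace()] produced from `model`.
#' @param model The [transition_model()] supplying per-state costs and
#'   utilities.
#' @param discount_annual Annual discount rate; the per-cycle factor is
#'   `1 / (1 + discount_annual)^cycle_length`.  Default 0 (no
#'   discounting).
#' @param half_cycle Apply the half-cycle (trapezoidal) correction,
#'   weighting the first and last cycle occupancies by one half.
#' @return Named numeric vector `c(cost = ..., qaly = ...)`.  Utilities
#'   accrue per year, so each cycle contributes
#'   `occupancy * utility * cycle_length`.
#' @export
expected_outcomes <- function(trace, model, discount_annual = 0,
                              half_cycle = FALSE) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(model, "transition_model"))
  if (ncol(trace) != length(model$space$states)) {
    stop("trace and model state spaces differ")
  }
  nt <- nrow(trace)
  delta <- (1 / (1 + discount_annual)^model$cycle_length)^(0:(nt - 1L))
  w <- rep(1, nt)
  if (half_cycle && nt > 1L) w[c(1L, nt)] <- 0.5
  wt <- delta * w
  c(cost = sum(wt * (trace %*% model$cost)),
    qaly = sum(wt * (trace %*% model$utility)) * model$cycle_length)
}

#' Merge states of a transition model
#'
#' Collapses each merge group into a single state.  The merged state's
#' outward probabilities are the (common) member values, its inbound
#' probabilities are sums over members, and its cost and utility are
#' prevalence-weighted means of the member values.  Unless `force = TRUE`,
#' the member rows must already satisfy the equality constraints implied
#' by the merge (within `tol`); merging then leaves all cohort
#' predictions unchanged.
#'
#' @param model A [transition_model()].
#' @param merge A [merge_spec()].
#' @param prevalence Named list (one element per group) or named numeric
#'   vector of baseline prevalence weights for the member states, used to
#'   average costs and utilities (and, with `force`, probabilities).
#'   Defaults to equal weights.
#' @param force Merge even when the constraints are violated, averaging
#'   the member rows with the prevalence weights.
#' @param tol Tolerance for the constraint check.
#' @return A [transition_model()] on the merged state space; merged
#'   states take the position of their first member.
#' @export
merge_model <- function(model, merge, prevalence = NULL, force = FALSE,
                        tol = 1e-8) {
  stopifnot(inherits(model, "transition_model"),
            inherits(merge, "merge_spec"))
  states <- model$space$states
  bad <- setdiff(unlist(merge$groups), states)
  if (length(bad)) stop("unknown merge states: ", paste(bad, collapse = ", "))

  wts <- lapply(seq_along(merge$groups), function(i) {
    g <- merge$groups[[i]]
    w <- if (is.null(prevalence)) {
      stats::setNames(rep(1, length(g)), g)
    } else if (is.list(prevalence)) {
      pv <- prevalence[[merge$labels[i]]]
      if (is.null(pv)) pv <- prevalence[[i]]
      pv
    } else prevalence[g]
    if (is.null(names(w))) names(w) <- g
    w <- w[g]
    if (any(is.na(w)) || any(w < 0) || sum(w) == 0) {
      stop("invalid prevalence weights for group ", merge$labels[i])
    }
    # kept unnormalised: pooling as sum(w * v) / sum(w) is exact when
    # the member values are identical
    w
  })

  # merged label occupies the slot of the group's first member
  new_states <- states
  drop <- character()
  group_of <- stats::setNames(states, states)
  for (i in seq_along(merge$groups)) {
    g <- merge$groups[[i]]
    new_states[match(g[1], states)] <- merge$labels[i]
    drop <- c(drop, g[-1])
    group_of[g] <- merge$labels[i]
  }
  keep <- !(states %in% drop)
  new_states <- new_states[keep]

  ns <- length(new_states)
  newP <- matrix(0, ns, ns, dimnames = list(new_states, new_states))
  # aggregate columns (inbound sums) first
  colagg <- t(rowsum(t(model$P), group_of[states], reorder = FALSE))
  colagg <- colagg[, new_states, drop = FALSE]
  for (i in seq_len(ns)) {
    s <- new_states[i]
    if (s %in% merge$labels) {
      idx <- which(merge$labels == s)
      g <- merge$groups[[idx]]
      rows <- colagg[g, , drop = FALSE]
      spread <- apply(rows, 2, function(cc) diff(range(cc)))
      # the in-group column (stay probability) is automatically shared
      if (!force && any(spread > tol)) {
        stop("outward probabilities differ across {",
             paste(g, collapse = ", "),
             "} beyond tolerance; use force = TRUE to average")
      }
      newP[i, ] <- if (all(spread == 0)) {
        # members agree bitwise: the common value is exact
        rows[1, ]
      } else {
        as.numeric(wts[[idx]] %*% rows) / sum(wts[[idx]])
      }
    } else {
      newP[i, ] <- colagg[s, ]
    }
  }

  cost <- utility <- stats::setNames(numeric(ns), new_states)
  for (i in seq_len(ns)) {
    s <- new_states[i]
    if (s %in% merge$labels) {
      idx <- which(merge$labels == s)
      g <- merge$groups[[idx]]
      cost[i] <- merge_costs(model$cost[g], wts[[idx]])
      utility[i] <- merge_costs(model$utility[g], wts[[idx]])
    } else {
      cost[i] <- model$cost[s]
      utility[i] <- model$utility[s]
    }
  }

  absorbing <- unique(group_of[model$space$absorbing])
  absorbing <- absorbing[vapply(absorbing, function(a) {
    members <- states[group_of[states] == a]
    all(members %in% model$space$absorbing)
  }, TRUE)]
  transition_model(state_space(new_states, absorbing), newP,
                   cost, utility, model$cycle_length)
}

#' Check the merged/constrained-split equivalence
#'
#' When a split model satisfies the merge constraints (equal outward
#' probabilities, costs and utilities within each group), the merged
#' model reproduces its aggregated occupancy exactly, and therefore the
#' same expected costs and QALYs.  This function computes both sides and
#' reports the maximum absolute discrepancies.
#'
#' @param split A [transition_model()] on the split state space.
#' @param merged A [transition_model()] on the merged space, typically
#'   from [merge_model()].
#' @param merge The [merge_spec()] mapping split states to merged states.
#' @param init Initial distribution on the split space.
#' @param n_cycles Horizon in cycles.
#' @param discount_annual,half_cycle Passed to [expected_outcomes()].
#' @return A list with `occupancy` (max abs per-cycle difference between
#'   aggregated split occupancy and merged occupancy), `cost`, `qaly`
#'   (absolute differences in totals), and `max` (the largest of the
#'   three).
#' @export
check_equivalence <- function(split, merged, merge, init, n_cycles,
                              discount_annual = 0, half_cycle = FALSE) {
  stopifnot(inherits(split, "transition_model"),
            inherits(merged, "transition_model"))
  states <- split$space$states
  group_of <- stats::setNames(states, states)
  for (i in seq_along(merge$groups)) {
    group_of[merge$groups[[i]]] <- merge$labels[i]
  }
  if (!setequal(unique(group_of), merged$space$states)) {
    stop("merged model's states do not match the merge mapping")
  }
  init <- state_vector(init, split$space, "init")
  # both recursions run in compensated (double-double) arithmetic so the
  # comparison reflects structural differences, not rounding noise
  tr_s <- dd_cohort_trace(split$P, init, n_cycles)
  init_m <- rowsum(init, group_of[states], reorder = FALSE)[, 1]
  init_m <- init_m[merged$space$states]
  tr_m <- dd_cohort_trace(merged$P, init_m, n_cycles)

  # aggregate the split trace over merge groups, exactly
  mstates <- merged$space$states
  nt <- n_cycles + 1L
  agg <- list(hi = matrix(0, nt, length(mstates)),
              lo = matrix(0, nt, length(mstates)))
  for (s in seq_along(states)) {
    j <- match(group_of[states[s]], mstates)
    for (t in seq_len(nt)) {
      cur <- dd_add(list(hi = agg$hi[t, j], lo = agg$lo[t, j]),
                    list(hi = tr_s$hi[t, s], lo = tr_s$lo[t, s]))
      agg$hi[t, j] <- cur$hi
      agg$lo[t, j] <- cur$lo
    }
  }
  occ_diff <- max(abs((agg$hi - tr_m$hi) + (agg$lo - tr_m$lo)))

  delta <- (1 / (1 + discount_annual)^split$cycle_length)^(0:(nt - 1L))
  w <- rep(1, nt)
  if (half_cycle && nt > 1L) w[c(1L, nt)] <- 0.5
  wt <- delta * w
  diff_total <- function(v_split, v_merged) {
    tot_s <- dd_weighted_total(tr_s, wt, v_split)
    tot_m <- dd_weighted_total(tr_m, wt, v_merged)
    abs((tot_s$hi - tot_m$hi) + (tot_s$lo - tot_m$lo))
  }
  res <- list(
    occupancy = occ_diff,
    cost = unname(diff_total(split$cost, merged$cost)),
    qaly = unname(diff_total(split$utility, merged$utility) *
                    split$cycle_length))
  res$max <- max(unlist(res))
  res
}
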