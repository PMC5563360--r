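#' Ground truth for simulation studies
#'
#' Defines the data-generating process for synthetic transition
#' histories and individual-level outcome samples: a true transition
#' model, a cohort of independent subjects followed for a fixed number of
#' cycles, gamma-distributed costs and upper-truncated normal utilities.
#'
#' @param model A [transition_model()]: the true structure.
#' @param n_subjects Number of independent subjects (>= 1).
#' @param n_cycles Cycles observed per subject; one transition is
#'   recorded per subject-cycle, with no censoring.
#' @param init Initial distribution over states; the starting cohort is
#'   allocated deterministically in proportion to it (largest-remainder
#'   rounding), so row denominators are fixed by design.  Defaults to
#'   uniform over non-absorbing states.
#' @param cost_family Named list: state -> `c(mean, shape)` of a gamma
#'   cost distribution.
#' @param utility_family Named list: state -> `c(mean, sd, upper)` of an
#'   upper-truncated normal utility distribution (`upper` defaults 1).
#' @param seed Integer seed used by the generators.
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(model, n_subjects, n_cycles = 1, init = NULL,
                       cost_family = list(), utility_family = list(),
                       seed = 1) {
  stopifnot(inherits(model, "transition_model"))
  if (n_subjects < 1) stop("'n_subjects' must be at least 1")
  if (is.null(init)) {
    live <- setdiff(model$space$states, model$space$absorbing)
    init <- stats::setNames(rep(0, length(model$space$states)),
                            model$space$states)
    init[live] <- 1 / length(live)
  }
  init <- state_vector(init, model$space, "init")
  structure(list(model = model, n_subjects = as.integer(n_subjects),
                 n_cycles = as.integer(n_cycles), init = init,
                 cost_family = cost_family,
                 utility_family = utility_family, seed = seed),
            class = "truth_spec")
}

# largest-remainder allocation of n subjects to the initial states
allocate_init <- function(init, n) {
  target <- init * n
  base <- floor(target)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Simulate a transition count table from known truth
#'
#' Subjects move independently according to the true transition matrix;
#' all origin-destination transitions over all subject-cycles are
#' tabulated.  Destinations with positive true probability are listed
#' even when unobserved, so the table's support matches the truth.
#'
#' @param truth A [truth_spec()].
#' @param seed Optional seed overriding `truth$seed`.
#' @return A [count_table()].
#' @export
simulate_counts <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "truth_spec"))
  set.seed(if (is.null(seed)) truth$seed else seed)
  P <- truth$model$P
  states <- truth$model$space$states
  ns <- length(states)
  occupancy <- allocate_init(truth$init, truth$n_subjects)
  counts <- matrix(0, ns, ns, dimnames = list(states, states))
  for (cyc in seq_len(truth$n_cycles)) {
    nxt <- stats::setNames(numeric(ns), states)
    for (s in which(occupancy > 0)) {
      moves <- stats::rmultinom(1, occupancy[s], P[s, ])[, 1]
      counts[s, ] <- counts[s, ] + moves
      nxt <- nxt + moves
    }
    occupancy <- nxt
  }
  active <- rowSums(counts) > 0  # origins never occupied yield no data
  sup <- which((P > 0 | counts > 0) & active, arr.ind = TRUE)
  sup <- sup[order(sup[, 1], sup[, 2]), , drop = FALSE]
  count_table(states[sup[, 1]], states[sup[, 2]],
              counts[sup])
}

#' Simulate individual-level cost and utility samples
#'
#' @param truth A [truth_spec()] with cost and/or utility families
#'   parameterised for the requested states.
#' @param states States to sample for.
#' @param what `"cost"` or `"utility"`.
#' @param n_per_state Samples per state; defaults to `truth$n_subjects`.
#' @param seed Optional seed overriding `truth$seed`.
#' @return An [outcome_samples()].
#' @export
simulate_outcomes <- function(truth, states,
                              what = c("cost", "utility"),
                              n_per_state = NULL, seed = NULL) {
  stopifnot(inherits(truth, "truth_spec"))
  what <- match.arg(what)
  set.seed(if (is.null(seed)) truth$seed else seed)
  if (is.null(n_per_state)) n_per_state <- truth$n_subjects
  fam <- if (what == "cost") truth$cost_family else truth$utility_family
  miss <- setdiff(states, names(fam))
  if (length(miss)) {
    stop(what, " family not parameterised for: ",
         paste(miss, collapse = ", "))
  }
  g <- rep(states, each = n_per_state)
  v <- unlist(lapply(states, function(s) {
    pr <- fam[[s]]
    if (what == "cost") {
      mean <- pr[1]; shape <- pr[2]
      if (shape <= 0) stop("gamma shape must be positive")
      stats::rgamma(n_per_state, shape = shape, rate = shape / mean)
    } else {
      up <- if (length(pr) >= 3) pr[3] else 1
      rtruncnorm1(n_per_state, pr[1], pr[2], up)
    }
  }))
  outcome_samples(g, v)
}

#' Operating characteristics of AIC structure selection
#'
#' Repeatedly simulates count tables from the truth and records how often
#' AIC favours the merged (constrained) structure over the split
#' (unconstrained) one.  When the equality constraints truly hold with a
#' single constrained probability, large-sample theory gives the split
#' model a selection rate of about `P(chi-squared_1 > 2)`, roughly 15.7
#' per cent; under a gross violation the merge should essentially never
#' be selected.
#'
#' @param truth A [truth_spec()].
#' @param merge A [merge_spec()] naming the states whose equality is
#'   assessed.
#' @param n_reps Number of simulated datasets (0 gives an empty report).
#' @param seed Integer seed; replicate `r` uses `seed + r`.
#' @param exits Exit set passed to [constraints_from_merge()].
#' @return A list with `n_reps`, `merge_rate`, `split_rate`, and the
#'   per-replicate `delta_aic` vector.
#' @export
selection_experiment <- function(truth, merge, n_reps, seed = 1,
                                 exits = NULL) {
  stopifnot(inherits(truth, "truth_spec"), inherits(merge, "merge_spec"))
  if (n_reps == 0) {
    return(list(n_reps = 0L, merge_rate = NA_real_,
                split_rate = NA_real_, delta_aic = numeric()))
  }
  cs <- constraints_from_merge(truth$model$space, merge, exits)
  delta <- vapply(seq_len(n_reps), function(r) {
    tab <- simulate_counts(truth, seed = seed + r)
    cmp <- compare_structures(tab, list(merged = cs))
    cmp$delta_aic[2]
  }, 1)
  list(n_reps = as.integer(n_reps),
       merge_rate = mean(delta <= 0),
       split_rate = mean(delta > 0),
       delta_aic = delta)
}
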