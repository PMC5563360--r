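# Random-instance generators for property-style tests.

# sample() treats a length-1 numeric as 1:x; this helper never does
pick1 <- function(x) if (length(x) == 1L) x else sample(x, 1)

rdirich <- function(n, alpha = rep(1, n)) {
  g <- rgamma(n, alpha)
  g / sum(g)
}

# random count table with <= 4 origins / destinations, counts <= max_count
random_count_table <- function(seed, max_origins = 4, max_dests = 4,
                               max_count = 50) {
  set.seed(seed)
  no <- pick1(2:max_origins)
  nd <- pick1(2:max_dests)
  origins <- paste0("o", seq_len(no))
  dests <- paste0("d", seq_len(nd))
  df <- expand.grid(from = origins, to = dests, stringsAsFactors = FALSE)
  df <- df[order(df$from), ]
  df$count <- sample(0:max_count, nrow(df), replace = TRUE)
  # guarantee positive row totals
  for (o in origins) {
    idx <- which(df$from == o)
    if (sum(df$count[idx]) == 0) df$count[idx[1]] <- 1L
  }
  count_table(df$from, df$to, df$count)
}

# random equality constraint on one destination over a random origin group
random_constraint <- function(tab, seed) {
  set.seed(seed)
  origins <- names(row_totals(tab))
  dests <- unique(tab$to)
  d <- sample(dests, 1)
  g <- sample(origins, pick1(2:length(origins)))
  constraint_set(prob = list(list(dest = d, origins = g)))
}

# random split model whose merge group satisfies the equality
# constraints (common exit probabilities, costs and utilities), with
# free member-specific movement among the merging states ("reversible").
# Probabilities are dyadic rationals (integer multiples of 2^-20) so
# that rows sum to exactly 1 and the equality constraints hold exactly
# in double arithmetic: the generated instance satisfies the theorem's
# premise, not merely a rounded approximation of it.
random_constrained_model <- function(seed, max_states = 6) {
  set.seed(seed)
  denom <- 2^20
  dyadic_row <- function(total, k) {
    as.vector(rmultinom(1, total, runif(k) + 0.05))
  }
  ns <- pick1(3:max_states)
  states <- paste0("s", seq_len(ns))
  gsize <- pick1(2:min(3, ns - 1))
  group <- sample(states, gsize)
  others <- setdiff(states, group)
  exit_total <- round(denom * runif(1, 0.05, 0.6))
  exit_int <- dyadic_row(exit_total, length(others))
  P <- matrix(0, ns, ns, dimnames = list(states, states))
  for (s in group) {
    P[s, others] <- exit_int / denom
    P[s, group] <- dyadic_row(denom - exit_total, gsize) / denom
  }
  for (s in others) {
    P[s, ] <- dyadic_row(denom, ns) / denom
  }
  cost <- stats::setNames(runif(ns, 0, 2000), states)
  utility <- stats::setNames(runif(ns, 0, 1), states)
  cost[group] <- cost[group][1]
  utility[group] <- utility[group][1]
  sp <- state_space(states)
  model <- transition_model(sp, P, cost, utility)
  init <- stats::setNames(dyadic_row(denom, ns) / denom, states)
  list(model = model,
       merge = merge_spec(list(group), labels = "merged", space = sp),
       init = init,
       n_cycles = pick1(1:50))
}

# a small decision problem with a closed-form EVPI: the sampled utility
# of Ill is shared by both strategies, but 'treat' keeps the whole
# cohort in Ill at a drug cost while 'none' starts only 40% there, so
# NB(treat) - NB(none) = 1.2 * u - 0.6 ~ Normal(0, 0.12) for
# u ~ Normal(0.5, 0.1); EVPI = 0.12 / sqrt(2 * pi).  The 'Limbo' state
# is never occupied, so its sampled cost is decision-irrelevant.
evppi_problem <- function(n_draws, seed, with_limbo_prior = TRUE) {
  sp <- state_space(c("Ill", "Limbo", "Dead"), absorbing = "Dead")
  m <- transition_model(sp, diag(3))
  strategies <- list(
    strategy("treat", m, c(Ill = 1, Limbo = 0, Dead = 0),
             cost_add = c(Ill = 0.3, Limbo = 0, Dead = 0)),
    strategy("none", m, c(Ill = 0.4, Limbo = 0, Dead = 0.6)))
  cost_prior <- if (with_limbo_prior) list(Limbo = c(0, 0.5)) else list()
  spec <- psa_spec(utility_prior = list(Ill = c(0.5, 0.1, 10)),
                   cost_prior = cost_prior,
                   n_draws = n_draws, seed = seed, wtp = 1, n_cycles = 1)
  list(strategies = strategies, spec = spec)
}

cecat_death_constraint <- function() {
  constraint_set(prob = list(list(dest = "dead",
                                  origins = c("medium", "high"))))
}

cecat_mi_constraint <- function() {
  constraint_set(prob = list(list(dest = "mi",
                                  origins = c("medium", "high"))))
}

# two-row binomial truth for selection experiments: probabilities p1, p2
# of a single exit event, n subjects per row, one cycle
binomial_truth <- function(p1, p2, n_per_row, seed = 1) {
  sp <- state_space(c("A", "B", "Event"), absorbing = "Event")
  P <- rbind(c(1 - p1, 0, p1),
             c(0, 1 - p2, p2),
             c(0, 0, 1))
  truth_spec(transition_model(sp, P), n_subjects = 2 * n_per_row,
             n_cycles = 1, init = c(A = 0.5, B = 0.5, Event = 0),
             seed = seed)
}
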