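#' CECaT derived death counts
#'
#' One-year death counts for the medium- and high-risk coronary artery
#' disease states, back-derived from published relative risks of death:
#' 126 of 571 patients at medium risk and 259 of 754 at high risk.
#'
#' @return A [count_table()] with origins `medium`, `high` and
#'   destinations `dead`, `alive`.
#' @export
cecat_death_counts <- function() {
  count_table(from = c("medium", "medium", "high", "high"),
              to = c("dead", "alive", "dead", "alive"),
              count = c(126, 571 - 126, 259, 754 - 259))
}

#' CECaT derived non-fatal myocardial infarction counts
#'
#' Annual non-fatal MI counts: 39 of 1717 at medium risk and 62 of 2159
#' at high risk.
#'
#' @return A [count_table()] with origins `medium`, `high` and
#'   destinations `mi`, `no_mi`.
#' @export
cecat_mi_counts <- function() {
  count_table(from = c("medium", "medium", "high", "high"),
              to = c("mi", "no_mi", "mi", "no_mi"),
              count = c(39, 1717 - 39, 62, 2159 - 62))
}

#' CECaT published cost and utility summaries
#'
#' Mean, standard deviation and sample size of individual-level annual
#' costs and utilities for the medium- and high-risk states, from the
#' trial subset with known disease severity.  Shipped for documentation
#' and prior construction: the individual records behind them are not
#' public, so cost/utility likelihood comparisons on these states cannot
#' be recomputed from the summaries alone.
#'
#' @return A data frame with columns `outcome`, `group`, `mean`, `sd`,
#'   `n`.
#' @export
cecat_outcome_summary <- function() {
  data.frame(
    outcome = c("cost", "cost", "utility", "utility"),
    group = c("medium", "high", "medium", "high"),
    mean = c(1530, 1930, 0.81, 0.78),
    sd = c(880, 1070, 0.12, 0.21),
    n = c(59, 19, 59, 19),
    stringsAsFactors = FALSE)
}

#' Coronary artery disease split-severity model
#'
#' A four-state model (`Well`, `High`, `Low`, `Dead`) separating
#' high-risk and low-risk disease.  The defaults satisfy the merge
#' constraints (equal death probability, cost and utility for `High` and
#' `Low`), so [merge_model()] collapses the two severities without
#' changing any cohort prediction; pass unequal values to break the
#' constraints.
#'
#' @param p_high_dead,p_low_dead Per-cycle death probabilities from the
#'   two severity states.
#' @param p_high_low,p_low_high Per-cycle transitions between severities
#'   (the "reversible" variant; default 0).
#' @param cost,utility Named vectors over the four states.
#' @param cycle_length Cycle length in years.
#' @return A [transition_model()].
#' @export
cad_split_model <- function(p_high_dead = 0.1, p_low_dead = 0.1,
                            p_high_low = 0, p_low_high = 0,
                            cost = c(Well = 50, High = 1700, Low = 1700,
                                     Dead = 0),
                            utility = c(Well = 0.95, High = 0.8,
                                        Low = 0.8, Dead = 0),
                            cycle_length = 1) {
  sp <- state_space(c("Well", "High", "Low", "Dead"), absorbing = "Dead")
  P <- rbind(
    Well = c(0.84, 0.05, 0.10, 0.01),
    High = c(0, 1 - p_high_dead - p_high_low, p_high_low, p_high_dead),
    Low  = c(0, p_low_high, 1 - p_low_dead - p_low_high, p_low_dead),
    Dead = c(0, 0, 0, 1))
  transition_model(sp, P, cost, utility, cycle_length)
}

#' The CAD severity merge proposal
#'
#' @return A [merge_spec()] merging `High` and `Low` into `CAD`.
#' @export
cad_merge <- function() {
  merge_spec(list(c("High", "Low")), labels = "CAD")
}

#' The four-state depression state space and its merge candidates
#'
#' States `well`, `mild`, `moderate`, `severe` with all transitions
#' permitted, and the three candidate coarsenings considered for it:
#' merging all depression severities (`two_state`), merging moderate
#' with severe (`mod_severe`), and merging mild with moderate
#' (`mild_mod`).
#'
#' @return A list with `space` (a [state_space()]) and `merges` (named
#'   list of [merge_spec()] objects).
#' @export
depression_structures <- function() {
  sp <- state_space(c("well", "mild", "moderate", "severe"))
  list(space = sp,
       merges = list(
         two_state = merge_spec(list(c("mild", "moderate", "severe")),
                                labels = "depressed", space = sp),
         mod_severe = merge_spec(list(c("moderate", "severe")),
                                 labels = "mod_severe", space = sp),
         mild_mod = merge_spec(list(c("mild", "moderate")),
                               labels = "mild_mod", space = sp)))
}

#' Progressive three-state example with unshared exits
#'
#' A progressive model in which state 1 cannot reach the absorbing state
#' 3 directly while state 2 can, so merging states 1 and 2 requires the
#' encompassing-model construction of [extend_for_unshared_exits()].
#'
#' @param p13 Probability of the direct 1 to 3 transition in the
#'   encompassing model (`0` recovers the restricted model).
#' @return A list with `space`, `merge`, `transitions` (the restricted
#'   allowed set, without 1 to 3) and `model` (a [transition_model()] on
#'   the encompassing space).
#' @export
progressive_three_state <- function(p13 = 0) {
  sp <- state_space(c("1", "2", "3"), absorbing = "3")
  at <- data.frame(from = c("1", "1", "2", "2", "2", "3"),
                   to = c("1", "2", "1", "2", "3", "3"),
                   stringsAsFactors = FALSE)
  P <- rbind(c(0.7 - p13, 0.3, p13),
             c(0.1, 0.7, 0.2),
             c(0, 0, 1))
  list(space = sp,
       merge = merge_spec(list(c("1", "2")), labels = "1+2", space = sp),
       transitions = at,
       model = transition_model(sp, P))
}

#' A two-strategy example where structure choice flips the decision
#'
#' Two severities (`Low`, `High`) share their exit probability to `Dead`
#' but differ sharply in cost and utility.  The `treat` strategy shifts
#' the initial mix towards `Low` at a per-cycle drug cost; `usual` care
#' starts mostly in `High`.  Under the split structure (and under the
#' partially merged structure, which shares transitions but keeps
#' state-specific costs and utilities) treatment is clearly worthwhile;
#' the fully merged structure averages costs and utilities over a fixed
#' baseline prevalence, hides the severity shift, and recommends usual
#' care instead.
#'
#' @param wtp Willingness to pay per QALY.
#' @param n_cycles Horizon in cycles.
#' @return A list with strategy lists `split`, `merged`, `partial`
#'   (each two [strategy()] objects, `treat` and `usual`), the
#'   `merge` spec, the baseline `prevalence` weights, `wtp` and
#'   `n_cycles`.
#' @export
example_strategies <- function(wtp = 20000, n_cycles = 10) {
  sp <- state_space(c("Low", "High", "Dead"), absorbing = "Dead")
  P <- rbind(Low = c(0.9, 0, 0.1),
             High = c(0, 0.9, 0.1),
             Dead = c(0, 0, 1))
  split <- transition_model(
    sp, P, cost = c(Low = 100, High = 2000, Dead = 0),
    utility = c(Low = 0.85, High = 0.5, Dead = 0))
  ms <- merge_spec(list(c("Low", "High")), labels = "Ill", space = sp)
  prev <- c(Low = 0.5, High = 0.5)
  merged <- merge_model(split, ms, prevalence = prev)
  drug <- 300
  init_treat <- c(Low = 0.8, High = 0.2, Dead = 0)
  init_usual <- c(Low = 0.2, High = 0.8, Dead = 0)
  add_split_treat <- c(Low = drug, High = drug, Dead = 0)
  agg <- function(init) c(Ill = sum(init[c("Low", "High")]),
                          Dead = init[["Dead"]])
  list(
    split = list(
      treat = strategy("treat", split, init_treat, add_split_treat),
      usual = strategy("usual", split, init_usual)),
    merged = list(
      treat = strategy("treat", merged, agg(init_treat),
                       c(Ill = drug, Dead = 0)),
      usual = strategy("usual", merged, agg(init_usual))),
    # partially merged: transition structure shared (already equal here),
    # costs and utilities kept state specific
    partial = list(
      treat = strategy("treat", split, init_treat, add_split_treat),
      usual = strategy("usual", split, init_usual)),
    merge = ms, prevalence = prev, wtp = wtp, n_cycles = n_cycles)
}
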