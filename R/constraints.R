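#' Derive the equality constraints implied by a merge proposal
#'
#' Merging a group of states is equivalent, for cohort predictions, to
#' keeping the split state space but constraining (i) the transition
#' probability into each shared exit state to be equal across the group,
#' (ii) the per-cycle costs of the group members to be equal, and (iii)
#' their utilities to be equal.  Transitions among the members of a group
#' are left unconstrained: any internal movement is allowed without
#' affecting the equivalence.
#'
#' @param space A [state_space()].
#' @param merge A [merge_spec()].
#' @param exits Exit destinations per group: either a character vector
#'   (shared by all groups) or a list with one character vector per group.
#'   Exits must lie outside the group.  If `NULL`, the exits default to all
#'   states outside the group.
#'
#' @return A [constraint_set()] with one probability constraint per
#'   (group, exit) pair and one cost- and utility-equality set per group.
#' @examples
#' sp <- state_space(c("Well", "High", "Low", "Dead"), absorbing = "Dead")
#' ms <- merge_spec(list(c("High", "Low")), labels = "CAD", space = sp)
#' constraints_from_merge(sp, ms, exits = "Dead")
#' @seealso [validate_mergeability()] for checking that group members share
#'   their exits, and [extend_for_unshared_exits()] when they do not.
#' @export
constraints_from_merge <- function(space, merge, exits = NULL) {
  stopifnot(inherits(space, "state_space"), inherits(merge, "merge_spec"))
  ngrp <- length(merge$groups)
  if (is.null(exits)) {
    exits <- lapply(merge$groups, function(g) setdiff(space$states, g))
  } else if (is.character(exits)) {
    exits <- rep(list(exits), ngrp)
  }
  if (length(exits) != ngrp) stop("need one exit set per merge group")

  prob <- list()
  for (i in seq_len(ngrp)) {
    g <- merge$groups[[i]]
    ex <- as.character(exits[[i]])
    bad <- setdiff(c(g, ex), space$states)
    if (length(bad)) stop("unknown state label: ", paste(bad, collapse = ", "))
    if (length(intersect(ex, g))) {
      stop("exit states must lie outside the merge group")
    }
    for (d in ex) {
      prob[[length(prob) + 1L]] <- list(dest = d, origins = g)
    }
  }
  constraint_set(prob = prob,
                 cost_equal = unname(merge$groups),
                 utility_equal = unname(merge$groups))
}

#' Check whether merge groups share their exit states
#'
#' A direct merge (equivalently, equality constraints) is only available
#' when every member of a group can reach the same set of destinations
#' outside the group.  When members have different exits -- for instance a
#' progressive model where only the later state can reach death -- the
#' comparison must go through the encompassing model built by
#' [extend_for_unshared_exits()].
#'
#' @param space A [state_space()].
#' @param merge A [merge_spec()].
#' @param allowed_transitions Two-column matrix or data frame of allowed
#'   (origin, destination) pairs, or a list of such pairs.
#'
#' @return A data frame with one row per group: `group` (label), `verdict`
#'   (`"shared"` or `"non-shared"`), and `missing` (comma-separated
#'   origin->destination transitions absent for some member but present for
#'   another).
#' @export
validate_mergeability <- function(space, merge, allowed_transitions) {
  stopifnot(inherits(space, "state_space"), inherits(merge, "merge_spec"))
  at <- normalise_transitions(allowed_transitions)
  out <- data.frame(group = character(), verdict = character(),
                    missing = character(), stringsAsFactors = FALSE)
  for (i in seq_along(merge$groups)) {
    g <- merge$groups[[i]]
    # exit set of each member: destinations outside the group
    exit_of <- lapply(g, function(s) {
      setdiff(at$to[at$from == s], g)
    })
    union_exits <- sort(unique(unlist(exit_of)))
    missing <- character()
    for (j in seq_along(g)) {
      lack <- setdiff(union_exits, exit_of[[j]])
      if (length(lack)) {
        missing <- c(missing, paste0(g[j], "->", lack))
      }
    }
    out <- rbind(out, data.frame(
      group = merge$labels[i],
      verdict = if (length(missing)) "non-shared" else "shared",
      missing = paste(missing, collapse = ", "),
      stringsAsFactors = FALSE))
  }
  out
}

#' Build the encompassing model for groups with unshared exits
#'
#' When the states proposed for merging have different exit states, neither
#' the smaller model nor the merged model nests the other, so they cannot be
#' compared directly.  Both are instead expressed as constrained versions of
#' an encompassing model in which every member of the group has every exit
#' observed for any member: constraint set A forces the added transitions to
#' zero (recovering the original smaller model), while constraint set B
#' equates the exit probabilities across the group (recovering the merged
#' model).  Fitting A and B against the same encompassing model makes the
#' AIC comparison valid.
#'
#' @inheritParams validate_mergeability
#'
#' @return A list with `transitions` (the extended allowed-transition data
#'   frame), `constraints_zero` (set A) and `constraints_equal` (set B).
#' @examples
#' sp <- state_space(c("1", "2", "3"), absorbing = "3")
#' ms <- merge_spec(list(c("1", "2")), space = sp)
#' at <- rbind(c("1", "1"), c("1", "2"), c("2", "1"), c("2", "2"), c("2", "3"))
#' ext <- extend_for_unshared_exits(sp, ms, at)
#' ext$constraints_zero   # P(1 -> 3) = 0 recovers the original model
#' ext$constraints_equal  # P(1 -> 3) = P(2 -> 3) recovers the merged model
#' @export
extend_for_unshared_exits <- function(space, merge, allowed_transitions) {
  stopifnot(inherits(space, "state_space"), inherits(merge, "merge_spec"))
  if (length(merge$groups) == 0L) stop("merge spec has no groups")
  at <- normalise_transitions(allowed_transitions)
  zero <- list()
  prob <- list()
  for (i in seq_along(merge$groups)) {
    g <- merge$groups[[i]]
    exit_of <- lapply(g, function(s) setdiff(at$to[at$from == s], g))
    union_exits <- sort(unique(unlist(exit_of)))
    for (j in seq_along(g)) {
      for (d in setdiff(union_exits, exit_of[[j]])) {
        at <- rbind(at, data.frame(from = g[j], to = d,
                                   stringsAsFactors = FALSE))
        zero[[length(zero) + 1L]] <- c(g[j], d)
      }
    }
    for (d in union_exits) {
      prob[[length(prob) + 1L]] <- list(dest = d, origins = g)
    }
  }
  at <- unique(at)
  rownames(at) <- NULL
  list(transitions = at,
       constraints_zero = constraint_set(zero = zero),
       constraints_equal = constraint_set(
         prob = prob,
         cost_equal = unname(merge$groups),
         utility_equal = unname(merge$groups)))
}

normalise_transitions <- function(x) {
  if (is.matrix(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.list(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, function(p) {
      data.frame(from = p[1], to = p[2], stringsAsFactors = FALSE)
    }))
  }
  names(x)[1:2] <- c("from", "to")
  x$from <- as.character(x$from)
  x$to <- as.character(x$to)
  unique(x[, c("from", "to")])
}
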