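#' Define a state space for a discrete-time multi-state model
#'
#' A state space is an ordered set of uniquely labelled health states.  The
#' ordering is canonical: it fixes the row/column order of every transition
#' matrix, count table and cohort trace built on this space.
#'
#' @param states Character vector of unique, non-empty state labels.
#' @param absorbing Character vector of labels flagged as absorbing (e.g.
#'   "Dead").  Must be a subset of `states`.
#'
#' @return An object of class `state_space` with elements `states` and
#'   `absorbing`.
#' @examples
#' state_space(c("Well", "High", "Low", "Dead"), absorbing = "Dead")
#' @export
state_space <- function(states, absorbing = character()) {
  states <- as.character(states)
  absorbing <- as.character(absorbing)
  if (length(states) == 0L) stop("state space must contain at least one state")
  if (anyDuplicated(states)) stop("state labels must be unique")
  if (any(!nzchar(states))) stop("state labels must be non-empty")
  bad <- setdiff(absorbing, states)
  if (length(bad)) {
    stop("absorbing labels not in state space: ", paste(bad, collapse = ", "))
  }
  structure(list(states = states, absorbing = absorbing),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space with", length(x$states), "states:",
      paste(x$states, collapse = ", "), "\n")
  if (length(x$absorbing)) {
    cat("Absorbing:", paste(x$absorbing, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Propose merging groups of states
#'
#' A merge specification names one or more disjoint groups of states that
#' are candidates for merging into a single state each.  Merging a group is
#' equivalent to constraining the outward transition probabilities, the
#' costs and the utilities of its member states to be equal; the implied
#' constraints are produced by [constraints_from_merge()].
#'
#' @param groups List of character vectors, each with at least two state
#'   labels; groups must be pairwise disjoint.
#' @param labels Character vector of labels for the merged states, one per
#'   group.  Defaults to the member labels joined by `"+"`.
#' @param space Optional [state_space()]; when supplied, membership is
#'   validated against it.
#'
#' @return An object of class `merge_spec` with elements `groups` (named
#'   list) and `labels`.
#' @examples
#' sp <- state_space(c("Well", "High", "Low", "Dead"), absorbing = "Dead")
#' merge_spec(list(c("High", "Low")), labels = "CAD", space = sp)
#' @export
merge_spec <- function(groups, labels = NULL, space = NULL) {
  if (is.character(groups)) groups <- list(groups)
  groups <- lapply(groups, as.character)
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every merge group must have at least two member states")
  }
  all_members <- unlist(groups)
  if (anyDuplicated(all_members)) {
    stop("merge groups must be pairwise disjoint")
  }
  if (!is.null(space)) {
    stopifnot(inherits(space, "state_space"))
    bad <- setdiff(all_members, space$states)
    if (length(bad)) {
      stop("merge group members not in state space: ",
           paste(bad, collapse = ", "))
    }
  }
  if (is.null(labels)) {
    labels <- vapply(groups, paste, "", collapse = "+")
  }
  if (length(labels) != length(groups)) {
    stop("need exactly one label per merge group")
  }
  names(groups) <- labels
  structure(list(groups = groups, labels = labels), class = "merge_spec")
}

#' @export
print.merge_spec <- function(x, ...) {
  for (i in seq_along(x$groups)) {
    cat(x$labels[i], "<- {", paste(x$groups[[i]], collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Construct a set of parameter constraints
#'
#' Constraint sets encode the equalities that re-express a merged-state
#' model on the split state space: equal outward transition probabilities
#' into shared destinations, equal per-state costs and utilities, and
#' structural zeroes used by the encompassing-model construction for
#' states with unshared exits.
#'
#' @param prob List of probability-equality constraints; each element is a
#'   list with `dest` (a destination label) and `origins` (character vector
#'   of origin labels whose transition probability into `dest` is equal).
#' @param cost_equal List of character vectors; the states in each vector
#'   share a common cost.
#' @param utility_equal List of character vectors; the states in each
#'   vector share a common utility.
#' @param zero List of `c(origin, dest)` pairs whose transition probability
#'   is fixed at exactly zero.
#'
#' @return An object of class `constraint_set`.
#' @examples
#' # P(High -> Dead) = P(Low -> Dead), shared cost and utility
#' constraint_set(
#'   prob = list(list(dest = "Dead", origins = c("High", "Low"))),
#'   cost_equal = list(c("High", "Low")),
#'   utility_equal = list(c("High", "Low"))
#' )
#' @export
constraint_set <- function(prob = list(), cost_equal = list(),
                           utility_equal = list(), zero = list()) {
  prob <- lapply(prob, function(pc) {
    if (is.null(pc$dest) || is.null(pc$origins)) {
      stop("each prob constraint needs a 'dest' and an 'origins' field")
    }
    list(dest = as.character(pc$dest)[1],
         origins = unique(as.character(pc$origins)))
  })
  # an origin may not be tied to two different groups for one destination
  for (d in unique(vapply(prob, `[[`, "", "dest"))) {
    orig <- unlist(lapply(prob[vapply(prob, `[[`, "", "dest") == d],
                          `[[`, "origins"))
    if (anyDuplicated(orig)) {
      stop("origin appears in two constraints for destination '", d, "'")
    }
  }
  zero <- lapply(zero, function(z) {
    z <- as.character(z)
    if (length(z) != 2L) stop("zero constraints are (origin, dest) pairs")
    z
  })
  structure(list(prob = prob,
                 cost_equal = lapply(cost_equal, as.character),
                 utility_equal = lapply(utility_equal, as.character),
                 zero = zero),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  if (!length(x$prob) && !length(x$cost_equal) &&
      !length(x$utility_equal) && !length(x$zero)) {
    cat("Empty constraint set (unconstrained model)\n")
    return(invisible(x))
  }
  for (pc in x$prob) {
    cat("P(", paste0(pc$origins, "->", pc$dest, collapse = " = "), ")\n",
        sep = " ")
  }
  for (g in x$cost_equal) cat("equal costs: {", paste(g, collapse = ", "), "}\n")
  for (g in x$utility_equal) {
    cat("equal utilities: {", paste(g, collapse = ", "), "}\n")
  }
  for (z in x$zero) cat("P(", z[1], "->", z[2], ") = 0\n")
  invisible(x)
}

# number of probability-equality reductions implied by the set:
# (g-1) per equality over g origins, 1 per structural zero
n_constraint_reductions <- function(constraints) {
  sum(vapply(constraints$prob, function(pc) length(pc$origins) - 1L, 1L)) +
    length(constraints$zero)
}
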