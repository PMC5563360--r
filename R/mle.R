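#' Unconstrained maximum-likelihood fit of a transition count table
#'
#' Each origin row is an independent multinomial observation; the MLE of
#' each transition probability is the observed proportion.  The reported
#' log-likelihood includes the multinomial normalising coefficient, so
#' absolute AICs (not only differences) are meaningful and comparable
#' across nested constrained fits of the same table.
#'
#' @param table A [count_table()] with positive row totals.
#' @return An object of class `fit_result`: list with `estimates` (data
#'   frame `from`, `to`, `prob`), `loglik` (nats), `k` (free parameters:
#'   destinations minus one, per row), and `aic`.
#' @examples
#' tab <- count_table(c("medium", "medium", "high", "high"),
#'                    c("dead", "alive", "dead", "alive"),
#'                    c(126, 445, 259, 495))
#' row_mle(tab)  # AIC 17.4: separate death risks for medium and high
#' @export
row_mle <- function(table) {
  constrained_mle(table, constraint_set())
}

#' Constrained maximum-likelihood fit of a transition count table
#'
#' Maximises the product-multinomial likelihood subject to the equality
#' and structural-zero constraints of a [constraint_set()].  When each
#' origin in a constrained group is subject to the same set of
#' destination constraints (the case arising from any merge proposal),
#' the MLE is available in closed form: the common probability for
#' destination \eqn{i} over origin group \eqn{G} is the pooled proportion
#' \deqn{\hat q_i = \sum_{j \in G} x_{ji} / \sum_{j \in G} n_j,}
#' and the unconstrained probabilities in each constrained row are the
#' observed conditional proportions rescaled to the remaining mass.  For
#' constraint patterns that couple rows asymmetrically the fit falls back
#' to direct numerical maximisation.
#'
#' @param table A [count_table()].
#' @param constraints A [constraint_set()]; only its probability and zero
#'   constraints are used (cost/utility equalities do not enter the
#'   transition likelihood).
#' @return A `fit_result`; see [row_mle()].  `k` is reduced by
#'   \eqn{|G| - 1} per equality constraint and by 1 per structural zero.
#' @examples
#' tab <- count_table(c("medium", "medium", "high", "high"),
#'                    c("dead", "alive", "dead", "alive"),
#'                    c(126, 445, 259, 495))
#' cs <- constraint_set(prob = list(list(dest = "dead",
#'                                       origins = c("medium", "high"))))
#' constrained_mle(tab, cs)  # AIC 39.6: pooled death risk
#' @export
constrained_mle <- function(table, constraints = constraint_set()) {
  stopifnot(inherits(table, "count_table"))
  if (!inherits(constraints, "constraint_set")) {
    stop("'constraints' must be a constraint_set")
  }
  rt <- row_totals(table)
  if (any(rt <= 0)) stop("every origin row must have a positive total")
  origins <- names(rt)
  dest_of <- split(table$to, factor(table$from, levels = origins))
  x_of <- split(table$count, factor(table$from, levels = origins))

  labels <- c(table$from, table$to)
  for (pc in constraints$prob) {
    miss <- setdiff(c(pc$dest, pc$origins), labels)
    if (length(miss)) {
      stop("constraint references labels absent from table: ",
           paste(miss, collapse = ", "))
    }
    for (o in pc$origins) {
      if (!(pc$dest %in% dest_of[[o]])) {
        stop("constrained transition ", o, "->", pc$dest,
             " is not a destination listed for origin '", o, "'")
      }
    }
  }

  # structural zeroes: probability exactly 0; data with a positive count
  # there have zero likelihood
  zero_key <- vapply(constraints$zero, paste, "", collapse = "\r")
  pair_key <- paste(table$from, table$to, sep = "\r")
  miss_zero <- setdiff(zero_key, pair_key)
  if (length(miss_zero)) {
    stop("zero constraint references transitions absent from table")
  }
  is_zero <- pair_key %in% zero_key

  # constraint signature per origin: which (dest, group) constraints bind it
  grp_id <- seq_along(constraints$prob)
  cons_of <- lapply(origins, function(o) {
    which(vapply(constraints$prob, function(pc) o %in% pc$origins, TRUE))
  })
  names(cons_of) <- origins

  prob <- numeric(nrow(table))
  prob[is_zero] <- 0
  if (any(table$count[is_zero] > 0)) {
    # p = 0 with observed events: likelihood is zero
    loglik_zero_violation <- TRUE
  } else loglik_zero_violation <- FALSE

  closed_ok <- length(constraints$prob) == 0L || all(vapply(
    grp_id, function(g) {
      G <- constraints$prob[[g]]$origins
      sigs <- lapply(cons_of[G], sort)
      all(vapply(sigs, identical, TRUE, y = sigs[[1]]))
    }, TRUE))

  if (closed_ok) {
    q <- vapply(constraints$prob, function(pc) {
      num <- sum(table$count[table$from %in% pc$origins &
                               table$to == pc$dest])
      num / sum(rt[pc$origins])
    }, 1)
    for (o in origins) {
      idx <- which(table$from == o)
      d <- table$to[idx]
      zi <- is_zero[idx]
      ci <- rep(NA_integer_, length(idx))
      for (g in cons_of[[o]]) {
        ci[d == constraints$prob[[g]]$dest] <- g
      }
      pr <- numeric(length(idx))
      pr[!is.na(ci)] <- q[ci[!is.na(ci)]]
      free <- is.na(ci) & !zi
      rem <- 1 - sum(pr[!is.na(ci)])
      if (rem < -1e-12) stop("constraints force a row sum above 1 for '",
                             o, "'")
      rem <- max(rem, 0)
      xf <- table$count[idx][free]
      if (any(free)) {
        pr[free] <- if (sum(xf) > 0) rem * xf / sum(xf)
                    else rem / sum(free)
      }
      prob[idx] <- pr
    }
  } else {
    prob <- fit_constrained_numeric(table, constraints, is_zero, cons_of)
  }

  ll <- table_loglik(table, prob)
  if (loglik_zero_violation) ll <- -Inf

  m <- vapply(dest_of, length, 1L)
  k <- sum(m - 1L) -
    sum(vapply(constraints$prob, function(pc) length(pc$origins) - 1L, 1L)) -
    length(constraints$zero)

  est <- data.frame(from = table$from, to = table$to, prob = prob,
                    stringsAsFactors = FALSE)
  structure(list(estimates = est, loglik = ll, k = k, aic = aic(ll, k),
                 constraints = constraints),
            class = "fit_result")
}

# product-multinomial log-likelihood at given probabilities, with the
# normalising coefficient and the 0*log(0) = 0 convention
table_loglik <- function(table, prob) {
  rt <- row_totals(table)
  coef <- sum(lgamma(rt + 1)) - sum(lgamma(table$count + 1))
  pos <- table$count > 0
  if (any(pos & prob == 0)) return(-Inf)
  coef + sum(table$count[pos] * log(prob[pos]))
}

# numerical maximisation of the profile likelihood in the shared
# probabilities q, for constraint patterns without the homogeneity that
# makes the pooled closed form exact
fit_constrained_numeric <- function(table, constraints, is_zero, cons_of) {
  rt <- row_totals(table)
  origins <- names(rt)
  nq <- length(constraints$prob)
  prob_at <- function(q) {
    prob <- numeric(nrow(table))
    for (o in origins) {
      idx <- which(table$from == o)
      d <- table$to[idx]
      zi <- is_zero[idx]
      ci <- rep(NA_integer_, length(idx))
      for (g in cons_of[[o]]) ci[d == constraints$prob[[g]]$dest] <- g
      pr <- numeric(length(idx))
      pr[!is.na(ci)] <- q[ci[!is.na(ci)]]
      free <- is.na(ci) & !zi
      rem <- 1 - sum(pr[!is.na(ci)])
      if (rem < 0) return(NULL)
      xf <- table$count[idx][free]
      if (any(free)) {
        pr[free] <- if (sum(xf) > 0) rem * xf / sum(xf)
                    else rem / sum(free)
      } else if (rem > 1e-9) return(NULL)
      prob[idx] <- pr
    }
    prob
  }
  obj <- function(z) {
    q <- 1 / (1 + exp(-z))
    prob <- prob_at(q)
    if (is.null(prob)) return(1e10)
    ll <- table_loglik(table, prob)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  # start from the pooled estimates, mildly shrunk off the boundary
  q0 <- vapply(constraints$prob, function(pc) {
    num <- sum(table$count[table$from %in% pc$origins & table$to == pc$dest])
    (num + 0.5) / (sum(rt[pc$origins]) + 1)
  }, 1)
  opt <- stats::optim(stats::qlogis(q0), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  prob_at(1 / (1 + exp(-opt$par)))
}

#' Akaike's information criterion
#'
#' @param loglik Maximised log-likelihood in nats.
#' @param k Number of free parameters (non-negative).
#' @return `2 * k - 2 * loglik`.  Lower is better.
#' @export
aic <- function(loglik, k) {
  if (k < 0) stop("'k' must be non-negative")
  2 * k - 2 * loglik
}

#' @export
print.fit_result <- function(x, digits = 4, ...) {
  cat("Maximum-likelihood fit: loglik = ", format(x$loglik, digits = digits),
      ", k = ", x$k, ", AIC = ", format(x$aic, digits = digits), "\n",
      sep = "")
  est <- x$estimates
  est$prob <- round(est$prob, digits)
  print.data.frame(est)
  invisible(x)
}

#' Compare candidate constraint sets by AIC
#'
#' Fits the unconstrained model and each candidate constrained model to
#' the same count table and tabulates log-likelihood, parameter count,
#' AIC, and the AIC difference versus the unconstrained model.  A
#' positive difference favours separate parameters (keep the states
#' split); a negative difference favours the constraint (merge).  Ties
#' resolve to the more parsimonious, constrained model.
#'
#' @param table A [count_table()].
#' @param candidates Named list of [constraint_set()] objects (a single
#'   constraint set is also accepted).
#' @return An object of class `comparison_table`: a data frame with
#'   columns `constraint`, `loglik`, `k`, `aic`, `delta_aic`, `verdict`.
#'   The first row is the unconstrained reference (`delta_aic` 0 by
#'   definition, verdict `"reference"`).
#' @examples
#' tab <- count_table(c("medium", "medium", "high", "high"),
#'                    c("dead", "alive", "dead", "alive"),
#'                    c(126, 445, 259, 495))
#' eq <- constraint_set(prob = list(list(dest = "dead",
#'                                       origins = c("medium", "high"))))
#' compare_structures(tab, list(`medium=high` = eq))
#' @export
compare_structures <- function(table, candidates) {
  if (inherits(candidates, "constraint_set")) {
    candidates <- list(candidates)
  }
  if (length(candidates) == 0L) stop("need at least one candidate")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    names(candidates) <- paste0("candidate_", seq_along(candidates))
  }
  base <- constrained_mle(table, constraint_set())
  rows <- data.frame(constraint = "unconstrained", loglik = base$loglik,
                     k = base$k, aic = base$aic, delta_aic = 0,
                     verdict = "reference", stringsAsFactors = FALSE)
  for (nm in names(candidates)) {
    fit <- constrained_mle(table, candidates[[nm]])
    d <- fit$aic - base$aic
    rows <- rbind(rows, data.frame(
      constraint = nm, loglik = fit$loglik, k = fit$k, aic = fit$aic,
      delta_aic = d, verdict = if (d > 0) "split" else "merge",
      stringsAsFactors = FALSE))
  }
  class(rows) <- c("comparison_table", "data.frame")
  rows
}

#' @export
print.comparison_table <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in intersect(c("loglik", "aic", "delta_aic"), names(y))) {
    y[[col]] <- round(y[[col]], 1)
  }
  print.data.frame(y)
  invisible(x)
}

#' Per-destination assessment of a merge proposal
#'
#' For each destination reachable from the proposed merge group, compares
#' the fit with the transition probabilities into that destination
#' constrained equal across the group against the unconstrained fit,
#' leaving all other destinations unconstrained.  This isolates which
#' consequences of occupying the states (which exit risks) support the
#' merge and which oppose it.  Destinations inside the group itself are
#' reported with the unconstrained cell only, since a merge does not
#' constrain internal transitions.
#'
#' @param table A [count_table()].
#' @param merge A [merge_spec()] with a single group whose members all
#'   appear as origins in `table`.
#' @return A `comparison_table` with one constrained row per eligible
#'   destination, named `dest=<label>`.
#' @export
per_destination_table <- function(table, merge) {
  stopifnot(inherits(merge, "merge_spec"))
  if (length(merge$groups) != 1L) {
    stop("per-destination assessment takes a single merge group")
  }
  g <- intersect(merge$groups[[1]], unique(table$from))
  if (length(g) == 0L) stop("no merge-group member appears as an origin")
  dests <- unique(table$to[table$from %in% g])
  cand <- list()
  for (d in setdiff(dests, merge$groups[[1]])) {
    gg <- g[vapply(g, function(o) {
      d %in% table$to[table$from == o]
    }, TRUE)]
    if (length(gg) >= 2L) {
      cand[[paste0("dest=", d)]] <-
        constraint_set(prob = list(list(dest = d, origins = gg)))
    }
  }
  if (length(cand) == 0L) {
    base <- constrained_mle(table, constraint_set())
    rows <- data.frame(constraint = "unconstrained", loglik = base$loglik,
                       k = base$k, aic = base$aic, delta_aic = 0,
                       verdict = "reference", stringsAsFactors = FALSE)
    class(rows) <- c("comparison_table", "data.frame")
    return(rows)
  }
  compare_structures(table, cand)
}
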