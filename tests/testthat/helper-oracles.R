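# Independent numerical oracles used to validate closed-form fits.
# They share no code with the package internals: the constrained
# multinomial oracle optimises over an explicit minimal parameter
# vector (one logit per shared probability, softmax scores for the free
# probabilities of every row) with a general-purpose optimiser.

oracle_constrained_loglik <- function(tab, constraints) {
  rt <- row_totals(tab)
  origins <- names(rt)
  cons <- constraints$prob
  ncons <- length(cons)
  zero_key <- vapply(constraints$zero, paste, "", collapse = "\r")
  pair_key <- paste(tab$from, tab$to, sep = "\r")
  is_zero <- pair_key %in% zero_key

  # index free cells per row
  free_idx <- lapply(origins, function(o) {
    idx <- which(tab$from == o)
    cidx <- rep(NA_integer_, length(idx))
    for (g in seq_len(ncons)) {
      hit <- tab$to[idx] == cons[[g]]$dest & o %in% cons[[g]]$origins
      cidx[hit] <- g
    }
    list(idx = idx, cons = cidx, zero = is_zero[idx])
  })
  nfree <- vapply(free_idx, function(fi) {
    sum(is.na(fi$cons) & !fi$zero)
  }, 1L)

  par_len <- ncons + sum(nfree)
  loglik_at <- function(par) {
    q <- stats::plogis(par[seq_len(ncons)])
    off <- ncons
    prob <- numeric(nrow(tab))
    for (r in seq_along(free_idx)) {
      fi <- free_idx[[r]]
      pr <- numeric(length(fi$idx))
      pr[!is.na(fi$cons)] <- q[fi$cons[!is.na(fi$cons)]]
      S <- sum(pr[!is.na(fi$cons)])
      if (S > 1) return(-Inf)
      fr <- is.na(fi$cons) & !fi$zero
      if (any(fr)) {
        sc <- exp(par[off + seq_len(sum(fr))] -
                    max(par[off + seq_len(sum(fr))]))
        pr[fr] <- (1 - S) * sc / sum(sc)
        off <- off + sum(fr)
      }
      prob[fi$idx] <- pr
    }
    x <- tab$count
    if (any(x > 0 & prob == 0)) return(-Inf)
    pos <- x > 0
    sum(lgamma(rt + 1)) - sum(lgamma(x + 1)) +
      sum(x[pos] * log(prob[pos]))
  }
  obj <- function(par) {
    v <- loglik_at(par)
    if (!is.finite(v)) 1e10 else -v
  }
  start <- rep(0, par_len)
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-15))
  -opt$value
}

# brute-force gamma ML: optimise group means and a shared shape directly
oracle_gamma_loglik <- function(value, group) {
  group <- factor(group)
  g <- as.integer(group)
  ng <- nlevels(group)
  obj <- function(par) {
    mu <- exp(par[seq_len(ng)])
    shape <- exp(par[ng + 1])
    -sum(stats::dgamma(value, shape = shape, rate = shape / mu[g],
                       log = TRUE))
  }
  start <- c(log(tapply(value, group, mean)), 0)
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-15))
  -opt$value
}

# brute-force upper-truncated normal ML
oracle_truncnorm_loglik <- function(value, group, b) {
  group <- factor(group)
  g <- as.integer(group)
  ng <- nlevels(group)
  obj <- function(par) {
    mu <- par[seq_len(ng)]
    sigma <- exp(par[ng + 1])
    ll <- sum(stats::dnorm(value, mu[g], sigma, log = TRUE))
    if (is.finite(b)) {
      ll <- ll - sum(stats::pnorm((b - mu[g]) / sigma, log.p = TRUE))
    }
    -ll
  }
  start <- c(tapply(value, group, mean), log(stats::sd(value)))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-15))
  -opt$value
}

# enumeration EVPI for a finite set of equiprobable states of the world
oracle_evpi_enumerate <- function(nb_matrix) {
  mean(apply(nb_matrix, 1, max)) - max(colMeans(nb_matrix))
}
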