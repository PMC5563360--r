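# Compensated (double-double) arithmetic for the equivalence check.
#
# The merged/constrained-split equivalence is exact in real arithmetic,
# but two independent cohort recursions in double precision drift apart
# by a few ulps per cycle, which on currency-scale totals over 50
# cycles can reach ~1e-10 of pure rounding noise.  check_equivalence()
# therefore runs both recursions with error-free transformations
# (Dekker/Knuth two-sum and two-product), so the reported discrepancies
# reflect structural differences between the models, not the
# accumulation order of floating-point sums.  All numbers are carried
# as unevaluated pairs hi + lo with |lo| <= ulp(hi)/2.

dd_two_sum <- function(a, b) {
  s <- a + b
  bb <- s - a
  list(hi = s, lo = (a - (s - bb)) + (b - bb))
}

dd_split_const <- 134217729  # 2^27 + 1

dd_two_prod <- function(a, b) {
  p <- a * b
  ca <- dd_split_const * a
  ahi <- ca - (ca - a)
  alo <- a - ahi
  cb <- dd_split_const * b
  bhi <- cb - (cb - b)
  blo <- b - bhi
  err <- ((ahi * bhi - p) + ahi * blo + alo * bhi) + alo * blo
  list(hi = p, lo = err)
}

dd_add <- function(x, y) {
  s <- dd_two_sum(x$hi, y$hi)
  lo <- s$lo + (x$lo + y$lo)
  hi <- s$hi + lo
  list(hi = hi, lo = lo - (hi - s$hi))
}

# double-double times plain double
dd_mul_d <- function(x, d) {
  p <- dd_two_prod(x$hi, d)
  lo <- p$lo + x$lo * d
  hi <- p$hi + lo
  list(hi = hi, lo = lo - (hi - p$hi))
}

dd_zero <- function(n) list(hi = numeric(n), lo = numeric(n))

# occupancy recursion occ_{t+1} = occ_t %*% P in double-double; returns
# list of hi and lo matrices of dimension (n_cycles + 1) x n_states
dd_cohort_trace <- function(P, init, n_cycles) {
  ns <- length(init)
  hi <- matrix(0, n_cycles + 1L, ns)
  lo <- matrix(0, n_cycles + 1L, ns)
  occ <- list(hi = init, lo = numeric(ns))
  hi[1L, ] <- occ$hi
  for (t in seq_len(n_cycles)) {
    nxt <- dd_zero(ns)
    for (j in seq_len(ns)) {
      acc <- list(hi = 0, lo = 0)
      for (i in seq_len(ns)) {
        if (P[i, j] == 0 && occ$hi[i] == 0) next
        term <- dd_mul_d(list(hi = occ$hi[i], lo = occ$lo[i]), P[i, j])
        acc <- dd_add(acc, term)
      }
      nxt$hi[j] <- acc$hi
      nxt$lo[j] <- acc$lo
    }
    occ <- nxt
    hi[t + 1L, ] <- occ$hi
    lo[t + 1L, ] <- occ$lo
  }
  list(hi = hi, lo = lo)
}

# discounted weighted total sum_t w_t * sum_s occ_{t,s} v_s in
# double-double; w and v are plain doubles
dd_weighted_total <- function(trace, w, v) {
  acc <- list(hi = 0, lo = 0)
  for (t in seq_len(nrow(trace$hi))) {
    row <- list(hi = 0, lo = 0)
    for (s in seq_along(v)) {
      if (v[s] == 0) next
      row <- dd_add(row, dd_mul_d(list(hi = trace$hi[t, s],
                                       lo = trace$lo[t, s]), v[s]))
    }
    acc <- dd_add(acc, dd_mul_d(row, w[t]))
  }
  acc
}
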