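test_that("unconstrained MLE is the observed proportion, with exact loglik", {
  # single binomial row
  tab <- count_table(c("medium", "medium"), c("dead", "alive"),
                     c(126, 445))
  fit <- row_mle(tab)
  p <- fit$estimates$prob[fit$estimates$to == "dead"]
  expect_equal(p, 126 / 571, tolerance = 1e-12)
  expect_equal(fit$loglik, dbinom(126, 571, 126 / 571, log = TRUE),
               tolerance = 1e-10)
  expect_identical(fit$k, 1L)

  # one destination only: certain transition, zero loglik, no parameters
  tab1 <- count_table("A", "B", 17)
  fit1 <- row_mle(tab1)
  expect_equal(fit1$estimates$prob, 1)
  expect_equal(fit1$loglik, 0)
  expect_identical(fit1$k, 0L)

  # three destinations: loglik equals the multinomial pmf at the MLE
  tab3 <- count_table(rep("A", 3), c("x", "y", "z"), c(2, 3, 5))
  fit3 <- row_mle(tab3)
  expect_equal(fit3$loglik,
               dmultinom(c(2, 3, 5), prob = c(0.2, 0.3, 0.5), log = TRUE),
               tolerance = 1e-12)
  expect_identical(fit3$k, 2L)
})

test_that("row MLE rejects empty and degenerate tables", {
  expect_error(count_table(character(), character(), numeric()), "empty")
  expect_error(count_table("A", "B", -1), "non-negative")
  tab <- count_table(c("A", "A"), c("x", "y"), c(0, 0))
  expect_error(row_mle(tab), "positive row total|positive total")
})

test_that("equality constraints pool the counts", {
  tab <- cecat_death_counts()
  fit <- constrained_mle(tab, cecat_death_constraint())
  q <- unique(fit$estimates$prob[fit$estimates$to == "dead"])
  expect_equal(q, 385 / 1325, tolerance = 1e-12)
  expect_identical(fit$k, 1L)
  # row sums remain exactly one
  sums <- tapply(fit$estimates$prob, fit$estimates$from, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("constraining every destination of identical rows changes nothing", {
  tab <- count_table(rep(c("A", "B"), each = 2),
                     rep(c("x", "y"), 2), c(30, 70, 30, 70))
  cs <- constraint_set(prob = list(
    list(dest = "x", origins = c("A", "B")),
    list(dest = "y", origins = c("A", "B"))))
  expect_equal(constrained_mle(tab, cs)$loglik, row_mle(tab)$loglik,
               tolerance = 1e-12)
})

test_that("closed-form constrained MLE agrees with a numerical maximiser", {
  for (seed in 1:20) {
    tab <- random_count_table(seed)
    cs <- random_constraint(tab, seed + 1000)
    fit <- constrained_mle(tab, cs)
    ll_oracle <- oracle_constrained_loglik(tab, cs)
    expect_equal(fit$loglik, ll_oracle, tolerance = 1e-8)
    expect_gte(fit$loglik, ll_oracle - 1e-8)
  }
})

test_that("constrained loglik never exceeds the unconstrained one", {
  for (seed in 21:50) {
    tab <- random_count_table(seed)
    cs <- random_constraint(tab, seed + 2000)
    fit_c <- constrained_mle(tab, cs)
    fit_u <- row_mle(tab)
    expect_lte(fit_c$loglik, fit_u$loglik + 1e-12)
    # equality holds iff the unconstrained MLEs already satisfy it
    p_hat <- fit_u$estimates$prob
    d <- cs$prob[[1]]$dest
    g <- cs$prob[[1]]$origins
    already <- diff(range(p_hat[fit_u$estimates$to == d &
                                  fit_u$estimates$from %in% g])) < 1e-12
    expect_identical(abs(fit_c$loglik - fit_u$loglik) < 1e-10, already)
  }
})

test_that("heterogeneous overlapping constraints fall back to numerical fit", {
  # destination d1 shared by {o1, o2}, destination d2 shared by {o2, o3}:
  # origin o2 couples the two groups, so no pooled closed form applies
  tab <- count_table(rep(c("o1", "o2", "o3"), each = 3),
                     rep(c("d1", "d2", "d3"), 3),
                     c(10, 5, 35, 8, 12, 30, 4, 20, 26))
  cs <- constraint_set(prob = list(
    list(dest = "d1", origins = c("o1", "o2")),
    list(dest = "d2", origins = c("o2", "o3"))))
  fit <- constrained_mle(tab, cs)
  ll_oracle <- oracle_constrained_loglik(tab, cs)
  expect_equal(fit$loglik, ll_oracle, tolerance = 1e-6)
  sums <- tapply(fit$estimates$prob, fit$estimates$from, sum)
  expect_true(all(abs(sums - 1) < 1e-8))
})

test_that("AIC arithmetic and the CECaT absolute values", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-5, 2), 14)
  expect_error(aic(0, -1), "non-negative")
  expect_equal(round(row_mle(cecat_death_counts())$aic, 1), 17.4)
  expect_equal(round(constrained_mle(cecat_death_counts(),
                                     cecat_death_constraint())$aic, 1),
               39.6)
})

test_that("structure comparison reproduces the published AIC differences", {
  cmp_d <- compare_structures(cecat_death_counts(),
                              list(`medium=high` = cecat_death_constraint()))
  expect_equal(cmp_d$delta_aic[1], 0)
  expect_equal(round(cmp_d$delta_aic[2], 1), 22.2)
  expect_identical(cmp_d$verdict[2], "split")

  cmp_m <- compare_structures(cecat_mi_counts(),
                              list(`medium=high` = cecat_mi_constraint()))
  expect_equal(round(cmp_m$delta_aic[2], 1), -0.6)
  expect_identical(cmp_m$verdict[2], "merge")
})

test_that("identical rows give delta AIC of exactly -2 per constraint", {
  tab <- count_table(rep(c("A", "B"), each = 2),
                     rep(c("x", "y"), 2), c(12, 28, 12, 28))
  cs <- constraint_set(prob = list(list(dest = "x",
                                        origins = c("A", "B"))))
  cmp <- compare_structures(tab, list(eq = cs))
  expect_equal(cmp$delta_aic[2], -2, tolerance = 1e-12)
  expect_identical(cmp$verdict[2], "merge")
})

test_that("delta AIC is additive over constraints on disjoint origin rows", {
  # the product-multinomial likelihood factorises over origin rows, so
  # candidates touching disjoint row sets contribute independently
  for (seed in 1:5) {
    set.seed(seed)
    tab <- count_table(
      rep(c("a1", "a2", "b1", "b2"), each = 2),
      rep(c("x", "y"), 4),
      sample(5:50, 8, replace = TRUE))
    cs_a <- constraint_set(prob = list(list(dest = "x",
                                            origins = c("a1", "a2"))))
    cs_b <- constraint_set(prob = list(list(dest = "y",
                                            origins = c("b1", "b2"))))
    cs_ab <- constraint_set(prob = c(cs_a$prob, cs_b$prob))
    cmp <- compare_structures(tab, list(a = cs_a, b = cs_b, ab = cs_ab))
    expect_equal(cmp$delta_aic[4], cmp$delta_aic[2] + cmp$delta_aic[3],
                 tolerance = 1e-10)
  }
})

test_that("per-destination assessment isolates each exit risk", {
  # a single shared destination reproduces the whole-model comparison
  tab <- cecat_death_counts()
  per <- per_destination_table(tab, merge_spec(list(c("medium", "high"))))
  cmp <- compare_structures(tab, list(cecat_death_constraint()))
  drow <- per[per$constraint == "dest=dead", ]
  expect_equal(drow$delta_aic, cmp$delta_aic[2], tolerance = 1e-12)
  # 'alive' is also outside the group: both destinations assessed
  expect_setequal(per$constraint[-1], c("dest=dead", "dest=alive"))

  # group members that never appear as origins leave only the reference
  tab2 <- count_table(c("A", "A"), c("x", "y"), c(3, 7))
  per2 <- per_destination_table(tab2, merge_spec(list(c("A", "Z"))))
  expect_identical(per2$constraint, "unconstrained")
})

test_that("per-destination AIC favours a truly shared recovery rate", {
  # four-state truth where the two middle states share their exit
  # probabilities; the equal-probability cell should win for that
  # destination in a clear majority of replicates
  sp <- state_space(c("well", "mild", "moderate", "severe"))
  P <- rbind(well = c(0.7, 0.1, 0.1, 0.1),
             mild = c(0.25, 0.45, 0.2, 0.1),
             moderate = c(0.25, 0.2, 0.45, 0.1),
             severe = c(0.05, 0.1, 0.15, 0.7))
  model <- transition_model(sp, P)
  ms <- merge_spec(list(c("mild", "moderate")), space = sp)
  wins <- 0L
  n_reps <- 500L
  for (r in seq_len(n_reps)) {
    truth <- truth_spec(model, n_subjects = 1200, n_cycles = 1,
                        init = rep(0.25, 4), seed = 6000 + r)
    tab <- simulate_counts(truth)
    per <- per_destination_table(tab, ms)
    if (per$delta_aic[per$constraint == "dest=well"] < 0) wins <- wins + 1L
  }
  expect_gte(wins / n_reps, 0.8)
})

test_that("counts derived from published summaries round-trip their CI", {
  s <- risk_summary("absolute", 0.022, 0.016, 0.029)
  d <- derive_counts(s)
  expect_lte(d$ci_check$max_discrepancy, 0.001)
  expect_equal(d$events / d$denominator, d$risk)

  # relative risk against a known baseline
  rr <- risk_summary("relative", 2.3, 1.9, 2.8, baseline_risk = 0.096)
  drr <- derive_counts(rr)
  expect_equal(drr$risk, 2.3 * 0.096, tolerance = 0.05)

  # degenerate interval: no information about the variance
  expect_error(derive_counts(risk_summary("absolute", 0.5, 0.5, 0.5)),
               "zero or negative variance")
  expect_error(risk_summary("absolute", 0.5, 0.6, 0.7), "ci_low")
  expect_error(risk_summary("relative", 2, 1.5, 2.5), "baseline")
})

test_that("a denominator hint pins the derived denominator", {
  s <- risk_summary("absolute", 0.022, 0.016, 0.029)
  d <- derive_counts(s, denominator_hint = 1717)
  expect_identical(d$denominator, 1717L)
  expect_identical(d$events, 38L)
})

test_that("structural zeroes are honoured exactly", {
  tab <- count_table(rep("A", 3), c("x", "y", "z"), c(0, 4, 6))
  cs <- constraint_set(zero = list(c("A", "x")))
  fit <- constrained_mle(tab, cs)
  expect_equal(fit$estimates$prob[fit$estimates$to == "x"], 0)
  expect_identical(fit$k, 1L)
  expect_equal(fit$loglik,
               dbinom(4, 10, 0.4, log = TRUE), tolerance = 1e-12)

  # observed events at a structural zero make the data impossible
  tab2 <- count_table(rep("A", 3), c("x", "y", "z"), c(2, 4, 4))
  expect_equal(constrained_mle(tab2, cs)$loglik, -Inf)
})
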