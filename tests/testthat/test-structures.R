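test_that("state spaces validate their labels", {
  expect_error(state_space(character()), "at least one")
  expect_error(state_space(c("A", "A")), "unique")
  expect_error(state_space(c("A", "")), "non-empty")
  expect_error(state_space(c("A", "B"), absorbing = "C"), "absorbing")
  sp <- state_space(c("A", "B"), absorbing = "B")
  expect_identical(sp$states, c("A", "B"))
})

test_that("merge specs require disjoint groups of at least two states", {
  sp <- state_space(c("A", "B", "C", "D"))
  expect_error(merge_spec(list("A"), space = sp), "at least two")
  expect_error(merge_spec(list(c("A", "B"), c("B", "C")), space = sp),
               "disjoint")
  expect_error(merge_spec(list(c("A", "X")), space = sp), "not in state")
  ms <- merge_spec(list(c("A", "B")), space = sp)
  expect_identical(ms$labels, "A+B")
})

test_that("a merge implies equal exit probabilities, costs and utilities", {
  sp <- state_space(c("Well", "High", "Low", "Dead"), absorbing = "Dead")
  ms <- merge_spec(list(c("High", "Low")), labels = "CAD", space = sp)
  cs <- constraints_from_merge(sp, ms, exits = "Dead")
  expect_length(cs$prob, 1)
  expect_identical(cs$prob[[1]]$dest, "Dead")
  expect_setequal(cs$prob[[1]]$origins, c("High", "Low"))
  expect_identical(cs$cost_equal, list(c("High", "Low")))
  expect_identical(cs$utility_equal, list(c("High", "Low")))
})

test_that("merging mild with moderate depression constrains both exits", {
  dep <- depression_structures()
  cs <- constraints_from_merge(dep$space, dep$merges$mild_mod,
                               exits = c("well", "severe"))
  dests <- vapply(cs$prob, `[[`, "", "dest")
  expect_setequal(dests, c("well", "severe"))
  for (pc in cs$prob) {
    expect_setequal(pc$origins, c("mild", "moderate"))
  }
})

test_that("a merge of n states with m exits removes n*m - m parameters", {
  # count via the fitted parameter dimension on a synthetic table
  set.seed(42)
  sp <- state_space(paste0("s", 1:5))
  ms <- merge_spec(list(c("s1", "s2", "s3")), space = sp)
  cs <- constraints_from_merge(sp, ms, exits = c("s4", "s5"))
  df <- expand.grid(from = sp$states, to = sp$states,
                    stringsAsFactors = FALSE)
  df$count <- sample(1:30, nrow(df), replace = TRUE)
  tab <- count_table(df$from, df$to, df$count)
  n <- 3; m <- 2
  expect_equal(row_mle(tab)$k - constrained_mle(tab, cs)$k, n * m - m)
})

test_that("constraint generation is idempotent and order-independent", {
  sp <- state_space(c("A", "B", "C", "X", "Y"))
  ms1 <- merge_spec(list(c("A", "B"), c("X", "Y")), space = sp)
  ms2 <- merge_spec(list(c("X", "Y"), c("A", "B")), space = sp)
  cs1 <- constraints_from_merge(sp, ms1)
  cs1b <- constraints_from_merge(sp, ms1)
  cs2 <- constraints_from_merge(sp, ms2)
  expect_identical(cs1, cs1b)
  key <- function(cs) {
    sort(vapply(cs$prob, function(pc) {
      paste(pc$dest, paste(sort(pc$origins), collapse = ","))
    }, ""))
  }
  expect_identical(key(cs1), key(cs2))
})

test_that("mergeability reports unshared exits and shared ones", {
  pg <- progressive_three_state()
  rep <- validate_mergeability(pg$space, pg$merge, pg$transitions)
  expect_identical(rep$verdict, "non-shared")
  expect_match(rep$missing, "1->3")

  sp <- state_space(c("Well", "High", "Low", "Dead"), absorbing = "Dead")
  ms <- merge_spec(list(c("High", "Low")), space = sp)
  at <- data.frame(from = c("High", "High", "Low", "Low"),
                   to = c("High", "Dead", "Low", "Dead"))
  expect_identical(validate_mergeability(sp, ms, at)$verdict, "shared")

  empty <- merge_spec(list())
  expect_identical(nrow(validate_mergeability(sp, empty, at)), 0L)
})

test_that("the encompassing model nests both candidate structures", {
  pg <- progressive_three_state()
  ext <- extend_for_unshared_exits(pg$space, pg$merge, pg$transitions)
  expect_identical(ext$constraints_zero$zero, list(c("1", "3")))
  dests <- vapply(ext$constraints_equal$prob, `[[`, "", "dest")
  expect_identical(dests, "3")
  expect_setequal(ext$constraints_equal$prob[[1]]$origins, c("1", "2"))
  expect_true(any(ext$transitions$from == "1" & ext$transitions$to == "3"))

  # shared-exit input: nothing to extend
  sp <- state_space(c("A", "B", "D"))
  at <- data.frame(from = c("A", "A", "A", "B", "B", "B"),
                   to = c("A", "B", "D", "A", "B", "D"))
  ms <- merge_spec(list(c("A", "B")), space = sp)
  ext2 <- extend_for_unshared_exits(sp, ms, at)
  expect_length(ext2$constraints_zero$zero, 0)
  expect_identical(nrow(ext2$transitions), nrow(at))

  expect_error(extend_for_unshared_exits(sp, merge_spec(list()), at),
               "no groups")
})

test_that("zero-constrained encompassing fit equals the direct sub-model fit", {
  # data simulated from the restricted model never use the added exit,
  # so constraining it to zero must reproduce the direct fit exactly
  pg <- progressive_three_state()
  truth <- truth_spec(pg$model, n_subjects = 500, n_cycles = 3, seed = 11)
  tab <- simulate_counts(truth)
  direct <- row_mle(tab)

  ext <- extend_for_unshared_exits(pg$space, pg$merge, pg$transitions)
  # encompassing table: same data plus the structurally absent cell
  tab_ext <- count_table(c(tab$from, "1"), c(tab$to, "3"),
                         c(tab$count, 0))
  fit_a <- constrained_mle(tab_ext, ext$constraints_zero)
  expect_equal(fit_a$loglik, direct$loglik, tolerance = 1e-12)
  expect_identical(fit_a$k, direct$k)
})

test_that("three-way unshared exits: constrained fits match direct sub-model fits", {
  # states a, b, c with pairwise-different exits to x and y
  sp <- state_space(c("a", "b", "c", "x", "y"), absorbing = c("x", "y"))
  at <- data.frame(
    from = c("a", "a", "a", "b", "b", "b", "c", "c", "c"),
    to = c("a", "b", "x", "a", "b", "y", "c", "x", "y"))
  ms <- merge_spec(list(c("a", "b", "c")), space = sp)
  ext <- extend_for_unshared_exits(sp, ms, at)
  expect_setequal(vapply(ext$constraints_zero$zero, paste, "",
                         collapse = "->"),
                  c("a->y", "b->x"))
  counts <- c(30, 10, 5, 12, 25, 7, 40, 3, 9)
  tab <- count_table(rep(c("a", "b", "c"), each = 3),
                     c("a", "b", "x", "a", "b", "y", "c", "x", "y"),
                     counts)
  direct <- row_mle(tab)
  # the encompassing table: every transition in the extended set, with
  # the structurally absent cells observed at zero
  key <- paste(tab$from, tab$to)
  ext_key <- paste(ext$transitions$from, ext$transitions$to)
  tab_ext <- count_table(
    ext$transitions$from, ext$transitions$to,
    ifelse(ext_key %in% key, tab$count[match(ext_key, key)], 0))
  fit_zero <- constrained_mle(tab_ext, ext$constraints_zero)
  expect_equal(fit_zero$loglik, direct$loglik, tolerance = 1e-10)
  expect_identical(fit_zero$k, direct$k)
})

test_that("free parameter count follows the direct formula", {
  for (seed in 1:10) {
    tab <- random_count_table(seed)
    cs <- random_constraint(tab, seed + 100)
    fit <- constrained_mle(tab, cs)
    dests_per_row <- table(tab$from)
    expected_k <- sum(dests_per_row - 1L) -
      (length(cs$prob[[1]]$origins) - 1L)
    expect_identical(fit$k, as.integer(expected_k))
  }
})
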