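test_that("design presets enumerate the published trial structure", {
  tr <- design_preset("training")
  expect_identical(tr$total_trials, 432L)
  expect_length(tr$reference_contrasts, 9)
  expect_equal(tr$reference_contrasts, seq(21, 39, by = 2.25))

  e1 <- design_preset("exp1")
  expect_identical(e1$total_trials, 3520L)
  expect_identical(e1$trials_per_session, 440L)
  expect_length(unique(e1$reference_contrasts), 11)
  expect_setequal(e1$reference_contrasts, c(14, seq(18, 34, 2), 38))

  e3 <- design_preset("exp3")
  expect_identical(e3$trials_per_session, 396L)
  expect_identical(e3$total_trials, 2772L)
  expect_length(e3$conditions, 3)

  expect_error(design_preset("exp4"), regexp = "training",
               class = "indecision_input_error")
})

test_that("simulated tables are balanced within session and deterministic", {
  truth <- truth_preset("exp1")
  t1 <- simulate_trials(design_preset("exp1"), truth, seed = 21)
  t2 <- simulate_trials(design_preset("exp1"), truth, seed = 21)
  t3 <- simulate_trials(design_preset("exp1"), truth, seed = 22)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
  expect_identical(nrow(t1), 3520L)

  # every (contrast, condition, order) cell appears exactly 5 times/session
  cell_counts <- dplyr::count(t1, session, ref_contrast, condition, order)
  expect_true(all(cell_counts$n == 5L))
  expect_identical(nrow(cell_counts), 8L * 11L * 4L * 2L)

  expect_error(
    simulate_trials(design_preset("exp1"), truth[-1, ], seed = 1),
    class = "indecision_input_error")
})

test_that("empirical response fractions converge to the closed form", {
  d <- design_preset("training")
  d$reference_contrasts <- 30   # x = 0 against one test contrast
  d$conditions <- "C"; d$test_contrast <- c(C = 30)
  d$repeats_per_session <- 50000L; d$n_sessions <- 1L  # x 2 orders = 1e5
  trials <- simulate_trials(d, list(C = model_params(0, 1, -1, 1)), seed = 23)
  n <- nrow(trials)
  expect_identical(n, 100000L)
  p_true <- pnorm(1) - pnorm(-1)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(trials$response == "DK") - p_true), 4 * se)
})

test_that("aggregation conserves trials and matches a brute-force tally", {
  truth <- truth_preset("exp3")
  trials <- simulate_trials(design_preset("exp3"), truth, seed = 24)
  counts <- aggregate_counts(trials)
  expect_identical(sum(counts$n_ref_higher + counts$n_ref_lower + counts$n_dk),
                   nrow(trials))
  expect_identical(nrow(counts), 3L * 11L * 2L)

  # independent tally via base table()
  tab <- table(paste(trials$condition,
                     trials$ref_contrast - trials$test_contrast,
                     trials$order),
               trials$response)
  for (i in sample(nrow(counts), 10)) {
    key <- paste(counts$condition[i], counts$x[i], counts$order[i])
    expect_identical(counts$n_ref_higher[i], as.integer(tab[key, "REF_HIGHER"]))
    expect_identical(counts$n_ref_lower[i], as.integer(tab[key, "REF_LOWER"]))
    expect_identical(counts$n_dk[i], as.integer(tab[key, "DK"]))
  }

  one <- trials[1, ]; one$response <- "REF_HIGHER"
  c1 <- aggregate_counts(one)
  expect_identical(nrow(c1), 1L)
  expect_identical(c1$n_ref_higher, 1L)
  expect_identical(c1$n_ref_lower + c1$n_dk, 0L)

  expect_identical(nrow(aggregate_counts(trials[0, ])), 0L)
})

test_that("training assessment applies the veridicality gate", {
  tr <- simulate_trials(design_preset("training"),
                        truth_preset("training") |>
                          dplyr::mutate(sigma = 3, delta1 = -1, delta2 = 1),
                        seed = 25)
  gate <- assess_training(tr)
  expect_identical(nrow(gate), 2L)
  expect_true(all(abs(gate$mu) <= 1))
  expect_true(attr(gate, "pass"))

  # a strongly non-veridical observer fails the gate
  bad_truth <- truth_preset("training") |>
    dplyr::mutate(mu = 4, sigma = 3, delta1 = -1, delta2 = 1)
  tr_bad <- simulate_trials(design_preset("training"), bad_truth, seed = 26)
  expect_false(attr(assess_training(tr_bad), "pass"))
})

test_that("observer heterogeneity draws vary around the group truth", {
  sim <- simulate_observers(design_preset("exp3"), truth_preset("exp3"),
                            n_observers = 3, seed = 27)
  expect_identical(nrow(sim$trials), 3L * 2772L)
  expect_identical(length(unique(sim$trials$observer)), 3L)
  ot <- sim$observer_truth
  expect_identical(nrow(ot), 9L)
  expect_true(all(ot$sigma >= 0.5))
  # criterion separation preserved within observer (shared bias shift)
  expect_equal(ot$delta2 - ot$delta1, rep(4, 9))
})
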