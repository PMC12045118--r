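test_that("closed-form probabilities match hand-computable cases", {
  # coincident criteria: symmetric forced split, no opt-out
  p <- response_probabilities(model_params(0, 1, 0, 0), 0, "REF_SECOND")
  expect_equal(p$p_ref_higher, 0.5)
  expect_equal(p$p_ref_lower, 0.5)
  expect_equal(p$p_dk, 0)

  # standard-normal criteria at +/-1: tails and central mass
  for (ord in c("REF_FIRST", "REF_SECOND")) {
    p <- response_probabilities(model_params(0, 1, -1, 1), 0, ord)
    expect_equal(p$p_ref_higher, pnorm(-1), tolerance = 1e-12)
    expect_equal(p$p_ref_lower, pnorm(-1), tolerance = 1e-12)
    expect_equal(p$p_dk, pnorm(1) - pnorm(-1), tolerance = 1e-12)
  }
})

test_that("analytic probabilities agree with the Monte-Carlo generative rule", {
  params <- model_params(-8, 5, -2, 3)
  n <- 1e6
  for (ord in c("REF_FIRST", "REF_SECOND")) {
    mc <- mc_response_probs(params, x = -4, order = ord, n = n, seed = 7)
    an <- response_probabilities(params, -4, ord)
    an <- c(an$p_ref_higher, an$p_ref_lower, an$p_dk)
    se <- sqrt(an * (1 - an) / n)
    expect_true(all(abs(mc - an) <= 4 * pmax(se, 1e-8)))
  }
})

test_that("probability triples are normalized, monotone and order-symmetric", {
  withr::local_seed(11)
  xs <- seq(-20, 20, by = 0.5)
  for (i in 1:25) {
    params <- random_params()
    for (ord in c("REF_FIRST", "REF_SECOND")) {
      p <- response_probabilities(params, xs, ord)
      expect_true(all(p$p_ref_higher >= 0 & p$p_ref_higher <= 1))
      expect_true(all(abs(p$p_ref_higher + p$p_ref_lower + p$p_dk - 1) < 1e-12))
      expect_true(all(diff(p$p_ref_higher) >= -1e-12))
      expect_true(all(diff(p$p_ref_lower) <= 1e-12))
    }
  }
  # symmetric criteria make the two order curves identical
  for (i in 1:10) {
    h <- abs(rnorm(1, 1.5, 1))
    params <- model_params(runif(1, -8, 8), runif(1, 0.5, 6), -h, h)
    p1 <- response_probabilities(params, xs, "REF_FIRST")
    p2 <- response_probabilities(params, xs, "REF_SECOND")
    expect_equal(p1$p_ref_higher, p2$p_ref_higher, tolerance = 1e-12)
    expect_equal(p1$p_ref_lower, p2$p_ref_lower, tolerance = 1e-12)
  }
})

test_that("order-averaged DK probability is even about mu", {
  withr::local_seed(12)
  for (i in 1:20) {
    params <- random_params()
    u <- seq(0.25, 15, by = 0.25)
    dk_avg <- function(xx) {
      (response_probabilities(params, xx, "REF_FIRST")$p_dk +
         response_probabilities(params, xx, "REF_SECOND")$p_dk) / 2
    }
    expect_equal(dk_avg(params$mu + u), dk_avg(params$mu - u),
                 tolerance = 1e-12)
  }
})

test_that("negative log-likelihood matches hand values and per-trial oracle", {
  one <- tibble::tibble(x = 0, order = "REF_SECOND",
                        n_ref_higher = 1L, n_ref_lower = 0L, n_dk = 0L)
  expect_equal(indecision_nll(model_params(0, 1, 0, 0), one), -log(0.5),
               tolerance = 1e-12)

  # an all-zero cell contributes nothing
  zero <- dplyr::mutate(one, n_ref_higher = 0L)
  both <- dplyr::bind_rows(one, dplyr::mutate(zero, x = 5))
  expect_equal(indecision_nll(model_params(0, 1, 0, 0), both), -log(0.5),
               tolerance = 1e-12)

  # per-cell multinomial form equals direct per-trial enumeration
  withr::local_seed(13)
  for (i in 1:5) {
    params <- random_params()
    counts <- tidyr::expand_grid(x = c(-6, -2, 0, 3), order = c("REF_FIRST", "REF_SECOND"))
    counts$n_ref_higher <- rpois(nrow(counts), 6)
    counts$n_ref_lower <- rpois(nrow(counts), 6)
    counts$n_dk <- rpois(nrow(counts), 3)
    expect_equal(indecision_nll(params, counts),
                 nll_per_trial_oracle(params, counts), tolerance = 1e-8)
  }
})

test_that("invalid parameters and inputs are refused", {
  expect_error(model_params(0, -1, 0, 0), class = "indecision_domain_error")
  expect_error(model_params(0, 1, 2, 1), class = "indecision_domain_error")
  expect_error(response_probabilities(model_params(), NaN, "REF_FIRST"),
               class = "indecision_input_error")
  expect_error(response_probabilities(model_params(), 0, "FIRST"),
               class = "indecision_input_error")
  empty <- tibble::tibble(x = numeric(), order = character(),
                          n_ref_higher = integer(), n_ref_lower = integer(),
                          n_dk = integer())
  expect_error(indecision_nll(model_params(), empty),
               class = "indecision_input_error")
})

test_that("DK-peak location equals mu when unimodal and flags bimodality", {
  expect_equal(dk_peak(model_params(-5, 3, -1, 1))$peak, -5, tolerance = 1e-6)
  pk <- dk_peak(model_params(2, 4, -0.5, 2.5))
  expect_false(pk$bimodal)
  expect_equal(pk$peak, 2, tolerance = 1e-4)

  # narrow signal with far-offset criteria: two symmetric DK maxima
  bi <- dk_peak(model_params(0, 0.5, 4, 6))
  expect_true(bi$bimodal)
  expect_length(bi$peaks, 2)
  expect_equal(bi$peaks[1], -bi$peaks[2], tolerance = 1e-6)
  # confirm with a dense grid that the flagged peaks dominate x = mu
  g <- function(xx) {
    (response_probabilities(model_params(0, 0.5, 4, 6), xx, "REF_FIRST")$p_dk +
       response_probabilities(model_params(0, 0.5, 4, 6), xx, "REF_SECOND")$p_dk) / 2
  }
  expect_gt(g(bi$peaks[2]), g(0) + 0.01)

  expect_error(dk_peak(model_params(0, 1, 1, 1)),
               class = "indecision_domain_error")
})
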