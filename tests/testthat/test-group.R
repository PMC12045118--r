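make_2x2_data <- function(n, seed) {
  withr::with_seed(seed, {
    d <- tidyr::expand_grid(observer = sprintf("s%02d", seq_len(n)),
                            a = c("Iso", "Cross"), b = c("Flat", "Depth"))
    d$value <- rnorm(nrow(d))
    d
  })
}

test_that("2x2 within-subject F equals squared paired t and the aov oracle", {
  for (seed in c(41, 42, 43)) {
    d <- make_2x2_data(8, seed)
    res <- rm_anova_2x2(d, value = value, observer = observer, a = a, b = b)
    expect_identical(res$effect, c("a", "b", "a:b"))
    expect_true(all(res$df1 == 1 & res$df2 == 7))
    expect_true(all(res$statistic >= 0 & res$p.value >= 0 & res$p.value <= 1))

    # t^2 identity on the subject contrasts
    wide <- tidyr::pivot_wider(d, names_from = c(a, b), values_from = value)
    ca <- (wide$Iso_Flat + wide$Iso_Depth - wide$Cross_Flat - wide$Cross_Depth) / 2
    tt <- t.test(ca)
    # factor level "Cross" sorts before "Iso", so effect a is Iso - Cross up to sign
    expect_equal(res$statistic[res$effect == "a"], unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(res$p.value[res$effect == "a"], tt$p.value, tolerance = 1e-10)

    # brute-force SS decomposition via aov() Error strata
    fa <- aov_rm_f(d, "a * b", "(a * b)")
    expect_equal(res$statistic[res$effect == "a"], fa[["a"]], tolerance = 1e-8)
    expect_equal(res$statistic[res$effect == "b"], fa[["b"]], tolerance = 1e-8)
    expect_equal(res$statistic[res$effect == "a:b"], fa[["a:b"]],
                 tolerance = 1e-8)
  }
})

test_that("degenerate inputs give flagged F values, not exceptions", {
  d <- make_2x2_data(6, 44)
  d$value <- 1  # identical across conditions and observers
  res <- rm_anova_2x2(d, value = value, observer = observer, a = a, b = b)
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p.value == 1))

  # constant nonzero contrast: infinite F
  d2 <- make_2x2_data(6, 45)
  d2$value <- ifelse(d2$a == "Iso", 1, 0)
  res2 <- rm_anova_2x2(d2, value = value, observer = observer, a = a, b = b)
  expect_identical(res2$statistic[res2$effect == "a"], Inf)
  expect_identical(res2$p.value[res2$effect == "a"], 0)

  expect_error(rm_anova_2x2(make_2x2_data(8, 46)[-1, ], value = value,
                            observer = observer, a = a, b = b),
               class = "indecision_input_error")
})

test_that("one-way repeated-measures ANOVA matches the SS oracle", {
  withr::local_seed(47)
  for (i in 1:3) {
    d <- tidyr::expand_grid(observer = sprintf("s%d", 1:7),
                            condition = c("Bump", "Average", "Near"))
    d$value <- rnorm(nrow(d))
    res <- rm_anova_oneway(d, value = value, observer = observer,
                           condition = condition)
    expect_identical(res$df1, 2)
    expect_identical(res$df2, 12)
    fa <- aov_rm_f(d, "condition", "condition")
    expect_equal(res$statistic, fa[["condition"]], tolerance = 1e-8)
  }

  # k = 2 reduces to the squared paired t
  d2 <- tidyr::expand_grid(observer = sprintf("s%d", 1:9),
                           condition = c("A", "B"))
  d2$value <- rnorm(nrow(d2))
  res2 <- rm_anova_oneway(d2, value = value, observer = observer,
                          condition = condition)
  w <- tidyr::pivot_wider(d2, names_from = condition, values_from = value)
  tt <- t.test(w$A, w$B, paired = TRUE)
  expect_equal(res2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)

  # shuffling condition labels within subjects preserves the total SS
  d3 <- d
  ss_tot <- function(x) sum((x$value - mean(x$value))^2)
  d3$condition <- unlist(withr::with_seed(48, {
    tapply(d3$condition, d3$observer, sample)
  }))
  expect_equal(ss_tot(d), ss_tot(d3))
})

test_that("post-hoc paired comparisons match the textbook formula", {
  withr::local_seed(49)
  d <- tidyr::expand_grid(observer = sprintf("s%d", 1:8),
                          condition = c("A", "B", "C"))
  d$value <- rnorm(nrow(d))
  cmp <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  res <- posthoc_paired_bonferroni(d, cmp, value = value,
                                   observer = observer, condition = condition)
  expect_identical(nrow(res), 3L)
  w <- tidyr::pivot_wider(d, names_from = condition, values_from = value)
  diffs <- w$A - w$B
  t_manual <- mean(diffs) / (sd(diffs) / sqrt(length(diffs)))
  p_manual <- 2 * pt(-abs(t_manual), df = length(diffs) - 1)
  expect_equal(res$statistic[1], t_manual, tolerance = 1e-10)
  expect_equal(res$p.value[1], p_manual, tolerance = 1e-10)
  expect_equal(res$p.adjusted, pmin(1, res$p.value * 3))
  expect_true(all(res$p.adjusted >= res$p.value))

  # single comparison: correction factor 1
  res1 <- posthoc_paired_bonferroni(d, list(c("A", "B")), value = value,
                                    observer = observer, condition = condition)
  expect_equal(res1$p.adjusted, res1$p.value)

  # identical paired samples
  d0 <- d; d0$value <- rep(1:8, each = 3)
  res0 <- posthoc_paired_bonferroni(d0, list(c("A", "B")), value = value,
                                    observer = observer, condition = condition)
  expect_identical(res0$statistic, 0)
  expect_identical(res0$p.adjusted, 1)

  expect_error(posthoc_paired_bonferroni(d, list(c("A", "Z")), value = value,
                                         observer = observer,
                                         condition = condition),
               class = "indecision_input_error")
})

test_that("factor coding splits combined condition labels", {
  d <- tibble::tibble(condition = c("IsoFlat", "IsoDepth", "CrossFlat",
                                    "CrossDepth"))
  coded <- factor_coding(d, c("Iso", "Cross"), c("Flat", "Depth"))
  expect_identical(coded$factor_a, c("Iso", "Iso", "Cross", "Cross"))
  expect_identical(coded$factor_b, c("Flat", "Depth", "Flat", "Depth"))
  expect_error(factor_coding(tibble::tibble(condition = "Bump"),
                             c("Iso", "Cross"), c("Flat", "Depth")),
               class = "indecision_input_error")
})
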