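#' Two-by-two repeated-measures ANOVA via subject contrasts
#'
#' Within-subject 2 x 2 ANOVA on a complete observer-by-condition table of
#' parameter estimates (typically the fitted `mu`). For each effect (main
#' effect of each factor and their interaction) the per-subject contrast
#' over the four cells (+/-1 coding, halved) is computed; the test is
#' `F = n * mean(c)^2 / var(c)` on (1, n-1) degrees of freedom — identical
#' to the square of the paired t-test on the contrast. Subjects with a
#' degenerate zero-variance contrast yield `F = Inf` (mean nonzero) or
#' `F = 0` (mean zero) rather than an error, so simulation sweeps do not
#' abort.
#'
#' @param data A data frame with one row per observer x condition cell.
#' @param value,observer Column names (tidy-eval) holding the estimate and
#'   the observer label.
#' @param a,b Column names (tidy-eval) of the two within-subject factors,
#'   each with exactly two levels. Use [factor_coding()] to split combined
#'   condition labels into factors.
#' @return A tibble with columns `effect` (`"a"`, `"b"`, `"a:b"` renamed to
#'   the factor column names), `statistic` (F), `df1`, `df2`, `p.value`.
#' @examples
#' d <- tidyr::expand_grid(obs = paste0("s", 1:8),
#'                         ori = c("Iso", "Cross"), depth = c("Flat", "Depth"))
#' d$mu <- rnorm(nrow(d))
#' rm_anova_2x2(d, value = mu, observer = obs, a = ori, b = depth)
#' @export
rm_anova_2x2 <- function(data, value, observer, a, b) {
  df <- dplyr::transmute(data,
    observer = {{ observer }},
    a = as.character({{ a }}), b = as.character({{ b }}),
    value = {{ value }})
  la <- sort(unique(df$a)); lb <- sort(unique(df$b))
  if (length(la) != 2L || length(lb) != 2L) {
    abort("Each factor must have exactly two levels.",
          class = "indecision_input_error")
  }
  wide <- tidyr::pivot_wider(df, names_from = c("a", "b"),
                             values_from = "value", names_sep = ".")
  cells <- paste(rep(la, each = 2), rep(lb, 2), sep = ".")
  if (!all(cells %in% names(wide)) ||
      anyNA(wide[cells]) || nrow(wide) < 2L) {
    abort("Complete cases required: every observer needs all four cells (n >= 2).",
          class = "indecision_input_error")
  }
  m <- as.matrix(wide[cells])  # columns: a1.b1, a1.b2, a2.b1, a2.b2
  contrasts <- list(
    a = c(-1, -1, 1, 1) / 2,
    b = c(-1, 1, -1, 1) / 2,
    `a:b` = c(1, -1, -1, 1) / 2)
  an <- rlang::as_name(rlang::enquo(a))
  bn <- rlang::as_name(rlang::enquo(b))
  labels <- c(an, bn, paste0(an, ":", bn))
  out <- purrr::imap(contrasts, function(w, nm) {
    ci <- drop(m %*% w)
    contrast_f_test(ci)
  })
  dplyr::bind_cols(tibble(effect = labels), dplyr::bind_rows(out))
}

contrast_f_test <- function(ci) {
  n <- length(ci)
  v <- var(ci)
  mbar <- mean(ci)
  f <- if (v == 0) {
    if (mbar == 0) 0 else Inf
  } else {
    n * mbar^2 / v
  }
  tibble(statistic = f, df1 = 1, df2 = n - 1,
         p.value = pf(f, 1, n - 1, lower.tail = FALSE))
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition: the condition sum of squares on
#' `k - 1` degrees of freedom is tested against the condition-by-subject
#' residual on `(k - 1)(n - 1)` degrees of freedom. Sphericity is assumed
#' (no correction is applied to the degrees of freedom).
#'
#' @inheritParams rm_anova_2x2
#' @param condition Column name (tidy-eval) of the within-subject factor
#'   (k >= 2 levels).
#' @return A one-row tibble: `effect`, `statistic`, `df1`, `df2`, `p.value`.
#' @export
rm_anova_oneway <- function(data, value, observer, condition) {
  df <- dplyr::transmute(data,
    observer = {{ observer }},
    condition = as.character({{ condition }}),
    value = {{ value }})
  wide <- tidyr::pivot_wider(df, names_from = "condition",
                             values_from = "value")
  m <- as.matrix(wide[, setdiff(names(wide), "observer")])
  if (anyNA(m) || ncol(m) < 2L || nrow(m) < 2L) {
    abort("Complete cases required (n >= 2 observers, k >= 2 conditions).",
          class = "indecision_input_error")
  }
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_res <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_res <- ss_res / df2
  f <- if (ms_res == 0) {
    if (ss_cond == 0) 0 else Inf
  } else {
    (ss_cond / df1) / ms_res
  }
  cn <- rlang::as_name(rlang::enquo(condition))
  tibble(effect = cn, statistic = f, df1 = df1, df2 = df2,
         p.value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Bonferroni-corrected paired post-hoc comparisons
#'
#' Two-sided paired t-tests for a chosen family of condition pairs, with
#' `p_corrected = min(1, p_raw * number of comparisons)`.
#'
#' @inheritParams rm_anova_oneway
#' @param comparisons A list of length-2 character vectors naming condition
#'   pairs, e.g. `list(c("IsoFlat", "IsoDepth"))`.
#' @return A tibble with one row per pair: `comparison`, `estimate` (mean
#'   within-observer difference, first minus second), `statistic` (t), `df`,
#'   `p.value`, `p.adjusted`.
#' @export
posthoc_paired_bonferroni <- function(data, comparisons, value, observer,
                                      condition) {
  df <- dplyr::transmute(data,
    observer = {{ observer }},
    condition = as.character({{ condition }}),
    value = {{ value }})
  conds <- unique(df$condition)
  m <- length(comparisons)
  out <- purrr::map(comparisons, function(pair) {
    if (length(pair) != 2L || !all(pair %in% conds)) {
      abort(paste0("Unknown condition label in comparison: ",
                   paste(pair, collapse = " vs ")),
            class = "indecision_input_error")
    }
    wide <- tidyr::pivot_wider(df[df$condition %in% pair, ],
                               names_from = "condition",
                               values_from = "value")
    d1 <- wide[[pair[1]]]; d2 <- wide[[pair[2]]]
    if (anyNA(d1) || anyNA(d2)) {
      abort("Complete cases required for paired comparisons.",
            class = "indecision_input_error")
    }
    diffs <- d1 - d2
    if (sd(diffs) == 0) {
      tt <- list(statistic = c(t = if (mean(diffs) == 0) 0 else Inf * sign(mean(diffs))),
                 parameter = c(df = length(diffs) - 1),
                 p.value = if (mean(diffs) == 0) 1 else 0,
                 estimate = mean(diffs))
    } else {
      tt <- t.test(d1, d2, paired = TRUE)
    }
    tibble(comparison = paste(pair, collapse = " vs "),
           estimate = unname(tt$estimate[1]),
           statistic = unname(tt$statistic),
           df = unname(tt$parameter),
           p.value = tt$p.value,
           p.adjusted = pmin(1, tt$p.value * m))
  })
  dplyr::bind_rows(out)
}

#' Split combined condition labels into a 2 x 2 factor coding
#'
#' Maps condition labels like `"IsoFlat"` onto two factor columns given the
#' level names of each factor.
#'
#' @param data A data frame with a `condition` column.
#' @param a_levels,b_levels Character vectors of the two levels of each
#'   factor; each condition label must be the concatenation of one level of
#'   each (e.g. `"Iso" + "Flat"`).
#' @param a_name,b_name Names for the new factor columns.
#' @return `data` with the two factor columns added.
#' @export
factor_coding <- function(data, a_levels, b_levels,
                          a_name = "factor_a", b_name = "factor_b") {
  conds <- as.character(data$condition)
  a <- rep(NA_character_, length(conds))
  b <- rep(NA_character_, length(conds))
  for (la in a_levels) for (lb in b_levels) {
    hit <- conds == paste0(la, lb)
    a[hit] <- la; b[hit] <- lb
  }
  if (anyNA(a)) {
    abort(paste0("Conditions not expressible as ", paste(a_levels, collapse = "/"),
                 " x ", paste(b_levels, collapse = "/"), ": ",
                 paste(unique(conds[is.na(a)]), collapse = ", ")),
          class = "indecision_input_error")
  }
  data[[a_name]] <- a
  data[[b_name]] <- b
  data
}
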