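#' Balanced experiment design presets
#'
#' Fully enumerated designs of the training task and the three main
#' surround-suppression experiments. Every design crosses a ladder of
#' reference contrasts with the condition set and the two presentation
#' orders, repeated a fixed number of times per session:
#'
#' * `"training"` — no surround, two test contrasts (27.75% and 32.25%)
#'   acting as the conditions, reference ladder 21%–39% in steps of 2.25%
#'   (9 levels), 12 repeats, one session: 432 trials.
#' * `"exp1"` — test at 30%, surround orientation x surround depth
#'   (IsoFlat, IsoDepth, CrossFlat, CrossDepth), ladder 14, 18–34 step 2,
#'   38 (11 levels), 5 repeats/session, 8 sessions: 440 x 8 = 3,520 trials.
#' * `"exp2"` — as exp1 with Near instead of Depth conditions (wedge
#'   surround moved toward the observer): 3,520 trials.
#' * `"exp3"` — test at 30%, conditions Bump, Average, Near, same ladder,
#'   6 repeats/session, 7 sessions: 396 x 7 = 2,772 trials.
#'
#' The repeats-per-session values for exp1–exp3 are back-derived from the
#' session totals (440 = 11 x 4 x 2 x 5; 396 = 11 x 3 x 2 x 6).
#'
#' @param name One of `"training"`, `"exp1"`, `"exp2"`, `"exp3"`.
#' @return An object of class `experiment_design`: a list with fields
#'   `name`, `reference_contrasts`, `test_contrast` (named by condition),
#'   `conditions`, `orders`, `repeats_per_session`, `n_sessions`,
#'   `trials_per_session`, `total_trials`.
#' @examples
#' design_preset("exp1")$total_trials  # 3520
#' @export
design_preset <- function(name) {
  presets <- c("training", "exp1", "exp2", "exp3")
  if (length(name) != 1L || !name %in% presets) {
    abort(paste0("Unknown design preset. Valid presets: ",
                 paste(presets, collapse = ", ")),
          class = "indecision_input_error")
  }
  d <- switch(name,
    training = list(
      name = "training",
      reference_contrasts = seq(21, 39, by = 2.25),
      conditions = c("Test27.75", "Test32.25"),
      test_contrast = c(Test27.75 = 27.75, Test32.25 = 32.25),
      repeats_per_session = 12L, n_sessions = 1L),
    exp1 = list(
      name = "exp1",
      reference_contrasts = c(14, seq(18, 34, by = 2), 38),
      conditions = c("IsoFlat", "IsoDepth", "CrossFlat", "CrossDepth"),
      test_contrast = 30,
      repeats_per_session = 5L, n_sessions = 8L),
    exp2 = list(
      name = "exp2",
      reference_contrasts = c(14, seq(18, 34, by = 2), 38),
      conditions = c("IsoFlat", "IsoNear", "CrossFlat", "CrossNear"),
      test_contrast = 30,
      repeats_per_session = 5L, n_sessions = 8L),
    exp3 = list(
      name = "exp3",
      reference_contrasts = c(14, seq(18, 34, by = 2), 38),
      conditions = c("Bump", "Average", "Near"),
      test_contrast = 30,
      repeats_per_session = 6L, n_sessions = 7L))
  d$orders <- order_levels()
  if (length(d$test_contrast) == 1L && is.null(names(d$test_contrast))) {
    d$test_contrast <- setNames(rep(d$test_contrast, length(d$conditions)),
                                d$conditions)
  }
  d$trials_per_session <- length(d$reference_contrasts) *
    length(d$conditions) * length(d$orders) * d$repeats_per_session
  d$total_trials <- d$trials_per_session * d$n_sessions
  structure(d, class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %s\n", x$name))
  cat(sprintf("  %d reference contrasts x %d conditions x 2 orders x %d repeats\n",
              length(x$reference_contrasts), length(x$conditions),
              x$repeats_per_session))
  cat(sprintf("  %d trials/session x %d sessions = %d trials\n",
              x$trials_per_session, x$n_sessions, x$total_trials))
  invisible(x)
}

#' Generating ("truth") parameters mirroring the reported condition effects
#'
#' Default per-condition indecision-model parameters for simulated studies.
#' The `mu` values reproduce the studies' marginal condition means (for the
#' 2 x 2 experiments the cell means are back-solved from the printed
#' marginal means together with the pattern that depth releases suppression
#' for iso-oriented but not cross-oriented surrounds); `sigma` and the
#' criteria are a common realistic operating point (sigma = 5% contrast,
#' mildly asymmetric criteria).
#'
#' @param name Design preset name.
#' @return A tibble with columns `condition`, `mu`, `sigma`, `delta1`,
#'   `delta2`.
#' @export
truth_preset <- function(name) {
  mus <- switch(name,
    training = c(Test27.75 = 0, Test32.25 = 0),
    exp1 = c(IsoFlat = -9.25, IsoDepth = -7.01,
             CrossFlat = -4.95, CrossDepth = -4.83),
    exp2 = c(IsoFlat = -2.25, IsoNear = -0.75,
             CrossFlat = -0.55, CrossNear = -0.45),
    exp3 = c(Bump = 0.89, Average = 2.1, Near = 1.7),
    abort("Unknown preset.", class = "indecision_input_error"))
  tibble(condition = names(mus), mu = unname(mus),
         sigma = 5, delta1 = -1.5, delta2 = 2.5)
}

truth_to_list <- function(truth) {
  if (inherits(truth, "model_params")) {
    abort("`truth` must map condition labels to parameters.",
          class = "indecision_input_error")
  }
  if (is.data.frame(truth)) {
    out <- lapply(seq_len(nrow(truth)), function(i) {
      model_params(truth$mu[i], truth$sigma[i], truth$delta1[i], truth$delta2[i])
    })
    names(out) <- truth$condition
    return(out)
  }
  lapply(truth, as_model_params)
}

#' Simulate a balanced trial table from an experiment design
#'
#' Enumerates every (reference contrast, condition, order) cell
#' `repeats_per_session` times per session, shuffles the order of trials
#' uniformly within each session, draws the internal difference signal
#' `D ~ Normal(order-signed (x - mu), sigma)` for each trial, and applies
#' the two-criterion rule to produce a categorical response. Identical
#' seeds yield identical tables.
#'
#' @param design An [design_preset()] object (or a compatible list).
#' @param truth Per-condition generating parameters: a tibble like
#'   [truth_preset()] or a named list of [model_params()].
#' @param seed Integer seed; the generator state outside the call is left
#'   untouched.
#' @param observer Observer label stored in the table.
#' @return A tibble with columns `observer`, `session`, `trial`,
#'   `condition`, `order`, `ref_contrast`, `test_contrast`, `response`.
#' @examples
#' trials <- simulate_trials(design_preset("exp3"), truth_preset("exp3"),
#'                           seed = 42)
#' nrow(trials)  # 2772
#' @export
simulate_trials <- function(design, truth, seed, observer = "obs1") {
  truth <- truth_to_list(truth)
  missing_cond <- setdiff(design$conditions, names(truth))
  if (length(missing_cond)) {
    abort(paste0("`truth` has no parameters for condition(s): ",
                 paste(missing_cond, collapse = ", ")),
          class = "indecision_input_error")
  }
  cells <- tidyr::expand_grid(
    ref_contrast = design$reference_contrasts,
    condition = design$conditions,
    order = design$orders,
    rep = seq_len(design$repeats_per_session))

  withr::with_seed(seed, {
    sessions <- lapply(seq_len(design$n_sessions), function(s) {
      tab <- cells[sample.int(nrow(cells)), c("ref_contrast", "condition", "order")]
      tab$session <- s
      tab
    })
    trials <- dplyr::bind_rows(sessions)
    trials$trial <- stats::ave(seq_len(nrow(trials)), trials$session,
                               FUN = seq_along)
    trials$test_contrast <- unname(design$test_contrast[trials$condition])
    pars <- do.call(rbind, lapply(truth, function(p) {
      c(p$mu, p$sigma, p$delta1, p$delta2)
    }))
    pm <- pars[trials$condition, , drop = FALSE]
    x <- trials$ref_contrast - trials$test_contrast
    signed <- ifelse(trials$order == "REF_SECOND", 1, -1)
    d_signal <- rnorm(nrow(trials), mean = signed * (x - pm[, 1]), sd = pm[, 2])
    # interval-frame decision: below delta1 -> "second lower",
    # above delta2 -> "second higher", between -> DK
    second_higher <- d_signal > pm[, 4]
    second_lower <- d_signal < pm[, 3]
    response <- ifelse(
      !second_higher & !second_lower, "DK",
      ifelse(trials$order == "REF_SECOND",
             ifelse(second_higher, "REF_HIGHER", "REF_LOWER"),
             ifelse(second_higher, "REF_LOWER", "REF_HIGHER")))
    trials$response <- response
    trials$observer <- observer
    tibble::as_tibble(trials[, c("observer", "session", "trial", "condition",
                                 "order", "ref_contrast", "test_contrast",
                                 "response")])
  })
}

#' Aggregate a trial table into per-cell response counts
#'
#' Tallies responses by condition, signed contrast difference
#' `x = ref_contrast - test_contrast`, and presentation order — the
#' sufficient statistic for the multinomial likelihood. The total of all
#' counts equals the number of input rows.
#'
#' @param trials A trial table as produced by [simulate_trials()] or
#'   [read_trial_table()]. An `observer` column, when present with several
#'   levels, is retained in the grouping.
#' @return A tibble with columns (`observer`,) `condition`, `x`, `order`,
#'   `n_ref_higher`, `n_ref_lower`, `n_dk`.
#' @export
aggregate_counts <- function(trials) {
  if (nrow(trials) == 0L) {
    return(tibble(condition = character(), x = numeric(), order = character(),
                  n_ref_higher = integer(), n_ref_lower = integer(),
                  n_dk = integer()))
  }
  bad <- !trials$response %in% response_levels()
  if (any(bad)) {
    abort(paste0("Unknown response label(s) in rows: ",
                 paste(head(which(bad), 10), collapse = ", "),
                 if (sum(bad) > 10) " ..." else ""),
          class = "indecision_input_error")
  }
  keys <- c(
    if ("observer" %in% names(trials) &&
        length(unique(trials$observer)) > 1L) "observer",
    "condition", "x", "order")
  trials |>
    dplyr::mutate(x = .data$ref_contrast - .data$test_contrast) |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), .data$response) |>
    tidyr::pivot_wider(names_from = "response", values_from = "n",
                       values_fill = 0L) |>
    add_missing_count_cols() |>
    dplyr::rename(n_ref_higher = "REF_HIGHER", n_ref_lower = "REF_LOWER",
                  n_dk = "DK") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

add_missing_count_cols <- function(tab) {
  for (lev in response_levels()) {
    if (!lev %in% names(tab)) tab[[lev]] <- 0L
  }
  tab
}

#' Simulate a group of observers with parameter heterogeneity
#'
#' Draws per-observer parameters around the group-level truth and simulates
#' one full trial table per observer. Heterogeneity is Normal on `mu`,
#' truncated-Normal on `sigma` (floored at 0.5% contrast), and a shared
#' Normal bias shift applied to both criteria, so the criterion separation
#' (the width of the indecision zone) is preserved within observer.
#'
#' @param design An [design_preset()] object.
#' @param truth Group-level truth as in [simulate_trials()].
#' @param n_observers Number of observers.
#' @param seed Integer seed.
#' @param sd_mu,sd_sigma,sd_bias Hyper-level standard deviations
#'   (% contrast) for the observer draws.
#' @return A list with `trials` (all observers' trial tables bound
#'   together) and `observer_truth` (tibble of each observer's drawn
#'   parameters per condition).
#' @export
simulate_observers <- function(design, truth, n_observers, seed,
                               sd_mu = 1, sd_sigma = 0.75, sd_bias = 0.5) {
  truth_tab <- if (is.data.frame(truth)) truth else {
    tl <- truth_to_list(truth)
    tibble(condition = names(tl),
           mu = purrr::map_dbl(tl, "mu"),
           sigma = purrr::map_dbl(tl, "sigma"),
           delta1 = purrr::map_dbl(tl, "delta1"),
           delta2 = purrr::map_dbl(tl, "delta2"))
  }
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(n_observers), function(i) {
      obs <- truth_tab
      obs$observer <- sprintf("obs%02d", i)
      obs$mu <- obs$mu + rnorm(nrow(obs), 0, sd_mu)
      obs$sigma <- pmax(obs$sigma + rnorm(nrow(obs), 0, sd_sigma), 0.5)
      bias <- rnorm(1, 0, sd_bias)
      obs$delta1 <- obs$delta1 + bias
      obs$delta2 <- obs$delta2 + bias
      obs
    })
  })
  seeds <- seed + seq_len(n_observers)
  trials <- purrr::map2(draws, seeds, function(obs, s) {
    simulate_trials(design, obs, seed = s, observer = obs$observer[1])
  })
  list(trials = dplyr::bind_rows(trials),
       observer_truth = dplyr::bind_rows(draws))
}

#' Assess training-task veridicality
#'
#' Fits the indecision model separately per training test contrast and
#' checks that the estimated perceived contrast of each test grating is
#' within `tol` of its physical contrast (the gate used to admit observers
#' to the main experiments).
#'
#' @param trials A training-task trial table (conditions = test contrasts).
#' @param tol Permitted absolute deviation of the fitted `mu` from zero,
#'   percent contrast. Default 1.
#' @param ... Passed to [fit_indecision()].
#' @return A tibble with one row per test contrast: `condition`,
#'   `test_contrast`, `mu`, `pass`, plus an attribute `"pass"` giving the
#'   overall gate decision.
#' @export
assess_training <- function(trials, tol = 1, ...) {
  counts <- aggregate_counts(trials)
  per <- counts |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_indecision(df, ...)
      tibble(mu = fit$params$mu, pass = abs(fit$params$mu) <= tol)
    }) |>
    dplyr::ungroup()
  tc <- trials |>
    dplyr::distinct(.data$condition, .data$test_contrast)
  out <- dplyr::left_join(per, tc, by = "condition")
  out <- out[, c("condition", "test_contrast", "mu", "pass")]
  attr(out, "pass") <- all(out$pass)
  out
}
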