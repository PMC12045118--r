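#' Response probabilities of the difference-with-indecision model
#'
#' The observer's internal decision variable `D` is the perceived contrast of
#' the second interval minus that of the first, normally distributed with
#' standard deviation `sigma`. When the reference is shown second its mean is
#' `+(x - mu)`, when first `-(x - mu)`, where `x` is the physical contrast of
#' the reference minus that of the test and `mu` the perceived-contrast shift
#' of the test. Two fixed criteria partition `D`: below `delta1` the observer
#' reports "second interval lower", above `delta2` "second interval higher",
#' and in between "don't know". Interval-frame responses are mapped back to
#' reference-frame responses according to the presentation order, so criterion
#' shifts capture interval bias while `mu` stays identified.
#'
#' @param params A [model_params()] object.
#' @param x Numeric vector of signed contrast differences
#'   (reference minus test), percent contrast.
#' @param order Character vector (recycled against `x`), each element
#'   `"REF_FIRST"` or `"REF_SECOND"`.
#'
#' @return A tibble with columns `x`, `order`, `p_ref_higher`, `p_ref_lower`,
#'   `p_dk`. The three probabilities sum to 1 in each row.
#' @examples
#' p <- model_params(mu = 0, sigma = 1, delta1 = -1, delta2 = 1)
#' response_probabilities(p, x = 0, order = "REF_SECOND")
#' @export
response_probabilities <- function(params, x, order) {
  params <- as_model_params(params)
  if (!is.numeric(x) || length(x) == 0L || !all(is.finite(x))) {
    abort("`x` must be a non-empty finite numeric vector.",
          class = "indecision_input_error")
  }
  order <- check_order(order)
  n <- max(length(x), length(order))
  x <- rep_len(x, n); order <- rep_len(order, n)

  u <- x - params$mu
  s <- params$sigma
  second <- order == "REF_SECOND"
  # reference second: D ~ N(u, s); reference first: D ~ N(-u, s)
  p_lo <- ifelse(second,
                 pnorm((params$delta1 - u) / s),        # D < delta1 -> ref lower
                 pnorm(-(params$delta2 + u) / s))       # D > delta2 -> ref lower
  p_hi <- ifelse(second,
                 pnorm(-(params$delta2 - u) / s),       # D > delta2 -> ref higher
                 pnorm((params$delta1 + u) / s))        # D < delta1 -> ref higher
  p_dk <- 1 - p_lo - p_hi
  # clamp tiny negative values from floating cancellation
  p_dk <- pmin(pmax(p_dk, 0), 1)
  tibble(x = x, order = order,
         p_ref_higher = p_hi, p_ref_lower = p_lo, p_dk = p_dk)
}

check_order <- function(order) {
  order <- as.character(order)
  bad <- !order %in% order_levels()
  if (length(order) == 0L || any(bad)) {
    abort(paste0("`order` must be one of ",
                 paste(order_levels(), collapse = ", "), "."),
          class = "indecision_input_error")
  }
  order
}

#' Negative log-likelihood of aggregated 2-AFC-DK counts
#'
#' Sums, over stimulus cells, the multinomial log-mass of the observed
#' response counts under the model's response probabilities (the constant
#' multinomial coefficient is omitted). Probabilities are floored at
#' `prob_floor` inside the logarithm only, so the objective stays finite at
#' boundary parameter values.
#'
#' @param params A [model_params()] object (or coercible list).
#' @param counts A data frame of response counts with columns `x`, `order`,
#'   `n_ref_higher`, `n_ref_lower`, `n_dk` — one row per stimulus cell, as
#'   produced by [aggregate_counts()].
#' @param prob_floor Small positive floor applied to probabilities before
#'   taking logs. Default `1e-9`.
#'
#' @return A non-negative scalar.
#' @examples
#' cts <- tibble::tibble(x = 0, order = "REF_SECOND",
#'                       n_ref_higher = 1, n_ref_lower = 0, n_dk = 0)
#' indecision_nll(model_params(0, 1, 0, 0), cts)  # -log(0.5)
#' @export
indecision_nll <- function(params, counts, prob_floor = 1e-9) {
  counts <- check_counts(counts)
  params <- as_model_params(params)
  nll_impl(c(params$mu, params$sigma, params$delta1, params$delta2),
           counts, prob_floor)
}

# fast path used by the optimizer: par = (mu, sigma, delta1, delta2),
# counts already validated, columns extracted as plain vectors
nll_impl <- function(par, counts, prob_floor) {
  u <- counts$x - par[1]
  s <- par[2]
  second <- counts$order == "REF_SECOND"
  p_lo <- ifelse(second, pnorm((par[3] - u) / s), pnorm(-(par[4] + u) / s))
  p_hi <- ifelse(second, pnorm(-(par[4] - u) / s), pnorm((par[3] + u) / s))
  p_dk <- pmax(1 - p_lo - p_hi, 0)
  -sum(counts$n_ref_higher * log(pmax(p_hi, prob_floor)) +
       counts$n_ref_lower  * log(pmax(p_lo, prob_floor)) +
       counts$n_dk         * log(pmax(p_dk, prob_floor)))
}

check_counts <- function(counts) {
  needed <- c("x", "order", "n_ref_higher", "n_ref_lower", "n_dk")
  if (!is.data.frame(counts) || nrow(counts) == 0L) {
    abort("`counts` must be a non-empty data frame.",
          class = "indecision_input_error")
  }
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols)) {
    abort(paste0("`counts` is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "indecision_input_error")
  }
  check_order(counts$order)
  ns <- as.matrix(counts[, c("n_ref_higher", "n_ref_lower", "n_dk")])
  if (any(!is.finite(ns)) || any(ns < 0) || any(ns != round(ns))) {
    abort("Counts must be non-negative integers.",
          class = "indecision_input_error")
  }
  if (any(!is.finite(counts$x))) {
    abort("`x` must be finite.", class = "indecision_input_error")
  }
  counts
}

#' Location of the peak of the order-averaged "don't know" curve
#'
#' The probability of a "don't know" response, averaged over the two
#' presentation orders, is an even function of `x - mu`; when it is unimodal
#' its maximum sits exactly at `x = mu`, which is why the fitted `mu` is read
#' as the perceived-contrast difference. When the criterion midpoint is far
#' from zero relative to the criterion separation the averaged curve splits
#' into two symmetric peaks at `mu +/- u*`; that case is flagged rather than
#' silently averaged away.
#'
#' @param params A [model_params()] object with `delta1 < delta2`.
#' @param grid_n Number of grid points used to locate the maximum before
#'   local refinement.
#'
#' @return A list of class `dk_peak` with elements `peak` (the peak location,
#'   `NA` when bimodal), `peaks` (all peak locations, length 1 or 2),
#'   `bimodal` (logical).
#' @examples
#' dk_peak(model_params(-5, 3, -1, 1))$peak  # -5
#' @export
dk_peak <- function(params, grid_n = 4001L) {
  params <- as_model_params(params)
  if (params$delta1 == params$delta2) {
    abort("Degenerate model: `delta1 == delta2` makes P(don't know) = 0 everywhere.",
          class = "indecision_domain_error")
  }
  mid <- (params$delta1 + params$delta2) / 2
  span <- abs(mid) + (params$delta2 - params$delta1) + 6 * params$sigma
  # order-averaged DK probability as a function of u = x - mu (even in u)
  g <- function(u) {
    a <- pnorm((params$delta2 - u) / params$sigma) -
         pnorm((params$delta1 - u) / params$sigma)
    b <- pnorm((params$delta2 + u) / params$sigma) -
         pnorm((params$delta1 + u) / params$sigma)
    (a + b) / 2
  }
  u <- seq(0, span, length.out = grid_n)
  gu <- g(u)
  i <- which.max(gu)
  step <- u[2] - u[1]
  if (u[i] <= 2 * step && gu[i] <= g(0) + 1e-12) {
    structure(list(peak = params$mu, peaks = params$mu, bimodal = FALSE),
              class = "dk_peak")
  } else {
    lo <- max(u[i] - 2 * step, 0); hi <- min(u[i] + 2 * step, span)
    opt <- optimize(g, c(lo, hi), maximum = TRUE, tol = 1e-10)
    ustar <- opt$maximum
    structure(list(peak = NA_real_,
                   peaks = params$mu + c(-ustar, ustar),
                   bimodal = TRUE),
              class = "dk_peak")
  }
}

#' @export
print.dk_peak <- function(x, ...) {
  if (x$bimodal) {
    cat(sprintf("<dk_peak> bimodal; peaks at %.4f and %.4f %% contrast\n",
                x$peaks[1], x$peaks[2]))
  } else {
    cat(sprintf("<dk_peak> unimodal; peak at %.4f %% contrast\n", x$peak))
  }
  invisible(x)
}
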