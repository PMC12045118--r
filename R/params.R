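#' Indecision-model parameters
#'
#' Bundle the four parameters of the difference-with-indecision model. All
#' four are expressed in percent Michelson contrast, the unit of the
#' physical contrast difference between the reference and test gratings.
#'
#' @param mu Perceived-contrast shift of the test stimulus relative to its
#'   physical contrast. Negative values mean the context makes the test
#'   appear lower in contrast; `mu` is the contrast offset at which the
#'   observer is maximally uncertain.
#' @param sigma Standard deviation of the internal difference signal
#'   (steepness of the psychometric functions). Must be positive.
#' @param delta1,delta2 Lower and upper decision criteria on the internal
#'   difference signal. Differences between the criteria produce "don't
#'   know" responses; their midpoint captures interval/response bias.
#'   `delta1 <= delta2` is required; equality forces P(don't know) = 0.
#'
#' @return An object of class `model_params`: a named list with elements
#'   `mu`, `sigma`, `delta1`, `delta2`.
#' @examples
#' model_params(mu = -8.13, sigma = 5, delta1 = -1.5, delta2 = 2.5)
#' @export
model_params <- function(mu = 0, sigma = 1, delta1 = 0, delta2 = 0) {
  p <- list(mu = as.numeric(mu), sigma = as.numeric(sigma),
            delta1 = as.numeric(delta1), delta2 = as.numeric(delta2))
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  vals <- unlist(p[c("mu", "sigma", "delta1", "delta2")])
  if (length(vals) != 4L || !all(is.finite(vals))) {
    abort("All four model parameters must be finite scalars.",
          class = "indecision_domain_error")
  }
  if (p$sigma <= 0) {
    abort("`sigma` must be > 0.", class = "indecision_domain_error")
  }
  if (p$delta1 > p$delta2) {
    abort("`delta1` must be <= `delta2`.", class = "indecision_domain_error")
  }
  invisible(p)
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  x <- as.list(x)
  model_params(mu = x$mu, sigma = x$sigma,
               delta1 = x$delta1, delta2 = x$delta2)
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> mu = %.3f, sigma = %.3f, delta1 = %.3f, delta2 = %.3f (%% contrast)\n",
    x$mu, x$sigma, x$delta1, x$delta2))
  invisible(x)
}

#' @export
as.data.frame.model_params <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

# canonical order / response level sets used throughout the package
order_levels <- function() c("REF_FIRST", "REF_SECOND")
response_levels <- function() c("REF_HIGHER", "REF_LOWER", "DK")
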