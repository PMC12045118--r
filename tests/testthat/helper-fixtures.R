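# Shared fixtures and independent oracles used across the suite.

# Monte-Carlo oracle: simulates the generative response rule directly
# (interval-frame Gaussian difference signal, two criteria, order mapping)
# without touching the package's closed-form code path.
mc_response_probs <- function(params, x, order, n = 1e6, seed = 99) {
  withr::with_seed(seed, {
    signed <- if (order == "REF_SECOND") 1 else -1
    d <- rnorm(n, signed * (x - params$mu), params$sigma)
    second_higher <- d > params$delta2
    second_lower <- d < params$delta1
    dk <- !second_higher & !second_lower
    if (order == "REF_SECOND") {
      c(p_ref_higher = mean(second_higher), p_ref_lower = mean(second_lower),
        p_dk = mean(dk))
    } else {
      c(p_ref_higher = mean(second_lower), p_ref_lower = mean(second_higher),
        p_dk = mean(dk))
    }
  })
}

# Per-trial log-likelihood oracle: expands counts to individual trials and
# sums -log(p) category by category. Shares the documented probability
# floor so the comparison isolates the per-cell-multinomial aggregation.
nll_per_trial_oracle <- function(params, counts, prob_floor = 1e-9) {
  tot <- 0
  for (i in seq_len(nrow(counts))) {
    p <- response_probabilities(params, counts$x[i], counts$order[i])
    probs <- pmax(c(p$p_ref_higher, p$p_ref_lower, p$p_dk), prob_floor)
    ns <- c(counts$n_ref_higher[i], counts$n_ref_lower[i], counts$n_dk[i])
    for (j in 1:3) {
      if (ns[j] > 0) tot <- tot - sum(rep(log(probs[j]), ns[j]))
    }
  }
  tot
}

# A single-condition variant of the main 2x2 design: 11 contrasts x 2
# orders x 5 repeats x 8 sessions = 880 trials, the per-condition trial
# count of the full experiment.
single_condition_design <- function() {
  d <- design_preset("exp1")
  d$conditions <- "C"
  d$test_contrast <- c(C = 30)
  d$trials_per_session <- length(d$reference_contrasts) * 2 *
    d$repeats_per_session
  d$total_trials <- d$trials_per_session * d$n_sessions
  d
}

# random draw of valid model parameters for property tests
random_params <- function() {
  mid <- rnorm(1, 0, 1.5)
  half <- abs(rnorm(1, 1.5, 1))
  model_params(mu = runif(1, -10, 10), sigma = runif(1, 0.5, 8),
               delta1 = mid - half, delta2 = mid + half)
}

# brute-force within-subject SS decomposition via aov() Error strata
aov_rm_f <- function(data, formula_rhs, error_term) {
  fml <- stats::as.formula(paste("value ~", formula_rhs,
                                 "+ Error(observer/", error_term, ")"))
  data$observer <- factor(data$observer)
  fit <- stats::aov(fml, data = data)
  s <- summary(fit)
  out <- list()
  for (stratum in s) {
    tab <- stratum[[1]]
    rows <- rownames(tab)
    for (r in seq_along(rows)) {
      nm <- trimws(rows[r])
      if (nm != "Residuals") out[[nm]] <- tab[r, "F value"]
    }
  }
  out
}
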