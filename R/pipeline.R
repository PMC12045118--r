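#' Read and write trial tables as CSV
#'
#' The canonical trial-table header is `observer, session, trial, condition,
#' order, ref_contrast, test_contrast, response` with `order` in
#' `REF_FIRST`/`REF_SECOND` and `response` in `REF_HIGHER`/`REF_LOWER`/`DK`.
#' `read_trial_table()` can ingest foreign schemas through a column mapping
#' (standard name -> source column) and a response recoding (source label ->
#' standard label); unknown response labels after recoding raise an error
#' naming the offending rows.
#'
#' @param trials A trial table tibble.
#' @param path CSV file path.
#' @param mapping Optional named character vector, e.g.
#'   `c(observer = "subj", ref_contrast = "refC", ...)`. Unmapped standard
#'   columns must already exist in the file.
#' @param response_map Optional named character vector recoding response
#'   labels, e.g. `c("1" = "REF_HIGHER", "0" = "REF_LOWER", "d" = "DK")`.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns the standardised tibble.
#' @export
write_trial_table <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path, mapping = NULL, response_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  std <- c("observer", "session", "trial", "condition", "order",
           "ref_contrast", "test_contrast", "response")
  if (!is.null(mapping)) {
    missing_src <- setdiff(unname(mapping), names(raw))
    if (length(missing_src)) {
      abort(paste0("Mapped source column(s) not in file: ",
                   paste(missing_src, collapse = ", ")),
            class = "indecision_input_error")
    }
    for (dst in names(mapping)) raw[[dst]] <- raw[[mapping[[dst]]]]
  }
  missing_cols <- setdiff(std, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Trial table is missing column(s): ",
                 paste(missing_cols, collapse = ", "),
                 ". Supply a `mapping`."),
          class = "indecision_input_error")
  }
  out <- raw[std]
  out$response <- as.character(out$response)
  if (!is.null(response_map)) {
    hit <- out$response %in% names(response_map)
    out$response[hit] <- unname(response_map[out$response[hit]])
  }
  bad <- !out$response %in% response_levels()
  if (any(bad)) {
    abort(paste0("Unknown response label(s) ",
                 paste(unique(out$response[bad]), collapse = ", "),
                 " in rows: ", paste(head(which(bad), 10), collapse = ", "),
                 if (sum(bad) > 10) " ..." else ""),
          class = "indecision_input_error")
  }
  out$order <- as.character(out$order)
  check_order(out$order)
  out
}

#' Fit the indecision model per observer and condition
#'
#' @param counts Aggregated counts with (optionally) `observer` and
#'   `condition` grouping columns.
#' @param ... Passed to [fit_indecision()].
#' @return A tibble with one row per group: the fitted parameters, the
#'   negative log-likelihood, convergence metadata and
#'   `delta_perceived_contrast`.
#' @export
fit_by_observer <- function(counts, ...) {
  keys <- intersect(c("observer", "condition"), names(counts))
  counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_indecision(df, ...)
      glance(fit) |>
        dplyr::mutate(mu = fit$params$mu, sigma = fit$params$sigma,
                      delta1 = fit$params$delta1, delta2 = fit$params$delta2,
                      .before = 1)
    }) |>
    dplyr::ungroup()
}

#' Run a full synthetic study
#'
#' End-to-end composition of the simulation and analysis chain: simulate a
#' group of observers under a design preset -> aggregate counts -> fit the
#' indecision model per observer x condition -> within-subject group
#' statistics on the fitted `mu` values. Deterministic given `seed`; the
#' returned report embeds the resolved configuration, its hash, the seed
#' and the package version.
#'
#' @param preset Design preset name (see [design_preset()]), or an
#'   `experiment_design` object via `design`.
#' @param truth Per-condition generating parameters; default
#'   [truth_preset()] for the preset.
#' @param n_observers Number of simulated observers (>= 2).
#' @param seed Integer seed for all randomness in the run.
#' @param design Optional explicit design overriding `preset`.
#' @param sd_mu,sd_sigma,sd_bias Observer-heterogeneity standard
#'   deviations; see [simulate_observers()].
#' @param factors For 2 x 2 designs, a list
#'   `list(a = c(...), b = c(...))` of factor levels whose concatenation
#'   forms the condition labels; defaults are supplied for the built-in
#'   presets. Set `NULL` to force a one-way analysis.
#' @param comparisons Post-hoc comparison family; defaults mirror the
#'   analyses of the corresponding experiment (depth effect within each
#'   orientation for the 2 x 2 presets; all three pairs for exp3).
#' @param fit_options List of arguments passed to [fit_indecision()].
#' @return A `study_report`: a list with `config`, `observer_truth`,
#'   `fits`, `group_means`, `anova`, `posthoc`.
#' @examples
#' \donttest{
#' rep <- run_synthetic_study("exp3", n_observers = 3, seed = 7)
#' rep$group_means
#' }
#' @export
run_synthetic_study <- function(preset = "exp1", truth = NULL,
                                n_observers = 8, seed = 1,
                                design = NULL,
                                sd_mu = 1, sd_sigma = 0.75, sd_bias = 0.5,
                                factors = default_factors(preset),
                                comparisons = default_comparisons(preset),
                                fit_options = list()) {
  if (n_observers < 2) {
    abort("Group statistics need >= 2 observers (df would be 0).",
          class = "indecision_input_error")
  }
  design <- design %||% design_preset(preset)
  truth <- truth %||% truth_preset(preset)
  config <- list(preset = preset, design_name = design$name,
                 truth = as.data.frame(truth),
                 n_observers = n_observers, seed = seed,
                 sd_mu = sd_mu, sd_sigma = sd_sigma, sd_bias = sd_bias,
                 factors = factors, comparisons = comparisons,
                 fit_options = fit_options)
  sim <- simulate_observers(design, truth, n_observers, seed,
                            sd_mu = sd_mu, sd_sigma = sd_sigma,
                            sd_bias = sd_bias)
  counts <- aggregate_counts(sim$trials)
  fits <- do.call(fit_by_observer, c(list(counts), fit_options))
  report_from_fits(fits, config = config,
                   observer_truth = sim$observer_truth,
                   dk_usage = dk_usage(sim$trials))
}

default_factors <- function(preset) {
  switch(preset,
         exp1 = list(a = c("Iso", "Cross"), b = c("Flat", "Depth")),
         exp2 = list(a = c("Iso", "Cross"), b = c("Flat", "Near")),
         NULL)
}

default_comparisons <- function(preset) {
  switch(preset,
    exp1 = list(c("IsoFlat", "IsoDepth"), c("CrossFlat", "CrossDepth")),
    exp2 = list(c("IsoFlat", "IsoNear"), c("CrossFlat", "CrossNear")),
    exp3 = list(c("Bump", "Average"), c("Bump", "Near"),
                c("Average", "Near")),
    NULL)
}

dk_usage <- function(trials) {
  trials |>
    dplyr::group_by(.data$observer) |>
    dplyr::summarise(dk_fraction = mean(.data$response == "DK"),
                     .groups = "drop")
}

report_from_fits <- function(fits, config, observer_truth = NULL,
                             dk_usage = NULL) {
  group_means <- fits |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_mu = mean(.data$mu),
                     sem_mu = sd(.data$mu) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  n_obs <- length(unique(fits$observer))
  anova_tab <- posthoc_tab <- NULL
  if (n_obs >= 2) {
    if (!is.null(config$factors)) {
      coded <- factor_coding(fits, config$factors$a, config$factors$b)
      anova_tab <- rm_anova_2x2(coded, value = mu, observer = observer,
                                a = factor_a, b = factor_b)
    } else if (length(unique(fits$condition)) >= 2) {
      anova_tab <- rm_anova_oneway(fits, value = mu, observer = observer,
                                   condition = condition)
    }
    if (!is.null(config$comparisons)) {
      posthoc_tab <- posthoc_paired_bonferroni(
        fits, config$comparisons, value = mu, observer = observer,
        condition = condition)
    }
  }
  structure(list(
    config = config,
    config_hash = rlang::hash(config),
    seed = config$seed,
    package_version = as.character(packageVersion("indecision")),
    observer_truth = observer_truth,
    dk_usage = dk_usage,
    fits = fits,
    group_means = group_means,
    anova = anova_tab,
    posthoc = posthoc_tab
  ), class = "study_report")
}

#' Re-analyse an external trial-table deposit
#'
#' Applies the same analysis chain as [run_synthetic_study()] from the
#' aggregation stage onward to externally collected data (e.g. a public
#' raw-data deposit): ingest CSV (with optional column mapping), aggregate,
#' fit per observer x condition, and — when at least two observers with
#' complete condition sets are present — compute the group statistics. The
#' report includes each observer's opt-out usage fraction.
#'
#' @param path CSV file path.
#' @param mapping,response_map See [read_trial_table()].
#' @param factors,comparisons See [run_synthetic_study()]; default `NULL`
#'   (one-way ANOVA, no post-hocs).
#' @param fit_options List of arguments passed to [fit_indecision()].
#' @return A `study_report`.
#' @export
run_reanalysis <- function(path, mapping = NULL, response_map = NULL,
                           factors = NULL, comparisons = NULL,
                           fit_options = list()) {
  trials <- read_trial_table(path, mapping = mapping,
                             response_map = response_map)
  config <- list(data_path = path, mapping = mapping,
                 response_map = response_map, factors = factors,
                 comparisons = comparisons, fit_options = fit_options,
                 seed = NA_integer_)
  counts <- aggregate_counts(trials)
  if (!"observer" %in% names(counts)) {
    counts$observer <- trials$observer[1]
  }
  fits <- do.call(fit_by_observer, c(list(counts), fit_options))
  report_from_fits(fits, config = config, dk_usage = dk_usage(trials))
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", x$config$design_name %||% x$config$data_path, "\n")
  cat(sprintf("  seed: %s  config hash: %s  version: %s\n",
              x$seed, substr(x$config_hash, 1, 8), x$package_version))
  cat("  group means (delta perceived contrast, % +/- SEM):\n")
  gm <- x$group_means
  for (i in seq_len(nrow(gm))) {
    cat(sprintf("    %-12s %6.2f +/- %.2f (n = %d)\n", gm$condition[i],
                gm$mean_mu[i], gm$sem_mu[i], gm$n[i]))
  }
  if (!is.null(x$anova)) {
    cat("  ANOVA:\n")
    a <- x$anova
    for (i in seq_len(nrow(a))) {
      cat(sprintf("    %-24s F(%d,%d) = %.2f, p = %.4g\n", a$effect[i],
                  a$df1[i], a$df2[i], a$statistic[i], a$p.value[i]))
    }
  }
  if (!is.null(x$posthoc)) {
    cat("  post-hoc paired t (Bonferroni):\n")
    ph <- x$posthoc
    for (i in seq_len(nrow(ph))) {
      cat(sprintf("    %-28s t(%d) = %.2f, p = %.4g\n", ph$comparison[i],
                  ph$df[i], ph$statistic[i], ph$p.adjusted[i]))
    }
  }
  invisible(x)
}

#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, ...) {
  gm <- object$group_means
  ggplot2::ggplot(gm, ggplot2::aes(x = .data$condition, y = .data$mean_mu)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_mu - .data$sem_mu,
                   ymax = .data$mean_mu + .data$sem_mu), width = 0.2) +
    ggplot2::geom_point(data = object$fits,
                        ggplot2::aes(y = .data$mu), alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "Delta perceived contrast (%)") +
    ggplot2::theme_minimal()
}

#' Serialise a study report to JSON
#'
#' @param report A `study_report`.
#' @param path Optional output path.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "study_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
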