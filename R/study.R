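# Replication harness for the Type I error / power study: for each cell of
# a scenario grid, repeatedly simulate -> fit -> score -> test and tabulate
# rejection rates per statistic. Statistic-to-covariate pairing follows the
# study design: DM, CvM and maxLM are applied to the metric covariate Znum,
# WDMo and maxLMo to the ordinal Zord, LMuo to the categorical Zcat.

.study_stats <- tibble::tibble(
  statistic = c("DM", "CvM", "maxLM", "WDMo", "maxLMo", "LMuo"),
  covariate = c("Znum", "Znum", "Znum", "Zord", "Zord", "Zcat"),
  type = c("metric", "metric", "metric", "ordinal", "ordinal", "categorical"))

#' Build a study grid
#'
#' One row per simulation cell; arguments are crossed.
#'
#' @param model,k,n,scenario Vectors of [dif_scenario()] settings.
#' @param n_reps Replications per cell.
#' @return Tibble with one row per cell.
#' @export
study_grid <- function(model = "unidimensional", k = 2, n = 1000,
                       scenario = "all_params", n_reps = 100) {
  g <- tidyr::expand_grid(model = model, k = k, n = n, scenario = scenario)
  g$n_reps <- n_reps
  g$cell <- seq_len(nrow(g))
  g
}

#' Run one simulate-fit-score-test replication
#'
#' @param model,k,n,scenario Cell settings, see [dif_scenario()].
#' @param seed Replication seed (set before the parameter draw).
#' @param alpha Significance level.
#' @param statistics Subset of the six statistics to apply.
#' @param ... Passed to [test_statistic()] (e.g. `crit_reps`).
#' @return Tibble with one row per statistic: `statistic`, `value`,
#'   `p_value`, `reject`; or a zero-row tibble with attribute
#'   `"error"` if the fit failed.
#' @export
run_replication <- function(model, k, n, scenario, seed, alpha = 0.05,
                            statistics = .study_stats$statistic, ...) {
  set.seed(seed)
  scn <- dif_scenario(model, k = k, n = n, scenario = scenario)
  dat <- simulate_dif_study(scn)
  res <- try({
    fit <- fit_ofa(dat, scn$spec)
    sc <- approx_scores(fit)
    plan <- .study_stats[.study_stats$statistic %in% statistics, ]
    purrr::map_dfr(unique(plan$covariate), function(cv) {
      rows <- plan[plan$covariate == cv, ]
      dif_test(fit, z = dat[[cv]], type = rows$type[1],
               stats = rows$statistic, scores = sc, covariate = cv, ...)
    })
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    out <- .study_stats[0, c("statistic", "covariate")]
    out$value <- numeric(0)
    out$p_value <- numeric(0)
    out$reject <- logical(0)
    attr(out, "error") <- attr(res, "condition")$message
    return(out)
  }
  dplyr::mutate(res[, c("statistic", "covariate", "value", "p_value")],
                reject = .data$p_value < alpha)
}

#' Run a Type I error / power study
#'
#' Executes every cell of a [study_grid()]: per replication a fresh
#' parameter draw and data set, a WLS fit, approximated scores, and the
#' statistics applied to their matched covariates. Replication seeds are
#' derived from the master seed by a fixed counter scheme
#' (`master + 100000 * cell + replication`), so reruns with the same master
#' seed reproduce the table exactly and cells are independent of execution
#' order. Failed fits are counted and excluded from the denominator.
#'
#' @param grid A [study_grid()] tibble.
#' @param master_seed Master seed for the whole study.
#' @param alpha Significance level (rejection when `p < alpha`).
#' @param statistics Statistics to apply.
#' @param ... Passed to [test_statistic()].
#' @param verbose Print per-cell progress.
#' @return Tibble of class `ofa_rejection`: one row per cell x statistic
#'   with `rejection_rate`, `mc_se` (binomial Monte-Carlo standard error),
#'   `n_used`, `n_failed`.
#' @export
run_study <- function(grid, master_seed = 1, alpha = 0.05,
                      statistics = .study_stats$statistic, ...,
                      verbose = FALSE) {
  stopifnot(all(grid$n_reps >= 1), alpha > 0, alpha < 1)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(ci) {
    cell <- grid[ci, ]
    reps <- purrr::map(seq_len(cell$n_reps), function(r) {
      run_replication(cell$model, cell$k, cell$n, cell$scenario,
                      seed = master_seed + 100000L * cell$cell + r,
                      alpha = alpha, statistics = statistics, ...)
    })
    failed <- sum(vapply(reps, function(x) nrow(x) == 0L, logical(1)))
    flat <- dplyr::bind_rows(reps)
    agg <- dplyr::summarise(
      dplyr::group_by(flat, .data$statistic, .data$covariate),
      rejection_rate = mean(.data$reject),
      n_used = dplyr::n(), .groups = "drop")
    agg$mc_se <- sqrt(agg$rejection_rate * (1 - agg$rejection_rate) /
                        agg$n_used)
    agg$n_failed <- failed
    if (verbose)
      message(sprintf("cell %d/%d (%s k=%d n=%d %s): done, %d failed",
                      ci, nrow(grid), cell$model, cell$k, cell$n,
                      cell$scenario, failed))
    dplyr::bind_cols(cell[rep(1L, nrow(agg)),
                          c("model", "k", "n", "scenario", "cell")], agg)
  })
  class(out) <- c("ofa_rejection", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "master_seed") <- master_seed
  out
}

#' Plot a rejection-rate table
#'
#' @param object An `ofa_rejection` from [run_study()].
#' @param ... Unused.
#' @return A ggplot: rejection rate by statistic, faceted by cell.
#' @method autoplot ofa_rejection
#' @export
autoplot.ofa_rejection <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$cell_lab <- sprintf("%s k=%d n=%d\n%s", substr(df$model, 1, 5), df$k,
                         df$n, df$scenario)
  ggplot2::ggplot(df, ggplot2::aes(.data$statistic, .data$rejection_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$rejection_rate - 2 * .data$mc_se),
      ymax = pmin(1, .data$rejection_rate + 2 * .data$mc_se)), width = 0.3) +
    ggplot2::geom_hline(yintercept = attr(object, "alpha"),
                        linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~cell_lab) +
    ggplot2::labs(x = NULL, y = "rejection rate") +
    ggplot2::theme_minimal()
}

#' Write a rejection table to CSV
#'
#' @param table An `ofa_rejection`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_rejection_csv <- function(table, path) {
  utils::write.csv(tibble::as_tibble(table), path, row.names = FALSE)
  invisible(path)
}
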