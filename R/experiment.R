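#' Non-inferiority decision rule
#'
#' Non-inferiority is concluded when the upper bound of the two-sided
#' confidence interval for the risk difference (experimental minus control
#' failure probability) lies strictly below the non-inferiority margin.
#' The boundary case `ci_upper == margin` is judged not non-inferior; the
#' strict inequality is fixed for determinism (it is a measure-zero event
#' under the simulation model).
#'
#' @param estimate An `ni_estimate`.
#' @param margin Non-inferiority margin (> 0), on the absolute risk scale.
#' @return A list of class `ni_decision` with fields `noninferior`
#'   (logical, `NA` if the estimate failed), `margin` and `ci_upper_used`.
#' @examples
#' est <- estimate_itt(simulate_trial("both-cross-nonconf", 505, 1, seed = 1))
#' test_noninferiority(est, margin = 0.1)
#' @export
test_noninferiority <- function(estimate, margin) {
  if (!is.numeric(margin) || length(margin) != 1 || margin <= 0) {
    stop("`margin` must be a single positive number.", call. = FALSE)
  }
  ni <- if (isTRUE(estimate$failed)) NA else estimate$ci_upper < margin
  structure(list(noninferior = ni,
                 margin = margin,
                 ci_upper_used = estimate$ci_upper),
            class = "ni_decision")
}

#' Monte-Carlo experiment over an adherence grid
#'
#' For each adherence level, simulates `iterations` independent trials
#' under the given scenario and parameters, analyzes each trial with every
#' requested method, applies the non-inferiority decision rule, and
#' aggregates the proportion of iterations concluding non-inferiority
#' (the empirical type-I error when `true_effect` equals the margin, the
#' empirical power when `true_effect = 0`) together with the mean risk
#' difference across successful iterations.
#'
#' Each iteration gets its own child seed derived reproducibly from
#' `master_seed`, so the same master seed yields bit-identical results and
#' all methods see the same simulated trials. The IV estimator is skipped
#' (recorded as not applicable, with `NA` summaries) for
#' alternative-destination scenarios, where received treatment is not
#' binary.
#'
#' @param spec An `ni_scenario` or scenario label.
#' @param methods Character subset of `c("ITT", "PP", "IPW", "IV")`.
#' @param adherence_grid Numeric vector of adherence proportions in
#'   \[0, 1\]; default 0.60 to 1.00 in steps of 0.05.
#' @param n_per_arm Expected participants per arm; default 505, the sample
#'   size required for 90% power at full adherence with a 40% failure
#'   probability in both arms and a 10% margin.
#' @param params An [effect_params()] object.
#' @param margin Non-inferiority margin; default 0.1.
#' @param iterations Monte-Carlo iterations per cell; default 1000.
#' @param master_seed Integer master seed.
#' @param ci_level Two-sided confidence level; default 0.95.
#' @param covariate_subset Confounder indices adjusted in the IPW
#'   adherence model; default all.
#' @param failure_policy `"exclude"` (default: iterations where an
#'   estimator fails are dropped from that estimator's denominator) or
#'   `"conservative"` (failures count as not concluding non-inferiority).
#' @param ipw_ci_method Passed to [estimate_ipw()].
#' @param adherence_mode Passed to [simulate_trial()].
#' @param uptake_sign Passed to [simulate_trial()].
#' @return A data frame of class `ni_experiment` with one row per
#'   (adherence, method): columns `scenario`, `adherence`, `method`,
#'   `n_per_arm`, `mean_estimate`, `ni_rate`, `mc_se`, `iterations`,
#'   `failed`.
#' @examples
#' \donttest{
#' run_experiment("both-cross-nonconf", methods = "ITT",
#'                adherence_grid = c(0.9, 1), iterations = 200,
#'                master_seed = 1)
#' }
#' @export
run_experiment <- function(spec,
                           methods = c("ITT", "PP", "IPW", "IV"),
                           adherence_grid = seq(0.6, 1, by = 0.05),
                           n_per_arm = 505,
                           params = effect_params(),
                           margin = 0.1,
                           iterations = 1000,
                           master_seed = 1,
                           ci_level = 0.95,
                           covariate_subset = NULL,
                           failure_policy = c("exclude", "conservative"),
                           ipw_ci_method = "sandwich",
                           adherence_mode = c("threshold", "stochastic"),
                           uptake_sign = NULL) {
  if (is.character(spec)) spec <- parse_scenario_id(spec)
  spec <- validate_scenario(spec)
  methods <- match.arg(methods, c("ITT", "PP", "IPW", "IV"), several.ok = TRUE)
  failure_policy <- match.arg(failure_policy)
  adherence_mode <- match.arg(adherence_mode)
  if (iterations < 1) stop("`iterations` must be >= 1.", call. = FALSE)
  if (any(adherence_grid < 0 | adherence_grid > 1)) {
    stop("All adherence values must lie in [0, 1].", call. = FALSE)
  }
  if (!is.numeric(margin) || margin <= 0) {
    stop("`margin` must be positive.", call. = FALSE)
  }
  .validate_params(params)

  iv_applicable <- spec$destination == "crossover"
  label <- scenario_id(spec)

  # One child seed per (adherence level, iteration), all derived from the
  # master seed up front so cells are independent of evaluation order.
  set.seed(master_seed)
  seed_mat <- matrix(
    sample.int(.Machine$integer.max - 1L, length(adherence_grid) * iterations),
    nrow = iterations, ncol = length(adherence_grid)
  )

  rows <- list()
  for (gi in seq_along(adherence_grid)) {
    rho <- adherence_grid[gi]
    est_rd <- matrix(NA_real_, nrow = iterations, ncol = length(methods),
                     dimnames = list(NULL, methods))
    est_ni <- matrix(NA, nrow = iterations, ncol = length(methods),
                     dimnames = list(NULL, methods))
    for (it in seq_len(iterations)) {
      trial <- simulate_trial(spec, n_per_arm, rho, params,
                              seed = seed_mat[it, gi],
                              adherence_mode = adherence_mode,
                              uptake_sign = uptake_sign)
      for (m in methods) {
        if (m == "IV" && !iv_applicable) next
        # estimator errors on degenerate trials (e.g. an empty allocation
        # arm at tiny n) are recorded as failed iterations, like the
        # estimators' own failure signals
        est <- tryCatch(
          switch(m,
            ITT = estimate_itt(trial, ci_level),
            PP  = estimate_pp(trial, ci_level),
            IPW = estimate_ipw(trial, covariate_subset, ci_level, ipw_ci_method),
            IV  = estimate_iv(trial, ci_level)
          ),
          error = function(e) {
            ni_estimate(m, ci_level = ci_level, failed = TRUE,
                        message = conditionMessage(e))
          }
        )
        if (!isTRUE(est$failed)) {
          est_rd[it, m] <- est$risk_difference
          est_ni[it, m] <- test_noninferiority(est, margin)$noninferior
        }
      }
    }
    for (m in methods) {
      if (m == "IV" && !iv_applicable) {
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = label, adherence = rho, method = m,
          n_per_arm = as.integer(n_per_arm),
          mean_estimate = NA_real_, ni_rate = NA_real_, mc_se = NA_real_,
          iterations = 0L, failed = 0L, stringsAsFactors = FALSE)
        next
      }
      ok <- !is.na(est_ni[, m])
      n_fail <- sum(!ok)
      if (failure_policy == "exclude") {
        denom <- sum(ok)
        ni_rate <- if (denom > 0) mean(est_ni[ok, m]) else NA_real_
      } else {
        denom <- iterations
        ni_rate <- sum(est_ni[ok, m]) / denom
      }
      mc_se <- if (!is.na(ni_rate) && denom > 0) {
        sqrt(ni_rate * (1 - ni_rate) / denom)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = label, adherence = rho, method = m,
        n_per_arm = as.integer(n_per_arm),
        mean_estimate = if (any(ok)) mean(est_rd[ok, m]) else NA_real_,
        ni_rate = ni_rate, mc_se = mc_se,
        iterations = as.integer(denom), failed = as.integer(n_fail),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("ni_experiment", "data.frame")
  attr(res, "master_seed") <- master_seed
  attr(res, "margin") <- margin
  attr(res, "params") <- params
  res
}

#' Summarize experiment results into a deterministically ordered table
#'
#' @param results One `ni_experiment` data frame, or a list of them to be
#'   stacked (e.g. several scenarios).
#' @return A data frame with one row per (scenario, adherence, method),
#'   sorted by those keys. An empty input yields a zero-row table with the
#'   standard columns.
#' @export
summarize_experiment <- function(results) {
  cols <- c("scenario", "adherence", "method", "n_per_arm",
            "mean_estimate", "ni_rate", "mc_se", "iterations", "failed")
  if (is.data.frame(results)) results <- list(results)
  results <- Filter(function(x) !is.null(x) && nrow(x) > 0, results)
  if (length(results) == 0) {
    empty <- data.frame(scenario = character(), adherence = numeric(),
                        method = character(), n_per_arm = integer(),
                        mean_estimate = numeric(), ni_rate = numeric(),
                        mc_se = numeric(), iterations = integer(),
                        failed = integer(), stringsAsFactors = FALSE)
    return(empty)
  }
  out <- do.call(rbind, lapply(results, function(x) as.data.frame(x)[, cols]))
  out <- out[order(out$scenario, out$adherence, out$method), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write experiment results as CSV with a reproducibility header
#'
#' Floats are printed with six decimals; `#`-prefixed comment lines record
#' the effective configuration (margin, master seed and any extra fields
#' supplied).
#'
#' @param results An `ni_experiment` or summarized data frame.
#' @param path Output path.
#' @param config Optional named list echoed into the comment header.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(results, path, config = NULL) {
  tab <- summarize_experiment(results)
  meta <- c(
    if (!is.null(attr(results, "master_seed")))
      paste0("# master_seed: ", attr(results, "master_seed")),
    if (!is.null(attr(results, "margin")))
      paste0("# margin: ", attr(results, "margin")),
    if (!is.null(config))
      paste0("# ", names(config), ": ",
             vapply(config, function(v) paste(format(v), collapse = " "),
                    character(1)))
  )
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.6f", x))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(meta, con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
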