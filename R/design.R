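#' Closed-form sample size for a non-inferiority trial at full adherence
#'
#' Normal-approximation (unpooled variance) sample size per arm for a
#' two-arm non-inferiority comparison of failure proportions:
#' \deqn{n = \left\lceil \frac{(z_{1-\alpha} + z_{1-\beta})^2 \,
#'   [p_c(1-p_c) + p_e(1-p_e)]}{(M - (p_e - p_c))^2} \right\rceil}
#' where \eqn{M} is the non-inferiority margin and \eqn{\alpha} the
#' one-sided significance level (the upper bound of the two-sided
#' \eqn{1 - 2\alpha} confidence interval is compared against \eqn{M}).
#' At the default design (40% failure in both arms, 10% margin, one-sided
#' 0.025, 90% power) this gives 505 participants per arm.
#'
#' @param p_control Anticipated failure probability in the control arm.
#' @param p_experimental Anticipated failure probability in the
#'   experimental arm.
#' @param margin Non-inferiority margin (> `p_experimental - p_control`,
#'   else the design is infeasible).
#' @param alpha_one_sided One-sided type-I error level; default 0.025.
#' @param power Target power; default 0.9.
#' @return Integer sample size per arm.
#' @examples
#' closed_form_n(0.4, 0.4, 0.1)          # 505
#' closed_form_n(0.4, 0.4, 0.2)          # wider margin, smaller trial
#' @export
closed_form_n <- function(p_control, p_experimental, margin,
                          alpha_one_sided = 0.025, power = 0.9) {
  stopifnot(p_control > 0, p_control < 1,
            p_experimental > 0, p_experimental < 1,
            margin > 0, alpha_one_sided > 0, alpha_one_sided < 1,
            power > 0, power < 1)
  effect <- p_experimental - p_control
  if (margin <= effect) {
    stop("Design infeasible: margin (", margin, ") must exceed the ",
         "anticipated effect (", effect, ").", call. = FALSE)
  }
  z_a <- stats::qnorm(1 - alpha_one_sided)
  z_b <- stats::qnorm(power)
  v <- p_control * (1 - p_control) + p_experimental * (1 - p_experimental)
  as.integer(ceiling((z_a + z_b)^2 * v / (margin - effect)^2))
}

#' Empirical power by simulation at one adherence level
#'
#' Power here is the probability of correctly concluding non-inferiority
#' when the experimental treatment is truly equivalent to control, so the
#' true effect must be zero; a nonzero `true_effect` in `params` is an
#' error. Delegates to [run_experiment()] for a single
#' (adherence, method) cell.
#'
#' @inheritParams run_experiment
#' @param method One of `"ITT"`, `"PP"`, `"IPW"`, `"IV"`.
#' @param rho Adherence proportion.
#' @param seed Master seed.
#' @return A list with `power`, `mc_se`, `iterations`, `failed`.
#' @export
empirical_power <- function(spec, method, n_per_arm, rho,
                            params = effect_params(true_effect = 0),
                            margin = 0.1, iterations = 1000, seed = 1,
                            ...) {
  if (params$true_effect != 0) {
    stop("Power is defined under a true effect of zero; got true_effect = ",
         params$true_effect, ".", call. = FALSE)
  }
  res <- run_experiment(spec, methods = method, adherence_grid = rho,
                        n_per_arm = n_per_arm, params = params,
                        margin = margin, iterations = iterations,
                        master_seed = seed, ...)
  list(power = res$ni_rate[1], mc_se = res$mc_se[1],
       iterations = res$iterations[1], failed = res$failed[1])
}

#' Smallest sample size achieving a target power under non-adherence
#'
#' Searches a lattice of candidate per-arm sample sizes (default step 5)
#' by bisection for the smallest n whose simulated power meets
#' `target_power`. The same master seed is reused at every candidate
#' (common random numbers), which makes the power curve monotone enough in
#' practice for the bisection to be stable at moderate iteration counts.
#'
#' @inheritParams empirical_power
#' @param target_power Target power in (0, 1); estimated power exactly at
#'   the target accepts the candidate.
#' @param n_bounds Length-2 integer vector bracketing the answer; errors
#'   if the upper bound's power is still below target.
#' @param lattice_step Granularity of the n search lattice.
#' @return A list with `n_per_arm`, `power`, `mc_se`, `iterations`.
#' @export
required_n <- function(spec, method, rho, target_power = 0.9,
                       params = effect_params(true_effect = 0),
                       margin = 0.1, iterations = 1000, seed = 1,
                       n_bounds = c(50, 20000), lattice_step = 5, ...) {
  stopifnot(target_power > 0, target_power < 1,
            length(n_bounds) == 2, n_bounds[1] >= 1,
            n_bounds[2] > n_bounds[1], lattice_step >= 1)
  pw <- function(n) {
    empirical_power(spec, method, n, rho, params, margin, iterations,
                    seed, ...)
  }
  hi <- as.integer(n_bounds[2])
  lo <- as.integer(n_bounds[1])
  p_hi <- pw(hi)
  if (is.na(p_hi$power) || p_hi$power < target_power) {
    stop("Upper bound n = ", hi, " gives power ",
         format(p_hi$power, digits = 3), " < target ", target_power,
         "; widen `n_bounds`.", call. = FALSE)
  }
  p_lo <- pw(lo)
  if (!is.na(p_lo$power) && p_lo$power >= target_power) {
    return(c(list(n_per_arm = lo), p_lo[c("power", "mc_se", "iterations")]))
  }
  best <- p_hi
  while (hi - lo > lattice_step) {
    mid <- lo + lattice_step * ((hi - lo) %/% (2 * lattice_step))
    if (mid <= lo) mid <- lo + lattice_step
    p_mid <- pw(mid)
    if (!is.na(p_mid$power) && p_mid$power >= target_power) {
      hi <- mid
      best <- p_mid
    } else {
      lo <- mid
    }
  }
  c(list(n_per_arm = hi), best[c("power", "mc_se", "iterations")])
}

#' Simulated power curve across an adherence grid
#'
#' @inheritParams run_experiment
#' @param method One estimator label.
#' @param seed Master seed.
#' @return A data frame of class `ni_power_curve` with columns `scenario`,
#'   `method`, `n_per_arm`, `adherence`, `power`, `mc_se`.
#' @export
power_curve <- function(spec, method, n_per_arm,
                        adherence_grid = seq(0.6, 1, by = 0.05),
                        params = effect_params(true_effect = 0),
                        margin = 0.1, iterations = 1000, seed = 1, ...) {
  if (params$true_effect != 0) {
    stop("Power curves are computed under a true effect of zero.",
         call. = FALSE)
  }
  res <- run_experiment(spec, methods = method,
                        adherence_grid = adherence_grid,
                        n_per_arm = n_per_arm, params = params,
                        margin = margin, iterations = iterations,
                        master_seed = seed, ...)
  out <- data.frame(scenario = res$scenario, method = res$method,
                    n_per_arm = res$n_per_arm, adherence = res$adherence,
                    power = res$ni_rate, mc_se = res$mc_se,
                    stringsAsFactors = FALSE)
  class(out) <- c("ni_power_curve", "data.frame")
  out
}
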