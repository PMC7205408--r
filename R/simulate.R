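#' Effect and nuisance parameters of the data-generating mechanism
#'
#' Bundles the parameters that define the counterfactual outcome model and
#' the confounder distribution. Failure probabilities follow a clipped
#' linear probability model on the centred confounder(s):
#' \deqn{p_a(C) = \mathrm{clip}\{\mu_a + \gamma \sum_k (C_k - E[C]),\ 0,\ 1\}}
#' with \eqn{\mu_{a_0}} = `p_fail_control`, \eqn{\mu_{a_1}} = `p_fail_control
#' + true_effect`, and \eqn{\mu_{a_2} = \max(\mu_{a_0}, \mu_{a_1})} `+
#' alt_penalty` (the alternative treatment is inferior to both trial
#' treatments). Because the confounders are centred, the population mean
#' difference between the experimental and control counterfactual failure
#' probabilities equals `true_effect` whenever no individual probability is
#' clipped.
#'
#' @param p_fail_control Baseline probability of treatment failure under the
#'   control treatment; default 0.4.
#' @param true_effect Average risk difference (experimental minus control)
#'   of the counterfactual failure probabilities; 0.1 for type-I-error
#'   studies (experimental inferior by exactly the margin), 0 for power
#'   studies.
#' @param alt_penalty Excess failure probability of the alternative
#'   treatment over the worse of the two trial treatments; default 0.1.
#' @param confounder_outcome_slope Pre-clipping linear slope of the failure
#'   probability on each centred confounder (\eqn{\gamma}); 0 removes any
#'   confounder-outcome effect. Large magnitudes (5, 9) imply heavy clipping
#'   of individual probabilities at 0 and 1.
#' @param confounder_adherence_slope Strength \eqn{\delta} of the confounder
#'   influence on the adherence propensity, on the log-odds scale; used only
#'   in the stochastic adherence mode. The logistic propensity is strictly
#'   inside (0, 1), so every participant keeps a positive probability of
#'   adhering (the positivity condition the weighting estimator needs). The
#'   default 3 gives moderate confounding: at 80% adherence the adherence
#'   probability spans roughly 0.5 to 0.95 across the confounder range.
#' @param n_confounders Number of independent confounders K (>= 1).
#' @param beta_shape_a,beta_shape_b Shape parameters of the Beta
#'   distribution from which each confounder is drawn; default Beta(2, 2)
#'   (symmetric on \[0, 1\], mean 0.5).
#'
#' @return An object of class `ni_params` (a validated list).
#' @examples
#' effect_params()                    # type-I-error defaults
#' effect_params(true_effect = 0)     # power-study configuration
#' @export
effect_params <- function(p_fail_control = 0.4,
                          true_effect = 0.1,
                          alt_penalty = 0.1,
                          confounder_outcome_slope = 1,
                          confounder_adherence_slope = 3,
                          n_confounders = 1L,
                          beta_shape_a = 2,
                          beta_shape_b = 2) {
  p <- structure(
    list(
      p_fail_control = p_fail_control,
      true_effect = true_effect,
      alt_penalty = alt_penalty,
      confounder_outcome_slope = confounder_outcome_slope,
      confounder_adherence_slope = confounder_adherence_slope,
      n_confounders = as.integer(n_confounders),
      beta_shape_a = beta_shape_a,
      beta_shape_b = beta_shape_b
    ),
    class = "ni_params"
  )
  .validate_params(p)
  p
}

.validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  stopifnot(
    num1(p$p_fail_control), p$p_fail_control >= 0, p$p_fail_control <= 1,
    num1(p$true_effect),
    num1(p$alt_penalty), p$alt_penalty >= 0,
    num1(p$confounder_outcome_slope),
    num1(p$confounder_adherence_slope),
    length(p$n_confounders) == 1, p$n_confounders >= 1,
    num1(p$beta_shape_a), p$beta_shape_a > 0,
    num1(p$beta_shape_b), p$beta_shape_b > 0
  )
  mu <- .treatment_means(p)
  if (any(mu < 0 | mu > 1)) {
    stop("Mean failure probabilities (control ", mu[["a0"]],
         ", experimental ", mu[["a1"]], ", alternative ", mu[["a2"]],
         ") must all lie in [0, 1]; adjust p_fail_control, true_effect or ",
         "alt_penalty.", call. = FALSE)
  }
  invisible(p)
}

# Mean failure probability per treatment before the confounder shift.
.treatment_means <- function(params) {
  mu0 <- params$p_fail_control
  mu1 <- params$p_fail_control + params$true_effect
  mu2 <- max(mu0, mu1) + params$alt_penalty
  c(a0 = mu0, a1 = mu1, a2 = mu2)
}

.confounder_mean <- function(params) {
  params$beta_shape_a / (params$beta_shape_a + params$beta_shape_b)
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

# Sign of the confounder effect on uptake of the *experimental* treatment,
# derived from the scenario direction relative to the outcome slope:
# concordant = same sign as the confounder-failure slope, discordant =
# opposite. A zero outcome slope is treated as positive for this purpose.
.uptake_sign <- function(spec, params, uptake_sign = NULL) {
  if (!is.null(uptake_sign)) {
    stopifnot(uptake_sign %in% c(-1, 1))
    return(uptake_sign)
  }
  out_sign <- if (params$confounder_outcome_slope < 0) -1 else 1
  switch(spec$direction,
         concordant = out_sign,
         discordant = -out_sign,
         none = 1)
}

#' Draw the trial population: confounders and randomized allocation
#'
#' Allocation is iid Bernoulli(0.5) per individual (each participant has a
#' 50% chance of the experimental arm), so realized arm sizes vary around
#' n/2. Confounders are iid Beta(`beta_shape_a`, `beta_shape_b`),
#' independent of allocation.
#'
#' @param n_total Total number of participants (>= 2).
#' @param params An [effect_params()] object.
#' @return A list with `confounder` (an `n_total` x K matrix in \[0, 1\])
#'   and `allocation` (an integer vector of 0/1, 1 = experimental arm).
#' @export
draw_population <- function(n_total, params = effect_params()) {
  if (!is.numeric(n_total) || length(n_total) != 1 || n_total < 2) {
    stop("`n_total` must be a single integer >= 2.", call. = FALSE)
  }
  n_total <- as.integer(n_total)
  K <- params$n_confounders
  confounder <- matrix(
    stats::rbeta(n_total * K, params$beta_shape_a, params$beta_shape_b),
    nrow = n_total, ncol = K,
    dimnames = list(NULL, paste0("c", seq_len(K)))
  )
  allocation <- stats::rbinom(n_total, 1L, 0.5)
  list(confounder = confounder, allocation = allocation)
}

#' Determine adherence status for each participant
#'
#' Only participants in the scenario's targeted arm(s) can be non-adherent.
#' In the non-confounded mechanism adherence is independent of the
#' confounder: `"threshold"` mode selects exactly
#' `ceiling((1 - rho) * n_arm)` non-adherent participants uniformly at
#' random within each targeted arm (so the realized adherence proportion
#' equals `rho` up to integer rounding), while `"stochastic"` mode draws iid
#' Bernoulli(`rho`) adherence flags.
#'
#' In the confounded mechanism, non-adherence concentrates in the
#' participants whose confounder score makes them least likely to take
#' their own arm's treatment. The score is the mean of the K centred
#' confounders, signed by the direction of the confounder effect on
#' experimental-treatment uptake. `"threshold"` mode deterministically
#' selects the `ceiling((1 - rho) * n_arm)` participants with the lowest
#' propensity to adhere to their allocated arm (e.g. when the confounder
#' decreases experimental-treatment uptake, the highest-confounder
#' participants in the experimental arm and the lowest-confounder
#' participants in the control arm are the non-adherers). `"stochastic"`
#' mode uses a logistic adherence propensity
#' `plogis(lambda + delta * score)` whose intercept `lambda` is solved by
#' monotone bisection so the targeted arm's mean propensity equals `rho`;
#' the logistic form keeps every propensity strictly inside (0, 1) and
#' matches the logistic working model of the inverse-probability-weighted
#' analysis.
#'
#' @param confounder n x K matrix of confounder values.
#' @param allocation 0/1 allocation vector (1 = experimental).
#' @param spec An `ni_scenario`.
#' @param rho Adherence proportion in \[0, 1\] within each targeted arm.
#' @param params An [effect_params()] object.
#' @param mode `"threshold"` (default) or `"stochastic"`.
#' @param uptake_sign Optional override (+1/-1) of the confounder effect
#'   direction on experimental-treatment uptake; by default it is derived
#'   from the scenario direction and the sign of
#'   `confounder_outcome_slope`.
#' @return Integer 0/1 vector of adherence flags (1 = adherent).
#' @export
adherence_status <- function(confounder, allocation, spec, rho,
                             params = effect_params(),
                             mode = c("threshold", "stochastic"),
                             uptake_sign = NULL) {
  mode <- match.arg(mode)
  spec <- validate_scenario(spec)
  if (!is.matrix(confounder)) confounder <- as.matrix(confounder)
  if (nrow(confounder) != length(allocation)) {
    stop("`confounder` and `allocation` lengths differ.", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho > 1) {
    stop("`rho` must be a single value in [0, 1].", call. = FALSE)
  }
  n <- length(allocation)
  adherent <- rep(1L, n)
  targeted <- switch(spec$nonadherent_arms,
                     experimental_only = allocation == 1L,
                     control_only      = allocation == 0L,
                     both              = rep(TRUE, n))
  if (rho == 1) return(adherent)

  u_sign <- .uptake_sign(spec, params, uptake_sign)
  score <- rowMeans(confounder) - .confounder_mean(params)

  for (arm in unique(allocation[targeted])) {
    idx <- which(targeted & allocation == arm)
    n_arm <- length(idx)
    if (n_arm == 0) next
    if (spec$mechanism == "non_confounded") {
      if (mode == "threshold") {
        k <- min(n_arm, ceiling((1 - rho) * n_arm - 1e-12))
        nonadh <- sample(idx, k)
      } else {
        nonadh <- idx[stats::runif(n_arm) > rho]
      }
    } else {
      # Propensity to adhere to one's own arm increases with
      # (2 * arm - 1) * u_sign * score.
      adh_score <- (2 * arm - 1) * u_sign * score[idx]
      if (mode == "threshold") {
        k <- min(n_arm, ceiling((1 - rho) * n_arm - 1e-12))
        # least adherence-prone first; random tie-break via secondary key
        ord <- order(adh_score, stats::runif(n_arm))
        nonadh <- idx[ord[seq_len(k)]]
      } else {
        delta <- params$confounder_adherence_slope
        lambda <- .solve_intercept(adh_score, delta, rho)
        p_adh <- stats::plogis(lambda + delta * adh_score)
        nonadh <- idx[stats::runif(n_arm) > p_adh]
      }
    }
    adherent[nonadh] <- 0L
  }
  adherent
}

# Monotone bisection for the intercept of the logistic propensity so that
# mean(plogis(lambda + delta * s)) = rho over the arm.
.solve_intercept <- function(score, delta, rho) {
  f <- function(lambda) mean(stats::plogis(lambda + delta * score)) - rho
  span <- abs(delta) * max(abs(score))
  lo <- stats::qlogis(min(max(rho, 1e-12), 1 - 1e-12)) - span - 1
  hi <- stats::qlogis(min(max(rho, 1e-12), 1 - 1e-12)) + span + 1
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Treatment actually received
#'
#' Adherent participants receive their allocated treatment. Non-adherent
#' participants either cross over to the opposite arm's treatment
#' (`destination = "crossover"`) or receive the alternative treatment `a2`
#' (`destination = "alternative"`).
#'
#' @inheritParams adherence_status
#' @param adherent 0/1 adherence flags.
#' @return Character vector with values `"a0"` (control), `"a1"`
#'   (experimental), `"a2"` (alternative).
#' @export
received_treatment <- function(allocation, adherent, spec) {
  spec <- validate_scenario(spec)
  if (length(allocation) != length(adherent)) {
    stop("`allocation` and `adherent` lengths differ.", call. = FALSE)
  }
  allocated <- ifelse(allocation == 1L, "a1", "a0")
  if (spec$destination == "crossover") {
    opposite <- ifelse(allocation == 1L, "a0", "a1")
    ifelse(adherent == 1L, allocated, opposite)
  } else {
    ifelse(adherent == 1L, allocated, "a2")
  }
}

#' Per-individual counterfactual failure probabilities
#'
#' Evaluates the clipped linear probability model for all three treatments
#' at each individual's confounder values (see [effect_params()] for the
#' model). The same confounder-outcome slope applies to all three
#' treatments, so the confounder shifts all three counterfactual
#' probabilities in parallel.
#'
#' @inheritParams adherence_status
#' @return A data frame with columns `p0`, `p1`, `p2` (failure
#'   probabilities under control, experimental, alternative).
#' @export
counterfactual_probs <- function(confounder, params = effect_params()) {
  if (!is.matrix(confounder)) confounder <- as.matrix(confounder)
  if (any(confounder < 0 | confounder > 1)) {
    stop("Confounder values must lie in [0, 1].", call. = FALSE)
  }
  .validate_params(params)
  mu <- .treatment_means(params)
  shift <- params$confounder_outcome_slope *
    rowSums(confounder - .confounder_mean(params))
  data.frame(
    p0 = .clip01(mu[["a0"]] + shift),
    p1 = .clip01(mu[["a1"]] + shift),
    p2 = .clip01(mu[["a2"]] + shift)
  )
}

#' Draw counterfactual and observed outcomes
#'
#' Each of the three counterfactual outcomes is drawn Bernoulli at the
#' individual's counterfactual failure probability, independently across
#' individuals. The observed outcome is copied from the counterfactual
#' matching the received treatment (consistency).
#'
#' @param probs Data frame from [counterfactual_probs()].
#' @param received Character vector of received treatments
#'   (`"a0"`/`"a1"`/`"a2"`).
#' @return A data frame with columns `y0`, `y1`, `y2` (counterfactual
#'   failures under control/experimental/alternative) and `y` (observed).
#' @export
draw_outcomes <- function(probs, received) {
  n <- nrow(probs)
  if (length(received) != n) {
    stop("`received` length must match `probs` rows.", call. = FALSE)
  }
  y0 <- stats::rbinom(n, 1L, probs$p0)
  y1 <- stats::rbinom(n, 1L, probs$p1)
  y2 <- stats::rbinom(n, 1L, probs$p2)
  y <- ifelse(received == "a0", y0, ifelse(received == "a1", y1, y2))
  data.frame(y0 = y0, y1 = y1, y2 = y2, y = as.integer(y))
}

#' Simulate one complete non-inferiority trial
#'
#' Composes the full data-generating mechanism: draw confounders and
#' Bernoulli(0.5) allocation for `2 * n_per_arm` participants, assign
#' adherence under the scenario's mechanism at adherence proportion `rho`,
#' map adherence to the received treatment, evaluate the counterfactual
#' failure probabilities, and draw counterfactual plus observed outcomes.
#'
#' @param spec An `ni_scenario` (see [scenario_spec()]) or scenario label.
#' @param n_per_arm Expected participants per arm; total n is
#'   `2 * n_per_arm` with Bernoulli(0.5) allocation.
#' @param rho Adherence proportion in targeted arm(s).
#' @param params An [effect_params()] object.
#' @param seed Optional integer seed for reproducibility.
#' @param adherence_mode `"threshold"` or `"stochastic"`, see
#'   [adherence_status()].
#' @param uptake_sign Optional +1/-1 override, see [adherence_status()].
#' @return An object of class `ni_trial`: a data frame with one row per
#'   participant and columns `id`, `z` (allocation), `c1..cK`
#'   (confounders), `adherent`, `received`, `y0`, `y1`, `y2`, `y`.
#'   Attributes record the scenario, parameters, `rho` and seed.
#' @examples
#' trial <- simulate_trial(scenario_spec("both", "crossover", "non_confounded"),
#'                         n_per_arm = 100, rho = 0.9, seed = 1)
#' head(trial)
#' @export
simulate_trial <- function(spec, n_per_arm, rho,
                           params = effect_params(),
                           seed = NULL,
                           adherence_mode = c("threshold", "stochastic"),
                           uptake_sign = NULL) {
  if (is.character(spec)) spec <- parse_scenario_id(spec)
  spec <- validate_scenario(spec)
  adherence_mode <- match.arg(adherence_mode)
  if (!is.numeric(n_per_arm) || length(n_per_arm) != 1 || n_per_arm < 1) {
    stop("`n_per_arm` must be a single integer >= 1.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  n_total <- 2L * as.integer(n_per_arm)
  pop <- draw_population(n_total, params)
  adherent <- adherence_status(pop$confounder, pop$allocation, spec, rho,
                               params, mode = adherence_mode,
                               uptake_sign = uptake_sign)
  received <- received_treatment(pop$allocation, adherent, spec)
  probs <- counterfactual_probs(pop$confounder, params)
  out <- draw_outcomes(probs, received)

  trial <- data.frame(
    id = seq_len(n_total),
    z = pop$allocation,
    pop$confounder,
    adherent = adherent,
    received = received,
    out,
    stringsAsFactors = FALSE
  )
  structure(trial,
            class = c("ni_trial", "data.frame"),
            scenario = spec,
            params = params,
            rho = rho,
            adherence_mode = adherence_mode,
            seed = seed)
}

#' Write a simulated trial to a flat CSV
#'
#' One row per participant with a `#`-prefixed metadata header recording
#' the scenario, adherence proportion and seed, for inspection and
#' cross-language checks.
#'
#' @param trial An `ni_trial` from [simulate_trial()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "ni_trial"))
  spec <- attr(trial, "scenario")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# scenario: ", scenario_id(spec)),
    paste0("# rho: ", attr(trial, "rho")),
    paste0("# seed: ", if (is.null(attr(trial, "seed"))) "NA" else attr(trial, "seed"))
  ), con)
  utils::write.csv(as.data.frame(trial), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
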