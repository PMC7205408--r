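#' @title Effect estimates: risk differences with confidence intervals
#' @description Constructor used internally by the four estimators. An
#'   `ni_estimate` records the method, the risk-difference point estimate
#'   (experimental minus control failure probability under the method's
#'   estimand), its standard error, a two-sided Wald confidence interval,
#'   the number of participants contributing and method-specific
#'   diagnostics. Estimation failures (e.g. an empty per-protocol arm or a
#'   vanishing instrumental-variable denominator) are recorded as objects
#'   with `failed = TRUE` rather than raised, so Monte-Carlo loops can
#'   count them.
#' @param method Method label.
#' @param rd Point estimate.
#' @param se Standard error.
#' @param ci_level Two-sided confidence level.
#' @param n_used Number of participants contributing.
#' @param diagnostics Named list of method-specific diagnostics.
#' @param failed Logical failure flag.
#' @param message Failure description when `failed`.
#' @return An object of class `ni_estimate`.
#' @keywords internal
ni_estimate <- function(method, rd = NA_real_, se = NA_real_,
                        ci_level = 0.95, n_used = NA_integer_,
                        diagnostics = list(), failed = FALSE,
                        message = NULL) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(
    list(
      method = method,
      risk_difference = rd,
      std_error = se,
      ci_lower = if (failed) NA_real_ else rd - z * se,
      ci_upper = if (failed) NA_real_ else rd + z * se,
      ci_level = ci_level,
      n_used = as.integer(n_used),
      diagnostics = diagnostics,
      failed = failed,
      message = message
    ),
    class = "ni_estimate"
  )
}

#' @export
print.ni_estimate <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("<%s estimate: FAILED (%s)>\n", x$method, x$message))
    return(invisible(x))
  }
  cat(sprintf("<%s> risk difference %.4f (SE %.4f), %g%% CI [%.4f, %.4f], n = %d\n",
              x$method, x$risk_difference, x$std_error, 100 * x$ci_level,
              x$ci_lower, x$ci_upper, x$n_used))
  invisible(x)
}

# Unpooled Wald risk difference between two binary samples.
.wald_rd <- function(y1, y0) {
  p1 <- mean(y1); p0 <- mean(y0)
  n1 <- length(y1); n0 <- length(y0)
  se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  list(rd = p1 - p0, se = se, n = n1 + n0)
}

.confounder_cols <- function(trial) grep("^c[0-9]+$", names(trial), value = TRUE)

#' Intention-to-treat risk difference
#'
#' Compares observed failure proportions between the randomized arms,
#' regardless of the treatment actually received: the effect of assignment.
#' Unpooled Wald standard error, normal-approximation confidence interval.
#'
#' @param trial An `ni_trial` (or any data frame with columns `z` and `y`).
#' @param ci_level Two-sided confidence level; default 0.95.
#' @return An `ni_estimate`.
#' @export
estimate_itt <- function(trial, ci_level = 0.95) {
  y1 <- trial$y[trial$z == 1L]
  y0 <- trial$y[trial$z == 0L]
  if (length(y1) == 0 || length(y0) == 0) {
    stop("ITT requires both allocation arms to be non-empty.", call. = FALSE)
  }
  w <- .wald_rd(y1, y0)
  ni_estimate("ITT", w$rd, w$se, ci_level, w$n)
}

#' Per-protocol risk difference
#'
#' Restricts the Wald comparison to participants who received the
#' treatment they were allocated to. If either arm has no adherent
#' participants the estimate is returned as a recorded failure rather than
#' an error, so simulation loops can count inestimable iterations.
#'
#' @inheritParams estimate_itt
#' @return An `ni_estimate`; `failed = TRUE` when an arm has no adherent
#'   participants.
#' @export
estimate_pp <- function(trial, ci_level = 0.95) {
  keep <- trial$adherent == 1L
  y1 <- trial$y[keep & trial$z == 1L]
  y0 <- trial$y[keep & trial$z == 0L]
  if (length(y1) == 0 || length(y0) == 0) {
    return(ni_estimate("PP", ci_level = ci_level, failed = TRUE,
                       message = "no adherent participants in one arm"))
  }
  w <- .wald_rd(y1, y0)
  ni_estimate("PP", w$rd, w$se, ci_level, w$n)
}

#' Inverse-probability-of-adherence weights
#'
#' Fits a logistic regression of adherence on the selected confounders
#' separately within each allocation arm, and returns, for each adherent
#' participant, the reciprocal of the fitted adherence probability. In a
#' fully adherent arm the fit is degenerate and the adherence probability
#' is taken as 1 (all weights 1). Non-convergence or fitted probabilities
#' collapsing to zero for adherent participants are signalled via an
#' attribute `failed` with a message, not an error.
#'
#' @param trial An `ni_trial` (needs columns `z`, `adherent`, `c1..cK`).
#' @param covariate_subset Integer indices into `1..K` selecting which
#'   confounders enter the adherence model; default all.
#' @return A numeric weight vector aligned with the adherent subset of
#'   `trial` (in trial row order), with attribute `adherent_idx` giving the
#'   corresponding row indices; or, on failure, a zero-length vector with
#'   attribute `failed = TRUE` and `message`.
#' @export
fit_adherence_weights <- function(trial, covariate_subset = NULL) {
  ccols <- .confounder_cols(trial)
  if (length(ccols) == 0) stop("No confounder columns (c1..cK) found.", call. = FALSE)
  if (is.null(covariate_subset)) covariate_subset <- seq_along(ccols)
  if (length(covariate_subset) == 0 ||
      any(covariate_subset < 1 | covariate_subset > length(ccols))) {
    stop("`covariate_subset` must be non-empty indices into 1..",
         length(ccols), ".", call. = FALSE)
  }
  use_cols <- ccols[covariate_subset]

  prob <- rep(NA_real_, nrow(trial))
  for (arm in c(0L, 1L)) {
    idx <- which(trial$z == arm)
    adh <- trial$adherent[idx]
    if (all(adh == 1L)) {
      prob[idx] <- 1
      next
    }
    if (all(adh == 0L)) {
      prob[idx] <- 0
      next
    }
    dat <- trial[idx, c("adherent", use_cols), drop = FALSE]
    fml <- stats::as.formula(paste("adherent ~", paste(use_cols, collapse = " + ")))
    # maxit raised so that completely separated data (deterministic
    # threshold adherence) reach the degenerate 0/1 fitted-probability
    # limit instead of tripping the iteration cap
    fit <- tryCatch(
      suppressWarnings(stats::glm(fml, family = stats::binomial(), data = dat,
                                  control = stats::glm.control(maxit = 100))),
      error = function(e) e
    )
    if (inherits(fit, "error") || !fit$converged) {
      out <- numeric(0)
      attr(out, "failed") <- TRUE
      attr(out, "message") <- "adherence model did not converge"
      return(out)
    }
    prob[idx] <- stats::fitted(fit)
  }

  adherent_idx <- which(trial$adherent == 1L)
  p_adh <- prob[adherent_idx]
  if (any(p_adh < 1e-10)) {
    out <- numeric(0)
    attr(out, "failed") <- TRUE
    attr(out, "message") <- "fitted adherence probability ~0 for an adherent participant"
    return(out)
  }
  w <- 1 / p_adh
  attr(w, "adherent_idx") <- adherent_idx
  w
}

#' Inverse-probability-weighted risk difference
#'
#' Reweights adherent participants by the inverse of their fitted
#' probability of adherence (see [fit_adherence_weights()]) to undo the
#' selection that confounded non-adherence induces on the per-protocol
#' population, then contrasts the weighted failure proportions between
#' arms. The default interval uses a Horvitz-Thompson-style sandwich
#' variance treating weights as known; a nonparametric bootstrap
#' percentile interval (refitting the weights in each resample) is
#' available for verification.
#'
#' @inheritParams estimate_itt
#' @param covariate_subset See [fit_adherence_weights()].
#' @param ci_method `"sandwich"` (default) or `"bootstrap"`.
#' @param boot_samples Bootstrap resamples when `ci_method = "bootstrap"`.
#' @return An `ni_estimate` with diagnostics `min_weight`, `max_weight`
#'   and `covariates`.
#' @export
estimate_ipw <- function(trial, covariate_subset = NULL, ci_level = 0.95,
                         ci_method = c("sandwich", "bootstrap"),
                         boot_samples = 200) {
  ci_method <- match.arg(ci_method)
  w <- fit_adherence_weights(trial, covariate_subset)
  if (isTRUE(attr(w, "failed"))) {
    return(ni_estimate("IPW", ci_level = ci_level, failed = TRUE,
                       message = attr(w, "message")))
  }
  idx <- attr(w, "adherent_idx")
  z <- trial$z[idx]; y <- trial$y[idx]
  if (!any(z == 1L) || !any(z == 0L)) {
    return(ni_estimate("IPW", ci_level = ci_level, failed = TRUE,
                       message = "no adherent participants in one arm"))
  }
  wmean <- function(arm) {
    sel <- z == arm
    mu <- sum(w[sel] * y[sel]) / sum(w[sel])
    v <- sum(w[sel]^2 * (y[sel] - mu)^2) / sum(w[sel])^2
    c(mu = mu, var = v)
  }
  m1 <- wmean(1L); m0 <- wmean(0L)
  rd <- m1[["mu"]] - m0[["mu"]]
  se <- sqrt(m1[["var"]] + m0[["var"]])

  est <- ni_estimate("IPW", rd, se, ci_level, length(idx),
                     diagnostics = list(min_weight = min(w),
                                        max_weight = max(w),
                                        covariates = covariate_subset))
  if (ci_method == "bootstrap") {
    n <- nrow(trial)
    boot <- vapply(seq_len(boot_samples), function(b) {
      bt <- trial[sample.int(n, n, replace = TRUE), , drop = FALSE]
      wb <- fit_adherence_weights(bt, covariate_subset)
      if (isTRUE(attr(wb, "failed"))) return(NA_real_)
      ib <- attr(wb, "adherent_idx")
      zb <- bt$z[ib]; yb <- bt$y[ib]
      if (!any(zb == 1L) || !any(zb == 0L)) return(NA_real_)
      sum(wb[zb == 1L] * yb[zb == 1L]) / sum(wb[zb == 1L]) -
        sum(wb[zb == 0L] * yb[zb == 0L]) / sum(wb[zb == 0L])
    }, numeric(1))
    boot <- boot[is.finite(boot)]
    qs <- stats::quantile(boot, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                          names = FALSE)
    est$ci_lower <- qs[1]
    est$ci_upper <- qs[2]
    est$diagnostics$boot_samples_used <- length(boot)
  }
  est
}

#' Instrumental-variable (structural mean model) risk difference
#'
#' Uses randomization as a binary instrument for the treatment actually
#' received. With a single binary instrument and binary treatment the
#' linear structural mean model reduces to the Wald ratio: the
#' intention-to-treat risk difference divided by the between-arm
#' difference in the proportion actually receiving the experimental
#' treatment. The standard error comes from the delta method for a ratio
#' of two arm-wise mean differences (accounting for the within-arm
#' covariance between outcome and received treatment). Applicable only to
#' crossover-type non-adherence, where the received treatment is binary;
#' calling it on a trial containing alternative-treatment (`a2`) receipt
#' is a usage error.
#'
#' @inheritParams estimate_itt
#' @return An `ni_estimate` with diagnostic `compliance_difference` (the
#'   denominator); `failed = TRUE` if the denominator is numerically zero.
#' @export
estimate_iv <- function(trial, ci_level = 0.95) {
  spec <- attr(trial, "scenario")
  if (!is.null(spec) && spec$destination == "alternative") {
    stop("IV estimation applies only to crossover non-adherence ",
         "(binary received treatment); this trial uses an alternative ",
         "treatment destination.", call. = FALSE)
  }
  if (any(trial$received == "a2")) {
    stop("IV estimation requires a binary received treatment; found 'a2'.",
         call. = FALSE)
  }
  a <- as.integer(trial$received == "a1")
  z1 <- trial$z == 1L; z0 <- trial$z == 0L
  n1 <- sum(z1); n0 <- sum(z0)
  if (n1 == 0 || n0 == 0) {
    stop("IV requires both allocation arms to be non-empty.", call. = FALSE)
  }
  num <- mean(trial$y[z1]) - mean(trial$y[z0])
  den <- mean(a[z1]) - mean(a[z0])
  if (abs(den) < 1e-8) {
    return(ni_estimate("IV", ci_level = ci_level, failed = TRUE,
                       message = "compliance difference (IV denominator) is zero"))
  }
  rd <- num / den
  # delta method: var(num/den) with arm-wise means; covariance of the two
  # differences comes from the within-arm covariance of (y, a).
  vy <- stats::var(trial$y[z1]) / n1 + stats::var(trial$y[z0]) / n0
  va <- stats::var(a[z1]) / n1 + stats::var(a[z0]) / n0
  cya <- stats::cov(trial$y[z1], a[z1]) / n1 + stats::cov(trial$y[z0], a[z0]) / n0
  vr <- (vy + rd^2 * va - 2 * rd * cya) / den^2
  se <- sqrt(max(vr, 0))
  ni_estimate("IV", rd, se, ci_level, n1 + n0,
              diagnostics = list(compliance_difference = den))
}

#' Apply a set of estimators to one trial
#'
#' @param trial An `ni_trial`.
#' @param methods Character subset of `c("ITT", "PP", "IPW", "IV")`.
#' @param covariate_subset Confounder indices for the IPW adherence model.
#' @param ci_level Two-sided confidence level.
#' @param ipw_ci_method Passed to [estimate_ipw()].
#' @return A named list of `ni_estimate` objects.
#' @export
estimate_all <- function(trial, methods = c("ITT", "PP", "IPW", "IV"),
                         covariate_subset = NULL, ci_level = 0.95,
                         ipw_ci_method = "sandwich") {
  methods <- match.arg(methods, c("ITT", "PP", "IPW", "IV"),
                       several.ok = TRUE)
  out <- list()
  for (m in methods) {
    out[[m]] <- switch(m,
      ITT = estimate_itt(trial, ci_level),
      PP  = estimate_pp(trial, ci_level),
      IPW = estimate_ipw(trial, covariate_subset, ci_level, ipw_ci_method),
      IV  = estimate_iv(trial, ci_level)
    )
  }
  out
}
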