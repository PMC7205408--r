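test_that("population draw has the right support, balance and determinism", {
  params <- effect_params()
  set.seed(42)
  pop <- draw_population(1010, params)
  expect_equal(dim(pop$confounder), c(1010, 1))
  expect_true(all(pop$confounder >= 0 & pop$confounder <= 1))
  expect_true(all(pop$allocation %in% 0:1))
  # allocation mean within 4 binomial SEs of 0.5
  expect_lt(abs(mean(pop$allocation) - 0.5), 4 * sqrt(0.25 / 1010))
  # independence of allocation and confounder
  expect_lt(abs(cor(pop$allocation, pop$confounder[, 1])), 4 / sqrt(1010))

  set.seed(7); a <- draw_population(10, params)
  set.seed(7); b <- draw_population(10, params)
  expect_identical(a, b)
  expect_error(draw_population(1, params), ">= 2")
})

test_that("counterfactual probabilities follow the clipped linear model", {
  params <- effect_params()  # 0.4 baseline, theta = 0.1, penalty 0.1, Beta(2,2)
  p <- counterfactual_probs(matrix(0.5), params)
  expect_equal(unlist(p), c(p0 = 0.4, p1 = 0.5, p2 = 0.6))

  flat <- effect_params(confounder_outcome_slope = 0)
  p <- counterfactual_probs(matrix(runif(50)), flat)
  expect_true(all(p$p0 == 0.4 & p$p1 == 0.5 & p$p2 == 0.6))

  steep <- effect_params(confounder_outcome_slope = 5)
  expect_equal(counterfactual_probs(matrix(1), steep)$p0, 1)  # clip at 1
  expect_equal(counterfactual_probs(matrix(0), steep)$p1, 0)  # clip at 0

  # infeasible mean probabilities are a configuration error
  expect_error(effect_params(p_fail_control = 0.95, true_effect = 0.1),
               "must all lie")
  expect_error(counterfactual_probs(matrix(1.5), params), "\\[0, 1\\]")
})

test_that("true-effect conservation holds without clipping", {
  params <- effect_params(confounder_outcome_slope = 0.5)
  set.seed(3)
  C <- matrix(rbeta(50000, 2, 2))
  p <- counterfactual_probs(C, params)
  expect_lt(max(abs(p$p1 - p$p0 - params$true_effect)), 1e-12)  # parallel shift
  expect_lt(abs(mean(p$p1) - mean(p$p0) - 0.1), 1e-12)
})

test_that("received treatment maps adherence and destination correctly", {
  cross <- spec_noncf
  alt <- scenario_spec("both", "alternative", "non_confounded")
  expect_equal(received_treatment(c(1L, 0L), c(1L, 1L), cross), c("a1", "a0"))
  expect_equal(received_treatment(c(1L, 0L), c(0L, 0L), cross), c("a0", "a1"))
  expect_equal(received_treatment(c(1L, 0L), c(0L, 0L), alt), c("a2", "a2"))
  expect_equal(received_treatment(c(1L, 0L), c(1L, 0L), alt), c("a1", "a2"))
})

test_that("full adherence yields no non-adherent participants", {
  set.seed(1)
  pop <- draw_population(200, effect_params())
  for (s in enumerate_scenarios()) {
    expect_true(all(adherence_status(pop$confounder, pop$allocation, s, 1,
                                     effect_params()) == 1L))
  }
})

test_that("threshold adherence is exactly calibrated and targets extremes", {
  params <- effect_params()  # gamma > 0
  set.seed(11)
  pop <- draw_population(1000, params)
  z <- pop$allocation
  cval <- pop$confounder[, 1]
  spec <- scenario_spec("experimental_only", "crossover", "confounded",
                        "discordant")
  adh <- adherence_status(pop$confounder, z, spec, 0.9, params,
                          mode = "threshold")
  n_exp <- sum(z == 1L)
  k <- ceiling(0.1 * n_exp)
  # exact count in the targeted arm, none in the control arm
  expect_equal(sum(adh == 0L & z == 1L), k)
  expect_equal(sum(adh == 0L & z == 0L), 0L)
  # discordant direction with a positive outcome slope: the confounder
  # lowers experimental uptake, so the k largest confounder values in the
  # experimental arm are the non-adherers
  cutoff <- sort(cval[z == 1L], decreasing = TRUE)[k]
  expect_true(all(cval[adh == 0L] >= cutoff))

  # concordant flips the extreme: lowest confounder values cross over
  adh2 <- adherence_status(pop$confounder, z,
                           scenario_spec("experimental_only", "crossover",
                                         "confounded", "concordant"),
                           0.9, params, mode = "threshold")
  cutoff2 <- sort(cval[z == 1L])[k]
  expect_true(all(cval[adh2 == 0L] <= cutoff2))

  # non-confounded threshold mode: exact count, unrelated to C
  adh3 <- adherence_status(pop$confounder, z, spec_noncf, 0.8, params,
                           mode = "threshold")
  expect_equal(sum(adh3 == 0L & z == 1L), ceiling(0.2 * n_exp))
  expect_equal(sum(adh3 == 0L & z == 0L), ceiling(0.2 * sum(z == 0L)))

  expect_error(adherence_status(pop$confounder, z, spec_noncf, 1.2,
                                params), "\\[0, 1\\]")
})

test_that("stochastic adherence is calibrated in expectation", {
  params <- effect_params()
  set.seed(5)
  pop <- draw_population(4000, params)
  z <- pop$allocation
  for (s in list(spec_noncf, spec_disc)) {
    adh <- adherence_status(pop$confounder, z, s, 0.6, params,
                            mode = "stochastic")
    for (arm in 0:1) {
      rate <- mean(adh[z == arm])
      n_arm <- sum(z == arm)
      expect_lt(abs(rate - 0.6), 4 * sqrt(0.6 * 0.4 / n_arm))
    }
  }
  # confounded stochastic mode: adherence probability decreases with the
  # confounder in the experimental arm under the discordant direction
  adh <- adherence_status(pop$confounder, z, spec_disc, 0.7, params,
                          mode = "stochastic")
  hi <- pop$confounder[, 1] > 0.6 & z == 1L
  lo <- pop$confounder[, 1] < 0.4 & z == 1L
  expect_lt(mean(adh[hi]), mean(adh[lo]))
})

test_that("simulated trials satisfy consistency and reproduce under a seed", {
  for (id in c("both-cross-nonconf", "exp-alt-conf-disc",
               "ctrl-cross-conf-conc")) {
    tr <- simulate_trial(id, 300, 0.8, seed = 99)
    matched <- ifelse(tr$received == "a0", tr$y0,
                      ifelse(tr$received == "a1", tr$y1, tr$y2))
    expect_identical(tr$y, as.integer(matched))
    # adherent participants received their allocation
    expect_true(all(tr$received[tr$adherent == 1L] ==
                      ifelse(tr$z[tr$adherent == 1L] == 1L, "a1", "a0")))
    # a2 only for alternative-destination non-adherers
    spec <- attr(tr, "scenario")
    if (spec$destination == "crossover") {
      expect_false(any(tr$received == "a2"))
    } else {
      expect_true(all(tr$adherent[tr$received == "a2"] == 0L))
    }
    expect_identical(as.data.frame(simulate_trial(id, 300, 0.8, seed = 99)),
                     as.data.frame(tr))
  }
  tr <- simulate_trial(spec_noncf, 505, 1.0, seed = 2)
  expect_true(all(tr$adherent == 1L))
  expect_equal(nrow(tr), 1010)
})

test_that("baseline failure rate and randomization balance hold on average", {
  params <- effect_params()
  set.seed(21)
  # control-arm counterfactual failure ~ 40%
  tr <- simulate_trial(spec_noncf, 505, 1.0, params)
  expect_lt(abs(mean(tr$y0) - 0.4), 4 * sqrt(0.4 * 0.6 / nrow(tr)))
  # across replicates the between-arm confounder difference is centred at 0
  diffs <- replicate(200, {
    p <- draw_population(200, params)
    mean(p$confounder[p$allocation == 1L, 1]) -
      mean(p$confounder[p$allocation == 0L, 1])
  })
  expect_lt(abs(mean(diffs)) / (sd(diffs) / sqrt(length(diffs))), 4)
})

test_that("trial CSV round-trips the participant table", {
  tr <- simulate_trial("both-cross-nonconf", 50, 0.9, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(tr, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# scenario: both-cross-nonconf", lines)))
  back <- read.csv(path, comment.char = "#")
  expect_equal(back$y, tr$y)
  expect_equal(back$received, tr$received)
})
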