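# Hand-built micro-trials for exercising the estimators without the
# simulator. Columns mirror the ni_trial layout; estimators only need the
# columns they read.
make_trial <- function(z, y, adherent = rep(1L, length(z)),
                       received = NULL, c1 = NULL) {
  if (is.null(received)) {
    allocated <- ifelse(z == 1L, "a1", "a0")
    opposite <- ifelse(z == 1L, "a0", "a1")
    received <- ifelse(adherent == 1L, allocated, opposite)
  }
  if (is.null(c1)) c1 <- seq(0.1, 0.9, length.out = length(z))
  data.frame(id = seq_along(z), z = as.integer(z), c1 = c1,
             adherent = as.integer(adherent), received = received,
             y = as.integer(y), stringsAsFactors = FALSE)
}

spec_noncf <- scenario_spec("both", "crossover", "non_confounded")
spec_disc  <- scenario_spec("both", "crossover", "confounded", "discordant")
spec_conc  <- scenario_spec("both", "crossover", "confounded", "concordant")
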