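#' Scenario specification for a pattern of non-adherence
#'
#' A trial scenario is identified by four factors: which allocation arm(s)
#' contain non-adherent participants, what treatment the non-adherent
#' participants actually receive, whether the factors driving non-adherence
#' also influence the outcome (confounding), and -- for confounded
#' mechanisms -- whether the confounder pushes uptake of the experimental
#' treatment and the probability of treatment failure in the same direction
#' (concordant) or in opposite directions (discordant). Crossing the three
#' arm choices with the two destinations and the three mechanism/direction
#' combinations yields the 18 distinct non-adherence patterns the simulator
#' covers.
#'
#' @param nonadherent_arms One of `"experimental_only"`, `"control_only"`,
#'   `"both"`: the allocation arm(s) in which non-adherence occurs.
#' @param destination One of `"crossover"` (non-adherent participants take
#'   the opposite arm's treatment) or `"alternative"` (they take a third
#'   treatment inferior to both trial treatments).
#' @param mechanism One of `"non_confounded"` (non-adherence is independent
#'   of prognosis) or `"confounded"` (a prognostic variable drives both
#'   adherence and outcome).
#' @param direction One of `"concordant"`, `"discordant"`, `"none"`. Must be
#'   `"none"` if and only if `mechanism = "non_confounded"`. Concordant
#'   means the confounder's effects on experimental-treatment uptake and on
#'   failure probability share the same sign; discordant means they oppose.
#'
#' @return An object of class `ni_scenario`, a validated list with the four
#'   fields above.
#' @seealso [enumerate_scenarios()], [scenario_id()], [parse_scenario_id()]
#' @examples
#' scenario_spec("both", "crossover", "non_confounded")
#' scenario_spec("experimental_only", "alternative", "confounded", "discordant")
#' @export
scenario_spec <- function(nonadherent_arms,
                          destination,
                          mechanism,
                          direction = if (identical(mechanism, "non_confounded")) "none" else NULL) {
  if (is.null(direction)) {
    stop("`direction` must be supplied for confounded scenarios ",
         "('concordant' or 'discordant').", call. = FALSE)
  }
  spec <- structure(
    list(
      nonadherent_arms = match.arg(nonadherent_arms, .ni_arms),
      destination      = match.arg(destination, .ni_destinations),
      mechanism        = match.arg(mechanism, .ni_mechanisms),
      direction        = match.arg(direction, .ni_directions)
    ),
    class = "ni_scenario"
  )
  validate_scenario(spec)
}

.ni_arms         <- c("experimental_only", "control_only", "both")
.ni_destinations <- c("crossover", "alternative")
.ni_mechanisms   <- c("non_confounded", "confounded")
.ni_directions   <- c("concordant", "discordant", "none")

#' Validate a scenario specification
#'
#' Checks the structural invariant linking mechanism and direction: a
#' non-confounded mechanism has no direction (`"none"`), and a confounded
#' mechanism must specify `"concordant"` or `"discordant"`.
#'
#' @param spec An `ni_scenario` object (or a list with the same fields).
#' @return `spec`, unchanged, invisibly classed as `ni_scenario`.
#' @export
validate_scenario <- function(spec) {
  required <- c("nonadherent_arms", "destination", "mechanism", "direction")
  missing <- setdiff(required, names(spec))
  if (length(missing) > 0) {
    stop("Scenario is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  chk <- function(value, allowed, field) {
    if (!(is.character(value) && length(value) == 1 && value %in% allowed)) {
      stop("Scenario field `", field, "` must be one of: ",
           paste(allowed, collapse = ", "), call. = FALSE)
    }
  }
  chk(spec$nonadherent_arms, .ni_arms, "nonadherent_arms")
  chk(spec$destination, .ni_destinations, "destination")
  chk(spec$mechanism, .ni_mechanisms, "mechanism")
  chk(spec$direction, .ni_directions, "direction")
  if (spec$mechanism == "non_confounded" && spec$direction != "none") {
    stop("A non-confounded scenario must have direction = 'none', got '",
         spec$direction, "'.", call. = FALSE)
  }
  if (spec$mechanism == "confounded" && spec$direction == "none") {
    stop("A confounded scenario must have direction 'concordant' or ",
         "'discordant'.", call. = FALSE)
  }
  class(spec) <- "ni_scenario"
  spec
}

#' Enumerate all 18 non-adherence scenarios
#'
#' Produces every valid scenario in a fixed lexicographic order over
#' (non-adherent arm, destination, mechanism/direction), so that repeated
#' runs and CSV output are reproducibly ordered. There are 18 scenarios in
#' total: 6 with a non-confounded mechanism and 12 confounded (two
#' directions each).
#'
#' @return A list of `ni_scenario` objects of length 18, named by
#'   [scenario_id()].
#' @examples
#' length(enumerate_scenarios())
#' @export
enumerate_scenarios <- function() {
  out <- list()
  for (arm in .ni_arms) {
    for (dest in .ni_destinations) {
      specs <- list(
        scenario_spec(arm, dest, "non_confounded", "none"),
        scenario_spec(arm, dest, "confounded", "concordant"),
        scenario_spec(arm, dest, "confounded", "discordant")
      )
      out <- c(out, specs)
    }
  }
  names(out) <- vapply(out, scenario_id, character(1))
  out
}

.ni_label_part <- list(
  nonadherent_arms = c(experimental_only = "exp", control_only = "ctrl", both = "both"),
  destination      = c(crossover = "cross", alternative = "alt"),
  direction        = c(concordant = "conc", discordant = "disc")
)

#' Short stable label for a scenario
#'
#' Labels have the form `<arm>-<destination>-<mechanism[/direction]>`, e.g.
#' `"both-cross-nonconf"` or `"exp-alt-conf-disc"`. They are unique across
#' the 18 scenarios, safe as CSV keys and command-line arguments, and
#' round-trip through [parse_scenario_id()].
#'
#' @param spec An `ni_scenario` object.
#' @return A length-one character label.
#' @export
scenario_id <- function(spec) {
  spec <- validate_scenario(spec)
  arm  <- .ni_label_part$nonadherent_arms[[spec$nonadherent_arms]]
  dest <- .ni_label_part$destination[[spec$destination]]
  mech <- if (spec$mechanism == "non_confounded") {
    "nonconf"
  } else {
    paste0("conf-", .ni_label_part$direction[[spec$direction]])
  }
  paste(arm, dest, mech, sep = "-")
}

#' Parse a scenario label back into its specification
#'
#' Inverse of [scenario_id()]. Unknown labels raise an error listing the
#' valid labels.
#'
#' @param id A scenario label, e.g. `"both-cross-nonconf"`.
#' @return The corresponding `ni_scenario` object.
#' @export
parse_scenario_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1)
  all_specs <- enumerate_scenarios()
  hit <- match(id, names(all_specs))
  if (is.na(hit)) {
    stop("Unknown scenario label '", id, "'. Valid labels: ",
         paste(names(all_specs), collapse = ", "), call. = FALSE)
  }
  all_specs[[hit]]
}

#' @export
print.ni_scenario <- function(x, ...) {
  cat("Non-adherence scenario <", scenario_id(x), ">\n", sep = "")
  cat("  non-adherent arm(s): ", x$nonadherent_arms, "\n", sep = "")
  cat("  destination:         ", x$destination, "\n", sep = "")
  cat("  mechanism:           ", x$mechanism, "\n", sep = "")
  if (x$mechanism == "confounded") {
    cat("  direction:           ", x$direction, "\n", sep = "")
  }
  invisible(x)
}

#' Table view of the scenario taxonomy
#'
#' @return A data frame with one row per scenario: `scenario` (the label)
#'   plus the four factor columns.
#' @export
scenario_table <- function() {
  specs <- enumerate_scenarios()
  data.frame(
    scenario = names(specs),
    nonadherent_arms = vapply(specs, `[[`, character(1), "nonadherent_arms"),
    destination = vapply(specs, `[[`, character(1), "destination"),
    mechanism = vapply(specs, `[[`, character(1), "mechanism"),
    direction = vapply(specs, `[[`, character(1), "direction"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
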