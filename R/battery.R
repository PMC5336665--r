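#' Construct a neuropsychological battery configuration
#'
#' A battery configuration maps each cognitive test to exactly one of the six
#' DSM-5 neurocognitive domains, records the scoring direction of every test
#' (whether larger raw scores mean better or worse performance, e.g. timed
#' trail-making tests are `lower_better`), and lists the tests for which
#' wave-to-wave decline scores are computed.
#'
#' @param domain_map named list mapping each of the six domains
#'   (`complex_attention`, `executive`, `learning_memory`, `language`,
#'   `perceptual_motor`, `social_cognition`) to a character vector of test
#'   names.  Every test must appear in exactly one domain.
#' @param decline_tests character vector of tests eligible for wave-3 to
#'   wave-4 decline scoring; must be a subset of the tests in `domain_map`.
#' @param direction named character vector over all tests with values
#'   `"higher_better"` or `"lower_better"`.
#' @return an object of class `ncd_battery` with elements `domain_map`,
#'   `decline_tests`, `direction` and `tests` (all tests, in domain order).
#' @seealso [default_battery()] for the standard battery.
#' @export
battery_config <- function(domain_map, decline_tests, direction) {
  expected <- c("complex_attention", "executive", "learning_memory",
                "language", "perceptual_motor", "social_cognition")
  if (!setequal(names(domain_map), expected)) {
    stop("domain_map must name exactly the six cognitive domains: ",
         paste(expected, collapse = ", "))
  }
  domain_map <- domain_map[expected]
  tests <- unlist(domain_map, use.names = FALSE)
  if (anyDuplicated(tests)) {
    stop("each test must belong to exactly one domain; duplicated: ",
         paste(unique(tests[duplicated(tests)]), collapse = ", "))
  }
  if (!all(decline_tests %in% tests)) {
    stop("decline_tests not in the battery: ",
         paste(setdiff(decline_tests, tests), collapse = ", "))
  }
  if (!setequal(names(direction), tests) ||
      !all(direction %in% c("higher_better", "lower_better"))) {
    stop("direction must give 'higher_better'/'lower_better' for every test")
  }
  structure(
    list(domain_map = domain_map,
         decline_tests = decline_tests,
         direction = direction[tests],
         tests = tests),
    class = "ncd_battery")
}

#' Default neuropsychological battery
#'
#' The standard battery covering the six DSM-5 domains: complex attention
#' (Symbol Digit Modalities Test, Trail Making A, simple and choice reaction
#' time), executive function (Digit Span Backwards, Trail Making B, Stroop,
#' Zoo Map, Game of Dice), learning and memory (CVLT immediate and delayed
#' recall, Benton Visual Retention administration B), language (letter fluency
#' COWAT, 15-item Boston Naming Test, Spot-the-Word), perceptual-motor
#' function (Purdue Pegboard, Ideomotor Apraxia Test, Benton administration
#' C), and social cognition (Reading the Mind in the Eyes).  Timed tests
#' (trails, reaction time, Stroop) are scored `lower_better`.
#'
#' Decline-eligible tests (those with wave-3 baselines suitable for change
#' scoring) are CVLT immediate and delayed recall, Digit Span Backwards,
#' SDMT, Purdue Pegboard, COWAT, Trail Making B, and simple and choice
#' reaction time.
#'
#' @return an `ncd_battery` object.
#' @export
default_battery <- function() {
  domain_map <- list(
    complex_attention = c("sdmt", "tmt_a", "srt", "crt"),
    executive        = c("digits_back", "tmt_b", "stroop", "zoo_map", "dice"),
    learning_memory  = c("cvlt_immediate", "cvlt_delayed", "bvrt_b"),
    language         = c("cowat", "bnt15", "stw"),
    perceptual_motor = c("purdue_pegboard", "iat", "bvrt_c"),
    social_cognition = c("rmie"))
  tests <- unlist(domain_map, use.names = FALSE)
  direction <- stats::setNames(rep("higher_better", length(tests)), tests)
  direction[c("tmt_a", "tmt_b", "srt", "crt", "stroop")] <- "lower_better"
  decline_tests <- c("cvlt_immediate", "cvlt_delayed", "digits_back", "sdmt",
                     "purdue_pegboard", "cowat", "tmt_b", "srt", "crt")
  battery_config(domain_map, decline_tests, direction)
}

#' Map a test to its cognitive domain
#' @param battery an `ncd_battery`.
#' @return named character vector test -> domain.
#' @keywords internal
test_domains <- function(battery) {
  stats::setNames(rep(names(battery$domain_map), lengths(battery$domain_map)),
                  battery$tests)
}

#' Read / write a battery configuration as YAML
#'
#' @param path file path.
#' @return `read_battery()` returns an `ncd_battery`.
#' @export
read_battery <- function(path) {
  y <- yaml::read_yaml(path)
  battery_config(y$domain_map, unlist(y$decline_tests),
                 unlist(y$direction))
}

#' @rdname read_battery
#' @param battery an `ncd_battery`.
#' @export
write_battery <- function(battery, path) {
  yaml::write_yaml(
    list(domain_map = battery$domain_map,
         decline_tests = as.list(battery$decline_tests),
         direction = as.list(battery$direction)),
    path)
  invisible(path)
}

#' @export
print.ncd_battery <- function(x, ...) {
  cat("Neuropsychological battery:", length(x$tests), "tests in 6 domains\n")
  for (d in names(x$domain_map)) {
    cat(sprintf("  %-17s %s\n", d, paste(x$domain_map[[d]], collapse = ", ")))
  }
  cat("  decline-eligible:", paste(x$decline_tests, collapse = ", "), "\n")
  invisible(x)
}
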