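# ICHD-3 criterion evaluators: the first (fuzzy C) and second (two-valued D)
# levels of the hierarchy.

#' Evaluate the pain-characteristic criterion C as a fuzzy subsystem
#'
#' Criterion C requires at least two of four pain characteristics (for
#' migraine: unilateral location, pulsating quality, moderate-or-severe
#' intensity, aggravation by routine physical activity; for tension-type
#' headache: bilateral, non-pulsating, mild-or-moderate, no aggravation).
#' Location, quality and aggravation are crisp; intensity is fuzzified over
#' mild/moderate/severe, so near an intensity band boundary the criterion is
#' fulfilled to a degree. The first-level rule base enumerates all feature
#' combinations with consequent `fit`/`unfit`; the fulfilment degree is the
#' weighted average of fit (1) versus unfit (0) over the summed rule
#' activations, and the binary outcome is `degree >= 0.5`.
#'
#' @param case A [patient_case()].
#' @param config An `engine_config`; defaults to the shipped reference
#'   configuration.
#' @return A `criterion_outcome`: list with `id`, `degree` in `[0, 1]`,
#'   `fulfilled` flag and the rule activation `trace`.
#' @export
evaluate_criterion_C_migraine <- function(case, config = default_config()) {
  .criterion_C(case, config, "migraine")
}

#' @rdname evaluate_criterion_C_migraine
#' @export
evaluate_criterion_C_tth <- function(case, config = default_config()) {
  .criterion_C(case, config, "tension_type")
}

.criterion_C <- function(case, config, output) {
  case <- as_patient_case(case)
  fz <- list(intensity = fuzzify(config$variables$intensity, case$intensity_vas))
  crisp <- c(location = case$location, quality = case$quality,
             aggravation_by_activity = case$aggravation_by_activity)
  agg <- aggregate_activations(config$level1_rules[[output]], fz, crisp)
  alphas <- agg$criterion_C
  for (t in c("fit", "unfit")) if (is.na(alphas[t])) alphas[t] <- 0
  degree <- withCallingHandlers(
    defuzzify_weighted_average(alphas[c("fit", "unfit")], c(fit = 1, unfit = 0)),
    fuzzyichd_no_applicable_rule = function(w) invokeRestart("muffleWarning"))
  if (is.na(degree)) degree <- 0
  structure(list(id = paste0("C_", output), degree = degree,
                 fulfilled = degree >= 0.5,
                 trace = attr(agg, "trace")),
            class = "criterion_outcome")
}

#' Evaluate the accompanying-symptom criterion D (two-valued)
#'
#' For migraine, criterion D is fulfilled when the headache is accompanied
#' by nausea and/or vomiting, or by both photophobia and phonophobia. For
#' tension-type headache it requires no nausea, no vomiting, and not both
#' photophobia and phonophobia (one of the two is allowed).
#'
#' @inheritParams evaluate_criterion_C_migraine
#' @return A `criterion_outcome` with `degree` in `{0, 1}`.
#' @export
evaluate_criterion_D_migraine <- function(case, config = default_config()) {
  case <- as_patient_case(case)
  yes <- function(f) identical(case[[f]], "yes")
  ok <- (yes("nausea") || yes("vomiting")) ||
    (yes("photophobia") && yes("phonophobia"))
  structure(list(id = "D_migraine", degree = as.numeric(ok), fulfilled = ok,
                 trace = NULL), class = "criterion_outcome")
}

#' @rdname evaluate_criterion_D_migraine
#' @export
evaluate_criterion_D_tth <- function(case, config = default_config()) {
  case <- as_patient_case(case)
  yes <- function(f) identical(case[[f]], "yes")
  ok <- !yes("nausea") && !yes("vomiting") &&
    !(yes("photophobia") && yes("phonophobia"))
  structure(list(id = "D_tth", degree = as.numeric(ok), fulfilled = ok,
                 trace = NULL), class = "criterion_outcome")
}

#' @export
print.criterion_outcome <- function(x, ...) {
  cat(sprintf("<criterion_outcome> %s: degree %.4f (%s)\n", x$id, x$degree,
              if (x$fulfilled) "fulfilled" else "not fulfilled"))
  invisible(x)
}

# Crisp characteristic count used by the rule-based backbone; intensity is
# classified by the band cutoffs (the 0.5-crossings of the fuzzy sets).
.crisp_characteristic_count <- function(case, config, output) {
  ch <- config$characteristics[[output]]
  cut <- config$crisp$intensity_cutoffs
  grade_ok <- if (identical(ch$intensity_terms, list("mild", "moderate")) ||
                  setequal(unlist(ch$intensity_terms), c("mild", "moderate"))) {
    case$intensity_vas <= cut$moderate_max
  } else {
    case$intensity_vas >= cut$mild_max
  }
  (case$location == ch$location) + (case$quality == ch$quality) +
    grade_ok + (case$aggravation_by_activity == ch$aggravation_by_activity)
}
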