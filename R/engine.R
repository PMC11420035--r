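# Diagnostic engine: crisp rule-based backbone, three-level hierarchical
# fuzzy inference, and the hybrid dispatcher.

.label_map <- list(migraine = c(definite = "MO", probable = "PM", others = "others"),
                   tension_type = c(definite = "TTH", probable = "PTTH",
                                    others = "others"))

.diagnosis <- function(label, f_migraine, f_tth, stage, trace = NULL,
                       criteria = NULL) {
  structure(list(label = label, f_migraine = f_migraine, f_tth = f_tth,
                 stage = stage, trace = trace, criteria = criteria),
            class = "diagnosis")
}

#' @export
print.diagnosis <- function(x, ...) {
  cat(sprintf("<diagnosis> %s (stage: %s)\n", x$label, x$stage))
  if (!is.na(x$f_migraine) || !is.na(x$f_tth))
    cat(sprintf("  f_migraine = %.4f, f_tth = %.4f\n",
                x$f_migraine, x$f_tth))
  invisible(x)
}

# Map a crisp score to definite/probable/others by nearest constant;
# ties break toward the lower-severity constant (non-diagnosis is the
# clinically safe default).
.nearest_term <- function(f, constants) {
  constants <- sort(constants) # ascending: others, probable, definite
  d <- abs(f - constants)
  names(constants)[which(d == min(d))[1]]
}

#' Crisp rule-based diagnosis (decision-diagram backbone)
#'
#' Evaluates the ICHD-3 criteria with two-valued logic: migraine without
#' aura needs at least 5 attacks (A), every attack lasting 4-72 h (B), at
#' least two of four pain characteristics (C) and accompanying symptoms (D);
#' tension-type headache needs at least 10 attacks, durations within
#' 0.5-168 h, its own characteristic set, and absence of migrainous
#' accompaniments. A case failing exactly one criterion of a set receives
#' the corresponding probable diagnosis; anything else is `others`.
#' Criterion B requires the whole reported duration range inside the window.
#'
#' @param case A [patient_case()] (or coercible via [as_patient_case()]).
#' @param config An `engine_config`.
#' @return A `diagnosis` object with `stage = "rule_based"`. Crisp scores
#'   `f_migraine`/`f_tth` are `NA` at this stage.
#' @export
rule_based_diagnose <- function(case, config = default_config()) {
  case <- as_patient_case(case)
  fails <- .criterion_failures(case, config)
  label <- if (fails$migraine == 0) "MO"
    else if (fails$tension_type == 0) "TTH"
    else if (fails$migraine == 1) "PM"   # migraine preferred on double near-miss
    else if (fails$tension_type == 1) "PTTH"
    else "others"
  .diagnosis(label, NA_real_, NA_real_, "rule_based",
             criteria = fails$detail)
}

.criterion_failures <- function(case, config) {
  windows <- config$crisp
  in_window <- function(w)
    case$duration_low >= w[[1]] && case$duration_high <= w[[2]]
  detail <- list()
  n_fail <- c(migraine = 0, tension_type = 0)
  for (o in c("migraine", "tension_type")) {
    A <- case$number_of_attacks >= windows[[o]]$min_attacks
    B <- in_window(windows[[o]]$duration_window)
    C <- .crisp_characteristic_count(case, config, o) >= 2
    D <- if (o == "migraine") evaluate_criterion_D_migraine(case, config)$fulfilled
         else evaluate_criterion_D_tth(case, config)$fulfilled
    detail[[o]] <- c(A = A, B = B, C = C, D = D)
    n_fail[o] <- sum(!detail[[o]])
  }
  list(migraine = n_fail[["migraine"]], tension_type = n_fail[["tension_type"]],
       detail = detail)
}

#' Three-level hierarchical fuzzy diagnosis
#'
#' Level 1 evaluates criterion C as a small fuzzy system
#' ([evaluate_criterion_C_migraine()]); level 2 evaluates criterion D with
#' two-valued logic; level 3 fuzzifies the attack count and duration,
#' combines them with the binary C and D outcomes through the generated rule
#' base, sums the activation degrees per output term, and defuzzifies with
#' the weighted average over the constants (definite 2, probable 1,
#' others 0) to crisp scores `f_migraine` and `f_tth`. The final label comes
#' from the output with the larger score mapped to its nearest constant
#' (ties between outputs prefer the migraine output; ties between constants
#' prefer the lower-severity label). Duration ranges enter fuzzification at
#' their lower bound, the end at which the duration criteria typically fail.
#'
#' @inheritParams rule_based_diagnose
#' @return A `diagnosis` with `stage = "fuzzy"`, crisp scores, per-rule
#'   activation `trace` and the level-1/2 `criteria` outcomes.
#' @export
fuzzy_diagnose <- function(case, config = default_config()) {
  case <- as_patient_case(case)
  fz <- list(
    number_of_attacks = fuzzify(config$variables$number_of_attacks,
                                case$number_of_attacks),
    duration = fuzzify(config$variables$duration, case$duration_low))
  crit <- list(C_migraine = evaluate_criterion_C_migraine(case, config),
               C_tth = evaluate_criterion_C_tth(case, config),
               D_migraine = evaluate_criterion_D_migraine(case, config),
               D_tth = evaluate_criterion_D_tth(case, config))
  yn <- function(b) if (b) "yes" else "no"
  f <- c(migraine = NA_real_, tension_type = NA_real_)
  traces <- list()
  for (o in c("migraine", "tension_type")) {
    crisp <- c(criterion_C = yn(crit[[paste0("C_", if (o == "migraine") "migraine" else "tth")]]$fulfilled),
               criterion_D = yn(crit[[paste0("D_", if (o == "migraine") "migraine" else "tth")]]$fulfilled))
    rules <- Filter(function(r) r$output == o, config$level3_rules)
    agg <- aggregate_activations(rules, fz, crisp)
    tr <- attr(agg, "trace")
    traces[[o]] <- tr[tr$activation > 0, , drop = FALSE]
    alphas <- agg[[o]]
    f[o] <- withCallingHandlers(
      defuzzify_weighted_average(alphas, config$output_constants[[o]]),
      fuzzyichd_no_applicable_rule = function(w) invokeRestart("muffleWarning"))
  }
  trace <- do.call(rbind, traces)
  rownames(trace) <- NULL
  if (all(is.na(f))) {
    warning("no rule fired for either output; defaulting to non-diagnosis")
    return(.diagnosis("others", NA_real_, NA_real_, "fuzzy", trace, crit))
  }
  fm <- if (is.na(f["migraine"])) 0 else f[["migraine"]]
  ft <- if (is.na(f["tension_type"])) 0 else f[["tension_type"]]
  out <- if (ft > fm) "tension_type" else "migraine" # migraine wins ties
  score <- if (out == "migraine") fm else ft
  term <- .nearest_term(score, config$output_constants[[out]])
  .diagnosis(.label_map[[out]][[term]], fm, ft, "fuzzy", trace, crit)
}

#' Hybrid diagnosis: rule-based backbone with fuzzy fallback
#'
#' Runs the crisp backbone first; a definite diagnosis (MO or TTH) is final
#' and is never overridden. Otherwise -- probable or no diagnosis -- the
#' hierarchical fuzzy stage decides, which is where boundary-valued features
#' (4 attacks instead of 5, attacks slightly shorter than 4 h) recover a
#' probable diagnosis.
#'
#' @inheritParams rule_based_diagnose
#' @return A `diagnosis` from whichever stage decided.
#' @export
hybrid_diagnose <- function(case, config = default_config()) {
  rb <- rule_based_diagnose(case, config)
  if (rb$label %in% c("MO", "TTH")) rb else fuzzy_diagnose(case, config)
}

#' Diagnose a batch of cases
#'
#' @param cases List of [patient_case()] objects or a data.frame with one
#'   row per case.
#' @param config An `engine_config`.
#' @param stage `"hybrid"` (default), `"fuzzy"` or `"rule_based"`.
#' @return A data.frame with columns `label`, `f_migraine`, `f_tth`,
#'   `stage`, plus `gold_label` when present in the input.
#' @export
diagnose_batch <- function(cases, config = default_config(),
                           stage = c("hybrid", "fuzzy", "rule_based")) {
  stage <- match.arg(stage)
  if (is.data.frame(cases)) cases <- cases_from_df(cases)
  if (inherits(cases, "patient_case")) cases <- list(cases)
  fn <- switch(stage, hybrid = hybrid_diagnose, fuzzy = fuzzy_diagnose,
               rule_based = rule_based_diagnose)
  rows <- lapply(cases, function(cs) {
    d <- fn(cs, config)
    data.frame(label = d$label, f_migraine = d$f_migraine, f_tth = d$f_tth,
               stage = d$stage, gold_label = cs$gold_label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$gold_label))) out$gold_label <- NULL
  out
}
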