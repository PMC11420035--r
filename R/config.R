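# Configuration loading, validation, and rule-base generation.
#
# The whole knowledge base -- membership breakpoints, pain-characteristic
# sets, qualifying-term sets and crisp windows -- lives in an editable YAML
# (or JSON) file so that the clinical content can be reviewed and changed
# without touching code. The shipped default is the reference instantiation.

.fuzzyichd_env <- new.env(parent = emptyenv())

# Published anchor degrees the shipped membership functions must satisfy.
.anchors <- list(
  list(variable = "number_of_attacks", term = "low",      x = 4,  degree = 1 / 3),
  list(variable = "number_of_attacks", term = "moderate", x = 4,  degree = 1 / 2),
  list(variable = "number_of_attacks", term = "high",     x = 10, degree = 1)
)

.required_terms <- list(
  number_of_attacks = c("low", "moderate", "high"),
  duration = c("very short", "short", "moderate", "long", "very long"),
  intensity = c("mild", "moderate", "severe")
)

#' Load and validate an engine configuration
#'
#' Parses a YAML or JSON configuration file describing the membership
#' functions, pain-characteristic sets (criterion C), qualifying-term sets
#' (criteria A/B) and crisp windows, validates it, and expands the
#' first-level and third-level rule bases.
#'
#' @param path Path to a YAML (`.yaml`/`.yml`) or JSON configuration file.
#' @return An object of class `engine_config` with components `variables`
#'   (list of [linguistic_variable()]), `output_constants`,
#'   `characteristics`, `criteria`, `crisp`, `tolerance`, `level1_rules` and
#'   `level3_rules`.
#' @seealso [validate_config()], [default_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- validate_config(raw)
  cfg$source <- path
  cfg
}

#' Validate a parsed configuration and build the engine knowledge base
#'
#' Collects every violation (breakpoint ordering, degree ranges, duplicate
#' or missing term labels, malformed characteristic/criteria/crisp blocks)
#' and reports them all in a single error. Published anchor degrees (such as
#' the attack-count "low" membership of 1/3 at 4 attacks) are checked last;
#' a mismatch raises a warning naming the anchor, not an error, so that
#' deliberately modified configurations remain usable.
#'
#' @param raw A named list as returned by parsing a configuration file.
#' @return A validated `engine_config` object.
#' @export
validate_config <- function(raw) {
  problems <- character()
  note <- function(...) problems <<- c(problems, paste0(...))

  if (!is.list(raw$variables) || !length(raw$variables)) {
    note("`variables` block missing or empty")
    stop("invalid configuration:\n- ", paste(problems, collapse = "\n- "))
  }

  vars <- list()
  for (vn in names(raw$variables)) {
    vraw <- raw$variables[[vn]]
    terms <- list()
    if (anyDuplicated(names(vraw$terms)))
      note("variable '", vn, "': duplicate term labels")
    for (tn in names(vraw$terms)) {
      traw <- vraw$terms[[tn]]
      mf <- tryCatch(membership_function(tn, traw$x, traw$degree),
                     error = function(e) {
                       note("variable '", vn, "': ", conditionMessage(e))
                       NULL
                     })
      if (!is.null(mf)) terms[[tn]] <- mf
    }
    if (vn %in% names(.required_terms)) {
      missing <- setdiff(.required_terms[[vn]], names(terms))
      if (length(missing))
        note("variable '", vn, "' lacks required term(s): ",
             paste(missing, collapse = ", "))
    }
    if (length(terms))
      vars[[vn]] <- linguistic_variable(vn, vraw$unit %||% "", terms)
  }

  for (o in c("migraine", "tension_type")) {
    oc <- raw$output_constants[[o]]
    if (is.null(oc) || !setequal(names(oc), c("definite", "probable", "others")))
      note("output_constants$", o, " must map definite/probable/others")
    else if (anyDuplicated(unlist(oc)))
      note("output_constants$", o, " must be distinct")
    ch <- raw$characteristics[[o]]
    if (is.null(ch) || !all(c("location", "quality", "intensity_terms",
                              "aggravation_by_activity") %in% names(ch)))
      note("characteristics$", o, " incomplete")
    cr <- raw$criteria[[o]]
    if (is.null(cr) || !all(c("attacks_terms", "duration_terms") %in% names(cr)))
      note("criteria$", o, " incomplete")
    cw <- raw$crisp[[o]]
    if (is.null(cw) || !is.numeric(cw$min_attacks) ||
        length(cw$duration_window %||% NULL) != 2L)
      note("crisp$", o, " must give min_attacks and a duration_window of length 2")
  }

  if (length(problems))
    stop("invalid configuration:\n- ", paste(problems, collapse = "\n- "))

  cfg <- structure(list(
    variables = vars,
    output_constants = lapply(raw$output_constants, function(oc) unlist(oc)),
    characteristics = raw$characteristics,
    criteria = raw$criteria,
    crisp = raw$crisp,
    tolerance = raw$tolerance %||% 1e-9
  ), class = "engine_config")
  cfg$level1_rules <- list(
    migraine = build_level1_rules(cfg, "migraine"),
    tension_type = build_level1_rules(cfg, "tension_type"))
  cfg$level3_rules <- c(build_level3_rules(cfg, "migraine"),
                        build_level3_rules(cfg, "tension_type"))

  for (a in .anchors) {
    v <- cfg$variables[[a$variable]]
    if (is.null(v) || is.null(v$terms[[a$term]])) next
    got <- eval_membership(v$terms[[a$term]], a$x)
    if (abs(got - a$degree) > 1e-6)
      warning(sprintf(
        "membership anchor violated: mu_%s(%g) of '%s' is %.6f, expected %.6f",
        a$term, a$x, a$variable, got, a$degree))
  }
  cfg
}

#' @export
print.engine_config <- function(x, ...) {
  cat("<engine_config>\n")
  for (v in x$variables) print(v)
  cat(sprintf("  level-1 rules: %d + %d; level-3 rules: %d\n",
              length(x$level1_rules$migraine),
              length(x$level1_rules$tension_type), length(x$level3_rules)))
  invisible(x)
}

#' The shipped reference configuration
#'
#' Reads (and caches) the default YAML configuration installed with the
#' package.
#'
#' @return An `engine_config` object.
#' @export
default_config <- function() {
  if (is.null(.fuzzyichd_env$default_config)) {
    path <- system.file("extdata", "default_config.yaml", package = "fuzzyichd",
                        mustWork = TRUE)
    .fuzzyichd_env$default_config <- load_config(path)
  }
  .fuzzyichd_env$default_config
}

#' Write a configuration back to YAML
#'
#' Serializes the raw blocks of an `engine_config` so that a written file
#' re-validates to an identical knowledge base.
#'
#' @param config An `engine_config`.
#' @param path Output file path (YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "engine_config"))
  raw <- list(
    tolerance = config$tolerance,
    output_constants = lapply(config$output_constants, as.list),
    variables = lapply(config$variables, function(v) list(
      unit = v$unit,
      terms = lapply(v$terms, function(mf) list(x = mf$x, degree = mf$degree)))),
    characteristics = config$characteristics,
    criteria = config$criteria,
    crisp = config$crisp)
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' First-level rule base: fuzzy criterion C
#'
#' Enumerates location x quality x intensity-term x aggravation and marks
#' each combination `fit` when at least two of the four pain characteristics
#' of the given diagnosis hold (with the intensity term substituted for the
#' crisp grade), `unfit` otherwise.
#'
#' @param config An `engine_config`.
#' @param output `"migraine"` or `"tension_type"`.
#' @return List of [fuzzy_rule()] with output `criterion_C` and terms
#'   `fit`/`unfit`.
#' @export
build_level1_rules <- function(config, output = c("migraine", "tension_type")) {
  output <- match.arg(output)
  ch <- config$characteristics[[output]]
  grid <- expand.grid(location = c("unilateral", "bilateral"),
                      quality = c("pulsating", "non-pulsating", "other"),
                      intensity = names(config$variables$intensity$terms),
                      aggravation_by_activity = c("yes", "no"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    count <- (g$location == ch$location) + (g$quality == ch$quality) +
      (g$intensity %in% ch$intensity_terms) +
      (g$aggravation_by_activity == ch$aggravation_by_activity)
    fuzzy_rule(
      c(location = g$location, quality = g$quality, intensity = g$intensity,
        aggravation_by_activity = g$aggravation_by_activity),
      output = "criterion_C",
      term = if (count >= 2) "fit" else "unfit",
      id = sprintf("C_%s_%02d", output, i))
  })
}

#' Third-level rule base: final diagnosis inference
#'
#' Full cross product of attack-count terms, duration terms and the binary
#' criterion C and D outcomes. Consequents follow the ICHD-3 structure: a
#' combination failing none of A (attack-count term qualifying), B (duration
#' term qualifying), C and D concludes the definite diagnosis; failing
#' exactly one concludes the probable diagnosis; anything else concludes
#' others.
#'
#' @param config An `engine_config`.
#' @param output `"migraine"` or `"tension_type"`.
#' @return List of [fuzzy_rule()] for the given output variable.
#' @export
build_level3_rules <- function(config, output = c("migraine", "tension_type")) {
  output <- match.arg(output)
  cr <- config$criteria[[output]]
  grid <- expand.grid(attacks = names(config$variables$number_of_attacks$terms),
                      duration = names(config$variables$duration$terms),
                      C = c("yes", "no"), D = c("yes", "no"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    failures <- sum(!(g$attacks %in% cr$attacks_terms),
                    !(g$duration %in% cr$duration_terms),
                    g$C == "no", g$D == "no")
    fuzzy_rule(
      c(number_of_attacks = g$attacks, duration = g$duration,
        criterion_C = g$C, criterion_D = g$D),
      output = output,
      term = if (failures == 0) "definite" else if (failures == 1) "probable" else "others",
      id = sprintf("L3_%s_%02d", output, i))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
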