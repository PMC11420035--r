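#' Conjunctive fuzzy rule
#'
#' A rule's antecedent is a conjunction of clauses, each requiring a
#' linguistic term of a fuzzified variable or an exact value of a crisp
#' (two-valued) input; the consequent names an output variable and one of
#' its terms. Example: IF number_of_attacks is low AND duration is moderate
#' AND criterion_C is yes AND criterion_D is yes THEN migraine is probable.
#'
#' @param antecedent Named character vector or named list: names are input
#'   variable names, values the required term (fuzzy inputs) or required
#'   value (crisp inputs, e.g. `"yes"`).
#' @param output Output variable name, e.g. `"migraine"`.
#' @param term Consequent term of the output variable, e.g. `"probable"`.
#' @param id Optional rule identifier used in activation traces.
#' @return Object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(antecedent, output, term, id = NULL) {
  antecedent <- unlist(antecedent)
  if (!length(antecedent) || is.null(names(antecedent)) || any(!nzchar(names(antecedent))))
    stop("antecedent must be a non-empty named vector")
  structure(list(antecedent = antecedent,
                 output = as.character(output),
                 term = as.character(term),
                 id = if (is.null(id)) NA_character_ else as.character(id)),
            class = "fuzzy_rule")
}

#' @export
print.fuzzy_rule <- function(x, ...) {
  cat(sprintf("IF %s THEN %s is %s\n",
              paste(names(x$antecedent), "is", x$antecedent, collapse = " AND "),
              x$output, x$term))
  invisible(x)
}

#' Activation degree of one rule (min t-norm)
#'
#' The activation degree is the minimum over the antecedent clause degrees.
#' A fuzzy clause contributes the fuzzified degree of its required term; a
#' crisp clause contributes 1 when the case value matches and 0 otherwise.
#'
#' @param rule A [fuzzy_rule()].
#' @param fuzzified Named list: one named degree vector per fuzzified input
#'   variable (as returned by [fuzzify()]).
#' @param crisp Named character vector of crisp input values.
#' @return Activation degree `alpha >= 0` (a single number in `[0, 1]`).
#' @export
rule_activation <- function(rule, fuzzified, crisp = character()) {
  stopifnot(inherits(rule, "fuzzy_rule"))
  degs <- vapply(seq_along(rule$antecedent), function(i) {
    v <- names(rule$antecedent)[i]
    want <- rule$antecedent[[i]]
    if (v %in% names(fuzzified)) {
      d <- fuzzified[[v]][want]
      if (is.na(d))
        stop("term '", want, "' is not a term of fuzzified variable '", v, "'")
      as.numeric(d)
    } else if (v %in% names(crisp)) {
      as.numeric(identical(as.character(crisp[[v]]), as.character(want)))
    } else {
      stop("incomplete case: input variable '", v, "' is missing",
           call. = FALSE)
    }
  }, numeric(1))
  min(degs)
}

#' Aggregate rule activations per output term
#'
#' For each output variable, sums the activation degrees of all rules whose
#' consequent names that term. Summation (not max) is used, so a term's
#' aggregated activation may exceed 1 when several rules support it.
#'
#' @param rules List of [fuzzy_rule()] objects (the rule base).
#' @param fuzzified,crisp Inputs as for [rule_activation()].
#' @return A list with one element per output variable, each a named numeric
#'   vector of aggregated activations, with a `"trace"` attribute: a
#'   data.frame of every fired rule (id, output, term, activation).
#' @export
aggregate_activations <- function(rules, fuzzified, crisp = character()) {
  stopifnot(length(rules) > 0)
  acts <- vapply(rules, rule_activation, numeric(1),
                 fuzzified = fuzzified, crisp = crisp)
  outs <- vapply(rules, `[[`, character(1), "output")
  terms <- vapply(rules, `[[`, character(1), "term")
  ids <- vapply(rules, `[[`, character(1), "id")
  res <- lapply(split(seq_along(rules), outs), function(idx) {
    tl <- unique(terms[idx])
    a <- vapply(tl, function(t) sum(acts[idx][terms[idx] == t]), numeric(1))
    names(a) <- tl
    a
  })
  attr(res, "trace") <- data.frame(
    rule = ids, output = outs, term = terms, activation = acts,
    stringsAsFactors = FALSE)
  res
}

#' Weighted-average defuzzification
#'
#' Maps aggregated per-term activations to a crisp output score
#' `f = sum(alpha_t * c_t) / sum(alpha_t)` where `c_t` are the constant
#' scores attached to the output terms (2 for a definite diagnosis, 1 for a
#' probable one, 0 for others). `f` always lies within the convex hull of
#' the constants and is invariant to rescaling all activations by a common
#' positive factor.
#'
#' @param alphas Named numeric vector of aggregated activations (each
#'   `>= 0`).
#' @param constants Named numeric vector mapping term labels to constant
#'   scores; names must cover those of `alphas`.
#' @return The crisp score, or `NA_real_` with a warning of class
#'   `fuzzyichd_no_applicable_rule` when all activations are zero (the
#'   quotient is 0/0; callers treat this as a non-diagnosis, not as score 0).
#' @examples
#' defuzzify_weighted_average(
#'   c(definite = 0.25, probable = 0.75, others = 0.3333),
#'   c(definite = 2, probable = 1, others = 0)) # 0.9375
#' @export
defuzzify_weighted_average <- function(alphas, constants) {
  stopifnot(is.numeric(alphas), is.numeric(constants),
            !is.null(names(alphas)), !is.null(names(constants)))
  if (any(alphas < 0)) stop("activations must be nonnegative")
  missing <- setdiff(names(alphas), names(constants))
  if (length(missing))
    stop("no output constant for term(s): ", paste(missing, collapse = ", "))
  total <- sum(alphas)
  if (total <= 0) {
    warning(warningCondition("all rule activations are zero; crisp output undefined",
                             class = "fuzzyichd_no_applicable_rule"))
    return(NA_real_)
  }
  sum(alphas * constants[names(alphas)]) / total
}
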