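#' Piecewise-linear fuzzy membership function
#'
#' A membership function maps a crisp value of a numeric headache feature
#' (attack count, duration in hours, VAS intensity) to a degree of belonging
#' in a linguistic term, in `[0, 1]`. The curve is piecewise linear between
#' ordered breakpoints and continues the terminal degree constantly beyond
#' the first/last breakpoint, so triangles, trapezoids and shoulders are all
#' expressible.
#'
#' @param label Linguistic term name, e.g. `"low"` or `"very short"`.
#' @param x Numeric vector of breakpoint positions, nondecreasing, in the
#'   variable's unit.
#' @param degree Numeric vector of membership degrees at `x`, each in
#'   `[0, 1]`; same length as `x`.
#' @return An object of class `membership_function`.
#' @examples
#' low <- membership_function("low", x = c(2, 5), degree = c(1, 0))
#' eval_membership(low, 4) # 1/3
#' @seealso [eval_membership()], [linguistic_variable()]
#' @export
membership_function <- function(label, x, degree) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  x <- as.numeric(x)
  degree <- as.numeric(degree)
  if (length(x) < 1L || length(x) != length(degree))
    stop("`x` and `degree` must be non-empty vectors of equal length")
  if (anyNA(x) || anyNA(degree))
    stop("breakpoints must not contain NA")
  if (is.unsorted(x))
    stop("breakpoint x-values must be nondecreasing in term '", label, "'")
  if (any(degree < 0 | degree > 1))
    stop("membership degrees must lie in [0, 1] in term '", label, "'")
  structure(list(label = label, x = x, degree = degree),
            class = "membership_function")
}

#' Evaluate a membership function at crisp values
#'
#' Linear interpolation between adjacent breakpoints, constant extension of
#' the terminal degree outside the breakpoint range. Total on the reals and
#' vectorized over `x`.
#'
#' @param mf A [membership_function()].
#' @param x Numeric vector of crisp values.
#' @return Numeric vector of degrees in `[0, 1]`.
#' @export
eval_membership <- function(mf, x) {
  stopifnot(inherits(mf, "membership_function"))
  if (length(mf$x) == 1L) return(rep(mf$degree, length(x)))
  stats::approx(mf$x, mf$degree, xout = x, rule = 2, ties = "ordered")$y
}

#' @export
print.membership_function <- function(x, ...) {
  cat(sprintf("<membership_function> %s: (%s)\n", x$label,
              paste(sprintf("%g|%g", x$x, x$degree), collapse = ", ")))
  invisible(x)
}

#' Linguistic variable: a named, ordered set of fuzzy terms
#'
#' @param name Variable name, e.g. `"number_of_attacks"`.
#' @param unit Unit of the underlying crisp scale (`"attacks"`, `"hours"`,
#'   `"VAS"`).
#' @param terms List of [membership_function()] objects with unique labels.
#' @return An object of class `linguistic_variable`.
#' @examples
#' attacks <- linguistic_variable("number_of_attacks", "attacks", list(
#'   membership_function("low", c(2, 5), c(1, 0)),
#'   membership_function("moderate", c(3, 5, 8, 10), c(0, 1, 1, 0)),
#'   membership_function("high", c(8, 10), c(0, 1))
#' ))
#' fuzzify(attacks, 4)
#' @export
linguistic_variable <- function(name, unit, terms) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!length(terms) || !all(vapply(terms, inherits, logical(1), "membership_function")))
    stop("`terms` must be a non-empty list of membership functions")
  labels <- vapply(terms, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate term labels in variable '", name, "': ",
         paste(labels[duplicated(labels)], collapse = ", "))
  names(terms) <- labels
  structure(list(name = name, unit = unit, terms = terms),
            class = "linguistic_variable")
}

#' @export
print.linguistic_variable <- function(x, ...) {
  cat(sprintf("<linguistic_variable> %s [%s]: {%s}\n", x$name, x$unit,
              paste(names(x$terms), collapse = ", ")))
  invisible(x)
}

#' Fuzzify a crisp value over all terms of a linguistic variable
#'
#' Returns one degree per term. No normalization is imposed: the shipped
#' membership functions are not a partition of unity (for example the attack
#' count 4 belongs to "low" with degree 1/3 and to "moderate" with degree
#' 1/2).
#'
#' @param var A [linguistic_variable()].
#' @param x A single finite crisp value.
#' @return Named numeric vector of degrees, one per term, each in `[0, 1]`.
#' @export
fuzzify <- function(var, x) {
  stopifnot(inherits(var, "linguistic_variable"),
            is.numeric(x), length(x) == 1L, is.finite(x))
  vapply(var$terms, eval_membership, numeric(1), x = x)
}
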