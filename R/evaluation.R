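# Diagnostic-test evaluation: multi-class agreement tables, per-class
# binary collapse, sensitivity/specificity-family metrics, and Cohen's
# kappa with asymptotic standard errors.

#' Construct a confusion (agreement) matrix
#'
#' Orientation is fixed: rows are the evaluated method's predictions,
#' columns the gold standard. Prediction labels outside the gold classes
#' (typically `"others"`, the engine's non-diagnosis) get their own rows
#' with no diagonal.
#'
#' @param counts Integer matrix of counts with row names (predicted) and
#'   column names (gold).
#' @return Object of class `confusion_matrix` (an integer matrix).
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry predicted (row) and gold (column) labels")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) <= 0) stop("confusion matrix must have a positive total")
  storage.mode(counts) <- "integer"
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = predicted, columns = gold standard\n")
  print(unclass(x))
  invisible(x)
}

#' Cross-tabulate predicted against gold labels
#'
#' @param pred Character vector of predicted labels.
#' @param gold Character vector of gold-standard labels, same length.
#' @param classes Gold-standard class order; defaults to the sorted unique
#'   gold labels. Predicted labels outside `classes` become extra rows;
#'   gold labels outside `classes` are an error.
#' @return A [confusion_matrix()].
#' @export
build_confusion <- function(pred, gold, classes = NULL) {
  pred <- as.character(pred); gold <- as.character(gold)
  if (!length(pred) || length(pred) != length(gold))
    stop("`pred` and `gold` must be non-empty vectors of equal length")
  if (is.null(classes)) classes <- sort(unique(gold))
  bad <- setdiff(gold, classes)
  if (length(bad))
    stop("gold label(s) outside `classes`: ", paste(unique(bad), collapse = ", "))
  rows <- c(classes, setdiff(unique(pred), classes))
  tab <- unclass(table(factor(pred, levels = rows),
                       factor(gold, levels = classes)))
  names(dimnames(tab)) <- NULL
  confusion_matrix(tab)
}

#' Collapse a multi-class agreement table to 2x2 for one class
#'
#' The positive class keeps its own row/column; every other prediction
#' (including `"others"`) counts as negative, every other gold label as
#' disease-absent.
#'
#' @param m A [confusion_matrix()].
#' @param positive_class One of `colnames(m)`.
#' @return A 2x2 `confusion_matrix` with labels `positive`/`negative`.
#' @export
binary_collapse <- function(m, positive_class) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (!positive_class %in% colnames(m))
    stop("'", positive_class, "' is not a gold class of the matrix")
  pos_row <- rownames(m) == positive_class
  pos_col <- colnames(m) == positive_class
  tp <- sum(m[pos_row, pos_col])
  fp <- sum(m[pos_row, !pos_col])
  fn <- sum(m[!pos_row, pos_col])
  tn <- sum(m[!pos_row, !pos_col])
  out <- matrix(c(tp, fn, fp, tn), nrow = 2,
                dimnames = list(c("positive", "negative"),
                                c("positive", "negative")))
  confusion_matrix(out)
}

.ci_prop <- function(x, n, method, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  if (method == "clopper-pearson") {
    as.numeric(stats::binom.test(x, n, conf.level = conf)$conf.int)
  } else {
    as.numeric(stats::prop.test(x, n, conf.level = conf,
                                correct = FALSE)$conf.int)
  }
}

#' Diagnostic-test metrics from a 2x2 table
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive values, Youden index
#' (`sensitivity + specificity - 1`), total consistency rate
#' `(TP+TN)/N`, mistaken-diagnosis rate (`1 - specificity`, the false
#' positive rate) and omission-diagnosis rate (`1 - sensitivity`, the false
#' negative rate). Proportions carry two-sided confidence intervals,
#' Clopper-Pearson exact by default or Wilson score.
#'
#' @param b A 2x2 [confusion_matrix()] (see [binary_collapse()]).
#' @param ci_method `"clopper-pearson"` or `"wilson"`.
#' @param conf Confidence level, default 0.95.
#' @return Object of class `diagnostic_metrics`: a data.frame with one row
#'   per metric (`estimate`, `lower`, `upper`). Ratios with a zero
#'   denominator are `NA` (undefined), never 0.
#' @export
diagnostic_metrics <- function(b, ci_method = c("clopper-pearson", "wilson"),
                               conf = 0.95) {
  stopifnot(inherits(b, "confusion_matrix"), all(dim(b) == c(2, 2)))
  ci_method <- match.arg(ci_method)
  tp <- b[1, 1]; fp <- b[1, 2]; fn <- b[2, 1]; tn <- b[2, 2]
  n <- tp + fp + fn + tn
  ratio <- function(x, d) if (d == 0) NA_real_ else x / d
  sens <- ratio(tp, tp + fn); spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp); npv <- ratio(tn, tn + fn)
  prop_rows <- list(
    sensitivity = c(tp, tp + fn), specificity = c(tn, tn + fp),
    ppv = c(tp, tp + fp), npv = c(tn, tn + fn),
    consistency = c(tp + tn, n))
  rows <- lapply(names(prop_rows), function(nm) {
    xn <- prop_rows[[nm]]
    est <- ratio(xn[1], xn[2])
    ci <- if (is.na(est)) c(NA_real_, NA_real_)
          else .ci_prop(xn[1], xn[2], ci_method, conf)
    data.frame(metric = nm, estimate = est, lower = ci[1], upper = ci[2])
  })
  extra <- data.frame(
    metric = c("youden", "mistake_rate", "omission_rate"),
    estimate = c(sens + spec - 1, 1 - spec, 1 - sens),
    lower = NA_real_, upper = NA_real_)
  out <- rbind(do.call(rbind, rows), extra)
  rownames(out) <- out$metric
  structure(out, class = c("diagnostic_metrics", "data.frame"),
            counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
            ci_method = ci_method, conf = conf)
}

#' @export
print.diagnostic_metrics <- function(x, digits = 2, ...) {
  cts <- attr(x, "counts")
  cat(sprintf("<diagnostic_metrics> TP=%d FP=%d FN=%d TN=%d (%s CI)\n",
              cts["tp"], cts["fp"], cts["fn"], cts["tn"], attr(x, "ci_method")))
  pct <- c("sensitivity", "specificity", "ppv", "npv", "consistency",
           "mistake_rate", "omission_rate")
  for (i in seq_len(nrow(x))) {
    m <- x$metric[i]
    if (m %in% pct) {
      cat(sprintf("  %-14s %6.2f%%", m, 100 * x$estimate[i]))
      if (!is.na(x$lower[i]))
        cat(sprintf("  (%.2f-%.2f)", 100 * x$lower[i], 100 * x$upper[i]))
      cat("\n")
    } else {
      cat(sprintf("  %-14s %.4f\n", m, x$estimate[i]))
    }
  }
  invisible(x)
}

#' Overall agreement of a multi-class table
#'
#' The fraction of cases on the diagonal over the gold classes; rows for
#' non-diagnosis predictions contribute no agreement.
#'
#' @param m A [confusion_matrix()].
#' @return Proportion in `[0, 1]`.
#' @export
overall_agreement <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  shared <- intersect(rownames(m), colnames(m))
  sum(vapply(shared, function(l) m[l, l], integer(1))) / sum(m)
}

#' Cohen's kappa with asymptotic standard errors
#'
#' Chance-corrected agreement `kappa = (P_A - P_e) / (1 - P_e)` where `P_A`
#' is the observed agreement and `P_e` the agreement expected from the
#' marginals. The reported standard error is the Fleiss-Cohen-Everitt
#' large-sample formula; the significance test uses the null
#' (`kappa = 0`) standard error. Interpretation bands: very good
#' (`>= 0.85`), good (`[0.6, 0.85)`), moderate (`[0.45, 0.6)`), poor
#' (`< 0.45`).
#'
#' @param m A square [confusion_matrix()] with matching row/column labels
#'   (collapse multi-class tables with [binary_collapse()] first).
#' @param conf Confidence level for the kappa interval.
#' @return Object of class `kappa_result`: list with `kappa`, `p_a`, `p_e`,
#'   `se` (large-sample), `se0` (null), `z`, `p_value`, `conf_int`, `n`,
#'   `interpretation`.
#' @export
cohen_kappa <- function(m, conf = 0.95) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m)))
    stop("kappa needs a square matrix with matching labels; ",
         "use binary_collapse() for per-class agreement")
  n <- sum(m)
  p <- m / n
  prow <- rowSums(p); pcol <- colSums(p)
  p_a <- sum(diag(p))
  p_e <- sum(prow * pcol)
  if (1 - p_e <= .Machine$double.eps)
    stop("degenerate marginals (expected agreement 1); kappa undefined")
  kappa <- (p_a - p_e) / (1 - p_e)

  # Fleiss, Cohen & Everitt large-sample variance
  k_idx <- seq_len(nrow(m))
  term1 <- sum(diag(p) * (1 - (prow + pcol) * (1 - kappa))^2)
  term2 <- (1 - kappa)^2 * sum(vapply(k_idx, function(i)
    sum(p[i, -i] * (pcol[-i] + prow[i])^2), numeric(1)))
  term3 <- (kappa - p_e * (1 - kappa))^2
  var_k <- (term1 + term2 - term3) / (n * (1 - p_e)^2)
  se <- sqrt(max(var_k, 0))

  # null (kappa = 0) variance for the significance test
  var0 <- (p_e + p_e^2 - sum(prow * pcol * (prow + pcol))) / (n * (1 - p_e)^2)
  se0 <- sqrt(max(var0, 0))
  z <- if (se0 > 0) kappa / se0 else NA_real_
  p_value <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  interpretation <- if (kappa >= 0.85) "very good"
    else if (kappa >= 0.6) "good"
    else if (kappa >= 0.45) "moderate"
    else "poor"
  structure(list(kappa = kappa, p_a = p_a, p_e = p_e, se = se, se0 = se0,
                 z = z, p_value = p_value,
                 conf_int = c(kappa - zq * se, kappa + zq * se),
                 n = n, interpretation = interpretation),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa = %.3f +/- %.3f (%s), p = %s\n",
              x$kappa, x$se, x$interpretation, format.pval(x$p_value)))
  cat(sprintf("  P_A = %.4f, P_e = %.4f, n = %d\n", x$p_a, x$p_e, x$n))
  invisible(x)
}

#' Per-class metric and kappa tables for a multi-class agreement matrix
#'
#' Collapses the table on each gold class in turn and tabulates the
#' diagnostic metrics (`metrics_table()`) or Cohen's kappa
#' (`kappa_table()`), mirroring the per-diagnosis layout of validation-study
#' reports.
#'
#' @param m A [confusion_matrix()].
#' @param classes Gold classes to evaluate; defaults to all columns.
#' @param ... Passed to [diagnostic_metrics()] or [cohen_kappa()].
#' @return A data.frame: metrics (rows) by class (columns) for
#'   `metrics_table()`; one row per class for `kappa_table()`.
#' @export
metrics_table <- function(m, classes = colnames(m), ...) {
  cols <- lapply(classes, function(cl) {
    dm <- diagnostic_metrics(binary_collapse(m, cl), ...)
    stats::setNames(dm$estimate, dm$metric)
  })
  out <- as.data.frame(cols, col.names = classes, check.names = FALSE)
  out
}

#' @rdname metrics_table
#' @export
kappa_table <- function(m, classes = colnames(m), ...) {
  rows <- lapply(classes, function(cl) {
    k <- cohen_kappa(binary_collapse(m, cl), ...)
    data.frame(class = cl, kappa = k$kappa, se = k$se, z = k$z,
               p_value = k$p_value, interpretation = k$interpretation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read and write confusion-matrix CSV files
#'
#' The format is a square or rectangular labeled table: header row of gold
#' classes, first column of predicted labels.
#'
#' @param path CSV path.
#' @return `read_confusion_csv()`: a [confusion_matrix()].
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  confusion_matrix(m)
}

#' @rdname read_confusion_csv
#' @param m A [confusion_matrix()].
#' @export
write_confusion_csv <- function(m, path) {
  stopifnot(inherits(m, "confusion_matrix"))
  df <- data.frame(predicted = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published validation-study agreement tables
#'
#' The agreement tables between the CDSS diagnoses and the headache expert
#' group's gold standard from the engine's validation studies: a
#' retrospective study (n = 325; both the hierarchical fuzzy engine and the
#' crisp rule-based engine) and a prospective study (n = 380; fuzzy engine).
#' Shipped as plain-text CSV under `extdata`.
#'
#' @param study `"retrospective"` or `"prospective"`.
#' @param method `"fuzzy"` or `"rule_based"` (rule_based exists only for
#'   the retrospective study).
#' @return A [confusion_matrix()] with rows MO/TTH/PM/PTTH/Others and
#'   columns MO/TTH/PM/PTTH.
#' @export
validation_confusion <- function(study = c("retrospective", "prospective"),
                                 method = c("fuzzy", "rule_based")) {
  study <- match.arg(study)
  method <- match.arg(method)
  if (study == "prospective" && method == "rule_based")
    stop("no rule-based agreement table exists for the prospective study")
  file <- sprintf("agreement_%s_%s.csv", study, method)
  read_confusion_csv(system.file("extdata", file, package = "fuzzyichd",
                                 mustWork = TRUE))
}
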