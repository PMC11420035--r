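#' A single patient's headache feature vector
#'
#' The engine's input record. Numeric features are the attack count over the
#' recall window, the attack duration in hours (a range; give equal bounds
#' for a single value) and pain intensity on the 0-10 visual analogue scale.
#' Categorical features are the headache location, quality, aggravation by
#' routine physical activity and the four accompanying symptoms.
#'
#' @param number_of_attacks Nonnegative count of attacks as reported.
#' @param duration_low,duration_high Attack duration bounds in hours,
#'   `0 < duration_low <= duration_high`. `duration_high` defaults to
#'   `duration_low`.
#' @param intensity_vas Pain intensity, VAS 0-10.
#' @param location `"unilateral"` or `"bilateral"`.
#' @param quality `"pulsating"`, `"non-pulsating"` or `"other"`.
#' @param aggravation_by_activity,nausea,vomiting,photophobia,phonophobia
#'   `"yes"`/`"no"` (logicals also accepted).
#' @param age,sex Optional free metadata (not used by the engine).
#' @param gold_label Optional expert diagnosis (`"MO"`, `"PM"`, `"TTH"`,
#'   `"PTTH"` or `"others"`) carried along for evaluation.
#' @return Object of class `patient_case`.
#' @examples
#' worked_case_1()
#' @export
patient_case <- function(number_of_attacks, duration_low,
                         duration_high = duration_low, intensity_vas,
                         location, quality, aggravation_by_activity,
                         nausea, vomiting, photophobia, phonophobia,
                         age = NA, sex = NA_character_,
                         gold_label = NA_character_) {
  yn <- function(x, what) {
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    x <- as.character(x)
    if (!x %in% c("yes", "no"))
      stop("`", what, "` must be yes/no, got '", x, "'")
    x
  }
  number_of_attacks <- as.numeric(number_of_attacks)
  duration_low <- as.numeric(duration_low)
  duration_high <- as.numeric(duration_high)
  intensity_vas <- as.numeric(intensity_vas)
  if (is.na(number_of_attacks) || number_of_attacks < 0)
    stop("`number_of_attacks` must be a nonnegative count")
  if (is.na(duration_low) || is.na(duration_high) || duration_low <= 0 ||
      duration_low > duration_high)
    stop("durations must satisfy 0 < duration_low <= duration_high")
  if (is.na(intensity_vas) || intensity_vas < 0 || intensity_vas > 10)
    stop("`intensity_vas` must lie in [0, 10]")
  location <- match.arg(location, c("unilateral", "bilateral"))
  quality <- match.arg(quality, c("pulsating", "non-pulsating", "other"))
  structure(list(
    number_of_attacks = number_of_attacks,
    duration_low = duration_low, duration_high = duration_high,
    intensity_vas = intensity_vas, location = location, quality = quality,
    aggravation_by_activity = yn(aggravation_by_activity, "aggravation_by_activity"),
    nausea = yn(nausea, "nausea"), vomiting = yn(vomiting, "vomiting"),
    photophobia = yn(photophobia, "photophobia"),
    phonophobia = yn(phonophobia, "phonophobia"),
    age = age, sex = sex, gold_label = gold_label
  ), class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  dur <- if (x$duration_low == x$duration_high) sprintf("%g h", x$duration_low)
         else sprintf("%g-%g h", x$duration_low, x$duration_high)
  cat(sprintf("<patient_case> %g attacks, %s, VAS %g, %s, %s\n",
              x$number_of_attacks, dur, x$intensity_vas, x$location, x$quality))
  acc <- c("aggravation_by_activity", "nausea", "vomiting", "photophobia",
           "phonophobia")
  present <- acc[vapply(x[acc], identical, logical(1), "yes")]
  cat("  yes:", if (length(present)) paste(present, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

.case_fields <- c("number_of_attacks", "duration_low", "duration_high",
                  "intensity_vas", "location", "quality",
                  "aggravation_by_activity", "nausea", "vomiting",
                  "photophobia", "phonophobia", "age", "sex", "gold_label")

#' Coerce a named list or one-row data.frame to a patient case
#'
#' @param x Named list or one-row data.frame with `patient_case` fields;
#'   `duration_high`, `age`, `sex`, `gold_label` are optional.
#' @return A [patient_case()].
#' @export
as_patient_case <- function(x) {
  if (inherits(x, "patient_case")) return(x)
  if (is.data.frame(x)) x <- as.list(x[1, , drop = FALSE])
  req <- setdiff(.case_fields, c("duration_high", "age", "sex", "gold_label"))
  missing <- setdiff(req, names(x)[!vapply(x, function(v) all(is.na(v)), logical(1))])
  if (length(missing))
    stop("incomplete case: missing field(s) ", paste(missing, collapse = ", "))
  do.call(patient_case, x[intersect(.case_fields, names(x))])
}

#' Convert between case lists and data frames
#'
#' @param cases List of [patient_case()] objects.
#' @return `cases_to_df()`: a data.frame with one row per case;
#'   `cases_from_df()`: a list of `patient_case`.
#' @export
cases_to_df <- function(cases) {
  if (inherits(cases, "patient_case")) cases <- list(cases)
  do.call(rbind, lapply(cases, function(cs)
    as.data.frame(cs[.case_fields], stringsAsFactors = FALSE)))
}

#' @rdname cases_to_df
#' @param df A data.frame with one row per case.
#' @export
cases_from_df <- function(df) {
  lapply(seq_len(nrow(df)), function(i) as_patient_case(df[i, , drop = FALSE]))
}

#' Read and write case batch files
#'
#' JSON batches are arrays of case objects; CSV batches have one row per
#' case with a mandatory header, `"yes"`/`"no"` literals for binary fields
#' and durations in hours. An optional `gold_label` column carries the
#' expert diagnosis.
#'
#' @param path File path; format inferred from the `.json`/`.csv` extension
#'   unless `format` is given.
#' @param format `"json"` or `"csv"`.
#' @return `read_cases()`: list of [patient_case()]. `write_cases()`:
#'   `path`, invisibly.
#' @export
read_cases <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- if (format == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (!is.data.frame(df) || !nrow(df)) stop("no cases found in ", path)
  cases_from_df(df)
}

#' @rdname read_cases
#' @param cases List of [patient_case()] (or a single case, or a data.frame).
#' @export
write_cases <- function(cases, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- if (is.data.frame(cases)) cases else cases_to_df(cases)
  if (format == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
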