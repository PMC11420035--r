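# Seedable synthetic patient-cohort generator. Features are sampled
# independently from the marginal summaries reported for the two validation
# cohorts (no joint distribution is published), plus archetype presets that
# impose the criterion structure by construction.

# inverse-CDF truncated normal (vectorized)
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# closed-form mean of the truncated normal (test oracle for marginals)
.truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd; b <- (upper - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Specification of a synthetic patient cohort
#'
#' Per-feature marginal distribution parameters: continuous features are
#' truncated normal (age, duration in hours, VAS intensity), the attack
#' count is drawn from three bins (below 5 / 6-9 / 10 or more, matching the
#' reported cohort breakdown) uniformly within each bin, and categorical
#' features are Bernoulli/multinomial.
#'
#' @param n Cohort size (`> 0`).
#' @param seed Integer seed; identical specs generate identical cohorts.
#' @param p_female Proportion of female patients.
#' @param age_mean,age_sd Age distribution (years), truncated to `[14, 90]`.
#' @param duration_mean,duration_sd Attack duration (hours), truncated
#'   below at one minute.
#' @param attack_bin_probs Probabilities of the three attack-count bins;
#'   must sum to 1.
#' @param attack_bin_ranges List of three integer ranges `c(min, max)`
#'   sampled uniformly within each bin.
#' @param p_unilateral Proportion with unilateral location.
#' @param quality_probs Named probabilities for
#'   pulsating/non-pulsating/other; must sum to 1.
#' @param vas_mean,vas_sd VAS intensity, truncated to `[0, 10]`.
#' @param p_nausea,p_vomiting,p_photophobia,p_phonophobia
#'   Accompanying-symptom prevalences.
#' @return Object of class `cohort_spec`.
#' @seealso [cohort_preset()], [generate_cohort()]
#' @export
cohort_spec <- function(n, seed,
                        p_female = 0.665,
                        age_mean = 38.7, age_sd = 12.7,
                        duration_mean = 17.0, duration_sd = 28.2,
                        attack_bin_probs = c(0.068, 0.064, 0.868),
                        attack_bin_ranges = list(c(1, 4), c(6, 9), c(10, 60)),
                        p_unilateral = 0.28,
                        quality_probs = c(pulsating = 0.529,
                                          `non-pulsating` = 0.437,
                                          other = 0.034),
                        vas_mean = 6.0, vas_sd = 1.8,
                        p_nausea = 0.338, p_vomiting = 0.169,
                        p_photophobia = 0.268, p_phonophobia = 0.311) {
  check_prob <- function(p, what) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
      stop("`", what, "` must lie in [0, 1]")
  }
  if (!is.numeric(n) || n < 1) stop("`n` must be a positive cohort size")
  if (!is.numeric(seed) || length(seed) != 1L) stop("`seed` must be an integer")
  for (w in c("p_female", "p_unilateral", "p_nausea", "p_vomiting",
              "p_photophobia", "p_phonophobia"))
    check_prob(get(w), w)
  check_prob(attack_bin_probs, "attack_bin_probs")
  if (abs(sum(attack_bin_probs) - 1) > 1e-6)
    stop("`attack_bin_probs` must sum to 1")
  if (abs(sum(quality_probs) - 1) > 1e-6)
    stop("`quality_probs` must sum to 1")
  if (any(c(age_sd, duration_sd, vas_sd) <= 0))
    stop("standard deviations must be positive")
  if (length(attack_bin_ranges) != length(attack_bin_probs))
    stop("`attack_bin_ranges` must match `attack_bin_probs` in length")
  structure(as.list(environment())[c(
    "n", "seed", "p_female", "age_mean", "age_sd", "duration_mean",
    "duration_sd", "attack_bin_probs", "attack_bin_ranges", "p_unilateral",
    "quality_probs", "vas_mean", "vas_sd", "p_nausea", "p_vomiting",
    "p_photophobia", "p_phonophobia")], class = "cohort_spec")
}

#' Ready-made cohort specifications
#'
#' `"retrospective"` and `"prospective"` mirror the marginal feature
#' summaries of the two validation cohorts. `"typical_mo"` and
#' `"typical_tth"` are class-conditional archetypes whose draws satisfy
#' every definite criterion of the respective diagnosis by construction
#' (used for engine smoke properties).
#'
#' @param preset Preset name.
#' @param n Cohort size (defaults to the study size for the two study
#'   presets, 100 otherwise).
#' @param seed Integer seed.
#' @return A `cohort_spec` with an attribute `preset`.
#' @export
cohort_preset <- function(preset = c("retrospective", "prospective",
                                     "typical_mo", "typical_tth"),
                          n = NULL, seed = 1) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    retrospective = cohort_spec(n %||% 325, seed),
    prospective = cohort_spec(
      n %||% 380, seed, p_female = 0.774, age_mean = 39.6, age_sd = 12.3,
      duration_mean = 24.3, duration_sd = 27.1,
      attack_bin_probs = c(0.047, 0.089, 0.864),
      p_unilateral = 0.468,
      quality_probs = c(pulsating = 0.605, `non-pulsating` = 0.361,
                        other = 0.034),
      vas_mean = 6.4, vas_sd = 1.5, p_nausea = 0.471, p_vomiting = 0.508,
      p_photophobia = 0.489, p_phonophobia = 0.626),
    typical_mo = cohort_spec(
      n %||% 100, seed, attack_bin_probs = c(0, 0.5, 0.5),
      attack_bin_ranges = list(c(1, 4), c(6, 9), c(10, 30)),
      duration_mean = 20, duration_sd = 10,
      p_unilateral = 1,
      quality_probs = c(pulsating = 1, `non-pulsating` = 0, other = 0),
      vas_mean = 7, vas_sd = 1.5, p_nausea = 1),
    typical_tth = cohort_spec(
      n %||% 100, seed, attack_bin_probs = c(0, 0, 1),
      attack_bin_ranges = list(c(1, 4), c(6, 9), c(10, 60)),
      duration_mean = 30, duration_sd = 30,
      p_unilateral = 0,
      quality_probs = c(pulsating = 0, `non-pulsating` = 1, other = 0),
      vas_mean = 4, vas_sd = 1, p_nausea = 0, p_vomiting = 0,
      p_photophobia = 0, p_phonophobia = 0))
  attr(spec, "preset") <- preset
  spec
}

#' Generate a synthetic cohort
#'
#' Draws exactly `spec$n` cases, reproducibly for a given seed. Continuous
#' draws are truncated to the field invariants (durations positive, VAS in
#' 0-10). Archetype presets additionally clamp the features that the
#' definite criteria constrain (attack durations inside the criterion-B
#' window; archetype-specific categorical features are degenerate in the
#' spec itself).
#'
#' @param spec A [cohort_spec()].
#' @return List of [patient_case()] with the spec attached as attribute
#'   `"spec"`; convert with [cases_to_df()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  preset <- attr(spec, "preset") %||% "custom"
  withr::with_seed(as.integer(spec$seed), {
    n <- spec$n
    sex <- ifelse(stats::runif(n) < spec$p_female, "female", "male")
    age <- round(.rtruncnorm(n, spec$age_mean, spec$age_sd, 14, 90))
    bins <- sample.int(length(spec$attack_bin_probs), n, replace = TRUE,
                       prob = spec$attack_bin_probs)
    attacks <- vapply(bins, function(b) {
      r <- spec$attack_bin_ranges[[b]]
      r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1
    }, numeric(1))
    dur_lo <- if (preset == "typical_mo") 4 else if (preset == "typical_tth") 0.5 else 1 / 60
    dur_hi <- if (preset == "typical_mo") 72 else if (preset == "typical_tth") 168 else Inf
    duration <- .rtruncnorm(n, spec$duration_mean, spec$duration_sd,
                            dur_lo, dur_hi)
    location <- ifelse(stats::runif(n) < spec$p_unilateral,
                       "unilateral", "bilateral")
    quality <- sample(names(spec$quality_probs), n, replace = TRUE,
                      prob = spec$quality_probs)
    vas <- .rtruncnorm(n, spec$vas_mean, spec$vas_sd, 0, 10)
    aggr <- if (preset == "typical_tth") rep("no", n)
            else if (preset == "typical_mo") rep("yes", n)
            else ifelse(stats::runif(n) < 0.465, "yes", "no")
    draw_yn <- function(p) ifelse(stats::runif(n) < p, "yes", "no")
    nausea <- draw_yn(spec$p_nausea)
    vomiting <- draw_yn(spec$p_vomiting)
    photo <- draw_yn(spec$p_photophobia)
    phono <- draw_yn(spec$p_phonophobia)
    cases <- lapply(seq_len(n), function(i) patient_case(
      number_of_attacks = attacks[i],
      duration_low = duration[i], intensity_vas = vas[i],
      location = location[i], quality = quality[i],
      aggravation_by_activity = aggr[i], nausea = nausea[i],
      vomiting = vomiting[i], photophobia = photo[i],
      phonophobia = phono[i], age = age[i], sex = sex[i]))
    attr(cases, "spec") <- spec
    cases
  })
}

#' The two worked single-patient cases
#'
#' Reconstructions of the two published case studies. Case 1: four attacks
#' over the recall window, each lasting 2 h to half a day, unilateral,
#' pulsating, mild-to-moderate pain (encoded VAS 3.5, the mild/moderate
#' crossover), aggravated by activity, with nausea and vomiting. Case 2:
#' three attacks of about 20 minutes, bilateral, non-pulsating, VAS 3, no
#' aggravation, no accompanying symptoms.
#'
#' @return A [patient_case()].
#' @export
worked_case_1 <- function() {
  patient_case(number_of_attacks = 4, duration_low = 2, duration_high = 12,
               intensity_vas = 3.5, location = "unilateral",
               quality = "pulsating", aggravation_by_activity = "yes",
               nausea = "yes", vomiting = "yes", photophobia = "no",
               phonophobia = "no", gold_label = "PM")
}

#' @rdname worked_case_1
#' @export
worked_case_2 <- function() {
  patient_case(number_of_attacks = 3, duration_low = 1 / 3,
               intensity_vas = 3, location = "bilateral",
               quality = "non-pulsating", aggravation_by_activity = "no",
               nausea = "no", vomiting = "no", photophobia = "no",
               phonophobia = "no", gold_label = "PTTH")
}

#' Deterministic boundary-case suite
#'
#' Cases at and adjacent to every membership breakpoint: attack counts 3-11
#' around the 5 and 10 boundaries, durations around 0.5, 4, 72 and 168 h,
#' and VAS values at each intensity band boundary, plus the two worked
#' cases. Useful for exercising the fuzzy boundaries without clinical data.
#'
#' @return Named list of [patient_case()].
#' @export
generate_boundary_cases <- function() {
  cases <- list(case1 = worked_case_1(), case2 = worked_case_2())
  mo_like <- function(attacks, dur) patient_case(
    number_of_attacks = attacks, duration_low = dur, intensity_vas = 7,
    location = "unilateral", quality = "pulsating",
    aggravation_by_activity = "yes", nausea = "yes", vomiting = "no",
    photophobia = "no", phonophobia = "no")
  tth_like <- function(attacks, dur) patient_case(
    number_of_attacks = attacks, duration_low = dur, intensity_vas = 3,
    location = "bilateral", quality = "non-pulsating",
    aggravation_by_activity = "no", nausea = "no", vomiting = "no",
    photophobia = "no", phonophobia = "no")
  for (a in c(3, 4, 5, 9, 10, 11)) {
    cases[[sprintf("mo_attacks_%g", a)]] <- mo_like(a, 10)
    cases[[sprintf("tth_attacks_%g", a)]] <- tth_like(a, 10)
  }
  for (d in c(0.4, 0.5, 3, 4, 72, 80, 168, 200)) {
    cases[[sprintf("mo_duration_%g", d)]] <- mo_like(6, d)
    cases[[sprintf("tth_duration_%g", d)]] <- tth_like(12, d)
  }
  for (v in c(3, 3.5, 4, 6, 6.5, 7)) {
    cases[[sprintf("vas_%g", v)]] <- patient_case(
      number_of_attacks = 6, duration_low = 10, intensity_vas = v,
      location = "bilateral", quality = "pulsating",
      aggravation_by_activity = "yes", nausea = "yes", vomiting = "no",
      photophobia = "no", phonophobia = "no")
  }
  cases
}
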