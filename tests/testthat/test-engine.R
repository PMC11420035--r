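# ICHD-3 criterion evaluators and the three diagnostic stages.

cfg <- default_config()

test_that("migraine criterion D follows the accompanying-symptom rule", {
  base <- worked_case_1() # nausea + vomiting, no photo/phonophobia
  expect_true(evaluate_criterion_D_migraine(base)$fulfilled)
  none <- worked_case_2() # everything "no"
  expect_false(evaluate_criterion_D_migraine(none)$fulfilled)
  photo_only <- patient_case(6, 10, , 7, "unilateral", "pulsating", "yes",
                             nausea = "no", vomiting = "no",
                             photophobia = "yes", phonophobia = "no")
  expect_false(evaluate_criterion_D_migraine(photo_only)$fulfilled)
  both <- patient_case(6, 10, , 7, "unilateral", "pulsating", "yes",
                       nausea = "no", vomiting = "no",
                       photophobia = "yes", phonophobia = "yes")
  expect_true(evaluate_criterion_D_migraine(both)$fulfilled)
})

test_that("TTH criterion D excludes migrainous accompaniments but allows one photo/phono", {
  expect_true(evaluate_criterion_D_tth(worked_case_2())$fulfilled)
  expect_false(evaluate_criterion_D_tth(worked_case_1())$fulfilled) # nausea
  one_of_two <- patient_case(12, 10, , 3, "bilateral", "non-pulsating", "no",
                             nausea = "no", vomiting = "no",
                             photophobia = "yes", phonophobia = "no")
  expect_true(evaluate_criterion_D_tth(one_of_two)$fulfilled)
})

test_that("fuzzy criterion C counts pain characteristics with fuzzified intensity", {
  mk <- function(vas, loc = "bilateral", qual = "non-pulsating", aggr = "yes")
    patient_case(6, 10, , vas, loc, qual, aggr, "no", "no", "no", "no")
  # bilateral, non-pulsating, aggravation: migraine needs intensity to decide
  expect_equal(evaluate_criterion_C_migraine(mk(2))$degree, 0)   # fully mild: unfit
  expect_equal(evaluate_criterion_C_migraine(mk(5))$degree, 1)   # fully moderate: fit
  # unilateral + pulsating + aggravation: >= 2 characteristics at any intensity
  for (vas in c(0, 2, 3.5, 5, 8, 10)) {
    out <- evaluate_criterion_C_migraine(mk(vas, "unilateral", "pulsating"))
    expect_equal(out$degree, 1)
    expect_true(out$fulfilled)
  }
})

test_that("TTH criterion C mirrors the migraine subsystem with its own set", {
  expect_equal(evaluate_criterion_C_tth(worked_case_2())$degree, 1)
  worst <- patient_case(6, 10, , 8, "unilateral", "pulsating", "yes",
                        "no", "no", "no", "no")
  expect_equal(evaluate_criterion_C_tth(worst)$degree, 0) # 0 of 4
  # bilateral + pulsating on an intensity boundary: degree strictly inside (0,1)
  boundary <- patient_case(6, 10, , 6.5, "bilateral", "pulsating", "yes",
                           "no", "no", "no", "no")
  d <- evaluate_criterion_C_tth(boundary)$degree
  expect_gt(d, 0); expect_lt(d, 1)
})

test_that("the crisp backbone applies the definite and probable criteria", {
  # worked case 1 fulfils no criterion set (A and B fail for migraine)
  rb1 <- rule_based_diagnose(worked_case_1(), cfg)
  expect_identical(rb1$label, "others")
  expect_false(any(rb1$criteria$migraine[c("A", "B")]))
  # worked case 2: TTH criteria A and B both fail
  rb2 <- rule_based_diagnose(worked_case_2(), cfg)
  expect_false(rb2$criteria$tension_type[["A"]])
  expect_false(rb2$criteria$tension_type[["B"]])
  expect_identical(rb2$label, "others")
  # textbook migraine without aura
  mo <- patient_case(6, 10, , 7, "unilateral", "pulsating", "yes",
                     nausea = "yes", vomiting = "no", photophobia = "no",
                     phonophobia = "no")
  expect_identical(rule_based_diagnose(mo, cfg)$label, "MO")
  # single failed criterion gives the probable diagnosis
  pm <- patient_case(6, 10, , 7, "unilateral", "pulsating", "yes",
                     nausea = "no", vomiting = "no", photophobia = "no",
                     phonophobia = "no") # only D fails
  expect_identical(rule_based_diagnose(pm, cfg)$label, "PM")
  tth <- patient_case(12, 10, , 3, "bilateral", "non-pulsating", "no",
                      "no", "no", "no", "no")
  expect_identical(rule_based_diagnose(tth, cfg)$label, "TTH")
})

test_that("worked case 1 reproduces end-to-end: activations, scores, label", {
  d <- fuzzy_diagnose(worked_case_1(), cfg)
  expect_identical(d$label, "PM")
  expect_equal(round(d$f_migraine, 4), 0.9375)
  expect_equal(round(d$f_tth, 4), 0)
  # the printed per-term activations of the migraine output
  tr <- d$trace[d$trace$output == "migraine", ]
  alpha <- vapply(c("definite", "probable", "others"),
                  function(t) sum(tr$activation[tr$term == t]), numeric(1))
  expect_equal(round(unname(alpha), 4), c(0.25, 0.75, 0.3333))
  # and the tension-type output collects everything under "others"
  tr2 <- d$trace[d$trace$output == "tension_type", ]
  expect_equal(round(sum(tr2$activation[tr2$term == "others"]), 5), 1.33333)
  expect_equal(sum(tr2$activation[tr2$term != "others"]), 0)
  expect_identical(hybrid_diagnose(worked_case_1(), cfg)$label, "PM")
  expect_identical(hybrid_diagnose(worked_case_1(), cfg)$stage, "fuzzy")
})

test_that("worked case 2 is labelled probable tension-type headache", {
  d <- fuzzy_diagnose(worked_case_2(), cfg)
  expect_identical(d$label, "PTTH")
  expect_equal(round(d$f_migraine, 4), 0)
  expect_gt(d$f_tth, 0.5) # closer to the probable constant than to others
  expect_identical(hybrid_diagnose(worked_case_2(), cfg)$label, "PTTH")
})

test_that("a saturated definite-migraine path defuzzifies to 2", {
  sat <- patient_case(10, 10, , 8, "unilateral", "pulsating", "yes",
                      nausea = "yes", vomiting = "yes", photophobia = "no",
                      phonophobia = "no")
  d <- fuzzy_diagnose(sat, cfg)
  expect_equal(d$f_migraine, 2)
  expect_identical(d$label, "MO")
})

test_that("definite diagnoses are never overridden by the fuzzy stage", {
  withr::with_seed(99, {
    for (i in 1:50) {
      case <- rand_definite_mo_case()
      d <- hybrid_diagnose(case, cfg)
      expect_identical(d$label, "MO")
      expect_identical(d$stage, "rule_based")
    }
  })
})

test_that("fuzzy results are exclusive, auditable and nearest-constant consistent", {
  consts <- cfg$output_constants$migraine
  withr::with_seed(123, {
    for (i in 1:60) {
      case <- rand_case()
      d <- suppressWarnings(fuzzy_diagnose(case, cfg))
      expect_length(d$label, 1)
      expect_true(d$label %in% c("MO", "PM", "TTH", "PTTH", "others"))
      expect_true(all(d$trace$activation >= 0))
      # re-aggregating the trace reproduces the defuzzified scores
      for (o in c("migraine", "tension_type")) {
        tr <- d$trace[d$trace$output == o, ]
        a <- vapply(names(consts), function(t)
          sum(tr$activation[tr$term == t]), numeric(1))
        f_re <- if (sum(a) > 0) sum(a * consts[names(a)]) / sum(a) else NA_real_
        f_ref <- if (o == "migraine") d$f_migraine else d$f_tth
        got <- if (is.na(f_re)) 0 else f_re
        if (!is.na(f_ref)) expect_equal(got, f_ref, tolerance = 1e-9)
      }
      # nearest-constant label mapping on the winning output
      if (d$label != "others" && !is.na(d$f_migraine)) {
        f <- if (d$label %in% c("MO", "PM")) d$f_migraine else d$f_tth
        const <- if (d$label %in% c("MO", "TTH")) 2 else 1
        other_consts <- setdiff(c(2, 1, 0), const)
        expect_true(all(abs(f - const) <= abs(f - other_consts) + 1e-12))
      }
    }
  })
})

test_that("incomplete cases report the missing field", {
  expect_error(as_patient_case(list(number_of_attacks = 4, duration_low = 2)),
               "missing field")
  expect_error(as_patient_case(list()), "incomplete case")
})

test_that("diagnose_batch runs each stage over data frames and case lists", {
  cases <- list(worked_case_1(), worked_case_2())
  res <- diagnose_batch(cases, cfg)
  expect_identical(res$label, c("PM", "PTTH"))
  expect_identical(res$gold_label, c("PM", "PTTH"))
  res_rb <- diagnose_batch(cases_to_df(cases), cfg, stage = "rule_based")
  expect_identical(res_rb$label, c("others", "others"))
})
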