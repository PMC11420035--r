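# Diagnostic-test statistics: confusion matrices, per-class collapse,
# metric identities, Cohen's kappa.

retro <- validation_confusion("retrospective", "fuzzy")

test_that("build_confusion cross-tabulates and round-trips the published table", {
  m <- build_confusion(c("MO", "TTH"), c("MO", "TTH"))
  expect_true(all(diag(unclass(m)) == 1) && sum(m) == 2)
  # regenerate the 325 retrospective pairs from the cell counts and rebuild
  pred <- rep(rownames(retro), times = rowSums(retro))
  gold <- unlist(lapply(rownames(retro), function(r)
    rep(colnames(retro), times = retro[r, ])))
  rebuilt <- build_confusion(pred, gold, classes = colnames(retro))
  expect_equal(unclass(rebuilt)[rownames(retro), ], unclass(retro))
  expect_error(build_confusion(character(), character()), "non-empty")
  expect_error(build_confusion("MO", "XX", classes = c("MO", "TTH")),
               "outside")
})

test_that("binary collapse recovers the per-class 2x2 cells", {
  mo <- binary_collapse(retro, "MO")
  expect_equal(as.vector(unclass(mo)), c(128, 3, 0, 194)) # TP FN FP TN
  pm <- binary_collapse(retro, "PM")
  expect_equal(as.vector(unclass(pm)), c(73, 7, 3, 242))
  diagm <- build_confusion(c("a", "b"), c("a", "b"))
  d2 <- binary_collapse(diagm, "a")
  expect_equal(d2["positive", "negative"] + d2["negative", "positive"], 0L)
})

test_that("diagnostic metrics match hand arithmetic and handle edge cases", {
  toy <- confusion_matrix(matrix(c(50, 10, 10, 30), 2,
                                 dimnames = list(c("positive", "negative"),
                                                 c("positive", "negative"))))
  dm <- diagnostic_metrics(toy)
  expect_equal(dm["sensitivity", "estimate"], 50 / 60)
  expect_equal(dm["specificity", "estimate"], 30 / 40)
  expect_equal(dm["youden", "estimate"], 50 / 60 + 30 / 40 - 1)
  perfect <- confusion_matrix(matrix(c(5, 0, 0, 5), 2,
                                     dimnames = list(c("p", "n"), c("p", "n"))))
  dmp <- diagnostic_metrics(perfect)
  expect_true(all(dmp[c("sensitivity", "specificity", "ppv", "npv",
                        "consistency"), "estimate"] == 1))
  # zero denominator: undefined, not zero
  nopos <- confusion_matrix(matrix(c(0, 0, 2, 8), 2,
                                   dimnames = list(c("p", "n"), c("p", "n"))))
  expect_true(is.na(diagnostic_metrics(nopos)["sensitivity", "estimate"]))
})

test_that("metric identities hold on random matrices", {
  withr::with_seed(5, {
    for (i in 1:1000) {
      b <- rand_confusion(2)
      dimnames(b) <- list(c("positive", "negative"), c("positive", "negative"))
      dm <- suppressWarnings(diagnostic_metrics(b))
      sens <- dm["sensitivity", "estimate"]; spec <- dm["specificity", "estimate"]
      if (!is.na(sens) && !is.na(spec))
        expect_equal(dm["youden", "estimate"], sens + spec - 1, tolerance = 1e-12)
      if (!is.na(spec))
        expect_equal(dm["mistake_rate", "estimate"], 1 - spec, tolerance = 1e-12)
      if (!is.na(sens))
        expect_equal(dm["omission_rate", "estimate"], 1 - sens, tolerance = 1e-12)
      est <- dm$estimate[!is.na(dm$estimate) & dm$metric != "youden"]
      expect_true(all(est >= 0 & est <= 1))
    }
  })
})

test_that("confidence intervals bracket the point estimate under both methods", {
  b <- binary_collapse(retro, "PM")
  for (method in c("clopper-pearson", "wilson")) {
    dm <- diagnostic_metrics(b, ci_method = method)
    prop <- dm[!is.na(dm$lower), ]
    expect_true(all(prop$lower <= prop$estimate & prop$estimate <= prop$upper))
    expect_true(all(prop$lower >= 0 & prop$upper <= 1))
  }
})

test_that("overall agreement counts the diagnosis-class diagonal", {
  expect_equal(overall_agreement(retro), 310 / 325)
  rule <- validation_confusion("retrospective", "rule_based")
  expect_equal(overall_agreement(rule), 293 / 325)
  diagm <- build_confusion(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(overall_agreement(diagm), 1)
})

test_that("Cohen's kappa matches hand evaluation and known fixed points", {
  toy <- confusion_matrix(matrix(c(50, 10, 10, 30), 2,
                                 dimnames = list(c("p", "n"), c("p", "n"))))
  expect_equal(cohen_kappa(toy)$kappa, 0.28 / 0.48, tolerance = 1e-12)
  perfect <- confusion_matrix(matrix(c(7, 0, 0, 3), 2,
                                     dimnames = list(c("p", "n"), c("p", "n"))))
  expect_equal(cohen_kappa(perfect)$kappa, 1)
  # counts proportional to independent marginals: kappa = 0
  indep <- confusion_matrix(matrix(c(8, 2, 32, 8), 2, byrow = TRUE,
                                   dimnames = list(c("p", "n"), c("p", "n"))))
  expect_equal(cohen_kappa(indep)$kappa, 0, tolerance = 1e-12)
  expect_error(cohen_kappa(retro), "square")
  degenerate <- confusion_matrix(matrix(c(4L, 0L, 0L, 0L), 2,
                                        dimnames = list(c("p", "n"), c("p", "n"))))
  expect_error(cohen_kappa(degenerate), "degenerate")
})

test_that("observed/expected agreement match a brute-force double loop", {
  withr::with_seed(17, {
    for (i in 1:1000) {
      m <- rand_confusion(sample(2:5, 1))
      k <- cohen_kappa(m)
      oracle <- brute_agreement(unclass(m))
      expect_equal(k$p_a, oracle$p_a, tolerance = 1e-12)
      expect_equal(k$p_e, oracle$p_e, tolerance = 1e-12)
      expect_gte(k$kappa, -1); expect_lte(k$kappa, 1)
      # invariance under scaling all counts by a positive integer
      k3 <- cohen_kappa(confusion_matrix(unclass(m) * 3L))
      expect_equal(k3$kappa, k$kappa, tolerance = 1e-12)
    }
  })
})

test_that("kappa equals 1 exactly when all off-diagonal counts vanish", {
  withr::with_seed(31, {
    for (i in 1:50) {
      m <- rand_confusion(3)
      k <- cohen_kappa(m)
      off <- sum(m) - sum(diag(unclass(m)))
      expect_identical(isTRUE(all.equal(k$kappa, 1)), off == 0L)
    }
  })
})

test_that("kappa interpretation bands follow the stated thresholds", {
  band <- function(tp, fn) {
    m <- confusion_matrix(matrix(c(tp, fn, fn, tp), 2,
                                 dimnames = list(c("p", "n"), c("p", "n"))))
    cohen_kappa(m)$interpretation
  }
  expect_identical(band(50, 1), "very good")
  expect_identical(band(50, 8), "good")
  expect_identical(band(50, 14), "moderate")
  expect_identical(band(50, 40), "poor")
})

test_that("per-class kappa table reproduces the published consistency values", {
  kt <- kappa_table(retro)
  kap <- stats::setNames(kt$kappa, kt$class)
  expect_equal(round(kap[["TTH"]], 3), 0.991)
  expect_equal(round(kap[["PM"]], 3), 0.916)
  expect_equal(round(kap[["PTTH"]], 3), 0.932)
  expect_true(all(kt$p_value < 0.001))
  expect_true(all(kt$interpretation == "very good"))
})
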