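test_that("confusion tables tabulate predictions and their accuracy", {
  truth <- rep(stage_levels(), each = 20)
  ct <- confusion_from_predictions(truth, truth)
  expect_equal(unclass(ct), diag(c(20L, 20L, 20L)), ignore_attr = TRUE)
  expect_equal(accuracy(ct), 1.0)
  ct1 <- confusion_from_predictions("CON", "TAD")
  expect_equal(unclass(ct1)["CON", "TAD"], 1L)
  expect_equal(sum(ct1), 1L)
  # accuracy equals the mean per-pair correctness on random inputs
  set.seed(12)
  for (rep in 1:10) {
    tr <- sample(stage_levels(), 30, replace = TRUE)
    pr <- sample(stage_levels(), 30, replace = TRUE)
    expect_equal(accuracy(confusion_from_predictions(tr, pr)), mean(tr == pr))
  }
  expect_error(confusion_from_predictions(character(0), character(0)),
               "non-empty")
})

test_that("two-class collapse merges MCI and TAD conserving totals", {
  truth <- rep(stage_levels(), each = 20)
  perfect <- collapse_two_class(confusion_from_predictions(truth, truth))
  expect_equal(unclass(perfect),
               matrix(c(20L, 0L, 0L, 40L), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(sum(unclass(perfect)["predisposed", ]), 40L)  # merged class size
  # empty off-diagonals stay empty; totals conserved on random tables
  set.seed(7)
  for (rep in 1:10) {
    tr <- sample(stage_levels(), 25, replace = TRUE)
    pr <- sample(stage_levels(), 25, replace = TRUE)
    ct <- confusion_from_predictions(tr, pr)
    t2 <- collapse_two_class(ct)
    expect_equal(sum(t2), sum(ct))
    expect_equal(unclass(t2)["non_disposed", "YES"],
                 sum(unclass(ct)["CON", c("MCI", "TAD")]))
  }
})

test_that("type II error and power reproduce the printed reference tables", {
  default <- type2_error_rate(default_diagnosis_table())
  expect_identical(default$rate, 0.33)
  expect_identical(default$power_percent, 67L)
  expect_equal(default$false_negatives, 20L)
  expect_equal(default$total, 60L)

  eek <- type2_error_rate(eeknn_cm10_low_table())
  expect_identical(eek$rate, 0.13)
  expect_identical(eek$power_percent, 87L)
  expect_equal(eek$false_negatives, 8L)

  expect_equal(eek$power_percent - default$power_percent, 20L)

  perfect <- two_class_table(20, 0, 0, 40)
  expect_equal(type2_error_rate(perfect)$rate, 0)
  expect_equal(type2_error_rate(perfect)$power_percent, 100L)
  expect_error(type2_error_rate(two_class_table(0, 0, 0, 0)), "empty")
})

test_that("type II rate is scale invariant and complements power", {
  set.seed(2)
  for (rep in 1:20) {
    cells <- sample(0:30, 4, replace = TRUE)
    if (sum(cells) == 0) cells[1] <- 1
    t1 <- do.call(two_class_table, as.list(cells))
    t3 <- do.call(two_class_table, as.list(cells * 3))
    r1 <- type2_error_rate(t1); r3 <- type2_error_rate(t3)
    expect_identical(r1$rate, r3$rate)
    # rounding slack only between power and rate
    expect_true((r1$power_percent + round(100 * r1$rate)) %in% 99:101)
  }
})

test_that("misclassification breakdown assigns error types per true stage", {
  tr <- c(rep("CON", 4), rep("MCI", 4), rep("TAD", 4))
  pr <- c("CON", "CON", "MCI", "TAD",    # CON: 2 correct, 2 false alarms
          "MCI", "CON", "TAD", "MCI",    # MCI: 2 correct, 1 missed, 1 up
          "TAD", "CON", "MCI", "TAD")    # TAD: 2 correct, 1 missed, 1 down
  ct <- confusion_from_predictions(tr, pr)
  bd <- misclassification_breakdown(ct)
  expect_equal(nrow(bd), 9L)
  pick <- function(t, p) bd$error_type[bd$true == t & bd$predicted == p]
  expect_equal(pick("CON", "MCI"), "type_I_style")
  expect_equal(pick("CON", "TAD"), "type_I_style")
  expect_equal(pick("TAD", "CON"), "type_II_style")
  expect_equal(pick("MCI", "CON"), "type_II_style")
  expect_equal(pick("MCI", "TAD"), "within_predisposed")
  expect_equal(pick("TAD", "MCI"), "within_predisposed")
  expect_equal(pick("CON", "CON"), "correct")
  # true CON strata can only hold type-I-style errors, true TAD only
  # type-II-style (plus within-predisposed confusions)
  expect_false("type_II_style" %in% bd$error_type[bd$true == "CON"])
  expect_false("type_I_style" %in% bd$error_type[bd$true == "TAD"])
  # stratum sums equal the confusion row sums
  for (s in stage_levels())
    expect_equal(sum(bd$count[bd$true == s]), sum(unclass(ct)[s, ]))
  expect_match(attr(bd, "convention"), "convention")
  # all-correct table has zero errors everywhere
  bd0 <- misclassification_breakdown(
    confusion_from_predictions(tr, tr))
  expect_true(all(bd0$count[bd0$error_type != "correct"] == 0))
})

test_that("fuzzy MCI assessment tracks the pull of the vote proportions", {
  all_tad <- fuzzy_mci_assess(rep("TAD", 10))
  expect_equal(all_tad$direction, "incipient_TAD")
  expect_equal(all_tad$score, 1.0)
  all_con <- fuzzy_mci_assess(rep("CON", 7))
  expect_equal(all_con$direction, "relapsing_CON")
  expect_equal(all_con$score, 1.0)
  # 30% CON / 40% MCI / 30% TAD balances to stable MCI at score 0.5
  votes <- c(rep("CON", 3), rep("MCI", 4), rep("TAD", 3))
  bal <- fuzzy_mci_assess(votes)
  expect_equal(bal$direction, "stable_MCI")
  expect_equal(bal$score, 0.5)
  # works directly on a classify_datapoint vote table
  co <- small_cohort(17, n_peaks = 12, per_stage = 4)
  res <- classify_datapoint(co$members$MCI[[1]], co,
                            classifier_config("mdc"))
  fz <- fuzzy_mci_assess(res$votes)
  expect_true(fz$direction %in% c("incipient_TAD", "relapsing_CON",
                                  "stable_MCI"))
  expect_gte(fz$score, 0); expect_lte(fz$score, 1)
  expect_error(fuzzy_mci_assess(character(0)), "empty")
})

test_that("counts are conserved through the full evaluation pipeline", {
  co <- generate_cohort(make_separability_presets(seed = 23,
                                                  n_peaks = 40)$high_energy)
  co$members <- lapply(co$members, function(ms) ms[1:6])   # trim for speed
  sp <- split_cohort(co, 0.7, seed = 23)
  res <- classify_cohort(sp$test, sp$train, classifier_config("mdc"))
  n_test <- nrow(res$predictions)
  ct <- confusion_from_predictions(res$predictions$stage,
                                   res$predictions$predicted)
  expect_equal(sum(ct), n_test)
  t2 <- collapse_two_class(ct)
  expect_equal(sum(t2), n_test)
  bd <- misclassification_breakdown(ct)
  expect_equal(sum(bd$count), n_test)
  expect_equal(accuracy(ct),
               mean(res$predictions$stage == res$predictions$predicted))
})
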