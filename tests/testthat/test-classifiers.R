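test_that("exponential-Euclidean distance follows its stated composition", {
  # identical vectors
  expect_equal(exp_euclidean_distance(1000, 1000, 5, 5), 0)
  # equal masses: reduces to |dI|
  expect_equal(exp_euclidean_distance(1000, 1000, 5, 2), 3)
  # unit mass gap, equal intensities: sqrt((e - 1)^2) = e - 1
  expect_equal(exp_euclidean_distance(1001, 1000, 1, 1), exp(1) - 1)
  # both candidate compositions against direct evaluation
  dm <- 0.8; di <- 1.7
  penalty <- (exp(dm^2) - 1)^2
  expect_equal(exp_euclidean_distance(10 + dm, 10, 3 + di, 3),
               sqrt(penalty + di^2))
  expect_equal(exp_euclidean_distance(10 + dm, 10, 3 + di, 3,
                                      square_mass_term = TRUE),
               sqrt(penalty^2 + di^2))
  # the compositions agree whenever masses match
  expect_equal(exp_euclidean_distance(7, 7, 9, 4, square_mass_term = TRUE),
               exp_euclidean_distance(7, 7, 9, 4))
  # overflow saturates to Inf instead of raising
  expect_equal(exp_euclidean_distance(2000, 1000, 1, 1), Inf)
  expect_equal(exp_euclidean_distance(1027, 1000, 0, 0), Inf)
})

test_that("both distances are symmetric, non-negative, and dominate |dI|", {
  set.seed(3)
  for (rep in 1:50) {
    ma <- runif(1, 1000, 1002); mb <- runif(1, 1000, 1002)
    ia <- rnorm(1, 10, 5); ib <- rnorm(1, 10, 5)
    dee <- exp_euclidean_distance(ma, mb, ia, ib)
    dman <- manhattan_distance(ma, mb, ia, ib)
    expect_equal(dee, exp_euclidean_distance(mb, ma, ib, ia))
    expect_equal(dman, manhattan_distance(mb, ma, ib, ia))
    expect_gte(dee, abs(ia - ib))           # mass penalty only adds
    if (ma != mb) expect_gt(dee, abs(ia - ib))
    expect_gte(dman, 0)
  }
  expect_equal(manhattan_distance(100, 101, 5, 7), 3)   # 1 + 2
  expect_equal(manhattan_distance(100, 100, 5, 5), 0)
})

test_that("per-vector EE-kNN votes match the hand-sorted neighbor rule", {
  leaf <- leaf_meta()
  train <- cohort(list(
    CON = list(spectrum_matrix(1000, 5.0, "CON", 1, leaf),
               spectrum_matrix(1000, 5.1, "CON", 2, leaf)),
    TAD = list(spectrum_matrix(1000, 9.0, "TAD", 1, leaf))), leaf)
  # k=3, intensities {CON: 5.0, CON: 5.1, TAD: 9.0}, test 5.05 -> CON 2 of 3
  v <- classify_vector(1000, 5.05, train, classifier_config("eeknn", k = 3))
  expect_equal(v$predicted, "CON")
  expect_equal(v$CON, 2)
  expect_equal(v$TAD, 1)
  # k=1 on an exact copy of a train peak
  v1 <- classify_vector(1000, 9.0, train, classifier_config("eeknn", k = 1))
  expect_equal(v1$predicted, "TAD")
  expect_equal(v1$TAD, 1)
  # equidistant CON and MCI neighbors at k=2 tie toward CON
  train2 <- cohort(list(
    CON = list(spectrum_matrix(1000, 4, "CON", 1, leaf)),
    MCI = list(spectrum_matrix(1000, 6, "MCI", 1, leaf))), leaf)
  v2 <- classify_vector(1000, 5, train2, classifier_config("eeknn", k = 2))
  expect_equal(v2$predicted, "CON")
  # no mass-matched train peak -> instructive error
  expect_error(classify_vector(5000, 5, train, classifier_config("eeknn")),
               "align")
})

test_that("per-vector MDC picks the most significant (nearest) train peak", {
  leaf <- leaf_meta()
  train <- cohort(list(
    CON = list(spectrum_matrix(1000, 4, "CON", 1, leaf)),
    MCI = list(spectrum_matrix(1000, 10, "MCI", 1, leaf)),
    TAD = list(spectrum_matrix(1000, 20, "TAD", 1, leaf))), leaf)
  v <- classify_vector(1000, 5, train, classifier_config("mdc"))
  expect_equal(v$predicted, "CON")          # distance 1 beats 5 and 15
  expect_equal(v$CON, 1)                    # winning distance
  v2 <- classify_vector(1000, 20, train, classifier_config("mdc"))
  expect_equal(v2$predicted, "TAD")
  # two stages at the same minimum distance tie toward the less severe
  train2 <- cohort(list(
    MCI = list(spectrum_matrix(1000, 4, "MCI", 1, leaf)),
    TAD = list(spectrum_matrix(1000, 6, "TAD", 1, leaf))), leaf)
  v3 <- classify_vector(1000, 5, train2, classifier_config("mdc"))
  expect_equal(v3$predicted, "MCI")
})

test_that("neighbor sets and votes match a brute-force recomputation", {
  # independent oracle: flatten, filter by mass equality, sort all distances
  brute_vote <- function(m, i, train, cfg) {
    rows <- do.call(rbind, lapply(cohort_matrices(train), function(mat)
      data.frame(mass = mat$peaks[, "mass"],
                 intensity = mat$peaks[, "intensity"], stage = mat$stage)))
    rows <- rows[order(rows$mass), ]
    rows <- rows[abs(rows$mass - m) <= cfg$mass_match_tolerance * m + 1e-12, ]
    if (cfg$method == "eeknn") {
      d <- mapply(function(mm, ii)
        sqrt((exp((m - mm)^2) - 1)^2 + (i - ii)^2), rows$mass, rows$intensity)
      nn <- rows$stage[order(d)][seq_len(min(cfg$k, nrow(rows)))]
      counts <- sapply(stage_levels(), function(s) sum(nn == s))
      stage_levels()[which.max(counts)]
    } else {
      d <- abs(m - rows$mass) + abs(i - rows$intensity)
      best <- sapply(stage_levels(), function(s)
        if (any(rows$stage == s)) min(d[rows$stage == s]) else Inf)
      stage_levels()[which.min(best)]
    }
  }
  for (seed in 1:4) {
    co <- small_cohort(seed, n_peaks = 10, per_stage = 4, noise_sd = 0.6)
    sp <- split_cohort(co, 0.5, seed = seed)
    test <- cohort_matrices(sp$test)[[1]]
    for (method in c("eeknn", "mdc")) {
      cfg <- classifier_config(method, k = 3)
      got <- classify_datapoint(test, sp$train, cfg)
      for (j in seq_len(n_peaks(test))) {
        expect_equal(got$votes$predicted[j],
                     brute_vote(test$peaks[j, "mass"],
                                test$peaks[j, "intensity"], sp$train, cfg))
      }
      # matrix label equals the mode of the vote list (severity tie-break)
      tal <- sapply(stage_levels(), function(s)
        sum(got$votes$predicted == s))
      expect_equal(got$stage, stage_levels()[which.max(tal)])
    }
  }
})

test_that("a test matrix copied from training is classified to its own stage", {
  co <- small_cohort(31, n_peaks = 20, per_stage = 4)
  tad <- co$members$TAD[[2]]
  res <- classify_datapoint(tad, co, classifier_config("eeknn", k = 1))
  expect_equal(res$stage, "TAD")
  expect_true(all(res$votes$predicted == "TAD"))   # every self-match wins
  # EE-kNN with k=1 on train-as-test: 100% accuracy
  res_all <- classify_cohort(co, co, classifier_config("eeknn", k = 1))
  expect_equal(mean(res_all$predictions$stage == res_all$predictions$predicted),
               1.0)
})

test_that("classifier config validates its fields", {
  expect_error(classifier_config("eeknn", k = 0), "positive")
  expect_error(classifier_config("eeknn", mass_match_tolerance = -1), ">= 0")
  expect_error(classifier_config("nope"), "arg")
})
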