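# Distance-based classification: exponential-Euclidean k-NN (EE-kNN) and the
# Manhattan distance classifier (MDC). Both classify every peak vector of a
# test data point against mass-matched training peaks and aggregate the
# per-vector labels into a matrix-level label by majority vote.

#' Classifier configuration
#'
#' @param method `"eeknn"` (exponential-Euclidean k-nearest neighbours) or
#'   `"mdc"` (Manhattan distance classifier; equivalent to a 1-NN vote under
#'   the Manhattan metric).
#' @param k neighbour count for EE-kNN (default 3; odd values reduce voting
#'   ties, which resolve toward the less severe stage).
#' @param mass_match_tolerance relative tolerance under which a training
#'   peak's mass counts as "equal" to a test peak's. After common-grid
#'   alignment masses match exactly, so the default reuses the alignment
#'   default.
#' @param square_mass_term the exponential mass penalty
#'   `(exp((ma - mb)^2) - 1)^2` enters the distance as the already-squared
#'   mass contribution (`FALSE`, default: `d = sqrt(penalty + dI^2)`); set
#'   `TRUE` to square it again (`d = sqrt(penalty^2 + dI^2)`). The two
#'   compositions coincide whenever masses match.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(method = c("eeknn", "mdc"), k = 3L,
                              mass_match_tolerance = 1e-4,
                              square_mass_term = FALSE) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (!is.numeric(mass_match_tolerance) || mass_match_tolerance < 0)
    stop("mass_match_tolerance must be >= 0", call. = FALSE)
  structure(list(method = method, k = k,
                 mass_match_tolerance = as.numeric(mass_match_tolerance),
                 square_mass_term = isTRUE(square_mass_term)),
            class = "classifier_config")
}

#' Exponential-Euclidean distance between two peak vectors
#'
#' The mass difference is penalized exponentially via
#' `penalty = (exp((ma - mb)^2) - 1)^2` while the intensity difference stays
#' linear, giving `d = sqrt(penalty + (Ia - Ib)^2)` (the penalty is treated
#' as the squared mass term; see [classifier_config()] for the alternative
#' composition). The steep penalty effectively excludes mass-mismatched
#' pairs from nearest-neighbour sets; when masses are equal the distance
#' reduces to `|Ia - Ib|`. Squared mass differences above 700 saturate to
#' `Inf` instead of overflowing.
#'
#' @param ma,mb masses (Daltons).
#' @param ia,ib intensities.
#' @param square_mass_term see [classifier_config()].
#' @return Non-negative scalar (possibly `Inf`); vectorized over inputs.
#' @export
#' @examples
#' exp_euclidean_distance(1000, 1000, 5, 2)  # equal masses: |dI| = 3
#' exp_euclidean_distance(1001, 1000, 1, 1)  # e - 1
exp_euclidean_distance <- function(ma, mb, ia, ib, square_mass_term = FALSE) {
  dm2 <- (ma - mb)^2
  penalty <- ifelse(dm2 > 700, Inf, (exp(dm2) - 1)^2)
  if (square_mass_term) penalty <- penalty^2
  sqrt(penalty + (ia - ib)^2)
}

#' Manhattan distance between two peak vectors
#'
#' `|ma - mb| + |Ia - Ib|`; the per-vector metric of the MDC.
#'
#' @inheritParams exp_euclidean_distance
#' @return Non-negative scalar; vectorized over inputs.
#' @export
manhattan_distance <- function(ma, mb, ia, ib) {
  abs(ma - mb) + abs(ia - ib)
}

# flatten a training cohort into a peak pool indexed for mass lookup
build_train_pool <- function(train) {
  stopifnot(inherits(train, "seldi_cohort"))
  mats <- cohort_matrices(train)
  if (length(mats) == 0L) stop("training cohort is empty", call. = FALSE)
  mass <- unlist(lapply(mats, function(m) m$peaks[, "mass"]))
  intensity <- unlist(lapply(mats, function(m) m$peaks[, "intensity"]))
  stage <- rep(vapply(mats, function(m) m$stage, character(1)),
               vapply(mats, n_peaks, integer(1)))
  ord <- order(mass)      # stable: preserves train order within equal masses
  list(mass = mass[ord], intensity = intensity[ord], stage = stage[ord])
}

match_mass_range <- function(pool_mass, m, tol) {
  lo <- findInterval(m - tol * m - 1e-12, pool_mass) + 1L
  hi <- findInterval(m + tol * m + 1e-12, pool_mass)
  if (hi < lo) integer(0) else lo:hi
}

classify_vector_impl <- function(m, i, pool, config) {
  idx <- match_mass_range(pool$mass, m, config$mass_match_tolerance)
  if (length(idx) == 0L)
    stop("no training peaks mass-matched at m/z ", format(m),
         "; align train and test to a common grid", call. = FALSE)
  stages <- pool$stage[idx]
  if (config$method == "eeknn") {
    d <- exp_euclidean_distance(m, pool$mass[idx], i, pool$intensity[idx],
                                config$square_mass_term)
    k <- min(config$k, length(idx))
    nn <- stages[order(d)[seq_len(k)]]  # order() is stable: train-order ties
    counts <- vapply(stage_levels(), function(s) sum(nn == s), numeric(1))
    predicted <- stage_levels()[which.max(counts)]  # first max = least severe
    list(predicted = predicted, margin = counts)
  } else {
    d <- manhattan_distance(m, pool$mass[idx], i, pool$intensity[idx])
    best <- vapply(stage_levels(),
                   function(s) if (any(stages == s)) min(d[stages == s]) else Inf,
                   numeric(1))
    predicted <- stage_levels()[which.min(best)]
    list(predicted = predicted, margin = best)
  }
}

#' Classify one test peak vector
#'
#' Restricts the training pool to peaks whose mass equals the test peak's
#' within the configured relative tolerance, then votes: EE-kNN takes the
#' stage holding the majority among the `k` nearest neighbours under
#' [exp_euclidean_distance()] (distance ties keep training order, stage-vote
#' ties resolve to the less severe stage); MDC takes the stage of the single
#' minimum-[manhattan_distance()] peak (ties to the less severe stage).
#'
#' @param mass,intensity coordinates of the test peak vector.
#' @param train training `seldi_cohort` (or a pool from an earlier call,
#'   see [classify_datapoint()]).
#' @param config a [classifier_config()].
#' @return A one-row data.frame (a vector vote) with columns `mass`,
#'   `predicted`, and per-stage margins `CON`, `MCI`, `TAD` (neighbour
#'   counts for EE-kNN; minimal per-stage distances for MDC).
#' @export
classify_vector <- function(mass, intensity, train, config = classifier_config()) {
  pool <- if (inherits(train, "seldi_cohort")) build_train_pool(train) else train
  v <- classify_vector_impl(mass, intensity, pool, config)
  out <- data.frame(mass = mass, predicted = v$predicted)
  out[stage_levels()] <- as.list(v$margin)
  out
}

#' Classify a test data point by per-vector voting
#'
#' Runs the configured per-vector classifier over all n peak vectors of the
#' test data point and labels the matrix with the stage receiving the most
#' vector votes; vote ties resolve to the less severe stage. The full vote
#' table is returned for downstream misclassification-degree and fuzzy-MCI
#' reporting.
#'
#' @param test a `spectrum_matrix` aligned to the training grid.
#' @param train training `seldi_cohort`.
#' @param config a [classifier_config()].
#' @return List with `stage` (the matrix-level label) and `votes`
#'   (data.frame, one row per test peak: `sample`, `mass`, `predicted` and
#'   per-stage margins).
#' @export
classify_datapoint <- function(test, train, config = classifier_config()) {
  stopifnot(inherits(test, "spectrum_matrix"))
  pool <- if (inherits(train, "seldi_cohort")) build_train_pool(train) else train
  n <- n_peaks(test)
  predicted <- character(n)
  margins <- matrix(0, n, 3, dimnames = list(NULL, stage_levels()))
  for (j in seq_len(n)) {
    v <- classify_vector_impl(test$peaks[j, "mass"], test$peaks[j, "intensity"],
                              pool, config)
    predicted[j] <- v$predicted
    margins[j, ] <- v$margin
  }
  tallies <- vapply(stage_levels(), function(s) sum(predicted == s),
                    numeric(1))
  votes <- data.frame(sample = test$sample_index,
                      mass = test$peaks[, "mass"],
                      predicted = predicted)
  votes[stage_levels()] <- as.data.frame(margins)
  list(stage = stage_levels()[which.max(tallies)], votes = votes)
}

#' Classify every member of a test cohort
#'
#' Convenience wrapper applying [classify_datapoint()] to all members of a
#' test cohort against one training cohort.
#'
#' @param test,train `seldi_cohort` objects on a common grid.
#' @param config a [classifier_config()].
#' @return List with `predictions` (data.frame: `stage` = true label,
#'   `sample`, `predicted`) and `votes` (list of per-sample vote tables, in
#'   prediction order).
#' @export
classify_cohort <- function(test, train, config = classifier_config()) {
  pool <- build_train_pool(train)
  mats <- cohort_matrices(test)
  res <- lapply(mats, classify_datapoint, train = pool, config = config)
  predictions <- data.frame(
    stage = vapply(mats, function(m) m$stage, character(1)),
    sample = vapply(mats, function(m) m$sample_index, integer(1)),
    predicted = vapply(res, function(r) r$stage, character(1)))
  list(predictions = predictions, votes = lapply(res, `[[`, "votes"))
}
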