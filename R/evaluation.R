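# Evaluation machinery: 3-class confusion tables, the two-class
# predisposed/non-disposed collapse, type II error and power, the
# misclassification-degree breakdown, and the fuzzy MCI-centered criterion.

#' Build a 3x3 stage confusion table
#'
#' @param truth character vector of true stage labels.
#' @param predicted character vector of predicted stage labels, same length.
#' @return An object of class `confusion_table`: a 3x3 integer matrix indexed
#'   (true stage, predicted stage).
#' @export
#' @examples
#' confusion_from_predictions(c("CON", "MCI", "TAD"), c("CON", "TAD", "TAD"))
confusion_from_predictions <- function(truth, predicted) {
  if (length(truth) == 0L || length(truth) != length(predicted))
    stop("truth and predicted must be non-empty and equal length",
         call. = FALSE)
  truth <- vapply(truth, as_stage, character(1), USE.NAMES = FALSE)
  predicted <- vapply(predicted, as_stage, character(1), USE.NAMES = FALSE)
  counts <- table(factor(truth, stage_levels()),
                  factor(predicted, stage_levels()))
  m <- matrix(as.integer(counts), 3, 3,
              dimnames = list(true = stage_levels(),
                              predicted = stage_levels()))
  structure(m, class = c("confusion_table", "matrix"))
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table> accuracy =", format(accuracy(x), digits = 4), "\n")
  print(unclass(x))
  invisible(x)
}

#' Classification accuracy of a confusion table
#'
#' Trace over total, for either a 3x3 `confusion_table` or a 2x2
#' `two_class_table`.
#'
#' @param x a confusion or two-class table.
#' @return Proportion in \[0, 1\].
#' @export
accuracy <- function(x) {
  stopifnot(inherits(x, "confusion_table") || inherits(x, "two_class_table"))
  sum(diag(unclass(x))) / sum(x)
}

#' Collapse a stage confusion table to the two-class design
#'
#' CON constitutes the non-disposed class; MCI and TAD merge into the
#' predisposed class (so a balanced 20-per-stage cohort yields 40 predisposed
#' data points). Rows are the true class, columns the predicted call
#' (`NO` = non-disposed, `YES` = predisposed); totals are conserved.
#'
#' @param ct a `confusion_table`.
#' @return An object of class `two_class_table`: 2x2 integer matrix with rows
#'   `non_disposed`, `predisposed` and columns `NO`, `YES`.
#' @export
collapse_two_class <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  m <- unclass(ct)
  two_class_table(no_no = m["CON", "CON"],
                  no_yes = m["CON", "MCI"] + m["CON", "TAD"],
                  yes_no = m["MCI", "CON"] + m["TAD", "CON"],
                  yes_yes = sum(m[c("MCI", "TAD"), c("MCI", "TAD")]))
}

#' Construct a two-class (predisposed) table directly
#'
#' @param no_no,no_yes true non-disposed samples called NO / YES.
#' @param yes_no,yes_yes true predisposed samples called NO / YES.
#' @return An object of class `two_class_table`.
#' @export
two_class_table <- function(no_no, no_yes, yes_no, yes_yes) {
  counts <- c(no_no, no_yes, yes_no, yes_yes)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  m <- matrix(as.integer(counts), 2, 2, byrow = TRUE,
              dimnames = list(true = c("non_disposed", "predisposed"),
                              predicted = c("NO", "YES")))
  structure(m, class = c("two_class_table", "matrix"))
}

#' @export
print.two_class_table <- function(x, ...) {
  t2 <- type2_error_rate(x)
  cat(sprintf("<two_class_table> type II error = %.2f, power = %d%%\n",
              t2$rate, t2$power_percent))
  print(unclass(x))
  invisible(x)
}

#' Type II error rate and diagnostic power
#'
#' The type II error counts predisposed samples called NO (false negatives)
#' and divides by the total number of evaluated samples in the table --
#' the convention under which the coin-flip default diagnosis scores
#' 20/60 = 0.33 and the weakest distance classifier 8/60 = 0.13. Power is
#' `round(100 * (1 - rate))` percent.
#'
#' @param t a `two_class_table`.
#' @return List with `rate` (false negatives over total, rounded to 2
#'   decimals), `power_percent` (integer), `false_negatives` and `total`.
#' @export
#' @examples
#' type2_error_rate(default_diagnosis_table())
type2_error_rate <- function(t) {
  stopifnot(inherits(t, "two_class_table"))
  total <- sum(t)
  if (total == 0L) stop("empty two-class table", call. = FALSE)
  fn <- unclass(t)["predisposed", "NO"]
  rate <- fn / total
  list(rate = round(rate, 2),
       power_percent = as.integer(round(100 * (1 - rate))),
       false_negatives = as.integer(fn),
       total = as.integer(total))
}

#' Reference two-class tables
#'
#' `default_diagnosis_table()` is the coin-flip "default diagnosis" on the
#' balanced 20-per-stage design: of 20 non-disposed samples, 10 are called
#' YES; of the 40 predisposed, 20 are called NO. It commits a type II error
#' of 0.33 (power 67%). `eeknn_cm10_low_table()` is the corresponding table
#' for the weakest distance-classifier result (EE-kNN on the CM10 low-energy
#' leaf): type II error 0.13, power 87% -- a 20-percentage-point improvement
#' over the default.
#'
#' @return A `two_class_table`.
#' @export
#' @examples
#' type2_error_rate(eeknn_cm10_low_table())
default_diagnosis_table <- function() {
  two_class_table(no_no = 10, no_yes = 10, yes_no = 20, yes_yes = 20)
}

#' @rdname default_diagnosis_table
#' @export
eeknn_cm10_low_table <- function() {
  two_class_table(no_no = 13, no_yes = 7, yes_no = 8, yes_yes = 32)
}

#' Misclassification-degree breakdown
#'
#' Expands a confusion table into the full predicted-stage distribution per
#' true stage, annotating each cell with its error type under the
#' predisposed-positive convention: errors from a true CON sample are
#' type-I-style (false alarms), predisposed samples called CON are
#' type-II-style (missed disease), and MCI/TAD confusions stay within the
#' predisposed class (no two-class error, but a real degree of
#' misclassification). Hence true CON samples can only incur type-I-style
#' errors, true TAD samples only type-II-style ones, and true MCI samples
#' both.
#'
#' @param ct a `confusion_table`.
#' @return data.frame with columns `true`, `predicted`, `count`,
#'   `error_type` in `{correct, type_I_style, type_II_style,
#'   within_predisposed}`, carrying a `convention` attribute stating the
#'   labelling convention (some sources state the opposite assignment for
#'   TAD samples).
#' @export
misclassification_breakdown <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  m <- unclass(ct)
  out <- expand.grid(true = stage_levels(), predicted = stage_levels(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$count <- mapply(function(tr, pr) m[tr, pr], out$true, out$predicted)
  classify_cell <- function(tr, pr) {
    if (tr == pr) return("correct")
    if (tr == "CON") return("type_I_style")
    if (pr == "CON") return("type_II_style")
    "within_predisposed"
  }
  out$error_type <- mapply(classify_cell, out$true, out$predicted)
  out <- out[order(match(out$true, stage_levels()),
                   match(out$predicted, stage_levels())), ]
  rownames(out) <- NULL
  attr(out, "convention") <-
    paste("Error types follow the predisposed-positive convention:",
          "false alarms on true CON samples are type-I-style and missed",
          "predisposed samples are type-II-style. Some sources state the",
          "opposite assignment for TAD samples; the counts themselves are",
          "convention-free.")
  out
}

#' Fuzzy MCI-centered assessment of a vote table
#'
#' Treats the data point under assessment as an MCI element and asks which
#' way its per-vector votes pull: toward TAD (`incipient_TAD`), toward CON
#' (`relapsing_CON`), or neither (`stable_MCI`). The score is the winning
#' pull's share of the CON + TAD votes (0.5 when balanced, 1 when
#' unanimous).
#'
#' @param votes a vote table from [classify_datapoint()] (or any data.frame
#'   with a `predicted` column of stage labels, or a bare character vector
#'   of per-vector labels).
#' @return An object of class `fuzzy_assessment`: list with `direction`,
#'   `score` and `proportions` (the per-stage vote shares).
#' @export
fuzzy_mci_assess <- function(votes) {
  labels <- if (is.data.frame(votes)) votes$predicted else votes
  if (length(labels) == 0L) stop("empty vote list", call. = FALSE)
  labels <- vapply(labels, as_stage, character(1), USE.NAMES = FALSE)
  p <- vapply(stage_levels(), function(s) mean(labels == s), numeric(1))
  direction <- if (p[["TAD"]] > p[["CON"]]) "incipient_TAD"
               else if (p[["CON"]] > p[["TAD"]]) "relapsing_CON"
               else "stable_MCI"
  denom <- p[["CON"]] + p[["TAD"]]
  score <- if (denom == 0) 0.5 else max(p[["CON"]], p[["TAD"]]) / denom
  structure(list(direction = direction, score = score, proportions = p),
            class = "fuzzy_assessment")
}

#' @export
print.fuzzy_assessment <- function(x, ...) {
  cat(sprintf("<fuzzy_assessment> %s (score %.2f)\n", x$direction, x$score))
  invisible(x)
}
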