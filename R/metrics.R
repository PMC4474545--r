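#' Micro-averaged F-measure
#'
#' Pools true positives, false positives and false negatives over all
#' classes before computing precision, recall and F1. For a single-label
#' binary task this equals plain accuracy, but the pooled computation also
#' covers evaluation settings with more classes.
#'
#' @param predictions,gold Equal-length vectors of labels (logical,
#'   character or factor).
#' @return The micro-averaged F1 as a single number.
#' @export
micro_f1 <- function(predictions, gold) {
  if (length(predictions) == 0L || length(predictions) != length(gold)) {
    abort("`predictions` and `gold` must be non-empty and of equal length.")
  }
  predictions <- as.character(predictions)
  gold <- as.character(gold)
  classes <- union(predictions, gold)
  tp <- fp <- fn <- 0
  for (cls in classes) {
    tp <- tp + sum(predictions == cls & gold == cls)
    fp <- fp + sum(predictions == cls & gold != cls)
    fn <- fn + sum(predictions != cls & gold == cls)
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Macro-averaged F-measure
#'
#' Per-class F1 averaged with equal class weight; reported alongside the
#' micro average for completeness.
#'
#' @inheritParams micro_f1
#' @return The macro-averaged F1.
#' @export
macro_f1 <- function(predictions, gold) {
  if (length(predictions) == 0L || length(predictions) != length(gold)) {
    abort("`predictions` and `gold` must be non-empty and of equal length.")
  }
  predictions <- as.character(predictions)
  gold <- as.character(gold)
  classes <- union(predictions, gold)
  f1s <- vapply(classes, function(cls) {
    tp <- sum(predictions == cls & gold == cls)
    fp <- sum(predictions == cls & gold != cls)
    fn <- sum(predictions != cls & gold == cls)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s)
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between two label
#' sequences. When the expected agreement is 1 (both raters constant and
#' identical) the observed agreement must also be 1 and kappa is defined as
#' 1; constant raters that disagree raise an error.
#'
#' @param rater_a,rater_b Equal-length label vectors.
#' @return Kappa in \[-1, 1\].
#' @examples
#' cohens_kappa(c(1, 1, 0), c(1, 1, 0))
#' @export
cohens_kappa <- function(rater_a, rater_b) {
  if (length(rater_a) == 0L || length(rater_a) != length(rater_b)) {
    abort("Rater vectors must be non-empty and of equal length.")
  }
  a <- as.character(rater_a)
  b <- as.character(rater_b)
  classes <- union(a, b)
  po <- mean(a == b)
  pe <- sum(vapply(classes, function(cls) mean(a == cls) * mean(b == cls),
                   numeric(1)))
  if (pe >= 1) {
    if (po == 1) return(1)
    abort("Expected agreement is 1 but observed agreement is not.")
  }
  (po - pe) / (1 - pe)
}

#' Compare two classifiers by chi-squared test
#'
#' Default method `"proportions"` tests the 2x2 table classifier x
#' correct/incorrect (are the two accuracies different?) with Pearson's
#' chi-squared statistic without continuity correction; identical
#' predictions then give a statistic of zero. Method `"mcnemar"` runs the
#' paired McNemar test on the discordant instances instead. Degenerate
#' tables (an all-zero margin) are reported as not significant and flagged.
#'
#' @param preds_a,preds_b Predictions of the two classifiers.
#' @param gold Gold labels, aligned with both prediction vectors.
#' @param alpha Significance level (default 0.05).
#' @param method `"proportions"` (unpaired) or `"mcnemar"` (paired).
#' @return Tibble with `statistic`, `p_value`, `significant`, `degenerate`,
#'   `method`.
#' @export
compare_classifiers <- function(preds_a, preds_b, gold, alpha = 0.05,
                                method = c("proportions", "mcnemar")) {
  method <- match.arg(method)
  stopifnot(length(preds_a) == length(gold), length(preds_b) == length(gold))
  correct_a <- as.character(preds_a) == as.character(gold)
  correct_b <- as.character(preds_b) == as.character(gold)
  degenerate <- FALSE
  stat <- NA_real_
  p <- NA_real_
  if (method == "proportions") {
    tab <- rbind(
      a = c(sum(correct_a), sum(!correct_a)),
      b = c(sum(correct_b), sum(!correct_b))
    )
    if (identical(correct_a, correct_b)) {
      stat <- 0
      p <- 1
    } else if (any(colSums(tab) == 0)) {
      degenerate <- TRUE
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic)
      p <- ct$p.value
    }
  } else {
    n01 <- sum(correct_a & !correct_b)
    n10 <- sum(!correct_a & correct_b)
    if (n01 + n10 == 0) {
      stat <- 0
      p <- 1
    } else {
      tab <- matrix(c(sum(correct_a & correct_b), n01, n10,
                      sum(!correct_a & !correct_b)), 2, 2, byrow = TRUE)
      ct <- suppressWarnings(mcnemar.test(tab, correct = FALSE))
      stat <- unname(ct$statistic)
      p <- ct$p.value
    }
  }
  tibble(
    statistic = stat,
    p_value = p,
    significant = !degenerate && !is.na(p) && p < alpha,
    degenerate = degenerate,
    method = method
  )
}

#' Rule baselines for the two tasks
#'
#' The abbreviation baseline classifies a candidate as an abbreviation
#' exactly when the character following the period (the first character of
#' the raw right token) is a lower-case letter. The sentence baseline
#' classifies a site as a sentence delimiter exactly when the normalized
#' right token is capitalized.
#'
#' @param sites Period-site tibble.
#' @return Logical vector of predicted labels.
#' @export
baseline_abbrev <- function(sites) {
  stringr::str_detect(sites$right_token, "^\\p{Ll}")
}

#' @rdname baseline_abbrev
#' @export
baseline_sentence <- function(sites) {
  stringr::str_detect(normalize_right(sites$right_token), "^\\p{Lu}")
}

#' Distribution-free sample size from a Chernoff bound
#'
#' `n >= (2 + eps) / eps^2 * ln(2 / delta)` bounds the sample size needed
#' so that, with confidence `1 - delta`, estimates from the sample are
#' within `eps` of the truth, independently of the collection size. The
#' fractional part of the bound is truncated.
#'
#' @param epsilon Accuracy (half-width), e.g. 0.05.
#' @param delta One minus the confidence, e.g. 0.05 for 95% confidence.
#' @return Integer sample size.
#' @examples
#' chernoff_sample_size(0.05, 0.05)
#' @export
chernoff_sample_size <- function(epsilon, delta) {
  if (!is.numeric(epsilon) || epsilon <= 0) abort("`epsilon` must be > 0.")
  if (!is.numeric(delta) || delta <= 0 || delta >= 1) {
    abort("`delta` must be in (0, 1).")
  }
  as.integer(floor((2 + epsilon) / epsilon^2 * log(2 / delta)))
}
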