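#' Train a period-site classifier
#'
#' Fits one of the two linear-SVM classifiers over labeled period sites:
#' `task = "abbreviation"` predicts whether the period marks an
#' abbreviation, `task = "sentence"` whether it delimits a sentence. The
#' function assembles the enabled feature blocks, freezes the word-type
#' vocabularies from the training sites, scales features to \[-1, 1\],
#' normalizes instances to unit length, optionally selects the cost
#' parameter by cross-validation, and fits the linear SVM. The returned
#' model is self-contained: it carries the collocation table, length
#' statistics, lexicons and vocabularies needed to featurize new sites.
#'
#' @param sites Labeled period-site tibble (columns `is_abbrev` /
#'   `is_sentence_end` must be filled for the chosen task).
#' @param task `"abbreviation"` or `"sentence"`.
#' @param counts `count_table` from the training corpus
#'   ([count_collocations()]).
#' @param mddict,ccdict Lexicons; `ccdict` is needed for the sentence task.
#' @param abbrev_model A fitted abbreviation model, required when the
#'   sentence `abbreviation` block is enabled.
#' @param sets Enabled feature blocks; defaults to all blocks of the task.
#' @param stats Optional precomputed `length_stats`; derived from `counts`
#'   when `NULL`.
#' @param alpha Significance level for the length-statistics collocation
#'   filter.
#' @param cost SVM cost parameter (used when `select_cost = FALSE`).
#' @param select_cost If `TRUE`, choose the cost from `grid` by stratified
#'   cross-validation on the training sites.
#' @param grid Candidate costs for `select_cost`.
#' @param folds,seed Cross-validation folds and seed for cost selection.
#' @param cc_capitalized Semantics of the closed-class sentence feature
#'   (see [sentence_features()]).
#' @return An object of class `period_model`.
#' @export
fit_period_classifier <- function(sites, task = c("abbreviation", "sentence"),
                                  counts, mddict, ccdict = NULL,
                                  abbrev_model = NULL, sets = NULL,
                                  stats = NULL, alpha = 0.01,
                                  cost = 1, select_cost = FALSE,
                                  grid = 10^seq(-3, 3), folds = 5, seed = 1,
                                  cc_capitalized = TRUE) {
  task <- match.arg(task)
  labels <- site_labels(sites, task)
  if (anyNA(labels)) abort("Training sites must carry gold labels.")
  if (is.null(stats)) stats <- abbreviation_length_stats(counts, alpha = alpha)

  if (task == "abbreviation") {
    if (is.null(sets)) sets <- abbrev_feature_sets()
    feats <- abbrev_features(sites, counts, stats, mddict, sets = sets)
    vocabs <- list(vocab = attr(feats, "vocab"))
  } else {
    if (is.null(sets)) sets <- sentence_feature_sets()
    if (is.null(ccdict) && "language" %in% sets) {
      abort("The sentence task needs `ccdict` for its language features.")
    }
    feats <- sentence_features(
      sites, counts, stats, mddict, ccdict, sets = sets,
      abbrev_model = abbrev_model, cc_capitalized = cc_capitalized
    )
    vocabs <- list(
      l_vocab = attr(feats, "l_vocab"),
      r_vocab = attr(feats, "r_vocab")
    )
  }

  x <- as.matrix(feats)
  pp <- preprocess(x)
  if (select_cost) {
    cost <- select_c(pp$train, labels, grid = grid, folds = folds,
                     seed = seed)$cost
  }
  svm <- fit_linear_svm(pp$train, labels, cost = cost)

  model <- structure(
    list(
      task = task,
      svm = svm,
      scaling = pp$params,
      feature_names = colnames(x),
      set_tags = attr(feats, "set_tags"),
      sets = sets,
      vocabs = vocabs,
      counts = counts,
      stats = stats,
      mddict = mddict,
      ccdict = ccdict,
      abbrev_model = if (task == "sentence") abbrev_model,
      abbrev_model_hash = if (task == "sentence" && !is.null(abbrev_model)) {
        rlang::hash(abbrev_model$svm)
      },
      cc_capitalized = cc_capitalized,
      cost = cost,
      n_train = nrow(sites)
    ),
    class = "period_model"
  )
  model
}

site_labels <- function(sites, task) {
  if (task == "abbreviation") as.logical(sites$is_abbrev)
  else as.logical(sites$is_sentence_end)
}

# featurize new sites with the model's frozen vocabularies and scaling
model_matrix <- function(model, sites) {
  if (model$task == "abbreviation") {
    feats <- abbrev_features(
      sites, model$counts, model$stats, model$mddict,
      sets = model$sets, vocab = model$vocabs$vocab
    )
  } else {
    feats <- sentence_features(
      sites, model$counts, model$stats, model$mddict, model$ccdict,
      sets = model$sets, abbrev_model = model$abbrev_model,
      l_vocab = model$vocabs$l_vocab, r_vocab = model$vocabs$r_vocab,
      cc_capitalized = model$cc_capitalized
    )
  }
  scale_with(as.matrix(feats), model$scaling)
}

#' Predict period-site labels
#'
#' @param object A `period_model`.
#' @param newdata A period-site tibble.
#' @param type `"class"` for logical labels, `"score"` for the signed
#'   decision value `w'x + b`.
#' @param ... Unused.
#' @return Logical vector (`TRUE` = abbreviation / sentence end) or numeric
#'   scores.
#' @export
predict.period_model <- function(object, newdata,
                                 type = c("class", "score"), ...) {
  type <- match.arg(type)
  predict(object$svm, model_matrix(object, newdata), type = type)
}

#' @export
print.period_model <- function(x, ...) {
  cat(sprintf(
    "<period_model task=%s, %d features [%s], C=%g, n_train=%d>\n",
    x$task, length(x$feature_names), paste(x$sets, collapse = "+"),
    x$cost, x$n_train
  ))
  invisible(x)
}

#' Evaluate a model on labeled sites
#'
#' @param model A `period_model`.
#' @param sites Labeled period-site tibble.
#' @return One-row tibble with `n`, `tp`, `fp`, `tn`, `fn`,
#'   `micro_f1`, `macro_f1`.
#' @export
evaluate_model <- function(model, sites) {
  gold <- site_labels(sites, model$task)
  pred <- predict(model, sites)
  tibble(
    n = length(gold),
    tp = sum(pred & gold),
    fp = sum(pred & !gold),
    tn = sum(!pred & !gold),
    fn = sum(!pred & gold),
    micro_f1 = micro_f1(pred, gold),
    macro_f1 = macro_f1(pred, gold)
  )
}

#' Stratified k-fold cross-validation of the linear SVM
#'
#' Splits instances into stratified folds, preprocesses each training fold
#' (scaling parameters from the fold's training part only), fits the SVM
#' and pools the held-out predictions into one micro-averaged F1.
#'
#' @param x Raw (unscaled) feature matrix.
#' @param y Logical labels.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param cost SVM cost.
#' @return List of class `period_cv`: `micro_f1`, `macro_f1`, `per_fold`
#'   tibble and the pooled confusion counts.
#' @export
cross_validate <- function(x, y, k = 10, seed = 1, cost = 1) {
  x <- as.matrix(x)
  y <- as.logical(y)
  fold_id <- stratified_folds(y, k, seed)
  pred <- logical(length(y))
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold_id != f
    pp <- preprocess(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    model <- fit_linear_svm(pp$train, y[tr], cost = cost)
    pf <- predict(model, pp$test)
    pred[!tr] <- pf
    per_fold[f] <- micro_f1(pf, y[!tr])
  }
  structure(
    list(
      micro_f1 = micro_f1(pred, y),
      macro_f1 = macro_f1(pred, y),
      per_fold = tibble(fold = seq_len(k), micro_f1 = per_fold),
      confusion = c(
        tp = sum(pred & y), fp = sum(pred & !y),
        tn = sum(!pred & !y), fn = sum(!pred & y)
      )
    ),
    class = "period_cv"
  )
}

#' @export
print.period_cv <- function(x, ...) {
  cat(sprintf("<period_cv micro_f1=%.4f over %d folds>\n",
              x$micro_f1, nrow(x$per_fold)))
  invisible(x)
}

#' Stepwise feature-set evaluation
#'
#' Reproduces the stepwise protocol: feature blocks are added cumulatively
#' in their canonical order, a model is trained per step, and training-set
#' and test-set micro-F1 are reported together with the rule baseline.
#'
#' @param train_sites,test_sites Labeled period-site tibbles.
#' @param task `"abbreviation"` or `"sentence"`.
#' @param counts,mddict,ccdict,abbrev_model,stats,cost,cc_capitalized
#'   Passed to [fit_period_classifier()].
#' @param order Block order; defaults to the canonical order of the task.
#' @param isolation If `TRUE`, evaluate each block alone instead of
#'   cumulatively.
#' @param select_cost,grid,folds,seed Per-step cost selection by
#'   cross-validation (see [fit_period_classifier()]); `cost` is used as-is
#'   when `select_cost = FALSE`.
#' @return Tibble with one row per step: `step`, `sets` (label), `n_features`,
#'   `cost`, `f1_train`, `f1_test`.
#' @export
stepwise_evaluation <- function(train_sites, test_sites,
                                task = c("abbreviation", "sentence"),
                                counts, mddict, ccdict = NULL,
                                abbrev_model = NULL, stats = NULL,
                                cost = 1, cc_capitalized = TRUE,
                                order = NULL, isolation = FALSE,
                                select_cost = FALSE,
                                grid = c(0.01, 1, 100), folds = 3, seed = 1) {
  task <- match.arg(task)
  if (is.null(order)) {
    order <- if (task == "abbreviation") abbrev_feature_sets()
             else sentence_feature_sets()
  }
  if (is.null(stats)) stats <- abbreviation_length_stats(counts)
  steps <- lapply(seq_along(order), function(i) {
    if (isolation) order[i] else order[seq_len(i)]
  })
  rows <- purrr::map2(steps, seq_along(steps), function(sets, i) {
    model <- fit_period_classifier(
      train_sites, task = task, counts = counts, mddict = mddict,
      ccdict = ccdict, abbrev_model = abbrev_model, sets = sets,
      stats = stats, cost = cost, cc_capitalized = cc_capitalized,
      select_cost = select_cost, grid = grid, folds = folds, seed = seed
    )
    tibble(
      step = i,
      sets = paste(sets, collapse = "+"),
      n_features = length(model$feature_names),
      cost = model$cost,
      f1_train = evaluate_model(model, train_sites)$micro_f1,
      f1_test = evaluate_model(model, test_sites)$micro_f1
    )
  })
  bind_rows(rows)
}

# ---- broom-style accessors -------------------------------------------------

#' Tidy a period-site classifier
#'
#' @param x A `period_model`.
#' @param ... Unused.
#' @return Tibble of all features with weights and squared weights, in
#'   relevance order.
#' @exportS3Method generics::tidy
tidy.period_model <- function(x, ...) {
  rank_features(x, n = length(x$svm$w))
}

#' Summarize a period-site classifier
#'
#' @param x A `period_model`.
#' @param ... Unused.
#' @return One-row tibble: task, number of features, cost, training size.
#' @exportS3Method generics::glance
glance.period_model <- function(x, ...) {
  tibble(
    task = x$task,
    n_features = length(x$feature_names),
    cost = x$cost,
    n_train = x$n_train,
    mu = x$stats$mu,
    sigma = x$stats$sigma
  )
}

#' Plot the feature-relevance ranking of a model
#'
#' @param object A `period_model`.
#' @param n Number of top features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.period_model <- function(object, n = 10, ...) {
  df <- rank_features(object, n = n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$w2,
    y = stats::reorder(.data$feature, .data$w2)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = expression(w^2), y = NULL,
      title = sprintf("Top %d features (%s model)", nrow(df), object$task)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a stepwise feature-set evaluation
#'
#' @param steps Tibble from [stepwise_evaluation()].
#' @return A ggplot object.
#' @export
plot_stepwise <- function(steps) {
  long <- tidyr::pivot_longer(steps, c("f1_train", "f1_test"),
                              names_to = "split", values_to = "micro_f1")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$step, y = .data$micro_f1, colour = .data$split
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = steps$step, labels = steps$sets) +
    ggplot2::labs(x = NULL, y = "micro-averaged F1") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
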