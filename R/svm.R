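#' Min-max scaling to \[-1, 1\] and unit-length normalization
#'
#' Each training feature is affinely mapped onto \[-1, 1\] (constant
#' features map to 0); a test matrix is mapped with the training parameters
#' and may therefore leave that range. Afterwards every row vector is
#' divided by its Euclidean norm (zero rows stay zero).
#'
#' @param train Numeric matrix (rows = instances) or data frame.
#' @param test Optional matrix/data frame sharing the feature ordering.
#' @param params Optional precomputed scaling parameters (list with `mins`,
#'   `maxs`); when supplied, `train` is treated like a test matrix.
#' @param unit_norm Divide each row by its Euclidean norm after scaling
#'   (default `TRUE`); set to `FALSE` to inspect the bare affine map.
#' @return List with `train`, `test` (or `NULL`) and `params`.
#' @examples
#' preprocess(matrix(c(0, 5, 10), ncol = 1))
#' @export
preprocess <- function(train, test = NULL, params = NULL, unit_norm = TRUE) {
  train <- as.matrix(train)
  if (is.null(params)) {
    params <- list(
      mins = apply(train, 2, min),
      maxs = apply(train, 2, max)
    )
  }
  list(
    train = scale_with(train, params, unit_norm),
    test = if (!is.null(test)) scale_with(as.matrix(test), params, unit_norm),
    params = params
  )
}

scale_with <- function(x, params, unit_norm = TRUE) {
  rng <- params$maxs - params$mins
  const <- rng == 0
  x <- sweep(x, 2, params$mins)
  x <- sweep(x, 2, ifelse(const, 1, rng), "/")
  x <- 2 * x - 1
  x[, const] <- 0
  if (unit_norm) x <- unit_rows(x)
  x
}

unit_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}

#' Fit a linear soft-margin SVM
#'
#' Thin wrapper around a standard solver exposing the linear decision
#' function `f(x) = sign(w'x + b)` with an explicit weight vector per
#' feature, as needed for squared-weight relevance ranking. Inputs are
#' expected to be preprocessed (see [preprocess()]).
#'
#' @param x Numeric matrix of preprocessed instances with column names.
#' @param y Logical vector (or coercible) of instance labels.
#' @param cost Soft-margin cost C: small values tolerate training errors,
#'   large values approach a hard margin.
#' @return List of class `linear_svm` with `w` (named weights), `b`,
#'   `cost`, `positive_label`.
#' @export
fit_linear_svm <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  y <- as.logical(y)
  if (length(unique(y)) < 2L) abort("Need both classes to fit the SVM.")
  yf <- factor(ifelse(y, "yes", "no"))
  m <- e1071::svm(x, yf, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(m$coefs, m$SV))
  b <- -m$rho
  # the solver's decision-value sign convention depends on class order;
  # anchor it against the solver's own decision values
  dv <- attr(predict(m, x[1:min(nrow(x), 50L), , drop = FALSE],
                     decision.values = TRUE), "decision.values")
  dv_positive <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  raw <- drop(x[1:nrow(dv), , drop = FALSE] %*% w) + b
  if (sum(raw * dv[, 1]) < 0) {
    w <- -w
    b <- -b
  }
  names(w) <- colnames(x)
  structure(
    list(w = w, b = b, cost = cost, positive_label = dv_positive == "yes"),
    class = "linear_svm"
  )
}

#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  score <- drop(as.matrix(newdata) %*% object$w) + object$b
  if (!object$positive_label) score <- -score
  if (type == "score") score else score > 0
}

#' Select the SVM cost parameter by cross-validation
#'
#' Evaluates each candidate cost on stratified k-fold cross-validation and
#' returns the one maximizing mean micro-averaged F1; ties go to the
#' smallest cost, preferring stronger regularization.
#'
#' @param x Preprocessed instance matrix.
#' @param y Logical labels.
#' @param grid Candidate costs, by default seven values log-spaced over
#'   \[0.001, 1000\].
#' @param folds Number of cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @return List with `cost` (the winner) and `results` (tibble of per-cost
#'   mean F1).
#' @export
select_c <- function(x, y, grid = 10^seq(-3, 3), folds = 5, seed = 1) {
  x <- as.matrix(x)
  y <- as.logical(y)
  grid <- sort(grid)
  fold_id <- stratified_folds(y, folds, seed)
  f1 <- vapply(grid, function(cost) {
    per_fold <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      model <- fit_linear_svm(x[tr, , drop = FALSE], y[tr], cost = cost)
      micro_f1(predict(model, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    mean(per_fold)
  }, numeric(1))
  list(
    cost = grid[which.max(f1)], # which.max takes the first (smallest) tie
    results = tibble(cost = grid, micro_f1 = f1)
  )
}

# fold ids 1..k, each class spread evenly across folds
stratified_folds <- function(y, k, seed = 1) {
  if (length(y) < k) abort("Fewer instances than folds.")
  fold_id <- integer(length(y))
  withr_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold_id[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold_id
}

# evaluate `code` under a temporary RNG seed, restoring the previous state
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Rank features by squared weight
#'
#' For a linear kernel the squared component of the weight vector measures
#' the feature's contribution to the decision function, giving a relevance
#' ranking of the trained model's features. Ties are broken
#' lexicographically by feature name for determinism.
#'
#' @param model A `linear_svm` or `period_model`.
#' @param n Number of top features to return (the full list when `n`
#'   exceeds the dimension).
#' @return Tibble with `rank`, `feature`, `weight`, `w2`, sorted by
#'   descending `w2`.
#' @export
rank_features <- function(model, n = 10) {
  if (inherits(model, "period_model")) model <- model$svm
  stopifnot(inherits(model, "linear_svm"))
  out <- tibble(
    feature = names(model$w),
    weight = unname(model$w),
    w2 = unname(model$w)^2
  ) %>%
    arrange(desc(.data$w2), .data$feature) %>%
    mutate(rank = row_number(), .before = 1)
  head(out, n)
}
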