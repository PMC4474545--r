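#' Read and write snippet files
#'
#' A snippet file stores one period site per row as UTF-8 tab-separated
#' values with a header: `left_context`, `left_token`, `right_token`,
#' `right_context`, `newline_count`, `is_abbrev`, `is_sentence_end`.
#' Labels are 0/1 and may be empty (unannotated). Literal newlines inside
#' the context columns are escaped as `\n` so that each site stays on one
#' physical line.
#'
#' @param sites Period-site tibble.
#' @param path File path.
#' @return `write_snippets()` returns `path` invisibly; `read_snippets()`
#'   returns a period-site tibble with logical label columns.
#' @export
write_snippets <- function(sites, path) {
  esc <- function(x) {
    x <- gsub("\\", "\\\\", x, fixed = TRUE)
    gsub("\n", "\\n", x, fixed = TRUE)
  }
  out <- tibble(
    left_context = esc(sites$left_context),
    left_token = sites$left_token,
    right_token = sites$right_token,
    right_context = esc(sites$right_context),
    newline_count = sites$newline_count,
    is_abbrev = as.integer(sites$is_abbrev),
    is_sentence_end = as.integer(sites$is_sentence_end)
  )
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' @rdname write_snippets
#' @export
read_snippets <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      left_context = readr::col_character(),
      left_token = readr::col_character(),
      right_token = readr::col_character(),
      right_context = readr::col_character(),
      newline_count = readr::col_integer(),
      is_abbrev = readr::col_integer(),
      is_sentence_end = readr::col_integer()
    ),
    na = character(),
    trim_ws = FALSE,
    progress = FALSE
  )
  unesc <- function(x) {
    x[is.na(x)] <- ""
    vapply(x, function(s) {
      s <- gsub("(?<!\\\\)((\\\\\\\\)*)\\\\n", "\\1\n", s, perl = TRUE)
      gsub("\\\\", "\\", s, fixed = TRUE)
    }, character(1), USE.NAMES = FALSE)
  }
  df$is_abbrev <- suppressWarnings(as.logical(as.integer(df$is_abbrev)))
  df$is_sentence_end <- suppressWarnings(as.logical(as.integer(df$is_sentence_end)))
  df$left_context <- unesc(df$left_context)
  df$right_context <- unesc(df$right_context)
  df$right_token[is.na(df$right_token)] <- ""
  as_tibble(df)
}

#' Persist a trained model as JSON
#'
#' Models are written as self-contained JSON (weights, bias, cost, scaling
#' parameters, vocabularies, length statistics, collocation table and
#' lexicons); no binary serialization is involved. A sentence model embeds
#' its abbreviation model and records that model's hash, tying the two
#' together.
#'
#' @param model A `period_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_period_model <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = FALSE)
  invisible(path)
}

model_to_list <- function(model) {
  list(
    task = model$task,
    svm = list(
      feature = names(model$svm$w),
      weight = unname(model$svm$w),
      bias = model$svm$b,
      cost = model$svm$cost,
      positive_label = model$svm$positive_label
    ),
    scaling = list(
      mins = unname(model$scaling$mins),
      maxs = unname(model$scaling$maxs)
    ),
    set_tags = model$set_tags,
    sets = model$sets,
    vocabs = model$vocabs,
    counts = list(
      type = model$counts$type,
      c_dot = model$counts$c_dot,
      c_nodot = model$counts$c_nodot,
      total_dot = attr(model$counts, "total_dot"),
      total_nodot = attr(model$counts, "total_nodot")
    ),
    stats = unclass(model$stats),
    mddict = model$mddict$entries,
    ccdict = if (!is.null(model$ccdict)) model$ccdict$entries,
    abbrev_model = if (!is.null(model$abbrev_model)) {
      model_to_list(model$abbrev_model)
    },
    abbrev_model_hash = model$abbrev_model_hash,
    cc_capitalized = model$cc_capitalized,
    cost = model$cost,
    n_train = model$n_train
  )
}

#' @rdname write_period_model
#' @export
read_period_model <- function(path) {
  model_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

model_from_list <- function(obj) {
  counts <- tibble(
    type = as.character(obj$counts$type %||% character()),
    c_dot = as.integer(obj$counts$c_dot %||% integer()),
    c_nodot = as.integer(obj$counts$c_nodot %||% integer())
  )
  attr(counts, "total_dot") <- as.integer(obj$counts$total_dot)
  attr(counts, "total_nodot") <- as.integer(obj$counts$total_nodot)
  class(counts) <- c("count_table", class(counts))
  structure(
    list(
      task = obj$task,
      svm = structure(
        list(
          w = setNames(as.numeric(obj$svm$weight), obj$svm$feature),
          b = obj$svm$bias,
          cost = obj$svm$cost,
          positive_label = obj$svm$positive_label
        ),
        class = "linear_svm"
      ),
      scaling = list(
        mins = setNames(as.numeric(obj$scaling$mins), obj$svm$feature),
        maxs = setNames(as.numeric(obj$scaling$maxs), obj$svm$feature)
      ),
      feature_names = obj$svm$feature,
      set_tags = obj$set_tags,
      sets = obj$sets,
      vocabs = lapply(obj$vocabs, as.character),
      counts = counts,
      stats = structure(as.list(obj$stats), class = "length_stats"),
      mddict = lexicon(as.character(obj$mddict %||% character()), "MDDict"),
      ccdict = if (!is.null(obj$ccdict)) {
        lexicon(as.character(obj$ccdict), "CCDict")
      },
      abbrev_model = if (!is.null(obj$abbrev_model)) {
        model_from_list(obj$abbrev_model)
      },
      abbrev_model_hash = obj$abbrev_model_hash,
      cc_capitalized = obj$cc_capitalized,
      cost = obj$cost,
      n_train = obj$n_train
    ),
    class = "period_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
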