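#' Whitespace tokenization with newline bookkeeping
#'
#' Splits raw clinical text on spaces, tabs and newlines, so that periods are
#' always part of a token. The number of newline characters separating a token
#' from its predecessor is recorded on the token itself, because line breaks
#' carry formatting information (paragraph ends) that later becomes a
#' classification feature. Tokens consisting solely of non-alphanumeric
#' characters (stray punctuation produced by record extraction) are merged
#' into the preceding token; a purely non-alphanumeric first token is kept
#' standalone.
#'
#' @param text A single UTF-8 string. Newlines must be preserved in raw form.
#' @return A tibble with one row per token and columns
#'   \describe{
#'     \item{surface}{token text (merged punctuation separated by one space)}
#'     \item{leading_newlines}{number of `\n` characters between this token
#'       and the previous one}
#'     \item{start,end}{character offsets of the token's raw span in `text`}
#'   }
#'   The original text is attached as attribute `"text"`.
#' @examples
#' tokenize("St.p. TE eines exulz. sek.knot.SSM")
#' @export
tokenize <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("`text` must be a single non-NA character string.")
  }
  empty <- tibble(
    surface = character(), leading_newlines = integer(),
    start = integer(), end = integer()
  )
  if (!nzchar(text)) {
    attr(empty, "text") <- text
    return(empty)
  }

  m <- gregexpr("[^ \t\r\n]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    attr(empty, "text") <- text
    return(empty)
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  ends <- starts + lens - 1L
  surfaces <- substring(text, starts, ends)

  # newlines in the whitespace gap preceding each token
  gap_from <- c(1L, ends[-length(ends)] + 1L)
  gaps <- substring(text, gap_from, starts - 1L)
  nl <- vapply(gaps, function(g) {
    if (!nzchar(g)) 0L else stringr::str_count(g, stringr::fixed("\n"))
  }, integer(1), USE.NAMES = FALSE)

  # single left-to-right pass: punctuation-only tokens attach to the token
  # built so far; consecutive punctuation tokens therefore accumulate
  punct_only <- !stringr::str_detect(surfaces, "[\\p{L}\\p{N}]")
  out_surface <- character(0)
  out_nl <- integer(0)
  out_start <- integer(0)
  out_end <- integer(0)
  for (i in seq_along(surfaces)) {
    if (punct_only[i] && length(out_surface) > 0L) {
      j <- length(out_surface)
      out_surface[j] <- paste(out_surface[j], surfaces[i])
      out_end[j] <- ends[i]
    } else {
      out_surface <- c(out_surface, surfaces[i])
      out_nl <- c(out_nl, nl[i])
      out_start <- c(out_start, starts[i])
      out_end <- c(out_end, ends[i])
    }
  }

  out <- tibble(
    surface = out_surface, leading_newlines = out_nl,
    start = out_start, end = out_end
  )
  attr(out, "text") <- text
  out
}

#' Extract candidate period sites from a token stream
#'
#' A candidate site is a token whose surface ends with a period: by
#' construction of the whitespace tokenizer that period is followed by a
#' space, tab, newline or the end of the text. Token-internal periods
#' (flanked by alphanumerics, as in `"C43.5"` or the agglutination
#' `"sek.knot.SSM"`) never create sites, and neither do cases where a space
#' after the period was omitted by the typist.
#'
#' @param tokens A tibble from [tokenize()] (carries the source text as an
#'   attribute).
#' @param context_len Number of raw characters of left and right context to
#'   keep around the candidate period (default 60).
#' @return A tibble with one row per site: `left_token`, `right_token`
#'   (empty string at end of text), `left_context`, `right_context` (raw
#'   slices of the original text, newlines included), `newline_count` (the
#'   newlines between the period and the following token) and label columns
#'   `is_abbrev`, `is_sentence_end` initialised to `NA`.
#' @examples
#' extract_period_sites(tokenize("St.p. TE eines exulz. sek.knot.SSM"))
#' @export
extract_period_sites <- function(tokens, context_len = 60L) {
  text <- attr(tokens, "text")
  if (is.null(text)) {
    abort("`tokens` must come from tokenize(): missing \"text\" attribute.")
  }
  hits <- which(endsWith(tokens$surface, "."))
  n_char <- nchar(text)
  if (length(hits) == 0L) {
    return(tibble(
      left_token = character(), right_token = character(),
      left_context = character(), right_context = character(),
      newline_count = integer(), is_abbrev = logical(),
      is_sentence_end = logical()
    ))
  }
  pos <- tokens$end[hits] # offset of the candidate period itself
  nxt <- hits + 1L
  has_next <- nxt <= nrow(tokens)
  tibble(
    left_token = tokens$surface[hits],
    right_token = ifelse(has_next, tokens$surface[nxt], ""),
    left_context = substring(text, pmax(1L, pos - context_len), pos - 1L),
    right_context = substring(text, pos + 1L, pmin(n_char, pos + context_len)),
    newline_count = ifelse(has_next, tokens$leading_newlines[nxt], 0L),
    is_abbrev = NA,
    is_sentence_end = NA
  )
}

#' Extract period sites directly from text
#'
#' Convenience wrapper chaining [tokenize()] and [extract_period_sites()].
#'
#' @inheritParams tokenize
#' @inheritParams extract_period_sites
#' @return See [extract_period_sites()].
#' @export
period_sites <- function(text, context_len = 60L) {
  extract_period_sites(tokenize(text), context_len = context_len)
}

#' Normalize the left token of a period site
#'
#' Removes every character that is neither a Unicode letter, a digit nor a
#' period (umlauts and Eszett count as letters), then collapses runs of
#' adjacent periods into one. Internal periods are deliberately kept: they
#' are strong abbreviation evidence.
#'
#' @param x Character vector of left tokens (each typically ending in ".").
#' @return Character vector of the same length; may contain empty strings
#'   when nothing survives the filter.
#' @examples
#' normalize_left(c("(C43.5)", "St.p..", "St.p."))
#' @export
normalize_left <- function(x) {
  x <- stringr::str_remove_all(x, "[^\\p{L}\\p{N}.]")
  stringr::str_replace_all(x, "\\.{2,}", ".")
}

#' Normalize the right token of a period site
#'
#' Strips all non-alphanumeric characters (periods included), keeping only
#' the word content of the token following the candidate period.
#'
#' @param x Character vector of right tokens.
#' @return Character vector of the same length.
#' @examples
#' normalize_right(c("majus.", "(C43.5)", "IV"))
#' @export
normalize_right <- function(x) {
  stringr::str_remove_all(x, "[^\\p{L}\\p{N}]")
}

# drop one terminal period if present; the collocation type key and most
# left-token features operate on this form
strip_terminal_period <- function(x) {
  sub("\\.$", "", x)
}

# normalized left token without its terminal period
l_norm_of <- function(left_token) {
  strip_terminal_period(normalize_left(left_token))
}
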