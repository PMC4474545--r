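#' Lexicon objects
#'
#' A lexicon is a set of word forms with a role: either a medical-domain
#' dictionary guaranteed free of abbreviations (`"MDDict"`) or a closed-class
#' dictionary of function words such as prepositions, determiners,
#' conjunctions, pronouns and auxiliary/modal verbs (`"CCDict"`). Closed-class
#' words are the only German words not capitalized by default, so their
#' capitalization marks a sentence start.
#'
#' @param entries Character vector of word forms.
#' @param role `"MDDict"` or `"CCDict"`.
#' @return An object of class `lexicon`.
#' @export
lexicon <- function(entries = character(), role = c("MDDict", "CCDict")) {
  role <- match.arg(role)
  entries <- unique(entries[!is.na(entries) & nzchar(entries)])
  structure(
    list(
      entries = entries,
      entries_lower = tolower(entries),
      # prefix-query key: first character case-sensitive (German nouns are
      # capitalized and truncations preserve that), remainder case-folded
      entries_canon = canon_prefix_key(entries),
      role = role
    ),
    class = "lexicon"
  )
}

canon_prefix_key <- function(x) {
  ifelse(nchar(x) <= 1L, x, paste0(substr(x, 1L, 1L), tolower(substring(x, 2L))))
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon role=%s, %d entries>\n", x$role, length(x$entries)))
  invisible(x)
}

#' @export
length.lexicon <- function(x) length(x$entries)

#' Build an abbreviation-free medical-domain dictionary
#'
#' Takes one or more word sources, discards every token that ends with a
#' period, and then removes every word that matches a known short form
#' (abbreviation or acronym) once its terminal period(s) are stripped. The
#' result is a dictionary that can be assumed devoid of abbreviations, so a
#' successful lookup argues against the abbreviation reading of a period.
#'
#' @param word_sources Character vector or list of character vectors of
#'   candidate dictionary words.
#' @param abbreviation_lists Character vector or list of character vectors of
#'   known short forms (with or without their terminal periods).
#' @return A [lexicon()] with role `"MDDict"`.
#' @examples
#' build_mddict(c("Melanom", "etc."), "etc.")
#' @export
build_mddict <- function(word_sources, abbreviation_lists = character()) {
  words <- unlist(word_sources, use.names = FALSE)
  abbrevs <- unlist(abbreviation_lists, use.names = FALSE)
  if (length(words) == 0L) {
    warn("Empty word sources: returning an empty MDDict.")
    return(lexicon(character(), "MDDict"))
  }
  words <- unique(words[!is.na(words) & nzchar(words)])
  words <- words[!endsWith(words, ".")]
  stripped <- tolower(sub("\\.+$", "", abbrevs))
  words <- words[!(tolower(words) %in% stripped)]
  lexicon(words, "MDDict")
}

#' Build a closed-class dictionary
#'
#' @param closed_class_words Character vector of (non-capitalized) function
#'   word forms.
#' @return A [lexicon()] with role `"CCDict"`.
#' @export
build_ccdict <- function(closed_class_words) {
  lexicon(unlist(closed_class_words, use.names = FALSE), "CCDict")
}

#' Lexicon membership
#'
#' @param lex A [lexicon()].
#' @param words Character vector to look up.
#' @param case_insensitive Fold case before comparing?
#' @return Logical vector, one element per word.
#' @export
lex_contains <- function(lex, words, case_insensitive = FALSE) {
  stopifnot(inherits(lex, "lexicon"))
  if (case_insensitive) {
    tolower(words) %in% lex$entries_lower
  } else {
    words %in% lex$entries
  }
}

#' Count dictionary substring matches for a period-delimited form
#'
#' Ad-hoc abbreviations are truncations of longer dictionary words
#' ("exulz." from "exulzerierendes"), so each period-terminated subword of a
#' normalized left token is queried as a prefix against the dictionary. The
#' form `"St.p."` splits into the subwords `"St"` and `"p"`, and the counts
#' of dictionary entries having each subword as a prefix (exact matches
#' included) are summed. Prefix queries are case-sensitive on the first
#' character only, since truncations preserve the initial capitalization.
#'
#' @param lex A [lexicon()], normally the MDDict.
#' @param l_norm_with_period Character vector of normalized left tokens,
#'   each ending with a period (e.g. `"exulz."`, `"St.p."`).
#' @return Integer vector of summed prefix-match counts.
#' @examples
#' md <- build_mddict(c("exulzerierend", "exulzerierendes"))
#' substring_match_count(md, "exulz.")
#' @export
substring_match_count <- function(lex, l_norm_with_period) {
  stopifnot(inherits(lex, "lexicon"))
  bad <- nzchar(l_norm_with_period) & !endsWith(l_norm_with_period, ".")
  if (any(bad)) {
    abort("All inputs to substring_match_count() must end with a period.")
  }
  if (length(lex$entries) == 0L) {
    return(rep(0L, length(l_norm_with_period)))
  }
  uq <- unique(l_norm_with_period)
  counts <- vapply(uq, function(s) {
    subwords <- strsplit(s, ".", fixed = TRUE)[[1]]
    subwords <- subwords[nzchar(subwords)]
    if (length(subwords) == 0L) return(0L)
    total <- 0L
    for (w in canon_prefix_key(subwords)) {
      total <- total + sum(startsWith(lex$entries_canon, w))
    }
    total
  }, integer(1))
  unname(counts[match(l_norm_with_period, uq)])
}

#' Read a word list
#'
#' One word per line, UTF-8; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path Path to a plain-text word list.
#' @return Character vector of words.
#' @export
read_wordlist <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Write a word list
#'
#' @param words Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wordlist <- function(words, path) {
  readr::write_lines(words, path)
  invisible(path)
}
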