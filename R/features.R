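#' Feature-set configuration
#'
#' Both classifiers are trained on switchable feature blocks so that each
#' block can be evaluated in isolation or added stepwise. Abbreviation
#' blocks: `rules`, `statistical`, `scaling`, `dictionary`, `length`,
#' `wordtype`. Sentence blocks: `language`, `rules`, `textformat`, `length`,
#' `rc_wordtype`, `wordtype`, `abbreviation`.
#'
#' @param abbrev Character vector of enabled abbreviation blocks.
#' @param sentence Character vector of enabled sentence blocks.
#' @param cc_capitalized Should the closed-class sentence feature require
#'   the right token to be capitalized (a capitalized function word marks a
#'   sentence start), rather than plain membership? Default `TRUE`.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(abbrev = abbrev_feature_sets(),
                           sentence = sentence_feature_sets(),
                           cc_capitalized = TRUE) {
  abbrev <- match.arg(abbrev, abbrev_feature_sets(), several.ok = TRUE)
  sentence <- match.arg(sentence, sentence_feature_sets(), several.ok = TRUE)
  structure(
    list(abbrev = abbrev, sentence = sentence,
         cc_capitalized = isTRUE(cc_capitalized)),
    class = "feature_config"
  )
}

#' @rdname feature_config
#' @export
abbrev_feature_sets <- function() {
  c("rules", "statistical", "scaling", "dictionary", "length", "wordtype")
}

#' @rdname feature_config
#' @export
sentence_feature_sets <- function() {
  c("language", "rules", "textformat", "length", "rc_wordtype", "wordtype",
    "abbreviation")
}

#' Word-type masking
#'
#' Collapses each maximal run of digits to a single `"d"` so that numeric
#' tokens share a type (`"C43.5"` becomes `"Cd.d"`, every ordinal becomes
#' `"d"`), keeping the word-type vocabulary small.
#'
#' @param x Character vector of normalized tokens.
#' @return Character vector of masked types.
#' @examples
#' word_type("C43.5")
#' @export
word_type <- function(x) {
  stringr::str_replace_all(x, "\\p{N}+", "d")
}

# --- single rule helpers (0/1 numerics) ------------------------------------

contains_period <- function(x) as.numeric(stringr::str_detect(x, stringr::fixed(".")))
contains_digit <- function(x) as.numeric(stringr::str_detect(x, "\\p{N}"))
# every character an upper-case letter (acronym shape); strings containing
# digits, periods or any lower-case letter fail, as does the empty string
all_upper <- function(x) {
  as.numeric(stringr::str_detect(x, "^\\p{Lu}+$"))
}
is_capitalized <- function(x) as.numeric(stringr::str_detect(x, "^\\p{Lu}"))

length_block <- function(norm, stats, prefix = "") {
  len <- word_length(norm)
  n <- length(norm)
  out <- tibble(
    LT = as.numeric(len),
    LTborder.b1 = rep(stats$b1, n),
    LTborder.b2 = rep(stats$b2, n),
    LTborder.b3 = rep(stats$b3, n),
    GT.b1 = as.numeric(len > stats$b1),
    GT.b2 = as.numeric(len > stats$b2),
    GT.b3 = as.numeric(len > stats$b3),
    Mean.LT = stats$mu - len
  )
  if (nzchar(prefix)) names(out) <- paste0(prefix, names(out))
  out
}

onehot_block <- function(types, vocab, suffix = "") {
  m <- matrix(0, nrow = length(types), ncol = length(vocab))
  hit <- match(types, vocab)
  ok <- which(!is.na(hit))
  m[cbind(ok, hit[ok])] <- 1
  colnames(m) <- paste0(vocab, suffix)
  as_tibble(m, .name_repair = "minimal")
}

# per-unique-type statistical and scaling values, joined back onto sites
type_stat_table <- function(types, counts, mddict, want_scaling) {
  uq <- unique(types)
  cc <- collocation_counts(counts, uq)
  loglam <- log_lambda(cc$c_l_dot, cc$c_l_nodot, cc$c_notl_dot, cc$c_notl_nodot)
  out <- bind_cols(tibble(.type = uq), cc, tibble(logLambda = loglam))
  if (want_scaling) {
    combos <- scaling_combos()
    sc <- lapply(combos, function(co) {
      scaled_feature(co, loglam, uq, cc$c_l_dot, cc$c_l_nodot, mddict)
    })
    out <- bind_cols(out, as_tibble(sc))
  }
  out
}

#' Abbreviation-detection feature vectors
#'
#' Assembles the enabled feature blocks for each period site, in fixed
#' order: three binary rules on the normalized left token (internal period,
#' digit, all upper case), the four contingency counts plus the
#' log-likelihood ratio, the 63 power-set scaling features, the MDDict
#' lookup, the eight length features (absolute length, the three border
#' constants, three above-border flags, mean minus length) and the one-hot
#' word-type block over the masked left types.
#'
#' @param sites Period-site tibble from [extract_period_sites()].
#' @param counts `count_table` built from the training corpus.
#' @param stats `length_stats` from [abbreviation_length_stats()].
#' @param mddict MDDict [lexicon()].
#' @param sets Enabled blocks, a subset of [abbrev_feature_sets()].
#' @param vocab Frozen word-type vocabulary (character). When `NULL`
#'   (training) the vocabulary is built from `sites` and attached to the
#'   result as attribute `"vocab"`; unseen types at prediction time produce
#'   an all-zero block.
#' @return A tibble of numeric features, one row per site; attributes
#'   `"vocab"` and `"set_tags"` (block label per column).
#' @export
abbrev_features <- function(sites, counts, stats, mddict,
                            sets = abbrev_feature_sets(), vocab = NULL) {
  sets <- match.arg(sets, abbrev_feature_sets(), several.ok = TRUE)
  l_norm <- l_norm_of(sites$left_token)
  blocks <- list()
  tags <- list()

  if ("rules" %in% sets) {
    blocks$rules <- tibble(
      ContainsPeriod = contains_period(l_norm),
      ContainsDigit = contains_digit(l_norm),
      AllUpperCase = all_upper(l_norm)
    )
  }
  need_types <- any(c("statistical", "scaling") %in% sets)
  if (need_types) {
    ts <- type_stat_table(l_norm, counts, mddict, "scaling" %in% sets)
    row <- match(l_norm, ts$.type)
    if ("statistical" %in% sets) {
      blocks$statistical <- ts[row, c(
        "c_l_dot", "c_notl_dot", "c_l_nodot", "c_notl_nodot", "logLambda"
      )]
      names(blocks$statistical) <- c(
        "C.L.dot", "C.notL.dot", "C.L.nodot", "C.notL.nodot", "logLambda"
      )
    }
    if ("scaling" %in% sets) {
      blocks$scaling <- ts[row, names(scaling_combos())]
    }
  }
  if ("dictionary" %in% sets) {
    blocks$dictionary <- tibble(
      InMDDict = as.numeric(lex_contains(mddict, l_norm, case_insensitive = TRUE))
    )
  }
  if ("length" %in% sets) {
    blocks$length <- length_block(l_norm, stats)
  }
  if ("wordtype" %in% sets) {
    types <- word_type(l_norm)
    if (is.null(vocab)) vocab <- sort(unique(types))
    blocks$wordtype <- onehot_block(types, vocab)
  }

  out <- bind_cols(blocks, .name_repair = "minimal")
  tags <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
  attr(out, "set_tags") <- tags
  attr(out, "vocab") <- vocab
  out
}

#' Sentence-delimiter feature vectors
#'
#' Assembles the enabled feature blocks for each period site, in fixed
#' order: two language features (capitalized closed-class right token and
#' MDDict lookup of the right token), four binary rules (period in the raw
#' right token; digit, all-upper and capitalization on the normalized right
#' token), the three-way one-hot text-format block (no / single / double
#' newline before the right token), the eight length features computed on
#' the normalized right token, the one-hot right-context word types
#' (column names suffixed `"_RC"`), the one-hot left word types, and the
#' prediction of an abbreviation model on the very same site (an
#' abbreviation reading argues against a sentence boundary).
#'
#' @inheritParams abbrev_features
#' @param ccdict CCDict [lexicon()].
#' @param abbrev_model A fitted abbreviation `period_model`; required when
#'   the `abbreviation` block is enabled.
#' @param l_vocab,r_vocab Frozen word-type vocabularies for the left and
#'   right token blocks (built from `sites` when `NULL`).
#' @param cc_capitalized If `TRUE` (default) the closed-class feature fires
#'   only when the right token is capitalized and its lower-cased form is in
#'   CCDict; if `FALSE`, plain case-insensitive membership.
#' @param sets Enabled blocks, a subset of [sentence_feature_sets()].
#' @return A tibble of numeric features, one row per site; attributes
#'   `"l_vocab"`, `"r_vocab"` and `"set_tags"`.
#' @export
sentence_features <- function(sites, counts, stats, mddict, ccdict,
                              sets = sentence_feature_sets(),
                              abbrev_model = NULL,
                              l_vocab = NULL, r_vocab = NULL,
                              cc_capitalized = TRUE) {
  sets <- match.arg(sets, sentence_feature_sets(), several.ok = TRUE)
  r_norm <- normalize_right(sites$right_token)
  blocks <- list()

  if ("language" %in% sets) {
    if (cc_capitalized) {
      cc_feat <- is_capitalized(r_norm) *
        as.numeric(lex_contains(ccdict, tolower(r_norm)))
    } else {
      cc_feat <- as.numeric(lex_contains(ccdict, r_norm, case_insensitive = TRUE))
    }
    blocks$language <- tibble(
      InCCDict = cc_feat,
      InMDDict = as.numeric(lex_contains(mddict, r_norm, case_insensitive = TRUE))
    )
  }
  if ("rules" %in% sets) {
    blocks$rules <- tibble(
      ContainsPeriod = contains_period(sites$right_token),
      ContainsDigit = contains_digit(r_norm),
      AllUpperCase = all_upper(r_norm),
      Capitalization = is_capitalized(r_norm)
    )
  }
  if ("textformat" %in% sets) {
    nl <- sites$newline_count
    blocks$textformat <- tibble(
      NoNewline = as.numeric(nl == 0L),
      SingleNewline = as.numeric(nl == 1L),
      DoubleNewline = as.numeric(nl >= 2L)
    )
  }
  if ("length" %in% sets) {
    blocks$length <- length_block(r_norm, stats)
  }
  if ("rc_wordtype" %in% sets) {
    r_types <- word_type(r_norm)
    if (is.null(r_vocab)) r_vocab <- sort(unique(r_types))
    blocks$rc_wordtype <- onehot_block(r_types, r_vocab, suffix = "_RC")
  }
  if ("wordtype" %in% sets) {
    l_types <- word_type(l_norm_of(sites$left_token))
    if (is.null(l_vocab)) l_vocab <- sort(unique(l_types))
    blocks$wordtype <- onehot_block(l_types, l_vocab)
  }
  if ("abbreviation" %in% sets) {
    if (is.null(abbrev_model)) {
      abort("The `abbreviation` block requires a fitted `abbrev_model`.")
    }
    blocks$abbreviation <- tibble(
      Abbreviation = as.numeric(predict(abbrev_model, sites))
    )
  }

  out <- bind_cols(blocks, .name_repair = "minimal")
  attr(out, "set_tags") <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
  attr(out, "l_vocab") <- l_vocab
  attr(out, "r_vocab") <- r_vocab
  out
}
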