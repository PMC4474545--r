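#' Configuration for the synthetic clinical-corpus generator
#'
#' The generator emulates the statistical structure of German dermatology
#' discharge summaries: telegram-style sentences over a medical vocabulary,
#' lexicalized abbreviations ("St.p.", "ca.", "Pat."), ad-hoc truncations of
#' long dictionary words ("exulz.", "Tumordurchm."), ordinals ("3."), dates
#' ("3.5.2014"), acronyms ("SSM"), ICD-style codes ("(C43.5)"), capitalized
#' sentence starts, double-role periods (an abbreviation that also ends its
#' sentence) and newline contamination from record extraction.
#'
#' Token-category rates apply per internal sentence slot and must sum to at
#' most 1 (the remainder are ordinary words); `cc_rate` is the share of
#' ordinary words drawn from the closed-class list. Defaults are chosen to
#' keep the two label marginals roughly balanced.
#'
#' @param n_sentences Number of sentences to generate.
#' @param abbrev_rate Rate of lexicalized abbreviations per internal slot.
#' @param adhoc_rate Rate of ad-hoc truncations of dictionary words.
#' @param ordinal_rate Rate of ordinal numbers ("3.").
#' @param date_rate Rate of full dates ("3.5.2014", no candidate period).
#' @param acronym_rate Rate of acronyms (never period-terminated).
#' @param icd_rate Rate of parenthesized ICD-style codes.
#' @param cc_rate Share of ordinary-word slots filled by closed-class words.
#' @param double_role_rate Probability that a sentence ends in an
#'   abbreviation whose period doubles as the sentence delimiter.
#' @param paragraph_rate Probability of a double newline after a sentence.
#' @param sentence_newline_rate Probability of a single newline (instead of
#'   a space) after a sentence, a mild extraction artifact.
#' @param newline_contamination Probability of a spurious single newline
#'   replacing a space between two tokens inside a sentence.
#' @param sentence_length Integer range (min, max) of tokens per sentence.
#' @param seed Seed fixing the output bit-exactly.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_sentences = 1200,
                             abbrev_rate = 0.18,
                             adhoc_rate = 0.08,
                             ordinal_rate = 0.05,
                             date_rate = 0.03,
                             acronym_rate = 0.04,
                             icd_rate = 0.03,
                             cc_rate = 0.25,
                             double_role_rate = 0.15,
                             paragraph_rate = 0.30,
                             sentence_newline_rate = 0.20,
                             newline_contamination = 0.08,
                             sentence_length = c(4L, 9L),
                             seed = 1L) {
  cfg <- list(
    n_sentences = as.integer(n_sentences),
    abbrev_rate = abbrev_rate, adhoc_rate = adhoc_rate,
    ordinal_rate = ordinal_rate, date_rate = date_rate,
    acronym_rate = acronym_rate, icd_rate = icd_rate,
    cc_rate = cc_rate, double_role_rate = double_role_rate,
    paragraph_rate = paragraph_rate,
    sentence_newline_rate = sentence_newline_rate,
    newline_contamination = newline_contamination,
    sentence_length = as.integer(sentence_length),
    seed = as.integer(seed)
  )
  probs <- unlist(cfg[c(
    "abbrev_rate", "adhoc_rate", "ordinal_rate", "date_rate",
    "acronym_rate", "icd_rate", "cc_rate", "double_role_rate",
    "paragraph_rate", "sentence_newline_rate", "newline_contamination"
  )])
  if (any(probs < 0 | probs > 1)) abort("All rates must lie in [0, 1].")
  cat_sum <- cfg$abbrev_rate + cfg$adhoc_rate + cfg$ordinal_rate +
    cfg$date_rate + cfg$acronym_rate + cfg$icd_rate
  if (cat_sum > 1) {
    abort("Token-category rates sum to more than 1; no room for words.")
  }
  if (cfg$paragraph_rate + cfg$sentence_newline_rate > 1) {
    abort("paragraph_rate + sentence_newline_rate must not exceed 1.")
  }
  if (cfg$n_sentences < 1L) abort("`n_sentences` must be at least 1.")
  if (length(cfg$sentence_length) != 2L ||
      cfg$sentence_length[1] < 2L ||
      cfg$sentence_length[2] < cfg$sentence_length[1]) {
    abort("`sentence_length` must be c(min, max) with 2 <= min <= max.")
  }
  structure(cfg, class = "generator_config")
}

# fixed closed-class inventory: prepositions, determiners, conjunctions,
# pronouns, auxiliaries and modals
.cc_words <- c(
  "der", "die", "das", "ein", "eine", "eines", "einem", "und", "oder",
  "im", "in", "am", "an", "mit", "ohne", "bei", "nach", "von", "vor",
  "zur", "zum", "auf", "unter", "aus", "sowie", "bis", "dem", "den",
  "des", "ist", "war", "sind", "waren", "wird", "wurde", "wurden",
  "kann", "soll", "keine", "kein", "sich", "es", "auch", "wir", "sie"
)

# lexicalized clinical short forms, weighted roughly zipf-like
.abbrev_inventory <- c(
  "St.p." = 10, "Z.n." = 8, "ca." = 9, "Pat." = 8, "o.B." = 6,
  "bds." = 5, "li." = 5, "re." = 5, "max." = 4, "unauff." = 4,
  "Amb." = 3, "sek." = 3, "tgl." = 3, "ggf." = 3, "z.B." = 3,
  "bzw." = 3, "inkl." = 2, "Lab." = 2, "Tbl." = 2, "u.a." = 2,
  "Exz." = 2, "lat." = 2, "med." = 2, "n." = 1, "St." = 1
)

.acronyms <- c("TE", "SSM", "CT", "MRT", "OP", "PE", "LK", "BB", "EKG")

.noun_stems <- c(
  "Tumor", "Haut", "Zell", "Gewebe", "Melanom", "Exzision", "Therapie",
  "Befund", "Kontroll", "Narben", "Lymph", "Knoten", "Leber", "Lungen",
  "Rippen", "Schnitt", "Rand", "Punktion", "Biopsie", "Infiltrat",
  "Pigment", "Wund", "Haar", "Nagel", "Muttermal", "Basal", "Plattenepithel"
)

.noun_suffixes <- c(
  "befund", "kontrolle", "durchmesser", "entfernung", "veränderung",
  "gewebe", "anteil", "region", "struktur", "zeichnung", "bereich",
  "randsaum", "bildung", "dicke", "exzision", "läsion", "knoten"
)

.adj_stems <- c(
  "exulzerier", "pigmentier", "knot", "entzünd", "verschieb", "erforder",
  "patholog", "unauffäll", "oberflächl", "tastbar", "derb", "narbig",
  "melanozyt", "suspekt", "regulär", "vergrößer", "druckschmerzhaf"
)

.adj_suffixes <- c("end", "ende", "endes", "t", "te", "tes", "ig", "ige",
                   "lich", "liche", "licher")

.verbs <- c(
  "zeigt", "zeigte", "besteht", "bestand", "erfolgte", "empfohlen",
  "durchgeführt", "reseziert", "entfernt", "kontrolliert", "dokumentiert",
  "beschrieben", "tastet", "imponiert", "persistiert"
)

#' Generate synthetic lexicons
#'
#' Builds a synthetic medical vocabulary of inflected-looking compound
#' words (so that ad-hoc truncations are genuine prefixes of dictionary
#' entries), a fixed closed-class list, and a weighted inventory of
#' lexicalized clinical abbreviations. The dictionary is passed through
#' [build_mddict()] against the abbreviation inventory, so its entries
#' never collide with a stripped short form.
#'
#' @param seed Seed fixing the vocabulary.
#' @param n_words Minimum dictionary size.
#' @return List with `mddict`, `ccdict` (lexicons) and `abbreviations`
#'   (named numeric vector of sampling weights).
#' @export
generate_lexicons <- function(seed = 1L, n_words = 400L) {
  nouns <- as.vector(outer(.noun_stems, .noun_suffixes, paste0))
  adjs <- as.vector(outer(.adj_stems, .adj_suffixes, paste0))
  words <- withr_seed(seed, {
    n_nouns <- min(length(nouns), ceiling(n_words * 0.6))
    n_adjs <- min(length(adjs), ceiling(n_words * 0.3))
    c(sample(nouns, n_nouns), sample(adjs, n_adjs), .verbs)
  })
  list(
    mddict = build_mddict(list(words), list(names(.abbrev_inventory))),
    ccdict = build_ccdict(.cc_words),
    abbreviations = .abbrev_inventory
  )
}

#' Generate a labeled synthetic clinical corpus
#'
#' Emits raw text plus a gold-standard tibble of every candidate period
#' site with its abbreviation and sentence-delimiter labels. Labels are
#' assigned at generation time, when the role of each period is known by
#' construction, never re-derived from the rendered text; this keeps the
#' generator and the site extractor independent of each other.
#'
#' @param cfg A [generator_config()].
#' @param lexicons Output of [generate_lexicons()]; generated from
#'   `cfg$seed` when `NULL`.
#' @return List with `text` (single string) and `gold` (period-site tibble
#'   with filled `is_abbrev`, `is_sentence_end`).
#' @export
generate_corpus <- function(cfg = generator_config(), lexicons = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(lexicons)) lexicons <- generate_lexicons(cfg$seed)
  md_words <- lexicons$mddict$entries
  truncatable <- md_words[nchar(md_words) >= 8 &
                            !stringr::str_detect(md_words, "[^\\p{L}]")]
  abbrevs <- lexicons$abbreviations
  abbrev_names <- names(abbrevs)
  abbrev_p <- abbrevs / sum(abbrevs)

  withr_seed(cfg$seed, {
    surfaces <- character(0)
    is_site <- logical(0)
    lab_abbrev <- logical(0)
    lab_sentence <- logical(0)
    delim <- character(0)

    draw_word <- function() {
      if (stats::runif(1) < cfg$cc_rate) sample(.cc_words, 1)
      else sample(md_words, 1)
    }
    draw_adhoc <- function() {
      w <- sample(truncatable, 1)
      cut <- sample(4:(nchar(w) - 2L), 1)
      paste0(substr(w, 1, cut), ".")
    }
    draw_internal <- function() {
      u <- stats::runif(1)
      breaks <- cumsum(c(cfg$abbrev_rate, cfg$adhoc_rate, cfg$ordinal_rate,
                         cfg$date_rate, cfg$acronym_rate, cfg$icd_rate))
      if (u < breaks[1]) {
        list(surface = sample(abbrev_names, 1, prob = abbrev_p),
             site = TRUE, abbrev = TRUE)
      } else if (u < breaks[2]) {
        list(surface = draw_adhoc(), site = TRUE, abbrev = TRUE)
      } else if (u < breaks[3]) {
        list(surface = paste0(sample(1:30, 1), "."), site = TRUE,
             abbrev = TRUE)
      } else if (u < breaks[4]) {
        list(surface = sprintf("%d.%d.%d", sample(1:28, 1), sample(1:12, 1),
                               sample(2007:2014, 1)),
             site = FALSE, abbrev = FALSE)
      } else if (u < breaks[5]) {
        list(surface = sample(.acronyms, 1), site = FALSE, abbrev = FALSE)
      } else if (u < breaks[6]) {
        list(surface = sprintf("(C%d.%d)", sample(0:99, 1), sample(0:9, 1)),
             site = FALSE, abbrev = FALSE)
      } else {
        list(surface = draw_word(), site = FALSE, abbrev = FALSE)
      }
    }
    capitalize <- function(x) {
      paste0(toupper(substr(x, 1, 1)), substring(x, 2))
    }

    for (s in seq_len(cfg$n_sentences)) {
      len <- sample(cfg$sentence_length[1]:cfg$sentence_length[2], 1)
      # internal slots
      for (j in seq_len(len - 1L)) {
        tok <- if (j == 1L) {
          list(surface = capitalize(draw_word()), site = FALSE, abbrev = FALSE)
        } else {
          draw_internal()
        }
        surfaces <- c(surfaces, tok$surface)
        is_site <- c(is_site, tok$site)
        lab_abbrev <- c(lab_abbrev, tok$abbrev)
        lab_sentence <- c(lab_sentence, FALSE)
        d <- if (stats::runif(1) < cfg$newline_contamination) "\n" else " "
        delim <- c(delim, d)
      }
      # final slot: ordinary word + "." or a double-role abbreviation
      if (stats::runif(1) < cfg$double_role_rate) {
        final <- if (stats::runif(1) < 0.5 && length(truncatable) > 0) {
          draw_adhoc()
        } else {
          sample(abbrev_names, 1, prob = abbrev_p)
        }
        final_abbrev <- TRUE
      } else {
        final <- paste0(draw_word(), ".")
        final_abbrev <- FALSE
      }
      surfaces <- c(surfaces, final)
      is_site <- c(is_site, TRUE)
      lab_abbrev <- c(lab_abbrev, final_abbrev)
      lab_sentence <- c(lab_sentence, TRUE)
      u <- stats::runif(1)
      d <- if (u < cfg$paragraph_rate) "\n\n"
           else if (u < cfg$paragraph_rate + cfg$sentence_newline_rate) "\n"
           else " "
      delim <- c(delim, d)
    }
    delim[length(delim)] <- "" # no trailing delimiter

    text <- paste0(surfaces, delim, collapse = "")
    ends <- cumsum(nchar(surfaces) + nchar(delim)) - nchar(delim)
    nl_after <- stringr::str_count(delim, stringr::fixed("\n"))
    n_tok <- length(surfaces)
    site_idx <- which(is_site)
    has_next <- site_idx < n_tok
    n_char <- nchar(text)
    pos <- ends[site_idx]

    gold <- tibble(
      left_token = surfaces[site_idx],
      right_token = ifelse(has_next, surfaces[pmin(site_idx + 1L, n_tok)], ""),
      left_context = substring(text, pmax(1L, pos - 60L), pos - 1L),
      right_context = substring(text, pos + 1L, pmin(n_char, pos + 60L)),
      newline_count = ifelse(has_next, nl_after[site_idx], 0L),
      is_abbrev = lab_abbrev[site_idx],
      is_sentence_end = lab_sentence[site_idx]
    )
    list(text = text, gold = gold)
  })
}
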