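#' Corpus collocation counts between word types and the period
#'
#' For every token, its normalized form with the terminal period stripped is
#' the type key; the token contributes to `c_dot` when its surface ends with
#' a period and to `c_nodot` otherwise. From this table the full 2x2
#' contingency for any type (type vs. rest of corpus, period vs. no period)
#' can be derived.
#'
#' @param tokens Token tibble from [tokenize()].
#' @return A tibble of class `count_table` with columns `type`, `c_dot`,
#'   `c_nodot`, and attributes `total_dot` / `total_nodot` (corpus totals).
#' @examples
#' count_collocations(tokenize("ca. 5 mm ca. groß ca"))
#' @export
count_collocations <- function(tokens) {
  if (nrow(tokens) == 0L) {
    out <- tibble(type = character(), c_dot = integer(), c_nodot = integer())
    attr(out, "total_dot") <- 0L
    attr(out, "total_nodot") <- 0L
    class(out) <- c("count_table", class(out))
    return(out)
  }
  has_dot <- endsWith(tokens$surface, ".")
  type <- l_norm_of(tokens$surface)
  keep <- nzchar(type)
  df <- tibble(type = type[keep], dot = has_dot[keep])
  out <- df %>%
    group_by(.data$type) %>%
    summarise(
      c_dot = sum(.data$dot),
      c_nodot = sum(!.data$dot),
      .groups = "drop"
    ) %>%
    arrange(.data$type)
  attr(out, "total_dot") <- sum(out$c_dot)
  attr(out, "total_nodot") <- sum(out$c_nodot)
  class(out) <- c("count_table", class(out))
  out
}

#' Look up the period contingency for word types
#'
#' @param table A `count_table` from [count_collocations()].
#' @param types Character vector of type keys (normalized left tokens without
#'   their terminal period). Unseen types get zero type counts.
#' @return A tibble with one row per input type and columns `c_l_dot`,
#'   `c_l_nodot`, `c_notl_dot`, `c_notl_nodot`.
#' @export
collocation_counts <- function(table, types) {
  idx <- match(types, table$type)
  c_l_dot <- ifelse(is.na(idx), 0L, table$c_dot[idx])
  c_l_nodot <- ifelse(is.na(idx), 0L, table$c_nodot[idx])
  tibble(
    c_l_dot = as.numeric(c_l_dot),
    c_l_nodot = as.numeric(c_l_nodot),
    c_notl_dot = as.numeric(attr(table, "total_dot")) - c_l_dot,
    c_notl_nodot = as.numeric(attr(table, "total_nodot")) - c_l_nodot
  )
}

#' Dunning log-likelihood ratio for a 2x2 period collocation table
#'
#' Measures the association between a word type and a following period:
#' `-2 log(L(H0)/L(HA))` where H0 holds that the period occurs independently
#' of the preceding word and HA that it does not. Computed in log space as
#' the G statistic of the 2x2 table (observed-vs-expected entropy form) with
#' the convention `0 * log(0) = 0`. Always non-negative; zero exactly when
#' the two rows have identical period proportions.
#'
#' @param c_l_dot,c_l_nodot,c_notl_dot,c_notl_nodot Numeric vectors: counts
#'   of the type with / without a period and of all other tokens with /
#'   without a period. Vectors are recycled to a common length.
#' @return Numeric vector of log-likelihood ratio statistics.
#' @examples
#' log_lambda(10, 10, 10, 10) # independence -> 0
#' log_lambda(20, 10, 5, 1000)
#' @export
log_lambda <- function(c_l_dot, c_l_nodot, c_notl_dot, c_notl_nodot) {
  k <- cbind(c_l_dot, c_l_nodot, c_notl_dot, c_notl_nodot)
  if (any(k < 0)) abort("Counts must be non-negative.")
  n <- rowSums(k)
  if (any(n == 0)) abort("All-zero contingency table.")
  row1 <- k[, 1] + k[, 2]
  row2 <- k[, 3] + k[, 4]
  col1 <- k[, 1] + k[, 3]
  col2 <- k[, 2] + k[, 4]
  expected <- cbind(row1 * col1, row1 * col2, row2 * col1, row2 * col2) / n
  # log1p of the relative deviation keeps near-independent tables accurate
  term <- k * log1p((k - expected) / expected)
  term[k == 0] <- 0 # 0 * log 0 convention
  g <- 2 * rowSums(term)
  pmax(g, 0) # guard against tiny negative rounding residue
}

#' Non-period word length
#'
#' The length of a candidate counts only its non-period characters, so
#' internal periods (themselves abbreviation evidence) are not penalized:
#' `word_length("St.p.")` is 3.
#'
#' @param token Character vector.
#' @return Integer vector of non-period character counts.
#' @examples
#' word_length("St.p.")
#' @export
word_length <- function(token) {
  nchar(gsub(".", "", token, fixed = TRUE))
}

# exponent guard for S1: exp() overflows to Inf above ~709 and feature
# values must stay finite
.s1_exponent_cap <- 700

#' Scaling functions for the log-likelihood ratio
#'
#' Six functions re-weight the raw collocation statistic `loglam` with
#' abbreviation evidence. S1-S5 multiply it by a factor, S6 adds the
#' dictionary substring-match count:
#' \describe{
#'   \item{S1}{`loglam * exp(C(L,dot)/C(L,nodot))` - boosts types that
#'     collocate with the period (denominator floored at 1 to stay finite).}
#'   \item{S2}{`loglam * (C(L,dot)-C(L,nodot))/(C(L,dot)+C(L,nodot))` - a
#'     factor in \[-1, 1\], negative when the type occurs mostly without a
#'     period (0 when both counts are 0).}
#'   \item{S3}{`loglam / exp(word_length(l_norm))` - punishes long words;
#'     most abbreviations are short.}
#'   \item{S4}{`loglam * (number of internal periods + 1)` - internal
#'     periods suggest abbreviations.}
#'   \item{S5}{`loglam * (1/word_length)^C(L,nodot)` - exponentially
#'     penalizes types frequently seen without a period, more so for long
#'     ones (word length floored at 1).}
#'   \item{S6}{`loglam + N(l_norm.)` - adds the dictionary prefix-match
#'     count ([substring_match_count()]); being additive it can push a
#'     negatively weighted value back above zero.}
#' }
#'
#' @param k Index of the scaling function, 1 to 6.
#' @param loglam Numeric vector: the value being scaled (the raw statistic,
#'   or a running value during composition).
#' @param l_norm Character vector: normalized left token without its
#'   terminal period (e.g. `"St.p"`).
#' @param c_l_dot,c_l_nodot Numeric vectors of type/period counts.
#' @param mddict [lexicon()] used by S6.
#' @return Numeric vector of scaled values.
#' @examples
#' scaling_factor(4, loglam = 2, l_norm = "St.p", c_l_dot = 3, c_l_nodot = 0)
#' @export
scaling_factor <- function(k, loglam, l_norm, c_l_dot, c_l_nodot,
                           mddict = NULL) {
  stopifnot(length(k) == 1L, k %in% 1:6)
  switch(k,
    { # S1
      expo <- pmin(c_l_dot / pmax(c_l_nodot, 1), .s1_exponent_cap)
      loglam * exp(expo)
    },
    { # S2
      ratio <- (c_l_dot - c_l_nodot) / (c_l_dot + c_l_nodot)
      ratio[!is.finite(ratio)] <- 0
      loglam * ratio
    },
    loglam * exp(-word_length(l_norm)), # S3
    loglam * (stringr::str_count(l_norm, stringr::fixed(".")) + 1), # S4
    loglam * (1 / pmax(word_length(l_norm), 1))^c_l_nodot, # S5
    { # S6
      if (is.null(mddict)) abort("S6 requires `mddict`.")
      loglam + substring_match_count(mddict, paste0(l_norm, "."))
    }
  )
}

#' All non-empty subsets of the six scaling functions
#'
#' @return A named list of 63 integer vectors, ordered by the binary
#'   encoding of the subset (S1 is the low bit); names like `"S2.S3"`.
#' @export
scaling_combos <- function() {
  combos <- lapply(1:63, function(m) which(bitwAnd(m, 2^(0:5)) > 0L))
  names(combos) <- vapply(
    combos, function(co) paste0("S", co, collapse = "."), character(1)
  )
  combos
}

#' Sequential composition of scaling functions
#'
#' Applies the scaling functions of a subset in ascending index order, each
#' transforming the running value; every one of the 63 non-empty subsets
#' yields one feature.
#'
#' @param combo Non-empty integer subset of 1:6.
#' @inheritParams scaling_factor
#' @return Numeric vector of composed scaled values.
#' @examples
#' # {2, 3}: first S2, then S3
#' scaled_feature(c(2, 3), loglam = 4, l_norm = "x", c_l_dot = 3, c_l_nodot = 1)
#' @export
scaled_feature <- function(combo, loglam, l_norm, c_l_dot, c_l_nodot,
                           mddict = NULL) {
  combo <- sort(unique(as.integer(combo)))
  if (length(combo) == 0L || !all(combo %in% 1:6)) {
    abort("`combo` must be a non-empty subset of 1:6.")
  }
  value <- loglam
  for (k in combo) {
    value <- scaling_factor(k, value, l_norm, c_l_dot, c_l_nodot, mddict)
  }
  value
}

#' Abbreviation length statistics from corpus collocations
#'
#' Selects the word types whose collocation with the period is significant
#' (log-likelihood ratio above the chi-squared critical value with one
#' degree of freedom at level `alpha`) and which occur more often with a
#' period than without. These types are treated as corpus abbreviations and
#' the mean and population standard deviation of their non-period lengths
#' define three right-tailed decision borders.
#'
#' @param table A `count_table` from [count_collocations()].
#' @param alpha Significance level for the collocation filter (default 0.01).
#' @return An object of class `length_stats`: list with `mu`, `sigma`,
#'   `b1 = mu + 1.645 sigma`, `b2 = mu + 1.960 sigma`,
#'   `b3 = mu + 2.576 sigma`, and `n_types`, the number of selected types.
#' @export
abbreviation_length_stats <- function(table, alpha = 0.01) {
  if (nrow(table) == 0L) abort("Empty count table.")
  cc <- collocation_counts(table, table$type)
  loglam <- log_lambda(cc$c_l_dot, cc$c_l_nodot, cc$c_notl_dot, cc$c_notl_nodot)
  crit <- qchisq(1 - alpha, df = 1)
  sel <- loglam > crit & table$c_dot > table$c_nodot
  if (!any(sel)) {
    abort(paste(
      "No word type shows a significant period collocation;",
      "use a larger corpus to estimate abbreviation length statistics."
    ))
  }
  lens <- word_length(table$type[sel])
  mu <- mean(lens)
  sigma <- sqrt(mean((lens - mu)^2)) # population SD
  structure(
    list(
      mu = mu, sigma = sigma,
      b1 = mu + 1.645 * sigma,
      b2 = mu + 1.960 * sigma,
      b3 = mu + 2.576 * sigma,
      n_types = sum(sel)
    ),
    class = "length_stats"
  )
}

#' @export
print.length_stats <- function(x, ...) {
  cat(sprintf(
    "<length_stats: mu=%.3f sigma=%.3f b1=%.3f b2=%.3f b3=%.3f (%d types)>\n",
    x$mu, x$sigma, x$b1, x$b2, x$b3, x$n_types
  ))
  invisible(x)
}
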