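# Shared fixtures and independent oracles. Heavy objects are built lazily
# and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small training/test corpora for pipeline-level tests
small_world <- function() {
  cached("small_world", function() {
    lex <- generate_lexicons(7)
    train <- generate_corpus(generator_config(n_sentences = 180, seed = 11), lex)
    test <- generate_corpus(generator_config(n_sentences = 120, seed = 22), lex)
    counts <- count_collocations(tokenize(train$text))
    list(
      lex = lex, train = train, test = test, counts = counts,
      stats = abbreviation_length_stats(counts)
    )
  })
}

# full-scale corpora for the acceptance-level checks (~3,000 sites each)
acceptance_world <- function() {
  cached("acceptance_world", function() {
    lex <- generate_lexicons(1)
    train <- generate_corpus(generator_config(n_sentences = 1250, seed = 101), lex)
    test <- generate_corpus(generator_config(n_sentences = 1250, seed = 202), lex)
    counts <- count_collocations(tokenize(train$text))
    list(
      lex = lex, train = train, test = test, counts = counts,
      stats = abbreviation_length_stats(counts)
    )
  })
}

acceptance_abbrev_model <- function() {
  cached("acceptance_abbrev_model", function() {
    w <- acceptance_world()
    fit_period_classifier(
      w$train$gold, "abbreviation", w$counts, w$lex$mddict, stats = w$stats
    )
  })
}

# independent oracle: Dunning's ratio -2 log(L(H0)/L(HA)) evaluated directly
# from the two binomial likelihoods, cell by cell (each factor of the
# likelihood ratio contributes k * log(p_alt / p_null))
oracle_log_lambda <- function(k11, k12, k21, k22) {
  n1 <- k11 + k12
  n2 <- k21 + k22
  p1 <- k11 / n1
  p2 <- k21 / n2
  p <- (k11 + k21) / (n1 + n2)
  cell <- function(k, p_alt, p_null) if (k == 0) 0 else k * log(p_alt / p_null)
  2 * (cell(k11, p1, p) + cell(k12, 1 - p1, 1 - p) +
         cell(k21, p2, p) + cell(k22, 1 - p2, 1 - p))
}

# random 2x2 tables with positive row sums
random_tables <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    k11 = rpois(n, 8),
    k12 = rpois(n, 15),
    k21 = rpois(n, 25) + 1L,
    k22 = rpois(n, 150) + 1L
  ) |> dplyr::mutate(k12 = ifelse(k11 + k12 == 0, 1L, k12))
}

# build a count_table directly from per-type counts
make_count_table <- function(type, c_dot, c_nodot) {
  out <- tibble::tibble(type = type, c_dot = as.integer(c_dot),
                        c_nodot = as.integer(c_nodot))
  attr(out, "total_dot") <- sum(out$c_dot)
  attr(out, "total_nodot") <- sum(out$c_nodot)
  class(out) <- c("count_table", class(out))
  out
}

# minimal period-site tibble for feature tests
make_sites <- function(left_token, right_token = "", newline_count = 0L,
                       is_abbrev = NA, is_sentence_end = NA) {
  n <- max(length(left_token), length(right_token), length(newline_count))
  tibble::tibble(
    left_token = rep_len(left_token, n),
    right_token = rep_len(right_token, n),
    left_context = rep_len("", n),
    right_context = rep_len("", n),
    newline_count = rep_len(as.integer(newline_count), n),
    is_abbrev = rep_len(is_abbrev, n),
    is_sentence_end = rep_len(is_sentence_end, n)
  )
}

# separable two-blob classification problem
blobs <- function(n = 60, d = 4, gap = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n / 2 * d, gap), n / 2, d),
    matrix(rnorm(n / 2 * d, -gap), n / 2, d)
  )
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, y = rep(c(TRUE, FALSE), each = n / 2))
}
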