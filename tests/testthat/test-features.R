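ws <- function() small_world()

test_that("word-type masking collapses digit runs", {
  expect_equal(word_type("C43.5"), "Cd.d")
  expect_equal(word_type("3"), "d")
  expect_equal(word_type("3.5.2014"), "d.d.d")
  expect_equal(word_type("St.p"), "St.p")
})

test_that("abbreviation rule features follow the left-token definitions", {
  w <- ws()
  sites <- make_sites(c("(C43.5).", "TE.", "abc.", "5."))
  f <- abbrev_features(sites, w$counts, w$stats, w$lex$mddict, sets = "rules")
  expect_equal(f$ContainsPeriod, c(1, 0, 0, 0))
  expect_equal(f$ContainsDigit, c(1, 0, 0, 1))
  # mixed-case and digit-only strings are not all-upper; pure caps are
  expect_equal(f$AllUpperCase, c(0, 1, 0, 0))
})

test_that("the scaling block holds exactly 63 features per site", {
  w <- ws()
  sites <- make_sites(c("St.p.", "ca."))
  f <- abbrev_features(sites, w$counts, w$stats, w$lex$mddict, sets = "scaling")
  expect_equal(ncol(f), 63L)
  expect_equal(names(f), names(scaling_combos()))
  expect_true(all(is.finite(as.matrix(f))))
})

test_that("isolated feature sets yield only their own block", {
  w <- ws()
  sites <- make_sites(c("ca.", "Melanom."))
  for (set in abbrev_feature_sets()) {
    f <- abbrev_features(sites, w$counts, w$stats, w$lex$mddict, sets = set)
    expect_true(all(attr(f, "set_tags") == set))
  }
  f2 <- abbrev_features(sites, w$counts, w$stats, w$lex$mddict,
                        sets = c("rules", "dictionary"))
  expect_equal(unique(attr(f2, "set_tags")), c("rules", "dictionary"))
  expect_equal(ncol(f2), 4L)
})

test_that("length block carries borders, flags and mean-minus-length", {
  w <- ws()
  sites <- make_sites("Lymphknotenentfernung.")
  f <- abbrev_features(sites, w$counts, w$stats, w$lex$mddict, sets = "length")
  expect_equal(ncol(f), 8L)
  expect_equal(f$LT, word_length("Lymphknotenentfernung"))
  expect_equal(f$LTborder.b2, w$stats$b2)
  expect_equal(f$GT.b3, as.numeric(f$LT > w$stats$b3))
  expect_equal(f$Mean.LT, w$stats$mu - f$LT)
})

test_that("word-type one-hot blocks are frozen and at most one-hot", {
  w <- ws()
  train_sites <- w$train$gold[1:200, ]
  f <- abbrev_features(train_sites, w$counts, w$stats, w$lex$mddict,
                       sets = "wordtype")
  m <- as.matrix(f)
  expect_true(all(rowSums(m) <= 1))
  vocab <- attr(f, "vocab")
  # unseen type at prediction time -> all-zero block, same columns
  new_sites <- make_sites("Qqqqzzz.")
  f2 <- abbrev_features(new_sites, w$counts, w$stats, w$lex$mddict,
                        sets = "wordtype", vocab = vocab)
  expect_equal(names(f2), names(f))
  expect_equal(sum(as.matrix(f2)), 0)
})

test_that("sentence language and rule features read the right token", {
  w <- ws()
  cc <- build_ccdict(c("die", "der"))
  sites <- make_sites(
    left_token = "ca.",
    right_token = c("Die", "die", "majus.", "(C43.5)", "TE")
  )
  f <- sentence_features(sites, w$counts, w$stats, w$lex$mddict, cc,
                         sets = c("language", "rules"))
  # capitalized closed-class form marks a sentence start
  expect_equal(f$InCCDict, c(1, 0, 0, 0, 0))
  # "(C43.5)" normalizes to "C435", which starts with an upper-case letter
  expect_equal(f$Capitalization, c(1, 0, 0, 1, 1))
  # ContainsPeriod applies to the raw right token
  expect_equal(f$ContainsPeriod, c(0, 0, 1, 1, 0))
  expect_equal(f$ContainsDigit, c(0, 0, 0, 1, 0))
  # "(C43.5)" normalizes to "C435": digits block the acronym shape
  expect_equal(f$AllUpperCase, c(0, 0, 0, 0, 1))

  # plain-membership variant
  f2 <- sentence_features(sites, w$counts, w$stats, w$lex$mddict, cc,
                          sets = "language", cc_capitalized = FALSE)
  expect_equal(f2$InCCDict, c(1, 1, 0, 0, 0))
})

test_that("text-format block is exactly one-hot", {
  w <- ws()
  sites <- make_sites("ca.", right_token = "Der", newline_count = c(0, 1, 2, 5))
  f <- sentence_features(sites, w$counts, w$stats, w$lex$mddict,
                         build_ccdict("der"), sets = "textformat")
  m <- as.matrix(f)
  expect_true(all(rowSums(m) == 1))
  expect_equal(f$NoNewline, c(1, 0, 0, 0))
  expect_equal(f$SingleNewline, c(0, 1, 0, 0))
  expect_equal(f$DoubleNewline, c(0, 0, 1, 1))

  # and over generated data too
  gen <- sentence_features(w$train$gold, w$counts, w$stats, w$lex$mddict,
                           w$lex$ccdict, sets = "textformat")
  expect_true(all(rowSums(as.matrix(gen)) == 1))
})

test_that("sentence length features are computed on the right token", {
  w <- ws()
  sites <- make_sites("ca.", right_token = "Befundkontrolle")
  f <- sentence_features(sites, w$counts, w$stats, w$lex$mddict,
                         build_ccdict("der"), sets = "length")
  expect_equal(f$LT, nchar("Befundkontrolle"))
  expect_equal(f$Mean.LT, w$stats$mu - f$LT)
})

test_that("the abbreviation feature equals the abbreviation model's prediction", {
  w <- ws()
  am <- fit_period_classifier(w$train$gold, "abbreviation", w$counts,
                              w$lex$mddict, stats = w$stats,
                              sets = c("rules", "dictionary", "length"))
  sites <- w$test$gold[1:100, ]
  f <- sentence_features(sites, w$counts, w$stats, w$lex$mddict,
                         w$lex$ccdict, sets = "abbreviation",
                         abbrev_model = am)
  expect_equal(f$Abbreviation, as.numeric(predict(am, sites)))
  expect_error(
    sentence_features(sites, w$counts, w$stats, w$lex$mddict, w$lex$ccdict,
                      sets = "abbreviation"),
    "abbrev_model"
  )
})
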