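test_that("collocation counting keys on the normalized, period-stripped type", {
  ct <- count_collocations(tokenize("ca. ca. ca"))
  expect_equal(ct$type, "ca")
  expect_equal(ct$c_dot, 2L)
  expect_equal(ct$c_nodot, 1L)

  expect_equal(nrow(count_collocations(tokenize(""))), 0L)

  ct5 <- count_collocations(tokenize("5."))
  expect_equal(ct5$type, "5")
  expect_equal(ct5$c_dot, 1L)

  # unseen types look up as zero with complements from the totals
  cc <- collocation_counts(ct, c("ca", "neu"))
  expect_equal(cc$c_l_dot, c(2, 0))
  expect_equal(cc$c_notl_dot, c(0, 2))
  expect_equal(cc$c_notl_nodot, c(0, 1))
})

test_that("log-likelihood ratio is zero at independence, positive otherwise", {
  expect_equal(log_lambda(10, 10, 10, 10), 0)
  expect_gt(log_lambda(5, 0, 0, 7), 0)
  expect_gt(log_lambda(20, 5, 10, 1000), 0)
  expect_error(log_lambda(0, 0, 0, 0))
  expect_error(log_lambda(-1, 2, 3, 4))
})

test_that("log-likelihood ratio matches the direct binomial oracle", {
  tabs <- random_tables(300, seed = 77)
  got <- log_lambda(tabs$k11, tabs$k12, tabs$k21, tabs$k22)
  for (i in seq_len(nrow(tabs))) {
    want <- oracle_log_lambda(tabs$k11[i], tabs$k12[i], tabs$k21[i], tabs$k22[i])
    if (abs(want) < 1e-10 && abs(got[i]) < 1e-10) next
    expect_lt(abs(got[i] - want) / abs(want), 1e-9)
  }
})

test_that("log-likelihood ratio is invariant under consistent row swap", {
  tabs <- random_tables(50, seed = 12)
  expect_equal(
    log_lambda(tabs$k11, tabs$k12, tabs$k21, tabs$k22),
    log_lambda(tabs$k21, tabs$k22, tabs$k11, tabs$k12)
  )
})

test_that("word length ignores periods", {
  expect_equal(word_length("St.p."), 3L)
  expect_equal(word_length(""), 0L)
  expect_equal(word_length("C43.5"), 4L)
})

test_that("individual scaling functions follow their formulas", {
  # S2 vanishes when the two counts agree, regardless of loglam
  expect_equal(scaling_factor(2, 17.3, "x", 4, 4), 0)
  expect_equal(scaling_factor(2, 1, "x", 0, 0), 0)
  # S4: one internal period doubles
  expect_equal(scaling_factor(4, 2, "St.p", 1, 1), 4)
  # S3: length-2 word cancels e^2
  expect_equal(scaling_factor(3, exp(2), "ca", 1, 1), 1, tolerance = 1e-12)
  # S1 floors the denominator at 1 and stays finite
  expect_equal(scaling_factor(1, 1, "x", 3, 0), exp(3))
  expect_true(is.finite(scaling_factor(1, 1, "x", 5000, 0)))
  # S5 penalizes non-period occurrences exponentially in 1/length
  expect_equal(scaling_factor(5, 1, "abc", 0, 2), (1 / 3)^2)
  # S6 adds the dictionary substring count
  md <- build_mddict(c("Status", "post"))
  expect_equal(scaling_factor(6, 1.5, "St.p", 0, 0, md), 3.5)
})

test_that("scaling factor ranges hold over random inputs", {
  set.seed(8)
  for (i in 1:100) {
    cd <- rpois(1, 5)
    cn <- rpois(1, 5)
    if (cd + cn == 0) cd <- 1
    word <- paste(sample(letters, sample(1:8, 1), replace = TRUE), collapse = "")
    f2 <- scaling_factor(2, 1, word, cd, cn)
    f3 <- scaling_factor(3, 1, word, cd, cn)
    f4 <- scaling_factor(4, 1, word, cd, cn)
    expect_true(f2 >= -1 && f2 <= 1)
    expect_true(f3 > 0 && f3 <= 1)
    expect_true(f4 >= 1)
  }
})

test_that("power-set composition is the ascending-order fold", {
  combos <- scaling_combos()
  expect_length(combos, 63L)
  expect_equal(anyDuplicated(names(combos)), 0L)

  md <- build_mddict(c("Status", "post"))
  # singletons match the individual functions
  for (k in 1:6) {
    expect_equal(
      scaled_feature(k, 4, "St.p", 3, 1, md),
      scaling_factor(k, 4, "St.p", 3, 1, md)
    )
  }
  # hand-computed composite {2,3}: (4 * 0.5) * exp(-1)
  expect_equal(scaled_feature(c(2, 3), 4, "x", 3, 1), 2 / exp(1))
  # full set equals an explicit sequential fold
  val <- 4
  for (k in 1:6) val <- scaling_factor(k, val, "St.p", 3, 1, md)
  expect_equal(scaled_feature(1:6, 4, "St.p", 3, 1, md), val)
  expect_error(scaled_feature(integer(0), 1, "x", 1, 1))
})

test_that("abbreviation length statistics select significant period types", {
  # two period-collocated types of lengths 2 and 4 against heavy background
  ct <- make_count_table(
    type = c("ab", "wxyz", "hintergrund"),
    c_dot = c(30, 30, 0),
    c_nodot = c(0, 0, 800)
  )
  st <- abbreviation_length_stats(ct)
  expect_equal(st$n_types, 2L)
  expect_equal(st$mu, 3)
  expect_equal(st$sigma, 1) # population SD
  expect_equal(st$b1, 3 + 1.645)
  expect_equal(st$b2, 3 + 1.960)
  expect_equal(st$b3, 3 + 2.576)

  one <- abbreviation_length_stats(make_count_table(
    c("abc", "rest"), c(30, 0), c(0, 500)
  ))
  expect_equal(one$sigma, 0)
  expect_equal(one$b1, one$mu)
  expect_equal(one$b3, one$mu)

  # nothing significant -> instructive error
  expect_error(
    abbreviation_length_stats(make_count_table("a", 1, 1)),
    "larger corpus"
  )
  # significance alone is not enough: needs C(dot) > C(nodot)
  skew <- make_count_table(c("a", "b"), c(5, 200), c(200, 5))
  st2 <- abbreviation_length_stats(skew)
  expect_equal(st2$n_types, 1L)
})
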