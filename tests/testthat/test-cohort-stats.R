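test_that("donor aggregation admits only index, middle and ring fingers", {
  prints <- data.frame(finger = c("index", "middle", "ring"),
                       concentration = c(80, 90, 100))
  expect_equal(aggregate_donor(prints), 90)

  with_extremes <- data.frame(
    finger = c("thumb", "index", "middle", "ring", "little"),
    concentration = c(500, 80, 90, 100, 1))
  expect_equal(aggregate_donor(with_extremes), 90)

  thumb_only <- data.frame(finger = "thumb", concentration = 500)
  expect_error(aggregate_donor(thumb_only), "admitted")
})

test_that("midpoint classification separates the literature means", {
  expect_equal(classify_sex(96.4), "female")
  expect_equal(classify_sex(55.3), "male")
  expect_equal(classify_sex(74.4), "inconclusive")  # exactly the midpoint

  # monotone: raising the donor mean never flips female back to male
  levels <- c(male = 1, inconclusive = 2, female = 3)
  calls <- levels[classify_sex(seq(0, 200, by = 2.5))]
  expect_true(all(diff(calls) >= 0))
})

test_that("cohort summary reproduces hand-computed SEM and t-based CI", {
  s <- cohort_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-12)  # sd = 1
  half <- qt(0.975, df = 2) * s$sem                    # t oracle: 4.3027 * sem
  expect_equal(s$ci95_low, 2 - half, tolerance = 1e-12)
  expect_equal(s$ci95_high, 2 + half, tolerance = 1e-12)
  expect_equal(round(s$ci95_low, 3), -0.484)
  expect_equal(round(s$ci95_high, 3), 4.484)

  flat <- cohort_summary(c(5, 5, 5, 5))
  expect_equal(flat$sem, 0)
  expect_equal(flat$ci95_high - flat$ci95_low, 0)

  expect_error(cohort_summary(42), "two values")
})

test_that("pooled-SEM normal test reproduces the blind-study comparisons", {
  f <- compare_summary_to_reference(96.4, 5.1, 94.8, 12.9)
  expect_equal(f$statistic, 1.6 / sqrt(5.1^2 + 12.9^2), tolerance = 1e-12)
  expect_equal(round(f$p_value, 3), 0.908)
  expect_false(f$significant)

  m <- compare_summary_to_reference(55.3, 5.3, 94.8, 12.9)
  expect_equal(round(m$p_value, 4), 0.0046)  # z ~ 2.83, normal-CDF oracle
  expect_true(m$significant)

  # symmetry in the two summaries
  sw <- compare_summary_to_reference(94.8, 12.9, 96.4, 5.1)
  expect_equal(sw$p_value, f$p_value, tolerance = 1e-15)

  expect_equal(compare_summary_to_reference(50, 3, 50, 4)$p_value, 1)
  degen <- compare_summary_to_reference(10, 0, 20, 0)
  expect_equal(degen$p_value, 0)
  expect_true(degen$degenerate)
})

test_that("Welch comparison flags separated groups and not identical ones", {
  same <- compare_print_samples(c(10, 11, 12), c(10, 11, 12))
  expect_equal(same$p_value, 1)

  apart <- compare_print_samples(c(10, 11, 12), c(110, 111, 112))
  expect_lt(apart$p_value, 0.001)
  expect_true(apart$significant)

  # agrees with stats::t.test run independently
  withr::with_seed(8, {
    g1 <- rnorm(15, 50, 10); g2 <- rnorm(12, 60, 14)
  })
  got <- compare_print_samples(g1, g2)
  ref <- t.test(g1, g2)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)

  expect_error(compare_print_samples(1, c(2, 3)), "two values")
})

test_that("blind-study scoring counts matches and rounds to whole percent", {
  all4 <- data.frame(presumptive_sex = c("female", "male", "female", "male"),
                     actual_sex = c("female", "male", "female", "male"))
  expect_equal(score_blind_study(all4),
               list(matches = 4L, total = 4L, accuracy = 100))

  one_of_three <- data.frame(presumptive_sex = c("female", "male", "male"),
                             actual_sex = c("female", "female", "female"))
  expect_equal(score_blind_study(one_of_three)$accuracy, 33)

  # inconclusive is conservative: never a match
  inc <- data.frame(presumptive_sex = c("inconclusive", "female"),
                    actual_sex = c("female", "female"))
  expect_equal(score_blind_study(inc)$matches, 1L)

  missing <- data.frame(presumptive_sex = "female", actual_sex = NA_character_)
  expect_error(score_blind_study(missing), "actual sex")
})

test_that("the shipped blind-study table has the published shape", {
  tbl <- blind_study_table()
  expect_equal(nrow(tbl), 15L)
  expect_equal(sum(tbl$actual_sex == "female"), 11L)
  expect_equal(sum(tbl$actual_sex == "male"), 4L)
})
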