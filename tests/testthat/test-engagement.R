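rec <- function(id, dates) {
  tibble::tibble(recorder_id = id, date = as.Date(dates))
}

test_that("histories deduplicate days and count records", {
  r <- dplyr::bind_rows(
    rec("a", c("2010-01-01", "2010-01-01", "2010-01-01")),
    rec("b", c("2010-01-01", "2010-01-10"))
  )
  h <- build_histories(r)
  expect_equal(nrow(h), 2)
  expect_equal(h$n_active_days, c(1, 2))
  expect_equal(h$n_observations, c(3, 2))
  expect_equal(h$linked_days, c(1, 10))
})

test_that("activity ratio spans (0,1] with the documented endpoints", {
  h <- build_histories(dplyr::bind_rows(
    rec("one_day", "2010-01-01"),
    rec("sparse", c("2010-01-01", "2010-01-10")),
    rec("daily", as.character(as.Date("2010-01-01") + 0:29))
  ))
  ar <- activity_ratio(h)
  names(ar) <- h$recorder_id
  expect_equal(unname(ar["one_day"]), 1)
  expect_equal(unname(ar["sparse"]), 2 / 10)
  expect_equal(unname(ar["daily"]), 1)
})

test_that("relative activity duration is active days over the window", {
  w <- study_window("2010-01-01", "2010-04-10") # 100 days
  h <- build_histories(rec("a", c("2010-01-05", "2010-02-01")))
  expect_equal(relative_activity_duration(h, w), 0.02)
  expect_error(relative_activity_duration(
    h, study_window("2010-01-10", "2010-04-10")), "outside")
})

test_that("variation in periodicity matches the worked example", {
  # A active days {1,3,5}: mean gap 2; B {1,11}: mean gap 10; G = 6
  r <- dplyr::bind_rows(
    rec("A", as.character(as.Date("2010-01-01") + c(0, 2, 4))),
    rec("B", as.character(as.Date("2010-01-01") + c(0, 10)))
  )
  vp <- variation_in_periodicity(build_histories(r))
  expect_equal(vp, c(1 / 3, 5 / 3))

  # identical gap structure -> all 1; single-day volunteer -> 0
  r2 <- dplyr::bind_rows(
    rec("A", c("2010-01-01", "2010-01-03")),
    rec("B", c("2010-02-01", "2010-02-03")),
    rec("C", "2010-03-01")
  )
  expect_equal(variation_in_periodicity(build_histories(r2)), c(1, 1, 0))

  expect_error(variation_in_periodicity(
    build_histories(rec("solo", "2010-01-01"))), "undefined")
})

test_that("engagement table composes the metrics and flags single days", {
  w <- study_window("2010-01-01", "2010-01-20")
  r <- dplyr::bind_rows(
    rec("A", as.character(as.Date("2010-01-01") + c(0, 2, 4))),
    rec("B", as.character(as.Date("2010-01-01") + c(0, 10)))
  )
  tab <- engagement_table(r, w)
  expect_equal(tab$variation_in_periodicity, c(1 / 3, 5 / 3))
  expect_equal(tab$activity_ratio, c(3 / 5, 2 / 11))
  expect_equal(tab$relative_activity_duration, c(3 / 20, 2 / 20))

  # degenerate cohorts
  expect_equal(nrow(engagement_table(rec(character(0), as.Date(character(0))))), 0)
  solo <- engagement_table(rec("s", "2010-01-01"),
                           study_window("2010-01-01", "2010-01-10"))
  expect_equal(solo$n_observations, 1L)
  expect_equal(solo$activity_ratio, 1)
  expect_equal(solo$relative_activity_duration, 1 / 10)
  expect_equal(solo$variation_in_periodicity, 0)
  expect_true(solo$single_day)
})

test_that("metrics agree exactly with a naive per-volunteer oracle", {
  set.seed(11)
  w <- study_window("2010-01-01", as.Date("2010-01-01") + 199)
  for (i in 1:200) {
    cohort <- random_cohort(sample(2:15, 1))
    got <- engagement_table(cohort, w)
    want <- oracle_engagement(cohort, w)
    got <- got[order(got$recorder_id), ]
    expect_identical(got$n_observations, as.integer(want$n_observations))
    expect_identical(got$activity_ratio, want$activity_ratio)
    expect_identical(got$relative_activity_duration,
                     want$relative_activity_duration)
    expect_identical(got$variation_in_periodicity,
                     want$variation_in_periodicity)
  }
})

test_that("metrics are invariant to record order and same-day duplicates", {
  set.seed(3)
  cohort <- random_cohort(10)
  w <- study_window("2010-01-01", as.Date("2010-01-01") + 199)
  shuffled <- cohort[sample(nrow(cohort)), ]
  a <- engagement_table(cohort, w)
  b <- engagement_table(shuffled, w)
  expect_equal(a, b)

  dup <- dplyr::bind_rows(cohort, cohort[1, ]) # one extra same-day record
  d <- engagement_table(dup, w)
  expect_equal(d$activity_ratio, a$activity_ratio)
  expect_equal(d$variation_in_periodicity, a$variation_in_periodicity)
  expect_equal(sum(d$n_observations), sum(a$n_observations) + 1L)
})

test_that("mean VP over multi-day volunteers is 1 and RAD <= AR always", {
  set.seed(5)
  w <- study_window("2010-01-01", as.Date("2010-01-01") + 199)
  for (i in 1:25) {
    tab <- engagement_table(random_cohort(sample(3:30, 1)), w)
    multi <- !tab$single_day
    expect_equal(mean(tab$variation_in_periodicity[multi]), 1,
                 tolerance = 1e-12)
    expect_true(all(tab$relative_activity_duration <=
                      tab$activity_ratio + 1e-12))
    expect_true(all(tab$activity_ratio > 0 & tab$activity_ratio <= 1))
  }
})
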