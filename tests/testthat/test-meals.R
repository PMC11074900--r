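test_that("payments within 2 hours of the anchor form one meal", {
  m <- segment_meals(data.frame(time = c(7 * 3600, 7.75 * 3600),
                                amount = c(3.5, 2.0)))
  expect_equal(nrow(m), 1L)
  expect_equal(m$start_time, 7 * 3600)
  expect_equal(m$expenditure, 5.5)
  expect_equal(m$n_transactions, 2L)
})

test_that("a payment beyond the anchor window opens a new meal", {
  m <- segment_meals(data.frame(time = c(11.5, 12, 17 + 40 / 60) * 3600,
                                amount = c(5, 5, 8)))
  expect_equal(nrow(m), 2L)
  expect_equal(m$start_time, c(11.5 * 3600, (17 + 40 / 60) * 3600))
})

test_that("unsorted input errors and empty input yields an empty meal list", {
  expect_error(segment_meals(data.frame(time = c(200, 100), amount = 1)),
               "sorted")
  expect_equal(nrow(segment_meals(data.frame(time = numeric(0),
                                             amount = numeric(0)))), 0L)
})

test_that("segmentation equals the brute-force re-anchoring oracle on random days", {
  set.seed(314)
  for (rep in 1:200) {
    tx <- random_day_tx(sample(1:15, 1))
    m <- segment_meals(tx)
    oracle <- oracle_segment_groups(tx$time)
    expect_equal(nrow(m), max(oracle))
    expect_equal(m$start_time,
                 as.vector(tapply(tx$time, oracle, min)), ignore_attr = TRUE)
    expect_equal(m$expenditure,
                 as.vector(tapply(tx$amount, oracle, sum)), ignore_attr = TRUE)
  }
})

test_that("vectorized log segmentation matches the per-day surface", {
  set.seed(2718)
  days <- lapply(1:60, function(i) {
    tx <- random_day_tx(sample(1:12, 1), date = as.Date("2020-10-01") + (i %% 20))
    tx$student_id <- sprintf("S%02d", i %% 7)
    tx
  })
  tx <- do.call(rbind, days)
  tx <- tx[order(tx$student_id, tx$date, tx$time, tx$amount, tx$item_id), ]
  meals <- segment_log(tx)
  dropped <- attr(meals, "dropped")
  per_day <- do.call(rbind, lapply(split(tx, list(tx$student_id, tx$date),
                                         drop = TRUE), function(d) {
    m <- segment_meals(d)
    m$student_id <- d$student_id[1]; m$date <- d$date[1]
    m
  }))
  # before trimming/dedupe the segment sets must agree
  expect_equal(nrow(meals) + nrow(dropped), nrow(per_day))
  key <- function(df) sort(paste(df$student_id, df$date, df$start_time,
                                 round(df$expenditure, 2)))
  all_mine <- rbind(meals[, .(student_id, date, start_time, expenditure)],
                    dropped[, .(student_id, date, start_time, expenditure)])
  expect_equal(key(all_mine), key(per_day))
})

test_that("expenditure is conserved across kept and dropped meals", {
  set.seed(12)
  tx <- do.call(rbind, lapply(1:10, function(i) {
    d <- random_day_tx(15, date = as.Date("2020-10-01") + i)
    d$student_id <- "S1"
    d
  }))
  meals <- segment_log(tx)
  dropped <- attr(meals, "dropped")
  expect_equal(sum(meals$expenditure) + sum(dropped$expenditure),
               sum(tx$amount), tolerance = 1e-9)
})

test_that("start times map to slots with inclusive bounds and earlier-slot ties", {
  cl <- classify_meal(c(7 + 10 / 60, 13, 9.75, 6.5, 19.5, 23) * 3600)
  expect_equal(cl$meal_class,
               c("breakfast", "lunch", "breakfast", "breakfast", "dinner",
                 "dinner"))
  expect_equal(cl$out_of_slot, c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  # 09:45 sits 4500 s from both breakfast and lunch; tie goes to breakfast
  d <- abs(c(9.75 * 3600 - 8.5 * 3600, 11 * 3600 - 9.75 * 3600))
  expect_equal(d[1], d[2])
})

test_that("class collisions keep the in-slot, then earlier, meal", {
  meals <- data.frame(start_time = c(7 * 3600, 12 * 3600),
                      meal_class = c("breakfast", "lunch"),
                      out_of_slot = FALSE)
  dd <- dedupe_meal_classes(meals)
  expect_equal(nrow(dd$kept), 2L)
  expect_equal(nrow(dd$dropped), 0L)

  meals <- data.frame(start_time = c(11 + 10 / 60, 13 + 40 / 60) * 3600,
                      meal_class = "lunch",
                      out_of_slot = c(FALSE, TRUE))
  dd <- dedupe_meal_classes(meals)
  expect_equal(dd$kept$start_time, (11 + 10 / 60) * 3600)

  set.seed(5)
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    meals <- data.frame(start_time = sort(sample.int(86000, n)),
                        meal_class = sample(c("breakfast", "lunch", "dinner"),
                                            n, replace = TRUE),
                        out_of_slot = sample(c(TRUE, FALSE), n, replace = TRUE))
    dd <- dedupe_meal_classes(meals)
    expect_true(all(table(dd$kept$meal_class) <= 1))
    expect_equal(nrow(dd$kept) + nrow(dd$dropped), n)
  }
})

test_that("days with more than 3 segments keep the 3 closest to the slots", {
  # 5 well-separated payments: 03:00, 07:00, 12:00, 15:00, 18:00
  tx <- data.frame(student_id = "S1", date = as.Date("2020-10-05"),
                   time = c(3, 7, 12, 15, 18) * 3600,
                   amount = 1, cafeteria_id = 1L, item_id = "C1-I01")
  meals <- segment_log(tx)
  expect_equal(nrow(meals), 3L)
  expect_equal(sort(meals$start_time), c(7, 12, 18) * 3600)
  expect_equal(nrow(attr(meals, "dropped")), 2L)
})

test_that("segmenting already-segmented in-slot meals is a no-op", {
  fx <- fixture_cohort()
  meals <- fx$meals
  asx <- data.frame(student_id = meals$student_id, date = meals$date,
                    time = meals$start_time, amount = meals$expenditure,
                    cafeteria_id = meals$cafeteria_id,
                    item_id = meals$item_ids)
  again <- segment_log(asx)
  # both tables are sorted by (student, date, start time)
  expect_equal(nrow(again), nrow(meals))
  expect_equal(again$start_time, meals$start_time)
  expect_equal(again$meal_class, meals$meal_class)
  expect_equal(again$expenditure, meals$expenditure, tolerance = 1e-9)
})

test_that("an out-of-slot drop policy removes flagged meals into the audit log", {
  tx <- data.frame(student_id = "S1", date = as.Date("2020-10-05"),
                   time = c(7, 9.75, 12) * 3600, amount = 1,
                   cafeteria_id = 1L, item_id = "C1-I01")
  kept <- segment_log(tx, out_of_slot = "drop")
  expect_equal(nrow(kept), 2L)
  expect_false(any(kept$out_of_slot))
  expect_error(segment_log(tx[0, ]), "empty")
})
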