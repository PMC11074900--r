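test_that("summary statistics follow the direct formulas", {
  s <- summary_stats(c(5, 5, 5))
  expect_equal(s$mad, 0)
  expect_equal(s$min, 5)
  expect_equal(s$max, 5)

  s <- summary_stats(1:5)
  expect_equal(s$median, 3)
  expect_equal(s$mad, 1)  # |x - 3| = {2,1,0,1,2}, median 1

  expect_true(all(is.na(unlist(summary_stats(numeric(0))))))

  # mean-absolute-deviation toggle
  expect_equal(summary_stats(1:5, mad_type = "mean")$mad, mean(c(2, 1, 0, 1, 2)))
})

test_that("the MAD is translation invariant and scales linearly, matching enumeration", {
  set.seed(17)
  for (rep in 1:20) {
    x <- rnorm(sample(3:40, 1), sd = 50)
    m <- summary_stats(x)$mad
    expect_equal(m, oracle_mad(x))
    expect_equal(summary_stats(x + 123.4)$mad, m)
    expect_equal(summary_stats(x * 2.5)$mad, m * 2.5)
  }
})

test_that("inter-meal gaps subtract start times for pairs present", {
  day <- data.frame(meal_class = c("breakfast", "lunch"),
                    start_time = c(7.5, 12) * 3600)
  g <- interval_features(day)
  expect_equal(g$gap[g$pair == "bre_lun"], 16200)
  expect_equal(nrow(g), 1L)
  expect_equal(nrow(interval_features(
    data.frame(meal_class = "dinner", start_time = 18 * 3600))), 0L)
})

test_that("cafeteria shares are normalized visit tallies", {
  m <- data.frame(meal_class = "lunch", cafeteria_id = 2L)[rep(1, 8), ]
  sh <- location_shares(m)
  expect_equal(sh$overall, c(0, 1, 0))

  m <- data.frame(meal_class = "lunch",
                  cafeteria_id = rep(c(1L, 3L), c(6, 4)))
  sh <- location_shares(m)
  expect_equal(unname(sh$per_class["lunch", ]), c(0.6, 0, 0.4))
  expect_true(all(is.na(sh$per_class["breakfast", ])))

  set.seed(31)
  m <- data.frame(meal_class = sample(c("breakfast", "lunch", "dinner"), 200,
                                      replace = TRUE),
                  cafeteria_id = sample.int(3L, 200, replace = TRUE))
  sh <- location_shares(m)
  expect_equal(sh$overall,
               as.vector(table(factor(m$cafeteria_id, 1:3))) / 200)
  expect_equal(sum(sh$overall), 1)
})

test_that("all-day patterns biject with the non-empty meal subsets", {
  expect_equal(allday_pattern(c("lunch", "dinner")), "LD")
  expect_equal(allday_pattern(c("breakfast", "lunch", "dinner")), "BLD")
  subsets <- list("breakfast", "lunch", "dinner",
                  c("breakfast", "lunch"), c("lunch", "dinner"),
                  c("breakfast", "dinner"), c("breakfast", "lunch", "dinner"))
  got <- vapply(subsets, allday_pattern, character(1))
  expect_setequal(got, c("B", "L", "D", "BL", "LD", "BD", "BLD"))
  expect_equal(anyDuplicated(got), 0L)
  expect_error(allday_pattern(character(0)), "no meals")
})

test_that("pattern frequencies are tallies over observed days and sum to 1", {
  pats <- rep(c("LD", "BLD"), c(5, 15))
  f <- pattern_frequency(pats)
  expect_equal(unname(f["LD"]), 0.25)
  expect_equal(sum(f), 1)
  f <- pattern_frequency(rep("BLD", 9))
  expect_equal(unname(f["BLD"]), 1)
  expect_equal(sum(f != 0), 1L)
  f <- pattern_frequency(rep("BLD", 9), n_calendar_days = 18,
                         denominator = "calendar")
  expect_equal(unname(f["BLD"]), 0.5)
})

test_that("diversity and meal frequency match direct counting", {
  cal <- study_calendar()
  wd <- as.Date(cal$date[cal$day_type == "weekday"])  # 22 weekdays
  meals <- data.frame(date = rep(wd[1:11], each = 1), meal_class = "breakfast",
                      item_ids = "C1-I01+C1-I02+C1-I03")
  r <- diversity_and_meal_frequency(meals, cal, "weekday")
  expect_equal(r$diversity, 3)
  expect_equal(unname(r$freq["breakfast"]), 0.5)
  expect_equal(unname(r$freq["lunch"]), 0)
})

test_that("z-scoring standardizes and bands by the 1-SD rule", {
  x <- cbind(f1 = c(0, 0, 10), f2 = c(1, 2, 3))
  zb <- zscore_and_band(x, sd_type = "population")
  expect_equal(unname(zb$z[3, "f1"]), sqrt(2),
               tolerance = 1e-6)  # (10 - 10/3)/sqrt(200/9)
  expect_equal(unname(zb$band[3, "f1"]), "Always")
  expect_equal(unname(zb$band[2, "f2"]), "Normal")

  set.seed(8)
  x <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("c", 1:5)))
  zb <- zscore_and_band(x)
  expect_equal(unname(colMeans(zb$z)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(zb$z, 2, sd)), rep(1, 5), tolerance = 1e-9)

  expect_message(zb <- zscore_and_band(cbind(flat = rep(2, 5), ok = 1:5)),
                 "zero-variance")
  expect_equal(zb$dropped, "flat")
})

test_that("cohort feature extraction matches per-student oracle recomputation", {
  fx <- fixture_cohort()
  ft <- fx$features
  meals <- as.data.frame(fx$meals)
  cal <- fx$config$calendar
  wd_days <- as.Date(cal$date[cal$day_type == "weekday"])
  set.seed(404)
  for (sid in sample(ft$student_id, 4)) {
    sub <- meals[meals$student_id == sid & as.Date(meals$date) %in% wd_days, ]
    row <- ft[ft$student_id == sid]
    # lunch time MAD
    lt <- sub$start_time[sub$meal_class == "lunch"]
    expect_equal(row[["time.weekday.lunch.mad"]], oracle_mad(lt))
    # dinner expenditure mean
    expect_equal(row[["expenditure.weekday.dinner.mean"]],
                 mean(sub$expenditure[sub$meal_class == "dinner"]))
    # breakfast frequency over calendar weekdays
    expect_equal(row[["freq.weekday.breakfast"]],
                 length(unique(sub$date[sub$meal_class == "breakfast"])) /
                   length(wd_days))
    # pattern frequency over observed days
    pats <- vapply(split(sub$meal_class, as.character(sub$date)),
                   allday_pattern, character(1))
    expect_equal(row[["pattern.weekday.BLD"]],
                 unname(pattern_frequency(pats)["BLD"]))
    # lunch-dinner interval mean
    both <- split(sub, as.character(sub$date))
    gaps <- unlist(lapply(both, function(d) {
      g <- interval_features(d); g$gap[g$pair == "lun_din"]
    }))
    expect_equal(row[["interval.weekday.lun_din.mean"]], mean(gaps))
    # overall cafeteria share
    expect_equal(row[["location.weekday.overall.caf2"]],
                 mean(sub$cafeteria_id == 2))
  }
})

test_that("pattern frequencies sum to 1 per student and day type", {
  fx <- fixture_cohort()
  ft <- fx$features
  for (dt in c("weekday", "weekend")) {
    cols <- paste("pattern", dt, ALLDAY_PATTERNS_TEST, sep = ".")
    cols <- intersect(cols, names(ft))
    tot <- rowSums(as.matrix(ft[, cols, with = FALSE]), na.rm = TRUE)
    expect_equal(unname(tot), rep(1, nrow(ft)), tolerance = 1e-9)
  }
})
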