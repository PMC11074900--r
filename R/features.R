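# Dietary feature families: meal timing, inter-meal intervals, expenditure,
# cafeteria location shares, diversity, meal frequency and all-day patterns,
# each stratified by weekday/weekend over the observation month.

#' Robust summary statistics
#'
#' Mean, median, median absolute deviation, maximum and minimum. The MAD is
#' the raw `median(|x - median(x)|)` with no consistency scaling, so it
#' reads directly in the unit of the input (seconds for times, currency for
#' expenditure). `mad_type = "mean"` switches to the mean absolute
#' deviation about the median.
#'
#' @param values numeric vector.
#' @param mad_type `"median"` (default) or `"mean"` absolute deviation.
#' @return named list `mean`, `median`, `mad`, `max`, `min`; all `NA` for an
#'   empty input (the feature is missing, not zero).
#' @export
#' @examples
#' summary_stats(c(1, 2, 3, 4, 5))  # mad 1
summary_stats <- function(values, mad_type = c("median", "mean")) {
  mad_type <- match.arg(mad_type)
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    return(list(mean = NA_real_, median = NA_real_, mad = NA_real_,
                max = NA_real_, min = NA_real_))
  med <- stats::median(values)
  dev <- abs(values - med)
  list(mean = mean(values), median = med,
       mad = if (mad_type == "median") stats::median(dev) else mean(dev),
       max = max(values), min = min(values))
}

PAIR_DEFS <- data.frame(
  pair = c("bre_lun", "lun_din", "bre_din"),
  from = c("breakfast", "lunch", "breakfast"),
  to   = c("lunch", "dinner", "dinner"),
  stringsAsFactors = FALSE
)

#' Inter-meal intervals for one student-day
#'
#' For each pair of meals present on the day (breakfast-lunch, lunch-dinner,
#' breakfast-dinner), the gap between the later and the earlier start time,
#' in seconds. Pairs with a missing member contribute nothing.
#'
#' @param day_meals data.frame of deduped classified meals for one
#'   student-day (`meal_class`, `start_time`).
#' @return data.frame with columns `pair` and `gap` (seconds).
#' @export
interval_features <- function(day_meals) {
  t_of <- function(cls) {
    i <- match(cls, day_meals$meal_class)
    if (is.na(i)) NA_real_ else day_meals$start_time[i]
  }
  gaps <- vapply(seq_len(nrow(PAIR_DEFS)), function(i)
    t_of(PAIR_DEFS$to[i]) - t_of(PAIR_DEFS$from[i]), numeric(1))
  out <- data.frame(pair = PAIR_DEFS$pair, gap = gaps, stringsAsFactors = FALSE)
  out[!is.na(out$gap), , drop = FALSE]
}

#' Cafeteria visit shares
#'
#' Overall share of meals at each cafeteria and, per meal class, the share
#' of that class's meals at each cafeteria. Shares sum to 1 over cafeterias
#' whenever the denominator is positive; classes never observed yield
#' missing shares.
#'
#' @param meals data.frame of meals for one student (needs `cafeteria_id`,
#'   `meal_class`).
#' @param n_cafeterias number of cafeterias (default 3).
#' @return list with `overall` (length-`n_cafeterias` vector) and
#'   `per_class` (matrix meal class x cafeteria).
#' @export
location_shares <- function(meals, n_cafeterias = 3L) {
  if (nrow(meals) == 0L) stop("location shares need at least one meal")
  tab <- function(sub) {
    if (nrow(sub) == 0L) return(rep(NA_real_, n_cafeterias))
    as.vector(table(factor(sub$cafeteria_id, levels = seq_len(n_cafeterias)))) /
      nrow(sub)
  }
  per_class <- t(vapply(MEAL_CLASSES,
                        function(m) tab(meals[meals$meal_class == m, , drop = FALSE]),
                        numeric(n_cafeterias)))
  list(overall = tab(meals), per_class = per_class)
}

#' All-day dietary behavior pattern of one day
#'
#' The set of meal classes eaten that day, as one of the 7 non-empty subsets
#' `B, L, D, BL, LD, BD, BLD`.
#'
#' @param meal_classes character vector of the day's (deduped) meal classes.
#' @return pattern string.
#' @export
#' @examples
#' allday_pattern(c("lunch", "dinner"))  # "LD"
allday_pattern <- function(meal_classes) {
  if (length(meal_classes) == 0L) stop("a day with no meals has no pattern")
  letters3 <- c(breakfast = "B", lunch = "L", dinner = "D")
  present <- MEAL_CLASSES %in% meal_classes
  paste(letters3[MEAL_CLASSES[present]], collapse = "")
}

#' Frequency of the 7 all-day patterns
#'
#' `freq_p` = days with pattern p / days with at least one recorded meal.
#' An unobserved-day denominator variant (`denominator = "calendar"`,
#' dividing by all calendar days of the day type) is available; the default
#' conditions on observed days, since a day without any record is
#' indistinguishable from off-campus eating.
#'
#' @param patterns character vector of daily patterns (one per observed day).
#' @param n_calendar_days required when `denominator = "calendar"`.
#' @param denominator `"observed"` (default) or `"calendar"`.
#' @return named numeric 7-vector over `B, L, D, BL, LD, BD, BLD`.
#' @export
pattern_frequency <- function(patterns, n_calendar_days = NULL,
                              denominator = c("observed", "calendar")) {
  denominator <- match.arg(denominator)
  if (length(patterns) == 0L)
    return(stats::setNames(rep(NA_real_, 7L), ALLDAY_PATTERNS))
  counts <- table(factor(patterns, levels = ALLDAY_PATTERNS))
  den <- if (denominator == "observed") length(patterns) else {
    if (is.null(n_calendar_days)) stop("calendar denominator needs n_calendar_days")
    n_calendar_days
  }
  stats::setNames(as.numeric(counts) / den, ALLDAY_PATTERNS)
}

#' Daily dietary diversity and meal-class frequency
#'
#' Diversity is the mean over observed days of the number of distinct food
#' items bought that day; meal-class frequency is the share of calendar days
#' of the day type on which that class was eaten (skipping is the signal, so
#' the denominator is the calendar, not observed days).
#'
#' @param meals meals for one student (with `date`, `meal_class`,
#'   `item_ids`).
#' @param calendar study calendar (`date`, `day_type`).
#' @param day_type `"weekday"` or `"weekend"`.
#' @return list with `diversity` (scalar) and `freq` (named 3-vector over
#'   meal classes).
#' @export
diversity_and_meal_frequency <- function(meals, calendar, day_type) {
  cal_days <- as.Date(calendar$date[calendar$day_type == day_type])
  sub <- meals[as.Date(meals$date) %in% cal_days, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(list(diversity = NA_real_,
                freq = stats::setNames(rep(0, 3), MEAL_CLASSES)))
  day_items <- tapply(sub$item_ids, as.character(sub$date), function(s)
    length(unique(unlist(strsplit(s[!is.na(s) & s != ""], "+", fixed = TRUE)))))
  freq <- vapply(MEAL_CLASSES, function(m)
    length(unique(sub$date[sub$meal_class == m])) / length(cal_days), numeric(1))
  list(diversity = mean(day_items), freq = freq)
}

FEATURE_FAMILIES <- c("time", "interval", "expenditure", "location",
                      "diversity", "frequency", "pattern")

#' Extract the per-student dietary feature table
#'
#' Computes every feature family for every student, stratified by weekday
#' and weekend, and returns a wide table with one row per student. Columns
#' are named `family.daytype.item.statistic` (e.g. `time.weekday.lunch.mad`,
#' `interval.weekend.bre_lun.max`, `pattern.weekday.BLD`); see
#' [feature_dictionary()] for the full enumeration. Statistics use
#' [summary_stats()]; features with no observations are missing, not zero.
#'
#' @param meals meals table from [segment_log()].
#' @param calendar study calendar (`date`, `day_type`).
#' @param families subset of feature families to compute (default all);
#'   restricting the set speeds up large simulation sweeps.
#' @param mad_type passed to [summary_stats()].
#' @param pattern_denominator passed to [pattern_frequency()].
#' @return data.table, one row per student with at least one meal.
#' @export
extract_features <- function(meals, calendar, families = FEATURE_FAMILIES,
                             mad_type = "median",
                             pattern_denominator = "observed") {
  families <- match.arg(families, FEATURE_FAMILIES, several.ok = TRUE)
  m <- data.table::as.data.table(meals)
  m[, date := as.Date(date)]
  cal <- data.table::as.data.table(calendar)
  cal[, date := as.Date(date)]
  m <- cal[m, on = "date"]
  m <- m[!is.na(day_type)]  # meals outside the calendar carry no day type
  n_cal <- cal[, .(n_cal_days = .N), by = day_type]
  long <- list()
  push <- function(dt) long[[length(long) + 1L]] <<- dt

  stat_block <- function(value_col, family, item_col) {
    m[, {
      s <- summary_stats(get(value_col), mad_type = mad_type)
      .(stat = names(s), value = as.numeric(unlist(s)))
    }, by = c("student_id", "day_type", item_col)][
      , .(student_id,
          column = paste(family, day_type, get(item_col), stat, sep = "."),
          value)]
  }

  if ("time" %in% families)
    push(stat_block("start_time", "time", "meal_class"))
  if ("expenditure" %in% families)
    push(stat_block("expenditure", "expenditure", "meal_class"))

  if ("interval" %in% families) {
    wide <- data.table::dcast(m, student_id + date + day_type ~ meal_class,
                              value.var = "start_time", fun.aggregate = min,
                              fill = NA)
    for (cls in MEAL_CLASSES) if (is.null(wide[[cls]])) wide[, (cls) := NA_real_]
    gaps <- data.table::rbindlist(lapply(seq_len(nrow(PAIR_DEFS)), function(i)
      wide[, .(student_id, day_type, pair = PAIR_DEFS$pair[i],
               gap = get(PAIR_DEFS$to[i]) - get(PAIR_DEFS$from[i]))]))
    gaps <- gaps[!is.na(gap)]
    push(gaps[, {
      s <- summary_stats(gap, mad_type = mad_type)
      .(stat = names(s), value = as.numeric(unlist(s)))
    }, by = .(student_id, day_type, pair)][
      , .(student_id,
          column = paste("interval", day_type, pair, stat, sep = "."),
          value)])
  }

  if ("location" %in% families) {
    ov <- m[, .(n = .N), by = .(student_id, day_type, cafeteria_id)]
    ov <- ov[data.table::CJ(student_id = unique(m$student_id),
                            day_type = c("weekday", "weekend"),
                            cafeteria_id = 1:3),
             on = c("student_id", "day_type", "cafeteria_id")]
    ov[is.na(n), n := 0L]
    ov[, tot := sum(n), by = .(student_id, day_type)]
    push(ov[tot > 0, .(student_id,
                       column = paste("location", day_type, "overall",
                                      paste0("caf", cafeteria_id), sep = "."),
                       value = n / tot)])
    pc <- m[, .(n = .N), by = .(student_id, day_type, meal_class, cafeteria_id)]
    pc <- pc[data.table::CJ(student_id = unique(m$student_id),
                            day_type = c("weekday", "weekend"),
                            meal_class = MEAL_CLASSES, cafeteria_id = 1:3),
             on = c("student_id", "day_type", "meal_class", "cafeteria_id")]
    pc[is.na(n), n := 0L]
    pc[, tot := sum(n), by = .(student_id, day_type, meal_class)]
    push(pc[tot > 0, .(student_id,
                       column = paste("location", day_type, meal_class,
                                      paste0("caf", cafeteria_id), sep = "."),
                       value = n / tot)])
  }

  if ("diversity" %in% families) {
    dd <- m[!is.na(item_ids) & item_ids != "",
            .(items = paste(item_ids, collapse = "+")),
            by = .(student_id, day_type, date)]
    spl <- strsplit(dd$items, "+", fixed = TRUE)
    dd[, n_distinct := vapply(spl, function(x) length(unique(x)), integer(1))]
    push(dd[, .(column = paste("diversity", day_type, "mean", sep = "."),
                value = mean(n_distinct)), by = .(student_id, day_type)][
      , .(student_id, column, value)])
  }

  if ("frequency" %in% families) {
    fr <- m[, .(n_days = data.table::uniqueN(date)),
            by = .(student_id, day_type, meal_class)]
    fr <- fr[data.table::CJ(student_id = unique(m$student_id),
                            day_type = c("weekday", "weekend"),
                            meal_class = MEAL_CLASSES),
             on = c("student_id", "day_type", "meal_class")]
    fr[is.na(n_days), n_days := 0L]
    fr <- n_cal[fr, on = "day_type"]
    push(fr[, .(student_id,
                column = paste("freq", day_type, meal_class, sep = "."),
                value = n_days / n_cal_days)])
  }

  if ("pattern" %in% families) {
    letters3 <- c(breakfast = "B", lunch = "L", dinner = "D")
    pat <- m[order(factor(meal_class, levels = MEAL_CLASSES)),
             .(pattern = paste(letters3[MEAL_CLASSES[MEAL_CLASSES %in% meal_class]],
                               collapse = "")),
             by = .(student_id, day_type, date)]
    pcount <- pat[, .(n = .N), by = .(student_id, day_type, pattern)]
    pcount <- pcount[data.table::CJ(student_id = unique(m$student_id),
                                    day_type = c("weekday", "weekend"),
                                    pattern = ALLDAY_PATTERNS),
                     on = c("student_id", "day_type", "pattern")]
    pcount[is.na(n), n := 0L]
    pcount[, n_obs := sum(n), by = .(student_id, day_type)]
    if (pattern_denominator == "calendar") {
      pcount <- n_cal[pcount, on = "day_type"]
      pcount[, den := n_cal_days]
    } else pcount[, den := n_obs]
    push(pcount[n_obs > 0,
                .(student_id,
                  column = paste("pattern", day_type, pattern, sep = "."),
                  value = n / den)])
    push(pat[, .(n = data.table::uniqueN(date)), by = .(student_id, day_type)][
      , .(student_id, column = paste("ndays", day_type, sep = "."), value = as.numeric(n))])
  }

  long_dt <- data.table::rbindlist(long, use.names = TRUE)
  wide <- data.table::dcast(long_dt, student_id ~ column, value.var = "value")
  data.table::setorder(wide, student_id)
  wide[]
}

#' Enumerate feature columns
#'
#' @param features wide table from [extract_features()].
#' @return data.frame decomposing each column name into `family`,
#'   `day_type`, `item` and `statistic`.
#' @export
feature_dictionary <- function(features) {
  cols <- setdiff(names(features), "student_id")
  parts <- strsplit(cols, ".", fixed = TRUE)
  data.frame(
    column = cols,
    family = vapply(parts, `[`, character(1), 1L),
    day_type = vapply(parts, `[`, character(1), 2L),
    item = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_,
                  character(1)),
    statistic = vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_,
                       character(1)),
    stringsAsFactors = FALSE
  )
}

#' Z-score features and code SD bands
#'
#' Each feature column is standardized over all included students, then
#' coded into the three SD bands used for association analyses: `Rare`
#' (z < -1), `Normal` (-1 <= z <= 1) and `Always` (z > 1). The default SD is
#' the sample (n-1) estimator; `sd_type = "population"` divides by n.
#' Zero-variance columns cannot be standardized and are dropped with a
#' message; missing values propagate.
#'
#' @param x numeric matrix or data.frame of features (students x features).
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return list with `z` (matrix), `band` (character matrix with levels
#'   Rare/Normal/Always) and `dropped` (names of zero-variance columns).
#' @export
zscore_and_band <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("features must be numeric")
  sds <- apply(x, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2L) return(0)
    s <- stats::sd(col)
    if (sd_type == "population") s <- s * sqrt((length(col) - 1) / length(col))
    s
  })
  drop <- names(sds)[sds == 0 | is.na(sds)]
  if (length(drop)) {
    message("dropping zero-variance feature(s): ", paste(drop, collapse = ", "))
    x <- x[, !(colnames(x) %in% drop), drop = FALSE]
    sds <- sds[!(names(sds) %in% drop)]
  }
  mus <- colMeans(x, na.rm = TRUE)
  z <- sweep(sweep(x, 2L, mus), 2L, sds, "/")
  band <- matrix(NA_character_, nrow(z), ncol(z), dimnames = dimnames(z))
  band[!is.na(z)] <- ifelse(z[!is.na(z)] < -1, "Rare",
                            ifelse(z[!is.na(z)] > 1, "Always", "Normal"))
  list(z = z, band = band, dropped = drop)
}
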