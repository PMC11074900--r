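# Meal segmentation: payments within 2 hours of a meal's first transaction
# belong to that meal; a day holds at most breakfast, lunch and dinner.

MEAL_WINDOW <- 7200L  # seconds: membership window anchored at the first payment

#' Segment one student-day of transactions into meals
#'
#' Greedy anchored grouping: the first payment of the day anchors the first
#' meal; each subsequent payment joins the current meal iff its time is
#' within 2 hours of that anchor, otherwise it anchors a new meal. The meal
#' time is the anchor time, the expenditure the sum of member amounts, and
#' the cafeteria that of the anchor payment.
#'
#' @param day_tx data.frame of transactions for a single student and date,
#'   sorted by time (columns `time`, `amount`, and optionally
#'   `cafeteria_id`, `item_id`).
#' @return data.frame of meals: `start_time`, `expenditure`, `cafeteria_id`,
#'   `item_ids` ("+"-joined distinct items), `n_items`, `n_transactions`.
#' @export
#' @examples
#' segment_meals(data.frame(time = c(25200, 27900), amount = c(3, 2)))
segment_meals <- function(day_tx) {
  if (nrow(day_tx) == 0L) return(empty_meal_frame())
  if (is.unsorted(day_tx$time)) stop("transactions must be sorted by time")
  if (!is.null(day_tx$student_id) && length(unique(day_tx$student_id)) > 1L)
    stop("segment_meals expects a single student")
  if (!is.null(day_tx$date) && length(unique(day_tx$date)) > 1L)
    stop("segment_meals expects a single date")
  idx <- integer(nrow(day_tx)); anchor <- -Inf; k <- 0L
  for (i in seq_len(nrow(day_tx))) {
    if (day_tx$time[i] > anchor + MEAL_WINDOW) { k <- k + 1L; anchor <- day_tx$time[i] }
    idx[i] <- k
  }
  caf <- if (is.null(day_tx$cafeteria_id)) rep(NA_integer_, nrow(day_tx)) else day_tx$cafeteria_id
  itm <- if (is.null(day_tx$item_id)) rep(NA_character_, nrow(day_tx)) else day_tx$item_id
  out <- lapply(split(seq_len(nrow(day_tx)), idx), function(rows) {
    items <- unique(unlist(strsplit(itm[rows][!is.na(itm[rows])], "+", fixed = TRUE)))
    data.frame(start_time = day_tx$time[rows[1L]],
               expenditure = sum(day_tx$amount[rows]),
               cafeteria_id = caf[rows[1L]],
               item_ids = paste(items, collapse = "+"),
               n_items = length(items),
               n_transactions = length(rows),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

empty_meal_frame <- function() {
  data.frame(start_time = integer(0), expenditure = numeric(0),
             cafeteria_id = integer(0), item_ids = character(0),
             n_items = integer(0), n_transactions = integer(0),
             stringsAsFactors = FALSE)
}

# distance from a time to each slot interval (0 when inside)
slot_distances <- function(times) {
  slots <- meal_slots()
  d <- sapply(seq_len(nrow(slots)), function(i)
    pmax(0, slots$slot_start[i] - times, times - slots$slot_end[i]))
  if (is.null(dim(d))) d <- matrix(d, nrow = length(times))
  colnames(d) <- slots$meal_class
  d
}

#' Classify meal times into breakfast, lunch or dinner
#'
#' A start time inside an operating slot (06:30-08:30, 11:00-13:00,
#' 17:30-19:30, bounds inclusive) takes that slot's class. A time outside
#' every slot is assigned the nearest slot by absolute gap to the interval,
#' ties resolved toward the earlier slot, and flagged `out_of_slot`.
#'
#' @param start_time numeric vector of meal start times (seconds since
#'   midnight).
#' @return data.frame with `meal_class` and logical `out_of_slot`.
#' @export
#' @examples
#' classify_meal(c(7.5, 13, 9.75) * 3600)
classify_meal <- function(start_time) {
  d <- slot_distances(start_time)
  j <- max.col(-d, ties.method = "first")  # ties resolve toward the earlier slot
  data.frame(meal_class = MEAL_CLASSES[j],
             out_of_slot = d[cbind(seq_along(j), j)] > 0,
             stringsAsFactors = FALSE)
}

#' Resolve duplicate meal classes within a day
#'
#' When two meals of one student-day share a class, the one whose start time
#' lies inside the slot is kept; if both or neither do, the earlier one is
#' kept. Dropped meals are returned for the audit log.
#'
#' @param meals data.frame of classified meals for one student-day
#'   (`start_time`, `meal_class`, `out_of_slot`, ...).
#' @return list with `kept` and `dropped` data.frames; `kept` has at most
#'   one meal per class.
#' @export
dedupe_meal_classes <- function(meals) {
  if (nrow(meals) <= 1L) return(list(kept = meals, dropped = meals[0, ]))
  ord <- order(meals$meal_class, meals$out_of_slot, meals$start_time)
  m <- meals[ord, , drop = FALSE]
  keep <- !duplicated(m$meal_class)
  kept <- m[keep, , drop = FALSE]
  kept <- kept[order(kept$start_time), , drop = FALSE]
  list(kept = kept, dropped = m[!keep, , drop = FALSE])
}

# keep at most 3 meals per day: the 3 whose start times are closest to any
# slot, ties toward the earlier meal
trim_to_three <- function(meals) {
  if (nrow(meals) <= 3L) return(list(kept = meals, dropped = meals[0, ]))
  d <- apply(slot_distances(meals$start_time), 1L, min)
  ord <- order(d, meals$start_time)
  keep <- sort(ord[1:3])
  list(kept = meals[keep, , drop = FALSE], dropped = meals[-keep, , drop = FALSE])
}

#' Segment a full transaction log into classified meals
#'
#' Applies anchored 2-hour segmentation to every student-day (vectorized,
#' equivalent to [segment_meals()] per day), keeps at most 3 meals per day
#' (closest to the operating slots), classifies start times into
#' breakfast/lunch/dinner, and resolves class collisions with
#' [dedupe_meal_classes()]. Out-of-slot meals are reassigned to the nearest
#' slot and flagged by default, or dropped when `out_of_slot = "drop"`.
#'
#' @param tx transaction data.table/data.frame: `student_id`, `date`, `time`
#'   (seconds since midnight), `amount`, `cafeteria_id`, `item_id`.
#' @param out_of_slot `"reassign"` (default) or `"drop"`.
#' @return data.table of meals (`student_id`, `date`, `meal_class`,
#'   `start_time`, `expenditure`, `cafeteria_id`, `item_ids`, `n_items`,
#'   `n_transactions`, `out_of_slot`) with attribute `"dropped"` holding the
#'   audit log of trimmed, deduplicated or out-of-slot-dropped meals.
#' @export
segment_log <- function(tx, out_of_slot = c("reassign", "drop")) {
  out_of_slot <- match.arg(out_of_slot)
  if (nrow(tx) == 0L) stop("empty transaction log: nothing to segment")
  dt <- data.table::as.data.table(tx)
  dt[, date := as.Date(date)]
  if (is.null(dt$cafeteria_id)) dt[, cafeteria_id := NA_integer_]
  if (is.null(dt$item_id)) dt[, item_id := NA_character_]
  data.table::setorder(dt, student_id, date, time, amount, item_id)
  dt[, meal_idx := 0L]
  k <- 0L
  while (anyNA(dt$meal_idx) || any(dt$meal_idx == 0L)) {
    k <- k + 1L
    if (k > 50L) stop("segmentation did not converge")
    anchors <- dt[meal_idx == 0L, .(anchor = time[1L]), by = .(student_id, date)]
    dt[anchors, on = c("student_id", "date"),
       meal_idx := ifelse(meal_idx == 0L & time <= i.anchor + MEAL_WINDOW,
                          k, meal_idx)]
  }
  meals <- dt[, .(start_time = time[1L], expenditure = sum(amount),
                  cafeteria_id = cafeteria_id[1L], n_transactions = .N),
              by = .(student_id, date, meal_idx)]
  # distinct items per meal, from the "+"-joined receipt strings
  if (!is.null(dt$item_id) && !all(is.na(dt$item_id))) {
    it <- dt[!is.na(item_id), .(student_id, date, meal_idx, item_id)]
    spl <- strsplit(it$item_id, "+", fixed = TRUE)
    long <- it[rep(seq_len(.N), lengths(spl))]
    long[, item := unlist(spl)]
    uitems <- unique(long[, .(student_id, date, meal_idx, item)])
    agg <- uitems[, .(item_ids = paste(item, collapse = "+"), n_items = .N),
                  by = .(student_id, date, meal_idx)]
    meals <- agg[meals, on = c("student_id", "date", "meal_idx")]
    meals[is.na(n_items), `:=`(n_items = 0L, item_ids = "")]
  } else {
    meals[, `:=`(item_ids = NA_character_, n_items = NA_integer_)]
  }
  meals[, meal_idx := NULL]

  dropped <- list()
  # trim days with more than 3 segments
  meals[, n_day := .N, by = .(student_id, date)]
  if (any(meals$n_day > 3L)) {
    over <- meals[n_day > 3L]
    kept_over <- over[, {
      tr <- trim_to_three(.SD)
      dropped[[length(dropped) + 1L]] <<- cbind(
        data.table::data.table(student_id = student_id[1], date = date[1],
                               reason = "trimmed_gt3"), tr$dropped)
      tr$kept
    }, by = .(student_id, date)]
    meals <- rbind(meals[n_day <= 3L, !"n_day"],
                   kept_over[, names(meals)[names(meals) != "n_day"], with = FALSE])
  } else meals[, n_day := NULL]

  cls <- classify_meal(meals$start_time)
  meals[, `:=`(meal_class = cls$meal_class, out_of_slot_flag = cls$out_of_slot)]
  if (out_of_slot == "drop") {
    if (any(meals$out_of_slot_flag))
      dropped[[length(dropped) + 1L]] <- cbind(
        data.table::data.table(reason = "out_of_slot"),
        meals[out_of_slot_flag == TRUE])
    meals <- meals[out_of_slot_flag == FALSE]
  }

  # resolve class collisions within each day
  meals[, dup := .N > 1L, by = .(student_id, date, meal_class)]
  if (any(meals$dup)) {
    dups <- meals[dup == TRUE]
    kept_dups <- dups[, {
      dd <- dedupe_meal_classes(data.frame(.SD, out_of_slot = out_of_slot_flag))
      if (nrow(dd$dropped))
        dropped[[length(dropped) + 1L]] <<- cbind(
          data.table::data.table(student_id = student_id[1], date = date[1],
                                 reason = "class_collision"),
          data.table::as.data.table(dd$dropped)[, !"out_of_slot"])
      data.table::as.data.table(dd$kept)[, !"out_of_slot"]
    }, by = .(student_id, date)]
    meals <- rbind(meals[dup == FALSE], kept_dups, use.names = TRUE, fill = TRUE)
  }
  meals[, dup := NULL]
  data.table::setnames(meals, "out_of_slot_flag", "out_of_slot")
  data.table::setcolorder(meals, c("student_id", "date", "meal_class",
                                   "start_time", "expenditure", "cafeteria_id",
                                   "item_ids", "n_items", "n_transactions",
                                   "out_of_slot"))
  data.table::setorder(meals, student_id, date, start_time)
  drop_log <- if (length(dropped)) data.table::rbindlist(dropped, fill = TRUE)
              else data.table::data.table()
  data.table::setattr(meals, "dropped", drop_log)
  meals[]
}

#' Write a meals table to CSV
#'
#' @param meals output of [segment_log()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_meals_csv <- function(meals, path) {
  out <- data.table::copy(meals)
  out[, start_time := seconds_to_hms(start_time)]
  data.table::fwrite(out, path)
  invisible(path)
}
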