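# Synthetic cohort generator: transaction logs and screening surveys with
# the group-conditional structure the downstream analysis assumes.

# truncated normal via inverse-CDF; sd = 0 collapses to the mean
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  if (length(mean) == 1L) mean <- rep(mean, n)
  if (length(sd) == 1L)   sd <- rep(sd, n)
  degen <- sd <= 0
  u <- stats::runif(n)
  if (any(!degen)) {
    plo <- stats::pnorm(lo, mean[!degen], sd[!degen])
    phi <- stats::pnorm(hi, mean[!degen], sd[!degen])
    out[!degen] <- stats::qnorm(plo + u[!degen] * (phi - plo),
                                mean[!degen], sd[!degen])
  }
  out[degen] <- pmin(pmax(mean[degen], lo), hi)
  out
}

# screening-band limits per instrument and group
score_band <- function(instrument, group_name) {
  hc <- group_name == "HC"
  switch(instrument,
    phq9 = switch(group_name, HC = c(0, 4), mild = c(5, 9),
                  moderate_severe = c(10, 27)),
    gad7  = if (hc) c(0, 4)  else c(0, 21),
    pss14 = if (hc) c(0, 28) else c(0, 56),
    isi   = if (hc) c(0, 7)  else c(0, 28)
  )
}

#' Draw survey scores for one screening group
#'
#' PHQ-9 is a discretized truncated normal confined to the group's screening
#' band (HC < 5, mild 5-9, moderate-severe >= 10). GAD-7 is generated with
#' the preset's positive coupling to the standardized PHQ-9 draw and then
#' clipped to the instrument range (additionally < 5 for HC); PSS-14 and ISI
#' are independent discretized truncated normals within their HC bounds or
#' full ranges. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param group_name `"HC"`, `"mild"` or `"moderate_severe"`.
#' @param preset a [group_preset].
#' @param n number of students to draw.
#' @return data.frame with columns `phq9`, `gad7`, `pss14`, `isi`.
#' @export
survey_scores_for_group <- function(group_name, preset, n) {
  sp <- preset$survey_score_params
  draw <- function(instrument) {
    b <- score_band(instrument, group_name)
    p <- sp[[instrument]]
    pmin(pmax(round(rtrunc_norm(n, p[["location"]], p[["scale"]],
                                b[1] - 0.49, b[2] + 0.49)), b[1]), b[2])
  }
  phq <- draw("phq9")
  # couple GAD-7 to the standardized PHQ-9 draw, then clip to its band
  pb <- sp$phq9; gb <- sp$gad7; rho <- sp$coupling
  z <- if (pb[["scale"]] > 0) (phq - pb[["location"]]) / pb[["scale"]] else rep(0, n)
  gad_cont <- gb[["location"]] +
    gb[["scale"]] * (rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
  gband <- score_band("gad7", group_name)
  gad <- pmin(pmax(round(gad_cont), gband[1]), gband[2])
  data.frame(phq9 = as.integer(phq), gad7 = as.integer(gad),
             pss14 = as.integer(draw("pss14")), isi = as.integer(draw("isi")))
}

draw_demographics <- function(preset, n) {
  dp <- preset$demo_params
  data.frame(
    age = as.integer(round(rtrunc_norm(n, dp$age_mean, dp$age_sd, 16, 35))),
    gender = ifelse(stats::runif(n) < dp$p_male, "male", "female"),
    bmi_class = sample(c("lt18.5", "18.5-24", "gt24"), n, replace = TRUE,
                       prob = dp$bmi_probs),
    education = sample(c("undergrad", "postgrad", "doctoral"), n, replace = TRUE,
                       prob = dp$edu_probs),
    stringsAsFactors = FALSE
  )
}

# one-group transaction log; students eat at up to 3 slotted meals per day
simulate_group_transactions <- function(ids, preset, calendar) {
  if (length(ids) == 0L) return(empty_transaction_table())
  slots <- meal_slots()
  grid <- data.table::CJ(student_id = ids, date = as.Date(calendar$date),
                         meal_class = MEAL_CLASSES, sorted = FALSE)
  cal <- data.table::as.data.table(calendar)
  cal[, date := as.Date(date)]
  grid <- cal[grid, on = "date"]
  p <- preset$p_skip[cbind(grid$meal_class, grid$day_type)]
  eaten <- grid[stats::runif(nrow(grid)) >= p]
  if (nrow(eaten) == 0L) return(empty_transaction_table())

  sl <- slots[match(eaten$meal_class, slots$meal_class), ]
  eaten[, meal_time := round(rtrunc_norm(
    .N,
    mean = preset$meal_time_mean[meal_class],
    sd = preset$meal_time_jitter_sd[meal_class],
    lo = sl$slot_start, hi = sl$slot_end))]
  eaten[, slot_end := sl$slot_end]
  eaten[, expenditure := round(stats::rlnorm(
    .N, preset$expenditure_log_mean[meal_class],
    preset$expenditure_log_sd[meal_class]), 2)]
  eaten[, cafeteria_id := sample.int(3L, .N, replace = TRUE,
                                     prob = preset$cafeteria_probs)]
  eaten[, n_items := 1L + stats::rpois(.N, max(preset$items_rate - 1, 0))]
  # per-cafeteria catalogue of 50 item ids; a payment may cover several items,
  # so the receipt string joins them with "+"
  eaten[, item_id := {
    ks <- pmin(n_items, 50L)
    vapply(seq_len(.N), function(i) {
      paste0("C", cafeteria_id[i], "-I",
             sprintf("%02d", sort(sample.int(50L, ks[i]))), collapse = "+")
    }, character(1))
  }]
  eaten[, n_tx := sample(1:3, .N, replace = TRUE, prob = c(0.7, 0.2, 0.1))]
  eaten[, meal_id := .I]

  tx <- eaten[rep(seq_len(nrow(eaten)), eaten$n_tx)]
  tx[, tx_index := seq_len(.N), by = meal_id]
  # amounts: Dirichlet split of the meal expenditure, rounded to 2 decimals
  # with the rounding residual folded into the largest share
  tx[, w := stats::rexp(.N)]
  tx[, share := w / sum(w) * expenditure[1L], by = meal_id]
  tx[, amount := round(share, 2)]
  tx[, amount := {
    resid <- round(expenditure[1L], 2) - sum(amount)
    if (abs(resid) > 1e-9) amount[which.max(share)] <- amount[which.max(share)] + resid
    round(amount, 2)
  }, by = meal_id]
  # later payments of the same meal stay inside the slot, close to the anchor
  gap <- pmin(1800, tx$slot_end - tx$meal_time)
  off <- floor(stats::runif(nrow(tx)) * pmax(gap, 0))
  tx[, time := as.integer(meal_time + ifelse(tx_index == 1L, 0, off))]
  out <- tx[, .(student_id, date, time, amount, cafeteria_id, item_id)]
  data.table::setorder(out, student_id, date, time, amount, item_id)
  out[]
}

empty_transaction_table <- function() {
  data.table::data.table(student_id = character(0), date = as.Date(character(0)),
                         time = integer(0), amount = numeric(0),
                         cafeteria_id = integer(0), item_id = character(0))
}

#' Generate a synthetic cohort
#'
#' Draws one screening survey row per student and a month-long transaction
#' log per group under the configured presets. Each simulated meal emits 1-3
#' payment rows (probabilities 0.7/0.2/0.1) whose first timestamp is the
#' drawn meal time and whose amounts sum to the drawn expenditure; all
#' timestamps lie inside the emitting meal's operating slot, so downstream
#' segmentation and slot classification recover the simulated meals exactly.
#' Identical `(config, seed)` give byte-identical output.
#'
#' @param config a [sim_config].
#' @return list with `survey` (one row per student: demographics plus the
#'   four instrument totals and the intended `group`), `transactions`
#'   (the payment log, times in seconds since midnight), and `ground_truth`
#'   (the presets and per-student group map used).
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(
#'   n_per_group = c(HC = 5, mild = 5, moderate_severe = 5), seed = 1))
#' nrow(cohort$survey)
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  groups <- c("HC", "mild", "moderate_severe")
  surveys <- list(); logs <- list(); offset <- 0L
  for (g in groups) {
    n <- as.integer(config$n_per_group[[g]])
    preset <- config$presets[[g]]
    ids <- if (n > 0) sprintf("S%05d", offset + seq_len(n)) else character(0)
    offset <- offset + n
    if (n > 0) {
      scores <- survey_scores_for_group(g, preset, n)
      demo <- draw_demographics(preset, n)
      surveys[[g]] <- cbind(data.frame(student_id = ids, stringsAsFactors = FALSE),
                            demo, scores, data.frame(group = g))
    }
    logs[[g]] <- simulate_group_transactions(ids, preset, config$calendar)
  }
  survey <- if (length(surveys)) do.call(rbind, c(surveys, make.row.names = FALSE))
            else data.frame(student_id = character(0), age = integer(0),
                            gender = character(0), bmi_class = character(0),
                            education = character(0), phq9 = integer(0),
                            gad7 = integer(0), pss14 = integer(0),
                            isi = integer(0), group = character(0),
                            stringsAsFactors = FALSE)
  transactions <- data.table::rbindlist(logs)
  ground_truth <- list(
    presets = config$presets,
    group_of = stats::setNames(as.character(survey$group), survey$student_id),
    calendar = config$calendar, seed = config$seed
  )
  list(survey = survey, transactions = transactions, ground_truth = ground_truth)
}

#' Write a cohort to CSV files
#'
#' Transaction log columns: `student_id`, `date` (ISO-8601), `time`
#' (HH:MM:SS), `amount` (2 decimals), `cafeteria_id` (1-3), `item_id`.
#' Survey columns: `student_id`, `age`, `gender`, `bmi_class`, `education`,
#' `phq9`, `gad7`, `pss14`, `isi`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tx <- data.table::copy(cohort$transactions)
  tx[, time := seconds_to_hms(time)]
  tx[, amount := sprintf("%.2f", amount)]
  tx_path <- file.path(dir, "transactions.csv")
  sv_path <- file.path(dir, "survey.csv")
  data.table::fwrite(tx, tx_path)
  sv <- cohort$survey[, c("student_id", "age", "gender", "bmi_class",
                          "education", "phq9", "gad7", "pss14", "isi")]
  data.table::fwrite(sv, sv_path)
  invisible(c(transactions = tx_path, survey = sv_path))
}

#' Read a transaction log CSV
#'
#' @param path CSV with the schema written by [write_cohort_csv()].
#' @return data.table with `time` converted to seconds since midnight and
#'   `amount` numeric.
#' @export
read_transactions <- function(path) {
  tx <- data.table::fread(path, colClasses = list(character = "item_id"))
  tx[, date := as.Date(date)]
  if (is.character(tx$time)) tx[, time := hms_to_seconds(time)]
  tx[, amount := as.numeric(amount)]
  if (any(tx$time < 0 | tx$time >= 86400)) stop("transaction times outside [0, 86400)")
  if (any(tx$amount < 0)) stop("negative transaction amounts")
  tx[]
}

#' Read a survey CSV
#'
#' @param path CSV with the survey schema.
#' @return data.frame of survey records.
#' @export
read_survey <- function(path) {
  as.data.frame(data.table::fread(path))
}
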