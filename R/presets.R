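#' Group-conditional simulation preset
#'
#' Bundles every distributional parameter the cohort generator needs for one
#' screening group: per-meal-class skip probabilities by day type, meal-time
#' location and jitter, log-normal expenditure parameters, the item-diversity
#' rate, cafeteria visit probabilities, survey-score parameters and the
#' demographic mix.
#'
#' @param group_name one of `"HC"`, `"mild"`, `"moderate_severe"`.
#' @param p_skip numeric matrix `[meal_class x day_type]` of per-day skip
#'   probabilities; rownames breakfast/lunch/dinner, colnames weekday/weekend.
#' @param meal_time_mean named numeric, mean meal time per class in seconds
#'   since midnight; must lie inside the class's operating slot.
#' @param meal_time_jitter_sd named numeric, timing jitter SD per class in
#'   seconds (>= 0). Drawn times are truncated to the slot.
#' @param expenditure_log_mean,expenditure_log_sd named numeric per class,
#'   parameters of the log-normal single-meal expenditure (currency units on
#'   the natural scale after exponentiation).
#' @param items_rate mean distinct food items per meal (>= 0); realized as
#'   `1 + Poisson(items_rate - 1)` floored at 1.
#' @param cafeteria_probs length-3 probability vector over the campus
#'   cafeterias, summing to 1.
#' @param survey_score_params list with per-instrument `location`/`scale`
#'   (phq9, gad7, pss14, isi) and `coupling`, the PHQ-9 to GAD-7 coupling
#'   coefficient in [-1, 1].
#' @param demo_params list with `age_mean`, `age_sd`, `p_male`, `bmi_probs`
#'   (3-vector over <18.5 / 18.5-24 / >24), `edu_probs` (3-vector over
#'   undergrad / postgrad / doctoral).
#' @return a validated list of class `"group_preset"`.
#' @export
group_preset <- function(group_name, p_skip, meal_time_mean, meal_time_jitter_sd,
                         expenditure_log_mean, expenditure_log_sd, items_rate,
                         cafeteria_probs, survey_score_params, demo_params) {
  preset <- list(
    group_name = group_name, p_skip = p_skip,
    meal_time_mean = meal_time_mean, meal_time_jitter_sd = meal_time_jitter_sd,
    expenditure_log_mean = expenditure_log_mean,
    expenditure_log_sd = expenditure_log_sd,
    items_rate = items_rate, cafeteria_probs = cafeteria_probs,
    survey_score_params = survey_score_params, demo_params = demo_params
  )
  class(preset) <- "group_preset"
  validate_preset(preset)
  preset
}

validate_preset <- function(preset) {
  with(preset, {
    if (!group_name %in% c("HC", "mild", "moderate_severe"))
      stop("group_name must be HC, mild or moderate_severe")
    if (any(p_skip < 0 | p_skip > 1))
      stop("p_skip: probabilities must lie in [0, 1]")
    if (!all(MEAL_CLASSES %in% rownames(p_skip)) ||
        !all(c("weekday", "weekend") %in% colnames(p_skip)))
      stop("p_skip must be a [meal_class x day_type] matrix")
    slots <- meal_slots()
    for (m in MEAL_CLASSES) {
      s <- slots[slots$meal_class == m, ]
      if (is.na(meal_time_mean[[m]]) ||
          meal_time_mean[[m]] < s$slot_start || meal_time_mean[[m]] > s$slot_end)
        stop(sprintf("meal_time_mean[%s] = %s lies outside the %s slot [%d, %d]",
                     m, meal_time_mean[[m]], m, s$slot_start, s$slot_end))
      if (meal_time_jitter_sd[[m]] < 0)
        stop(sprintf("meal_time_jitter_sd[%s] must be >= 0", m))
    }
    if (items_rate < 0) stop("items_rate must be >= 0")
    if (length(cafeteria_probs) != 3L || any(cafeteria_probs < 0) ||
        abs(sum(cafeteria_probs) - 1) > 1e-9)
      stop("cafeteria_probs must be a 3-vector summing to 1")
    cp <- survey_score_params$coupling
    if (is.null(cp) || abs(cp) > 1)
      stop("survey_score_params$coupling must lie in [-1, 1]")
  })
  invisible(preset)
}

skip_matrix <- function(breakfast, lunch, dinner) {
  m <- rbind(breakfast = breakfast, lunch = lunch, dinner = dinner)
  colnames(m) <- c("weekday", "weekend")
  m
}

#' Default group presets
#'
#' The packaged study conditions. Meal-time jitter SDs are calibrated so the
#' implied raw median absolute deviations of lunch and dinner times match the
#' reported group dispersions (about 17-19 min for lunch, 23-26 min for
#' dinner, moderate-severe > mild > HC); survey locations and scales equal
#' the cohort's printed instrument means (SDs); breakfast skipping is more
#' probable, dinner spending higher and item diversity lower with increasing
#' depression severity; cafeteria preferences are identical across groups,
#' matching the null location finding.
#'
#' @return named list of three [group_preset] objects (`HC`, `mild`,
#'   `moderate_severe`).
#' @export
default_presets <- function() {
  times <- c(breakfast = 27000, lunch = 43200, dinner = 66600)  # 07:30, 12:00, 18:30
  exp_sd <- c(breakfast = 0.35, lunch = 0.35, dinner = 0.35)
  caf <- c(0.40, 0.35, 0.25)
  demo <- function(age_mean, age_sd, p_male, bmi, edu)
    list(age_mean = age_mean, age_sd = age_sd, p_male = p_male,
         bmi_probs = bmi, edu_probs = edu / sum(edu))
  svy <- function(phq_m, phq_s, gad_m, gad_s, pss_m, pss_s, isi_m, isi_s, rho = 0.5)
    list(phq9  = c(location = phq_m, scale = phq_s),
         gad7  = c(location = gad_m, scale = gad_s),
         pss14 = c(location = pss_m, scale = pss_s),
         isi   = c(location = isi_m, scale = isi_s),
         coupling = rho)
  list(
    HC = group_preset(
      "HC",
      p_skip = skip_matrix(c(0.25, 0.40), c(0.08, 0.15), c(0.08, 0.12)),
      meal_time_mean = times,
      meal_time_jitter_sd = c(breakfast = 900, lunch = 1520, dinner = 2080),
      expenditure_log_mean = c(breakfast = 1.61, lunch = 2.40, dinner = 2.30),
      expenditure_log_sd = exp_sd, items_rate = 3.0, cafeteria_probs = caf,
      survey_score_params = svy(1.42, 1.41, 0.49, 0.92, 15.77, 6.79, 1.78, 1.86),
      demo_params = demo(19.46, 1.49, 0.389, c(0.127, 0.731, 0.142),
                         c(0.9856, 0.0072, 0.0032))
    ),
    mild = group_preset(
      "mild",
      p_skip = skip_matrix(c(0.30, 0.45), c(0.09, 0.16), c(0.08, 0.12)),
      meal_time_mean = times,
      meal_time_jitter_sd = c(breakfast = 930, lunch = 1565, dinner = 2105),
      expenditure_log_mean = c(breakfast = 1.61, lunch = 2.40, dinner = 2.42),
      expenditure_log_sd = exp_sd, items_rate = 2.9, cafeteria_probs = caf,
      survey_score_params = svy(6.58, 1.33, 3.60, 2.74, 23.08, 6.50, 5.42, 3.46),
      demo_params = demo(19.48, 1.35, 0.344, c(0.155, 0.713, 0.132),
                         c(0.9913, 0.0033, 0.0022))
    ),
    moderate_severe = group_preset(
      "moderate_severe",
      p_skip = skip_matrix(c(0.45, 0.60), c(0.12, 0.20), c(0.08, 0.14)),
      meal_time_mean = times,
      meal_time_jitter_sd = c(breakfast = 1000, lunch = 1690, dinner = 2330),
      expenditure_log_mean = c(breakfast = 1.61, lunch = 2.40, dinner = 2.44),
      expenditure_log_sd = exp_sd, items_rate = 2.5, cafeteria_probs = caf,
      survey_score_params = svy(12.94, 3.31, 7.47, 4.26, 32.41, 6.63, 8.93, 5.79),
      demo_params = demo(19.64, 1.52, 0.430, c(0.128, 0.733, 0.140),
                         c(0.9884, 0.0058, 0.0058))
    )
  )
}

#' Simulation configuration
#'
#' @param n_per_group named integer vector of group sizes
#'   (`HC`, `mild`, `moderate_severe`); zero sizes allowed.
#' @param seed integer RNG seed; mandatory.
#' @param calendar data.frame with `date` and `day_type` columns, dates
#'   strictly increasing (default: [study_calendar()]).
#' @param presets named list of [group_preset] objects
#'   (default: [default_presets()]).
#' @param n_cafeterias number of cafeterias on campus; fixed at 3.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_per_group = c(HC = 200, mild = 200, moderate_severe = 200),
                       seed,
                       calendar = study_calendar(),
                       presets = default_presets(),
                       n_cafeterias = 3L) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_per_group = n_per_group, seed = as.integer(seed),
              calendar = calendar, presets = presets,
              n_cafeterias = as.integer(n_cafeterias))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  grp <- c("HC", "mild", "moderate_severe")
  if (!all(grp %in% names(cfg$n_per_group)))
    stop("n_per_group must name HC, mild and moderate_severe")
  if (any(cfg$n_per_group < 0)) stop("group sizes must be non-negative")
  if (nrow(cfg$calendar) == 0L) stop("calendar must be non-empty")
  d <- as.Date(cfg$calendar$date)
  if (any(diff(d) <= 0)) stop("calendar dates must be strictly increasing")
  if (!all(cfg$calendar$day_type %in% c("weekday", "weekend")))
    stop("calendar day_type must be weekday or weekend")
  if (cfg$n_cafeterias != 3L) stop("n_cafeterias is fixed at 3")
  for (g in grp) validate_preset(cfg$presets[[g]])
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' The YAML mirrors [sim_config()]: `seed` (mandatory), `n_per_group`,
#' optional `calendar: {from, to, holidays}` and optional per-group
#' overrides are not supported -- presets beyond the defaults are built in
#' code.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config YAML must set seed")
  cal <- if (is.null(y$calendar)) study_calendar() else
    study_calendar(y$calendar$from, y$calendar$to,
                   holiday_dates = y$calendar$holidays)
  npg <- if (is.null(y$n_per_group)) c(HC = 200, mild = 200, moderate_severe = 200)
         else unlist(y$n_per_group)
  sim_config(n_per_group = npg, seed = y$seed, calendar = cal)
}
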