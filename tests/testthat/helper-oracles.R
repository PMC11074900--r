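# Independent oracles and shared fixtures for the test suite.

ALLDAY_PATTERNS_TEST <- c("B", "L", "D", "BL", "LD", "BD", "BLD")

# brute-force re-anchoring scan: walks the sorted times, opening a new group
# whenever a time exceeds the current anchor by more than 2 hours
oracle_segment_groups <- function(times) {
  groups <- integer(length(times)); g <- 0L; i <- 1L
  while (i <= length(times)) {
    g <- g + 1L
    anchor <- times[i]
    while (i <= length(times) && times[i] <= anchor + 7200) {
      groups[i] <- g
      i <- i + 1L
    }
  }
  groups
}

# direct-formula median and MAD by sorting and enumeration
oracle_median <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
oracle_mad <- function(x) oracle_median(abs(x - oracle_median(x)))

# random survey scores spanning every screening band
random_survey_scores <- function(n) {
  data.frame(
    phq9 = sample(0:27, n, replace = TRUE),
    gad7 = sample(0:21, n, replace = TRUE),
    pss14 = sample(0:56, n, replace = TRUE),
    isi = sample(0:28, n, replace = TRUE)
  )
}

# row-by-row re-application of the inclusion rules
oracle_label <- function(r) {
  if (r$phq9 >= 10) return("moderate_severe")
  if (r$phq9 >= 5) return("mild")
  if (r$gad7 < 5 && r$pss14 < 29 && r$isi < 8) return("HC")
  "excluded"
}

# survey table realizing given per-group counts of demographic and
# comorbidity cells (used to check cohort-summary arithmetic)
count_survey <- function(n, n_gad_gt5 = 0, n_pss_gt28 = 0, n_isi_gt8 = 0,
                         n_male = 0, phq9 = 7) {
  data.frame(
    student_id = sprintf("X%04d", seq_len(n)),
    age = 20L,
    gender = rep(c("male", "female"), c(n_male, n - n_male)),
    bmi_class = "18.5-24", education = "undergrad",
    phq9 = phq9,
    gad7 = rep(c(6L, 0L), c(n_gad_gt5, n - n_gad_gt5)),
    pss14 = rep(c(30L, 0L), c(n_pss_gt28, n - n_pss_gt28)),
    isi = rep(c(9L, 0L), c(n_isi_gt8, n - n_isi_gt8)),
    stringsAsFactors = FALSE
  )
}

# one moderately sized cohort under the packaged study conditions, generated
# once and shared across test files
.fixture_env <- new.env(parent = emptyenv())
fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- sim_config(n_per_group = c(HC = 200, mild = 200, moderate_severe = 200),
                      seed = 20201001L)
    cohort <- generate_cohort(cfg)
    meals <- segment_log(cohort$transactions)
    features <- extract_features(meals, cfg$calendar)
    .fixture_env$cohort <- list(config = cfg, cohort = cohort, meals = meals,
                                features = features,
                                labels = assign_group(cohort$survey))
  }
  .fixture_env$cohort
}

# random single-day transaction frames for segmentation property tests
random_day_tx <- function(n_tx, date = as.Date("2020-10-05")) {
  data.frame(
    student_id = "S1", date = date,
    time = sort(sample.int(86399L, n_tx)),
    amount = round(runif(n_tx, 0.5, 20), 2),
    cafeteria_id = sample.int(3L, n_tx, replace = TRUE),
    item_id = sprintf("C1-I%02d", sample.int(50L, n_tx, replace = TRUE)),
    stringsAsFactors = FALSE
  )
}
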