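# Screening rules: PHQ-9 bands define the depression groups, and students
# without depressive symptoms but with anxiety, stress or insomnia above
# threshold are excluded from the healthy control pool.

#' Assign screening groups from survey scores
#'
#' Group bands: mild depression for PHQ-9 in 5-9; moderate-severe for
#' PHQ-9 >= 10; healthy control (HC) requires PHQ-9 < 5 together with
#' GAD-7 < 5, PSS-14 < 29 and ISI < 8; students with PHQ-9 < 5 but any of
#' those comorbid scores at or above threshold are `excluded`. The four
#' labels partition any complete survey table.
#'
#' @param survey data.frame with integer columns `phq9`, `gad7`, `pss14`,
#'   `isi` (one row per student). Scalar scores also accepted.
#' @return character vector of labels in
#'   `{"HC", "mild", "moderate_severe", "excluded"}`.
#' @export
#' @examples
#' assign_group(data.frame(phq9 = c(3, 3, 10), gad7 = c(2, 6, 0),
#'                         pss14 = c(15, 10, 0), isi = c(1, 2, 0)))
assign_group <- function(survey) {
  for (col in c("phq9", "gad7", "pss14", "isi")) {
    if (is.null(survey[[col]])) stop(sprintf("missing instrument score: %s", col))
    if (anyNA(survey[[col]])) stop(sprintf("missing values in instrument score: %s", col))
  }
  phq <- survey$phq9
  out <- rep(NA_character_, length(phq))
  out[phq >= 5 & phq <= 9] <- "mild"
  out[phq >= 10] <- "moderate_severe"
  hc <- phq < 5 & survey$gad7 < 5 & survey$pss14 < 29 & survey$isi < 8
  out[phq < 5] <- ifelse(hc[phq < 5], "HC", "excluded")
  out
}

#' Count screened-out students
#'
#' @param n_recruited number of students recruited.
#' @param labels group labels from [assign_group()].
#' @return list with `n_excluded` (count of `excluded` labels),
#'   `n_included` and `consistent` (whether recruited = HC + mild +
#'   moderate-severe + excluded).
#' @export
exclusion_count <- function(n_recruited, labels) {
  if (n_recruited < length(labels)) stop("n_recruited below number of labelled rows")
  n_excl <- sum(labels == "excluded")
  n_incl <- sum(labels %in% c("HC", "mild", "moderate_severe"))
  list(n_excluded = n_excl, n_included = n_incl,
       consistent = n_recruited == n_excl + n_incl)
}

#' Cohort characteristics summary
#'
#' Per-group sample sizes, mean (SD) of age and each instrument total,
#' counts and percentages for gender, BMI class and education, and the
#' comorbidity flags GAD-7 > 5, PSS-14 > 28 and ISI > 8. Percentages are
#' 100 * n_cell / n_group, rounded to 2 decimals; for an empty group the
#' percentage is left missing rather than zero. Note the flag thresholds
#' are strict ">" and differ at the boundary from the inclusion cutoffs
#' (GAD-7 >= 5 etc.); both rules are kept as printed sources state them.
#'
#' @param survey survey data.frame (see [read_survey()]).
#' @param labels group labels aligned with `survey` rows.
#' @param groups which labels to tabulate (default the three study groups).
#' @return long data.frame with columns `group`, `variable`, `level`, `n`,
#'   `mean`, `sd`, `pct`.
#' @export
cohort_summary <- function(survey, labels,
                           groups = c("HC", "mild", "moderate_severe")) {
  stopifnot(nrow(survey) == length(labels))
  rows <- list()
  add <- function(group, variable, level = NA, n = NA, mean = NA, sd = NA, pct = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      group = group, variable = variable, level = level, n = n,
      mean = mean, sd = sd, pct = pct, stringsAsFactors = FALSE)
  }
  cat_levels <- list(
    gender = c("male", "female"),
    bmi_class = c("lt18.5", "18.5-24", "gt24"),
    education = c("undergrad", "postgrad", "doctoral")
  )
  flags <- list(gad7_gt5 = quote(gad7 > 5), pss14_gt28 = quote(pss14 > 28),
                isi_gt8 = quote(isi > 8))
  for (g in groups) {
    sub <- survey[labels == g, , drop = FALSE]
    ng <- nrow(sub)
    add(g, "n", n = ng)
    for (v in c("age", "phq9", "gad7", "pss14", "isi")) {
      x <- sub[[v]][!is.na(sub[[v]])]
      add(g, v, mean = if (length(x)) mean(x) else NA,
          sd = if (length(x) > 1) stats::sd(x) else NA)
    }
    for (v in names(cat_levels)) for (lev in cat_levels[[v]]) {
      ncell <- sum(sub[[v]] == lev, na.rm = TRUE)
      add(g, v, level = lev, n = ncell,
          pct = if (ng > 0) round(100 * ncell / ng, 2) else NA)
    }
    for (f in names(flags)) {
      ncell <- if (ng > 0) sum(eval(flags[[f]], sub)) else 0L
      add(g, f, level = "yes", n = ncell,
          pct = if (ng > 0) round(100 * ncell / ng, 2) else NA)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Render a cohort summary as plain text
#'
#' @param summary output of [cohort_summary()].
#' @return character vector of formatted lines.
#' @export
format_cohort_summary <- function(summary) {
  apply(summary, 1, function(r) {
    val <- if (!is.na(r[["mean"]])) sprintf("%.2f (%.2f)", as.numeric(r[["mean"]]),
                                            as.numeric(r[["sd"]]))
           else if (!is.na(r[["pct"]])) sprintf("%s (%.2f%%)", r[["n"]],
                                                as.numeric(r[["pct"]]))
           else as.character(r[["n"]])
    sprintf("%-16s %-10s %-8s %s", r[["group"]], r[["variable"]],
            ifelse(is.na(r[["level"]]), "", r[["level"]]), val)
  })
}
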