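# End-to-end orchestration: simulate or load -> screen -> segment ->
# featurize -> analyze -> classify, with artifacts and a run manifest.

#' Covariate-adjusted comparisons across all features
#'
#' Runs [ancova()] for each feature column and applies FDR correction to the
#' group-effect p-values within each feature family (the post hoc pairwise
#' p-values are FDR-corrected across the 3 pairs inside [ancova()]).
#'
#' @param features wide feature table from [extract_features()].
#' @param survey survey table aligned by `student_id`.
#' @param labels group labels aligned with `survey`.
#' @param columns feature columns to test (default: all).
#' @return data.frame: one row per (feature, contrast) with the family-wise
#'   FDR-adjusted group p and contrast statistics.
#' @export
run_group_comparisons <- function(features, survey, labels, columns = NULL) {
  idx <- match(features$student_id, survey$student_id)
  grp <- factor(labels[idx], levels = c("HC", "mild", "moderate_severe"))
  keep <- !is.na(grp)
  cov <- covariate_set(survey[idx, , drop = FALSE])
  if (is.null(columns)) columns <- setdiff(names(features), "student_id")
  res <- lapply(columns, function(col) {
    y <- features[[col]][keep]
    if (sum(!is.na(y)) < 10 || stats::var(y, na.rm = TRUE) == 0) return(NULL)
    a <- tryCatch(ancova(y, grp[keep], cov[keep, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(a)) return(NULL)
    cbind(data.frame(feature = col, F = a$F, df1 = a$df[1], df2 = a$df[2],
                     p_group = a$p, stringsAsFactors = FALSE),
          a$posthoc[, c("contrast", "estimate", "se", "p", "p_adj")])
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) return(NULL)
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  fam <- vapply(strsplit(out$feature, ".", fixed = TRUE), `[`, character(1), 1L)
  one <- !duplicated(out$feature)
  adj <- stats::ave(out$p_group[one], fam[one], FUN = fdr_adjust)
  out$p_group_fdr <- adj[match(out$feature, out$feature[one])]
  out
}

#' Pattern-band logistic associations with depression severity
#'
#' For each all-day pattern frequency feature, codes students into SD bands
#' and fits two binary logistic models (mild vs HC; moderate-severe vs HC)
#' with Rare as the reference band, adjusted for age, gender, BMI class and
#' education.
#'
#' @param features wide feature table.
#' @param survey,labels aligned survey table and group labels.
#' @param patterns feature columns to band (default: weekday BLD and LD
#'   pattern frequencies).
#' @return data.frame with `pattern`, `outcome`, `band`, `or`, `ci_lo`,
#'   `ci_hi`, `p`, `unstable`.
#' @export
run_pattern_associations <- function(features, survey, labels,
                                     patterns = c("pattern.weekday.BLD",
                                                  "pattern.weekday.LD")) {
  patterns <- intersect(patterns, names(features))
  zb <- zscore_and_band(as.matrix(features[, patterns, with = FALSE]))
  idx <- match(features$student_id, survey$student_id)
  grp <- labels[idx]
  cov <- covariate_set(survey[idx, , drop = FALSE])
  out <- list()
  for (pat in colnames(zb$band)) for (target in c("mild", "moderate_severe")) {
    sel <- grp %in% c("HC", target)
    res <- tryCatch(
      logistic_association(zb$band[sel, pat],
                           as.integer(grp[sel] == target),
                           cov[sel, , drop = FALSE]),
      error = function(e) NULL)
    if (!is.null(res))
      out[[length(out) + 1L]] <- cbind(
        data.frame(pattern = pat, outcome = target, stringsAsFactors = FALSE), res)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Default mediation: depression group -> anxiety -> BLD pattern
#'
#' X is the ordinal group score (HC = 0, mild = 1, moderate-severe = 2),
#' M the raw GAD-7 total and Y the weekday breakfast-lunch-dinner pattern
#' frequency, with the demographic covariates; percentile bootstrap CI for
#' the indirect effect.
#'
#' @param features,survey,labels aligned tables.
#' @param outcome_col Y column (default `pattern.weekday.BLD`).
#' @param n_boot,seed bootstrap controls (see [mediate()]).
#' @param reverse if `TRUE`, swap X and Y (pattern as the independent
#'   variable).
#' @return a `mediation_result`.
#' @export
run_mediation <- function(features, survey, labels,
                          outcome_col = "pattern.weekday.BLD",
                          n_boot = 5000L, seed, reverse = FALSE) {
  idx <- match(features$student_id, survey$student_id)
  grp_score <- c(HC = 0, mild = 1, moderate_severe = 2)[labels[idx]]
  cov <- covariate_set(survey[idx, , drop = FALSE])
  yv <- features[[outcome_col]]
  if (reverse)
    mediate(yv, survey$gad7[idx], grp_score, cov, n_boot = n_boot, seed = seed)
  else
    mediate(grp_score, survey$gad7[idx], yv, cov, n_boot = n_boot, seed = seed)
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> screen -> segment -> featurize -> analyze
#' -> classify, writing every stage's artifact plus a JSON manifest (config
#' hash, seed, per-stage row counts and timings, dropped-record log) to
#' `out_dir`. The global seed fans out to per-stage seeds through a fixed
#' derivation so stages are independently reproducible.
#'
#' @param sim a [sim_config] to simulate from, or `NULL` when loading CSVs.
#' @param transactions_csv,survey_csv input paths (used when `sim` is NULL).
#' @param out_dir output directory.
#' @param seed global seed.
#' @param out_of_slot passed to [segment_log()].
#' @param n_boot mediation bootstrap resamples.
#' @param run_classifier set `FALSE` to skip the SVM stage.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(sim = NULL, transactions_csv = NULL, survey_csv = NULL,
                         out_dir, seed = 20201001L, out_of_slot = "reassign",
                         n_boot = 2000L, run_classifier = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = list())
  t_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    val
  }

  if (!is.null(sim)) {
    cohort <- stage("simulate", generate_cohort(sim))
    survey <- cohort$survey
    tx <- cohort$transactions
    paths <- write_cohort_csv(cohort, out_dir)
    cfg_path <- file.path(out_dir, "sim_config.yaml")
    yaml::write_yaml(list(seed = sim$seed,
                          n_per_group = as.list(sim$n_per_group),
                          calendar = list(from = as.character(min(sim$calendar$date)),
                                          to = as.character(max(sim$calendar$date)))),
                     cfg_path)
    manifest$config_hash <- unname(tools::md5sum(cfg_path))
    calendar <- sim$calendar
  } else {
    survey <- stage("load", read_survey(survey_csv))
    tx <- stage("load_tx", read_transactions(transactions_csv))
    calendar <- if (nrow(tx) > 0) study_calendar(min(tx$date), max(tx$date))
                else study_calendar()
    manifest$config_hash <- unname(tools::md5sum(transactions_csv))
  }
  manifest$stages$input <- list(n_students = nrow(survey), n_transactions = nrow(tx))

  labels <- stage("screen", assign_group(survey))
  summ <- cohort_summary(survey, labels)
  data.table::fwrite(summ, file.path(out_dir, "cohort_summary.csv"))
  manifest$stages$screen$n_by_group <- as.list(table(labels))

  meals <- stage("segment", segment_log(tx, out_of_slot = out_of_slot))
  write_meals_csv(meals, file.path(out_dir, "meals.csv"))
  dropped <- attr(meals, "dropped")
  manifest$stages$segment$n_meals <- nrow(meals)
  manifest$stages$segment$n_dropped <- if (is.null(dropped)) 0L else nrow(dropped)

  features <- stage("featurize", extract_features(meals, calendar))
  included <- labels[match(features$student_id, survey$student_id)] %in%
    c("HC", "mild", "moderate_severe")
  no_meals <- setdiff(survey$student_id[labels != "excluded"], features$student_id)
  features <- features[included]
  data.table::fwrite(features, file.path(out_dir, "features.csv"))
  data.table::fwrite(feature_dictionary(features),
                     file.path(out_dir, "feature_dictionary.csv"))
  manifest$stages$featurize$n_students <- nrow(features)
  manifest$stages$featurize$n_without_meals <- length(no_meals)

  stats_out <- stage("analyze", {
    anc <- run_group_comparisons(features, survey, labels)
    logi <- run_pattern_associations(features, survey, labels)
    med <- run_mediation(features, survey, labels, n_boot = n_boot,
                         seed = derive_seed(seed, "mediation"))
    list(ancova = anc, logistic = logi, mediation = med)
  })
  if (!is.null(stats_out$ancova))
    data.table::fwrite(stats_out$ancova, file.path(out_dir, "stats_ancova.csv"))
  if (!is.null(stats_out$logistic))
    data.table::fwrite(stats_out$logistic, file.path(out_dir, "stats_logistic.csv"))
  jsonlite::write_json(
    stats_out$mediation[c("a", "b", "c_prime", "indirect", "ci", "r_squared",
                          "n", "n_boot")],
    file.path(out_dir, "stats_mediation.json"), auto_unbox = TRUE, digits = NA)

  if (run_classifier) {
    metrics <- stage("classify", {
      idx <- match(features$student_id, survey$student_id)
      grp <- labels[idx]
      z <- zscore_and_band(as.matrix(features[, !"student_id"]))$z
      ok_col <- colSums(is.na(z)) == 0
      cfg <- svm_config(seed = derive_seed(seed, "classify"))
      tri <- crossval_svm(z[, ok_col, drop = FALSE], grp, cfg)
      bsel <- grp %in% c("HC", "moderate_severe")
      bin <- crossval_svm(z[bsel, ok_col, drop = FALSE], grp[bsel], cfg)
      list(tri = tri, binary = bin)
    })
    mdf <- rbind(data.frame(task = "tri", t(metrics$tri$summary)),
                 data.frame(task = "binary", t(metrics$binary$summary)))
    data.table::fwrite(mdf, file.path(out_dir, "metrics.csv"))
    jsonlite::write_json(list(tri = as.list(metrics$tri$summary),
                              binary = as.list(metrics$binary$summary)),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$classify$accuracy <- list(
      tri = unname(metrics$tri$summary["accuracy"]),
      binary = unname(metrics$binary$summary["accuracy"]))
  }

  manifest$total_seconds <- round(as.numeric(difftime(Sys.time(), t_all,
                                                      units = "secs")), 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
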