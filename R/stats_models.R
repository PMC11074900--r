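# Group comparison and association models: covariate-adjusted ANCOVA with
# FDR-corrected post hoc contrasts, SD-band logistic regression, and
# percentile-bootstrap single-mediator analysis.

#' Assemble the covariate set
#'
#' Age (continuous), gender, BMI class and education, with declared
#' reference levels (female, 18.5-24, undergrad). Unused factor levels are
#' dropped; any missing value among modelled rows is an error in the model
#' functions.
#'
#' @param survey survey data.frame.
#' @return data.frame of model-ready covariates.
#' @export
covariate_set <- function(survey) {
  out <- data.frame(
    age = as.numeric(survey$age),
    gender = stats::relevel(factor(survey$gender, levels = c("female", "male")),
                            "female"),
    bmi_class = stats::relevel(factor(survey$bmi_class,
                                      levels = c("18.5-24", "lt18.5", "gt24")),
                               "18.5-24"),
    education = stats::relevel(factor(survey$education,
                                      levels = c("undergrad", "postgrad", "doctoral")),
                               "undergrad")
  )
  droplevels(out)
}

# constant covariates are inestimable alongside an intercept; drop them
prune_covariates <- function(cov) {
  if (is.null(cov)) return(NULL)
  cov <- droplevels(cov)
  keep <- vapply(cov, function(col) {
    if (is.factor(col)) nlevels(col) >= 2L
    else stats::var(col, na.rm = TRUE) > 0
  }, logical(1))
  if (!all(keep)) cov <- cov[, keep, drop = FALSE]
  if (ncol(cov) == 0L) NULL else cov
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH with monotonicity enforcement; output preserves input length
#' and order, and adjusted values never fall below the raw ones.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03))  # all 0.03
fdr_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Fits the linear model `feature ~ group + covariates` and tests the group
#' effect by the partial F-test of the group dummies (equivalent to Type II
#' sums of squares in a main-effects model). Post hoc pairwise contrasts of
#' the covariate-adjusted group means come from the coefficient vector
#' (mild - HC, moderate_severe - HC, moderate_severe - mild), with BH-FDR
#' adjustment across the three pairs.
#'
#' @param feature numeric response vector.
#' @param group factor-like group labels (>= 3 levels represented).
#' @param covariates data.frame from [covariate_set()], or `NULL`.
#' @return list of class `"ancova_result"`: `F`, `df`, `p`, `posthoc`
#'   (data.frame with `contrast`, `estimate`, `se`, `p`, `p_adj`), and the
#'   fitted `model`.
#' @export
ancova <- function(feature, group, covariates = NULL) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 3L) stop("ANCOVA requires at least 3 groups represented")
  df <- data.frame(y = as.numeric(feature), group = group)
  covariates <- prune_covariates(covariates)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  rhs <- paste(setdiff(names(df), "y"), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = df)
  if (any(is.na(stats::coef(full))))
    stop("rank-deficient model; aliased: ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))], collapse = ", "))
  rhs_red <- paste(setdiff(names(df), c("y", "group")), collapse = " + ")
  reduced <- stats::lm(stats::as.formula(
    paste("y ~", if (nzchar(rhs_red)) rhs_red else "1")), data = df)
  ftest <- stats::anova(reduced, full)
  Fval <- ftest$F[2L]; p <- ftest$`Pr(>F)`[2L]
  dfs <- c(ftest$Df[2L], ftest$Res.Df[2L])

  lv <- levels(group)
  co <- stats::coef(full); V <- stats::vcov(full)
  cn <- paste0("group", lv[-1L])
  pairs <- list(c(2, 1), c(3, 1), c(3, 2))  # indices into lv
  posthoc <- do.call(rbind, lapply(pairs, function(pr) {
    w <- stats::setNames(rep(0, length(co)), names(co))
    if (pr[1] > 1) w[paste0("group", lv[pr[1]])] <- 1
    if (pr[2] > 1) w[paste0("group", lv[pr[2]])] <- -1
    est <- sum(w * co); se <- sqrt(drop(t(w) %*% V %*% w))
    tval <- est / se
    data.frame(contrast = paste(lv[pr[1]], "-", lv[pr[2]]), estimate = est,
               se = se, t = tval,
               p = 2 * stats::pt(abs(tval), full$df.residual, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  posthoc$p_adj <- fdr_adjust(posthoc$p)
  structure(list(F = Fval, df = dfs, p = p, posthoc = posthoc, model = full,
                 n = nrow(df)),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA group effect: F(%d, %d) = %.3f, p = %.4g (n = %d)\n",
              x$df[1], x$df[2], x$F, x$p, x$n))
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' SD-band logistic association
#'
#' Binary logistic regression of depression status (target group = 1 vs
#' HC = 0) on a banded feature (levels Rare/Normal/Always with Rare as
#' reference), adjusted for the covariates. Odds ratios are `exp(B)` with
#' 95% Wald confidence intervals `exp(B +/- 1.96 SE)`. Suspected separation
#' (|B| > 10 or SE > 50) flags the band's CI as unstable.
#'
#' @param band character/factor vector of feature bands for the modelled
#'   rows (`Rare`, `Normal`, `Always`).
#' @param outcome 0/1 vector (1 = target depression group).
#' @param covariates data.frame from [covariate_set()], or `NULL`.
#' @return data.frame with one row per non-reference band: `band`, `or`,
#'   `ci_lo`, `ci_hi`, `p`, `unstable`.
#' @export
logistic_association <- function(band, outcome, covariates = NULL) {
  band <- factor(band, levels = c("Rare", "Normal", "Always"))
  band <- droplevels(band)
  df <- data.frame(y = as.integer(outcome), band = band)
  covariates <- prune_covariates(covariates)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  sm <- summary(fit)$coefficients
  rows <- grep("^band", rownames(sm), value = TRUE)
  out <- do.call(rbind, lapply(rows, function(r) {
    b <- sm[r, "Estimate"]; se <- sm[r, "Std. Error"]
    data.frame(band = sub("^band", "", r), or = exp(b),
               ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
               p = sm[r, "Pr(>|z|)"],
               unstable = abs(b) > 10 || se > 50,
               stringsAsFactors = FALSE)
  }))
  attr(out, "model") <- fit
  out
}

#' Single-mediator analysis with percentile bootstrap
#'
#' The product-of-paths model: `M ~ X + covariates` gives path `a`,
#' `Y ~ X + M + covariates` gives path `b` and the direct effect `c'`; the
#' indirect effect is `a * b`, with a percentile bootstrap confidence
#' interval from resampling rows with replacement. The default orientation
#' takes X = depression group score (0/1/2), M = anxiety score and
#' Y = breakfast-lunch-dinner pattern frequency; pass the arguments swapped
#' for the reverse orientation.
#'
#' @param x numeric independent variable (e.g. group coded 0/1/2).
#' @param m numeric mediator.
#' @param y numeric outcome.
#' @param covariates optional data.frame of covariates.
#' @param n_boot bootstrap resamples (default 5000; < 1000 warns).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return list of class `"mediation_result"`: paths `a`, `b`, `c_prime`,
#'   `indirect`, `ci` (percentile), `r_squared` of the outcome equation,
#'   `n`, `n_boot`, `seed`, and the bootstrap draws.
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 5000L, seed, conf = 0.95) {
  if (missing(seed)) stop("seed is mandatory for the bootstrap")
  if (n_boot < 1000L) warning("fewer than 1000 bootstrap resamples")
  df <- data.frame(x = as.numeric(x), m = as.numeric(m), y = as.numeric(y))
  cv <- NULL
  covariates <- prune_covariates(covariates)
  if (!is.null(covariates)) {
    cv <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
    keep <- stats::complete.cases(df) & stats::complete.cases(cv)
    df <- df[keep, , drop = FALSE]; cv <- cv[keep, , drop = FALSE]
  } else df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (stats::var(df$x) == 0 || stats::var(df$m) == 0)
    stop("degenerate variance in x or m")

  Xm <- cbind(1, df$x, cv)                 # M-equation design
  Xy <- cbind(1, df$x, df$m, cv)           # Y-equation design
  fit_paths <- function(Xm, Xy, mm, yy) {
    a <- stats::.lm.fit(Xm, mm)$coefficients[2L]
    cb <- stats::.lm.fit(Xy, yy)$coefficients
    c(a = a, b = cb[3L], c_prime = cb[2L])
  }
  pt <- fit_paths(Xm, Xy, df$m, df$y)
  yhat <- Xy %*% stats::.lm.fit(Xy, df$y)$coefficients
  r2 <- 1 - sum((df$y - yhat)^2) / sum((df$y - mean(df$y))^2)

  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, 2L)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    ab <- fit_paths(Xm[idx, , drop = FALSE], Xy[idx, , drop = FALSE],
                    df$m[idx], df$y[idx])
    boots[i, ] <- ab[1:2]
  }
  ind_boot <- boots[, 1L] * boots[, 2L]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(ind_boot, c(alpha, 1 - alpha), names = FALSE)
  structure(list(a = unname(pt["a"]), b = unname(pt["b"]),
                 c_prime = unname(pt["c_prime"]),
                 indirect = unname(pt["a"] * pt["b"]),
                 ci = ci, r_squared = r2, n = n, n_boot = n_boot, seed = seed,
                 boot_indirect = ind_boot),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(paste0("Mediation (n = %d, %d bootstraps): a = %.4f, b = %.4f, ",
                     "c' = %.4f\n  indirect a*b = %.4f, 95%% CI [%.4f, %.4f], ",
                     "Y-equation R^2 = %.3f\n"),
              x$n, x$n_boot, x$a, x$b, x$c_prime, x$indirect,
              x$ci[1], x$ci[2], x$r_squared))
  invisible(x)
}
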