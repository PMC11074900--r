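make_groups <- function(n_per = 60) {
  factor(rep(c("HC", "mild", "moderate_severe"), each = n_per),
         levels = c("HC", "mild", "moderate_severe"))
}

make_covariates <- function(n, seed = 1) {
  set.seed(seed)
  covariate_set(data.frame(
    age = sample(18:24, n, replace = TRUE),
    gender = sample(c("male", "female"), n, replace = TRUE),
    bmi_class = sample(c("lt18.5", "18.5-24", "gt24"), n, replace = TRUE),
    education = sample(c("undergrad", "postgrad"), n, replace = TRUE,
                       prob = c(0.9, 0.1))
  ))
}

test_that("BH adjustment matches hand computation and its elementwise bound", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.005, 0.04, 0.02, 0.9)),
               c(0.02, 0.05333333, 0.04, 0.9), tolerance = 1e-6)
  set.seed(2)
  p <- runif(50)
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("adjusted group contrasts equal raw mean differences under covariate balance", {
  grp <- make_groups(30)
  cov1 <- make_covariates(30, seed = 9)
  cov3 <- rbind(cov1, cov1, cov1)  # identical covariates in every group
  set.seed(10)
  y <- rnorm(90) + c(0, 0.5, 1.2)[as.integer(grp)]
  a <- ancova(y, grp, cov3)
  raw <- tapply(y, grp, mean)
  expect_equal(a$posthoc$estimate[1], unname(raw["mild"] - raw["HC"]),
               tolerance = 1e-9)
  expect_equal(a$posthoc$estimate[2],
               unname(raw["moderate_severe"] - raw["HC"]), tolerance = 1e-9)
  expect_true(all(a$posthoc$p_adj >= a$posthoc$p))
})

test_that("a 1-SD group shift is detected and posthoc agrees with emmeans", {
  skip_if_not_installed("emmeans")
  grp <- make_groups(200)
  cov <- make_covariates(600, seed = 11)
  set.seed(12)
  y <- rnorm(600) + 0.2 * cov$age + ifelse(grp == "moderate_severe", 1, 0)
  a <- ancova(y, grp, cov)
  expect_lt(a$p, 1e-10)
  em <- emmeans::emmeans(a$model, "group")
  ct <- as.data.frame(emmeans::contrast(em, "revpairwise", adjust = "none"))
  # same contrasts, same order (mild-HC, msd-HC, msd-mild)
  expect_equal(a$posthoc$estimate, ct$estimate, tolerance = 1e-8)
  expect_equal(a$posthoc$se, ct$SE, tolerance = 1e-8)
  expect_equal(a$posthoc$p, ct$p.value, tolerance = 1e-8)
})

test_that("ANCOVA refuses fewer than 3 groups and rank-deficient designs", {
  expect_error(ancova(rnorm(20), rep(c("a", "b"), 10)), "3 groups")
  grp <- make_groups(10)
  cov <- make_covariates(30, seed = 3)
  cov$age2 <- cov$age  # aliased column
  expect_error(ancova(rnorm(30), grp, cov), "alias")
})

test_that("the no-covariate binary-exposure OR equals the cross-product ratio", {
  band <- rep(c("Always", "Always", "Rare", "Rare"), c(10, 20, 20, 10))
  outcome <- rep(c(1, 0, 1, 0), c(10, 20, 20, 10))
  res <- logistic_association(band, outcome)
  expect_equal(res$or[res$band == "Always"], (10 * 10) / (20 * 20),
               tolerance = 1e-6)
  expect_true(res$ci_lo < res$or & res$or < res$ci_hi)
})

test_that("odds ratios are invariant to relabelling the non-reference bands", {
  set.seed(21)
  band <- sample(c("Rare", "Normal", "Always"), 300, replace = TRUE)
  outcome <- rbinom(300, 1, ifelse(band == "Always", 0.6, 0.4))
  r1 <- logistic_association(band, outcome)
  swap <- c(Rare = "Rare", Normal = "Always", Always = "Normal")
  r2 <- logistic_association(unname(swap[band]), outcome)
  expect_equal(r1$or[r1$band == "Always"], r2$or[r2$band == "Normal"],
               tolerance = 1e-9)
  expect_equal(r1$or[r1$band == "Normal"], r2$or[r2$band == "Always"],
               tolerance = 1e-9)
})

test_that("separation is flagged as unstable", {
  band <- rep(c("Rare", "Always"), each = 20)
  outcome <- rep(c(0, 1), each = 20)
  res <- suppressWarnings(logistic_association(band, outcome))
  expect_true(res$unstable[res$band == "Always"])
})

test_that("mediation recovers a known indirect effect and is seed-deterministic", {
  set.seed(33)
  n <- 4000
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.8 * m + 0.3 * x + rnorm(n)
  res <- mediate(x, m, y, n_boot = 2000, seed = 44)
  # SE of a*b at this n is about 0.015; allow 4 sigma
  expect_lt(abs(res$indirect - 0.4), 0.06)
  expect_true(res$ci[1] < 0.4 && 0.4 < res$ci[2])
  expect_gt(res$r_squared, 0.3)
  res2 <- mediate(x, m, y, n_boot = 2000, seed = 44)
  expect_identical(res$ci, res2$ci)
  expect_warning(mediate(x, m, y, n_boot = 500, seed = 1), "1000")
})

test_that("a null b path drives the indirect effect to zero", {
  set.seed(35)
  n <- 4000
  x <- rnorm(n)
  m <- 0.7 * x + rnorm(n)
  y <- 0.5 * x + rnorm(n)  # y ignores m
  res <- mediate(x, m, y, n_boot = 1000, seed = 2)
  expect_lt(abs(res$indirect), 0.05)
  expect_equal(res$indirect, res$a * res$b, tolerance = 1e-12)
})

test_that("mediation accepts covariates and rejects degenerate variance", {
  set.seed(36)
  cov <- make_covariates(200, seed = 37)
  x <- rnorm(200); m <- 0.5 * x + rnorm(200); y <- 0.8 * m + rnorm(200)
  res <- mediate(x, m, y, covariates = cov, n_boot = 1000, seed = 3)
  expect_true(is.finite(res$indirect))
  expect_error(mediate(rep(1, 50), rnorm(50), rnorm(50), n_boot = 1000, seed = 1),
               "degenerate")
})

test_that("full-scale synthetic cohort shows FDR-significant timing irregularity in moderate-severe depression", {
  cfg <- sim_config(n_per_group = c(HC = 2222, mild = 916, moderate_severe = 172),
                    seed = 60541L)
  ch <- generate_cohort(cfg)
  meals <- segment_log(ch$transactions)
  ft <- extract_features(meals, cfg$calendar, families = c("time"))
  labels <- assign_group(ch$survey)
  idx <- match(ft$student_id, ch$survey$student_id)
  a <- ancova(ft[["time.weekday.lunch.mad"]], labels[idx],
              covariate_set(ch$survey[idx, ]))
  expect_lt(a$p, 0.05)
  ph <- a$posthoc
  msd <- grepl("moderate_severe", ph$contrast) & !grepl("mild -", ph$contrast)
  expect_true(all(ph$p_adj[ph$contrast %in%
    c("moderate_severe - HC", "moderate_severe - mild")] < 0.05))
  expect_true(all(ph$estimate[ph$contrast %in%
    c("moderate_severe - HC", "moderate_severe - mild")] > 0))
})
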