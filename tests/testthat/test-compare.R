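test_that("rank-sum test matches exact enumeration on tiny untied samples", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)                       # 2/20 assignments
  expect_equal(res$p_value, ranksum_enum_p(c(1, 2, 3), c(4, 5, 6)))

  x <- c(0.1, 0.9, 0.4); y <- c(0.2, 0.6, 0.35, 0.8)
  expect_equal(rank_sum_test(x, y)$p_value, ranksum_enum_p(x, y))
})

test_that("rank-sum handles ties, symmetry, and degenerate groups", {
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  x <- rnorm(12); y <- rnorm(15) + 0.5
  expect_equal(rank_sum_test(x, y)$p_value, rank_sum_test(y, x)$p_value)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
  # ties force the approximate path even at small n
  expect_false(rank_sum_test(c(0, 0, 1), c(1, 2, 3))$exact)
})

test_that("covariate screening drops single-level, missing, absent columns", {
  d <- data.frame(sample_id = paste0("S", 1:8),
                  age = c(50, 60, NA, 70, 55, 65, 45, 75),
                  gender = rep("female", 8),            # all-female cohort
                  race = NA_character_,                 # entirely missing
                  stringsAsFactors = FALSE)
  spec <- screen_covariates(d)
  expect_equal(spec$used, "age")
  expect_equal(spec$dropped_reasons[["gender"]], "single level")
  expect_match(spec$dropped_reasons[["race"]], "missingness")
  expect_equal(spec$dropped_reasons[["vital_status"]], "absent")

  d2 <- data.frame(age = rnorm(6, 60), gender = rep(c("m", "f"), 3),
                   race = rep(c("w", "b"), 3),
                   vital_status = rep(c("alive", "dead"), 3))
  expect_equal(screen_covariates(d2)$used,
               c("age", "gender", "race", "vital_status"))
})

test_that("adjusted model matches the normal-equations oracle", {
  # 8-row toy table solved directly via (X'X)^{-1} X'y
  fco <- c(0.10, 0.20, 0.05, 0.15, 0.30, 0.40, 0.25, 0.35)
  grp <- rep(c("tumor", "nontumor"), each = 4)
  age <- c(60, 55, 70, 65, 50, 45, 62, 58)
  res <- adjusted_linear_model(fco, grp, data = data.frame(age = age),
                               covariates = "age")
  X <- cbind(1, as.numeric(grp == "tumor"), age)
  beta <- solve(t(X) %*% X, t(X) %*% fco)
  rss <- sum((fco - X %*% beta)^2)
  se <- sqrt(rss / (8 - 3) * solve(t(X) %*% X)[2, 2])
  expect_equal(res$coef, beta[2], tolerance = 1e-8)
  expect_equal(res$t, beta[2] / se, tolerance = 1e-8)
  expect_equal(res$p, 2 * pt(-abs(beta[2] / se), 5), tolerance = 1e-10)
  expect_equal(res$n, 8L)
})

test_that("adjusted model behaves under null effects and shifts", {
  fco <- rep(c(0.2, 0.3, 0.4), 2)
  grp <- rep(c("tumor", "nontumor"), each = 3)
  res <- adjusted_linear_model(fco, grp)
  expect_equal(res$coef, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-9)
  # shifting all responses changes only the intercept
  res2 <- adjusted_linear_model(fco + 0.1, grp)
  expect_equal(res2$coef, res$coef, tolerance = 1e-12)
  expect_equal(res2$t, res$t, tolerance = 1e-9)
  # coefficient orientation: tumor minus nontumor
  res3 <- adjusted_linear_model(c(0.1, 0.12, 0.11, 0.3, 0.31, 0.29),
                                c(rep("tumor", 3), rep("nontumor", 3)))
  expect_lt(res3$coef, 0)
  # rank deficiency names the collinear column
  d <- data.frame(age = c(60, 55, 70, 65, 50, 45),
                  age2 = c(60, 55, 70, 65, 50, 45))
  expect_error(adjusted_linear_model(fco, grp, data = d,
                                     covariates = c("age", "age2")),
               "rank-deficient.*age2")
})

test_that("randomization test is seed-deterministic and matches lm under
           exhaustive enumeration", {
  set.seed(80)
  fco <- c(rnorm(3, 0.35, 0.05), rnorm(3, 0.2, 0.05))
  grp <- rep(c("nontumor", "tumor"), each = 3)

  r1 <- randomization_test(fco, grp, B = 500, seed = 123)
  r2 <- randomization_test(fco, grp, B = 500, seed = 123)
  expect_identical(r1, r2)

  # exhaustive mode equals the independent full-refit enumeration oracle
  ex <- randomization_test(fco, grp, exhaustive = TRUE)
  expect_equal(ex$B, choose(6, 3))
  expect_equal(ex$p_value, perm_enum_p_lm(fco, grp))

  # with a covariate as well
  d <- data.frame(age = c(62, 55, 71, 48, 66, 59))
  ex2 <- randomization_test(fco, grp, data = d, covariates = "age",
                            exhaustive = TRUE)
  expect_equal(ex2$p_value, perm_enum_p_lm(fco, grp, data = d,
                                           covariates = "age"))
})

test_that("randomization p is near 1 for a null-centred statistic", {
  # symmetric design with t_obs essentially 0
  fco <- c(0.1, 0.2, 0.3, 0.4, 0.1, 0.2, 0.3, 0.4)
  grp <- rep(c("tumor", "nontumor"), each = 4)
  res <- randomization_test(fco, grp, B = 2000, seed = 7)
  mc_se <- sqrt(0.5 / 2000)                # bound on the MC standard error
  expect_gt(res$p_value, 1 - 3 * mc_se)
})

test_that("zero exceedances report the 1/B floor with its rendering", {
  set.seed(81)
  fco <- c(rnorm(20, 0.6, 0.02), rnorm(20, 0.05, 0.02))
  grp <- rep(c("nontumor", "tumor"), each = 20)
  res <- randomization_test(fco, grp, B = 5000, seed = 3)
  expect_true(res$floor)
  expect_equal(res$p_value, 1 / 5000)
  expect_equal(format_perm_p(res$p_value, res$floor, res$B), "<2E-04")
  expect_equal(format_perm_p(2e-5, TRUE, 50000L), "<2E-05")
  expect_equal(format_perm_p(0.0216, FALSE), "2.16E-02")
  expect_error(randomization_test(fco, grp, B = 0), "at least 1")
})

test_that("residual diagnostics standardize correctly", {
  # exact fit: all standardized residuals zero
  y <- c(1, 2, 3, 4); x <- c(0, 1, 2, 3)
  exact <- lm(y ~ x)
  d0 <- residual_diagnostics(exact)
  expect_equal(d0$std_resid, rep(0, 4))
  expect_equal(nrow(d0), 4L)

  # hand-computed standardization at n = 4
  y2 <- c(0.1, 0.5, 0.2, 0.9)
  fit <- lm(y2 ~ x)
  d <- residual_diagnostics(fit)
  r <- residuals(fit)
  h <- hatvalues(fit)
  s <- sqrt(sum(r^2) / 2)
  expect_equal(d$std_resid, unname(r / (s * sqrt(1 - h))), tolerance = 1e-10)
  expect_equal(d$sqrt_abs_std, sqrt(abs(d$std_resid)))
  # theoretical quantiles follow the (i - 0.5)/n convention in rank order
  expect_equal(sort(d$theo_quantile), qnorm((1:4 - 0.5) / 4))
  expect_equal(order(d$theo_quantile), order(d$std_resid))
})

test_that("per-cohort comparison handles degenerate and small cohorts", {
  lib <- simulate_reference(6, 0.6, seed = 90)
  # PRAD-like: FCO identically zero in both groups
  est <- data.frame(sample_id = paste0("S", 1:8), fco = 0,
                    stringsAsFactors = FALSE)
  sheet <- data.frame(sample_id = paste0("S", 1:8),
                      group = rep(c("tumor", "nontumor"), each = 4),
                      study = "PRADlike", stringsAsFactors = FALSE)
  cmp <- fco_compare(est, sheet, B = 100)
  expect_true(cmp$degenerate)
  expect_true(is.na(cmp$wilcoxon_p) && is.na(cmp$lm_p) && is.na(cmp$perm_p))
  expect_equal(cmp$perm_p_rendered, "NA")

  # fewer than 3 in one group: NA row, no error
  sheet$group <- c(rep("tumor", 6), rep("nontumor", 2))
  est$fco <- runif(8)
  cmp2 <- fco_compare(est, sheet, B = 100)
  expect_true(is.na(cmp2$wilcoxon_p))
  expect_false(cmp2$degenerate)
})

test_that("the three tests agree qualitatively on a real effect", {
  coh <- simulate_cohort(sim_config(n_tumor = 25, n_nontumor = 25,
                                    seed = 91))
  fit <- quiet_fit(coh$betas, coh$library)
  cmp <- fco_compare(fit, coh$sheet, B = 2000, seed = 14)
  expect_lt(cmp$lm_coef, 0)                    # tumor below nontumor
  expect_lt(cmp$wilcoxon_p, 0.05)
  expect_lt(cmp$lm_p, 0.05)
  expect_lte(cmp$perm_p, 0.05)
})
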