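test_that("correlations match closed forms and respect invariances", {
  # perfectly decreasing monotone pairs
  res <- correlate_fco(c(0.5, 0.4, 0.3, 0.2), c(10, 20, 30, 40))
  expect_equal(res$r, -1)

  # 5-pair Pearson against the closed-form formula
  x <- c(0.1, 0.3, 0.2, 0.5, 0.4); z <- c(60, 50, 70, 40, 55)
  res2 <- correlate_fco(x, z, method = "pearson")
  r_hand <- sum((x - mean(x)) * (z - mean(z))) /
    sqrt(sum((x - mean(x))^2) * sum((z - mean(z))^2))
  expect_equal(res2$r, r_hand, tolerance = 1e-10)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res2$p, 2 * pt(-abs(t_hand), 3), tolerance = 1e-10)

  # zero-variance flag, not an exception
  res3 <- correlate_fco(rep(0, 5), z)
  expect_true(is.na(res3$r))
  expect_equal(res3$flag, "zero variance")
  expect_error(correlate_fco(c(0.1, 0.2), c(1, 2)), "fewer than 3")

  # Spearman invariant under strictly monotone transforms of either input
  set.seed(100)
  a <- runif(20); b <- runif(20)
  base <- correlate_fco(a, b)
  expect_equal(correlate_fco(a^3, exp(b))$r, base$r, tolerance = 1e-12)
  expect_equal(correlate_fco(a^3, exp(b))$p, base$p, tolerance = 1e-12)

  # pairwise-complete handling
  a[3] <- NA
  expect_equal(correlate_fco(a, b)$n, 19)
})

test_that("purity-adjusted model recovers exact linear truth and nulls", {
  purity <- seq(0.4, 0.9, length.out = 12)
  fco <- 0.5 - 0.3 * purity
  res <- suppressWarnings(purity_adjusted_model(fco, purity))
  expect_equal(res$coef, -0.3, tolerance = 1e-10)

  # purity independent of FCO: nominal rejection rate over replicates
  set.seed(101)
  rej <- mean(replicate(200, {
    purity_adjusted_model(runif(30, 0, 0.5), runif(30, 0.4, 1))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.05)

  # duplicated covariate is rank-deficient
  d <- data.frame(pdup = purity)
  expect_error(purity_adjusted_model(fco + rnorm(12, 0, 0.01), purity,
                                     data = d, covariates = "pdup"),
               "rank-deficient")
})

test_that("IQR screen uses linear-interpolation quartiles", {
  expect_equal(iqr_screen(1:8)$iqr, 3.5)       # type-7 quartiles on 1..8
  z <- iqr_screen(rep(0, 10))
  expect_equal(z$iqr, 0)
  expect_false(z$included)
  expect_true(iqr_screen(c(0, 0, 0, 0.4, 0.8))$included)

  # order invariance across cohorts
  fco <- c(runif(10), rep(0, 10))
  study <- rep(c("VAR", "ZERO"), each = 10)
  set.seed(102)
  perm <- sample(20)
  expect_identical(iqr_screen(fco, study), iqr_screen(fco[perm], study[perm]))
})

test_that("stage trend matches the shared OLS core and flags degeneracy", {
  fco <- c(0.40, 0.35, 0.28, 0.22, 0.15, 0.10)
  stage <- c(1, 1, 2, 3, 3, 4)
  res <- stage_association(fco, stage)
  X <- cbind(1, stage)
  beta <- solve(t(X) %*% X, t(X) %*% fco)
  expect_equal(res$slope, beta[2], tolerance = 1e-10)
  expect_lt(res$slope, 0)
  expect_lt(res$p, 0.01)
  # identical numbers through the group-comparison OLS core
  core <- fcomix:::ols_focal(fco, stage)
  expect_equal(res$slope, core$coef)
  expect_equal(res$t, core$t)

  expect_equal(stage_association(fco, rep(2, 6))$flag, "single stage level")
  expect_error(stage_association(c(0.1, 0.2), c(1, 2)), "fewer than 3")

  # permuted stage: null rejection near nominal
  set.seed(103)
  rej <- mean(replicate(200, {
    stage_association(runif(24, 0, 0.5), sample(1:4, 24, TRUE))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.05)
})

test_that("stage strings parse with sub-stage collapsing", {
  expect_equal(parse_tumor_stage(c("Stage I", "stage iia", "III", "IVB",
                                   "Stage X", NA)),
               c(1L, 2L, 3L, 4L, NA, NA))
  expect_equal(parse_tumor_stage(c(2, 4)), c(2L, 4L))
})

test_that("probe extraction returns a tidy, invertible long table", {
  lib <- simulate_reference(27, 0.5, seed = 110)
  coh <- simulate_cohort(sim_config(n_tumor = 4, n_nontumor = 4, seed = 110,
                                    missing_rate = 0))
  probes <- coh$library$probe_id[1:3]
  long <- extract_probe_betas(coh$betas, probes, coh$sheet)
  expect_equal(nrow(long), 3 * ncol(coh$betas))
  expect_setequal(unique(long$group), c("tumor", "nontumor"))

  # pivot back reproduces the sub-matrix
  wide <- with(long, tapply(beta, list(probe, sample), identity))
  expect_equal(wide[probes, colnames(coh$betas)],
               coh$betas[probes, ], tolerance = 0)

  expect_warning(out <- extract_probe_betas(coh$betas,
                                            c(probes[1], "cg_absent")),
                 "cg_absent")
  expect_equal(attr(out, "missing_probes"), "cg_absent")
  expect_equal(nrow(out), ncol(coh$betas))
})
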