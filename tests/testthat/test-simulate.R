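test_that("reference simulation hits the requested separation", {
  # maximal separation: strictly alternating 0/1 profiles
  lib1 <- simulate_reference(6, delta = 1, seed = 1)
  expect_equal(lib1$fetal_beta, c(1, 0, 1, 0, 1, 0))
  expect_equal(lib1$adult_beta, c(0, 1, 0, 1, 0, 1))

  # seeded reproducibility
  expect_identical(simulate_reference(27, 0.5, seed = 8),
                   simulate_reference(27, 0.5, seed = 8))

  # law of large numbers on the mean separation
  big <- simulate_reference(1000, 0.5, seed = 9)
  expect_lt(abs(mean(abs(big$fetal_beta - big$adult_beta)) - 0.5), 0.02)
  expect_true(all(big$fetal_beta >= 0 & big$fetal_beta <= 1))
  expect_true(all(big$adult_beta >= 0 & big$adult_beta <= 1))

  expect_error(simulate_reference(5, delta = 0), "degenerate")
})

test_that("cohort simulation is bounded, seeded, and validated", {
  cfg <- sim_config(n_tumor = 20, n_nontumor = 15, missing_rate = 0.05,
                    seed = 12)
  coh <- simulate_cohort(cfg)
  expect_equal(dim(coh$betas), c(27L, 35L))
  vals <- coh$betas[!is.na(coh$betas)]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(coh$truth$true_fco >= 0 & coh$truth$true_fco <= 1))
  expect_true(any(is.na(coh$betas)))
  expect_equal(coh$sheet$group, rep(c("tumor", "nontumor"), c(20, 15)))
  expect_true(all(coh$sheet$age >= 18 & coh$sheet$age <= 95))
  expect_true(all(is.na(coh$sheet$purity[coh$sheet$group == "nontumor"])))

  expect_identical(simulate_cohort(cfg), coh)   # determinism
  coh2 <- simulate_cohort(sim_config(n_tumor = 20, n_nontumor = 15,
                                     missing_rate = 0.05, seed = 13))
  expect_false(identical(coh2$betas, coh$betas))

  expect_error(sim_config(missing_rate = 1.5), "missing_rate")
  expect_error(sim_config(n_tumor = 0), "group sizes")
  expect_error(sim_config(delta = 0), "delta")
})

test_that("noiseless cohorts are recovered exactly", {
  coh <- simulate_cohort(sim_config(n_tumor = 6, n_nontumor = 6,
                                    noise_sd = 0, missing_rate = 0,
                                    seed = 14))
  est <- estimate_fco(coh$betas, coh$library)
  expect_equal(est$fco, coh$truth$true_fco, tolerance = 1e-6)
  expect_true(all(est$rss < 1e-12))
})

test_that("heavy missingness pushes samples into the QC excluded list", {
  coh <- simulate_cohort(sim_config(n_tumor = 15, n_nontumor = 15,
                                    missing_rate = 0.08, seed = 15))
  qc <- qc_filter_samples(quiet_align(coh$betas, coh$library), 25)
  present <- colSums(!is.na(coh$betas))
  expect_identical(qc$excluded$sample_id, names(present)[present < 25])
  expect_gt(nrow(qc$excluded), 0)          # 8% missing on 27 probes: expected
})

test_that("covariate effects shift the true fractions as configured", {
  cfg <- sim_config(n_tumor = 200, n_nontumor = 200, age_effect = -0.005,
                    noise_sd = 0, seed = 16)
  coh <- simulate_cohort(cfg)
  r <- cor(coh$sheet$age, coh$truth$true_fco, method = "spearman")
  expect_lt(r, -0.2)                       # inverse FCO-age correlation
})

test_that("fixture suite is byte-identical across runs and usable end-to-end", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixture_suite(d1)
  p2 <- make_fixture_suite(d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }

  lib <- read_fco_library(p1[["library"]])
  expect_equal(sum(lib$gene == "EZH2", na.rm = TRUE), 3)
  b_plain <- read_beta_matrix(p1[["betas_plain"]], "plain_tsv")
  b_series <- read_beta_matrix(p1[["betas_series"]], "series_matrix")
  expect_identical(b_plain, b_series)

  sheet <- read_sample_sheet(p1[["sheet"]])
  truth <- read.delim(p1[["truth"]])
  fit <- quiet_fit(b_plain, lib, min_present = 25)
  expect_gt(nrow(fit$estimates), 0)

  # direction of effect built into the fixtures: tumor below nontumor
  grp <- sheet$group[match(truth$sample_id, sheet$sample_id)]
  expect_lt(mean(truth$true_fco[grp == "tumor"]),
            mean(truth$true_fco[grp == "nontumor"]))
})

test_that("fco_fit methods are mutually consistent", {
  coh <- simulate_cohort(sim_config(n_tumor = 10, n_nontumor = 10,
                                    seed = 17))
  fit <- quiet_fit(coh$betas, coh$library)
  expect_s3_class(fit, "fco_fit")
  expect_equal(length(coef(fit)), 20)
  expect_equal(unname(coef(fit)), fit$estimates$fco)

  # residuals = observed - fitted on non-missing cells
  res <- residuals(fit)
  expect_equal(res, fit$betas - fitted(fit))
  # per-sample rss equals the stored objective
  rss_cols <- colSums(res^2, na.rm = TRUE)
  expect_equal(unname(rss_cols), fit$estimates$rss, tolerance = 1e-10)

  # predict on the training matrix reproduces the estimates
  pred <- suppressMessages(predict(fit, coh$betas))
  expect_equal(pred$fco, fit$estimates$fco, tolerance = 1e-12)

  s <- summary(fit, group = setNames(coh$sheet$group, coh$sheet$sample_id))
  expect_equal(rownames(s$per_group), c("nontumor", "tumor"))

  sims <- simulate(fit, nsim = 2, seed = 99, noise_sd = 0.05)
  expect_equal(dim(sims[[1]]), dim(fit$betas))
  expect_true(all(sims[[1]] >= 0 & sims[[1]] <= 1))

  expect_output(print(fit), "FCO mixture fit")
})
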