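#' Simulation configuration for synthetic methylation cohorts
#'
#' Bundles and validates the parameters of [simulate_cohort()]. Defaults
#' emulate the structure of the real tumor/nontumor 450K cohorts the method
#' is applied to: a 27-probe reference panel with mean fetal/adult beta
#' separation 0.5, true fetal fractions drawn from truncated normals with
#' the nontumor mean above the tumor mean (the direction observed in
#' tissue), logit-scale per-probe noise, optional per-cell missingness, and
#' demographic covariates whose distributions follow the pooled cohort
#' table (age ~ N(61.85, 13.60) truncated to \[18, 95\]; 48.9% male;
#' race frequencies 0.804/0.111/0.081/0.004).
#'
#' @param n_probes library size (default 27).
#' @param delta mean absolute fetal-adult beta separation, in `(0, 1]`.
#' @param n_tumor,n_nontumor group sizes.
#' @param fco_mean_tumor,fco_sd_tumor,fco_mean_nontumor,fco_sd_nontumor
#'   mean/sd of the truncated-to-`[0,1]` normal true-fraction distributions.
#' @param noise_sd logit-scale per-probe noise sd (>= 0).
#' @param noise_model `"logit"` (logit-normal, the standard methylation
#'   choice; keeps betas in bounds) or `"additive"` (Gaussian with
#'   clipping).
#' @param missing_rate per-cell missingness probability.
#' @param age_effect,gender_effect optional linear effects of (centred) age
#'   and male gender on the true-fraction mean.
#' @param study cohort label written to the sample sheet.
#' @param seed integer seed; one global seed drives derived per-component
#'   streams.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_probes = 27L, delta = 0.5,
                       n_tumor = 50L, n_nontumor = 50L,
                       fco_mean_tumor = 0.10, fco_sd_tumor = 0.10,
                       fco_mean_nontumor = 0.30, fco_sd_nontumor = 0.15,
                       noise_sd = 0.05,
                       noise_model = c("logit", "additive"),
                       missing_rate = 0,
                       age_effect = 0, gender_effect = 0,
                       study = "SYNTH", seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- list(n_probes = as.integer(n_probes), delta = delta,
              n_tumor = as.integer(n_tumor),
              n_nontumor = as.integer(n_nontumor),
              fco_mean_tumor = fco_mean_tumor, fco_sd_tumor = fco_sd_tumor,
              fco_mean_nontumor = fco_mean_nontumor,
              fco_sd_nontumor = fco_sd_nontumor,
              noise_sd = noise_sd, noise_model = noise_model,
              missing_rate = missing_rate,
              age_effect = age_effect, gender_effect = gender_effect,
              study = as.character(study), seed = as.integer(seed))
  if (cfg$n_probes < 2L) stop("n_probes must be >= 2", call. = FALSE)
  if (!is.numeric(cfg$delta) || cfg$delta <= 0 || cfg$delta > 1)
    stop("delta must lie in (0, 1]", call. = FALSE)
  if (cfg$n_tumor < 1L || cfg$n_nontumor < 1L)
    stop("group sizes must be >= 1", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  for (nm in c("fco_mean_tumor", "fco_mean_nontumor"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(nm, " must lie in [0, 1]", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate a fetal/adult reference library
#'
#' Draws `n_probes` probe profiles with per-probe fetal-adult separation
#' centred on `delta` (jittered within a small window) and random midpoints;
#' the fetal-high/adult-high direction alternates along the panel, so
#' `delta = 1` yields strictly alternating 0/1 profiles. Probe IDs carry a
#' `"cgS"` prefix marking them as synthetic (no real Illumina cg IDs).
#'
#' @param n_probes number of probes (>= 2).
#' @param delta target mean absolute beta separation, in `(0, 1]`.
#' @param seed integer seed.
#' @return An `fco_library`.
#' @export
simulate_reference <- function(n_probes = 27L, delta = 0.5, seed = 1L) {
  n_probes <- as.integer(n_probes)
  if (n_probes < 2L) stop("n_probes must be >= 2", call. = FALSE)
  if (!is.numeric(delta) || delta <= 0 || delta > 1)
    stop("delta must lie in (0, 1] (0 would be a degenerate library)",
         call. = FALSE)
  set.seed(seed)
  w <- 0.1 * min(delta, 1 - delta)
  d <- stats::runif(n_probes, delta - w, delta + w)
  mid <- stats::runif(n_probes, d / 2, 1 - d / 2)
  s <- rep_len(c(1, -1), n_probes)
  fetal <- mid + s * d / 2
  adult <- mid - s * d / 2
  fco_library(sprintf("cgS%07d", seq_len(n_probes)), fetal, adult)
}

# truncated normal via inverse CDF (fixed RNG draw count => reproducible)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (length(mean) == 1L) mean <- rep(mean, n)
  if (sd <= 0) return(pmin(pmax(mean, lo), hi))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# logit-normal observation noise; exact 0/1 nudged by 1e-6 before logit
add_logit_noise <- function(mu, noise_sd) {
  if (noise_sd <= 0) return(mu)
  p <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  stats::plogis(stats::qlogis(p) +
                  stats::rnorm(length(p), 0, noise_sd))
}

#' Simulate a two-group methylation cohort with known ground truth
#'
#' Each sample i draws a true fetal fraction f_i from its group's truncated
#' normal (optionally shifted by covariate effects); its expected beta at
#' probe j is the convex mixture `f_i * fetal_j + (1 - f_i) * adult_j`;
#' observed betas add logit-scale Gaussian noise (or clipped additive noise)
#' and independent per-cell missingness. Covariates (age, gender, race,
#' vital status, tumor purity, leukocyte infiltration percentages, stage)
#' are generated into the sample sheet. Fully seeded and reproducible.
#'
#' @param config a [sim_config()] (or arguments passed on to it).
#' @param ... convenience: overrides forwarded to [sim_config()] when
#'   `config` is missing.
#' @return A list of class `"fco_cohort"`: `library` (an `fco_library`),
#'   `betas` (probes x samples matrix), `sheet` (sample sheet data frame),
#'   `truth` (data frame `sample_id`, `true_fco`), `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_tumor = 5, n_nontumor = 5, seed = 7))
#' range(coh$truth$true_fco)
#' @export
simulate_cohort <- function(config = sim_config(...), ...) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  lib <- simulate_reference(cfg$n_probes, cfg$delta,
                            seed = derive_seed(cfg$seed, 101L))
  nt <- cfg$n_tumor; nn <- cfg$n_nontumor
  n <- nt + nn
  group <- c(rep("tumor", nt), rep("nontumor", nn))
  ids <- sprintf("S%04d", seq_len(n))

  # covariates
  set.seed(derive_seed(cfg$seed, 102L))
  age <- rtrunc_norm(n, 61.85, 13.60, 18, 95)
  gender <- sample(c("male", "female"), n, replace = TRUE,
                   prob = c(0.489, 0.511))
  race <- sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                 prob = c(0.804, 0.111, 0.081, 0.004))
  vital_status <- sample(c("alive", "dead"), n, replace = TRUE,
                         prob = c(0.7, 0.3))
  purity <- ifelse(group == "tumor", stats::runif(n, 0.4, 0.95), NA_real_)
  monocyte_pct <- round(stats::runif(n, 0, 10), 1)
  lymphocyte_pct <- round(stats::runif(n, 0, 20), 1)
  neutrophil_pct <- round(stats::runif(n, 0, 10), 1)
  stage <- ifelse(group == "tumor",
                  sample(1:4, n, replace = TRUE,
                         prob = c(0.3, 0.3, 0.25, 0.15)), NA_integer_)

  # true fetal fractions
  set.seed(derive_seed(cfg$seed, 103L))
  mu <- ifelse(group == "tumor", cfg$fco_mean_tumor, cfg$fco_mean_nontumor) +
    cfg$age_effect * (age - 61.85) +
    cfg$gender_effect * (gender == "male")
  sdv <- ifelse(group == "tumor", cfg$fco_sd_tumor, cfg$fco_sd_nontumor)
  f <- vapply(seq_len(n), function(i)
    rtrunc_norm(1L, mu[i], sdv[i], 0, 1), numeric(1))

  # observed betas
  mix <- outer(lib$fetal_beta, f) + outer(lib$adult_beta, 1 - f)
  set.seed(derive_seed(cfg$seed, 104L))
  betas <- if (cfg$noise_sd > 0) {
    if (cfg$noise_model == "logit") {
      matrix(add_logit_noise(mix, cfg$noise_sd), nrow = nrow(mix))
    } else {
      matrix(pmin(pmax(mix + stats::rnorm(length(mix), 0, cfg$noise_sd),
                       0), 1), nrow = nrow(mix))
    }
  } else mix
  dimnames(betas) <- list(lib$probe_id, ids)

  if (cfg$missing_rate > 0) {
    set.seed(derive_seed(cfg$seed, 105L))
    betas[stats::runif(length(betas)) < cfg$missing_rate] <- NA_real_
  }

  sheet <- data.frame(sample_id = ids, group = group,
                      age = round(age, 1), gender = gender, race = race,
                      vital_status = vital_status,
                      purity = round(purity, 3),
                      monocyte_pct = monocyte_pct,
                      lymphocyte_pct = lymphocyte_pct,
                      neutrophil_pct = neutrophil_pct,
                      stage = stage, study = cfg$study,
                      stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids, true_fco = f,
                      stringsAsFactors = FALSE)
  structure(list(library = lib, betas = betas, sheet = sheet,
                 truth = truth, config = cfg),
            class = "fco_cohort")
}

#' @export
print.fco_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic FCO cohort '%s': %d probes, %d tumor + %d nontumor samples\n",
    x$config$study, x$config$n_probes, x$config$n_tumor,
    x$config$n_nontumor))
  cat(sprintf("  true FCO mean: tumor %.3f, nontumor %.3f; noise_sd %.3g (%s); missing %.3g\n",
              mean(x$truth$true_fco[x$sheet$group == "tumor"]),
              mean(x$truth$true_fco[x$sheet$group == "nontumor"]),
              x$config$noise_sd, x$config$noise_model,
              x$config$missing_rate))
  invisible(x)
}

#' Write the canonical fixture file suite
#'
#' Generates a small synthetic cohort and writes it to disk in the package's
#' on-disk formats: reference library TSV, the beta matrix in both the plain
#' and the series-matrix dialect, the sample sheet, and the ground-truth
#' table. Deterministic: the same seed produces byte-identical files. Three
#' library probes are annotated `"EZH2"` to exercise the gene-based probe
#' extraction (the annotation, like the whole library, is synthetic).
#'
#' @param out_dir writable directory (created if needed).
#' @param seed integer seed (default 42).
#' @param n_tumor,n_nontumor group sizes for the fixture cohort.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 42L, n_tumor = 12L,
                               n_nontumor = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(n_tumor = n_tumor, n_nontumor = n_nontumor,
                    noise_sd = 0.05, missing_rate = 0.02,
                    study = "FIXTURE", seed = seed)
  coh <- simulate_cohort(cfg)
  coh$library$gene[1:3] <- "EZH2"

  paths <- c(library = file.path(out_dir, "library.tsv"),
             betas_plain = file.path(out_dir, "betas_plain.tsv"),
             betas_series = file.path(out_dir, "betas_series_matrix.txt"),
             sheet = file.path(out_dir, "sample_sheet.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_fco_library(coh$library, paths["library"])
  write_beta_matrix(coh$betas, paths["betas_plain"])

  plain <- readLines(paths["betas_plain"])
  series <- c("!Series_title\tsynthetic FCO fixture cohort",
              "!Series_platform\tsimulated-450K-subset",
              sprintf("!Series_sample_count\t%d", ncol(coh$betas)),
              "!series_matrix_table_begin",
              plain,
              "!series_matrix_table_end")
  writeLines(series, paths["betas_series"])

  utils::write.table(coh$sheet, paths["sheet"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  truth_out <- data.frame(sample_id = coh$truth$sample_id,
                          true_fco = num_repr(coh$truth$true_fco),
                          stringsAsFactors = FALSE)
  utils::write.table(truth_out, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
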