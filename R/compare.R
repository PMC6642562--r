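#' Wilcoxon rank-sum test for FCO between two groups
#'
#' Thin wrapper over [stats::wilcox.test()] with the exactness policy pinned:
#' the null distribution is enumerated exactly when the combined sample size
#' is at most 10 and there are no ties; otherwise the normal approximation
#' with midranks, tie-corrected variance and continuity correction is used.
#' When every observation is tied (no separation at all, e.g. two all-zero
#' groups), p is 1.
#'
#' @param x,y numeric FCO values for the two groups (both non-empty).
#' @return A list with `statistic` (rank-sum W for `x`), `p_value`
#'   (two-sided), and `exact`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 by enumeration
#' @export
rank_sum_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 10L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  p <- wt$p.value
  if (is.nan(p) || is.na(p)) p <- 1  # zero tie-corrected variance
  list(statistic = unname(wt$statistic), p_value = min(p, 1), exact = exact)
}

#' Screen covariates for availability and relevance
#'
#' Decides which of the requested adjustment covariates (default age, gender,
#' race, vital status) can actually be adjusted for in a cohort. A covariate
#' is dropped when it is absent from the sheet, when it has a single unique
#' non-missing level or value (e.g. gender in an all-female cohort), or when
#' its missingness fraction exceeds `max_missing`.
#'
#' @param data sample sheet data frame for the cohort.
#' @param requested ordered character vector of covariate names.
#' @param max_missing maximum tolerated missingness fraction (default 0.5).
#' @return A list with `requested`, `used` (subset of `requested`, order
#'   preserved), and `dropped_reasons` (named character).
#' @export
screen_covariates <- function(data,
                              requested = c("age", "gender", "race",
                                            "vital_status"),
                              max_missing = 0.5) {
  reasons <- character(0)
  used <- character(0)
  for (nm in requested) {
    if (!nm %in% names(data)) {
      reasons[nm] <- "absent"
      next
    }
    v <- data[[nm]]
    if (is.character(v)) v[!is.na(v) & v == ""] <- NA
    miss <- mean(is.na(v))
    if (miss > max_missing) {
      reasons[nm] <- sprintf("missingness (%.0f%%)", 100 * miss)
      next
    }
    if (length(unique(v[!is.na(v)])) < 2L) {
      reasons[nm] <- "single level"
      next
    }
    used <- c(used, nm)
  }
  list(requested = requested, used = used, dropped_reasons = reasons)
}

# Shared OLS core: response ~ focal + covariates, complete cases,
# dummy-coded categoricals with the first sorted level as reference.
# Used by the group comparison, the purity-adjusted models and the stage
# trend so all of them share one code path.
ols_focal <- function(y, focal, data = NULL, covariates = NULL,
                      focal_name = "focal") {
  n <- length(y)
  df <- data.frame(.y = as.numeric(y))
  df$.focal <- focal
  for (nm in covariates) {
    v <- data[[nm]]
    if (is.character(v)) v[!is.na(v) & v == ""] <- NA
    if (is.character(v) || is.logical(v)) v <- factor(v, levels = sort(unique(v[!is.na(v)])))
    df[[nm]] <- v
  }
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  fml <- stats::as.formula(paste(".y ~ .focal",
                                 if (length(covariates))
                                   paste("+", paste(covariates, collapse = " + "))
                                 else ""))
  fit <- stats::lm(fml, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("design matrix rank-deficient; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  row <- grep("^\\.focal", rownames(sm))
  if (length(row) != 1L)
    stop("focal term must contribute exactly one coefficient", call. = FALSE)
  list(coef = unname(sm[row, "Estimate"]),
       t = unname(sm[row, "t value"]),
       p = unname(sm[row, "Pr(>|t|)"]),
       n = nrow(df),
       model = fit,
       complete = cc,
       data = df,
       focal_name = focal_name)
}

#' Covariate-adjusted linear model for tumor versus nontumor FCO
#'
#' Ordinary least squares of per-sample FCO fraction on group status plus the
#' screened covariates, on complete cases. Categorical covariates are
#' dummy-coded with the first sorted level as reference; the group factor is
#' coded the same way, so with the conventional labels the reported
#' coefficient is tumor minus nontumor (in FCO-fraction units). The p-value
#' comes from the t distribution with residual degrees of freedom.
#'
#' @param fco numeric FCO fractions.
#' @param group character/factor group labels with exactly two levels
#'   (e.g. `"tumor"`/`"nontumor"`).
#' @param data sample sheet rows aligned with `fco` (needed when adjusting).
#' @param covariates character vector of covariate names in `data`, e.g.
#'   `screen_covariates(...)$used`.
#' @return A list with `coef`, `t`, `p`, `n` (complete-case rows), `levels`
#'   (reference first), and `model` (the `lm` fit, usable with
#'   [residual_diagnostics()]).
#' @export
adjusted_linear_model <- function(fco, group, data = NULL,
                                  covariates = NULL) {
  group <- as.character(group)
  lev <- sort(unique(group[!is.na(group)]))
  if (length(lev) != 2L)
    stop("group must have exactly two levels, got: ",
         paste(lev, collapse = ", "), call. = FALSE)
  g <- factor(group, levels = lev)
  res <- ols_focal(fco, g, data = data, covariates = covariates,
                   focal_name = "group")
  counts <- table(res$data$.focal)
  if (any(counts < 2L))
    stop("fewer than 2 complete-case samples in group ",
         names(counts)[which.min(counts)], call. = FALSE)
  res$levels <- lev
  res
}

#' Randomization-based test for the group effect
#'
#' Builds an empirical null for the group t-statistic of
#' [adjusted_linear_model()] by repeatedly permuting the tumor/nontumor
#' labels (covariates stay attached to their samples), refitting, and
#' recording the statistic; by default 50,000 permutations. The two-sided
#' empirical p is `#\{|t*| >= |t_obs|\} / B`; when no null statistic reaches
#' `|t_obs|`, the floor `1/B` is reported with `floor = TRUE` (rendered
#' `"<2E-05"` at B = 50,000 by [format_perm_p()]).
#'
#' Permuted refits use the Frisch-Waugh-Lovell identity: covariates are
#' residualised once, so each permutation costs one projection rather than a
#' full `lm` fit. The statistic is identical to the full refit.
#'
#' @param fco,group,data,covariates as in [adjusted_linear_model()].
#' @param B number of permutations (ignored when `exhaustive`).
#' @param seed integer seed; identical seed gives identical p.
#' @param exhaustive if `TRUE`, enumerate all distinct assignments of the
#'   group labels (exact permutation test; feasible for small n).
#' @return A list with `p_value`, `floor`, `B` (permutations actually used),
#'   `t_obs`, `count` (null exceedances), `seed`, `exhaustive`.
#' @export
randomization_test <- function(fco, group, data = NULL, covariates = NULL,
                               B = 50000L, seed = 1L, exhaustive = FALSE) {
  B <- as.integer(B)
  if (!exhaustive && B < 1L) stop("B must be at least 1", call. = FALSE)
  obs <- adjusted_linear_model(fco, group, data = data,
                               covariates = covariates)
  df <- obs$data
  n <- nrow(df)
  y <- df$.y
  g <- as.numeric(df$.focal == levels(df$.focal)[2L])

  Z <- stats::model.matrix(
    stats::as.formula(paste("~",
                            if (length(covariates))
                              paste(covariates, collapse = " + ") else "1")),
    data = df)
  qrZ <- qr(Z)
  Q <- qr.Q(qrZ)
  e_y <- y - Q %*% crossprod(Q, y)
  ssy <- sum(e_y * e_y)
  resid_df <- n - qrZ$rank - 1L
  if (resid_df < 1L)
    stop("no residual degrees of freedom for the randomization test",
         call. = FALSE)

  t_of <- function(gp) {
    eg <- gp - Q %*% crossprod(Q, gp)
    S <- sum(eg * eg)
    if (S < 1e-12) return(0)
    beta <- sum(e_y * eg) / S
    s2 <- max(ssy - beta * beta * S, 0) / resid_df
    if (s2 <= 0) return(sign(beta) * Inf)
    beta / sqrt(s2 / S)
  }
  t_obs <- t_of(g)

  if (exhaustive) {
    n1 <- sum(g == 1)
    total <- choose(n, n1)
    if (total > 250000)
      stop("exhaustive enumeration infeasible: ", total, " assignments",
           call. = FALSE)
    combos <- utils::combn(n, n1, simplify = FALSE)
    tstar <- vapply(combos, function(idx) {
      gp <- numeric(n); gp[idx] <- 1
      t_of(gp)
    }, numeric(1))
    count <- sum(abs(tstar) >= abs(t_obs) - 1e-12)
    p <- count / total
    return(list(p_value = p, floor = FALSE, B = total, t_obs = t_obs,
                count = count, seed = seed, exhaustive = TRUE))
  }

  set.seed(seed)
  count <- 0L
  for (b in seq_len(B)) {
    gp <- g[sample.int(n)]
    if (abs(t_of(gp)) >= abs(t_obs) - 1e-12) count <- count + 1L
  }
  floor_hit <- count == 0L
  p <- if (floor_hit) 1 / B else count / B
  list(p_value = p, floor = floor_hit, B = B, t_obs = t_obs, count = count,
       seed = seed, exhaustive = FALSE)
}

#' Render a permutation p-value
#'
#' Floored values print as a bound, e.g. `"<2E-05"` at B = 50,000; otherwise
#' scientific notation with 3 significant digits.
#'
#' @param p numeric p-value.
#' @param floor logical floor flag from [randomization_test()].
#' @param B permutation count.
#' @return Character scalar.
#' @export
format_perm_p <- function(p, floor = FALSE, B = 50000L) {
  if (is.na(p)) return("NA")
  if (isTRUE(floor)) paste0("<", toupper(format(1 / B, scientific = TRUE)))
  else toupper(formatC(p, format = "e", digits = 2))
}

#' Diagnostics for a fitted comparison model
#'
#' Returns the quantities needed to draw normal-QQ and spread-location plots
#' for an OLS fit: fitted values, standardized residuals, theoretical normal
#' quantiles at the `(i - 0.5)/n` positions (matched by residual rank), and
#' the square root of absolute standardized residuals. For an exact-fit model
#' all standardized residuals are 0.
#'
#' @param model an `lm` object (e.g. `adjusted_linear_model(...)$model`).
#' @return A data frame with one row per complete-case observation.
#' @export
residual_diagnostics <- function(model) {
  stopifnot(inherits(model, "lm"))
  r <- stats::residuals(model)
  n <- length(r)
  s2 <- sum(r^2) / stats::df.residual(model)
  if (!is.finite(s2) || s2 < 1e-24) {
    std <- rep(0, n)
  } else {
    std <- unname(stats::rstandard(model))
    std[!is.finite(std)] <- 0
  }
  theo <- stats::qnorm((rank(std, ties.method = "first") - 0.5) / n)
  data.frame(fitted = unname(stats::fitted(model)),
             std_resid = std,
             theo_quantile = theo,
             sqrt_abs_std = sqrt(abs(std)))
}

#' Three-way tumor versus nontumor comparison per cohort
#'
#' For each study in the sample sheet, compares estimated FCO between tumor
#' and nontumor samples with (1) the Wilcoxon rank-sum test, (2) the
#' covariate-adjusted linear model, and (3) the randomization-based test.
#' Covariates are screened per study with [screen_covariates()]. Cohorts with
#' fewer than `min_group` samples in either group get an `NA` row (the
#' analysis excluded studies with fewer than 3 nontumor normal samples), as
#' do cohorts whose FCO is one constant in both groups (degenerate variance;
#' in the real data the prostate cohort has 0% FCO in both groups).
#'
#' @param estimates data frame from [estimate_fco()] (or an `fco_fit`).
#' @param sheet sample sheet with `sample_id`, `group`, optional `study` and
#'   covariate columns.
#' @param covariates requested covariates, screened per study.
#' @param B permutations for the randomization test.
#' @param seed integer seed; each study uses a seed derived from it.
#' @param min_group minimum per-group size (default 3).
#' @return A data frame of class `"fco_compare"`, one row per study:
#'   group sizes and mean FCO percent, `wilcoxon_p`, `lm_coef`, `lm_t`,
#'   `lm_p`, `perm_p`, `perm_floor`, `perm_p_rendered`, `B`, `seed`,
#'   `covariates_used`, `degenerate`.
#' @export
fco_compare <- function(estimates, sheet,
                        covariates = c("age", "gender", "race",
                                       "vital_status"),
                        B = 50000L, seed = 1L, min_group = 3L) {
  if (inherits(estimates, "fco_fit")) estimates <- estimates$estimates
  stopifnot(all(c("sample_id", "fco") %in% names(estimates)),
            all(c("sample_id", "group") %in% names(sheet)))
  merged <- merge(estimates, sheet, by = "sample_id", sort = FALSE)
  if (!"study" %in% names(merged)) merged$study <- "cohort"
  studies <- unique(merged$study)

  rows <- lapply(seq_along(studies), function(si) {
    st <- studies[si]
    d <- merged[merged$study == st, , drop = FALSE]
    fco <- d$fco
    grp <- as.character(d$group)
    n_t <- sum(grp == "tumor", na.rm = TRUE)
    n_n <- sum(grp == "nontumor", na.rm = TRUE)
    base <- data.frame(
      study = st, n_tumor = n_t, n_nontumor = n_n,
      mean_fco_tumor_pct = round(100 * mean(fco[grp == "tumor"]), 1),
      mean_fco_nontumor_pct = round(100 * mean(fco[grp == "nontumor"]), 1),
      wilcoxon_p = NA_real_, lm_coef = NA_real_, lm_t = NA_real_,
      lm_p = NA_real_, perm_p = NA_real_, perm_floor = FALSE,
      perm_p_rendered = "NA", B = as.integer(B), seed = NA_integer_,
      covariates_used = NA_character_, degenerate = FALSE,
      stringsAsFactors = FALSE)
    if (n_t < min_group || n_n < min_group) return(base)
    if (length(unique(fco)) == 1L) {  # e.g. all-zero FCO in both groups
      base$degenerate <- TRUE
      return(base)
    }
    spec <- screen_covariates(d, requested = covariates)
    st_seed <- derive_seed(seed, si)
    w <- rank_sum_test(fco[grp == "tumor"], fco[grp == "nontumor"])
    lmres <- adjusted_linear_model(fco, grp, data = d,
                                   covariates = spec$used)
    perm <- randomization_test(fco, grp, data = d, covariates = spec$used,
                               B = B, seed = st_seed)
    base$wilcoxon_p <- w$p_value
    base$lm_coef <- lmres$coef
    base$lm_t <- lmres$t
    base$lm_p <- lmres$p
    base$perm_p <- perm$p_value
    base$perm_floor <- perm$floor
    base$perm_p_rendered <- format_perm_p(perm$p_value, perm$floor, perm$B)
    base$seed <- st_seed
    base$covariates_used <- paste(spec$used, collapse = ",")
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fco_compare", "data.frame")
  out
}

#' @export
print.fco_compare <- function(x, ...) {
  cat("Tumor vs nontumor FCO comparison (",
      nrow(x), " cohort", if (nrow(x) != 1) "s", ")\n", sep = "")
  show <- x[, c("study", "n_tumor", "n_nontumor", "mean_fco_tumor_pct",
                "mean_fco_nontumor_pct", "wilcoxon_p", "lm_p",
                "perm_p_rendered")]
  print.data.frame(show, row.names = FALSE, digits = 3)
  invisible(x)
}
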