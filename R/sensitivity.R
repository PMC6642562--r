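#' Correlate FCO with a numeric covariate
#'
#' Pairwise-complete correlation between per-sample FCO and a covariate such
#' as age, tumor purity, or a leukocyte infiltration percentage. Spearman
#' (the default; robust to the heavy zero-inflation of FCO estimates) is
#' computed as Pearson on midranks with the t approximation for the p-value;
#' Pearson is selectable. A zero-variance input yields an `NA` result with a
#' flag rather than an error.
#'
#' @param fco numeric FCO fractions.
#' @param covariate numeric vector, same length.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param variable label for the covariate in the output.
#' @return A list with `variable`, `method`, `r`, `p` (two-sided), `n`
#'   (complete pairs), and `flag` (`NA` or `"zero variance"`).
#' @export
correlate_fco <- function(fco, covariate,
                          method = c("spearman", "pearson"),
                          variable = "covariate") {
  method <- match.arg(method)
  ok <- !is.na(fco) & !is.na(covariate)
  x <- as.numeric(fco[ok]); z <- as.numeric(covariate[ok])
  n <- length(x)
  if (n < 3L)
    stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(z) == 0) {
    return(list(variable = variable, method = method, r = NA_real_,
                p = NA_real_, n = n, flag = "zero variance"))
  }
  if (method == "spearman") {
    x <- rank(x); z <- rank(z)  # midranks for ties
  }
  ct <- suppressWarnings(stats::cor.test(x, z, method = "pearson"))
  list(variable = variable, method = method,
       r = unname(ct$estimate), p = ct$p.value, n = n, flag = NA_character_)
}

#' Purity-adjusted linear model for FCO
#'
#' OLS of FCO on tumor purity plus the screened demographic covariates; the
#' purity coefficient tests whether the purity-FCO association survives
#' adjustment. Shares the OLS core of [adjusted_linear_model()].
#'
#' @param fco numeric FCO fractions.
#' @param purity numeric tumor purity in `[0, 1]`.
#' @param data sample sheet rows aligned with `fco`.
#' @param covariates covariate names in `data` (e.g. from
#'   [screen_covariates()]).
#' @return A list with `coef`, `t`, `p`, `n`, `model` for the purity term.
#' @export
purity_adjusted_model <- function(fco, purity, data = NULL,
                                  covariates = NULL) {
  ols_focal(fco, as.numeric(purity), data = data, covariates = covariates,
            focal_name = "purity")
}

#' Screen cohorts by interquartile range of FCO
#'
#' Secondary analyses (stage, subtype) are restricted to cohorts whose FCO
#' actually varies, i.e. has nonzero interquartile range. Quartiles use the
#' linear-interpolation convention (R quantile type 7).
#'
#' @param fco numeric FCO fractions.
#' @param study cohort labels, same length (defaults to one cohort).
#' @return A data frame with `study`, `iqr`, `included` (`iqr > 0`), sorted
#'   by study label; invariant to sample order.
#' @export
iqr_screen <- function(fco, study = rep("cohort", length(fco))) {
  stopifnot(length(fco) == length(study))
  labs <- sort(unique(as.character(study)))
  rows <- lapply(labs, function(st) {
    v <- fco[study == st]
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(study = st, iqr = q[2L] - q[1L], included = q[2L] - q[1L] > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Linear trend of FCO across tumor stage
#'
#' OLS of FCO on stage coded as an integer score (I-IV as 1-4; see
#' [parse_tumor_stage()] for sub-stage collapsing). A single observed stage
#' level yields an `NA` result with a flag.
#'
#' @param fco numeric FCO fractions.
#' @param stage integer-coded ordinal stage.
#' @return A list with `slope`, `t`, `p`, `n`, `flag`.
#' @export
stage_association <- function(fco, stage) {
  ok <- !is.na(fco) & !is.na(stage)
  if (sum(ok) < 3L)
    stop("fewer than 3 samples with stage and FCO", call. = FALSE)
  st <- as.numeric(stage[ok])
  if (length(unique(st)) < 2L) {
    return(list(slope = NA_real_, t = NA_real_, p = NA_real_,
                n = sum(ok), flag = "single stage level"))
  }
  res <- ols_focal(fco[ok], st, focal_name = "stage")
  list(slope = res$coef, t = res$t, p = res$p, n = res$n, flag = NA_character_)
}

#' Parse pathological stage strings to integer scores
#'
#' Maps Roman-numeral stage labels (`"Stage IIIA"`, `"iv"`, `"II"`, ...) to
#' 1-4; sub-stages (a/b/c) collapse to the major stage. Unrecognised values
#' become `NA`.
#'
#' @param x character vector of stage labels (numeric input is passed
#'   through).
#' @return Integer vector.
#' @export
parse_tumor_stage <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  s <- toupper(trimws(as.character(x)))
  s <- sub("^STAGE\\s*", "", s)
  s <- sub("[ABC][0-9]*$", "", s)
  out <- rep(NA_integer_, length(s))
  out[s == "I"] <- 1L
  out[s == "II"] <- 2L
  out[s == "III"] <- 3L
  out[s == "IV"] <- 4L
  out
}

#' Extract per-probe betas in long format
#'
#' Pulls selected probes (e.g. the three EZH2-associated library CpGs) out of
#' a beta matrix as a tidy probe/sample/group/beta table suitable for
#' external plotting. Requested probes absent from the matrix are reported
#' with a warning and contribute no rows.
#'
#' @param betas probes x samples matrix.
#' @param probe_ids probes to extract.
#' @param sheet optional sample sheet supplying the `group` column.
#' @return A data frame with columns `probe`, `sample`, `group`, `beta`;
#'   absent probes are listed in the `"missing_probes"` attribute.
#' @export
extract_probe_betas <- function(betas, probe_ids, sheet = NULL) {
  validate_beta_matrix(betas)
  probe_ids <- as.character(probe_ids)
  present <- probe_ids[probe_ids %in% rownames(betas)]
  missing <- setdiff(probe_ids, present)
  if (length(missing))
    warning("probe(s) not found in matrix: ",
            paste(missing, collapse = ", "), call. = FALSE)
  m <- betas[present, , drop = FALSE]
  out <- data.frame(
    probe = rep(present, times = ncol(m)),
    sample = rep(colnames(m), each = length(present)),
    beta = as.vector(m),
    stringsAsFactors = FALSE
  )
  out$group <- if (!is.null(sheet) && "group" %in% names(sheet)) {
    as.character(sheet$group[match(out$sample, sheet$sample_id)])
  } else NA_character_
  out <- out[, c("probe", "sample", "group", "beta")]
  attr(out, "missing_probes") <- missing
  out
}
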