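#' Run the end-to-end FCO analysis pipeline
#'
#' Orchestrates read -> align -> QC -> estimate -> compare -> sensitivity and
#' writes deterministic, seeded outputs to a directory: per-sample estimates,
#' the QC exclusion log, the per-cohort three-test comparison table,
#' sensitivity tables (correlations with age/purity/infiltration, IQR
#' screen, stage trend, gene-annotated probe extraction), and a
#' machine-readable JSON manifest (config echo, seed, library hash, stage
#' counts, collected warnings). Rerunning with identical inputs and seed
#' reproduces all numeric outputs bit-identically.
#'
#' Stages can be run separately: the `compare` and `sensitivity` stages read
#' `estimates.tsv` from `out_dir` when the `estimate` stage is not part of
#' the same call, so staged execution equals a single-shot run.
#'
#' @param config named list or path to a YAML file with entries: `betas`,
#'   `library`, `sample_sheet` (paths), `dialect` (default `"plain_tsv"`),
#'   `min_present` (default 25), `covariates` (default age, gender, race,
#'   vital_status), `permutations` (default 50000), `seed` (default 1),
#'   `out_dir`, `stages` (default all of estimate, compare, sensitivity).
#'   Arguments in `...` override file/list entries.
#' @param ... individual config overrides.
#' @return A result bundle (list of class `"fco_pipeline"`) with the
#'   in-memory tables and the manifest, invisibly.
#' @export
run_fco_pipeline <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  over <- list(...)
  config[names(over)] <- over
  defaults <- list(dialect = "plain_tsv", min_present = 25L,
                   covariates = c("age", "gender", "race", "vital_status"),
                   permutations = 50000L, seed = 1L,
                   stages = c("estimate", "compare", "sensitivity"))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$out_dir))
    stop("config must name an out_dir", call. = FALSE)
  stages <- match.arg(config$stages,
                      c("estimate", "compare", "sensitivity"),
                      several.ok = TRUE)
  if (as.integer(config$permutations) < 1L)
    stop("permutations must be >= 1", call. = FALSE)
  for (nm in c("betas", "library", "sample_sheet")) {
    if (is.null(config[[nm]]))
      stop("config must name a ", nm, " file", call. = FALSE)
    if (!file.exists(config[[nm]]))
      stop(nm, " file does not exist: ", config[[nm]], call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  warn_log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    msg
  }
  log <- character(0)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  lib <- run_stage("read", read_fco_library(config$library))
  sheet <- run_stage("read", read_sample_sheet(config$sample_sheet))
  bundle <- list(config = config, library = lib, sheet = sheet)

  est_path <- file.path(config$out_dir, "estimates.tsv")
  if ("estimate" %in% stages) {
    betas <- run_stage("read",
                       read_beta_matrix(config$betas, config$dialect))
    log <- c(log, note("read %d probes x %d samples (%s)",
                       nrow(betas), ncol(betas), config$dialect))
    fit <- run_stage("estimate",
                     suppressMessages(
                       fco_fit(betas, lib,
                               min_present = config$min_present)))
    log <- c(log, note("estimated FCO for %d samples (%d excluded by QC)",
                       nrow(fit$estimates), nrow(fit$qc$excluded)))
    est <- fit$estimates
    est_out <- est
    est_out$fco <- num_repr(est$fco)
    est_out$adult <- num_repr(est$adult)
    est_out$adult_pct <- round(100 * est$adult, 1)
    est_out$rss <- num_repr(est$rss)
    est_out <- est_out[, c("sample_id", "fco_pct", "adult_pct",
                           "probes_used", "rss", "fco", "adult")]
    utils::write.table(est_out, est_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(fit$qc$excluded,
                       file.path(config$out_dir, "qc_exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$fit <- fit
    bundle$estimates <- est
    bundle$qc_excluded <- fit$qc$excluded
  } else {
    if (!file.exists(est_path))
      stop("stage 'compare'/'sensitivity' needs estimates.tsv in out_dir ",
           "(run the estimate stage first)", call. = FALSE)
    est <- utils::read.delim(est_path, stringsAsFactors = FALSE)
    est$fco <- as.numeric(est$fco)
    est$adult <- as.numeric(est$adult)
    bundle$estimates <- est
  }

  if ("compare" %in% stages) {
    cmp <- run_stage("compare",
                     fco_compare(bundle$estimates, sheet,
                                 covariates = config$covariates,
                                 B = as.integer(config$permutations),
                                 seed = as.integer(config$seed)))
    log <- c(log, note("compared %d cohort(s), B = %d permutations",
                       nrow(cmp), as.integer(config$permutations)))
    utils::write.table(format_compare_table(cmp),
                       file.path(config$out_dir, "comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$comparison <- cmp
  }

  if ("sensitivity" %in% stages) {
    sens <- run_stage("sensitivity",
                      sensitivity_tables(bundle$estimates, sheet))
    for (nm in names(sens$tables)) {
      utils::write.table(sens$tables[[nm]],
                         file.path(config$out_dir,
                                   paste0("sensitivity_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         na = "NA")
    }
    warn_log <- c(warn_log, sens$warnings)
    log <- c(log, note("wrote %d sensitivity table(s)",
                       length(sens$tables)))
    bundle$sensitivity <- sens$tables
  }

  manifest <- list(
    package = "fcomix",
    version = as.character(utils::packageVersion("fcomix")),
    seed = as.integer(config$seed),
    permutations = as.integer(config$permutations),
    min_present = as.integer(config$min_present),
    dialect = config$dialect,
    covariates = config$covariates,
    stages = stages,
    inputs = list(betas = config$betas, library = config$library,
                  sample_sheet = config$sample_sheet),
    library_md5 = unname(tools::md5sum(config$library)),
    n_library_probes = nrow(lib),
    log = log,
    warnings = warn_log,
    outputs = list.files(config$out_dir)
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bundle$manifest <- manifest
  class(bundle) <- "fco_pipeline"
  invisible(bundle)
}

# comparison table in the on-disk layout (rendered perm p, scientific p's)
format_compare_table <- function(cmp) {
  data.frame(
    study = cmp$study,
    n_tumor = cmp$n_tumor,
    n_nontumor = cmp$n_nontumor,
    mean_fco_tumor_pct = cmp$mean_fco_tumor_pct,
    mean_fco_nontumor_pct = cmp$mean_fco_nontumor_pct,
    wilcoxon_p = p_sci(cmp$wilcoxon_p),
    lm_coef = ifelse(is.na(cmp$lm_coef), "NA",
                     sprintf("%.6g", cmp$lm_coef)),
    lm_t = ifelse(is.na(cmp$lm_t), "NA", sprintf("%.4f", cmp$lm_t)),
    lm_p = p_sci(cmp$lm_p),
    perm_p = cmp$perm_p_rendered,
    B = cmp$B,
    seed = cmp$seed,
    covariates_used = cmp$covariates_used,
    stringsAsFactors = FALSE
  )
}

p_sci <- function(p) {
  ifelse(is.na(p), "NA", toupper(formatC(p, format = "e", digits = 2)))
}

# all per-cohort sensitivity analyses on the merged estimate/sheet table
sensitivity_tables <- function(estimates, sheet) {
  merged <- merge(estimates, sheet, by = "sample_id", sort = FALSE)
  if (!"study" %in% names(merged)) merged$study <- "cohort"
  warnings <- character(0)
  studies <- unique(merged$study)

  cor_rows <- list()
  for (st in studies) {
    d <- merged[merged$study == st, , drop = FALSE]
    tum <- d[!is.na(d$group) & d$group == "tumor", , drop = FALSE]
    specs <- list(
      list(var = "age", data = d),
      list(var = "purity", data = tum),
      list(var = "monocyte_pct", data = tum),
      list(var = "lymphocyte_pct", data = tum),
      list(var = "neutrophil_pct", data = tum)
    )
    for (sp in specs) {
      v <- sp$var
      dd <- sp$data
      if (!v %in% names(dd) || sum(!is.na(dd[[v]]) & !is.na(dd$fco)) < 3)
        next
      for (meth in c("spearman", "pearson")) {
        r <- correlate_fco(dd$fco, dd[[v]], method = meth, variable = v)
        cor_rows[[length(cor_rows) + 1L]] <-
          data.frame(study = st, variable = v, method = meth,
                     r = r$r, p = r$p, n = r$n,
                     flag = ifelse(is.na(r$flag), "", r$flag),
                     stringsAsFactors = FALSE)
      }
    }
  }
  tables <- list()
  if (length(cor_rows)) tables$correlations <- do.call(rbind, cor_rows)

  tables$iqr_screen <- iqr_screen(merged$fco, merged$study)

  stage_rows <- list()
  for (st in tables$iqr_screen$study[tables$iqr_screen$included]) {
    d <- merged[merged$study == st & !is.na(merged$group) &
                  merged$group == "tumor", , drop = FALSE]
    if (!"stage" %in% names(d) ||
        sum(!is.na(d$stage) & !is.na(d$fco)) < 3) next
    sa <- stage_association(d$fco, d$stage)
    stage_rows[[length(stage_rows) + 1L]] <-
      data.frame(study = st, slope = sa$slope, t = sa$t, p = sa$p,
                 n = sa$n, flag = ifelse(is.na(sa$flag), "", sa$flag),
                 stringsAsFactors = FALSE)
  }
  if (length(stage_rows)) tables$stage <- do.call(rbind, stage_rows)

  purity_rows <- list()
  for (st in studies) {
    d <- merged[merged$study == st & !is.na(merged$group) &
                  merged$group == "tumor", , drop = FALSE]
    if (!"purity" %in% names(d) ||
        sum(!is.na(d$purity) & !is.na(d$fco)) < 5) next
    spec <- screen_covariates(d)
    res <- tryCatch(
      purity_adjusted_model(d$fco, d$purity, data = d,
                            covariates = spec$used),
      error = function(e) {
        warnings <<- c(warnings,
                       paste0("purity model (", st, "): ",
                              conditionMessage(e)))
        NULL
      })
    if (!is.null(res))
      purity_rows[[length(purity_rows) + 1L]] <-
        data.frame(study = st, coef = res$coef, t = res$t, p = res$p,
                   n = res$n,
                   covariates_used = paste(spec$used, collapse = ","),
                   stringsAsFactors = FALSE)
  }
  if (length(purity_rows)) tables$purity_adjusted <- do.call(rbind,
                                                             purity_rows)

  list(tables = tables, warnings = warnings)
}

#' Render a human-readable pipeline summary
#'
#' One line per cohort with group sizes, mean FCO percent per group, and the
#' three p-values (permutation p with floor rendering, e.g. `"<2E-05"`;
#' degenerate cohorts render `"NA"`). Deterministic formatting; an empty
#' comparison yields the header only.
#'
#' @param bundle an `"fco_pipeline"` result, or an `fco_compare` table.
#' @return Character vector of report lines (also printable via `cat`).
#' @export
render_report <- function(bundle) {
  cmp <- if (inherits(bundle, "fco_pipeline")) bundle$comparison else bundle
  header <- sprintf("%-12s %8s %10s %12s %14s %12s %12s %12s",
                    "study", "n_tumor", "n_nontumor", "meanFCO_tum%",
                    "meanFCO_nontum%", "wilcoxon_p", "lm_p", "perm_p")
  if (is.null(cmp) || nrow(cmp) == 0L) return(header)
  lines <- vapply(seq_len(nrow(cmp)), function(i) {
    sprintf("%-12s %8d %10d %12s %14s %12s %12s %12s",
            cmp$study[i], cmp$n_tumor[i], cmp$n_nontumor[i],
            ifelse(is.finite(cmp$mean_fco_tumor_pct[i]),
                   sprintf("%.1f", cmp$mean_fco_tumor_pct[i]), "NA"),
            ifelse(is.finite(cmp$mean_fco_nontumor_pct[i]),
                   sprintf("%.1f", cmp$mean_fco_nontumor_pct[i]), "NA"),
            p_sci(cmp$wilcoxon_p[i]), p_sci(cmp$lm_p[i]),
            cmp$perm_p_rendered[i])
  }, character(1))
  c(header, lines)
}

#' @export
print.fco_pipeline <- function(x, ...) {
  cat("FCO pipeline run (stages: ",
      paste(x$manifest$stages, collapse = ", "), ")\n", sep = "")
  cat(paste0("  ", x$manifest$log, collapse = "\n"), "\n")
  if (!is.null(x$comparison))
    cat(paste(render_report(x), collapse = "\n"), "\n")
  invisible(x)
}
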