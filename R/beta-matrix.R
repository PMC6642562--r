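#' Read a beta-value matrix
#'
#' Reads probes x samples methylation beta values (`Beta = M/(M+U)`, in
#' `[0, 1]`) from a tab-separated table whose first column holds the CpG probe
#' identifier and remaining columns one sample each. Three dialects are
#' supported:
#'
#' * `"plain_tsv"` — header line plus data rows.
#' * `"tcga_level3"` — as `plain_tsv`; TCGA level-3 exports mask
#'   SNP/repeat-overlapping and non-detected probes as the string `"NA"`,
#'   and may label the probe column `Composite Element REF`.
#' * `"series_matrix"` — GEO series-matrix style: lines beginning with `"!"`
#'   (metadata, including a terminal `!series_matrix_table_end`) are skipped
#'   and sample identifiers may be quoted.
#'
#' The strings `"NA"`, `"na"`, `"NaN"` and empty cells all map to the single
#' missing marker (`NA`). Values exactly 0 or 1 are legal.
#'
#' @param path path to the file.
#' @param dialect one of `"plain_tsv"`, `"tcga_level3"`, `"series_matrix"`.
#' @return A numeric matrix (probes x samples) with probe IDs as rownames and
#'   sample IDs as colnames; missing entries are `NA`.
#' @export
read_beta_matrix <- function(path,
                             dialect = c("plain_tsv", "tcga_level3",
                                         "series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("beta matrix file does not exist: ", path, call. = FALSE)

  na_strings <- c("NA", "na", "NaN", "")
  if (dialect == "series_matrix") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!")]
    lines <- lines[nzchar(lines)]
    con <- textConnection(lines)
    on.exit(close(con))
    tab <- utils::read.table(con, header = TRUE, sep = "\t",
                             na.strings = na_strings, quote = "\"",
                             check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "")
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             na.strings = na_strings, quote = "\"",
                             check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "")
  }
  if (ncol(tab) < 2L)
    stop("beta matrix needs a probe column plus at least one sample",
         call. = FALSE)

  probes <- as.character(tab[[1L]])
  dup <- probes[duplicated(probes)]
  if (length(dup))
    stop("duplicate probe row: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  samples <- colnames(tab)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample column: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)

  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
  }
  rownames(vals) <- probes
  colnames(vals) <- samples
  validate_beta_matrix(vals)
  vals
}

#' Validate a beta matrix
#'
#' Checks dimension names are unique and every non-missing value lies in
#' `[0, 1]`; out-of-range values are reported with their probe and sample
#' coordinates.
#'
#' @param betas numeric matrix, probes x samples.
#' @return `betas`, invisibly.
#' @export
validate_beta_matrix <- function(betas) {
  stopifnot(is.matrix(betas))
  if (is.null(rownames(betas)) || is.null(colnames(betas)))
    stop("beta matrix must carry probe rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(betas)))
    stop("duplicate probe row: ",
         rownames(betas)[duplicated(rownames(betas))][1L], call. = FALSE)
  if (anyDuplicated(colnames(betas)))
    stop("duplicate sample column: ",
         colnames(betas)[duplicated(colnames(betas))][1L], call. = FALSE)
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1 | is.nan(betas)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta value out of [0,1] at probe %s, sample %s (%g)",
                 rownames(betas)[bad[1L, 1L]], colnames(betas)[bad[1L, 2L]],
                 betas[bad[1L, , drop = FALSE]]),
         call. = FALSE)
  invisible(betas)
}

#' Write a beta matrix in the plain tab-separated dialect
#'
#' Values are written at full precision so that a write/read round trip
#' reproduces the matrix bit-exactly; missing cells are written as `"NA"`.
#'
#' @param betas numeric probes x samples matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(betas, path) {
  validate_beta_matrix(betas)
  chr <- apply(betas, 2L, num_repr)
  if (is.null(dim(chr))) chr <- matrix(chr, nrow = nrow(betas))
  out <- cbind(probe_id = rownames(betas), as.data.frame(chr))
  colnames(out) <- c("probe_id", colnames(betas))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with a header; must contain `sample_id`. Recognised optional
#' columns: `group` (tumor/nontumor), `age` (years), `gender`, `race`,
#' `vital_status`, `purity` (fraction in `[0,1]`), `monocyte_pct`,
#' `lymphocyte_pct`, `neutrophil_pct` (percent in `[0,100]`), `stage`
#' (ordinal integer), `study`. Unknown columns are preserved and ignored.
#'
#' @param path path to the TSV file.
#' @return A data frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path))
    stop("sample sheet does not exist: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = c("NA", ""), check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab))
    stop("sample sheet lacks a sample_id column", call. = FALSE)
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         tab$sample_id[duplicated(tab$sample_id)][1L], call. = FALSE)
  for (col in c("age", "purity", "monocyte_pct", "lymphocyte_pct",
                "neutrophil_pct", "stage")) {
    if (col %in% names(tab)) tab[[col]] <- as.numeric(tab[[col]])
  }
  if ("purity" %in% names(tab)) {
    bad <- which(!is.na(tab$purity) & (tab$purity < 0 | tab$purity > 1))
    if (length(bad))
      stop("purity outside [0,1] for sample ", tab$sample_id[bad[1L]],
           call. = FALSE)
  }
  for (col in c("monocyte_pct", "lymphocyte_pct", "neutrophil_pct")) {
    if (col %in% names(tab)) {
      bad <- which(!is.na(tab[[col]]) & (tab[[col]] < 0 | tab[[col]] > 100))
      if (length(bad))
        stop(col, " outside [0,100] for sample ", tab$sample_id[bad[1L]],
             call. = FALSE)
    }
  }
  tab
}

#' Align a beta matrix to a reference library
#'
#' Restricts and reorders the matrix to the library's probes. Library probes
#' absent from the input are kept as all-missing rows so the quality-control
#' denominator stays at the library size (mirroring the "25 of 27" accounting
#' used when two panel probes are absent from a platform export). Probe IDs
#' are matched exactly and case-sensitively.
#'
#' @param betas numeric probes x samples matrix.
#' @param lib an `fco_library`.
#' @return A matrix with `nrow(lib)` rows in library order. The number of
#'   library probes found is reported via [message()] and stored in the
#'   `"probes_found"` attribute.
#' @export
align_to_library <- function(betas, lib) {
  validate_beta_matrix(betas)
  stopifnot(inherits(lib, "fco_library"))
  idx <- match(lib$probe_id, rownames(betas))
  found <- sum(!is.na(idx))
  if (found == 0L)
    stop("no overlap with library: none of the ", nrow(lib),
         " library probes are present", call. = FALSE)
  out <- matrix(NA_real_, nrow = nrow(lib), ncol = ncol(betas),
                dimnames = list(lib$probe_id, colnames(betas)))
  out[!is.na(idx), ] <- betas[idx[!is.na(idx)], , drop = FALSE]
  message(sprintf("aligned to library: %d of %d library probes found",
                  found, nrow(lib)))
  attr(out, "probes_found") <- found
  out
}

#' Filter samples by present-probe count
#'
#' Retains samples with at least `min_present` non-missing library probes
#' (default 25 of the canonical 27), the quality-control rule applied before
#' FCO estimation.
#'
#' @param betas matrix aligned to a library (see [align_to_library()]).
#' @param min_present minimum number of non-missing library probes.
#' @return A list with `betas` (retained samples, values untouched) and
#'   `excluded`, a data frame of removed samples with their present-probe
#'   counts.
#' @export
qc_filter_samples <- function(betas, min_present = 25L) {
  validate_beta_matrix(betas)
  min_present <- as.integer(min_present)
  if (min_present > nrow(betas))
    stop("min_present (", min_present, ") exceeds library size (",
         nrow(betas), ")", call. = FALSE)
  present <- colSums(!is.na(betas))
  keep <- present >= min_present
  excluded <- data.frame(sample_id = colnames(betas)[!keep],
                         probes_present = unname(present[!keep]),
                         stringsAsFactors = FALSE)
  list(betas = betas[, keep, drop = FALSE], excluded = excluded,
       min_present = min_present)
}
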