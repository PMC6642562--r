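#' Construct a fetal/adult reference library
#'
#' An FCO (fetal cell origin) reference library holds, for a panel of
#' ontogeny-informative CpG probes, the mean methylation beta value observed
#' in fetal tissue and in adult tissue. The canonical panel has 27 probes,
#' but any size >= 2 is accepted.
#'
#' @param probe_id character vector of CpG identifiers (e.g. `"cg10338787"`).
#' @param fetal_beta numeric vector of fetal mean betas in `[0, 1]`.
#' @param adult_beta numeric vector of adult mean betas in `[0, 1]`.
#' @param gene optional character vector of gene annotations (`NA` allowed).
#' @return A data frame of class `"fco_library"` with columns `probe_id`,
#'   `fetal_beta`, `adult_beta`, `gene`, in the given row order.
#' @examples
#' lib <- fco_library(c("cgS1", "cgS2"), c(0.9, 0.1), c(0.1, 0.8))
#' @export
fco_library <- function(probe_id, fetal_beta, adult_beta,
                        gene = NA_character_) {
  probe_id <- as.character(probe_id)
  fetal_beta <- as.numeric(fetal_beta)
  adult_beta <- as.numeric(adult_beta)
  n <- length(probe_id)
  if (n < 2L)
    stop("reference library must have at least 2 probes", call. = FALSE)
  if (length(fetal_beta) != n || length(adult_beta) != n)
    stop("probe_id, fetal_beta and adult_beta must have equal length",
         call. = FALSE)
  gene <- rep_len(as.character(gene), n)

  dup <- probe_id[duplicated(probe_id)]
  if (length(dup))
    stop("duplicate probe in reference library: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(fetal_beta) | !is.finite(adult_beta) |
                 fetal_beta < 0 | fetal_beta > 1 |
                 adult_beta < 0 | adult_beta > 1)
  if (length(bad))
    stop("reference beta outside [0,1] at row ", bad[1L], call. = FALSE)
  if (all(fetal_beta == adult_beta))
    stop("degenerate library: fetal and adult profiles are identical",
         call. = FALSE)

  structure(
    data.frame(probe_id = probe_id, fetal_beta = fetal_beta,
               adult_beta = adult_beta, gene = gene,
               stringsAsFactors = FALSE),
    class = c("fco_library", "data.frame")
  )
}

#' Read a reference library from a tab-separated file
#'
#' Expects a header line naming `probe_id`, `fetal_beta`, `adult_beta` and
#' optionally `gene`. Row order is preserved; validation is as in
#' [fco_library()].
#'
#' @param path path to the TSV file.
#' @return An `fco_library` object.
#' @export
read_fco_library <- function(path) {
  if (!file.exists(path))
    stop("library file does not exist: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe_id", "fetal_beta", "adult_beta")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("library header lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  gene <- if ("gene" %in% names(tab)) tab$gene else NA_character_
  fco_library(tab$probe_id, tab$fetal_beta, tab$adult_beta, gene)
}

#' Write a reference library to a tab-separated file
#'
#' @param lib an `fco_library` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fco_library <- function(lib, path) {
  stopifnot(inherits(lib, "fco_library"))
  out <- data.frame(
    probe_id = lib$probe_id,
    fetal_beta = num_repr(lib$fetal_beta),
    adult_beta = num_repr(lib$adult_beta),
    gene = ifelse(is.na(lib$gene), "NA", lib$gene),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.fco_library <- function(x, ...) {
  cat(sprintf("FCO reference library: %d probes, mean |fetal - adult| = %.3f\n",
              nrow(x), mean(abs(x$fetal_beta - x$adult_beta))))
  NextMethod()
}

# full-precision decimal rendering so write/read round-trips bit-exactly
num_repr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}
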