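#' Fit the FCO mixture model to a cohort
#'
#' The main fitting function: aligns a beta matrix to a fetal/adult reference
#' library, applies the present-probe quality-control rule (default: at least
#' 25 of the 27 library CpGs non-missing), and estimates each retained
#' sample's fetal-origin fraction by constrained least-squares projection
#' (see [project_sample()]).
#'
#' @param betas numeric probes x samples beta matrix (any probe superset of
#'   the library; rownames are probe IDs).
#' @param library an `fco_library`, or a path read via [read_fco_library()].
#' @param min_present minimum non-missing library probes per sample
#'   (default 25).
#' @return An object of class `"fco_fit"`: a list with `estimates` (the
#'   [estimate_fco()] data frame), `library`, `betas` (aligned, retained
#'   samples), `qc` (excluded-sample table and threshold), `probes_found`,
#'   and `call`.
#' @seealso [estimate_fco()], [predict.fco_fit()], [fco_compare()]
#' @examples
#' lib <- fco_library(paste0("cgS", 1:5),
#'                    c(0.9, 0.85, 0.1, 0.15, 0.8),
#'                    c(0.1, 0.2, 0.9, 0.8, 0.25))
#' truth <- c(0, 0.5, 1)
#' betas <- sapply(truth, function(f)
#'   f * lib$fetal_beta + (1 - f) * lib$adult_beta)
#' dimnames(betas) <- list(lib$probe_id, paste0("S", 1:3))
#' fit <- fco_fit(betas, lib, min_present = 2)
#' coef(fit)
#' @export
fco_fit <- function(betas, library, min_present = 25L) {
  if (is.character(library)) library <- read_fco_library(library)
  stopifnot(inherits(library, "fco_library"))
  aligned <- align_to_library(betas, library)
  probes_found <- attr(aligned, "probes_found")
  qc <- qc_filter_samples(aligned, min_present = min_present)
  est <- estimate_fco(qc$betas, library)
  structure(
    list(estimates = est,
         library = library,
         betas = qc$betas,
         qc = list(excluded = qc$excluded, min_present = qc$min_present),
         probes_found = probes_found,
         call = match.call()),
    class = "fco_fit"
  )
}

#' @export
print.fco_fit <- function(x, ...) {
  cat("FCO mixture fit\n")
  cat(sprintf("  library: %d probes (%d found in data)\n",
              nrow(x$library), x$probes_found))
  cat(sprintf("  samples: %d retained, %d excluded by QC (min %d probes)\n",
              nrow(x$estimates), nrow(x$qc$excluded), x$qc$min_present))
  cat(sprintf("  FCO (%%): mean %.1f, median %.1f, range [%.1f, %.1f]\n",
              mean(x$estimates$fco) * 100, stats::median(x$estimates$fco) * 100,
              min(x$estimates$fco) * 100, max(x$estimates$fco) * 100))
  invisible(x)
}

#' Summarise an FCO fit
#'
#' @param object an `fco_fit`.
#' @param group optional vector of group labels (e.g. tumor/nontumor), in
#'   sample order or named by sample ID, for per-group summaries.
#' @param ... unused.
#' @return A list of class `"summary.fco_fit"`.
#' @export
summary.fco_fit <- function(object, group = NULL, ...) {
  est <- object$estimates
  if (!is.null(group)) {
    if (!is.null(names(group))) group <- group[est$sample_id]
    stopifnot(length(group) == nrow(est))
  }
  qtab <- function(v) {
    c(stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7), mean = mean(v))
  }
  per_group <- if (is.null(group)) NULL else {
    t(sapply(split(est$fco, group), qtab))
  }
  structure(list(n = nrow(est), excluded = nrow(object$qc$excluded),
                 overall = qtab(est$fco), per_group = per_group,
                 mean_rss = mean(est$rss),
                 probes_used = range(est$probes_used)),
            class = "summary.fco_fit")
}

#' @export
print.summary.fco_fit <- function(x, ...) {
  cat(sprintf("FCO fit: %d samples (%d excluded), probes used %d-%d, mean rss %.2e\n",
              x$n, x$excluded, x$probes_used[1L], x$probes_used[2L],
              x$mean_rss))
  cat("FCO fraction quantiles:\n")
  print(round(x$overall, 4))
  if (!is.null(x$per_group)) {
    cat("by group:\n")
    print(round(x$per_group, 4))
  }
  invisible(x)
}

#' Extract FCO fractions from a fit
#'
#' @param object an `fco_fit`.
#' @param ... unused.
#' @return Named numeric vector of fetal-origin fractions (names are sample
#'   IDs).
#' @export
coef.fco_fit <- function(object, ...) {
  stats::setNames(object$estimates$fco, object$estimates$sample_id)
}

#' @export
fitted.fco_fit <- function(object, ...) {
  lib <- object$library
  w <- rbind(object$estimates$fco, object$estimates$adult)
  out <- cbind(lib$fetal_beta, lib$adult_beta) %*% w
  dimnames(out) <- dimnames(object$betas)
  out
}

#' Residuals of the mixture fit
#'
#' Observed minus reconstructed betas per probe and sample (`NA` where the
#' observed beta was missing).
#'
#' @param object an `fco_fit`.
#' @param ... unused.
#' @return A probes x samples matrix.
#' @export
residuals.fco_fit <- function(object, ...) {
  object$betas - fitted(object)
}

#' Estimate FCO for new samples using a fitted model's library and QC rule
#'
#' @param object an `fco_fit`.
#' @param newdata probes x samples beta matrix.
#' @param min_present QC threshold; defaults to the fitted one.
#' @param ... unused.
#' @return An [estimate_fco()] data frame for the retained new samples, with
#'   the excluded-sample table attached as attribute `"excluded"`.
#' @export
predict.fco_fit <- function(object, newdata,
                            min_present = object$qc$min_present, ...) {
  aligned <- align_to_library(newdata, object$library)
  qc <- qc_filter_samples(aligned, min_present = min_present)
  out <- estimate_fco(qc$betas, object$library)
  attr(out, "excluded") <- qc$excluded
  out
}

#' Plot the distribution of estimated FCO
#'
#' Kernel density of FCO percent, optionally split by group (the display the
#' tumor-versus-normal comparisons summarise).
#'
#' @param x an `fco_fit`.
#' @param group optional group labels as in [summary.fco_fit()].
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.fco_fit <- function(x, group = NULL, ...) {
  pct <- x$estimates$fco * 100
  if (is.null(group)) {
    if (stats::sd(pct) == 0) {
      graphics::hist(pct, main = "Predicted FCO (%)", xlab = "FCO (%)")
    } else {
      plot(stats::density(pct, from = 0, to = 100),
           main = "Predicted FCO (%)", xlab = "FCO (%)", ...)
    }
  } else {
    if (!is.null(names(group))) group <- group[x$estimates$sample_id]
    groups <- sort(unique(as.character(group)))
    dens <- lapply(groups, function(g) {
      v <- pct[group == g]
      if (length(v) > 1 && stats::sd(v) > 0)
        stats::density(v, from = 0, to = 100) else NULL
    })
    ok <- !vapply(dens, is.null, logical(1))
    if (!any(ok)) {
      graphics::hist(pct, main = "Predicted FCO (%)", xlab = "FCO (%)")
    } else {
      ymax <- max(unlist(lapply(dens[ok], function(d) max(d$y))))
      plot(NA, xlim = c(0, 100), ylim = c(0, ymax), xlab = "FCO (%)",
           ylab = "Density", main = "Predicted FCO (%) by group", ...)
      for (i in seq_along(groups)) {
        if (ok[i]) graphics::lines(dens[[i]], col = i, lty = i)
      }
      graphics::legend("topright", legend = groups,
                       col = seq_along(groups), lty = seq_along(groups))
    }
  }
  invisible(x)
}

#' Simulate beta matrices from a fitted mixture
#'
#' Draws new probes x samples beta matrices around the fitted mixture means
#' using logit-normal per-probe noise, the same observation model as
#' [simulate_cohort()].
#'
#' @param object an `fco_fit`.
#' @param nsim number of matrices.
#' @param seed integer seed.
#' @param noise_sd logit-scale noise standard deviation.
#' @param ... unused.
#' @return A list of `nsim` matrices.
#' @export
simulate.fco_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = 0.05, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  lapply(seq_len(nsim), function(i) {
    out <- matrix(add_logit_noise(mu, noise_sd), nrow = nrow(mu),
                  dimnames = dimnames(mu))
    out
  })
}
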