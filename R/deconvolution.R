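#' Project one sample onto the fetal/adult reference profiles
#'
#' Solves the constrained least-squares problem at the heart of FCO
#' estimation: over the sample's non-missing library probes j, minimise
#' \deqn{\sum_j (y_j - w_F f_j - w_A a_j)^2}
#' subject to \eqn{w_F \ge 0}, \eqn{w_A \ge 0}, \eqn{w_F + w_A \le 1},
#' where f and a are the fetal and adult reference betas. The feasible
#' region is a triangle, so the quadratic programme is solved exactly by
#' Karush-Kuhn-Tucker case enumeration: the unconstrained 2x2 normal-equation
#' solution if feasible, otherwise the best of the three edge projections and
#' vertices. Deterministic; no iterative solver.
#'
#' The sum-to-at-most-one constraint (rather than equal-one) lets samples
#' contain cell states matching neither reference profile; the remainder
#' `1 - w_F - w_A` is implicit.
#'
#' @param y numeric beta vector over the library probes (library order);
#'   `NA` entries are dropped (pairwise deletion, no imputation).
#' @param lib an `fco_library`.
#' @return A list with `fco_fraction` (\eqn{w_F}), `adult_fraction`
#'   (\eqn{w_A}), `probes_used`, and `rss` (objective value). Fractions are
#'   clipped to `[0, 1]` after the feasibility check.
#' @examples
#' lib <- fco_library(paste0("cgS", 1:4),
#'                    c(0.9, 0.8, 0.1, 0.2), c(0.1, 0.2, 0.9, 0.7))
#' y <- 0.6 * lib$fetal_beta + 0.4 * lib$adult_beta
#' project_sample(y, lib)$fco_fraction  # 0.6
#' @export
project_sample <- function(y, lib) {
  stopifnot(inherits(lib, "fco_library"))
  y <- as.numeric(y)
  if (length(y) != nrow(lib))
    stop("beta vector length (", length(y), ") does not match library size (",
         nrow(lib), ")", call. = FALSE)
  use <- !is.na(y)
  if (sum(use) < 2L)
    stop("fewer than 2 usable probes", call. = FALSE)
  f <- lib$fetal_beta[use]
  a <- lib$adult_beta[use]
  yy <- y[use]
  if (all(f == a))
    stop("unidentifiable mixture: fetal and adult profiles identical on ",
         "all usable probes", call. = FALSE)

  g11 <- sum(f * f); g22 <- sum(a * a); g12 <- sum(f * a)
  b1 <- sum(f * yy); b2 <- sum(a * yy)
  yty <- sum(yy * yy)
  dfa <- g11 - 2 * g12 + g22            # ||f - a||^2 > 0 here

  rss_at <- function(wf, wa) {
    r <- yty - 2 * (wf * b1 + wa * b2) +
      wf * wf * g11 + 2 * wf * wa * g12 + wa * wa * g22
    max(r, 0)
  }
  clamp01 <- function(v) min(max(v, 0), 1)

  cand <- list()
  det <- g11 * g22 - g12 * g12
  if (det > 1e-12 * max(g11 * g22, 1e-300)) {
    wf <- (b1 * g22 - b2 * g12) / det
    wa <- (b2 * g11 - b1 * g12) / det
    if (wf >= -1e-10 && wa >= -1e-10 && wf + wa <= 1 + 1e-10)
      cand[[length(cand) + 1L]] <- c(wf, wa)
  }
  # edge w_A = 0 (and vertex fallbacks when a 1-D curvature vanishes)
  cand[[length(cand) + 1L]] <-
    c(if (g11 > 0) clamp01(b1 / g11) else 0, 0)
  # edge w_F = 0
  cand[[length(cand) + 1L]] <-
    c(0, if (g22 > 0) clamp01(b2 / g22) else 0)
  # edge w_F + w_A = 1
  wf_e <- clamp01((b1 - b2 + g22 - g12) / dfa)
  cand[[length(cand) + 1L]] <- c(wf_e, 1 - wf_e)
  # vertices
  cand[[length(cand) + 1L]] <- c(0, 0)
  cand[[length(cand) + 1L]] <- c(1, 0)
  cand[[length(cand) + 1L]] <- c(0, 1)

  rss <- vapply(cand, function(w) rss_at(w[1L], w[2L]), numeric(1))
  best <- cand[[which.min(rss)]]
  wf <- clamp01(best[1L]); wa <- clamp01(best[2L])
  if (wf + wa > 1) {                     # numeric guard, at most ~1e-16 over
    s <- wf + wa
    wf <- wf / s; wa <- wa / s
  }
  list(fco_fraction = wf, adult_fraction = wa,
       probes_used = sum(use), rss = rss_at(wf, wa))
}

#' Estimate FCO fractions for every sample of a beta matrix
#'
#' Applies [project_sample()] column-wise; each sample's missing probes are
#' dropped before projection, so `probes_used` varies by sample. Errors from
#' individual samples are re-raised with the sample identifier attached.
#'
#' @param betas matrix aligned to `lib` (see [align_to_library()]), one
#'   column per sample. Samples are expected to have passed
#'   [qc_filter_samples()].
#' @param lib an `fco_library`.
#' @return A data frame with one row per sample, in input order: `sample_id`,
#'   `fco` and `adult` (fractions), `fco_pct` (percent, the external
#'   reporting unit), `probes_used`, `rss`.
#' @export
estimate_fco <- function(betas, lib) {
  validate_beta_matrix(betas)
  stopifnot(inherits(lib, "fco_library"))
  if (!identical(rownames(betas), lib$probe_id))
    stop("beta matrix is not aligned to the library; ",
         "call align_to_library() first", call. = FALSE)
  res <- lapply(seq_len(ncol(betas)), function(i) {
    tryCatch(project_sample(betas[, i], lib),
             error = function(e) {
               stop("sample ", colnames(betas)[i], ": ", conditionMessage(e),
                    call. = FALSE)
             })
  })
  data.frame(
    sample_id = colnames(betas),
    fco = vapply(res, `[[`, numeric(1), "fco_fraction"),
    adult = vapply(res, `[[`, numeric(1), "adult_fraction"),
    fco_pct = round(100 * vapply(res, `[[`, numeric(1), "fco_fraction"), 1L),
    probes_used = vapply(res, `[[`, numeric(1), "probes_used"),
    rss = vapply(res, `[[`, numeric(1), "rss"),
    stringsAsFactors = FALSE
  )
}

#' Exhaustive grid-search oracle for the constrained projection
#'
#' Brute-force reference for [project_sample()]: evaluates the residual sum
#' of squares at every feasible grid point
#' \eqn{(w_F, w_A) \in \{0, s, 2s, \dots, 1\}^2}, \eqn{w_F + w_A \le 1},
#' and returns the minimiser. Ties are broken toward smaller \eqn{w_F}, then
#' smaller \eqn{w_A}. Intended for testing; cost grows as \eqn{1/s^2}.
#'
#' @param y numeric beta vector over library probes (`NA` dropped).
#' @param lib an `fco_library`.
#' @param step grid resolution in `(0, 0.5]`.
#' @return A list with `fco_fraction`, `adult_fraction`, `rss`.
#' @export
fco_grid_search <- function(y, lib, step = 1e-3) {
  stopifnot(inherits(lib, "fco_library"))
  if (!is.numeric(step) || length(step) != 1L || step <= 0 || step > 0.5)
    stop("step must lie in (0, 0.5]", call. = FALSE)
  y <- as.numeric(y)
  use <- !is.na(y)
  if (sum(use) < 2L)
    stop("fewer than 2 usable probes", call. = FALSE)
  f <- lib$fetal_beta[use]
  a <- lib$adult_beta[use]
  yy <- y[use]

  vals <- seq(0, 1, by = step)
  if (vals[length(vals)] < 1 - 1e-12) vals <- c(vals, 1)
  # w_F varies slowest so the first minimum has smallest w_F, then w_A
  grid <- cbind(wf = rep(vals, each = length(vals)),
                wa = rep(vals, times = length(vals)))
  grid <- grid[grid[, 1L] + grid[, 2L] <= 1 + 1e-9, , drop = FALSE]
  resid <- grid %*% rbind(f, a)
  resid <- sweep(resid, 2L, yy)
  rss <- rowSums(resid * resid)
  i <- which.min(rss)
  list(fco_fraction = unname(grid[i, 1L]),
       adult_fraction = unname(grid[i, 2L]),
       rss = rss[i])
}

#' Leave-k-probes-out stability of an FCO estimate
#'
#' Re-estimates the fetal fraction with every combination of `1..max_drop`
#' library probes removed (leave-one-out, leave-two-out, ... up to five by
#' default) and summarises, per k, the deviation from the full-library
#' estimate. When the number of k-subsets exceeds `cap`, a seeded random
#' sample of `cap` subsets is used instead (choose(27, 5) = 80,730 makes
#' exhaustion expensive at the canonical library size).
#'
#' @param y numeric beta vector over library probes.
#' @param lib an `fco_library`.
#' @param max_drop largest number of probes removed (at most
#'   `nrow(lib) - 2`).
#' @param cap exhaustive enumeration threshold on `choose(L, k)`.
#' @param seed integer seed for the subsampled regime.
#' @return A data frame with columns `k`, `n_subsets`, `exhaustive`,
#'   `max_abs_dev`, `mean_abs_dev`; deviations are in fetal-fraction units
#'   relative to the full-library estimate.
#' @export
probe_dropout_stability <- function(y, lib, max_drop = 5L, cap = 10000L,
                                    seed = 1L) {
  stopifnot(inherits(lib, "fco_library"))
  L <- nrow(lib)
  max_drop <- as.integer(max_drop)
  if (max_drop >= L - 1L)
    stop("max_drop must leave at least 2 probes (library size ", L, ")",
         call. = FALSE)
  full <- project_sample(y, lib)$fco_fraction

  one_subset <- function(drop_idx) {
    y2 <- y
    y2[drop_idx] <- NA_real_
    est <- tryCatch(project_sample(y2, lib)$fco_fraction,
                    error = function(e) NA_real_)
    abs(est - full)
  }

  rows <- lapply(seq_len(max_drop), function(k) {
    n_comb <- choose(L, k)
    if (n_comb <= cap) {
      subsets <- utils::combn(L, k, simplify = FALSE)
      exhaustive <- TRUE
    } else {
      set.seed(derive_seed(seed, k))
      subsets <- replicate(cap, sort(sample.int(L, k)), simplify = FALSE)
      exhaustive <- FALSE
    }
    dev <- vapply(subsets, one_subset, numeric(1))
    dev <- dev[!is.na(dev)]
    data.frame(k = k, n_subsets = length(subsets), exhaustive = exhaustive,
               max_abs_dev = max(dev), mean_abs_dev = mean(dev))
  })
  do.call(rbind, rows)
}

# one global seed drives derived per-component streams; kept < 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003) * 2017 + 7919 * k) %% 2147483647L
}
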