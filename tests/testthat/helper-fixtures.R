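# Shared in-code fixtures for the test suite.

# small hand-written library with well-separated, linearly independent profiles
toy_library <- function() {
  fco_library(
    probe_id = paste0("cgT", 1:5),
    fetal_beta = c(0.90, 0.85, 0.10, 0.15, 0.80),
    adult_beta = c(0.10, 0.20, 0.90, 0.80, 0.25)
  )
}

# beta matrix whose samples are exact mixtures at the given true fractions
mixture_matrix <- function(lib, fractions, ids = NULL) {
  m <- sapply(fractions, function(f)
    f * lib$fetal_beta + (1 - f) * lib$adult_beta)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(fractions))
  dimnames(m) <- list(lib$probe_id, ids)
  m
}

# independent enumeration oracle for the two-sided rank-sum p
ranksum_enum_p <- function(x, y) {
  m <- length(x)
  all_v <- c(x, y)
  n <- length(all_v)
  W_obs <- sum(rank(all_v)[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(n, m)
  W_null <- apply(combos, 2, function(idx)
    sum(rank(all_v)[idx]) - m * (m + 1) / 2)
  mu <- m * (n - m) / 2
  mean(abs(W_null - mu) >= abs(W_obs - mu))
}

# independent exact permutation p for the adjusted-model group t-statistic,
# via full refits with lm (no FWL shortcut)
perm_enum_p_lm <- function(fco, group, data = NULL, covariates = NULL) {
  lev <- sort(unique(group))
  t_of <- function(g) {
    adjusted_linear_model(fco, g, data = data, covariates = covariates)$t
  }
  t_obs <- t_of(group)
  idx1 <- utils::combn(length(group), sum(group == lev[2]))
  tstar <- apply(idx1, 2, function(ix) {
    g <- rep(lev[1], length(group))
    g[ix] <- lev[2]
    t_of(g)
  })
  mean(abs(tstar) >= abs(t_obs) - 1e-12)
}

quiet_align <- function(...) suppressMessages(align_to_library(...))
quiet_fit <- function(...) suppressMessages(fco_fit(...))
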