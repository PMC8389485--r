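#' Chao1 species-richness estimator
#'
#' Nonparametric lower-bound estimate of total richness from singleton and
#' doubleton counts. Classic form: `S_obs + F1^2 / (2 * F2)`; bias-
#' corrected form: `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))`. The default
#' (`bias_corrected = NA`) applies the classic form unless `F2 = 0`, where
#' it is undefined and the bias-corrected form is substituted.
#'
#' @param counts non-negative integer abundance vector (one entry per
#'   species; zeros allowed and ignored).
#' @param bias_corrected `TRUE`, `FALSE`, or `NA` for the automatic rule.
#' @return list with `estimate`, `s_obs`, `f1`, `f2`, `variant`.
#' @export
chao1 <- function(counts, bias_corrected = NA) {
  counts <- check_abundances(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  use_bc <- if (is.na(bias_corrected)) f2 == 0 else isTRUE(bias_corrected)
  est <- if (use_bc) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + f1^2 / (2 * f2)
  }
  list(estimate = est, s_obs = s_obs, f1 = f1, f2 = f2,
       variant = if (use_bc) "bias_corrected" else "classic")
}

#' Expected richness under individual-based rarefaction
#'
#' Expected number of species in a random subsample of `n` of the `N`
#' collected individuals, by the hypergeometric formulation
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`. Binomial
#' ratios are computed on the log scale, so the result is stable for
#' totals up to at least 1e5 individuals.
#'
#' @param counts non-negative integer abundance vector.
#' @param n subsample size, `0 <= n <= sum(counts)`.
#' @return expected species count (non-decreasing in `n`; equals observed
#'   richness at `n = N` and 0 at `n = 0`).
#' @export
rarefied_richness <- function(counts, n) {
  counts <- check_abundances(counts)
  N <- sum(counts)
  if (n < 0 || n > N) {
    stop("subsample size must lie in [0, total individuals]",
         call. = FALSE)
  }
  if (n == 0) return(0)
  counts <- counts[counts > 0]
  # P(species i absent from the subsample) = C(N - N_i, n) / C(N, n)
  p_absent <- exp(lchoose(N - counts, n) - lchoose(N, n))
  p_absent[N - counts < n] <- 0
  sum(1 - p_absent)
}

check_abundances <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || anyNA(counts) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop("abundances must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("at least one positive abundance required", call. = FALSE)
  }
  counts
}
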