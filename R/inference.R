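#' Permutation one-way ANOVA
#'
#' Observed one-way ANOVA F statistic for k groups, with significance from
#' random reassignment of the pooled values to groups of the original
#' sizes. Intended for comparing groups of pairwise dissimilarities across
#' systems; note that pairwise values within a system are not independent
#' observations, so the p-value is descriptive rather than strictly
#' inferential.
#'
#' @param groups list of numeric vectors, one per group (each length >=
#'   2).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `statistic` (F), `p_value`
#'   (`(1 + #\{F_null >= F_obs\}) / (1 + n_perm)`), `n_perm`, `seed`,
#'   `group_labels`, `group_sizes`.
#' @export
perm_anova <- function(groups, n_perm = 9999, seed = 1) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least two groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs at least two values", call. = FALSE)
  }
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), sizes)
  f_obs <- anova_f(pooled, g, sizes)
  count <- 0L
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      f_null <- anova_f(pooled[sample.int(length(pooled))], g, sizes)
      if (f_null >= f_obs - 1e-12) count <- count + 1L
    }
  })
  list(statistic = f_obs, p_value = (1 + count) / (1 + n_perm),
       n_perm = as.integer(n_perm), seed = as.integer(seed),
       group_labels = labels, group_sizes = as.integer(sizes))
}

anova_f <- function(x, g, sizes) {
  k <- length(sizes)
  N <- length(x)
  gm <- vapply(split(x, g), mean, numeric(1))
  ssb <- sum(sizes * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / (k - 1)) / (ssw / (N - k))
}

#' Permutation two-sample t-test
#'
#' Observed pooled-variance two-sample t statistic with a two-sided
#' label-permutation p-value. Degenerate input (zero variance in both
#' samples and equal means) returns statistic 0 and p = 1 by convention.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `statistic` (t), `p_value`, `n_perm`, `seed`,
#'   `group_labels`, `group_sizes`.
#' @export
perm_t_test <- function(x, y, n_perm = 9999, seed = 1) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least two values", call. = FALSE)
  }
  pooled <- c(x, y)
  n1 <- length(x)
  t_obs <- pooled_t(pooled, n1)
  if (is.na(t_obs)) {           # zero variance everywhere, equal means
    return(list(statistic = 0, p_value = 1,
                n_perm = as.integer(n_perm), seed = as.integer(seed),
                group_labels = c("x", "y"),
                group_sizes = c(n1, length(y))))
  }
  count <- 0L
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      t_null <- pooled_t(pooled[sample.int(length(pooled))], n1)
      if (is.na(t_null) || abs(t_null) >= abs(t_obs) - 1e-12) {
        count <- count + 1L
      }
    }
  })
  list(statistic = t_obs, p_value = (1 + count) / (1 + n_perm),
       n_perm = as.integer(n_perm), seed = as.integer(seed),
       group_labels = c("x", "y"), group_sizes = c(n1, length(y)))
}

pooled_t <- function(pooled, n1) {
  N <- length(pooled)
  x <- pooled[seq_len(n1)]
  y <- pooled[seq.int(n1 + 1L, N)]
  sp2 <- ((n1 - 1) * stats::var(x) + (N - n1 - 1) * stats::var(y)) /
    (N - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / (N - n1)))
  diff <- mean(x) - mean(y)
  if (se == 0) {
    if (diff == 0) return(NA_real_)
    return(sign(diff) * Inf)
  }
  diff / se
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall rank correlation with a two-sided p-value:
#' exact enumeration for small tie-free samples, otherwise the normal
#' approximation (via [stats::cor.test()]). Used to screen environmental
#' variables against site-level diversity.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `tau`, `p_value`, `method`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need two equal-length vectors of at least 3 values",
         call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("tau undefined for a constant vector", call. = FALSE)
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(tau = unname(ht$estimate), p_value = ht$p.value,
       method = ht$method)
}
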