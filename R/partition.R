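#' Pairwise pattern components and beta-diversity partition for one pair
#'
#' For two species sets with `a` shared species, `b` unique to the first
#' and `c` unique to the second (`n = a + b + c`), the Jaccard-family
#' pairwise pattern components are
#' overlap `O = a/n`, replacement `R = 2*min(b,c)/n` and richness
#' difference `D = |b - c|/n`, which sum to 1. Beta diversity is
#' `beta = 1 - O = R + D`; relativized nestedness is `N = O + D` when the
#' pair shares at least one species and 0 otherwise. Nestedness intersects
#' beta diversity in `I = D` (when `a > 0`, else `I = 0`) with relative
#' complement `RC = beta - I`, and `beta_ratio = I/beta` (undefined for
#' identical sites) locates the dominant component: values below 0.5 mean
#' replacement-dominated beta diversity, above 0.5 richness-difference-
#' dominated.
#'
#' @param x,y species sets: character vectors of species labels, or
#'   logical/0-1 vectors over a common species pool.
#' @param site_i,site_j labels used in the output row.
#' @return one-row data.frame with columns `site_i`, `site_j`, `a`, `b`,
#'   `c`, `o_j`, `r_j`, `d_j`, `beta_j`, `n_j`, `i_j`, `rc_j`,
#'   `beta_ratio`.
#' @examples
#' decompose_pair(c("s1", "s2", "s3", "s4", "s5"), c("s1", "s2", "s3", "s6"))
#' @export
decompose_pair <- function(x, y, site_i = "i", site_j = "j") {
  if (is.logical(x) || (is.numeric(x) && is.numeric(y))) {
    if (length(x) != length(y)) {
      stop("0/1 vectors must share one species pool", call. = FALSE)
    }
    x <- which(as.logical(x))
    y <- which(as.logical(y))
  }
  x <- unique(x)
  y <- unique(y)
  a <- length(intersect(x, y))
  b <- length(setdiff(x, y))
  c_ <- length(setdiff(y, x))
  decompose_counts(a, b, c_, site_i, site_j)
}

decompose_counts <- function(a, b, c_, site_i, site_j) {
  n <- a + b + c_
  if (any(n == 0)) {
    stop("pair with both species sets empty is undefined", call. = FALSE)
  }
  o <- a / n
  r <- 2 * pmin(b, c_) / n
  d <- abs(b - c_) / n
  beta <- (b + c_) / n
  nest <- ifelse(a > 0, (a + abs(b - c_)) / n, 0)
  i_j <- ifelse(a > 0, d, 0)
  rc <- beta - i_j
  ratio <- ifelse(beta > 0, i_j / beta, NA_real_)
  data.frame(site_i = site_i, site_j = site_j, a = a, b = b, c = c_,
             o_j = o, r_j = r, d_j = d, beta_j = beta, n_j = nest,
             i_j = i_j, rc_j = rc, beta_ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Decompose every site pair of an incidence matrix
#'
#' @param m an [incidence_matrix()] with at least two sites.
#' @return data.frame with one row per unordered site pair, ordered
#'   lexicographically by site index (1-2, 1-3, ..., 2-3, ...); columns as
#'   in [decompose_pair()].
#' @export
decompose_all <- function(m) {
  m <- as_incidence(m)
  n_sites <- nrow(m)
  if (n_sites < 2L) {
    stop("pairwise decomposition needs at least two sites", call. = FALSE)
  }
  occ <- unclass(m)
  shared <- tcrossprod(occ)
  alpha <- rowSums(occ)
  idx <- which(upper.tri(shared), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  i <- idx[, 1L]
  j <- idx[, 2L]
  a <- shared[idx]
  decompose_counts(a, alpha[i] - a, alpha[j] - a,
                   site_ids(m)[i], site_ids(m)[j])
}

#' Summary statistics of a pairwise decomposition
#'
#' Mean, median, min and max of each relativized component across pairs;
#' `beta_ratio` statistics use only the pairs where it is defined
#' (non-identical sites).
#'
#' @param pairs data.frame from [decompose_all()].
#' @param components which columns to summarize.
#' @return data.frame with one row per component.
#' @export
summarize_decomposition <- function(pairs,
                                    components = c("beta_j", "n_j", "i_j",
                                                   "rc_j", "beta_ratio")) {
  if (nrow(pairs) == 0L) stop("no pairs to summarize", call. = FALSE)
  rows <- lapply(components, function(cmp) {
    v <- pairs[[cmp]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {      # e.g. beta_ratio with all pairs identical
      return(data.frame(component = cmp, mean = NA_real_,
                        median = NA_real_, min = NA_real_,
                        max = NA_real_, n = 0L,
                        stringsAsFactors = FALSE))
    }
    data.frame(component = cmp, mean = mean(v), median = stats::median(v),
               min = min(v), max = max(v), n = length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Whittaker's multiplicative ("true") beta diversity
#'
#' `gamma / mean(alpha)`: regional richness over mean local richness.
#' Supply either an incidence matrix or the per-site alpha values and
#' gamma directly (the latter reproduces published richness tables without
#' the underlying matrix).
#'
#' @param m an [incidence_matrix()], or `NULL` when `alpha`/`gamma` given.
#' @param alpha numeric vector of per-site richness.
#' @param gamma regional species richness.
#' @return a single number, `>= 1` for any realizable community.
#' @export
whittaker_ratio <- function(m = NULL, alpha = NULL, gamma = NULL) {
  if (!is.null(m)) {
    m <- as_incidence(m)
    alpha <- rowSums(unclass(m))
    gamma <- sum(colSums(unclass(m)) > 0)
  }
  if (is.null(alpha) || is.null(gamma)) {
    stop("supply a matrix or alpha and gamma", call. = FALSE)
  }
  if (mean(alpha) <= 0) {
    stop("all sites empty: Whittaker ratio undefined", call. = FALSE)
  }
  gamma / mean(alpha)
}

#' Simplex (ternary) coordinates of pairwise pattern components
#'
#' Barycentric coordinates (O, R, D) per pair plus a 2-D projection onto
#' an equilateral triangle for plotting: richness difference D at the
#' lower-left vertex (0,0), overlap O at the lower-right vertex (1,0) and
#' replacement R at the apex (1/2, sqrt(3)/2).
#'
#' @param pairs data.frame from [decompose_all()].
#' @return data.frame with `site_i`, `site_j`, `o_j`, `r_j`, `d_j`, `x`,
#'   `y`.
#' @export
ternary_coordinates <- function(pairs) {
  data.frame(site_i = pairs$site_i, site_j = pairs$site_j,
             o_j = pairs$o_j, r_j = pairs$r_j, d_j = pairs$d_j,
             x = pairs$o_j + pairs$r_j / 2,
             y = pairs$r_j * sqrt(3) / 2,
             stringsAsFactors = FALSE)
}
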