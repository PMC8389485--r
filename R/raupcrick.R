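# Seed scoping helper: run code under a temporary RNG state so package
# functions are reproducible without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Draw one null incidence matrix under the fixed-richness,
#' frequency-weighted model
#'
#' Each site independently receives exactly its observed richness; species
#' are drawn without replacement with probability proportional to their
#' observed occupancy frequency (sequential weighted draws with
#' renormalization). Species occurring nowhere have zero weight and never
#' appear.
#'
#' @param m an [incidence_matrix()].
#' @param weights optional non-negative per-species sampling weights;
#'   defaults to the observed occupancy frequencies of `m`.
#' @param seed optional integer seed (omit when calling inside an outer
#'   randomization loop).
#' @return an [incidence_matrix()] with the same dimensions, labels and
#'   row sums as `m`.
#' @export
simulate_null_matrix <- function(m, weights = NULL, seed = NULL) {
  m <- as_incidence(m)
  occ <- unclass(m)
  if (is.null(weights)) weights <- colSums(occ)
  if (length(weights) != ncol(occ) || any(weights < 0)) {
    stop("weights must be non-negative, one per species", call. = FALSE)
  }
  alpha <- rowSums(occ)
  pool <- which(weights > 0)
  if (any(alpha > length(pool))) {
    stop("site richness exceeds the number of positive-weight species",
         call. = FALSE)
  }
  with_seed(seed, {
    null <- matrix(0L, nrow(occ), ncol(occ), dimnames = dimnames(occ))
    w <- weights[pool]
    for (s in seq_len(nrow(occ))) {
      if (alpha[s] > 0) {
        null[s, pool[sample.int(length(pool), alpha[s], prob = w)]] <- 1L
      }
    }
    incidence_matrix(null)
  })
}

#' Raup-Crick null-model dissimilarities
#'
#' For every site pair, compares the observed number of shared species
#' with its distribution over `n_sim` whole-matrix null replicates drawn
#' by [simulate_null_matrix()]. The probability-scale dissimilarity is
#' `rc_dissim = (#\{shared_null > shared_obs\} + 0.5 * #\{shared_null ==
#' shared_obs\}) / n_sim` (ties half-weighted), rescaled to
#' `beta_rc = 2 * rc_dissim - 1` on \[-1, 1\]. Pairs with `beta_rc <=
#' -ci_level` are classified significantly `similar` (they share more
#' species than random assemblages of the same richness essentially ever
#' produce), pairs with `beta_rc >= ci_level` significantly `dissimilar`,
#' the rest `ns`.
#'
#' @param m an [incidence_matrix()] with at least two sites.
#' @param n_sim number of null replicates (default 9999).
#' @param ci_level confidence level in (0, 1); significance is
#'   `|beta_rc| >= ci_level`.
#' @param seed integer seed; results are a pure function of
#'   `(m, n_sim, ci_level, seed)`.
#' @param weights optional species weights passed to
#'   [simulate_null_matrix()].
#' @return data.frame with one row per unordered pair: `site_i`,
#'   `site_j`, `observed_shared`, `rc_dissim`, `beta_rc`, `sig_class`,
#'   `n_sim`, `seed`.
#' @export
raup_crick <- function(m, n_sim = 9999, ci_level = 0.95, seed = 1,
                       weights = NULL) {
  m <- as_incidence(m)
  if (nrow(m) < 2L) stop("need at least two sites", call. = FALSE)
  if (!is.numeric(n_sim) || n_sim < 1) {
    stop("n_sim must be a positive count", call. = FALSE)
  }
  if (ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must lie in (0, 1)", call. = FALSE)
  }
  occ <- unclass(m)
  if (is.null(weights)) weights <- colSums(occ)
  obs <- tcrossprod(occ)
  ut <- upper.tri(obs)
  gt <- matrix(0, nrow(occ), nrow(occ))
  eq <- gt
  with_seed(seed, {
    for (rep in seq_len(n_sim)) {
      null <- unclass(simulate_null_matrix(m, weights = weights))
      s_null <- tcrossprod(null)
      gt <- gt + (s_null > obs)
      eq <- eq + (s_null == obs)
    }
  })
  idx <- which(ut, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  rc <- (gt[idx] + 0.5 * eq[idx]) / n_sim
  beta_rc <- 2 * rc - 1
  sig <- rep("ns", length(rc))
  sig[beta_rc <= -ci_level] <- "similar"
  sig[beta_rc >= ci_level] <- "dissimilar"
  data.frame(site_i = site_ids(m)[idx[, 1L]],
             site_j = site_ids(m)[idx[, 2L]],
             observed_shared = obs[idx],
             rc_dissim = rc, beta_rc = beta_rc, sig_class = sig,
             n_sim = as.integer(n_sim), seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

#' Percentage of significant Raup-Crick pairs
#'
#' @param results data.frame from [raup_crick()].
#' @return `100 * #\{sig_class != "ns"\} / #pairs`.
#' @export
percent_significant <- function(results) {
  if (nrow(results) == 0L) stop("empty result set", call. = FALSE)
  100 * mean(results$sig_class != "ns")
}
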